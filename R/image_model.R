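#' Calibrated en-face angiogram
#'
#' Wraps a square grayscale raster together with its physical calibration.
#' Intensities are stored rescaled to `[0, 1]`; the physical pixel pitch is
#' `extent_mm / width_px` (0.0140625 mm for the nominal 4.5 mm / 320 px
#' acquisition).
#'
#' Coordinate convention used throughout the package: pixel `(x, y)` uses
#' 0-based indices with `x` the column and `y` the row; the continuous-space
#' centre of pixel `(x, y)` is `(x + 0.5, y + 0.5)`.  All geometry (polygon
#' containment, disc crops, centroids) is evaluated at pixel centres.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param extent_mm physical side length of the imaged field in mm.
#' @return An object of class `enface_angiogram` with elements `pixels`,
#'   `width_px`, `height_px`, `extent_mm`, `pixel_pitch_mm`.
#' @export
enface_angiogram <- function(pixels, extent_mm = 4.5) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!isTRUE(extent_mm > 0)) stop("extent_mm must be positive")
  if (nrow(pixels) != ncol(pixels))
    stop("angiogram must be square: got ", nrow(pixels), " x ", ncol(pixels))
  pixels <- rescale01(pixels)
  structure(
    list(pixels = pixels,
         width_px = ncol(pixels), height_px = nrow(pixels),
         extent_mm = extent_mm,
         pixel_pitch_mm = extent_mm / ncol(pixels)),
    class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("En-face angiogram: %d x %d px, %.3g x %.3g mm (pitch %.6g mm/px)\n",
              x$width_px, x$height_px, x$extent_mm, x$extent_mm, x$pixel_pitch_mm))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Min-max rescale intensities to [0, 1]
#'
#' A constant (flat) image maps to all zeros rather than dividing by zero.
#' Rescaling is idempotent.
#'
#' @param m numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (!is.finite(lo) || !is.finite(hi)) stop("non-finite intensities")
  if (hi == lo) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Load an en-face angiogram from a PNG or TIFF file
#'
#' RGB input is collapsed to luminance with the Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B) and the result is min-max rescaled to
#' `[0, 1]`, so binarization downstream is reproducible bit-exactly.
#' Non-square rasters are rejected.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param extent_mm physical side length of the field (default 4.5 mm).
#' @return An [enface_angiogram()].
#' @export
load_enface_image <- function(path, extent_mm = 4.5) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  enface_angiogram(arr, extent_mm = extent_mm)
}

#' Rasterize a closed polygon outline to a binary mask
#'
#' Foreground pixels are those whose centres lie inside the closed polygon
#' (even-odd rule); a centre lying exactly on an edge counts as inside.
#' Vertices are continuous pixel coordinates `(x, y)` in the package's
#' 0-based convention; the last vertex implicitly joins the first.
#'
#' @param vertices two-column matrix (or data frame) of `(x, y)` vertices,
#'   at least 3 rows.
#' @param shape integer vector `c(height, width)` of the target raster.
#' @return logical matrix of the given shape.
#' @export
rasterize_polygon <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("polygon needs at least 3 vertices")
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  nr <- shape[1]; nc <- shape[2]
  # pixel centres
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- points_in_polygon(cx, cy, vertices[, 1], vertices[, 2])
  mask <- matrix(inside, nr, nc)
  if (!any(mask)) warning("polygon covers no pixel centres: empty mask")
  mask
}

# Even-odd point-in-polygon with on-edge points counted inside.
points_in_polygon <- function(px, py, vx, vy, edge_tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    straddle <- (yi > py) != (yj > py)
    if (any(straddle)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, straddle & (px < xint))
    }
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
      on_edge <- on_edge | d2 <= edge_tol^2
    }
    j <- i
  }
  inside | on_edge
}

#' Read a FAZ outline polygon from file
#'
#' Accepts either a JSON file holding a list of `[x, y]` pairs (optionally
#' under a top-level `"vertices"` key) or an ImageJ-style plain-text ROI:
#' one `x y` (or `x,y`) pair per line.
#'
#' @param path path to the polygon file.
#' @return two-column numeric matrix of `(x, y)` vertices.
#' @export
read_faz_polygon <- function(path) {
  if (!file.exists(path)) stop("cannot read polygon file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.list(obj) && !is.null(obj$vertices)) obj <- obj$vertices
    v <- as.matrix(obj)
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    parts <- lapply(strsplit(trimws(txt), "[,[:space:]]+"), as.numeric)
    v <- do.call(rbind, parts)
  }
  if (is.null(dim(v)) || ncol(v) != 2L || nrow(v) < 3L)
    stop("polygon file must contain at least 3 (x, y) pairs")
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  v
}

#' Write per-eye metric records to CSV
#'
#' One row per eye, full numeric precision; the file round-trips through
#' [read_metrics_table()] without loss (within double formatting).
#'
#' @param records data frame of per-eye metric rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-eye metric records as a JSON bundle
#'
#' One JSON object per eye, keyed by `eye_id`.
#'
#' @inheritParams write_metrics_table
#' @export
write_metrics_json <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  lst <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  names(lst) <- records$eye_id
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
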