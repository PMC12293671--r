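#' Centroid of a binary mask
#'
#' Unweighted mean of the foreground pixel-centre coordinates, returned as
#' `(x, y)` in continuous pixel units.
#'
#' @param mask logical matrix.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
compute_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute centroid of an empty mask")
  c(x = mean(idx[, 2]) - 0.5, y = mean(idx[, 1]) - 0.5)
}

#' Crop the FAZ-centred analysis disc
#'
#' Builds the circular analysis region: a disc of the given physical
#' diameter (default 3 mm) about the FAZ centroid, minus the FAZ mask.
#' The disc contains every pixel whose centre lies within `diameter_mm / 2`
#' of the centroid.  Portions of the disc falling outside the frame are
#' clipped and the clipped fraction reported; metrics are computed on the
#' clipped effective region.
#'
#' @param img an [enface_angiogram()].
#' @param centroid `(x, y)` centre in continuous pixel coordinates.
#' @param diameter_mm disc diameter in mm (default 3).
#' @param exclude logical mask to subtract (the FAZ); `NULL` for none.
#' @return An object of class `analysis_region` with `disc_mask`,
#'   `excluded_mask`, `effective_mask`, `effective_area_px`,
#'   `clipped_fraction`.
#' @export
crop_analysis_disc <- function(img, centroid, diameter_mm = 3.0, exclude = NULL) {
  stopifnot(inherits(img, "enface_angiogram"))
  if (!isTRUE(diameter_mm > 0)) stop("diameter_mm must be positive")
  nr <- img$height_px; nc <- img$width_px
  if (centroid[1] < 0 || centroid[1] > nc || centroid[2] < 0 || centroid[2] > nr)
    stop("centroid lies outside the image frame")
  r_px <- (diameter_mm / 2) / img$pixel_pitch_mm
  cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  cy <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  disc <- (cx - centroid[1])^2 + (cy - centroid[2])^2 <= r_px^2
  # how much of the ideal disc lies beyond the frame (count virtual centres)
  xr <- floor(centroid[1] - r_px):ceiling(centroid[1] + r_px)
  yr <- floor(centroid[2] - r_px):ceiling(centroid[2] + r_px)
  vx <- rep(xr + 0.5, each = length(yr)); vy <- rep(yr + 0.5, times = length(xr))
  full_n <- sum((vx - centroid[1])^2 + (vy - centroid[2])^2 <= r_px^2)
  clipped <- if (full_n > 0) 1 - sum(disc) / full_n else 0
  if (clipped > 1e-12)
    warning(sprintf("analysis disc clipped by frame: %.2f%% lost", 100 * clipped))
  if (is.null(exclude)) exclude <- matrix(FALSE, nr, nc)
  stopifnot(identical(dim(exclude), dim(disc)))
  eff <- disc & !exclude
  structure(list(disc_mask = disc, excluded_mask = exclude,
                 effective_mask = eff, effective_area_px = sum(eff),
                 clipped_fraction = clipped,
                 radius_px = r_px, centroid = centroid),
            class = "analysis_region")
}

#' @export
print.analysis_region <- function(x, ...) {
  cat(sprintf("Analysis region: disc %d px (radius %.2f px) - excluded %d px = %d px effective\n",
              sum(x$disc_mask), x$radius_px, sum(x$disc_mask & x$excluded_mask),
              x$effective_area_px))
  if (x$clipped_fraction > 0)
    cat(sprintf("  clipped fraction: %.3f\n", x$clipped_fraction))
  invisible(x)
}

#' FAZ area by pixel counting
#'
#' Area is the foreground pixel count times the squared pixel pitch.
#'
#' @param mask logical matrix.
#' @param pitch_mm pixel pitch in mm/px.
#' @return area in mm^2.
#' @export
faz_area <- function(mask, pitch_mm) {
  if (!isTRUE(pitch_mm > 0)) stop("pitch must be positive")
  n <- sum(mask)
  if (n == 0L) warning("empty mask: area 0")
  n * pitch_mm^2
}

#' FAZ perimeter by boundary tracing
#'
#' Traces the closed outer boundary of the (single) foreground component
#' with 8-connected Moore neighbour tracing and sums the pixel-to-pixel
#' step distances — 1 for axis steps, sqrt(2) for diagonal steps — scaled
#' by the pixel pitch.  The raw (1, sqrt 2) chain length systematically
#' overestimates the perimeter of smooth digitized contours by about 5%
#' (its expected value over random orientations exceeds the true length),
#' so by default the classical Kulpa calibration `pi (1 + sqrt 2) / 8
#' (approximately 0.948)` is applied to the chain length; this keeps the
#' circularity of a large rasterized disc within about 1% of 1.  Set
#' `weights = "chain"` for the uncalibrated chain length.
#'
#' A disconnected mask is reduced to its largest component with a warning.
#' Degenerate contours (single pixel) fall back to `4 * pitch_mm`.
#'
#' @param mask logical matrix with a single connected foreground component.
#' @param pitch_mm pixel pitch in mm/px.
#' @param weights `"kulpa"` (default, calibrated) or `"chain"` (raw
#'   1 / sqrt(2) step lengths).
#' @return perimeter in mm.
#' @export
faz_perimeter <- function(mask, pitch_mm, weights = c("kulpa", "chain")) {
  weights <- match.arg(weights)
  if (!isTRUE(pitch_mm > 0)) stop("pitch must be positive")
  if (!any(mask)) stop("cannot trace the boundary of an empty mask")
  lab <- label_components8(mask)
  if (max(lab) > 1L) {
    warning("mask has multiple components; using the largest")
    mask <- largest_component(mask)
  }
  chain <- trace_boundary(mask)
  if (nrow(chain) < 2L) return(4 * pitch_mm)  # single-pixel fallback
  steps <- diff(rbind(chain, chain[1, , drop = FALSE]))
  len <- sum(sqrt(steps[, 1]^2 + steps[, 2]^2))
  if (weights == "kulpa") len <- len * pi * (1 + sqrt(2)) / 8
  len * pitch_mm
}

# Moore-neighbour boundary tracing (clockwise).  The trace carries the
# (current pixel, backtrack background pixel) state; the circuit is complete
# when a state recurs.  Returns the boundary chain as (row, col) indices;
# consecutive entries are 8-adjacent and the chain closes on itself.
trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(idx)
  ord <- order(idx[, 1], idx[, 2])
  s <- c(idx[ord[1], 1], idx[ord[1], 2])  # topmost, then leftmost
  nr <- nrow(mask); nc <- ncol(mask)
  # clockwise Moore neighbourhood starting West
  off <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  fg <- function(r, c2) r >= 1 && r <= nr && c2 >= 1 && c2 <= nc && mask[r, c2]
  p <- s
  b <- c(s[1], s[2] - 1L)  # West of start is background by construction
  seen <- new.env(hash = TRUE, parent = emptyenv())
  chain_r <- integer(0); chain_c <- integer(0)
  maxit <- 8L * nrow(idx) + 16L
  for (it in seq_len(maxit)) {
    key <- paste(p[1], p[2], b[1], b[2])
    if (!is.null(seen[[key]])) break
    assign(key, TRUE, envir = seen)
    chain_r <- c(chain_r, p[1]); chain_c <- c(chain_c, p[2])
    db <- which(off[, 1] == b[1] - p[1] & off[, 2] == b[2] - p[2])
    prev <- b
    moved <- FALSE
    for (k in seq_len(8L)) {
      d <- ((db - 1L + k) %% 8L) + 1L
      cr <- p[1] + off[d, 1]; cc <- p[2] + off[d, 2]
      if (fg(cr, cc)) { b <- prev; p <- c(cr, cc); moved <- TRUE; break }
      prev <- c(cr, cc)
    }
    if (!moved) break
  }
  cbind(row = chain_r, col = chain_c)
}

#' Circularity index
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, smaller for
#' irregular shapes.  Dimensionless and invariant under uniform rescaling.
#'
#' @param area area (mm^2 or px^2 — any unit, consistent with perimeter).
#' @param perimeter perimeter in the matching linear unit.
#' @return circularity index.
#' @export
circularity <- function(area, perimeter) {
  if (!isTRUE(perimeter > 0)) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Littmann-Bennett axial-length magnification correction
#'
#' The true retinal size of a feature measured on a fundus image scales
#' with the ocular magnification factor `q(AL) = 0.01306 * (AL - 1.82)`.
#' Relative to the instrument's assumed reference axial length, lengths
#' scale by `q(AL) / q(AL_ref)` and areas by its square.  Circularity and
#' other length ratios are invariant.
#'
#' @param al_mm measured axial length in mm.
#' @param reference_al_mm axial length assumed by the instrument
#'   (default 24.39 mm).
#' @return object of class `al_correction` with `linear_factor` and
#'   `area_factor`.
#' @export
axial_length_correction <- function(al_mm, reference_al_mm = 24.39) {
  if (!isTRUE(al_mm > 1.82) || !isTRUE(reference_al_mm > 1.82))
    stop("axial lengths must exceed 1.82 mm (formula domain)")
  lf <- (0.01306 * (al_mm - 1.82)) / (0.01306 * (reference_al_mm - 1.82))
  structure(list(axial_length_mm = al_mm, reference_al_mm = reference_al_mm,
                 linear_factor = lf, area_factor = lf^2),
            class = "al_correction")
}

#' @export
print.al_correction <- function(x, ...) {
  cat(sprintf("Axial-length correction: AL %.2f mm vs reference %.2f mm -> linear x%.4f, area x%.4f\n",
              x$axial_length_mm, x$reference_al_mm, x$linear_factor, x$area_factor))
  invisible(x)
}

#' Full FAZ morphometry from a polygon outline
#'
#' Rasterizes the manually delineated FAZ outline, keeps the largest
#' connected component, and computes centroid, area, perimeter and
#' circularity.  If an axial length is supplied, area and perimeter are
#' additionally reported adjusted via [axial_length_correction()];
#' circularity is scale-invariant and unchanged.
#'
#' @param img an [enface_angiogram()].
#' @param polygon two-column `(x, y)` vertex matrix (see
#'   [read_faz_polygon()]).
#' @param axial_length_mm optional axial length in mm.
#' @param reference_al_mm reference axial length (default 24.39 mm).
#' @return object of class `faz_delineation` with the mask, centroid and
#'   raw + adjusted morphometry.
#' @export
delineate_faz <- function(img, polygon, axial_length_mm = NULL,
                          reference_al_mm = 24.39) {
  stopifnot(inherits(img, "enface_angiogram"))
  mask <- rasterize_polygon(polygon, c(img$height_px, img$width_px))
  if (!any(mask)) stop("FAZ polygon rasterized to an empty mask")
  lab <- label_components8(mask)
  multi <- max(lab) > 1L
  if (multi) {
    warning("FAZ mask has multiple components; using the largest")
    mask <- largest_component(mask)
  }
  pitch <- img$pixel_pitch_mm
  a <- faz_area(mask, pitch)
  p <- faz_perimeter(mask, pitch)
  res <- list(mask = mask, centroid_px = compute_centroid(mask),
              area_mm2 = a, perimeter_mm = p,
              circularity = circularity(a, p),
              multi_component = multi)
  if (!is.null(axial_length_mm) && is.finite(axial_length_mm)) {
    corr <- axial_length_correction(axial_length_mm, reference_al_mm)
    res$al_correction <- corr
    res$area_adj_mm2 <- a * corr$area_factor
    res$perimeter_adj_mm <- p * corr$linear_factor
  }
  structure(res, class = "faz_delineation")
}

#' @export
print.faz_delineation <- function(x, ...) {
  cat(sprintf("FAZ: area %.4f mm^2, perimeter %.4f mm, circularity %.4f\n",
              x$area_mm2, x$perimeter_mm, x$circularity))
  cat(sprintf("  centroid (x, y) = (%.2f, %.2f) px\n",
              x$centroid_px[1], x$centroid_px[2]))
  if (!is.null(x$area_adj_mm2))
    cat(sprintf("  axial-length adjusted: area %.4f mm^2, perimeter %.4f mm\n",
                x$area_adj_mm2, x$perimeter_adj_mm))
  invisible(x)
}
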