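#' Vessel density
#'
#' Fraction of the effective analysis area (3-mm disc minus FAZ by
#' default) occupied by binarized vessel pixels.
#'
#' @param vessel_mask logical matrix of binarized vessels.
#' @param region an `analysis_region` (see [crop_analysis_disc()]) or a
#'   logical matrix used directly as the effective region.
#' @return fraction in `[0, 1]`.
#' @export
vessel_density <- function(vessel_mask, region) {
  eff <- effective_mask_of(region)
  stopifnot(identical(dim(vessel_mask), dim(eff)))
  denom <- sum(eff)
  if (denom == 0L) stop("empty analysis region")
  sum(vessel_mask & eff) / denom
}

effective_mask_of <- function(region) {
  if (inherits(region, "analysis_region")) region$effective_mask
  else if (is.matrix(region)) region
  else stop("region must be an analysis_region or a logical matrix")
}

# ---- topology-preserving thinning ------------------------------------------

# Neighbour offsets in the fixed bit order N, NE, E, SE, S, SW, W, NW.
.nb_off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

# Lookup tables over the 256 possible 8-neighbourhoods:
#   .simple_tab[pat + 1]  TRUE if the centre pixel is 8-simple (deleting it
#                         preserves both foreground 8-topology and
#                         background 4-topology locally)
#   .nn_tab[pat + 1]      number of foreground neighbours
# Built once by brute-force component counting on the 3x3 ring.
.thin_env <- new.env(parent = emptyenv())

thin_tables <- function() {
  if (!is.null(.thin_env$simple)) return(.thin_env)
  simple <- logical(256); nn <- integer(256)
  # ring adjacency under 8- and 4-connectivity
  adj8 <- matrix(FALSE, 8, 8); adj4 <- matrix(FALSE, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    d <- abs(.nb_off[i, ] - .nb_off[j, ])
    if (i != j && max(d) <= 1) adj8[i, j] <- TRUE
    if (i != j && sum(d) == 1) adj4[i, j] <- TRUE
  }
  edge_ids <- c(1L, 3L, 5L, 7L)  # N, E, S, W: 4-neighbours of the centre
  ncomp <- function(ids, adj) {
    if (length(ids) == 0L) return(0L)
    seen <- logical(length(ids)); comp <- 0L
    for (st in seq_along(ids)) {
      if (seen[st]) next
      comp <- comp + 1L
      stack <- st
      while (length(stack)) {
        v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (seen[v]) next
        seen[v] <- TRUE
        for (w in seq_along(ids))
          if (!seen[w] && adj[ids[v], ids[w]]) stack <- c(stack, w)
      }
    }
    comp
  }
  for (pat in 0:255) {
    fg <- which(bitwAnd(pat, bitwShiftL(1L, 0:7)) != 0L)
    bg <- setdiff(1:8, fg)
    nn[pat + 1] <- length(fg)
    # background components restricted to those touching a 4-neighbour of
    # the centre (standard (8,4) simple-point condition)
    nbg <- 0L
    if (length(bg)) {
      # label 4-components of the background ring, count those containing
      # an edge cell
      labs <- integer(length(bg)); comp <- 0L
      for (st in seq_along(bg)) {
        if (labs[st] > 0L) next
        comp <- comp + 1L; stack <- st
        while (length(stack)) {
          v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
          if (labs[v] > 0L) next
          labs[v] <- comp
          for (w in seq_along(bg))
            if (labs[w] == 0L && adj4[bg[v], bg[w]]) stack <- c(stack, w)
        }
      }
      nbg <- length(unique(labs[bg %in% edge_ids]))
    }
    simple[pat + 1] <- ncomp(fg, adj8) == 1L && nbg == 1L
  }
  .thin_env$simple <- simple
  .thin_env$nn <- nn
  .thin_env
}

#' Skeletonize a binary vessel mask
#'
#' Medial-axis-preserving thinning: border pixels that are 8-simple and not
#' curve endpoints are deleted sequentially (directional North/South/East/
#' West sub-passes) until no further deletion is possible.  Because each
#' deletion is individually topology-preserving, connected-component and
#' hole counts are exactly preserved; the result is contained in the input,
#' is one pixel wide (no 2x2 foreground block survives), and the operation
#' is idempotent.
#'
#' @param vessel_mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(vessel_mask) {
  stopifnot(is.matrix(vessel_mask))
  tab <- thin_tables()
  nr <- nrow(vessel_mask); nc <- ncol(vessel_mask)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- vessel_mask
  Morig <- M
  pow2 <- bitwShiftL(1L, 0:7)
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, -1L))
  repeat {
    repeat {
      changed <- FALSE
      for (dd in dirs) {
      inner <- M[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
      nbm <- M[2:(nr + 1L) + dd[1], 2:(nc + 1L) + dd[2], drop = FALSE]
      cand <- which(inner & !nbm, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1] + 1L; c2 <- cand[i, 2] + 1L
        if (!M[r, c2]) next
        pat <- 0L
        for (k in 1:8) {
          if (M[r + .nb_off[k, 1], c2 + .nb_off[k, 2]])
            pat <- pat + pow2[k]
        }
        if (tab$nn[pat + 1] >= 2L && tab$simple[pat + 1]) {
          M[r, c2] <- FALSE
          changed <- TRUE
        }
      }
    }
      if (!changed) break
    }
    M2 <- rewire_crossings(M, Morig)
    if (identical(M2, M)) break
    M <- M2
  }
  M[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# Residual 2x2 blocks after thinning are X-crossings whose four diagonal
# arms each attach to a different corner; no corner is 8-simple, so
# deletion alone cannot thin them.  Rewire: drop one corner whose only
# outside neighbour is its diagonal arm tip, and re-attach that arm via an
# orthogonal pixel adjacent to both the tip and the remaining block.  The
# bridge pixel must lie inside the original mask so the skeleton stays
# contained in its input; the rewiring is connectivity-preserving and
# removes the 2x2 block.
rewire_crossings <- function(M, Morig) {
  nr <- nrow(M); nc <- ncol(M)
  repeat {
    blk <- which(M[-nr, -nc] & M[-1, -nc] & M[-nr, -1] & M[-1, -1],
                 arr.ind = TRUE)
    if (nrow(blk) == 0L) return(M)
    fixed_any <- FALSE
    for (i in seq_len(nrow(blk))) {
      r0 <- blk[i, 1]; c0 <- blk[i, 2]  # top-left of the 2x2
      if (!(M[r0, c0] && M[r0 + 1, c0] && M[r0, c0 + 1] && M[r0 + 1, c0 + 1]))
        next  # already altered by an earlier fix
      corners <- rbind(c(r0, c0), c(r0, c0 + 1), c(r0 + 1, c0), c(r0 + 1, c0 + 1))
      for (j in 1:4) {
        p <- corners[j, ]
        # outside-of-block 8-neighbours of p
        out_nb <- matrix(0L, 0, 2)
        for (k in 1:8) {
          q <- p + .nb_off[k, ]
          if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
          inblock <- q[1] >= r0 && q[1] <= r0 + 1 && q[2] >= c0 && q[2] <= c0 + 1
          if (!inblock && M[q[1], q[2]]) out_nb <- rbind(out_nb, q)
        }
        if (nrow(out_nb) != 1L) next
        a <- out_nb[1, ]
        if (max(abs(a - p)) != 1L || sum(abs(a - p)) != 2L) next  # need diagonal tip
        for (q in list(c(p[1], a[2]), c(a[1], p[2]))) {
          if (M[q[1], q[2]] || !Morig[q[1], q[2]]) next
          M[p[1], p[2]] <- FALSE
          M[q[1], q[2]] <- TRUE
          # reject if the bridge pixel creates a fresh 2x2 block
          sub <- M[max(1, q[1] - 1):min(nr, q[1] + 1),
                   max(1, q[2] - 1):min(nc, q[2] + 1), drop = FALSE]
          if (any(sub[-nrow(sub), -ncol(sub)] & sub[-1, -ncol(sub)] &
                  sub[-nrow(sub), -1] & sub[-1, -1])) {
            M[q[1], q[2]] <- FALSE
            M[p[1], p[2]] <- TRUE
            next
          }
          fixed_any <- TRUE
          break
        }
        if (fixed_any) break
      }
    }
    if (!fixed_any) return(M)
  }
}

#' Skeleton length
#'
#' Default convention (`"count"`): length = skeleton pixel count, matching
#' the raster definition of skeleton density.  `"weighted"` instead sums
#' chain steps between 8-adjacent skeleton pixels with diagonal steps
#' weighted sqrt(2) (each adjacency counted once).
#'
#' @param skeleton logical matrix.
#' @param method `"count"` or `"weighted"`.
#' @return length in pixel units.
#' @export
skeleton_length <- function(skeleton, method = c("count", "weighted")) {
  method <- match.arg(method)
  if (method == "count") return(sum(skeleton))
  len <- 0
  for (k in c(3L, 4L, 5L, 6L)) {  # E, SE, S, SW: each undirected pair once
    nb <- shift_mat(skeleton, .nb_off[k, 1], .nb_off[k, 2], FALSE)
    w <- if (sum(abs(.nb_off[k, ])) == 2L) sqrt(2) else 1
    len <- len + w * sum(skeleton & nb)
  }
  len
}

#' Vessel length density (skeleton density)
#'
#' Skeleton pixel count within the effective region divided by the
#' effective region's pixel count.  Caliber-independent perfusion measure;
#' bounded above by the vessel density whenever mean caliber >= 1 px.
#'
#' @param skeleton logical 1-px-wide skeleton matrix.
#' @inheritParams vessel_density
#' @return fraction in `[0, 1]`.
#' @export
vessel_length_density <- function(skeleton, region) {
  eff <- effective_mask_of(region)
  stopifnot(identical(dim(skeleton), dim(eff)))
  denom <- sum(eff)
  if (denom == 0L) stop("empty analysis region")
  sum(skeleton & eff) / denom
}

#' Box-counting fractal dimension
#'
#' Overlays grids of square boxes of side `eps` (powers of two from 2 up to
#' a quarter of the frame side by default), anchored at the foreground
#' bounding-box origin, and counts boxes containing at least one foreground
#' pixel.  The fractal dimension is minus the least-squares slope of
#' `log N(eps)` versus `log eps`; the fit's R-squared is reported and a
#' warning raised below 0.95.
#'
#' @param mask logical matrix (typically a skeleton).
#' @param box_sizes optional integer vector of box sides; default powers of
#'   two up to `floor(min(dim(mask)) / 4)`.  At least 4 sizes are required.
#' @return object of class `fd_estimate` with `box_sizes`, `box_counts`,
#'   `slope` (the FD) and `r_squared`.
#' @export
box_counting_fd <- function(mask, box_sizes = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot estimate the fractal dimension of an empty mask")
  if (is.null(box_sizes)) {
    emax <- floor(min(dim(mask)) / 4)
    if (emax < 2) stop("image too small for box counting")
    box_sizes <- 2^seq(1L, floor(log2(emax)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 4L)
    stop("need at least 4 box sizes for a stable fit (got ", length(box_sizes), ")")
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  counts <- vapply(box_sizes, function(e) {
    br <- (idx[, 1] - r0) %/% e
    bc <- (idx[, 2] - c0) %/% e
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(box_sizes))
  slope <- -unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (is.finite(r2) && r2 < 0.95)
    warning(sprintf("box-count fit R^2 = %.3f < 0.95: FD estimate unreliable", r2))
  structure(list(box_sizes = box_sizes, box_counts = counts,
                 slope = slope, r_squared = r2),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension: %.4f (R^2 = %.4f)\n",
              x$slope, x$r_squared))
  cat("  sizes:", paste(x$box_sizes, collapse = " "),
      "\n  counts:", paste(x$box_counts, collapse = " "), "\n")
  invisible(x)
}

#' Combined perfusion metrics for one eye
#'
#' Convenience wrapper computing vessel density, skeleton, vessel length
#' density and fractal dimension from a binarized vessel mask and an
#' analysis region.  The FD is computed on the skeleton restricted to the
#' effective region, consistent with the FAZ being masked out upstream.
#'
#' @param vessel_mask logical matrix.
#' @param region analysis region or logical mask.
#' @param fd_box_sizes optional box sizes forwarded to [box_counting_fd()].
#' @return object of class `perfusion_metrics`.
#' @export
perfusion_metrics <- function(vessel_mask, region, fd_box_sizes = NULL) {
  eff <- effective_mask_of(region)
  vd <- vessel_density(vessel_mask, eff)
  skel <- skeletonize(vessel_mask)
  vld <- vessel_length_density(skel, eff)
  fd <- box_counting_fd(skel & eff, box_sizes = fd_box_sizes)
  structure(list(vessel_density = vd, vessel_length_density = vld,
                 fractal_dimension = fd$slope, fd_fit = fd,
                 skeleton = skel, effective_area_px = sum(eff)),
            class = "perfusion_metrics")
}

#' @export
print.perfusion_metrics <- function(x, ...) {
  cat(sprintf("Perfusion metrics: VD %.4f, VLD %.4f, FD %.4f (over %d px)\n",
              x$vessel_density, x$vessel_length_density,
              x$fractal_dimension, x$effective_area_px))
  invisible(x)
}
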