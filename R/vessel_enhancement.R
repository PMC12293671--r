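#' Vesselness filter parameters
#'
#' Defaults target capillaries on the nominal 14 um/px en-face sampling,
#' where vessel calibers span roughly 1-3 px: Gaussian scales
#' `{1, 1.5, 2, 2.5}` px, blobness sensitivity `beta = 0.5`, and an
#' adaptive structureness constant `c` set per scale to half the maximum
#' Frobenius norm of the Hessian (`c = NULL` requests this).
#'
#' @param scales Gaussian scales sigma in px (non-empty, all positive).
#' @param beta blobness sensitivity (> 0).
#' @param c structureness sensitivity; `NULL` for the adaptive half-max rule.
#' @param polarity `"bright_vessels"` (flow signal brighter than background)
#'   or `"dark_vessels"`.
#' @return list of class `vesselness_params`.
#' @export
vesselness_params <- function(scales = c(1, 1.5, 2, 2.5), beta = 0.5,
                              c = NULL, polarity = c("bright_vessels", "dark_vessels")) {
  polarity <- match.arg(polarity)
  if (length(scales) == 0L) stop("scale list must be non-empty")
  stopifnot(all(scales > 0), beta > 0, is.null(c) || c > 0)
  structure(list(scales = scales, beta = beta, c = c, polarity = polarity),
            class = "vesselness_params")
}

# 1-D Gaussian and derivative kernels sampled on an integer grid.
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- dnorm(x, sd = sigma)
  g <- g / sum(g)
  g1 <- -(x / sigma^2) * g
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - mean(g2)  # zero-mean: exact null response on constants
  list(g = g, g1 = g1, g2 = g2, r = r)
}

# Separable convolution with replicate padding; kx along columns (x),
# ky along rows (y).  Kernels must be odd-length, centred.
sep_convolve <- function(img, kx, ky) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  p <- pad_replicate(img, max(rx, ry))
  m <- max(rx, ry)
  nr <- nrow(img); nc <- ncol(img)
  # rows (y direction) with kernel ky
  acc <- matrix(0, nr, nc + 2L * m)
  for (i in seq_along(ky)) {
    dr <- i - 1L - ry
    acc <- acc + ky[i] * p[(m + 1L + dr):(m + nr + dr), , drop = FALSE]
  }
  # columns (x direction) with kernel kx
  out <- matrix(0, nr, nc)
  for (i in seq_along(kx)) {
    dc <- i - 1L - rx
    out <- out + kx[i] * acc[, (m + 1L + dc):(m + nc + dc), drop = FALSE]
  }
  out
}

#' Scale-normalized Hessian eigenvalues
#'
#' Second-derivative responses of the sigma-smoothed image, computed with
#' separable Gaussian-derivative kernels and gamma-normalized by `sigma^2`.
#' Per pixel the two eigenvalues of the 2x2 Hessian are returned ordered by
#' absolute value, `|lambda1| <= |lambda2|`.
#'
#' @param img numeric intensity matrix.
#' @param sigma Gaussian scale in px (> 0).
#' @return list with matrices `lambda1`, `lambda2`.
#' @export
hessian_eigenvalues <- function(img, sigma) {
  stopifnot(sigma > 0)
  k <- gauss_kernels(sigma)
  Ixx <- sigma^2 * sep_convolve(img, k$g2, k$g)
  Iyy <- sigma^2 * sep_convolve(img, k$g, k$g2)
  Ixy <- sigma^2 * sep_convolve(img, k$g1, k$g1)
  tr2 <- (Ixx + Iyy) / 2
  disc <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  e1 <- tr2 + disc
  e2 <- tr2 - disc
  swap <- abs(e1) > abs(e2)
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' Frangi multiscale vesselness
#'
#' Per scale, the tubularity response is zero where the dominant eigenvalue
#' has the non-vessel sign for the chosen polarity (bright vessels require
#' `lambda2 < 0`); elsewhere
#' `V = exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' with blobness `R_B = lambda1 / lambda2` and structureness
#' `S = sqrt(lambda1^2 + lambda2^2)`.  The final map is the pixelwise
#' maximum over scales, so adding a scale can never decrease the response.
#'
#' @param img numeric intensity matrix (any range; derivatives are linear).
#' @param params a [vesselness_params()] object.
#' @return vesselness matrix with values in `[0, 1]`.
#' @export
frangi_vesselness <- function(img, params = vesselness_params()) {
  stopifnot(inherits(params, "vesselness_params"))
  if (length(params$scales) == 0L) stop("scale list must be non-empty")
  out <- matrix(0, nrow(img), ncol(img))
  for (sigma in params$scales) {
    ev <- hessian_eigenvalues(img, sigma)
    l1 <- ev$lambda1; l2 <- ev$lambda2
    S <- sqrt(l1^2 + l2^2)
    cc <- if (is.null(params$c)) max(S) / 2 else params$c
    if (cc <= 1e-8) next  # flat image at this scale: zero response
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
    bad <- if (params$polarity == "bright_vessels") l2 >= 0 else l2 <= 0
    v[bad] <- 0
    out <- pmax(out, v)
  }
  out
}

#' Invert a vesselness map
#'
#' Returns `1 - v`.  Mirrors the display step of the original pipeline; the
#' binarization stage consumes whichever polarity is configured (default:
#' the non-inverted map, with foreground = high vesselness).
#'
#' @param v matrix with values in `[0, 1]`.
#' @return inverted matrix.
#' @export
invert_vesselness <- function(v) {
  if (min(v) < 0 || max(v) > 1) stop("vesselness values must lie in [0, 1]")
  1 - v
}

#' Phansalkar local-threshold parameters
#'
#' Published defaults for low-contrast images: window radius `R = 7` px,
#' `k = 0.25`, `r = 0.5`, `p = 2`, `q = 10`.
#'
#' @param window_radius half-width of the square window in px (>= 1).
#' @param k local standard-deviation weight.
#' @param r standard-deviation normalization constant (> 0).
#' @param p exponential amplitude.
#' @param q exponential decay.
#' @return list of class `threshold_params`.
#' @export
threshold_params <- function(window_radius = 7L, k = 0.25, r = 0.5,
                             p = 2, q = 10) {
  stopifnot(window_radius >= 1, r > 0)
  structure(list(window_radius = as.integer(window_radius),
                 k = k, r = r, p = p, q = q),
            class = "threshold_params")
}

#' Phansalkar local thresholding
#'
#' For each pixel, with `m` and `s` the mean and standard deviation over
#' the square window of radius `R` (edge-replicated padding), the local
#' threshold is `T = m * (1 + p * exp(-q * m) + k * ((s / r) - 1))` and the
#' pixel is foreground iff its value is strictly greater than `T`.  Window
#' statistics always use the full window, including pixels outside
#' `region`, to avoid boundary bias; the region constraint is applied to
#' the output mask only.
#'
#' @param img intensity matrix with values in `[0, 1]`.
#' @param params a [threshold_params()] object.
#' @param region optional logical mask; pixels outside it are background.
#' @return logical matrix.
#' @export
phansalkar_threshold <- function(img, params = threshold_params(), region = NULL) {
  stopifnot(inherits(params, "threshold_params"))
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("intensities must be normalized to [0, 1]")
  R <- params$window_radius
  nr <- nrow(img); nc <- ncol(img)
  if (2L * R + 1L > min(nr, nc))
    stop("threshold window larger than the image")
  pm <- pad_replicate(img, R)
  n <- (2 * R + 1)^2
  m <- box_mean(pm, R, nr, nc)
  m2 <- box_mean(pm * pm, R, nr, nc)
  s <- sqrt(pmax(0, m2 - m * m))
  thr <- m * (1 + params$p * exp(-params$q * m) + params$k * ((s / params$r) - 1))
  out <- img > thr
  if (!is.null(region)) {
    stopifnot(identical(dim(region), dim(img)))
    out <- out & region
  }
  out
}

# Windowed mean over (2R+1)^2 squares of a replicate-padded matrix,
# via a summed-area table.
box_mean <- function(pm, R, nr, nc) {
  I <- matrix(0, nrow(pm) + 1L, ncol(pm) + 1L)
  I[-1, -1] <- apply(pm, 2, cumsum)
  I[-1, -1] <- t(apply(I[-1, -1, drop = FALSE], 1, cumsum))
  w <- 2L * R + 1L
  A <- I[(w + 1L):(w + nr), (w + 1L):(w + nc), drop = FALSE]
  B <- I[1:nr, (w + 1L):(w + nc), drop = FALSE]
  C <- I[(w + 1L):(w + nr), 1:nc, drop = FALSE]
  D <- I[1:nr, 1:nc, drop = FALSE]
  (A - B - C + D) / (w * w)
}
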