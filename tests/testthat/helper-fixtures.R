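# Fixture builders and independent oracles shared across the suite.

# Rasterized disc: pixel centres within radius r of (cx, cy) on a square frame.
make_disc <- function(frame, r, cx = frame / 2, cy = frame / 2) {
  gx <- matrix(rep(seq_len(frame) - 0.5, each = frame), frame, frame)
  gy <- matrix(rep(seq_len(frame) - 0.5, times = frame), frame, frame)
  (gx - cx)^2 + (gy - cy)^2 <= r^2
}

# Sierpinski triangle raster of side 2^depth (bitwise-AND construction).
make_sierpinski <- function(depth) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0)
}

# Brute-force Phansalkar oracle: per-pixel loops recomputing window mean,
# SD and threshold directly (edge-replicated padding, strict >).
phansalkar_oracle <- function(img, R = 7L, k = 0.25, r = 0.5, p = 2, q = 10) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax(seq(i - R, i + R), 1L), nr)
      ci <- pmin(pmax(seq(j - R, j + R), 1L), nc)
      w <- img[ri, ci]
      m <- mean(w)
      s <- sqrt(mean(w^2) - m^2)
      if (is.nan(s)) s <- 0
      thr <- m * (1 + p * exp(-q * m) + k * ((s / r) - 1))
      out[i, j] <- img[i, j] > thr
    }
  }
  out
}

# Independent point-in-polygon oracle: winding-number accumulation (distinct
# formulation from the package's even-odd crossing test).  Points must not
# lie exactly on an edge.
winding_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- rep(0L, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
    isleft <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- y1 <= py & y2 > py & isleft > 0
    dn <- y1 > py & y2 <= py & isleft < 0
    wn <- wn + up - dn
  }
  wn != 0L
}

# Small phantom spec used where the property under test is scale-free.
small_phantom_spec <- function(seed, ...) {
  phantom_spec(seed = seed, frame_px = 192L, extent_mm = 4.5 * 192 / 320, ...)
}

expect_no_2x2 <- function(sk) {
  blk <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -1] & sk[-1, -1]
  expect_equal(sum(blk), 0L)
}
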