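# Internal helpers shared across modules.

#' @importFrom stats rnorm runif dnorm pnorm pt cor quantile sd
#' @importFrom utils write.csv read.csv head
NULL

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(rep(1L, r), seq_len(nr), rep(nr, r)),
    c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
}

# 8-connected component labelling.  EBImage::bwlabel is 4-connected, so we
# label 4-connected first and then union labels that touch diagonally.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[rb] <<- ra }
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(lab, sh[1], sh[2], 0L)
    sel <- lab > 0L & nb > 0L & lab != nb
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], nb[sel]))
      for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(nlab), findp, integer(1))
  relab <- match(roots, unique(roots))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Largest 8-connected foreground component of a logical mask.
largest_component <- function(mask) {
  lab <- label_components8(mask)
  if (max(lab) <= 1L) return(mask & TRUE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Truncated-normal draws by rejection; bounds must not exclude mean +/- 4 sd.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (lower > mean + 4 * sd || upper < mean - 4 * sd)
    stop("truncation bounds exclude mean +/- 4 sd")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}
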