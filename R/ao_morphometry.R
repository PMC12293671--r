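#' Arteriolar wall metrics from one ROI's diameter pair
#'
#' From an adaptive-optics total (outer) vessel diameter and lumen (inner)
#' diameter, derives:
#' \itemize{
#'   \item mean single-wall thickness `WT = (TVD - LD) / 2`,
#'   \item wall-to-lumen ratio `WLR = (TVD - LD) / LD = 2 WT / LD`,
#'   \item wall cross-sectional area `WCSA = (pi / 4) (TVD^2 - LD^2)`.
#' }
#' The two-wall WLR convention `(TVD - LD) / LD` is used: it is the one
#' consistent with published AO morphometry software output (a single-wall
#' `WT / LD` definition would halve the ratio).
#'
#' @param tvd_um total vessel (outer) diameter in um.
#' @param ld_um lumen (inner) diameter in um; must satisfy
#'   `tvd_um > ld_um > 0`.
#' @return object of class `ao_vessel_metrics`.
#' @export
derive_wall_metrics <- function(tvd_um, ld_um) {
  if (!isTRUE(ld_um > 0)) stop("lumen diameter must be positive")
  if (!isTRUE(tvd_um > ld_um))
    stop("total vessel diameter must exceed lumen diameter (non-physical wall)")
  wt <- (tvd_um - ld_um) / 2
  structure(list(tvd_um = tvd_um, ld_um = ld_um,
                 wt_um = wt,
                 wlr = (tvd_um - ld_um) / ld_um,
                 wcsa_um2 = (pi / 4) * (tvd_um^2 - ld_um^2),
                 n_rois = 1L, al_adjusted = FALSE),
            class = "ao_vessel_metrics")
}

#' @export
print.ao_vessel_metrics <- function(x, ...) {
  cat(sprintf("AO wall metrics (%d ROI%s%s):\n", x$n_rois,
              if (x$n_rois > 1) "s" else "",
              if (x$al_adjusted) ", AL-adjusted" else ""))
  cat(sprintf("  TVD %.2f um, LD %.2f um, WT %.3f um, WLR %.4f, WCSA %.1f um^2\n",
              x$tvd_um, x$ld_um, x$wt_um, x$wlr, x$wcsa_um2))
  invisible(x)
}

#' Aggregate wall metrics over the ROIs of one vessel
#'
#' Each parameter is derived per ROI and then arithmetically averaged
#' (mean of per-ROI WLRs — not the WLR of mean diameters, which differs on
#' heterogeneous triplets).  Three ROIs are expected; fewer are accepted
#' with a warning, at least one is required.
#'
#' @param rois data frame with columns `tvd_um` and `ld_um`, one row per
#'   ROI (nominally 3).
#' @return object of class `ao_vessel_metrics` with averaged parameters.
#' @export
aggregate_rois <- function(rois) {
  rois <- as.data.frame(rois)
  n <- nrow(rois)
  if (n == 0L) stop("at least one ROI measurement is required")
  if (n != 3L) warning("expected 3 ROIs per vessel, got ", n)
  per <- lapply(seq_len(n), function(i)
    derive_wall_metrics(rois$tvd_um[i], rois$ld_um[i]))
  avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
  structure(list(tvd_um = avg("tvd_um"), ld_um = avg("ld_um"),
                 wt_um = avg("wt_um"), wlr = avg("wlr"),
                 wcsa_um2 = avg("wcsa_um2"),
                 n_rois = n, al_adjusted = FALSE),
            class = "ao_vessel_metrics")
}

#' Axial-length adjustment of AO wall metrics
#'
#' Lengths (TVD, LD, WT) scale by the Littmann-Bennett linear factor,
#' areas (WCSA) by its square; WLR is a ratio of lengths and is invariant.
#'
#' @param metrics an `ao_vessel_metrics` object.
#' @param correction an [axial_length_correction()] object.
#' @return adjusted `ao_vessel_metrics` with `al_adjusted = TRUE`.
#' @export
ao_axial_length_adjust <- function(metrics, correction) {
  stopifnot(inherits(metrics, "ao_vessel_metrics"),
            inherits(correction, "al_correction"))
  lf <- correction$linear_factor
  metrics$tvd_um <- metrics$tvd_um * lf
  metrics$ld_um <- metrics$ld_um * lf
  metrics$wt_um <- metrics$wt_um * lf
  metrics$wcsa_um2 <- metrics$wcsa_um2 * correction$area_factor
  metrics$al_adjusted <- TRUE
  metrics
}

#' Read per-ROI AO measurements from CSV
#'
#' Expects columns `eye_id`, `roi_index`, `tvd_um`, `ld_um` (a `vessel_id`
#' column is carried through if present).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_ao_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "roi_index", "tvd_um", "ld_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("AO ROI file missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Per-eye AO analysis
#'
#' Aggregates the ROI triplet of each eye via [aggregate_rois()] and
#' optionally applies the axial-length adjustment.
#'
#' @param rois data frame of per-ROI measurements (see [read_ao_rois()]).
#' @param axial_lengths optional named numeric vector of axial lengths (mm)
#'   keyed by `eye_id`; when supplied, metrics are AL-adjusted.
#' @param reference_al_mm reference axial length (default 24.39 mm).
#' @return data frame with one row per eye: `eye_id`, `tvd_um`, `ld_um`,
#'   `wt_um`, `wlr`, `wcsa_um2`, `n_rois`, `al_adjusted`.
#' @export
run_ao_eyes <- function(rois, axial_lengths = NULL, reference_al_mm = 24.39) {
  out <- lapply(split(rois, rois$eye_id), function(d) {
    m <- aggregate_rois(d[, c("tvd_um", "ld_um")])
    id <- d$eye_id[1]
    if (!is.null(axial_lengths) && !is.na(axial_lengths[as.character(id)])) {
      corr <- axial_length_correction(unname(axial_lengths[as.character(id)]),
                                      reference_al_mm)
      m <- ao_axial_length_adjust(m, corr)
    }
    data.frame(eye_id = id, tvd_um = m$tvd_um, ld_um = m$ld_um,
               wt_um = m$wt_um, wlr = m$wlr, wcsa_um2 = m$wcsa_um2,
               n_rois = m$n_rois, al_adjusted = m$al_adjusted)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
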