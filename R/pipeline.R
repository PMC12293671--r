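#' Pipeline configuration
#'
#' Collects every tunable default of the per-eye OCTA pipeline in one
#' object.  All values are documented with their rationale in the package
#' vignette.
#'
#' @param vesselness a [vesselness_params()] object.
#' @param threshold a [threshold_params()] object.
#' @param disc_diameter_mm analysis disc diameter (default 3 mm).
#' @param reference_al_mm instrument reference axial length (24.39 mm).
#' @param apply_inversion if `TRUE`, binarize `1 - vesselness` with
#'   reversed polarity semantics; default `FALSE` (binarize the vesselness
#'   map directly, foreground = high vesselness).
#' @param denominator `"disc_minus_faz"` (default) or `"full_disc"`: the
#'   area used as denominator of the density metrics.
#' @param fd_box_sizes optional box sizes for [box_counting_fd()].
#' @param skeleton_length_method `"count"` or `"weighted"`.
#' @param alpha significance level of the statistics stage.
#' @param dunn_adjust Dunn adjustment (`"bonferroni"` or `"holm"`).
#' @return list of class `octa_config`.
#' @export
octa_config <- function(vesselness = vesselness_params(),
                        threshold = threshold_params(),
                        disc_diameter_mm = 3.0,
                        reference_al_mm = 24.39,
                        apply_inversion = FALSE,
                        denominator = c("disc_minus_faz", "full_disc"),
                        fd_box_sizes = NULL,
                        skeleton_length_method = c("count", "weighted"),
                        alpha = 0.05,
                        dunn_adjust = "bonferroni") {
  denominator <- match.arg(denominator)
  skeleton_length_method <- match.arg(skeleton_length_method)
  structure(list(vesselness = vesselness, threshold = threshold,
                 disc_diameter_mm = disc_diameter_mm,
                 reference_al_mm = reference_al_mm,
                 apply_inversion = apply_inversion,
                 denominator = denominator,
                 fd_box_sizes = fd_box_sizes,
                 skeleton_length_method = skeleton_length_method,
                 alpha = alpha, dunn_adjust = dunn_adjust),
            class = "octa_config")
}

#' Per-eye OCTA analysis
#'
#' Executes the full quantification chain on one en-face angiogram:
#' rasterize the FAZ outline, compute FAZ morphometry (with axial-length
#' adjustment when an axial length is given), crop the FAZ-centred
#' analysis disc and mask out the FAZ, enhance vessels with the multiscale
#' Hessian filter, binarize with Phansalkar local thresholding inside the
#' effective region, then compute vessel density, skeletonize, vessel
#' length density and box-counting fractal dimension.
#'
#' @param image an [enface_angiogram()] or a path readable by
#'   [load_enface_image()].
#' @param faz_polygon two-column `(x, y)` vertex matrix or a path readable
#'   by [read_faz_polygon()].
#' @param eye_id identifier carried into the output record.
#' @param group optional group label carried into the output record.
#' @param axial_length_mm optional axial length in mm.
#' @param config an [octa_config()].
#' @return object of class `octa_eye_record`: a list with the one-row
#'   data.frame `record`, plus the intermediate `faz`, `region`,
#'   `vesselness`, `vessel_mask` and `metrics` objects.
#' @export
run_octa_eye <- function(image, faz_polygon, eye_id = "eye", group = NA,
                         axial_length_mm = NULL, config = octa_config()) {
  stopifnot(inherits(config, "octa_config"))
  if (is.character(image)) image <- load_enface_image(image)
  stopifnot(inherits(image, "enface_angiogram"))
  if (is.character(faz_polygon)) faz_polygon <- read_faz_polygon(faz_polygon)

  faz <- delineate_faz(image, faz_polygon, axial_length_mm = axial_length_mm,
                       reference_al_mm = config$reference_al_mm)
  region <- crop_analysis_disc(image, faz$centroid_px,
                               diameter_mm = config$disc_diameter_mm,
                               exclude = if (config$denominator == "disc_minus_faz")
                                 faz$mask else NULL)
  v <- frangi_vesselness(image$pixels, config$vesselness)
  if (config$apply_inversion) v <- invert_vesselness(v)
  fg <- if (config$apply_inversion) 1 - v else v  # binarize high-vesselness
  vessel_mask <- phansalkar_threshold(fg, config$threshold,
                                      region = region$effective_mask)
  vd <- vessel_density(vessel_mask, region)
  skel <- skeletonize(vessel_mask)
  vld <- vessel_length_density(skel, region)
  fd <- box_counting_fd(skel & region$effective_mask,
                        box_sizes = config$fd_box_sizes)
  record <- data.frame(
    eye_id = eye_id, group = group,
    axial_length_mm = if (is.null(axial_length_mm)) NA_real_ else axial_length_mm,
    faz_area_mm2 = faz$area_mm2, faz_perimeter_mm = faz$perimeter_mm,
    faz_circularity = faz$circularity,
    faz_area_adj_mm2 = if (is.null(faz$area_adj_mm2)) NA_real_ else faz$area_adj_mm2,
    faz_perimeter_adj_mm = if (is.null(faz$perimeter_adj_mm)) NA_real_ else faz$perimeter_adj_mm,
    vessel_density = vd, vessel_length_density = vld,
    fractal_dimension = fd$slope, fd_r_squared = fd$r_squared,
    effective_area_px = region$effective_area_px,
    clipped_fraction = region$clipped_fraction,
    faz_multi_component = faz$multi_component,
    stringsAsFactors = FALSE)
  structure(list(record = record, faz = faz, region = region,
                 vesselness = v, vessel_mask = vessel_mask,
                 skeleton = skel, fd_fit = fd, config = config),
            class = "octa_eye_record")
}

#' @export
print.octa_eye_record <- function(x, ...) {
  r <- x$record
  cat(sprintf("OCTA eye record '%s':\n", r$eye_id))
  cat(sprintf("  FAZ: area %.4f mm^2, perimeter %.4f mm, circularity %.4f\n",
              r$faz_area_mm2, r$faz_perimeter_mm, r$faz_circularity))
  cat(sprintf("  VD %.4f, VLD %.4f, FD %.4f (effective area %d px)\n",
              r$vessel_density, r$vessel_length_density,
              r$fractal_dimension, r$effective_area_px))
  invisible(x)
}

#' Batch per-eye OCTA analysis from a manifest
#'
#' The manifest has one row per eye with columns `eye_id`, `image`,
#' `polygon` (file paths) and optionally `group` and `axial_length_mm`.
#' Failing eyes are quarantined (recorded with the error message) and do
#' not stop the batch.
#'
#' @param manifest data frame or CSV path.
#' @param config an [octa_config()].
#' @return list with `records` (row-bound per-eye records) and `failures`
#'   (data frame of eye_id + message).
#' @export
run_octa_batch <- function(manifest, config = octa_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("eye_id", "image", "polygon")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  recs <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(
      run_octa_eye(row$image, row$polygon, eye_id = row$eye_id,
                   group = if ("group" %in% names(row)) row$group else NA,
                   axial_length_mm = if ("axial_length_mm" %in% names(row))
                     row$axial_length_mm else NULL,
                   config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        eye_id = row$eye_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- res$record
    }
  }
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(eye_id = character(0), message = character(0)))
}

# The 11 vascular parameters compared across groups, plus visual acuity.
default_comparison_parameters <- function() {
  c("faz_area_mm2", "faz_perimeter_mm", "faz_circularity",
    "scp_density_pct", "vl_density_pct", "fd",
    "tvd_um", "ld_um", "wt_um", "wlr", "wcsa_um2", "bcva")
}

#' Cohort statistics over a per-eye metrics table
#'
#' Runs the normality-gated omnibus + post hoc comparison
#' ([run_full_comparison()]) over the standard 11 vascular parameters plus
#' best-corrected visual acuity (or any subset present in the table).
#'
#' @param table per-eye data frame with a `group` column (e.g. from
#'   [generate_cohort()] or [run_octa_batch()]).
#' @param parameters metric columns to test; defaults to the standard set,
#'   restricted to columns present.
#' @param config an [octa_config()] (supplies `alpha` and the Dunn
#'   adjustment).
#' @return a `cohort_comparison` object.
#' @export
run_cohort <- function(table, parameters = NULL, config = octa_config()) {
  if (is.null(parameters))
    parameters <- intersect(default_comparison_parameters(), names(table))
  if (length(unique(table$group)) < 2L) stop("need at least 2 groups")
  run_full_comparison(table, parameters, alpha = config$alpha,
                      dunn_adjust = config$dunn_adjust)
}
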