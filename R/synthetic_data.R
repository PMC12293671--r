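#' Vascular phantom specification
#'
#' Parameters of the synthetic en-face angiogram generator.  Defaults
#' emulate the nominal acquisition this package targets: a 4.5 mm field
#' sampled at 320 px (14.06 um/px), a central avascular zone whose mean
#' radius (0.268 mm) matches a healthy FAZ area of about 0.226 mm^2, mean
#' capillary caliber 3 px (~42 um rendered ribbon) and a vessel-pixel
#' coverage of 35% of the 3-mm analysis disc, the scale reported for
#' healthy superficial-plexus density.
#'
#' @param seed integer seed fixing the full output.
#' @param frame_px square frame side in px.
#' @param extent_mm physical field side in mm.
#' @param faz_radius_mm mean radius of the avascular zone.
#' @param faz_irregularity RMS relative amplitude of the radial Fourier
#'   perturbation of the FAZ boundary (0 = circle).
#' @param n_seed_vessels number of initial vessels entering from the frame
#'   edges.
#' @param branching_prob per-step probability that a walker spawns a branch.
#' @param vessel_width_px mean rendered vessel caliber in px.
#' @param target_density vessel coverage fraction of the disc-minus-FAZ
#'   region at which growth stops (+/- 0.01); must be <= 0.85.
#' @param noise_sigma additive Gaussian intensity noise SD.
#' @param dropout_fraction fraction of vessel segments deleted after growth
#'   (severity knob; 0 = none).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, frame_px = 320L, extent_mm = 4.5,
                         faz_radius_mm = 0.268, faz_irregularity = 0.05,
                         n_seed_vessels = 16L, branching_prob = 0.06,
                         vessel_width_px = 3, target_density = 0.35,
                         noise_sigma = 0.05, dropout_fraction = 0) {
  stopifnot(frame_px >= 64, extent_mm > 0, faz_radius_mm > 0,
            faz_irregularity >= 0, n_seed_vessels >= 1,
            branching_prob >= 0, branching_prob <= 1,
            vessel_width_px >= 1,
            target_density > 0, noise_sigma >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1)
  if (target_density > 0.85)
    stop("target_density > 0.85 is not reachable by the growth model")
  structure(as.list(environment()), class = "phantom_spec")
}

# Radial-Fourier FAZ outline: r(theta) = R0 (1 + sum a_k cos(k theta + phi_k)),
# harmonics 3..8, RMS relative amplitude = irregularity.
generate_faz_polygon <- function(centre_px, radius_px, irregularity,
                                 n_vertices = 180L, harmonics = 3:8) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  pert <- rep(0, n_vertices)
  if (irregularity > 0) {
    a <- rnorm(length(harmonics))
    phi <- runif(length(harmonics), 0, 2 * pi)
    a <- a * irregularity / sqrt(sum(a^2) / 2)  # RMS of sum(a_k cos) = irregularity
    for (i in seq_along(harmonics))
      pert <- pert + a[i] * cos(harmonics[i] * theta + phi[i])
  }
  r <- radius_px * pmax(0.05, 1 + pert)
  cbind(x = centre_px[1] + r * cos(theta), y = centre_px[2] + r * sin(theta))
}

# Shoelace area of a closed polygon (continuous units).
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Stamp a dilated stroke of the given width around skeleton path pixels.
stamp_offsets <- function(width_px) {
  r <- width_px / 2
  ri <- floor(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

render_segments <- function(segments, frame, width_px, faz_mask) {
  skel <- matrix(FALSE, frame, frame)
  render <- matrix(FALSE, frame, frame)
  off <- stamp_offsets(width_px)
  for (seg in segments) {
    if (nrow(seg) == 0L) next
    skel[seg] <- TRUE
    for (i in seq_len(nrow(off))) {
      r <- seg[, 1] + off$dr[i]; c2 <- seg[, 2] + off$dc[i]
      ok <- r >= 1L & r <= frame & c2 >= 1L & c2 <= frame
      render[cbind(r[ok], c2[ok])] <- TRUE
    }
  }
  skel[faz_mask] <- FALSE
  render[faz_mask] <- FALSE
  list(skeleton = skel, vessel_mask = render)
}

render_intensity <- function(vessel_mask, noise_sigma, blur_sigma = 0.8) {
  img <- matrix(0, nrow(vessel_mask), ncol(vessel_mask))
  img[vessel_mask] <- 1
  img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma)),
                nrow(vessel_mask), ncol(vessel_mask))
  if (noise_sigma > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sigma),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic vascular angiogram phantom with ground truth
#'
#' Seed vessels enter from the frame edges and random-walk with momentum;
#' walkers branch with the configured probability and never enter the
#' avascular-zone polygon.  Strokes are dilated to the mean caliber and
#' growth stops once vessel coverage of the disc-minus-FAZ analysis region
#' reaches `target_density` (within +/- 0.01).  The intensity image is the
#' blurred vessel mask plus additive Gaussian noise clipped to `[0, 1]`;
#' truth masks are returned pre-noise.  The same seed reproduces the
#' output bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `vascular_phantom` with elements `image` (an
#'   [enface_angiogram()]), `truth` (vessel/skeleton/FAZ masks, effective
#'   region, `true_density`, analytic FAZ area) and `spec`.
#' @export
generate_vascular_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  frame <- spec$frame_px
  pitch <- spec$extent_mm / frame
  centre <- c(frame / 2, frame / 2)
  poly <- generate_faz_polygon(centre, spec$faz_radius_mm / pitch,
                               spec$faz_irregularity)
  faz_mask <- rasterize_polygon(poly, c(frame, frame))
  disc_r <- min(1.5 / pitch, frame / 2 - 1)  # 3 mm disc, clipped to frame
  cx <- matrix(rep(seq_len(frame) - 0.5, each = frame), frame, frame)
  cy <- matrix(rep(seq_len(frame) - 0.5, times = frame), frame, frame)
  ctr <- compute_centroid(faz_mask)
  eff <- ((cx - ctr[1])^2 + (cy - ctr[2])^2 <= disc_r^2) & !faz_mask
  eff_n <- sum(eff)

  segments <- grow_vessels(spec, frame, faz_mask, eff, eff_n)
  if (spec$dropout_fraction > 0) {
    ndel <- round(spec$dropout_fraction * length(segments))
    if (ndel > 0) segments <- segments[-sample(length(segments), ndel)]
  }
  finish_phantom(segments, spec, faz_mask, poly, eff)
}

# Space-filling branching growth; returns a list of (row, col) path matrices.
grow_vessels <- function(spec, frame, faz_mask, eff, eff_n) {
  off <- stamp_offsets(spec$vessel_width_px)
  render <- matrix(FALSE, frame, frame)
  skel_px <- matrix(integer(0), 0L, 2L)
  segments <- list()
  max_len <- 120L
  target_lo <- spec$target_density - 0.005
  budget <- 60000L + 600L * frame  # total step budget before giving up
  steps_used <- 0L

  new_edge_walker <- function() {
    side <- sample.int(4L, 1L)
    pos <- runif(1, 0.1, 0.9) * frame
    switch(side,
           c(pos, 1, pi / 2), c(pos, frame - 1, -pi / 2),
           c(1, pos, 0), c(frame - 1, pos, pi))[c(1, 2, 3)]
  }
  queue <- lapply(seq_len(spec$n_seed_vessels), function(i) new_edge_walker())
  coverage <- 0
  repeat {
    if (coverage >= target_lo) break
    if (steps_used > budget)
      stop("target density unreachable with the given growth parameters")
    if (length(queue) == 0L) {
      if (nrow(skel_px) > 0L && runif(1) < 0.7) {
        p <- skel_px[sample.int(nrow(skel_px), 1L), ]
        queue <- list(c(p[2] - 0.5, p[1] - 0.5, runif(1, 0, 2 * pi)))
      } else {
        queue <- list(new_edge_walker())
      }
    }
    w <- queue[[1]]; queue <- queue[-1]
    x <- w[1]; y <- w[2]; ang <- w[3]
    path_r <- integer(0); path_c <- integer(0)
    for (s in seq_len(max_len)) {
      steps_used <- steps_used + 1L
      ang <- ang + rnorm(1, 0, 0.2)
      x <- x + cos(ang); y <- y + sin(ang)
      r <- floor(y) + 1L; c2 <- floor(x) + 1L
      if (r < 1L || r > frame || c2 < 1L || c2 > frame) break
      if (faz_mask[r, c2]) break
      if (length(path_r) == 0L || r != path_r[length(path_r)] ||
          c2 != path_c[length(path_c)]) {
        path_r <- c(path_r, r); path_c <- c(path_c, c2)
      }
      if (runif(1) < spec$branching_prob && length(queue) < 64L) {
        queue <- c(queue, list(c(x, y, ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.2))))
      }
    }
    if (length(path_r) == 0L) next
    seg <- cbind(path_r, path_c)
    segments[[length(segments) + 1L]] <- seg
    skel_px <- rbind(skel_px, seg)
    for (i in seq_len(nrow(off))) {
      rr <- seg[, 1] + off$dr[i]; cc <- seg[, 2] + off$dc[i]
      ok <- rr >= 1L & rr <= frame & cc >= 1L & cc <= frame
      render[cbind(rr[ok], cc[ok])] <- TRUE
    }
    coverage <- sum(render & eff) / eff_n
  }
  segments
}

finish_phantom <- function(segments, spec, faz_mask, poly, eff) {
  frame <- spec$frame_px
  masks <- render_segments(segments, frame, spec$vessel_width_px, faz_mask)
  truth <- structure(
    list(vessel_mask = masks$vessel_mask,
         true_skeleton = masks$skeleton,
         faz_mask = faz_mask,
         faz_polygon = poly,
         faz_area_analytic_px2 = polygon_area(poly),
         effective_mask = eff,
         true_density = sum(masks$vessel_mask & eff) / sum(eff),
         segments = segments),
    class = "phantom_truth")
  img <- render_intensity(masks$vessel_mask, spec$noise_sigma)
  structure(list(image = enface_angiogram(img, extent_mm = spec$extent_mm),
                 truth = truth, spec = spec),
            class = "vascular_phantom")
}

#' @export
print.vascular_phantom <- function(x, ...) {
  cat(sprintf("Vascular phantom (seed %d): %d x %d px, %d segments, true density %.3f\n",
              x$spec$seed, x$spec$frame_px, x$spec$frame_px,
              length(x$truth$segments), x$truth$true_density))
  invisible(x)
}

#' Degrade a phantom: capillary dropout and FAZ irregularity
#'
#' Deletes a seeded random subset of vessel segments (and their dilated
#' pixels) and optionally perturbs the avascular-zone boundary with
#' higher-amplitude radial noise, emulating the capillary dropout and FAZ
#' irregularity of worsening retinopathy.  The intensity image and truth
#' masks are re-rendered.
#'
#' @param phantom a `vascular_phantom` from [generate_vascular_phantom()].
#' @param dropout_fraction fraction of segments to delete in `[0, 1]`.
#' @param irregularity_boost added to the spec's FAZ irregularity before
#'   regenerating the boundary (0 keeps the original FAZ).
#' @param seed seed for the deletion / boundary draw.
#' @return a new `vascular_phantom`.
#' @export
degrade_phantom <- function(phantom, dropout_fraction, irregularity_boost = 0,
                            seed = 1L) {
  stopifnot(inherits(phantom, "vascular_phantom"),
            dropout_fraction >= 0, dropout_fraction <= 1,
            irregularity_boost >= 0)
  spec <- phantom$spec
  set.seed(seed)
  segments <- phantom$truth$segments
  if (dropout_fraction > 0 && length(segments) > 0L) {
    ndel <- round(dropout_fraction * length(segments))
    if (ndel > 0) segments <- segments[-sample(length(segments), ndel)]
  }
  faz_mask <- phantom$truth$faz_mask
  poly <- phantom$truth$faz_polygon
  eff <- phantom$truth$effective_mask
  if (irregularity_boost > 0) {
    frame <- spec$frame_px
    pitch <- spec$extent_mm / frame
    centre <- c(frame / 2, frame / 2)
    poly <- generate_faz_polygon(centre, spec$faz_radius_mm / pitch,
                                 spec$faz_irregularity + irregularity_boost)
    faz_mask <- rasterize_polygon(poly, c(frame, frame))
    disc_r <- min(1.5 / pitch, frame / 2 - 1)
    cx <- matrix(rep(seq_len(frame) - 0.5, each = frame), frame, frame)
    cy <- matrix(rep(seq_len(frame) - 0.5, times = frame), frame, frame)
    ctr <- compute_centroid(faz_mask)
    eff <- ((cx - ctr[1])^2 + (cy - ctr[2])^2 <= disc_r^2) & !faz_mask
  }
  finish_phantom(segments, spec, faz_mask, poly, eff)
}

# ---- synthetic cohorts ------------------------------------------------------

# Per-group means and SDs of the per-eye metrics the generator draws from,
# with domain truncation bounds.  Group order: control, no_DR, NPDR, PDR.
default_cohort_metrics <- function() {
  m <- function(means, sds, lower = -Inf, upper = Inf)
    list(mean = means, sd = sds, lower = lower, upper = upper)
  list(
    faz_area_mm2     = m(c(0.226, 0.214, 0.248, 0.248), c(0.100, 0.060, 0.084, 0.087), 0.01),
    faz_perimeter_mm = m(c(1.774, 1.772, 1.933, 1.958), c(0.446, 0.293, 0.354, 0.378), 0.1),
    faz_circularity  = m(c(0.853, 0.845, 0.816, 0.792), c(0.028, 0.054, 0.062, 0.081), 0, 1),
    scp_density_pct  = m(c(37.693, 38.274, 35.685, 34.338), c(1.950, 3.799, 3.455, 3.670), 0, 100),
    vl_density_pct   = m(c(29.385, 29.586, 27.049, 25.971), c(1.711, 3.020, 2.837, 2.992), 0, 100),
    fd               = m(c(1.771, 1.770, 1.753, 1.745), c(0.009, 0.013, 0.018, 0.018), 1, 2),
    ld_um            = m(c(81.085, 68.542, 73.820, 60.787), c(16.323, 12.510, 25.796, 17.906), 20),
    wlr              = m(c(0.237, 0.305, 0.320, 0.390), c(0.048, 0.054, 0.080, 0.090), 0.02),
    axial_length_mm  = m(c(23.68, 23.89, 23.34, 23.42), c(1.00, 0.79, 0.38, 0.74), 15, 35),
    bcva             = m(c(0.976, 0.921, 0.916, 0.685), c(0.007, 0.142, 0.133, 0.271), 0.05, 1)
  )
}

#' Cohort generator specification
#'
#' Group sizes and per-group metric distributions of the synthetic cohort.
#' Defaults reproduce the four study groups (17 control, 14 diabetic
#' without retinopathy, 18 NPDR, 20 PDR eyes; 69 in total) with each
#' metric drawn from a truncated Gaussian at the group's reported mean and
#' SD.  Lumen diameter and wall-to-lumen ratio are the independently drawn
#' AO quantities; TVD, WT and WCSA are derived from them so that the wall
#' identities hold exactly per eye.
#'
#' @param group_sizes named integer vector (order: control, no_DR, NPDR,
#'   PDR).
#' @param metrics per-metric list of per-group `mean`/`sd` plus truncation
#'   bounds; see `default_cohort_metrics` in the package source.
#' @param roi_jitter_sd SD (um) of the centred across-ROI jitter applied to
#'   per-eye diameters when emitting the ROI triplet table.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(control = 17L, no_DR = 14L,
                                        NPDR = 18L, PDR = 20L),
                        metrics = default_cohort_metrics(),
                        roi_jitter_sd = 2, seed = 1L) {
  stopifnot(all(group_sizes > 0), roi_jitter_sd >= 0)
  for (nm in names(metrics)) {
    met <- metrics[[nm]]
    if (any(met$sd < 0)) stop("negative SD for metric ", nm)
    if (length(met$mean) != length(group_sizes) ||
        length(met$sd) != length(group_sizes))
      stop("metric ", nm, " needs one mean and sd per group")
  }
  structure(list(group_sizes = group_sizes, metrics = metrics,
                 roi_jitter_sd = roi_jitter_sd, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic per-eye cohort table
#'
#' Draws one row per eye: group label, axial length, BCVA, the OCTA
#' metrics, and the AO wall metrics (TVD/WT/WCSA derived from the drawn
#' lumen diameter and wall-to-lumen ratio).  A per-ROI AO measurement
#' table whose ROI means reproduce the per-eye diameters exactly is
#' attached as `attr(x, "ao_rois")`.  Fully deterministic for a given
#' spec.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `sum(group_sizes)` rows.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- names(spec$group_sizes)
  rows <- list()
  roi_rows <- list()
  for (gi in seq_along(groups)) {
    n <- spec$group_sizes[[gi]]
    g <- groups[gi]
    draws <- lapply(spec$metrics, function(met)
      rtrunc_norm(n, met$mean[gi], met$sd[gi], met$lower, met$upper))
    ld <- draws$ld_um
    wlr <- draws$wlr
    tvd <- ld * (1 + wlr)
    wt <- (tvd - ld) / 2
    wcsa <- (pi / 4) * (tvd^2 - ld^2)
    eye_id <- sprintf("%s_%02d", g, seq_len(n))
    rows[[gi]] <- data.frame(
      eye_id = eye_id, group = g,
      laterality = sample(c("right", "left"), n, replace = TRUE),
      axial_length_mm = draws$axial_length_mm, bcva = draws$bcva,
      faz_area_mm2 = draws$faz_area_mm2,
      faz_perimeter_mm = draws$faz_perimeter_mm,
      faz_circularity = draws$faz_circularity,
      scp_density_pct = draws$scp_density_pct,
      vl_density_pct = draws$vl_density_pct,
      fd = draws$fd,
      tvd_um = tvd, ld_um = ld, wt_um = wt, wlr = wlr, wcsa_um2 = wcsa,
      stringsAsFactors = FALSE)
    # ROI triplets with centred jitter: ROI means equal the per-eye values
    for (i in seq_len(n)) {
      jt <- rnorm(3, 0, spec$roi_jitter_sd); jt <- jt - mean(jt)
      jl <- rnorm(3, 0, spec$roi_jitter_sd); jl <- jl - mean(jl)
      tvd_i <- tvd[i] + jt; ld_i <- ld[i] + jl
      while (any(tvd_i <= ld_i) || any(ld_i <= 0)) {
        jt <- jt / 2; jl <- jl / 2
        tvd_i <- tvd[i] + jt; ld_i <- ld[i] + jl
      }
      roi_rows[[length(roi_rows) + 1L]] <- data.frame(
        eye_id = eye_id[i], roi_index = 1:3,
        tvd_um = tvd_i, ld_um = ld_i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ao_rois") <- do.call(rbind, roi_rows)
  out
}
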