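#' Lumen area profile along a centerline
#'
#' Per-centerline-point lumen areas with their z-score normalisation
#' `z = (A - mu) / sigma`. The z-score removes systematic size offsets
#' between models (printing shrinkage, imaging scale), leaving profile
#' shape. `sigma` uses the population convention (divide by N) by default.
#'
#' @param areas numeric areas (mm^2), `NA` for centerline points without a
#'   section.
#' @param centerline_indices integer indices the areas belong to.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return object of class `area_profile` with fields `centerline_indices`,
#'   `areas`, `mu`, `sigma`, `zscores`.
#' @export
area_profile <- function(areas, centerline_indices = seq_along(areas),
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(areas) == length(centerline_indices))
  ok <- !is.na(areas)
  mu <- mean(areas[ok])
  n <- sum(ok)
  sigma <- if (sd_type == "population") {
    sqrt(sum((areas[ok] - mu)^2) / n)
  } else stats::sd(areas[ok])
  z <- if (sigma > 0) (areas - mu) / sigma else rep(NA_real_, length(areas))
  structure(list(centerline_indices = as.integer(centerline_indices),
                 areas = areas, mu = mu, sigma = sigma, zscores = z),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf(
    "<area_profile> %d stations (%d missing), area %.2f +/- %.2f mm^2\n",
    length(x$areas), sum(is.na(x$areas)), x$mu, x$sigma))
  invisible(x)
}

#' @export
plot.area_profile <- function(x, y = NULL, zscore = FALSE, ...) {
  vals <- if (zscore) x$zscores else x$areas
  graphics::plot(x$centerline_indices, vals, type = "l",
                 xlab = "centerline index",
                 ylab = if (zscore) "z-score" else "lumen area [mm^2]", ...)
  invisible(x)
}

#' Percent area stenosis
#'
#' `%AS = (RVA - MLA) / RVA * 100` with the reference vessel area (RVA)
#' taken proximal to the minimum lumen area (MLA) in a healthier segment.
#'
#' @param rva reference vessel area (mm^2, > 0).
#' @param mla minimum lumen area (mm^2, `0 <= mla <= rva`).
#' @return stenosis severity in percent.
#' @examples
#' pct_area_stenosis(10, 2)  # 80
#' @export
pct_area_stenosis <- function(rva, mla) {
  if (!is.finite(rva) || rva <= 0) {
    stop("pct_area_stenosis: RVA must be positive", call. = FALSE)
  }
  if (!is.finite(mla) || mla < 0) {
    stop("pct_area_stenosis: MLA must be non-negative", call. = FALSE)
  }
  if (mla > rva) {
    stop("pct_area_stenosis: MLA exceeds RVA; the reference must be the larger healthier area",
         call. = FALSE)
  }
  (rva - mla) / rva * 100
}

#' Stenosis metrics from an area profile
#'
#' MLA is the minimum area within the search window; RVA automates the
#' "healthier proximal segment" choice as the maximum of a moving-median
#' smoothed area over the stations proximal to the MLA. The profile runs
#' proximal to distal.
#'
#' @param profile an [area_profile] (>= 5 stations).
#' @param search_window optional index range (positions in the profile) to
#'   search for the MLA.
#' @param median_window moving-median width for the RVA (default 5).
#' @return object of class `stenosis_metrics`: `RVA`, `MLA`, `pct_AS`,
#'   `mla_index`, `rva_index` (profile positions).
#' @export
stenosis_from_profile <- function(profile, search_window = NULL,
                                  median_window = 5L) {
  stopifnot(inherits(profile, "area_profile"))
  a <- profile$areas
  if (sum(!is.na(a)) < 5L) {
    stop("stenosis_from_profile: need at least 5 profile points",
         call. = FALSE)
  }
  idx <- seq_along(a)
  if (!is.null(search_window)) {
    idx <- idx[idx >= search_window[1L] & idx <= search_window[2L]]
  }
  cand <- idx[!is.na(a[idx])]
  # ties (e.g. flat healthy profiles) resolve to the most distal minimum so
  # a proximal reference segment exists
  amin <- min(a[cand])
  mla_i <- max(cand[a[cand] <= amin + 1e-12])
  prox <- which(seq_along(a) < mla_i & !is.na(a))
  if (length(prox) == 0L) {
    stop("stenosis_from_profile: MLA at the proximal boundary; no reference segment",
         call. = FALSE)
  }
  ap <- a[prox]
  k <- min(median_window, length(ap))
  if (k %% 2L == 0L) k <- k - 1L
  sm <- if (k >= 3L) stats::runmed(ap, k, endrule = "median") else ap
  rva_i <- prox[which.max(sm)]
  rva <- max(sm)
  mla <- a[mla_i]
  if (mla > rva) mla <- rva  # flat profiles: smoothing can dip below min
  structure(list(RVA = rva, MLA = mla,
                 pct_AS = pct_area_stenosis(rva, mla),
                 mla_index = mla_i, rva_index = rva_i),
            class = "stenosis_metrics")
}

#' @export
print.stenosis_metrics <- function(x, ...) {
  cat(sprintf(
    "<stenosis_metrics> MLA %.2f mm^2 @%d, RVA %.2f mm^2 @%d, %.1f %%AS\n",
    x$MLA, x$mla_index, x$RVA, x$rva_index, x$pct_AS))
  invisible(x)
}

#' Lumen area profile of a mesh along a centerline
#'
#' Sections the model with the plane perpendicular to the centerline at
#' every centerline point; the lumen at a station is the section component
#' nearest to the centerline point (guarding against side-branch cuts).
#' Stations without an intersection are `NA`.
#'
#' @param mesh a [surface_mesh] (lumen surface).
#' @param cl a [centerline] (resampled as desired).
#' @param sd_type passed to [area_profile].
#' @return an [area_profile] over all centerline indices.
#' @export
lumen_area_profile <- function(mesh, cl, sd_type = "population") {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cl, "centerline"))
  n <- nrow(cl$points)
  areas <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- plane(cl$points[i, ], cl$frames$tangent[i, ])
    secs <- plane_mesh_section(mesh, p)
    if (length(secs) == 0L) next
    cents <- attr(secs, "centroids3d")
    d <- vapply(cents, function(cc) sum((cc - cl$points[i, ])^2), numeric(1))
    areas[i] <- polygon_area(secs[[which.min(d)]])
  }
  if (sum(!is.na(areas)) < 5L) {
    stop("lumen_area_profile: fewer than 5 valid sections", call. = FALSE)
  }
  area_profile(areas, seq_len(n), sd_type = sd_type)
}

#' Validation configuration
#'
#' @param vd_exclusion_mm vertex distances strictly below this are excluded
#'   from the vertex-distance statistics (default 0.05 mm), avoiding bias
#'   from negligible meshing differences.
#' @return object of class `validation_config`.
#' @export
validation_config <- function(vd_exclusion_mm = 0.05) {
  if (vd_exclusion_mm < 0) {
    stop("validation_config: exclusion must be >= 0", call. = FALSE)
  }
  structure(list(vd_exclusion_mm = vd_exclusion_mm),
            class = "validation_config")
}

#' Vertex-distance statistics between two models
#'
#' For every vertex of the derivative model (DM) the distance to the nearest
#' point on the original model (OM) surface is computed (point-to-surface,
#' not vertex-to-vertex; set `symmetric` for the two-directional pooled
#' variant). Distances strictly below the exclusion threshold are dropped
#' from the median/IQR; the full per-vertex list is retained for heatmap
#' export. When every distance is excluded the comparison is flagged
#' degenerate and the statistics are `NA`.
#'
#' @param dm,om [surface_mesh] objects (derivative and original model).
#' @param cfg a [validation_config].
#' @param symmetric also measure OM vertices against the DM surface and pool.
#' @return list with `median`, `iqr` (Q1, Q3), `n_used`, `degenerate`,
#'   `distances` (per-vertex, unfiltered).
#' @export
vertex_distance_stats <- function(dm, om, cfg = validation_config(),
                                  symmetric = FALSE) {
  stopifnot(inherits(dm, "surface_mesh"), inherits(om, "surface_mesh"))
  if (nrow(dm$vertices) == 0L || nrow(om$vertices) == 0L) {
    stop("vertex_distance_stats: empty mesh", call. = FALSE)
  }
  d <- point_mesh_distance(dm$vertices, om)
  if (symmetric) d <- c(d, point_mesh_distance(om$vertices, dm))
  keep <- d >= cfg$vd_exclusion_mm
  if (!any(keep)) {
    return(list(median = NA_real_, iqr = c(NA_real_, NA_real_),
                n_used = 0L, degenerate = TRUE, distances = d))
  }
  qs <- stats::quantile(d[keep], c(0.25, 0.5, 0.75), names = FALSE)
  list(median = qs[2L], iqr = c(qs[1L], qs[3L]), n_used = sum(keep),
       degenerate = FALSE, distances = d)
}

#' Export per-vertex distances as a heatmap-ready PLY
#'
#' Writes the DM with per-vertex `quality` set to the vertex distance, the
#' usual exchange format for distance heatmaps.
#'
#' @param dm a [surface_mesh].
#' @param distances per-vertex distances (from [vertex_distance_stats]).
#' @param path output PLY path.
#' @export
write_distance_heatmap <- function(dm, distances, path) {
  stopifnot(length(distances) >= nrow(dm$vertices))
  write_ply_mesh(dm, path,
                 vertex_quality = distances[seq_len(nrow(dm$vertices))])
  invisible(path)
}

#' Area-difference and z-score comparison of two profiles
#'
#' Pairs the profiles on shared centerline indices (stations missing in
#' either are dropped), reports the absolute area difference
#' `|A_om - A_dm|` (median, IQR) and the per-station absolute z-score
#' difference (mean, sd). The z comparison is invariant to shifts and
#' positive rescalings of either profile.
#'
#' @param om_profile,dm_profile [area_profile]s on the same resampled
#'   centerline.
#' @return list with `ad_median`, `ad_iqr`, `zdiff_mean`, `zdiff_sd`,
#'   `n_pairs`, plus the paired vectors.
#' @export
area_difference_stats <- function(om_profile, dm_profile) {
  stopifnot(inherits(om_profile, "area_profile"),
            inherits(dm_profile, "area_profile"))
  shared <- intersect(om_profile$centerline_indices[!is.na(om_profile$areas)],
                      dm_profile$centerline_indices[!is.na(dm_profile$areas)])
  if (length(shared) < 5L) {
    stop("area_difference_stats: fewer than 5 shared stations",
         call. = FALSE)
  }
  io <- match(shared, om_profile$centerline_indices)
  id <- match(shared, dm_profile$centerline_indices)
  # re-normalise z over the paired stations so both profiles are compared on
  # the same support
  zo <- scale_z(om_profile$areas[io])
  zd <- scale_z(dm_profile$areas[id])
  ad <- abs(om_profile$areas[io] - dm_profile$areas[id])
  zdiff <- abs(zo - zd)
  qs <- stats::quantile(ad, c(0.25, 0.5, 0.75), names = FALSE)
  list(ad_median = qs[2L], ad_iqr = c(qs[1L], qs[3L]),
       zdiff_mean = mean(zdiff), zdiff_sd = stats::sd(zdiff),
       n_pairs = length(shared), ad = ad, zdiff = zdiff,
       z_om = zo, z_dm = zd)
}

scale_z <- function(a) {
  mu <- mean(a)
  sigma <- sqrt(mean((a - mu)^2))
  if (sigma == 0) rep(0, length(a)) else (a - mu) / sigma
}

#' Ordinary least-squares slope, intercept and R-squared
#'
#' @param x,y paired numeric vectors (>= 3 pairs, x not constant).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
regression_slope_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("regression_slope_r2: need at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("regression_slope_r2: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = unname(stats::cor(x, y)^2))
}

#' Along-pullback distance between two frames
#'
#' Side-branch separation as measured on the pullback: frame index
#' difference times the physical frame spacing, rounded to the millimetre
#' for report parity.
#'
#' @param series a [pullback_series] or a registered stack (for the frame
#'   spacing and index range).
#' @param frame_i,frame_j distinct frame indices present in the series.
#' @return distance in mm (integer-rounded).
#' @export
side_branch_distance <- function(series, frame_i, frame_j) {
  fidx <- series$frame_indices
  spacing <- series$calibration$frame_spacing_mm
  if (!(frame_i %in% fidx) || !(frame_j %in% fidx)) {
    stop("side_branch_distance: frame index out of range", call. = FALSE)
  }
  if (frame_i == frame_j) {
    stop("side_branch_distance: the two frames must differ", call. = FALSE)
  }
  round(abs(frame_i - frame_j) * spacing)
}

#' Full model-versus-model validation report
#'
#' Combines vertex-distance statistics, area-difference and z-score profile
#' comparison, per-model stenosis metrics and the z-score regression into
#' one report object.
#'
#' @param om,dm original / derivative [surface_mesh] models.
#' @param cl shared [centerline].
#' @param cfg a [validation_config].
#' @param spacing_mm centerline resampling used for the area profiles.
#' @return a validation report object (see [validate_models()]).
#' @export
validate_models <- function(om, dm, cl, cfg = validation_config(),
                            spacing_mm = 0.5) {
  clr <- resample_centerline(cl, spacing_mm)
  vd <- vertex_distance_stats(dm, om, cfg)
  om_prof <- lumen_area_profile(om, clr)
  dm_prof <- lumen_area_profile(dm, clr)
  ad <- area_difference_stats(om_prof, dm_prof)
  reg <- regression_slope_r2(ad$z_om, ad$z_dm)
  sten_om <- tryCatch(stenosis_from_profile(om_prof), error = function(e) NULL)
  sten_dm <- tryCatch(stenosis_from_profile(dm_prof), error = function(e) NULL)
  structure(list(vd_median = vd$median, vd_iqr = vd$iqr,
                 vd_degenerate = vd$degenerate,
                 per_vertex_distances = vd$distances,
                 ad_median = ad$ad_median, ad_iqr = ad$ad_iqr,
                 zdiff_mean = ad$zdiff_mean, zdiff_sd = ad$zdiff_sd,
                 r_squared = reg$r_squared, slope = reg$slope,
                 stenosis_om = sten_om, stenosis_dm = sten_dm,
                 om_profile = om_prof, dm_profile = dm_prof),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (x$vd_degenerate) {
    cat("  VD: degenerate (all distances below exclusion)\n")
  } else {
    cat(sprintf("  VD median %.3f (%.3f-%.3f) mm\n", x$vd_median,
                x$vd_iqr[1L], x$vd_iqr[2L]))
  }
  cat(sprintf("  AD median %.3f (%.3f-%.3f) mm^2\n", x$ad_median,
              x$ad_iqr[1L], x$ad_iqr[2L]))
  cat(sprintf("  z-diff %.3f +/- %.3f, z regression R^2 %.3f\n",
              x$zdiff_mean, x$zdiff_sd, x$r_squared))
  if (!is.null(x$stenosis_om) && !is.null(x$stenosis_dm)) {
    cat(sprintf("  %%AS OM %.1f vs DM %.1f\n",
                x$stenosis_om$pct_AS, x$stenosis_dm$pct_AS))
  }
  invisible(x)
}

#' Write a validation report as CSV
#'
#' One-row CSV mirroring the tabular comparison layout: %AS of both models,
#' VD median/IQR and AD median/IQR.
#'
#' @param report a validation report from [validate_models()].
#' @param path CSV output path.
#' @export
write_validation_report <- function(report, path) {
  df <- data.frame(
    pct_AS_om = if (!is.null(report$stenosis_om))
      report$stenosis_om$pct_AS else NA_real_,
    pct_AS_dm = if (!is.null(report$stenosis_dm))
      report$stenosis_dm$pct_AS else NA_real_,
    vd_median_mm = report$vd_median,
    vd_q1_mm = report$vd_iqr[1L], vd_q3_mm = report$vd_iqr[2L],
    ad_median_mm2 = report$ad_median,
    ad_q1_mm2 = report$ad_iqr[1L], ad_q3_mm2 = report$ad_iqr[2L],
    zdiff_mean = report$zdiff_mean, zdiff_sd = report$zdiff_sd,
    z_r_squared = report$r_squared)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
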