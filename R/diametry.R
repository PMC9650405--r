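#' Measurement configuration for vessel diametry
#'
#' Defaults encode the standard measurement windows: the aortic diameter is
#' averaged from 0.5 cm after the heart-exit anchor to 2.5 cm, sampled every
#' 0.09 cm; the pulmonary-artery diameter is averaged on the main trunk from
#' 0.5 to 1.5 cm proximal to the branching point, sampled every 0.04 cm. A
#' ratio of at least `ratio_threshold` (default 1, inclusive) classifies the
#' pulmonary artery as enlarged.
#'
#' @param ao_window_cm Aortic window (start, end), cm from the anchor.
#' @param ao_interval_cm Aortic sampling interval, cm.
#' @param pa_window_cm Pulmonary window (start, end), cm from the bifurcation.
#' @param pa_interval_cm Pulmonary sampling interval, cm.
#' @param plane_halfwidth_mm Half-extent of the sampled cross-section plane, mm.
#' @param plane_grid_mm In-plane sampling step, mm.
#' @param ratio_threshold Enlargement threshold on PA/Ao (inclusive).
#' @return A `measurement_config` list.
#' @export
measurement_config <- function(ao_window_cm = c(0.5, 2.5), ao_interval_cm = 0.09,
                               pa_window_cm = c(0.5, 1.5), pa_interval_cm = 0.04,
                               plane_halfwidth_mm = 60, plane_grid_mm = 0.2,
                               ratio_threshold = 1.0) {
  stopifnot(length(ao_window_cm) == 2, ao_window_cm[1] < ao_window_cm[2],
            length(pa_window_cm) == 2, pa_window_cm[1] < pa_window_cm[2],
            ao_interval_cm > 0, pa_interval_cm > 0,
            plane_halfwidth_mm > 0, plane_grid_mm > 0, ratio_threshold > 0)
  structure(list(ao_window_cm = ao_window_cm, ao_interval_cm = ao_interval_cm,
                 pa_window_cm = pa_window_cm, pa_interval_cm = pa_interval_cm,
                 plane_halfwidth_mm = plane_halfwidth_mm,
                 plane_grid_mm = plane_grid_mm,
                 ratio_threshold = ratio_threshold),
            class = "measurement_config")
}

# orthonormal in-plane basis perpendicular to a unit tangent
plane_basis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ref[2] * t[3] - ref[3] * t[2],
         ref[3] * t[1] - ref[1] * t[3],
         ref[1] * t[2] - ref[2] * t[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v)
}

#' Equivalent-area diameter of a perpendicular cross-section
#'
#' Samples the plane through `point_mm` perpendicular to `tangent` on a
#' square grid, trilinearly interpolates the mask and thresholds at 0.5,
#' keeps the in-plane connected component containing the plane centre, and
#' returns the equivalent-area diameter `2 * sqrt(A / pi)`.
#'
#' @param mask A [volume_mask()].
#' @param point_mm Centre of the cross-section, mm.
#' @param tangent Unit vessel direction at the point.
#' @param plane_halfwidth_mm,plane_grid_mm Plane extent and step, mm.
#' @return Diameter in mm.
#' @export
cross_section_diameter <- function(mask, point_mm, tangent,
                                   plane_halfwidth_mm = 60, plane_grid_mm = 0.2) {
  stopifnot_mask(mask)
  b <- plane_basis(tangent)
  g <- seq(-plane_halfwidth_mm, plane_halfwidth_mm, by = plane_grid_mm)
  n <- length(g)
  uu <- rep(g, times = n); vv <- rep(g, each = n)
  pts <- cbind(point_mm[1] + uu * b$u[1] + vv * b$v[1],
               point_mm[2] + uu * b$u[2] + vv * b$v[2],
               point_mm[3] + uu * b$u[3] + vv * b$v[3])
  vol <- array(as.numeric(mask$voxels), dim = dim(mask$voxels))
  vals <- cpp_trilinear(vol, dim(mask$voxels), mm_to_voxel(mask, pts))
  plane <- array(vals >= 0.5, dim = c(n, n, 1L))
  centre <- (n + 1L) %/% 2L
  if (!plane[centre, centre, 1]) stop("centerline exited lumen", call. = FALSE)
  lab <- cpp_label(plane, c(n, n, 1L), 26L) # 8-connectivity in-plane
  area <- sum(lab == lab[centre, centre, 1]) * plane_grid_mm^2
  2 * sqrt(area / pi)
}

#' Diameter profile along a measurement window
#'
#' Enumerates arc-length positions `start, start + interval, ...` (inclusive
#' start, last position at most `end`) measured from either the path anchor
#' or a supplied bifurcation point (toward the anchored end), and evaluates
#' the perpendicular cross-section diameter at each.
#'
#' @param mask A [volume_mask()].
#' @param cl A `centerline` from [main_path()].
#' @param window_cm Window (start, end), cm.
#' @param interval_cm Sampling interval, cm.
#' @param anchor `"path_anchor"` or `"bifurcation"`.
#' @param bifurcation_mm Physical bifurcation point (required when
#'   `anchor = "bifurcation"`).
#' @param config A [measurement_config()] supplying the plane sampling.
#' @return A tibble with `position_cm` and `diameter_mm` (class
#'   `diameter_profile`).
#' @export
diameter_profile <- function(mask, cl, window_cm, interval_cm,
                             anchor = c("path_anchor", "bifurcation"),
                             bifurcation_mm = NULL,
                             config = measurement_config()) {
  anchor <- match.arg(anchor)
  k <- 0:floor((window_cm[2] - window_cm[1]) / interval_cm + 1e-9)
  pos_cm <- window_cm[1] + k * interval_cm

  total_cm <- max(cl$cum_arclen_mm) / 10
  if (anchor == "path_anchor") {
    from_anchor <- pos_cm
  } else {
    if (is.null(bifurcation_mm)) stop("bifurcation_mm required", call. = FALSE)
    bif_cm <- nearest_arclen(cl, bifurcation_mm) / 10
    bif_from_anchor <- if (cl$anchor_index == 1L) bif_cm else total_cm - bif_cm
    from_anchor <- bif_from_anchor - pos_cm # toward the anchored trunk origin
    if (any(from_anchor < -1e-9)) stop("trunk too short", call. = FALSE)
  }
  if (any(from_anchor > total_cm + 1e-9))
    stop("window exceeds vessel extent", call. = FALSE)

  d <- vapply(from_anchor, function(p) {
    pt <- point_at_arclen(cl, p)
    cross_section_diameter(mask, pt$point_mm, pt$tangent,
                           config$plane_halfwidth_mm, config$plane_grid_mm)
  }, numeric(1))
  out <- tibble::tibble(position_cm = pos_cm, diameter_mm = d)
  class(out) <- c("diameter_profile", class(out))
  attr(out, "window_cm") <- window_cm
  attr(out, "interval_cm") <- interval_cm
  out
}

new_vessel_measurement <- function(profile, label) {
  structure(list(mean_diameter_mm = mean(profile$diameter_mm),
                 profile = profile, vessel_label = label),
            class = "vessel_measurement")
}

#' @export
print.vessel_measurement <- function(x, ...) {
  cat(sprintf("<vessel_measurement> %s: mean diameter %.2f mm over %d sections\n",
              x$vessel_label, x$mean_diameter_mm, nrow(x$profile)))
  invisible(x)
}

#' Mean aortic diameter over the anchored window
#'
#' @param mask Aorta [volume_mask()].
#' @param cl Anchored `centerline` (anchor at the heart-exit end).
#' @param config A [measurement_config()].
#' @return A `vessel_measurement`.
#' @export
measure_aorta <- function(mask, cl, config = measurement_config()) {
  prof <- diameter_profile(mask, cl, config$ao_window_cm, config$ao_interval_cm,
                           anchor = "path_anchor", config = config)
  new_vessel_measurement(prof, "aorta")
}

#' Mean pulmonary-artery diameter proximal to the bifurcation
#'
#' The window runs from the branching point along the main trunk toward the
#' anchored (pulmonic-valve-side) end.
#'
#' @param mask Pulmonary-artery [volume_mask()].
#' @param cl Anchored `centerline` of the trunk.
#' @param bifurcation_mm Branch point, mm (e.g. from [detect_bifurcation()]).
#' @param config A [measurement_config()].
#' @return A `vessel_measurement`.
#' @export
measure_pa <- function(mask, cl, bifurcation_mm = attr(cl, "bifurcation_mm"),
                       config = measurement_config()) {
  if (is.null(bifurcation_mm)) stop("no bifurcation present", call. = FALSE)
  total_cm <- max(cl$cum_arclen_mm) / 10
  bif_cm <- nearest_arclen(cl, bifurcation_mm) / 10
  bif_from_anchor <- if (cl$anchor_index == 1L) bif_cm else total_cm - bif_cm
  if (bif_from_anchor < config$pa_window_cm[2] - 1e-9)
    stop("trunk too short", call. = FALSE)
  prof <- diameter_profile(mask, cl, config$pa_window_cm, config$pa_interval_cm,
                           anchor = "bifurcation", bifurcation_mm = bifurcation_mm,
                           config = config)
  new_vessel_measurement(prof, "pulmonary_artery")
}

#' PA/Ao diameter ratio and enlargement classification
#'
#' @param pa,ao `vessel_measurement` objects.
#' @param config A [measurement_config()] (supplies `ratio_threshold`).
#' @return A `ratio_result`: list with `ratio` and `enlarged`
#'   (`ratio >= threshold`, inclusive).
#' @export
pa_ao_ratio <- function(pa, ao, config = measurement_config()) {
  if (!(pa$mean_diameter_mm > 0) || !(ao$mean_diameter_mm > 0))
    stop("nonpositive mean diameter", call. = FALSE)
  ratio <- pa$mean_diameter_mm / ao$mean_diameter_mm
  structure(list(ratio = ratio,
                 enlarged = ratio >= config$ratio_threshold,
                 threshold = config$ratio_threshold),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> PA/Ao = %.3f (%s at threshold %g)\n",
              x$ratio, if (x$enlarged) "enlarged" else "not enlarged", x$threshold))
  invisible(x)
}

#' Single-slice axial 2D diameter emulation
#'
#' Emulates the manual caliper protocol: on the axial slice at the level of
#' the pulmonary bifurcation, each vessel's diameter is taken as the largest
#' inscribed circle (twice the maximum of the in-plane Euclidean distance
#' transform) of the in-plane component nearest the vessel's slice centroid.
#' The slice is resampled on a sub-voxel in-plane grid (trilinear, matching
#' the 3D plane sampling) so the inscribed radius is not quantized to whole
#' voxels.
#'
#' @param ao_mask,pa_mask [volume_mask()] objects on the same grid.
#' @param bifurcation_point_mm Physical point whose z selects the slice.
#' @param grid_mm In-plane resampling step, mm. Default 0.25.
#' @return A tibble with `ao_mm`, `pa_mm`, `ratio2d`.
#' @export
measure_2d_axial <- function(ao_mask, pa_mask, bifurcation_point_mm,
                             grid_mm = 0.25) {
  stopifnot_mask(ao_mask); stopifnot_mask(pa_mask)
  one <- function(mask) {
    d <- dim(mask$voxels)
    kz <- round((bifurcation_point_mm[3] - mask$origin_mm[3]) / mask$spacing_mm[3]) + 1
    if (kz < 1 || kz > d[3]) stop("bifurcation z outside volume", call. = FALSE)
    z_mm <- mask$origin_mm[3] + (kz - 1) * mask$spacing_mm[3]
    xs <- seq(mask$origin_mm[1], mask$origin_mm[1] + (d[1] - 1) * mask$spacing_mm[1],
              by = grid_mm)
    ys <- seq(mask$origin_mm[2], mask$origin_mm[2] + (d[2] - 1) * mask$spacing_mm[2],
              by = grid_mm)
    nx <- length(xs); ny <- length(ys)
    pts <- cbind(rep(xs, times = ny), rep(ys, each = nx), z_mm)
    vol <- array(as.numeric(mask$voxels), dim = d)
    vals <- cpp_trilinear(vol, d, mm_to_voxel(mask, pts))
    sl <- array(vals >= 0.5, dim = c(nx, ny, 1L))
    if (!any(sl)) stop("empty slice", call. = FALSE)
    dims2 <- c(nx, ny, 1L)
    lab <- cpp_label(sl, dims2, 26L)
    idx <- which(sl[, , 1], arr.ind = TRUE)
    cen <- colMeans(idx)
    comp_ids <- sort(unique(lab[lab > 0]))
    pick <- comp_ids[which.min(vapply(comp_ids, function(ci) {
      ii <- which(array(lab, dim = dims2)[, , 1] == ci, arr.ind = TRUE)
      sum((colMeans(ii) - cen)^2)
    }, numeric(1)))]
    comp <- array(array(lab, dim = dims2)[, , 1] == pick, dim = dims2)
    dsq <- cpp_edt_sq(comp, dims2, c(grid_mm, grid_mm, 1e6), TRUE)
    2 * sqrt(max(dsq))
  }
  ao <- one(ao_mask); pa <- one(pa_mask)
  tibble::tibble(ao_mm = ao, pa_mm = pa, ratio2d = pa / ao)
}

#' Full phantom-pair measurement pipeline
#'
#' Convenience wrapper: skeletonizes both masks, extracts anchored
#' centerlines, locates the pulmonary bifurcation, measures both vessels and
#' returns the ratio classification.
#'
#' @param ao_mask,pa_mask [volume_mask()] objects.
#' @param ao_anchor_mm,pa_anchor_mm Anchor hint points (heart-exit end of the
#'   aorta; trunk-origin end of the pulmonary artery).
#' @param config A [measurement_config()].
#' @return List with `ao`, `pa` (vessel_measurements), `ratio`
#'   (a `ratio_result`) and `bifurcation_mm`.
#' @export
measure_vessel_pair <- function(ao_mask, pa_mask, ao_anchor_mm, pa_anchor_mm,
                                config = measurement_config()) {
  ao_sg <- skeletonize(ao_mask)
  ao_cl <- main_path(ao_sg, anchor_hint_mm = ao_anchor_mm)
  ao <- measure_aorta(ao_mask, ao_cl, config)

  pa_sg <- skeletonize(pa_mask)
  bif <- detect_bifurcation(pa_sg)
  pa_cl <- main_path(pa_sg, anchor_hint_mm = pa_anchor_mm)
  pa <- measure_pa(pa_mask, pa_cl, bifurcation_mm = bif, config = config)

  list(ao = ao, pa = pa, ratio = pa_ao_ratio(pa, ao, config),
       bifurcation_mm = bif)
}
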