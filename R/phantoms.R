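#' Specification of a ground-truthed tubular phantom
#'
#' Phantoms stand in for segmented great vessels: a voxel is foreground iff
#' its centre lies within `tube_radius_mm` of an analytic centerline curve
#' (before optional surface noise). Four kinds are supported:
#' a straight `cylinder`, a circular-`arc_tube` (aorta-like), a `bifurcation`
#' (pulmonary-trunk-like: trunk splitting into two daughters) and a
#' `tapered_cylinder` with linearly varying radius.
#'
#' The resolvability floor `tube_radius_mm >= 3 * max(spacing_mm)` guarantees
#' the tube is several voxels wide everywhere so that thinning and
#' cross-section sampling are well posed.
#'
#' @param kind One of `"cylinder"`, `"arc_tube"`, `"bifurcation"`,
#'   `"tapered_cylinder"`.
#' @param tube_radius_mm Tube radius in mm; for `tapered_cylinder` a length-2
#'   vector `(r_start, r_end)`.
#' @param length_mm Axial length (cylinder/tapered: full length; bifurcation:
#'   trunk length).
#' @param arc_radius_mm,arc_angle_deg Arc geometry (arc_tube only).
#' @param branch_radius_mm,branch_angle_deg,branch_length_mm Daughter-tube
#'   geometry (bifurcation only); `branch_angle_deg` is the angle between the
#'   two daughters and `branch_length_mm` defaults to three trunk radii so
#'   daughters outlast downstream spur pruning.
#' @param spacing_mm Voxel spacing triple in mm.
#' @param axis Unit direction of the main axis (cylinder/tapered/bifurcation
#'   trunk); arc_tube uses `orientation`.
#' @param orientation 3x3 rotation applied to the canonical geometry.
#' @param noise_flip_prob Probability in `[0, 1)` that each surface-adjacent
#'   voxel is flipped.
#' @param margin_mm Background margin around the geometry.
#' @param seed RNG seed used for the noise flips.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("cylinder", "arc_tube", "bifurcation", "tapered_cylinder"),
                         tube_radius_mm, length_mm = 60,
                         arc_radius_mm = 40, arc_angle_deg = 120,
                         branch_radius_mm = NULL, branch_angle_deg = 60,
                         branch_length_mm = NULL,
                         spacing_mm = c(0.7, 0.7, 1.0),
                         axis = c(0, 0, 1),
                         orientation = diag(3),
                         noise_flip_prob = 0, margin_mm = NULL, seed = 1L) {
  kind <- match.arg(kind)
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0)) stop("non-positive spacing", call. = FALSE)
  r <- as.numeric(tube_radius_mm)
  if (kind == "tapered_cylinder") {
    if (length(r) != 2L || any(r <= 0)) stop("tapered_cylinder needs (r_start, r_end) > 0", call. = FALSE)
  } else if (length(r) != 1L || r <= 0) stop("tube_radius_mm must be a positive scalar", call. = FALSE)
  if (min(r) < 3 * max(spacing_mm))
    stop(sprintf("unresolvable radius: %.3g mm < 3 x max spacing %.3g mm",
                 min(r), max(spacing_mm)), call. = FALSE)
  if (noise_flip_prob < 0 || noise_flip_prob >= 1)
    stop("noise_flip_prob must be in [0, 1)", call. = FALSE)
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  if (is.null(branch_radius_mm)) branch_radius_mm <- min(r) * 0.8
  # daughters must outlast the spur-pruning scale (2 x trunk radius)
  if (is.null(branch_length_mm)) branch_length_mm <- 3 * min(r)
  if (is.null(margin_mm)) margin_mm <- 2 * max(spacing_mm) + 1
  structure(list(
    kind = kind, tube_radius_mm = r, length_mm = length_mm,
    arc_radius_mm = arc_radius_mm, arc_angle_deg = arc_angle_deg,
    branch_radius_mm = branch_radius_mm, branch_angle_deg = branch_angle_deg,
    branch_length_mm = branch_length_mm,
    spacing_mm = spacing_mm, axis = axis, orientation = orientation,
    noise_flip_prob = noise_flip_prob, margin_mm = margin_mm,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# rotation taking canonical +z to a given unit axis
rotation_to_axis <- function(axis) {
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  if (sum(v^2) < 1e-14) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1))) # 180 degrees about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate a phantom mask with analytic ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `mask` (a [volume_mask()]) and `truth`, where
#'   `truth` holds the exact centerline polyline (`centerline_mm`, sampled at
#'   0.2 mm), the true diameter at every arc-length position
#'   (`diameter_mm`), the anchor point (`anchor_mm`, the trunk-origin /
#'   heart-exit end), `arc_length_mm`, and for bifurcations the true branch
#'   point `bifurcation_mm` and daughter directions.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec", call. = FALSE)
  geo <- phantom_geometry(spec)
  ext <- geo$extent # 2 x 3 matrix (min; max) of the solid, mm
  m <- spec$margin_mm
  origin <- ext[1, ] - m
  span <- (ext[2, ] + m) - origin
  dims <- pmax(ceiling(span / spec$spacing_mm) + 1L, 3L)

  # voxel-centre coordinate grids (physical mm)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spec$spacing_mm[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spec$spacing_mm[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spec$spacing_mm[3]
  fg <- geo$inside(xs, ys, zs)

  if (spec$noise_flip_prob > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    surf <- surface_adjacent(fg)
    flip <- which(surf)[stats::runif(sum(surf)) < spec$noise_flip_prob]
    fg[flip] <- !fg[flip]
  }

  mask <- volume_mask(array(as.integer(fg), dim = dims), spec$spacing_mm, origin)
  list(mask = mask, truth = geo$truth)
}

# voxels (fg or bg) 6-adjacent to the opposite phase
surface_adjacent <- function(fg) {
  d <- dim(fg)
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim = d)
    idx <- lapply(d, seq_len); src <- idx
    if (by > 0) { idx[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { idx[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  touch_bg <- array(FALSE, dim = d)
  touch_fg <- array(FALSE, dim = d)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    s <- shift(fg, ax, by)
    # border counts as background for the fg-surface test
    sb <- shift(!fg, ax, by)
    edge <- array(TRUE, dim = d); e2 <- shift(edge, ax, by)
    touch_bg <- touch_bg | sb | !e2
    touch_fg <- touch_fg | s
  }
  (fg & touch_bg) | (!fg & touch_fg)
}

# analytic geometry per kind: inside() predicate over a coordinate grid,
# truth centerline + diameters, physical extent of the solid
phantom_geometry <- function(spec) {
  R <- spec$orientation %*% rotation_to_axis(spec$axis)
  step <- 0.2
  kind <- spec$kind

  if (kind %in% c("cylinder", "tapered_cylinder")) {
    L <- spec$length_mm
    r <- spec$tube_radius_mm
    r0 <- r[1]; r1 <- if (length(r) == 2) r[2] else r[1]
    ts <- seq(0, L, by = step)
    cl <- cbind(0, 0, ts) %*% t(R)
    truth <- list(
      kind = kind,
      centerline_mm = cl,
      arclen_mm = ts,
      diameter_mm = 2 * (r0 + (r1 - r0) * ts / L),
      anchor_mm = cl[1, ],
      arc_length_mm = L
    )
    inside <- function(xs, ys, zs) {
      p <- expand_grid_mm(xs, ys, zs) %*% R # rotate back to canonical frame
      t_ <- p[, 3]
      rad2 <- p[, 1]^2 + p[, 2]^2
      rt <- r0 + (r1 - r0) * pmin(pmax(t_ / L, 0), 1)
      array(t_ >= 0 & t_ <= L & rad2 <= rt^2, dim = c(length(xs), length(ys), length(zs)))
    }
    rmax <- max(r0, r1)
    corners <- rbind(c(-rmax, -rmax, 0), c(rmax, rmax, L))
    ext <- extent_of(corners, R)
    return(list(inside = inside, truth = truth, extent = ext))
  }

  if (kind == "arc_tube") {
    Ra <- spec$arc_radius_mm
    th <- spec$arc_angle_deg * pi / 180
    r <- spec$tube_radius_mm
    if (Ra <= r) stop("arc_radius_mm must exceed tube radius", call. = FALSE)
    ths <- seq(0, th, by = step / Ra)
    cl <- cbind(Ra * cos(ths) - Ra, Ra * sin(ths), 0) %*% t(R) # starts at origin
    truth <- list(
      kind = kind,
      centerline_mm = cl,
      arclen_mm = ths * Ra,
      diameter_mm = rep(2 * r, length(ths)),
      anchor_mm = cl[1, ],
      arc_length_mm = Ra * th
    )
    inside <- function(xs, ys, zs) {
      p <- expand_grid_mm(xs, ys, zs) %*% R
      wx <- p[, 1] + Ra; wy <- p[, 2]
      ang <- atan2(wy, wx)
      inplane <- sqrt(wx^2 + wy^2)
      d2 <- (inplane - Ra)^2 + p[, 3]^2
      array(ang >= 0 & ang <= th & d2 <= r^2,
            dim = c(length(xs), length(ys), length(zs)))
    }
    # bounding corners of the arc sweep (canonical frame), padded by r
    thq <- seq(0, th, length.out = 64)
    pts <- cbind(Ra * cos(thq) - Ra, Ra * sin(thq), 0)
    corners <- rbind(apply(pts, 2, min) - r, apply(pts, 2, max) + r)
    ext <- extent_of(rbind(corners, expand_corners(corners)), R)
    return(list(inside = inside, truth = truth, extent = ext))
  }

  # bifurcation: trunk along +z from 0 to Lt, daughters from the branch
  # point at +/- half the branch angle around the y-axis
  Lt <- spec$length_mm
  Ld <- spec$branch_length_mm
  r <- spec$tube_radius_mm
  rb <- spec$branch_radius_mm
  half <- spec$branch_angle_deg / 2 * pi / 180
  d1 <- c(sin(half), 0, cos(half))
  d2 <- c(-sin(half), 0, cos(half))
  ts <- seq(0, Lt, by = step)
  cl <- cbind(0, 0, ts) %*% t(R)
  bif <- c(0, 0, Lt) %*% t(R)
  truth <- list(
    kind = kind,
    centerline_mm = cl,
    arclen_mm = ts,
    diameter_mm = rep(2 * r, length(ts)),
    anchor_mm = cl[1, ],
    bifurcation_mm = as.numeric(bif),
    daughter_dirs = rbind(as.numeric(R %*% d1), as.numeric(R %*% d2)),
    arc_length_mm = Lt
  )
  inside <- function(xs, ys, zs) {
    p <- expand_grid_mm(xs, ys, zs) %*% R
    t_ <- p[, 3]
    in_trunk <- t_ >= 0 & t_ <= Lt & (p[, 1]^2 + p[, 2]^2) <= r^2
    q <- p; q[, 3] <- q[, 3] - Lt
    seg <- function(dir) {
      tt <- q %*% dir
      perp2 <- rowSums(q^2) - tt^2
      tt >= 0 & tt <= Ld & perp2 <= rb^2
    }
    array(in_trunk | seg(d1) | seg(d2),
          dim = c(length(xs), length(ys), length(zs)))
  }
  spread <- Ld * sin(half) + rb
  corners <- rbind(c(-max(r, spread), -max(r, rb), 0),
                   c(max(r, spread), max(r, rb), Lt + Ld * cos(half) + rb))
  ext <- extent_of(rbind(corners, expand_corners(corners)), R)
  list(inside = inside, truth = truth, extent = ext)
}

expand_grid_mm <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  cbind(rep(xs, times = ny * nz),
        rep(rep(ys, each = nx), times = nz),
        rep(zs, each = nx * ny))
}

expand_corners <- function(box) {
  as.matrix(expand.grid(box[, 1], box[, 2], box[, 3]))
}

extent_of <- function(corners_canonical, R) {
  pts <- expand_corners(rbind(apply(corners_canonical, 2, min),
                              apply(corners_canonical, 2, max))) %*% t(R)
  rbind(apply(pts, 2, min), apply(pts, 2, max))
}

#' Generate a matched aorta/pulmonary-artery phantom pair
#'
#' Produces an arc-tube "aorta" and a bifurcating "pulmonary artery" whose
#' true diameter ratio is `pa_trunk_radius_mm / ao_radius_mm`, with anchors
#' (the heart-exit / trunk-origin ends) populated in the truths. Geometry is
#' sized so the standard measurement windows fit: the aortic arc is at least
#' 35 mm long and the pulmonary trunk at least 25 mm.
#'
#' @param ao_radius_mm,pa_trunk_radius_mm Tube radii, mm.
#' @param spacing_mm Voxel spacing triple, mm.
#' @param seed RNG seed (used when `noise_flip_prob > 0`).
#' @param ao_arc_radius_mm,ao_arc_angle_deg Aortic arc geometry.
#' @param pa_trunk_length_mm Pulmonary trunk length, mm.
#' @param noise_flip_prob Surface-voxel flip probability.
#' @return A list with elements `aorta` and `pa`, each a
#'   `list(mask, truth)` as from [make_phantom()], plus `truth_ratio`.
#' @export
make_vessel_pair <- function(ao_radius_mm, pa_trunk_radius_mm,
                             spacing_mm = c(0.7, 0.7, 1.0), seed = 1L,
                             ao_arc_radius_mm = 40, ao_arc_angle_deg = 90,
                             pa_trunk_length_mm = 30,
                             noise_flip_prob = 0) {
  ao_len <- ao_arc_radius_mm * ao_arc_angle_deg * pi / 180
  if (ao_len < 35)
    stop(sprintf("aorta window does not fit: arc length %.1f mm < 35 mm", ao_len),
         call. = FALSE)
  if (pa_trunk_length_mm < 25)
    stop(sprintf("pulmonary-artery window does not fit: trunk length %.1f mm < 25 mm",
                 pa_trunk_length_mm), call. = FALSE)
  # arc swept in a vertical plane, rising along +z like the ascending aorta,
  # so the axial slice at the pulmonary bifurcation level cuts both vessels
  vertical <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  ao <- make_phantom(phantom_spec(
    "arc_tube", tube_radius_mm = ao_radius_mm,
    arc_radius_mm = ao_arc_radius_mm, arc_angle_deg = ao_arc_angle_deg,
    orientation = vertical,
    spacing_mm = spacing_mm, noise_flip_prob = noise_flip_prob, seed = seed
  ))
  pa <- make_phantom(phantom_spec(
    "bifurcation", tube_radius_mm = pa_trunk_radius_mm,
    length_mm = pa_trunk_length_mm,
    branch_radius_mm = 0.8 * pa_trunk_radius_mm,
    spacing_mm = spacing_mm, noise_flip_prob = noise_flip_prob,
    seed = seed + 1L
  ))
  list(aorta = ao, pa = pa,
       truth_ratio = pa_trunk_radius_mm / ao_radius_mm)
}

#' Write a phantom truth sidecar as JSON
#'
#' @param truth The `truth` element from [make_phantom()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$centerline_mm <- unname(apply(truth$centerline_mm, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
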