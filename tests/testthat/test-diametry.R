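test_that("perpendicular sections of a cylinder give the caliper diameter", {
  ph <- fx_cylinder()
  mid <- c(0, 0, 30)
  d <- cross_section_diameter(ph$mask, mid, c(0, 0, 1),
                              plane_halfwidth_mm = 25, plane_grid_mm = 0.2)
  expect_lt(abs(d - 30), max(0.5, 2 * 0.2))
  expect_error(cross_section_diameter(ph$mask, c(40, 40, 30), c(0, 0, 1), 25, 0.2),
               "centerline exited lumen")
})

test_that("oblique sections match a numerically integrated ellipse oracle", {
  ph <- fx_cylinder() # r = 15, axis z
  theta <- 30 * pi / 180
  tg <- c(sin(theta), 0, cos(theta))
  d <- cross_section_diameter(ph$mask, c(0, 0, 30), tg,
                              plane_halfwidth_mm = 30, plane_grid_mm = 0.2)
  # oracle: area of the oblique plane cut of an infinite cylinder by grid
  # integration in the plane frame (u along the tilt, v across)
  g <- seq(-30, 30, by = 0.1)
  uu <- rep(g, times = length(g)); vv <- rep(g, each = length(g))
  # plane point p = u*e_u + v*e_v with e_u = (cos t, 0, -sin t), e_v = (0,1,0);
  # inside iff x^2 + y^2 <= r^2
  inside <- (uu * cos(theta))^2 + vv^2 <= 15^2
  d_oracle <- 2 * sqrt(sum(inside) * 0.01 / pi)
  expect_lt(abs(d - d_oracle) / d_oracle, 0.02)
  expect_equal(d_oracle, 30 / sqrt(cos(theta)), tolerance = 0.01)
})

test_that("window enumeration gives 23 aortic and 26 pulmonary positions", {
  cfg <- measurement_config()
  k_ao <- 0:floor(diff(cfg$ao_window_cm) / cfg$ao_interval_cm + 1e-9)
  expect_length(k_ao, 23)
  k_pa <- 0:floor(diff(cfg$pa_window_cm) / cfg$pa_interval_cm + 1e-9)
  expect_length(k_pa, 26)
  # and the profiles actually carry those lengths
  ph <- fx_cylinder(); cl <- fx_cylinder_cl()$cl
  cfg2 <- fx_config(25)
  prof_ao <- diameter_profile(ph$mask, cl, cfg2$ao_window_cm, cfg2$ao_interval_cm,
                              config = cfg2)
  expect_identical(nrow(prof_ao), 23L)
  prof_pa <- diameter_profile(ph$mask, cl, cfg2$pa_window_cm, cfg2$pa_interval_cm,
                              config = cfg2)
  expect_identical(nrow(prof_pa), 26L)
  # constant-radius phantom: profile variation under 2% of the mean
  expect_lt(stats::sd(prof_ao$diameter_mm) / mean(prof_ao$diameter_mm), 0.02)
})

test_that("measure_aorta recovers constant and tapered truth diameters", {
  ph <- fx_cylinder(); cl <- fx_cylinder_cl()$cl
  m <- measure_aorta(ph$mask, cl, fx_config(25))
  expect_lt(abs(m$mean_diameter_mm - 30), 1)
  expect_equal(m$mean_diameter_mm, mean(m$profile$diameter_mm))
  # linear taper: radii 13 -> 17 across the window, window mean = midpoint 30 mm
  tp <- make_phantom(phantom_spec("tapered_cylinder", tube_radius_mm = c(12, 24),
                                  length_mm = 60, spacing_mm = c(0.7, 0.7, 1.0)))
  tsg <- skeletonize(tp$mask)
  tcl <- main_path(tsg, anchor_hint_mm = tp$truth$anchor_mm)
  tm <- measure_aorta(tp$mask, tcl, fx_config(30))
  expect_lt(abs(tm$mean_diameter_mm - 30), 1)
  # a window that does not fit errors out
  short <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 6, length_mm = 20,
                                     spacing_mm = c(0.5, 0.5, 0.5)))
  ssg <- skeletonize(short$mask)
  scl <- main_path(ssg, anchor_hint_mm = short$truth$anchor_mm)
  expect_error(measure_aorta(short$mask, scl, fx_config(12)), "window exceeds")
})

test_that("measure_pa recovers the trunk diameter proximal to the bifurcation", {
  pair <- fx_pair()
  sg <- skeletonize(pair$pa$mask)
  bif <- detect_bifurcation(sg)
  cl <- main_path(sg, anchor_hint_mm = pair$pa$truth$anchor_mm)
  m <- measure_pa(pair$pa$mask, cl, bifurcation_mm = bif, config = fx_config(25))
  expect_lt(abs(m$mean_diameter_mm - 27.8), 1)
  expect_identical(nrow(m$profile), 26L)
  # short trunk is refused
  stub <- make_phantom(phantom_spec("bifurcation", tube_radius_mm = 5, length_mm = 12,
                                    branch_radius_mm = 4,
                                    spacing_mm = c(0.5, 0.5, 0.5)))
  ssg <- skeletonize(stub$mask)
  sbif <- detect_bifurcation(ssg)
  scl <- main_path(ssg, anchor_hint_mm = stub$truth$anchor_mm)
  expect_error(measure_pa(stub$mask, scl, bifurcation_mm = sbif,
                          config = fx_config(10)), "trunk too short")
})

test_that("the ratio classification is inclusive at the threshold and scale-free", {
  fake <- function(mean) structure(list(mean_diameter_mm = mean,
                                        profile = tibble::tibble(),
                                        vessel_label = "x"),
                                   class = "vessel_measurement")
  cfg <- measurement_config()
  at <- pa_ao_ratio(fake(30), fake(30), cfg)
  expect_equal(at$ratio, 1.0)
  expect_true(at$enlarged)
  below <- pa_ao_ratio(fake(27.8), fake(34.75), cfg)
  expect_equal(below$ratio, 0.8)
  expect_false(below$enlarged)
  scaled <- pa_ao_ratio(fake(27.8 * 1.37), fake(34.75 * 1.37), cfg)
  expect_equal(scaled$ratio, below$ratio)
  expect_identical(scaled$enlarged, below$enlarged)
  expect_error(pa_ao_ratio(fake(0), fake(30), cfg), "nonpositive")
})

test_that("diameter recovery holds across radii and scanner spacings", {
  for (case in list(list(r = 10, sp = c(0.38, 0.38, 0.6)),
                    list(r = 18, sp = c(0.89, 0.89, 1.25)))) {
    ph <- make_phantom(phantom_spec("cylinder", tube_radius_mm = case$r,
                                    length_mm = 45, spacing_mm = case$sp))
    sg <- skeletonize(ph$mask)
    cl <- main_path(sg, anchor_hint_mm = ph$truth$anchor_mm)
    m <- measure_aorta(ph$mask, cl, fx_config(case$r + 10))
    expect_lt(abs(m$mean_diameter_mm - 2 * case$r),
              max(1, 0.03 * 2 * case$r))
  }
})

test_that("dilating a phantom strictly increases the measured mean diameter", {
  ph <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 8, length_mm = 40,
                                  spacing_mm = c(0.6, 0.6, 0.8)))
  sg <- skeletonize(ph$mask)
  cl <- main_path(sg, anchor_hint_mm = ph$truth$anchor_mm)
  base <- measure_aorta(ph$mask, cl, fx_config(15))$mean_diameter_mm
  # one-voxel 6-neighbourhood dilation
  fg <- ph$mask$voxels == 1L
  dil <- fg
  d <- dim(fg)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    idx <- lapply(d, seq_len); src <- idx
    if (by > 0) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else        { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    dil[idx[[1]], idx[[2]], idx[[3]]] <-
      dil[idx[[1]], idx[[2]], idx[[3]]] | fg[src[[1]], src[[2]], src[[3]]]
  }
  big <- volume_mask(array(as.integer(dil), dim = d), ph$mask$spacing_mm,
                     ph$mask$origin_mm)
  bsg <- skeletonize(big)
  bcl <- main_path(bsg, anchor_hint_mm = ph$truth$anchor_mm)
  expect_gt(measure_aorta(big, bcl, fx_config(15))$mean_diameter_mm, base)
})

test_that("rotating the vessel changes the measured mean by under 1.5%", {
  set.seed(7)
  sp <- c(0.6, 0.6, 0.8)
  ph0 <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 12, length_mm = 45,
                                   spacing_mm = sp))
  sg0 <- skeletonize(ph0$mask)
  cl0 <- main_path(sg0, anchor_hint_mm = ph0$truth$anchor_mm)
  base <- measure_aorta(ph0$mask, cl0, fx_config(20))$mean_diameter_mm
  for (i in 1:3) {
    R <- rotation_about(stats::rnorm(3), stats::runif(1, 0.3, 1.2))
    ph <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 12, length_mm = 45,
                                    spacing_mm = sp,
                                    axis = as.numeric(R %*% c(0, 0, 1))))
    sg <- skeletonize(ph$mask)
    cl <- main_path(sg, anchor_hint_mm = ph$truth$anchor_mm)
    m <- measure_aorta(ph$mask, cl, fx_config(20))
    expect_lt(abs(m$mean_diameter_mm / base - 1), 0.015)
  }
})

test_that("the axial 2D emulation matches vertical-tube geometry", {
  a <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 15, length_mm = 40,
                                 spacing_mm = c(0.6, 0.6, 0.8)))
  b <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 12, length_mm = 40,
                                 spacing_mm = c(0.6, 0.6, 0.8)))
  r <- measure_2d_axial(a$mask, b$mask, c(0, 0, 20))
  expect_lt(abs(r$ao_mm - 30), 1)
  expect_lt(abs(r$pa_mm - 24), 1)
  expect_lt(abs(r$ratio2d - 0.8), 1 / 24)
  same <- measure_2d_axial(a$mask, a$mask, c(0, 0, 20))
  expect_identical(same$ratio2d, 1.0)
  expect_error(measure_2d_axial(a$mask, b$mask, c(0, 0, 500)), "outside volume")
})
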