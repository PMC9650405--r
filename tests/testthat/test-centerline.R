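test_that("a straight tube thins to a two-endpoint, branch-free curve", {
  sg <- fx_cylinder_cl()$sg
  expect_length(sg$endpoints, 2)
  expect_length(sg$branch_nodes, 0)
})

test_that("a bifurcating tube thins to a Y: three endpoints, one junction", {
  sg <- fx_bifurcation_sg()
  expect_length(sg$endpoints, 3)
  expect_gte(length(sg$branch_nodes), 1)
})

test_that("skeletonize enforces its preconditions", {
  expect_error(skeletonize(volume_mask(array(0L, dim = c(5, 5, 5)), c(1, 1, 1))),
               "empty")
  vox <- array(0L, dim = c(12, 6, 6))
  vox[2:3, 2:3, 2:3] <- 1L
  vox[9:10, 2:3, 2:3] <- 1L
  expect_error(skeletonize(volume_mask(vox, c(1, 1, 1))), "largest_component")
})

test_that("a ball yields a degenerate skeleton and tiny blobs give no admissible path", {
  # sphere: skeletonize succeeds; its anchored medial path is a diameter chord
  grid <- seq(-12, 12, by = 0.8)
  fg <- array(FALSE, dim = rep(length(grid), 3))
  for (k in seq_along(grid))
    fg[, , k] <- outer(grid^2, grid^2, "+") + grid[k]^2 <= 100
  sph <- volume_mask(array(as.integer(fg), dim = dim(fg)), rep(0.8, 3))
  expect_s3_class(skeletonize(sph), "skeleton_graph")
  # a sub-millimetre blob has no path of at least 1 mm
  blob <- array(0L, dim = c(5, 5, 5)); blob[3, 3, 3] <- 1L
  bsg <- skeletonize(volume_mask(blob, c(0.3, 0.3, 0.3)))
  expect_error(main_path(bsg), "no admissible path")
})

test_that("the recovered centerline tracks the truth axis within a voxel diagonal", {
  ph <- fx_cylinder()
  cl <- fx_cylinder_cl()$cl
  tr <- ph$truth$centerline_mm
  dev <- vapply(seq(1, nrow(cl$points_mm), by = 5), function(i) {
    min(sqrt(rowSums(sweep(tr, 2, cl$points_mm[i, ], "-")^2)))
  }, numeric(1))
  expect_lt(max(dev), sqrt(sum(ph$mask$spacing_mm^2)))
  # structural invariants
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-6))
  expect_true(all(diff(cl$cum_arclen_mm) > 0))
  step <- diff(cl$cum_arclen_mm)
  expect_true(all(step > 0.18 & step < 0.22))
})

test_that("arc length is recovered within 3% and beats the chord (triangle inequality)", {
  pair <- fx_pair()
  sg <- skeletonize(pair$aorta$mask)
  cl <- main_path(sg, anchor_hint_mm = pair$aorta$truth$anchor_mm)
  total <- max(cl$cum_arclen_mm)
  expect_lt(abs(total - pair$aorta$truth$arc_length_mm) /
              pair$aorta$truth$arc_length_mm, 0.03)
  chord <- sqrt(sum((cl$points_mm[nrow(cl$points_mm), ] - cl$points_mm[1, ])^2))
  expect_gte(total, chord)
})

test_that("the anchor hint selects the nearer path end", {
  ph <- fx_cylinder()
  cl <- fx_cylinder_cl()$cl
  end <- cl$points_mm[cl$anchor_index, ]
  expect_lt(sqrt(sum((end - ph$truth$anchor_mm)^2)), 15) # within a tube radius
  # opposite hint anchors the opposite end
  far_hint <- ph$truth$centerline_mm[nrow(ph$truth$centerline_mm), ]
  sg <- fx_cylinder_cl()$sg
  cl2 <- main_path(sg, anchor_hint_mm = far_hint)
  end2 <- cl2$points_mm[cl2$anchor_index, ]
  expect_lt(sqrt(sum((end2 - far_hint)^2)), 15)
  expect_gt(sqrt(sum((end2 - ph$truth$anchor_mm)^2)), 30)
})

test_that("skeleton and main path are rotation-equivariant within a voxel diagonal", {
  set.seed(42)
  sp <- c(0.6, 0.6, 0.8)
  for (i in 1:3) {
    R <- rotation_about(stats::rnorm(3), stats::runif(1, 0.3, 1.2))
    axis <- as.numeric(R %*% c(0, 0, 1))
    ph <- make_phantom(phantom_spec("cylinder", tube_radius_mm = 12, length_mm = 45,
                                    spacing_mm = sp, axis = axis))
    sg <- skeletonize(ph$mask)
    cl <- main_path(sg, anchor_hint_mm = ph$truth$anchor_mm)
    # rotated truth axis = phantom truth centerline; compare pointwise over
    # the medial portion (the reconstructed cap extensions are compared
    # against truth end segments that thinning cannot observe, so the first
    # and last tube radius of arc length are excluded)
    tr <- ph$truth$centerline_mm
    s <- cl$cum_arclen_mm
    interior <- which(s > 12 & s < max(s) - 12)
    dev <- vapply(interior[seq(1, length(interior), by = 10)], function(j) {
      min(sqrt(rowSums(sweep(tr, 2, cl$points_mm[j, ], "-")^2)))
    }, numeric(1))
    expect_lt(max(dev), sqrt(sum(sp^2)))
  }
})

test_that("bifurcation localization is within two voxel spacings of truth", {
  for (sp in list(c(0.7, 0.7, 1.0), c(0.89, 0.89, 1.25))) {
    pair <- make_vessel_pair(17.4, 13.9, spacing_mm = sp)
    bif <- detect_bifurcation(skeletonize(pair$pa$mask))
    expect_lt(sqrt(sum((bif - pair$pa$truth$bifurcation_mm)^2)), 2 * max(sp))
  }
})

test_that("a one-millimetre spur does not move the detected bifurcation", {
  ph <- fx_bifurcation()
  base <- detect_bifurcation(fx_bifurcation_sg())
  vox <- ph$mask$voxels
  # bolt a small bump onto the trunk surface half-way up
  kz <- round((15 - ph$mask$origin_mm[3]) / ph$mask$spacing_mm[3]) + 1
  sl <- vox[, , kz]
  edge <- which(sl == 1L, arr.ind = TRUE)
  imax <- edge[which.max(edge[, 1]), ]
  vox[imax[1] + 1, imax[2], kz] <- 1L
  vox[imax[1] + 2, imax[2], kz] <- 1L
  spurred <- volume_mask(vox, ph$mask$spacing_mm, ph$mask$origin_mm)
  bif <- detect_bifurcation(skeletonize(spurred))
  expect_lt(sqrt(sum((bif - base)^2)), 2 * max(ph$mask$spacing_mm))
})

test_that("detect_bifurcation refuses a branch-free skeleton", {
  expect_error(detect_bifurcation(fx_cylinder_cl()$sg), "no bifurcation")
})

test_that("point_at_arclen interpolates from the anchored end", {
  cl <- fx_cylinder_cl()$cl
  p0 <- point_at_arclen(cl, 0)
  anchor_pt <- cl$points_mm[cl$anchor_index, ]
  expect_lt(sqrt(sum((p0$point_mm - anchor_pt)^2)), 1e-6)
  p25 <- point_at_arclen(cl, 2.5)
  expect_lt(abs(sqrt(sum((p25$point_mm - anchor_pt)^2)) - 25), 0.3)
  expect_error(point_at_arclen(cl, 7.0), "window exceeds vessel extent")
})

test_that("centerline JSON export is stable and parseable", {
  cl <- fx_cylinder_cl()$cl
  p <- tempfile(fileext = ".json")
  write_centerline(cl, p)
  parsed <- jsonlite::read_json(p)
  expect_length(parsed$points_mm, nrow(cl$points_mm))
  expect_equal(parsed$anchor_index, cl$anchor_index)
  unlink(p)
})
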