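# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# standard straight tube: r = 15 mm, 60 mm long, mid-range spacing
fx_cylinder <- function() fx_cached("cyl", function() {
  make_phantom(phantom_spec("cylinder", tube_radius_mm = 15, length_mm = 60,
                            spacing_mm = c(0.7, 0.7, 1.0)))
})

fx_cylinder_cl <- function() fx_cached("cyl_cl", function() {
  ph <- fx_cylinder()
  sg <- skeletonize(ph$mask)
  list(sg = sg, cl = main_path(sg, anchor_hint_mm = ph$truth$anchor_mm))
})

# pulmonary-trunk-like bifurcation
fx_bifurcation <- function() fx_cached("bif", function() {
  make_phantom(phantom_spec("bifurcation", tube_radius_mm = 13.9, length_mm = 30,
                            branch_radius_mm = 0.8 * 13.9,
                            spacing_mm = c(0.7, 0.7, 1.0)))
})

fx_bifurcation_sg <- function() fx_cached("bif_sg", function() {
  skeletonize(fx_bifurcation()$mask)
})

# cohort-scale aorta/PA pair (true ratio 13.9 / 17.4 = 0.799)
fx_pair <- function() fx_cached("pair", function() {
  make_vessel_pair(17.4, 13.9, spacing_mm = c(0.7, 0.7, 1.0))
})

fx_config <- function(halfwidth = 30) {
  measurement_config(plane_halfwidth_mm = halfwidth)
}

# rotation matrix about an arbitrary axis (Rodrigues)
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# independent flood-fill component counter (oracle for cpp labeling)
oracle_components <- function(fg, connectivity) {
  d <- dim(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  seen <- array(FALSE, dim = d)
  ncomp <- 0L
  idx <- which(fg)
  for (s in idx) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (t in seq_len(nrow(offs))) {
        nb <- ci + offs[t, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (fg[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
  }
  ncomp
}
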