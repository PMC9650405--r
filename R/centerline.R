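#' Skeletonize a binary vessel mask into a graph
#'
#' Runs topology-preserving curve thinning on the mask, ordered by the
#' interior Euclidean distance transform so the retained curve stays on the
#' medial ridge, then converts the skeleton voxels into a weighted graph
#' (edges between 26-adjacent skeleton voxels, weighted by physical
#' distance). Spurious leaf branches shorter than `prune_factor` times the
#' local vessel radius (distance-transform value at the attachment node) are
#' pruned; a leaf's length is credited with its endpoint's own inscribed
#' radius, since thinning retracts the skeleton of a blunt tube by one
#' radius at the cap.
#'
#' @param mask A single-component, nonempty [volume_mask()].
#' @param prune_factor Leaf branches shorter than `prune_factor * local
#'   radius` are removed. Default 2.
#' @return A `skeleton_graph`: list with `graph` (igraph, vertices carry mm
#'   coordinates and local radius), `endpoints`, `branch_nodes` (vertex
#'   names), and the source mask.
#' @export
skeletonize <- function(mask, prune_factor = 2) {
  stopifnot_mask(mask)
  if (sum(mask$voxels) == 0L) stop("empty segmentation", call. = FALSE)
  dims <- dim(mask$voxels)
  fg <- array(mask$voxels == 1L, dim = dims)
  if (max(cpp_label(fg, dims, 26L)) > 1L)
    stop("mask has multiple components; apply largest_component() first", call. = FALSE)

  dsq <- cpp_edt_sq(fg, dims, mask$spacing_mm, TRUE)
  anchors <- skeleton_anchors(fg, dims, dsq, mask$spacing_mm)
  skel <- cpp_thin3d(fg, dims, dsq, anchors)

  idx <- which(skel)
  if (length(idx) == 0L) stop("thinning removed all voxels", call. = FALSE)
  ijk0 <- arrayInd(idx, dims) - 1L
  pts <- voxel_to_mm(mask, ijk0)
  radius <- sqrt(dsq[idx])

  g <- skeleton_voxel_graph(idx, ijk0, pts, dims)
  igraph::V(g)$radius <- radius

  sg <- structure(list(graph = g, mask = mask), class = "skeleton_graph")
  sg <- prune_skeleton(sg, prune_factor)
  sg
}

# Anchor voxels for the thinning: one medial voxel per geodesic extremity
# (limb tip) of the foreground. Tip candidates are the plateau clusters of
# local maxima of the geodesic distance from each of the two mutually
# farthest voxels; each cluster's representative is then ascended along the
# distance transform to the nearest interior ridge, so anchors sit where
# the true medial axis ends (not on cap-rim corners).
skeleton_anchors <- function(fg, dims, dsq, spacing) {
  d0 <- cpp_geodesic_bfs(fg, dims, spacing, which.max(dsq) - 1)
  f1 <- which.max(d0)
  d1 <- cpp_geodesic_bfs(fg, dims, spacing, f1 - 1)
  f2 <- which.max(d1)
  d2 <- cpp_geodesic_bfs(fg, dims, spacing, f2 - 1)
  locmax <- cpp_locmax26(d1, fg, dims) | cpp_locmax26(d2, fg, dims)
  lab <- cpp_label(locmax, dims, 26L)
  cand <- vapply(seq_len(max(lab)), function(ci) {
    vs <- which(lab == ci)
    edt_ascend(vs[which.max(dsq[vs])], dsq, dims, spacing)
  }, numeric(1))
  # ascent from different rim corners of one cap converges to the same
  # medial end region: keep one anchor per neighbourhood
  cand <- unique(cand)
  ord <- cand[order(-dsq[cand], cand)]
  ijk <- arrayInd(ord, dims)
  pos <- sweep(ijk - 1L, 2, spacing, "*")
  thr2 <- (2.5 * max(spacing))^2
  keep <- logical(length(ord))
  for (t in seq_along(ord)) {
    if (t == 1L || all(rowSums(sweep(pos[which(keep), , drop = FALSE], 2,
                                     pos[t, ], "-")^2) > thr2))
      keep[t] <- TRUE
  }
  anchors <- array(FALSE, dim = dims)
  anchors[ord[keep]] <- TRUE
  anchors
}

# Steepest-ascent of the distance transform from a surface tip toward the
# end of the local medial axis. Each step must gain at least 2% in squared
# depth: climbing out of a surface tip gains far more per step, while
# discretization jitter on the interior medial plateau gains almost
# nothing. On steeply tapering vessels the ascent can follow the radius
# gradient some way up the trunk; the main-path end extension compensates.
edt_ascend <- function(idx, dsq, dims, spacing) {
  nxy <- dims[1] * dims[2]
  repeat {
    k0 <- (idx - 1) %/% nxy
    j0 <- ((idx - 1) %% nxy) %/% dims[1]
    i0 <- (idx - 1) %% dims[1]
    scan <- function(rad) {
      best <- idx
      for (dk in -rad:rad) for (dj in -rad:rad) for (di in -rad:rad) {
        i <- i0 + di; j <- j0 + dj; k <- k0 + dk
        if (i < 0 || i >= dims[1] || j < 0 || j >= dims[2] || k < 0 || k >= dims[3]) next
        u <- 1 + i + dims[1] * (j + dims[2] * k)
        if (dsq[u] > dsq[best]) best <- u
      }
      best
    }
    best <- scan(1L)
    # a single jutting corner voxel can be a strict local maximum of its
    # immediate neighbourhood while sitting on the surface: allow a radius-2
    # escape only when no adjacent voxel is deeper at all
    if (best == idx) best <- scan(2L)
    if (dsq[best] < dsq[idx] * 1.02 + 1e-9) return(idx)
    idx <- best
  }
}

shift_arr <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    by <- off[ax]
    if (by >= 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else         { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    if (abs(by) >= d[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

skeleton_voxel_graph <- function(idx, ijk0, pts, dims) {
  key <- as.character(idx)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  idxmap <- stats::setNames(seq_along(idx), key)
  for (t in seq_len(nrow(offs))) {
    nb <- sweep(ijk0, 2, offs[t, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
          nb[, 2] >= 0 & nb[, 2] < dims[2] &
          nb[, 3] >= 0 & nb[, 3] < dims[3]
    lin <- 1 + nb[, 1] + dims[1] * (nb[, 2] + dims[2] * nb[, 3])
    hit <- idxmap[as.character(lin)]
    keep <- ok & !is.na(hit)
    a <- which(keep); b <- unname(hit[keep])
    up <- a < b # each undirected edge once
    from <- c(from, a[up]); to <- c(to, b[up])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  igraph::V(g)$name <- as.character(seq_along(idx))
  g <- igraph::add_edges(g, rbind(from, to))
  w <- sqrt(rowSums((pts[from, , drop = FALSE] - pts[to, , drop = FALSE])^2))
  igraph::E(g)$weight <- w
  igraph::V(g)$x <- pts[, 1]; igraph::V(g)$y <- pts[, 2]; igraph::V(g)$z <- pts[, 3]
  g
}

skeleton_degrees <- function(sg) igraph::degree(sg$graph)

#' @export
print.skeleton_graph <- function(x, ...) {
  deg <- skeleton_degrees(x)
  cat(sprintf("<skeleton_graph> %d voxels, %d endpoints, %d branch nodes\n",
              igraph::vcount(x$graph), sum(deg == 1), sum(deg >= 3)))
  invisible(x)
}

# remove leaf branches shorter than prune_factor * radius at their
# attachment node; iterate to a fixed point
prune_skeleton <- function(sg, prune_factor) {
  g <- sg$graph
  repeat {
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) break
    leaves <- which(deg == 1)
    drop <- character(0)
    for (lf in leaves) {
      path <- integer(0)
      cur <- lf; prev <- 0L
      # thinning retracts a leaf by its local radius (the medial axis of a
      # blunt tube ends one radius short of the cap); credit it back so
      # genuine continuations are not mistaken for spurs
      len <- igraph::V(g)$radius[lf]
      repeat {
        path <- c(path, cur)
        nbs <- as.integer(igraph::neighbors(g, cur))
        nxt <- setdiff(nbs, prev)
        if (length(nxt) != 1L) break # reached branch or end
        e <- igraph::get_edge_ids(g, c(cur, nxt[1]))
        len <- len + igraph::E(g)$weight[e]
        if (igraph::degree(g, nxt[1]) >= 3) {
          if (len < prune_factor * igraph::V(g)$radius[nxt[1]])
            drop <- c(drop, igraph::V(g)$name[path])
          break
        }
        prev <- cur; cur <- nxt[1]
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0L) break
    g <- igraph::delete_vertices(g, drop)
    if (igraph::vcount(g) == 0L) break
  }
  sg$graph <- g
  deg <- igraph::degree(g)
  sg$endpoints <- igraph::V(g)$name[deg <= 1]
  sg$branch_nodes <- igraph::V(g)$name[deg >= 3]
  sg
}

skeleton_points <- function(sg, vids) {
  g <- sg$graph
  cbind(igraph::V(g)$x[vids], igraph::V(g)$y[vids], igraph::V(g)$z[vids])
}

#' Extract the main centerline path
#'
#' Finds the endpoint-to-endpoint geodesic of maximal physical length in the
#' skeleton graph, smooths it with a centred moving average, optionally
#' extends each end to the mask surface along its osculating circle
#' (thinning with endpoint preservation retracts about one local radius
#' inside blunt tube ends), and
#' resamples it at uniform 0.2 mm arc steps. Tangents are unit central
#' differences.
#'
#' @param sg A `skeleton_graph` from [skeletonize()].
#' @param anchor_hint_mm Optional physical point; the path end nearest to it
#'   becomes the measurement anchor. Without a hint the path start is used.
#' @param smooth_window Centred moving-average window (points). Default 5.
#' @param step_mm Resampling arc step, mm. Default 0.2.
#' @param extend_to_mask Extend the path ends to the lumen surface. Default TRUE.
#' @return A `centerline`: list with `points_mm` (n x 3), `tangents` (n x 3
#'   unit rows), `cum_arclen_mm`, `anchor_index` (1 or n).
#' @export
main_path <- function(sg, anchor_hint_mm = NULL, smooth_window = 5,
                      step_mm = 0.2, extend_to_mask = TRUE) {
  if (!inherits(sg, "skeleton_graph")) stop("expected a skeleton_graph", call. = FALSE)
  g <- sg$graph
  eps <- sg$endpoints
  if (length(eps) < 2L) {
    # degenerate ends (e.g. a wide cap whose medial sheet survives as a
    # small web) may leave no degree-1 vertex; fall back to the farthest
    # vertex pair, the natural generalization of endpoint-to-endpoint
    if (igraph::vcount(g) < 2L)
      stop("no admissible path: skeleton has fewer than 2 endpoints", call. = FALSE)
    eps <- igraph::V(g)$name
  }
  D <- igraph::distances(g, v = eps, to = eps, weights = igraph::E(g)$weight)
  D[!is.finite(D)] <- -Inf
  if (!is.null(anchor_hint_mm)) {
    # the hint designates the anchor end: take the longest geodesic that
    # starts at the endpoint nearest the hint (on a branched skeleton the
    # globally longest path may omit the anchored trunk entirely)
    ep_pts <- skeleton_points(sg, match(eps, igraph::V(g)$name))
    a <- which.min(rowSums(sweep(ep_pts, 2, anchor_hint_mm, "-")^2))
    best <- c(a, which.max(D[a, ]))
  } else {
    best <- which(D == max(D), arr.ind = TRUE)[1, ]
  }
  if (!is.finite(D[best[1], best[2]]) || D[best[1], best[2]] < 1)
    stop("no admissible path: maximal skeleton path shorter than 1 mm", call. = FALSE)
  vp <- igraph::shortest_paths(g, from = eps[best[1]], to = eps[best[2]],
                               weights = igraph::E(g)$weight)$vpath[[1]]
  pts <- skeleton_points(sg, as.integer(vp))
  path_radius <- igraph::V(g)$radius[as.integer(vp)]
  # on oblique tubes the curve can end in a diagonal ramp to a cap-rim
  # corner, where the inscribed radius climbs at ~1 mm per mm of path;
  # on a genuine medial end it stays flat — drop ramp-like end runs
  tr <- trim_end_ramps(pts, path_radius)
  pts <- tr$pts; path_radius <- tr$radius
  end_radius <- path_radius[c(1, length(path_radius))]

  pts <- smooth_polyline(pts, smooth_window)
  pts <- resample_polyline(pts, step_mm)
  if (extend_to_mask) {
    pts <- extend_polyline(pts, sg$mask, step_mm, end_radius = end_radius)
    pts <- resample_polyline(pts, step_mm)
  }

  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arclen <- c(0, cumsum(seg))

  anchor_index <- 1L
  if (!is.null(anchor_hint_mm)) {
    d1 <- sum((pts[1, ] - anchor_hint_mm)^2)
    d2 <- sum((pts[nrow(pts), ] - anchor_hint_mm)^2)
    anchor_index <- if (d2 < d1) nrow(pts) else 1L
  }

  tang <- central_tangents(pts)
  structure(list(points_mm = pts, tangents = tang, cum_arclen_mm = arclen,
                 anchor_index = anchor_index),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.1f mm, anchor at %s end\n",
              nrow(x$points_mm), max(x$cum_arclen_mm),
              if (x$anchor_index == 1L) "start" else "far"))
  invisible(x)
}

# Trim ramp-like path ends: walking inward from each end, points where the
# local inscribed radius still grows faster than 0.5 mm per mm of arc are
# part of a corner ramp, not the medial axis. The surviving end sits where
# the radius profile flattens (the true retracted medial end).
trim_end_ramps <- function(pts, radius, slope = 0.5) {
  n <- nrow(pts)
  if (n < 5) return(list(pts = pts, radius = radius))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s_head <- c(0, cumsum(seg))
  cut_head <- ramp_cut(radius, s_head)
  s_rev <- c(0, cumsum(rev(seg)))
  cut_tail <- n + 1 - ramp_cut(rev(radius), s_rev)
  lo <- min(cut_head, n - 4); hi <- max(cut_tail, lo + 4)
  hi <- min(hi, n)
  keep <- lo:hi
  list(pts = pts[keep, , drop = FALSE], radius = radius[keep])
}

ramp_cut <- function(radius, s, slope = 0.5, look_mm = 25) {
  lim <- which(s <= look_mm)
  if (length(lim) < 3) return(1L)
  rmax <- max(radius[lim])
  deep <- which(radius >= 0.9 * rmax)[1]
  if (!is.finite(deep) || deep <= 1) return(1L)
  # ramp-like end: the tip radius falls short of the deep point's radius by
  # more than `slope` mm per mm of arc (a medial end stays flat; a taper or
  # a slightly off-centre end does not climb this fast)
  if (radius[1] >= radius[deep] - slope * s[deep]) return(1L)
  cut <- which(radius >= radius[deep] - slope * (s[deep] - s))[1]
  min(cut, deep)
}

smooth_polyline <- function(pts, window) {
  if (window <= 1 || nrow(pts) < 3) return(pts)
  h <- floor(window / 2)
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

resample_polyline <- function(pts, step_mm) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  ns <- seq(0, total, by = step_mm)
  if (ns[length(ns)] < total - 1e-9) ns <- c(ns, total)
  out <- cbind(stats::approx(s, pts[, 1], xout = ns)$y,
               stats::approx(s, pts[, 2], xout = ns)$y,
               stats::approx(s, pts[, 3], xout = ns)$y)
  out
}

# Extend both ends to the lumen surface. Thinning retracts the skeleton of a
# blunt tube by one local radius, so each end is continued along the
# osculating circle fitted to the terminal stretch of the path (which
# degenerates to a straight line for uncurved vessels) until the running
# point exits the mask (interpolated occupancy < 0.5). The extension is
# capped at ~1.5 local radii, the largest retraction thinning can cause.
extend_polyline <- function(pts, mask, step_mm, end_radius = c(15, 15),
                            fit_mm = 20) {
  vol <- array(as.numeric(mask$voxels), dim = dim(mask$voxels))
  dims <- dim(mask$voxels)
  inside <- function(p) {
    cpp_trilinear(vol, dims, mm_to_voxel(mask, rbind(p))) >= 0.5
  }
  n <- nrow(pts)
  k <- min(n, max(5L, ceiling(fit_mm / step_mm)))

  one_end <- function(seg, r_end) {
    # seg: points ordered so the open end is the LAST row; the extension is
    # capped at the local radius (the retraction thinning can cause) plus
    # slack, and a fitted curvature radius below 1.5 tube radii is rejected
    # as voxel wobble (a real vessel cannot bend that sharply) in favour of
    # a straight continuation along the principal direction.
    max_len <- 1.3 * r_end + 4
    end_pt <- seg[nrow(seg), ]
    if (nrow(seg) < 3) {
      dir <- end_pt - seg[1, ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) return(NULL)
      dir <- dir / nd
      extended <- NULL
      for (i in seq_len(ceiling(max_len / step_mm))) {
        q <- end_pt + i * step_mm * dir
        if (!inside(q)) break
        extended <- rbind(extended, q)
      }
      return(extended)
    }
    ctr <- colMeans(seg)
    sv <- svd(sweep(seg, 2, ctr, "-"))
    e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
    a <- as.numeric(sweep(seg, 2, ctr, "-") %*% e1)
    b <- as.numeric(sweep(seg, 2, ctr, "-") %*% e2)
    circ <- fit_circle2d(a, b)
    # A curved continuation is only trusted when the osculating circle is
    # either much larger than the tube (gentle, harmless curvature) or
    # demonstrably a better description of the terminal stretch than a
    # straight line — voxel wobble can otherwise fit a spuriously tight
    # circle that steers the extension into the cap rim.
    use_circle <- FALSE
    if (!is.null(circ) && circ$R < 1000 && circ$R > 1.5 * r_end) {
      if (circ$R > 4 * r_end) {
        use_circle <- TRUE
      } else {
        rms_line <- sqrt(mean(b^2))
        rms_circ <- sqrt(mean((sqrt((a - circ$cx)^2 + (b - circ$cy)^2) - circ$R)^2))
        use_circle <- rms_line > max(2 * rms_circ, 0.25)
      }
    }
    extended <- NULL
    if (use_circle) {
      ae <- a[length(a)]; be <- b[length(b)]
      phi <- atan2(be - circ$cy, ae - circ$cx)
      phi_prev <- atan2(b[length(b) - 1] - circ$cy, a[length(a) - 1] - circ$cx)
      dphi <- sign_angle(phi - phi_prev) # direction of travel
      if (dphi == 0) return(NULL)
      step_phi <- sign(dphi) * step_mm / circ$R
      for (i in seq_len(ceiling(max_len / step_mm))) {
        ph <- phi + i * step_phi
        q <- ctr + (circ$cx + circ$R * cos(ph)) * e1 + (circ$cy + circ$R * sin(ph)) * e2
        if (!inside(q)) break
        extended <- rbind(extended, q)
      }
    } else {
      dir <- e1 * sign(sum(e1 * (end_pt - ctr)))
      for (i in seq_len(ceiling(max_len / step_mm))) {
        q <- end_pt + i * step_mm * dir
        if (!inside(q)) break
        extended <- rbind(extended, q)
      }
    }
    extended
  }

  head_ext <- one_end(pts[k:1, , drop = FALSE], end_radius[1])
  tail_ext <- one_end(pts[(n - k + 1):n, , drop = FALSE], end_radius[2])
  rbind(if (!is.null(head_ext)) head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE],
        pts, tail_ext)
}

# algebraic (Kasa) circle fit; NULL when degenerate (collinear points)
fit_circle2d <- function(a, b) {
  A <- cbind(2 * a, 2 * b, 1)
  y <- a^2 + b^2
  sol <- tryCatch(qr.solve(A, y), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  R2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(R2) || R2 <= 0) return(NULL)
  list(cx = sol[1], cy = sol[2], R = sqrt(R2))
}

sign_angle <- function(x) {
  x <- ((x + pi) %% (2 * pi)) - pi
  if (abs(x) < 1e-12) 0 else sign(x)
}

# central differences over a +/- span_pts support (3 mm at the 0.2 mm
# resampling): adjacent-sample differences still carry voxel staircase
# noise, which tilts the measurement planes and inflates cross-sections
central_tangents <- function(pts, span_pts = 15L) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  if (n == 1) return(tg)
  h <- max(1L, min(span_pts, n - 1L))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tg <- pts[hi, , drop = FALSE] - pts[lo, , drop = FALSE]
  tg / sqrt(rowSums(tg^2))
}

#' Locate the trunk bifurcation in a skeleton graph
#'
#' Scores each branch node by the physical length of the third-longest
#' subtree incident to it: a genuine trunk split carries three substantial
#' limbs, whereas a node created by a residual spur scores only the spur
#' length. The winning node is then refined to sub-voxel precision as the
#' least-squares intersection point of the three limb axes (a line is fitted
#' to the skeleton points of each incident limb, excluding the junction
#' neighbourhood where thinning is biased); the branch node itself is
#' returned when the refinement is degenerate.
#'
#' @param sg A `skeleton_graph`.
#' @return Numeric length-3 point, mm.
#' @export
detect_bifurcation <- function(sg) {
  if (!inherits(sg, "skeleton_graph")) stop("expected a skeleton_graph", call. = FALSE)
  g <- sg$graph
  bn <- sg$branch_nodes
  if (length(bn) == 0L) stop("no bifurcation present", call. = FALSE)
  # digitization can split one anatomical junction into a small cluster of
  # adjacent branch voxels: merge branch nodes closer than two voxel
  # diagonals (graph distance) into one junction
  spacing <- sg$mask$spacing_mm
  thr <- 2 * sqrt(sum(spacing^2))
  Dbn <- igraph::distances(g, v = bn, to = bn, weights = igraph::E(g)$weight)
  adj <- Dbn <= thr
  cl_g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  membership <- igraph::components(cl_g)$membership
  clusters <- split(bn, membership)

  subtree_info <- function(nodes) {
    gb <- igraph::delete_vertices(g, nodes)
    comp <- igraph::components(gb)
    lens <- vapply(seq_len(comp$no), function(ci) {
      vs <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(gb, vs)
      sum(igraph::E(sub)$weight)
    }, numeric(1))
    list(gb = gb, comp = comp, lens = lens)
  }
  infos <- lapply(clusters, subtree_info)
  score <- vapply(infos, function(si) {
    lens <- sort(si$lens, decreasing = TRUE)
    third <- if (length(lens) >= 3) lens[3] else 0
    third + 1e-9 * sum(lens)
  }, numeric(1))
  best <- which.max(score)
  vb <- match(clusters[[best]], igraph::V(g)$name)
  node_pt <- colMeans(skeleton_points(sg, vb))
  refined <- refine_junction(sg, infos[[best]], node_pt)
  if (is.null(refined)) node_pt else refined
}

# Least-squares point closest to the three limb axes. Near the junction the
# skeleton follows the medial ridge of the merged daughter lobes (a
# "pitchfork" that only gradually converges to the daughter axes), so each
# limb's line is fitted on the OUTER half of the limb, where it is straight.
refine_junction <- function(sg, si, node_pt) {
  gb <- si$gb; comp <- si$comp
  limb_ids <- order(si$lens, decreasing = TRUE)[seq_len(min(3, length(si$lens)))]
  if (length(limb_ids) < 3) return(NULL)
  A <- matrix(0, 3, 3); rhs <- numeric(3)
  radius <- igraph::V(sg$graph)$radius
  vb_r <- radius[which(apply(skeleton_points(sg, seq_len(igraph::vcount(sg$graph))), 1,
                             function(p) all(abs(p - node_pt) < 1e-9)))][1]
  for (ci in limb_ids) {
    vs <- which(comp$membership == ci)
    pts <- cbind(igraph::V(gb)$x[vs], igraph::V(gb)$y[vs], igraph::V(gb)$z[vs])
    d <- sqrt(rowSums(sweep(pts, 2, node_pt, "-")^2))
    sel <- d >= 0.5 * max(d)
    if (sum(sel) < 3) sel <- rank(-d) <= 3
    p <- pts[sel, , drop = FALSE]
    if (nrow(p) < 2) return(NULL)
    ctr <- colMeans(p)
    sv <- svd(sweep(p, 2, ctr, "-"))
    dir <- sv$v[, 1]
    P <- diag(3) - outer(dir, dir)
    A <- A + P
    rhs <- rhs + as.numeric(P %*% ctr)
  }
  x <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(x)) return(NULL)
  # reject refinements that wander away from the junction
  lim <- max(3 * ifelse(is.finite(vb_r), vb_r, 10), 10)
  if (sqrt(sum((x - node_pt)^2)) > lim) return(NULL)
  as.numeric(x)
}

#' Interpolate a point (and tangent) at an arc-length position
#'
#' Positions are measured in centimetres from the anchored end of the
#' centerline.
#'
#' @param cl A `centerline`.
#' @param from_anchor_cm Arc-length position from the anchor, cm.
#' @return List with `point_mm` and `tangent`.
#' @export
point_at_arclen <- function(cl, from_anchor_cm) {
  if (!inherits(cl, "centerline")) stop("expected a centerline", call. = FALSE)
  s_mm <- from_anchor_cm * 10
  total <- max(cl$cum_arclen_mm)
  if (s_mm < -1e-9 || s_mm > total + 1e-9)
    stop("window exceeds vessel extent", call. = FALSE)
  s_mm <- min(max(s_mm, 0), total)
  s <- if (cl$anchor_index == 1L) s_mm else total - s_mm
  pt <- c(stats::approx(cl$cum_arclen_mm, cl$points_mm[, 1], xout = s)$y,
          stats::approx(cl$cum_arclen_mm, cl$points_mm[, 2], xout = s)$y,
          stats::approx(cl$cum_arclen_mm, cl$points_mm[, 3], xout = s)$y)
  tg <- c(stats::approx(cl$cum_arclen_mm, cl$tangents[, 1], xout = s)$y,
          stats::approx(cl$cum_arclen_mm, cl$tangents[, 2], xout = s)$y,
          stats::approx(cl$cum_arclen_mm, cl$tangents[, 3], xout = s)$y)
  tg <- tg / sqrt(sum(tg^2))
  list(point_mm = pt, tangent = tg)
}

# arc-length coordinate (mm, in the centerline's own parameterization)
# of the polyline point nearest to a physical point
nearest_arclen <- function(cl, point_mm) {
  d2 <- rowSums(sweep(cl$points_mm, 2, point_mm, "-")^2)
  cl$cum_arclen_mm[which.min(d2)]
}

#' Export a centerline as JSON
#'
#' @param cl A `centerline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cl, path) {
  out <- list(
    points_mm = unname(apply(cl$points_mm, 1, as.numeric, simplify = FALSE)),
    cum_arclen_mm = cl$cum_arclen_mm,
    anchor_index = cl$anchor_index
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
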