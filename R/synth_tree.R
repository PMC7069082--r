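#' Construct a vessel tree from explicit branches
#'
#' A branch is a polyline (ordered 3D points in mm) with a constant tube
#' radius. Ground-truth morphometrics are computed exactly from the
#' polylines: arc length, endpoint chord, tortuosity = chord/length (<= 1),
#' per-branch cylinder volume `pi r^2 L`, and the node set as the distinct
#' branch endpoints (endpoints shared between branches count once).
#'
#' @param branches list of `list(points = n x 3 matrix (mm), radius_mm = r)`.
#' @return object of class `vessel_tree` with `branches`, `truth` (per-branch
#'   data.frame) and `truth_summary` (`n_nodes`, `vessel_volume_mm3`).
#' @export
vessel_tree <- function(branches) {
  stopifnot(length(branches) >= 0)
  ends <- list()
  rows <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    p <- as.matrix(b$points)
    if (ncol(p) != 3 || nrow(p) < 2) stop("branch polyline needs >= 2 3D points")
    if (b$radius_mm <= 0) stop("branch radius must be > 0")
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    len <- sum(seg)
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    ends[[length(ends) + 1]] <<- p[1, ]
    ends[[length(ends) + 1]] <<- p[nrow(p), ]
    data.frame(branch = i, length_mm = len, chord_mm = chord,
               tortuosity = chord / len, radius_mm = b$radius_mm,
               volume_mm3 = pi * b$radius_mm^2 * len)
  })
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = integer(), length_mm = numeric(), chord_mm = numeric(),
               tortuosity = numeric(), radius_mm = numeric(),
               volume_mm3 = numeric())
  n_nodes <- if (length(ends)) {
    em <- unique(round(do.call(rbind, ends), 6))
    nrow(em)
  } else 0L
  structure(list(branches = branches, truth = truth,
                 truth_summary = list(n_nodes = n_nodes,
                                      vessel_volume_mm3 = sum(truth$volume_mm3))),
            class = "vessel_tree")
}

#' A straight branch (helper for phantoms and tests)
#' @param from,to 3D endpoints in mm.
#' @param radius_mm tube radius (mm).
#' @param n_points polyline sampling.
#' @export
straight_branch <- function(from, to, radius_mm, n_points = 21) {
  tt <- seq(0, 1, length.out = n_points)
  list(points = cbind(from[1] + tt * (to[1] - from[1]),
                      from[2] + tt * (to[2] - from[2]),
                      from[3] + tt * (to[3] - from[3])),
       radius_mm = radius_mm)
}

#' A semicircular branch of given bend radius
#'
#' Arc length is `pi * bend_radius`, the chord `2 * bend_radius`, so the
#' truth tortuosity is exactly `2/pi`.
#'
#' @param bend_radius_mm radius of the semicircle (mm).
#' @param radius_mm tube radius (mm).
#' @param center center of the semicircle (mm).
#' @param n_points polyline sampling.
#' @export
semicircle_branch <- function(bend_radius_mm, radius_mm,
                              center = c(0, 0, 0), n_points = 181) {
  th <- seq(0, pi, length.out = n_points)
  list(points = cbind(center[1] + bend_radius_mm * cos(th),
                      center[2] + bend_radius_mm * sin(th),
                      rep(center[3], n_points)),
       radius_mm = radius_mm)
}

# Rotate unit vector u by angle (rad) at azimuth phi around it.
rotate_about <- function(u, angle, phi) {
  # build an orthonormal frame around u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  d <- cos(angle) * u + sin(angle) * (cos(phi) * v + sin(phi) * w)
  d / sqrt(sum(d^2))
}

#' Generate a random branching vascular tree with exact ground truth
#'
#' Roots start near the bottom-center of the domain and grow upward as
#' gently curved polylines; each non-terminal branch spawns two children
#' rotated away from the parent direction at opposed azimuths. Growth is
#' steered back toward the domain center when a branch approaches the
#' boundary, and candidate branches that would collide with non-adjacent
#' parts of the tree (tube surfaces closer than one voxel-scale margin) are
#' regrown, so the rasterized tree keeps the tree topology of the ground
#' truth. Truth metrics come from [vessel_tree()].
#'
#' @param seed RNG seed (fixed seed gives identical trees).
#' @param n_roots number of root branches.
#' @param branching_depth number of branching generations (0 = roots only).
#' @param radius_range_mm (min, max) tube radius; roots take the max, each
#'   generation shrinks by 25% but never below the min. Must lie within
#'   `(0, min(domain)/4)`.
#' @param domain_mm domain extents (mm), length 3.
#' @param branch_length_mm (min, max) branch arc length.
#' @param curvature per-step angular jitter (radians at unit step); 0 gives
#'   straight branches.
#' @param branch_angle_deg mean angle between a child and its parent.
#' @return a [vessel_tree()].
#' @export
generate_vessel_tree <- function(seed = 0, n_roots = 1, branching_depth = 2,
                                 radius_range_mm = c(0.15, 0.3),
                                 domain_mm = c(8, 8, 8),
                                 branch_length_mm = c(1.5, 2.8),
                                 curvature = 0.12, branch_angle_deg = 35) {
  stopifnot(branching_depth >= 0, n_roots >= 1,
            length(radius_range_mm) == 2, length(domain_mm) == 3)
  if (radius_range_mm[1] <= 0 || radius_range_mm[2] >= min(domain_mm) / 4)
    stop("radius range must lie within (0, min(domain)/4)")
  margin <- 2 * radius_range_mm[2]
  if (min(domain_mm) < max(branch_length_mm) / 2 + 4 * margin)
    stop("domain too small to host the requested tree")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  center <- domain_mm / 2
  branches <- list()
  step_mm <- 0.05
  clear_mm <- 0.15  # surface clearance between non-adjacent branches
  # sampled points of accepted branches, for collision checks
  all_pts <- matrix(numeric(0), 0, 3)
  all_r <- numeric(0)

  collides <- function(pts, radius, start) {
    if (!nrow(all_pts)) return(FALSE)
    # ignore the candidate's own first quarter and existing points near the
    # shared junction
    d_start <- sqrt(rowSums(sweep(all_pts, 2, start)^2))
    keep <- d_start > (all_r + radius + clear_mm)
    if (!any(keep)) return(FALSE)
    P <- all_pts[keep, , drop = FALSE]; R <- all_r[keep]
    from <- max(2L, ceiling(nrow(pts) * 0.25))
    for (i in from:nrow(pts)) {
      dd <- sqrt(rowSums(sweep(P, 2, pts[i, ])^2))
      if (any(dd < R + radius + clear_mm)) return(TRUE)
    }
    FALSE
  }

  grow <- function(start, dir, len, radius) {
    n_steps <- max(4L, ceiling(len / step_mm))
    h <- len / n_steps
    pts <- matrix(0, n_steps + 1, 3)
    pts[1, ] <- start
    u <- dir / sqrt(sum(dir^2))
    for (i in seq_len(n_steps)) {
      if (curvature > 0) {
        u <- u + curvature * sqrt(h) * stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
      }
      nxt <- pts[i, ] + h * u
      # steer back toward the center when close to the boundary
      lo <- nxt < margin; hi <- nxt > domain_mm - margin
      if (any(lo | hi)) {
        pull <- center - pts[i, ]
        pull <- pull / sqrt(sum(pull^2))
        u <- 0.5 * u + 0.5 * pull
        u <- u / sqrt(sum(u^2))
        nxt <- pts[i, ] + h * u
      }
      if (any(nxt < 0) || any(nxt > domain_mm))
        stop("domain too small to host the requested tree")
      pts[i + 1, ] <- nxt
    }
    list(points = pts, radius_mm = radius, end_dir = u)
  }

  queue <- lapply(seq_len(n_roots), function(i) {
    start <- c(center[1] + stats::rnorm(1, 0, domain_mm[1] / 12),
               center[2] + stats::rnorm(1, 0, domain_mm[2] / 12),
               margin + 0.15 * domain_mm[3])
    dir <- c(stats::rnorm(1, 0, 0.15), stats::rnorm(1, 0, 0.15), 1)
    list(start = start, dir = dir, depth = 0L,
         radius = radius_range_mm[2])
  })
  while (length(queue)) {
    task <- queue[[1]]; queue <- queue[-1]
    br <- NULL
    for (try in 1:15) {
      len <- stats::runif(1, branch_length_mm[1], branch_length_mm[2])
      cand <- grow(task$start, task$dir, len, task$radius)
      if (!collides(cand$points, task$radius, task$start)) { br <- cand; break }
    }
    if (is.null(br))
      stop("domain too small to host the requested tree without collisions")
    branches[[length(branches) + 1]] <- br[c("points", "radius_mm")]
    all_pts <- rbind(all_pts, br$points)
    all_r <- c(all_r, rep(br$radius_mm, nrow(br$points)))
    if (task$depth < branching_depth) {
      tip <- br$points[nrow(br$points), ]
      r_child <- max(radius_range_mm[1], task$radius * 0.75)
      phi0 <- stats::runif(1, 0, 2 * pi)
      for (k in 1:2) {
        ang <- (branch_angle_deg + stats::rnorm(1, 0, 5)) * pi / 180
        queue[[length(queue) + 1]] <- list(
          start = tip,
          dir = rotate_about(br$end_dir, ang, phi0 + (k - 1) * pi),
          depth = task$depth + 1L, radius = r_child)
      }
    }
  }
  vessel_tree(branches)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rasterize a vessel tree onto a voxel grid
#'
#' Marks every voxel whose center lies within the tube radius of a branch
#' centerline; additionally stamps the polyline itself (sampled at half-voxel
#' steps) so that branches thinner than one voxel keep a guaranteed
#' one-voxel-wide centerline (with a warning). The radius map holds the local
#' truth radius on vessel voxels (max where branches overlap).
#'
#' @param tree a [vessel_tree()].
#' @param grid a [vox_grid()]; world coordinates of the tree must fall inside.
#' @return list with logical `mask`, numeric `radius_map` (mm), and `grid`.
#' @export
rasterize_vessel_tree <- function(tree, grid) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(grid, "vox_grid"))
  d <- grid$dim; sp <- grid$spacing_mm; or <- grid$origin_mm
  mask <- array(FALSE, d)
  rmap <- array(0, d)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  thin_warned <- FALSE
  for (b in tree$branches) {
    r <- b$radius_mm
    if (r < max(sp) / 2 && !thin_warned) {
      warning("branch thinner than one voxel: guaranteeing 1-voxel centerline")
      thin_warned <- TRUE
    }
    p <- as.matrix(b$points)
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; bb <- p[i + 1, ]
      lo <- pmin(a, bb) - r - max(sp); hi <- pmax(a, bb) + r + max(sp)
      ix <- which(cx >= lo[1] & cx <= hi[1])
      iy <- which(cy >= lo[2] & cy <= hi[2])
      iz <- which(cz >= lo[3] & cz <= hi[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz]))
      ab <- bb - a
      ab2 <- sum(ab^2)
      tpar <- if (ab2 > 0)
        pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                     (pts[, 3] - a[3]) * ab[3]) / ab2, 0), 1) else 0
      dx <- pts[, 1] - (a[1] + tpar * ab[1])
      dy <- pts[, 2] - (a[2] + tpar * ab[2])
      dz <- pts[, 3] - (a[3] + tpar * ab[3])
      inside <- dx * dx + dy * dy + dz * dz <= r * r
      if (any(inside)) {
        sub <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))[inside, ,
                                                                 drop = FALSE]
        lin <- sub[, 1] + d[1] * (sub[, 2] - 1) + d[1] * d[2] * (sub[, 3] - 1)
        mask[lin] <- TRUE
        rmap[lin] <- pmax(rmap[lin], r)
      }
    }
    # guaranteed centerline: resample polyline at half-voxel steps
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    ss <- seq(0, s[length(s)], by = min(sp) / 2)
    cl <- cbind(stats::approx(s, p[, 1], xout = ss)$y,
                stats::approx(s, p[, 2], xout = ss)$y,
                stats::approx(s, p[, 3], xout = ss)$y)
    vi <- cbind(round((cl[, 1] - or[1]) / sp[1]) + 1,
                round((cl[, 2] - or[2]) / sp[2]) + 1,
                round((cl[, 3] - or[3]) / sp[3]) + 1)
    ok <- vi[, 1] >= 1 & vi[, 1] <= d[1] & vi[, 2] >= 1 & vi[, 2] <= d[2] &
      vi[, 3] >= 1 & vi[, 3] <= d[3]
    vi <- vi[ok, , drop = FALSE]
    if (nrow(vi)) {
      lin <- vi[, 1] + d[1] * (vi[, 2] - 1) + d[1] * d[2] * (vi[, 3] - 1)
      mask[lin] <- TRUE
      rmap[lin] <- pmax(rmap[lin], r)
    }
  }
  list(mask = mask, radius_map = rmap, grid = grid)
}
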