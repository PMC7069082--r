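# Shared fixtures and independent oracles, all generated in code.

# Independent RK4 integration of the irreversible 2TC system (the ODE oracle
# for the analytic forward model). Rates in min^-1, times in seconds.
ode_2tc <- function(K1, k2, k3, input, h = 0.05) {
  K1 <- K1 / 60; k2 <- k2 / 60; k3 <- k3 / 60
  cpf <- stats::approxfun(input$times_s, input$Cp, rule = 2)
  tt <- input$times_s
  tg <- seq(0, max(tt), by = h)
  f <- function(t, y) c(K1 * cpf(t) - (k2 + k3) * y[1], k3 * y[1])
  y <- c(0, 0)
  sol <- numeric(length(tt))
  j <- if (tt[1] == 0) 2L else 1L
  for (i in seq_len(length(tg) - 1)) {
    t0 <- tg[i]
    k1v <- f(t0, y); k2v <- f(t0 + h / 2, y + h / 2 * k1v)
    k3v <- f(t0 + h / 2, y + h / 2 * k2v); k4v <- f(t0 + h, y + h * k3v)
    y <- y + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    while (j <= length(tt) && tt[j] <= tg[i + 1] + h / 2) {
      sol[j] <- sum(y); j <- j + 1L
    }
  }
  sol
}

# Number of samples >= half maximum along a profile (integer FWHM).
fwhm_vox <- function(prof) sum(prof >= max(prof) / 2)

# A straight bright tube in noise, with its truth mask.
tube_scene <- function(radius_mm = 0.2, noise = 0.05, seed = 42,
                       dim = c(60, 40, 40), spacing = 0.1) {
  set.seed(seed)
  g <- vox_grid(dim, spacing)
  ctr <- (dim[2:3] / 2) * spacing
  tr <- vessel_tree(list(straight_branch(
    c(5 * spacing, ctr[1], ctr[2]),
    c((dim[1] - 5) * spacing, ctr[1], ctr[2]), radius_mm)))
  ras <- rasterize_vessel_tree(tr, g)
  vol <- array(noise * stats::runif(prod(dim)), dim) + 1.0 * ras$mask
  list(grid = g, tree = tr, mask = ras$mask, radius_map = ras$radius_map,
       volume = vol)
}

# Default ultrafast test scene: thin vessel lines in a 48x48 plane.
vessel_plane_mask <- function() {
  m <- matrix(FALSE, 48, 48)
  m[10, 5:40] <- TRUE
  m[30, 10:45] <- TRUE
  m[5:44, 24] <- TRUE
  m
}

# 3D Gaussian kernel as an array (unit sum).
gauss3 <- function(sigma_vox) {
  k <- exp(-0.5 * ((-ceiling(4 * sigma_vox):ceiling(4 * sigma_vox)) /
                     sigma_vox)^2)
  k <- k / sum(k)
  k3 <- outer(outer(k, k), k)
  dim(k3) <- rep(length(k), 3)
  k3 / sum(k3)
}
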