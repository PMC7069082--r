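#' Generate a synthetic immunofluorescence field with known truth
#'
#' Places `n_cd31_objects` disjoint bright discs (vessel cross-sections) in
#' the CD31 channel; a fixed `round(pericyte_fraction * n)` of them are also
#' marked in the alpha-SMA channel (pericyte-covered vessels). Mild Gaussian
#' background noise is added to both channels.
#'
#' @param seed RNG seed (fixed seed gives an identical field).
#' @param n_cd31_objects number of vessel objects (>= 0).
#' @param pericyte_fraction fraction in [0, 1] of objects covered by
#'   alpha-SMA.
#' @param field_px field shape in pixels (length 2).
#' @param radius_px (min, max) disc radius in pixels.
#' @param noise_amp background noise standard deviation (object intensity 1).
#' @param max_tries placement attempts before declaring the field too small.
#' @return list with `cd31` and `sma` intensity matrices and `truth`
#'   (data.frame of object centers/radii/covered plus `n_objects`,
#'   `coverage_pct`; coverage is `NA` when there are no objects).
#' @export
generate_histo_field <- function(seed = 0, n_cd31_objects = 15,
                                 pericyte_fraction = 0.4,
                                 field_px = c(256, 256),
                                 radius_px = c(4, 9), noise_amp = 0.02,
                                 max_tries = 10000) {
  stopifnot(pericyte_fraction >= 0, pericyte_fraction <= 1,
            n_cd31_objects >= 0, length(field_px) == 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nx <- field_px[1]; ny <- field_px[2]
  cd31 <- matrix(0, nx, ny); sma <- matrix(0, nx, ny)
  centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
  tries <- 0
  while (nrow(centers) < n_cd31_objects) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("cannot place the requested objects disjointly in the field")
    r <- stats::runif(1, radius_px[1], radius_px[2])
    cx <- stats::runif(1, r + 2, nx - r - 1)
    cy <- stats::runif(1, r + 2, ny - r - 1)
    if (nrow(centers)) {
      dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(dd < radii + r + 3)) next
    }
    centers <- rbind(centers, c(cx, cy)); radii <- c(radii, r)
  }
  n <- n_cd31_objects
  n_cov <- if (n > 0) round(pericyte_fraction * n) else 0L
  covered <- rep(FALSE, n)
  if (n_cov > 0) covered[sample.int(n, n_cov)] <- TRUE
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(n)) {
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2
    cd31[inside] <- 1
    if (covered[i]) sma[inside] <- 1
  }
  if (noise_amp > 0) {
    cd31 <- pmax(cd31 + matrix(stats::rnorm(nx * ny, 0, noise_amp), nx, ny), 0)
    sma <- pmax(sma + matrix(stats::rnorm(nx * ny, 0, noise_amp), nx, ny), 0)
  }
  truth <- if (n > 0)
    data.frame(x = centers[, 1], y = centers[, 2], radius_px = radii,
               covered = covered)
  else data.frame(x = numeric(), y = numeric(), radius_px = numeric(),
                  covered = logical())
  list(cd31 = cd31, sma = sma,
       truth = list(objects = truth, n_objects = n,
                    coverage_pct = if (n > 0) 100 * n_cov / n else NA_real_))
}
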