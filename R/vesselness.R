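# Shift a 3D array by an integer offset with edge replication.
shift3 <- function(v, off) {
  d <- dim(v)
  i1 <- pmin(pmax(seq_len(d[1]) + off[1], 1), d[1])
  i2 <- pmin(pmax(seq_len(d[2]) + off[2], 1), d[2])
  i3 <- pmin(pmax(seq_len(d[3]) + off[3], 1), d[3])
  v[i1, i2, i3, drop = FALSE]
}

# Eigenvalues of symmetric 3x3 matrices, vectorized (Smith's trigonometric
# method). Returns an n x 3 matrix sorted by increasing |lambda|.
eig_sym3_by_abs <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  nz <- p > 1e-300
  ps <- ifelse(nz, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[!nz] <- q[!nz]; l2[!nz] <- q[!nz]; l3[!nz] <- q[!nz]
  # sort each triple by |lambda| with a 3-element compare-swap network
  e <- cbind(l1, l2, l3)
  swap <- function(e, i, j) {
    s <- abs(e[, i]) > abs(e[, j])
    tmp <- e[s, i]; e[s, i] <- e[s, j]; e[s, j] <- tmp
    e
  }
  e <- swap(e, 1, 2); e <- swap(e, 2, 3); e <- swap(e, 1, 2)
  e
}

#' Multi-scale Hessian (Frangi) vesselness
#'
#' Bright-tube enhancement: at each scale the volume is Gaussian-smoothed,
#' the scale-normalized Hessian computed by central differences, and the
#' eigenvalue ratios combined into the tubularity response
#' `V = (1 - exp(-Ra^2/2a^2)) exp(-Rb^2/2b^2) (1 - exp(-S^2/2c^2))`,
#' zero wherever the two principal curvatures are not both negative. The
#' final response is the maximum over scales.
#'
#' @param volume 3D array (dims >= 3 voxels on each axis).
#' @param spacing_mm voxel spacing (mm), scalar or length 3.
#' @param scales_mm Gaussian scales in mm, spanning the expected vessel radii.
#' @param alpha,beta Frangi plate/blob discrimination parameters.
#' @param c structureness parameter; `NULL` uses half the maximum Hessian
#'   norm at each scale.
#' @return non-negative response volume, same shape.
#' @export
hessian_vesselness <- function(volume, spacing_mm = 0.1,
                               scales_mm = c(0.1, 0.2, 0.4),
                               alpha = 0.5, beta = 0.5, c = NULL) {
  v <- as_array3(volume)
  d <- dim(v)
  if (any(d < 3)) stop("volume too small for Hessian estimation")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(all(scales_mm > 0))
  resp <- array(0, d)
  for (s in scales_mm) {
    sm <- gaussian_smooth(v, s / spacing_mm)
    ax <- function(i) { o <- c(0, 0, 0); o[i] <- 1; o }
    d2 <- function(i) {
      (shift3(sm, ax(i)) - 2 * sm + shift3(sm, -ax(i))) / spacing_mm[i]^2
    }
    dxy <- function(i, j) {
      (shift3(sm, ax(i) + ax(j)) - shift3(sm, ax(i) - ax(j)) -
         shift3(sm, ax(j) - ax(i)) + shift3(sm, -ax(i) - ax(j))) /
        (4 * spacing_mm[i] * spacing_mm[j])
    }
    s2 <- s^2  # gamma = 2 scale normalization
    h11 <- s2 * d2(1); h22 <- s2 * d2(2); h33 <- s2 * d2(3)
    h12 <- s2 * dxy(1, 2); h13 <- s2 * dxy(1, 3); h23 <- s2 * dxy(2, 3)
    e <- eig_sym3_by_abs(as.numeric(h11), as.numeric(h22), as.numeric(h33),
                         as.numeric(h12), as.numeric(h13), as.numeric(h23))
    l1 <- e[, 1]; l2 <- e[, 2]; l3 <- e[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    # numerically flat at this scale: nothing but FFT rounding noise
    if (max(S) <= 1e-8 * max(abs(v), 1e-300)) next
    cc <- if (is.null(c)) max(S) / 2 else c
    if (cc <= 0) next
    Ra <- abs(l2) / pmax(abs(l3), 1e-300)
    Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-300)
    V <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    V[l2 > 0 | l3 > 0] <- 0  # bright tubes need both principal curvatures < 0
    dim(V) <- d
    resp <- pmax(resp, V)
  }
  resp
}

#' Isodata (Ridler-Calvard) automatic threshold
#'
#' Iterates `tau <- (mean below tau + mean above tau) / 2` from the global
#' mean until the change falls below `tol`; the fixed point is returned.
#'
#' @param volume numeric array with at least two distinct values.
#' @param tol convergence tolerance on tau (default 1e-6).
#' @param max_iter iteration cap.
#' @return the threshold value.
#' @export
isodata_threshold <- function(volume, tol = 1e-6, max_iter = 1000) {
  x <- as.numeric(volume)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) stop("volume is constant: no threshold exists")
  tau <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= tau]; hi <- x[x > tau]
    if (!length(hi) || !length(lo)) break
    tau_new <- (mean(lo) + mean(hi)) / 2
    if (abs(tau_new - tau) < tol) return(tau_new)
    tau <- tau_new
  }
  tau
}

#' Threshold a vesselness response into a vessel mask
#'
#' Voxels above the threshold are kept; connected components (26) smaller
#' than `min_component_voxels` are removed. An empty result is flagged, not
#' an error, so downstream metrics can emit explicit empty records.
#'
#' @param response_volume response array.
#' @param threshold scalar threshold; `NULL` uses [isodata_threshold()].
#' @param min_component_voxels minimum component size kept (0 = pure
#'   thresholding).
#' @return list with `mask`, `threshold`, `n_components`, logical `empty`.
#' @export
segment_vessels <- function(response_volume, threshold = NULL,
                            min_component_voxels = 0) {
  v <- as_array3(response_volume)
  if (is.null(threshold)) threshold <- isodata_threshold(v)
  if (!is.finite(threshold)) stop("threshold must be finite")
  mask <- v > threshold
  n_comp <- 0L
  if (any(mask) && min_component_voxels > 0) {
    lab <- label_components(mask, 26)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_voxels)
    mask <- array(lab %in% keep, dim(mask))
    n_comp <- length(keep)
  } else if (any(mask)) {
    lab <- label_components(mask, 26)
    n_comp <- max(lab)
  }
  list(mask = mask, threshold = threshold, n_components = n_comp,
       empty = !any(mask))
}
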