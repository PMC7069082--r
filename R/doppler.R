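#' SVD clutter filter for an ultrafast frame stack
#'
#' Reshapes the stack to its space x time Casorati matrix, removes the
#' `n_cut` largest singular components (slowly varying tissue clutter) and
#' reconstructs the residual (blood) stack. The filter is an orthogonal
#' projection: applying it twice with the same `n_cut` changes nothing.
#'
#' @param stack 3D array (nx, nz, n_frames).
#' @param n_cut number of leading components to remove; must be smaller than
#'   the number of time samples. 0 is the identity.
#' @param basis optional temporal clutter basis (n_frames x k matrix, e.g.
#'   the `"clutter_basis"` attribute of a previous call): the fixed
#'   projection `C (I - V V^T)` is applied instead of re-estimating the
#'   subspace, which makes the filter exactly idempotent.
#' @return filtered stack, same shape, with the temporal basis of the removed
#'   subspace attached as attribute `"clutter_basis"`.
#' @export
svd_clutter_filter <- function(stack, n_cut = 2, basis = NULL) {
  stack <- as_array3(stack)
  d <- dim(stack)
  nt <- d[3]
  C <- matrix(stack, d[1] * d[2], nt)
  if (!is.null(basis)) {
    basis <- as.matrix(basis)
    stopifnot(nrow(basis) == nt)
    out <- C - (C %*% basis) %*% t(basis)
    dim(out) <- d
    attr(out, "clutter_basis") <- basis
    return(out)
  }
  if (n_cut >= nt) stop("n_cut must be smaller than the number of time samples")
  if (n_cut == 0) return(stack)
  sv <- svd(C, nu = 0, nv = min(n_cut, nt))
  rank_eff <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_cut >= rank_eff) {
    warning("n_cut >= numerical rank of the stack: output is all zero")
    out <- array(0, d)
    attr(out, "clutter_basis") <- sv$v[, seq_len(n_cut), drop = FALSE]
    return(out)
  }
  V <- sv$v[, seq_len(n_cut), drop = FALSE]
  out <- C - (C %*% V) %*% t(V)
  dim(out) <- d
  attr(out, "clutter_basis") <- V
  out
}

#' Suggest a clutter cutoff from the singular-value energy spectrum
#'
#' Returns the smallest number of leading components that carry at least
#' `energy` of the total stack energy — the components flagged as tissue.
#'
#' @param stack 3D array (nx, nz, n_frames).
#' @param energy cumulative energy fraction (default 0.95).
#' @export
select_clutter_rank <- function(stack, energy = 0.95) {
  stack <- as_array3(stack)
  d <- dim(stack)
  sv <- svd(matrix(stack, d[1] * d[2], d[3]), nu = 0, nv = 0)
  e <- cumsum(sv$d^2) / sum(sv$d^2)
  which(e >= energy)[1]
}

#' Power Doppler image: per-pixel power integrated over the frames
#'
#' `P(x) = sum_t |s(x, t)|^2`.
#'
#' @param filtered_stack 3D array (nx, nz, n_frames), typically the output of
#'   [svd_clutter_filter()].
#' @return non-negative matrix (nx, nz).
#' @export
power_doppler <- function(filtered_stack) {
  s <- as_array3(filtered_stack)
  d <- dim(s)
  matrix(rowSums(matrix(abs(s)^2, d[1] * d[2], d[3])), d[1], d[2])
}

#' Assemble per-plane power images into a 3D power-Doppler volume
#'
#' Planes are stacked along the elevation axis in list order (plane i becomes
#' slice i) with the given inter-plane spacing.
#'
#' @param per_plane_power_images list of equally shaped matrices.
#' @param plane_spacing_mm elevation spacing in mm (> 0).
#' @param in_plane_spacing_mm pixel spacing within a plane (mm), scalar or
#'   length 2.
#' @return list with `power` (3D array) and `grid` ([vox_grid()]).
#' @export
assemble_power_volume <- function(per_plane_power_images, plane_spacing_mm = 0.1,
                                  in_plane_spacing_mm = 0.1) {
  stopifnot(length(per_plane_power_images) >= 1, plane_spacing_mm > 0)
  d1 <- dim(per_plane_power_images[[1]])
  if (!all(vapply(per_plane_power_images,
                  function(p) identical(dim(p), d1), logical(1))))
    stop("all planes must have the same shape")
  np <- length(per_plane_power_images)
  vol <- array(0, c(d1, np))
  for (i in seq_len(np)) vol[, , i] <- per_plane_power_images[[i]]
  if (length(in_plane_spacing_mm) == 1)
    in_plane_spacing_mm <- rep(in_plane_spacing_mm, 2)
  list(power = vol,
       grid = vox_grid(c(d1, np),
                       c(in_plane_spacing_mm, plane_spacing_mm)))
}

flip_kernel <- function(k) {
  d <- dim(k)
  if (is.null(d)) return(rev(k))
  if (length(d) == 2) return(k[rev(seq_len(d[1])), rev(seq_len(d[2]))])
  k[rev(seq_len(d[1])), rev(seq_len(d[2])), rev(seq_len(d[3])), drop = FALSE]
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative update
#' `f <- f * (K^T (c / (K f)))` with a unit-sum kernel; the output stays
#' non-negative and total intensity is conserved (within 1% for content away
#' from the volume faces).
#'
#' @param volume non-negative array (2D or 3D).
#' @param kernel non-negative kernel with odd dims summing to 1 (a plain
#'   vector is applied along the elevation axis).
#' @param n_iter number of iterations (>= 1).
#' @param eps numerical floor in the ratio.
#' @return deconvolved array, same shape as `volume`.
#' @export
richardson_lucy <- function(volume, kernel, n_iter = 10, eps = 1e-12) {
  vmax <- max(abs(volume), 1e-300)
  if (any(volume < -1e-8 * vmax)) stop("volume must be non-negative")
  volume <- pmax(volume, 0)  # FFT rounding can leave tiny negatives
  if (is.null(dim(kernel)) && length(kernel) > 1)
    kernel <- array(kernel, c(1, 1, length(kernel)))
  if (any(kernel < 0)) stop("kernel must be non-negative")
  if (abs(sum(kernel) - 1) > 1e-6) stop("kernel must sum to 1")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (length(kernel) == 1) return(volume)  # impulse kernel: exact fixed point
  d0 <- dim(volume)
  v <- as_array3(volume)
  kf <- flip_kernel(kernel)
  est <- v
  for (i in seq_len(n_iter)) {
    den <- fft_convolve(est, kernel)
    ratio <- v / pmax(den, eps)
    est <- est * fft_convolve(ratio, kf)
    est <- pmax(est, 0)
  }
  dim(est) <- d0
  est
}

# Windowed cross-correlation X(z) = sum_v f(v) r(v + z) for |z| within the
# kernel half-width, computed by zero-padded FFT. Returned with z ascending,
# center lag at floor(dk/2)+1.
xcorr_window <- function(f, r, dk) {
  dc <- dim(f)
  h <- (dk - 1L) %/% 2L
  dpad <- dc + dk
  fp <- array(0, dpad); rp <- array(0, dpad)
  fp[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3])] <- f
  rp[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3])] <- r
  X <- Re(stats::fft(Conj(stats::fft(fp)) * stats::fft(rp), inverse = TRUE)) /
    prod(dpad)
  ix <- lapply(1:3, function(ax) ((-h[ax]:h[ax]) %% dpad[ax]) + 1)
  X[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Blind estimation of the blurring kernel from a bead/wire phantom
#'
#' Alternating Richardson-Lucy updates of the scene and of the kernel (blind
#' deconvolution): the scene is initialized to the observed phantom and the
#' kernel to a broad centered Gaussian; each outer iteration refines the
#' scene with a few RL steps at the current kernel, then refines the kernel
#' by the multiplicative update with scene and observation swapped. The
#' kernel is renormalized to unit sum at every step.
#'
#' @param bead_phantom_volume non-negative array containing at least one
#'   sub-resolution bright structure.
#' @param kernel_dim odd kernel extents (default 11^3).
#' @param n_iter outer (kernel) iterations.
#' @param inner scene RL steps per outer iteration.
#' @param eps numerical floor.
#' @return list with `kernel` (array, unit sum) and `scene` (the deblurred
#'   phantom estimate).
#' @export
estimate_blur_kernel <- function(bead_phantom_volume, kernel_dim = c(11, 11, 11),
                                 n_iter = 20, inner = 3, eps = 1e-12) {
  v <- as_array3(bead_phantom_volume)
  if (any(v < -1e-8 * max(abs(v), 1e-300))) stop("phantom must be non-negative")
  v <- pmax(v, 0)
  if (max(v) - min(v) <= 0) stop("flat phantom: cannot estimate a kernel")
  kernel_dim <- as.integer(kernel_dim)
  if (any(kernel_dim %% 2 == 0)) stop("kernel dims must be odd")
  h <- (kernel_dim - 1L) %/% 2L
  # broad centered Gaussian start
  g1 <- function(n, hh) if (n == 1) 1 else exp(-0.5 * ((-hh:hh) / (hh / 1.5))^2)
  k <- outer(outer(g1(kernel_dim[1], h[1]), g1(kernel_dim[2], h[2])),
             g1(kernel_dim[3], h[3]))
  dim(k) <- kernel_dim
  k <- k / sum(k)
  f <- v
  for (it in seq_len(n_iter)) {
    for (j in seq_len(inner)) {
      ratio <- v / pmax(fft_convolve(f, k), eps)
      f <- pmax(f * fft_convolve(ratio, flip_kernel(k)), 0)
    }
    ratio <- v / pmax(fft_convolve(f, k), eps)
    upd <- xcorr_window(f, ratio, kernel_dim) / sum(f)
    k <- pmax(k * upd, 0)
    s <- sum(k)
    if (s <= 0) stop("kernel estimate collapsed to zero")
    k <- k / s
  }
  list(kernel = k, scene = f)
}
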