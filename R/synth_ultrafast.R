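#' Simulate one ultrafast Doppler plane: low-rank tissue + blood + noise
#'
#' The tissue (clutter) component is an exact sum of `tissue_rank` separable
#' space x time terms built from orthonormalized smooth random spatial fields
#' and slow temporal profiles; component amplitudes decay geometrically
#' (`component_decay`), emulating a dominant bulk-motion clutter component.
#' The blood component is a temporally decorrelated (white) unit-variance
#' sequence on vessel pixels, scaled by `blood_amp`. White sensor noise of
#' amplitude `noise_amp` is added everywhere.
#'
#' @param vessel_slice_mask logical matrix marking vessel pixels in the plane.
#' @param tissue_rank number of tissue components (>= 1).
#' @param tissue_amp Frobenius amplitude of the leading tissue component.
#' @param blood_amp per-sample standard deviation of the blood signal.
#' @param noise_amp white-noise standard deviation (0 for noiseless).
#' @param n_frames frames per plane (300 per protocol).
#' @param component_decay geometric amplitude decay of successive tissue
#'   components.
#' @param seed RNG seed.
#' @return object of class `ultrafast_scene`: list with `stack`
#'   (nx x nz x n_frames), `vessel_mask`, `tissue` (the noiseless clutter
#'   stack), `tissue_rank`, `seed`.
#' @export
simulate_ultrafast_stack <- function(vessel_slice_mask, tissue_rank = 1,
                                     tissue_amp = 100, blood_amp = 1,
                                     noise_amp = 0.01, n_frames = 300,
                                     component_decay = 0.05, seed = 1) {
  mask <- as.matrix(vessel_slice_mask)
  stopifnot(tissue_rank >= 1, tissue_amp >= 0, blood_amp >= 0, noise_amp >= 0,
            n_frames >= 2)
  if (!any(mask) && blood_amp > 0)
    stop("vessel mask is empty but blood_amp > 0")
  nx <- nrow(mask); nz <- ncol(mask)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # smooth random spatial fields, orthonormalized (QR) so component energies
  # are exactly the squared amplitudes
  S <- matrix(0, nx * nz, tissue_rank)
  for (r in seq_len(tissue_rank)) {
    f <- gaussian_smooth(array(stats::rnorm(nx * nz), c(nx, nz, 1)),
                         c(4, 4, 0))
    S[, r] <- as.numeric(f)
  }
  S <- qr.Q(qr(S))
  # slow temporal profiles: r cycles over the acquisition, orthonormalized
  tt <- seq_len(n_frames)
  U <- vapply(seq_len(tissue_rank), function(r)
    cos(2 * pi * r * tt / n_frames + stats::runif(1, 0, 2 * pi)),
    numeric(n_frames))
  U <- qr.Q(qr(matrix(U, n_frames)))
  amps <- tissue_amp * component_decay^(seq_len(tissue_rank) - 1)
  tissue <- S %*% (amps * t(U))

  stack <- tissue
  if (blood_amp > 0) {
    vi <- which(as.logical(mask))
    stack[vi, ] <- stack[vi, ] +
      matrix(stats::rnorm(length(vi) * n_frames, 0, blood_amp),
             length(vi), n_frames)
  }
  if (noise_amp > 0)
    stack <- stack + matrix(stats::rnorm(length(stack), 0, noise_amp),
                            nrow(stack), ncol(stack))
  dim(stack) <- c(nx, nz, n_frames)
  tis <- tissue; dim(tis) <- c(nx, nz, n_frames)
  structure(list(stack = stack, vessel_mask = mask, tissue = tis,
                 tissue_rank = tissue_rank, tissue_amp = tissue_amp,
                 blood_amp = blood_amp, noise_amp = noise_amp, seed = seed),
            class = "ultrafast_scene")
}

#' Apply a known elevational blur to a volume
#'
#' Convolves along the elevation (third) axis with a normalized 1D Gaussian
#' kernel and returns both the blurred volume and the exact kernel used, so
#' deconvolution can be tested against ground truth. Total intensity is
#' conserved for content away from the elevation faces (zero padding).
#'
#' @param volume 3D array.
#' @param kernel_sigma_mm Gaussian sigma in mm (0 = identity).
#' @param spacing_mm voxel spacing along the elevation axis (mm).
#' @return list with `volume` (blurred) and `kernel` (1D numeric, unit sum).
#' @export
apply_elevational_blur <- function(volume, kernel_sigma_mm, spacing_mm = 0.1) {
  stopifnot(kernel_sigma_mm >= 0, spacing_mm > 0)
  volume <- as_array3(volume)
  if (kernel_sigma_mm == 0)
    return(list(volume = volume, kernel = 1))
  k <- gaussian_kernel_1d(kernel_sigma_mm / spacing_mm)
  if (length(k) > 2 * dim(volume)[3] - 1)
    stop("blur kernel exceeds the volume extent along elevation")
  blurred <- fft_convolve(volume, array(k, c(1, 1, length(k))))
  list(volume = blurred, kernel = k)
}
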