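#' Voxel grid descriptor
#'
#' Light container for a 3D voxel lattice shared by all modalities. World
#' coordinates follow `world = (index - 1) * spacing + origin` (voxel centers,
#' 1-based indices), so the first voxel center sits at the origin.
#'
#' @param dim integer vector of length 3, grid shape.
#' @param spacing_mm voxel spacing in mm; scalar (isotropic) or length 3.
#' @param origin_mm world position of the first voxel center (mm).
#' @return an object of class `vox_grid`.
#' @export
vox_grid <- function(dim, spacing_mm = 0.1, origin_mm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  structure(list(dim = dim, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "vox_grid")
}

#' @export
format.vox_grid <- function(x, ...) {
  sprintf("<vox_grid %s @ %s mm>", paste(x$dim, collapse = "x"),
          paste(signif(x$spacing_mm, 3), collapse = "x"))
}

#' @export
print.vox_grid <- function(x, ...) cat(format(x), "\n")

#' Voxel volume of a grid in mm^3 (or mL with `ml = TRUE`)
#' @param grid a [vox_grid()].
#' @param ml return millilitres instead of mm^3.
#' @export
voxel_volume <- function(grid, ml = FALSE) {
  v <- prod(grid$spacing_mm)
  if (ml) v / 1000 else v
}

#' Voxel-center world coordinates along one axis
#' @keywords internal
axis_coords <- function(grid, axis) {
  (seq_len(grid$dim[axis]) - 1) * grid$spacing_mm[axis] + grid$origin_mm[axis]
}

as_array3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array or matrix", call. = FALSE)
  if (length(d) == 2) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 3) stop("expected a 2D or 3D array", call. = FALSE)
  x
}

#' Label connected components of a logical mask
#'
#' 26-connectivity (default) or 6-connectivity in 3D; 2D matrices are handled
#' as single-slice volumes (26-connectivity then equals 8-connectivity in the
#' plane).
#'
#' @param mask logical array (2D or 3D).
#' @param connectivity 26 or 6.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in order of first voxel (column-major) encountered.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d0 <- dim(mask)
  m <- as_array3(mask)
  lab <- cpp_cc_label(as.logical(m), dim(m), as.integer(connectivity))
  dim(lab) <- d0
  lab
}

#' Euclidean distance transform of a mask
#'
#' Distance (mm) from each voxel to the nearest background voxel; exact
#' squared-distance transform computed separably per axis.
#'
#' @param mask logical array (2D or 3D); distances are 0 on background.
#' @param spacing_mm voxel spacing, scalar or per-axis.
#' @return numeric array of distances in mm.
#' @export
distance_transform <- function(mask, spacing_mm = 1) {
  d0 <- dim(mask)
  m <- as_array3(mask)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) == 2) spacing_mm <- c(spacing_mm, 1)
  d <- cpp_edt(as.logical(m), dim(m), as.numeric(spacing_mm))
  dim(d) <- d0
  d
}

# ---- FFT convolution helpers ------------------------------------------------

#' Same-size convolution of an array with a small kernel (zero padding)
#'
#' Linear (non-circular) convolution computed by FFT on a zero-padded grid,
#' cropped back to the input extent with the kernel center at
#' `floor(dim(kernel)/2) + 1`. Kernel dims must be odd.
#' @keywords internal
fft_convolve <- function(x, kernel) {
  d_out <- dim(x)
  to3 <- function(a) {
    d <- dim(a)
    if (is.null(d)) d <- length(a)
    array(a, c(d, rep(1L, 3 - length(d))))
  }
  x <- to3(x); kernel <- to3(kernel)
  dx <- dim(x); dk <- dim(kernel)
  if (any(dk %% 2 == 0)) stop("kernel dims must be odd")
  dpad <- dx + dk - 1L
  xp <- array(0, dpad); kp <- array(0, dpad)
  xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  conv <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    prod(dpad)
  ctr <- (dk - 1L) %/% 2L
  out <- conv[ctr[1] + seq_len(dx[1]), ctr[2] + seq_len(dx[2]),
              ctr[3] + seq_len(dx[3]), drop = FALSE]
  if (!is.null(d_out)) dim(out) <- d_out else out <- as.numeric(out)
  out
}

#' Normalized 1D Gaussian kernel
#' @keywords internal
gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  k <- exp(-0.5 * ((-h:h) / sigma_vox)^2)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Normalized convolution: the zero-padded result is divided by the blurred
#' indicator of the volume extent, so constant volumes stay exactly constant
#' up to FFT rounding (no edge roll-off).
#'
#' @param x 3D array.
#' @param sigma_vox standard deviation in voxels, scalar or per-axis.
#' @keywords internal
gaussian_smooth <- function(x, sigma_vox) {
  x <- as_array3(x)
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  ones <- array(1, dim(x))
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    k1 <- gaussian_kernel_1d(sigma_vox[ax])
    kd <- c(1L, 1L, 1L); kd[ax] <- length(k1)
    x <- fft_convolve(x, array(k1, kd))
    ones <- fft_convolve(ones, array(k1, kd))
  }
  x / pmax(ones, 1e-12)
}
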