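#' Dynamic PET container
#'
#' @param data 4D array (x, y, z, frame) of activity concentration (kBq/mL).
#' @param grid a [vox_grid()].
#' @param schedule a [frame_schedule()]; its frame count must match.
#' @param injected_dose_MBq injected activity (MBq).
#' @param body_weight_g animal weight (g).
#' @export
dynamic_pet <- function(data, grid, schedule, injected_dose_MBq = 10,
                        body_weight_g = 30) {
  stopifnot(length(dim(data)) == 4, inherits(schedule, "frame_schedule"))
  if (dim(data)[4] != nrow(schedule$frames))
    stop("frame axis length does not match the schedule")
  structure(list(data = data, grid = grid, schedule = schedule,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_g = body_weight_g),
            class = "dynamic_pet")
}

#' Ellipsoidal tumor phantom with concentric kinetic shells
#'
#' Builds a per-voxel kinetic label map: background (label 1) plus
#' concentric ellipsoidal shells of the tumor (labels 2..n, innermost last),
#' emulating a metabolically heterogeneous tumor (hot core, cooler rim).
#'
#' @param grid a [vox_grid()].
#' @param center_mm tumor center (mm); default is the grid center.
#' @param radii_mm outer semi-axes of each shell, one row per shell from
#'   outermost to innermost (matrix n x 3) or a vector of isotropic radii.
#' @return integer label array (1 = background, 2 = outer shell, ...).
#' @export
tumor_label_map <- function(grid, center_mm = NULL, radii_mm = c(2.4, 1.6, 0.8)) {
  stopifnot(inherits(grid, "vox_grid"))
  if (is.null(center_mm))
    center_mm <- (grid$dim - 1) / 2 * grid$spacing_mm + grid$origin_mm
  if (is.null(dim(radii_mm))) radii_mm <- matrix(radii_mm, ncol = 3,
                                                 nrow = length(radii_mm))
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  X <- array(cx, grid$dim)
  Y <- array(rep(cy, each = grid$dim[1]), grid$dim)
  Z <- array(rep(cz, each = grid$dim[1] * grid$dim[2]), grid$dim)
  lab <- array(1L, grid$dim)
  for (s in seq_len(nrow(radii_mm))) {
    r <- radii_mm[s, ]
    inside <- ((X - center_mm[1]) / r[1])^2 + ((Y - center_mm[2]) / r[2])^2 +
      ((Z - center_mm[3]) / r[3])^2 <= 1
    lab[inside] <- s + 1L
  }
  lab
}

#' Simulate a dynamic FDG-PET acquisition from a kinetic label map
#'
#' Each labeled region follows the analytic irreversible
#' two-tissue-compartment solution driven by the plasma input; per-frame
#' values are the exact time average of the model over the frame window.
#' Noise is a Poisson surrogate: zero-mean Gaussian with variance
#' proportional to the frame mean and inversely proportional to the frame
#' duration, `sd = noise_scale * sqrt(mean * mean(durations)/duration)`.
#' `noise_scale = 0` returns the exact forward model.
#'
#' @param labels integer 3D array of region labels (>= 1).
#' @param params_by_label list of [kinetic_params()] (or K1/k2/k3 lists),
#'   one per label value; the string `"blood"` marks a blood-pool region
#'   whose activity follows the plasma input itself (a synthetic vena cava).
#' @param input an [input_function()] finely sampled over the schedule.
#' @param schedule a [frame_schedule()].
#' @param grid a [vox_grid()] matching `labels`.
#' @param noise_scale noise magnitude (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param injected_dose_MBq,body_weight_g stored on the result for SUV.
#' @return a [dynamic_pet()].
#' @export
simulate_dynamic_pet <- function(labels, params_by_label, input, schedule,
                                 grid, noise_scale = 0, seed = 1,
                                 injected_dose_MBq = 10, body_weight_g = 30) {
  labs <- sort(unique(as.integer(labels)))
  if (max(labs) > length(params_by_label))
    stop("kinetic map does not cover all labels on the grid")
  nf <- nrow(schedule$frames)
  d <- dim(labels)
  dat <- array(0, c(d, nf))
  frames_by_label <- lapply(labs, function(l) {
    p <- params_by_label[[l]]
    if (identical(p, "blood"))
      return(frame_average(input$times_s, input$Cp, schedule))
    if (any(c(p$K1, p$k2, p$k3) < 0)) stop("rate constants must be non-negative")
    ct <- forward_2tc(p, input)
    frame_average(input$times_s, ct, schedule)
  })
  names(frames_by_label) <- as.character(labs)
  for (f in seq_len(nf)) {
    vol <- array(0, d)
    for (l in labs) vol[labels == l] <- frames_by_label[[as.character(l)]][f]
    dat[, , , f] <- vol
  }
  if (noise_scale > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    dur <- schedule$frames$duration_s
    mdur <- mean(dur)
    for (f in seq_len(nf)) {
      m <- dat[, , , f]
      sdv <- noise_scale * sqrt(pmax(m, 0) * mdur / dur[f])
      dat[, , , f] <- pmax(m + stats::rnorm(length(m), 0, 1) * sdv, 0)
    }
  }
  dynamic_pet(dat, grid, schedule, injected_dose_MBq, body_weight_g)
}
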