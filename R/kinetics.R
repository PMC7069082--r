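#' Kinetic parameters of the irreversible two-tissue-compartment model
#'
#' K1 carries the plasma-to-tissue transport (mL/cm^3/min expressed here in
#' the time unit of the curves, i.e. per second when curves are sampled in
#' seconds), k2 the reverse transport and k3 the phosphorylation
#' (trapping) rate; k4 is fixed at 0. The net influx constant is
#' `Ki = K1*k3/(k2 + k3)`.
#'
#' @param K1,k2,k3 non-negative rate constants.
#' @param PG plasma glucose concentration (units are the caller's; MRGlu
#'   inherits them).
#' @param LC lumped constant in (0, 1]; default 0.69.
#' @return object of class `kinetic_params` with derived `Ki` (and `MRGlu`
#'   when `PG` is given).
#' @export
kinetic_params <- function(K1, k2, k3, PG = NULL, LC = 0.69) {
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be non-negative")
  if (LC <= 0 || LC > 1) stop("LC must be in (0, 1]")
  Ki <- if (k2 + k3 > 0) ki_from_rates(K1, k2, k3) else NA_real_
  out <- list(K1 = K1, k2 = k2, k3 = k3, Ki = Ki, PG = PG, LC = LC,
              MRGlu = if (!is.null(PG) && !is.na(Ki)) mrglu(Ki, PG, LC)
                      else NA_real_)
  structure(out, class = "kinetic_params")
}

#' Net influx constant Ki from the rate constants
#'
#' `Ki = (K1 * k3) / (k2 + k3)`.
#'
#' @param K1,k2,k3 rate constants; `k2 + k3` must be > 0.
#' @export
ki_from_rates <- function(K1, k2, k3) {
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be non-negative")
  if (k2 + k3 <= 0) stop("Ki undefined when k2 + k3 = 0")
  K1 * k3 / (k2 + k3)
}

#' Metabolic rate of glucose
#'
#' `MRGlu = Ki * PG / LC`; MRGlu inherits the concentration units of `PG`.
#'
#' @param Ki net influx constant.
#' @param plasma_glucose plasma glucose concentration.
#' @param LC lumped constant (> 0); default 0.69.
#' @export
mrglu <- function(Ki, plasma_glucose, LC = 0.69) {
  if (LC <= 0) stop("LC must be > 0")
  Ki * plasma_glucose / LC
}

# Exact exponential convolution of a piecewise-linear curve:
# E(t) = integral_0^t Cp(s) exp(-beta (t - s)) ds, evaluated at the sample
# times, computed recursively per linear segment (no quadrature error beyond
# the piecewise-linear representation of Cp).
exp_convolve <- function(times_s, Cp, beta) {
  if (beta == 0) return(cumtrapz(times_s, Cp))
  cpp_exp_convolve(times_s, Cp, beta)
}

#' Forward irreversible two-tissue-compartment model
#'
#' Total tissue activity `C_T = C1 + C2` with
#' `dC1/dt = K1 Cp - (k2 + k3) C1`, `dC2/dt = k3 C1` (k4 = 0), evaluated by
#' the analytic exponential-convolution solution
#' `C_T(t) = K1 k3/(k2+k3) * Int(Cp) + K1 k2/(k2+k3) * Int(Cp e^{-(k2+k3)(t-s)})`
#' on the sample grid of the input function (piecewise-linear Cp).
#'
#' Rate constants are in min^-1 (the field convention) while curve times are
#' in seconds; the conversion happens internally.
#'
#' @param params a [kinetic_params()] or list with K1, k2, k3 (min^-1).
#' @param input an [input_function()] (times in seconds).
#' @param times_s optional times at which to return the TAC (interpolated from
#'   the input grid); defaults to the input sample times.
#' @return numeric TAC in the units of Cp.
#' @export
forward_2tc <- function(params, input, times_s = NULL) {
  K1 <- params$K1 / 60; k2 <- params$k2 / 60; k3 <- params$k3 / 60
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be non-negative")
  tt <- input$times_s; Cp <- input$Cp
  beta <- k2 + k3
  Icp <- cumtrapz(tt, Cp)
  ct <- if (beta == 0) {
    K1 * Icp           # k2 = k3 = 0: pure uptake into the first compartment
  } else {
    K1 * k3 / beta * Icp + K1 * k2 / beta * exp_convolve(tt, Cp, beta)
  }
  if (is.null(times_s)) return(ct)
  stats::approx(tt, ct, xout = times_s, rule = 2)$y
}

#' Fit the irreversible two-tissue-compartment model to a framed TAC
#'
#' Weighted least squares over frame-averaged model predictions; weights
#' default to frame durations. Bounded quasi-Newton optimization from the
#' default start (K1 = 0.1, k2 = 0.1, k3 = 0.05 min^-1) plus two fixed
#' alternate starts; the best objective wins. Rates and bounds are in
#' min^-1; curves are sampled in seconds.
#'
#' @param tac_frames per-frame tissue activity (same units as Cp).
#' @param input an [input_function()] sampled finely over the schedule.
#' @param schedule a [frame_schedule()] (>= 6 frames).
#' @param init start vector (K1, k2, k3).
#' @param lower,upper box bounds on all three rates.
#' @param weights per-frame weights; `NULL` uses frame durations.
#' @return a [kinetic_params()] with extra fields `residual` (weighted RMSE),
#'   `converged` (logical flag) and `fitted` (per-frame model values).
#' @export
fit_2tc <- function(tac_frames, input, schedule,
                    init = c(0.1, 0.1, 0.05), lower = 0, upper = 2,
                    weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  nf <- nrow(schedule$frames)
  if (nf < 6) stop("need at least 6 frames to fit three rate constants")
  if (length(tac_frames) != nf) stop("tac length does not match schedule")
  w <- if (is.null(weights)) schedule$frames$duration_s else weights
  w <- w / sum(w)

  predict_frames <- function(theta) {
    ct <- forward_2tc(list(K1 = theta[1], k2 = theta[2], k3 = theta[3]), input)
    frame_average(input$times_s, ct, schedule)
  }
  obj <- function(theta) sum(w * (predict_frames(theta) - tac_frames)^2)

  starts <- list(init, c(0.05, 0.3, 0.1), c(0.5, 0.05, 0.02))
  best <- NULL
  for (s0 in starts) {
    fit <- try(stats::optim(pmin(pmax(s0, lower), upper), obj,
                            method = "L-BFGS-B",
                            lower = rep(lower, 3), upper = rep(upper, 3),
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    out <- kinetic_params(init[1], init[2], init[3])
    out$converged <- FALSE
    out$residual <- NA_real_
    out$fitted <- rep(NA_real_, nf)
    return(out)
  }
  th <- best$par
  out <- kinetic_params(th[1], th[2], th[3])
  out$converged <- best$convergence == 0
  out$residual <- sqrt(best$value)
  out$fitted <- predict_frames(th)
  out
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of `y = C_T(t)/Cp(t)` against
#' `x = (integral_0^t Cp) / Cp(t)` restricted to frame midpoints at or after
#' `t_star_s`; the slope estimates the net influx constant Ki for an
#' irreversible tracer.
#'
#' @param tac_frames per-frame tissue activity.
#' @param input an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param t_star_s start of the linear range (s); default 600 s.
#' @return list with `Ki` (slope), `intercept`, `r_squared`, `n_frames`.
#' @export
patlak <- function(tac_frames, input, schedule, t_star_s = 600) {
  stopifnot(inherits(schedule, "frame_schedule"))
  mids <- frame_midpoints(schedule)
  keep <- mids >= t_star_s
  if (sum(keep) < 3) stop("need >= 3 frames with midpoint >= t_star")
  Cp_mid <- interp_input(input, mids[keep])
  if (any(Cp_mid <= 0)) stop("Cp must be positive at all frames used")
  # integrate Cp over minutes so the slope is Ki in min^-1
  Icp <- cumtrapz(input$times_s / 60, input$Cp)
  Icp_mid <- stats::approx(input$times_s, Icp, xout = mids[keep], rule = 2)$y
  x <- Icp_mid / Cp_mid
  y <- tac_frames[keep] / Cp_mid
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  list(Ki = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n_frames = sum(keep))
}

#' Caliper tumor volume and enrollment flag
#'
#' `V = 0.5 * length * width^2` (mm^3); animals are enrolled when the volume
#' reaches 140 mm^3 (inclusive boundary).
#'
#' @param length_mm longest axis (mm).
#' @param width_mm perpendicular axis (mm); must not exceed `length_mm`.
#' @param threshold_mm3 enrollment threshold (default 140).
#' @return list with `volume_mm3` and logical `enrolled`.
#' @export
caliper_volume <- function(length_mm, width_mm, threshold_mm3 = 140) {
  if (width_mm <= 0) stop("width must be > 0")
  if (width_mm > length_mm)
    stop("width exceeds length: axes swapped (length is the longest axis)")
  v <- 0.5 * length_mm * width_mm^2
  list(volume_mm3 = v, enrolled = v >= threshold_mm3)
}
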