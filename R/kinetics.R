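#' Perfusion kinetic parameters for one ROI curve
#'
#' Parameterizes the noiseless ICG inflow/outflow model used throughout the
#' simulator. The curve is zero until dye arrival at `onset_time_s`, rises
#' along a gamma-variate-shaped bolus front to `peak_intensity_gs` over
#' `time_to_peak_s`, and then washes out as a plateau-plus-exponential tail
#'
#' \deqn{F(t_{peak} + \Delta t) = P\,[p + (1 - p) e^{-k \Delta t}]}
#'
#' where `p = plateau_fraction` models ICG retention (non-washing residual,
#' characteristic of malignant tissue) and `k = washout_rate_per_s` the
#' clearance rate. The rise is \eqn{P (\tau/\tau_p)^\alpha
#' e^{\alpha(1 - \tau/\tau_p)}} with \eqn{\alpha = 2}, continuous at the
#' peak.
#'
#' @param onset_time_s Injection-to-arrival delay, seconds >= 0.
#' @param time_to_peak_s Rise duration after onset, seconds > 0.
#' @param peak_intensity_gs Peak intensity, greyscale units in (0, 255].
#' @param washout_rate_per_s Exponential decay rate of the post-peak tail,
#'   per second, >= 0. Zero gives a flat post-peak tail.
#' @param plateau_fraction Non-washing residual fraction in \[0, 1\].
#' @return An object of class `kinetic_params`.
#' @seealso [kinetic_curve()], [analytic_downslope()], [class_presets()]
#' @export
kinetic_params <- function(onset_time_s = 5, time_to_peak_s = 20,
                           peak_intensity_gs = 150,
                           washout_rate_per_s = 0.005,
                           plateau_fraction = 0) {
  check_field <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("%s must be a finite number", name), call. = FALSE)
    bad_lo <- if (lo_open) x <= lo else x < lo
    bad_hi <- if (hi_open) x >= hi else x > hi
    if (bad_lo || bad_hi)
      stop(sprintf("%s = %g out of range %s%g, %g%s", name, x,
                   if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"), call. = FALSE)
  }
  check_field(onset_time_s, "onset_time_s", 0, Inf)
  check_field(time_to_peak_s, "time_to_peak_s", 0, Inf, lo_open = TRUE)
  check_field(peak_intensity_gs, "peak_intensity_gs", 0, 255, lo_open = TRUE)
  check_field(washout_rate_per_s, "washout_rate_per_s", 0, Inf)
  check_field(plateau_fraction, "plateau_fraction", 0, 1)
  structure(
    list(onset_time_s = onset_time_s, time_to_peak_s = time_to_peak_s,
         peak_intensity_gs = peak_intensity_gs,
         washout_rate_per_s = washout_rate_per_s,
         plateau_fraction = plateau_fraction),
    class = "kinetic_params"
  )
}

#' Evaluate the noiseless kinetic curve
#'
#' @param t Numeric vector of times (seconds from recording start).
#' @param params A [kinetic_params()] object.
#' @param alpha Shape exponent of the gamma-variate rise (default 2).
#' @return Intensities in greyscale units, same length as `t`.
#' @export
kinetic_curve <- function(t, params, alpha = 2) {
  stopifnot(inherits(params, "kinetic_params"))
  tau <- t - params$onset_time_s
  tp <- params$time_to_peak_s
  P <- params$peak_intensity_gs
  k <- params$washout_rate_per_s
  p <- params$plateau_fraction
  out <- numeric(length(t))
  rising <- tau > 0 & tau <= tp
  out[rising] <- P * (tau[rising] / tp)^alpha * exp(alpha * (1 - tau[rising] / tp))
  decaying <- tau > tp
  dt <- tau[decaying] - tp
  out[decaying] <- P * (p + (1 - p) * exp(-k * dt))
  out
}

#' Closed-form curve milestones of the kinetic model
#'
#' `analytic_tmax()` gives the time of peak intensity; `analytic_downslope()`
#' the normalized downslope at horizon `N` seconds after the peak,
#' \eqn{((p + (1-p) e^{-kN}) - 1)/N}; `analytic_t_half()` the first crossing
#' of half-maximal intensity on the rise (solved numerically on the smooth
#' rise function). These are the oracles that sampled-trace milestone
#' extraction is validated against.
#'
#' @param params A [kinetic_params()] object.
#' @param horizon_s Downslope horizon in seconds after the peak.
#' @return A time in seconds (`analytic_tmax`, `analytic_t_half`) or a slope
#'   per second (`analytic_downslope`).
#' @export
analytic_tmax <- function(params) {
  params$onset_time_s + params$time_to_peak_s
}

#' @rdname analytic_tmax
#' @export
analytic_downslope <- function(params, horizon_s) {
  p <- params$plateau_fraction
  k <- params$washout_rate_per_s
  ((p + (1 - p) * exp(-k * horizon_s)) - 1) / horizon_s
}

#' @rdname analytic_tmax
#' @param alpha Shape exponent of the rise (must match [kinetic_curve()]).
#' @export
analytic_t_half <- function(params, alpha = 2) {
  # normalized rise r(u) = u^alpha * exp(alpha (1 - u)), u = tau/tau_p in (0,1]
  f <- function(u) u^alpha * exp(alpha * (1 - u)) - 0.5
  u_half <- stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
  params$onset_time_s + u_half * params$time_to_peak_s
}

#' Solve the washout rate that yields a target 10-s downslope
#'
#' Given a target normalized downslope at `horizon_s` seconds after the peak
#' and a plateau (retention) fraction, returns the exponential washout rate
#' `k` such that \eqn{((p + (1-p)e^{-k N}) - 1)/N} equals the target.
#'
#' @param downslope Target normalized downslope (per second, <= 0).
#' @param plateau_fraction Retention fraction in \[0, 1).
#' @param horizon_s Horizon the target refers to (default 10 s).
#' @return Washout rate in s^-1.
#' @export
washout_rate_for_downslope <- function(downslope, plateau_fraction = 0,
                                       horizon_s = 10) {
  if (downslope > 0) stop("downslope target must be <= 0", call. = FALSE)
  drop <- -downslope * horizon_s            # total normalized drop over horizon
  inner <- 1 - drop / (1 - plateau_fraction)
  if (inner <= 0)
    stop("target downslope unattainable with this plateau_fraction",
         call. = FALSE)
  -log(inner) / horizon_s
}

#' Tissue-class kinetic presets
#'
#' Per-class distributions of kinetic parameters anchored to the normalized
#' 10-s post-peak outflow slopes characteristic of each tissue type:
#' healthy tissue washes ICG out quickly (downslope about -0.0065 s^-1),
#' benign neoplasia is intermediate (about -0.004 s^-1) and cancer retains
#' dye (about -0.001 s^-1). Each field has a mean and a coefficient of
#' variation (relative spread, default 20%) used when drawing per-ROI
#' parameters in [generate_cohort()].
#'
#' @param cv_spread Coefficient of variation applied to every kinetic field.
#' @param downslope_10 Named vector of target 10-s downslopes per class.
#' @return A named list (healthy/benign/cancer), each with `mean` (a
#'   [kinetic_params()]) and `cv`.
#' @export
class_presets <- function(cv_spread = 0.20,
                          downslope_10 = c(healthy = -0.0065,
                                           benign = -0.004,
                                           cancer = -0.001)) {
  plateau <- c(healthy = 0.0, benign = 0.3, cancer = 0.6)
  ttp <- c(healthy = 15, benign = 20, cancer = 25)
  onset <- c(healthy = 5, benign = 6, cancer = 7)
  peak <- c(healthy = 150, benign = 150, cancer = 150)
  out <- lapply(c(healthy = "healthy", benign = "benign", cancer = "cancer"),
                function(cls) {
    k <- washout_rate_for_downslope(downslope_10[[cls]], plateau[[cls]])
    list(
      mean = kinetic_params(
        onset_time_s = onset[[cls]], time_to_peak_s = ttp[[cls]],
        peak_intensity_gs = peak[[cls]], washout_rate_per_s = k,
        plateau_fraction = plateau[[cls]]),
      cv = cv_spread
    )
  })
  out
}
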