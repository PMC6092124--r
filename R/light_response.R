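#' Hyperbolic speed-vs-intensity response
#'
#' Constructs the saturating response curve linking projected light intensity
#' to the population-mean swimming speed,
#' \deqn{v(I) = v_{dark} + (v_{sat} - v_{dark}) \frac{I}{I + I_{half}},}
#' a rectangular hyperbola rising from the dark baseline `v_dark` to the
#' saturation speed `v_sat`, with half-rise at `I = I_half`. Individual cell
#' speeds follow a homogeneous growth law `v_i(I) = v_i^s f(I)` with
#' `f(I) = v(I)/v_sat`, so the whole speed distribution scales with light and
#' the speed standard deviation stays proportional to the mean.
#'
#' @param v_dark mean speed at zero light (µm/s), `>= 0`.
#' @param v_sat saturation speed at bright light (µm/s), `> v_dark`.
#' @param I_half intensity at which the rise is half complete; same units as
#'   the intensities later passed to [mean_speed()] (8-bit projector levels
#'   by default, or mW/mm² after calibration).
#' @return an object of class `intensity_response`.
#' @seealso [mean_speed()], [speed_std()], [light_to_speed_map()]
#' @export
intensity_response <- function(v_dark = 2, v_sat = 8, I_half = 50) {
  stopifnot(is.numeric(v_dark), is.numeric(v_sat), is.numeric(I_half))
  if (v_dark < 0) stop("v_dark must be >= 0")
  if (v_sat <= v_dark) stop("v_sat must exceed v_dark")
  if (I_half <= 0) stop("I_half must be > 0")
  structure(list(v_dark = v_dark, v_sat = v_sat, I_half = I_half),
            class = "intensity_response")
}

#' @export
print.intensity_response <- function(x, ...) {
  cat(sprintf(
    "Intensity response: v(I) = %.3g + %.3g I/(I + %.3g) um/s\n",
    x$v_dark, x$v_sat - x$v_dark, x$I_half))
  invisible(x)
}

#' Mean swimming speed at a given light intensity
#'
#' @param I light intensity (vectorised), `>= 0`.
#' @param resp an [intensity_response()].
#' @return mean speed in µm/s, same length as `I`.
#' @examples
#' r <- intensity_response(v_dark = 2, v_sat = 8, I_half = 50)
#' mean_speed(c(0, 50, 1e6), r)  # dark baseline, midpoint, saturation
#' @export
mean_speed <- function(I, resp) {
  stopifnot(inherits(resp, "intensity_response"), is.numeric(I))
  if (any(I < 0)) stop("intensity must be non-negative")
  resp$v_dark + (resp$v_sat - resp$v_dark) * I / (I + resp$I_half)
}

#' Dimensionless response fraction f(I) = v(I)/v_sat
#'
#' Under the homogeneous growth law every cell's speed is its saturation
#' speed times `f(I)`; `f` saturates at 1 for bright light.
#'
#' @inheritParams mean_speed
#' @export
response_fraction <- function(I, resp) mean_speed(I, resp) / resp$v_sat

#' Speed standard deviation at a given intensity
#'
#' The speed spread is proportional to the mean speed at every intensity
#' (a single ratio `r = sigma/v` across the whole light range), as implied
#' by the homogeneous growth law.
#'
#' @inheritParams mean_speed
#' @param r ratio sigma/v, `>= 0`.
#' @export
speed_std <- function(I, resp, r) {
  stopifnot(is.numeric(r), r >= 0)
  r * mean_speed(I, resp)
}

#' Schultz shape parameter from speed moments
#'
#' The Schultz (gamma-like) speed distribution with mean `v` and standard
#' deviation `sigma` has shape parameter `Z = (v/sigma)^2 - 1`; `Z = 0` is
#' the exponential distribution and `Z -> Inf` the monodisperse limit.
#'
#' @param v mean speed, `> 0`.
#' @param sigma speed standard deviation, `> 0` (`sigma = 0` gives `Inf`).
#' @export
schultz_shape <- function(v, sigma) {
  stopifnot(v > 0, sigma >= 0)
  if (any(sigma == 0)) {
    warning("sigma = 0: degenerate (monodisperse) distribution, Z = Inf")
  }
  (v / sigma)^2 - 1
}

#' Two-timescale memory parameters of the speed response
#'
#' A light step changes the swimming speed in two stages: an instantaneous
#' jump covering a fraction `beta` of the total change, followed by an
#' exponential relaxation of the remainder with time constant `tau_m`
#' (attributed to ATP-synthase and stator dynamics; `tau_m` is shared by
#' rising and falling responses).
#'
#' @param beta instantaneous fraction in `[0, 1]`.
#' @param tau_m slow relaxation time (s), `> 0`.
#' @export
memory_params <- function(beta = 0.44, tau_m = 35) {
  stopifnot(is.numeric(beta), is.numeric(tau_m))
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (tau_m <= 0) stop("tau_m must be > 0")
  structure(list(beta = beta, tau_m = tau_m), class = "memory_params")
}

#' Speed after a single light step
#'
#' Mean speed at time `t >= 0` after the imposed speed switches from `V1`
#' (fully adapted) to `V2` at `t = 0`:
#' \deqn{v(t) = V_2 - (1-\beta)(V_2 - V_1) e^{-t/\tau_m},}
#' i.e. an instantaneous jump by `beta * (V2 - V1)` followed by exponential
#' relaxation. Equivalent to convolving the imposed speed history with the
#' unit-mass exponential kernel `exp(-t'/tau_m)/tau_m` weighted `1 - beta`,
#' plus the instantaneous term weighted `beta`.
#'
#' @param t time since the step (s), vectorised, `>= 0`.
#' @param V1,V2 imposed speeds before and after the step (µm/s).
#' @param mem a [memory_params()].
#' @export
step_response <- function(t, V1, V2, mem) {
  stopifnot(inherits(mem, "memory_params"), all(t >= 0))
  V2 - (1 - mem$beta) * (V2 - V1) * exp(-t / mem$tau_m)
}

#' Periodic steady-state response to a square-wave light pattern
#'
#' Mean speed under square-wave forcing of period `period` (s) that switches
#' the imposed speed to `V_hi` at `t = 0` and back to `V_lo` at
#' `t = period/2`, in the periodic steady state (all start-up transients
#' decayed). Each branch is a jump-plus-exponential; because a half period
#' may be shorter than a few `tau_m`, the memory does not fully adapt and
#' the branch endpoints are the self-consistent fixed points of the
#' alternating relaxation.
#'
#' @param t times (s), interpreted modulo `period`.
#' @param period forcing period (s).
#' @param V_lo,V_hi imposed speeds in the dim and bright half-periods (µm/s).
#' @param mem a [memory_params()].
#' @export
square_wave_response <- function(t, period, V_lo, V_hi, mem) {
  stopifnot(inherits(mem, "memory_params"), period > 0)
  T2 <- period / 2
  e2 <- exp(-T2 / mem$tau_m)
  # memory state just before the rising / falling switches
  m_lo <- (V_lo + e2 * V_hi) / (1 + e2)
  m_hi <- V_hi + (m_lo - V_hi) * e2
  tt <- t %% period
  hi <- tt < T2
  m <- ifelse(hi,
              V_hi + (m_lo - V_hi) * exp(-tt / mem$tau_m),
              V_lo + (m_hi - V_lo) * exp(-(tt - T2) / mem$tau_m))
  mem$beta * ifelse(hi, V_hi, V_lo) + (1 - mem$beta) * m
}

#' Simulate a square-wave speed-response experiment
#'
#' Integrates the two-timescale response to a square-wave illumination
#' (imposed speed alternating `V_lo`/`V_hi` every half period, bright phase
#' first), starting fully adapted to `V_lo`, and returns the mean-speed
#' trace sampled on a regular grid — the in-silico analogue of measuring the
#' population speed by DDM once per second during periodic illumination.
#' Optionally folds the trace over periods (discarding the first) and adds
#' multiplicative Gaussian noise.
#'
#' @param period forcing period (s).
#' @param n_periods number of periods to simulate.
#' @param V_lo,V_hi imposed speeds (µm/s).
#' @param mem a [memory_params()].
#' @param dt_sample sampling interval (s), default 1.
#' @param noise_frac relative (multiplicative) Gaussian noise s.d., e.g.
#'   0.02 for 2\% noise; 0 for a noiseless trace.
#' @param fold if `TRUE` (default) average the samples over periods 2..n,
#'   returning one period's worth of data (as done when averaging repeated
#'   stimulation cycles); otherwise return the full trace.
#' @return data.frame with columns `t_s` and `v_um_per_s`.
#' @export
simulate_square_wave_trace <- function(period = 200, n_periods = 8,
                                       V_lo = 4, V_hi = 8,
                                       mem = memory_params(),
                                       dt_sample = 1, noise_frac = 0,
                                       fold = TRUE) {
  stopifnot(n_periods >= 2, dt_sample > 0)
  t <- seq(0, n_periods * period - dt_sample, by = dt_sample)
  # exact integration of dm/dt = (V - m)/tau_m between samples; the
  # memory relaxes toward the level imposed DURING each sampling interval
  # (interval midpoint), while the instantaneous jump term uses the level
  # at the sample time itself
  tt <- t %% period
  hi <- tt < period / 2
  V <- ifelse(hi, V_hi, V_lo)
  V_int <- ifelse(((t - dt_sample / 2) %% period) < period / 2, V_hi, V_lo)
  m <- numeric(length(t))
  m[1] <- V_lo                       # fully adapted to the dim level
  decay <- exp(-dt_sample / mem$tau_m)
  for (i in seq_along(t)[-1]) {
    m[i] <- V_int[i] + (m[i - 1] - V_int[i]) * decay
  }
  v <- mem$beta * V + (1 - mem$beta) * m
  if (noise_frac > 0) v <- v * (1 + rnorm(length(v), sd = noise_frac))
  if (fold) {
    per <- t %/% period
    keep <- per >= 1                 # discard start-up period
    ph <- tt[keep]
    v <- tapply(v[keep], ph, mean)
    data.frame(t_s = as.numeric(names(v)), v_um_per_s = as.numeric(v),
               row.names = NULL)
  } else {
    data.frame(t_s = t, v_um_per_s = v)
  }
}

#' Fit the jump-plus-exponential model to a square-wave speed trace
#'
#' Least-squares fit of [square_wave_response()] — instantaneous fraction
#' `beta`, shared relaxation time `tau_m`, and the two imposed speed levels —
#' to a measured mean-speed trace under square-wave forcing with known
#' period (bright switch at `t = 0`, dim switch at `t = period/2`). Rising
#' and falling branches are fitted jointly with a single `tau_m`.
#'
#' @param times sample times (s).
#' @param speeds measured mean speeds (µm/s).
#' @param period square-wave period (s).
#' @param start optional named list of starting values
#'   (`V_lo`, `V_hi`, `beta`, `tau_m`).
#' @return list with elements `V_lo`, `V_hi`, `beta`, `tau_m`, the fitted
#'   `nls` object (`fit`), and the residual standard deviation `sigma`.
#' @export
fit_step_response <- function(times, speeds, period, start = NULL) {
  stopifnot(length(times) == length(speeds), length(times) >= 10)
  if (sd(speeds) < 1e-12 * max(abs(speeds), 1)) {
    stop("constant speed trace: beta and tau_m are unidentifiable")
  }
  tt <- times %% period
  hi <- tt < period / 2
  if (!any(hi) || all(hi)) stop("trace must sample both half-periods")
  if (is.null(start)) {
    start <- list(V_lo = min(speeds), V_hi = max(speeds),
                  beta = 0.5, tau_m = period / 6)
  }
  df <- data.frame(t = times, v = speeds)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ square_wave_response(t, period, V_lo, V_hi,
                               memory_params(beta, tau_m)),
      data = df, start = start,
      lower = c(V_lo = 0, V_hi = 0, beta = 0, tau_m = 1e-3),
      upper = c(V_lo = Inf, V_hi = Inf, beta = 1, tau_m = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("step-response fit failed: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  list(V_lo = unname(cf["V_lo"]), V_hi = unname(cf["V_hi"]),
       beta = unname(cf["beta"]), tau_m = unname(cf["tau_m"]),
       fit = fit, sigma = summary(fit)$sigma)
}
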