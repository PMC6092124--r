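#' Feedback-loop configuration
#'
#' Proportional control of the light pattern: every `period` seconds the
#' measured (rescaled) density is compared to the target and the pattern is
#' updated by `P * (rho_s - target)`, clipped to the projector's intensity
#' bounds (8-bit by default) and optionally quantized to integer levels, as
#' a hardware projector would.
#'
#' @param gain proportional gain `P` (intensity levels per unit density
#'   error), `> 0`. The default moves the pattern by roughly 10% of the
#'   dynamic range per iteration for an order-one density error.
#' @param period iteration period (s), default 20.
#' @param bounds intensity bounds `c(min, max)`, default 0-255.
#' @param quantize round updated patterns to integer levels.
#' @param snapshot_every interval (s) between position snapshots averaged
#'   into one density measurement.
#' @param smooth_sigma Gaussian smoothing (µm) applied to the measured
#'   density map before rescaling (the counting-noise filter).
#' @param diverge_after flag divergence if the distance grows this many
#'   consecutive feedback iterations.
#' @export
feedback_config <- function(gain = 60, period = 20, bounds = c(0, 255),
                            quantize = TRUE, snapshot_every = 2,
                            smooth_sigma = 4, diverge_after = 6) {
  stopifnot(gain > 0, period > 0, bounds[1] < bounds[2],
            snapshot_every > 0, snapshot_every <= period,
            smooth_sigma >= 0, diverge_after >= 2)
  structure(list(gain = gain, period = period, bounds = bounds,
                 quantize = quantize, snapshot_every = snapshot_every,
                 smooth_sigma = smooth_sigma, diverge_after = diverge_after),
            class = "feedback_config")
}

#' Proportional update of the illumination pattern
#'
#' `I_{n+1} = clip(I_n + P * (rho_s - target))`: pixels where the measured
#' density exceeds the target get more light, which speeds the swimmers up
#' and depletes them; pixels below target get dimmer.
#'
#' @param I_n current light pattern (matrix of intensity levels).
#' @param rho_s measured density map, already rescaled against the target.
#' @param target target density map.
#' @param cfg a [feedback_config()].
#' @export
update_pattern <- function(I_n, rho_s, target, cfg) {
  stopifnot(inherits(cfg, "feedback_config"))
  if (!all(dim(as.matrix(I_n)) == dim(as.matrix(rho_s))) ||
      !all(dim(as.matrix(rho_s)) == dim(as.matrix(target)))) {
    stop("pattern, density and target must share one grid")
  }
  I1 <- as.matrix(I_n) + cfg$gain * (as.matrix(rho_s) - as.matrix(target))
  I1 <- pmin(pmax(I1, cfg$bounds[1]), cfg$bounds[2])
  if (cfg$quantize) I1 <- round(I1)
  I1
}

#' Create a stateful swimmer-simulation handle for the control loop
#'
#' Bundles an agent population, the current light pattern, the response
#' curve and the simulation configuration into an environment that the
#' closed-loop driver advances in place.
#'
#' @param cfg a [sim_config()].
#' @param light initial light pattern (matrix of intensity levels).
#' @param resp an [intensity_response()].
#' @param pixel_size pixel edge (µm).
#' @export
make_swimmer_sim <- function(cfg, light, resp, pixel_size = 2) {
  sim <- new.env(parent = emptyenv())
  sim$cfg <- cfg
  sim$resp <- resp
  sim$pixel_size <- pixel_size
  sim$light <- as.matrix(light)
  sim$box <- c(ncol(sim$light) * pixel_size, nrow(sim$light) * pixel_size)
  sim$pop <- init_population(cfg, sim$box)
  sim$t <- 0
  class(sim) <- "swimmer_sim"
  sim
}

# advance the simulation, returning snapshots every `every` seconds
sim_advance <- function(sim, duration, every) {
  field <- light_to_speed_map(sim$light, sim$resp, sim$pixel_size)
  n_steps <- round(duration / sim$cfg$dt)
  ev <- max(1L, round(every / sim$cfg$dt))
  snaps <- list()
  for (s in seq_len(n_steps)) {
    sim$pop <- sim_step(sim$pop, field, sim$cfg)
    if (s %% ev == 0) snaps[[length(snaps) + 1L]] <- cbind(sim$pop$x,
                                                           sim$pop$y)
  }
  sim$t <- sim$t + n_steps * sim$cfg$dt
  snaps
}

# one density measurement: histogram of snapshots, smoothed, mean 1
measure_density <- function(sim, snaps, cfg) {
  rho <- density_histogram(snaps, dim(sim$light), sim$pixel_size)
  if (cfg$smooth_sigma > 0) {
    sm <- gaussian_filter(unclass(rho), cfg$smooth_sigma, sim$pixel_size)
    rho <- structure(sm / mean(sm), pixel_size = sim$pixel_size,
                     class = class(rho))
  }
  rho
}

#' Run the closed-loop density-shaping experiment in silico
#'
#' Alternates simulation and control: each iteration advances the swimmers
#' for one period under the current pattern, measures the time-averaged
#' density, rescales it against the target ([percentile_rescale()]),
#' records the distance ([map_distance()]), and — once feedback is on —
#' updates the pattern with [update_pattern()]. With `fb_on_after > 0` the
#' first iterations run open loop (static initial pattern), reproducing a
#' feedback-off warm-up; with `gain` effectively ignored via
#' `feedback = FALSE` the whole run is open loop.
#'
#' @param sim a [make_swimmer_sim()] handle (advanced in place).
#' @param target target density map (matrix, same grid as the pattern;
#'   mean-1 normalized).
#' @param cfg a [feedback_config()].
#' @param n_iter number of iterations.
#' @param fb_on_after time (s) before the controller starts updating the
#'   pattern (0 = immediately).
#' @param feedback set `FALSE` to run fully open loop (distance is still
#'   recorded each iteration).
#' @return a `loop_state` list: `dist` (per iteration), `dist_norm`
#'   (normalized to the first value), `t_s`, the final `light` pattern and
#'   measured `rho_s`, the `target`, `fb_active` flags, and the `sim`
#'   handle.
#' @export
run_closed_loop <- function(sim, target, cfg, n_iter = 30,
                            fb_on_after = 0, feedback = TRUE) {
  stopifnot(inherits(sim, "swimmer_sim"), inherits(cfg, "feedback_config"))
  target <- as.matrix(target)
  if (!all(dim(target) == dim(sim$light))) {
    stop("target and light pattern must share one grid")
  }
  dist <- numeric(n_iter); t_s <- numeric(n_iter)
  fb_active <- logical(n_iter)
  rho_s <- NULL
  grow <- 0L
  for (it in seq_len(n_iter)) {
    snaps <- sim_advance(sim, cfg$period, cfg$snapshot_every)
    rho <- measure_density(sim, snaps, cfg)
    rho_s <- percentile_rescale(rho, target)
    dist[it] <- map_distance(rho_s, target)
    t_s[it] <- sim$t
    fb_active[it] <- feedback && sim$t >= fb_on_after
    if (fb_active[it]) {
      sim$light <- update_pattern(sim$light, rho_s, target, cfg)
      if (it > 1 && dist[it] > dist[it - 1]) grow <- grow + 1L else grow <- 0L
      if (grow >= cfg$diverge_after) {
        warning("distance grew for ", grow,
                " consecutive iterations: loop may be diverging, ",
                "consider reducing the gain")
        grow <- 0L
      }
    }
  }
  dist_norm <- if (dist[1] > 0) dist / dist[1] else dist
  structure(list(dist = dist, dist_norm = dist_norm, t_s = t_s,
                 light = sim$light, rho_s = rho_s, target = target,
                 fb_active = fb_active, cfg = cfg, sim = sim),
            class = "loop_state")
}

#' Morph a converged pattern toward a new target
#'
#' Swaps the target of a running closed loop and continues iterating,
#' recording the distance to both the old and the new target each
#' iteration, then fits an exponential `d(t) = d_inf + a * exp(-t/tau)` to
#' the distance-to-new-target decay.
#'
#' @param state a `loop_state` from [run_closed_loop()].
#' @param new_target new target density map (same grid).
#' @param n_iter number of morphing iterations.
#' @return list with `t_s`, `dist_new`, `dist_old` (both unnormalized),
#'   `tau_s` and `r_squared` of the exponential fit, the final `light`
#'   pattern, and the updated `sim`.
#' @export
morph_target <- function(state, new_target, n_iter = 20) {
  stopifnot(inherits(state, "loop_state"))
  sim <- state$sim; cfg <- state$cfg
  old_target <- state$target
  new_target <- as.matrix(new_target)
  dist_new <- numeric(n_iter); dist_old <- numeric(n_iter)
  t_s <- numeric(n_iter)
  t0 <- sim$t
  for (it in seq_len(n_iter)) {
    snaps <- sim_advance(sim, cfg$period, cfg$snapshot_every)
    rho <- measure_density(sim, snaps, cfg)
    rs_new <- percentile_rescale(rho, new_target)
    rs_old <- percentile_rescale(rho, old_target)
    dist_new[it] <- map_distance(rs_new, new_target)
    dist_old[it] <- map_distance(rs_old, old_target)
    t_s[it] <- sim$t - t0
    sim$light <- update_pattern(sim$light, rs_new, new_target, cfg)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ dinf + a * exp(-t / tau),
                      data = data.frame(t = t_s, d = dist_new),
                      start = list(dinf = min(dist_new),
                                   a = max(dist_new) - min(dist_new),
                                   tau = diff(range(t_s)) / 3),
                      lower = c(dinf = 0, a = 0, tau = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tau_s <- NA_real_; r2 <- NA_real_
  if (!is.null(fit)) {
    tau_s <- unname(coef(fit)["tau"])
    res <- dist_new - predict(fit)
    r2 <- 1 - sum(res^2) / sum((dist_new - mean(dist_new))^2)
  }
  list(t_s = t_s, dist_new = dist_new, dist_old = dist_old,
       tau_s = tau_s, r_squared = r2, light = sim$light, sim = sim)
}

#' @importFrom stats predict
NULL
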