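#' Configuration for the photokinetic swimmer simulation
#'
#' Parameters of the 2-D agent-based simulation: smooth swimmers whose
#' target speed is set by the local light level through the response curve,
#' with per-agent saturation speeds (Schultz-distributed), a two-timescale
#' speed memory, rotational diffusion of the heading (decorrelation time
#' `tau_rot`), optional tumbling, and a non-motile fraction undergoing
#' Brownian motion. The simulation box is defined by the speed/light map
#' passed to [sim_step()]; positions are in µm.
#'
#' @param n_agents total number of agents (motile + non-motile).
#' @param dt integration time step (s). Must satisfy `dt <= tau_m / 50`
#'   (memory well resolved) and keep the fastest agent under one pixel per
#'   step (checked at run time against the actual map).
#' @param alpha_motile fraction of agents that are motile and
#'   light-responsive; the rest are passive Brownian scatterers.
#' @param tau_rot heading decorrelation time (s); default 20 s, typical of a
#'   smooth-swimming strain.
#' @param tau_run mean run duration (s) for run-and-tumble dynamics, or
#'   `NULL` (default) for pure smooth swimming.
#' @param mean_sat_speed population-mean saturation speed (µm/s).
#' @param Z Schultz shape parameter of the saturation-speed distribution.
#' @param mem a [memory_params()]; use `beta = 1` for a memoryless response.
#' @param D_brownian translational diffusivity of non-motile agents (µm²/s).
#' @param seed integer RNG seed, or `NULL`.
#' @param boundary `"periodic"` (default) or `"reflecting"`.
#' @export
sim_config <- function(n_agents = 20000, dt = 0.1, alpha_motile = 0.5,
                       tau_rot = 20, tau_run = NULL,
                       mean_sat_speed = 8, Z = 4,
                       mem = memory_params(), D_brownian = 0.3,
                       seed = NULL, boundary = c("periodic", "reflecting")) {
  boundary <- match.arg(boundary)
  stopifnot(n_agents > 0, dt > 0, alpha_motile >= 0, alpha_motile <= 1,
            tau_rot > 0, mean_sat_speed > 0, Z > -1, D_brownian >= 0,
            inherits(mem, "memory_params"))
  if (!is.null(tau_run)) stopifnot(tau_run > 0)
  if (dt > mem$tau_m / 50 && mem$beta < 1) {
    stop(sprintf("dt = %g too coarse for tau_m = %g: need dt <= tau_m/50",
                 dt, mem$tau_m))
  }
  structure(list(n_agents = as.integer(n_agents), dt = dt,
                 alpha_motile = alpha_motile, tau_rot = tau_rot,
                 tau_run = tau_run, mean_sat_speed = mean_sat_speed, Z = Z,
                 mem = mem, D_brownian = D_brownian, seed = seed,
                 boundary = boundary),
            class = "sim_config")
}

#' Sample saturation speeds from the Schultz distribution
#'
#' The Schultz distribution with mean `v` and shape `Z` is the gamma
#' distribution with shape `Z + 1` and rate `(Z + 1)/v`; its standard
#' deviation is `v / sqrt(Z + 1)`.
#'
#' @param n number of draws.
#' @param v mean speed (µm/s).
#' @param Z shape parameter, `> -1`.
#' @export
sample_schultz <- function(n, v, Z) {
  stopifnot(v > 0, Z > -1)
  rgamma(n, shape = Z + 1, rate = (Z + 1) / v)
}

#' Initialize an agent population
#'
#' Positions uniform in the box, headings uniform on `[0, 2*pi)`,
#' saturation speeds Schultz-distributed, motile flags Bernoulli with
#' probability `alpha_motile`. The speed-memory state starts fully adapted
#' to bright light (each agent at its saturation speed), matching a uniform
#' bright pre-exposure long compared to the memory time.
#'
#' @param cfg a [sim_config()].
#' @param box box size `c(width, height)` in µm (must match the map used for
#'   stepping: `ncol(map) * pixel`, `nrow(map) * pixel`).
#' @return an `agent_population`: list of per-agent vectors `x`, `y`,
#'   `theta`, `v_s`, `u` (saturation speed relative to the population mean),
#'   `m` (memory state, µm/s), `motile`, plus the box.
#' @export
init_population <- function(cfg, box) {
  stopifnot(inherits(cfg, "sim_config"), length(box) == 2, all(box > 0))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_agents
  v_s <- sample_schultz(n, cfg$mean_sat_speed, cfg$Z)
  pop <- list(
    x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
    theta = runif(n, 0, 2 * pi),
    v_s = v_s, u = v_s / cfg$mean_sat_speed,
    m = v_s,
    motile = runif(n) < cfg$alpha_motile,
    box = box)
  class(pop) <- "agent_population"
  pop
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("Agent population: %d agents (%.0f%% motile) in %g x %g um\n",
              length(x$x), 100 * mean(x$motile), x$box[1], x$box[2]))
  invisible(x)
}

# resolve a light pattern or speed map to a mean-speed matrix + pixel size
resolve_field <- function(field, resp = NULL) {
  if (inherits(field, "speed_map")) {
    list(V = unclass(field), px = attr(field, "pixel_size"))
  } else {
    if (is.null(resp)) stop("a raw light pattern needs an intensity_response")
    list(V = mean_speed(as.matrix(field), resp), px = 2)
  }
}

#' Advance the agent population by one time step
#'
#' Euler-Maruyama update: each motile agent reads the local imposed speed
#' `V_i = u_i * V(x)` from the map, relaxes its memory state toward it
#' (exact exponential update over `dt`), moves at the actual speed
#' `v = beta * V_i + (1 - beta) * m` along its heading, and diffuses its
#' heading with decorrelation time `tau_rot` (plus optional Poisson
#' tumbles). Non-motile agents take Brownian steps. The boundary is then
#' applied.
#'
#' @param pop an `agent_population`.
#' @param field a [speed_map()] covering the box (or a light matrix, with
#'   `resp` supplied).
#' @param cfg a [sim_config()].
#' @param resp an [intensity_response()], only needed when `field` is a raw
#'   light pattern.
#' @return the updated population.
#' @export
sim_step <- function(pop, field, cfg, resp = NULL) {
  f <- resolve_field(field, resp)
  V <- f$V; px <- f$px
  ny <- nrow(V); nx <- ncol(V)
  if (abs(nx * px - pop$box[1]) > 1e-9 || abs(ny * px - pop$box[2]) > 1e-9) {
    stop("speed map does not cover the simulation box")
  }
  dt <- cfg$dt
  mot <- pop$motile
  if (any(mot)) {
    ix <- pmin(nx, floor(pop$x[mot] / px) + 1L)
    iy <- pmin(ny, floor(pop$y[mot] / px) + 1L)
    Vt <- pop$u[mot] * V[cbind(iy, ix)]
    beta <- cfg$mem$beta
    if (beta < 1) {
      decay <- exp(-dt / cfg$mem$tau_m)
      pop$m[mot] <- Vt + (pop$m[mot] - Vt) * decay
      v <- beta * Vt + (1 - beta) * pop$m[mot]
    } else {
      pop$m[mot] <- Vt
      v <- Vt
    }
    if (max(v) * dt > px) {
      stop(sprintf(
        "fastest agent moves %.2g um > 1 pixel (%.2g um) per step; reduce dt",
        max(v) * dt, px))
    }
    th <- pop$theta[mot]
    pop$x[mot] <- pop$x[mot] + v * dt * cos(th)
    pop$y[mot] <- pop$y[mot] + v * dt * sin(th)
    nm <- sum(mot)
    th <- th + sqrt(2 * dt / cfg$tau_rot) * rnorm(nm)
    if (!is.null(cfg$tau_run)) {
      tum <- runif(nm) < dt / cfg$tau_run
      th[tum] <- runif(sum(tum), 0, 2 * pi)
    }
    pop$theta[mot] <- th
  }
  if (any(!mot) && cfg$D_brownian > 0) {
    nb <- sum(!mot)
    s <- sqrt(2 * cfg$D_brownian * dt)
    pop$x[!mot] <- pop$x[!mot] + s * rnorm(nb)
    pop$y[!mot] <- pop$y[!mot] + s * rnorm(nb)
  }
  if (cfg$boundary == "periodic") {
    pop$x <- pop$x %% pop$box[1]
    pop$y <- pop$y %% pop$box[2]
  } else {
    pop$x <- reflect_coord(pop$x, pop$box[1])
    pop$y <- reflect_coord(pop$y, pop$box[2])
  }
  pop
}

reflect_coord <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Run the simulation to its stationary state and collect snapshots
#'
#' Steps the population for `t_total` seconds and records position
#' snapshots every `sample_every` seconds once the burn-in `t_burn` has
#' passed (pattern formation takes a few minutes of swimming, so a burn-in
#' of several memory/transport times is needed before the density is
#' stationary).
#'
#' @inheritParams sim_step
#' @param t_total total simulated time (s).
#' @param t_burn burn-in discarded before sampling (s).
#' @param sample_every snapshot interval (s).
#' @return list with `snapshots` (list of `n x 2` position matrices),
#'   `motile` (logical vector), `times`, and the final `pop`.
#' @export
run_to_stationary <- function(pop, field, cfg, t_total, t_burn,
                              sample_every, resp = NULL) {
  stopifnot(t_total > t_burn, sample_every > 0)
  n_steps <- round(t_total / cfg$dt)
  every <- max(1L, round(sample_every / cfg$dt))
  burn <- round(t_burn / cfg$dt)
  snaps <- list(); times <- numeric(0)
  n0 <- length(pop$x)
  for (s in seq_len(n_steps)) {
    pop <- sim_step(pop, field, cfg, resp)
    if (s > burn && (s - burn) %% every == 0) {
      stopifnot(length(pop$x) == n0)   # number conservation
      snaps[[length(snaps) + 1L]] <- cbind(pop$x, pop$y)
      times <- c(times, s * cfg$dt)
    }
  }
  list(snapshots = snaps, motile = pop$motile, times = times, pop = pop)
}

#' Normalized density histogram from position snapshots
#'
#' Bins positions onto the pixel grid and normalizes the counts to spatial
#' mean 1; multiple snapshots are accumulated (time average).
#'
#' @param positions an `n x 2` matrix of positions (µm) or a list of such
#'   matrices (snapshots).
#' @param grid_dim `c(ny, nx)` pixels.
#' @param pixel_size pixel edge (µm).
#' @return a `density_map` matrix (spatial mean exactly 1).
#' @export
density_histogram <- function(positions, grid_dim, pixel_size) {
  if (is.matrix(positions)) positions <- list(positions)
  if (length(positions) == 0 || nrow(positions[[1]]) == 0) {
    stop("no positions to histogram")
  }
  ny <- grid_dim[1]; nx <- grid_dim[2]
  counts <- numeric(ny * nx)
  for (p in positions) {
    ix <- pmin(nx - 1L, pmax(0L, floor(p[, 1] / pixel_size)))
    iy <- pmin(ny - 1L, pmax(0L, floor(p[, 2] / pixel_size)))
    counts <- counts + tabulate(1L + iy + ny * ix, nbins = ny * nx)
  }
  rho <- matrix(counts, ny, nx)
  rho <- rho / mean(rho)
  structure(rho, pixel_size = pixel_size,
            class = c("density_map", "matrix", "array"))
}

#' Snapshots of a 3-D swimmer suspension imaged in projection
#'
#' Generates in-plane position snapshots of swimmers moving ballistically
#' in 3-D (headings uniform on the sphere, decorrelating by rotational
#' diffusion) plus a non-motile Brownian fraction — the thick-sample
#' geometry of bright-field video microscopy, where the camera sees the
#' (x, y) projection of cells swimming in all three dimensions. This is the
#' appropriate generator for DDM stacks analysed with the 3-D (`sinc`)
#' swimmer model; the in-plane 2-D simulator corresponds to the `J0`
#' orientation factor instead.
#'
#' @param n number of agents.
#' @param box `c(width, height)` of the imaged field (µm), periodic.
#' @param v mean swimming speed (µm/s).
#' @param Z Schultz shape of the speed distribution.
#' @param alpha motile fraction.
#' @param D Brownian diffusivity of the non-motile fraction (µm²/s).
#' @param n_frames number of snapshots.
#' @param frame_interval time between snapshots (s).
#' @param tau_rot rotational decorrelation time (s).
#' @param dt integration step (s).
#' @return list of `n x 2` position matrices.
#' @export
simulate_projected_swimmers <- function(n, box, v, Z, alpha, D,
                                        n_frames, frame_interval,
                                        tau_rot = 20, dt = frame_interval) {
  stopifnot(n > 0, all(box > 0), v > 0, Z > -1, alpha >= 0, alpha <= 1,
            D >= 0, n_frames >= 2, frame_interval > 0, dt <= frame_interval)
  x <- runif(n, 0, box[1]); y <- runif(n, 0, box[2])
  vs <- sample_schultz(n, v, Z)
  mot <- runif(n) < alpha
  # headings uniform on the unit sphere
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  per <- max(1L, round(frame_interval / dt))
  snaps <- vector("list", n_frames)
  nb <- sum(!mot)
  for (k in seq_len(n_frames)) {
    snaps[[k]] <- cbind(x %% box[1], y %% box[2])
    for (s in seq_len(per)) {
      x[mot] <- x[mot] + vs[mot] * u[mot, 1] * dt
      y[mot] <- y[mot] + vs[mot] * u[mot, 2] * dt
      if (is.finite(tau_rot)) {
        du <- matrix(rnorm(3 * n, sd = sqrt(2 * dt / tau_rot)), n, 3)
        u <- u + du - u * rowSums(u * du)   # tangential kick
        u <- u / sqrt(rowSums(u^2))
      }
      if (nb > 0 && D > 0) {
        sdd <- sqrt(2 * D * dt)
        x[!mot] <- x[!mot] + rnorm(nb, sd = sdd)
        y[!mot] <- y[!mot] + rnorm(nb, sd = sdd)
      }
    }
  }
  snaps
}

#' Simulate the stationary density under a static light pattern
#'
#' Convenience wrapper: initialize a population, run to stationarity, and
#' return the time-averaged normalized density on the map's pixel grid.
#'
#' @inheritParams run_to_stationary
#' @return list with `rho` (density_map), `run` (the [run_to_stationary()]
#'   result), and the resolved speed map `V`.
#' @export
simulate_density <- function(field, cfg, t_total, t_burn, sample_every,
                             resp = NULL) {
  f <- resolve_field(field, resp)
  box <- c(ncol(f$V) * f$px, nrow(f$V) * f$px)
  pop <- init_population(cfg, box)
  run <- run_to_stationary(pop, field, cfg, t_total, t_burn, sample_every,
                           resp)
  rho <- density_histogram(run$snapshots, dim(f$V), f$px)
  list(rho = rho, run = run, V = f$V)
}
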