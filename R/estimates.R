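#' Physical constants for patterning estimates
#'
#' Thermal energy and the speed of light at a configurable temperature
#' (default 298 K, water at room temperature): `kBT = 4.11e-3` pN·µm.
#'
#' @param temperature_K absolute temperature (K).
#' @return list with `kBT_J` (J), `kBT_pN_um` (pN·µm), `c_m_per_s`,
#'   `temperature_K`.
#' @export
physical_constants <- function(temperature_K = 298) {
  stopifnot(temperature_K > 0)
  kB <- 1.380649e-23                       # J/K
  list(kBT_J = kB * temperature_K,
       kBT_pN_um = kB * temperature_K * 1e18,  # 1 J = 1e12 pN * 1e6 um
       c_m_per_s = 299792458,
       temperature_K = temperature_K)
}

#' Nearest power of ten
#'
#' Order-of-magnitude report used throughout the estimates: the power of
#' ten nearest to `x` on a log scale, `10^round(log10(x))`.
#'
#' @param x positive value(s).
#' @export
order_of_magnitude <- function(x) {
  stopifnot(all(x > 0))
  10^round(log10(x))
}

#' Logarithmic density contrast of Brownian colloids in a light pattern
#'
#' For passive colloids the stationary density obeys the Boltzmann law:
#' `log(rho_max/rho_min) = -dU/kBT` with `dU` the optical energy difference
#' between the brightest and darkest regions.
#'
#' @param delta_U energy difference (J).
#' @param const a [physical_constants()].
#' @export
boltzmann_log_contrast <- function(delta_U, const = physical_constants()) {
  -delta_U / const$kBT_J
}

#' Rayleigh estimate of the optical energy of a dielectric bead
#'
#' Order-of-magnitude optical energy of a bead of radius `a` in a light
#' field of power density `I`, in the Rayleigh regime: `dU ~ a^3 I / c`.
#'
#' @param a bead radius (µm), `> 0`.
#' @param I power density (W/mm²), `>= 0`.
#' @param const a [physical_constants()].
#' @return energy in J.
#' @export
rayleigh_energy <- function(a, I, const = physical_constants()) {
  stopifnot(a > 0, I >= 0)
  # a^3 in m^3 (1 um^3 = 1e-18 m^3); I in W/m^2 (1 W/mm^2 = 1e6 W/m^2)
  (a^3 * 1e-18) * (I * 1e6) / const$c_m_per_s
}

#' Power density needed for unit Boltzmann contrast of a Rayleigh bead
#'
#' Inverts the Rayleigh estimate at `|dU| = kBT`:
#' `I ~ kBT c / a^3`, about 1 W/mm² for a 1 µm bead — three orders of
#' magnitude above the power that modulates photokinetic swimmers.
#'
#' @param a bead radius (µm).
#' @param round_to_magnitude report the nearest power of ten instead of the
#'   exact value.
#' @param const a [physical_constants()].
#' @return power density in W/mm².
#' @export
required_power_density <- function(a, round_to_magnitude = FALSE,
                                   const = physical_constants()) {
  stopifnot(a > 0)
  I <- const$kBT_J * const$c_m_per_s / (a^3 * 1e-18) / 1e6   # W/mm^2
  if (round_to_magnitude) order_of_magnitude(I) else I
}

#' Active translational diffusivity (order-of-magnitude convention)
#'
#' `D = v^2 tau` for a swimmer reorienting on timescale `tau` (run duration
#' for run-and-tumble, rotational decorrelation time for smooth swimmers).
#' Deliberately prefactor-free — the convention used in scaling comparisons;
#' the simulator's 2-D effective diffusivity is `v^2 tau_rot / 2`.
#'
#' @param v swimming speed (µm/s).
#' @param tau reorientation time (s).
#' @return diffusivity in µm²/s.
#' @export
active_diffusivity <- function(v, tau) {
  stopifnot(v >= 0, tau >= 0)
  v^2 * tau
}

#' Drift timescale over a pattern length
#'
#' `tau_drift = l / v`: time for a swimmer to cross the largest feature of
#' the target pattern.
#'
#' @param l length scale (µm).
#' @param v speed (µm/s), `> 0`.
#' @param round_to_magnitude report the nearest power of ten.
#' @export
drift_time <- function(l, v, round_to_magnitude = FALSE) {
  stopifnot(l > 0)
  if (v <= 0) stop("v must be > 0")
  t <- l / v
  if (round_to_magnitude) order_of_magnitude(t) else t
}

#' Diffusion timescale over a pattern length
#'
#' `tau_diff = l^2 / (2 D)`.
#'
#' @param l length scale (µm).
#' @param D diffusivity (µm²/s), `> 0`.
#' @param round_to_magnitude report the nearest power of ten.
#' @export
diffusion_time <- function(l, D, round_to_magnitude = FALSE) {
  stopifnot(l > 0)
  if (D <= 0) stop("D must be > 0")
  t <- l^2 / (2 * D)
  if (round_to_magnitude) order_of_magnitude(t) else t
}

#' Einstein diffusivity of a Brownian particle
#'
#' `D = mu kBT` for a particle of mobility `mu`; about 0.2 µm²/s for a
#' 1 µm-radius sphere in water (`mu = 50` µm/(s·pN)).
#'
#' @param mu mobility (µm per second per pN).
#' @param const a [physical_constants()].
#' @return diffusivity in µm²/s.
#' @export
einstein_diffusivity <- function(mu, const = physical_constants()) {
  stopifnot(mu > 0)
  mu * const$kBT_pN_um
}

#' Summary table of active-vs-Brownian patterning estimates
#'
#' Closed-form comparison of pattern-formation timescales and required
#' optical power between photokinetic swimmers and passive Brownian beads,
#' over a pattern length scale `l`: active drift and diffusion times for
#' run-and-tumble and smooth swimmers, the Brownian diffusion time at the
#' Einstein diffusivity, and the power density a Rayleigh bead would need
#' for unit logarithmic density contrast.
#'
#' @param l largest pattern length scale (µm), default 1 mm.
#' @param v typical swimming speed (µm/s), default 5.
#' @param tau_run mean run duration of a run-and-tumble swimmer (s).
#' @param tau_rot rotational decorrelation time of a smooth swimmer (s).
#' @param mu colloid mobility (µm/(s·pN)), default 50 (1 µm-radius bead).
#' @param a bead radius (µm).
#' @param const a [physical_constants()].
#' @return data.frame with columns `quantity`, `formula`, `value`, `units`,
#'   `magnitude` (nearest power of ten).
#' @export
patterning_estimates <- function(l = 1000, v = 5, tau_run = 1, tau_rot = 20,
                                 mu = 50, a = 1,
                                 const = physical_constants()) {
  D_rt <- active_diffusivity(v, tau_run)
  D_sm <- active_diffusivity(v, tau_rot)
  D_br <- einstein_diffusivity(mu, const)
  vals <- data.frame(
    quantity = c("active drift time",
                 "run-and-tumble diffusivity",
                 "run-and-tumble diffusion time",
                 "smooth-swimmer diffusivity",
                 "smooth-swimmer diffusion time",
                 "Brownian diffusivity",
                 "Brownian diffusion time",
                 "required power density (Rayleigh bead)"),
    formula = c("l/v", "v^2 tau_run", "l^2/(2 v^2 tau_run)",
                "v^2 tau_rot", "l^2/(2 v^2 tau_rot)",
                "mu kBT", "l^2/(2 mu kBT)", "kBT c / a^3"),
    value = c(drift_time(l, v), D_rt, diffusion_time(l, D_rt),
              D_sm, diffusion_time(l, D_sm),
              D_br, diffusion_time(l, D_br),
              required_power_density(a, const = const)),
    units = c("s", "um^2/s", "s", "um^2/s", "s", "um^2/s", "s", "W/mm^2"),
    stringsAsFactors = FALSE)
  vals$magnitude <- order_of_magnitude(vals$value)
  vals
}
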