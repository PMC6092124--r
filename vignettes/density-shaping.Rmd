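---
title: "Density shaping of photokinetic swimmers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density shaping of photokinetic swimmers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not
demonstrate.

## 1. The density-speed law and its preconditions

A self-propelled particle that reorients isotropically and moves at a
space-dependent speed `v(r)` spends time at `r` in inverse proportion to
`v(r)`; the stationary density is `rho ∝ 1/v`. Three assumptions matter:

1. **Isotropic reorientation** — smooth swimmers whose heading
   decorrelates by rotational diffusion (time `tau_rot`, default 20 s)
   satisfy this; so do run-and-tumble swimmers with unbiased tumbles.
2. **Homogeneous light response** — individual speeds must scale with one
   common factor, `v_i(I) = v_i^s f(I)`. Then every cell's density is
   proportional to `1/f(I)` and the *population* density follows the mean
   speed even though speeds are broadly distributed. The package encodes
   this as Schultz-distributed saturation speeds (`sample_schultz()`)
   times the shared response fraction `f(I) = v(I)/v_sat`, which also
   forces `sigma ∝ v` across intensities.
3. **Instantaneous adaptation** — speed must be a local function of
   position. It is not, which is where the memory model below comes in.

The response curve `v(I)` is a rectangular hyperbola
`v_dark + (v_sat − v_dark) I/(I + I_half)` (defaults 2 µm/s, 8 µm/s, 50
8-bit levels). The functional form is a modelling choice: any saturating
three-parameter curve fits speed-vs-light data of this kind about equally
well, so `intensity_response()` keeps the parametrization isolated behind
one constructor and `mean_speed()`.

## 2. Two-timescale memory and the blur kernel

A light step changes the swimming speed in two stages: an instantaneous
jump covering a fraction `beta = 0.44` of the change, and an exponential
relaxation of the remainder with `tau_m = 35 s` (shared by rising and
falling branches). These two numbers are the package-wide defaults of
`memory_params()` and parameterize everything downstream.

The temporal response is written as a convolution of the imposed speed
history with the exponential kernel `e^{-t'/tau_m}/tau_m`. The kernel is
normalized to unit mass: without the `1/tau_m` factor a constant speed
history would not reproduce itself, so the normalized form is the only
dimensionally consistent reading. `step_response()` is the closed-form
solution for a single step; `square_wave_response()` gives the periodic
steady state under square-wave forcing, in which a half period of
`100 s ≈ 2.9 tau_m` leaves adaptation measurably incomplete — the branch
endpoints are the self-consistent fixed points of the alternating
relaxation, not `V_lo`/`V_hi` themselves. `fit_step_response()` fits that
periodic model with one shared `tau_m`, which is how the package's
synthetic photoresponse experiment recovers `beta` and `tau_m`.

Transported along a trajectory at mean speed `v̄`, the exponential memory
becomes a spatial kernel of range `k⁻¹ = v̄ tau_m` (~175 µm at 5 µm/s).
Averaged over 3-D swimming directions the kernel is
`Γ(r) = (k/4 pi r²) e^{-kr}`; projecting along the optical axis (light
patterns are taken depth-invariant) gives a 2-D kernel with no closed
real-space form but the analytic transform
`γ̃(q) = (k/q) arctan(q/k)`. `blur_speed_map()` therefore works entirely
in Fourier space:

```{r}
w <- blur_speed_map(V, memory_params(0.44, 35))   # w = beta V + (1-beta) gamma*V
rho <- predict_density(w, alpha = 0.5)
```

`predict_density()` implements
`rho* = alpha (w⁻¹/mean(w⁻¹) − 1) + 1`: the responsive fraction `alpha`
modulates about the uniform baseline `1 − alpha` contributed by
non-motile cells and stray light, and the construction pins the spatial
mean at exactly 1.

**Validity.** The space-convolution form is derived for weak speed
modulations about a baseline. The package does not hard-code a validity
check (the regime boundary is not sharply known); `speed_map` contrast is
up to the caller, and the model-consistency test below uses a 10 %
modulation where the linearization is comfortably good.

**Boundaries.** FFT convolution is periodic by default — which is also
what makes the single-mode eigenfunction test exact — with a mirror-pad
option for non-periodic fields of view.

**`k` and `alpha`.** `k` defaults to `1/(mean(V) tau_m)` and can be
overridden. The `alpha` of the density prediction is the same quantity as
the DDM motile fraction in the ISF model; nothing in the code couples
them, so they can be set independently when stray light contributes to
the baseline.

## 3. The agent-based simulator

`sim_step()` advances, per agent: target speed `u_i V(x)` (with `u_i` the
agent's saturation speed relative to the population mean), an exact
exponential memory update over `dt`, displacement at
`v = beta V_i + (1−beta) m_i` along the heading, heading diffusion with
`tau_rot`, optional Poisson tumbling, Brownian steps for the non-motile
fraction, then the boundary. The per-agent first-order memory is
mathematically identical to convolving the imposed speed along the
trajectory with the normalized exponential kernel.

Choices worth knowing:

* **Two dimensions.** All observables (density maps, light patterns) are
  2-D; the experiment's quasi-2-D layer is imaged in projection. The 3-D
  orientation average enters analytically through the blur kernel and the
  DDM model instead (see below).
* **Time step.** `dt` must resolve the memory (`dt ≤ tau_m/50`) and keep
  the fastest agent under one pixel per step — with the Schultz tail
  (`Z = 4` gives `sd/mean ≈ 0.45` and occasional agents at 3-4× the mean
  speed) the study conditions use `dt = 0.05 s`. The step function
  enforces the pixel bound at run time rather than trusting the
  configuration.
* **Effective diffusivity.** The simulator's smooth swimmers obey the
  2-D active-Brownian result `D_eff = v² tau_rot/2` (verified against the
  exact mean-squared-displacement expression in the tests). The
  `estimates` module deliberately uses the prefactor-free `D = v² tau`
  convention of order-of-magnitude comparisons; both are documented where
  they appear.
* **Boundaries.** Periodic by default. The experimental field of view
  loses swimmers at its dark edge (a documented limitation of the
  technique, ~50 % of motile cells per hour); the simulator does not
  model this loss, and reflecting boundaries are available for
  closed-chamber scenarios.
* **Initialization.** Memory starts fully adapted to bright light
  (saturation speed), mirroring a uniform bright pre-exposure long
  compared to `tau_m`; every density experiment discards a burn-in long
  compared to both `tau_m` and the transport time across a pattern
  feature.

## 4. DDM: structure function, ISF, and the orientation average

`image_structure_function()` computes
`g(q,t) = ⟨|M(q,t′) − M(q,t′+t)|²⟩` with FFTs of raw frames (no window by
default, matching the plain definition; a Hann option exists), averages
over start times, and bins azimuthally in shells one FFT-grid spacing
wide, excluding `q = 0` and moduli beyond the Nyquist limit of the
shorter image side. The shell average is tested exactly against a
per-pixel brute-force oracle.

`fit_ddm()` fits `g = A(q)[1 − F(q,t)] + B(q)` per shell over
`(A, B, v, sigma, alpha, D)` and band-averages over the default
`0.45–1.2 µm⁻¹`. The form `A(1−F) + B` is required by the limiting
behaviour (`g(q,0) = B`, the camera noise floor; `g → A + B` when all
correlation is lost); fits are per-q with band averaging rather than one
global fit, so shell-to-shell spread doubles as a diagnostic.

The swimmer ISF uses the Schultz speed distribution (gamma with shape
`Z + 1 = (v/sigma)²`, evaluated in log space). Its orientation factor
depends on the geometry:

* `geometry = "3d"` (default): `sinc(q v t)` — the isotropic average over
  3-D swimming directions, correct when a thick sample is imaged in
  projection. The Schultz-weighted sinc integral has a closed form,
  validated against adaptive quadrature to 10⁻⁶.
* `geometry = "2d"`: `J0(q v t)` — the average over in-plane directions,
  correct for the package's own 2-D agent simulator. The Schultz-weighted
  `J0` is computed by Gauss–Legendre integration over the angle with the
  speed average in closed form, validated against a Monte-Carlo oracle.

This distinction matters: fitting 2-D-simulated stacks with the 3-D model
overestimates `v` by ~20 %, because `J0` decays faster than `sinc` at
equal `qvt`. The package therefore ships two stack generators —
`simulate_projected_swimmers()` (3-D ballistic ensemble seen in
projection, for the `sinc` route) and the 2-D simulator (for the `J0`
route) — and the parameter-recovery tests use matched pairs.

Rendered frames deposit each agent with bilinear (cloud-in-cell)
weighting before PSF convolution: nearest-pixel binning would quantize
positions to the 2 µm grid and measurably distort `g(q,t)` at
`q ~ 1/pixel`, which is inside the fit band.

## 5. Imaging chain and the distance metric

Dark-field rendering is linear in the local cell count (Gaussian PSF,
stray background, multiplicative illumination envelope, Poisson/Gaussian
noise); bright-field rendering is signed contrast on a gray background so
that frame differences carry the density fluctuations DDM needs.

The analysis chain is: flat-field reference `rho0` (frame average of a
homogeneous sample, wide Gaussian blur, default sigma 100 µm);
`rho* = rho/rho0`; optional 5th-percentile background subtraction
(clipped at zero — dark-field intensities are non-negative); and, for
comparisons against a target, an affine rescaling that matches the 10th
and 90th percentiles of the two histograms followed by
`dist = sqrt(sum((rho_s − target)²))`. Percentiles use linear
interpolation between order statistics (R's default type 7) — the exact
percentile algorithm is a convention, fixed here for reproducibility.
`dist` is reported as the root of the pixel sum; normalized curves divide
by the value at the first iteration.

## 6. Closed-loop control

`run_closed_loop()` alternates: simulate one iteration period (default
20 s), measure the density (snapshot histogram, Gaussian-smoothed with
sigma 4 µm as a counting-noise filter, mean-normalized), rescale against
the target, record `dist`, and update
`I_{n+1} = clip(I_n + P (rho_s − target))` with 8-bit clipping and
(default) integer quantization, as projector hardware would. The
rescaling is recomputed every iteration; the controller consequently
corrects shape, not absolute contrast.

The gain default `P = 60` levels per unit density error is not a measured
quantity: it is set so that a typical initial error of a few tenths moves
the pattern by ≲10 % of the dynamic range per iteration. The loop flags
probable divergence (distance growing over several consecutive
iterations) and suggests reducing the gain.

With memory on, the converged illumination is a sharpened version of the
naive pattern: the controller pre-compensates the blur by pushing
intensity toward the bounds near edges. The package demonstrates this in
silico: the closed-loop `dist` plateau falls below the open-loop value,
and target morphing decays near-exponentially (the tests require
R² > 0.9 for the exponential fit of the distance to the new target).

## 7. Estimates module conventions

Temperature defaults to 298 K (`kBT = 4.11×10⁻³ pN µm`). The
comparisons use the prefactor-free conventions of scaling arguments:
`D = v² tau`, Rayleigh energy `a³ I/c`, required power `kBT c/a³`
(`≈ 1.2 W/mm²` for `a = 1 µm`, reported to order of magnitude as 1).
The Brownian drift time printed in such comparisons is sometimes quoted
through the dimensionally inconsistent shortcut `mu kBT/l`; the package
implements only the defensible `l²/(2 mu kBT)` diffusion time and does
not report a Brownian drift time at all.

## 8. What the synthetic experiments show — and what they cannot

The generators emulate: hyperbolic speed response with homogeneous
growth, Schultz speed dispersion, two-timescale memory, rotational
diffusion, a non-responsive Brownian fraction, microscopy-like noise,
envelopes and PSF. They do **not** emulate: steric or hydrodynamic
interactions (which hinder accumulation at high density), cell growth or
loss, z-resolved dynamics, phototactic (directional) responses, or
field-of-view edge depletion. Consequently, passing tests validate the
package's implementation of the models and the internal consistency of
the model chain (simulator ↔ blur prediction ↔ DDM ↔ controller) under
those assumptions — they do not validate the assumptions themselves
against a real bacterial suspension. The known deviation of real data —
density falling below the `1/v` line at low speed — is reproduced here
exactly insofar as the memory-blur mechanism causes it.

## 9. Study conditions and problem sizes

The package's quantitative experiments (tests and `scripts/acceptance.R`)
use: 20 000 agents, half responsive; 12-level chessboard with 40 µm tiles
on a 240 µm periodic box, 900 simulated seconds (300 s burn-in); a 2:1
two-level stripe map, 700 s; square-wave photoresponse with 200 s period
and 8 periods at 1 s sampling with 2 % noise; DDM stacks of 500 frames at
10 Hz, 128² pixels, 10⁴ swimmers; and 32-iteration feedback runs at 20 s
per iteration with 8 000 agents. The 12 chessboard intensities are spaced
evenly in *inverse* speed: a uniform intensity ladder, pushed through the
saturating response, crams all fast levels into a sliver of the `1/v`
axis and makes the intercept extrapolation ill-conditioned, whereas
uniform leverage in `1/v` conditions the fit well. For the 2:1-contrast
ratio measurement the non-responsive baseline is taken from the
chessboard intercept fit — an independent measurement — because a line
refitted through the same two level points would return the speed ratio
identically, by construction.
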