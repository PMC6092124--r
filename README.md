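# photokin

Shaping the spatial density of light-responsive swimming bacteria with
projected light — modelling, simulation, measurement and control, on
synthetic data.

## The science

Bacteria engineered to express proteorhodopsin (a light-driven proton pump
feeding the flagellar motor) swim at a speed set by the local light
intensity. A self-propelled particle with isotropic reorientation and a
space-dependent speed `v(r)` has the stationary density

```
rho(r) ∝ 1 / v(r)
```

so a grayscale light pattern projected onto a bacterial layer becomes a
density image: bright regions speed cells up and empty out, dim regions
collect them. `photokin` implements the full modelling chain around this
law:

* **Speed response.** A rectangular hyperbola
  `v(I) = v_dark + (v_sat − v_dark)·I/(I + I_half)`, with a homogeneous
  growth law for individual cells (`v_i = v_i^s f(I)`, Schultz-distributed
  saturation speeds, so `σ ∝ v`), and a two-timescale temporal response: a
  light step moves the speed by an instantaneous fraction `β` followed by
  exponential relaxation with time constant `τ_m`.
* **Memory blur.** Because adaptation is not instantaneous, swimmers carry
  their speed over a distance `k⁻¹ = v̄ τ_m`. The effective speed map is
  the convolution `w = β V + (1−β) γ * V`, with a kernel analytic only in
  Fourier space, `γ̃(q) = (k/q)·arctan(q/k)`, and the predicted stationary
  density of a suspension in which only a fraction `α` responds to light is
  `ρ* = α (w⁻¹/mean(w⁻¹) − 1) + 1`.
* **Agent-based simulation.** Smooth swimmers with per-agent saturation
  speeds, first-order speed memory, rotational diffusion (`τ_rot`),
  optional tumbling, a passive Brownian fraction, periodic or reflecting
  boundaries.
* **DDM.** The image structure function
  `g(q,t) = ⟨|M(q,t′) − M(q,t′+t)|²⟩` of a rendered bright-field stack is
  fitted per q-shell with the swimmer intermediate scattering function
  (Schultz speed distribution, motile fraction `α`, diffusivity `D`) to
  recover `(v, σ, α, D)`.
* **Imaging chain.** Microscope-like dark-field/bright-field rendering
  (PSF, stray background, illumination envelope, shot noise), flat-field
  correction, 5th-percentile background subtraction, 10/90-percentile
  histogram rescaling, and the `dist` metric (root summed squared pixel
  difference).
* **Feedback control.** Proportional closed loop
  `I_{n+1} = clip(I_n + P·(ρ_s − ρ_target))` run against the simulator,
  including target morphing.
* **Estimates.** Closed-form comparison with passive optical trapping of
  Brownian colloids (Boltzmann contrast, Rayleigh energy, drift/diffusion
  timescales, Einstein diffusivity).

## Worked example

Predict the stationary density under a sinusoidal light-imposed speed
pattern (period 128 µm, 10 % contrast about 5 µm/s), with and without
memory blur:

```r
library(photokin)

resp <- intensity_response(v_dark = 2, v_sat = 8, I_half = 50)
mem  <- memory_params(beta = 0.44, tau_m = 35)

V <- speed_map(pattern_sine(c(64, 256), period_px = 64,
                            mean_value = 5, contrast = 0.1),
               pixel_size = 2)
w <- blur_speed_map(V, mem)
w
#> Speed map 64 x 256 px (2 um/px), blurred (w), range 4.73-5.27 um/s

rho <- predict_density(w, alpha = 0.5)
range(rho)
#> 0.974 1.027       (unblurred prediction: 0.952 - 1.053)
```

The memory blur roughly halves the achievable density modulation at this
spatial frequency: the imposed ±10 % speed contrast survives only as
±5.4 % in `w` (the kernel gain at `q = 2π/128 µm⁻¹` with
`k⁻¹ = 5·35 = 175 µm` is `β + (1−β)·γ̃ ≈ 0.53`), and with half the
population unresponsive the predicted density modulation is ±2.7 %.

The active-vs-passive estimates table:

```r
patterning_estimates()
#>                                 quantity             formula    value  units magnitude
#> 1                      active drift time                 l/v 2.00e+02      s     1e+02
#> 3          run-and-tumble diffusion time l^2/(2 v^2 tau_run) 2.00e+04      s     1e+04
#> 5          smooth-swimmer diffusion time l^2/(2 v^2 tau_rot) 1.00e+03      s     1e+03
#> 7                Brownian diffusion time      l^2/(2 mu kBT) 2.43e+06      s     1e+06
#> 8 required power density (Rayleigh bead)         kBT c / a^3 1.23e+00 W/mm^2     1e+00
```

A millimetre-scale density pattern forms in minutes in the active
suspension; the equivalent passive-colloid experiment would need ~10³×
more optical power and 10³–10⁴× more time.

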