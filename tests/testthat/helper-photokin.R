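# shared fixtures: the package's canonical response curve and memory
default_resp <- function() intensity_response(v_dark = 2, v_sat = 8,
                                              I_half = 50)
default_mem <- function() memory_params(beta = 0.44, tau_m = 35)

# independent wave-vector-modulus grid for an ny x nx FFT layout
# (re-derived here so tests do not lean on the package's internal helper)
test_q_grid <- function(ny, nx, px) {
  freqs <- function(n) {
    f <- c(seq(0, floor((n - 1) / 2)), seq(-(n - floor((n - 1) / 2) - 1), -1))
    2 * pi * f / (n * px)
  }
  sqrt(outer(freqs(ny)^2, freqs(nx)^2, "+"))
}
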