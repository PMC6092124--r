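test_that("identical frames give a vanishing structure function", {
  fr <- array(rep(matrix(runif(64), 8, 8), 4), c(8, 8, 4))
  st <- image_stack(fr, pixel_size = 1, frame_interval = 0.1)
  curves <- image_structure_function(st, lags = c(0.1, 0.2))
  expect_true(all(curves$g == 0))
})

test_that("azimuthal binning equals a brute-force per-pixel average", {
  set.seed(23)
  f1 <- matrix(runif(64), 8, 8)
  f2 <- matrix(runif(64), 8, 8)
  px <- 2
  st <- image_stack(array(c(f1, f2), c(8, 8, 2)), px, 0.5)
  curves <- image_structure_function(st, lags = 0.5)
  # oracle: loop over pixels, assign shells by rounded |q|/dq
  dmat <- fft(f2) - fft(f1)
  p <- Mod(dmat)^2
  qmag <- test_q_grid(8, 8, px)
  dq <- 2 * pi / (8 * px)
  shells <- sort(unique(as.integer(round(qmag / dq))))
  shells <- shells[shells >= 1]
  for (s in shells) {
    sel <- as.integer(round(qmag / dq)) == s & qmag <= pi / px
    if (!any(sel)) next
    i <- which.min(abs(curves$q - mean(qmag[sel])))
    expect_equal(curves$g[i, 1], mean(p[sel]), tolerance = 1e-12)
  }
})

test_that("lags beyond the stack duration are rejected", {
  st <- image_stack(array(runif(128), c(4, 4, 8)), 1, 0.1)
  expect_error(image_structure_function(st, lags = 2), "duration")
})

test_that("Schultz density has unit mass and the stated moments", {
  v <- 10; Z <- 3
  mass <- integrate(function(x) schultz_pdf(x, v, Z), 0, Inf,
                    rel.tol = 1e-10)$value
  m1 <- integrate(function(x) x * schultz_pdf(x, v, Z), 0, Inf,
                  rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * schultz_pdf(x, v, Z), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  expect_equal(m1, v, tolerance = 1e-8)
  expect_equal(m2 - m1^2, v^2 / (Z + 1), tolerance = 1e-6)  # 25
  # large-Z evaluation stays finite (log-space)
  expect_true(is.finite(schultz_pdf(10, 10, 5e4)))
})

test_that("ISF limits: t = 0, Brownian-only, and monodisperse", {
  expect_equal(isf_smooth_swimmer(1, 0, 6, 2, 0.5, 0.3), 1)
  # alpha = 0: pure Brownian decay
  t <- c(0.5, 2, 8)
  expect_equal(isf_smooth_swimmer(0.8, t, 6, 2, 0, 0.4),
               exp(-0.8^2 * 0.4 * t), tolerance = 1e-12)
  # sigma -> 0: Schultz average approaches plain sinc
  q <- 0.7; v <- 5; tt <- c(0.3, 1, 3)
  narrow <- isf_smooth_swimmer(q, tt, v, v / sqrt(1e4 + 1), 1, 0)
  expect_equal(narrow, sin(q * v * tt) / (q * v * tt), tolerance = 1e-3)
})

test_that("closed-form Schultz-sinc average matches adaptive quadrature", {
  for (qt in c(0.2, 1, 4, 15)) {
    a <- isf_smooth_swimmer(1, qt, 6, 2.7, 0.5, 0.3)
    b <- isf_smooth_swimmer(1, qt, 6, 2.7, 0.5, 0.3,
                            method = "quadrature")
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("2-D orientation average matches a Monte-Carlo oracle", {
  set.seed(77)
  q <- 0.6; v <- 6; Z <- 4
  n <- 1e6
  vs <- sample_schultz(n, v, Z)
  th <- runif(n, 0, 2 * pi)
  for (t in c(0.5, 1.5)) {
    mc <- mean(cos(q * vs * cos(th) * t))
    # Monte-Carlo standard error ~ 1/sqrt(n) = 1e-3
    expect_lt(abs(isf_smooth_swimmer(q, t, v, v / sqrt(Z + 1), 1, 0,
                                     geometry = "2d") - mc), 4e-3)
  }
})

test_that("fitting analytic curves recovers the generating parameters", {
  # inverse-crime check: g built from the model itself
  q_grid <- seq(0.5, 1.1, by = 0.1)
  lags <- c(0.1, 0.2, 0.4, 0.7, 1, 1.5, 2.5, 4, 6, 10, 16, 25)
  true <- list(v = 6, sigma = 2.4, alpha = 0.55, D = 0.35)
  g <- t(vapply(q_grid, function(q)
    1e4 * (1 - isf_smooth_swimmer(q, lags, true$v, true$sigma,
                                  true$alpha, true$D)) + 50,
    numeric(length(lags))))
  curves <- structure(list(q = q_grid, lags = lags, g = g,
                           n_px = rep(100L, length(q_grid)),
                           pixel_size = 2, dim = c(64L, 64L)),
                      class = "ddm_curves")
  fit <- fit_ddm(curves, 0.45, 1.2)
  expect_equal(fit$v, true$v, tolerance = 1e-4)
  expect_equal(fit$sigma, true$sigma, tolerance = 1e-3)
  expect_equal(fit$alpha, true$alpha, tolerance = 1e-4)
  expect_equal(fit$D, true$D, tolerance = 1e-3)
  expect_error(fit_ddm(curves, 5, 6), "band")
})

test_that("swimmer parameters are recovered from a rendered image stack", {
  # full synthetic pipeline: 3-D-projected swimmers, bright-field frames,
  # structure function, per-q fits
  set.seed(3)
  snaps <- simulate_projected_swimmers(10000, c(256, 256), v = 6, Z = 4,
                                       alpha = 0.5, D = 0.3,
                                       n_frames = 500,
                                       frame_interval = 0.1)
  stack <- render_stack(snaps, c(128, 128), 2, 0.1, mode = "brightfield",
                        psf_sigma = 1.5, background = 100, contrast = -20,
                        noise_sd = 1)
  curves <- image_structure_function(
    stack, lags = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1, 1.4, 2, 3, 4, 6, 8,
                    12, 16, 24, 32))
  fit <- fit_ddm(curves, 0.45, 1.2)
  expect_equal(fit$v, 6, tolerance = 0.05)
  expect_equal(fit$sigma, 6 / sqrt(5), tolerance = 0.15)
  expect_lt(abs(fit$alpha - 0.5), 0.05)
})
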