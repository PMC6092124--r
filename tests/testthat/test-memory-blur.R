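test_that("kernel transform has the analytic limits", {
  expect_equal(kernel_ft(0, 0.02), 1)
  expect_equal(kernel_ft(1e-9, 0.02), 1, tolerance = 1e-12)
  expect_equal(kernel_ft(0.02, 0.02), pi / 4)
  # monotone decreasing, bounded in (0, 1]
  q <- seq(0, 5, by = 0.01)
  g <- kernel_ft(q, 0.05)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(kernel_ft(1, -1), "positive")
  expect_error(kernel_ft(-1, 1), "non-negative")
})

test_that("3-D kernel is normalized, monotone, and singular at zero", {
  k <- 0.03
  mass <- integrate(function(r) 4 * pi * r^2 * kernel_3d(r, k),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  r <- seq(0.1, 100, by = 0.1)
  expect_true(all(diff(kernel_3d(r, k)) < 0))
  expect_error(kernel_3d(0, k), "singular")
})

test_that("kernel transform matches the brute-force projected-kernel
           transform", {
  # oracle: z-project the 3-D kernel numerically, then Hankel-transform
  # the resulting 2-D radial profile
  for (k in c(0.02, 0.1)) {
    gamma2d <- function(r)
      vapply(r, function(ri) {
        2 * integrate(function(z) kernel_3d(sqrt(ri^2 + z^2), k),
                      0, Inf, rel.tol = 1e-10)$value
      }, numeric(1))
    for (q in c(0.3 * k, k, 4 * k)) {
      # piecewise radial integration (the Bessel factor oscillates)
      edges <- seq(0, 60 / k, length.out = 121)
      oracle <- 2 * pi * sum(vapply(seq_len(120), function(i)
        integrate(function(r) gamma2d(r) * besselJ(q * r, 0) * r,
                  edges[i], edges[i + 1], rel.tol = 1e-9)$value,
        numeric(1)))
      expect_equal(kernel_ft(q, k), oracle, tolerance = 1e-4)
    }
  }
})

test_that("blur leaves uniform maps unchanged and preserves the mean", {
  mem <- default_mem()
  V0 <- speed_map(matrix(5, 32, 48))
  w0 <- blur_speed_map(V0, mem)
  expect_equal(unclass(w0), unclass(V0), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(7)
  V <- speed_map(matrix(runif(32 * 48, 4, 6), 32, 48))
  w <- blur_speed_map(V, mem)
  expect_equal(mean(w), mean(V), tolerance = 1e-10)
  # beta = 1 is the identity
  w1 <- blur_speed_map(V, memory_params(1, 35))
  expect_equal(unclass(w1), unclass(V), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a cosine speed profile is an eigenfunction of the blur", {
  mem <- default_mem()
  period_px <- 64; px <- 2
  V <- speed_map(pattern_sine(c(8, 256), period_px, 5, 0.1),
                 pixel_size = px)
  k <- 1 / (mean(V) * mem$tau_m)
  w <- blur_speed_map(V, mem, k = k)
  q <- 2 * pi / (period_px * px)
  gain <- mem$beta + (1 - mem$beta) * kernel_ft(q, k)
  expected <- 5 + 0.1 * 5 * gain *
    cos(2 * pi * (seq_len(256) - 1) / period_px)
  expect_equal(unclass(w)[1, ], expected, tolerance = 1e-10)
})

test_that("mirror padding also preserves uniform maps", {
  V <- speed_map(matrix(4, 16, 16))
  w <- blur_speed_map(V, default_mem(), pad = "mirror")
  expect_equal(unclass(w), unclass(V), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("density prediction follows the inverse-speed law", {
  # uniform map: flat density
  rho0 <- predict_density(speed_map(matrix(3, 10, 10)), alpha = 1)
  expect_equal(unclass(rho0), matrix(1, 10, 10), ignore_attr = TRUE)
  # equal-area two-level map, alpha = 1: {4/3, 2/3}
  two <- speed_map(cbind(matrix(2, 8, 8), matrix(4, 8, 8)))
  r1 <- predict_density(two, alpha = 1)
  expect_equal(sort(unique(as.vector(r1))), c(2 / 3, 4 / 3))
  # alpha = 0.5: {5/6, 7/6}, and the baseline-subtracted ratio is 2
  r2 <- predict_density(two, alpha = 0.5)
  expect_equal(sort(unique(as.vector(r2))), c(5 / 6, 7 / 6))
  expect_equal((max(r2) - 0.5) / (min(r2) - 0.5), 2)
  # spatial mean exactly 1
  set.seed(11)
  V <- speed_map(matrix(runif(400, 2, 8), 20, 20))
  expect_equal(mean(predict_density(V, 0.73)), 1, tolerance = 1e-14)
  expect_error(speed_map(matrix(c(1, -1, 2, 3), 2)), "positive")
})

test_that("level table from an exact prediction sits on the line", {
  resp <- default_resp()
  lv <- inverse_speed_levels(resp, 8)
  ch <- pattern_chessboard(c(4, 4), 8, lv)
  V <- light_to_speed_map(ch$pattern, resp)
  alpha <- 0.5
  rho <- predict_density(V, alpha)
  tbl <- density_vs_inverse_speed(rho, V, ch$labels)
  fit <- fit_density_line(tbl, top_fraction = 1)
  expect_equal(fit$intercept, 1 - alpha, tolerance = 1e-10)
  # residuals identically zero: prediction is exactly linear in 1/v
  expect_lt(max(abs(residuals(fit$fit))), 1e-12)
  # a single level cannot be fitted
  one <- density_vs_inverse_speed(rho, V, matrix(1, nrow(V), ncol(V)))
  expect_equal(nrow(one), 1)
  expect_error(fit_density_line(one), "at least 2 levels")
})

test_that("blur bends the slow levels below the inverse-speed line", {
  # fine pattern (period comparable to the memory length): the blurred
  # density under-shoots the naive line at the slow (dim) levels
  resp <- default_resp()
  lv <- inverse_speed_levels(resp, 6)
  ch <- pattern_chessboard(c(6, 6), 8, lv)          # 16 um tiles
  V <- light_to_speed_map(ch$pattern, resp)
  w <- blur_speed_map(V, default_mem())
  rho <- predict_density(w, alpha = 0.5)
  tbl <- density_vs_inverse_speed(rho, V, ch$labels)
  fit <- fit_density_line(tbl, top_fraction = 0.5)
  slowest <- tbl[which.min(tbl$speed_um_per_s), ]
  on_line <- fit$intercept + fit$slope * slowest$inv_speed_s_per_um
  expect_lt(slowest$mean_density, on_line)
})
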