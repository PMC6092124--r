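test_that("population initialization honours the configuration", {
  cfg <- sim_config(n_agents = 5000, alpha_motile = 1, seed = 3,
                    mean_sat_speed = 8, Z = 4, dt = 0.05)
  pop <- init_population(cfg, box = c(100, 100))
  expect_true(all(pop$motile))
  expect_true(all(pop$x >= 0 & pop$x < 100 & pop$y >= 0 & pop$y < 100))
  # sample mean of saturation speeds within a few standard errors
  se <- 8 / sqrt(4 + 1) / sqrt(5000)
  expect_lt(abs(mean(pop$v_s) - 8), 4 * se)
  # memory starts fully adapted (bright pre-exposure)
  expect_equal(pop$m, pop$v_s)
  # same seed, bit-identical population
  pop2 <- init_population(cfg, box = c(100, 100))
  expect_identical(pop, pop2)
})

test_that("memoryless agents in uniform light move at their own speed", {
  cfg <- sim_config(n_agents = 200, dt = 0.05, alpha_motile = 1,
                    mem = memory_params(1, 35), tau_rot = 1e12, seed = 4,
                    mean_sat_speed = 5, Z = 1e6)
  V <- speed_map(matrix(5, 32, 32))
  pop <- init_population(cfg, c(64, 64))
  x0 <- pop$x; y0 <- pop$y
  pop1 <- sim_step(pop, V, cfg)
  dx <- pop1$x - x0; dy <- pop1$y - y0
  dx <- dx - 64 * round(dx / 64); dy <- dy - 64 * round(dy / 64)
  expect_equal(sqrt(dx^2 + dy^2), pop$u * 5 * cfg$dt, tolerance = 1e-9)
})

test_that("fixed seed gives bit-identical trajectories and conserves
           agents", {
  cfg <- sim_config(n_agents = 500, dt = 0.05, seed = 12,
                    mem = memory_params(1, 35))
  V <- speed_map(matrix(6, 16, 16))
  r1 <- {
    pop <- init_population(cfg, c(32, 32))
    run_to_stationary(pop, V, cfg, t_total = 5, t_burn = 1,
                      sample_every = 1)
  }
  r2 <- {
    pop <- init_population(cfg, c(32, 32))
    run_to_stationary(pop, V, cfg, t_total = 5, t_burn = 1,
                      sample_every = 1)
  }
  expect_identical(r1$snapshots, r2$snapshots)
  expect_true(all(vapply(r1$snapshots, nrow, integer(1)) == 500))
})

test_that("a too-coarse time step is rejected with advice", {
  cfg <- sim_config(n_agents = 100, dt = 0.9, seed = 1,
                    mem = memory_params(1, 35), mean_sat_speed = 8)
  V <- speed_map(matrix(8, 16, 16))
  pop <- init_population(cfg, c(32, 32))
  expect_error(sim_step(pop, V, cfg), "reduce dt")
})

test_that("mean squared displacement follows active-Brownian theory", {
  # near-monodisperse smooth swimmers in uniform light: the exact ABP
  # result is MSD(t) = 2 v^2 tau (t - tau (1 - exp(-t/tau)))
  cfg <- sim_config(n_agents = 3000, dt = 0.05, alpha_motile = 1,
                    mem = memory_params(1, 35), tau_rot = 2, seed = 31,
                    mean_sat_speed = 5, Z = 1e6)
  v <- 5; tau <- 2
  L <- 512
  V <- speed_map(matrix(v, 16, 16), pixel_size = 32)
  pop <- init_population(cfg, c(L, L))
  x <- pop$x; y <- pop$y       # track unwrapped displacements
  xs <- pop$x; ys <- pop$y
  steps <- 400                  # 20 s = 10 tau_rot
  msd_t <- c(2, 10, 20)
  msd <- numeric(length(msd_t))
  for (s in seq_len(steps)) {
    old_x <- pop$x; old_y <- pop$y
    pop <- sim_step(pop, V, cfg)
    dx <- pop$x - old_x; dy <- pop$y - old_y
    dx <- dx - L * round(dx / L); dy <- dy - L * round(dy / L)
    xs <- xs + dx; ys <- ys + dy
    ti <- s * cfg$dt
    j <- match(ti, msd_t)
    if (!is.na(j)) msd[j] <- mean((xs - x)^2 + (ys - y)^2)
  }
  theory <- 2 * v^2 * tau * (msd_t - tau * (1 - exp(-msd_t / tau)))
  expect_equal(msd, theory, tolerance = 0.1)
  # and the long-time slope approaches 4 D_eff with D_eff = v^2 tau / 2
  expect_equal(msd[3] / (4 * (v^2 * tau / 2) * msd_t[3]), 1,
               tolerance = 0.15)
})

test_that("density histogram normalizes to unit mean", {
  set.seed(5)
  pos <- cbind(runif(4000, 0, 64), runif(4000, 0, 64))
  rho <- density_histogram(pos, c(32, 32), 2)
  expect_equal(mean(rho), 1, tolerance = 1e-14)
  expect_equal(dim(rho), c(32L, 32L))
  # all agents in one bin
  one <- density_histogram(cbind(rep(1, 50), rep(1, 50)), c(4, 4), 2)
  expect_equal(max(one), 16)
  expect_equal(sum(one > 0), 1)
  expect_error(density_histogram(pos[0, , drop = FALSE], c(4, 4), 2),
               "no positions")
})

test_that("uniform light gives a flat time-averaged density", {
  cfg <- sim_config(n_agents = 8000, dt = 0.05, alpha_motile = 1,
                    mem = memory_params(1, 35), seed = 6,
                    mean_sat_speed = 5)
  V <- speed_map(matrix(5, 16, 16), pixel_size = 4)
  res <- simulate_density(V, cfg, t_total = 60, t_burn = 20,
                          sample_every = 4)
  counts_per_bin <- 8000 / 256 * length(res$run$snapshots)
  # fluctuations consistent with (correlated-sample) counting noise
  expect_lt(sd(res$rho), 4 / sqrt(counts_per_bin / 10))
  expect_equal(mean(res$rho), 1, tolerance = 1e-12)
})

test_that("two-level map yields the inverse-speed density ratio", {
  st <- pattern_stripes(c(32, 64), 32, c(3, 6))
  V <- speed_map(st$pattern, pixel_size = 2)
  cfg <- sim_config(n_agents = 6000, dt = 0.1, alpha_motile = 1,
                    mem = memory_params(1, 35), seed = 17,
                    mean_sat_speed = 6, Z = 1e6)
  res <- simulate_density(V, cfg, t_total = 300, t_burn = 120,
                          sample_every = 4)
  tbl <- density_vs_inverse_speed(res$rho, V, st$labels)
  prod <- tbl$mean_density * tbl$speed_um_per_s
  # rho * v constant across the two levels within a few percent
  expect_equal(prod[1] / prod[2], 1, tolerance = 0.05)
})

test_that("projected 3-D swimmer snapshots stay in the box", {
  set.seed(8)
  snaps <- simulate_projected_swimmers(500, c(64, 64), 6, 4, 0.5, 0.3,
                                       n_frames = 10, frame_interval = 0.5)
  expect_length(snaps, 10)
  expect_true(all(vapply(snaps, function(p)
    all(p >= 0 & p < 64), logical(1))))
  expect_true(all(vapply(snaps, nrow, integer(1)) == 500))
})
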