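test_that("pair energy has the screened form with contact amplitude A'", {
  m <- energy_model(A_prime = 3, kappa = 2, D = 1, d_c = 10)
  # contact of perpendicular rods: exactly A' (in k_B T)
  expect_equal(pair_energy(1, 1, m), 3)
  # one Debye length out: factor e^{-1}
  expect_equal(pair_energy(1 + 1 / 2, 1, m), 3 * exp(-1), tolerance = 1e-14)
  # halving sin(theta) doubles the energy
  expect_equal(pair_energy(1.3, 0.25, m), 2 * pair_energy(1.3, 0.5, m),
               tolerance = 1e-14)
  # hard-core violation is infinitely penalized
  expect_identical(pair_energy(0.99, 1, m), Inf)
  expect_error(pair_energy(1.2, 0, m), "sin_theta")
})

test_that("truncated-shifted potential vanishes continuously at the cutoff", {
  m <- energy_model(A_prime = 2.5, kappa = 1, D = 1, d_c = 6)
  expect_identical(truncated_shifted_energy(6, 1, m), 0)
  expect_identical(truncated_shifted_energy(8, 0.4, m), 0)
  eps <- truncated_shifted_energy(6 - 1e-8, 1, m)
  expect_gt(eps, 0)
  expect_lt(eps, 1e-7)
  # equals the unshifted energy minus the theta-matched shift term,
  # recomputed independently, on random (x, theta)
  set.seed(4)
  x <- runif(200, 1, 7)
  s <- runif(200, 0.05, 1)
  ref <- oracle_ts_energy(x, s, 2.5, 1, 1, 6)
  expect_equal(truncated_shifted_energy(x, s, m), ref, tolerance = 1e-12)
  expect_equal(
    truncated_shifted_energy(x[x < 6], s[x < 6], m),
    pair_energy(x[x < 6], s[x < 6], m) - pair_energy(6, s[x < 6], m),
    tolerance = 1e-12)
})

test_that("sweeps preserve the hard core and the energy cache", {
  set.seed(77)
  m <- energy_model(2, 1, 1, 5)
  cfg <- random_dilute_config(40, 0.04, 5, 1)
  st <- mc_state(cfg, m)
  for (k in 1:6) {
    st <- metropolis_sweep(st, m, 25)
    tot <- chargedrods:::cpp_total_energy(
      st$configuration$centers, st$configuration$orientations,
      st$configuration$L / 2, st$configuration$box, m$A_prime, m$kappa,
      m$D, m$d_c, m$sin_theta_floor)
    expect_false(tot$overlap)
    expect_lt(abs(tot$energy - st$energy) / max(1, abs(tot$energy)), 1e-8)
  }
  expect_silent(audit_energy(st, m))
  # a corrupted cache is caught
  st$energy <- st$energy + 1
  expect_error(audit_energy(st, m), "cache")
})

test_that("zero-amplitude dilute system accepts almost every small move", {
  set.seed(8)
  m <- energy_model(0, 1, 1, 1.5)
  cfg <- random_dilute_config(30, 0.005, 5, 1)
  st <- mc_state(cfg, m)
  st$max_disp <- 0.05
  st$max_rot <- 0.05
  st <- metropolis_sweep(st, m, 30)
  expect_gt(st$acceptance["translation"], 0.97)
  expect_gt(st$acceptance["rotation"], 0.97)
})

test_that("two-rod chain reproduces the Boltzmann average of the pair energy", {
  set.seed(55)
  m <- energy_model(A_prime = 2, kappa = 1, D = 1, d_c = 4)
  L <- 3
  box <- c(8.5, 8.5, 8.5)
  cfg <- rod_configuration(rbind(c(1, 1, 1), c(4, 4, 4)),
                           rbind(c(0, 0, 1), c(0, 1, 0)), box, L, 1)
  st <- mc_state(cfg, m)
  st <- tune_move_sizes(st, m)
  st <- metropolis_sweep(st, m, 500)
  es <- replicate(800, {
    st <<- metropolis_sweep(st, m, 5)
    st$energy
  })
  mc_mean <- mean(es)
  mc_se <- sd(es) / sqrt(400)  # ~2x correlation allowance
  # oracle: <U e^{-U}> / <e^{-U}> over uniform relative placements,
  # computed entirely in R (independent geometry + energy)
  n <- 3e5
  w <- matrix(runif(3 * n, -box[1] / 2, box[1] / 2), n, 3)
  ua <- matrix(rnorm(3 * n), n, 3); ua <- ua / sqrt(rowSums(ua^2))
  ub <- matrix(rnorm(3 * n), n, 3); ub <- ub / sqrt(rowSums(ub^2))
  x <- oracle_seg_dist(w, ua, ub, L / 2)
  sint <- sqrt(pmax(0, 1 - rowSums(ua * ub)^2))
  u <- oracle_ts_energy(x, sint, 2, 1, 1, 4)
  wgt <- exp(-u)
  ref <- sum(u[is.finite(u)] * wgt[is.finite(u)]) / sum(wgt)
  expect_lt(abs(mc_mean - ref), 3 * mc_se + 0.01)
})

test_that("move-size tuning pushes acceptance toward the window or saturates", {
  set.seed(19)
  m <- energy_model(0, 1, 1, 1.5)
  # moderately dense: tunable into (0.3, 0.4)
  cfg <- annealed_config(80, 0.15, 4, 1, m)
  st <- mc_state(cfg, m)
  st$max_disp <- 0.02  # far too small: acceptance ~1, sizes must grow
  st$max_rot <- 0.02
  st0 <- st
  st <- tune_move_sizes(st, m)
  expect_gt(st$max_disp, st0$max_disp)
  expect_true(all(st$acceptance >= 0.25 & st$acceptance <= 0.45))
  expect_false(st$tuning_saturated)
  # dilute gas: acceptance stays high with capped move sizes
  cfg2 <- random_dilute_config(20, 0.002, 4, 1)
  st2 <- mc_state(cfg2, m)
  st2 <- tune_move_sizes(st2, m, disp_cap = 1, rot_cap = 0.8)
  expect_true(st2$tuning_saturated)
  expect_true(all(st2$acceptance > 0.4))
})

test_that("expansion protocol relaxes an aligned start and expands affinely", {
  set.seed(23)
  m <- energy_model(0, 1, 1, 1.5)
  res <- expansion_protocol(m, density_schedule = c(0.06, 0.04), n_rods = 48,
                            L = 4, D = 1, n_snapshots = 3, sample_every = 5,
                            init = "aligned", block = 40, max_blocks = 30)
  expect_length(res, 2)
  # the aligned start (S = 1) has decayed toward the isotropic baseline
  s_end <- vapply(res, function(r) nematic_order(r$state$configuration),
                  numeric(1))
  expect_true(all(s_end < 0.45))
  # densities realized exactly, snapshots carry the right geometry
  phis <- vapply(res, function(r)
    config_volume_fraction(r$state$configuration), numeric(1))
  expect_equal(phis, c(0.06, 0.04), tolerance = 1e-10)
  expect_error(expansion_protocol(m, c(0.04, 0.06), 48, 4, 1),
               "decreasing")
  # one-density schedule reduces to plain equilibrate + sample
  res1 <- expansion_protocol(m, 0.03, n_rods = 24, L = 4, D = 1,
                             n_snapshots = 2, init = "random",
                             block = 30, max_blocks = 20)
  expect_length(res1, 1)
  expect_length(res1[[1]]$snapshots, 2)
})

test_that("isotropic baseline of the order parameter scales as N^{-1/2}", {
  set.seed(2)
  s64 <- replicate(40, {
    u <- matrix(rnorm(64 * 3), 64, 3)
    nematic_order(u / sqrt(rowSums(u^2)))
  })
  s256 <- replicate(40, {
    u <- matrix(rnorm(256 * 3), 256, 3)
    nematic_order(u / sqrt(rowSums(u^2)))
  })
  expect_equal(mean(s64) / mean(s256), 2, tolerance = 0.35)
  expect_lt(mean(s256), 0.2)
})
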