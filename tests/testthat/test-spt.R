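test_that("pressure has the correct limits and shape", {
  expect_identical(spt_pressure(0, 6), 0)
  # ideal-gas limit: Pi v_r/kT -> phi
  phi <- 1e-8
  expect_equal(spt_pressure(phi, 11) / phi, 1, tolerance = 1e-6)
  # spheres: matches an independently coded SPT hard-sphere EOS,
  # beta P / rho = (1 + eta + eta^2)/(1 - eta)^3
  eta <- 0.2
  expect_equal(spt_pressure(eta, 1),
               eta * (1 + eta + eta^2) / (1 - eta)^3, tolerance = 1e-12)
  # strictly increasing and convex in phi
  phi <- seq(0, 0.4, by = 0.01)
  p <- spt_pressure(phi, 6)
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(diff(p)) > 0))
  expect_error(spt_pressure(1, 6), "phi")
  expect_error(spt_pressure(0.2, 0.5), "gamma")
})

test_that("free volume fraction: limits, explicit form, dilute slope", {
  expect_identical(spt_alpha(0, 6), 1)
  phi <- seq(0.02, 0.3, by = 0.02)
  a <- spt_alpha(phi, 6)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(diff(a) < 0))
  # the explicit form equals the pressure-input form fed with the SPT
  # pressure, and both match an independently hand-coded expression
  g <- 6
  xi <- g * (g + 1) / (3 * g - 1)
  y <- 0.1 / 0.9
  hand <- (1 - 0.1) * exp(-(6 * xi * y + 4.5 * xi^2 * y^2 +
                              (y + 3 * xi * y^2 + 3 * xi^2 * y^3)))
  expect_equal(spt_alpha(0.1, 6), hand, tolerance = 1e-12)
  expect_equal(spt_alpha(0.1, 6, Pi_tilde = spt_pressure(0.1, 6)), hand,
               tolerance = 1e-12)
  # dilute limit of the insertion work is the isotropic excluded volume
  for (g in c(2, 6, 11)) {
    L <- g - 1
    slope <- -log(spt_alpha(1e-7, g)) / 1e-7
    expect_equal(slope, excluded_volume_iso(L, 1) / rod_volume(L, 1),
                 tolerance = 1e-5)
  }
})

test_that("free-volume route reproduces the analytic pressure (Gibbs-Duhem)", {
  for (g in c(2, 6, 11, 21)) {
    crv <- spt_curve(g, phi_max = 0.3, n = 200)
    crv <- crv[crv$phi > 0, c("phi", "alpha")]
    out <- pressure_from_alpha(crv)
    ref <- spt_pressure(out$phi, g)
    expect_lt(max(abs(out$Pi_tilde - ref) / ref), 1e-3)
  }
  # ideal gas: alpha = 1 everywhere gives Pi_tilde = phi
  phi <- seq(0.01, 0.5, by = 0.01)
  out <- pressure_from_alpha(data.frame(phi = phi, alpha = 1))
  expect_equal(out$Pi_tilde, phi, tolerance = 1e-12)
  expect_error(pressure_from_alpha(data.frame(phi = phi, alpha = 0 * phi)),
               "positive")
})

test_that("charged-rod route reduces to and extends the hard-rod route", {
  phi <- c(0, 0.05, 0.2)
  # identity substitution D_eff = D
  expect_equal(charged_pressure(phi, 11), spt_pressure(phi, 11))
  expect_identical(charged_pressure(0, 3), 0)
  # effective volume fraction plumbing: linear in density, recovers the
  # hard-core volume fraction at D_eff = D
  rho <- 0.01
  expect_equal(effective_volume_fraction(rho, 10, 1),
               rho * rod_volume(10, 1))
  expect_equal(effective_volume_fraction(2 * rho, 10, 3),
               2 * effective_volume_fraction(rho, 10, 3))
  expect_identical(effective_volume_fraction(0, 10, 3), 0)
  # at fixed number density, a larger effective diameter raises the pressure
  L <- 10
  deffs <- c(1, 2, 4, 6)
  p <- vapply(deffs, function(de) {
    charged_pressure(effective_volume_fraction(0.001, L, de),
                     1 + L / de) / rod_volume(L, de)
  }, numeric(1))  # compare on a common scale: pressure per unit volume
  expect_true(all(diff(p) > 0))
})

test_that("thermodynamic curves satisfy their invariants", {
  crv <- spt_curve(6, 0.35, 100)
  expect_silent(validate_thermo_curve(crv))
  expect_equal(crv$alpha[1], 1)
  expect_equal(crv$Pi_tilde[1], 0)
  bad <- crv
  bad$alpha <- rev(bad$alpha)
  expect_error(validate_thermo_curve(bad), "non-increasing")
  g <- rod_geometry(10, 1)
  expect_equal(g$gamma, 11)
  expect_equal(g$v_r, pi * 10 / 4 + pi / 6)
})
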