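# Reference values for the exact infinite-cutoff effective diameter on the
# 3 x 3 (A, kappaD) grid, frozen from a 30-digit independent quadrature of
# the sin^2-weighted orientation average.
deff_inf_oracle <- rbind(
  "0.5" = c("1" = 2.26493001, "4" = 4.34890235, "16" = 7.08590809),
  "1"   = c("1" = 1.41231358, "4" = 2.23124877, "16" = 3.54316130),
  "2"   = c("1" = 1.08195375, "4" = 1.28768351, "16" = 1.78441377))

test_that("exact orientation-averaged diameter matches the frozen oracle", {
  for (kD in c(0.5, 1, 2)) {
    for (A in c(1, 4, 16)) {
      got <- exact_effective_diameter(A * exp(-kD), kappa = kD, D = 1)$D_eff
      expect_equal(got, deff_inf_oracle[as.character(kD), as.character(A)],
                   tolerance = 1e-7)
    }
  }
})

test_that("angular kernel agrees with direct quadrature and is monotone", {
  # infinite cutoff, perpendicular rods, A' = 2: kernel equals
  # int_0^inf (1 - exp(-2 e^{-t})) dt, evaluated independently
  direct <- integrate(function(t) 1 - exp(-2 * exp(-t)), 0, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(scaled_excluded_volume(2, 1, 1, pi / 2), direct,
               tolerance = 1e-9)
  expect_equal(direct, 1.31926335616954, tolerance = 1e-12)
  # screening makes a cutoff of 1e4 Debye lengths indistinguishable from inf
  k_fin <- scaled_excluded_volume(2, 1, 1, pi / 2, d_c = 1e4)
  expect_lt(abs(k_fin - direct) / direct, 1e-6)
  # kernel is continuous and increasing in d_c at fixed angle
  dcs <- c(1.5, 2, 3, 5, 8, 15)
  ks <- vapply(dcs, function(dc)
    scaled_excluded_volume(2, 1, 1, pi / 3, d_c = dc), numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks < scaled_excluded_volume(2, 1, 1, pi / 3)))
  # parallel rods are rejected
  expect_error(scaled_excluded_volume(2, 1, 1, 0), "parallel")
  expect_error(scaled_excluded_volume(2, 1, 1, pi), "parallel")
})

test_that("closed form obeys its validity contract", {
  expect_error(slo_closed_form(-1), "positive")
  expect_warning(slo_closed_form(0.5), "A' >= 2")
  # monotone in A' and in the screening length 1/kappa
  a <- c(2, 4, 8, 16, 32)
  expect_true(all(diff(slo_closed_form(a, kappa = 1)) > 0))
  expect_true(slo_closed_form(4, kappa = 0.5) > slo_closed_form(4, kappa = 2))
  # large kappa drives D_eff -> D at fixed A'
  expect_equal(slo_closed_form(4, kappa = 1e6, D = 1), 1, tolerance = 1e-4)
  # within 2.2% of the exact integral for A' >= 2 (spot grid; the full
  # bound is measured in the acceptance suite)
  for (ap in c(2, 6, 20)) {
    for (kD in c(0.5, 2)) {
      ex <- exact_effective_diameter(ap, kappa = kD, D = 1)$D_eff
      expect_lt(abs(slo_closed_form(ap, kappa = kD) - ex) / ex, 0.022)
    }
  }
})

test_that("finite-cutoff diameter is monotone and approaches the limit", {
  ap <- 4 * exp(-1)
  ds <- vapply(c(1.5, 2, 3, 5, 9, 20),
               function(dc) exact_effective_diameter(ap, 1, 1, dc)$D_eff,
               numeric(1))
  dinf <- exact_effective_diameter(ap, 1, 1)$D_eff
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds < dinf))
  expect_lt((dinf - ds[length(ds)]) / dinf, 1e-6)
  # vanishing amplitude recovers the hard-core diameter
  expect_equal(exact_effective_diameter(1e-12, 1, 1)$D_eff, 1,
               tolerance = 1e-9)
  # quadrature is converged: loosening the tolerance does not move it
  d1 <- exact_effective_diameter(ap, 1, 1, rel_tol = 1e-9)$D_eff
  d2 <- exact_effective_diameter(ap, 1, 1, rel_tol = 1e-7)$D_eff
  expect_lt(abs(d1 - d2) / d1, 1e-6)
})

test_that("threshold cutoff reproduces the printed reference table", {
  printed_dct <- rbind(c(11.3, 12.6, 14.2),
                       c(5.3, 6.3, 7.1),
                       c(2.3, 3.0, 3.5))
  printed_deff <- rbind(c(2.2, 4.3, 6.9),
                        c(1.4, 2.2, 3.5),
                        c(1.1, 1.3, 1.7))
  tab <- threshold_cutoff_table(c(1, 4, 16), c(0.5, 1, 2))
  got_dct <- matrix(tab$dct_over_D, 3, 3, byrow = TRUE)
  got_deff <- matrix(tab$Deff_over_D, 3, 3, byrow = TRUE)
  expect_true(all(abs(round(got_dct, 1) - printed_dct) < 0.051))
  expect_true(all(abs(round(got_deff, 1) - printed_deff) < 0.051))
  expect_true(all(got_deff >= 1))
  # threshold decreases with screening and increases with amplitude
  expect_true(all(apply(got_dct, 2, diff) < 0))
  expect_true(all(apply(got_dct, 1, diff) > 0))
})

test_that("automatic method selection follows the decision tree", {
  # strong amplitude, unbounded range: closed form is acceptable
  r1 <- effective_diameter(16, 0.5)
  expect_identical(r1$method, "slo_closed_form")
  # weak amplitude (A' < 2): exact integral regardless of cutoff
  r2 <- effective_diameter(1, 0.5)
  expect_identical(r2$method, "exact_integral")
  # cutoff below threshold: exact finite-cutoff integral
  r3 <- effective_diameter(16, 0.5, d_c_over_D = 5)
  expect_identical(r3$method, "exact_integral")
  expect_identical(r3$d_c_used, 5)
  expect_gt(r3$rel_diff_vs_infinite, 0.022)
  # degenerate one-cell table
  one <- threshold_cutoff_table(4, 1)
  expect_identical(nrow(one), 1L)
  expect_error(threshold_cutoff_table(numeric(0), 1), "non-empty")
})
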