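test_that("segment distance handles canonical geometries exactly", {
  L <- 5
  # parallel rods, perpendicular offset d, no longitudinal offset
  g <- min_segment_distance(c(0, 0, 0), c(0, 0, 1), c(0.8, 0, 0),
                            c(0, 0, 1), L)
  expect_equal(g$x, 0.8, tolerance = 1e-14)
  expect_equal(g$theta, 0)
  # collinear rods with center separation L + s: gap s
  g <- min_segment_distance(c(0, 0, 0), c(0, 0, 1), c(0, 0, L + 0.3),
                            c(0, 0, 1), L)
  expect_equal(g$x, 0.3, tolerance = 1e-12)
  # crossing perpendicular rods through the same point
  g <- min_segment_distance(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0),
                            c(1, 0, 0), L)
  expect_equal(g$x, 0, tolerance = 1e-14)
  expect_equal(g$sin_theta, 1)
})

test_that("segment distance matches dense-sampling and exhaustive oracles", {
  set.seed(101)
  worst_exh <- worst_brute <- 0
  for (k in 1:40) {
    r1 <- runif(3, 0, 6)
    r2 <- runif(3, 0, 6)
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    got <- min_segment_distance(r1, u1, r2, u2, 4)$x
    worst_exh <- max(worst_exh,
                     abs(got - oracle_seg_dist(r1 - r2, u1, u2, 2)))
    worst_brute <- max(worst_brute,
                       got - oracle_seg_dist_sampled(r1, u1, r2, u2, 2))
  }
  expect_lt(worst_exh, 1e-10)
  # the sampled oracle only overestimates by its grid resolution
  expect_lt(abs(worst_brute), 1e-3)
  # a large vectorized sweep against the exhaustive oracle, including
  # near-parallel pairs
  n <- 4000
  w <- matrix(runif(3 * n, -4, 4), n, 3)
  ua <- matrix(rnorm(3 * n), n, 3); ua <- ua / sqrt(rowSums(ua^2))
  noise <- matrix(rnorm(3 * n), n, 3)
  noise[seq_len(n / 2), ] <- 1e-4 * noise[seq_len(n / 2), ] # near-parallel half
  ub <- ua + noise
  ub <- ub / sqrt(rowSums(ub^2))
  ref <- oracle_seg_dist(w, ua, ub, 2)
  got <- vapply(seq_len(n), function(i) {
    min_segment_distance(w[i, ], ua[i, ], c(0, 0, 0), ub[i, ], 4)$x
  }, numeric(1))
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("distance is symmetric and invariant under rigid motions", {
  set.seed(7)
  for (k in 1:30) {
    r1 <- runif(3); r2 <- runif(3, 0, 3)
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    a <- min_segment_distance(r1, u1, r2, u2, 6)
    b <- min_segment_distance(r2, u2, r1, u1, 6)
    expect_equal(a$x, b$x, tolerance = 1e-12)
    expect_equal(a$sin_theta, b$sin_theta, tolerance = 1e-12)
    rot <- random_rotation()
    shift <- runif(3, -2, 2)
    a2 <- min_segment_distance(rot %*% r1 + shift, rot %*% u1,
                               rot %*% r2 + shift, rot %*% u2, 6)
    expect_equal(a2$x, a$x, tolerance = 1e-9)
  }
})

test_that("minimum image sees rods through the periodic boundary", {
  box <- c(12, 12, 12)
  # two rods hugging opposite faces: true gap crosses the boundary
  g <- min_segment_distance(c(0.4, 6, 6), c(0, 0, 1), c(11.8, 6, 6),
                            c(0, 0, 1), 4, box)
  expect_equal(g$x, 0.6, tolerance = 1e-12)
  g_free <- min_segment_distance(c(0.4, 6, 6), c(0, 0, 1), c(11.8, 6, 6),
                                 c(0, 0, 1), 4)
  expect_equal(g_free$x, 11.4, tolerance = 1e-12)
})

test_that("overlap convention is strict and configurations validate", {
  expect_true(hard_overlap(0.99, 1))
  expect_false(hard_overlap(1.01, 1))
  expect_false(hard_overlap(1, 1))   # boundary counts as non-overlapping
  expect_error(rod_configuration(matrix(0, 1, 3), matrix(c(0, 0, 2), 1),
                                 c(10, 10, 10), 5, 1), "unit")
  expect_error(rod_configuration(matrix(0, 1, 3), matrix(c(0, 0, 1), 1),
                                 c(5, 10, 10), 5, 1), "L \\+ D")
  # centers are wrapped into the primary box
  cfg <- rod_configuration(matrix(c(-1, 25, 3), 1), matrix(c(0, 0, 1), 1),
                           c(12, 12, 12), 5, 1)
  expect_true(all(cfg$centers >= 0 & cfg$centers < 12))
})

test_that("neighbor pruning never drops a true neighbor", {
  set.seed(33)
  model <- energy_model(1.5, kappa = 1, D = 1, d_c = 3)
  for (rep in 1:20) {
    cfg <- random_dilute_config(25, 0.03, 4, 1)
    n <- nrow(cfg$centers)
    for (i in sample(n, 3)) {
      cand <- neighbor_candidates(cfg, i, range = model$d_c)
      # exact neighbor set from an all-pairs scan
      truth <- setdiff(which(vapply(seq_len(n), function(j) {
        if (j == i) return(FALSE)
        min_segment_distance(cfg$centers[i, ], cfg$orientations[i, ],
                             cfg$centers[j, ], cfg$orientations[j, ],
                             cfg$L, cfg$box)$x < model$d_c
      }, logical(1))), i)
      expect_true(all(truth %in% cand))
    }
    # pruned energy equals the all-pairs compiled energy
    e_pruned <- config_energy_pruned(cfg, model)
    e_all <- chargedrods:::cpp_total_energy(
      cfg$centers, cfg$orientations, cfg$L / 2, cfg$box, model$A_prime,
      model$kappa, model$D, model$d_c, model$sin_theta_floor)$energy
    expect_equal(e_pruned, e_all, tolerance = 1e-10)
  }
  # two-rod system: the other rod is always a candidate
  cfg2 <- random_dilute_config(2, 0.001, 4, 1)
  expect_identical(neighbor_candidates(cfg2, 1, 3), 2L)
})

test_that("snapshot files round-trip bit-exactly", {
  set.seed(12)
  cfg <- random_dilute_config(15, 0.02, 5, 1)
  f <- tempfile(fileext = ".snap")
  write_snapshot(cfg, f)
  back <- read_snapshot(f)
  expect_identical(back$centers, cfg$centers)
  expect_identical(back$orientations, cfg$orientations)
  expect_identical(back$box, cfg$box)
  expect_identical(c(back$L, back$D), c(cfg$L, cfg$D))
  # and writing the read-back copy changes nothing
  f2 <- tempfile(fileext = ".snap")
  write_snapshot(back, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})

test_that("affine rescaling preserves relative coordinates exactly", {
  set.seed(3)
  cfg <- random_dilute_config(10, 0.02, 5, 1)
  big <- rescale_config(cfg, 1.37)
  expect_equal(big$box, cfg$box * 1.37)
  expect_equal(big$centers / big$box[1], cfg$centers / cfg$box[1],
               tolerance = 1e-12)
  expect_identical(big$orientations, cfg$orientations)
})
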