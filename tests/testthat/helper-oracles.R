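# Independent oracles used across the suite.  Everything here is pure R and
# deliberately avoids the package's compiled kernels.

# Exact minimum distance between two segments of half-length h (centers
# separated by w, unit axes ua/ub), by exhaustive minimization: the interior
# stationary point plus exact 1-D minimization on all four edges of the
# (s, t) box.  Vectorized over rows of w/ua/ub.
oracle_seg_dist <- function(w, ua, ub, h) {
  if (is.null(dim(w))) {
    w <- matrix(w, 1)
    ua <- matrix(ua, 1)
    ub <- matrix(ub, 1)
  }
  b <- rowSums(ua * ub)
  p <- rowSums(w * ua)
  q <- rowSums(w * ub)
  den <- 1 - b^2
  s0 <- ifelse(den > 1e-12, (q * b - p) / den, Inf)
  t0 <- ifelse(den > 1e-12, (q - p * b) / den, Inf)
  d2 <- function(s, t) {
    dd <- w + s * ua - t * ub
    rowSums(dd^2)
  }
  best <- ifelse(abs(s0) <= h & abs(t0) <= h,
                 d2(pmin(pmax(s0, -h), h), pmin(pmax(t0, -h), h)), Inf)
  for (sf in c(-h, h)) {
    t <- pmin(pmax(q + sf * b, -h), h)
    best <- pmin(best, d2(rep(sf, length(t)), t))
  }
  for (tf in c(-h, h)) {
    s <- pmin(pmax(tf * b - p, -h), h)
    best <- pmin(best, d2(s, rep(tf, length(s))))
  }
  sqrt(best)
}

# Brute-force dense-sampling distance between two segments (free space)
oracle_seg_dist_sampled <- function(r1, u1, r2, u2, h, n = 1000) {
  s <- seq(-h, h, length.out = n)
  p1 <- sweep(outer(s, u1), 2, r1, "+")
  p2 <- sweep(outer(s, u2), 2, r2, "+")
  m <- Inf
  for (i in seq_len(n)) {
    d <- sweep(p2, 2, p1[i, ])
    m <- min(m, min(rowSums(d^2)))
  }
  sqrt(m)
}

# minimum-image displacement
oracle_mi <- function(v, box) v - box * round(v / box)

# Truncated-shifted pair energy, recomputed from its definition
oracle_ts_energy <- function(x, sint, A_prime, kappa, D, d_c,
                             floor_s = 1e-6) {
  s <- pmax(sint, floor_s)
  ifelse(x < D, Inf,
         ifelse(x >= d_c, 0,
                A_prime * (exp(-kappa * (x - D)) -
                             exp(-kappa * (d_c - D))) / s))
}

# Uniform-insertion oracle on a fixed configuration: returns per-trial
# (hard_ok at D, success at Deff, exp(-dU)) using only pure-R geometry
oracle_insertions <- function(config, A_prime, kappa, D, d_c, D_eff,
                              n_trials) {
  h <- config$L / 2
  box <- config$box
  n <- nrow(config$centers)
  out <- matrix(0, n_trials, 2)
  for (t in seq_len(n_trials)) {
    r <- runif(3) * box
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    w <- sweep(-config$centers, 2, r, "+")   # r - centers, sign-free in |.|
    w <- sweep(w, 2, box, function(v, b) v - b * round(v / b))
    ua <- matrix(u, n, 3, byrow = TRUE)
    x <- oracle_seg_dist(w, ua, config$orientations, h)
    sint <- sqrt(pmax(0, 1 - (config$orientations %*% u)^2))
    e <- sum(oracle_ts_energy(x, sint, A_prime, kappa, D, d_c))
    out[t, ] <- c(all(x >= D_eff), exp(-e))
  }
  list(success = out[, 1], boltz = out[, 2])
}

# quick dilute configurations for estimator tests
make_dilute_config <- function(n = 20, phi = 0.02, L = 5, D = 1) {
  random_dilute_config(n, phi, L, D)
}

# random rotation matrix (Haar-ish via QR)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
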