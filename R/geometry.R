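# Spherocylinder configurations under periodic boundaries: construction,
# minimum-image segment-segment distance, overlap tests, neighbor pruning and
# plain-text snapshot I/O.

#' Rod configuration under periodic boundary conditions
#'
#' Holds the centers and unit orientation vectors of `N` identical
#' spherocylinders in an orthorhombic box with periodic boundaries in all
#' three directions.  Centers are wrapped into the primary box; orientation
#' vectors are validated to unit norm (tolerance `1e-9`) and renormalized to
#' machine precision.  Every box edge must exceed `L + D` so a rod can never
#' reach its own periodic image.
#'
#' @param centers numeric `N x 3` matrix of rod center positions.
#' @param orientations numeric `N x 3` matrix of unit axis vectors.
#' @param box numeric length-3 vector of box edge lengths.
#' @param L,D shared cylinder length and hard-core diameter.
#' @return Object of class `"rod_configuration"`.
#' @export
rod_configuration <- function(centers, orientations, box, L, D) {
  centers <- as.matrix(centers)
  orientations <- as.matrix(orientations)
  stopifnot(ncol(centers) == 3, ncol(orientations) == 3,
            nrow(centers) == nrow(orientations), length(box) == 3)
  .check_positive(box = box, D = D)
  .check_positive(L = L, .allow_zero = TRUE)
  if (any(box <= L + D)) {
    stop("every box edge must exceed L + D = ", L + D,
         " so a rod cannot overlap its own periodic image")
  }
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("orientation vectors must be unit vectors (tolerance 1e-9)")
  }
  orientations <- orientations / nrm
  centers <- sweep(centers, 2, box, function(x, b) x - b * floor(x / b))
  structure(list(centers = unname(centers),
                 orientations = unname(orientations),
                 box = as.numeric(box), L = L, D = D),
            class = "rod_configuration")
}

#' @export
print.rod_configuration <- function(x, ...) {
  cat(sprintf("Rod configuration: %d spherocylinders (L = %g, D = %g)\n",
              nrow(x$centers), x$L, x$D))
  cat(sprintf("  box = [%g, %g, %g], phi = %.4g\n", x$box[1], x$box[2],
              x$box[3], config_volume_fraction(x)))
  invisible(x)
}

#' @rdname rod_configuration
#' @param config a `rod_configuration`.
#' @export
config_volume_fraction <- function(config) {
  nrow(config$centers) * rod_volume(config$L, config$D) / prod(config$box)
}

#' Minimum distance and crossing angle between two rods
#'
#' Computes the exact closest distance between two finite line segments of
#' length `L` directed along `u1` and `u2`, applying the minimum-image
#' convention to the center-center separation when a periodic `box` is given
#' (legal because configurations enforce `box > L + D`).  The crossing angle
#' is reported in the `(0, pi/2]` convention through `sin(theta) = |u1 x u2|`,
#' which is the only angular dependence the screened pair potential carries.
#'
#' The segment-segment minimization uses the clamped closest-point
#' parametric algorithm with a dedicated parallel-segment branch.
#'
#' @param center1,center2 length-3 center positions.
#' @param u1,u2 length-3 unit axis vectors.
#' @param L segment (cylinder) length.
#' @param box optional periodic box edges; `NULL` for free space.
#' @return List with `x` (closest distance), `theta` (radians, `[0, pi/2]`)
#'   and `sin_theta`.
#' @examples
#' # parallel rods offset sideways by 0.8
#' min_segment_distance(c(0, 0, 0), c(0, 0, 1), c(0.8, 0, 0), c(0, 0, 1), 5)
#' @export
min_segment_distance <- function(center1, u1, center2, u2, L, box = NULL) {
  pbc <- !is.null(box)
  if (!pbc) box <- c(1, 1, 1)
  out <- cpp_pair_geom(as.numeric(center1), as.numeric(u1) / sqrt(sum(u1^2)),
                       as.numeric(center2), as.numeric(u2) / sqrt(sum(u2^2)),
                       L / 2, as.numeric(box), pbc)
  s <- min(max(out[2], 0), 1)
  list(x = out[1], theta = asin(s), sin_theta = s)
}

#' Hard-core overlap criterion
#'
#' Two rods overlap when the closest distance between their axes is strictly
#' below the diameter; `x == D` counts as non-overlapping (a zero-measure
#' boundary, fixed by convention).  Used with the bare diameter `D` for
#' system rods and with an effective diameter for insertion trials.
#'
#' @param x closest axis-axis distance(s) (>= 0).
#' @param D diameter (> 0).
#' @return Logical vector, `TRUE` where the rods overlap.
#' @export
hard_overlap <- function(x, D) {
  .check_positive(D = D)
  .check_positive(x = x, .allow_zero = TRUE)
  x < D
}

#' Candidate interaction partners of one rod
#'
#' Returns a superset of the rods whose segment-segment distance to rod `i`
#' can be below `range`, by pruning on the minimum-image center-center
#' distance: two segments of length `L` can only approach within `range` if
#' their centers are within `range + L`.  When that pruning radius reaches
#' half the box the function falls back to all other rods.
#'
#' @param config a [rod_configuration()].
#' @param i rod index (1-based).
#' @param range interaction reach (at least `D`; typically `d_c`).
#' @return Integer vector of candidate rod indices (never dropping a true
#'   neighbor).
#' @export
neighbor_candidates <- function(config, i, range) {
  n <- nrow(config$centers)
  stopifnot(i >= 1, i <= n)
  others <- setdiff(seq_len(n), i)
  reach <- range + config$L
  if (reach >= min(config$box) / 2) return(others)
  d <- sweep(config$centers[others, , drop = FALSE], 2, config$centers[i, ])
  d <- sweep(d, 2, config$box, function(x, b) x - b * round(x / b))
  others[rowSums(d^2) <= reach^2]
}

#' Total pair energy evaluated through neighbor pruning
#'
#' Pure-R reference evaluation of the total truncated-shifted pair energy of
#' a configuration, summing over [neighbor_candidates()] pairs; used to audit
#' the compiled all-pairs kernel.
#'
#' @param config a [rod_configuration()].
#' @param model an [energy_model()].
#' @return Total reduced energy (k_B T units); `Inf` if any hard-core
#'   overlap.
#' @export
config_energy_pruned <- function(config, model) {
  n <- nrow(config$centers)
  e <- 0
  for (i in seq_len(n)) {
    cand <- neighbor_candidates(config, i, model$d_c)
    cand <- cand[cand > i]
    for (j in cand) {
      g <- min_segment_distance(config$centers[i, ], config$orientations[i, ],
                                config$centers[j, ], config$orientations[j, ],
                                config$L, config$box)
      if (g$x < model$D) return(Inf)
      e <- e + truncated_shifted_energy(g$x, max(g$sin_theta,
                                                 model$sin_theta_floor),
                                        model)
    }
  }
  e
}

#' Affine rescaling of a configuration
#'
#' Rescales the box and the rod centers by a common factor, leaving
#' orientations (and the rods themselves) untouched -- the elementary step of
#' box expansion or compression.  Relative center coordinates are preserved
#' exactly.
#'
#' @param config a [rod_configuration()].
#' @param factor positive scale factor for box edges and center coordinates.
#' @return The rescaled [rod_configuration()].
#' @export
rescale_config <- function(config, factor) {
  .check_positive(factor = factor)
  rod_configuration(config$centers * factor, config$orientations,
                    config$box * factor, config$L, config$D)
}

#' Plain-text snapshot files
#'
#' Writes/reads a rod configuration as readable text: a format line, a header
#' `N bx by bz L D`, then one `x y z ux uy uz` row per rod, all printed with
#' 17 significant digits so a write/read cycle is bit-exact.
#'
#' @param config a [rod_configuration()].
#' @param file path of the snapshot file.
#' @return `write_snapshot()` returns `file` invisibly; `read_snapshot()`
#'   returns a [rod_configuration()].
#' @export
write_snapshot <- function(config, file) {
  n <- nrow(config$centers)
  head1 <- "chargedrods snapshot 1"
  head2 <- paste(c(n, sprintf("%.17g", c(config$box, config$L, config$D))),
                 collapse = " ")
  rows <- apply(cbind(config$centers, config$orientations), 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(head1, head2, rows), file)
  invisible(file)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(file) {
  lines <- readLines(file)
  if (!startsWith(lines[1], "chargedrods snapshot")) {
    stop("not a chargedrods snapshot file")
  }
  hdr <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  n <- hdr[1]
  m <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + n)]), "\\s+"))),
              ncol = 6, byrow = TRUE)
  rod_configuration(m[, 1:3], m[, 4:6], hdr[2:4], hdr[5], hdr[6])
}

#' Random and aligned starting configurations
#'
#' `random_dilute_config()` builds an isotropic configuration by random
#' sequential insertion (positions uniform in the box, orientations uniform
#' on the sphere, overlapping placements rejected) -- suitable for volume
#' fractions well below the jamming density of the rod fluid.
#' `aligned_config()` places all rods parallel to the z axis on a simple
#' lattice, the classic dense starting point that is then relaxed and
#' expanded.
#'
#' @param n number of rods.
#' @param phi target rod volume fraction (sets the cubic box edge).
#' @param L,D rod geometry.
#' @param max_attempts insertion attempts per rod before giving up.
#' @return A [rod_configuration()].
#' @export
random_dilute_config <- function(n, phi, L, D, max_attempts = 2000) {
  .check_positive(n = n, phi = phi)
  edge <- (n * rod_volume(L, D) / phi)^(1 / 3)
  if (edge <= L + D) {
    stop("requested density too high: cubic box edge ", signif(edge, 4),
         " does not exceed L + D")
  }
  box <- rep(edge, 3)
  centers <- matrix(0, n, 3)
  us <- matrix(0, n, 3)
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- runif(3) * box
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      if (placed == 0L) {
        ok <- TRUE
      } else {
        d <- cpp_rod_vs_all(centers[seq_len(placed), , drop = FALSE],
                            us[seq_len(placed), , drop = FALSE],
                            r, u, L / 2, box, 0L)
        ok <- all(d[, 1] >= D)
      }
      if (ok) break
    }
    if (!ok) {
      stop("random sequential insertion failed at rod ", placed + 1,
           "; lower `phi` or use aligned_config() + expansion")
    }
    placed <- placed + 1L
    centers[placed, ] <- r
    us[placed, ] <- u
  }
  rod_configuration(centers, us, box, L, D)
}

#' @rdname random_dilute_config
#' @export
aligned_config <- function(n, phi, L, D) {
  .check_positive(n = n, phi = phi)
  edge <- (n * rod_volume(L, D) / phi)^(1 / 3)
  if (edge <= L + D) {
    stop("aligned lattice impossible: box edge ", signif(edge, 4),
         " does not exceed L + D")
  }
  nz <- max(1L, floor(edge / (L + D * 1.05)))
  nxy <- ceiling(sqrt(n / nz))
  while (nxy * nxy * nz < n) nxy <- nxy + 1L
  sxy <- edge / nxy
  if (sxy <= 1.02 * D) {
    stop("aligned lattice impossible at this density: lateral spacing ",
         signif(sxy, 4), " below the rod diameter")
  }
  idx <- seq_len(n) - 1L
  iz <- idx %% nz
  ixy <- idx %/% nz
  ix <- ixy %% nxy
  iy <- ixy %/% nxy
  centers <- cbind((ix + 0.5) * sxy, (iy + 0.5) * sxy,
                   (iz + 0.5) * edge / nz)
  us <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  rod_configuration(centers, us, rep(edge, 3), L, D)
}
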