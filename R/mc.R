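# Metropolis Monte Carlo of charged hard spherocylinders with the
# truncated-shifted screened-Coulomb pair potential.

#' Pair interaction model for charged rods
#'
#' The screened double-layer repulsion between two rods whose axes cross at
#' angle `theta` with closest distance `x` is
#' \deqn{U(x,\theta)/k_BT = \frac{A'\,e^{-\kappa(x - D)}}{\sin\theta},}
#' i.e. the amplitude at hard-core contact of perpendicular rods is `A'`.
#' In a simulation the interaction is truncated at `d_c` and shifted so that
#' it vanishes continuously there (see [truncated_shifted_energy()]).
#' The `1/sin(theta)` divergence of exactly parallel rods is floored at
#' `sin_theta_floor`, which keeps an aligned starting configuration at a
#' finite, relaxable energy; the floor is part of the model record.
#'
#' @param A_prime contact amplitude `A' = A exp(-kappa D)` (>= 0; 0 gives
#'   pure hard rods).
#' @param kappa inverse Debye length.
#' @param D hard-core diameter.
#' @param d_c interaction cutoff distance (> D).
#' @param sin_theta_floor numerical floor for `sin(theta)`.
#' @return Object of class `"energy_model"`.
#' @export
energy_model <- function(A_prime, kappa, D, d_c, sin_theta_floor = 1e-6) {
  .check_positive(kappa = kappa, D = D, d_c = d_c,
                  sin_theta_floor = sin_theta_floor)
  .check_positive(A_prime = A_prime, .allow_zero = TRUE)
  if (d_c <= D) stop("`d_c` must exceed the hard-core diameter `D`")
  structure(list(A_prime = A_prime, kappa = kappa, D = D, d_c = d_c,
                 sin_theta_floor = sin_theta_floor), class = "energy_model")
}

#' Pair energies of the screened rod-rod repulsion
#'
#' `pair_energy()` is the bare screened form
#' `A' exp(-kappa (x - D)) / sin(theta)`; `truncated_shifted_energy()`
#' subtracts the same-angle value at the cutoff and is exactly zero for
#' `x >= d_c`, making the potential continuous at the cutoff.  Distances
#' below the hard core return `Inf`.
#'
#' @param x closest axis-axis distance(s).
#' @param sin_theta sine of the crossing angle, in (0, 1].
#' @param model an [energy_model()].
#' @return Reduced energy in units of `k_B T`.
#' @examples
#' m <- energy_model(A_prime = 2, kappa = 1, D = 1, d_c = 8)
#' pair_energy(1, 1, m)            # contact, perpendicular: exactly A'
#' truncated_shifted_energy(8, 1, m)  # zero at the cutoff
#' @export
pair_energy <- function(x, sin_theta, model) {
  stopifnot(inherits(model, "energy_model"))
  if (any(sin_theta <= 0 | sin_theta > 1)) {
    stop("`sin_theta` must lie in (0, 1]")
  }
  n <- max(length(x), length(sin_theta))
  x <- rep_len(x, n)
  s <- pmax(rep_len(sin_theta, n), model$sin_theta_floor)
  ifelse(x < model$D, Inf,
         model$A_prime * exp(-model$kappa * (x - model$D)) / s)
}

#' @rdname pair_energy
#' @export
truncated_shifted_energy <- function(x, sin_theta, model) {
  stopifnot(inherits(model, "energy_model"))
  if (any(sin_theta <= 0 | sin_theta > 1)) {
    stop("`sin_theta` must lie in (0, 1]")
  }
  n <- max(length(x), length(sin_theta))
  x <- rep_len(x, n)
  s <- pmax(rep_len(sin_theta, n), model$sin_theta_floor)
  shift <- model$A_prime * exp(-model$kappa * (model$d_c - model$D)) / s
  ifelse(x < model$D, Inf,
         ifelse(x >= model$d_c, 0,
                model$A_prime * exp(-model$kappa * (x - model$D)) / s - shift))
}

#' Simulation controls
#'
#' Collects the run parameters of a Metropolis simulation.  Defaults follow
#' the reference protocol for production runs (1352 rods, acceptance kept
#' between 0.3 and 0.4 by adapting the maximum displacement and rotation);
#' tests and examples use smaller systems.
#'
#' @param N_r number of rods.
#' @param L_over_D aspect ratio `L/D` (the aspect parameter is
#'   `gamma = 1 + L/D`).
#' @param D hard-core diameter (unit of length).
#' @param densities schedule of target volume fractions (hard-core `phi`),
#'   strictly decreasing for the expansion protocol.
#' @param max_disp,max_rot initial maximum displacement (units of `D`) and
#'   rotation (radians) of trial moves.
#' @param target_acceptance acceptance-ratio window for move-size tuning.
#' @param n_sweeps_equil,n_sweeps_sample sweeps for equilibration and
#'   sampling (one sweep = `N_r` trial moves).
#' @param sample_every sweeps between stored snapshots.
#' @param seed optional RNG seed recorded with the run.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(N_r = 1352, L_over_D = 10, D = 1,
                              densities = NULL, max_disp = 0.5, max_rot = 0.5,
                              target_acceptance = c(0.3, 0.4),
                              n_sweeps_equil = 500, n_sweeps_sample = 200,
                              sample_every = 10, seed = NULL) {
  .check_positive(N_r = N_r, L_over_D = L_over_D, D = D, max_disp = max_disp,
                  max_rot = max_rot, n_sweeps_equil = n_sweeps_equil,
                  n_sweeps_sample = n_sweeps_sample,
                  sample_every = sample_every)
  stopifnot(length(target_acceptance) == 2,
            all(target_acceptance > 0 & target_acceptance < 1),
            diff(target_acceptance) > 0)
  if (!is.null(densities)) .check_positive(densities = densities)
  structure(list(N_r = as.integer(N_r), L_over_D = L_over_D, D = D,
                 densities = densities, max_disp = max_disp,
                 max_rot = max_rot, target_acceptance = target_acceptance,
                 n_sweeps_equil = n_sweeps_equil,
                 n_sweeps_sample = n_sweeps_sample,
                 sample_every = sample_every, seed = seed),
            class = "simulation_config")
}

#' Monte Carlo simulation state
#'
#' Wraps a configuration with its cached total energy, move sizes, sweep
#' counter and acceptance statistics.  The cached energy is updated
#' incrementally during sweeps and can be audited against a full
#' recomputation with [audit_energy()].
#'
#' @param config a [rod_configuration()].
#' @param model an [energy_model()].
#' @param max_disp,max_rot initial move sizes.
#' @return Object of class `"mc_state"`.
#' @export
mc_state <- function(config, model, max_disp = 0.5 * config$D,
                     max_rot = 0.5) {
  stopifnot(inherits(config, "rod_configuration"),
            inherits(model, "energy_model"))
  tot <- cpp_total_energy(config$centers, config$orientations, config$L / 2,
                          config$box, model$A_prime, model$kappa, model$D,
                          model$d_c, model$sin_theta_floor)
  if (tot$overlap) stop("initial configuration contains hard-core overlaps")
  structure(list(configuration = config, energy = tot$energy,
                 sweep_index = 0L, max_disp = max_disp, max_rot = max_rot,
                 acceptance = c(translation = NA_real_, rotation = NA_real_),
                 tuning_saturated = FALSE),
            class = "mc_state")
}

#' @export
print.mc_state <- function(x, ...) {
  cat(sprintf(
    "MC state: %d rods, phi = %.4g, U/kT = %.6g after %d sweeps\n",
    nrow(x$configuration$centers), config_volume_fraction(x$configuration),
    x$energy, x$sweep_index))
  cat(sprintf("  move sizes: disp %.3g, rot %.3g; acceptance: %s\n",
              x$max_disp, x$max_rot,
              paste(sprintf("%.2f", x$acceptance), collapse = "/")))
  invisible(x)
}

#' Run Metropolis sweeps
#'
#' One sweep is `N` single-particle trial moves, each (with equal
#' probability) a random displacement of a random rod or a rotation of its
#' axis about a random direction, accepted with probability
#' `min(1, exp(-dU/kT))`.  Any trial producing a hard-core overlap is
#' rejected.  The energy cache is updated incrementally.
#'
#' @param state an [mc_state()].
#' @param model an [energy_model()].
#' @param n_sweeps number of sweeps to run.
#' @param p_trans probability that a trial move is a translation.
#' @return The updated `mc_state`.
#' @export
metropolis_sweep <- function(state, model, n_sweeps = 1, p_trans = 0.5) {
  stopifnot(inherits(state, "mc_state"))
  cfg <- state$configuration
  out <- cpp_run_sweeps(cfg$centers, cfg$orientations, cfg$L / 2, cfg$box,
                        model$A_prime, model$kappa, model$D, model$d_c,
                        model$sin_theta_floor, as.integer(n_sweeps),
                        state$max_disp, state$max_rot, p_trans, 0)
  cfg$centers <- out$centers
  cfg$orientations <- out$us
  state$configuration <- cfg
  state$energy <- state$energy + out$dE
  state$sweep_index <- state$sweep_index + as.integer(n_sweeps)
  state$acceptance <- c(translation = out$acc_trans, rotation = out$acc_rot)
  state
}

#' Audit the incremental energy cache
#'
#' Recomputes the total energy from scratch and compares it to the cached
#' value; deviations beyond `tol` (in k_B T) indicate a bookkeeping bug and
#' raise an error.
#'
#' @param state an [mc_state()].
#' @param model an [energy_model()].
#' @param tol allowed absolute drift of the cache.
#' @return The state with the cache replaced by the fresh value, invisibly.
#' @export
audit_energy <- function(state, model, tol = 1e-8) {
  cfg <- state$configuration
  tot <- cpp_total_energy(cfg$centers, cfg$orientations, cfg$L / 2, cfg$box,
                          model$A_prime, model$kappa, model$D, model$d_c,
                          model$sin_theta_floor)
  drift <- abs(tot$energy - state$energy)
  scale <- max(1, abs(tot$energy))
  if (!isTRUE(drift / scale <= tol) && !(tot$energy == 0 && drift <= tol)) {
    stop(sprintf("energy cache drifted by %g kT (tolerance %g)", drift, tol))
  }
  state$energy <- tot$energy
  invisible(state)
}

#' Nematic order parameter of a set of orientations
#'
#' Largest eigenvalue of the traceless tensor
#' `Q = (3 <u u^T> - I) / 2`; 1 for perfect alignment, `O(N^{-1/2})` for an
#' isotropic finite sample.
#'
#' @param orientations `N x 3` matrix of unit vectors, or a
#'   [rod_configuration()].
#' @return Scalar order parameter `S`.
#' @export
nematic_order <- function(orientations) {
  if (inherits(orientations, "rod_configuration")) {
    orientations <- orientations$orientations
  }
  q <- crossprod(orientations) / nrow(orientations)
  max(eigen((3 * q - diag(3)) / 2, symmetric = TRUE,
            only.values = TRUE)$values)
}

#' Tune trial-move sizes toward the target acceptance window
#'
#' Runs short bursts of sweeps and rescales the maximum displacement and
#' rotation until both acceptance ratios fall inside `target` (default
#' (0.3, 0.4)), move sizes hit their caps, or the iteration budget is
#' exhausted.  At low density the acceptance stays above the window even at
#' the capped move sizes; the state is then flagged `tuning_saturated`.
#' Tuning breaks detailed balance while it runs, so it must precede
#' sampling.
#'
#' @param state an [mc_state()].
#' @param model an [energy_model()].
#' @param window sweeps per tuning burst.
#' @param target acceptance window (length 2).
#' @param max_iter maximum number of bursts.
#' @param disp_cap,rot_cap upper bounds for the move sizes (defaults: a
#'   quarter box edge and `pi/2`).
#' @return The tuned `mc_state`.
#' @export
tune_move_sizes <- function(state, model, window = 20,
                            target = c(0.3, 0.4), max_iter = 40,
                            disp_cap = min(state$configuration$box) / 4,
                            rot_cap = pi / 2) {
  stopifnot(inherits(state, "mc_state"))
  state$tuning_saturated <- FALSE
  for (it in seq_len(max_iter)) {
    state <- metropolis_sweep(state, model, n_sweeps = window)
    acc <- state$acceptance
    adjust <- function(size, a, cap) {
      if (is.na(a)) return(size)
      if (a > target[2]) min(size * 1.25, cap)
      else if (a < target[1]) size * 0.8
      else size
    }
    new_disp <- adjust(state$max_disp, acc["translation"], disp_cap)
    new_rot <- adjust(state$max_rot, acc["rotation"], rot_cap)
    in_window <- all(acc >= target[1] & acc <= target[2], na.rm = TRUE)
    saturated <- (acc["translation"] > target[2] &&
                    state$max_disp >= disp_cap * 0.999) ||
      (acc["rotation"] > target[2] && state$max_rot >= rot_cap * 0.999)
    unchanged <- new_disp == state$max_disp && new_rot == state$max_rot
    state$max_disp <- new_disp
    state$max_rot <- new_rot
    if (in_window || (saturated && unchanged)) {
      state$tuning_saturated <- !in_window
      break
    }
  }
  state
}

#' Equilibrate a state
#'
#' Runs sweeps in blocks and tracks the total energy and the nematic order
#' parameter.  A trace is considered relaxed when the linear drift over its
#' most recent blocks is statistically indistinguishable from its scatter
#' (|slope| below twice its standard error) or negligible on the observable's
#' scale; both traces must be relaxed for `n_flat` consecutive blocks.  For
#' hard rods the energy trace is identically zero and only the
#' order-parameter criterion is active.  If `max_blocks` is exhausted first a
#' warning is issued.
#'
#' @param state an [mc_state()].
#' @param model an [energy_model()].
#' @param block sweeps per block.
#' @param max_blocks iteration budget.
#' @param slope_tol relative drift per block considered negligible.
#' @param n_flat number of consecutive flat checks required.
#' @return The equilibrated `mc_state`, with the block traces in attribute
#'   `"equilibration"`.
#' @export
equilibrate <- function(state, model, block = 50, max_blocks = 60,
                        slope_tol = 1e-3, n_flat = 3) {
  e_trace <- s_trace <- numeric(0)
  flat <- 0L
  relaxed <- function(tr, scale) {
    k <- min(length(tr), 6L)
    if (k < 4L) return(FALSE)
    y <- tail(tr, k)
    x <- seq_len(k)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(res^2) / (k - 2) / sxx)
    abs(slope) <= 2 * se + slope_tol * scale
  }
  for (b in seq_len(max_blocks)) {
    state <- metropolis_sweep(state, model, n_sweeps = block)
    e_trace <- c(e_trace, state$energy)
    s_trace <- c(s_trace, nematic_order(state$configuration))
    ok_e <- model$A_prime == 0 ||
      relaxed(e_trace, max(abs(mean(tail(e_trace, 6))), 1))
    ok_s <- relaxed(s_trace, 1) ||
      tail(s_trace, 1) < 4 / sqrt(nrow(state$configuration$centers))
    flat <- if (ok_e && ok_s) flat + 1L else 0L
    if (flat >= n_flat) break
  }
  if (flat < n_flat) {
    warning("equilibration budget exhausted before the drift criterion ",
            "was met; inspect attr(state, 'equilibration')")
  }
  state <- audit_energy(state, model)
  attr(state, "equilibration") <- list(energy = e_trace,
                                       nematic_order = s_trace,
                                       blocks = length(e_trace),
                                       converged = flat >= n_flat)
  state
}

#' Expansion protocol: dense aligned start, relax, expand, re-equilibrate
#'
#' Reproduces the standard preparation of charged-rod ensembles: initialize
#' at the highest density of the schedule with all rods aligned, relax to the
#' equilibrium (isotropic) state, then repeatedly expand the box affinely
#' (centers rescaled, orientations untouched) to each lower density,
#' re-equilibrating and sampling snapshots at every step.
#'
#' @param model an [energy_model()].
#' @param density_schedule strictly decreasing hard-core volume fractions.
#' @param n_rods number of rods.
#' @param L,D rod geometry.
#' @param n_snapshots,sample_every snapshots stored per density and their
#'   sweep spacing.
#' @param init `"aligned"` (dense aligned lattice) or `"random"` (random
#'   sequential insertion at the first density).
#' @param block,max_blocks equilibration controls passed to [equilibrate()].
#' @return List with one element per density: `phi`, the equilibrated
#'   `state`, and `snapshots` (list of configurations).
#' @export
expansion_protocol <- function(model, density_schedule, n_rods, L, D,
                               n_snapshots = 10, sample_every = 5,
                               init = c("aligned", "random"),
                               block = 50, max_blocks = 60) {
  init <- match.arg(init)
  if (length(density_schedule) > 1 &&
      any(diff(density_schedule) >= 0)) {
    stop("`density_schedule` must be strictly decreasing")
  }
  phi0 <- density_schedule[1]
  config <- switch(init,
                   aligned = aligned_config(n_rods, phi0, L, D),
                   random = random_dilute_config(n_rods, phi0, L, D))
  state <- mc_state(config, model)
  results <- vector("list", length(density_schedule))
  for (k in seq_along(density_schedule)) {
    phi <- density_schedule[k]
    if (k > 1) {
      f <- (density_schedule[k - 1] / phi)^(1 / 3)
      cfg <- rescale_config(state$configuration, f)
      state <- mc_state(cfg, model, state$max_disp, state$max_rot)
    }
    state <- tune_move_sizes(state, model)
    state <- equilibrate(state, model, block = block,
                         max_blocks = max_blocks)
    eq <- attr(state, "equilibration")
    if (!eq$converged && k == 1 && init == "aligned" &&
        tail(eq$nematic_order, 1) > 0.9) {
      stop("aligned initial state failed to relax at phi = ", phi,
           " (nematic order ", signif(tail(eq$nematic_order, 1), 3),
           "); lower the starting density")
    }
    snaps <- vector("list", n_snapshots)
    for (s in seq_len(n_snapshots)) {
      state <- metropolis_sweep(state, model, n_sweeps = sample_every)
      snaps[[s]] <- state$configuration
    }
    state <- audit_energy(state, model)
    results[[k]] <- list(phi = phi, state = state, snapshots = snaps)
  }
  results
}

#' Annealed starting configuration at arbitrary fluid density
#'
#' Builds an overlap-free, orientationally isotropic configuration directly
#' at the target density by the standard push-off construction: rods are
#' placed with ideal-gas positions and orientations, the hard core is
#' temporarily replaced by a finite linear overlap penalty, and Metropolis
#' sweeps under a rising penalty schedule anneal the overlaps away.  The
#' result is only a starting point; the strict hard-core Markov chain that
#' follows ([equilibrate()]) is what samples the target ensemble.
#'
#' @param n number of rods.
#' @param phi target hard-core volume fraction (sets the cubic box edge).
#' @param L,D rod geometry.
#' @param model optional [energy_model()] whose soft repulsion is active
#'   during the annealing (default: pure hard rods).
#' @param penalties increasing overlap-penalty schedule (k_B T units).
#' @param sweeps_per_stage annealing sweeps per penalty value.
#' @param max_extra_sweeps budget of additional sweeps at the stiffest
#'   penalty if overlaps persist.
#' @return An overlap-free [rod_configuration()].
#' @export
annealed_config <- function(n, phi, L, D,
                            model = energy_model(0, 1, D, 1.5 * D),
                            penalties = c(5, 20, 80, 320),
                            sweeps_per_stage = 40,
                            max_extra_sweeps = 2000) {
  .check_positive(n = n, phi = phi)
  edge <- (n * rod_volume(L, D) / phi)^(1 / 3)
  if (edge <= L + D) {
    stop("density too high: cubic box edge ", signif(edge, 4),
         " does not exceed L + D")
  }
  box <- rep(edge, 3)
  centers <- matrix(runif(3 * n), n, 3) %*% diag(box)
  us <- matrix(rnorm(3 * n), n, 3)
  us <- us / sqrt(rowSums(us^2))
  n_over <- function() {
    cpp_total_energy(centers, us, L / 2, box, model$A_prime, model$kappa,
                     model$D, model$d_c, model$sin_theta_floor)$n_overlap
  }
  run <- function(pen, nsw) {
    out <- cpp_run_sweeps(centers, us, L / 2, box, model$A_prime,
                          model$kappa, model$D, model$d_c,
                          model$sin_theta_floor, as.integer(nsw),
                          0.5 * D, 0.5, 0.5, pen)
    centers <<- out$centers
    us <<- out$us
  }
  for (pen in penalties) {
    run(pen, sweeps_per_stage)
    if (n_over() == 0) break
  }
  extra <- 0
  while (n_over() > 0 && extra < max_extra_sweeps) {
    run(max(penalties) * 4, sweeps_per_stage)
    extra <- extra + sweeps_per_stage
  }
  if (n_over() > 0) {
    stop("push-off annealing failed to remove all overlaps at phi = ", phi)
  }
  rod_configuration(centers, us, box, L, D)
}
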