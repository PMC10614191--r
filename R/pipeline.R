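# Study drivers: hard-rod benchmark of SPT, the two insertion routes for
# charged rods, and the theory-versus-simulation comparison tables.

#' Benchmark SPT against hard-spherocylinder Monte Carlo
#'
#' For each volume fraction, prepares an equilibrated hard-rod ensemble
#' (random sequential insertion, compressed where needed), measures the free
#' volume fraction by Widom insertion at the bare diameter, and converts the
#' measured `alpha(phi)` into an osmotic pressure through the exact
#' free-volume relation ([pressure_from_alpha()]).  Both observables are
#' compared against the SPT predictions.
#'
#' Trial-insertion budgets are sized per density from the SPT-predicted
#' `alpha` so that every point collects roughly `target_successes`
#' successes.
#'
#' @param gamma aspect parameter `1 + L/D`.
#' @param phi_grid hard-core volume fractions to simulate (increasing).
#' @param n_rods rods per ensemble.
#' @param n_c snapshots (independent configurations) per density.
#' @param target_successes sampling budget control per density.
#' @param n_t_max cap on trial insertions per configuration.
#' @param equil options list passed to [equilibrate()] (fields `block`,
#'   `max_blocks`).
#' @param min_equil_sweeps sweeps run unconditionally before the drift-based
#'   [equilibrate()] check (translational decorrelation of long rods is slow
#'   and not visible to the drift criterion of an athermal system).
#' @param sample_every sweeps between snapshots.
#' @return Data frame with columns `phi`, `alpha_sim`, `alpha_se`,
#'   `n_success`, `alpha_spt`, `rel_dev_alpha`, `Pi_sim`, `Pi_spt`,
#'   `rel_dev_Pi`.
#' @export
run_hard_rod_benchmark <- function(gamma, phi_grid, n_rods = 256, n_c = 24,
                                   target_successes = 2000, n_t_max = 4e7,
                                   equil = list(block = 50, max_blocks = 40),
                                   min_equil_sweeps = 3000,
                                   sample_every = 10) {
  stopifnot(gamma > 1, !is.unsorted(phi_grid, strictly = TRUE))
  D <- 1
  L <- (gamma - 1) * D
  model <- energy_model(0, kappa = 1, D = D, d_c = 1.5 * D)
  rows <- vector("list", length(phi_grid))
  for (k in seq_along(phi_grid)) {
    phi <- phi_grid[k]
    cfg <- annealed_config(n_rods, phi, L, D, model)
    state <- mc_state(cfg, model)
    state <- tune_move_sizes(state, model)
    state <- metropolis_sweep(state, model, n_sweeps = min_equil_sweeps)
    state <- equilibrate(state, model, block = equil$block,
                         max_blocks = equil$max_blocks)
    snaps <- vector("list", n_c)
    for (s in seq_len(n_c)) {
      state <- metropolis_sweep(state, model, n_sweeps = sample_every)
      snaps[[s]] <- state$configuration
    }
    # two-stage trial budget: a cheap pilot fixes the scale of alpha, the
    # second stage sizes n_t to collect ~target_successes successes
    a_pred <- spt_alpha(phi, gamma)
    n_t1 <- min(n_t_max, max(2e4, ceiling(50 / (a_pred * n_c))))
    est <- alpha_eff_estimator(snaps, D_eff = D, n_t = n_t1)
    if (est$n_s_total < target_successes && est$alpha > 0) {
      n_t2 <- min(n_t_max,
                  ceiling(target_successes / (est$alpha * n_c)))
      if (n_t2 > n_t1) est <- alpha_eff_estimator(snaps, D_eff = D,
                                                  n_t = n_t2)
    }
    rows[[k]] <- data.frame(phi = phi, alpha_sim = est$alpha,
                            alpha_se = est$std_err,
                            n_success = est$n_s_total, alpha_spt = a_pred)
  }
  out <- do.call(rbind, rows)
  out$rel_dev_alpha <- (out$alpha_sim - out$alpha_spt) / out$alpha_spt
  prs <- pressure_from_alpha(data.frame(phi = out$phi,
                                        alpha = out$alpha_sim))
  out$Pi_sim <- prs$Pi_tilde
  out$Pi_spt <- spt_pressure(out$phi, gamma)
  out$rel_dev_Pi <- (out$Pi_sim - out$Pi_spt) / out$Pi_spt
  out
}

#' Charged-rod study at one interaction parameter set
#'
#' Runs the full measurement chain for one `(A, kappaD, d_c)` combination:
#' computes the exact finite-cutoff effective diameter, prepares equilibrated
#' ensembles of soft repulsive rods at each requested effective volume
#' fraction, and evaluates both insertion routes (`alpha_eff` at `D_eff`,
#' `alpha_ref` from the immersion free energy) on a shared trial stream.
#'
#' @param A,kappaD dimensionless amplitude and screening ratio; the contact
#'   amplitude is `A' = A exp(-kappaD)`.
#' @param d_c_over_D interaction cutoff in units of `D`.
#' @param L_over_D rod aspect ratio.
#' @param phi_eff_grid effective volume fractions (of rods with diameter
#'   `D_eff`) to simulate, increasing.
#' @param n_rods,n_c,n_t,sample_every sampling controls.
#' @param equil options passed to [equilibrate()].
#' @return List of class `"charged_study"` with the parameter set, `D_eff`,
#'   and one record per density carrying both insertion estimates.
#' @export
run_charged_study <- function(A, kappaD, d_c_over_D, L_over_D = 10,
                              phi_eff_grid, n_rods = 128, n_c = 16,
                              n_t = 2e4, sample_every = 10,
                              equil = list(block = 40, max_blocks = 40)) {
  .check_positive(A = A, kappaD = kappaD, d_c_over_D = d_c_over_D)
  D <- 1
  L <- L_over_D * D
  kappa <- kappaD / D
  A_prime <- A * exp(-kappaD)
  D_eff <- exact_effective_diameter(A_prime, kappa, D,
                                    d_c = d_c_over_D * D)$D_eff
  model <- energy_model(A_prime, kappa, D, d_c = d_c_over_D * D)
  v_eff <- rod_volume(L, D_eff)
  entries <- vector("list", length(phi_eff_grid))
  for (k in seq_along(phi_eff_grid)) {
    phi_eff <- phi_eff_grid[k]
    phi_hard <- phi_eff * rod_volume(L, D) / v_eff
    cfg <- annealed_config(n_rods, phi_hard, L, D, model)
    state <- mc_state(cfg, model)
    state <- tune_move_sizes(state, model)
    state <- metropolis_sweep(state, model, n_sweeps = 400)
    state <- equilibrate(state, model, block = equil$block,
                         max_blocks = equil$max_blocks)
    snaps <- vector("list", n_c)
    for (s in seq_len(n_c)) {
      state <- metropolis_sweep(state, model, n_sweeps = sample_every)
      snaps[[s]] <- state$configuration
    }
    est <- alpha_estimators(snaps, model, D_eff = D_eff, n_t = n_t)
    entries[[k]] <- list(phi_eff = phi_eff, phi_hard = phi_hard,
                         eff = est$eff, ref = est$ref)
  }
  structure(list(A = A, kappaD = kappaD, d_c_over_D = d_c_over_D,
                 L_over_D = L_over_D, D_eff_over_D = D_eff / D,
                 entries = entries),
            class = "charged_study")
}

#' Comparison table of the two free-volume routes
#'
#' Assembles, from one or more charged-rod studies, the tidy record table
#' underlying every downstream comparison: one row per (parameter set,
#' density) with both insertion estimates, their signed relative difference
#' `(alpha_eff - alpha_ref) / alpha_ref`, the reliability flag (at least 10
#' successful insertions) and the systematic-error flag (relative difference
#' beyond 2.2\%, the accuracy of the effective-diameter mapping itself).
#'
#' @param studies a `"charged_study"` or list of them (as returned by
#'   [run_charged_study()]); an empty list yields an empty table.
#' @return Data frame of comparison records.
#' @export
compare_alpha_routes <- function(studies) {
  if (inherits(studies, "charged_study")) studies <- list(studies)
  rows <- list()
  for (st in studies) {
    stopifnot(inherits(st, "charged_study"))
    for (en in st$entries) {
      rel <- (en$eff$alpha - en$ref$alpha) / en$ref$alpha
      rows[[length(rows) + 1]] <- data.frame(
        A = st$A, kappaD = st$kappaD, d_c_over_D = st$d_c_over_D,
        D_eff_over_D = st$D_eff_over_D, phi_eff = en$phi_eff,
        alpha_eff = en$eff$alpha, se_eff = en$eff$std_err,
        alpha_ref = en$ref$alpha, se_ref = en$ref$std_err,
        n_success = en$eff$n_s_total, rel_diff_sim = rel,
        reliable = en$eff$reliable && en$ref$reliable,
        systematic_flag = is.finite(rel) && abs(rel) > 0.022)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(A = numeric(0), kappaD = numeric(0),
                      d_c_over_D = numeric(0), D_eff_over_D = numeric(0),
                      phi_eff = numeric(0), alpha_eff = numeric(0),
                      se_eff = numeric(0), alpha_ref = numeric(0),
                      se_ref = numeric(0), n_success = numeric(0),
                      rel_diff_sim = numeric(0), reliable = logical(0),
                      systematic_flag = logical(0)))
  }
  do.call(rbind, rows)
}

#' Anchor the route comparison at a fixed reference free volume
#'
#' Summarizes one parameter set by a single number: interpolate
#' `alpha_ref(phi_eff)` to find the effective volume fraction where the
#' reference route equals `alpha_anchor` (0.3 by default), then evaluate the
#' relative difference `(alpha_eff - alpha_anchor) / alpha_anchor` at that
#' density, interpolating `alpha_eff(phi_eff)` the same way.
#'
#' @param records comparison records for a single parameter set
#'   (monotone-decreasing `alpha_ref` against increasing `phi_eff`).
#' @param alpha_anchor reference free volume fraction to anchor at.
#' @param method `"monotone"` (monotone piecewise-cubic Hermite) or
#'   `"linear"` interpolation.
#' @return List with `phi_eff_at_anchor`, `alpha_eff_at_anchor`,
#'   `rel_diff_at_anchor`, and `bracketed`.  When the anchor lies outside the
#'   measured range the result is flagged `bracketed = FALSE` and the values
#'   are `NA` (no extrapolation).
#' @examples
#' rec <- data.frame(phi_eff = c(0.1, 0.2, 0.3, 0.4),
#'                   alpha_ref = exp(-4 * c(0.1, 0.2, 0.3, 0.4)),
#'                   alpha_eff = exp(-4 * c(0.1, 0.2, 0.3, 0.4)))
#' anchor_at_alpha_ref(rec)$phi_eff_at_anchor  # log(1/0.3)/4
#' @export
anchor_at_alpha_ref <- function(records, alpha_anchor = 0.3,
                                method = c("monotone", "linear")) {
  method <- match.arg(method)
  stopifnot(all(c("phi_eff", "alpha_ref", "alpha_eff") %in% names(records)))
  ord <- order(records$phi_eff)
  phi <- records$phi_eff[ord]
  aref <- records$alpha_ref[ord]
  aeff <- records$alpha_eff[ord]
  if (alpha_anchor > max(aref) || alpha_anchor < min(aref)) {
    return(list(phi_eff_at_anchor = NA_real_, alpha_eff_at_anchor = NA_real_,
                rel_diff_at_anchor = NA_real_, bracketed = FALSE))
  }
  interp <- function(x, y, xout) {
    if (method == "linear") {
      approx(x, y, xout = xout, ties = "ordered")$y
    } else {
      splinefun(x, y, method = "monoH.FC")(xout)
    }
  }
  # invert alpha_ref(phi): interpolate phi as a function of alpha_ref
  phi0 <- interp(rev(aref), rev(phi), alpha_anchor)
  aeff0 <- interp(phi, aeff, phi0)
  list(phi_eff_at_anchor = phi0, alpha_eff_at_anchor = aeff0,
       rel_diff_at_anchor = (aeff0 - alpha_anchor) / alpha_anchor,
       bracketed = TRUE)
}

#' Add SLO-SPT theory columns to a comparison table
#'
#' For every record, evaluates the theoretical free volume fraction from the
#' explicit SPT insertion formula at the effective aspect parameter
#' `gamma* = 1 + L/D_eff` and the record's `phi_eff`, the corresponding
#' reduced osmotic pressure, and the signed deviation from the simulated
#' effective free volume `(alpha_theory - alpha_eff) / alpha_eff`.  Flags
#' are recomputed from the table's own columns.
#'
#' @param records comparison records (see [compare_alpha_routes()]).
#' @param L_over_D rod aspect ratio used in the simulations.
#' @return The records with columns `alpha_theory`, `Pi_theory`,
#'   `rel_diff_theory` added and flags refreshed.
#' @export
theory_vs_simulation <- function(records, L_over_D = 10) {
  if (nrow(records) == 0) {
    records$alpha_theory <- records$Pi_theory <-
      records$rel_diff_theory <- numeric(0)
    return(records)
  }
  if (any(records$phi_eff >= 1)) {
    stop("effective volume fraction >= 1 is outside the model's domain")
  }
  gamma_star <- 1 + L_over_D / records$D_eff_over_D
  records$alpha_theory <- spt_alpha(records$phi_eff, gamma_star)
  records$Pi_theory <- charged_pressure(records$phi_eff, gamma_star)
  records$rel_diff_theory <-
    (records$alpha_theory - records$alpha_eff) / records$alpha_eff
  records$systematic_flag <- is.finite(records$rel_diff_sim) &
    abs(records$rel_diff_sim) > 0.022
  records
}

#' Validate a study configuration without running it
#'
#' Dry-run check that a parameter set is internally consistent at any scale,
#' including production scale: rod counts, box size against rod reach and
#' cutoff, effective diameter, and the density schedule.  Returns the derived
#' quantities instead of running sweeps.
#'
#' @param A,kappaD,d_c_over_D interaction parameters.
#' @param L_over_D aspect ratio.
#' @param n_rods rod count (production default 1352).
#' @param phi_eff_grid effective volume fractions of the planned runs.
#' @return List with `D_eff_over_D`, `gamma_star`, `phi_hard`, `box_edges`
#'   and `valid = TRUE` (errors describe any inconsistency).
#' @export
validate_study_config <- function(A, kappaD, d_c_over_D, L_over_D = 10,
                                  n_rods = 1352, phi_eff_grid) {
  .check_positive(A = A, kappaD = kappaD, d_c_over_D = d_c_over_D,
                  n_rods = n_rods, phi_eff_grid = phi_eff_grid)
  D <- 1
  L <- L_over_D * D
  A_prime <- A * exp(-kappaD)
  D_eff <- exact_effective_diameter(A_prime, kappaD, D,
                                    d_c = d_c_over_D * D)$D_eff
  phi_hard <- phi_eff_grid * rod_volume(L, D) / rod_volume(L, D_eff)
  edges <- (n_rods * rod_volume(L, D) / phi_hard)^(1 / 3)
  reach <- L + max(D, d_c_over_D * D)
  if (any(edges <= reach)) {
    stop("box edge (", paste(signif(edges, 4), collapse = ", "),
         ") must exceed rod length plus interaction reach = ", reach)
  }
  list(D_eff_over_D = D_eff / D, gamma_star = 1 + L / D_eff,
       phi_hard = phi_hard, box_edges = edges, valid = TRUE)
}
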