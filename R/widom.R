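# Widom test-particle insertion: the effective free volume fraction
# (hard-overlap test at an effective diameter) and the reference route
# through the immersion free energy, <exp(-dU/kT)>.

#' Single Widom insertion trial
#'
#' Inserts a virtual rod at a uniform position with an orientation uniform on
#' the unit sphere and reports whether it fits, i.e. whether its axis keeps a
#' distance of at least `D_eff` from the axis of every rod in the system.
#' The system is never modified.
#'
#' @param config a [rod_configuration()].
#' @param D_eff insertion (effective) diameter (> 0).
#' @return Logical: `TRUE` for a successful insertion.
#' @export
insert_trial <- function(config, D_eff) {
  .check_positive(D_eff = D_eff)
  out <- cpp_widom(config$centers, config$orientations, config$L / 2,
                   config$box, 1, D_eff, 0, 1, config$D, config$D * 1.0001,
                   1e-6, FALSE)
  out$n_success == 1
}

.new_insertion_estimate <- function(per_config, n_t, n_s_total, which) {
  n_c <- length(per_config)
  est <- mean(per_config)
  se <- if (n_c > 1) sd(per_config) / sqrt(n_c) else NA_real_
  structure(list(alpha = est, std_err = se, per_config = per_config,
                 n_t = n_t, n_c = n_c, n_s_total = n_s_total,
                 reliable = n_s_total >= 10, estimator = which),
            class = "insertion_estimate")
}

#' @export
print.insertion_estimate <- function(x, ...) {
  cat(sprintf("Widom %s estimate: alpha = %.6g +/- %.2g  (%d x %g trials, %g successes%s)\n",
              x$estimator, x$alpha, x$std_err, x$n_c, x$n_t, x$n_s_total,
              if (x$reliable) "" else "; UNRELIABLE (< 10 successes)"))
  invisible(x)
}

#' Free-volume estimators by test-particle insertion
#'
#' `alpha_eff_estimator()` estimates the effective free volume fraction: the
#' fraction of trial insertions of a rod of diameter `D_eff` that create no
#' overlap, averaged over `n_t` trials in each of the supplied equilibrated
#' configurations.  `alpha_ref_estimator()` estimates the reference value
#' `alpha_ref = <exp(-dU/kT)>` from the immersion free energy, where `dU` is
#' the total truncated-shifted interaction of the virtual rod with the
#' system (a hard-core violation at diameter `D` contributes weight zero).
#' `alpha_estimators()` evaluates both on a shared trial stream, which makes
#' the identity `alpha_ref == alpha_eff(D)` exact, term by term, for a
#' hard-rod model (`A_prime = 0`, `D_eff = D`).
#'
#' Estimates are means over configurations with the between-configuration
#' standard error; estimates backed by fewer than 10 successful insertions
#' in total are flagged unreliable rather than rejected.
#'
#' @param snapshots list of equilibrated, decorrelated
#'   [rod_configuration()]s.
#' @param D_eff insertion diameter for the effective route.
#' @param model an [energy_model()] for the reference route.
#' @param n_t trial insertions per configuration.
#' @return An `"insertion_estimate"` (both, for `alpha_estimators()`, in a
#'   list with elements `eff` and `ref`).
#' @examples
#' set.seed(1)
#' cfg <- random_dilute_config(20, 0.02, L = 5, D = 1)
#' alpha_eff_estimator(list(cfg), D_eff = 1, n_t = 2000)
#' @export
alpha_eff_estimator <- function(snapshots, D_eff, n_t = 1e4) {
  .check_positive(D_eff = D_eff, n_t = n_t)
  snapshots <- .as_snapshot_list(snapshots)
  frac <- ns <- numeric(length(snapshots))
  for (i in seq_along(snapshots)) {
    cfg <- snapshots[[i]]
    out <- cpp_widom(cfg$centers, cfg$orientations, cfg$L / 2, cfg$box,
                     n_t, D_eff, 0, 1, cfg$D, cfg$D * 1.0001, 1e-6, FALSE)
    frac[i] <- out$n_success / out$n_trials
    ns[i] <- out$n_success
  }
  .new_insertion_estimate(frac, n_t, sum(ns), "effective")
}

#' @rdname alpha_eff_estimator
#' @export
alpha_ref_estimator <- function(snapshots, model, n_t = 1e4) {
  stopifnot(inherits(model, "energy_model"))
  .check_positive(n_t = n_t)
  snapshots <- .as_snapshot_list(snapshots)
  w <- ns <- numeric(length(snapshots))
  for (i in seq_along(snapshots)) {
    cfg <- snapshots[[i]]
    out <- cpp_widom(cfg$centers, cfg$orientations, cfg$L / 2, cfg$box,
                     n_t, model$D, model$A_prime, model$kappa, model$D,
                     model$d_c, model$sin_theta_floor, TRUE)
    w[i] <- out$sum_w / out$n_trials
    ns[i] <- out$n_hard_ok
  }
  .new_insertion_estimate(w, n_t, sum(ns), "reference")
}

#' @rdname alpha_eff_estimator
#' @export
alpha_estimators <- function(snapshots, model, D_eff, n_t = 1e4) {
  stopifnot(inherits(model, "energy_model"))
  .check_positive(D_eff = D_eff, n_t = n_t)
  snapshots <- .as_snapshot_list(snapshots)
  frac <- w <- ns <- nh <- numeric(length(snapshots))
  for (i in seq_along(snapshots)) {
    cfg <- snapshots[[i]]
    out <- cpp_widom(cfg$centers, cfg$orientations, cfg$L / 2, cfg$box,
                     n_t, D_eff, model$A_prime, model$kappa, model$D,
                     model$d_c, model$sin_theta_floor, TRUE)
    frac[i] <- out$n_success / out$n_trials
    w[i] <- out$sum_w / out$n_trials
    ns[i] <- out$n_success
    nh[i] <- out$n_hard_ok
  }
  list(eff = .new_insertion_estimate(frac, n_t, sum(ns), "effective"),
       ref = .new_insertion_estimate(w, n_t, sum(nh), "reference"))
}

.as_snapshot_list <- function(snapshots) {
  if (inherits(snapshots, "rod_configuration")) return(list(snapshots))
  stopifnot(is.list(snapshots), length(snapshots) > 0,
            all(vapply(snapshots, inherits, TRUE, "rod_configuration")))
  snapshots
}
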