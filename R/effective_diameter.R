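# SLO effective diameter: closed form, exact orientation-averaged integral
# (finite or infinite interaction cutoff), and the threshold-cutoff analysis.

# E1(z) = -Ei(-z), vectorized, 0 for very large arguments (underflow)
.e1 <- function(z) {
  out <- numeric(length(z))
  sm <- z < 700
  if (any(sm)) out[sm] <- pracma::expint_E1(z[sm])
  out
}

# exp(z) * E1(z), stable for large z via the asymptotic series
.e1_scaled <- function(z) {
  out <- numeric(length(z))
  hi <- z > 50
  if (any(hi)) {
    zz <- z[hi]
    out[hi] <- (1 / zz) * (1 - 1 / zz + 2 / zz^2 - 6 / zz^3 + 24 / zz^4)
  }
  if (any(!hi)) out[!hi] <- exp(z[!hi]) * pracma::expint_E1(z[!hi])
  out
}

# Per-angle effective diameter D_eff(theta)/D for two rods crossing at angle
# theta with sin(theta) = s, in units of D, with kappa D = kD:
#   D_eff(theta) = D + int_D^inf (1 - exp(-U(x, theta)/kT)) dx
# For the bare screened potential (infinite cutoff) the integral evaluates to
# (ln a + k_E + E1(a))/kappa with a = A'/sin(theta); for the truncated-shifted
# potential with cutoff d_c it evaluates to
#   d_c - D - [e^b (E1(b) - E1(a))]/kappa,  b = a exp(-kappa (d_c - D)).
.deff_theta <- function(A_prime, kD, s, dc_over_D = Inf) {
  a <- A_prime / s
  inf_form <- 1 + (log(a) + .k_euler + .e1(a)) / kD
  if (!is.finite(dc_over_D)) return(inf_form)
  b <- a * exp(-kD * (dc_over_D - 1))
  ifelse(b < 1e-13,
         inf_form,
         dc_over_D - (.e1_scaled(b) - exp(pmin(b - a, 0)) * .e1_scaled(a)) / kD)
}

# Orientation-averaged effective diameter over D.  The isotropic average
# weights each crossing angle by the excluded volume of long rods, i.e. by
# sin(theta), on top of the solid-angle weight sin(theta) d theta:
#   D_eff = int sin^2 D_eff(theta) d theta / int sin^2 d theta
#         = (4/pi) int_0^{pi/2} sin^2(theta) D_eff(theta) d theta.
.deff_exact <- function(A_prime, kD, dc_over_D = Inf, rel_tol = 1e-9) {
  val <- integrate(function(th) {
    sin(th)^2 * .deff_theta(A_prime, kD, sin(th), dc_over_D)
  }, 0, pi / 2, rel.tol = rel_tol, subdivisions = 500L)
  if (val$message != "OK") {
    stop("orientation quadrature did not converge: ", val$message)
  }
  val$value * 4 / pi
}

#' Closed-form SLO effective diameter of a charged rod
#'
#' The Stroobants-Lekkerkerker-Odijk mapping replaces the screened Coulomb
#' repulsion between rods by an enlarged hard diameter,
#' \deqn{D^{\mathrm{eff}} = D + \kappa^{-1}\left(\ln A' + k_E + \ln 2 -
#'   \tfrac12\right),}
#' with `k_E` Euler's constant (0.5772156649...).  The closed form descends
#' from the second-virial (excluded volume) average over isotropic rod
#' orientations in the limit of an unbounded interaction range and is
#' accurate (within 2.2\% of the exact orientation average,
#' [exact_effective_diameter()]) for `A_prime >= 2`; a warning is issued
#' below that amplitude.
#'
#' @param A_prime dimensionless contact amplitude `A' = A exp(-kappa D)` of
#'   the screened pair repulsion (> 0).
#' @param kappa inverse Debye length.
#' @param D hard-core diameter.
#' @return Effective diameter, in the units of `D` (vectorized over
#'   `A_prime`).
#' @examples
#' slo_closed_form(A_prime = 16 * exp(-0.5), kappa = 0.5, D = 1)
#' @export
slo_closed_form <- function(A_prime, kappa = 1, D = 1) {
  .check_positive(A_prime = A_prime, kappa = kappa, D = D)
  if (any(A_prime < 2)) {
    warning("closed form is derived for A' >= 2; ",
            "use exact_effective_diameter() for smaller amplitudes")
  }
  D + (log(A_prime) + .k_euler + log(2) - 0.5) / kappa
}

#' Scaled electrostatic excluded-distance kernel at fixed crossing angle
#'
#' For two rods crossing at angle `theta` the screened repulsion pushes the
#' distance of closest approach beyond the hard core by
#' \eqn{D_{\mathrm{eff}}(\theta) - D = \kappa^{-1} w(\theta)}.  This function
#' returns the dimensionless kernel \eqn{w(\theta) = \kappa\,
#' (D_{\mathrm{eff}}(\theta) - D)}, evaluated through exponential-integral
#' closed forms: with \eqn{a = A'/\sin\theta},
#' \eqn{w = \ln a + k_E + E_1(a)} for an unbounded interaction and
#' \eqn{w = \kappa(d_c - D) - e^{b}\,[E_1(b) - E_1(a)]},
#' \eqn{b = a\,e^{-\kappa(d_c - D)}}, for the truncated-shifted potential with
#' cutoff `d_c` (\eqn{E_1(z) = -\mathrm{Ei}(-z)}).  The kernel grows like
#' \eqn{\ln(1/\sin\theta)} for nearly parallel rods, where the weighted
#' orientation average remains finite; exactly parallel input is rejected.
#'
#' @inheritParams slo_closed_form
#' @param theta crossing angle in (0, pi), exclusive.
#' @param d_c interaction cutoff distance (> D), possibly `Inf`.
#' @return Dimensionless kernel value (vectorized over `theta`).
#' @export
scaled_excluded_volume <- function(A_prime, kappa = 1, D = 1, theta,
                                   d_c = Inf) {
  .check_positive(A_prime = A_prime, kappa = kappa, D = D)
  if (any(theta <= 0 | theta >= pi)) {
    stop("`theta` must lie strictly inside (0, pi): ",
         "the kernel diverges for parallel rods")
  }
  if (any(d_c <= D)) stop("`d_c` must exceed the hard-core diameter D")
  kD <- kappa * D
  kD * (.deff_theta(A_prime, kD, sin(theta), d_c / D) - 1)
}

#' Exact orientation-averaged effective diameter
#'
#' Numerically evaluates the isotropic orientation average of the per-angle
#' effective diameter (see [scaled_excluded_volume()]), the excluded-volume
#' weighted average
#' \deqn{D^{\mathrm{eff}} = \frac{\int \sin^2\theta\, D^{\mathrm{eff}}(\theta)
#'   \,\mathrm{d}\theta}{\int \sin^2\theta \,\mathrm{d}\theta},}
#' for an unbounded screened repulsion or for the truncated-shifted potential
#' with cutoff `d_c`.  This is the reference value against which the closed
#' form and any finite simulation cutoff are judged.
#'
#' @inheritParams scaled_excluded_volume
#' @param rel_tol relative tolerance of the adaptive quadrature.
#' @return An object of class `"effective_diameter"`: list with `D_eff`,
#'   `method`, `d_c_used`, and `rel_diff_vs_infinite` (the relative deficit of
#'   the finite-cutoff value, 0 for `d_c = Inf`).
#' @examples
#' exact_effective_diameter(A_prime = exp(-0.5), kappa = 0.5, D = 1)$D_eff
#' @export
exact_effective_diameter <- function(A_prime, kappa = 1, D = 1, d_c = Inf,
                                     rel_tol = 1e-9) {
  .check_positive(A_prime = A_prime, kappa = kappa, D = D)
  if (d_c <= D) stop("`d_c` must exceed the hard-core diameter D")
  kD <- kappa * D
  deff <- D * .deff_exact(A_prime, kD, d_c / D, rel_tol)
  rel <- 0
  if (is.finite(d_c)) {
    dinf <- D * .deff_exact(A_prime, kD, Inf, rel_tol)
    rel <- (dinf - deff) / deff
  }
  structure(list(D_eff = deff, method = "exact_integral", d_c_used = d_c,
                 rel_diff_vs_infinite = rel),
            class = "effective_diameter")
}

#' @export
print.effective_diameter <- function(x, ...) {
  cat(sprintf("Effective diameter (%s): D_eff = %g (d_c = %g)\n",
              x$method, x$D_eff, x$d_c_used))
  if (is.finite(x$d_c_used)) {
    cat(sprintf("  relative deficit vs infinite cutoff: %.3g%%\n",
                100 * x$rel_diff_vs_infinite))
  }
  invisible(x)
}

#' Threshold interaction cutoff for an accurate effective diameter
#'
#' In a simulation the screened repulsion must be truncated (and shifted) at
#' a finite cutoff `d_c`, which shrinks the effective diameter.  The
#' threshold cutoff `d_c^t` is the smallest cutoff for which the relative
#' difference between the infinite-range effective diameter and the exact
#' finite-cutoff value,
#' \eqn{[D^{\mathrm{eff}}(\infty) - D^{\mathrm{eff}}(d_c)] /
#'      D^{\mathrm{eff}}(d_c)}, drops to `tol` (2.2\% by default, the
#' accuracy of the closed form itself).  It decreases with `kappaD` and
#' increases with the amplitude `A`.
#'
#' @param A dimensionless bare amplitude of the screened repulsion (the
#'   contact amplitude is `A' = A exp(-kappaD)`).
#' @param kappaD `kappa * D`.
#' @param tol relative-difference criterion defining the threshold.
#' @param rel_tol quadrature tolerance passed to the exact integrals.
#' @return `d_c^t / D` as a numeric scalar, with attributes
#'   `Deff_threshold_over_D` (exact effective diameter at the threshold
#'   cutoff) and `Deff_infinite_over_D`.
#' @examples
#' round(threshold_cutoff(A = 4, kappaD = 1), 1)
#' @export
threshold_cutoff <- function(A, kappaD, tol = 0.022, rel_tol = 1e-9) {
  .check_positive(A = A, kappaD = kappaD, tol = tol)
  A_prime <- A * exp(-kappaD)
  dinf <- .deff_exact(A_prime, kappaD, Inf, rel_tol)
  f <- function(ldc) {
    dc <- (dinf - .deff_exact(A_prime, kappaD, exp(ldc), rel_tol))
    dc / .deff_exact(A_prime, kappaD, exp(ldc), rel_tol) - tol
  }
  lo <- log(1.001)
  hi <- log(1000)
  if (f(hi) > 0) {
    stop("failed to bracket the threshold cutoff within d_c/D <= 1000")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  dct <- exp(root)
  structure(dct,
            Deff_threshold_over_D = .deff_exact(A_prime, kappaD, dct, rel_tol),
            Deff_infinite_over_D = dinf)
}

#' Grid of threshold cutoffs and effective diameters
#'
#' Evaluates [threshold_cutoff()] over a grid of amplitudes and screening
#' ratios, reporting for each cell the threshold cutoff and the exact
#' effective diameter at that cutoff.
#'
#' @param A_values,kappaD_values non-empty numeric vectors.
#' @inheritParams threshold_cutoff
#' @return Data frame with columns `A`, `kappaD`, `dct_over_D`,
#'   `Deff_over_D`.
#' @examples
#' threshold_cutoff_table(c(1, 4), 1)
#' @export
threshold_cutoff_table <- function(A_values, kappaD_values, tol = 0.022,
                                   rel_tol = 1e-9) {
  if (length(A_values) == 0 || length(kappaD_values) == 0) {
    stop("parameter lists must be non-empty")
  }
  grid <- expand.grid(A = A_values, kappaD = kappaD_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    dct <- threshold_cutoff(grid$A[i], grid$kappaD[i], tol, rel_tol)
    data.frame(A = grid$A[i], kappaD = grid$kappaD[i],
               dct_over_D = as.numeric(dct),
               Deff_over_D = attr(dct, "Deff_threshold_over_D"))
  })
  do.call(rbind, res)
}

#' Effective diameter with automatic method selection
#'
#' Convenience front end implementing the recommended decision tree: beyond
#' the threshold cutoff the infinite-range value is accurate, and for
#' `A' >= 2` the closed form may stand in for the exact integral; at or below
#' the threshold the exact finite-cutoff integral is required.
#'
#' @inheritParams threshold_cutoff
#' @param d_c_over_D interaction cutoff in units of `D` (may be `Inf`).
#' @param method `"auto"` (decision tree), `"slo"` (closed form), or
#'   `"exact"` (orientation-averaged integral at the requested cutoff).
#' @return An `"effective_diameter"` object (units of `D`).
#' @export
effective_diameter <- function(A, kappaD, d_c_over_D = Inf,
                               method = c("auto", "slo", "exact")) {
  method <- match.arg(method)
  .check_positive(A = A, kappaD = kappaD)
  A_prime <- A * exp(-kappaD)
  if (method == "auto") {
    above_threshold <- is.infinite(d_c_over_D) ||
      d_c_over_D > as.numeric(threshold_cutoff(A, kappaD))
    method <- if (above_threshold && A_prime >= 2) "slo" else "exact"
    if (method == "exact" && above_threshold) d_c_over_D <- Inf
  }
  if (method == "slo") {
    structure(list(D_eff = slo_closed_form(A_prime, kappa = kappaD, D = 1),
                   method = "slo_closed_form", d_c_used = Inf,
                   rel_diff_vs_infinite = 0),
              class = "effective_diameter")
  } else {
    exact_effective_diameter(A_prime, kappa = kappaD, D = 1,
                             d_c = d_c_over_D)
  }
}
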