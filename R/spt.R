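# Scaled particle theory (SPT) for hard and charged spherocylinders, and the
# exact free-volume route from the insertion probability to the osmotic
# pressure.

#' Spherocylinder geometry
#'
#' A hard spherocylinder is a cylinder of length `L` and diameter `D` capped
#' by two hemispheres; its aspect parameter is `gamma = 1 + L/D` and its
#' hard-core volume `v_r = pi D^2 L / 4 + pi D^3 / 6`.
#'
#' @param L cylinder length (>= 0; `L = 0` gives a sphere).
#' @param D diameter (> 0).
#' @return Object of class `"rod_geometry"`: list with `L`, `D`, `gamma`,
#'   `v_r`.
#' @examples
#' rod_geometry(10, 1)$gamma
#' @export
rod_geometry <- function(L, D) {
  .check_positive(D = D)
  .check_positive(L = L, .allow_zero = TRUE)
  structure(list(L = L, D = D, gamma = 1 + L / D, v_r = rod_volume(L, D)),
            class = "rod_geometry")
}

#' @rdname rod_geometry
#' @export
rod_volume <- function(L, D) pi * D^2 * L / 4 + pi * D^3 / 6

#' Isotropic orientation-averaged excluded volume of two identical
#' spherocylinders: `(4/3) pi D^3 + 2 pi D^2 L + (pi/2) L^2 D`.
#' @rdname rod_geometry
#' @export
excluded_volume_iso <- function(L, D) {
  4 * pi * D^3 / 3 + 2 * pi * D^2 * L + pi * L^2 * D / 2
}

# SPT nonsphericity factor for a spherocylinder of aspect parameter gamma:
# (mean radius * surface) / (3 volume) = gamma (gamma + 1) / (3 gamma - 1)
.spt_xi <- function(gamma) gamma * (gamma + 1) / (3 * gamma - 1)

.check_phi <- function(phi_r) {
  if (any(phi_r < 0) || any(phi_r >= 1)) {
    stop("volume fraction must satisfy 0 <= phi < 1", call. = FALSE)
  }
}

#' SPT osmotic pressure of hard spherocylinders
#'
#' Reduced osmotic pressure of an isotropic fluid of hard spherocylinders
#' from scaled particle theory,
#' \deqn{\tilde\Pi \equiv \frac{\Pi v_r}{k_BT} = y + 3\xi\,y^2 + 3\xi^2 y^3,
#'   \qquad y = \frac{\phi_r}{1-\phi_r},\quad
#'   \xi = \frac{\gamma(\gamma+1)}{3\gamma-1},}
#' with `gamma = 1 + L/D`.  For `gamma = 1` this is the SPT hard-sphere
#' equation of state.
#'
#' @param phi_r rod volume fraction(s) in `[0, 1)`.
#' @param gamma aspect parameter `1 + L/D` (>= 1).
#' @return Reduced pressure `Pi * v_r / kT` (same length as `phi_r`).
#' @examples
#' spt_pressure(0.2, gamma = 6)
#' @export
spt_pressure <- function(phi_r, gamma) {
  .check_phi(phi_r)
  if (any(gamma < 1)) stop("`gamma` must be >= 1")
  y <- phi_r / (1 - phi_r)
  xi <- .spt_xi(gamma)
  y + 3 * xi * y^2 + 3 * xi^2 * y^3
}

#' SPT free volume fraction for a spherocylinder in its own fluid
#'
#' Probability `alpha` that a randomly placed and oriented spherocylinder can
#' be inserted without overlap, `alpha = exp(-W/kT)` with `W` the immersion
#' free energy.  SPT gives the insertion work as
#' \deqn{-\ln\alpha = -\ln(1-\phi_r) + 6\xi\,y + \tfrac92 \xi^2 y^2 +
#'   \tilde\Pi,}
#' where the reduced pressure may either be supplied (`Pi_tilde`, e.g. from a
#' measured equation of state) or, by default, taken from [spt_pressure()],
#' which yields the fully explicit SPT form.
#'
#' @inheritParams spt_pressure
#' @param Pi_tilde optional reduced pressure(s) to use in the insertion work;
#'   defaults to the SPT pressure at `(phi_r, gamma)`.
#' @return Free volume fraction(s) in (0, 1].
#' @examples
#' spt_alpha(0.1, gamma = 6)
#' @export
spt_alpha <- function(phi_r, gamma, Pi_tilde = NULL) {
  .check_phi(phi_r)
  if (any(gamma < 1)) stop("`gamma` must be >= 1")
  if (is.null(Pi_tilde)) Pi_tilde <- spt_pressure(phi_r, gamma)
  y <- phi_r / (1 - phi_r)
  xi <- .spt_xi(gamma)
  (1 - phi_r) * exp(-(6 * xi * y + 4.5 * xi^2 * y^2 + Pi_tilde))
}

#' Equation of state of charged rods via the effective diameter
#'
#' For charged rods the SLO construction replaces `D` by the effective
#' diameter `D_eff`, so the osmotic pressure takes the hard-rod SPT form
#' evaluated with `gamma* = 1 + L/D_eff` and the effective volume fraction
#' `phi_eff` of rods with diameter `D_eff`.  The reduced pressure returned
#' here is `Pi v_eff / kT` with `v_eff` the volume of the effective rod.
#'
#' @param phi_eff effective rod volume fraction(s) in `[0, 1)`.
#' @param gamma_star effective aspect parameter `1 + L/D_eff`.
#' @return Reduced pressure (effective-rod units).
#' @seealso [effective_volume_fraction()], [spt_pressure()]
#' @export
charged_pressure <- function(phi_eff, gamma_star) {
  spt_pressure(phi_eff, gamma_star)
}

#' @rdname charged_pressure
#' @param number_density rod number density `rho` (1/volume).
#' @param L cylinder length.
#' @param D_eff effective diameter.
#' @return `effective_volume_fraction()`: `rho * v_r(L, D_eff)`.
#' @export
effective_volume_fraction <- function(number_density, L, D_eff) {
  .check_positive(number_density = number_density, .allow_zero = TRUE)
  .check_positive(D_eff = D_eff)
  number_density * rod_volume(L, D_eff)
}

#' Osmotic pressure from a measured free-volume curve
#'
#' The free volume fraction determines the equation of state exactly: the
#' excess chemical potential is `-ln alpha` (Widom), and the Gibbs-Duhem
#' relation integrates to
#' \deqn{\tilde\Pi(\phi) = \phi - \phi\ln\alpha(\phi) +
#'   \int_0^{\phi} \ln\alpha(\phi')\,\mathrm{d}\phi'.}
#' The integral is evaluated by the trapezoidal rule on the supplied grid,
#' extended from the lowest measured point down to zero assuming
#' `ln alpha` linear in `phi` (exact in the dilute limit, where
#' `ln alpha(0) = 0`).
#'
#' @param curve data frame with columns `phi` (strictly increasing, > 0) and
#'   `alpha` (positive, non-increasing), e.g. Widom-insertion measurements.
#' @return The input data frame with a `Pi_tilde` column added (units
#'   `Pi v_r / kT` for whichever rod volume the `phi` grid refers to).
#' @examples
#' phi <- seq(0.01, 0.3, length.out = 150)
#' crv <- pressure_from_alpha(data.frame(phi = phi,
#'                                       alpha = spt_alpha(phi, gamma = 6)))
#' max(abs(crv$Pi_tilde - spt_pressure(phi, 6)) / spt_pressure(phi, 6))
#' @export
pressure_from_alpha <- function(curve) {
  if (!all(c("phi", "alpha") %in% names(curve))) {
    stop("`curve` needs columns `phi` and `alpha`")
  }
  phi <- curve$phi
  alpha <- curve$alpha
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive on the grid")
  if (is.unsorted(phi, strictly = TRUE) || any(phi <= 0)) {
    stop("`phi` must be strictly increasing and positive")
  }
  la <- log(alpha)
  # cumulative trapezoid of ln(alpha) d phi, plus the dilute extension
  # from (0, 0) to the first grid point
  n <- length(phi)
  increments <- c(phi[1] * la[1] / 2,
                  if (n > 1) diff(phi) * (head(la, -1) + tail(la, -1)) / 2)
  curve$Pi_tilde <- phi - phi * la + cumsum(increments)
  curve
}

#' Tabulated SPT thermodynamics of hard spherocylinders
#'
#' @param gamma aspect parameter.
#' @param phi_max upper end of the volume-fraction grid.
#' @param n number of grid points.
#' @return Data frame with columns `phi`, `y`, `alpha`, `Pi_tilde`.
#' @export
spt_curve <- function(gamma, phi_max = 0.3, n = 200) {
  phi <- seq(0, phi_max, length.out = n)
  data.frame(phi = phi, y = phi / (1 - phi),
             alpha = spt_alpha(phi, gamma),
             Pi_tilde = spt_pressure(phi, gamma))
}

#' Validate the monotonicity invariants of a thermodynamic curve
#'
#' Checks that `phi` is strictly increasing, `alpha` starts at 1 and is
#' non-increasing, and `Pi_tilde` starts at 0 and is non-decreasing.  Useful
#' as a guard on simulated or tabulated `(phi, alpha, Pi_tilde)` data.
#'
#' @param curve data frame with columns `phi`, and `alpha` and/or `Pi_tilde`.
#' @param tol slack for the monotonicity comparisons (sampling noise).
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_thermo_curve <- function(curve, tol = 0) {
  if (is.unsorted(curve$phi, strictly = TRUE)) {
    stop("`phi` must be strictly increasing")
  }
  if (!is.null(curve$alpha)) {
    if (any(curve$alpha < 0 | curve$alpha > 1)) {
      stop("`alpha` must lie in [0, 1]")
    }
    if (any(diff(curve$alpha) > tol)) stop("`alpha` must be non-increasing")
  }
  if (!is.null(curve$Pi_tilde)) {
    if (any(diff(curve$Pi_tilde) < -tol)) {
      stop("`Pi_tilde` must be non-decreasing")
    }
  }
  invisible(TRUE)
}
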