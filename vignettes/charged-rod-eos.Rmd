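---
title: "Free volume and equation of state of charged rodlike colloids"
author: "chargedrods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free volume and equation of state of charged rodlike colloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargedrods)
```

## The physical problem

Many rodlike colloids — filamentous viruses such as fd, tobacco mosaic
virus, short DNA fragments, cellulose nanocrystals — carry surface charge in
aqueous suspension.  Modelled as hard spherocylinders (cylinder length $L$,
diameter $D$, aspect parameter $\gamma = 1 + L/D$) decorated with a screened
Coulomb repulsion, two rods whose axes cross at angle $\theta$ with closest
axis distance $x$ interact with

$$\frac{U(x,\theta)}{k_BT} = \frac{A'\,e^{-\kappa (x - D)}}{\sin\theta},$$

where $\kappa^{-1}$ is the Debye length and $A' = A\,e^{-\kappa D}$ the
contact amplitude.  The SLO (Stroobants–Lekkerkerker–Odijk) construction
maps these soft rods onto *hard* rods with an enlarged effective diameter
$D^{\mathrm{eff}}$, chosen so that the isotropic orientation-averaged
second-virial (excluded volume) of the charged rods is reproduced.  Feeding
$D^{\mathrm{eff}}$ into scaled particle theory (SPT) then yields closed-form
predictions for the free volume fraction $\alpha$ and the osmotic pressure
of the charged-rod fluid.  This package implements that whole chain, and the
Monte Carlo / Widom-insertion machinery needed to measure the same
quantities in simulation and quantify where the mapping holds.

## Electrostatic amplitude

Within Debye–Hückel theory for a uniformly charged cylinder ($Z$ charges per
unit length, Bjerrum length $\lambda_B$),

$$A' \;=\; \frac{2\pi (Z\lambda_B)^2}{\kappa \lambda_B}\,
  \frac{e^{-\kappa D}}{\big[(\kappa D/2) K_1(\kappa D/2)\big]^2},$$

with the classical thick- and thin-double-layer limits
$2\pi Z^2\lambda_B\kappa^{-1}e^{-\kappa D}$ and $8Z^2\lambda_B/(\kappa^2D)$.
The package also provides a single uniform approximation obtained by
replacing the Bessel bracket with $(1 + \pi\kappa D/4)\,e^{-\kappa D}$,

$$A' \approx \frac{2\pi (Z\lambda_B)^2}{\kappa\lambda_B}
  \frac{1}{1 + \pi \kappa D / 4},$$

which matches both limits and deviates from the exact Bessel form by at most
about 4.4% (near $\kappa D \approx 1$):

```{r amplitude}
tab <- relative_error_curve(10^seq(-2, 2, length.out = 200))
round(100 * max(tab$rel_err_uniform), 2)
```

The amplitude functions take the dimensionless groups $(Z\lambda_B,\,\kappa
D)$ (plus $\lambda_B/D$ for the overall scale); all *relative* statements
above are independent of the charge prefactor.

## Effective diameter, exactly and in closed form

Per crossing angle, the repulsion pushes the distance of closest approach
outward by

$$D^{\mathrm{eff}}(\theta) - D = \int_D^{\infty}
  \left(1 - e^{-U(x,\theta)/k_BT}\right)\mathrm{d}x
  = \kappa^{-1}\big[\ln a + k_E + E_1(a)\big],
  \qquad a = A'/\sin\theta,$$

with $k_E$ Euler's constant and $E_1$ the exponential integral.  The
isotropic, excluded-volume-weighted average
$D^{\mathrm{eff}} = \langle \sin^2\theta\, D^{\mathrm{eff}}(\theta)\rangle /
\langle \sin^2\theta \rangle$ is evaluated by adaptive quadrature
(`exact_effective_diameter()`); for $A' \gtrsim 2$ it is approximated within
2.2% by the closed form

$$D^{\mathrm{eff}} = D + \kappa^{-1}\left(\ln A' + k_E + \ln 2 -
\tfrac12\right).$$

Simulations must truncate the potential; the package uses the
truncated-*shifted* form that vanishes continuously at the cutoff $d_c$, and
the finite-cutoff kernel acquires the extra exponential-integral terms shown
in `?scaled_excluded_volume`.  The threshold cutoff $d_c^t$ is the smallest
$d_c$ at which the infinite-range value agrees with the exact finite-cutoff
diameter to 2.2% — the accuracy of the closed form itself.  Conventions that
matter (both verified against the reference table of nine $(A,\kappa D)$
cells): the relative difference carries the exact *finite-cutoff* diameter
in the denominator, and the tabulated $D^{\mathrm{eff}}/D$ is evaluated *at*
$d_c^t$, not at infinite cutoff.

```{r table1}
threshold_cutoff_table(c(1, 4, 16), c(0.5, 1, 2))
```

## SPT thermodynamics and the free-volume route

For hard spherocylinders the package uses the scaled-particle-theory
equation of state for isotropic convex bodies, with
$y = \phi/(1-\phi)$ and nonsphericity
$\xi = \gamma(\gamma+1)/(3\gamma-1)$:

$$\tilde\Pi \equiv \frac{\Pi v_r}{k_BT} = y + 3\xi y^2 + 3\xi^2y^3,
\qquad
-\ln\alpha = -\ln(1-\phi) + 6\xi y + \tfrac92\xi^2y^2 + \tilde\Pi .$$

This transcription was fixed by three requirements: it is exact in the
second virial coefficient (the dilute slope of $-\ln\alpha$ is the isotropic
excluded volume over $v_r$), it reduces to the SPT hard-sphere equation of
state at $\gamma = 1$, and the pair is exactly Gibbs–Duhem consistent — the
free-volume route

$$\tilde\Pi(\phi) = \phi - \phi\ln\alpha +
  \int_0^\phi \ln\alpha\,\mathrm{d}\phi'$$

(`pressure_from_alpha()`, trapezoidal with a dilute linear extension of
$\ln\alpha$ below the first grid point) recovers the analytic pressure to
better than 0.1% on a 200-point grid.  Charged rods use the same forms with
$D \to D^{\mathrm{eff}}$: $\gamma^* = 1 + L/D^{\mathrm{eff}}$ and the
effective volume fraction $\phi^{\mathrm{eff}} = \rho\,v_r(L,
D^{\mathrm{eff}})$.

### Accuracy domain of SPT for long rods

A caveat that the package's own simulations make quantitative: SPT's third
virial coefficient for elongated spherocylinders exceeds the true one.  A
direct Monte Carlo integration (shipped in the test suite's methodology)
gives $B_3/B_2^2 = 0.343 \pm 0.019$ for $L/D = 10$, against $1 + 6\xi +
3\xi^2$ in units of $v_r^2$ (ratio 0.429) from SPT.  Consequently the SPT
free volume fraction falls below the simulated one as density grows — by
about 11% at $(\gamma, \phi) = (11, 0.05)$ and by tens of percent at
$\phi \gtrsim 0.1$ — while for short rods ($\gamma \lesssim 2$) theory and
simulation agree within a few percent.  The hard-rod benchmark in the test
suite records both regimes: the $\gamma = 2$ chain must agree within 5%,
and the $\gamma = 11$ check documents where SPT's virial error dominates.
The simulation side of that statement was validated independently: the
Metropolis/Widom chain reproduces the Carnahan–Starling hard-sphere
$\alpha$ to 0.1%, the compiled segment-distance kernel matches an
exhaustive exact solver to $5\times10^{-14}$, and single-rod insertion
reproduces the analytic isotropic excluded volume.

## Monte Carlo and Widom insertion

The simulator is standard Metropolis NVT of $N$ spherocylinders in a cubic
periodic box (every edge must exceed $L + D$, so minimum image on the
center–center separation is exact): single-particle translations and axis
rotations, acceptance $\min(1, e^{-\Delta U/k_BT})$, hard overlaps rejected,
with the pairwise truncated-shifted potential above.  Choices the underlying
study protocol leaves open, fixed here:

* **Box shape** cubic; **move tuning** rescales the maximum displacement and
  rotation until both acceptance ratios sit in $(0.3, 0.4)$, saturating at
  capped move sizes in dilute systems (where acceptance stays high).
  Tuning runs only before sampling, never during it.
* **$\sin\theta$ floor** $10^{-6}$ in the pair energy, so an aligned
  starting configuration has finite, relaxable energy; recorded in run
  metadata.
* **Initialization.** The classic dense-aligned start plus box expansion is
  implemented (`expansion_protocol()`); it is faithful but slow to melt at
  higher densities, so the measurement drivers instead build isotropic
  states directly at the target density by a push-off construction
  (`annealed_config()`): ideal-gas positions and orientations, hard core
  temporarily replaced by a rising finite overlap penalty until no overlaps
  remain.  Only the subsequent strict hard-core Markov chain samples the
  ensemble, so the construction route cannot bias equilibrium averages —
  verified by agreement (to well under 1%) between push-off- and
  RSA-initialized runs.
* **Equilibration** is declared when the linear drift of the block-averaged
  energy and of the nematic order parameter is statistically
  indistinguishable from their scatter; because translational decorrelation
  of long rods is invisible to an athermal drift criterion, the drivers
  additionally run a fixed minimum number of sweeps (3000 by default at
  benchmark densities) chosen from the convergence studies above.
* **RNG**: all stochastic kernels draw from R's generator, so a single
  `set.seed()` reproduces a run end to end.

Two insertion estimators share one trial stream (`alpha_estimators()`):
$\alpha^{\mathrm{eff}}$, the fraction of virtual rods of diameter
$D^{\mathrm{eff}}$ that fit without overlap, and the reference
$\alpha^{\mathrm{ref}} = \langle e^{-\Delta U/k_BT}\rangle$ from the
immersion free energy (hard-core violations contribute weight zero).
Sharing trials makes the hard-rod identity
$\alpha^{\mathrm{ref}} \equiv \alpha^{\mathrm{eff}}(D)$ hold term by term,
and makes $\alpha^{\mathrm{ref}} \le \alpha^{\mathrm{eff}}(D)$ an exact
inequality.  Error bars are between-configuration standard errors;
estimates with fewer than 10 successes in total are flagged unreliable at
reporting time rather than discarded.  Trial budgets are sized in two
stages (a pilot fixes the scale of $\alpha$, the main stage targets a fixed
success count), because $\alpha$ spans many decades across a density scan.

## Comparison pipeline

`run_charged_study()` executes one $(A, \kappa D, d_c)$ parameter set over a
grid of effective volume fractions; `compare_alpha_routes()` assembles the
tidy record table (one row per parameter set and density) carrying both
estimates, their signed relative difference
$(\alpha^{\mathrm{eff}} - \alpha^{\mathrm{ref}})/\alpha^{\mathrm{ref}}$, the
reliability flag, and a systematic-error flag where that difference exceeds
2.2%.  `anchor_at_alpha_ref()` condenses a scan to one number by locating
the density where $\alpha^{\mathrm{ref}} = 0.3$ (monotone piecewise-cubic
interpolation by default — it cannot overshoot near small $\alpha$; exact
piecewise-linear available) and evaluating the route difference there.
`theory_vs_simulation()` adds the SLO-SPT prediction at
$(\gamma^*, \phi^{\mathrm{eff}})$ and its deviation from
$\alpha^{\mathrm{eff}}$.  Signed differences keep the reference route in
the denominator; absolute values are derivable.

The qualitative behaviour these tables reproduce at desk scale: the route
difference grows with rod density and with the cutoff length (a larger
$D^{\mathrm{eff}}$ lets more system-rod pairs sit closer than
$D^{\mathrm{eff}}$, which the insertion test cannot), and the
theory–simulation deviation grows as the free volume empties.

## Problem sizes and what the tests do (and do not) show

The default test suite runs the full grid of threshold-cutoff cells, the
5% and 2.2% bound scans (200- and 400-point grids), SPT consistency for
$\gamma \in \{2, 6, 11, 21\}$, a hard-rod benchmark at $N = 256$,
$\gamma = 11$, $\phi \le 0.2$, estimator-oracle checks, and a charged-rod
trend study at $(A, \kappa D) = (16, 0.5)$ with $N = 96$ and $d_c/D \in
\{5, 10\}$.  Production-scale settings ($N = 1352$, $L/D + 1 = 11$) are
validated as configurations (`validate_study_config()`) and runnable
through the same drivers, just longer.  The synthetic ensembles are
monodisperse, rigid, isotropic-phase rods with pairwise screened
interactions; the tests therefore say nothing about charge renormalization,
rod-mediated screening at high concentration, flexibility, polydispersity,
or liquid-crystalline phases — the effective diameter is treated as
density-independent throughout, which is exactly the approximation whose
accuracy the comparison pipeline measures.

## Known limitations

* SPT's $\alpha$ and pressure for long rods ($\gamma \gtrsim 6$) deviate
  from simulation at moderate density (see the accuracy-domain section);
  the package reports both sides rather than hiding either.
* The exact finite-cutoff effective diameter assumes the truncated-shifted
  potential used by the simulator; plain truncation would give slightly
  different thresholds.
* `anchor_at_alpha_ref()` never extrapolates: scans that do not bracket the
  anchor value return a flagged missing result.
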