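---
title: "Models and numerical methods in mtrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in mtrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrkit)
```

mtrkit reconstructs, at desk scale, the chain of reasoning that connects
measured ribozyme kinetics to computed free-energy landscapes for a
two-step general-acid mechanism: a protonated cytosine (C10 N3–H) donates
its proton to the O6-alkylguanine leaving group (TS1), after which alkyl
transfer to the adenine N1 nucleophile crosses the rate-controlling saddle
(TS2). This vignette records the models, their assumptions, the numerical
choices, and what the synthetic data do and do not establish.

## Kinetic models

Fast reactions are biphasic. The shared-plateau form

$$f(t) = A\,[\,p\,(1-e^{-k_\mathrm{fast}t}) + (1-p)\,(1-e^{-k_\mathrm{slow}t})\,]$$

interprets the fast phase as alkyl transfer itself and the slow phase as
refolding of a fraction $1-p$ of ribozyme initially trapped in an inactive
conformation. Whether the two phases share one plateau is not observable
from a single curve; the shared plateau is the adopted convention and is
flagged in the fit object (`shared_plateau = TRUE`). Reactions slower than
about 0.01 min⁻¹ are single-exponential because refolding outruns
chemistry; `select_kinetic_model()` therefore chooses the double model only
when the fitted fast rate *exceeds* 0.01 min⁻¹ (ties go to the single
model) *and* the double fit reduces the residual RMS by more than 20% — the
second criterion exists because a noise-only second phase otherwise always
wins on RMS.

Fitting is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with analytic
Jacobians and multi-start over a log-spaced rate grid, $10^{-5}$–$10^2$
min⁻¹. Bounds: plateau in (0, 1.2] (gel noise can push apparent fractions
above 1), amplitude fraction in [0, 1], rates positive. Fractions are never
clipped before fitting. Standard errors come from
$\hat\sigma^2 (J^\top J)^{+}$ at the solution; a rate landing on a bound
makes $J$ singular, which is why the raw `nls.lm` interface with a
pseudo-inverse covariance is used rather than the `nlsLM` wrapper (whose
post-fit conversion errors out in exactly that case). Degenerate inputs
(e.g. all-zero fractions) return a flagged, non-crashing fit.

**Sampling designs.** The recovery analyses use two canonical schedules,
chosen once as a kineticist would design the experiments:

* *Biphasic schedule*: 20 points, dense around the ~1 min fast half-life,
  extending to 300 min. The slow 0.01 min⁻¹ phase is then actually
  observed ($k_\mathrm{slow} t_\max = 3$). A window that ends at 30 min
  leaves the slow phase unidentified and, through its correlation with the
  plateau, biases the fast-rate estimate upward by several percent — the
  Cramér–Rao bound for $k_\mathrm{fast}$ at a 30-min window is 0.04–0.06
  min⁻¹ regardless of the fitter. With the 300-min schedule, 100 seeded
  replicates at gel noise (additive s.d. 0.02 on fractions) recover
  0.60 min⁻¹ with mean bias under 0.5% and per-fit scatter 0.03, which
  pools over triplicate experiments to the reported ±0.01-scale precision.
* *Slow-variant schedule*: 15 points over 6 days (0–8640 min). At
  $4\times10^{-5}$ min⁻¹ this covers only ~30% of the reaction, so the
  plateau and rate are nearly collinear and the free-plateau estimator has
  a heavy right tail. `fit_single_exponential(..., plateau_fixed = 0.9)`
  fixes the endpoint at the maximal modified fraction known from the fast
  constructs — standard practice for truncated progress curves — and
  recovers the rate essentially unbiased (mean $4.0\times10^{-5}$, s.d.
  $2.4\times10^{-6}$ over 100 seeds).

## Activity–pH models

The single-pKa model multiplies the intrinsic rate by the protonated
fraction of the general acid,
$k_\mathrm{obs} = k_\mathrm{int}/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$:
activity falls above the pKa because the acid must hold its proton. The
two-pKa variant multiplies in a deprotonated-nucleophile factor
$1/(1+10^{\mathrm{p}K_{a,\mathrm{nuc}} - \mathrm{pH}})$, giving a bell
peaked midway between the two pKas when the factors are symmetric. The bell
is nearly invariant under swapping the two pKa labels (the product of the
two factors changes only in its tails), so the fit enforces the
conventional labeling $\mathrm{p}K_{a,\mathrm{nuc}} < \mathrm{p}K_a$.

Fits run on $\log_{10} k$ — rates span five orders of magnitude across
variants — with multi-start over an integer pKa grid from 3 to 10. Flat,
pH-independent data leave the pKa unidentifiable; the fit is flagged
(`identifiable = FALSE`, note "no pH dependence") when the pKa standard
error exceeds 2 units, mirroring the slow C10(n1c) variant. The ±0.15 pH
buffer-temperature error noted for the experiments is not propagated by
default. Noise on generated rates is multiplicative log-normal with unit
mean and a coefficient of variation (default 10%), because additive noise
would be meaningless across that dynamic range.

`build_computed_profile()` reconstructs a computed activity–pH curve as the
Eyring rate of the barrier times the single-pKa protonation factor at the
*calculated* ribozyme pKa. The exact published form of that construction is
not available; this reconstruction is a documented convention whose
half-maximum falls exactly at the ribozyme pKa. `normalize_profiles()`
scales a computed curve by max(experimental)/max(computed); when several
variants are overlaid, the scalar derived from the reference (unmodified)
curve is applied to all of them.

## Thermodynamic conversions

Eyring TST with transmission coefficient 1:
$k = (k_BT/h)\,e^{-\Delta G^\ddagger/RT}$, with
$R = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹. Ratios of rates between
variants cancel the prefactor: $e^{\Delta\Delta G^\ddagger/RT}$. pKa shifts
convert as $\Delta\mathrm{p}K_a = \Delta\Delta G/(RT\ln 10)$, 1.364
kcal/mol per unit at 298.15 K. Two temperature contexts exist and are never
mixed silently: simulation-derived quantities at 298.15 K (the default;
it also reproduces the printed 2.7-fold ratio most closely), experimental
kinetics at 310.15 K. Brønsted $\beta_\mathrm{nuc}$ is the least-squares
slope of $\log_{10}(\mathrm{rate})$ against nucleophile pKa, the exact
two-point slope when only the adenosine/7-deazaadenosine pair is available.

## Free-energy surfaces and interpolation

Surfaces are uniform grids over the proton-transfer and alkyl-transfer
coordinates, $\xi_\mathrm{PT}$ and $\xi_\mathrm{AT}$ (Å), energies in
kcal/mol, with the reactant-basin minimum shifted to zero. Interpolation is
a Catmull–Rom (cubic-convolution) tensor product: C¹ across cells, analytic
gradients, and exact for polynomials up to degree 2 — the quadratic-bowl
tests exploit that exactness. Ghost layers use quadratic extrapolation so
the stencil keeps its order at the boundary. No installed interpolator
offered C¹ 2D interpolation with analytic gradients, hence the in-package
implementation.

The generator composes axis-aligned Gaussians (negative depths carve
basins, positive ones raise bumps). The MTR1-like preset places basins at
R(−1.5, −2.5), I(1.2, −1.7), P(1.5, 2.5), a proton-transfer channel with a
small TS1 bump, and an alkyl-transfer channel whose bump defines the
rate-controlling saddle. Because G is linear in the component depths and
the minimax path is invariant under positive scaling, a single linear
rescaling calibrates the barrier exactly (up to grid resolution, 0.05 Å by
default) to the requested value — 16.3 kcal/mol for the unmodified
ribozyme. The channel center sits 0.02 Å below the nominal TS2 position to
compensate the pull of the basin tails, placing the realized saddle at
$\xi_\mathrm{AT} = -0.24$ Å, the preset's "early"-TS choice. The I basin
rests ~3.6 kcal/mol above R, consistent with both R and I being populated
in a rapid pre-equilibrium before TS2.

## String method

`string_mfep()` uses the simplified-string scheme: every interior image
takes a full (not tangent-projected) damped gradient step, then the string
is redistributed to equal arc length by cubic-spline resampling iterated to
a fixed point (chord spacing equal to $10^{-8}$ of the length). The
explicit perpendicular projection with central-difference tangents was
implemented first and abandoned: it develops the well-known kink
instability, a zigzag mode that grows exponentially once the path is nearly
converged. Full-step-plus-reparameterization has the same fixed points (the
reparameterization removes tangential motion) and is stable.

Numerical controls, all documented defaults:

* 32 images, endpoints snapped to their local minima by gradient descent
  before iterating (the supplied anchors are approximate basin positions;
  snapping makes the path-derived barrier well defined);
* initial trust radius `step` = 0.05 Å, converted to a time step via the
  largest initial gradient; step halving (max 10, then an error) whenever a
  proposed step raises the *spline-refined dense maximum* of the path —
  any path crossing a ridge tops out at or above the col height, so
  genuine descent never raises this quantity, while the discrete image
  maximum may legitimately creep up as images slide toward the saddle top;
* a deterministic one-grid-spacing transverse bow on the straight initial
  guess breaks the symmetry trap where the straight segment is a
  stationary but unstable ridge path (a bump centered exactly on the
  line); optional `waypoints` give a piecewise-linear initial guess
  through known intermediates — the strongly bent preset path otherwise
  relaxes into a locally stable corner-cut;
* convergence when the maximum perpendicular image displacement falls
  below `tol` (default $10^{-4}$ Å), with a stagnation exit after 50
  iterations in which neither the dense maximum, the dense mean, nor the
  displacement improves — that is the signature of the discrete limit
  cycle whose displacement floor can sit just above `tol`;
* default `max_iter = 30` matches the original sampling protocol;
  `until_converged = TRUE` (used throughout the tests) continues to 2000.

`profile_along_path()` evaluates the surface along an 8-fold spline
refinement of the images, shifts the first basin minimum to zero, and
labels minima R, I, …, P and interior maxima TS1, TS2, … in arc order;
plateau ties break to the leftmost point and endpoint maxima are never
transition states. `ts_coordinates()` refines each maximum by a parabolic
fit along the arc, recovering saddle positions well below the image
spacing. The validation standard is `minimax_barrier()`, an exhaustive
grid oracle (binary search over energy levels with 8-connected flood fill,
equivalent to minimax Dijkstra): on the test surfaces the 32-image string
barrier agrees with the oracle within 1%, the transition state within one
grid cell, and the barrier is unchanged at 64 images.

## Biased sampling and MBAR

`gen_biased_trajectories()` runs overdamped Euler–Maruyama Langevin
dynamics on surface-plus-harmonic-bias with a 10% burn-in; proposals
leaving the grid hull are rejected. On a harmonic surface the sampler
reproduces the Gaussian stationary distribution
($\mathrm{cov} = k_BT\,(K_\mathrm{surface}+K_\mathrm{bias})^{-1}$) within
sampling error, the closed-form check used in the tests. It is an ergodic
stand-in for QM/MM sampling, nothing more.

`mbar_solve()` implements the multistate Bennett acceptance ratio from its
self-consistent equations in log-space (reduced energies $u = G/k_BT$
internally, conversions only at module boundaries), with Newton polishing
inside the basin of attraction, gauge $f_1 = 0$, tolerance $10^{-8}$, and
the standard SVD form of the asymptotic covariance. Two independent
estimator routes are kept separate deliberately: the two-state BAR solver
(`bar_solve()`, bisection on the Fermi-function identity) agrees with
two-state MBAR to $10^{-6}$ reduced units in the tests. The overlap
diagnostic is the worst best-partner entry of the overlap matrix with
threshold 0.01 — healthy chains sit near 0.2–0.3, states ~5σ apart fall to
~0.01; a minimum-eigenvalue version misfires on perfectly healthy
25-window chains, whose overlap spectrum always contains tiny eigenvalues.

For umbrella reweighting the reduced-energy matrix contains *bias-only*
energies: the unbiased surface term is a per-sample constant across states
and cancels identically in the MBAR equations, so the reconstructed PMF is
a genuine inference from the biased samples, never a read-back of the
generating surface. `pmf_2d()` accumulates mixture weights in 2D bins,
masks empty bins, shifts the occupied minimum to zero, and errors when more
than half the bins in the sampled box are empty. On an analytic harmonic
surface sampled by a 5×5 window grid, the RMS deviation from the truth is
below 0.3 kcal/mol over the occupied region.

Alchemical datasets are chains of 1D Gaussian states with equally spaced
means and linearly accumulating offsets, so the end-to-end free-energy
difference is analytic. Only the estimator is in scope — no softcore
potentials or enhanced-sampling machinery. The default 25 λ windows with
`overlap = 1` (means 1σ apart) recover a 2.86 kcal/mol difference — the
2.1-unit pKa shift of the unmodified ribozyme — within 3 standard errors,
and chain through `delta_pka_from_ddg()` and `ribozyme_pka()` to the
calculated pKa of 6.3.

## Pipeline and reproduction of the published tables

`run_pipeline()` executes simulate → fit → landscape → alchemical with
per-stage seeds derived deterministically from one global seed; identical
configs give byte-identical artifacts (fixed-precision CSV plus an md5
manifest). Generating parameters are the published measured rates,
barriers, and pKas bundled under `inst/extdata/published_values/` — those
printed tables are inputs. `reproduce_published_tables()` re-derives every
derivable cell: relative rates match the printed values exactly at their
two-significant-figure precision; ribozyme pKas equal solution pKa plus
shift exactly for all four variants; TST relative intrinsic rates match
within 15% (the printed barriers carry 0.1 kcal/mol rounding, which is
±18% in a rate ratio), with the ~10⁻¹¹ suppression of the high-pKa variant
checked as an order of magnitude only, since its exact published rate
expression is not reproducible here.

## What the synthetic data do not show

The generators emulate the *statistical structure* of the study — biphasic
saturating curves with gel-scale additive noise, log-normally scattered
rates, landscape topology with controllable saddles, harmonic-bias
sampling with known stationary law, Gaussian alchemical windows. They do
not emulate gel-quantification systematics (saturation, background
subtraction), buffer chemistry or the low-pH downturn outside the measured
5.5–8.5 range, real QM/MM noise and its correlation structure, or force
fields and molecular coordinates of any kind. Passing recovery tests
therefore demonstrates that the estimators are correct and well calibrated
on data matching their assumptions — not that those assumptions hold for
any particular wet-lab or simulation dataset. Deep-barrier QM/MM results
(e.g. the 30.3 kcal/mol barrier of the high-pKa variant) enter only as
preset surface parameters whose calibration and TST consequences are
property-checked, never recomputed.

## Problem sizes

The shipped tests run the kinetics and pH recoveries at 100 seeds, the
string/oracle comparisons on three analytic surfaces plus the preset at
0.04–0.05 Å spacing, umbrella reconstruction with 25 windows × 2700
retained samples, and alchemical chains of 25 × 200 samples — sizes chosen
so the full suite completes in under two minutes while keeping Monte-Carlo
standard errors well inside the asserted tolerances.
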