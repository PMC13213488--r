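---
title: "Worm-like-chain analysis of repeat-protein pulling experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worm-like-chain analysis of repeat-protein pulling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripfit)
```

`ripfit` turns dual-trap optical-tweezers stretch–relax cycles on a
tandem-repeat protein into contour-length changes, rip forces and fold-state
classifications, together with the two ensemble assays (nanoDSF melts,
fluorescence-polarization titrations) used to characterise small-molecule
binders of the same protein. This vignette explains the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices a maintainer should know about.

## 1. The tether model

The construct is a 589-residue, 15-HEAT-repeat protein held between two
600 bp double-stranded DNA handles. Every compliant element follows the
extensible worm-like chain (Marko–Siggia interpolation plus enthalpic
stretching):

$$F = \frac{k_B T}{L_p}\left[\frac{1}{4\,(1 - x/L_c + F/K)^2} - \frac14 +
\frac{x}{L_c} - \frac{F}{K}\right]$$

The clamped constants (`wlc_constants()`) are the community-standard values
for this construct: DNA $L_p$ = 30 nm, $K$ = 500 pN (midpoint of the usual
400–600 pN range for dsDNA; the end members can be passed explicitly for
sensitivity runs), protein $L_p$ = 0.5 nm, $K$ = 300 pN, 0.34 nm/bp and
0.365 nm/residue, $k_BT$ = 4.114 pN·nm (298 K; instrument temperature is
rarely reported for such runs and enters only through this constant).

**Contour-length bookkeeping.** The folded protein core is modelled as a
rigid 15 nm N–C span, not as an elastic element — its compliance is
negligible next to the handles, and no measured persistence length exists
for the folded scaffold. Both the simulator's state and the branch fits are
parameterised by one coordinate, the *net* unfolded contour length
$\ell \in [0, 200]$ nm: the unfolded-chain contour is
$215\,(\ell/200)$ nm and the rigid span $15\,(1-\ell/200)$ nm. Complete
unfolding therefore reports $\Delta L_c = 215 - 15 \approx 200$ nm — the
unfolded chain gained minus the folded span lost — which is the convention
behind the "expected 200 nm" figure for this construct. All reported
contour lengths are protein-only; the handles' 408 nm never appear in them.

The Marko–Siggia relation is solved by vectorised bisection (60 halvings on
the relative extension, machine-precision for practical purposes); inverses
(`ewlc_force()`, `tether_force()`) bracket on $[0, 200]$ pN and error
beyond the cap. Monotonicity and $10^{-6}$-relative round-trips are enforced
by tests.

## 2. The pulling simulator

No raw tweezers data are publicly deposited for this assay, so the package
ships a generator (`simulate_experiment()`) whose defaults *are* the assay
conditions: 100 nm/s constant-velocity pulling, combined trap stiffness
0.3 pN/nm, high-bandwidth kinetics (0.1 ms steps) block-averaged to 100 Hz,
0.2 pN Gaussian force noise at the output stage (no noise figure is
published; 0.2 pN is typical for averaged dual-trap data). Each kinetics
step solves a quasi-static force balance between trap and tether — at
100 Hz output, sub-millisecond bead dynamics are averaged away, which is
what justifies skipping a Brownian-dynamics bead model. Measured extension
is the tether end-to-end distance $s - F/k$, so the output force noise
propagates into it with weight $-1/k$.

**Cooperative blocks.** Each cycle partitions the 15 repeats into
cooperative unfolding blocks: every inter-repeat junction is independently a
boundary with probability `boundary_prob`. Blocks flip with Bell rates
$k(F) = k_0 e^{\pm F\Delta x / k_B T}$ ($\Delta x$ = 8 nm both ways);
per-block stability multipliers $10^{\mathcal N(0,\,0.3)}$ are redrawn every
cycle, emulating domains of differing stability and spreading rip forces
over several pN. Flip times are sampled exactly for piecewise-constant
rates by cumulative-hazard inversion, so the kinetics are not
time-discretisation-limited.

**Why blocks are large (`boundary_prob` = 0.03).** With a 0.3 pN/nm trap
and these handles the measured extension jump of a rip is the force drop
divided by the trap stiffness, $\Delta x_{meas} = \Delta F/k$, and the load
line suppresses it several-fold relative to the contour released: near the
~7 pN unfolding forces of this protein only rips of $\gtrsim$120 nm
$\Delta L_c$ clear a 10 nm extension threshold. The partition prior
therefore favours one to three blocks per cycle — matching the few clearly
resolvable rips per pull such records show — while smaller sub-threshold
flips still occur and are handled by the analysis (below). This is the one
place where generator design was dictated by instrument physics rather than
by a published number.

**Kinetic defaults.** `unfold_rate0` defaults to $4\times10^{-6}$ /s, the
value one calibration pass (`calibrate_unfold_kinetics()`) returns for the
7.2 pN mean final-unfolding force at 100 nm/s. The calibration bisects
$\log_{10} k_0$ and — deliberately — measures its objective with the same
estimator the analysis applies to data (detected rips ≥ 10 nm, pre-rip
0.05 s windowed force), under common random numbers, so the calibrated
quantity is commensurate with what the pipeline later reports. Note the
error propagation: a 0.1–0.15 pN tolerance on the mean force maps through
the Bell slope $k_BT/\Delta x \approx 0.51$ pN into a ~1.3× band on the
rate itself; independent calibrations agree to about that factor, not
better. `refold_rate0` = 100 /s with refolding gated below 8 pN puts
refolds at 2–4 pN on relax — reproducing the stretch–relax hysteresis of
non-equilibrium pulling — while keeping mid-stretch refold/unfold "churn"
(a refold immediately reversed within milliseconds, invisible at 100 Hz)
negligible.

**Conditions.** `apply_condition()` switches the three assay conditions:

* `no_smap` — misfolding: with probability chosen so 22% of all stretching
  traces carry one (first pulls never misfold; later pulls compensate by
  $n/(n-1)$), a contiguous block of 2–8 repeats is sequestered
  (non-unfoldable at any force), shortening the attainable $\Delta L_c$.
  The 2-repeat lower bound keeps the sequestered contour above the
  classification margin: a 1-repeat misfold (~13 nm) would leave total
  $\Delta L_c$ above the 90% threshold and be indistinguishable from a full
  unfold by the stated rule.
* `atux` (functional ligand) — no misfolding, all unfolding rates scaled by
  0.1, raising unfolding forces by $\ln 10 \cdot k_BT/\Delta x \approx 1.2$
  pN.
* `dbk` (non-functional ligand) — after a molecule's first complete
  unfolding it locks in the unfolded state with probability 0.33 (drawn
  once per molecule, immediately after the stretch, so the engaging cycle
  already shows no refolds). The published 33% figure counts traces; with
  per-molecule sampling over 20 molecules × 10 cycles the expected trace
  fraction is 0.33 × 9/10 ≈ 30%, and the molecule-level Bernoulli noise
  dominates the trace-level one — both tallies are reported.

**What the generator does not emulate:** instrument drift and creep,
bead-in-trap hydrodynamics, DNA overstretching, tether breakage statistics,
multiple tethers, and any per-intermediate kinetic map of the real protein
(the Bell parameters are synthetic stand-ins, flagged as such in the
configuration). Passing tests therefore demonstrate that the analysis
recovers known ground truth under realistic mechanics and noise — not that
it is robust to every instrumental artefact of real data.

## 3. Rip detection and branch fitting

Detection (`detect_transitions()`) works on the extension signal: the
per-sample advance is compared with a running-median elastic baseline, and
samples whose residual exceeds 5× its MAD (floored at `min_size`/4 so
noiseless sweeps stay clean) seed candidate rips; candidates closer than 3
samples merge. Rip *size* is measured from the extension levels one sample
outside the candidate run, net of the elastic advance — block averaging can
split one rip unevenly across two output samples, and a level-based size is
unbiased under any split. A candidate only counts when its force change has
the right sign (drop for unfolding, rise for refolding) and its size
reaches `min_size` (default 10 nm, the conventional minimum). The rip force
is the mean over the 0.05 s (5 samples) before onset, shrinking with a
logged warning when the preceding branch is shorter.

Branch fits (`fit_branch()`) minimise force residuals at the measured
extensions — force noise dominates 100 Hz data — over the single free
parameter $\ell$, via golden-section search on a dense force-grid
interpolant of the tether model. Two robustness choices matter:

* **Tukey-bisquare reweighting** (4 IRLS passes, scale floored at 0.05 pN):
  flips below the detection threshold leave short foreign-state stretches
  inside a branch; the robust loss makes the fit follow the branch's
  majority state instead of averaging states.
* **State-pure cycle totals**: the per-cycle total $\Delta L_c$ is the
  difference between a fit of the high-force tail (> 15 pN, where every
  unfoldable block has long unfolded and refolding is suppressed) and one
  of the low-force head (before the force first reaches 4 pN, i.e. before
  any plausible rip). Sub-threshold flips cannot contaminate either
  segment, so the total is exact even when individual rips are unresolvable.
  The per-rip $\Delta L_c$ values remain differences of flanking branch
  fits (`cycle_delta_lc()`).

Points within 3 samples of a rip are excluded from branch fits (jump
smearing), and segments need ≥ 10 points spanning ≥ 1 pN.

## 4. Classification and summaries

`classify_cycle()` applies, in order: **locked** (no rip ≥ 10 nm in either
sweep *and* the head-segment contour length is at least half the expected
value, i.e. the molecule started the pull already unfolded), **full**
(total ≥ 90% of expected), **misfolded** (short total despite a ≥ 20 pN
load), else unclassified; invalid tethers (`validate_tether()`: cumulative
length > 125% of expected, or a mid-sweep force collapse) are excluded. The
start-state condition on "locked" is a deliberate refinement of the
qualitative rule: without it, any folded cycle whose rips happen to fall
below the measurable 10 nm would masquerade as locked, and no classifier
could reach the intended agreement with ground truth. A folded-start,
no-rip, high-force cycle instead lands in "misfolded" — which is exactly
what a fully sequestered record is.

`delta_lc_distribution()` histograms per-cycle totals on 5 nm bins centred
on multiples of the bin width (so 0 and 200 nm are bin centres), locates
the dominant peak by quadratic interpolation of the three bins around the
mode — stable at the 20–30-cycle sample sizes typical of these experiments
— and reports per-class fractions plus the zero-peak mass (bins within one
bin width of zero), the statistic used for the locked fraction.
`welch_t_test()` and `box_stats()` wrap `stats::t.test()` (unequal
variances) and `stats::quantile()` (type 7, linear interpolation) with the
box-plot convention used for force distributions: whiskers at the 10th/90th
percentiles, box at the IQR, line at the median, square at the mean.

## 5. Ensemble assays

**NanoDSF.** `generate_melt()` produces a two-state ratio curve (linear
baseline + logistic transition, width 2 °C by default) on a 20–90 °C grid;
`melt_ratio_derivative()` smooths the 350/330 ratio by Savitzky–Golay local
quadratic regression (window 7 points — unstated by convention, chosen as
the smallest window that stabilises the derivative) and differentiates by
central differences; `extract_tm()` takes the temperature of the
largest-magnitude interior extremum, refined by a 3-point quadratic. Using
the magnitude makes the result independent of whether an instrument plots
the derivative negated; the signed value is kept as an attribute. A series
whose derivative never departs from its median by more than `min_amplitude`
is "flat" and raises a no-transition error — a sloping baseline alone is
transition-free even though its derivative is nonzero. One caveat measured
here: the logistic-derivative peak is flat on the ±0.4 °C scale, so with
ratio noise of $10^{-3}$ the extremum location jitters by ~0.3 °C; on
noiseless 0.1 °C grids recovery is exact to the grid.

**Fluorescence polarization.** `polarization()` is
$(I_\parallel - I_\perp)/(I_\parallel + I_\perp)$, bounded in $[-1, 1]$,
×1000 on request for mP units. `fit_one_site()` fits
$P = P_{max} C/(K_d + C)$ by Levenberg–Marquardt (`minpack.lm`), with
standard errors from the fit curvature; zero-concentration wells are used
as background controls and subtracted first. No ligand-depletion correction
is applied — the isotherm is used exactly as written, appropriate when the
titrated protein far exceeds the fluorescent ligand. Titrations need ≥ 5
nonzero concentrations spanning a decade.

## 6. Problem sizes and determinism

All randomness flows from a single seed per experiment; molecules and
cycles consume the stream in a fixed order, so a fixed configuration gives
byte-identical output (`run_pipeline()` additionally stamps every report
with the seed and a configuration hash). The test-suite simulations use
30–60 cycles per scenario and the end-to-end recovery checks use the full
published-scale experiments (30 cycles for the $\Delta L_c$ peak, 200
cycles for the misfold/lock fractions and the force calibration); one such
check runs in roughly a minute on a single core.

## 7. Known limitations

* The quasi-static force balance has no instrument responses; detection
  windows and thresholds tuned here may need revisiting for data with
  drift or slow force feedback.
* Per-rip contour changes for rips below ~12 nm measured extension are not
  resolvable at this trap stiffness; only cycle totals are immune
  (section 3). Force–$L_c$ scatter tables consequently under-sample small
  intermediates.
* The misfold and lock mechanisms are phenomenological (block
  sequestration, refold switch-off); they reproduce the observable
  statistics, not the underlying structural chemistry.
* `welch_t_test()` assumes independent samples; repeated pulls of one
  molecule are correlated, so condition comparisons should aggregate per
  molecule first when molecule counts allow.
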