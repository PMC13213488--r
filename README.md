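# ripfit

`ripfit` analyses single-molecule pulling experiments on tandem-repeat
proteins — the kind of dual-trap optical-tweezers assay in which a
15-HEAT-repeat scaffold protein (PR65, the A-subunit of phosphatase PP2A) is
tethered between beads via two 600 bp DNA handles and repeatedly stretched
and relaxed at constant velocity. It is written for single-molecule
biophysicists who need a reproducible route from raw force–extension sweeps
to per-cycle contour-length changes, rip forces, and fold-state
classifications, and for anyone studying how small-molecule activators of
PP2A (SMAPs) shift that landscape. Companion tools cover the two ensemble
assays used alongside the tweezers work: nanoDSF thermal melts and
fluorescence-polarization (FP) binding titrations.

## The model

Every elastic element of the tether follows the extensible worm-like chain
(WLC), the Marko–Siggia interpolation with an enthalpic stretch term:

```
F = (kBT / Lp) · [ 1 / (4 (1 − x/Lc + F/K)²) − 1/4 + x/Lc − F/K ]
```

with persistence length `Lp`, contour length `Lc` and stretch modulus `K`.
The tether is a series of such elements — DNA handles (`Lp` 30 nm, `K`
500 pN, 408 nm combined contour), unfolded polypeptide (`Lp` 0.5 nm, `K`
300 pN, 0.365 nm per residue) — plus the folded core's rigid N–C span
(15 nm), which shrinks in proportion to the unfolded fraction. With 589
residues this bookkeeping makes complete unfolding worth a net contour gain
of ΔLc ≈ 200 nm.

The analysis pipeline:

1. **Rip detection** (`detect_transitions()`): extension jumps of ≥ 10 nm
   against a running elastic baseline; rip force = mean force over the
   0.05 s before the jump onset (`transition_force()`).
2. **Branch fitting** (`fit_branch()`): each inter-rip branch is fitted in
   force space with the series WLC model, the net unfolded contour length
   being the only free parameter (robust Tukey-bisquare reweighting by
   default).
3. **Classification** (`classify_cycle()`): cycles are `full` (total
   ΔLc ≥ 90% of expected), `misfolded` (short ΔLc despite ≥ 20 pN loads) or
   `locked` (no rips and an unfolded start) — the three behaviours seen
   without ligand, and under the functional (ATUX-8385) and non-functional
   (DBK-766) SMAPs respectively.
4. **Summaries** (`delta_lc_distribution()`, `force_vs_lc_table()`,
   `welch_t_test()`, `box_stats()`).

Because no public raw tweezers data accompany this assay, the package ships
a first-class kinetic Monte-Carlo simulator (`simulate_experiment()`):
cooperative blocks of repeats flip with Bell rates
`k(F) = k0·exp(±F·Δx/kBT)` under a quasi-static force balance against the
trap, at 100 nm/s, decimated to 100 Hz — so every stage of the pipeline is
verifiable end to end against known ground truth.

For the ensemble assays, `fit_tm()` extracts melting temperatures from the
first derivative of the 350/330 nm fluorescence ratio, and `fit_one_site()`
fits the one-site isotherm `P = Pmax·C/(Kd + C)` to FP titrations.

## Worked example

```r
library(ripfit)

cfg <- apply_condition(sim_config(), "no_smap")
sim <- simulate_experiment(cfg, n_molecules = 4, n_cycles = 5, seed = 421)
an  <- analyze_cycles(sim)
delta_lc_distribution(an$cycles)
```

```
<dlc_distribution> n = 20, peak 199.5 nm (sd 3.3), zero-peak mass 0.0%
# A tibble: 2 × 3
  label         n fraction
  <chr>     <int>    <dbl>
1 full         15     0.75
2 misfolded     5     0.25
```

The peak sits at the expected ~200 nm full-unfolding contour gain (the
handles' 408 nm are not included; contour lengths are protein-only), and a quarter
of the stretching traces misfolded — a contiguous block of repeats
that refuses to unfold even at high force, shortening the recoverable ΔLc.
`plot_fec(sim)` draws a stretch–relax cycle, `autoplot()` the distribution.

For the binding assays:

```r
fit_tm(generate_melt(tm = 52.7, noise_sd = 0))
#> <tm_fit> Tm = 52.70 degC (dFIR at extremum 0.038 / degC)

fit_one_site(generate_fp(kd = 4.7, pmax = 100, noise_sd = 0))
#> <fp_fit> Kd = 4.7 +/- 1.2e-15 uM, Pmax = 100 +/- 7e-15 (n = 13)
```

Both fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

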