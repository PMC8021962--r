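---
title: "From expression energy to relative adhesion: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression energy to relative adhesion: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadhesion)
```

## The scientific problem

Classical cadherins mediate calcium-dependent cell–cell adhesion through
trans-dimerization of their membrane-distal EC1 domains. The differential
adhesion hypothesis holds that quantitative differences in adhesive
strength are sufficient to sort cells into compartments — transverse
neuromeric segments of the neural tube, subpallial nuclei, cortical
layers. `cadhesion` implements a transparent chain from an ISH expression
measurement to a dimensionless relative adhesion between two cells, so
that expression differences between neuroanatomical structures can be
read as predicted adhesion differences.

## The measurement: expression energy and unionize

Expression energy is mean expressing-pixel intensity times the expressing
fraction of pixels, which algebraically is summed expressing intensity
over total pixels. `pixel_summary()` stores the three sufficient
statistics, `expression_energy()` applies the formula (zero when nothing
expresses), and `unionize()` aggregates per-section summaries by
component-wise summation, making energy invariant to how a structure
volume is partitioned — an associativity the tests exercise on random
partitions. ISH probes are not calibrated against an mRNA standard, so
energies are comparable across structures for one gene but only
suggestive between genes; the only cross-gene operation in the package is
the adhesion model, where each gene's affinity re-weights its counts.

The significance convention (`significant_expression_flags()`) is an
inclusive threshold of 1 energy unit.

## The ontology

All computations are indexed by a `structure_graph`: a forest of
structures on ontological levels 1–13, with the 19 transverse segments of
level 3 (RSP, CSP, p3–p1, m1–m2, isthmus, r1–r11) carrying an explicit
anterior–posterior rank. The rank is stored, not inferred, because the
prosomeric ordering is a convention of the field, not derivable from the
graph. Plates (roof/alar/basal/floor), subpallial strata and divisions
are enumerated attributes; cortical structures are (area, layer) pairs —
9 areas × 6 layers — stored in two dedicated columns rather than
overloading the stratum vocabulary, which enumerates the radial subpallial
strata only. The packaged fixture covers the levels the analyses index
(3, 5 and a level-11 set of nuclei and cortical units); the full atlas
ontology is intentionally not bundled, and published descriptions of the
adult strata differ slightly between sources, so the nucleus set here is
a representative selection, not an exhaustive one.

## The adhesion model

The chain implemented by `adhesion_work()` is:

1. **Calibration.** molecules = energy × 25,000. The calibration is a
   stated convention of the field, not a measurement; only ratios of
   works are interpreted downstream.
2. **Geometry.** A 10 µm spherical cell in a close packing touches 12
   neighbors, so one contact contains 1/12 of its surface molecules
   (`contact_fraction`, default exactly 1/12 rather than the rounded 8%);
   half of those (`participation_fraction` = 0.5) are assumed adhesive.
   The contact is a slab of area (1/12)·πd² and thickness 12 nm, the
   span in which EC1 domains from both membranes can meet. Note an exact
   cancellation: C_T = molecules × participation / (N_A × πd² × thickness
   × 1000), independent of the contact fraction — the fraction rescales
   both the molecule count and the volume. The default counts one cell's
   molecules (`count_both_cells = FALSE`); since only C_T/K_D enters any
   ratio, counting both membranes is observationally equivalent to
   halving K_D and is exposed as a flag rather than a second model.
3. **Equilibrium.** K_D = C_M²/C_D with conservation C_M + 2C_D = C_T has
   the unique non-negative root C_M = 2C_T/(1 + √(1 + 8C_T/K_D)) — the
   rationalized form, stable in the dilute limit where the naive
   quadratic formula cancels catastrophically. Conservation holds to
   ~1e-16 relative; tests compare against an independent bisection of the
   conservation residual over C_T/K_D ∈ [1e-4, 1e4]. The saturated limit
   C_D → C_T/2 is approached with deviation √(K_D/2C_T) (about 2.2% at
   C_T/K_D = 10³, under 1% by 10⁴); the dilute limit C_D → C_T²/K_D has
   deviation ≈ 4C_T/K_D.
4. **Thermodynamics.** Δg = −(RT/N_A) ln(K_D/c⁰), with R = 1.987
   cal·mol⁻¹·K⁻¹, T = 310.15 K (physiological) and an explicit 1 M
   reference state c⁰ keeping the logarithm dimensionless. At the
   reference Cdh2 affinity (25.8 µM) Δg ≈ 1.08 × 10⁻²⁰ cal per dimer.
5. **Work and normalization.** W = N_dimers × Δg with N_dimers =
   C_D·V·N_A, normalized to the work of 25,000 Cdh2 molecules. One
   global reference is used across all ages (configurable); Δg is a
   common factor per cadherin, so for a single cadherin the work ratio
   equals the dimer-count ratio and temperature cancels exactly — an
   invariance the tests assert to 1e-12.

At the reference configuration C_T ≈ 5.5 µM, i.e. C_T/K_D ≈ 0.21: the
equilibrium sits in the super-linear regime, which is why a 2.4-fold
molecule difference produces a 3.8-fold difference in work. In general
W(2.4m)/W(m) runs from 5.76 (= 2.4², dilute) down to 2.4 (saturated) and
always exceeds the molecule ratio itself.

`adjacent_fold_changes()` scans an anterior–posterior profile for
boundaries whose symmetric fold max/min meets a threshold (default 4, the
scale of difference observed between adjacent neuromeres for several
cadherins). Zeros are handled by convention: one zero side is an
infinite, flagged fold; two zero sides are fold 1.

### The K_D table

Affinities ship as data (`kd_table_synthetic.csv`), never as constants:
each row carries a source tag, and only the Cdh2 entry (25.8 µM,
analytical ultracentrifugation) is literature-anchored — all other rows
are synthetic placeholders on the plausible micromolar scale of EC1
trans-dimerization, shipped so the pipeline runs end to end and meant to
be replaced with curated values. Specificity-group assignments (A:
Cdh6/9/10; B: Cdh7/12/18/20/22; C: Cdh8/11/24) are validated on load.
Heterophilic binding is deliberately out of scope — the model considers
one cadherin at a time — but the table schema does not preclude pair
entries, so that extension is non-breaking.

## Correlation and ratio analyses

`pearson()` uses pairwise-complete observations (missing energies are
never imputed as zero), requires n ≥ 3 and non-constant vectors (a
constant vector is an error, not r = 0), and derives the two-sided
p-value from the t transform on n − 2 degrees of freedom; tests verify
agreement with `stats::cor.test` to 1e-12. Correlation bins are low
(< 0.70), intermediate (0.70–0.90) and high (≥ 0.90): the conventional
cutpoints leave gaps at 0.69–0.70 and 0.89–0.90, closed here with
half-open intervals; the thresholds are arguments.

`cortex_subpallium_correlation()` correlates, for every cortical
(area, layer) unit against every subpallial nucleus, the two 12-gene
cadherin panel vectors (the default panel follows the introduction-style
group assignment, with Cdh20 in group B; it is an argument). Units with
more than 25% missing panel values are excluded with a warning. Raw
energies are correlated by default, with a `normalize` switch for
within-unit proportions, since the field's practice is ambiguous on this
point.

`alar_basal_ratio()` reports per-segment log2(alar/basal), so the "zero
line" is exactly ratio 1 and −2 is a fourfold basal excess; a segment
with both plates at zero is missing, one zero side yields a signed
infinite sentinel with a flag.

`ish_scrnaseq_comparison()` normalizes both modalities to a housekeeping
reference (Actb), averages the ISH side over a cortical (area × layer)
grid and the scRNA-seq side over neuronal clusters only (study scale:
377 clusters, 24 non-neuronal removed, 353 used), and compares the two
per-gene mean profiles with a paired two-sided Wilcoxon signed-rank test
by default (a paired t-test is an option); no specific test is canonical
for this comparison, so the choice is explicit and logged in the result.
One caveat the tests made visible: normalizing both sides to a *noisy*
shared reference correlates the per-gene differences (a reference
fluctuation shifts every gene together), inflating any paired test's
size. The calibration test therefore fixes the reference when simulating
the null; with real data, reference noise is part of what the test sees.

## The synthetic generator

`generate_expression_table()` emulates the statistical structure the
analyses assume: log-normal energies (non-negative, multiplicative
noise), a Gaussian copula on the log scale carrying between-gene
correlation, and planted step folds across a named boundary. Two
details matter:

* Targets are requested on the observed (energy) scale. For common
  log-sd σ the latent correlation is the exact back-transform
  r_latent = log(1 + r(e^{σ²} − 1))/σ², so recovered Pearson r matches
  the target rather than sitting slightly below it. Infeasible target
  sets are repaired to the nearest positive-definite matrix; a repair
  that shifts any target by more than 0.05 is refused.
* Defaults are fixed once: σ = 0.3 (moderate multiplicative
  structure-to-structure variation, of the order seen between
  neighboring segments for one gene), baseline energy 1.0 (the
  calibration point, 25,000 molecules), 19 structures (one per level-3
  segment), age P56.

What the generator does *not* emulate: spatial autocorrelation between
neighboring structures, probe-specific sensitivity differences between
genes, and ISH image-processing artifacts. Tests passing on synthetic
tables therefore validate the arithmetic of the pipeline, not the
biological fidelity of atlas data.

`generate_pixel_grids()` emits pixel summaries with their closed-form
energies; `generate_scrnaseq_clusters()` emits cluster-mean tables with
the study's neuronal/non-neuronal split and a strictly positive
reference.

## Problem sizes and numerical choices

The shipped tests run the equilibrium oracle over a half-decade grid of
C_T/K_D ∈ [1e-4, 1e4], the correlation-recovery study at n = 500
structures × 50 seeds (mean within ±0.02 of target; a single seed within
the Fisher-z 95% interval), and the null calibration of the ISH/scRNA
comparison at 60 replicates of 40 clusters — sizes chosen so the whole
suite completes in seconds while keeping the Monte-Carlo bounds
meaningful. All randomness flows from per-call seeds; identical spec and
seed reproduce output tables byte for byte.

## Known limitations

* The molecule calibration (25,000 per energy unit) is a convention;
  absolute works in calories are not interpretable, only ratios.
* Single-subtype homophilic adhesion only: heterophilic pairs and
  combinatorial expression would increase between-structure differences
  beyond what this model reports.
* The non-Cdh2 affinities shipped are placeholders (see above).
* Energies across genes are only suggestive; cross-gene conclusions
  should rest on the K_D-weighted adhesion scale, not raw energies.
* The 2-D membrane-bound nature of cadherin binding is approximated by a
  3-D slab equilibrium; kinetics and mechanics (forces in newtons,
  membrane deformation, cis-clustering) are out of scope.
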