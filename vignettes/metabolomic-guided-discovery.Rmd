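---
title: "Metabolomic-guided discovery of cyclic nonribosomal peptides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic-guided discovery of cyclic nonribosomal peptides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclometab)
```

## Scope

`cyclometab` implements the two computational halves of an untargeted
LC-MS discovery workflow for fungal secondary metabolites:

1. **Feature prioritization.** An aligned feature table (features ×
   samples, with m/z, retention time and an upstream isotope annotation)
   is filtered, pareto-scaled and modeled by two-class OPLS-DA;
   cross-validated Q² decides model validity and VIP scores rank the
   features that drive the class difference. A parallel include/exclude
   validation decides whether the top-VIP subset alone carries the class
   signal.
2. **Peptide annotation.** Prioritized ions are dereplicated against a
   bundled accurate-mass library, and cyclic pentapeptide candidates are
   confirmed or sequenced de novo from their MS/MS b-ion ladders.

Peak picking, alignment, isotope grouping (XCMS/CAMERA territory), NMR
interpretation and bioassays are out of scope; the pipeline starts from
an aligned table and ends at annotated/sequenced candidates.

## Mass arithmetic

All masses derive from one monoisotopic element table (`element_masses()`,
six-decimal CODATA/NIST values) with the proton fixed at 1.007276 Da and
the electron at 0.000549 Da. Protonated ions are neutral + proton;
sodiated ions are neutral + Na − electron. The two computation routes
(neutral + adduct vs. ion-formula − electron) agree within 1 µDa and both
are exercised in the tests.

The ppm error convention is `(theoretical − measured) / measured × 1e6`,
inferred from the bundled library where rows of both signs pin the
convention down. Whether the denominator is the measured or the
calculated mass is indistinguishable at 4-decimal printed precision; the
measured mass was fixed as denominator and is used consistently.
Comparisons against printed values round half-up to the printed precision
(4 dp for masses, 2 dp for ppm): the library's printed ppm values are only
reproducible when the theoretical mass is first rounded to 4 dp, so that
rounding step is part of the recomputation, not an approximation.

Three rows of the bundled 19-compound library are internally inconsistent
as printed: one calculated mass disagrees with its own printed ion formula
by 1.8 mDa, and two printed ppm values disagree with their own printed
mass cells. The library ships the printed values verbatim alongside the
recomputed masses and the discrepancies are reported, not corrected —
the same policy used for an anomalous printed MS/MS fragment (below).

Ring-plus-double-bond equivalents use DBE = C + 1 + N/2 − (H + Cl)/2 on
the neutral formula; O, S and Na contribute nothing and Cl counts as H.

## Cyclic peptide model

A cyclic peptide is an ordered residue list read N→C with an amide bond
closing the ring; rotations are the same molecule. Cyclization removes
the water of the linear peptide, so the neutral mass is the plain residue
sum, and the protonated precursor is that sum + 1.007276.

Gas-phase fragmentation is modeled as ring opening at any one of the *n*
amide bonds followed by sequential C-terminal residue loss from the
resulting acylium: the k-th b-ion of an opening is the first-k residue
sum + proton, and the full-length b_n coincides with the precursor (no
water is added — acylium chemistry, which is exactly what the printed
ladders imply). Only b-ions are modeled; y-ions, neutral losses and
immonium ions are deliberately out of scope (every fragment in the source
ladders is a b-ion), and the annotation API is the extension point if
they are ever needed. Intensities, collision-energy effects and multiple
charging are not modeled.

The *cyclospectrum* is the union over all *n* openings: n(n−1) proper
prefixes plus the shared precursor ion, i.e. n(n−1)+1 theoretical masses
before deduplication of exact mass collisions.

Two identifiability limits are intrinsic to b-ion masses and are made
explicit rather than hidden:

* **Leu/Ile** are isobaric (113.08406 Da). Sequencing reports the
  collapsed `Xle` class by default; `expand_xle = TRUE` enumerates the
  explicit assignments. Distinguishing them requires NMR (or ion
  chemistry outside this model). Stereochemistry (D/L) is likewise
  invisible to MS and not modeled.
* **Ring direction.** The cyclospectrum of a ring equals that of its
  reversal: every contiguous cyclic substring of one is a reversed
  substring of the other with the same residue-mass sum. The two reading
  directions are therefore indistinguishable from single-stage fragment
  masses, and `sequence_candidates()` merges each reflection pair into a
  single candidate class by default (`merge_reflections = FALSE`
  separates them again, at which point both orientations appear with
  identical scores). Annotation against a *known* sequence is unaffected:
  there the direction is supplied by the user.

### Annotation

`annotate_spectrum()` matches every theoretical ion of every opening to
the nearest observed peak within an absolute tolerance (default 0.02 Da;
printed fragments carry one decimal, and a 0.02 Da window is conservative
for Orbitrap/qTOF fragment mass accuracy). One observed peak may satisfy
several theoretical ions. Each annotation carries both the opening site
(flanking residues of the cleaved bond) and the lost residue, because
"-Pro"-style labels conflate the two: the same printed mass can be a Pro
loss from one opening or a different residue's loss from another. The
bundled Val/Val pentapeptide is the worked example: its printed "471.3
(−Pro)" fragment is 2 Da below an actual Pro loss (473.3) but matches a
Val loss through the Val→Val opening exactly; the package reports both
facts and forces neither.

### Sequencing

`sequence_candidates()` is a leaderboard search (the standard
branch-and-bound relaxation for cyclopeptide sequencing): linear prefixes
grow one residue at a time over the mass-distinct alphabet, are scored by
how many of their prefix b-ions hit an observed peak within tolerance,
and only the `beam` best survive each round (ties broken deterministically
toward lighter prefixes, then stable order). Prefixes heavier than the
precursor are pruned; a full-length prefix closes the ring only if its
residue sum + proton matches the precursor within tolerance. Closed rings
are deduplicated by canonical rotation key (lexicographically smallest
rotation, reflections merged as above) and ranked by observed peaks
explained, then |precursor delta| (compared at 1 nDa granularity so
floating-point summation order cannot decide a tie), then key. With a
beam at least as large as the number of feasible prefixes the search is
exhaustive; the tests verify exact agreement with brute-force enumeration
for rings up to size 4 over a five-residue alphabet, and the default beam
of 1000 is far above the feasible prefix count for pentapeptides at 0.01
Da tolerance.

The default alphabet is the 20 proteinogenic residues plus
N-methyl-phenylalanine (Phe + CH₂), the nonproteinogenic residue of this
peptide family; residue masses are derived from their elemental
compositions through the same mass table as everything else.

## Feature table and filters

The final feature list is produced by three filters: isotope-flagged
features are dropped; a feature is dropped when its maximum integrated
area across the table's samples is strictly below 10,000 (the unit of a
feature list is the feature, so the threshold is applied per feature, not
per cell — the alternative would silently zero individual measurements);
and, for mycelium-matrix tables only, features eluting after 25 min are
dropped (the gradient's wash phase, which for mycelium extracts carries
lipid-like material rather than secondary metabolites). Mixed tables are
split by matrix first (`split_by_matrix()`), keeping the retention-time
rule scoped to the mycelium metabolome. Filters are idempotent,
order-insensitive among themselves, and never alter retained values.

Pareto scaling mean-centers each feature and divides by the square root
of its standard deviation (n−1 denominator) — the usual compromise for
LC-MS areas between unit-variance scaling (which inflates noise features)
and none (which lets the most abundant features dominate outright). A
scaled non-constant column has mean 0 and variance equal to its former
standard deviation; zero-variance columns are centered and flagged.
Scaling is not idempotent and is applied exactly once per model, which
the pipeline's provenance log makes auditable.

## OPLS-DA

For a binary class vector coded −1/+1 and centered, the O-PLS
decomposition extracts one predictive component (sufficient for a single
response) after iteratively removing `n_orth` Y-orthogonal components:
per round, the predictive weight is `w ∝ X'y`; the orthogonal weight is
the part of the X-loading orthogonal to `w`, whose scores/loadings are
deflated from X. The fit is deterministic, invariant under sample
duplication, and with `n_orth = 0` reduces exactly to PLS1 (verified
against an independent PLS implementation at cosine > 0.9999).

* **Number of orthogonal components.** Not stated by the originating
  software's defaults for this kind of data; the package default is 1,
  overridable. One component absorbs the dominant class-orthogonal
  variation (here, e.g., strain-to-strain baseline differences) without
  burning degrees of freedom at n ≈ 30–60.
* **Q².** 1 − PRESS/SS over class-stratified k-fold cross-validation,
  k = 7 by convention, seeded fold assignment, each training split
  re-fitted including its centering. When a class is smaller than the
  fold count, k is reduced to the minority class size so every fold
  retains both classes (15 samples split 4/11 cannot stratify 7 folds).
  Verdicts are strict: Q² ≤ 0.4 invalid, > 0.4 valid, > 0.7 highly
  significant.
* **VIP.** From the predictive component only (orthogonal variation is
  Y-uncorrelated by construction): VIP_j = √p·|w_j|/‖w‖, so ΣVIP² = p on
  every fit; the > 0.7 threshold marks significant drivers. Ties are
  broken by feature m/z, then id.
* **S-plot.** p1 = cov(t, x_j) against pcorr1 = cor(t, x_j);
  zero-variance features get pcorr1 = 0 with a flag.
* **Subset validation.** Three models — full, top-N VIP only, all but
  top-N — each with its own cross-validated Q²; the subset is "useful"
  when the include-model is at least valid and the exclude-model is
  invalid. A permutation null (`permutation_q2()`) guards against
  over-fitting: labels are permuted, Q² recomputed, and the observed Q²
  compared against the null's upper tail.

## What the synthetic generator emulates — and what it does not

`simulate_study()` reproduces the structure of the originating study:
15 strains (4 highbush, 11 wild), two media, two extract matrices (60
samples), 3856 features over m/z 150–1100 and a 31-min gradient, with a
5% isotope-flag rate and 30 planted markers per contrast (disjoint sets
for medium, host-within-ML, host-within-PDB).

Free parameters were fixed once at values conventional for untargeted
LC-MS and are surfaced in `study_design()`:

* integrated areas log-normal, between-feature baseline log-mean 10.5 and
  log-sd 1.2 (baselines spanning roughly two orders of magnitude, with a
  realistic fraction falling below the 10,000-area floor);
* within-feature log-sd 0.4 (≈ 40% CV across biological replicates);
* markers shifted by `effect_size` (default 3) within-feature log-sds in
  the designated group, direction random per marker;
* markers drawn from features above the 0.9 baseline quantile:
  the discriminant compounds of this kind of study are major
  chromatographic peaks, isolable at milligram scale — not trace
  features. This matters statistically because pareto scaling weights
  features by the square root of their spread, so a trace marker is
  structurally harder to rank than an abundant one.

The generator does **not** emulate chromatographic peak shapes, isotope
envelopes, adduct clusters, missing values, retention-time drift, or
correlated metabolite modules; features are independent given their
class. Passing tests therefore demonstrate that the statistics behave
correctly in a clean planted-marker regime, not that real data of this
difficulty will yield the same Q² values — on real data the printed
validation ledgers of such studies show hundreds of covarying
discriminant features rather than exactly 30 independent ones.

`simulate_msms()` jitters the deduplicated cyclospectrum with Gaussian
m/z noise, drops a configurable fraction of peaks, and adds uniform
contaminants; with all three at zero it returns the cyclospectrum
exactly.

## Problem sizes and budgets in the test suite

The acceptance-style checks run the full-size study (3856 × 60, 7-fold
CV, 20 permutations) — a few seconds of compute. Property-style
invariants (recovery monotone in effect size, null-effect behavior)
run on reduced designs (600–800 features, 10 seeds) because they repeat
whole simulate–fit–validate cycles; the regime probed is the same.
Sequencing oracle-equivalence uses rings of size ≤ 4 over a five-residue
alphabet where exhaustive enumeration is exact and immediate.

## Known limitations

* Two-class OPLS-DA only; no multi-class extension, no O2-PLS.
* Singly charged positive ions only; no isotope-pattern scoring.
* b-ions only; modified residues beyond N-methylation are not modeled.
* The bundled library is the study's 19 compounds, not an external
  database connection.
* Q² depends on the fold scheme; the fold count is configurable and
  logged, and other schemes (e.g. leave-one-out) will move third-decimal
  digits.
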