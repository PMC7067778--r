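# cyclometab

Metabolomic-guided discovery of cyclic nonribosomal peptides from
untargeted LC-MS data.

Fungal endophytes produce families of bioactive secondary metabolites —
cyclic pentapeptides, griseofulvin-type polyketides, cytochalasins — whose
discovery from culture extracts follows a now-standard route: align
thousands of LC-MS features across strains and culture conditions, use
supervised multivariate statistics to find the features that discriminate
conditions, dereplicate those against known-compound libraries by accurate
mass and retention time, and sequence the novel cyclic peptides from their
MS/MS fragment ladders. `cyclometab` implements that route end to end for
two-group contrasts, for analysts working on microbial natural-product
screens.

## What it computes

**Feature prioritization (OPLS-DA).** After isotope/area/retention-time
filtering and pareto scaling (x′ = (x − x̄)/√s), a two-class OPLS-DA is
fitted from scratch: one predictive component (w ∝ X′y) after iterative
removal of Y-orthogonal components. Model quality is R²X, R²Y and the
cross-validated predictive ability

    Q² = 1 − PRESS/SS,

with stratified 7-fold CV; Q² > 0.4 marks a valid model and Q² > 0.7 a
highly significant one. Feature influence is VIP_j = √p·|w_j|/‖w‖
(ΣVIP² = p; VIP > 0.7 significant), with S-plot coordinates
(cov(t, x_j), cor(t, x_j)) for visualization. A parallel validation
refits the model on the top-N VIP features only and on everything except
them: the subset is "useful" when the first model is valid and the second
is not. A label-permutation null guards against over-fit.

**Mass arithmetic and dereplication.** Molecular formulas are parsed and
summed over a monoisotopic element table; protonated ions are M + 1.007276,
sodiated ions M + 22.989770 − 0.000549. Signed mass errors use
ppm = (theoretical − measured)/measured × 10⁶, and ring-plus-double-bond
equivalents DBE = C + 1 + N/2 − (H + Cl)/2. Observed ions are matched
against a bundled 19-compound library (griseofulvin to the ellisiiamide
pentapeptides) inside ppm and retention-time windows.

**Cyclic peptide MS/MS.** A cyclic peptide fragments by ring opening at
any of its n amide bonds followed by sequential residue loss; the k-th
b-ion of an opening is the sum of its first k residue masses + 1.007276,
and the full-length b-ion equals the precursor [M+H]⁺. The package
enumerates all openings (the cyclospectrum has n(n−1)+1 theoretical
ions), annotates observed spectra against them, and sequences unknown
rings de novo by a leaderboard search verified against brute-force
enumeration. Leu/Ile are reported as the isobaric class Xle and the two
ring reading directions are merged — neither is decidable from b-ion
masses.

## Worked example

Fragment arithmetic for the alanine-substituted cyclic pentapeptide:

```r
library(cyclometab)

p <- cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")
p
#> cyclo(NMePhe-Ala-Ile-Leu-Pro)  [M+H]+ 556.3493

format(peptide_formula(p)); rdbe(peptide_formula(p))
#> [1] "C30H45N5O5"
#> [1] 11

# diagnostic b-ion ladder of the Pro->NMePhe ring opening
round(b_series(ring_openings(p)[[1]]$residues), 1)
#>    b1    b2    b3    b4    b5
#> 162.1 233.1 346.2 459.3 556.3
```

The precursor 556.3493 is the protonated C30H45N5O5 ion; the ladder reads
as sequential losses of Pro (556.3 → 459.3), Leu (→ 346.2), Ile (→ 233.1)
and Ala (→ 162.1, the N-methyl-phenylalanine b1). De novo sequencing from
the theoretical spectrum recovers the ring uniquely:

```r
cand <- sequence_candidates(precursor_mz(p), simulate_msms(p),
                            ring_size = 5, tol = 0.01, keep = 3)
as.data.frame(cand)
#>                 sequence matched_peaks  coverage precursor_delta
#> 1 Ala-NMePhe-Pro-Xle-Xle            19 1.0000000   -1.136868e-13
#> 2 Ala-NMePhe-Xle-Pro-Xle            15 0.8823529    0.000000e+00
#> 3 Ala-NMePhe-Xle-Xle-Pro            15 0.7894737    0.000000e+00
```

The top class (`Ala-NMePhe-Pro-Xle-Xle`, rotations/reflections merged,
Leu/Ile collapsed) explains all 19 distinct theoretical ions; the
runner-up explains 15.

The statistics half runs off a seeded synthetic study with the design of
the originating screen (15 strains × 2 media × 2 matrices, 3856 features,
30 planted markers per contrast):

```r
sim <- simulate_study(study_design(seed = 1))
res <- run_discovery(sim$table, contrast = "medium", top_n = 30, seed = 1)
res$q2; res$verdict
#> [1] 0.9019441
#> [1] "highly significant"
as.data.frame(res$validation$ledger[, c("model", "n_features", "q2", "verdict")])
#>             model n_features        q2            verdict
#> 1            full       3513 0.9019441 highly significant
#> 2 include_top_vip         30 0.9533483 highly significant
#> 3 exclude_top_vip       3483 0.3645052            invalid
res$validation$useful_subset
#> [1] TRUE
```

## Analysis workflow

The `analysis/` directory is a numbered driver sequence over the package —
simulate → filter → model/prioritize → dereplicate → annotate → sequence —
each stage writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R 1
Rscript analysis/02_filter_features.R
Rscript analysis/03_oplsda_vip.R 1
Rscript analysis/04_dereplicate.R
Rscript analysis/05_fragment_annotation.R
Rscript analysis/06_sequencing.R
```

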