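---
title: "Methods: the residual-cognition convergence pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the residual-cognition convergence pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residcog)
```

## The trait: residual cognition

Neuropathology explains only part of late-life cognitive performance.
`residcog` quantifies the unexplained part as a residual: last global
cognition is regressed on four demographic covariates (age at death, sex,
years of education, study cohort) and ten neuropathology indices —
square-root composites of regionally scaled tangle, neuritic-plaque, and
diffuse-plaque counts; an averaged four-region cerebral amyloid angiopathy
grade (0–4); four-level atherosclerosis and arteriolosclerosis scores; and
binary macroinfarct, microinfarct, Lewy-body, and hippocampal-sclerosis
indicators. TDP-43 measures are deliberately excluded from this model (they
are available for a subset only and are used as *conditioning* variables in
secondary analyses). The residual, in cognition z-score units, is positive
for people performing better than their pathology predicts and negative for
those performing worse. Every analysis is restricted to complete cases for
the variables it uses.

Two modelling choices deserve note:

* **Regional scaling without centering.** Regional counts are divided by
  their baseline standard deviation but not centered, so the averaged
  values stay nonnegative and the square root (which tames the strong
  positive skew of counts) is defined. Centering would produce negative
  averages incompatible with the square root. Whether baselines are
  cohort-combined or cohort-specific is configurable
  (`scale_regional_counts()`); combined baselines are the default.
* **Global cognition** is the mean of 17 per-test z-scores, each
  standardised against the battery's baseline mean and SD. At least half
  the tests must be present (configurable); the per-subject decline slope
  is an ordinary least-squares slope of global cognition on visit time
  rather than a mixed-model estimate — a deliberate simplification that
  preserves the contract (one decline rate per subject) while keeping the
  module dependency-light.

## Stage 1: the genetic scan

Each variant's dosage (expected minor-allele count in [0, 2], from
imputation) is tested in the additive model
`residual cognition ~ dosage + EV1 + EV2 + EV3`, with t-based inference at
n − k − 1 degrees of freedom. Scans run per genotyping platform and are
combined by fixed-effect inverse-variance meta-analysis (the standard
reading of a two-platform meta-analysis; heterogeneity is not acted on).
The vectorised scan uses the Frisch–Waugh residualization identity and is
exactly equal to the per-variant OLS fits — a property the test suite
asserts to 1e-10.

Thresholds are predefined, not tuned: suggestive p < 10⁻⁵ (strict
inequality), genome-wide 5×10⁻⁸ reported alongside. Suggestive variants are
clumped greedily: sort by ascending p (ties broken by chromosome, then
position, for determinism); the best unassigned variant seeds a clump and
absorbs all unassigned same-chromosome variants with squared dosage
correlation r² > 0.2 to it; repeat. r² is computed on dosages, not phased
haplotypes — that is what an imputed-dosage pipeline holds, and it is
allele-flip invariant. Clumping is lead-only (each member's r² is to the
seed), matching the common clumping convention rather than pairwise
linkage.

Candidate genes lie within 100 kb of the lead SNP (≤ 100,000 bp to the
nearest gene boundary, 1-based inclusive coordinates). Signed distances are
0 inside the gene, positive 5′ of the gene's start on its strand, negative
3′ of its end. Candidates continue only with non-zero expression in
strictly more than 80% of subjects; each lead SNP is also tested as a
cis-eQTL against the genes in its window, with RNA technical covariates.

## Stage 2: the methylation omnibus

A gene's region is its transcribed span ±100 kb. Each CpG's beta value
(fraction methylated, in [0, 1]) is regressed against residual cognition
with batch and mean bisulfite conversion as covariates. The per-CpG
p-values are combined by Fisher's method, T = −2·Σ ln pᵢ. Under
independence T would be χ²(2k), but neighbouring CpGs are correlated, so T
is calibrated empirically instead: the trait vector is permuted across
subjects B times (default 10,000; covariates and methylation stay fixed and
are refit within each permutation), T is recomputed each time, and

empirical p = (1 + #{T_perm ≥ T_obs}) / (B + 1).

The add-one convention guarantees a valid, nonzero p with minimum
1/(B + 1). One permutation is shared across all the region's CpGs per draw,
so T_perm is a valid joint statistic. Per-CpG p-values are floored at
1e-300 before logging, with a warning — never silently. Regions are
declared at Benjamini–Hochberg FDR < 0.05 across the regions tested in the
run; the per-CpG FDR universe is all CpGs tested in all candidate regions
of the run (the natural choice when the universe is otherwise unspecified;
both are configurable).

Significant regions are re-tested with the lead SNP's dosage and EV1–3
added to every per-CpG model, asking whether the epigenetic association is
genetically driven. The permutation scheme for this rerun keeps permuting
the raw trait, mirroring the unadjusted procedure; a Freedman–Lane scheme
(permute residuals from the nuisance model, add back its fitted values) is
available via `scheme = "freedman-lane"` and is better calibrated when the
added covariates carry strong signal.

Missing beta values are completed by k-nearest-neighbour imputation
(k = 100, capped at availability): subject distance is the root mean
squared difference over shared observed CpGs — a Euclidean distance
normalised for unequal overlap — and each gap takes the mean of its CpG's
value among the k nearest subjects with data there. Observed entries are
never modified.

## Stage 3 and the verdict

Expression association uses
`residual cognition ~ adjusted FPKM + RIN + log2 aligned reads + PMI +
ribosomal bases`; effects are per FPKM unit, so highly expressed genes show
small per-unit coefficients (rescaling expression by c rescales β by 1/c
and leaves p unchanged — asserted to 1e-10). ComBat-style batch adjustment
is upstream of this package; the simulator emits adjusted values directly.

A candidate is **convergent** when its locus is suggestive, its omnibus FDR
is below 0.05, and its expression p is below 0.05 — raw p for RNA mirrors
the reporting asymmetry between the stages and is configurable. One
methylation/expression signal gives `partial`; none gives `genetic-only`.
Convergence is a gene-level property: a gene adjacent to two independent
clumps is still one convergent gene.

Conditional models (`conditional_association()`) refit the marginal SNP
model with a TDP-43 stage/severity score (entered as a linear ordinal term,
matching single-coefficient reporting) or a partner SNP added, and report
the attenuation 1 − β_cond/β_marg.

## The variance ledger

`sequential_ledger()` fits two nested OLS models of *raw* last global
cognition (not the residual): base = demographics + ten pathologies; full =
base + candidate features (lead dosages, each region's top CpG entered as
its raw beta value, RNA levels). It reports adjusted R² —
1 − (1 − R²)(n − 1)/(n − p − 1) — for both, the increment, and the
unexplained remainder 1 − full; the three sum to one by construction, and
the increment may be negative because adjusted R² penalises predictor
count.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, with
defaults chosen once to match the study conditions: 979 subjects, ~88% on
platform A; age at death ~ N(88.8, 6.4), 64% female, education
~ N(16.4, 3.6), two cohorts; pathology + demographics targeting 41% of
cognitive variance.

* **Dosages** are sums of two Bernoulli(MAF) haplotype indicators drawn
  through a Gaussian copula whose latent correlation decays geometrically
  along the block (AR(1), default 0.8). Realised dosage correlations are
  attenuated relative to the latent parameter by the thresholding — the
  generator documents rather than corrects this, since only the ordering
  and magnitude of LD matter downstream. A configurable fraction of
  variants (default 30%) receives truncated N(0, 0.05) noise to mimic
  fractional imputed dosages; empirical MAF is kept ≥ 0.01 (the analysis
  floor) by redrawing rare degenerate columns.
* **Pathologies** derive from one latent burden factor. Regional counts
  for the three count-based pathologies are gamma-distributed (shape
  ~1.0–1.2) through a Gaussian copula — the positively skewed distribution
  the square-root composite is designed for; the neuropathology literature
  describes these counts as positively skewed without committing to a
  family, so gamma is a documented modelling choice. Ordinal and binary lesions come from latent thresholds and
  logistic prevalences (10–35%). TDP-43 stage/severity follow ordinal cuts
  of the same latent, optionally shifted by a designated variant's dosage
  so conditional analyses have known truth; ~15% of subjects lack TDP-43
  measures, mirroring its partial availability.
* **Cognition** is one latent trait: a standardised pathology+demographic
  component scaled to the target variance fraction f via √(f/(1−f)),
  plus every planted effect (per minor allele for SNPs, per SD of the
  feature's latent for CpG/RNA channels), plus N(0, noise_sd) subject
  noise. The 17 test scores are the latent plus test-specific noise
  (SD 0.5) on arbitrary raw scales; z-scoring against empirically
  estimated baseline moments reconstructs the latent with ~1–2%
  attenuation — the tests' recovery tolerances absorb this. Annual visits
  interpolate linearly from baseline to death so decline slopes exist.
* **Methylation** betas are logistic transforms of Gaussian latents with a
  region factor, batch and bisulfite-conversion effects, and
  missing-completely-at-random gaps (default 1%) to exercise imputation.
  **Expression** is 2^(Gaussian) — nonnegative, FPKM-like — with RIN,
  aligned-reads, PMI, and ribosomal-bases effects.

The truth ledger records the planted effects and realised variance
fractions of every draw; a fixed seed makes the bundle bit-identical.

What the generator does *not* emulate: realistic haplotype panels,
population structure (EV1–3 are plain standard normals with small planted
effects, because only their covariate role matters), array probe
artifacts, or cell-type composition. Passing tests therefore demonstrate
the pipeline's statistical correctness and calibration under the assumed
model — not robustness to the full messiness of real cohort data.

## Numerical and design notes

* All single-predictor inference goes through one OLS core with
  complete-case handling, explicit zero-variance and rank-deficiency
  errors (collinear columns are named), and a minimum of 20 complete
  cases. Scans and permutations use the Frisch–Waugh residualization
  identity, which is exact, and chunk permutation matrices (2,000 columns)
  to bound memory.
* All randomness flows from one root seed. Derived seeds are spread by a
  large multiplier because adjacent integer seeds initialise correlated
  Mersenne–Twister streams — observed directly as correlated replicate
  cohorts before the fix.
* Degenerate inputs fail loudly and early: monomorphic dosages, constant
  CpGs or expression, p-values of exactly 0 in the Fisher combination,
  B ≤ 0 permutations, subjects with no methylation data, misaligned
  subject ids across omics tables (offending ids are listed).
* Problem sizes in the test suite — cohorts of 150–2,000 subjects, B of
  200–20,000, 50-seed end-to-end repetitions — were chosen so each
  property is measured with useful precision while the whole suite stays
  quick to run.

## Limitations

The pipeline inherits the multistep design's asymmetries (FDR for
methylation, raw p for expression), uses linear models throughout, treats
LD through dosage correlation only, and validates against a generator
whose simplifications are listed above. The omnibus test's Fisher
combination ignores inter-CpG correlation by construction and relies
wholly on the permutation null for calibration — which the test suite
verifies empirically (type-I error within binomial bounds of 5%, omnibus
super-uniform under the null).
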