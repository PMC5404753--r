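# residcog

Multi-omic dissection of **residual cognition** — the part of late-life
cognitive performance that neuropathology and demographics do not explain.

## The scientific problem

Cognitive impairment in older adults is only partially explained by the
common neuropathologies (Alzheimer-type tangles and plaques, vascular
lesions, Lewy bodies, hippocampal sclerosis). Two people can carry the same
pathological burden and perform very differently. `residcog` operationalises
that dissociation as a quantitative trait: fit the multivariate linear model

```
last global cognition ~ age at death + sex + education + cohort
                        + tangles + neuritic plaques + diffuse plaques
                        + CAA + atherosclerosis + arteriolosclerosis
                        + macroinfarcts + microinfarcts + Lewy bodies
                        + hippocampal sclerosis
```

and take the residual as the trait ("residual cognition", in cognition
z-score units). The package then runs a multistep convergence analysis to
find genes whose molecular variation tracks this trait:

1. **Genetic scan.** Per-variant additive regression of residual cognition
   on imputed dosage with ancestry covariates (EV1–3), run separately per
   genotyping platform and combined by fixed-effect inverse-variance
   meta-analysis (β = Σβᵢ/seᵢ² / Σ1/seᵢ², se = 1/√Σ1/seᵢ²). Variants with
   p < 10⁻⁵ (suggestive; genome-wide 5×10⁻⁸ is also reported) are grouped
   into independent loci by greedy LD clumping at r² > 0.2, and each locus'
   lead SNP is annotated with genes within 100 kb. Genes with non-zero
   expression in >80% of subjects continue; the lead SNP is also tested as
   a cis-eQTL for the genes in its window.
2. **Methylation omnibus.** For each candidate gene, every CpG within
   100 kb of the gene span is regressed against residual cognition with
   technical covariates (batch, bisulfite conversion); the per-CpG p-values
   are combined by Fisher's method, T = −2·Σ ln pᵢ, and T is calibrated by
   permuting the trait (default B = 10,000), giving an empirical p
   (1 + #{T_perm ≥ T_obs})/(B + 1); regions are declared at FDR < 0.05 and
   re-tested with the lead SNP and EV1–3 as additional covariates to show
   the epigenetic signal is not genetically driven.
3. **Expression association.** Batch-adjusted FPKM against residual
   cognition with RNA technical covariates (RIN, log₂ aligned reads,
   postmortem interval, ribosomal bases), significant at p < 0.05.

A gene with all three signals is called **convergent**. A sequential
adjusted-R² ledger quantifies how much variance in last global cognition the
candidate features (lead dosages, top CpGs, RNA levels) add beyond pathology
and demographics.

Because the motivating cohort data are controlled-access, the package ships
a seeded synthetic multi-omic cohort generator (`simulate_cohort()`) with
planted SNP/CpG/RNA effects and a truth ledger, so every stage is testable
against known ground truth.

## Worked example

```r
library(residcog)

cfg <- sim_config(
  n_subjects = 2000, n_variants = 40, n_cpgs_per_region = 10,
  maf_range = c(0.2, 0.4),
  planted_effects = list(
    list(target_id = "var0001", effect_size = 0.3,  channel = "snp"),
    list(target_id = "cg01_004", effect_size = 0.2, channel = "cpg"),
    list(target_id = "GENE01",  effect_size = 0.2,  channel = "rna")),
  seed = 42)
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort, thresholds = list(B = 1000), seed = 7)
print(report)
```

which prints (elapsed ≈ 3 s):

```
Multistep residual-cognition convergence report
  residual model: n=2000, R2=0.420
  scan: 40 variants, 2 suggestive, 1 independent loci
  candidates:
    GENE01 [lead var0001, p=1.1e-17] omnibus q=0.000999 expr p=1.39e-13 -> convergent
  variance: base 42.5%, increment 5.3%, unexplained 52.2%
```

Reading: the residual-cognition model explains ~42% of cognitive variance
(the configured target is 41%); the planted variant and one LD partner are
the only suggestive associations and clump into a single locus; its gene
shows methylation (permutation q ≈ 0.001) and expression (p ≈ 10⁻¹³)
associations, so it is called convergent; and the planted molecular
features add ~5 percentage points of adjusted R² over pathology and
demographics, leaving ~52% unexplained — the variance decomposition the
pipeline is designed to produce.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/residcog.R simulate --config sim.yaml --out cohort/ --seed 1
Rscript inst/cli/residcog.R run      --config sim.yaml --out results/ --seed 1
```

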