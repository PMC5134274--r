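# gpresel — genomic prediction with preselected sequence variants

Dense imputed-sequence genotypes should contain the causal variants for
quantitative traits, which makes it tempting to preselect variants from a
GWAS and build genomic predictions from the selected set alone. `gpresel`
is an R package for studying what that preselection actually does to
variance partitioning and to prediction accuracy and bias, in the setting
where it is most used: progeny-tested dairy bulls with de-regressed proofs
(DRP) as pseudo-phenotypes, a discovery/validation split by birth cohort,
and strong half-sib family structure linking the two.

It is aimed at quantitative geneticists who want the full analysis chain as
inspectable, tested R code, runnable end to end on simulated populations
with known truth.

## What is implemented

* **De-regression** — `DRP = PA + (EBV − PA) · EDC_EBV / EDC_prog` with
  effective daughter contributions `EDC = α·REL/(1−REL)`,
  `α = (4−h²)/h²`, `REL_PA = (REL_sire + REL_dam)/4`; non-deregressable
  records (`EDC_prog ≤ 0`) are excluded with logged reasons.
* **Genomic relationship matrices** — off-diagonals
  `Σᵢ (x_ij − 2pᵢ)(x_ik − 2pᵢ) / (2pᵢ(1−pᵢ)) / N`, with either the
  distinct unbiased diagonal or the PSD crossprod form `WW′/N`;
  MAF filtering; LD (`r²`) utilities; complementary-set construction with
  a 2-Mb, `p < 0.01` LD-exclusion rule; eigenvalue bending to positive
  definiteness.
* **GREML** — average-information REML (EM fallback, component floors,
  AI-matrix standard errors) for one or two relationship matrices;
  genomic heritability with delta-method errors.
* **Mixed-model association** — null model fitted once, variance
  components frozen, per-variant GLS with Wald χ²(1) p-values;
  Manhattan/QQ export; expected-by-chance exceedance counts.
* **Conditional-and-joint selection** — forward selection by conditional
  significance under LD caps (r² 0.8 / 0.5), a 100-Mb independence
  assumption for distant pairs, collinearity guards, variance-gain gating,
  and a top-N mode; full audit trail.
* **Prediction** — GBLUP on the discovery cohort, per-variant effects
  back-solved from breeding values (`u = W′K⁺ĝ/N`), PLINK-scoreable
  effect files, validation accuracy (cor(DRP, GEBV)) and bias
  (regression slope of DRP on GEBV).
* **Simulator** — half-sib pedigrees with a validation last generation,
  Markov-LD founder haplotypes, Haldane gene dropping, QTL-plus-polygenic
  trait architectures, and progeny-based bull records, so every stage is
  testable without any external data.
* **Pipeline** — the 33-set scenario grid (3 sources × selection rules ×
  traits) and a one-call `run_scenario()` executing
  deregress → scan → select → GRM/GRMc → GREML → GBLUP → validate.

File formats: PLINK bed/bim/fam (v1.00 SNP-major), GCTA-style binary GRM
triplets, and TSV everywhere else.

## Worked example

```r
library(gpresel)

# de-regression of a single bull record (h2 = 0.25 => alpha = 15)
rec <- data.frame(EBV = 100, PA = 40, REL_EBV = 0.9,
                  REL_sire = 0.8, REL_dam = 0.4, h2 = 0.25)
deregress(rec)[, c("alpha", "EDC_EBV", "EDC_PA", "EDC_prog", "DRP")]
#>   alpha EDC_EBV   EDC_PA EDC_prog DRP
#> 1    15     135 6.428571 128.5714 103

# a small simulated population, then one full scenario
sim <- sim_dataset(n_sires = 8, sons_per_sire = 15, n_generations = 2,
                   n_chrom = 2, variants_per_chrom = 400, n_qtl = 8,
                   h2 = 0.5, seed = 42)
rep <- run_scenario(sim, source = "ISQ", selection = "PVAL3",
                    model = "GRM_PLUS_GRMC")
rep
#> scenario: ISQ / PVAL3 / GRM_PLUS_GRMC
#>   36 selected of 800 source variants; complement 764
#>   validation h2 total = 1.000; accuracy = 0.936, slope = 0.975
```

The bull's DRP expands the 60-unit deviation from its parent average by
`135/128.57 = 1.05` to 103. In the scenario, 36 of 800 sequence variants
pass `-log10(p) > 3` in the discovery scan; the selected-set GRM and its
complement are then fitted jointly on the validation cohort (here the DRP
are information-rich, so the two matrices absorb the full DRP variance),
and GBLUP trained on discovery predicts validation DRP with accuracy 0.936
and a regression slope of 0.975 (close to 1, i.e. nearly unbiased).

## The analysis workflow

The `analysis/` scripts run the study end to end on a fixed-seed desk-scale
population and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # population, LD decay, cohort summaries
Rscript analysis/02_deregress.R  # DRP and information-content checks
Rscript analysis/03_gwas.R       # discovery scan, exceedance counts, Manhattan export
Rscript analysis/04_select.R     # selected-set counts for every selection rule
Rscript analysis/05_variance.R   # GRM / GRMc / joint variance partitions
Rscript analysis/06_predict.R    # validation accuracy and bias, replicated bias study
```

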