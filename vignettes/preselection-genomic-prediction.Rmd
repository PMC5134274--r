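---
title: "Genomic prediction with preselected variants: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with preselected variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Dense (imputed) sequence genotypes in dairy cattle hold the causal variants
for quantitative traits, so one might expect genomic prediction to improve
when variants are *preselected* from a genome-wide association study (GWAS)
and fitted on their own, rather than diluted across hundreds of thousands of
array SNPs. In practice, selecting variants with the same data that trains
the predictor invites two failure modes: the selected set captures only part
of a largely polygenic signal, and the selected effects are inflated by
winner's curse, which over-disperses predictions (validation regression
slopes below 1). `gpresel` implements the full analysis chain — de-regressed
proofs, mixed-model association, conditional variant selection under
linkage-disequilibrium (LD) rules, variance partitioning with complementary
genomic relationship matrices, and GBLUP prediction via back-solved marker
effects — together with a population simulator so the chain can be exercised
end to end against known truth.

# Models

## De-regressed proofs

Progeny-tested bulls carry estimated breeding values (EBV) whose parent
average (PA) component must be removed before the records can serve as
pseudo-phenotypes. With trait heritability $h^2$ and
$\alpha = (4 - h^2)/h^2$, an EBV of reliability $r$ is backed by
$\mathrm{EDC} = \alpha r/(1 - r)$ effective daughters. The de-regressed
proof re-expands the deviation from the parent average by the ratio of total
to progeny-only information:

$$\mathrm{DRP} = \mathrm{PA} + (\mathrm{EBV} - \mathrm{PA})
  \cdot \frac{\mathrm{EDC}_{\mathrm{EBV}}}{\mathrm{EDC}_{\mathrm{prog}}},
  \qquad
  \mathrm{EDC}_{\mathrm{prog}} = \mathrm{EDC}_{\mathrm{EBV}} -
  \mathrm{EDC}_{\mathrm{PA}},$$

with $\mathrm{REL}_{\mathrm{PA}} = (\mathrm{REL}_{\mathrm{sire}} +
\mathrm{REL}_{\mathrm{dam}})/4$. Records with
$\mathrm{EDC}_{\mathrm{prog}} \le 0$ carry no progeny information of their
own; `deregress()` excludes them with a logged reason rather than clipping,
following the de-regression literature. Missing parent reliabilities are
taken as 0 (no parent information), the conservative choice. The effective
daughter contributions are carried through to the outputs, but variance
estimation is unweighted by default; per-record weighting is available as an
option.

## Genomic relationship matrices

For dosages $x_{ij} \in [0,2]$ and allele frequencies $p_i$, off-diagonals
average $(x_{ij} - 2p_i)(x_{ik} - 2p_i)/(2p_i(1-p_i))$ over the $N$
variants. Two diagonals are offered: the distinct unbiased estimator
$1 + \tfrac1N \sum_i (x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2)/(2p_i(1-p_i))$
(`diag_mode = "yang"`, the default, matching the estimator conventional in
GREML software) and the crossprod form $WW'/N$ with standardized dosages
(`diag_mode = "crossprod"`), which is positive semi-definite by construction
and is required wherever marker effects are back-solved exactly. Frequencies
are always recomputed on the analysis sample; matrices record which variant
set they came from (selected, complementary, or all). `ensure_pd()` floors
eigenvalues at `eps * mean(diag)` (default `eps = 1e-6`) and reports every
bending event, since variance components estimated on a bent matrix deserve
scrutiny.

The *complementary* matrix (GRMc) is built from the variants **not**
selected. For threshold selections only the selected ids are removed; for
conditional selections, variants in significant LD with a selected variant
($n r^2$ against $\chi^2_1$, $p < 0.01$, searched within a 2-Mb window on
either side) are removed too, otherwise the complement still tags the
selected loci. Windows are closed intervals in 1-based bp.

## GREML and the association scan

Variance components for $y = X\beta + \sum_k g_k + e$,
$g_k \sim N(0, K_k\sigma_k^2)$, are estimated by average-information REML
with an EM first step, EM fallback on inadmissible or likelihood-decreasing
AI proposals, components floored at $10^{-6}\,\mathrm{var}(y)$ (activations
logged), convergence at $|\Delta\ell| < 10^{-8}$, and at most 100
iterations. Standard errors come from the inverse AI matrix; heritabilities
$\sigma_k^2 / \sum \sigma^2$ carry delta-method errors. A singular AI matrix
(e.g. $K = I$, which aliases the genetic and residual components) is
reported via the `aliased` flag and infinite standard errors, never a crash.

The association scan fits the null model once, freezes
$V = K\sigma_g^2 + I\sigma_e^2$, and tests each variant by generalized least
squares: after whitening with $V^{-1/2}$ and projecting out the intercept,
$\hat b = \tilde x'\tilde y / \tilde x'\tilde x$ with known-variance Wald
$\chi^2_1$ p-values. Because the covariance is fully specified, no residual
variance is re-estimated per variant; estimates are invariant to shifting
$y$ or centering dosages. The structure matrix is built from a designated
array-panel subset (emulating a high-density chip), and candidate variants
may be inside it — proximal contamination is accepted, as in the reference
analysis design; a leave-one-chromosome-out mode is deliberately not the
default. Zero-variance variants yield flagged records with $p = 1$;
p-values that underflow are reported at the smallest positive double.

## Conditional-and-joint selection

Forward selection works on individual-level data under the fixed null
covariance, which at desk scale is simpler and better conditioned than the
summary-statistic approximation used by GWAS-scale software (and agrees with
it when the LD reference equals the analysis sample). Each step
residualizes all remaining candidates against the current model
(incremental Gram–Schmidt), takes the most conditionally significant one
(ties broken by chromosome, position, id — selection order is
deterministic), and applies the gates:

* **LD cap** — candidates with $r^2$ above the cap (0.8 for the
  prefiltered modes, 0.5 for the distance-capped modes) with any selected
  variant are retired permanently; pairs farther apart than 100 Mb (or on
  different chromosomes) are treated as independent in the capped modes.
* **Collinearity** — a candidate whose residual squared norm falls below
  $10^{-8}$ of its original norm is rejected; this is the Gram–Schmidt
  equivalent of a condition-number cap of about $10^8$ on the joint design
  and guards against the grossly inflated conditional effects that
  collinear adds produce in highly related samples.
* **Entry** — conditional $-\log_{10}(p)$ at or above the mode's threshold
  (3 or 5) and a strict decrease of the joint residual variance (tolerance
  $10^{-12}$); the top-$N$ mode drops the significance gate, ranks by
  conditional significance by default, and optionally by absolute
  conditional effect, since "largest effect" is ambiguous between the two.

Every rejection lands in an audit trail with its reason, and the joint
effects of the final model come from one joint GLS fit.

## Prediction and validation

GBLUP is trained on discovery-cohort DRP with components from REML:
$\hat g_k = \sigma_k^2 K_k V^{-1}(y - X\hat\beta)$. Per-variant effects are
back-solved on the standardized scale, $u = \tfrac1N W' K^{+} \hat g$, and
converted to per-dosage effects $a_i = u_i/\sqrt{2p_i(1-p_i)}$ under the
training frequencies; scoring is
$\mathrm{GEBV}_j = \sum_i a_i (x_{ij} - 2p_i) + \hat\beta_0$, so the
intercept choice is explicit (the GLS training intercept). Back-solving is
exact only for crossprod-built, full-column-space matrices; with a
Yang-diagonal matrix the crossprod form is substituted with a warning and
the maximum training-GEBV reconstruction error is reported. Two-component
models back-solve each component separately and sum the scores. Validation
reports the correlation of DRP with GEBV (accuracy) and the ordinary
regression of DRP on GEBV (slope below 1 = over-dispersed predictions).
DRP are treated as noiseless targets — no reliability correction is applied
to accuracy, consistent with validation on heavily progeny-tested bulls.

# The simulator

The simulator is first-class, tested code: every downstream stage is
exercised against truth it generates.

* **Pedigree** — paternal half-sib families: each generation, a fixed set
  of sires is mated to newly introduced unrelated dams; sons of one
  generation sire the next. The last generation forms the validation
  cohort, so essentially all validation animals have a discovery-cohort
  sire — the family overlap that makes validation-by-relatives optimistic.
* **Founder LD** — a first-order Markov copying model on haplotypes: the
  allele at a site is copied from the previous site with probability
  `ld_rho`, else drawn fresh. Adjacent-site correlation is about `ld_rho`
  with geometric decay; sites below the MAF floor are redrawn as
  independent sites. This creates the high-LD selection pathology at
  $O(nm)$ cost; it is not a coalescent and makes no claim about deep
  genealogy.
* **Gene dropping** — Haldane's map function on bp-proportional genetic
  distance (uniform recombination rate, default 1 Morgan per chromosome;
  no map detail is assumed), crossovers sampled per gap, LD never crossing
  chromosome boundaries.
* **Trait architecture** — `n_qtl` large-effect loci (normal per-allele
  effects) carrying `qtl_var_frac` of the genetic variance on top of a
  standardized polygenic background over all other variants. The default
  `qtl_var_frac = 0.3` reflects what sequence-based GWAS find for yield,
  fertility and udder-health traits: a handful of moderate QTL over a
  dominant polygenic background. A pure oligogenic trait
  (`qtl_var_frac = 1`) is available and makes threshold selection almost
  lossless — useful as a contrast, but not representative.
* **Bull records** — per bull, an effective daughter contribution drawn
  uniformly from `edc_range` (default 24–971, a realistic progeny-test
  span), reliability $\mathrm{EDC}/(\mathrm{EDC}+\alpha)$, and an EBV
  regressed toward the mean with noise chosen so that
  $\mathrm{cor}(\mathrm{EBV},\mathrm{TBV})^2$ equals the reliability.
  Parent averages and parent reliabilities are generated consistently, with
  the parent-average reliability capped below the bull's own so that
  de-regression always succeeds on simulated records.

Desk-scale defaults are 2–4 chromosomes with a few thousand variants each
and around two thousand individuals; the replicated studies in the test
suite use 20,000 variants and about 1,500 training / 500 validation
animals. What the simulator does **not** emulate: imputation error, real
bovine LD spectra and recombination maps, selection (the pedigree mates at
random within its design), multi-breed structure, and — importantly — the
sheer scale of a 13.8-million-variant scan. Scale matters for the
preselection pathology: at millions of correlated tests a $-\log_{10}(p) >
5$ threshold admits winners that are heavily luck-loaded, whereas at 20,000
tests the same threshold admits almost none by chance. The replicated bias
study therefore shows the accuracy cost of stringent preselection very
clearly, while the slope attenuation it produces is mild compared with what
full-scale data exhibit; passing desk-scale tests demonstrates the
machinery, not the full-scale effect sizes.

# Numerical choices

* Positions are 1-based bp; LD windows are closed intervals.
* Allele flips ($x \to 2-x$, $p \to 1-p$) leave every relationship matrix
  unchanged; scans are invariant to response shifts.
* Missing dosages are mean-imputed at load (imputed-dosage inputs are
  assumed complete).
* REML: tolerance $10^{-8}$ on the restricted log-likelihood, `maxit` 100,
  equal-split initialization, component floor $10^{-6}\mathrm{var}(y)$.
* PD bending: relative eigenvalue floor $10^{-6}$, logged.
* Selection: entry tolerance $10^{-12}$ on residual-variance decrease;
  collinearity at $10^{-8}$ relative residual norm; deterministic
  tie-breaks by (chromosome, bp, id).
* File formats: PLINK bed v1.00 SNP-major; GCTA-style binary GRM triplet
  (float32 lower triangle); TSV for records, association results, selection
  reports and variance tables.

# Scenario grid

`scenario_grid()` enumerates the default design: three variant sources
(dense sequence `ISQ` and two nested array panels `HD`, `K50`); per trait,
threshold selections at $-\log_{10}(p) > 3$ and $> 5$ on each source plus
four conditional modes on the sequence source; and one trait-independent
all-variant set per source — 33 variant sets for the default three traits.
Each set can be fitted as its GRM alone, its complement alone, or both
jointly; `run_scenario()` executes the full chain for one configuration and
reports variant bookkeeping, validation variance partitions and prediction
metrics. An all-variant sequence scenario has an empty complement by
construction and therefore supports only the single-matrix model.

# Known limitations

* REML is dense ($O(n^3)$ per iteration) and intended for desk-scale
  cohorts, not national evaluations.
* The conditional selection uses individual-level data; summary-statistic
  selection with an external LD reference is out of scope.
* Validation-cohort variance estimation refits REML on the validation
  block of the relationship matrices, making explicit a step that
  GWAS-scale software performs implicitly when phenotype availability
  restricts the sample.
* Intercepts of simulated traits are mean-zero; published-scale trait
  means (and hence intercept values of validation regressions on real
  data) are not reproduced.
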