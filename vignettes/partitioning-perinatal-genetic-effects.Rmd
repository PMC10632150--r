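---
title: "Partitioning fetal, maternal and paternal genetic effects on placental weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning fetal, maternal and paternal genetic effects on placental weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopart)
```

## The problem

Placental weight (PW), like birth weight, is influenced by three genomes:
the fetus's own genotype acting directly, the maternal genotype acting
through the intrauterine environment, and potentially the paternal
genotype. Because parent and offspring genotypes are correlated by 1/2,
a GWAS of any single genome estimates a mixture of the three underlying
conditional effects. `triopart` implements the machinery to separate
them — from summary statistics when trios are unavailable, and from
phased trio genotypes when they are — together with the downstream
analyses that interpret the partitioned signals (latent heritability
decomposition, colocalization, PW-vs-BW classification, Mendelian
randomization, expression enrichment), and a trio simulator that gives
every stage a ground-truth test surface.

## The model

Write $\eta_c$, $\eta_m$, $\eta_f$ for the conditional fetal, maternal
and paternal per-allele effects of a variant on standardized PW. Under
random mating the marginal per-genome GWAS slopes mix these through

$$\beta = A\,\eta, \qquad
A = \begin{pmatrix} 1 & 1/2 & 1/2 \\ 1/2 & 1 & 0 \\ 1/2 & 0 & 1 \end{pmatrix},$$

whose inverse gives the weighted linear model (WLM):

$$\eta_c = 2\beta_c - \beta_m - \beta_f,\quad
\eta_m = -\beta_c + \tfrac32\beta_m + \tfrac12\beta_f,\quad
\eta_f = -\beta_c + \tfrac12\beta_m + \tfrac32\beta_f.$$

The same fixed-path matrix drives the latent heritability decomposition:
an observed 3×3 genetic covariance matrix of the child/mother/father
GWAS (estimated upstream, e.g. by LD score regression, and consumed here
as input) satisfies $\Sigma_{obs} = A\,\Sigma_{lat}\,A^\top$, so with all
paths fixed the model is saturated and
$\Sigma_{lat} = A^{-1}\Sigma_{obs}A^{-\top}$ is the exact, unique
solution. `solve_latent()` therefore inverts in closed form; a DWLS mode
that minimizes the weighted moment distance numerically is provided as a
cross-check and must (and does, in the tests) agree, because a saturated
model fits the moments exactly for any positive weight matrix. Negative
latent variances are possible when the input matrix is noisy or the
additive model is wrong; they are reported and flagged rather than
silently truncated, with optional projection to the nearest PSD matrix.

### Standard errors under sample overlap

The WLM components are fixed linear combinations of three estimates that
are *correlated* whenever the GWAS share individuals (and, for
child–parent pairs, even without sharing a phenotype: the genotypes
themselves are correlated). With pairwise estimate correlations
$t_{ij} = n_{s,ij}\rho_{ij}/\sqrt{n_i n_j}$ (equivalently a bivariate
LD score regression intercept, accepted verbatim), the delta method
gives, e.g.,

$$\mathrm{Var}(\eta_c) = 4\sigma_c^2 + \sigma_m^2 + \sigma_f^2
 - 4\sigma_{cm} - 4\sigma_{cf} + 2\sigma_{mf},
 \qquad \sigma_{ij} = t_{ij}\sigma_i\sigma_j,$$

and analogously for $\eta_m$, $\eta_f$. This complete form is the
default (`se_mode = "full"`). A reduced form that keeps only one
covariance term per component (mother–father for $\eta_c$, child–father
for $\eta_m$, child–mother for $\eta_f$) circulates in the literature;
`se_mode = "paper"` reproduces it for comparability. The full form is
the mathematically coherent reading of the delta method and is what the
Monte-Carlo calibration tests validate: for fully overlapping trio
samples the implied $t_{cm} = t_{cf} = 0.5$, $t_{mf} = 0$ (null-variant
estimate correlations equal the genotype correlations), and with these
inputs the 95% CIs cover the generative effects at close to nominal
rate, matching the joint trio regression's variance exactly in the
equal-SE limit.

### Trio transmission analysis

With phased trios the conditional effects are estimable directly
(`fit_trio_conditional()`: PW ~ child + mother + father + covariates),
and the alleles can be decomposed further into maternal/paternal
transmitted and non-transmitted counts (mt, mnt, pt, pnt). Under a pure
fetal effect mt and pt carry equal weight; a maternal indirect effect
loads equally on mt and mnt; a parent-of-origin effect (POE), as at
imprinted loci, separates mt from pt. `fit_poe_conditional()` tests the
maternally transmitted allele net of all three additive dosages
(PW ~ mt + child + mother + father), which is the sharpest POE test the
design allows.

**Mendelian-error handling.** A phase-label flip is detectable at a
variant only in trios with a heterozygous child *and* at least one
homozygous parent: a homozygous child's two alleles are identical (a
flip is both harmless and invisible), and doubly heterozygous parents
are compatible with any labelling. The error share is therefore
computed over exactly those informative trios. This matters: counting
all homozygous-parent trios would cap the expected share of a fully
mis-phased variant at 0.5 (attained only at allele frequency 0.5), so
the ">50% errors ⇒ swap child alleles" repair rule could never fire.
Over detectable trios the share of a fully flipped variant approaches 1,
the swap rule triggers strictly above 0.5, and swapping is idempotent.
Trios flagged as Mendelian errors at a variant are excluded from that
variant's transmission fits, to avoid contaminating the allele coding.

## The synthetic cohort generator

`simulate_study()` generates mother/father dosages as Binomial(2, p)
under Hardy–Weinberg equilibrium and random mating, transmits one
uniformly chosen allele per parent with tracked origin, and builds the
latent phenotype

$$z = \textstyle\sum_j \big[\eta_{c,j}(g_c - 2p_j) + \eta_{m,j}(g_m - 2p_j)
 + \eta_{f,j}(g_f - 2p_j) + \delta_j(h_{mt} - p_j)\big]
 + \beta_{sex}\,\mathrm{sex} + \beta_{ga}\,\mathrm{ga}_{std} + \varepsilon .$$

Defaults define the reference study conditions: residual SD 1,
$\beta_{sex} = 0.1$, $\beta_{ga} = 0.3$ s.d. per standardized day,
gestational duration N(280, 9²) days, PW materialized as
$670 + 132.5\,z$ grams (132.5 g is the conversion constant between the
s.d. and gram scales used throughout; 670 g is a plumbing default for a
term placenta, configurable). Birth weight is generated with its own
effect vectors (by default the PW effects scaled by 0.6) and a residual
correlated 0.3 with the PW residual — values chosen once as realistic
for the PW/BW phenotypic relationship, not fitted to anything. The POE
term acts on the maternally transmitted allele only, matching the
imprinted-locus mechanism the transmission model probes. Phasing errors
are modeled as origin-label flips; base-calling errors are not modeled,
because the swap rule addresses mis-phasing, not genotyping noise.

What the generator deliberately omits: LD between variants (they are
independent, placed at configurable spacing on one synthetic chromosome
so locus clustering can be exercised), imputation uncertainty,
assortative mating, and non-European allele-frequency spectra. Passing
recovery tests therefore demonstrate correctness of the estimators
under the stated sampling model, not robustness to LD or population
structure.

## Numerical and design choices

* **Scale of recovery experiments.** The generative effects are defined
  on the latent s.d. scale. Recovery experiments standardize the
  simulated phenotype by the known generative SD (132.5 g), so estimates
  and truth share a scale exactly. Within-cohort z-scoring — the
  real-data path, applied by `zscore_phenotype()` — divides by the
  *total* phenotypic SD (which exceeds 1 when genetic and covariate
  variance are present) and attenuates all effects by that factor; it is
  tested separately for its own contract (per-cohort mean 0, SD 1).
* **QC bounds.** PW outside (200, 1500) g, PW beyond 5 s.d. of the
  within-cohort pre-exclusion mean (single pass, for determinism),
  gestational duration outside 259–300 days inclusive (37 completed
  weeks to 42 weeks 6 days).
* **Meta-analysis.** Closed-form inverse-variance fixed effects with
  Cochran's Q; alleles are harmonized by swap only — palindromic strand
  flips are rejected with a warning since the format carries no strand
  information. Variants in fewer than 2 studies or with n < 5000 are
  dropped.
* **Loci.** Significant variants (p < 5×10⁻⁸) are clustered by single
  linkage with a 500 kb window; lead SNP is the smallest p, ties broken
  by smaller position (the merging rule is stated only as a distance in
  the source methods; single linkage is the configurable choice here).
* **Classification.** Bonferroni denominator defaults to 37 (the number
  of signals classified in the motivating analysis) and is
  configurable; the threshold is computed as 0.05/n_tests. CI-overlap
  tests use closed intervals, so touching endpoints count as
  overlapping.
* **Colocalization.** Wakefield approximate Bayes factors with prior
  effect SD 0.15 (quantitative-trait convention) and priors
  p1 = p2 = 10⁻⁴, p12 = 10⁻⁵; verdicts: PP4 > 0.8 colocalized,
  PP3 > 0.8 distinct, else undetermined. Hypothesis sums are computed
  in log space with the exact pairwise-product correction for H3.
* **MR.** IVW is weighted regression through the origin (fixed-effect
  SE); Egger uses the multiplicative random-effects convention with the
  residual SD floored at 1; weighted-median SEs come from a parametric
  bootstrap (seeded, 1000 draws by default); the penalized variant
  downweights instruments by 20·min(1, p) of their χ²₁ heterogeneity
  contribution. Note that under *directional* pleiotropy carried by a
  40% minority of instruments the weighted median retains a bias of the
  order of the ratio-estimate noise (it targets an off-centre quantile
  of the valid instruments' ratio distribution); the robustness
  property holds cleanly for balanced-sign invalid instruments, and the
  tests reflect exactly that distinction.
* **Liability scale.** Observed↔liability conversion uses the standard
  factor $K(1-K)/\varphi(\Phi^{-1}(1-K))$; at the preeclampsia
  prevalence K = 0.046 the forward/inverse pair is an exact identity.
* **Enrichment.** Per-gene midranks scaled to (0, 1]; the rank-sum test
  is two-sided with the direction reported, so a one-sided p is p/2
  when the direction matches.

## Problem sizes used in the test suite

Recovery experiments use one cohort of 4,000 trios per replicate with
200 replicates for WLM calibration, 1,000 replicates of 500 trios for
POE type-I calibration, 100 regions of 50 variants per colocalization
arm, and 100 random matrices for the latent-model round trip — sizes at
which Monte-Carlo error is small relative to the tested tolerances
while the full suite stays fast.

## Known limitations

The WLM here requires all three marginal GWAS (duo-based variants are
out of scope), the simulator has no LD so locus definition is exercised
on physical spacing only, no X-chromosome or mixed-model adjustments
are provided, and LD score regression itself (the source of the genetic
covariance inputs to `solve_latent()` and of empirical overlap
intercepts) is not implemented — those quantities are inputs, not
outputs, of this package.
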