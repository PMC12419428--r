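---
title: "Methods: two-sample MR, meta-analysis and colocalization in tsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, meta-analysis and colocalization in tsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

# The problem

Observational associations between exposures (here, self-reported dietary
habits) and disease are confounded. Mendelian randomization (MR) sidesteps
much of that confounding by using genetic variants as instrumental
variables: alleles are assigned at conception, so a variant that raises an
exposure can reveal the exposure's causal effect on an outcome, provided the
variant (i) is robustly associated with the exposure, (ii) shares no common
cause with the outcome, and (iii) affects the outcome only through the
exposure. `tsmr` implements the two-sample flavour, where exposure and
outcome associations come from separate GWAS summary-statistic tables, plus
the two follow-on analyses such a study typically runs: pooling of
per-study estimates across cohorts measuring the same disease, and Bayesian
colocalization to ask whether a disease locus and the exposure share one
causal variant.

# Instrument selection and harmonization

Instruments are selected at a configurable association threshold (default
$p < 5\times10^{-6}$, the relaxed threshold used for exposures with few
genome-wide-significant hits), pruned by greedy LD clumping
($r^2 < 0.001$ within 10,000 kb by default) against a user- or
simulator-supplied LD matrix, and filtered against a plain-text exclusion
list standing in for confounder lookups against variant-phenotype databases
— the package performs no network queries, which keeps every analysis
reproducible offline.

Harmonization aligns each outcome record to the exposure's effect allele:
swapped alleles negate the outcome effect and flip its allele frequency,
strand flips are resolved by complementing, and palindromic (A/T, C/G)
variants are kept only when both allele frequencies fall outside the
0.42–0.58 ambiguity band and agree in direction. The band edge is the
conventional choice; it is exposed as `palindromic_eaf_limit`. Variants
with missing allele frequency cannot be disambiguated and are dropped as
palindromic. Clumping sorts candidates by (p-value, chromosome, position,
rsid) before the greedy pass, so its output does not depend on input row
order.

# The estimators

All five reported estimators combine per-SNP Wald ratios
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ (outcome effect over exposure
effect), with first-order standard errors
$\sigma_j = \mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$ that ignore
exposure-side noise — the conventional default, adequate when instruments
are strong.

* **IVW**: inverse-variance-weighted mean of the ratios. The fixed-effect
  standard error is $\sqrt{1/\sum w_j}$; the multiplicative random-effects
  version inflates it by $\sqrt{\max(1, Q/(k-1))}$. The `auto` model
  follows the usual switching rule — random effects when Cochran's $Q$ has
  $p < 0.05$.
* **MR-Egger**: weighted regression of outcome on exposure effects *with*
  an intercept, after orienting all pairs to positive exposure effects (the
  orientation the estimator requires; negating both effects on a flip).
  The intercept estimates average directional pleiotropy; p-values are
  t-based with $k-2$ degrees of freedom and the residual dispersion is not
  floored at 1.
* **Weighted median**: the ratio at standardized cumulative weight 0.5
  (linear interpolation), consistent when at least half the weight is
  valid. Its standard error comes from a seeded parametric bootstrap
  (default 1000 draws of $\hat\beta_j \sim N(\hat\beta_j, \sigma_j^2)$).
* **Simple / weighted mode**: the argmax of a Gaussian kernel density over
  the ratios on a 512-point grid spanning the data range ± 3 bandwidths,
  with Silverman-type bandwidth
  $\phi \cdot 0.9\min(\mathrm{SD}, \mathrm{IQR}/1.349)k^{-1/5}$;
  $\phi = 1$ by default and exposed because the literature varies. Equal
  standard errors make the two variants coincide; identical ratios
  degenerate to that value.

`mr_fit()` runs whichever estimators the instrument count admits (Wald
ratio at $k=1$, IVW at $k\ge2$, the rest at $k\ge3$) and flags primary
inference on IVW at $\alpha = 0.05$. Confidence intervals exponentiate with
$z = 1.959964$ so rendered OR tables round-trip exactly.

# Sensitivity battery

Cochran's $Q$ (with $I^2$), the Egger intercept test (surfaced from the
Egger fit — single source of truth), Steiger directionality, and
leave-one-out influence. Steiger approximates per-SNP explained variance by
$z^2/(z^2+n)$ on whichever scale the trait is measured (log-odds for
binary traits; the observational-scale refinement is out of scope) and
tests the difference of Fisher-z-transformed pooled correlations. Ties
report `FALSE` with $p = 1$. Multiple testing uses Benjamini–Hochberg
within configurable families; the pipeline groups all exposure × method
tests sharing one outcome dataset, which matches how per-outcome report
blocks are read while keeping the family explicit.

# Meta-analysis

Published per-study results arrive as ORs with 95% CIs, so pooling first
recovers $\log\mathrm{OR}$ and $\mathrm{se} =
(\log u - \log l)/(2\cdot1.959964)$, then pools on the log scale:
fixed-effect inverse variance, and DerSimonian–Laird random effects
($\tau^2$ by the moment estimator, floored at zero). The report's
"sensitivity" column is the heterogeneity p-value of the pooled studies —
the reading that best matches how such tables are used, and it is labelled
as such in the output. Note the random-effects interval is never narrower
than the fixed one, but it is not generally a superset: the two centres
differ whenever weights shift.

# Colocalization

Per SNP and trait, the Wakefield approximate Bayes factor is
$\mathrm{lABF} = \tfrac12(\log(1-r) + r z^2)$ with shrinkage
$r = W/(V+W)$, where $V$ is the effect-estimate variance and $W$ the prior
effect variance ($0.2^2$ for case/control traits; $(0.15\,\mathrm{sd}_Y)^2$
for quantitative ones, with $\mathrm{sd}_Y$ estimable from $V$, allele
frequency and $n$). Under one causal variant per trait, regional evidence
combines by log-sum-exp; the five configuration weights use priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the conventional defaults, all
exposed), and `logdiff` clamps the H3 term to $-\infty$ with a warning in
the (rounding-only) case where the paired sum does not exceed the shared
sum. All sums are overflow-safe; lABFs in the tens of thousands pose no
problem. Both the regional PP.H4 and the per-SNP attribution
SNP.PP.H4$_j = \exp(\mathrm{lABF}_{1j} + \mathrm{lABF}_{2j} - L_{12})$ are
reported, because published loci are sometimes quoted by either number;
regions are extracted with a closed ±500 kb window (boundary SNPs
included).

# ROC evaluation

Candidate-gene discrimination uses standard ROC/AUC machinery (via pROC):
AUC equals the Mann–Whitney statistic with ties at one half, the default
CI is DeLong's, and a stratified percentile bootstrap (default 2000 draws,
seeded) covers tiny groups. Scores are never direction-flipped
automatically — an AUC below 0.5 is reported as computed with an advisory,
since silent flipping hides label errors. An AUC above 0.6 sets the
`discriminative` flag, mirroring the working threshold for calling a
marker diagnostically useful.

# What the simulators emulate — and what they do not

`simulate_mr_pair()` generates summary statistics directly (no
individual-level genotypes): per SNP a minor-allele frequency from
`maf_range`, a true exposure effect with expected per-SNP variance
explained `h2_per_snp`, and sampling noise
$\mathrm{se} = 1/\sqrt{2f(1-f)n}$ — the standardized-trait approximation,
reused on the log-odds scale for binary traits. Two deliberate conventions
matter for interpreting the tests:

* Outcome effects are generated conditional on the *measured* exposure
  effects, so the first-order Wald standard errors are exact and IVW
  interval coverage is nominal by construction. Real data add
  exposure-side noise (regression dilution); the coverage test therefore
  validates the estimator's arithmetic, not robustness to weak
  instruments.
* A relevance floor (`instrument_z`, default 5) redraws true effects until
  each instrument's expected association z-score clears it, emulating the
  p-value selection every real instrument passes. Directional pleiotropy
  is applied on the exposure-increasing allele, as it would manifest in
  data where allele coding is arbitrary but pleiotropy tracks the
  exposure-raising direction.

`simulate_coloc_region()` uses exponential LD decay in *index* distance on
a uniform position grid over the ±500 kb window — a stylized stand-in for
physical-distance LD; z-scores are drawn from $N(R\lambda, R)$ with the
causal non-centrality $\lambda_c = b\sqrt{2f(1-f)n}$. The default effect
size (0.06 at $n = 10^5$) gives causal z-scores around 10–12, the
magnitude seen at strongly colocalized published loci. The expression
simulator is a two-group Gaussian design with the motivating study's
111/46 group sizes; it has no probe-level structure, batch effects or
normalization artefacts, so passing ROC tests demonstrate the estimator,
not robustness to microarray preprocessing.

None of the generators model population structure, imputation error, or
sample overlap between the exposure and outcome GWAS.

# Numerical and design choices

* Positions are 1-based and all windows are closed intervals.
* Alleles are restricted to single nucleotides A/C/G/T; indels are
  rejected at validation.
* Input p-values of exactly 0 (as some portals print) are floored at
  1e-300 with a warning.
* Clumping and report ordering are fully deterministic (stated tie-breaks),
  and every stochastic computation (bootstraps, simulators) takes an
  explicit seed; the pipeline refuses to run without one.
* Problem sizes in the test-suite property checks (for example 500
  replicates of a 30-instrument design at $n = 10^5$ for coverage, 100
  replicates of a 100-SNP region for colocalization power) were chosen as
  the smallest designs at which the Monte-Carlo error is comfortably below
  the property margins being asserted.
* The step-3 gate of the pipeline ("positive findings proceed to
  colocalization") is the pooled fixed-effect FDR-adjusted p-value below
  0.1, configurable — study descriptions are usually ambiguous about
  whether the gate is the pooled or the per-study FDR value, so the choice
  is explicit and logged.

# Known limitations

Exposure-side uncertainty is ignored in the Wald standard errors (no
second-order correction); no MR-PRESSO-style outlier removal,
multivariable MR, or SuSiE-style multi-signal colocalization; the LD model
is single-matrix and panel-free by design; and published per-study results
from proprietary accessions can only be *pooled* (from their printed
OR/CI), not re-derived from genotypes.

# A worked run

```{r, eval = FALSE}
sim <- simulate_mr_pair(n_snps = 30, theta = 0.5, seed = 1)
h <- harmonize(sim$exposure, sim$outcome)
fit <- mr_fit(h, seed = 1)
summary(fit)

reg <- simulate_coloc_region(n_snps = 100, scenario = "H4", seed = 1)
coloc_abf(reg$trait1, reg$trait2)
```
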