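# tsmr

Two-sample Mendelian randomization (MR) with meta-analysis, Bayesian
colocalization, and ROC-based diagnostic evaluation — a desk-scale,
fully offline pipeline over GWAS summary statistics.

The package is written for epidemiologists and statistical geneticists who
want to run (or audit) the common three-step summary-level causal-inference
design: estimate per-pair causal effects from genetic instruments, pool the
per-study estimates within disease groups, and test whether positive loci
share a causal variant with the exposure. Every stage also has a
seed-deterministic simulator, so the whole pipeline is testable without any
external accession.

## The statistics at the core

For instruments $j = 1,\dots,k$ with exposure effects
$\hat\gamma_j$ and outcome effects $\hat\Gamma_j$, each SNP contributes a
Wald ratio $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order
standard error $\sigma_j = \mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$.
`mr_fit()` combines these with the five standard estimators:

- **IVW**: $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$,
  $w_j = 1/\sigma_j^2$; fixed-effect SE $\sqrt{1/\sum w_j}$, multiplicative
  random-effects inflation $\sqrt{\max(1, Q/(k-1))}$ under heterogeneity.
- **MR-Egger**: weighted regression of $\hat\Gamma$ on $\hat\gamma$ with an
  intercept (the intercept estimates directional pleiotropy).
- **Weighted median** and the **simple / weighted mode** estimators, robust
  to minorities of invalid instruments.

Sensitivity: Cochran's $Q$ and $I^2$, Egger intercept test, Steiger
directionality ($r^2 = z^2/(z^2+n)$ per trait), leave-one-out influence,
and grouped Benjamini–Hochberg FDR. Meta-analysis pools published OR/CI
rows on the log scale (fixed-effect inverse variance and
DerSimonian–Laird random effects). Colocalization uses per-SNP Wakefield
approximate Bayes factors,
$\mathrm{lABF} = \tfrac12\{\log(1-r) + rz^2\}$ with $r = W/(V+W)$, combined
into posterior probabilities of the five configurations H0–H4 under priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. ROC/AUC with DeLong or bootstrap
CIs covers candidate-marker evaluation.

## A worked example

```r
library(tsmr)

sim <- simulate_mr_pair(n_snps = 30, theta = 0.5, seed = 1)   # true effect 0.5
h   <- harmonize(sim$exposure, sim$outcome)
fit <- mr_fit(h, seed = 1)
fit
```

```
Two-sample MR fit: sim-exposure -> sim-outcome (30 SNPs)
         method nsnp   beta     se      pval     or or_lci95 or_uci95
      IVW_fixed   30 0.4992 0.0152 6.16e-236 1.6473   1.5989   1.6972
          Egger   30 0.4891 0.0245  4.32e-18 1.6308   1.5543   1.7111
 WeightedMedian   30 0.4966 0.0203 1.67e-132 1.6431   1.5791   1.7097
     SimpleMode   30 0.5010 0.0312  3.98e-58 1.6503   1.5525   1.7543
   WeightedMode   30 0.4934 0.0244  1.34e-90 1.6379   1.5612   1.7182
Primary inference (IVW_fixed): significant at alpha = 0.05
```

All five estimators recover the simulated causal effect of 0.5 (an odds
ratio of about 1.65 per unit of exposure), with IVW the primary inference.
The sensitivity battery on the same set:

```r
mr_sensitivity(h)
```

```
Heterogeneity: Q = 16.088 (df 29), p = 0.975, I2 = 0.0%
Egger intercept: 0.0007 (se 0.0015), p = 0.645
Steiger direction: TRUE (p = 1.52e-123)
Leave-one-out: 30 refits, influential: none
```

No heterogeneity, no directional pleiotropy (intercept near 0), causal
direction exposure → outcome, and no single influential SNP — exactly the
profile valid simulated instruments should show. A colocalization run on a
region simulated with one shared causal variant:

```r
reg <- simulate_coloc_region(n_snps = 100, scenario = "H4", seed = 1)
coloc_abf(reg$trait1, reg$trait2)
```

```
Colocalization: sim-region-trait1 vs sim-region-trait2 over 100 SNPs
Posterior probabilities:
H0 H1 H2 H3 H4
 0  0  0  0  1
Top shared-variant candidate: rs000050 (SNP.PP.H4 = 1.000)
```

The shared-variant configuration (H4) takes essentially all the posterior
mass and the per-SNP attribution points at the planted causal marker.
`run_pipeline()` chains all of the above (instrument selection →
harmonization → estimation → meta-analysis → colocalization → optional
ROC) from one seeded YAML config and writes the three report tables plus a
hashed manifest.

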