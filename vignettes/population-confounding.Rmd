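---
title: "Simulating and diagnosing population-phenomena bias in genotype-phenotype associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing population-phenomena bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popconfound)
```

## The problem

SNP heritability, genetic correlation and polygenic-score associations
estimated from samples of nominally unrelated individuals are routinely
read as evidence that genotype causes phenotype. Three population
phenomena can inflate all of them without any within-individual causal
path:

* **population stratification** — allele frequencies and phenotype means
  both differ between subpopulations, so genotype tags ancestry and
  ancestry tags environment;
* **dynastic effects (genetic nurture)** — parental genotype shapes the
  rearing environment through the parental phenotype, so children inherit
  trait-associated alleles *and* trait-associated environments;
* **assortative mating** — spouses pair on phenotype, which induces
  spousal and cross-generational genotypic correlation and inflates
  genetic variance in offspring.

`popconfound` provides a forward genotype-phenotype simulator in which
each mechanism can be switched on with known magnitude, together with the
estimators the mechanisms bias (GREML heritability, bivariate GREML
genetic correlation, polygenic scores) and the diagnostics that reveal
them (PC-adjustment comparison, trio attenuation with nontransmitted
scores, spousal correlations, bivariate heritability). Everything is
therefore falsifiable against known truth without access to restricted
cohort data.

## The phenotype model

For individual $i$ the simulated phenotype is

$$y_i = g_i + s_{\text{pop}(i)} + d_i + \epsilon_i,$$

where $g_i = \sum_j \beta_j w_{ij}$ is the additive genetic value over
standardized dosages $w_{ij}$ (standardization is frozen at the founder
ancestral frequencies so the variant-substitution scale does not drift
across generations), $s$ is the per-subpopulation mean shift, $d_i$ is
the dynastic component, and $\epsilon$ the residual environment. Two
study traits A and B share causal variants with genetic effect
correlation `rg_true` and residual correlation `env_corr`; a
negative-control trait (a CRP-like biomarker) has its own independent
effect set and never receives a shift, dynastic term, or assortment.

At the founder generation the phenotype scale is defined exactly: effect
vectors are rescaled so the realized genetic variance equals `h2_target`,
and residuals are orthogonalized to the genetic values with their sample
covariance pinned to the target. Later generations are deliberately left
unscaled — variance inflation under assortment or dynastic transmission
is precisely the quantity under study. Effect draws use an
exact-covariance multivariate normal so the realized effect correlation
equals `rg_true` rather than a draw around it; parameter-recovery
experiments then compare estimates against the configured truth without
an extra layer of generative noise.

## The three mechanisms

**Stratification** uses the Balding–Nichols model: each variant has an
ancestral frequency $p$ drawn uniformly from `maf_range`, and each
subpopulation draws its own frequency from a Beta distribution with mean
$p$ and variance $F_{ST}\,p(1-p)$. The paper-scale preset uses two
subpopulations, $F_{ST} = 0.05$ and phenotype shifts of $\pm 0.5$ SD.
A Hudson-style estimator computed on the simulated dosages recovers the
configured $F_{ST}$ (tested to 0.01).

**Dynastic transmission** adds
$\kappa_m \tilde m_{\text{mother}} + \kappa_f \tilde m_{\text{father}}$
to each non-founder, where $\tilde m$ is the parental mediator
standardized within the parental generation. The mediator is the full
parental phenotype by default (the parental genotype expresses itself
through the parental phenotype); a `parental_genetic_value` mode gives a
clean genetic-nurture pathway for calibration experiments. Magnitude
0.3 per parent is used in the presets; the source cohort never reports a
generative value, so this is an emulation magnitude, not an estimate.

**Assortative mating** ranks males and females within each mating pool on
`trait_a` plus independent Gaussian noise and pairs them by rank. The
noise variance starts at the analytic value $\mathrm{Var}(y)(1-\rho)/\rho$
(rank-matching makes the noisy scores comonotone, so the spousal
correlation is approximately the squared score-phenotype correlation) and
is refined by bisection until the realized spousal correlation is within
0.02 of `spousal_corr_target`. The preset target, 0.56, emulates the
spousal correlation on educational attainment observed in UK cohort data;
mating is within-subpopulation by default, with a configurable
cross-subpopulation fraction. A target of 0 bypasses scoring and pairs
uniformly at random. Transmission is Mendelian with unlinked variants;
each parent's transmitted allele is recorded so nontransmitted-allele
scores are exact rather than reconstructed.

## Estimators

`reml_univariate()` and `reml_bivariate()` implement GREML: REML
estimation of $\sigma^2_g$ and $\sigma^2_\epsilon$ (and, bivariate, the
genetic and residual covariances) under
$y = X\beta + g + \epsilon,\ g \sim N(0, \sigma^2_g K)$ for the
standardized-dosage GRM $K$. Heritability is
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_\epsilon)$, genetic
correlation $r_g = \mathrm{cov}_g(A,B)/\sqrt{\mathrm{var}_g(A)\,\mathrm{var}_g(B)}$.
Because a single GRM enters the model, the covariance is diagonal (2×2
block-diagonal for two traits) in the GRM eigenbasis; the implementation
rotates once and runs average-information REML there, with EM warm-up
steps, step-halving so the restricted likelihood never decreases, a
variance floor of $10^{-6}\,\mathrm{Var}(y)$ with a boundary flag, and an
absolute log-likelihood convergence tolerance of $10^{-6}$ (at most 100
iterations). Standard errors come from the inverse average-information
matrix; $h^2$ and $r_g$ SEs by the delta method. Bivariate starting
values come from the univariate fits, pulled strictly into the interior
(boundary starts break the AI update), with a scaled-gradient fallback
step when the AI direction fails near a boundary. The dense-matrix
restricted likelihood maximized by a generic optimizer serves as the
independent oracle in the tests; with strongly genetically correlated
traits at very small $n$ the surface is nearly flat in $r_g$ and the
optimum sits on the $|r_g| = 1$ boundary, so that comparison is made on
the maximized likelihood, with parameter-level agreement checked on a
well-conditioned trait pair.

`he_regression()` is the method-of-moments cross-check: phenotype
cross-products of standardized traits regressed on off-diagonal GRM
entries. Its OLS standard error ignores the dependence between pairs
sharing an individual and is mildly anti-conservative; it is used as an
agreement oracle, not for inference.

Continuous phenotypes are passed through `inverse_normal_transform()`
(Blom offset 3/8, ties sharing mean ranks) before REML, and the first 20
principal components — eigenvectors of the GRM scaled by the square root
of their eigenvalues, sign-fixed so the largest-magnitude entry is
positive — are the standard covariate set.

### Bivariate heritability

`bivariate_h2()` computes
$h^2_{AB} = r_g \sqrt{h^2_A h^2_B} / r_p$ — the share of the phenotypic
correlation attributable to genetics. Values above 1 are legal (the
numerator is not nested in the denominator) and serve as a bias
indicator. Its SE is Monte-Carlo: each input is drawn independently from
a normal centred on its estimate with SD equal to its SE (one million
draws by default), the ratio evaluated per draw, and the SD of the draws
reported. Negative heritability draws are truncated at zero and draws
with $|r_p| < 10^{-3}$ rejected (the rejected fraction is reported); the
independence assumption makes the SE conservative when the inputs are fit
on shared data, which the test suite verifies by paired simulation.
`flag_inflation()` grades $(h^2_{AB}-1)/\mathrm{SE}$ at thresholds 0 and
2 and words every verdict as an *indicator of possible bias*, never a
causal conclusion. Whether $r_p$ should be computed before or after
covariate adjustment is not fixed by convention; the package uses the
covariate-residualized, transformed traits, which keeps $r_p$ on the same
scale as the REML variance components.

### Trio analyses

`build_pgs()` applies the standard construction rules: discovery
p-value threshold $5\times10^{-8}$, clumping that keeps the smallest-p
variant per 250-kb window and removes neighbours with dosage
$r^2 > 0.1$, allele harmonization with sign flips for swapped alleles and
removal of strand-ambiguous (A/T, C/G) variants, and standardization to
unit SD. `nontransmitted_score()` sums weights over the parental alleles
*not* transmitted to the child — those can only act through the
environment, so their association with the child phenotype is a direct
dynastic readout. `trio_regression()` fits the child-only, single-parent
and three-score models; attenuation is
$100\,(b_{\text{ind}} - b_{\text{adj}})/b_{\text{ind}}$ with the
independent-model coefficient as denominator (the convention that
reproduces all three published worked examples), its SE from a bootstrap
that resamples whole trios (parental and child rows are dependent), and
the difference in the child coefficient tested by a
seemingly-unrelated-regression Wald statistic whose cross-model
covariance comes from stacked influence functions (a paired bootstrap
mode is the cross-check). Replicate bootstrap fits with a child
coefficient below $10^{-8}$ in magnitude are dropped and counted.

## What the simulator does and does not emulate

The generator reproduces the *mechanisms* — frequency divergence with
phenotypic shifts, phenotype-mediated parental transmission, rank-based
phenotypic assortment, Mendelian trios — at the magnitudes reported for
the motivating UK cohort (spousal correlation 0.56; heritabilities
0.4–0.6). It does not attempt LD structure (variants are unlinked by
default; an optional Gaussian-copula block mode exists so clumping code
paths can be exercised), genotyping error, imputation, missingness
patterns, selection, or geographic continuity beyond discrete
subpopulations. Passing tests therefore demonstrate that the estimators
and diagnostics behave correctly *under the stated mechanisms*, not that
any particular real cohort is free of additional biases such as
LD-dependent architecture or school-level shared environment.

## Numerical and design choices

* Empirical (exact-covariance) scaling at the founder generation, as
  above; later generations drift freely.
* The negative-confounding scenario — a shared environmental factor with
  opposite-signed loadings on the two traits — is implemented as a
  negative residual correlation (`env_corr = -0.4`), which is its exact
  mathematical equivalent; with $r_g = 0.8$ and $h^2 = 0.5$ for both
  traits the true ratio is $0.4/0.2 = 2$.
* The unconfounded preset sets `env_corr = 0.3`: phenotypically
  correlated traits share environment in any realistic cohort, and it
  keeps the true $h^2_{AB}$ (0.78) strictly inside the consistent range
  so the null pipeline has an unambiguous expected verdict.
* Relatedness pruning uses a greedy highest-degree-first removal at
  threshold 0.1 (configurable; reported conventions differ between 0.1
  and 0.125 and the package exposes the choice).
* The negative-control harness tests three probes simultaneously, so each
  uses a `qnorm(0.995)` critical value to keep the family-wise false-alarm
  rate near 3%.
* Single pseudo-random stream per scenario, seeded once in
  `simulate_founders()`; the draw order (frequencies, dosages, effects,
  then per generation residuals, pairing noise including calibration
  trials, transmission coin flips) is fixed, so runs are byte-identical
  under a fixed seed. Monte-Carlo and bootstrap helpers take local seeds
  that leave the global stream untouched.
* Test and acceptance problem sizes: recovery experiments use
  $n = 2000$ individuals and $m = 2000$ variants (50 replicates);
  trio calibration uses 200 null and 100 powered replicates at 1000
  trios; unit tests use smaller cohorts (60–500 individuals) chosen so
  each check still has the power to fail.

## Known limitations

* Observed-scale analysis only; no liability-scale transformation for
  binary traits.
* Single-GRM models; no partitioned heritability, LD-score regression, or
  multi-component GREML.
* The Haseman–Elston SE underestimates sampling variance (dependent
  pairs); it is a cross-check, not an inferential tool.
* Nontransmitted alleles come from the simulator's transmission record;
  resolving them in real unphased data (possible only at
  homozygous-parent variants) is documented but not implemented.
* With few individuals and strong genetic correlation the bivariate REML
  optimum can sit on the $|r_g| = 1$ boundary; such fits return with the
  boundary/convergence flags set and should be interpreted accordingly.

## A minimal session

```{r example, eval = FALSE}
coh <- simulate_scenario(preset_config("assortment", seed = 1))
ph <- cohort_phenotypes(coh, generation = 2)
grm <- grm_with_eigen(compute_grm(coh$dosages[ph$id, ]))
fit <- reml_univariate(inverse_normal_transform(ph$trait_a), NULL, grm)
tidy(fit)

res <- run_pipeline(preset_config("crp_control", seed = 1),
                    out_dir = tempfile(), profile = "test")
res$tables$verdicts
```
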