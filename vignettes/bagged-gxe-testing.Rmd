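---
title: "Testing gene-environment interactions with bagged genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene-environment interactions with bagged genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxebag)
```

## The problem

A gene-environment (GxE) interaction is present when the effect of an
environmental exposure $E$ on a phenotype $Y$ differs by genotype — for
example, when carriers of particular risk alleles are more susceptible to
air pollution than non-carriers. Given $p$ SNPs coded as minor-allele
counts $\mathrm{SNP}_j \in \{0,1,2\}$, an exposure $E$, and optional
confounders $C_1,\dots,C_m$, the classical single-SNP test fits, per SNP,

$$g(\mathbb{E}[Y]) = \beta_0 + \beta_1\,\mathrm{SNP}_j + \beta_2 E +
  \beta_3\,\mathrm{SNP}_j \times E + \textstyle\sum_i \gamma_i C_i,$$

with $g = \mathrm{logit}$ for binary and $g = \mathrm{Id}$ for continuous
outcomes, Wald-tests $H_0\!: \beta_3 = 0$, and Bonferroni-corrects over
the $p$ SNPs. Multiple-testing adjustment and the inability to pool
signal across loci cost power.

Genetic-risk-score (GRS) tests instead summarise all SNPs into one scalar
$\widehat{\mathrm{GRS}} = \hat\alpha_0 + \sum_j \hat\alpha_j
\mathrm{SNP}_j$ and test its interaction with $E$ in

$$g(\mathbb{E}[Y]) = \beta_0 + \beta_1\,\widehat{\mathrm{GRS}} + \beta_2 E
  + \beta_3\,\widehat{\mathrm{GRS}} \times E + \textstyle\sum_i \gamma_i
  C_i.$$

When the GRS is learned internally (here: an elastic net with penalty
$\lambda\,[(1-\xi)\|\alpha\|_2^2/2 + \xi\|\alpha\|_1]$), the sample must
be split — GRS weights on a training half, the interaction test on the
held-out half — or the learned score overfits and the test is invalid.
Halving the testing sample costs substantial power.

## The bagged OOB tests

This package implements tests that remove the split. The GRS is
constructed by bagging: $B$ base models are fitted, each on a bootstrap
resample of all $N$ observations (or a subsample of $\lfloor 0.632
N\rfloor$ without replacement). For observation $i$, the out-of-bag (OOB)
prediction averages only the models whose resample excluded $i$:

$$\hat y_{\mathrm{OOB},i} = \frac{1}{|\mathcal F_i|}
  \sum_{f \in \mathcal F_i} f(x_i), \qquad
  \mathcal F_i = \{\,f : i \notin T_f\,\},$$

where $T_f$ is the training multiset of $f$. Every observation's score
thus comes from models that never saw it — a test-set prediction in
expectation — so the interaction GLM above can be fitted and Wald-tested
on **all** $N$ observations without overfitting. Two base learners are
provided:

* `gxe_test_bagged(..., base = "elastic_net")` — bagged cross-validated
  elastic nets; base models contribute their linear predictor, so the
  GRS lives on the link scale for both outcome families.
* `gxe_test_bagged(..., base = "random_forest")` — a random forest
  (bagged trees with `mtry` feature subsampling), able to pick up
  gene-gene interactions that linear scores cannot; trees are grown as
  0/1 regression for binary outcomes so leaves hold risk estimates, and
  the GRS is a probability-scale risk.

Reference procedures are included for comparison: the single-SNP
Bonferroni test, the split-sample GRS test (`gxe_test_split_grs`), and
SBERIA (`gxe_test_sberia`), which screens each SNP against $E$ (or $Y$)
and uses weights $w_j = \varepsilon$, $\varepsilon \pm 1$ depending on
the screening p-value (threshold $\theta$) and correlation sign.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `b` | 500 | bagging iterations / trees; high enough that more iterations barely change the ensemble |
| `xi` | 0.5 | elastic-net balance between lasso and ridge; an even compromise suits GRS construction |
| `nfolds` | 10 | CV folds for the per-fit penalty $\lambda$ |
| `mtry` | $\lfloor p/3 \rfloor$ | features tried per split (random forest) |
| `min_node` | $\lfloor 0.05\, n_{tree} \rfloor$ | minimum terminal-node size; keeps trees shallow so leaves hold stable risk estimates ($n_{tree}$ = per-tree training size) |
| `sampling` | bootstrap | `"subsample"` draws $\lfloor 0.632N \rfloor$ without replacement, removing the mild pessimistic bias of bootstrap OOB error |
| `alpha` | 0.05 | significance level |
| `eps`, `theta` | 0.0001, 0.1 | SBERIA offset and screening threshold |

## The synthetic-data generators

`simulate_gxe_data()` draws complete study data sets from three
generative models, all acting on dominant-coded SNPs
$S_j = 1(\mathrm{SNP}_j > 0)$ while the tests receive the raw 0/1/2
matrix:

* **null** (type-I error): four marginal SNP effects of $\log 1.5$, a
  gene-gene interaction $S_1 S_5$ of $\log 2.25$, and a marginal exposure
  effect $\log 1.02$ — no GxE term at all.
* **scenario1** (power): marginal effects $\log 1.5$ on $S_1, S_2$,
  exposure effect $\log 1.01$, GxE terms $\alpha_{GxE} (S_3 + S_4) E$ and
  a doubled gene-gene-involving term $2\alpha_{GxE} S_1 S_5 E$, with
  $\alpha_{GxE} \in \{\log 1.01, \log 1.03, \log 1.05\}$ spanning
  near-undetectable to strong interactions.
* **scenario2** (main effects and noise): $K = 10$ potential main-effect
  SNPs and interacting SNPs $j = K/2+1, \dots, 1.5K$, coefficients drawn
  uniformly per replicate from setting-specific ranges with random signs
  (settings 1-2 have no main effects); remaining SNPs are pure noise.

SNPs are independent (resembling LD-pruned panels) with MAF drawn
uniformly from $[0.15, 0.45]$ and Hardy-Weinberg genotype frequencies.
The continuous exposure is log-normal with median 23.91, mimicking an
NO$_2$-like air-pollution exposure; scenario 2 uses a fair binary
exposure. Binary outcomes are Bernoulli draws through the inverse logit,
with the intercept calibrated by bisection (tolerance $10^{-8}$ on the
mean) so each replicate is a balanced case-control sample; continuous
outcomes add standard-normal noise to the linear predictor and use no
intercept.

What the generators do **not** emulate: linkage disequilibrium between
SNPs, confounder structure, population stratification, genotyping error
or missingness, and exposure measurement error. Passing tests therefore
demonstrate correct operating characteristics under idealised
LD-pruned, complete-data conditions, not robustness to those real-data
complications.

## Design and numerical choices

* **Exposure spread.** Only the median (23.91) of the motivating
  exposure distribution is fixed by design; the log-scale SD defaults to
  0.25, giving a moderate interquartile spread relative to the median as
  seen in typical urban NO$_2$ data. It is exposed as `env_sdlog`.
  Because every GxE term multiplies $E$, the interaction signal — and
  hence power at fixed coefficients — scales directly with the exposure
  spread, so reported power figures are specific to the chosen
  `env_sdlog`.
* **Penalty selection.** $\lambda$ minimises the mean 10-fold CV deviance
  over 100 log-spaced values from the data-derived $\lambda_{max}$ down
  to $10^{-4}\lambda_{max}$; no 1-SE rule. Predictors are standardized
  internally and weights reported on the original scale.
* **Prediction scale.** Bagged elastic nets average linear predictors
  (the natural scale of a weighted-sum GRS); trees average leaf risk
  estimates. The Wald test of $\beta_3$ is invariant to affine
  rescaling of the GRS, so the choice of scale does not move the test
  decision for any monotone-linear re-expression.
* **Wald references.** Logistic fits use the asymptotic normal; linear
  fits the $t$ with residual degrees of freedom — the convention of
  standard GLM software. IRLS runs to tolerance $10^{-8}$, at most 100
  iterations.
* **Degenerate cases.** A constant GRS, an aliased interaction column, a
  single-class outcome half, or a non-converged fit yields a `NaN`
  p-value that never counts as a rejection; Monte-Carlo loops log these
  and continue. An observation in-bag for every resample receives the
  full-ensemble average, flagged in the diagnostics.
* **Ties in trees.** Candidate-feature sampling is the only
  randomization; equal-quality splits resolve by column order.
* **Seeding.** One master seed per run; replicate seeds derive from it
  by position and method seeds from each replicate seed by a fixed
  canonical method index, so adding a method to an experiment never
  changes the data or the other methods' results.

## Scale of the shipped validation

The package's test suite exercises the full pipeline at sizes chosen to
be informative yet quick on one CPU: type-I error at $N = 1000$, $p =
50$ with 200 replicates (random forest) and $N = 500$, $B = 50$ with 50
replicates (bagged elastic net); ceiling and floor power and the
method-ordering comparison at 100 replicates; monotonicity and
noise-robustness properties at 25 replicates. Full-scale studies (1000
replicates across all grids) are a matter of raising `reps` in
`run_experiment()`.

## Known limitations

* Variance-component (GESAT/iSKAT-style) and Bayes-factor (ADABF-style)
  reference tests are not implemented.
* The bagged tests do not report which SNPs drive a detected
  interaction; the ensemble GRS has no built-in attribution (variable
  importance extensions would be needed).
* Random-forest hyperparameters follow the fixed rules above; no tuning
  is performed, and tuned forests could be more powerful.
* Genotype input must be complete hard calls; there is no imputation.
* SBERIA's default screening variable is the exposure $E$; when
  genotypes are independent of $E$ (as in all three generators), the
  screening rarely selects the interacting SNPs and the test has little
  power — switch to `screen_on = "Y"` for outcome-driven screening.

## A worked run

```{r example, eval = FALSE}
spec <- scenario_spec("scenario1", n = 1000, p = 50, family = "binary",
                      alpha_gxe = log(1.05))
dat <- simulate_gxe_data(spec, seed = 1)
res <- gxe_test_bagged(dat$geno, dat$pheno, base = "random_forest",
                       seed = 1)
tidy(res)

ex <- run_experiment(spec, c("bagged_rf", "split_grs"), reps = 50,
                     seed = 1)
tidy(ex)
autoplot(ex)
```
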