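---
title: "Simulating predictors of intervention success in pre-post designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating predictors of intervention success in pre-post designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepostsim)
```

## The question the simulation answers

In a two-group pre/post intervention study — cognitive training is the
motivating example — researchers increasingly regress a measure of
training success on external predictors (age, education, baseline
ability) to ask *who benefits*. That analysis has four loosely pinned
degrees of freedom: which predictors enter the regression, which
criterion variable stands for "success", how many participants are
needed, and how reliable the measures are. Each choice changes power,
alpha error, and — for the pre-test score — even the *sign and meaning*
of coefficients. `prepostsim` makes the consequences measurable by
simulating the whole design under a known truth.

## The generative model

True scores first, noise second.

**True scores.** Every subject has a true pre-test score
$T_1 \sim N(\mu_1, \sigma_1^2)$ with $\mu_1 = 50$, $\sigma_1 = 10$
(T-scale norms), and two predictors $P_I, P_{II} \sim N(50, 10^2)$,
mutually independent and independent of $T_1$. The control group's true
gain is a deterministic shift $\mu_{\Delta,C}$. The experimental group's
true gain is
$$\Delta = \mu_{\Delta,E} + \beta\,(P_I - 50) + \varepsilon,\qquad
  \varepsilon \sim N\!\big(0,\; \sigma_\Delta^2 (1-\rho^2)\big),$$
so $\mathrm{var}(\Delta) = \sigma_\Delta^2$ and
$\mathrm{cor}(P_I, \Delta) = \rho$ exactly. $P_{II}$ has no pathway; it
exists to measure false-positive rates. True post score:
$T_2 = T_1 + \Delta$.

Two structural choices deserve emphasis because the design was genuinely
open there:

* **Zero true pre/gain covariance.** With
  $\mathrm{cov}(T_1, \Delta) = 0$, the true post-test variance
  decomposes as $\sigma_2^2 = \sigma_1^2 + \sigma_\Delta^2$, and the
  population slope of observed post on observed pre equals the
  reliability exactly. Any nonzero covariance would build a real
  baseline-dependence into the truth and make the change-score artifact
  (below) unidentifiable as an artifact.
* **Degenerate control gain.** The control group's post SD equals its
  pre SD by assumption; together with zero pre/gain covariance this
  forces $\mathrm{var}(\Delta \mid \text{control}) = 0$. Its
  standardized-change target is therefore defined on the *observed*
  change, whose spread is purely measurement noise.

**Measurement noise.** Observed = true + independent $N(0, e^2)$ noise
per measure and subject (Classical Test Theory), with
$e = sd_{\text{true}}\sqrt{(1-r_{tt})/r_{tt}}$ so that each measure has
reliability $r_{tt}$ = true variance / observed variance. Each measure
uses its *own* true SD — in particular the experimental post-test's
larger SD (13), since reliability is a per-measure variance ratio. Every
(dataset, reliability) cell redraws noise and truth independently;
datasets are never re-noised copies.

## Calibration: constant truth, moving observations

Observed effect sizes shrink with reliability while the truth does not.
The package therefore defines the familiar effect-size targets — $dz =
0.50$ (experimental), $dz = 0.05$ (control), $r(P_I, \Delta) = .30$ — as
*observed-score* quantities at one reference reliability ($r_{tt} =
.80$), backs out the constant true effects in closed form, and holds
those fixed across all reliability conditions:

* $\sigma_\Delta^2 = \sigma_2^2 - \sigma_1^2 = 13^2 - 10^2 = 69$;
* observed change = true gain + post noise − pre noise, so its variance
  at the reference reliability is $69 + 5^2 + 6.5^2 = 136.25$ and the
  change composite's reliability is $69/136.25 \approx .506$;
* $\rho = .30 / \sqrt{.80 \times .506} \approx .471$ (disattenuation);
  the calibration refuses to proceed if this leaves $(-1, 1)$;
* $\mu_{\Delta,E} = 0.50\sqrt{136.25} \approx 5.84$,
  $\mu_{\Delta,C} = 0.05\sqrt{50} \approx 0.354$,
  $\beta = \rho\sqrt{69}/10 \approx 0.392$.

```{r}
calibrate_true_effects(true_model_spec())
```

The mean-gain convention ($dz$ defined on the observed change SD at the
reference reliability) is one of several defensible calibrations — one
could instead let the targeted mean move with each reliability level.
Holding the truth constant keeps the reliability comparison clean: what
varies across conditions is only the noise, never the effect being
hunted.

## Criteria and models

Four criterion variables, computed on uncentered observed (or true)
scores: the post-test; the absolute change (post − pre, raw units); the
relative change ($100\,(post-pre)/pre$, percent — the percent scale
keeps the coefficients legible, and because the denominator is a noisy
variable the population mean of this ratio exceeds the ratio of means);
and the residualized change (residuals of one *pooled* post-on-pre
simple regression per dataset — pooling both groups is what makes the
control group's mean residual negative when the treatment works, since
one common line runs between the groups).

Five predictor sets: (1) $P_I + P_{II}$; (2) $+$ pre-test; (3) $+$
group; (4) $+\;P_I{\times}\text{group} + P_{II}{\times}\text{group}$;
(5) model 4 without the pre-test. Continuous predictors are centered at
their full-sample means *within each simulated dataset*; group is a 0/1
dummy (control = 0); interaction columns are centered predictor × dummy.
Inference is textbook OLS — classical homoskedastic standard errors and
two-sided t-tests with $df = n - p$ — despite the built-in group
heteroskedasticity, because that is the analysis practitioners run.
Significance is per-coefficient at $\alpha = .05$, strict inequality, no
multiplicity correction.

## The exact change-score algebra

Writing the post-test regression $T_2 = b_0 + b_1 T_1 + b_2 V$ and the
change regression $T_2 - T_{1,nc} = c_0 + c_1 T_1 + c_2 V$ (centered
$T_1$, any other predictor $V$), subtracting the identical design shows
$b_1 = c_1 + 1$, $b_2 = c_2$, and $b_0 = c_0 + \overline{T_{1,nc}}$ —
finite-sample identities that hold for *every* dataset, not in
expectation. `verify_change_identities()` checks them at an absolute
tolerance of $10^{-8}$ on the coefficient scale (`ols_fit()` solves by
QR; discrepancies are rounding-level). Because $b_1$ estimates the
test-retest reliability, $c_1 \approx r_{tt} - 1 < 0$: the notorious
negative pre-test coefficient for change scores grows as reliability
falls, and `verify_criterion_equivalence()` confirms the companion fact
that with the pre-test in the model, all other slopes are identical
across post-test, absolute-change, and residual criteria. The relative
change lives on another scale and is exempt from both identities.

## Running a study

`study_config()` defaults to the full factorial grid: total $n \in \{50,
100, 150, 200, 250, 300, 400, 500\}$ (split equally across groups —
every $n$ in the package is a *total* sample size), $r_{tt} \in \{.60,
.70, .80, .90\}$, 1000 replications, which plans
$5 \times 4 \times 8 \times 4 \times 1000 \times 2 = 1{,}280{,}000$
fits (each replicate is analysed on observed *and* true scores; the
paired true fits give the studentized bias
$\mathrm{mean}(b_{obs} - b_{true}) / (\mathrm{SD}(b_{obs})\sqrt{n})$).

Replicate seeds derive from a Lehmer-style integer mix (modulo the prime
$2147483629$, multiplier $48271$) of (master seed, $n$,
$1000\,r_{tt}$, replicate index, stream), with separate streams for
true-score and noise draws — any single replicate is reproducible in
isolation, and cells share no data. Replicates with a failed fit
(singular designs; essentially impossible at these $n$) are dropped and
counted; a cell aborts if more than 1% fail.

Per cell and term the summary reports `M` (mean estimate), `SE` (SD of
estimates — the Monte-Carlo estimate of the coefficient's standard
error), and `P` (significance rate: power where a true effect exists,
alpha error where none does).

## Numerical and testing choices

* OLS via one QR decomposition per design, shared across the four
  criteria (the design matrix does not depend on the criterion);
  standard errors from $\hat\sigma^2 (X^\top X)^{-1}$ computed off the
  $R$ factor. Rank deficiency and $df \le 0$ are hard errors, as are
  zero-variance predictor columns (named in the message).
* Degenerate inputs fail loudly: odd total $n$, reliabilities outside
  $(0, 1]$, zero pre-test scores under the percent criterion (the
  offending subjects are reported), disattenuation past $\pm 1$.
* The test suite exercises the generator at cohort sizes of
  $10^5$–$2\times 10^5$ subjects for moment checks (sampling error
  $\lesssim 0.005$ on a correlation), one full reference cell
  ($r_{tt}=.80$, $n=200$, 1000 replications) for the tabulated
  summaries, and 600-replication cells for the power-monotonicity
  properties; the exact identities are property-tested over dozens of
  small random datasets at mixed $n$, reliability and model.

## What the generator does and does not emulate

It emulates: attenuation of observed effect sizes with reliability,
regression to the mean in change scores, treatment-induced variance
inflation, a null predictor for alpha-error calibration, and the
power/sample-size/reliability trade-offs of the five models × four
criteria. It does **not** emulate: non-Gaussian or skewed scores, floor
and ceiling effects, correlated or heteroskedastic measurement error,
test-retest carryover, predictor intercorrelations, unequal group
allocation, dropout, or selection into treatment. Passing tests
therefore certify the arithmetic of the design under clean conditions,
not robustness of the recommendations to real-data pathologies.

Known limitations: the mean-gain calibration convention above shifts
intercept-scale summaries (intercepts and group-difference means) by a
few percent relative to other defensible conventions, while leaving
slope estimands, their standard errors, and the exact identities
untouched; and with predictors independent of the baseline by
construction, the interaction estimand is necessarily identical whether
or not the pre-test is in the model — including the pre-test buys
residual-variance reduction (power), never a different target quantity.
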