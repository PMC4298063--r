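---
title: "Selective attrition, regression toward the mean, and the prediction of change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective attrition, regression toward the mean, and the prediction of change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmbias)
```

## The scientific question

Longitudinal observational studies routinely ask how a baseline predictor
(relationship problems, physical activity, socioeconomic status, ...)
predicts *change* in a health measure between two waves. Two analysis
conventions dominate:

* **baseline-adjusted multiple regression (MR)** — regress the follow-up
  health score on the predictor, controlling for the baseline score; and
* **change-score analysis** — regress (follow-up − baseline) on the
  predictor.

The two build opposite assumptions about **regression toward the mean
(RTM)** into the model. MR assumes that extreme baseline scores will
partially revert, and credits that reversion to the baseline score rather
than the predictor; change scores assume no predictor-correlated reversion
at all. Whether each assumption is right depends on *why* the predictor and
baseline health are associated. On top of this, both analyses are usually
run on the subjects who stayed in the study — and dropping out is rarely
random.

`rtmbias` implements a Monte Carlo machinery for quantifying how these two
forces — selective attrition and inappropriate modeling of RTM — bias the
estimated effect of the predictor on change, separately and together.

## The structural populations

Every population contains four standardized Gaussian variables: the
predictor $P$, baseline health $H_1$, follow-up health $H_2$, and a latent
liability of dropping out $L$, plus one latent common cause $C$ of the
$P$–$H_1$ association. All structural shocks are independent standard
normals and every variable is scaled to unit variance, so coefficients are
standardized regression weights. With loading $a$, stability $s$, true
effect $b_{\text{pred}}$ and direct cause effect $d$:

$$
\begin{aligned}
P   &= a\,C + e_P, &
H_1 &= a\,C + e_1, \\
H_2 &= s\,H_1 + b_{\text{pred}}\,P + d\,C + e_2, &
L   &= g_P P + g_1 H_1 + g_2 H_2 + e_L .
\end{aligned}
$$

Two population types differ only in $d$:

* **Transient causes** ($d = 0$): $C$ moves $P$ and $H_1$ but not $H_2$
  directly, so it creates rank-order instability in health — RTM — that is
  *correlated with the predictor*. MR is the appropriate analysis.
* **Enduring causes** ($d = a(1-s)$): the total effect of $C$ on $H_2$
  ($a s + d$) equals its effect on $H_1$ ($a$), so $C$ creates no RTM.
  Change-score analysis is appropriate.

There is deliberately no direct $P \to H_1$ path: the populations represent
risk factors that operate over time rather than instantaneously.

Defaults are $a = 0.4$, $s = 0.50$, $b_{\text{pred}} = 0.10$, hence
$d = 0.2$ for enduring populations. The loading is pinned down by a
closed-form calibration: in the transient population the change-score
estimand is $b_{\text{pred}} - s\,a^2$, and the value $0.02$ that the
no-attrition inappropriate change-score cell must reproduce forces
$a^2 = 0.16$. The choice $d = a(1-s)$ (counting only the indirect path
through baseline health) is what makes the enduring-population change-score
estimand equal $b_{\text{pred}}$ *identically in* $a$ and $s$ — the other
reading of "total effect" (also counting the path through the predictor)
does not, and would leave the appropriate method biased even without
attrition.

```{r estimands}
mr_estimand(population_spec("transient"))   # appropriate: exactly 0.10
cs_estimand(population_spec("enduring"))    # appropriate: exactly 0.10
mr_estimand(population_spec("enduring"))    # inappropriate: RTM imposed where none occurs
cs_estimand(population_spec("transient"))   # inappropriate: RTM ignored where it occurs
```

The **negative sign variant** flips the signs of $a$ in the $P$ equation,
of $b_{\text{pred}}$, and of $g_P$, turning the predictor into a protective
factor with true effect $-0.10$; its implied covariance is the positive
variant's with the predictor coordinate negated.

## Attrition

Liability is regressed on the study variables under four scenarios,
$(g_P, g_1, g_2) \in \{(0,0,0),\ (.3,.3,0),\ (.3,.3,.1),\ (.3,.3,.3)\}$ —
MCAR, MAR, and two MNAR conditions of increasing severity. Attrition is
induced by **listwise deletion of the top $k = \mathrm{round}(\text{rate}
\cdot n)$ liability scores** (round-half-away-from-zero; exact at
$n = 1000$ with rates .3/.5/.7; ties — a probability-zero event — break by
row order). Deletion by rank is invariant to positive rescaling of the
liability, so the convention of giving $L$ unit total variance (rather than
unit residual variance) affects nothing downstream.

The analytic counterpart replaces the sample rank rule with truncation at
the fixed quantile $t = \Phi^{-1}(1-\text{rate})$. With inverse Mills ratio
$m = \phi(t)/\Phi(t)$ and $\gamma = \mathrm{Cov}(X, L)$,

$$
E[X \mid L < t] = -m\,\gamma, \qquad
\mathrm{Cov}[X \mid L < t] = \Sigma - (tm + m^2)\,\gamma\gamma^{\top}.
$$

Feeding these conditional moments back into the regression estimands gives
the $N \to \infty$ expected coefficient for every cell
(`attrition_estimand()`), an oracle that never touches the simulator's
RNG. The fixed-quantile idealization differs from top-$k$ deletion by
$O(1/\sqrt{N})$; we document rather than correct for this, and the test
suite checks the two routes against each other at large $N$.

## The Monte Carlo engine

The study conditions are 500 replicates of $N = 1000$ per cell; rates
30/50/70% for the appropriate-method cells and 50% for the
inappropriate-method and negative-variant cells. Per replicate the engine
generates a sample, deletes the top-liability rows, fits the analysis on
the retained rows by OLS (intercept always included; classical SEs;
95% intervals use the normal critical value 1.959964 — at roughly 500
retained subjects the $t$ correction is under 0.2% of the SE). Cells report
the mean coefficient, mean SE, CI coverage of the true effect (closed
endpoints), the mean change score, and the Monte Carlo SE of the mean
coefficient, $\mathrm{sd}(\hat b)/\sqrt{500}$ (about .002 at these sizes).

**Seeding.** Replicate $r$ of population stream $s$ uses seed
$(\text{master} \cdot 1000003 + s \cdot 10007 + r) \bmod (2^{31}-1)$, so
any replicate is reproducible in isolation. A stream is one
(cause type × dropout scenario) population: methods, attrition rates *and
sign variants* share replicate shocks, so every contrast is computed on
matched draws (common random numbers). For the sign contrast we take CRN to
its logical endpoint: the negative variant's reduced form also negates the
predictor's residual loading, so with shared shocks its draws are the exact
mirror image $P \mapsto -P$ of the positive draws. The marginal sampling
distribution is untouched — the residual shock is symmetric — but the
mirror contrast becomes noise-free. Without this coupling a per-cell
"within 2 Monte Carlo SE" antisymmetry check fails about 5% of the time
per cell purely by chance.

```{r cell, cache = FALSE}
cfg <- study_config(master_seed = 1, replicates = 100, n = 1000)
run_cell(population_spec("transient", "mnar-strong"), "mr", 0.5, cfg)
```

## What the generator does and does not emulate

The generator reproduces the populations of the study exactly:
multivariate-Gaussian, standardized, two waves, a single latent common
cause, deterministic rank deletion on a noisy liability. Passing tests
therefore demonstrate the *logic* of the two bias sources and their
interplay; they say nothing about features real cohort data add — skewed
or bounded scales, measurement error (a further, deliberately excluded,
source of RTM), item-level missingness, probabilistic (e.g. logistic)
dropout, more than two waves, or treatment-style interventions. The
conclusions transfer to real data only insofar as those omissions are
benign for the contrast being studied.

## Numerical and design choices

* **Estimands from moments, never from simulation** — keeps the oracle
  independent of the code path it validates.
* **Residual variances solved, not supplied** — a spec whose implied
  residual variance is non-positive (e.g. loading ≥ 1) is rejected at
  construction, so every accepted population is exactly standardized
  (unit variances to 1e-12).
* **Storage order** is fixed as (predictor, h1, h2, liability) in every
  matrix, sample and dump file.
* **Rounding in reports**: coefficients and SEs to two decimals, coverage
  to whole percent — the published precision; machine output keeps full
  precision.
* **Problem sizes in the test suite**: oracle-equivalence checks run one
  replicate of $n$ = 2–4 × 10^5 (tolerance three MC standard errors);
  the full-scale reproduction runs the complete 40-cell design at
  500 × 1000, about 45 s on one core.

## Known limitations

* The liability model is linear-Gaussian and deletion is deterministic in
  rank; real dropout is noisier and nonlinear.
* Only two waves and one latent cause; mixtures of transient and enduring
  causes (surely the common real case) are representable only by choosing
  $d$ between 0 and $a(1-s)$ manually.
* No missing-data corrections (multiple imputation, FIML) are implemented:
  the point of the study is the behaviour of listwise deletion itself.
* The closed-form selection moments assume the liability threshold is a
  fixed quantile; at $N = 1000$ the top-$k$ rule adds an $O(1/\sqrt{N})$
  wobble that is visible only below the Monte Carlo noise floor.
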