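---
title: "Validating dichotomous questionnaires with the Rasch model under item non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dichotomous questionnaires with the Rasch model under item non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(raschmiss)
```

## The problem

Patient-reported-outcome (PRO) questionnaires are routinely validated with
the Rasch model: a person with latent trait $\theta_n$ (quality of life,
fatigue, anxiety, ...) answers item $j$ positively with probability

$$P(X_{nj} = 1 \mid \theta_n) =
  \frac{e^{\theta_n - \delta_j}}{1 + e^{\theta_n - \delta_j}},$$

where $\delta_j$ is the item difficulty. Validation decisions rest on a
handful of quantities: the Loevinger scalability coefficient $H$, the
estimated difficulties (summarised by the constraint-free location
$\nu = \bar\delta - \mu$ and the across-item dispersion
$\mathrm{Var}(\delta)$), the latent-trait variance $\sigma^2$, the Q1
goodness-of-fit test, and the person separation index (PSI).

Validation samples practically always contain skipped items, and the
skipping is often informative: sicker respondents skip more. A common
reflex is to fill the holes by simple single imputation — most often the
personal mean score (PMS) recommended by the scoring manuals of widely
used instruments. This package provides the machinery to quantify what
such strategies do to every one of the validation quantities above: a
simulator of informative and non-informative non-response, sixteen
missing-data strategies, the estimation stack, and a Monte-Carlo
orchestration layer that measures the bias of each strategy under each
missingness condition.

## The simulator

A complete dataset is generated from the Rasch model with
$\theta_n \sim N(\mu, \sigma^2)$ and a fixed item bank; the default bank
has $J = 5$ items at $\delta = (-1, -0.5, 0, 0.5, 1)$ (population
variance exactly $0.5$), and the default study condition uses $N = 500$
persons with $\mu = 0$, $\sigma^2 = 1$.

Non-response is driven by a person-level propensity $\xi_n \sim N(0,1)$
drawn jointly normal with $\theta_n$ at correlation $\rho \le 0$
(`draw_latents()` constructs $\xi$ from the standardized $\theta$
component plus independent noise, so the joint distribution is exactly
normal). Each cell is then made missing independently with probability

$$\pi_{nj} = \mathrm{clip}\left(\pi\,(1 + 0.4\,\xi_n) +
  w \cdot 0.4\,\pi\,\delta_j,\ 0.01,\ 1\right),$$

a linear propensity centred on the target rate $\pi$ with a 1% floor.
With $\rho = 0, w = 0$ this is MCAR; $w = 1$ ties missingness to item
difficulty (MAR); $\rho < 0$ makes it MNAR because low-ability persons
skip more. The functional form of the propensity is a reconstruction:
the constraints it satisfies (centred on $\pi$, floored at 1%, driven by
$\xi$ and optionally by $\delta_j$) are fixed, and the slope $0.4\pi$ was
calibrated once so that the expected number of persons failing the 50%
imputation-eligibility rule matches the reference counts of roughly
6 / 37 / 97 persons per 500 at $\pi = 10/20/30\%$; the item slope
$0.4\pi$ is the symmetric choice that preserves the mean rate because
$\sum_j \delta_j = 0$. This is the one deliberately approximate component
of the generator, and quantities that are sensitive to the *shape* of the
per-person missing-count distribution (notably the $\sigma^2$ inflation
of mean-score imputation) inherit a few percent of reconstruction error,
while quantities pinned by the marginal rate (ineligibility counts,
$H$ bias, $\nu$ bias) reproduce reference values closely.

Seeding is hierarchical: a master seed spawns an independent child
stream per replication and stage (latents, responses, mask, each
randomized imputation), so every strategy sees the identical incomplete
dataset and adding a strategy never perturbs another's draws.

## The sixteen strategies

Imputation is only performed for persons with a strict majority of
observed items (at least 3 of 5); ineligible persons keep their observed
responses and their missing cells stay missing. Deterministic fills
round half up (0.5 becomes 1), uniformly across methods. The `-R`
variants replace rounding by a Bernoulli draw with the same probability.

* **NOIMP / LD** — no imputation (available-case analysis) and listwise
  deletion (complete-case analysis).
* **WORST** — every eligible missing cell becomes 0.
* **PMS(-R)** — the person's observed mean.
* **IMS(-R)** — the item's observed mean.
* **CIM(-R)** — the item mean rescaled by the person's score relative to
  the observed-item means, $q_{nj} = (S_n / \sum_{k \in O_n} p_k)\,p_j$,
  clipped to $[0,1]$.
* **ICS** — the response to the most correlated other item (signed
  pairwise Pearson correlation, ties to the lowest index; if the donor
  response is missing the cell stays missing). Signed rather than
  absolute correlation is used because a negative donor would require
  reflecting its response, a step the method's description never takes.
* **LOG(-R)** — per-item logistic regression on the other items with
  forward stepwise selection by likelihood-ratio test at
  $\alpha = 0.05$. Forward-only entry is the one direction guaranteed
  feasible when covariates themselves have missing values; entry tests
  refit the nested pair on the rows complete for the candidate set.
  Cells whose selected covariates are missing stay missing.
* **MOK** — the Guttman-consistency rules: sort items easiest to hardest
  by observed positive counts (stable ties); an observed positive at a
  harder position fills 1; else an observed negative at an easier
  position fills 0; else the easier-side counts decide 0, the
  harder-side counts decide 1, and a residual Bernoulli draw from the
  item's observed rate covers the remaining case. "Follows/precedes" is
  read as *any* harder/easier position, the reading consistent with the
  rule's Guttman-error motivation. Rules use only originally observed
  responses.
* **RAS(-R) / RAI** — model-based fills from
  $p_{nj} = \mathrm{expit}(\hat\theta_n - \hat\delta_j)$ with
  $\hat\delta$ from a marginal-maximum-likelihood fit on the observed
  data and $\hat\theta_n$ a per-person estimate from observed responses.
  The default person estimator is Warm's weighted likelihood estimate
  (WLE), which is finite at extreme scores; expected a posteriori (EAP)
  under $N(0, \hat\sigma^2)$ is available via `estimator = "eap"`. RAI
  iterates fit-then-fill deterministically to a fixed point, capped at
  ten iterations.

## Estimation stack

`fit_rasch()` maximizes the marginal likelihood with the latent trait
integrated out by non-adaptive Gauss-Hermite quadrature (30 nodes by
default; the suite asserts order-robustness against 60 nodes). Persons
are grouped by (observed-item set, response) pattern — at most $3^J$
groups — so the cost is essentially independent of $N$; the optimizer is
BFGS on $(\delta, \log\sigma)$ with analytic gradients, restarted until
the per-person gradient max-norm falls below $10^{-6}$. Missing
responses simply drop out of each person's likelihood product, which is
exactly available-case analysis. The identifiability constraint is
$\mu = 0$ by default; $\sum_j \delta_j = 0$ with free $\mu$ is
available, and $\hat\nu = \bar{\hat\delta} - \hat\mu$ is invariant
between the two (asserted to $10^{-6}$), which is what makes $\nu$ the
right location summary to track for bias. $\mathrm{Var}(\delta)$ uses
the population divisor $J$, so the generating bank's value is exactly
0.5. $\nu$ itself is not printed as a formula in the methods literature
the package follows; $\bar\delta - \mu$ is adopted because it is
constraint-invariant and a positive bias on it means globally
overestimated difficulties, matching the intended interpretation.

The Q1 test conditions on the score: within each non-extreme score group
$r$, observed positive counts per item are compared with
$N_r\,\epsilon_j \gamma^{(j)}_{r-1} / \gamma_r$, where the
$\gamma$ are elementary symmetric functions of
$\epsilon_j = e^{-\delta_j}$ computed by the stable summation recursion.
The statistic carries van den Wollenberg's $(J-1)/J$ correction. Its
degrees of freedom deserve a note: the classical count for $J$ items and
$J-1$ score groups is $(J-1)^2$, but the conditional probabilities are
evaluated at $J-1$ free *estimated* item parameters, and with that count
the test is far too conservative (empirical size below 1% at nominal
5%). The default therefore subtracts a further $J-1$, giving
$(J-1)(J-2) = 12$ for five items, under which the empirical size on
data simulated from the fitted model sits inside the binomial band of
5% — the calibration the test suite checks. `df_adjust = FALSE`
restores the classical count. Because score groups are undefined for
incomplete response vectors, Q1 is computed on complete rows only.

Loevinger's $H$ is the ratio-of-sums form
$\sum_{j<k}\mathrm{Cov}_{jk} / \sum_{j<k}\mathrm{Cov}^{(0)}_{jk}$ with
each pair evaluated on the persons observing both items and the maximum
covariance $\min(p_j,p_k) - p_j p_k$ recomputed from that joint
subsample — the pairwise handling that keeps $H$ asymptotically unbiased
under MCAR deletion. Degenerate pairs are dropped from both sums.

The PSI is the separation form $(V - \overline{se^2})/V$ with $V$ the
empirical variance of the person estimates and $\overline{se^2}$ their
mean squared standard error, computed from the same WLE estimates used
elsewhere. The reference formula is not printed in the source
literature, so this reconstruction carries risk: its *level* (about 0.25
on complete five-item data) and hence the size of paired biases need not
match the original implementation, but the directions — mean-score
imputation inflates PSI, item-mean imputation deflates it — are robust
to the formula choice and are what the test suite pins down.

## The bias study

`run_replication()` simulates one complete dataset, imposes missingness,
applies every requested strategy to the same incomplete data, and
computes all six quantities per strategy plus the full-data (FC)
reference. `aggregate_study()` turns replications into the bias table:
$H$ and PSI biases are means of *paired* per-replication differences to
the FC value; $\nu$, $\mathrm{Var}(\delta)$ and $\sigma^2$ biases
compare replication-averaged estimates to the generating truths (0, 0.5,
1), with $\mathrm{Var}(\delta)$ computed from the replication-averaged
difficulty estimates; the Q1 entry is the rejection rate at the 5% level
with a Wald 95% interval (Clopper-Pearson via `ci = "exact"`).
Negligibility flags use thresholds of 0.05 ($H$, PSI), 0.1 ($\nu$), 0.2
($\mathrm{Var}(\delta)$), the interval $[0.71, 1.37]$ for
$\hat\sigma^2$ (the central 95% interval of complete-data estimates),
and an interval containing 5% for Q1. Strategies that fail on a
replication (e.g. a non-convergent fit) contribute a missing entry and
the effective replication count is reported, rather than aborting the
study or zero-filling.

```{r, eval = FALSE}
cfg <- sim_config(N = 500, replications = 200, seed = 20110714)
res <- run_study(cfg, methods = c("NOIMP", "LD", "PMS", "PMS-R"),
                 pi = 0.3, rho = 0, w = 0, out_dir = "results")
subset(res, parameter == "H")
```

## Problem sizes and what the tests show

The package's own validation runs the full pipeline at the study's
native scale ($N = 500$, $J = 5$): 1000 replications for the cheap
quantities (eligibility counts, $H$ bias, the $\hat\sigma^2$ interval)
and 200-500 replications for quantities requiring a model fit per
replication, sizes at which the Monte-Carlo standard errors are an order
of magnitude below the tolerances being asserted. Large-sample
invariants (latent correlations, marginal rates, parameter recovery) use
$10^5$-$10^6$ draws, where the pattern-grouped fit keeps the cost in
seconds.

The generator emulates the study conditions — unidimensional Rasch
responses, normal latent trait, cell-independent non-response given the
propensity — and deliberately not other features of real PRO data:
multidimensionality, local dependence, polytomous items, longitudinal
dropout, or covariate-driven MAR. Conclusions about imputation bias
transfer to real data only to the extent that those assumptions hold;
what the passing tests demonstrate is that *under the stated model* the
implementation reproduces the published bias landscape.

## Known limitations

* The propensity's algebraic form is a calibrated reconstruction (see
  above); shape-sensitive biases carry a few percent of error.
* The PSI formula is a reconstruction; only its paired-difference
  directions are validated.
* The Q1 degrees of freedom are calibrated behaviourally for MML
  estimates; with other estimation methods the classical count may be
  appropriate.
* Deterministic Rasch imputation (RAS/RAI) interacts with the discrete
  support of five-item person estimates, making its
  $\mathrm{Var}(\delta)$ bias sensitive to the person-estimator choice;
  the magnitude, not the sign, of the reference value is reproduced.
* Conditional maximum likelihood, multiple imputation, hot-deck,
  response-function and two-way imputation are out of scope.
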