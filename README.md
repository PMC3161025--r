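# raschmiss

Bias of single-imputation strategies in Rasch-model validation of
dichotomous questionnaires with missing item responses.

Patient-reported-outcome (PRO) scales are validated with the Rasch
model, under which person *n* endorses item *j* with probability

    P(X_nj = 1 | theta_n) = exp(theta_n - delta_j) / (1 + exp(theta_n - delta_j)),

where `theta_n ~ N(mu, sigma^2)` is the latent trait and `delta_j` the
item difficulty. Validation hinges on a few indices — the Loevinger
scalability coefficient H, the difficulty estimates (their location
`nu = mean(delta) - mu` and dispersion `Var(delta)`), the latent
variance `sigma^2`, the Q1 goodness-of-fit test, and the person
separation index (PSI) — all of which can be distorted when skipped
items are filled in by the simple imputation rules that scoring manuals
recommend (most commonly the personal mean score).

`raschmiss` packages everything needed to measure those distortions:

* a simulator of complete Rasch data plus MCAR/MAR/MNAR item
  non-response driven by a latent response propensity `xi` correlated
  `rho` with the trait and optionally (`w = 1`) with item difficulty;
* sixteen missing-data strategies: no imputation (NOIMP), listwise
  deletion (LD), worst case (WORST), personal mean score (PMS/PMS-R),
  item mean score (IMS/IMS-R), corrected item mean (CIM/CIM-R), item
  correlation substitution (ICS), stepwise logistic models (LOG/LOG-R),
  Mokken Guttman rules (MOK), and Rasch-model imputation
  (RAS/RAS-R/RAI), all under the 50%-eligibility rule;
* marginal-maximum-likelihood Rasch estimation on incomplete data
  (Gauss–Hermite quadrature, pattern-grouped, analytic gradients),
  WLE/EAP person estimation, the Q1 fit test, pairwise Loevinger H and
  the PSI;
* a study layer that runs conditions x methods x replications and
  reports paired biases with Monte-Carlo errors and negligibility flags.

## Worked example

One replication of the harshest study condition (N = 500, five items at
difficulties -1…1, 30% missingness, MCAR), imputed by personal mean
score:

```r
library(raschmiss)
cfg <- sim_config(N = 500, pi = 0.3, rho = 0, w = 0, seed = 20110714)
sim <- simulate_replication(cfg, 1)
sim$incomplete
#> response_data: 500 persons x 5 items, 30.5% missing

filled <- handle_missing(sim$incomplete, "PMS")
attr(filled, "imputation")
#> PMS imputation: 445 cell(s) filled, 317 left missing

loevinger_h(sim$complete)   # complete-data reference
#> Loevinger H = 0.2152 (10 item pairs)
loevinger_h(filled)
#> Loevinger H = 0.4065 (10 item pairs)

fit_rasch(sim$complete)
#>   mu = 0.000  sigma2 = 0.871  nu = 0.016  Var(delta) = 0.482
fit_rasch(filled)
#>   mu = 0.000  sigma2 = 2.444  nu = 0.053  Var(delta) = 0.377
```

On this single dataset PMS nearly doubles the scalability coefficient
(0.22 to 0.41) and almost triples the estimated latent variance (0.87
to 2.44): the imputation manufactures scale quality and person
heterogeneity that are not in the data. Averaged over replications by
`run_study()`, these become the bias tables; the headline pattern is
that every method ignoring either the person's level or the item's
difficulty — and every method without a random component — biases
several validation indices, while available-case analysis (NOIMP) and
randomized Rasch imputation (RAS-R) stay close to the complete-data
reference.

```r
res <- run_study(sim_config(N = 500, replications = 200, seed = 1),
                 methods = c("NOIMP", "PMS", "PMS-R"),
                 pi = 0.3, rho = 0, w = 0, out_dir = "results")
```

A thin CLI over the same functions lives in `inst/cli/raschmiss.R`
(subcommands `impute`, `fit`, `indices`, `study`).

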