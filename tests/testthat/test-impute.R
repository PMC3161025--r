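test_that("the 50 percent rule is a strict majority of observed items", {
  m5 <- rbind(c(1, 0, 1, NA, NA),    # 3 observed: eligible
              c(1, 0, NA, NA, NA),   # 2 observed: not
              c(1, 1, 1, 1, 1))
  expect_equal(eligible_rows(response_data(m5)), c(1L, 3L))
  m4 <- rbind(c(1, 0, NA, NA),       # 2 of 4 is not a strict majority
              c(1, 0, 1, NA))
  expect_equal(eligible_rows(response_data(m4)), 2L)
})

test_that("worst-case imputation zero-fills only eligible missing cells", {
  d <- response_data(rbind(c(1, NA, 1, 1, 0),
                           c(1, 1, 1, 1, 0),
                           c(1, NA, NA, NA, NA)))
  imp <- impute_worst(d)
  expect_equal(imp$values[1, ], c(1, 0, 1, 1, 0), ignore_attr = TRUE)
  expect_equal(imp$values[2, ], c(1, 1, 1, 1, 0), ignore_attr = TRUE)
  expect_equal(imp$values[3, ], c(1, NA, NA, NA, NA), ignore_attr = TRUE)
  expect_equal(sum(imp$imputed_mask), 1)
  expect_equal(sum(imp$residual_missing), 4)
})

test_that("personal mean score fills round half-up and draw correctly", {
  d <- response_data(rbind(c(1, 1, 0, 1, NA),     # p = 0.75 -> 1
                           c(1, 0, NA, 0, 1)))    # p = 0.5  -> 1 (tie up)
  imp <- impute_pms(d)
  expect_equal(imp$values[1, 5], 1, ignore_attr = TRUE)
  expect_equal(imp$values[2, 3], 1, ignore_attr = TRUE)
  expect_equal(imp$probs[1, 5], 0.75)
  # randomized fill frequency obeys the Bernoulli parameter
  many <- response_data(matrix(rep(c(1, 1, 0, 1, NA), each = 4e4),
                               ncol = 5))
  freq <- mean(impute_pms(many, randomized = TRUE, seed = 5)$values[, 5])
  expect_equal(freq, 0.75, tolerance = 0.005)
})

test_that("item mean score fills from observed item rates", {
  # rates (0.8, 0.6, 0.5, 0.4, 0.2) -> deterministic fills (1, 1, 1, 0, 0)
  base <- sapply(c(0.8, 0.6, 0.5, 0.4, 0.2),
                 function(p) rep(c(1, 0), round(c(p, 1 - p) * 10)))
  full <- impute_ims(response_data(rbind(base, c(1, 0, 1, NA, NA))))
  expect_equal(full$values[11, 4:5], c(0, 0), ignore_attr = TRUE)   # rates 0.4, 0.2 round down
  expect_equal(full$probs[11, 4], 0.4)
  # a rate of exactly 0.5 rounds up under the tie rule
  tie <- response_data(rbind(c(1, 1, NA), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(impute_ims(tie)$values[1, 3], 1, ignore_attr = TRUE)
})

test_that("item mean score leaves wholly unobserved items missing", {
  m <- rbind(c(1, 0, NA), c(0, 1, NA), c(1, 1, NA))
  expect_warning(imp <- impute_ims(response_data(m)), "without observed")
  expect_true(all(is.na(imp$values[, 3])))
  expect_equal(sum(imp$residual_missing[, 3]), 3)
})

test_that("corrected item mean matches hand-computed values", {
  m <- rbind(c(1, 1, NA),
             c(1, 0, 1),
             c(0, 0, NA),
             c(1, 1, 1))
  d <- response_data(m)
  p <- colMeans(m, na.rm = TRUE)          # (0.75, 0.5, 1)
  imp <- impute_cim(d)
  # person 1: S = 2, observed set {1,2}: q = 2 / (p1 + p2) * p3, clipped
  q1 <- min(2 / (p[1] + p[2]) * p[3], 1)
  expect_equal(imp$probs[1, 3], q1, tolerance = 1e-12)
  expect_equal(imp$values[1, 3], round_half_up(q1), ignore_attr = TRUE)
  # person 3: S = 0 -> q = 0 -> fill 0
  expect_equal(imp$probs[3, 3], 0)
  expect_equal(imp$values[3, 3], 0, ignore_attr = TRUE)
})

test_that("corrected item mean clips at one for strong responders", {
  m <- rbind(c(1, 1, NA), c(1, 0, 0), c(0, 1, 1), c(0, 0, 0))
  imp <- impute_cim(response_data(m))
  expect_lte(max(imp$probs, na.rm = TRUE), 1)
  expect_equal(imp$values[1, 3], 1, ignore_attr = TRUE)
})

test_that("item correlation substitution uses the most correlated donor", {
  set.seed(42)
  a <- rbinom(200, 1, 0.5)
  b <- a                              # perfect copy of a
  c3 <- rbinom(200, 1, 0.5)
  m <- cbind(a, b, c3)
  m[1, 1] <- NA
  d <- response_data(m)
  imp <- impute_ics(d)
  expect_equal(imp$values[1, 1], m[1, 2], ignore_attr = TRUE)   # donor is the perfect copy
  # donor map equals an argmax over independently computed correlations
  donor <- attr(imp, "donor")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- NA
  expect_equal(unname(donor), unname(apply(r, 1, which.max)))
})

test_that("item correlation substitution leaves missing-donor cells empty", {
  set.seed(43)
  a <- rbinom(100, 1, 0.5)
  m <- cbind(a, a, rbinom(100, 1, 0.5), rbinom(100, 1, 0.4),
             rbinom(100, 1, 0.6))
  m[7, 1] <- NA
  m[7, 2] <- NA                       # donor of item 1 is item 2: missing
  imp <- impute_ics(response_data(m))
  expect_true(is.na(imp$values[7, 1]))
  expect_equal(imp$residual_missing[7, 1], 1, ignore_attr = TRUE)
})

test_that("logistic imputation reduces to the item mean when nothing predicts", {
  set.seed(44)
  m <- cbind(rbinom(400, 1, 0.7), rbinom(400, 1, 0.5), rbinom(400, 1, 0.5),
             rbinom(400, 1, 0.5), rbinom(400, 1, 0.5))
  m[1:10, 1] <- NA
  imp <- impute_log(response_data(m))
  expect_length(attr(imp, "selected")[[1]], 0)
  expect_true(all(imp$values[1:10, 1] ==
                    round_half_up(mean(m[-(1:10), 1]))))
})

test_that("logistic imputation recovers a deterministic predictor", {
  set.seed(45)
  k <- rbinom(300, 1, 0.5)
  m <- cbind(k, k, rbinom(300, 1, 0.5), rbinom(300, 1, 0.5),
             rbinom(300, 1, 0.5))
  m[1:15, 1] <- NA
  imp <- impute_log(response_data(m))
  expect_true(2 %in% attr(imp, "selected")[[1]])
  expect_equal(imp$values[1:15, 1], m[1:15, 2], ignore_attr = TRUE)
})

test_that("stepwise entry only accepts covariates passing the LRT", {
  sim <- fixture_simulated(N = 800, pi = 0.15, seed = 77)
  imp <- impute_log(sim$incomplete, alpha = 0.05)
  v <- sim$incomplete$values
  for (j in seq_len(5)) {
    sel <- attr(imp, "selected")[[j]]
    if (is.null(sel) || !length(sel)) next
    # each accepted covariate improves deviance significantly when added
    # last, per an independent refit on the same complete rows
    use <- !is.na(v[, j]) & rowSums(is.na(v[, sel, drop = FALSE])) == 0
    full <- glm(v[use, j] ~ v[use, sel, drop = FALSE], family = binomial)
    expect_true(full$deviance < full$null.deviance)
  }
})

test_that("Mokken rules follow the Guttman ordering", {
  # construct data whose observed positive counts order the items 1..5
  base <- t(sapply(seq_len(20), function(i) as.numeric(1:5 <= (i %% 6))))
  mk <- function(row) response_data(rbind(row, base))
  # rule (a): positive response at a harder position
  imp <- impute_mok(mk(c(1, NA, 1, 0, 0)))
  expect_equal(imp$values[1, 2], 1, ignore_attr = TRUE)
  # rule (b): negative response at an easier position
  imp <- impute_mok(mk(c(1, 0, NA, 0, 0)))
  expect_equal(imp$values[1, 3], 0, ignore_attr = TRUE)
  # rule (b) on a non-monotone row after (a) fails
  imp <- impute_mok(mk(c(0, 1, 1, NA, NA)))
  expect_equal(imp$values[1, 4], 0, ignore_attr = TRUE)
  expect_equal(imp$values[1, 5], 0, ignore_attr = TRUE)
  # trailing missing with all-positive prefix: (a),(b) fail, (c) fails
  # (no negatives precede, two positives), (d) fires on empty suffix
  imp <- impute_mok(mk(c(1, 1, 1, 1, NA)))
  expect_equal(imp$values[1, 5], 1, ignore_attr = TRUE)
  # ineligible rows stay untouched
  imp <- impute_mok(mk(c(1, 1, NA, NA, NA)))
  expect_true(all(is.na(imp$values[1, 3:5])))
})

test_that("Rasch imputation probabilities equal the model formula", {
  sim <- fixture_simulated(N = 400, pi = 0.2, seed = 88)
  imp <- impute_rasch(sim$incomplete)
  fit <- attr(imp, "fit")
  pe <- suppressWarnings(estimate_persons(fit, sim$incomplete))
  idx <- which(imp$imputed_mask == 1, arr.ind = TRUE)
  direct <- plogis(pe$theta_hat[idx[, 1]] - fit$delta_hat[idx[, 2]])
  expect_equal(unname(imp$probs[idx]), unname(direct), tolerance = 1e-12)
  expect_equal(unname(imp$values[idx]), unname(round_half_up(direct)))
})

test_that("iterative Rasch imputation reaches a fixed point within ten passes", {
  sim <- fixture_simulated(N = 250, pi = 0.2, seed = 89)
  imp <- impute_rasch_iterative(sim$incomplete)
  expect_lte(attr(imp, "iterations"), 10)
  # replaying one more deterministic pass on the final fill changes nothing
  cur <- completed_data(imp)
  fit <- fit_rasch(cur)
  pe <- estimate_persons(fit, cur)
  p <- plogis(outer(pe$theta_hat, fit$delta_hat, "-"))
  idx <- imp$imputed_mask == 1
  if (attr(imp, "iterations") < 10)
    expect_equal(unname(imp$values[idx]), unname(round_half_up(p[idx])))
})

test_that("listwise deletion keeps exactly the complete rows", {
  sim <- fixture_simulated(N = 2000, pi = 0.3, seed = 90)
  expect_identical(listwise_delete(sim$complete)$values,
                   sim$complete$values)
  ld <- listwise_delete(sim$incomplete)
  expect_false(anyNA(ld$values))
  # retained fraction matches E[(1 - pi_n)^5] by quadrature
  expected <- integrate(function(x) {
    p <- pmin(pmax(0.3 * (1 + 0.4 * x), 0.01), 1)
    (1 - p)^5 * dnorm(x)
  }, -Inf, Inf)$value
  expect_equal(nrow(ld$values) / 2000, expected, tolerance = 0.05)
  allna <- response_data(matrix(c(1, NA, NA, 1), 2, 2))
  expect_error(listwise_delete(allna), "every person")
})

test_that("no method ever alters an observed response", {
  sim <- fixture_simulated(N = 200, pi = 0.25, seed = 91)
  obs <- !is.na(sim$incomplete$values)
  for (m in setdiff(imputation_methods(), "LD")) {
    out <- handle_missing(sim$incomplete, m, seed = 3)
    expect_identical(out$values[obs], sim$incomplete$values[obs],
                     info = m)
  }
})

test_that("deterministic methods are idempotent on their own output", {
  sim <- fixture_simulated(N = 200, pi = 0.25, seed = 92)
  for (m in c("WORST", "PMS", "IMS", "CIM", "RAS")) {
    once <- handle_missing(sim$incomplete, m)
    twice <- handle_missing(once, m)
    expect_identical(once$values, twice$values, info = m)
  }
})

test_that("deterministic fills are the mode of the randomized distribution", {
  sim <- fixture_simulated(N = 200, pi = 0.25, seed = 93)
  for (m in c("PMS", "IMS", "CIM", "RAS")) {
    det <- attr(handle_missing(sim$incomplete, m), "imputation")
    p <- det$probs[det$imputed_mask == 1]
    v <- det$values[det$imputed_mask == 1]
    off_tie <- abs(p - 0.5) > 1e-9
    expect_identical(v[off_tie], as.numeric(p[off_tie] > 0.5), info = m)
  }
})
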