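# Independent oracles used across the suite.  All are brute-force or
# quadrature routines deliberately separate from the package internals.

# marginal P(X_j = 1) under theta ~ N(mu, sigma2), by adaptive quadrature
oracle_marginal_rate <- function(delta_j, mu = 0, sigma2 = 1) {
  integrate(function(t) plogis(t - delta_j) * dnorm(t, mu, sqrt(sigma2)),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# mean of clip(pi (1 + 0.4 xi), floor, 1) over xi ~ N(0,1)
oracle_clip_mean <- function(pi, floor = 0.01) {
  integrate(function(x) pmin(pmax(pi * (1 + 0.4 * x), floor), 1) * dnorm(x),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# E[ P(Binomial(J, p_n) >= k) ] with p_n = clip(pi (1 + 0.4 xi), floor, 1)
oracle_ineligible_rate <- function(pi, J = 5, k = 3, floor = 0.01) {
  integrate(function(x) {
    p <- pmin(pmax(pi * (1 + 0.4 * x), floor), 1)
    pbinom(k - 1, J, p, lower.tail = FALSE) * dnorm(x)
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

# elementary symmetric functions by exhaustive subset enumeration
oracle_esf <- function(eps) {
  J <- length(eps)
  vapply(0:J, function(r) {
    if (r == 0) return(1)
    sum(apply(combn(J, r), 2, function(s) prod(eps[s])))
  }, 0)
}

# score-conditional P(X_j = 1 | R = r) by enumerating all 2^J patterns at
# a fixed theta (sufficiency: the result must not depend on theta)
oracle_conditional_prob <- function(delta, theta, j, r) {
  J <- length(delta)
  patterns <- as.matrix(expand.grid(rep(list(0:1), J)))
  p <- plogis(theta - delta)
  prob <- apply(patterns, 1, function(x) prod(p^x * (1 - p)^(1 - x)))
  sel <- rowSums(patterns) == r
  sum(prob[sel & patterns[, j] == 1]) / sum(prob[sel])
}

# Loevinger H from explicit 2x2 contingency tables (complete data)
oracle_h_complete <- function(v) {
  J <- ncol(v)
  num <- den <- 0
  for (j in seq_len(J - 1)) for (k in (j + 1):J) {
    n <- nrow(v)
    n11 <- sum(v[, j] == 1 & v[, k] == 1)
    pj <- sum(v[, j]) / n
    pk <- sum(v[, k]) / n
    num <- num + (n11 / n - pj * pk)
    den <- den + (min(pj, pk) - pj * pk)
  }
  num / den
}

# brute-force marginal log-likelihood for complete data (adaptive
# quadrature per response pattern) -- oracle for the MML engine
oracle_marginal_loglik <- function(v, delta, mu, sigma2) {
  key <- apply(v, 1, paste, collapse = "")
  tab <- table(key)
  sum(vapply(names(tab), function(k) {
    x <- as.numeric(strsplit(k, "")[[1]])
    lik <- integrate(function(t) {
      p <- plogis(outer(t, delta, "-"))
      apply(p, 1, function(pr) prod(pr^x * (1 - pr)^(1 - x))) *
        dnorm(t, mu, sqrt(sigma2))
    }, -Inf, Inf, rel.tol = 1e-10)$value
    tab[[k]] * log(lik)
  }, 0))
}

# a small deterministic incomplete fixture used by several files
fixture_incomplete <- function() {
  m <- rbind(
    c(1, 1, 0, 1, NA),
    c(0, NA, 0, 0, 1),
    c(1, 1, 1, NA, NA),
    c(NA, NA, NA, 1, 0),   # ineligible: 2 observed
    c(1, 0, 1, 0, 1),
    c(0, 0, NA, 1, 1),
    c(1, NA, 1, 1, 0),
    c(0, 1, 0, NA, 1))
  response_data(m)
}

# moderately sized simulated incomplete dataset for property checks
fixture_simulated <- function(N = 300, pi = 0.25, rho = 0, w = 0,
                              seed = 420) {
  cfg <- sim_config(N = N, pi = pi, rho = rho, w = w, replications = 1,
                    seed = seed)
  simulate_replication(cfg, 1)
}
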