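#' Marginal maximum likelihood estimation of the Rasch model
#'
#' Fits the dichotomous Rasch model
#' \eqn{P(X_{nj} = 1 | \theta_n) = \mathrm{expit}(\theta_n - \delta_j)}
#' by maximizing the marginal likelihood, integrating the normal ability
#' distribution \eqn{N(\mu, \sigma^2)} out with (non-adaptive)
#' Gauss-Hermite quadrature.  Missing responses are handled by restricting
#' each person's likelihood contribution to their observed items, so the
#' fit uses every observed response (available-case analysis).
#'
#' Persons are grouped by their (observed-item set, response) pattern:
#' with J items there are at most \eqn{3^J} patterns, which makes the fit
#' essentially independent of the sample size.
#'
#' @param data a \code{\link{response_data}} object (complete or not).
#' @param constraint identifiability constraint: \code{"mu0"} fixes the
#'   latent mean at 0 and frees all J difficulties (the study's choice);
#'   \code{"sumdelta"} constrains the difficulties to sum to 0 and frees
#'   \eqn{\mu}.  The location summary \eqn{\nu = \bar\delta - \mu} is
#'   estimable and identical under either constraint.
#' @param quad number of Gauss-Hermite nodes (default 30).
#' @param max_restarts BFGS is restarted from the current optimum until
#'   the gradient norm drops below \code{tol} or this many restarts.
#' @param tol per-person gradient max-norm defining convergence
#'   (default 1e-6).
#' @return an object of class \code{rasch_fit} with components
#'   \code{delta_hat}, \code{mu_hat}, \code{sigma2_hat}, \code{nu_hat}
#'   (\eqn{\bar{\hat\delta} - \hat\mu}), \code{var_delta_hat} (population
#'   variance of the difficulties, divisor J), \code{loglik},
#'   \code{converged}, \code{iterations}, \code{gradient_norm},
#'   \code{quad}, \code{constraint}.
#' @export
fit_rasch <- function(data, constraint = c("mu0", "sumdelta"), quad = 30,
                      max_restarts = 4, tol = 1e-6) {
  constraint <- match.arg(constraint)
  v <- data$values
  J <- ncol(v)
  n1 <- colSums(v == 1, na.rm = TRUE)
  n0 <- colSums(v == 0, na.rm = TRUE)
  bad <- which(n1 == 0 | n0 == 0)
  if (length(bad))
    stop("degenerate item(s) without both response categories: ",
         paste(colnames(v)[bad], collapse = ", "))

  pat <- group_patterns(v)
  gh <- pracma::gaussHermite(quad)
  wn <- gh$w / sqrt(pi)          # normalized N(0,1) quadrature weights
  tq <- gh$x

  obj <- function(par) rasch_negll(par, pat, tq, wn, J, constraint)
  grd <- function(par) rasch_negll_grad(par, pat, tq, wn, J, constraint)

  # moment-style start: marginal positive rates mapped back through the
  # approximate normal-ogive scaling expit(x / sqrt(1 + 0.59 sigma^2))
  p_obs <- pmin(pmax(n1 / (n1 + n0), 0.01), 0.99)
  d0 <- -log(p_obs / (1 - p_obs)) * sqrt(1.35)
  par <- switch(constraint,
    mu0 = c(d0, 0),
    sumdelta = c(d0[-J] - mean(d0), -mean(d0), 0))

  iters <- 0L
  n_eff <- sum(pat$counts)
  for (k in seq_len(max_restarts + 1)) {
    opt <- optim(par, obj, grd, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    par <- opt$par
    iters <- iters + opt$counts[["function"]]
    gnorm <- max(abs(grd(par))) / n_eff   # per-person gradient norm
    if (gnorm < tol) break
  }

  est <- rasch_unpack(par, J, constraint)
  delta <- est$delta
  names(delta) <- colnames(v)
  structure(list(
    delta_hat = delta,
    mu_hat = as.numeric(est$mu),
    sigma2_hat = as.numeric(est$sigma^2),
    nu_hat = as.numeric(mean(delta) - est$mu),
    var_delta_hat = mean((delta - mean(delta))^2),
    loglik = -opt$value,
    converged = gnorm < max(tol, 1e-4),
    gradient_norm = gnorm,
    iterations = iters,
    quad = quad,
    constraint = constraint), class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "Rasch MML fit (%s, %d-node quadrature)%s\n",
    x$constraint, x$quad, if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  delta:", sprintf("%.3f", x$delta_hat), "\n")
  cat(sprintf("  mu = %.3f  sigma2 = %.3f  nu = %.3f  Var(delta) = %.3f\n",
              x$mu_hat, x$sigma2_hat, x$nu_hat, x$var_delta_hat))
  cat(sprintf("  logLik = %.3f\n", x$loglik))
  invisible(x)
}

# collapse rows of a 0/1/NA matrix into unique patterns with counts
group_patterns <- function(v) {
  keep <- rowSums(!is.na(v)) > 0
  v <- v[keep, , drop = FALSE]
  key <- apply(v, 1, function(r) paste(ifelse(is.na(r), "m", r),
                                       collapse = ""))
  idx <- which(!duplicated(key))
  U <- v[idx, , drop = FALSE]
  counts <- as.numeric(table(factor(key, levels = key[idx])))
  X1 <- (U == 1) & !is.na(U)
  X0 <- (U == 0) & !is.na(U)
  list(X1 = X1 * 1, X0 = X0 * 1, OBS = (X1 | X0) * 1,
       counts = counts, score = rowSums(X1),
       n_dropped = sum(!keep))
}

rasch_unpack <- function(par, J, constraint) {
  if (constraint == "mu0") {
    list(delta = par[1:J], mu = 0, sigma = exp(par[J + 1]))
  } else {
    d <- par[1:(J - 1)]
    list(delta = c(d, -sum(d)), mu = par[J], sigma = exp(par[J + 1]))
  }
}

# shared pieces of the marginal likelihood at a parameter point
rasch_mll_parts <- function(par, pat, tq, wn, J, constraint) {
  est <- rasch_unpack(par, J, constraint)
  theta <- est$mu + sqrt(2) * est$sigma * tq       # Q nodes
  z <- outer(theta, est$delta, "-")                # Q x J logits
  P <- expit(z)
  logP <- -log1p(exp(-z))                          # stable log expit
  log1mP <- -log1p(exp(z))
  logf <- logP %*% t(pat$X1) + log1mP %*% t(pat$X0)  # Q x U
  m <- apply(logf, 2, max)
  f <- exp(sweep(logf, 2, m, "-"))
  g <- f * wn                                      # Q x U, scaled
  L <- colSums(g)                                  # scaled marginal liks
  list(est = est, theta = theta, P = P, g = g, L = L, m = m)
}

rasch_negll <- function(par, pat, tq, wn, J, constraint) {
  p <- rasch_mll_parts(par, pat, tq, wn, J, constraint)
  -sum(pat$counts * (log(p$L) + p$m))
}

rasch_negll_grad <- function(par, pat, tq, wn, J, constraint) {
  p <- rasch_mll_parts(par, pat, tq, wn, J, constraint)
  ratio <- pat$counts / p$L                        # U
  GP <- crossprod(p$g, p$P)                        # U x J: sum_q g_qu P_qj
  gdelta <- colSums(pat$counts * pat$X1) - colSums(ratio * GP * pat$OBS)
  Prow <- p$P %*% t(pat$OBS)                       # Q x U: sum_{j in O_u} P
  core <- sweep(-Prow, 2, pat$score, "+")          # s_u - sum P (Q x U)
  gmu <- -sum(ratio * colSums(p$g * core))
  glsig <- -sum(ratio * colSums(p$g * core * (p$theta - p$est$mu)))
  if (constraint == "mu0") {
    c(gdelta, glsig)
  } else {
    c(gdelta[1:(J - 1)] - gdelta[J], gmu, glsig)
  }
}

#' Person ability estimates from a Rasch fit
#'
#' Computes per-person latent-trait estimates from the observed responses
#' only.  The default is Warm's weighted likelihood estimate (WLE), which
#' remains finite at extreme scores; expected-a-posteriori (EAP) estimates
#' under \eqn{N(\hat\mu, \hat\sigma^2)} are available as an alternative.
#' In the Rasch model both depend on a person's data only through the
#' observed-item set and the score, so persons are grouped accordingly.
#'
#' @param fit a \code{rasch_fit}.
#' @param data the \code{response_data} the estimates are wanted for.
#' @param estimator \code{"wle"} (default) or \code{"eap"}.
#' @param quad quadrature order for EAP posteriors.
#' @return an object of class \code{person_estimates}: \code{theta_hat}
#'   and \code{se} (length N, \code{NA} for persons with no observed
#'   response, who are excluded with a warning), plus the estimator label.
#' @export
estimate_persons <- function(fit, data, estimator = c("wle", "eap"),
                             quad = 60) {
  estimator <- match.arg(estimator)
  v <- data$values
  N <- nrow(v)
  delta <- fit$delta_hat
  obs <- !is.na(v)
  nobs <- rowSums(obs)
  if (any(nobs == 0))
    warning(sum(nobs == 0), " person(s) without observed responses excluded")
  score <- rowSums(v == 1 & obs)
  key <- paste(apply(obs, 1, paste, collapse = ""), score)
  theta <- se <- rep(NA_real_, N)
  for (k in unique(key[nobs > 0])) {
    rows <- which(key == k)
    d <- delta[obs[rows[1], ]]
    s <- score[rows[1]]
    est <- if (estimator == "wle") wle_one(s, d)
           else eap_one(s, d, fit$mu_hat, fit$sigma2_hat, quad)
    theta[rows] <- est[1]
    se[rows] <- est[2]
  }
  structure(list(theta_hat = theta, se = se, estimator = estimator),
            class = "person_estimates")
}

# Warm's WLE for one (item set, score): solve s - sum P + I'/(2I) = 0
wle_one <- function(s, d, lim = 20) {
  h <- function(th) {
    P <- expit(th - d)
    info <- sum(P * (1 - P))
    s - sum(P) + sum(P * (1 - P) * (1 - 2 * P)) / (2 * info)
  }
  th <- uniroot(h, c(-lim, lim), tol = 1e-10)$root
  P <- expit(th - d)
  c(th, 1 / sqrt(sum(P * (1 - P))))
}

# EAP posterior mean/SD for one (item set, score) under N(mu, sigma2)
eap_one <- function(s, d, mu, sigma2, quad) {
  gh <- pracma::gaussHermite(quad)
  th <- mu + sqrt(2 * sigma2) * gh$x
  wn <- gh$w / sqrt(pi)
  # likelihood of the score pattern depends on theta via s and sum log(1+e)
  ll <- s * th - vapply(th, function(t) sum(log1p(exp(t - d))), 0)
  post <- wn * exp(ll - max(ll))
  post <- post / sum(post)
  m <- sum(post * th)
  c(m, sqrt(sum(post * (th - m)^2)))
}

#' Elementary symmetric functions of item easiness parameters
#'
#' Computes \eqn{\gamma_r(\epsilon)}, the sum over all r-subsets of
#' products of \eqn{\epsilon_j = e^{-\delta_j}}, by the numerically stable
#' summation recursion.  These are the normalizing constants of the
#' score-conditional response distribution used by the Q1 fit test.
#'
#' @param eps positive numeric vector of item easiness values.
#' @return numeric vector \eqn{(\gamma_0, ..., \gamma_J)}.
#' @export
elementary_symmetric <- function(eps) {
  if (any(eps <= 0)) stop("easiness parameters must be positive")
  J <- length(eps)
  gam <- c(1, rep(0, J))
  for (j in seq_len(J)) {
    gam[(j + 1):2] <- gam[(j + 1):2] + eps[j] * gam[j:1]
  }
  gam
}

#' Q1 goodness-of-fit test for the Rasch model
#'
#' van den Wollenberg's Q1 statistic: within each non-extreme score group
#' r = 1..J-1 the observed count of positive responses to each item is
#' compared with the count expected under the fitted Rasch model,
#' \eqn{P(X_j = 1 | R = r) = \epsilon_j \gamma^{(j)}_{r-1} / \gamma_r}
#' (a quantity free of \eqn{\theta} by sufficiency of the score).  The
#' statistic, with its (J-1)/J correction, is referred to a chi-square
#' distribution.  The classical degrees of freedom for J items and J-1
#' score groups are \eqn{(J-1)^2}; because the conditional probabilities
#' are evaluated at J-1 free estimated item parameters, the default
#' subtracts a further J-1, giving \eqn{(J-1)(J-2)} for full score
#' coverage - the calibration under which the test holds its nominal
#' type-I error on data simulated from the fitted model
#' (\code{df_adjust = FALSE} restores the classical count).
#'
#' Score groups are only defined for fully observed response vectors, so
#' the test is computed on complete rows; incomplete rows are ignored.
#'
#' @param fit a \code{rasch_fit}.
#' @param data a \code{response_data}.
#' @param correction apply the (J-1)/J multiplier (default TRUE).
#' @param df_adjust subtract J-1 degrees of freedom for the estimated
#'   item parameters (default TRUE).
#' @return an object of class \code{rasch_fit_test}: \code{statistic},
#'   \code{df}, \code{p_value}, matrices of observed and expected counts
#'   (items x score groups), and the group sizes.
#' @export
q1_test <- function(fit, data, correction = TRUE, df_adjust = TRUE) {
  v <- data$values
  J <- ncol(v)
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete))
    stop("no complete response vectors; impute or listwise-delete first")
  v <- v[complete, , drop = FALSE]
  r <- rowSums(v)
  eps <- exp(-fit$delta_hat)
  gam <- elementary_symmetric(eps)
  Pjr <- matrix(0, J, J - 1)          # P(X_j = 1 | R = r)
  for (j in seq_len(J)) {
    gam_wo <- elementary_symmetric(eps[-j])
    for (s in seq_len(J - 1)) {
      Pjr[j, s] <- eps[j] * gam_wo[s] / gam[s + 1]
    }
  }
  Nr <- vapply(seq_len(J - 1), function(s) sum(r == s), 0)
  Ojr <- vapply(seq_len(J - 1),
                function(s) colSums(v[r == s, , drop = FALSE]), numeric(J))
  use <- which(Nr > 0)
  if (!length(use))
    stop("no complete rows with non-extreme scores; Q1 is undefined")
  Ejr <- sweep(Pjr, 2, Nr, "*")
  Vjr <- sweep(Pjr * (1 - Pjr), 2, Nr, "*")
  q1 <- sum((Ojr[, use, drop = FALSE] - Ejr[, use, drop = FALSE])^2 /
              Vjr[, use, drop = FALSE])
  if (correction) q1 <- q1 * (J - 1) / J
  df <- length(use) * (J - 1) - if (df_adjust) J - 1 else 0
  structure(list(statistic = q1, df = df,
                 p_value = pchisq(q1, df, lower.tail = FALSE),
                 observed = Ojr, expected = Ejr, group_sizes = Nr,
                 conditional_probs = Pjr, correction = correction),
            class = "rasch_fit_test")
}

#' @export
print.rasch_fit_test <- function(x, ...) {
  cat(sprintf("Q1 = %.3f on %d df, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
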