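#' Pairwise Loevinger H scalability coefficient
#'
#' The overall scalability coefficient of Mokken scale analysis,
#' \deqn{H = \frac{\sum_{j<k} \mathrm{Cov}(X_j, X_k)}
#'            {\sum_{j<k} \mathrm{Cov}^{(0)}(X_j, X_k)},}
#' where \eqn{\mathrm{Cov}^{(0)}_{jk} = \min(p_j, p_k) - p_j p_k} is the
#' maximum covariance attainable with the pair's marginal frequencies.
#' On incomplete data every pair is evaluated on the persons observing
#' both items (pairwise handling), with the marginals recomputed in that
#' joint subsample; this keeps the coefficient asymptotically unbiased
#' under MCAR deletion.  Pairs whose joint subsample is degenerate (an
#' item constant, or fewer than two persons) are dropped from both sums
#' with a warning.
#'
#' @param data a \code{\link{response_data}}.
#' @return an object of class \code{scalability_result}: \code{H}, the
#'   per-pair covariance table (\code{pairs}), and the number of dropped
#'   pairs.
#' @export
loevinger_h <- function(data) {
  v <- data$values
  J <- ncol(v)
  rows <- list()
  for (j in seq_len(J - 1)) {
    for (k in (j + 1):J) {
      both <- !is.na(v[, j]) & !is.na(v[, k])
      n <- sum(both)
      if (n < 2) {
        rows[[length(rows) + 1]] <- c(j, k, n, NA, NA)
        next
      }
      xj <- v[both, j]; xk <- v[both, k]
      pj <- mean(xj); pk <- mean(xk)
      if (pj %in% c(0, 1) || pk %in% c(0, 1)) {
        rows[[length(rows) + 1]] <- c(j, k, n, NA, NA)
        next
      }
      cov_jk <- mean(xj * xk) - pj * pk
      cov0_jk <- min(pj, pk) - pj * pk
      rows[[length(rows) + 1]] <- c(j, k, n, cov_jk, cov0_jk)
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("j", "k", "n_joint", "cov", "cov_max")
  ok <- !is.na(tab[, "cov"])
  if (!any(ok)) stop("Loevinger H undefined: all item pairs degenerate")
  if (any(!ok))
    warning(sum(!ok), " degenerate item pair(s) dropped from H")
  H <- sum(tab[ok, "cov"]) / sum(tab[ok, "cov_max"])
  structure(list(H = H, pairs = as.data.frame(tab),
                 n_dropped_pairs = sum(!ok)),
            class = "scalability_result")
}

#' @export
print.scalability_result <- function(x, ...) {
  cat(sprintf("Loevinger H = %.4f (%d item pairs)\n",
              x$H, sum(!is.na(x$pairs$cov))))
  invisible(x)
}

#' Person Separation Index
#'
#' A reliability-type index contrasting the dispersion of the person
#' ability estimates with their estimation error:
#' \deqn{PSI = \frac{V - \overline{se^2}}{V},}
#' with \eqn{V} the empirical variance of the ability estimates
#' \eqn{\hat\theta_n} and \eqn{\overline{se^2}} the mean squared standard
#' error.  PSI is 1 when the estimates are error-free and can be negative
#' when the error variance exceeds the observed dispersion.
#'
#' @param persons a \code{\link{estimate_persons}} result (persons with no
#'   estimate are ignored).
#' @return an object of class \code{reliability_result}: \code{psi},
#'   \code{theta_var}, \code{mean_se2}, \code{n}.
#' @export
psi <- function(persons) {
  keep <- !is.na(persons$theta_hat)
  th <- persons$theta_hat[keep]
  se <- persons$se[keep]
  if (length(th) < 2) stop("PSI needs at least two person estimates")
  V <- var(th)
  if (V == 0) stop("PSI undefined: person estimates have zero variance")
  structure(list(psi = (V - mean(se^2)) / V, theta_var = V,
                 mean_se2 = mean(se^2), n = length(th)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("PSI = %.4f  (var = %.3f, mean se^2 = %.3f, n = %d)\n",
              x$psi, x$theta_var, x$mean_se2, x$n))
  invisible(x)
}
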