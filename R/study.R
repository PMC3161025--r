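#' Parameter estimates for one dataset under one missing-data strategy
#'
#' Computes the six validation quantities the bias study tracks: the
#' pairwise Loevinger H, the Rasch location summary \eqn{\hat\nu}, the
#' across-item population variance of \eqn{\hat\delta}, the latent-trait
#' variance \eqn{\hat\sigma^2}, the Q1 rejection indicator at the 5
#' percent level, and the person separation index (WLE-based).
#'
#' @param data a \code{\link{response_data}} (already imputed / deleted /
#'   left as-is by the chosen strategy).
#' @param estimator person estimator for the PSI.
#' @return a list with components \code{H}, \code{nu}, \code{sigma2},
#'   \code{delta} (length-J vector), \code{var_delta}, \code{q1_reject}
#'   (0/1), \code{psi}.
#' @export
dataset_estimates <- function(data, estimator = "wle") {
  H <- tryCatch(loevinger_h(data)$H, error = function(e) NA_real_)
  fit <- fit_rasch(data)
  q1 <- tryCatch(q1_test(fit, data)$p_value < 0.05,
                 error = function(e) NA)
  pe <- suppressWarnings(estimate_persons(fit, data, estimator))
  psi_val <- tryCatch(psi(pe)$psi, error = function(e) NA_real_)
  list(H = H, nu = fit$nu_hat, sigma2 = fit$sigma2_hat,
       delta = fit$delta_hat, var_delta = fit$var_delta_hat,
       q1_reject = as.numeric(q1), psi = psi_val)
}

#' Run one replication of the bias study
#'
#' Simulates one complete dataset, imposes missingness, applies every
#' requested strategy to the same incomplete dataset and computes all
#' study parameters per strategy, together with the full-complete-data
#' (FC) reference estimates the paired biases difference against.  All
#' randomness comes from replication-specific child streams of the master
#' seed, so replications are reproducible in isolation and methods are
#' compared on identical data.
#'
#' @param config a \code{\link{sim_config}} (its \code{pi}, \code{rho},
#'   \code{w} define the missingness condition).
#' @param methods character vector of strategy names.
#' @param rep replication index.
#' @param estimator person estimator for the PSI.
#' @return a named list: one element per method plus \code{"FC"}, each a
#'   \code{\link{dataset_estimates}} result (a failing method yields a
#'   list of \code{NA}s, never an abort).
#' @export
run_replication <- function(config, methods = c("NOIMP", "PMS"), rep = 1L,
                            estimator = "wle") {
  sim <- simulate_replication(config, rep)
  na_est <- list(H = NA_real_, nu = NA_real_, sigma2 = NA_real_,
                 delta = rep(NA_real_, config$bank$J),
                 var_delta = NA_real_, q1_reject = NA_real_,
                 psi = NA_real_)
  out <- list()
  out[["FC"]] <- tryCatch(dataset_estimates(sim$complete, estimator),
                          error = function(e) na_est)
  for (m in methods) {
    out[[m]] <- tryCatch({
      analysed <- handle_missing(
        sim$incomplete, m,
        seed = child_seed(config$seed, rep, paste0("impute-", m)))
      dataset_estimates(analysed, estimator)
    }, error = function(e) na_est)
  }
  out
}

# population variance (divisor J) across items
pop_var <- function(x) mean((x - mean(x))^2)

#' Aggregate replication results into the study's bias table
#'
#' Computes, for each strategy, the paired biases of H and PSI (mean of
#' per-replication differences to the FC reference), the truth-referenced
#' biases of \eqn{\nu} (truth 0), \eqn{\mathrm{Var}(\delta)} (truth from
#' the generating bank, 0.5 for the default; computed from the
#' replication-averaged difficulty estimates) and \eqn{\sigma^2} (truth
#' 1), and the Q1 rejection rate with its Wald 95 percent confidence
#' interval.  Each entry carries a Monte-Carlo standard error where one
#' is defined and a negligibility flag at the study's thresholds:
#' |bias| < 0.05 for H and PSI, < 0.1 for \eqn{\nu}, < 0.2 for
#' \eqn{\mathrm{Var}(\delta)}, \eqn{\hat\sigma^2} within \[0.71, 1.37\],
#' and a Q1 confidence interval containing 5 percent.
#'
#' @param reps list of \code{\link{run_replication}} results.
#' @param var_delta_truth generating across-item difficulty variance.
#' @param ci \code{"wald"} (default) or \code{"exact"} (Clopper-Pearson)
#'   for the Q1 rejection-rate interval.
#' @return a long-format data frame with columns \code{method},
#'   \code{parameter}, \code{estimate}, \code{mc_se}, \code{n_reps},
#'   \code{negligible}.
#' @export
aggregate_study <- function(reps, var_delta_truth = 0.5, ci = "wald") {
  methods <- setdiff(names(reps[[1]]), "FC")
  pull <- function(m, f) vapply(reps, function(r) r[[m]][[f]], 0)
  rows <- list()
  add <- function(method, parameter, estimate, mc_se, n, flag) {
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, parameter = parameter, estimate = estimate,
      mc_se = mc_se, n_reps = n, negligible = flag)
  }
  mc_se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA
  for (m in methods) {
    # paired differences against the complete-data reference
    for (p in c("H", "psi")) {
      d <- pull(m, p) - pull("FC", p)
      d <- d[!is.na(d)]
      add(m, if (p == "H") "H" else "PSI", mean(d), mc_se(d), length(d),
          abs(mean(d)) < 0.05)
    }
    nu <- pull(m, "nu"); nu <- nu[!is.na(nu)]
    add(m, "nu", mean(nu), mc_se(nu), length(nu), abs(mean(nu)) < 0.1)
    s2 <- pull(m, "sigma2"); s2 <- s2[!is.na(s2)]
    add(m, "sigma2", mean(s2) - 1, mc_se(s2), length(s2),
        mean(s2) >= 0.71 && mean(s2) <= 1.37)
    dl <- vapply(reps, function(r) r[[m]]$delta, reps[[1]][[m]]$delta)
    dl <- dl[, colSums(is.na(dl)) == 0, drop = FALSE]
    vd <- pop_var(rowMeans(dl)) - var_delta_truth
    add(m, "var_delta", vd, NA, ncol(dl), abs(vd) < 0.2)
    rj <- pull(m, "q1_reject"); rj <- rj[!is.na(rj)]
    rate <- mean(rj)
    band <- if (ci == "exact") {
      stats::binom.test(sum(rj), length(rj))$conf.int
    } else {
      rate + c(-1, 1) * 1.96 * sqrt(rate * (1 - rate) / length(rj))
    }
    add(m, "q1_rejection_pct", 100 * rate,
        100 * sqrt(rate * (1 - rate) / length(rj)), length(rj),
        band[1] <= 0.05 && 0.05 <= band[2])
  }
  do.call(rbind, rows)
}

#' Mean number of persons failing the 50 percent rule
#'
#' Average, over replications, of the count of persons with too few
#' observed responses to be imputed (at most J/2 observed, i.e. 3 or more
#' missing of 5 items).  Only the missingness mask is needed, so no
#' responses are simulated.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with \code{mean_count}, \code{per_replication} and the
#'   Monte-Carlo standard error \code{mc_se}.
#' @export
ineligible_count_summary <- function(config) {
  des <- missingness_design(config$pi, config$w)
  counts <- vapply(seq_len(config$replications), function(rep) {
    lat <- draw_latents(config$N, config$rho, config$mu, config$sigma2,
                        seed = child_seed(config$seed, rep, "latents"))
    probs <- missingness_probabilities(lat, config$bank, des)
    miss <- with_seed(child_seed(config$seed, rep, "mask"),
                      matrix(runif(length(probs)) < probs, config$N))
    sum(config$bank$J - rowSums(miss) <= config$bank$J / 2)
  }, 0)
  list(mean_count = mean(counts), per_replication = counts,
       mc_se = sd(counts) / sqrt(length(counts)))
}

#' Run a bias study over a grid of missingness conditions
#'
#' Iterates conditions x methods x replications, aggregates, and writes
#' one long-format CSV per studied parameter (H, nu, Var(delta), sigma2,
#' Q1 rejection rate, PSI) with columns method, pi, rho, w, estimate,
#' mc_se, n_reps, negligible, plus a run log (per-method failure counts
#' and mean ineligible persons per condition) and a plain-text manifest
#' of the configuration.
#'
#' @param config a \code{\link{sim_config}} (its pi/rho/w are overridden
#'   by the grid).
#' @param methods strategy names to compare.
#' @param pi,rho,w vectors defining the condition grid (defaults: the
#'   full 18-cell study grid).
#' @param out_dir output directory (created if needed); \code{NULL}
#'   skips writing.
#' @param estimator person estimator for the PSI.
#' @return invisibly, a data frame of all aggregated results.
#' @export
run_study <- function(config, methods = imputation_methods(),
                      pi = c(0.10, 0.20, 0.30), rho = c(0, -0.4, -0.9),
                      w = c(0, 1), out_dir = NULL, estimator = "wle") {
  stopifnot(all(methods %in% imputation_methods()))
  grid <- expand.grid(pi = pi, rho = rho, w = w)
  all_rows <- list()
  log_lines <- character(0)
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$pi <- grid$pi[g]; cfg$rho <- grid$rho[g]; cfg$w <- grid$w[g]
    reps <- lapply(seq_len(cfg$replications), function(r)
      run_replication(cfg, methods, r, estimator))
    agg <- aggregate_study(reps,
                           var_delta_truth = pop_var(cfg$bank$difficulties))
    agg$pi <- cfg$pi; agg$rho <- cfg$rho; agg$w <- cfg$w
    all_rows[[g]] <- agg
    inel <- ineligible_count_summary(cfg)
    fails <- vapply(methods, function(m)
      sum(vapply(reps, function(r) is.na(r[[m]]$nu), TRUE)), 0)
    log_lines <- c(log_lines, sprintf(
      "pi=%.2f rho=%.2f w=%d: mean ineligible persons = %.2f; failures: %s",
      cfg$pi, cfg$rho, cfg$w, inel$mean_count,
      paste(sprintf("%s=%d", methods, fails), collapse = " ")))
  }
  res <- do.call(rbind, all_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in unique(res$parameter)) {
      write.csv(res[res$parameter == p, ],
                file.path(out_dir, paste0("table_", p, ".csv")),
                row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "study_log.txt"))
    writeLines(c(
      sprintf("N = %d", config$N),
      sprintf("difficulties = %s",
              paste(config$bank$difficulties, collapse = ", ")),
      sprintf("mu = %g", config$mu), sprintf("sigma2 = %g", config$sigma2),
      sprintf("replications = %d", config$replications),
      sprintf("seed = %d", config$seed),
      sprintf("methods = %s", paste(methods, collapse = ", ")),
      sprintf("R = %s", R.version.string)),
      file.path(out_dir, "manifest.txt"))
  }
  invisible(res)
}
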