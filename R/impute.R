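#' Names of the supported missing-data strategies
#'
#' Fourteen single-imputation strategies plus the two non-imputation
#' strategies (\code{NOIMP} = available-case analysis, \code{LD} =
#' complete-case analysis).  A \code{-R} suffix marks the randomized
#' variant, where the fill is a Bernoulli draw with the method's
#' imputation probability instead of its rounded value.
#'
#' @return character vector of method names.
#' @export
imputation_methods <- function() {
  c("NOIMP", "LD", "WORST", "PMS", "PMS-R", "IMS", "IMS-R", "CIM",
    "CIM-R", "ICS", "LOG", "LOG-R", "MOK", "RAS", "RAS-R", "RAI")
}

#' Persons eligible for imputation under the 50 percent rule
#'
#' Imputation is only carried out for persons with a strict majority of
#' observed responses (more than J/2, i.e. at least 3 of 5 items).
#' Ineligible persons are not removed: their observed responses stay in
#' the analysis, but their missing cells are never filled.
#'
#' @param data a \code{\link{response_data}}.
#' @return integer vector of eligible row indices.
#' @export
eligible_rows <- function(data) {
  which(person_obs_counts(data) > data$n_items / 2)
}

# Assemble an imputed_data object from per-cell fill values/probabilities.
# `fills` is an N x J matrix, NA where no fill was produced; only cells
# missing in `data` may carry a fill.
new_imputed <- function(data, fills, method, probs = NULL) {
  v <- data$values
  miss <- is.na(v)
  fill_here <- miss & !is.na(fills)
  v[fill_here] <- fills[fill_here]
  structure(list(
    values = v,
    imputed_mask = fill_here * 1,
    residual_missing = (miss & !fill_here) * 1,
    method = method,
    probs = probs), class = "imputed_data")
}

#' @export
print.imputed_data <- function(x, ...) {
  cat(sprintf("%s imputation: %d cell(s) filled, %d left missing\n",
              x$method, sum(x$imputed_mask), sum(x$residual_missing)))
  invisible(x)
}

#' Completed response matrix of an imputation result
#' @param imp an \code{imputed_data} object.
#' @return a \code{response_data} with the filled values (residual missing
#'   cells stay \code{NA}).
#' @export
completed_data <- function(imp) response_data(imp$values)

# fill value from a probability: deterministic half-up round or Bernoulli
fill_from_prob <- function(p, randomized, seed = NULL) {
  if (randomized) {
    with_seed(seed, rbinom(length(p), 1, p))
  } else {
    round_half_up(p)
  }
}

#' Worst-case imputation (WORST)
#'
#' Every eligible missing cell is set to the most negative response, 0.
#'
#' @param data a \code{\link{response_data}}.
#' @return an \code{imputed_data}.
#' @export
impute_worst <- function(data) {
  fills <- matrix(NA_real_, data$n_persons, data$n_items)
  el <- eligible_rows(data)
  fills[el, ] <- 0
  new_imputed(data, fills, "WORST")
}

#' Personal mean score imputation (PMS, PMS-R)
#'
#' A person's missing cells are filled from the mean of their observed
#' responses: rounded (PMS) or drawn from a Bernoulli distribution with
#' that mean as parameter (PMS-R).
#'
#' @param data a \code{\link{response_data}}.
#' @param randomized Bernoulli fill instead of rounding.
#' @param seed optional seed for the randomized variant.
#' @return an \code{imputed_data}.
#' @export
impute_pms <- function(data, randomized = FALSE, seed = NULL) {
  p_person <- person_scores(data) / person_obs_counts(data)
  probs <- matrix(NA_real_, data$n_persons, data$n_items)
  el <- eligible_rows(data)
  probs[el, ] <- p_person[el]
  probs[!is.na(data$values)] <- NA
  fills <- matrix(NA_real_, data$n_persons, data$n_items)
  idx <- which(!is.na(probs))
  fills[idx] <- fill_from_prob(probs[idx], randomized, seed)
  new_imputed(data, fills, if (randomized) "PMS-R" else "PMS", probs)
}

#' Item mean score imputation (IMS, IMS-R)
#'
#' Missing cells are filled from the item's observed positive rate,
#' rounded (IMS) or Bernoulli-drawn (IMS-R).  Items without any observed
#' response cannot be imputed and are left missing with a warning.
#'
#' @inheritParams impute_pms
#' @return an \code{imputed_data}.
#' @export
impute_ims <- function(data, randomized = FALSE, seed = NULL) {
  n_obs <- item_obs_counts(data)
  p_item <- ifelse(n_obs > 0, item_positive_counts(data) / n_obs, NA)
  if (anyNA(p_item))
    warning("item(s) without observed responses cannot be imputed: ",
            paste(colnames(data$values)[is.na(p_item)], collapse = ", "))
  probs <- matrix(NA_real_, data$n_persons, data$n_items)
  el <- eligible_rows(data)
  probs[el, ] <- matrix(p_item, length(el), data$n_items, byrow = TRUE)
  probs[!is.na(data$values)] <- NA
  fills <- matrix(NA_real_, data$n_persons, data$n_items)
  idx <- which(!is.na(probs))
  fills[idx] <- fill_from_prob(probs[idx], randomized, seed)
  new_imputed(data, fills, if (randomized) "IMS-R" else "IMS", probs)
}

#' Corrected item mean imputation (CIM, CIM-R)
#'
#' Combines person ability and item difficulty: the item's observed mean
#' is scaled by the ratio of the person's score to the sum of the
#' observed-item means on that person's observed set,
#' \eqn{q_{nj} = (S_n / \sum_{k \in O_n} p_k) \, p_j}, clipped to
#' \[0, 1\]; rounded (CIM) or Bernoulli-drawn (CIM-R).
#'
#' @inheritParams impute_pms
#' @return an \code{imputed_data}.
#' @export
impute_cim <- function(data, randomized = FALSE, seed = NULL) {
  v <- data$values
  n_obs <- item_obs_counts(data)
  p_item <- ifelse(n_obs > 0, item_positive_counts(data) / n_obs, NA)
  obs <- !is.na(v)
  denom <- obs %*% ifelse(is.na(p_item), 0, p_item)  # sum p_k over O_n
  s <- person_scores(data)
  probs <- matrix(NA_real_, data$n_persons, data$n_items)
  el <- eligible_rows(data)
  bad_denom <- denom[el] == 0 & s[el] > 0
  if (any(bad_denom))
    warning(sum(bad_denom), " person(s) with zero observed-item-mean sum")
  for (n in el) {
    if (denom[n] == 0) next
    probs[n, ] <- pmin(pmax(s[n] / denom[n] * p_item, 0), 1)
  }
  probs[!is.na(v)] <- NA
  fills <- matrix(NA_real_, data$n_persons, data$n_items)
  idx <- which(!is.na(probs))
  fills[idx] <- fill_from_prob(probs[idx], randomized, seed)
  new_imputed(data, fills, if (randomized) "CIM-R" else "CIM", probs)
}

#' Item correlation substitution (ICS)
#'
#' For each item the most correlated other item (pairwise Pearson
#' correlation over persons observing both) acts as donor: a missing
#' response is replaced by the person's response to the donor item.  If
#' the donor response is also missing the cell stays missing.  Pairs with
#' undefined correlation are excluded; ties go to the lowest item index.
#'
#' @param data a \code{\link{response_data}}.
#' @return an \code{imputed_data}; the donor map is attached as
#'   attribute \code{"donor"}.
#' @export
impute_ics <- function(data) {
  v <- data$values
  J <- data$n_items
  r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  diag(r) <- NA
  donor <- apply(r, 1, function(row)
    if (all(is.na(row))) NA_integer_ else which.max(row))
  fills <- matrix(NA_real_, data$n_persons, J)
  el <- eligible_rows(data)
  for (j in seq_len(J)) {
    if (is.na(donor[j])) next
    rows <- el[is.na(v[el, j]) & !is.na(v[el, donor[j]])]
    fills[rows, j] <- v[rows, donor[j]]
  }
  out <- new_imputed(data, fills, "ICS")
  attr(out, "donor") <- donor
  out
}

#' Logistic-model imputation (LOG, LOG-R)
#'
#' Each item with missing values is regressed on the other items by
#' logistic regression with forward stepwise selection (likelihood-ratio
#' entry test at level \code{alpha}); entry tests compare nested models
#' refitted on the rows complete for the candidate set.  Missing cells
#' whose selected covariates are all observed are filled by rounding the
#' predicted probability (LOG) or by a Bernoulli draw (LOG-R); cells with
#' missing selected covariates stay missing.
#'
#' @inheritParams impute_pms
#' @param alpha significance level of the likelihood-ratio entry test.
#' @return an \code{imputed_data}; selected covariate sets are attached
#'   as attribute \code{"selected"}.
#' @export
impute_log <- function(data, randomized = FALSE, alpha = 0.05,
                       seed = NULL) {
  v <- data$values
  J <- data$n_items
  probs <- matrix(NA_real_, data$n_persons, J)
  el <- eligible_rows(data)
  selected_sets <- vector("list", J)
  for (j in seq_len(J)) {
    targets <- el[is.na(v[el, j])]
    if (!length(targets)) next
    sel <- logistic_forward_select(v, j, alpha)
    selected_sets[[j]] <- sel
    use <- !is.na(v[, j]) & (if (length(sel))
      rowSums(is.na(v[, sel, drop = FALSE])) == 0 else TRUE)
    y <- v[use, j]
    if (length(unique(y)) < 2 || !length(sel)) {
      p_hat <- rep(mean(v[, j], na.rm = TRUE), length(targets))
      ok <- rep(TRUE, length(targets))
    } else {
      df_fit <- data.frame(y = y, v[use, sel, drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., binomial, df_fit))
      newd <- as.data.frame(v[targets, sel, drop = FALSE])
      colnames(newd) <- colnames(df_fit)[-1]
      ok <- rowSums(is.na(newd)) == 0
      p_hat <- rep(NA_real_, length(targets))
      if (any(ok))
        p_hat[ok] <- suppressWarnings(
          predict(fit, newd[ok, , drop = FALSE], type = "response"))
    }
    probs[cbind(targets[ok], j)] <- pmin(pmax(p_hat[ok], 0), 1)
  }
  fills <- matrix(NA_real_, data$n_persons, J)
  idx <- which(!is.na(probs))
  fills[idx] <- fill_from_prob(probs[idx], randomized, seed)
  out <- new_imputed(data, fills, if (randomized) "LOG-R" else "LOG",
                     probs)
  attr(out, "selected") <- selected_sets
  out
}

# forward stepwise covariate selection for item j by likelihood-ratio test
logistic_forward_select <- function(v, j, alpha) {
  candidates <- setdiff(seq_len(ncol(v)), j)
  sel <- integer(0)
  repeat {
    remaining <- setdiff(candidates, sel)
    if (!length(remaining)) break
    best_p <- Inf; best_c <- NA
    for (cand in remaining) {
      cols <- c(sel, cand)
      use <- !is.na(v[, j]) & rowSums(is.na(v[, cols, drop = FALSE])) == 0
      y <- v[use, j]
      if (length(y) < length(cols) + 2 || length(unique(y)) < 2) next
      xf <- data.frame(y = y, v[use, cols, drop = FALSE])
      xr <- data.frame(y = y, v[use, sel, drop = FALSE])
      dev_f <- tryCatch(suppressWarnings(glm(y ~ ., binomial, xf)$deviance),
                        error = function(e) NA)
      dev_r <- tryCatch(suppressWarnings(
        glm(y ~ ., binomial, xr)$deviance), error = function(e) NA)
      if (is.na(dev_f) || is.na(dev_r)) next
      p <- pchisq(max(dev_r - dev_f, 0), 1, lower.tail = FALSE)
      if (p < best_p) { best_p <- p; best_c <- cand }
    }
    if (is.na(best_c) || best_p >= alpha) break
    sel <- c(sel, best_c)
  }
  sel
}

#' Mokken-rule imputation (MOK)
#'
#' Fills each missing response with the value producing the fewest
#' Guttman errors.  Items are sorted from easiest to hardest by observed
#' positive counts (stable for ties) and five rules are applied per
#' missing cell, using only originally observed responses: (a) any
#' observed positive response at a harder position fills 1; (b) else any
#' observed negative response at an easier position fills 0; (c) else if
#' the easier positions hold at least as many observed negatives as
#' positives, fill 0; (d) else if the harder positions hold at most as
#' many observed negatives as positives, fill 1; (e) else fill a
#' Bernoulli draw with the item's observed positive proportion.
#'
#' @param data a \code{\link{response_data}}.
#' @param seed optional seed for rule (e) draws.
#' @return an \code{imputed_data}.
#' @export
impute_mok <- function(data, seed = NULL) {
  v <- data$values
  J <- data$n_items
  pos <- item_positive_counts(data)
  ord <- order(-pos, seq_len(J))     # easiest first, stable ties
  n_obs <- item_obs_counts(data)
  p_item <- ifelse(n_obs > 0, pos / n_obs, 0.5)
  el <- eligible_rows(data)
  fills <- matrix(NA_real_, data$n_persons, J)
  with_seed(seed, {
    for (n in el) {
      rs <- v[n, ord]
      if (!anyNA(rs)) next
      for (i in which(is.na(rs))) {
        after <- if (i < J) rs[(i + 1):J] else numeric(0)
        before <- if (i > 1) rs[1:(i - 1)] else numeric(0)
        fill <-
          if (any(after == 1, na.rm = TRUE)) 1
          else if (any(before == 0, na.rm = TRUE)) 0
          else if (sum(before == 0, na.rm = TRUE) >=
                   sum(before == 1, na.rm = TRUE)) 0
          else if (sum(after == 0, na.rm = TRUE) <=
                   sum(after == 1, na.rm = TRUE)) 1
          else rbinom(1, 1, p_item[ord[i]])
        fills[n, ord[i]] <- fill
      }
    }
  })
  new_imputed(data, fills, "MOK")
}

#' Rasch-model imputation (RAS, RAS-R)
#'
#' Fits the Rasch model by marginal maximum likelihood on the observed
#' responses, estimates each person's ability from their observed items,
#' and fills every eligible missing cell from
#' \eqn{p_{nj} = \mathrm{expit}(\hat\theta_n - \hat\delta_j)}, rounded
#' (RAS) or Bernoulli-drawn (RAS-R).
#'
#' @inheritParams impute_pms
#' @param estimator person estimator, \code{"wle"} or \code{"eap"}.
#' @param fit optionally a pre-computed \code{rasch_fit} on \code{data}.
#' @return an \code{imputed_data}; the fit is attached as attribute
#'   \code{"fit"}.
#' @export
impute_rasch <- function(data, randomized = FALSE, seed = NULL,
                         estimator = "wle", fit = NULL) {
  if (is.null(fit)) fit <- fit_rasch(data)
  if (!fit$converged) stop("Rasch fit did not converge; cannot impute")
  # persons without observed responses get no estimate; they are
  # ineligible for imputation anyway, so the warning is redundant here
  pe <- suppressWarnings(estimate_persons(fit, data, estimator))
  p_full <- expit(outer(pe$theta_hat, fit$delta_hat, "-"))
  probs <- matrix(NA_real_, data$n_persons, data$n_items)
  el <- eligible_rows(data)
  probs[el, ] <- p_full[el, ]
  probs[!is.na(data$values)] <- NA
  fills <- matrix(NA_real_, data$n_persons, data$n_items)
  idx <- which(!is.na(probs))
  fills[idx] <- fill_from_prob(probs[idx], randomized, seed)
  out <- new_imputed(data, fills,
                     if (randomized) "RAS-R" else "RAS", probs)
  attr(out, "fit") <- fit
  out
}

#' Iterative Rasch-model imputation (RAI)
#'
#' Deterministic Rasch imputation iterated to a fixed point: the model is
#' refitted on the completed data and the originally missing cells are
#' re-imputed, until two successive passes produce identical fills or ten
#' iterations are reached.
#'
#' @param data a \code{\link{response_data}}.
#' @param max_iter iteration cap (default 10).
#' @param estimator person estimator for each pass.
#' @return an \code{imputed_data} with attribute \code{"iterations"}.
#' @export
impute_rasch_iterative <- function(data, max_iter = 10,
                                   estimator = "wle") {
  imp <- impute_rasch(data, randomized = FALSE, estimator = estimator)
  target <- imp$imputed_mask == 1      # eligible, originally missing cells
  iterations <- 1L
  while (iterations < max_iter) {
    current <- completed_data(imp)     # data with the current fills
    fit <- tryCatch(fit_rasch(current), error = function(e) {
      warning("inner Rasch fit failed at iteration ", iterations + 1,
              ": ", conditionMessage(e))
      NULL
    })
    if (is.null(fit) || !fit$converged) break
    pe <- estimate_persons(fit, current, estimator)
    p_full <- expit(outer(pe$theta_hat, fit$delta_hat, "-"))
    new_fills <- matrix(NA_real_, data$n_persons, data$n_items)
    new_fills[target] <- round_half_up(p_full[target])
    cand <- new_imputed(data, new_fills, "RAI")
    iterations <- iterations + 1L
    if (identical(cand$values, imp$values)) { imp <- cand; break }
    imp <- cand
  }
  attr(imp, "iterations") <- iterations
  imp$method <- "RAI"
  imp
}

#' Listwise deletion (LD)
#'
#' Complete-case analysis: persons with one or more missing responses are
#' removed.
#'
#' @param data a \code{\link{response_data}}.
#' @return a \code{response_data} containing the fully observed rows; the
#'   retained-row count is attached as attribute \code{"n_retained"}.
#' @export
listwise_delete <- function(data) {
  keep <- rowSums(is.na(data$values)) == 0
  if (!any(keep)) stop("listwise deletion removed every person")
  out <- response_data(data$values[keep, , drop = FALSE],
                       colnames(data$values))
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Apply a missing-data strategy by name
#'
#' Dispatcher over all sixteen strategies.  Imputation methods return the
#' completed dataset (residual missing cells stay \code{NA} and are
#' handled downstream by available-case analysis); \code{NOIMP} returns
#' the data unchanged and \code{LD} the listwise-deleted data.
#'
#' @param data a \code{\link{response_data}}.
#' @param method one of \code{\link{imputation_methods}()}.
#' @param seed optional seed for randomized variants and MOK rule (e).
#' @param alpha stepwise entry level for LOG(-R).
#' @param estimator person estimator for RAS(-R)/RAI.
#' @return a \code{response_data} ready for analysis; for imputation
#'   methods the full \code{imputed_data} record is attached as attribute
#'   \code{"imputation"}.
#' @export
handle_missing <- function(data, method, seed = NULL, alpha = 0.05,
                           estimator = "wle") {
  method <- match.arg(method, imputation_methods())
  if (method == "NOIMP") return(data)
  if (method == "LD") return(listwise_delete(data))
  randomized <- grepl("-R$", method)
  imp <- switch(sub("-R$", "", method),
    WORST = impute_worst(data),
    PMS = impute_pms(data, randomized, seed),
    IMS = impute_ims(data, randomized, seed),
    CIM = impute_cim(data, randomized, seed),
    ICS = impute_ics(data),
    LOG = impute_log(data, randomized, alpha, seed),
    MOK = impute_mok(data, seed),
    RAS = impute_rasch(data, randomized, seed, estimator),
    RAI = impute_rasch_iterative(data, estimator = estimator))
  out <- completed_data(imp)
  attr(out, "imputation") <- imp
  out
}
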