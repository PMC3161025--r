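#' Item bank for the Rasch simulator
#'
#' @param difficulties numeric vector of item difficulties on the logit
#'   scale (at least two items).
#' @param labels optional item labels.
#' @return an object of class \code{item_bank}.
#' @details The default bank used throughout the bias study has five items
#'   with difficulties (-1, -0.5, 0, 0.5, 1); their population variance
#'   (divisor J) is exactly 0.5.
#' @export
item_bank <- function(difficulties = c(-1, -0.5, 0, 0.5, 1),
                      labels = NULL) {
  difficulties <- as.numeric(difficulties)
  if (length(difficulties) < 2) stop("an item bank needs at least 2 items")
  if (anyNA(difficulties)) stop("difficulties must be finite")
  if (is.null(labels)) labels <- paste0("item", seq_along(difficulties))
  structure(list(difficulties = difficulties, labels = labels,
                 J = length(difficulties)),
            class = "item_bank")
}

#' Draw correlated person latent variables
#'
#' Draws the ability \eqn{\Theta ~ N(\mu, \sigma^2)} and the non-response
#' propensity \eqn{\xi ~ N(0, 1)} jointly normal with correlation
#' \code{rho}.  Informative (MNAR) missingness arises when \code{rho} is
#' negative: persons with lower ability are more inclined to skip items.
#'
#' @param N number of persons.
#' @param rho correlation between ability and non-response propensity,
#'   in \[-1, 1\] (the study uses 0, -0.4, -0.9).
#' @param mu,sigma2 mean and variance of the ability distribution.
#' @param seed optional integer seed.
#' @return an object of class \code{latent_sample} with components
#'   \code{theta}, \code{xi}, \code{rho}, \code{mu}, \code{sigma2}.
#' @export
draw_latents <- function(N, rho = 0, mu = 0, sigma2 = 1, seed = NULL) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  with_seed(seed, {
    z_theta <- rnorm(N)
    z_perp <- rnorm(N)
    # exact joint normality: xi shares the standardized theta component
    xi <- rho * z_theta + sqrt(1 - rho^2) * z_perp
    structure(list(theta = mu + sqrt(sigma2) * z_theta, xi = xi,
                   rho = rho, mu = mu, sigma2 = sigma2),
              class = "latent_sample")
  })
}

#' Simulate complete Rasch responses
#'
#' Each cell is an independent Bernoulli draw with
#' \eqn{P(X_{nj} = 1) = \mathrm{expit}(\theta_n - \delta_j)}.
#'
#' @param latents a \code{latent_sample} (or a numeric vector of abilities).
#' @param bank an \code{item_bank}.
#' @param seed optional integer seed.
#' @return a complete \code{response_data} (mask all ones).
#' @export
simulate_responses <- function(latents, bank = item_bank(), seed = NULL) {
  theta <- if (inherits(latents, "latent_sample")) latents$theta else latents
  delta <- bank$difficulties
  N <- length(theta)
  J <- length(delta)
  p <- expit(outer(theta, delta, "-"))
  with_seed(seed, {
    x <- matrix(rbinom(N * J, 1, p), N, J)
    response_data(x, item_labels = bank$labels)
  })
}

#' Missingness design parameters
#'
#' @param pi target per-item rate of missing responses, in (0, 1).
#' @param w 0/1 flag: does the probability of non-response increase with
#'   item difficulty (1 = yes, the MAR-by-item-difficulty channel)?
#' @param floor lower bound on any per-cell missingness probability
#'   (default 0.01).
#' @return an object of class \code{missingness_design}.
#' @export
missingness_design <- function(pi, w = 0, floor = 0.01) {
  if (!(w %in% c(0, 1))) stop("w must be 0 or 1")
  if (pi == 0) floor <- 0            # degenerate complete-data design
  if (pi < floor || pi >= 1) stop("need floor <= pi < 1")
  structure(list(pi = pi, w = w, floor = floor),
            class = "missingness_design")
}

#' Per-cell non-response probabilities
#'
#' The probability that person n leaves item j unanswered is a linear
#' function of the person's non-response propensity and, when \code{w = 1},
#' of the item difficulty, clipped to \[floor, 1\] and centred on \code{pi}:
#' \deqn{\pi_{nj} = \mathrm{clip}(\pi (1 + 0.4 \xi_n) + w \cdot 0.4 \pi
#'   \delta_j,\; 0.01,\; 1).}
#' With \code{rho = 0, w = 0} this is MCAR; \code{w = 1} adds an item-side
#' MAR channel; \code{rho != 0} makes the mechanism MNAR because
#' \eqn{\xi} is correlated with the ability that generated the responses.
#'
#' @param latents a \code{latent_sample}.
#' @param bank an \code{item_bank}.
#' @param design a \code{missingness_design}.
#' @return N x J matrix of probabilities.
#' @export
missingness_probabilities <- function(latents, bank, design) {
  pi <- design$pi
  base <- pi * (1 + 0.4 * latents$xi)
  shift <- design$w * 0.4 * pi * bank$difficulties
  p <- outer(base, rep(1, bank$J)) + outer(rep(1, length(base)), shift)
  pmin(pmax(p, design$floor), 1)
}

#' Impose missingness on a complete dataset
#'
#' Each cell is independently set to missing with its own probability;
#' observed values are preserved.  Returns both the incomplete data and
#' the complete original so that per-replication paired bias (imputed vs
#' full-data estimate) can be computed downstream.
#'
#' @param complete a complete \code{response_data}.
#' @param probs N x J matrix of per-cell missingness probabilities.
#' @param seed optional integer seed.
#' @return a list with components \code{incomplete} and \code{complete},
#'   both \code{response_data}.
#' @export
apply_missingness <- function(complete, probs, seed = NULL) {
  v <- complete$values
  if (any(is.na(v))) stop("input dataset must be complete")
  if (!all(dim(probs) == dim(v))) stop("probability matrix shape mismatch")
  with_seed(seed, {
    drop <- matrix(runif(length(v)) < probs, nrow(v), ncol(v))
    v[drop] <- NA
    list(incomplete = response_data(v, colnames(complete$values)),
         complete = complete)
  })
}

#' Simulation configuration
#'
#' Bundles every generating parameter of the Monte-Carlo design: sample
#' size, item bank, ability distribution, informativity \code{rho}, the
#' item-difficulty missingness flag \code{w}, the target missingness rate
#' \code{pi}, replication count and master seed.
#'
#' @param N persons per replication (study default 500).
#' @param bank an \code{item_bank}.
#' @param mu,sigma2 ability distribution parameters (defaults 0, 1).
#' @param rho correlation between ability and non-response propensity.
#' @param w 0/1 item-difficulty missingness flag.
#' @param pi per-item missingness rate.
#' @param replications number of Monte-Carlo replications.
#' @param seed master seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(N = 500, bank = item_bank(), mu = 0, sigma2 = 1,
                       rho = 0, w = 0, pi = 0.1, replications = 1000,
                       seed = 1L) {
  if (N < 1 || replications < 1) stop("N and replications must be >= 1")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  structure(list(N = N, bank = bank, mu = mu, sigma2 = sigma2, rho = rho,
                 w = w, pi = pi, replications = replications,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a flat key-value file
#'
#' Plain-text format, one \code{key = value} (or \code{key: value}) pair
#' per line; \code{difficulties} is a comma-separated list.  Keys: N, J,
#' difficulties, mu, sigma2, rho, w, pi, replications, seed.  If only J is
#' given, difficulties default to an equally spaced symmetric bank.
#'
#' @param path file path.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  keys <- tolower(trimws(sub("[=:].*$", "", lines)))
  vals <- trimws(sub("^[^=:]*[=:]", "", lines))
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  num <- function(k, default) as.numeric(get(k, default))
  if (!is.null(get("difficulties"))) {
    delta <- as.numeric(strsplit(get("difficulties"), ",")[[1]])
  } else {
    J <- as.integer(num("j", 5))
    delta <- seq(-1, 1, length.out = J)
  }
  sim_config(N = as.integer(num("n", 500)), bank = item_bank(delta),
             mu = num("mu", 0), sigma2 = num("sigma2", 1),
             rho = num("rho", 0), w = num("w", 0), pi = num("pi", 0.1),
             replications = as.integer(num("replications", 1000)),
             seed = as.integer(num("seed", 1)))
}

#' Simulate one replication (complete + incomplete dataset)
#'
#' Convenience wrapper that draws latents, simulates complete responses
#' and imposes missingness, all from child streams of the master seed so
#' that replication \code{rep} is reproducible in isolation.
#'
#' @param config a \code{sim_config}.
#' @param rep replication index.
#' @return list with \code{incomplete}, \code{complete}, \code{latents}.
#' @export
simulate_replication <- function(config, rep = 1L) {
  lat <- draw_latents(config$N, config$rho, config$mu, config$sigma2,
                      seed = child_seed(config$seed, rep, "latents"))
  full <- simulate_responses(lat, config$bank,
                             seed = child_seed(config$seed, rep, "responses"))
  des <- missingness_design(config$pi, config$w)
  probs <- missingness_probabilities(lat, config$bank, des)
  out <- apply_missingness(full, probs,
                           seed = child_seed(config$seed, rep, "mask"))
  out$latents <- lat
  out
}
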