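#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor glm optim pchisq pnorm qnorm rbinom rnorm
#'   runif uniroot var sd binomial predict logLik quantile binom.test
#' @importFrom utils read.csv write.csv modifyList
NULL

expit <- function(x) 1 / (1 + exp(-x))

#' Round to the nearest integer with ties away from zero
#'
#' Base \code{round()} rounds half to even; the imputation rules here need
#' half-up rounding (0.5 becomes 1), applied uniformly across methods.
#'
#' @param p numeric vector of values in \[0, 1\].
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(p) floor(p + 0.5)

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' A master seed spawns one independent child stream per replication and
#' stage (latent draws, responses, missingness mask, each randomized
#' imputation), so that adding or removing a method never perturbs the
#' draws of another and all methods see identical incomplete datasets.
#'
#' @param master integer master seed.
#' @param rep replication index (1-based).
#' @param stage character stage label, e.g. "latents", "mask", "impute-PMS-R".
#' @return an integer seed in \[0, 2^31).
#' @export
child_seed <- function(master, rep = 1L, stage = "latents") {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # splitmix-style integer mix kept in double precision (< 2^31 throughout)
  x <- (as.double(master) %% 2147483647) * 48271 %% 2147483647
  x <- (x + as.double(rep) * 69621) %% 2147483647
  x <- (x * 16807 + stage_code * 75) %% 2147483647
  as.integer(x)
}
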