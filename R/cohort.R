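#' Draw the baseline covariate matrix
#'
#' Draws `n` rows from the latent multivariate normal (zero means, unit
#' variances, [default_correlation()] structure) and dichotomizes the first
#' three columns at the [binarization_thresholds()] cutoffs (strictly
#' greater than the cutoff codes 1). Columns 4-6 stay continuous.
#'
#' @param n Number of subjects (0 allowed).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible.
#' @return An `n` x 6 numeric matrix with columns `X1`..`X6`; `X1`-`X3`
#'   binary, `X4`-`X6` standard normal.
#' @export
draw_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  R <- default_correlation()
  if (n == 0L) {
    X <- matrix(numeric(0), nrow = 0, ncol = 6)
  } else {
    X <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = R)
    if (n == 1L) X <- matrix(X, nrow = 1)
  }
  thr <- binarization_thresholds()
  for (k in 1:3) X[, k] <- as.numeric(X[, k] > thr[k])
  colnames(X) <- paste0("X", 1:6)
  X
}

#' Treatment-assignment probabilities
#'
#' Evaluates the logistic treatment model
#' \eqn{logit(p_T) = \beta_0 + \beta^\top x} for every row of the covariate
#' matrix.
#'
#' @param X Covariate matrix with 6 columns.
#' @param beta0 Intercept (log-odds).
#' @param beta 6-vector of slopes (log-odds).
#' @return Vector of treatment probabilities in (0, 1).
#' @export
treatment_probabilities <- function(X, beta0, beta) {
  stopifnot(ncol(X) == 6, length(beta) == 6)
  stats::plogis(beta0 + drop(X %*% beta))
}

#' Counterfactual outcome probabilities
#'
#' Computes, for every subject, the probability of the outcome under
#' control (`p0`) and under treatment (`p1`). For the logistic family both
#' arise from the logistic outcome model with the treatment coefficient
#' switched off/on, so individual risk differences `p1 - p0` vary across
#' subjects. For the linear-probability family the treatment effect is
#' additive on the probability scale: `p0 = gamma0 + gamma' x` and
#' `p1 = p0 + gamma_T`, both truncated to `[0, 1]`; the fraction of subjects
#' affected by truncation is recorded in the `"clamp_fraction"` attribute.
#'
#' @param X Covariate matrix with 6 columns.
#' @param config A calibrated [scenario_config()].
#' @return List with vectors `p0` and `p1`, carrying attribute
#'   `clamp_fraction` (0 for the logistic family).
#' @export
outcome_probabilities <- function(X, config) {
  if (!is_calibrated(config)) {
    stop("scenario is not calibrated: gamma0/gamma_T missing; ",
         "run calibrate_scenario() first")
  }
  lp <- drop(X %*% config$gamma)
  if (config$outcome_family == "logistic") {
    p0 <- stats::plogis(config$gamma0 + lp)
    p1 <- stats::plogis(config$gamma0 + lp + config$gamma_T)
    clamp <- 0
  } else {
    raw0 <- config$gamma0 + lp
    p0 <- pmin(pmax(raw0, 0), 1)
    raw1 <- p0 + config$gamma_T
    p1 <- pmin(pmax(raw1, 0), 1)
    clamp <- mean(raw0 < 0 | raw0 > 1 | raw1 < 0 | raw1 > 1)
  }
  out <- list(p0 = p0, p1 = p1)
  attr(out, "clamp_fraction") <- clamp
  out
}

#' Oracle true ATT of a calibrated scenario
#'
#' Large-sample Monte Carlo evaluation of the mean counterfactual risk
#' difference among the treated, `E[p1 - p0 | T = 1]`. A large covariate
#' draw is taken and the conditional expectation over treatment assignment
#' is used (subjects weighted by their treatment probability), which removes
#' the Bernoulli noise of actually drawing `T`. This value - not the nominal
#' 0.15 target - is the truth against which bias and coverage are measured.
#'
#' @param config Calibrated [scenario_config()].
#' @param n_cal Size of the evaluation draw.
#' @param seed Seed for the evaluation draw.
#' @return The oracle risk difference among treated.
#' @export
true_att <- function(config, n_cal = 1e6, seed = 202111L) {
  if (!is_calibrated(config)) stop("scenario is not calibrated")
  X <- draw_covariates(n_cal, seed = seed)
  pT <- treatment_probabilities(X, config$beta0, config$beta)
  cf <- outcome_probabilities(X, config)
  sum(pT * (cf$p1 - cf$p0)) / sum(pT)
}

#' Generate one simulated cohort
#'
#' Draws covariates, assigns treatment `T ~ Bernoulli(p_T)` from the
#' calibrated treatment model, and draws the observed binary outcome
#' `Y ~ Bernoulli(T p1 + (1 - T) p0)`. The oracle fields (assignment and
#' counterfactual probabilities) are stored alongside the observables so
#' that simulation truth is available downstream.
#'
#' @param config Calibrated [scenario_config()].
#' @param seed Integer seed; the cohort is fully reproducible given
#'   `(config, seed)`.
#' @return An object of class `cohort`: list with `X` (n x 6 matrix),
#'   `treat`, `y`, `pT`, `p0`, `p1`, `seed` and the generating `config`.
#' @export
generate_cohort <- function(config, seed) {
  if (!is_calibrated(config)) stop("scenario is not calibrated")
  set.seed(seed)
  n <- config$sample_size
  X <- draw_covariates(n)
  pT <- treatment_probabilities(X, config$beta0, config$beta)
  treat <- stats::rbinom(n, 1L, pT)
  cf <- outcome_probabilities(X, config)
  pY <- treat * cf$p1 + (1 - treat) * cf$p0
  y <- stats::rbinom(n, 1L, pY)
  structure(
    list(X = X, treat = treat, y = y,
         pT = pT, p0 = cf$p0, p1 = cf$p1,
         seed = as.integer(seed), config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Simulated cohort: n =", length(x$treat),
      "| treated =", sum(x$treat),
      "| events =", sum(x$y), "\n")
  cat("  scenario:", scenario_id(x$config), "| seed:", x$seed, "\n")
  invisible(x)
}
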