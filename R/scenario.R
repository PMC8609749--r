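#' Latent covariate correlation matrix
#'
#' The six baseline covariates are drawn from a latent multivariate normal
#' with unit variances and a Toeplitz correlation structure: the lag-k
#' correlation is `0.6 - 0.1 * k`, so the off-diagonal entries span 0.1 to
#' 0.5 (strong dependence between neighbouring covariates, weak between
#' distant ones). The matrix is checked for positive definiteness at
#' construction.
#'
#' @return A 6x6 symmetric positive-definite correlation matrix.
#' @export
#' @examples
#' default_correlation()
default_correlation <- function() {
  k <- abs(outer(seq_len(6), seq_len(6), "-"))
  R <- ifelse(k == 0, 1, 0.6 - 0.1 * k)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("latent correlation matrix is not positive definite")
  }
  R
}

#' Binarization thresholds for the first three covariates
#'
#' The first three latent covariates are dichotomized so that their marginal
#' success probabilities are approximately 0.25, 0.30 and 0.20. Because the
#' latents are standard normal, the cutoff for target probability p is the
#' standard-normal quantile at 1 - p; the indicator is 1 when the latent
#' value strictly exceeds the cutoff.
#'
#' @param probs Target marginal probabilities for the three binary
#'   covariates.
#' @return Numeric vector of three cutoffs on the latent (z) scale.
#' @export
binarization_thresholds <- function(probs = c(0.25, 0.30, 0.20)) {
  stats::qnorm(1 - probs)
}

# Treatment-model coefficient vectors, on the log-odds scale.
assignment_beta <- function(strength = c("weak", "strong")) {
  strength <- match.arg(strength)
  if (strength == "weak") {
    log(c(1.25, 1.5, 1.25, 1.5, 1.25, 1.5))
  } else {
    log(c(1.5, 1.75, 1.5, 1.75, 1.5, 1.75))
  }
}

# Outcome-model covariate coefficients. Logistic family: log-odds, mixing
# weak and strong confounders. Linear-probability family: risk-difference
# units, same weak-to-strong ordering, scaled so that probability
# truncation stays rare (< 1% of subjects) in every scenario.
outcome_gamma <- function(family = c("logistic", "linear_probability")) {
  family <- match.arg(family)
  if (family == "logistic") {
    log(c(1.25, 1.25, 1.5, 1.5, 1.75, 1.75))
  } else {
    c(0.005, 0.005, 0.01, 0.01, 0.015, 0.015)
  }
}

#' Define one simulation scenario
#'
#' A scenario is one cell of the simulation grid: an assignment-strength
#' level, a target treated proportion, a sample size and an outcome family.
#' The treatment-model slopes and outcome-model covariate coefficients are
#' fixed by design; the intercepts and the treatment effect are filled in by
#' [calibrate_scenario()] so that the marginal treated proportion, outcome
#' prevalence (0.20) and true ATT (risk difference 0.15) hit their targets.
#'
#' @param assignment_strength `"weak"` or `"strong"` dependence of treatment
#'   assignment on the covariates.
#' @param treated_proportion Target marginal proportion treated; one of
#'   0.3, 0.5, 0.7.
#' @param sample_size Cohort size; one of 100, 250, 500, 1000.
#' @param outcome_family `"logistic"` (heterogeneous individual risk
#'   differences) or `"linear_probability"` (additive, homogeneous effect).
#' @param target_att Target ATT on the risk-difference scale.
#' @param target_prevalence Target marginal outcome prevalence.
#' @param calibration_tolerance Absolute probability tolerance for the
#'   calibration targets.
#' @return An object of class `scenario_config`.
#' @seealso [calibrate_scenario()], [generate_cohort()], [scenario_grid()]
#' @export
#' @examples
#' scenario_config("weak", 0.5, 250)
scenario_config <- function(assignment_strength = c("weak", "strong"),
                            treated_proportion = 0.5,
                            sample_size = 250,
                            outcome_family = c("logistic", "linear_probability"),
                            target_att = 0.15,
                            target_prevalence = 0.20,
                            calibration_tolerance = 5e-3) {
  assignment_strength <- match.arg(assignment_strength)
  outcome_family <- match.arg(outcome_family)
  if (!treated_proportion %in% c(0.3, 0.5, 0.7)) {
    stop("treated_proportion must be one of 0.3, 0.5, 0.7")
  }
  if (!sample_size %in% c(100, 250, 500, 1000)) {
    stop("sample_size must be one of 100, 250, 500, 1000")
  }
  structure(
    list(
      assignment_strength = assignment_strength,
      treated_proportion_target = treated_proportion,
      sample_size = as.integer(sample_size),
      outcome_family = outcome_family,
      beta = assignment_beta(assignment_strength),
      beta0 = NA_real_,
      gamma = outcome_gamma(outcome_family),
      gamma0 = NA_real_,
      gamma_T = NA_real_,
      target_att = target_att,
      target_prevalence = target_prevalence,
      att_true = NA_real_,
      calibration_tolerance = calibration_tolerance,
      calibrated = FALSE
    ),
    class = "scenario_config"
  )
}

is_calibrated <- function(config) {
  isTRUE(config$calibrated) &&
    is.finite(config$beta0) && is.finite(config$gamma0) &&
    is.finite(config$gamma_T)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario (", x$outcome_family, " outcome family)\n", sep = "")
  cat("  assignment strength:", x$assignment_strength,
      " | treated proportion:", x$treated_proportion_target,
      " | n:", x$sample_size, "\n")
  if (is_calibrated(x)) {
    cat(sprintf("  calibrated: beta0 = %.4f, gamma0 = %.4f, gamma_T = %.4f\n",
                x$beta0, x$gamma0, x$gamma_T))
    cat(sprintf("  oracle ATT (risk difference among treated): %.4f\n",
                x$att_true))
  } else {
    cat("  not calibrated (run calibrate_scenario())\n")
  }
  invisible(x)
}

#' Full factorial scenario grid
#'
#' All combinations of assignment strength (weak, strong), treated
#' proportion (0.3, 0.5, 0.7) and sample size (100, 250, 500, 1000) for one
#' outcome family: 24 scenarios.
#'
#' @param outcome_family Outcome family shared by all scenarios in the grid.
#' @return A list of (uncalibrated) `scenario_config` objects.
#' @export
scenario_grid <- function(outcome_family = c("logistic", "linear_probability")) {
  outcome_family <- match.arg(outcome_family)
  cells <- expand.grid(
    assignment_strength = c("weak", "strong"),
    treated_proportion = c(0.3, 0.5, 0.7),
    sample_size = c(100, 250, 500, 1000),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(cells)), function(i) {
    scenario_config(
      assignment_strength = cells$assignment_strength[i],
      treated_proportion = cells$treated_proportion[i],
      sample_size = cells$sample_size[i],
      outcome_family = outcome_family
    )
  })
}

# Short stable label for one scenario, used in output tables and seeds.
scenario_id <- function(config) {
  sprintf("%s_p%02d_n%d_%s",
          config$assignment_strength,
          round(100 * config$treated_proportion_target),
          config$sample_size,
          if (config$outcome_family == "logistic") "logit" else "linprob")
}
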