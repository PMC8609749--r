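# Conditional outcome variances for every control unit, estimated from the
# nearest control-group neighbour on the logit PS scale:
# sigma2_j = (y_j - y_l(j))^2 / 2, ties broken toward the lowest cohort
# index (among all units at the tied minimum distance). Computed in one
# pass over the controls sorted by (logit PS, index): within a run of equal
# scores the neighbour is the lowest-index other member; a singleton run
# looks at the adjacent runs.
control_conditional_variances <- function(y, logit_ps, treat) {
  co <- which(treat == 0)
  n <- length(co)
  if (n < 2) {
    warning("fewer than two controls; conditional variances set to 0")
    return(stats::setNames(numeric(n), co))
  }
  o <- order(logit_ps[co], co)
  ids <- co[o]
  s <- logit_ps[ids]
  new_run <- c(TRUE, diff(s) != 0)
  rid <- cumsum(new_run)
  run_start <- which(new_run)
  run_len <- tabulate(rid)
  first_pos <- run_start[rid]
  is_first <- seq_len(n) == first_pos
  # neighbour within the run (distance 0), defined when run_len >= 2
  nn_within <- ifelse(is_first, ids[pmin(first_pos + 1L, n)], ids[first_pos])
  # neighbour across runs, for singleton runs
  rv <- s[run_start]
  R <- length(rv)
  run_min_id <- ids[run_start]
  dprev <- c(Inf, diff(rv))
  dnext <- c(diff(rv), Inf)
  prev_min <- c(NA_integer_, run_min_id[-R])
  next_min <- c(run_min_id[-1], NA_integer_)
  use_prev <- dprev < dnext | (dprev == dnext & prev_min < next_min)
  nn_run <- ifelse(use_prev, prev_min, next_min)
  nn <- ifelse(run_len[rid] >= 2, nn_within, nn_run[rid])
  stats::setNames((y[ids] - y[nn])^2 / 2, ids)[as.character(co)]
}

# Per-set outcome differences d_i = y_treated - mean(y_controls).
set_differences <- function(sample, y) {
  if (sample$n_treated_matched == 0) stop("empty matched sample")
  y[sample$treated] -
    rowMeans(matrix(y[sample$controls], nrow = sample$n_treated_matched))
}

#' ATT point estimate on a matched sample
#'
#' The weighted absolute risk reduction: the average over matched sets of
#' the treated outcome minus the mean outcome of its K matched controls.
#' Under the reciprocal-weight convention (each control weighted 1/K
#' within its set) this equals the weighted difference in group means.
#'
#' @param sample A [ps_match()] result.
#' @param y Outcome vector on the cohort.
#' @return Risk difference in `[-1, 1]`.
#' @export
estimate_att <- function(sample, y) {
  mean(set_differences(sample, y))
}

#' Matched-sample ("standard") standard error
#'
#' Treats the per-set differences as paired observations: the SE of the
#' ATT is the sample SD of the set differences divided by the square root
#' of the number of sets. For 1:1 matching of a binary outcome this is the
#' classical matched-pairs difference-in-proportions SE.
#'
#' @inheritParams estimate_att
#' @export
standard_se <- function(sample, y) {
  d <- set_differences(sample, y)
  if (length(d) < 2) stop("at least two matched sets are required")
  stats::sd(d) / sqrt(length(d))
}

#' Abadie-Imbens standard error for matching with replacement
#'
#' Adds to the matched-pairs variance a correction for the extra
#' uncertainty created by reusing controls. With `K_j` the total weight of
#' control j across sets (sum of 1/m over the sets containing it) and
#' `K'_j` the corresponding sum of 1/m^2, the variance is
#' \deqn{\hat V = n_s^{-2} [ \sum_i (d_i - \hat\tau)^2 +
#'   \sum_j (K_j^2 - K'_j) \hat\sigma^2_j ]}
#' where the conditional outcome variance of control j is estimated from
#' its nearest control-group neighbour on the logit propensity scale,
#' \eqn{\hat\sigma^2_j = (y_j - y_{\ell(j)})^2 / 2} (ties toward the lower
#' index). The correction vanishes when no control is reused.
#'
#' @inheritParams estimate_att
#' @param logit_ps Logit propensity scores on the cohort.
#' @param treat Binary treatment vector on the cohort.
#' @param sigma2 Optional precomputed named vector of conditional variances
#'   for the control units (one entry per control, named by cohort index);
#'   computed internally when omitted.
#' @export
abadie_imbens_se <- function(sample, y, logit_ps, treat, sigma2 = NULL) {
  if (!sample$options$with_replacement) {
    stop("the Abadie-Imbens estimator is computed only for matching with replacement")
  }
  d <- set_differences(sample, y)
  n_sets <- length(d)
  if (n_sets < 2) stop("at least two matched sets are required")
  tau <- mean(d)
  m <- ncol(sample$controls)
  Kj <- sample$usage / m        # sum over sets of 1/m (m constant by design)
  Kpj <- sample$usage / m^2     # sum over sets of 1/m^2
  if (is.null(sigma2)) {
    sigma2 <- control_conditional_variances(y, logit_ps, treat)
  }
  sig2 <- sigma2[names(sample$usage)]
  V <- (sum((d - tau)^2) + sum((Kj^2 - Kpj) * sig2)) / n_sets^2
  sqrt(V)
}

#' Normal-theory confidence interval
#'
#' @param att Point estimate.
#' @param se Standard error.
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
confidence_interval <- function(att, se, level = 0.95) {
  stopifnot(se >= 0)
  z <- stats::qnorm((1 + level) / 2)
  c(lower = att - z * se, upper = att + z * se)
}

#' ATT estimate with both variance estimators
#'
#' Convenience wrapper combining [estimate_att()], [standard_se()],
#' [abadie_imbens_se()] (matching with replacement only) and 95% normal
#' intervals.
#'
#' @inheritParams abadie_imbens_se
#' @param level Confidence level.
#' @return Object of class `att_estimate` with fields `att`,
#'   `se_standard`, `se_ai` (`NA` without replacement), `ci_standard`,
#'   `ci_ai`, `n_sets`.
#' @export
att_estimate <- function(sample, y, logit_ps, treat, level = 0.95,
                         sigma2 = NULL) {
  att <- estimate_att(sample, y)
  se_std <- standard_se(sample, y)
  if (sample$options$with_replacement) {
    se_ai <- abadie_imbens_se(sample, y, logit_ps, treat, sigma2)
    ci_ai <- confidence_interval(att, se_ai, level)
  } else {
    se_ai <- NA_real_
    ci_ai <- c(lower = NA_real_, upper = NA_real_)
  }
  structure(
    list(att = att,
         se_standard = se_std,
         se_ai = se_ai,
         ci_standard = confidence_interval(att, se_std, level),
         ci_ai = ci_ai,
         n_sets = sample$n_treated_matched,
         level = level),
    class = "att_estimate")
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("ATT (risk difference): %.4f over %d matched sets\n",
              x$att, x$n_sets))
  cat(sprintf("  standard: SE %.4f, %d%% CI (%.4f, %.4f)\n",
              x$se_standard, round(100 * x$level),
              x$ci_standard[1], x$ci_standard[2]))
  if (is.finite(x$se_ai)) {
    cat(sprintf("  Abadie-Imbens: SE %.4f, %d%% CI (%.4f, %.4f)\n",
                x$se_ai, round(100 * x$level), x$ci_ai[1], x$ci_ai[2]))
  }
  invisible(x)
}
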