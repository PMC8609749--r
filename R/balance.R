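#' Pooled reference standard deviation for SMDs
#'
#' SMD denominators are computed once, on the unmatched cohort, so that
#' pre- and post-matching SMDs are on the same scale:
#' `sqrt((s_t^2 + s_c^2) / 2)`, with `p (1 - p)` variances for binary
#' covariates and the usual n-1 sample variance otherwise.
#'
#' @param x Covariate vector.
#' @param treat Binary group indicator on the unmatched cohort.
#' @return The pooled SD (possibly 0 for a constant covariate).
#' @export
pooled_sd_reference <- function(x, treat) {
  grp_var <- function(v) {
    u <- unique(v[!is.na(v)])
    if (all(u %in% c(0, 1))) {
      p <- mean(v)
      p * (1 - p)
    } else {
      stats::var(v)
    }
  }
  sqrt((grp_var(x[treat == 1]) + grp_var(x[treat == 0])) / 2)
}

#' Standardized mean difference of one covariate
#'
#' Weighted treated-minus-control mean difference divided by a reference
#' pooled SD (see [pooled_sd_reference()]); on a matched sample the weights
#' are the matching weights, with unmatched units at weight 0.
#'
#' @param x Covariate vector.
#' @param treat Binary group indicator.
#' @param w Unit weights (default 1).
#' @param sd_reference Denominator; by default the pooled SD of the groups
#'   defined by `treat` on the data at hand.
#' @return Signed SMD, or `NA` if the reference SD is 0.
#' @export
#' @examples
#' # 8/46 vs 7/57 females, unweighted
#' x <- c(rep(1, 8), rep(0, 38), rep(1, 7), rep(0, 50))
#' t <- c(rep(0, 46), rep(1, 57))
#' round(smd(x, t), 2)
smd <- function(x, treat, w = rep(1, length(x)),
                sd_reference = pooled_sd_reference(x, treat)) {
  wt <- w[treat == 1]
  wc <- w[treat == 0]
  if (sum(wt) <= 0 || sum(wc) <= 0) stop("both groups need positive weight")
  if (!is.finite(sd_reference) || sd_reference <= 0) return(NA_real_)
  m1 <- sum(x[treat == 1] * wt) / sum(wt)
  m0 <- sum(x[treat == 0] * wc) / sum(wc)
  (m1 - m0) / sd_reference
}

#' Average standardized mean difference
#'
#' Arithmetic mean of the absolute per-covariate SMDs - an overall
#' imbalance score (signed averaging would let imbalances cancel).
#'
#' @param smds Vector of signed SMDs.
#' @export
asmd <- function(smds) {
  if (anyNA(smds)) stop("missing SMD entries")
  mean(abs(smds))
}

#' Overlap coefficient of two weighted propensity-score samples
#'
#' The integrated minimum of the two groups' weighted Gaussian kernel
#' density estimates of the propensity score: 1 means identical
#' distributions, 0 disjoint ones. Bandwidths follow Silverman's rule per
#' group (with a small floor for degenerate one-value groups); both
#' densities are evaluated on a common 512-point grid spanning the pooled
#' range padded by three bandwidths, and the minimum is integrated by the
#' trapezoidal rule.
#'
#' @param ps_treated,ps_control Propensity scores in the two groups.
#' @param w_treated,w_control Nonnegative unit weights (default uniform).
#' @param n_grid Number of grid points.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(ps_treated, ps_control,
                                w_treated = rep(1, length(ps_treated)),
                                w_control = rep(1, length(ps_control)),
                                n_grid = 512L) {
  stopifnot(length(ps_treated) >= 1, length(ps_control) >= 1)
  bw_of <- function(x) {
    if (length(unique(x)) < 2) {
      warning("single distinct propensity value in a group; bandwidth floor applied")
      return(1e-3)
    }
    stats::bw.nrd0(x)
  }
  bw1 <- bw_of(ps_treated)
  bw0 <- bw_of(ps_control)
  pad <- 3 * max(bw1, bw0)
  lo <- min(ps_treated, ps_control) - pad
  hi <- max(ps_treated, ps_control) + pad
  dens <- function(x, w, bw) {
    stats::density(x, weights = w / sum(w), bw = bw,
                   from = lo, to = hi, n = n_grid)$y
  }
  f1 <- dens(ps_treated, w_treated, bw1)
  f0 <- dens(ps_control, w_control, bw0)
  g <- seq(lo, hi, length.out = n_grid)
  m <- pmin(f1, f0)
  ovl <- sum((m[-1] + m[-n_grid]) / 2 * diff(g))
  min(max(ovl, 0), 1)
}

#' Balance diagnostics of a matched sample
#'
#' Computes, with matching weights, the per-covariate SMDs (reference SDs
#' from the unmatched cohort), their average (ASMD) and the overlap
#' coefficient of the propensity-score distributions in the matched groups.
#'
#' @param cohort List with covariate matrix `X` and treatment `treat` (the
#'   unmatched cohort).
#' @param sample A [ps_match()] result on that cohort.
#' @param fit The [fit_propensity()] object providing the scores.
#' @return Object of class `balance_report`: `smd_per_covariate`, `asmd`,
#'   `ovl`, `one_minus_ovl`.
#' @export
balance_report <- function(cohort, sample, fit) {
  n <- length(cohort$treat)
  w <- match_weights(sample, n)
  sd_ref <- vapply(seq_len(ncol(cohort$X)), function(j) {
    pooled_sd_reference(cohort$X[, j], cohort$treat)
  }, numeric(1))
  keep <- w > 0
  smds <- vapply(seq_len(ncol(cohort$X)), function(j) {
    smd(cohort$X[keep, j], cohort$treat[keep], w[keep], sd_ref[j])
  }, numeric(1))
  names(smds) <- colnames(cohort$X)
  ti <- keep & cohort$treat == 1
  ci <- keep & cohort$treat == 0
  ovl <- overlap_coefficient(fit$ps[ti], fit$ps[ci], w[ti], w[ci])
  structure(
    list(smd_per_covariate = smds,
         asmd = asmd(smds),
         ovl = ovl,
         one_minus_ovl = 1 - ovl),
    class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Balance: ASMD = %.3f | OVL = %.3f (1-OVL = %.3f)\n",
              x$asmd, x$ovl, x$one_minus_ovl))
  print(round(x$smd_per_covariate, 3))
  invisible(x)
}
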