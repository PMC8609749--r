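#' Caliper width on the logit propensity scale
#'
#' The admissible matching distance is 0.2 times the sample standard
#' deviation (denominator n - 1) of the logit propensity score over the
#' full cohort, a width known to perform well across many settings.
#'
#' @param logit_ps Logit propensity scores of the whole cohort.
#' @param multiplier Fraction of the SD; fixed at 0.2 by design.
#' @return Nonnegative caliper width; a degenerate (constant) score yields
#'   width 0 with a warning.
#' @export
compute_caliper <- function(logit_ps, multiplier = 0.2) {
  stopifnot(length(logit_ps) >= 2)
  s <- stats::sd(logit_ps)
  if (!is.finite(s) || s == 0) {
    warning("degenerate logit propensity distribution; caliper width is 0")
    return(0)
  }
  multiplier * s
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment on the baseline
#' covariates, main effects only. Perfect separation (fitted probabilities
#' numerically at 0 or 1) or non-convergence flags the fit rather than
#' erroring, so a simulation replication can be marked invalid downstream.
#'
#' @param cohort A [generate_cohort()] object, or any list with a covariate
#'   matrix `X` and binary vector `treat`.
#' @return Object of class `propensity_fit`: `ps`, `logit_ps`,
#'   `coefficients` (intercept + slopes), `converged`, `caliper_width`.
#' @export
fit_propensity <- function(cohort) {
  X <- cohort$X
  treat <- cohort$treat
  if (length(unique(treat)) < 2) {
    stop("cohort must contain both treated and control units")
  }
  dat <- data.frame(treat = treat, X)
  fit <- stats::glm(treat ~ ., data = dat, family = stats::binomial())
  ps <- as.numeric(stats::fitted(fit))
  eps <- 1e-8
  separated <- any(ps < eps | ps > 1 - eps)
  converged <- isTRUE(fit$converged) && !separated
  logit_ps <- stats::qlogis(pmin(pmax(ps, eps), 1 - eps))
  structure(
    list(ps = ps,
         logit_ps = logit_ps,
         coefficients = stats::coef(fit),
         converged = converged,
         caliper_width = compute_caliper(logit_ps)),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity fit: n =", length(x$ps),
      "| converged:", x$converged,
      sprintf("| caliper (logit scale): %.4f\n", x$caliper_width))
  invisible(x)
}

#' Matching strategy options
#'
#' @param with_replacement Logical; may a control serve several treated
#'   units?
#' @param ratio Number of controls matched to each treated unit (K, 1-5).
#' @param order_seed Seed for the random processing order of treated units.
#' @return Object of class `match_options`.
#' @export
match_options <- function(with_replacement = TRUE, ratio = 1L,
                          order_seed = 1L) {
  ratio <- as.integer(ratio)
  if (!ratio %in% 1:5) stop("ratio (K) must be an integer in 1..5")
  structure(list(with_replacement = isTRUE(with_replacement),
                 ratio = ratio,
                 caliper_multiplier = 0.2,
                 order_seed = as.integer(order_seed)),
            class = "match_options")
}

#' Greedy nearest-neighbour caliper matching
#'
#' Forms 1:K matched sets on the logit propensity scale. Treated units are
#' processed in a random order (drawn from `options$order_seed`); each is
#' given its K nearest distinct controls within the caliper, ties broken by
#' the lower control index. Without replacement, matched controls leave the
#' pool. A treated unit that cannot obtain all K in-caliper controls is
#' discarded entirely (incomplete matching). Within a set each control
#' carries weight 1/K and the treated unit weight 1, so weights reflect the
#' reciprocal of the number of controls sharing a treated unit.
#'
#' @param fit A [fit_propensity()] object (or a list with `logit_ps` and
#'   `caliper_width`).
#' @param treat Binary treatment vector aligned with `fit$logit_ps`.
#' @param options A [match_options()] object.
#' @return Object of class `matched_sample`: `treated` (vector of matched
#'   treated indices), `controls` (n_sets x K index matrix, columns ordered
#'   by distance), `usage` (named counts of sets per distinct matched
#'   control), `n_treated_total`, `n_treated_matched`, `discarded_treated`,
#'   plus the options and the caliper used.
#' @export
ps_match <- function(fit, treat, options = match_options()) {
  lps <- fit$logit_ps
  caliper <- fit$caliper_width
  stopifnot(length(lps) == length(treat))
  K <- options$ratio
  t_idx <- which(treat == 1)
  c_idx <- which(treat == 0)

  empty <- function() {
    structure(
      list(treated = integer(0),
           controls = matrix(integer(0), nrow = 0, ncol = K),
           usage = integer(0),
           n_treated_total = length(t_idx),
           n_treated_matched = 0L,
           discarded_treated = t_idx,
           caliper_width = caliper,
           options = options),
      class = "matched_sample")
  }
  if (length(t_idx) == 0 || length(c_idx) == 0) return(empty())

  set.seed(options$order_seed)
  order_t <- t_idx[sample.int(length(t_idx))]

  # controls sorted by logit PS (then index) once; each treated unit then
  # collects its nearest candidates by expanding two pointers outward from
  # its insertion point, so candidates arrive in nondecreasing distance
  nc <- length(c_idx)
  ord_c <- order(lps[c_idx], c_idx)
  scid <- c_idx[ord_c]
  slps <- lps[scid]
  avail <- rep(TRUE, nc)
  repl <- options$with_replacement

  matched_t <- integer(0)
  control_rows <- vector("list", length(order_t))
  n_sets <- 0L
  pos_t <- findInterval(lps[order_t], slps)
  for (u in seq_along(order_t)) {
    ti <- order_t[u]
    v <- lps[ti]
    i <- pos_t[u]
    j <- i + 1L
    cand <- integer(0)
    cand_d <- numeric(0)
    repeat {
      if (!repl) {
        while (i >= 1L && !avail[i]) i <- i - 1L
        while (j <= nc && !avail[j]) j <- j + 1L
      }
      di <- if (i >= 1L) v - slps[i] else Inf
      dj <- if (j <= nc) slps[j] - v else Inf
      if (di <= dj) { d <- di; p <- i } else { d <- dj; p <- j }
      if (d > caliper) break
      if (length(cand) >= K && d > cand_d[K]) break  # keep exact ties in play
      cand <- c(cand, p)
      cand_d <- c(cand_d, d)
      if (p == i) i <- i - 1L else j <- j + 1L
    }
    if (length(cand) < K) next
    sel <- cand[order(cand_d, scid[cand])[seq_len(K)]]
    n_sets <- n_sets + 1L
    matched_t[n_sets] <- ti
    control_rows[[n_sets]] <- scid[sel]
    if (!repl) avail[sel] <- FALSE
  }

  if (n_sets == 0L) return(empty())
  controls <- matrix(unlist(control_rows[seq_len(n_sets)]),
                     nrow = n_sets, ncol = K, byrow = TRUE)
  usage <- table(factor(controls, levels = sort(unique(as.vector(controls)))))
  usage <- stats::setNames(as.integer(usage), names(usage))
  structure(
    list(treated = matched_t,
         controls = controls,
         usage = usage,
         n_treated_total = length(t_idx),
         n_treated_matched = n_sets,
         discarded_treated = setdiff(t_idx, matched_t),
         caliper_width = caliper,
         options = options),
    class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat("Matched sample:", x$n_treated_matched, "of", x$n_treated_total,
      "treated matched 1:", x$options$ratio,
      if (x$options$with_replacement) "with" else "without", "replacement\n")
  if (x$n_treated_matched > 0) {
    cat(sprintf("  distinct controls used: %d | resampled fraction: %.3f\n",
                length(x$usage), proportion_resampled_controls(x)))
  }
  invisible(x)
}

#' Tidy view of a matched sample
#'
#' One row per unit per matched set: set id, role (treated/control), cohort
#' index, logit propensity score and matching weight.
#'
#' @param x A [ps_match()] result.
#' @param logit_ps Optional logit propensity scores to annotate the rows.
#' @param ... Unused.
#' @export
as.data.frame.matched_sample <- function(x, logit_ps = NULL, ...) {
  if (x$n_treated_matched == 0) {
    return(data.frame(set = integer(0), role = character(0),
                      unit = integer(0), logit_ps = numeric(0),
                      weight = numeric(0)))
  }
  K <- ncol(x$controls)
  set_t <- seq_len(x$n_treated_matched)
  out <- data.frame(
    set = c(set_t, rep(set_t, times = K)),
    role = c(rep("treated", length(set_t)),
             rep("control", length(set_t) * K)),
    unit = c(x$treated, as.vector(x$controls)),
    weight = c(rep(1, length(set_t)), rep(1 / K, length(set_t) * K))
  )
  out$logit_ps <- if (is.null(logit_ps)) NA_real_ else logit_ps[out$unit]
  out[order(out$set, out$role == "control"), ]
}

#' Unit-level matching weights
#'
#' ATT weights over the whole cohort implied by a matched sample: each
#' matched treated unit has weight 1; each control accumulates 1/K for
#' every set it belongs to; unmatched units have weight 0.
#'
#' @param sample A [ps_match()] result.
#' @param n Cohort size.
#' @return Numeric weight vector of length `n`.
#' @export
match_weights <- function(sample, n) {
  w <- numeric(n)
  if (sample$n_treated_matched == 0) return(w)
  K <- ncol(sample$controls)
  w[sample$treated] <- 1
  idx <- as.integer(names(sample$usage))
  w[idx] <- sample$usage / K
  w
}

#' Proportion of matched treated (PMT)
#'
#' Fraction of treated units retained in the matched sample; values near 1
#' mean the ATT estimate still generalizes to the full treated population.
#'
#' @param sample A [ps_match()] result.
#' @export
proportion_matched_treated <- function(sample) {
  if (sample$n_treated_total == 0) stop("no treated units in the cohort")
  sample$n_treated_matched / sample$n_treated_total
}

#' Proportion of resampled controls (PRC)
#'
#' Among the distinct controls appearing in the matched sample, the
#' fraction used in more than one matched set. Identically 0 when matching
#' is done without replacement.
#'
#' @param sample A [ps_match()] result.
#' @return Fraction in `[0, 1]`, or `NA` if no control was matched.
#' @export
proportion_resampled_controls <- function(sample) {
  if (length(sample$usage) == 0) return(NA_real_)
  mean(sample$usage >= 2)
}
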