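#' Matching strategy grid
#'
#' All 10 strategies: with/without replacement crossed with oversampling
#' ratios K = 1..5.
#'
#' @return Data frame with columns `strategy` (label), `with_replacement`,
#'   `ratio`.
#' @export
strategy_grid <- function() {
  g <- expand.grid(ratio = 1:5, with_replacement = c(FALSE, TRUE))
  data.frame(
    strategy = sprintf("%s_K%d",
                       ifelse(g$with_replacement, "repl", "norepl"),
                       g$ratio),
    with_replacement = g$with_replacement,
    ratio = g$ratio,
    stringsAsFactors = FALSE
  )
}

# Hierarchical seed derivation: study seed -> scenario -> replication ->
# purpose. A rolling polynomial hash (base 131, prime modulus below 2^31,
# separator-terminated parts) keeps derived seeds collision-poor and always
# valid 32-bit seeds, so any single replication is reproducible in
# isolation.
derive_seed <- function(base_seed, ...) {
  parts <- vapply(c(list(base_seed), list(...)), as.character, character(1))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 131 + ch) %% 2147483629
    h <- (h * 131 + 1) %% 2147483629
  }
  as.integer(h + 1)
}

#' Run one simulation replication
#'
#' Generates one cohort from a calibrated scenario, fits the propensity
#' model once, and applies every requested matching strategy to it,
#' producing one record per strategy: the ATT estimate with both standard
#' errors and CIs, coverage indicators against the scenario's oracle ATT,
#' and the balance diagnostics (ASMD, 1-OVL, PMT, PRC). Failures
#' (propensity non-convergence, fewer than two matched sets) are encoded as
#' invalid records with a reason, never dropped silently.
#'
#' @param config Calibrated [scenario_config()].
#' @param strategies Data frame as from [strategy_grid()] (or a subset).
#' @param rep_index Replication number.
#' @param base_seed Study-level seed; all randomness is derived from
#'   `(base_seed, scenario, rep_index)`.
#' @return Data frame with one row per strategy.
#' @export
run_replication <- function(config, strategies = strategy_grid(),
                            rep_index = 1L, base_seed = 1L) {
  sid <- scenario_id(config)
  cohort_seed <- derive_seed(base_seed, sid, rep_index, "cohort")
  cohort <- generate_cohort(config, seed = cohort_seed)

  template <- data.frame(
    scenario = sid, strategy = strategies$strategy,
    replication = rep_index, seed = cohort_seed,
    att_hat = NA_real_, se_standard = NA_real_, se_ai = NA_real_,
    ci_standard_lo = NA_real_, ci_standard_hi = NA_real_,
    ci_ai_lo = NA_real_, ci_ai_hi = NA_real_,
    cover_standard = NA, cover_ai = NA,
    asmd = NA_real_, one_minus_ovl = NA_real_,
    pmt = NA_real_, prc = NA_real_,
    valid = FALSE, failure_reason = NA_character_,
    stringsAsFactors = FALSE
  )

  both_arms <- length(unique(cohort$treat)) == 2
  if (!both_arms) {
    template$failure_reason <- "degenerate cohort: single treatment arm"
    return(template)
  }
  fit <- fit_propensity(cohort)
  if (!fit$converged) {
    template$failure_reason <- "propensity model did not converge"
    return(template)
  }

  att_true <- config$att_true
  sigma2 <- if (any(strategies$with_replacement)) {
    control_conditional_variances(cohort$y, fit$logit_ps, cohort$treat)
  }
  for (i in seq_len(nrow(strategies))) {
    opts <- match_options(
      with_replacement = strategies$with_replacement[i],
      ratio = strategies$ratio[i],
      order_seed = derive_seed(base_seed, sid, rep_index, "order",
                               strategies$strategy[i])
    )
    ms <- ps_match(fit, cohort$treat, opts)
    template$pmt[i] <- proportion_matched_treated(ms)
    if (ms$n_treated_matched < 2) {
      template$failure_reason[i] <- "fewer than two matched sets"
      next
    }
    est <- att_estimate(ms, cohort$y, fit$logit_ps, cohort$treat,
                        sigma2 = sigma2)
    bal <- balance_report(cohort, ms, fit)
    template$att_hat[i] <- est$att
    template$se_standard[i] <- est$se_standard
    template$se_ai[i] <- est$se_ai
    template$ci_standard_lo[i] <- est$ci_standard[1]
    template$ci_standard_hi[i] <- est$ci_standard[2]
    template$ci_ai_lo[i] <- est$ci_ai[1]
    template$ci_ai_hi[i] <- est$ci_ai[2]
    template$cover_standard[i] <- est$ci_standard[1] <= att_true &&
      att_true <= est$ci_standard[2]
    template$cover_ai[i] <- if (is.finite(est$se_ai)) {
      est$ci_ai[1] <= att_true && att_true <= est$ci_ai[2]
    } else NA
    template$asmd[i] <- bal$asmd
    template$one_minus_ovl[i] <- bal$one_minus_ovl
    template$prc[i] <- proportion_resampled_controls(ms)
    template$valid[i] <- TRUE
  }
  template
}

#' Aggregate replication records into performance measures
#'
#' Per scenario x strategy cell, over the valid records only: relative bias
#' `|mean(att_hat) - att_true| / att_true * 100`, RMSE
#' `sqrt(var(att_hat) + bias^2)` (variance with denominator R), nominal
#' coverage of both 95% CI methods, and mean balance diagnostics. Invalid
#' records are excluded but counted.
#'
#' @param records Data frame of [run_replication()] rows (possibly many
#'   replications and scenarios).
#' @param att_true Named vector mapping scenario id to oracle ATT, or a
#'   single number when all records share one scenario.
#' @return Data frame of class `performance_summary`, one row per
#'   scenario x strategy.
#' @export
summarize_performance <- function(records, att_true) {
  cells <- unique(records[, c("scenario", "strategy")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- cells$scenario[i]
    st <- cells$strategy[i]
    truth <- if (length(att_true) == 1 && is.null(names(att_true))) {
      att_true
    } else {
      unname(att_true[sc])
    }
    sub <- records[records$scenario == sc & records$strategy == st, ]
    v <- sub[sub$valid, ]
    out <- data.frame(
      scenario = sc, strategy = st, att_true = truth,
      relative_bias = NA_real_, rmse = NA_real_,
      nc_standard = NA_real_, nc_ai = NA_real_,
      mean_asmd = NA_real_, mean_one_minus_ovl = NA_real_,
      mean_pmt = NA_real_, mean_prc = NA_real_,
      n_valid = nrow(v), n_total = nrow(sub),
      stringsAsFactors = FALSE
    )
    if (nrow(v) == 0) return(out)
    bias <- mean(v$att_hat) - truth
    var_r <- mean((v$att_hat - mean(v$att_hat))^2)  # denominator R
    out$relative_bias <- abs(bias / truth) * 100
    out$rmse <- sqrt(var_r + bias^2)
    out$nc_standard <- mean(v$cover_standard)
    out$nc_ai <- if (all(is.na(v$cover_ai))) NA_real_ else
      mean(v$cover_ai, na.rm = TRUE)
    out$mean_asmd <- mean(v$asmd)
    out$mean_one_minus_ovl <- mean(v$one_minus_ovl)
    out$mean_pmt <- mean(v$pmt, na.rm = TRUE)
    out$mean_prc <- mean(v$prc, na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_summary", class(out))
  out
}

#' Run a full simulation study
#'
#' Calibrates the scenarios (unless already calibrated), runs the
#' replications for every scenario x strategy cell, and aggregates the
#' performance measures. Replications are independent given their derived
#' seeds, so results do not depend on the worker count.
#'
#' @param scenarios List of [scenario_config()] objects (calibrated or
#'   not).
#' @param strategies Strategy data frame, default the full 10-strategy
#'   grid.
#' @param n_reps Replications per scenario (the study design uses 10,000;
#'   smaller values give desk-scale runs).
#' @param seed Study-level seed.
#' @param n_cal Calibration draw size.
#' @param workers Number of parallel workers (forked; 1 = sequential).
#' @param out_dir Optional directory: writes `replications.csv`,
#'   `summary.csv`, `calibration.csv` and `manifest.json`.
#' @return List with `records`, `summary`, `scenarios` (calibrated) and
#'   `manifest`.
#' @export
run_study <- function(scenarios, strategies = strategy_grid(),
                      n_reps = 10000L, seed = 1L, n_cal = 1e6,
                      workers = 1L, out_dir = NULL) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  needs_cal <- !vapply(scenarios, is_calibrated, logical(1))
  if (any(needs_cal)) {
    scenarios <- calibrate_grid(scenarios, n_cal = n_cal,
                                seed = derive_seed(seed, "calibration"))
  }
  one_scenario <- function(config) {
    runs <- if (workers > 1L) {
      parallel::mclapply(seq_len(n_reps), function(r) {
        run_replication(config, strategies, r, seed)
      }, mc.cores = workers)
    } else {
      lapply(seq_len(n_reps), function(r) {
        run_replication(config, strategies, r, seed)
      })
    }
    do.call(rbind, runs)
  }
  records <- do.call(rbind, lapply(scenarios, function(s) {
    message("scenario ", scenario_id(s), ": ", n_reps, " replications")
    one_scenario(s)
  }))
  truths <- stats::setNames(
    vapply(scenarios, function(s) s$att_true, numeric(1)),
    vapply(scenarios, scenario_id, character(1))
  )
  summary <- summarize_performance(records, truths)
  manifest <- list(
    seed = seed, n_reps = n_reps, n_cal = n_cal,
    scenarios = names(truths), att_true = as.list(truths),
    strategies = strategies$strategy,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("psmover"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "replications.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    write_calibration(scenarios, file.path(out_dir, "calibration.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(records = records, summary = summary, scenarios = scenarios,
       manifest = manifest)
}

#' Applied analysis of a user cohort
#'
#' Runs the full 10-strategy matching comparison on one observed cohort:
#' fits the propensity model (main effects), forms every matched sample,
#' and reports (i) a balance table (ASMD, 1-OVL, PMT, PRC per strategy),
#' (ii) an estimates table (ATT with standard and - with replacement -
#' Abadie-Imbens 95% CIs) and (iii) the propensity-score distribution by
#' group for plotting. Rows with missing values in the analysis variables
#' are dropped (complete-case) and counted.
#'
#' @param data Data frame, or path to a delimited file readable by
#'   [utils::read.csv()].
#' @param treatment,outcome Names of the binary treatment and outcome
#'   columns (values 0/1).
#' @param covariates Character vector of covariate column names.
#' @param order_seed Seed for the matchers' processing order.
#' @param out_dir Optional directory; writes `balance.csv`,
#'   `estimates.csv`, `ps_distribution.csv`.
#' @return List with `balance`, `estimates`, `ps_distribution`,
#'   `n_dropped`, `fit`.
#' @export
applied_analysis <- function(data, treatment, outcome, covariates,
                             order_seed = 1L, out_dir = NULL) {
  if (is.character(data) && length(data) == 1) {
    data <- utils::read.csv(data, stringsAsFactors = FALSE)
  }
  cols <- c(treatment, outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, cols])
  n_dropped <- sum(!cc)
  data <- data[cc, ]
  treat <- data[[treatment]]
  y <- data[[outcome]]
  if (!all(treat %in% c(0, 1)) || length(unique(treat)) < 2) {
    stop("treatment must be binary 0/1 with both arms present")
  }
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- as.matrix(data[, covariates, drop = FALSE])
  if (any(apply(X, 2, function(v) length(unique(v)) < 2))) {
    stop("every covariate must take at least two values")
  }

  cohort <- list(X = X, treat = treat, y = y)
  dat <- data.frame(treat = treat, X)
  fit_glm <- stats::glm(treat ~ ., data = dat, family = stats::binomial())
  ps <- as.numeric(stats::fitted(fit_glm))
  eps <- 1e-8
  logit_ps <- stats::qlogis(pmin(pmax(ps, eps), 1 - eps))
  fit <- structure(
    list(ps = ps, logit_ps = logit_ps,
         coefficients = stats::coef(fit_glm),
         converged = isTRUE(fit_glm$converged),
         caliper_width = compute_caliper(logit_ps)),
    class = "propensity_fit")

  strategies <- strategy_grid()
  bal_rows <- list()
  est_rows <- list()
  for (i in seq_len(nrow(strategies))) {
    opts <- match_options(strategies$with_replacement[i],
                          strategies$ratio[i],
                          order_seed = derive_seed(order_seed, "applied",
                                                   strategies$strategy[i]))
    ms <- ps_match(fit, treat, opts)
    pmt <- proportion_matched_treated(ms)
    prc <- proportion_resampled_controls(ms)
    prc <- if (!strategies$with_replacement[i]) 0 else prc
    if (ms$n_treated_matched >= 2) {
      bal <- balance_report(cohort, ms, fit)
      est <- att_estimate(ms, y, logit_ps, treat)
      bal_rows[[i]] <- data.frame(
        replacement = strategies$with_replacement[i],
        oversampling = strategies$ratio[i],
        asmd = bal$asmd, one_minus_ovl = bal$one_minus_ovl,
        pmt = pmt, prc = prc)
      est_rows[[i]] <- data.frame(
        replacement = strategies$with_replacement[i],
        oversampling = strategies$ratio[i],
        att = est$att,
        se_standard = est$se_standard,
        ci_standard_lo = est$ci_standard[1],
        ci_standard_hi = est$ci_standard[2],
        se_ai = est$se_ai,
        ci_ai_lo = est$ci_ai[1], ci_ai_hi = est$ci_ai[2],
        n_sets = est$n_sets)
    } else {
      bal_rows[[i]] <- data.frame(
        replacement = strategies$with_replacement[i],
        oversampling = strategies$ratio[i],
        asmd = NA_real_, one_minus_ovl = NA_real_, pmt = pmt, prc = prc)
      est_rows[[i]] <- data.frame(
        replacement = strategies$with_replacement[i],
        oversampling = strategies$ratio[i],
        att = NA_real_, se_standard = NA_real_,
        ci_standard_lo = NA_real_, ci_standard_hi = NA_real_,
        se_ai = NA_real_, ci_ai_lo = NA_real_, ci_ai_hi = NA_real_,
        n_sets = ms$n_treated_matched)
    }
  }
  balance <- do.call(rbind, bal_rows)
  estimates <- do.call(rbind, est_rows)
  rownames(balance) <- rownames(estimates) <- NULL
  ps_distribution <- data.frame(group = ifelse(treat == 1, "treated",
                                               "control"),
                                ps = ps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(balance, file.path(out_dir, "balance.csv"),
                     row.names = FALSE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(ps_distribution,
                     file.path(out_dir, "ps_distribution.csv"),
                     row.names = FALSE)
  }
  list(balance = balance, estimates = estimates,
       ps_distribution = ps_distribution,
       n_dropped = n_dropped, fit = fit)
}
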