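# Transparent reference implementations used as oracles in the tests.
# They are deliberately naive (full distance recomputation, explicit
# loops) and share only the documented contracts with the package code:
# greedy processing order, caliper rule, nearest-K selection, ties to the
# lowest control index, discard-if-incomplete, pool depletion without
# replacement.

# Brute-force matcher on a given processing order of treated units.
oracle_match <- function(logit_ps, treat, with_replacement, K,
                         order_treated, caliper) {
  c_all <- which(treat == 0)
  avail <- rep(TRUE, length(logit_ps))
  treated <- integer(0)
  sets <- list()
  for (ti in order_treated) {
    pool <- if (with_replacement) c_all else c_all[avail[c_all]]
    if (length(pool) == 0) next
    d <- abs(logit_ps[pool] - logit_ps[ti])
    keep <- pool[d <= caliper]
    dk <- d[d <= caliper]
    if (length(keep) < K) next
    sel <- keep[order(dk, keep)][seq_len(K)]
    treated <- c(treated, ti)
    sets[[length(sets) + 1]] <- sel
    if (!with_replacement) avail[sel] <- FALSE
  }
  list(treated = treated, sets = sets)
}

# The processing order ps_match() draws from its order seed.
greedy_order <- function(treat, order_seed) {
  t_idx <- which(treat == 1)
  set.seed(order_seed)
  t_idx[sample.int(length(t_idx))]
}

# Minimal stand-in for a propensity fit when scores are given directly.
fake_fit <- function(logit_ps, caliper_width) {
  list(logit_ps = logit_ps, caliper_width = caliper_width,
       ps = stats::plogis(logit_ps), converged = TRUE)
}

# A quick calibrated scenario for unit tests (smaller calibration draw
# than the study default; targets still hit well within tolerance).
# Memoised: calibration depends only on (strength, prop, family, n_cal).
.scenario_cache <- new.env(parent = emptyenv())
test_scenario <- function(strength = "weak", prop = 0.5, n = 250,
                          family = "logistic", n_cal = 2e5) {
  key <- paste(strength, prop, family, n_cal, sep = "|")
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- calibrate_scenario(
      scenario_config(strength, prop, 100, family),
      n_cal = n_cal, seed = 202111
    )
  }
  cfg <- .scenario_cache[[key]]
  cfg$sample_size <- as.integer(n)
  cfg
}
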