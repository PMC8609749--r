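test_that("caliper is 0.2 of the sample SD of the logit PS", {
  expect_equal(compute_caliper(c(-1, 0, 1)), 0.2)
  expect_warning(w0 <- compute_caliper(c(1, 1, 1)), "degenerate")
  expect_equal(w0, 0)
  x <- rnorm(50)
  expect_equal(compute_caliper(x), 0.2 * sd(x))
})

test_that("propensity fit recovers a null and a generating model", {
  set.seed(5)
  X <- draw_covariates(20000)
  treat <- rbinom(nrow(X), 1, 0.4)  # independent of X
  fit <- fit_propensity(list(X = X, treat = treat))
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients[-1]) < 0.05))
  expect_equal(unname(plogis(fit$coefficients[1])), mean(treat),
               tolerance = 0.02)
  expect_equal(fit$logit_ps, qlogis(fit$ps), tolerance = 1e-8)

  cfg <- test_scenario("weak", 0.5, 250)
  X <- draw_covariates(1e5, seed = 9)
  pT <- treatment_probabilities(X, cfg$beta0, cfg$beta)
  set.seed(10)
  treat <- rbinom(length(pT), 1, pT)
  fit <- fit_propensity(list(X = X, treat = treat))
  expect_true(all(abs(fit$coefficients[-1] - cfg$beta) < 0.05))

  expect_error(fit_propensity(list(X = X[1:5, ], treat = rep(1, 5))),
               "both treated and control")
})

test_that("toy matches reproduce the enumerated solutions", {
  lps <- c(0.00, 0.05, 0.30, 0.50)
  treat <- c(1, 0, 0, 0)
  # caliper 0.2: only one control within reach, K=2 cannot be filled
  ms <- ps_match(fake_fit(lps, 0.2), treat, match_options(TRUE, 2, 1))
  expect_equal(ms$n_treated_matched, 0L)
  expect_equal(ms$discarded_treated, 1L)
  expect_equal(proportion_matched_treated(ms), 0)
  # caliper 0.6: nearest two controls are 0.05 and 0.30
  ms <- ps_match(fake_fit(lps, 0.6), treat, match_options(TRUE, 2, 1))
  expect_equal(ms$n_treated_matched, 1L)
  expect_equal(sort(ms$controls[1, ]), c(2L, 3L))
  df <- as.data.frame(ms, logit_ps = lps)
  expect_equal(df$weight[df$role == "control"], c(0.5, 0.5))
  expect_equal(df$weight[df$role == "treated"], 1)
})

test_that("without replacement a control serves at most one set", {
  lps <- c(0.00, 0.02, 0.01)
  treat <- c(1, 1, 0)
  ms <- ps_match(fake_fit(lps, 0.5), treat,
                 match_options(FALSE, 1, order_seed = 3))
  expect_equal(ms$n_treated_matched, 1L)
  expect_equal(unname(ms$usage), 1L)
  expect_equal(length(ms$discarded_treated), 1L)
})

test_that("greedy matcher agrees with the brute-force oracle on small cohorts", {
  set.seed(42)
  for (case in 1:200) {
    n <- sample(4:8, 1)
    # duplicated values exercise the tie-break rule
    lps <- round(rnorm(n, sd = 0.5), 1)
    treat <- rbinom(n, 1, 0.5)
    if (length(unique(treat)) < 2) next
    K <- sample(1:3, 1)
    repl <- sample(c(TRUE, FALSE), 1)
    caliper <- runif(1, 0.1, 1)
    seed <- sample.int(1e6, 1)
    ms <- ps_match(fake_fit(lps, caliper), treat,
                   match_options(repl, K, order_seed = seed))
    oracle <- oracle_match(lps, treat, repl, K,
                           greedy_order(treat, seed), caliper)
    expect_equal(ms$treated, oracle$treated,
                 info = sprintf("case %d treated", case))
    expect_equal(lapply(seq_len(ms$n_treated_matched),
                        function(i) sort(ms$controls[i, ])),
                 lapply(oracle$sets, sort),
                 info = sprintf("case %d sets", case))
  }
})

test_that("matched-sample invariants hold on random cohorts", {
  set.seed(99)
  for (case in 1:40) {
    n <- 60
    lps <- rnorm(n)
    treat <- rbinom(n, 1, 0.4)
    if (sum(treat) < 2 || sum(1 - treat) < 2) next
    K <- sample(1:5, 1)
    repl <- sample(c(TRUE, FALSE), 1)
    caliper <- 0.2 * sd(lps)
    ms <- ps_match(fake_fit(lps, caliper), treat,
                   match_options(repl, K, order_seed = case))
    if (ms$n_treated_matched == 0) next
    # caliper respected for every pair
    d <- abs(lps[ms$controls] -
               lps[ms$treated][row(ms$controls)])
    expect_true(all(d <= caliper + 1e-12))
    # distinct controls within a set
    expect_true(all(apply(ms$controls, 1, function(r) !anyDuplicated(r))))
    # exclusivity without replacement
    if (!repl) expect_true(all(ms$usage <= 1L))
    # usage counts match the sets
    expect_equal(sum(ms$usage), length(ms$controls))
    # control weights sum to 1 per set
    df <- as.data.frame(ms)
    wsum <- tapply(df$weight[df$role == "control"],
                   df$set[df$role == "control"], sum)
    expect_true(all(abs(wsum - 1) < 1e-12))
  }
})

test_that("with replacement and K=1 the match is the global nearest neighbour", {
  set.seed(7)
  lps <- rnorm(40)
  treat <- rbinom(40, 1, 0.5)
  caliper <- 0.2 * sd(lps)
  controls <- which(treat == 0)
  ref <- NULL
  for (seed in c(1, 10, 999)) {
    ms <- ps_match(fake_fit(lps, caliper), treat,
                   match_options(TRUE, 1, order_seed = seed))
    got <- ms$controls[order(ms$treated), 1]
    expect_true(all(vapply(seq_len(ms$n_treated_matched), function(i) {
      ti <- sort(ms$treated)[i]
      d <- abs(lps[controls] - lps[ti])
      best <- controls[order(d, controls)][1]
      got[i] == best
    }, logical(1))))
    if (is.null(ref)) ref <- got else expect_identical(got, ref)
  }
})

test_that("PMT and PRC follow their definitions", {
  ms <- list(n_treated_total = 10L, n_treated_matched = 7L,
             usage = c(`3` = 1L, `4` = 1L, `5` = 2L, `8` = 3L))
  class(ms) <- "matched_sample"
  expect_equal(proportion_matched_treated(ms), 0.7)
  expect_equal(proportion_resampled_controls(ms), 0.5)
  ms$usage <- c(`3` = 2L, `4` = 2L)
  expect_equal(proportion_resampled_controls(ms), 1)
  ms$usage <- integer(0)
  expect_true(is.na(proportion_resampled_controls(ms)))
  # without replacement PRC is always 0
  set.seed(12)
  lps <- rnorm(30)
  treat <- rbinom(30, 1, 0.5)
  ms <- ps_match(fake_fit(lps, 1), treat, match_options(FALSE, 1, 5))
  if (ms$n_treated_matched > 0) {
    expect_equal(proportion_resampled_controls(ms), 0)
  }
})

test_that("degenerate inputs yield empty matched samples", {
  ms <- ps_match(fake_fit(c(0, 0.1), 0.2), c(1, 1), match_options(TRUE, 1, 1))
  expect_equal(ms$n_treated_matched, 0L)
  ms <- ps_match(fake_fit(c(0, 0.1), 0.2), c(0, 0), match_options(TRUE, 1, 1))
  expect_equal(ms$n_treated_matched, 0L)
  expect_equal(ms$n_treated_total, 0L)
})
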