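test_that("scenario grid is the full 24-cell factorial", {
  for (fam in c("logistic", "linear_probability")) {
    g <- scenario_grid(fam)
    expect_length(g, 24)
    keys <- vapply(g, function(s) {
      paste(s$assignment_strength, s$treated_proportion_target, s$sample_size)
    }, character(1))
    expect_equal(anyDuplicated(keys), 0L)
    expect_setequal(vapply(g, function(s) s$sample_size, integer(1)),
                    c(100L, 250L, 500L, 1000L))
    expect_true(all(vapply(g, function(s) s$outcome_family, character(1)) == fam))
  }
})

test_that("strategy grid holds the 10 replacement-by-ratio combinations", {
  g <- strategy_grid()
  expect_equal(nrow(g), 10L)
  expect_equal(anyDuplicated(g[, c("with_replacement", "ratio")]), 0L)
  expect_setequal(g$ratio, 1:5)
  expect_equal(sum(g$with_replacement), 5L)
})

test_that("derived seeds are distinct across replications and strategies", {
  sid <- "strong_p30_n500_logit"
  cohort_seeds <- vapply(1:2000, function(r) {
    psmover:::derive_seed(1L, sid, r, "cohort")
  }, integer(1))
  expect_equal(length(unique(cohort_seeds)), 2000L)
  expect_true(all(cohort_seeds > 0 & cohort_seeds < 2^31))
  order_seeds <- unlist(lapply(strategy_grid()$strategy, function(s) {
    vapply(1:200, function(r) {
      psmover:::derive_seed(1L, sid, r, "order", s)
    }, integer(1))
  }))
  expect_equal(anyDuplicated(c(cohort_seeds[1:200], order_seeds)), 0L)
  # deterministic
  expect_identical(psmover:::derive_seed(7L, "a", 3, "cohort"),
                   psmover:::derive_seed(7L, "a", 3, "cohort"))
})

test_that("replications are deterministic and well-formed", {
  cfg <- test_scenario("weak", 0.5, 100)
  r1 <- run_replication(cfg, strategy_grid(), rep_index = 2, base_seed = 77)
  r2 <- run_replication(cfg, strategy_grid(), rep_index = 2, base_seed = 77)
  expect_identical(r1, r2)
  r3 <- run_replication(cfg, strategy_grid(), rep_index = 3, base_seed = 77)
  expect_false(identical(r1$att_hat, r3$att_hat))
  expect_equal(nrow(r1), 10L)
  v <- r1[r1$valid, ]
  expect_true(all(v$att_hat >= -1 & v$att_hat <= 1))
  expect_true(all(v$prc[!grepl("^repl", v$strategy)] == 0))
  expect_true(all(is.na(v$se_ai[!grepl("^repl", v$strategy)])))
  expect_true(all(is.finite(v$se_ai[grepl("^repl", v$strategy)])))
  # invalid rows carry a reason
  bad <- r1[!r1$valid, ]
  expect_true(all(!is.na(bad$failure_reason)))
})

test_that("performance aggregation matches an independent recomputation", {
  # synthetic records with known moments
  rec <- data.frame(
    scenario = "s", strategy = "a",
    att_hat = c(0.10, 0.12, 0.14), cover_standard = c(TRUE, TRUE, FALSE),
    cover_ai = c(TRUE, FALSE, FALSE), asmd = c(0.1, 0.2, 0.3),
    one_minus_ovl = 0.05, pmt = 1, prc = 0, valid = TRUE
  )
  s <- summarize_performance(rec, att_true = 0.15)
  expect_equal(s$relative_bias, abs(mean(rec$att_hat) - 0.15) / 0.15 * 100)
  expect_equal(s$relative_bias, 20, tolerance = 1e-10)
  bias <- mean(rec$att_hat) - 0.15
  var_r <- mean((rec$att_hat - mean(rec$att_hat))^2)
  expect_equal(s$rmse, sqrt(var_r + bias^2))
  expect_equal(s$nc_standard, 2 / 3)
  expect_equal(s$nc_ai, 1 / 3)
  expect_equal(s$mean_asmd, 0.2)

  # zero variance collapses RMSE to |bias|
  rec$att_hat <- 0.12
  s <- summarize_performance(rec, 0.15)
  expect_equal(s$rmse, 0.03)
  expect_equal(s$relative_bias, 20)

  # unbiased records have zero relative bias
  rec$att_hat <- 0.15
  expect_equal(summarize_performance(rec, 0.15)$relative_bias, 0)

  # invalid records are excluded but counted
  rec$valid <- c(TRUE, TRUE, FALSE)
  rec$att_hat <- c(0.1, 0.2, 99)
  s <- summarize_performance(rec, 0.15)
  expect_equal(s$n_valid, 2L)
  expect_equal(s$n_total, 3L)
  expect_equal(s$relative_bias, 0, tolerance = 1e-10)

  # empty cells report missing statistics
  rec$valid <- FALSE
  s <- summarize_performance(rec, 0.15)
  expect_equal(s$n_valid, 0L)
  expect_true(is.na(s$rmse))
})

test_that("aggregation from run_replication records cross-checks by hand", {
  cfg <- test_scenario("weak", 0.5, 100)
  recs <- do.call(rbind, lapply(1:30, function(r) {
    run_replication(cfg, strategy_grid()[c(1, 6), ], r, base_seed = 5)
  }))
  s <- summarize_performance(recs, cfg$att_true)
  for (st in unique(s$strategy)) {
    v <- recs[recs$valid & recs$strategy == st, ]
    expect_equal(s$nc_standard[s$strategy == st], mean(v$cover_standard))
    expect_equal(s$mean_pmt[s$strategy == st], mean(v$pmt))
    expect_equal(
      s$rmse[s$strategy == st],
      sqrt(mean((v$att_hat - mean(v$att_hat))^2) +
             (mean(v$att_hat) - cfg$att_true)^2))
  }
})

test_that("run_study writes reproducible tidy outputs and a manifest", {
  cfg <- test_scenario("weak", 0.5, 100)
  strat <- strategy_grid()[c(2, 7), ]
  d1 <- file.path(tempdir(), "study1")
  d2 <- file.path(tempdir(), "study2")
  suppressMessages({
    out1 <- run_study(cfg, strat, n_reps = 25, seed = 9, out_dir = d1)
    out2 <- run_study(cfg, strat, n_reps = 25, seed = 9, out_dir = d2)
  })
  expect_equal(nrow(out1$summary), 2L)
  expect_true(file.exists(file.path(d1, "replications.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # same manifest seed, byte-identical summary table
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(m$seed, 9)
  expect_equal(m$n_reps, 25)
  # calibration table round-trips
  back <- read_calibration(file.path(d1, "calibration.csv"))
  expect_equal(back[[1]]$beta0, out1$scenarios[[1]]$beta0)
  expect_equal(back[[1]]$att_true, out1$scenarios[[1]]$att_true)
})

test_that("results are independent of the worker count", {
  skip_on_os("windows")
  cfg <- test_scenario("weak", 0.5, 100)
  strat <- strategy_grid()[c(1, 6), ]
  suppressMessages({
    seq_run <- run_study(cfg, strat, n_reps = 12, seed = 4, workers = 1)
    par_run <- run_study(cfg, strat, n_reps = 12, seed = 4, workers = 2)
  })
  expect_equal(seq_run$records, par_run$records)
})

test_that("applied analysis reproduces the report structure on a synthetic cohort", {
  cfg <- test_scenario("weak", 0.5, 250)
  cohort <- generate_cohort(cfg, seed = 14)
  dat <- data.frame(cohort$X, device = cohort$treat, infection = cohort$y)
  dat$X4[c(3, 9)] <- NA  # incomplete rows must be dropped and counted
  res <- applied_analysis(dat, treatment = "device", outcome = "infection",
                          covariates = paste0("X", 1:6), order_seed = 8)
  expect_equal(res$n_dropped, 2L)
  expect_equal(nrow(res$balance), 10L)
  expect_equal(nrow(res$estimates), 10L)
  # all no-replacement rows report PRC exactly 0
  expect_true(all(res$balance$prc[!res$balance$replacement] == 0))
  expect_true(all(res$balance$prc[res$balance$replacement] >= 0, na.rm = TRUE))
  # AI intervals only with replacement
  expect_true(all(is.na(res$estimates$se_ai[!res$estimates$replacement])))
  expect_true(all(res$estimates$ci_standard_lo <= res$estimates$att,
                  na.rm = TRUE))
  expect_equal(nrow(res$ps_distribution), nrow(dat) - 2L)
  expect_setequal(unique(res$ps_distribution$group), c("treated", "control"))

  expect_error(applied_analysis(dat, "X4", "infection", c("X1", "X2")),
               "binary")
  expect_error(applied_analysis(dat, "device", "infection", c("nope")),
               "not found")
})

test_that("a cohort with identical groups is reported as balanced", {
  set.seed(2)
  X <- matrix(rnorm(400 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  dat <- data.frame(X, tr = rep(c(0, 1), 200), yy = rbinom(400, 1, 0.3))
  res <- applied_analysis(dat, "tr", "yy", c("a", "b", "c"), order_seed = 1)
  expect_true(all(res$balance$asmd < 0.15, na.rm = TRUE))
})
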