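test_that("diagnostic_stats reproduces a published follow-up 2x2 block", {
  # 12 of 53 successes and 1 of 36 failures positive at the k=2
  # threshold of the six-month rule
  st <- diagnostic_stats(two_by_two(tp = 12, fp = 1, fn = 41, tn = 35))
  expect_equal(round(100 * st$se, 2), 22.64)
  expect_equal(round(100 * st$sp, 2), 97.22)
  expect_equal(round(st$lr_pos, 2), 8.15)
  expect_equal(round(st$lr_neg, 2), 0.80)
  expect_equal(round(100 * st$pv_pos, 1), 92.3)
  expect_equal(round(100 * st$se_ci, 2), c(11.37, 33.91))
  expect_equal(round(100 * st$sp_ci, 2), c(91.85, 100))
  expect_false(st$degenerate)
})

test_that("sensitivity at k=2 for the end-of-program rule is 43/54", {
  st <- diagnostic_stats(two_by_two(tp = 43, fp = 15, fn = 11, tn = 30))
  expect_equal(round(100 * st$se, 1), 79.6)
  expect_equal(round(100 * st$se_ci, 1), c(68.9, 90.4))
})

test_that("degenerate tables are flagged, not silently corrected", {
  st <- diagnostic_stats(two_by_two(tp = 20, fp = 0, fn = 0, tn = 15))
  expect_equal(st$se, 1)
  expect_equal(st$sp, 1)
  expect_true(is.na(st$lr_pos))
  expect_true(st$degenerate)

  # all-negative test: PV+ undefined
  st2 <- diagnostic_stats(two_by_two(tp = 0, fp = 0, fn = 10, tn = 10))
  expect_true(is.na(st2$pv_pos))
})

test_that("lr_from_rates matches its printed examples", {
  expect_equal(round(lr_from_rates(19 / 54, 43 / 45), 2), 7.92)
  expect_lt(abs(lr_from_rates(19 / 54, 43 / 45) - 7.91), 0.02)
  expect_equal(lr_from_rates(0.5, 0.5), 1)
  expect_equal(round(lr_from_rates(0.2264, 0.9722), 2), 8.14)
  expect_error(lr_from_rates(0.5, 1), "undefined")
})

test_that("count_positive_tests evaluates a rule per patient", {
  x <- tiny_cohort()
  rule <- cpr_rule(data.frame(
    name = c("ppt_reach", "abe_mvt", "beighton"),
    cut = c(0.75, 0.5, 4.5),
    direction = c("ge_positive", "ge_positive", "le_positive"),
    stringsAsFactors = FALSE
  ))
  # hand count: A (.80>=0.75, mvt 1, bei 2<5) = 3; B = 0; C = 0;
  # D = 3; E = 3; F = 0
  expect_equal(count_positive_tests(x, rule), c(3, 0, 0, 3, 3, 0))

  x$patients$abe_mvt[1] <- NA
  expect_true(is.na(count_positive_tests(x, rule)[1]))

  # all tests positive / none positive bounds
  expect_equal(max(count_positive_tests(tiny_cohort(), rule)),
               nrow(rule$tests))
  expect_equal(min(count_positive_tests(tiny_cohort(), rule)), 0)
})

test_that("rule_performance reproduces published per-threshold statistics", {
  # follow-up cohort per-k tallies: successes 41/12/2 and failures
  # 15/1/0 at k >= 1, 2, 3
  counts <- c(counts_from_cumulative(53, c(41, 12, 2)),
              counts_from_cumulative(36, c(15, 1, 0)))
  labels <- c(rep(1, 53), rep(0, 36))
  perf <- rule_performance(labels, counts, 2, pretest = 53 / 100)
  expect_equal(round(100 * perf$stats$se, 1), 22.6)
  expect_equal(round(100 * perf$stats$sp, 1), 97.2)
  expect_equal(round(perf$stats$lr_pos, 2), 8.15)
  expect_equal(round(100 * perf$stats$pv_pos, 1), 92.3)

  # k = 0: everyone positive
  p0 <- rule_performance(labels, counts, 0)
  expect_equal(p0$stats$se, 1)
  expect_equal(p0$stats$sp, 0)
})

test_that("per-threshold tables are nested and monotone in k", {
  set.seed(61)
  for (r in 1:5) {
    n <- 80
    counts <- sample(0:4, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    prev <- NULL
    for (k in 1:4) {
      perf <- rule_performance(labels, counts, k)
      ct <- perf$table
      # recount oracle
      expect_equal(ct$tp, sum(counts >= k & labels == 1))
      expect_equal(ct$fp, sum(counts >= k & labels == 0))
      if (!is.null(prev)) {
        expect_lte(ct$tp, prev$tp)
        expect_lte(ct$fp, prev$fp)
        expect_lte(perf$stats$se, prev_se + 1e-12)
        expect_gte(perf$stats$sp, prev_sp - 1e-12)
      }
      prev <- ct; prev_se <- perf$stats$se; prev_sp <- perf$stats$sp
    }
  }
})

test_that("zero-cell substitution borrows the donor failure split", {
  counts <- c(counts_from_cumulative(53, c(41, 12, 2)),
              counts_from_cumulative(36, c(15, 1, 0)))
  labels <- c(rep(1, 53), rep(0, 36))
  k1 <- rule_performance(labels, counts, 1, pretest = 0.53)
  k2 <- rule_performance(labels, counts, 2, pretest = 0.53)
  k3 <- rule_performance(labels, counts, 3, pretest = 0.53)
  expect_true(is.na(k3$stats$lr_pos))  # zero failure-positive cell

  # hand substitution: success split kept at k=3 (2/53), failure split
  # borrowed from k=1 (15 positive, 21 negative)
  fixed <- zero_cell_approximation(k3, donor = k1)
  expect_true(fixed$stats$approximated)
  expect_true(is.finite(fixed$stats$lr_pos))
  expect_equal(fixed$table$tp, 2)
  expect_equal(fixed$table$fp, 15)
  expect_equal(fixed$stats$lr_pos, (2 / 53) / (15 / 36), tolerance = 1e-12)

  # a single-failure cell (the published follow-up k=2 row) is also
  # eligible for the substitution
  fixed2 <- zero_cell_approximation(k2, donor = k1)
  expect_true(fixed2$stats$approximated)
  expect_equal(fixed2$table$fp, 15)

  # non-degenerate input passes through untouched
  counts8 <- c(counts_from_cumulative(54, c(54, 43, 10, 1)),
               counts_from_cumulative(45, c(40, 15, 0, 0)))
  labels8 <- c(rep(1, 54), rep(0, 45))
  p2 <- rule_performance(labels8, counts8, 2, 0.49)
  same <- zero_cell_approximation(p2,
                                  donor = rule_performance(labels8,
                                                           counts8, 1,
                                                           0.49))
  expect_false(same$stats$approximated)
  expect_identical(same$table, p2$table)

  # degenerate donor (or a donor not below k) is refused
  expect_error(zero_cell_approximation(k3, donor = k3), "below k")
  expect_error(zero_cell_approximation(k3, donor = k2), "degenerate")
})

test_that("post-test probability follows Bayes' odds form", {
  expect_equal(posttest_probability(0.3, 1)$posttest, 0.3)
  # strictly increasing in the likelihood ratio
  lrs <- c(0.2, 1, 2, 5, 10)
  posts <- vapply(lrs, function(l) posttest_probability(0.4, l)$posttest,
                  numeric(1))
  expect_true(all(diff(posts) > 0))
  expect_error(posttest_probability(0, 2), "strictly between")
  expect_error(posttest_probability(0.5, -1), "positive")

  # Bayes/PV+ identity: post-test at the table's own prevalence equals
  # the positive predictive value, exactly
  set.seed(71)
  for (r in 1:25) {
    tbl <- two_by_two(sample(1:30, 1), sample(1:30, 1),
                      sample(1:30, 1), sample(1:30, 1))
    st <- diagnostic_stats(tbl)
    prev <- (tbl$tp + tbl$fn) / (tbl$tp + tbl$fp + tbl$fn + tbl$tn)
    expect_equal(posttest_probability(prev, st$lr_pos)$posttest,
                 st$pv_pos, tolerance = 1e-12)
  }
})

test_that("LR confidence intervals are log-symmetric and calibrated", {
  st <- diagnostic_stats(two_by_two(25, 8, 14, 40))
  expect_equal(exp(mean(log(st$lr_pos_ci))), st$lr_pos,
               tolerance = 1e-12)
  expect_equal(exp(mean(log(st$lr_neg_ci))), st$lr_neg,
               tolerance = 1e-12)

  # coverage of the log-method interval across simulated tables
  set.seed(81)
  se_true <- 0.6; sp_true <- 0.8; n1 <- 80; n0 <- 80
  lr_true <- se_true / (1 - sp_true)
  covered <- 0; used <- 0
  for (r in 1:2000) {
    tp <- rbinom(1, n1, se_true)
    fp <- rbinom(1, n0, 1 - sp_true)
    if (tp == 0 || fp == 0 || tp == n1 || fp == n0) next
    st <- diagnostic_stats(two_by_two(tp, fp, n1 - tp, n0 - fp))
    used <- used + 1
    covered <- covered + (st$lr_pos_ci[1] <= lr_true &&
                            lr_true <= st$lr_pos_ci[2])
  }
  expect_gt(covered / used, 0.93)
  expect_lt(covered / used, 0.97)
})

test_that("derivation report carries all sections and matches the summary", {
  sim <- simulate_cohort(default_paper_config(seed = 3))
  d <- derive_cpr(sim$cohort, "T8")
  dir <- withr::local_tempdir()
  rep <- build_report(d, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "report.txt")))
  expect_setequal(names(rep),
                  c("time", "n_completers", "class_counts",
                    "pretest_probability", "outcome_summary", "cutpoints",
                    "screening", "models", "rule", "thresholds"))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(parsed$n_completers, d$n_completers)
  # report outcome section equals summarize_outcomes output
  expect_equal(rep$outcome_summary, summarize_outcomes(sim$cohort, "T8"))
})
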