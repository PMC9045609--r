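#' Diagnostic performance statistics for a 2x2 table
#'
#' Sensitivity, specificity, likelihood ratios and predictive values
#' with 95% confidence intervals.  Proportion intervals (Se, Sp, PV+,
#' PV-) use the Wald normal approximation truncated to \[0, 1\];
#' likelihood-ratio intervals use the log method with
#' `SE(ln LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` (mirrored
#' for LR-).  Degenerate cells (no false positives, an empty test
#' margin) leave the affected statistic `NA` and set a flag rather than
#' silently correcting; see [zero_cell_approximation()] for the
#' explicit, illustrative substitution mechanism.
#'
#' @param table a [two_by_two()].
#' @param conf_z normal quantile for the intervals (default 1.96).
#' @return object of class `"diagnostic_stats"`: fractions `se`, `sp`,
#'   `pv_pos`, `pv_neg`, ratios `lr_pos`, `lr_neg`, each with `*_ci`
#'   (length-2 vector), plus `table`, `degenerate` (any undefined
#'   statistic) and `approximated` (set by the substitution mechanism).
#' @export
diagnostic_stats <- function(table, conf_z = 1.96) {
  stopifnot(inherits(table, "two_by_two"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n1 <- tp + fn; n0 <- fp + tn
  if (n1 == 0 || n0 == 0) stop("both outcome columns must be non-empty")

  wald <- function(p, n) {
    half <- conf_z * sqrt(p * (1 - p) / n)
    pmin(pmax(c(p - half, p + half), 0), 1)
  }
  se <- tp / n1
  sp <- tn / n0
  lr_pos <- if (fp > 0) se / (1 - sp) else NA_real_
  lr_neg <- if (tn > 0) (1 - se) / sp else NA_real_
  pv_pos <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  pv_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_

  lr_ci <- function(lr, a, m, b, n) {
    # log-method interval for a ratio (a/m)/(b/n)
    if (is.na(lr) || lr == 0 || a == 0 || b == 0) return(c(NA_real_, NA_real_))
    se_log <- sqrt(1 / a - 1 / m + 1 / b - 1 / n)
    exp(log(lr) + c(-1, 1) * conf_z * se_log)
  }
  structure(
    list(se = se, se_ci = wald(se, n1),
         sp = sp, sp_ci = wald(sp, n0),
         lr_pos = lr_pos, lr_pos_ci = lr_ci(lr_pos, tp, n1, fp, n0),
         lr_neg = lr_neg, lr_neg_ci = lr_ci(lr_neg, fn, n1, tn, n0),
         pv_pos = pv_pos,
         pv_pos_ci = if (is.na(pv_pos)) c(NA_real_, NA_real_) else
           wald(pv_pos, tp + fp),
         pv_neg = pv_neg,
         pv_neg_ci = if (is.na(pv_neg)) c(NA_real_, NA_real_) else
           wald(pv_neg, tn + fn),
         table = table,
         degenerate = is.na(lr_pos) || is.na(lr_neg) ||
           is.na(pv_pos) || is.na(pv_neg),
         approximated = FALSE),
    class = "diagnostic_stats"
  )
}

#' @export
print.diagnostic_stats <- function(x, ...) {
  pct <- function(v, ci) {
    sprintf("%.1f%% (%.1f-%.1f)", 100 * v, 100 * ci[1], 100 * ci[2])
  }
  rat <- function(v, ci) {
    if (is.na(v)) return("undefined")
    sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
  }
  cat("  Se  ", pct(x$se, x$se_ci), "   Sp  ", pct(x$sp, x$sp_ci), "\n",
      "  LR+ ", rat(x$lr_pos, x$lr_pos_ci), "   LR- ",
      rat(x$lr_neg, x$lr_neg_ci), "\n",
      "  PV+ ", if (is.na(x$pv_pos)) "undefined" else pct(x$pv_pos, x$pv_pos_ci),
      "   PV- ", if (is.na(x$pv_neg)) "undefined" else pct(x$pv_neg, x$pv_neg_ci),
      "\n", sep = "")
  if (x$approximated) cat("  [approximated, illustrative only]\n")
  invisible(x)
}

#' Positive likelihood ratio from sensitivity and specificity
#'
#' @param se,sp fractions in \[0, 1\] with `sp < 1`.
#' @return `se / (1 - sp)`.
#' @export
lr_from_rates <- function(se, sp) {
  if (any(sp >= 1)) stop("LR+ undefined when specificity is 1")
  se / (1 - sp)
}

#' Define a count-of-positive-tests rule
#'
#' @param tests data.frame with columns `name`, `cut`, `direction`
#'   (`"ge_positive"`/`"le_positive"`); binary tests use `cut = 0.5`,
#'   `ge_positive` (wrapper [binary_test_spec()]).
#' @return object of class `"cpr_rule"`.
#' @export
cpr_rule <- function(tests) {
  tests <- as.data.frame(tests, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "cut", "direction") %in% names(tests)),
            all(tests$direction %in% c("ge_positive", "le_positive")),
            nrow(tests) >= 1)
  structure(list(tests = tests), class = "cpr_rule")
}

#' @rdname cpr_rule
#' @param name variable name of an already-binary test.
#' @export
binary_test_spec <- function(name) {
  data.frame(name = name, cut = 0.5, direction = "ge_positive",
             stringsAsFactors = FALSE)
}

#' @export
print.cpr_rule <- function(x, ...) {
  cat("<cpr_rule> ", nrow(x$tests), " component tests:\n", sep = "")
  for (i in seq_len(nrow(x$tests))) {
    cat("  ", x$tests$name[i],
        if (x$tests$direction[i] == "ge_positive") " >= " else " <= ",
        signif(x$tests$cut[i], 6), "\n", sep = "")
  }
  invisible(x)
}

#' Count positive rule components per patient
#'
#' @param x a `"cohort"`.
#' @param rule a [cpr_rule()].
#' @return integer vector (0..number of tests); `NA` where any
#'   component value is missing (patient non-evaluable).
#' @export
count_positive_tests <- function(x, rule) {
  stopifnot(inherits(x, "cohort"), inherits(rule, "cpr_rule"))
  cols <- lapply(seq_len(nrow(rule$tests)), function(i) {
    dichotomize(x, rule$tests$name[i], rule$tests$cut[i],
                rule$tests$direction[i])
  })
  m <- do.call(cbind, cols)
  counts <- rowSums(m)
  as.integer(counts)  # NA propagates through rowSums
}

#' Rule performance at a count threshold
#'
#' Declares the rule positive when at least `k` component tests are
#' positive, tabulates against the success/failure labels and attaches
#' diagnostic statistics and the Bayesian post-test probability of
#' success at the supplied pretest probability.
#'
#' @param labels 0/1 outcome (1 = success) for the evaluable patients;
#'   `NA` label or count pairs are dropped.
#' @param counts per-patient positive-test counts, aligned with
#'   `labels`.
#' @param k count threshold (>= 1).
#' @param pretest pretest probability of success (cohort prevalence);
#'   `NA` skips the post-test computation.
#' @return object of class `"threshold_performance"`: `k`, `table`,
#'   `stats` (a `"diagnostic_stats"`), `posttest` (fraction or `NA`).
#' @export
rule_performance <- function(labels, counts, k, pretest = NA_real_) {
  stopifnot(k >= 0)
  keep <- !is.na(labels) & !is.na(counts)
  labels <- labels[keep]; counts <- counts[keep]
  tbl <- table_from_binary(as.integer(counts >= k), labels)
  stats <- diagnostic_stats(tbl)
  post <- if (!is.na(pretest) && !is.na(stats$lr_pos)) {
    posttest_probability(pretest, stats$lr_pos)$posttest
  } else NA_real_
  structure(list(k = k, table = tbl, stats = stats, posttest = post,
                 pretest = pretest),
            class = "threshold_performance")
}

#' @export
print.threshold_performance <- function(x, ...) {
  cat(x$k, "or more positive tests:\n")
  print(x$stats)
  if (!is.na(x$posttest)) {
    cat(sprintf("  post-test probability of success: %.0f%% (pretest %.0f%%)\n",
                100 * x$posttest, 100 * x$pretest))
  }
  invisible(x)
}

#' Illustrative substitution for a degenerate failure cell
#'
#' When the failure-group count at a high threshold is 0 or 1, the
#' specificity-side indicators are incalculable or unstable.  This
#' reproduces the published workaround: substitute the failure-group
#' split observed at a lower (donor) threshold while keeping the
#' success-group split, and flag the result as approximated —
#' illustrative only, never a basis for inference.
#'
#' @param perf a `"threshold_performance"` whose failure-positive cell
#'   is 0 or 1.
#' @param donor a `"threshold_performance"` at a smaller `k` with a
#'   non-degenerate failure split.
#' @return a `"threshold_performance"` with substituted `fp`/`tn`,
#'   `approximated = TRUE`.  Non-degenerate input is returned unchanged.
#' @export
zero_cell_approximation <- function(perf, donor) {
  stopifnot(inherits(perf, "threshold_performance"),
            inherits(donor, "threshold_performance"))
  if (perf$table$fp > 1) return(perf)
  if (donor$k >= perf$k) stop("donor threshold must be below k")
  if (donor$table$fp <= 1) stop("donor table is itself degenerate")
  tbl <- two_by_two(tp = perf$table$tp, fp = donor$table$fp,
                    fn = perf$table$fn, tn = donor$table$tn)
  stats <- diagnostic_stats(tbl)
  stats$approximated <- TRUE
  post <- if (!is.na(perf$pretest) && !is.na(stats$lr_pos)) {
    posttest_probability(perf$pretest, stats$lr_pos)$posttest
  } else NA_real_
  structure(list(k = perf$k, table = tbl, stats = stats, posttest = post,
                 pretest = perf$pretest),
            class = "threshold_performance")
}

#' Bayesian post-test probability (algebraic Fagan nomogram)
#'
#' Converts a pretest probability and a likelihood ratio into the
#' post-test probability via the odds form of Bayes' theorem:
#' `odds_post = odds_pre * LR`.
#'
#' @param pretest pretest probability, strictly between 0 and 1.
#' @param lr likelihood ratio, > 0.
#' @return list with `pretest`, `lr`, `posttest`.
#' @export
posttest_probability <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1)) {
    stop("pretest probability must be strictly between 0 and 1")
  }
  if (any(lr <= 0)) stop("likelihood ratio must be positive")
  odds <- pretest / (1 - pretest) * lr
  list(pretest = pretest, lr = lr, posttest = odds / (1 + odds))
}
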