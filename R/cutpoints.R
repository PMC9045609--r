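#' 2x2 diagnostic table
#'
#' Counts cross-classifying a dichotomous test (rows) against treatment
#' outcome (columns success/failure): `tp` = test-positive successes,
#' `fp` = test-positive failures, `fn` = test-negative successes,
#' `tn` = test-negative failures.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return object of class `"two_by_two"`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be >= 0")
  if (sum(counts) < 1) stop("table is empty")
  structure(as.list(counts), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              outcome = c("success", "failure")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table from a binary test and outcome labels
#'
#' @param test 0/1 test results (1 = positive); `NA` pairs dropped.
#' @param labels 0/1 outcome (1 = success).
#' @return a [two_by_two()].
#' @export
table_from_binary <- function(test, labels) {
  keep <- !is.na(test) & !is.na(labels)
  test <- test[keep]; labels <- labels[keep]
  two_by_two(tp = sum(test == 1 & labels == 1),
             fp = sum(test == 1 & labels == 0),
             fn = sum(test == 0 & labels == 1),
             tn = sum(test == 0 & labels == 0))
}

CUTPOINT_METHODS <- c("ROC", "Md", "YI", "dMinSnSp", "LRmax", "KLfg", "KLgf")

## x*log(y) with the 0*log(0) = 0 convention used in the KL distances.
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

## Candidate cuts: midpoints between consecutive distinct sorted values,
## plus -Inf/+Inf sentinels ("everyone positive" / "nobody positive").
## Method results therefore depend only on the ranks of the data, and
## any threshold between two observed values is representable.
candidate_cuts <- function(values) {
  d <- sort(unique(values))
  if (length(d) < 2) return(c(-Inf, Inf))
  c(-Inf, (d[-1] + d[-length(d)]) / 2, Inf)
}

#' ROC operating points over all candidate cuts
#'
#' One row per candidate cut (midpoints of consecutive distinct values
#' plus infinite sentinels) with the 2x2 counts, sensitivity and
#' specificity under the stated positivity direction.
#'
#' @param values numeric predictor values (`NA` dropped pairwise).
#' @param labels 0/1 outcome (1 = success).
#' @param direction `"ge_positive"` (test positive iff value >= cut) or
#'   `"le_positive"` (value <= cut).
#' @return data.frame with columns `cut`, `tp`, `fp`, `fn`, `tn`, `se`,
#'   `sp`.
#' @export
roc_points <- function(values, labels,
                       direction = c("ge_positive", "le_positive")) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("degenerate input: both outcome classes must be present")
  }
  d <- sort(unique(values))
  cuts <- candidate_cuts(values)
  s_cum <- cumsum(tabulate(match(values[labels == 1], d), length(d)))
  f_cum <- cumsum(tabulate(match(values[labels == 0], d), length(d)))
  if (direction == "ge_positive") {
    tp <- n1 - c(0, s_cum); fp <- n0 - c(0, f_cum)
  } else {
    tp <- c(0, s_cum); fp <- c(0, f_cum)
  }
  if (length(d) < 2) {  # all values identical: sentinels only
    tp <- tp[c(1, length(tp))]; fp <- fp[c(1, length(fp))]
  }
  data.frame(cut = cuts, tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp,
             se = tp / n1, sp = (n0 - fp) / n0)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over (1 - Sp, Se); for points generated by
#' [roc_points()] this equals the Mann-Whitney concordance probability
#' of the underlying values.
#'
#' @param points data.frame with `se` and `sp` columns.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(points) {
  stopifnot(all(c("se", "sp") %in% names(points)), nrow(points) >= 2)
  x <- 1 - points$sp
  y <- points$se
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Select an optimal cut-point by one of six criteria
#'
#' Dichotomizes a continuous/ordinal predictor against the
#' success/failure outcome using the requested criterion:
#' \describe{
#'   \item{ROC}{cut closest to the perfect corner, minimizing
#'     `(1-Se)^2 + (1-Sp)^2`.}
#'   \item{Md}{median split of the pooled values.}
#'   \item{YI}{maximum Youden index `J = Se + Sp - 1`.}
#'   \item{dMinSnSp}{minimum `|Se - Sp|`, balancing the two error
#'     rates.}
#'   \item{LRmax}{maximum positive likelihood ratio `Se/(1-Sp)` over
#'     cuts with at least one false positive.}
#'   \item{KLfg, KLgf}{maximum Kullback-Leibler distance between the
#'     Bernoulli distributions of a positive result in the success (f)
#'     and failure (g) groups: `D(f||g) = Se log(Se/(1-Sp)) +
#'     (1-Se) log((1-Se)/Sp)` and its mirror; cuts producing an empty
#'     2x2 cell are excluded.}
#' }
#' Ties are broken toward the cut with the larger Youden index, then
#' the smaller cut value.  When LRmax/KL admit no cut (e.g. perfect
#' separation leaves an empty cell everywhere) the YI optimum is
#' returned with `fallback = TRUE`.
#'
#' @inheritParams roc_points
#' @param method one of `"ROC"`, `"Md"`, `"YI"`, `"dMinSnSp"`,
#'   `"LRmax"`, `"KLfg"`, `"KLgf"`.
#' @param variable optional variable name carried into the result.
#' @return object of class `"cutpoint_result"`: a list with `variable`,
#'   `method`, `cut`, `direction`, `table` ([two_by_two()]), `se`, `sp`,
#'   `youden_j`, `lr_pos`, `kl_fg`, `kl_gf`, `fallback`.
#' @export
select_cutpoint <- function(values, labels, method = "YI",
                            direction = c("ge_positive", "le_positive"),
                            variable = NULL) {
  method <- match.arg(method, CUTPOINT_METHODS)
  direction <- match.arg(direction)
  pts <- roc_points(values, labels, direction)

  if (method == "Md") {
    keep <- !is.na(values) & !is.na(labels)
    cut <- stats::median(values[keep])
    pos <- if (direction == "ge_positive") values[keep] >= cut else values[keep] <= cut
    tbl <- table_from_binary(as.integer(pos), labels[keep])
    return(cutpoint_result(variable, method, cut, direction, tbl,
                           fallback = FALSE))
  }

  j <- pts$se + pts$sp - 1
  objective <- switch(
    method,
    ROC = -((1 - pts$se)^2 + (1 - pts$sp)^2),
    YI = j,
    dMinSnSp = -abs(pts$se - pts$sp),
    LRmax = ifelse(pts$fp >= 1, pts$se / (1 - pts$sp), -Inf),
    KLfg = ifelse(pts$tp > 0 & pts$fp > 0 & pts$fn > 0 & pts$tn > 0,
                  xlogy(pts$se, pts$se / (1 - pts$sp)) +
                    xlogy(1 - pts$se, (1 - pts$se) / pts$sp), -Inf),
    KLgf = ifelse(pts$tp > 0 & pts$fp > 0 & pts$fn > 0 & pts$tn > 0,
                  xlogy(1 - pts$sp, (1 - pts$sp) / pts$se) +
                    xlogy(pts$sp, pts$sp / (1 - pts$se)), -Inf)
  )

  fallback <- FALSE
  if (all(!is.finite(objective))) {
    # no admissible cut for LRmax/KL: fall back to the Youden optimum
    objective <- j
    fallback <- TRUE
  }
  best <- max(objective)
  cand <- which(objective >= best - 1e-12)
  cand <- cand[order(-j[cand], pts$cut[cand])]
  i <- cand[1]
  tbl <- two_by_two(pts$tp[i], pts$fp[i], pts$fn[i], pts$tn[i])
  cutpoint_result(variable, method, pts$cut[i], direction, tbl, fallback)
}

cutpoint_result <- function(variable, method, cut, direction, tbl, fallback) {
  n1 <- tbl$tp + tbl$fn; n0 <- tbl$fp + tbl$tn
  se <- tbl$tp / n1; sp <- tbl$tn / n0
  lr_pos <- if (sp < 1) se / (1 - sp) else Inf
  all_pos <- tbl$tp > 0 && tbl$fp > 0 && tbl$fn > 0 && tbl$tn > 0
  kl_fg <- if (all_pos) {
    xlogy(se, se / (1 - sp)) + xlogy(1 - se, (1 - se) / sp)
  } else NA_real_
  kl_gf <- if (all_pos) {
    xlogy(1 - sp, (1 - sp) / se) + xlogy(sp, sp / (1 - se))
  } else NA_real_
  structure(
    list(variable = variable, method = method, cut = cut,
         direction = direction, table = tbl, se = se, sp = sp,
         youden_j = se + sp - 1, lr_pos = lr_pos,
         kl_fg = kl_fg, kl_gf = kl_gf, fallback = fallback),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint> ", if (!is.null(x$variable)) paste0(x$variable, " "),
      x$method, ": ",
      if (x$direction == "ge_positive") ">= " else "<= ",
      signif(x$cut, 6),
      sprintf("  (Se %.3f, Sp %.3f, J %.3f, LR+ %.2f%s)\n",
              x$se, x$sp, x$youden_j, x$lr_pos,
              if (x$fallback) ", YI fallback" else ""),
      sep = "")
  invisible(x)
}

#' Apply a (cut, direction) rule to a cohort variable
#'
#' Positive (1) iff `value >= cut` under `ge_positive` or `value <= cut`
#' under `le_positive`; strict printed rules like "Beighton < 5" are
#' expressed as `le_positive` with a cut between observed values (4.5
#' on an integer 0-9 score).  Missing values propagate.
#'
#' @param x a `"cohort"`.
#' @param variable predictor column name.
#' @param cut threshold in variable units.
#' @param direction `"ge_positive"` or `"le_positive"`.
#' @return integer 0/1/NA vector, one element per patient.
#' @export
dichotomize <- function(x, variable, cut,
                        direction = c("ge_positive", "le_positive")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "cohort"))
  if (!variable %in% names(x$patients)) {
    stop("unknown variable: ", variable)
  }
  v <- x$patients[[variable]]
  as.integer(if (direction == "ge_positive") v >= cut else v <= cut)
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) by default: the
#' screening criterion is deliberately liberal and the correction only
#' makes it more conservative.  A table with a zero margin is flagged
#' degenerate and returns `chi2 = 0, p = 1`.
#'
#' @param table a [two_by_two()].
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2`, `p`, `degenerate`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  m <- matrix(c(table$tp, table$fn, table$fp, table$tn), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       degenerate = FALSE)
}

## LR+ of a 2x2, with the Haldane-Anscombe 0.5-cell correction when a
## zero false-positive (or zero success) cell would make it undefined.
lr_pos_screen <- function(tbl) {
  corrected <- tbl$fp == 0 || tbl$tp + tbl$fn == 0 || tbl$fp + tbl$tn == 0
  if (corrected) {
    tp <- tbl$tp + 0.5; fp <- tbl$fp + 0.5
    fn <- tbl$fn + 0.5; tn <- tbl$tn + 0.5
  } else {
    tp <- tbl$tp; fp <- tbl$fp; fn <- tbl$fn; tn <- tbl$tn
  }
  list(lr = (tp / (tp + fn)) / (fp / (fp + tn)), corrected = corrected)
}

#' Univariate screening of dichotomous tests
#'
#' Compares each candidate test between the success and failure groups
#' (the improvement class is excluded upstream).  A test is accepted for
#' multivariate modeling when the uncorrected chi-square gives
#' `p < 0.20` (liberal criterion) or, failing that, when its positive
#' likelihood ratio is at least 2.
#'
#' @param tests data.frame (or matrix) of 0/1 test columns, rows aligned
#'   with `labels`.
#' @param labels 0/1 outcome (1 = success), success/failure rows only.
#' @param p_threshold chi-square acceptance threshold (default 0.20).
#' @param lr_threshold LR+ acceptance threshold (default 2).
#' @return data.frame with one row per test: `variable`, `chi2`, `p`,
#'   `lr_pos`, `lr_corrected` (Haldane 0.5 correction applied),
#'   `accepted`, `reason` (`"p_lt_020"`, `"lr_ge_2"` or `"rejected"`).
#' @export
screen_variables <- function(tests, labels, p_threshold = 0.20,
                             lr_threshold = 2) {
  tests <- as.data.frame(tests)
  out <- lapply(names(tests), function(nm) {
    tbl <- table_from_binary(tests[[nm]], labels)
    cs <- chi_square_2x2(tbl)
    lr <- lr_pos_screen(tbl)
    reason <- if (cs$p < p_threshold) {
      "p_lt_020"
    } else if (lr$lr >= lr_threshold) {
      "lr_ge_2"
    } else "rejected"
    data.frame(variable = nm, chi2 = cs$chi2, p = cs$p,
               lr_pos = lr$lr, lr_corrected = lr$corrected,
               accepted = reason != "rejected", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
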