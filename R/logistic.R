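#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression of a binary outcome
#' (1 = success) on a design of numeric/binary predictors, via
#' iteratively reweighted least squares.  Quasi-separation (diverging
#' coefficients, fitted probabilities at 0/1) is detected and flagged
#' rather than silently penalized; exactly collinear designs raise an
#' error naming the offending columns.
#'
#' @param design data.frame (possibly zero-column for an intercept-only
#'   model) of numeric predictors, rows aligned with `outcome`.
#' @param outcome 0/1 vector with both classes present.
#' @return object of class `"logistic_fit"`: `terms` (data.frame with
#'   `name`, `b`, `se`, `wald_p`, `ci_lo`, `ci_hi`, `odds_ratio`; Wald
#'   95% intervals `b +/- 1.96 se`), `intercept`, `minus2ll`,
#'   `null_minus2ll`, `n`, `converged`, `separation`, `fitted`, plus the
#'   data needed for refits (`design`, `outcome`).
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  outcome <- as.numeric(outcome)
  stopifnot(nrow(design) == 0 || nrow(design) == length(outcome))
  if (anyNA(outcome) || (ncol(design) && anyNA(design))) {
    stop("missing values in model data; use complete_case_subset() first")
  }
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both classes")
  }
  if (length(outcome) <= ncol(design) + 1) {
    stop("more terms than observations")
  }

  df <- if (ncol(design)) cbind(.y = outcome, design) else
    data.frame(.y = outcome)
  fml <- if (ncol(design)) .y ~ . else .y ~ 1
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(sub("^`|`$", "", names(cf)[is.na(cf)]), collapse = ", "))
  }
  separation <- sep_warned || any(abs(cf[-1]) > 15)
  sm <- summary(fit)$coefficients
  term_names <- names(design)
  terms <- if (length(term_names)) {
    b <- cf[-1]; se <- sm[-1, 2]; p <- sm[-1, 4]
    data.frame(name = term_names, b = unname(b), se = unname(se),
               wald_p = unname(p),
               ci_lo = unname(b - 1.96 * se), ci_hi = unname(b + 1.96 * se),
               odds_ratio = unname(exp(b)), stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), b = numeric(), se = numeric(),
               wald_p = numeric(), ci_lo = numeric(), ci_hi = numeric(),
               odds_ratio = numeric(), stringsAsFactors = FALSE)
  }
  structure(
    list(terms = terms, intercept = unname(cf[1]),
         minus2ll = stats::deviance(fit),
         null_minus2ll = fit$null.deviance,
         n = length(outcome),
         converged = fit$converged && !separation,
         separation = separation,
         fitted = unname(stats::fitted(fit)),
         design = design, outcome = outcome),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n = ", x$n, ", -2LL = ", round(x$minus2ll, 2),
      if (!x$converged) "  [NOT CONVERGED]",
      if (x$separation) "  [quasi-separation]", "\n", sep = "")
  cat("  intercept: ", round(x$intercept, 4), "\n", sep = "")
  if (nrow(x$terms)) {
    t <- x$terms
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %-24s B = %6.3f (%.2f-%.2f)  OR = %6.2f  p = %.4f\n",
                  t$name[i], t$b[i], t$ci_lo[i], t$ci_hi[i],
                  t$odds_ratio[i], t$wald_p[i]))
    }
  }
  invisible(x)
}

#' Nagelkerke's pseudo R-squared
#'
#' `R2 = (1 - exp((D - D0)/n)) / (1 - exp(-D0/n))` where `D` and `D0`
#' are the model and null deviances (-2 log-likelihoods); bounded in
#' \[0, 1).
#'
#' @param fit a `"logistic_fit"`.
#' @param null_minus2ll null-model deviance on the same rows (defaults
#'   to the one stored in `fit`).
#' @return fraction in \[0, 1).
#' @export
nagelkerke_r2 <- function(fit, null_minus2ll = fit$null_minus2ll) {
  n <- fit$n
  (1 - exp((fit$minus2ll - null_minus2ll) / n)) /
    (1 - exp(-null_minus2ll / n))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into bins of predicted risk (deciles by default,
#' identical predictions kept together), compares observed and expected
#' events per bin with a chi-square on `groups - 2` degrees of freedom.
#' Bins with zero expected count in either cell are merged with their
#' neighbor and the degrees of freedom adjusted.  With fewer than three
#' distinct predicted values (common when the model holds only a few
#' binary tests) the test is skipped and flagged.
#'
#' @param fit a `"logistic_fit"`.
#' @param groups number of risk bins (default 10).
#' @return list with `chi2`, `p`, `df`, `groups_used`, `skipped`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  p <- fit$fitted
  y <- fit$outcome
  if (length(unique(round(p, 12))) < 3) {
    return(list(chi2 = NA_real_, p = NA_real_, df = NA_integer_,
                groups_used = 0L, skipped = TRUE))
  }
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                   type = 7))
  bin <- cut(p, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(y, bin, sum)
  exp1 <- tapply(p, bin, sum)
  nbin <- tapply(y, bin, length)
  keep <- !is.na(nbin)
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; nbin <- nbin[keep]
  # merge bins whose expected successes or failures are ~0
  repeat {
    bad <- which(exp1 < 1e-9 | (nbin - exp1) < 1e-9)
    if (!length(bad) || length(obs1) <= 1) break
    i <- bad[1]
    j <- if (i == 1) 2 else i - 1
    obs1[j] <- obs1[j] + obs1[i]; exp1[j] <- exp1[j] + exp1[i]
    nbin[j] <- nbin[j] + nbin[i]
    obs1 <- obs1[-i]; exp1 <- exp1[-i]; nbin <- nbin[-i]
  }
  g <- length(obs1)
  df <- g - 2
  if (df < 1) {
    return(list(chi2 = NA_real_, p = NA_real_, df = df,
                groups_used = g, skipped = TRUE))
  }
  chi2 <- sum((obs1 - exp1)^2 / exp1 +
                ((nbin - obs1) - (nbin - exp1))^2 / (nbin - exp1))
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, groups_used = g, skipped = FALSE)
}

#' Adequacy statistic: per-predictor explanatory share
#'
#' For each term of a fitted model, refits the single-predictor model
#' on the same rows and reports the share of the full model's
#' log-likelihood improvement that the predictor achieves alone:
#' `(D0 - D_single) / (D0 - D_full)` in -2LL units.  Rank 1 is the most
#' influential predictor; equal values share a rank.
#'
#' @param fit a `"logistic_fit"` with at least one term.
#' @return data.frame with `name`, `adequacy`, `rank`.
#' @export
adequacy_ranks <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"), nrow(fit$terms) >= 1)
  full_gain <- fit$null_minus2ll - fit$minus2ll
  adequacy <- vapply(fit$terms$name, function(nm) {
    single <- fit_logistic(fit$design[, nm, drop = FALSE], fit$outcome)
    (fit$null_minus2ll - single$minus2ll) / full_gain
  }, numeric(1))
  rk <- rank(-round(adequacy, 8), ties.method = "min")
  data.frame(name = fit$terms$name, adequacy = unname(adequacy),
             rank = as.integer(rk), stringsAsFactors = FALSE)
}

#' Backward stepwise elimination by Wald tests
#'
#' Starting from all pooled terms, repeatedly removes the removable
#' term with the largest Wald p while that p is at or above
#' `alpha_retain`, so the final model contains only statistically
#' significant terms (plus any forced covariates).  If quasi-separation
#' appears, elimination halts and the fit is flagged.  Ties in p are
#' broken alphabetically so results do not depend on column order.
#'
#' @param pool character vector of candidate column names in `data`.
#' @param forced_stay names never removed regardless of p.
#' @param data data.frame holding all pooled columns.
#' @param outcome 0/1 vector aligned with `data`.
#' @param alpha_retain retention threshold on the Wald p (default 0.05).
#' @return list with `fit` (`"logistic_fit"`), `removal_trace`
#'   (data.frame `name`, `wald_p`), `empty_model`, `separation_halt`.
#' @export
backward_eliminate <- function(pool, forced_stay = character(), data,
                               outcome, alpha_retain = 0.05) {
  stopifnot(length(pool) >= 1, all(pool %in% names(data)),
            all(forced_stay %in% c(pool, names(data))))
  current <- union(pool, forced_stay)
  trace <- data.frame(name = character(), wald_p = numeric(),
                      stringsAsFactors = FALSE)
  separation_halt <- FALSE
  repeat {
    fit <- fit_logistic(data[, current, drop = FALSE], outcome)
    if (fit$separation) {
      separation_halt <- TRUE
      break
    }
    removable <- setdiff(fit$terms$name, forced_stay)
    if (!length(removable)) break
    p <- fit$terms$wald_p[match(removable, fit$terms$name)]
    o <- order(-p, removable)
    worst <- removable[o[1]]; worst_p <- p[o[1]]
    if (worst_p < alpha_retain) break
    trace <- rbind(trace, data.frame(name = worst, wald_p = worst_p,
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
    if (!length(current)) {
      fit <- fit_logistic(data[, character(0), drop = FALSE], outcome)
      break
    }
  }
  list(fit = fit, removal_trace = trace,
       empty_model = nrow(fit$terms) == 0,
       separation_halt = separation_halt)
}

#' Three-step hierarchical model building
#'
#' Builds candidate models in the tiered order of the variable classes:
#' step 1 considers the screened class-A (treatment-specific) tests plus
#' the adjustment covariates (age, sex, BMI; candidates, not forced,
#' unless `force_confounders`); step 2 adds screened class-B
#' (adherence-related) tests to the step-1 survivors and re-eliminates;
#' step 3 likewise adds class-C (treatment-nonspecific) tests.  Each
#' step is reduced by [backward_eliminate()] and summarized.
#'
#' @param screened data.frame from [screen_variables()].
#' @param variables the cohort's variable dictionary.
#' @param data data.frame holding dichotomized test columns and the
#'   covariate columns.
#' @param outcome 0/1 vector aligned with `data`.
#' @param covariates adjustment covariate column names present in
#'   `data` (default `c("age", "sex", "bmi")`; set `character()` to
#'   omit).
#' @param force_confounders keep the covariates in every model.
#' @param alpha_retain retention threshold for elimination.
#' @return list of three `"hierarchical_step"` objects (steps
#'   `"A_only"`, `"A_plus_B"`, `"A_plus_B_plus_C"`), each with
#'   `candidate_pool`, `result` (from [backward_eliminate()]) and
#'   `summary` (Nagelkerke R2, Hosmer-Lemeshow, AUC, adequacy ranks).
#' @export
hierarchical_modeling <- function(screened, variables, data, outcome,
                                  covariates = c("age", "sex", "bmi"),
                                  force_confounders = FALSE,
                                  alpha_retain = 0.05) {
  accepted <- screened$variable[screened$accepted]
  cls <- variables$class[match(accepted, variables$name)]
  by_class <- split(accepted, factor(cls, levels = VARIABLE_CLASSES))
  forced <- if (force_confounders) covariates else character()

  run_step <- function(step, pool) {
    pool <- intersect(union(pool, forced), names(data))
    if (!length(pool)) {
      fit <- fit_logistic(data[, character(0), drop = FALSE], outcome)
      res <- list(fit = fit,
                  removal_trace = data.frame(name = character(),
                                             wald_p = numeric()),
                  empty_model = TRUE, separation_halt = FALSE)
    } else {
      res <- backward_eliminate(pool, forced, data, outcome, alpha_retain)
    }
    structure(list(step = step, candidate_pool = pool, result = res,
                   summary = summarize_fit(res$fit)),
              class = "hierarchical_step")
  }

  s1 <- run_step("A_only", union(by_class$A, intersect(covariates, names(data))))
  surv1 <- s1$result$fit$terms$name
  s2 <- run_step("A_plus_B", union(surv1, by_class$B))
  surv2 <- s2$result$fit$terms$name
  s3 <- run_step("A_plus_B_plus_C", union(surv2, by_class$C))
  list(A_only = s1, A_plus_B = s2, A_plus_B_plus_C = s3)
}

#' Model-level performance summary
#'
#' @param fit a `"logistic_fit"`.
#' @return list with `nagelkerke_r2`, `hl` (Hosmer-Lemeshow list),
#'   `auc` (of the fitted probabilities) and `adequacy` (data.frame or
#'   `NULL` for an intercept-only model).
#' @export
summarize_fit <- function(fit) {
  a <- if (nrow(fit$terms) && length(unique(fit$fitted)) > 1) {
    auc(roc_points(fit$fitted, fit$outcome))
  } else 0.5
  list(
    nagelkerke_r2 = nagelkerke_r2(fit),
    hl = hosmer_lemeshow(fit),
    auc = a,
    adequacy = if (nrow(fit$terms)) adequacy_ranks(fit) else NULL
  )
}

#' @export
print.hierarchical_step <- function(x, ...) {
  cat("== step ", x$step, " (pool: ",
      paste(x$candidate_pool, collapse = ", "), ")\n", sep = "")
  print(x$result$fit)
  s <- x$summary
  cat(sprintf("  Nagelkerke R2 = %.1f%%  AUC = %.2f", 100 * s$nagelkerke_r2,
              s$auc))
  if (!s$hl$skipped) {
    cat(sprintf("  HL chi2 = %.2f (p = %.2f)", s$hl$chi2, s$hl$p))
  }
  cat("\n")
  invisible(x)
}
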