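## Orchestration of the full derivation pipeline: outcome
## classification -> cut-point selection -> univariate screening ->
## hierarchical logistic modeling -> count-of-positive-tests rule.

## Direction actually applied to a variable: from the dictionary hint,
## or chosen empirically when the hint is "unknown" (the direction whose
## optimum gives LR+ > 1, so a positive test predicts success).
resolve_direction <- function(hint, values, labels, method) {
  if (hint == "high_is_positive") return("ge_positive")
  if (hint == "low_is_positive") return("le_positive")
  cp_ge <- select_cutpoint(values, labels, method, "ge_positive")
  cp_le <- select_cutpoint(values, labels, method, "le_positive")
  ge_ok <- is.finite(cp_ge$lr_pos) && cp_ge$lr_pos > 1
  le_ok <- is.finite(cp_le$lr_pos) && cp_le$lr_pos > 1
  if (ge_ok && !le_ok) return("ge_positive")
  if (le_ok && !ge_ok) return("le_positive")
  if (cp_ge$youden_j >= cp_le$youden_j) "ge_positive" else "le_positive"
}

#' Cut-point audit table
#'
#' Runs every cut-point criterion on every continuous/ordinal candidate
#' variable (success vs failure rows at `time`) and tabulates the
#' results, so the final per-variable choice of criterion can be made
#' by a human with all six methods side by side.
#'
#' @param x a `"cohort"`.
#' @param time `"T8"` or `"T34"`.
#' @param variables subset of variable names (default: all
#'   continuous/ordinal candidates).
#' @return data.frame with one row per variable x method: `variable`,
#'   `method`, `cut`, `direction`, `se`, `sp`, `lr_pos`, `youden_j`,
#'   `kl_fg`, `kl_gf`, `fallback`.
#' @export
cutpoint_audit <- function(x, time = "T8", variables = NULL) {
  sf <- success_failure_frame(x, time)
  dict <- x$variables
  cand <- dict$name[dict$scale %in% c("continuous", "ordinal")]
  if (!is.null(variables)) cand <- intersect(cand, variables)
  rows <- list()
  for (nm in cand) {
    v <- sf$data[[nm]]
    ok <- !is.na(v) & !is.na(sf$labels)
    if (length(unique(sf$labels[ok])) < 2) next
    hint <- dict$direction_hint[dict$name == nm]
    for (m in CUTPOINT_METHODS) {
      dir <- resolve_direction(hint, v[ok], sf$labels[ok], m)
      cp <- select_cutpoint(v[ok], sf$labels[ok], m, dir, variable = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, method = m, cut = cp$cut, direction = cp$direction,
        se = cp$se, sp = cp$sp, lr_pos = cp$lr_pos,
        youden_j = cp$youden_j, kl_fg = cp$kl_fg, kl_gf = cp$kl_gf,
        fallback = cp$fallback, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Completers at `time` with observed outcomes, their response classes,
## the success/failure row subset and the cohort prevalence (pretest
## probability) under both conventions.
success_failure_frame <- function(x, time) {
  cc <- complete_case_subset(completers(x, time), character(), time,
                             quiet = TRUE)
  p <- cc$patients
  ocol <- paste0("odi_", time)
  cls <- classify_outcome(compute_change(p$odi_T0, p[[ocol]]))
  sf_idx <- which(cls %in% c("success", "failure"))
  list(
    cohort = cc,
    classes = cls,
    prevalence_cohort = mean(cls == "success"),
    prevalence_sf = mean(cls[sf_idx] == "success"),
    data = p[sf_idx, , drop = FALSE],
    labels = as.integer(cls[sf_idx] == "success")
  )
}

#' Derive a clinical prediction rule from a cohort
#'
#' End-to-end derivation for one assessment horizon: classify treatment
#' response from ODI change, dichotomize continuous/ordinal candidate
#' predictors with the chosen cut-point criterion (success vs failure
#' rows only), screen all dichotomous tests (chi-square p < 0.20 or
#' LR+ >= 2), run the three-step hierarchical backward-stepwise
#' logistic modeling, and convert the retained tests of the chosen step
#' into a count-of-positive-tests rule evaluated at every threshold k.
#'
#' @param x a `"cohort"`.
#' @param time `"T8"` (end of program) or `"T34"` (six-month
#'   follow-up).
#' @param cutpoint_method criterion for dichotomization (default
#'   `"YI"`, the Youden index); see [select_cutpoint()].
#' @param alpha_retain Wald retention threshold in the backward steps.
#' @param covariates adjustment covariates offered to step 1 (default
#'   age, sex, BMI; candidates, not forced).
#' @param force_confounders keep the covariates in every model.
#' @param rule_from which hierarchical step supplies the rule's tests
#'   (default `"A_only"`: the treatment-specific model).
#' @param pretest convention for the pretest probability fed to the
#'   post-test computation: `"cohort"` = successes over all completers
#'   including the improvement class (the published convention), or
#'   `"success_failure"` = successes over the 2x2 rows only.
#' @return object of class `"cpr_derivation"`: `time`, `n_completers`,
#'   `class_counts`, `prevalence`, `outcome_summary`, `cutpoints`
#'   (chosen per-variable results), `screen` (from
#'   [screen_variables()]), `steps` (from [hierarchical_modeling()]),
#'   `rule` (a [cpr_rule()] or `NULL` if no test survived),
#'   `thresholds` (list of [rule_performance()] per k), `model_n`.
#' @export
derive_cpr <- function(x, time = "T8", cutpoint_method = "YI",
                       alpha_retain = 0.05,
                       covariates = c("age", "sex", "bmi"),
                       force_confounders = FALSE,
                       rule_from = c("A_only", "A_plus_B",
                                     "A_plus_B_plus_C"),
                       pretest = c("cohort", "success_failure")) {
  stopifnot(inherits(x, "cohort"))
  time <- match.arg(time, c("T8", "T34"))
  rule_from <- match.arg(rule_from)
  pretest <- match.arg(pretest)

  sf <- success_failure_frame(x, time)
  dict <- x$variables
  labels <- sf$labels

  ## dichotomize every candidate; binary variables pass through
  cutpoints <- list()
  tests <- data.frame(row.names = seq_len(nrow(sf$data)))
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (!nm %in% names(sf$data)) next
    v <- sf$data[[nm]]
    ok <- !is.na(v)
    if (dict$scale[i] == "binary") {
      dir <- if (dict$direction_hint[i] == "low_is_positive")
        "le_positive" else "ge_positive"
      cut <- 0.5
    } else {
      if (length(unique(labels[ok])) < 2 || length(unique(v[ok])) < 2) next
      dir <- resolve_direction(dict$direction_hint[i], v[ok], labels[ok],
                               cutpoint_method)
      cp <- select_cutpoint(v[ok], labels[ok], cutpoint_method, dir,
                            variable = nm)
      cutpoints[[nm]] <- cp
      cut <- cp$cut
    }
    tests[[nm]] <- as.integer(if (dir == "ge_positive") v >= cut else
      v <= cut)
    attr(tests[[nm]], "cut") <- cut
    attr(tests[[nm]], "direction") <- dir
  }

  screen <- screen_variables(tests, labels)

  ## modeling frame: complete success/failure rows for the accepted
  ## tests and the covariates
  accepted <- screen$variable[screen$accepted]
  covs <- intersect(covariates, c("age", "sex", "bmi"))
  model_data <- tests[, accepted, drop = FALSE]
  for (cv in covs) {
    model_data[[cv]] <- if (cv == "sex") {
      as.integer(sf$data$sex == "F")
    } else {
      sf$data[[cv]]
    }
  }
  complete <- stats::complete.cases(model_data) & !is.na(labels)
  model_data <- model_data[complete, , drop = FALSE]
  model_labels <- labels[complete]

  steps <- hierarchical_modeling(screen, dict, model_data, model_labels,
                                 covariates = covs,
                                 force_confounders = force_confounders,
                                 alpha_retain = alpha_retain)

  ## rule = non-covariate terms of the chosen step's final model
  final_terms <- setdiff(steps[[rule_from]]$result$fit$terms$name, covs)
  prevalence <- if (pretest == "cohort") sf$prevalence_cohort else
    sf$prevalence_sf
  rule <- NULL
  thresholds <- list()
  if (length(final_terms)) {
    rule <- cpr_rule(data.frame(
      name = final_terms,
      cut = vapply(final_terms, function(nm) attr(tests[[nm]], "cut"),
                   numeric(1)),
      direction = vapply(final_terms,
                         function(nm) attr(tests[[nm]], "direction"),
                         character(1)),
      stringsAsFactors = FALSE))
    counts <- rowSums(tests[, final_terms, drop = FALSE])
    thresholds <- lapply(seq_along(final_terms), function(k) {
      rule_performance(labels, counts, k, prevalence)
    })
    names(thresholds) <- paste0("k", seq_along(final_terms))
  }

  structure(
    list(time = time, n_completers = nrow(sf$cohort$patients),
         class_counts = table(factor(sf$classes,
                                     levels = c("success", "improvement",
                                                "failure"))),
         prevalence = prevalence,
         outcome_summary = summarize_outcomes(x, time),
         cutpoints = cutpoints, screen = screen, steps = steps,
         rule = rule, thresholds = thresholds,
         model_n = length(model_labels)),
    class = "cpr_derivation"
  )
}

#' @export
print.cpr_derivation <- function(x, ...) {
  cat("<cpr_derivation> at ", x$time, ": ", x$n_completers,
      " completers (success/improvement/failure = ",
      paste(x$class_counts, collapse = "/"), ")\n", sep = "")
  cat("  pretest probability of success: ",
      sprintf("%.0f%%", 100 * x$prevalence), "\n", sep = "")
  cat("  screened in: ",
      paste(x$screen$variable[x$screen$accepted], collapse = ", "),
      "\n", sep = "")
  if (is.null(x$rule)) {
    cat("  no test survived the final model; no rule derived\n")
  } else {
    print(x$rule)
    for (tp in x$thresholds) {
      cat(sprintf("  k >= %d: Se %.1f%%, Sp %.1f%%, LR+ %s, post-test %s\n",
                  tp$k, 100 * tp$stats$se, 100 * tp$stats$sp,
                  if (is.na(tp$stats$lr_pos)) "undef" else
                    sprintf("%.2f", tp$stats$lr_pos),
                  if (is.na(tp$posttest)) "undef" else
                    sprintf("%.0f%%", 100 * tp$posttest)))
    }
  }
  invisible(x)
}

#' Serialize a derivation to report files
#'
#' Writes a machine-readable JSON report and a human-readable text
#' report mirroring the published table structure: outcome summaries by
#' response class, screening results, chosen cut-points, per-step
#' models, and per-threshold rule performance, with degenerate or
#' approximated quantities flagged.
#'
#' @param d a `"cpr_derivation"`.
#' @param dir output directory (created if needed).
#' @return the report list, invisibly; files `report.json` and
#'   `report.txt` are written under `dir`.
#' @export
build_report <- function(d, dir) {
  stopifnot(inherits(d, "cpr_derivation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  step_json <- function(s) {
    fit <- s$result$fit
    list(step = s$step,
         candidate_pool = s$candidate_pool,
         terms = fit$terms,
         intercept = fit$intercept,
         minus2ll = fit$minus2ll,
         converged = fit$converged,
         separation = fit$separation,
         nagelkerke_r2_pct = 100 * s$summary$nagelkerke_r2,
         hosmer_lemeshow = s$summary$hl,
         auc = s$summary$auc,
         adequacy = s$summary$adequacy,
         removal_trace = s$result$removal_trace)
  }
  thr_json <- function(tp) {
    list(k = tp$k,
         table = unclass(tp$table)[c("tp", "fp", "fn", "tn")],
         se = tp$stats$se, se_ci = tp$stats$se_ci,
         sp = tp$stats$sp, sp_ci = tp$stats$sp_ci,
         lr_pos = tp$stats$lr_pos, lr_pos_ci = tp$stats$lr_pos_ci,
         lr_neg = tp$stats$lr_neg, lr_neg_ci = tp$stats$lr_neg_ci,
         pv_pos = tp$stats$pv_pos, pv_neg = tp$stats$pv_neg,
         posttest = tp$posttest,
         posttest_pct = if (is.na(tp$posttest)) NA else
           round(100 * tp$posttest),
         degenerate = tp$stats$degenerate,
         approximated = tp$stats$approximated)
  }
  report <- list(
    time = d$time,
    n_completers = d$n_completers,
    class_counts = as.list(d$class_counts),
    pretest_probability = d$prevalence,
    outcome_summary = d$outcome_summary,
    cutpoints = lapply(d$cutpoints, function(cp) {
      list(variable = cp$variable, method = cp$method, cut = cp$cut,
           direction = cp$direction, se = cp$se, sp = cp$sp,
           lr_pos = cp$lr_pos, youden_j = cp$youden_j,
           fallback = cp$fallback)
    }),
    screening = d$screen,
    models = lapply(d$steps, step_json),
    rule = if (is.null(d$rule)) NULL else d$rule$tests,
    thresholds = lapply(d$thresholds, thr_json)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  txt <- utils::capture.output({
    print(d)
    cat("\n-- outcome summary --\n")
    print(d$outcome_summary, digits = 3)
    cat("\n-- screening --\n")
    print(d$screen, digits = 3)
    cat("\n-- models --\n")
    for (s in d$steps) print(s)
  })
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(report)
}
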