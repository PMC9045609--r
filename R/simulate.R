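#' Simulation configuration for synthetic cohorts
#'
#' Bundles the parameters of the synthetic-cohort generator: enrollment,
#' attrition, target success prevalences, baseline score distributions,
#' and the planted and noise candidate predictors.  [default_paper_config()]
#' returns the packaged calibration mirroring the study design the
#' package emulates.
#'
#' @param n_enrolled patients starting the program (>= 20).
#' @param seed integer RNG seed.
#' @param success_prevalence_t8,success_prevalence_t34 target expected
#'   success fractions among completers.
#' @param attrition_in_program per-patient probability of leaving during
#'   the program.
#' @param attrition_followup count of completers lost between T8 and the
#'   six-month follow-up.
#' @param improvement_frac fraction of non-successes assigned to the
#'   clinically-significant-improvement class (where baseline ODI
#'   permits it).
#' @param t8_t34_latent_cor Gaussian-copula correlation between the T8
#'   and T34 success draws.
#' @param odi_t0_mean,odi_t0_sd,nprs_t0_mean,nprs_t0_sd,bmi_mean,bmi_sd,age_mean,age_sd
#'   baseline marginals.
#' @param prop_female probability a patient is female.
#' @param planted_tests data.frame describing predictors with a real
#'   effect: columns `name`, `class`, `scale`, `direction_hint`, `cut`
#'   (true threshold), `odds_ratio` (per positive test, on success),
#'   `mean`, `sd`, `prob` (binary positivity rate), `sex_shift`,
#'   `sex_sd_shift` (female offsets, for the laxity score).
#' @param noise_tests data.frame of predictors with no effect: columns
#'   `name`, `class`, `scale`, `direction_hint`, `mean`, `sd`, `prob`.
#' @param attrition_outcome_dependent if `TRUE`, in-program dropout is
#'   biased toward patients with below-median latent success probability
#'   (sensitivity studies only; default independent).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_enrolled = 134,
                       seed = 1L,
                       success_prevalence_t8 = 0.49,
                       success_prevalence_t34 = 0.53,
                       attrition_in_program = 0.18,
                       attrition_followup = 10L,
                       improvement_frac = 0.20,
                       t8_t34_latent_cor = 0.8,
                       odi_t0_mean = 26.8, odi_t0_sd = 10,
                       nprs_t0_mean = 5.0, nprs_t0_sd = 1.3,
                       bmi_mean = 26.5, bmi_sd = 4.7,
                       age_mean = 43.5, age_sd = 12,
                       prop_female = 0.55,
                       planted_tests = default_planted_tests(),
                       noise_tests = default_noise_tests(),
                       attrition_outcome_dependent = FALSE) {
  cfg <- list(
    n_enrolled = as.integer(n_enrolled), seed = as.integer(seed),
    success_prevalence_t8 = success_prevalence_t8,
    success_prevalence_t34 = success_prevalence_t34,
    attrition_in_program = attrition_in_program,
    attrition_followup = as.integer(attrition_followup),
    improvement_frac = improvement_frac,
    t8_t34_latent_cor = t8_t34_latent_cor,
    odi_t0_mean = odi_t0_mean, odi_t0_sd = odi_t0_sd,
    nprs_t0_mean = nprs_t0_mean, nprs_t0_sd = nprs_t0_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    age_mean = age_mean, age_sd = age_sd,
    prop_female = prop_female,
    planted_tests = as.data.frame(planted_tests, stringsAsFactors = FALSE),
    noise_tests = as.data.frame(noise_tests, stringsAsFactors = FALSE),
    attrition_outcome_dependent = isTRUE(attrition_outcome_dependent)
  )
  probs <- c(cfg$success_prevalence_t8, cfg$success_prevalence_t34,
             cfg$attrition_in_program, cfg$improvement_frac,
             cfg$prop_female)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_enrolled < 20) stop("n_enrolled must be >= 20")
  if (any(cfg$planted_tests$odds_ratio <= 0)) {
    stop("odds ratios must be > 0")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_paper_config <- function(seed = 1L) sim_config(seed = seed)

## Four planted class-A "instability" tests: a loaded-reach physical
## performance ratio (cut 0.75, high positive), a pain-provocation
## binary test, an aberrant-movement binary test, and a 0-9 generalized
## joint laxity score (positive when BELOW 5; females score higher).
## Planted odds ratios are exp of the published model coefficients.
default_planted_tests <- function() {
  data.frame(
    name = c("ppt_reach", "mcis_hipar_pas", "abe_mvt", "beighton"),
    class = "A",
    scale = c("continuous", "binary", "binary", "ordinal"),
    direction_hint = c("high_is_positive", "high_is_positive",
                       "high_is_positive", "low_is_positive"),
    cut = c(0.75, 0.5, 0.5, 4.5),
    odds_ratio = exp(c(1.78, 1.58, 1.40, 1.65)),
    mean = c(0.70, NA, NA, 0.5),
    sd = c(0.15, NA, NA, 1.4),
    prob = c(NA, 0.35, 0.30, NA),
    sex_shift = c(0, 0, 0, 1.7),
    sex_sd_shift = c(0, 0, 0, 1.2),
    stringsAsFactors = FALSE
  )
}

## Adherence-related (class B) and treatment-nonspecific (class C)
## predictors with no planted effect.
default_noise_tests <- function() {
  data.frame(
    name = c("exercise_selfefficacy", "pain_during_exercise",
             "social_support", "pain_catastrophizing", "start_back",
             "psych_distress"),
    class = c("B", "B", "B", "C", "C", "C"),
    scale = c("continuous", "continuous", "continuous", "continuous",
              "ordinal", "continuous"),
    direction_hint = "unknown",
    mean = c(70, 3, 7, 20, 4, 24),
    sd = c(15, 2, 2, 12, 2, 14),
    prob = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n_enrolled = ", x$n_enrolled,
      ", seed = ", x$seed, "\n",
      "  prevalence T8/T34: ", x$success_prevalence_t8, "/",
      x$success_prevalence_t34,
      "; attrition: ", x$attrition_in_program, " in-program + ",
      x$attrition_followup, " at follow-up\n",
      "  planted tests: ", paste(x$planted_tests$name, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

## Solve the success-model intercept so that the mean predicted
## probability over the realized linear predictors hits the target.
solve_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  if (f(-30) > 0 || f(30) < 0) {
    stop("unsatisfiable prevalence: intercept search fails to bracket")
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

## Integer ODI at follow-up consistent with an assigned response class.
## success: percentage drop >= 50; improvement: absolute drop >= 10 but
## < 50%; failure: neither.  Improvement requires baseline ODI > 20.
odi_for_class <- function(odi_t0, class) {
  n <- length(odi_t0)
  out <- integer(n)
  for (i in seq_len(n)) {
    t0 <- odi_t0[i]
    out[i] <- switch(
      class[i],
      success = {
        dp <- stats::runif(1, 55, 95)
        max(0L, as.integer(floor(t0 * (1 - dp / 100))))
      },
      improvement = {
        dmax <- as.integer(ceiling(t0 / 2) - 1)
        t0 - sample(10:dmax, 1)
      },
      failure = {
        dmax <- min(9L, as.integer(ceiling(t0 / 2) - 1))
        t0 - sample(seq(-5L, dmax), 1)
      }
    )
  }
  pmin(pmax(out, 0L), 100L)
}

nprs_for_class <- function(class, means, sds) {
  mu <- means[class]
  s <- sds[class]
  as.integer(pmin(pmax(round(stats::rnorm(length(class), mu, s)), 0), 10))
}

#' Simulate a synthetic patient cohort
#'
#' Generates a cohort with realistic baseline marginals, a planted
#' association between a small set of "instability" tests and treatment
#' success, and outcome scores consistent with the response
#' classification.  Success is generated first from a logistic model on
#' the count of positive planted tests (per-test log odds-ratio
#' weights; intercept solved numerically so the expected prevalence
#' equals the configured target), then ODI change is generated
#' conditional on the assigned class so [classify_outcome()] reproduces
#' it.  Attrition is applied after outcome generation.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `"cohort"`) and `truth` (a
#'   `"planted_truth"`: per-patient latent success probabilities at both
#'   times, the per-test positivity matrix, generated classes, and the
#'   true rule as a [cpr_rule()]).  Deterministic given
#'   `config$seed`.
#' @export
simulate_cohort <- function(config = default_paper_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_enrolled

  sex <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
  age <- round(rnorm_trunc(n, config$age_mean, config$age_sd, 18, 65))
  bmi <- round(rnorm_trunc(n, config$bmi_mean, config$bmi_sd, 16, 45), 1)
  odi_t0 <- as.integer(round(rnorm_trunc(n, config$odi_t0_mean,
                                         config$odi_t0_sd, 12, 80)))
  nprs_t0 <- as.integer(round(rnorm_trunc(n, config$nprs_t0_mean,
                                          config$nprs_t0_sd, 0, 10)))

  ## candidate predictors
  pt <- config$planted_tests
  nt <- config$noise_tests
  gen_numeric <- function(scale, mean, sd, prob, sex_shift = 0,
                          sex_sd_shift = 0) {
    if (scale == "binary") {
      as.integer(stats::runif(n) < prob)
    } else if (scale == "ordinal") {
      mu <- mean + ifelse(sex == "F", sex_shift, 0)
      s <- sd + ifelse(sex == "F", sex_sd_shift, 0)
      as.integer(pmin(pmax(round(stats::rnorm(n, mu, s)), 0), 9))
    } else {
      round(stats::rnorm(n, mean, sd), 3)
    }
  }
  pred <- list()
  for (i in seq_len(nrow(pt))) {
    pred[[pt$name[i]]] <- gen_numeric(pt$scale[i], pt$mean[i], pt$sd[i],
                                      pt$prob[i], pt$sex_shift[i],
                                      pt$sex_sd_shift[i])
  }
  for (i in seq_len(nrow(nt))) {
    pred[[nt$name[i]]] <- gen_numeric(nt$scale[i], nt$mean[i], nt$sd[i],
                                      nt$prob[i])
  }

  ## planted-test positivity and the latent success model
  positives <- vapply(seq_len(nrow(pt)), function(i) {
    v <- pred[[pt$name[i]]]
    if (pt$direction_hint[i] == "low_is_positive") {
      as.integer(v <= pt$cut[i])
    } else {
      as.integer(v >= pt$cut[i])
    }
  }, integer(n))
  colnames(positives) <- pt$name
  lp <- as.numeric(positives %*% log(pt$odds_ratio))

  a8 <- solve_intercept(lp, config$success_prevalence_t8)
  a34 <- solve_intercept(lp, config$success_prevalence_t34)
  p8 <- stats::plogis(a8 + lp)
  p34 <- stats::plogis(a34 + lp)

  ## correlated success indicators at the two horizons (Gaussian copula
  ## preserves both marginal prevalences)
  rho <- config$t8_t34_latent_cor
  z <- stats::rnorm(n)
  z8 <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  z34 <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  succ8 <- stats::pnorm(z8) < p8
  succ34 <- stats::pnorm(z34) < p34

  assign_class <- function(succ) {
    cls <- ifelse(succ, "success", "failure")
    nonsucc <- which(!succ & odi_t0 > 20)
    n_imp <- min(round(config$improvement_frac * sum(!succ)),
                 length(nonsucc))
    if (n_imp > 0) {
      cls[sample(nonsucc, n_imp)] <- "improvement"
    }
    cls
  }
  cls8 <- assign_class(succ8)
  cls34 <- assign_class(succ34)

  odi_t8 <- odi_for_class(odi_t0, cls8)
  odi_t34 <- odi_for_class(odi_t0, cls34)
  nprs_t8 <- nprs_for_class(cls8,
                            c(success = 2.1, improvement = 3.0, failure = 3.4),
                            c(success = 1.0, improvement = 1.2, failure = 1.4))
  nprs_t34 <- nprs_for_class(cls34,
                             c(success = 2.1, improvement = 3.8, failure = 3.9),
                             c(success = 1.1, improvement = 1.9, failure = 1.8))

  patients <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    sex = sex, age = age, bmi = bmi,
    odi_T0 = odi_t0, odi_T4 = NA_integer_, odi_T8 = odi_t8,
    odi_T34 = odi_t34,
    nprs_T0 = nprs_t0, nprs_T4 = NA_integer_, nprs_T8 = nprs_t8,
    nprs_T34 = nprs_t34,
    dropout_stage = "completed_T34",
    stringsAsFactors = FALSE
  )
  for (nm in names(pred)) patients[[nm]] <- pred[[nm]]

  variables <- rbind(
    pt[, c("name", "class", "scale", "direction_hint")],
    nt[, c("name", "class", "scale", "direction_hint")]
  )
  x <- cohort(patients, variables,
              provenance = paste0("simulate_cohort(seed=", config$seed,
                                  ", n_enrolled=", n, ")"))

  truth <- structure(
    list(success_prob_t8 = p8, success_prob_t34 = p34,
         positives = positives, class_t8 = cls8, class_t34 = cls34,
         rule = cpr_rule(data.frame(
           name = pt$name, cut = pt$cut,
           direction = ifelse(pt$direction_hint == "low_is_positive",
                              "le_positive", "ge_positive"),
           stringsAsFactors = FALSE)),
         intercept_t8 = a8, intercept_t34 = a34),
    class = "planted_truth"
  )

  x <- apply_attrition(x, truth, config)
  list(cohort = x, truth = truth)
}

#' Apply in-program and follow-up attrition
#'
#' Marks `dropout_stage` and blanks the corresponding outcome scores.
#' Uses the current RNG stream (called by [simulate_cohort()] after
#' outcome generation).  By default dropout is independent of outcome;
#' with `config$attrition_outcome_dependent` the in-program dropout
#' probability is doubled for patients with below-median latent success
#' probability.
#'
#' @param x a `"cohort"` with outcomes generated.
#' @param truth the matching `"planted_truth"`.
#' @param config a [sim_config()].
#' @return the `"cohort"` with dropout stages assigned.
#' @export
apply_attrition <- function(x, truth, config) {
  p <- x$patients
  n <- nrow(p)
  pr <- rep(config$attrition_in_program, n)
  if (config$attrition_outcome_dependent) {
    lo <- truth$success_prob_t8 < stats::median(truth$success_prob_t8)
    pr[lo] <- pmin(1, 2 * pr[lo])
  }
  lost_prog <- stats::runif(n) < pr
  p$dropout_stage[lost_prog] <- "lost_in_program"
  p$odi_T8[lost_prog] <- NA_integer_
  p$nprs_T8[lost_prog] <- NA_integer_

  completer_idx <- which(!lost_prog)
  k <- min(config$attrition_followup, length(completer_idx))
  lost_fu <- if (k > 0) sample(completer_idx, k) else integer()
  p$dropout_stage[lost_fu] <- "lost_after_T8"
  p$odi_T34[lost_prog] <- NA_integer_
  p$odi_T34[lost_fu] <- NA_integer_
  p$nprs_T34[lost_prog] <- NA_integer_
  p$nprs_T34[lost_fu] <- NA_integer_

  x$patients <- p
  x
}
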