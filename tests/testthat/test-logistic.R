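test_that("fit_logistic reproduces closed forms", {
  # intercept-only: logit of the success fraction
  y <- c(rep(1, 54), rep(0, 45))
  f0 <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  expect_equal(f0$intercept, log(54 / 45), tolerance = 1e-8)
  expect_equal(nrow(f0$terms), 0)

  # single binary predictor: B equals the 2x2 log odds ratio
  x <- c(rep(1, 30), rep(0, 24), rep(1, 10), rep(0, 35))
  f1 <- fit_logistic(data.frame(x = x), y)
  expect_equal(f1$terms$b, log(30 * 35 / (24 * 10)), tolerance = 1e-8)
  expect_equal(f1$terms$odds_ratio, 30 * 35 / (24 * 10), tolerance = 1e-6)

  # Wald CI self-consistency: se = (hi - lo) / 3.92
  expect_equal(f1$terms$se, (f1$terms$ci_hi - f1$terms$ci_lo) / 3.92,
               tolerance = 1e-10)
})

test_that("IRLS matches an independent likelihood maximization", {
  set.seed(42)
  n <- 300
  X <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n))
  eta <- -0.3 + 0.8 * X$a + 1.1 * X$b - 0.5 * X$c
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)

  opt <- optim(rep(0, 4), oracle_nll, X = as.matrix(X), y = y,
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(fit$intercept, fit$terms$b)), opt$par,
               tolerance = 1e-3)
  expect_equal(fit$minus2ll, 2 * opt$value, tolerance = 1e-6)
})

test_that("degenerate designs are flagged, collinearity is an error", {
  set.seed(5)
  X <- data.frame(a = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))  # perfect separation
  f <- fit_logistic(X, y)
  expect_true(f$separation)
  expect_false(f$converged)

  X2 <- data.frame(a = rnorm(40), y0 = rbinom(40, 1, 0.5))
  X2$b <- 2 * X2$a
  expect_error(fit_logistic(X2[, c("a", "b")], X2$y0), "collinear.*b")
  expect_error(fit_logistic(data.frame(a = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("Nagelkerke R2 follows its formula and its bounds", {
  set.seed(10)
  X <- data.frame(x = rnorm(200))
  y <- rbinom(200, 1, plogis(2 * X$x))
  fit <- fit_logistic(X, y)
  r2 <- nagelkerke_r2(fit)
  # independent re-evaluation from the stored deviances
  expect_equal(r2,
               (1 - exp((fit$minus2ll - fit$null_minus2ll) / 200)) /
                 (1 - exp(-fit$null_minus2ll / 200)),
               tolerance = 1e-12)
  expect_gt(r2, 0)
  expect_lt(r2, 1)

  # null fit -> 0
  f0 <- fit_logistic(data.frame(row.names = 1:200), y)
  expect_equal(nagelkerke_r2(f0), 0, tolerance = 1e-12)
})

test_that("deviance and R2 are monotone under nesting", {
  set.seed(11)
  X <- data.frame(a = rnorm(150), b = rnorm(150), c = rnorm(150))
  y <- rbinom(150, 1, plogis(0.7 * X$a))
  fits <- lapply(1:3, function(k) fit_logistic(X[, 1:k, drop = FALSE], y))
  m2ll <- vapply(fits, `[[`, numeric(1), "minus2ll")
  r2 <- vapply(fits, nagelkerke_r2, numeric(1))
  expect_true(all(diff(m2ll) <= 1e-8))
  expect_true(all(diff(r2) >= -1e-8))
})

test_that("Hosmer-Lemeshow is calibrated under the null and detects miscalibration", {
  set.seed(30)
  reps <- 150
  reject_null <- reject_bad <- logical(reps)
  skips <- 0
  for (r in seq_len(reps)) {
    x <- rnorm(300)
    p_true <- plogis(-0.5 + x)
    y <- rbinom(300, 1, p_true)
    fit <- fit_logistic(data.frame(x = x), y)
    hl <- hosmer_lemeshow(fit)
    if (hl$skipped) { skips <- skips + 1; next }
    reject_null[r] <- hl$p < 0.05

    # same fitted model scored against outcomes from squared probabilities
    y_bad <- rbinom(300, 1, p_true^2)
    fit_bad <- fit
    fit_bad$outcome <- y_bad
    hl_bad <- hosmer_lemeshow(fit_bad)
    reject_bad[r] <- !hl_bad$skipped && hl_bad$p < 0.05
  }
  expect_equal(skips, 0)
  expect_lt(mean(reject_null), 0.12)   # ~5% nominal
  expect_gt(mean(reject_bad), 0.5)     # gross miscalibration
})

test_that("Hosmer-Lemeshow skips degenerate prediction patterns", {
  y <- rep(c(0, 1), 30)
  x <- rep(c(0, 1), each = 30)
  fit <- fit_logistic(data.frame(x = x), y)  # two distinct predictions
  hl <- hosmer_lemeshow(fit)
  expect_true(hl$skipped)
})

test_that("adequacy ranks reflect single-predictor explanatory shares", {
  set.seed(21)
  X <- data.frame(a = rbinom(300, 1, 0.5))
  y <- rbinom(300, 1, plogis(-0.5 + 1.5 * X$a))
  f1 <- fit_logistic(X, y)
  a1 <- adequacy_ranks(f1)
  expect_equal(a1$adequacy, 1, tolerance = 1e-10)
  expect_equal(a1$rank, 1L)

  # two independent equal-strength predictors: distinct ranks but
  # adequacies within sampling noise of each other
  set.seed(22)
  X3 <- data.frame(a = rbinom(2000, 1, 0.5), b = rbinom(2000, 1, 0.5))
  y3 <- rbinom(2000, 1, plogis(-0.5 + X3$a + X3$b))
  f3 <- fit_logistic(X3, y3)
  a3 <- adequacy_ranks(f3)
  expect_equal(sort(a3$rank), c(1L, 2L))

  # brute-force refit oracle on a 3-term fit
  set.seed(23)
  X4 <- data.frame(a = rnorm(250), b = rbinom(250, 1, 0.4),
                   c = rnorm(250))
  y4 <- rbinom(250, 1, plogis(0.9 * X4$a + 0.7 * X4$b))
  f4 <- fit_logistic(X4, y4)
  a4 <- adequacy_ranks(f4)
  for (i in seq_len(3)) {
    single <- glm(y4 ~ ., data = cbind(y4 = y4, X4[, i, drop = FALSE]),
                  family = binomial())
    want <- (f4$null_minus2ll - deviance(single)) /
      (f4$null_minus2ll - f4$minus2ll)
    expect_equal(a4$adequacy[i], want, tolerance = 1e-8)
  }
  expect_equal(a4$rank, rank(-a4$adequacy, ties.method = "min"))
})

test_that("backward elimination retains signal, discards noise, honors constraints", {
  set.seed(31)
  n <- 400
  data <- data.frame(signal = rbinom(n, 1, 0.4),
                     n1 = rnorm(n), n2 = rbinom(n, 1, 0.5),
                     n3 = rnorm(n), n4 = rnorm(n), n5 = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-0.7 + log(6) * data$signal))
  res <- backward_eliminate(names(data), character(), data, y)
  expect_true("signal" %in% res$fit$terms$name)
  expect_true(all(res$fit$terms$wald_p < 0.05))

  # forced covariate survives even with p near 1
  res2 <- backward_eliminate(c("signal", "n1"), "n1", data, y)
  expect_true("n1" %in% res2$fit$terms$name)

  # pure noise pool collapses to the intercept-only model most times
  empties <- vapply(1:40, function(r) {
    set.seed(100 + r)
    d <- data.frame(a = rnorm(300), b = rbinom(300, 1, 0.5),
                    c = rnorm(300))
    y0 <- rbinom(300, 1, 0.5)
    backward_eliminate(names(d), character(), d, y0)$empty_model
  }, logical(1))
  expect_gt(mean(empties), 0.6)

  # column order does not change the outcome
  resA <- backward_eliminate(c("signal", "n1", "n2", "n3"), character(),
                             data, y)
  resB <- backward_eliminate(c("n3", "n2", "n1", "signal"), character(),
                             data[, c(4, 3, 2, 1)], y)
  expect_setequal(resA$fit$terms$name, resB$fit$terms$name)
  expect_equal(sort(resA$removal_trace$name), sort(resB$removal_trace$name))
})

test_that("hierarchical steps reduce to step 1 when only class A is accepted", {
  sim <- simulate_cohort(default_paper_config(seed = 55))
  d <- derive_cpr(sim$cohort, "T8")
  accepted_classes <- sim$cohort$variables$class[
    match(d$screen$variable[d$screen$accepted], sim$cohort$variables$name)]
  steps <- d$steps
  if (!any(accepted_classes %in% c("B", "C"))) {
    expect_identical(steps$A_plus_B$result$fit$terms$name,
                     steps$A_only$result$fit$terms$name)
  }
  # rebuild with a screen table stripped of B/C acceptances: steps 2-3
  # must reproduce step 1 exactly
  screen2 <- d$screen
  bc <- sim$cohort$variables$name[sim$cohort$variables$class != "A"]
  screen2$accepted[screen2$variable %in% bc] <- FALSE
  sf <- cprderive:::success_failure_frame(sim$cohort, "T8")
  md <- data.frame(age = sf$data$age, bmi = sf$data$bmi,
                   sex = as.integer(sf$data$sex == "F"))
  for (nm in screen2$variable[screen2$accepted]) {
    dict <- sim$cohort$variables
    i <- match(nm, dict$name)
    v <- sf$data[[nm]]
    if (dict$scale[i] == "binary") {
      md[[nm]] <- v
    } else {
      cp <- select_cutpoint(v, sf$labels, "YI",
                            if (dict$direction_hint[i] == "low_is_positive")
                              "le_positive" else "ge_positive")
      md[[nm]] <- as.integer(if (cp$direction == "ge_positive") v >= cp$cut
                             else v <= cp$cut)
    }
  }
  keep <- complete.cases(md)
  hm <- hierarchical_modeling(screen2, sim$cohort$variables, md[keep, ],
                              sf$labels[keep])
  expect_identical(hm$A_plus_B$result$fit$terms$name,
                   hm$A_only$result$fit$terms$name)
  expect_identical(hm$A_plus_B_plus_C$result$fit$terms$name,
                   hm$A_only$result$fit$terms$name)
  expect_equal(hm$A_plus_B$result$fit$minus2ll,
               hm$A_only$result$fit$minus2ll)
})
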