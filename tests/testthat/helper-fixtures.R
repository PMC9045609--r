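# Hand-built six-patient cohort with known outcome classes:
# A success (27->7), B improvement (36->21), C failure (24->22),
# D success at the exact 50% boundary (30->15), E success (40->10),
# F failure (20->18).
tiny_cohort <- function() {
  patients <- data.frame(
    id = LETTERS[1:6],
    sex = c("M", "F", "F", "M", "F", "M"),
    age = c(35, 48, 52, 29, 61, 44),
    bmi = c(24.1, 27.5, 31.0, 22.8, 26.0, 29.3),
    odi_T0 = c(27, 36, 24, 30, 40, 20),
    odi_T8 = c(7, 21, 22, 15, 10, 18),
    odi_T34 = c(7, 21, 22, 15, 10, 18),
    nprs_T0 = c(5, 6, 5, 4, 7, 5),
    nprs_T8 = c(2, 3, 4, 2, 1, 4),
    nprs_T34 = c(2, 3, 4, 2, 1, 4),
    dropout_stage = "completed_T34",
    ppt_reach = c(0.80, 0.60, 0.70, 0.90, 0.85, 0.55),
    abe_mvt = c(1, 0, 0, 1, 1, 0),
    beighton = c(2, 6, 5, 1, 3, 7),
    stringsAsFactors = FALSE
  )
  variables <- data.frame(
    name = c("ppt_reach", "abe_mvt", "beighton"),
    class = "A",
    scale = c("continuous", "binary", "ordinal"),
    direction_hint = c("high_is_positive", "high_is_positive",
                       "low_is_positive"),
    stringsAsFactors = FALSE
  )
  cohort(patients, variables, provenance = "hand-built test fixture")
}

# Independent O(n^2) recount: 2x2 cells for one cut by direct counting.
oracle_counts <- function(values, labels, cut, direction) {
  pos <- if (direction == "ge_positive") values >= cut else values <= cut
  c(tp = sum(pos & labels == 1), fp = sum(pos & labels == 0),
    fn = sum(!pos & labels == 1), tn = sum(!pos & labels == 0))
}

# Independent exhaustive scan over all candidate cuts for one
# criterion, with the same tie-break (larger J, then smaller cut).
oracle_scan <- function(values, labels, method, direction) {
  d <- sort(unique(values))
  cuts <- if (length(d) < 2) c(-Inf, Inf) else
    c(-Inf, (d[-1] + d[-length(d)]) / 2, Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (cut in cuts) {
    ct <- oracle_counts(values, labels, cut, direction)
    se <- ct["tp"] / n1; sp <- ct["tn"] / n0
    j <- se + sp - 1
    obj <- switch(
      method,
      ROC = -((1 - se)^2 + (1 - sp)^2),
      YI = j,
      dMinSnSp = -abs(se - sp),
      LRmax = if (ct["fp"] >= 1) se / (1 - sp) else -Inf,
      KLfg = if (all(ct > 0)) {
        (if (se > 0) se * log(se / (1 - sp)) else 0) +
          (if (se < 1) (1 - se) * log((1 - se) / sp) else 0)
      } else -Inf,
      KLgf = if (all(ct > 0)) {
        (if (sp < 1) (1 - sp) * log((1 - sp) / se) else 0) +
          (if (sp > 0) sp * log(sp / (1 - se)) else 0)
      } else -Inf
    )
    if (!is.finite(obj)) next
    cand <- list(cut = cut, obj = obj, j = j)
    if (is.null(best) || obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
         (j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && cut < best$cut)))) {
      best <- cand
    }
  }
  if (is.null(best)) best <- list(cut = NA_real_, obj = -Inf, j = NA_real_)
  best
}

# Independent Bernoulli log-likelihood for a logistic model.
oracle_nll <- function(beta, X, y) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

# Counts vector realizing given per-k cumulative tallies, e.g. the
# published per-threshold headcounts.
counts_from_cumulative <- function(n_total, cum) {
  # cum[k] = number with count >= k, k = 1..K
  K <- length(cum)
  exact <- c(n_total - cum[1], -diff(c(cum, 0)))  # counts of 0, 1, ..., K
  rep(0:K, times = exact)
}
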