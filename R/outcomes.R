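#' Disability change scores
#'
#' Absolute and percentage improvement in the Oswestry Disability Index
#' between baseline and a later assessment: `delta = ODI_T0 - ODI_Tx`
#' and `delta_pct = (ODI_T0 - ODI_Tx) / ODI_T0 * 100`.  Positive values
#' mean improvement.
#'
#' @param odi_t0 baseline ODI (percent, must be > 0; eligibility
#'   requires >= 12 so this holds for any included patient).
#' @param odi_tx ODI at the later assessment (percent).
#' @return list with `delta` (percent points) and `delta_pct` (percent);
#'   vectorized over inputs.
#' @export
compute_change <- function(odi_t0, odi_tx) {
  if (any(!is.na(odi_t0) & odi_t0 <= 0)) {
    stop("odi_t0 must be > 0 to define a percentage change")
  }
  delta <- odi_t0 - odi_tx
  list(delta = delta, delta_pct = delta / odi_t0 * 100)
}

#' Trichotomous treatment-response classification
#'
#' Patients are classed by ODI change: *success* when the percentage
#' improvement is at least 50%; *improvement* (clinically significant)
#' when below 50% but the absolute drop reaches the 10-point minimal
#' clinically important change; *failure* otherwise.  Both boundaries
#' are inclusive as stated (>= 50, >= 10).
#'
#' @param change a list as returned by [compute_change()].
#' @return character vector in `c("success", "improvement", "failure")`
#'   (`NA` where either score is missing).
#' @export
classify_outcome <- function(change) {
  dp <- change$delta_pct
  d <- change$delta
  out <- ifelse(dp >= 50, "success",
                ifelse(d >= 10, "improvement", "failure"))
  out[is.na(dp) | is.na(d)] <- NA_character_
  out
}

#' Standardized pre/post effect size (Cohen's d)
#'
#' `d = (M_post - M_pre) / sqrt((SD_pre^2 + SD_post^2) / 2)`, i.e. the
#' mean change standardized by the pooled pre/post standard deviation.
#' Negative d means scores fell (improvement on ODI/NPRS).
#'
#' @param pre_mean,pre_sd,post_mean,post_sd group summary statistics;
#'   both SDs must be positive.
#' @return Cohen's d (dimensionless).
#' @export
cohens_d <- function(pre_mean, pre_sd, post_mean, post_sd) {
  if (any(pre_sd <= 0) || any(post_sd <= 0)) {
    stop("standard deviations must be positive")
  }
  (post_mean - pre_mean) / sqrt((pre_sd^2 + post_sd^2) / 2)
}

#' Outcome summary table by response class
#'
#' For completers with both ODI measurements at baseline and `time`:
#' per-class and overall n, mean (SD) of ODI and NPRS at both times,
#' plus overall Cohen's d for each instrument.
#'
#' @param x a `"cohort"`.
#' @param time `"T8"` or `"T34"`.
#' @return data.frame with one row per class (`failure`, `improvement`,
#'   `success`) and an `All` row; columns `group`, `n`, `odi_t0_mean`,
#'   `odi_t0_sd`, `odi_tx_mean`, `odi_tx_sd`, `nprs_t0_mean`,
#'   `nprs_t0_sd`, `nprs_tx_mean`, `nprs_tx_sd`, `cohens_d_odi`,
#'   `cohens_d_nprs` (d only for the `All` row; SD is `NA` when n = 1).
#' @export
summarize_outcomes <- function(x, time = "T8") {
  time <- match.arg(time, c("T8", "T34"))
  cc <- complete_case_subset(completers(x, time), character(), time,
                             quiet = TRUE)
  p <- cc$patients
  ocol <- paste0("odi_", time)
  ncol_ <- paste0("nprs_", time)
  cls <- classify_outcome(compute_change(p$odi_T0, p[[ocol]]))

  msd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  one_row <- function(group, idx) {
    o0 <- msd(p$odi_T0[idx]); ox <- msd(p[[ocol]][idx])
    n0 <- msd(p$nprs_T0[idx])
    nx <- msd(if (ncol_ %in% names(p)) p[[ncol_]][idx] else rep(NA_real_, sum(idx)))
    d_odi <- d_nprs <- NA_real_
    if (group == "All") {
      if (!anyNA(c(o0, ox))) d_odi <- cohens_d(o0[1], o0[2], ox[1], ox[2])
      if (!anyNA(c(n0, nx))) d_nprs <- cohens_d(n0[1], n0[2], nx[1], nx[2])
    }
    data.frame(group = group, n = sum(idx),
               odi_t0_mean = o0[1], odi_t0_sd = o0[2],
               odi_tx_mean = ox[1], odi_tx_sd = ox[2],
               nprs_t0_mean = n0[1], nprs_t0_sd = n0[2],
               nprs_tx_mean = nx[1], nprs_tx_sd = nx[2],
               cohens_d_odi = d_odi, cohens_d_nprs = d_nprs,
               stringsAsFactors = FALSE)
  }
  groups <- c("All", "failure", "improvement", "success")
  out <- do.call(rbind, lapply(groups, function(g) {
    idx <- if (g == "All") rep(TRUE, nrow(p)) else (!is.na(cls) & cls == g)
    one_row(g, idx)
  }))
  attr(out, "time") <- time
  out
}
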