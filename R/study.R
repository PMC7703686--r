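#' Total a Post-Concussion Symptom Scale response
#'
#' The PCSS has 21 symptom items, each self-rated on an integer 0–6
#' scale, so totals range 0–126.
#'
#' @param items Integer vector of exactly 21 ratings, each in 0–6.
#' @return The total score (integer in \[0, 126\]).
#' @export
pcss_total <- function(items) {
  if (length(items) != 21) {
    abort(sprintf("PCSS has 21 items; got %d", length(items)))
  }
  if (any(!is.finite(items)) || any(items != round(items)) ||
      any(items < 0) || any(items > 6)) {
    abort("each PCSS item must be an integer rating in [0, 6]")
  }
  as.integer(sum(items))
}

#' Summarise a group of metric values, pilot-report style
#'
#' Median (midpoint convention for even n) with range endpoints and n,
#' the reporting style of small cohort studies. Non-obtainable entries
#' (`NA`) are excluded from the summary but counted.
#'
#' @param values Numeric vector; `NA` marks not-obtainable entries.
#' @return One-row tibble: `median`, `min`, `max`, `n`,
#'   `n_not_obtainable`. All-`NA` input yields an empty summary (n = 0).
#' @export
summarize_group <- function(values) {
  if (length(values) == 0) abort("no values supplied")
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) == 0) {
    return(tibble(median = NA_real_, min = NA_real_, max = NA_real_,
                  n = 0L, n_not_obtainable = sum(!ok)))
  }
  tibble(median = median(v), min = min(v), max = max(v),
         n = length(v), n_not_obtainable = sum(!ok))
}

#' Per-group sample size for a two-sample comparison of autoregulation
#' indices
#'
#' Sizes a two-sided two-sample comparison of means between a healthy
#' index level and an abnormal boundary, assuming a common SD: the
#' normal-approximation formula `2 * sd^2 * (z[1-alpha/2] + z[power])^2
#' / delta^2` with the usual +1 correction for using the t distribution,
#' rounded up. Defaults are the healthy-adult nMxa/Mx mean 0.21 (SD
#' 0.16) against the 0.40 dysfunction boundary at 90% power and 5%
#' two-sided significance.
#'
#' @param mu0 Healthy mean index.
#' @param mu1 Abnormal boundary index.
#' @param sd Common SD of the index.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_groups Number of study groups recruited at this size.
#' @return One-row tibble: `n_per_group`, `n_total`, `delta`.
#' @export
power_sample_size <- function(mu0 = 0.21, mu1 = 0.40, sd = 0.16,
                              alpha = 0.05, power = 0.90, n_groups = 2) {
  check_num(mu0, "mu0"); check_num(mu1, "mu1")
  check_num(sd, "sd", lo = 0, strict_lo = TRUE)
  check_num(alpha, "alpha", lo = 0, hi = 1, strict_lo = TRUE, strict_hi = TRUE)
  check_num(power, "power", lo = 0, hi = 1, strict_lo = TRUE, strict_hi = TRUE)
  check_num(n_groups, "n_groups", lo = 1)
  delta <- abs(mu1 - mu0)
  if (delta == 0) abort("`mu1` must differ from `mu0`")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  n0 <- 2 * sd^2 * z^2 / delta^2
  n <- ceiling(n0 + 1)  # t-correction
  tibble(n_per_group = as.integer(n),
         n_total = as.integer(n * n_groups),
         delta = delta)
}

#' Classify a participant's autoregulation metrics
#'
#' Applies the published thresholds: nMxa strictly above 0.4 is
#' impaired autoregulation; THRR of at least 1.10 is preserved. Absent
#' metrics are labelled `not_obtainable`.
#'
#' @param participants Data frame with one row per participant and any
#'   of the columns `nmxa`, `thrr_left`, `thrr_right`, `thrr` (use `NA`
#'   for not-obtainable).
#' @param nmxa_threshold,thrr_threshold Classification boundaries.
#' @return The input tibble with `<metric>_label` columns appended.
#' @export
classify_participant <- function(participants, nmxa_threshold = 0.4,
                                 thrr_threshold = 1.10) {
  df <- as_tibble(participants)
  metric_cols <- intersect(c("nmxa", "thrr", "thrr_left", "thrr_right"),
                           names(df))
  if (length(metric_cols) == 0) abort("no metric columns found")
  for (mcol in metric_cols) {
    v <- df[[mcol]]
    lab <- if (startsWith(mcol, "thrr")) {
      dplyr::case_when(!is.finite(v) ~ "not_obtainable",
                       v >= thrr_threshold ~ "preserved",
                       TRUE ~ "impaired")
    } else {
      dplyr::case_when(!is.finite(v) ~ "not_obtainable",
                       v > nmxa_threshold ~ "impaired",
                       TRUE ~ "intact")
    }
    df[[paste0(mcol, "_label")]] <- lab
  }
  df
}

#' Cohort summary table in median (range, n) style
#'
#' Groups a participant table and summarises the requested metric
#' columns with [summarize_group()].
#'
#' @param participants Data frame with a `group` column and numeric
#'   metric columns.
#' @param metrics Character vector of metric column names.
#' @return Tidy tibble: one row per group x metric.
#' @export
cohort_summary <- function(participants,
                           metrics = intersect(c("nmxa", "thrr", "pcss"),
                                               names(participants))) {
  df <- as_tibble(participants)
  if (!"group" %in% names(df)) abort("participant table needs a `group` column")
  if (length(metrics) == 0) abort("no metric columns to summarise")
  out <- purrr::map(metrics, function(mcol) {
    gs <- dplyr::group_by(df, .data$group)
    res <- dplyr::group_modify(gs, function(d, key) summarize_group(d[[mcol]]))
    res <- dplyr::ungroup(res)
    res$metric <- mcol
    res
  })
  dplyr::relocate(dplyr::bind_rows(out), "group", "metric")
}
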