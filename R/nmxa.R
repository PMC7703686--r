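#' Moving-window correlation between ABP and FV block series
#'
#' Slides a window (default 5 min, stepping one block = 10 s) over the
#' shared block grid and computes, per placement, the Pearson
#' correlation of paired valid blocks. Pairs where either block is
#' invalid are dropped; windows with fewer than `min_blocks` valid pairs
#' or zero variance in either series are omitted (reason recorded).
#'
#' @param abp_blocks,fv_blocks `ca_blocks` tibbles on the same grid
#'   (same starts and block length).
#' @param window_s Window length, seconds (default 300).
#' @param step_s Window step, seconds (default 10, one block).
#' @param min_blocks Minimum valid pairs per window (default 25 of the
#'   30 possible, tolerating about 17% masked data).
#' @return Tibble of window records: `start_s`, `end_s`, `n_blocks`, `r`
#'   for retained windows; attribute `omitted` holds a tibble of dropped
#'   placements with reasons.
#' @export
windowed_correlation <- function(abp_blocks, fv_blocks, window_s = 300,
                                 step_s = 10, min_blocks = 25) {
  blen <- attr(abp_blocks, "block_len_s") %||% 10
  if (nrow(abp_blocks) != nrow(fv_blocks) ||
      any(abs(abp_blocks$start_s - fv_blocks$start_s) > 1e-9)) {
    abort("ABP and FV block series must share the same block grid")
  }
  span <- nrow(abp_blocks) * blen
  if (span < window_s) abort("recording span shorter than one window")

  t0 <- abp_blocks$start_s[1]
  starts <- seq(t0, t0 + span - window_s, by = step_s)
  ok_pair <- abp_blocks$valid & fv_blocks$valid

  res <- purrr::map(starts, function(s) {
    in_win <- abp_blocks$start_s >= s - 1e-9 &
      abp_blocks$start_s < s + window_s - 1e-9
    sel <- in_win & ok_pair
    n_ok <- sum(sel)
    if (n_ok < min_blocks) {
      return(list(start_s = s, n_blocks = n_ok, r = NA_real_,
                  reason = "too_few_blocks"))
    }
    a <- abp_blocks$mean[sel]
    f <- fv_blocks$mean[sel]
    if (sd(a) == 0 || sd(f) == 0) {
      return(list(start_s = s, n_blocks = n_ok, r = NA_real_,
                  reason = "zero_variance"))
    }
    list(start_s = s, n_blocks = n_ok, r = cor(a, f), reason = NA_character_)
  })
  df <- dplyr::bind_rows(res)
  df$end_s <- df$start_s + window_s
  kept <- dplyr::select(df[is.na(df$reason), ],
                        "start_s", "end_s", "n_blocks", "r")
  omitted <- dplyr::select(df[!is.na(df$reason), ],
                           "start_s", "end_s", "n_blocks", "reason")
  attr(kept, "omitted") <- omitted
  kept
}

#' Summarise windowed correlations into an nMxa result
#'
#' The per-side nMxa is the arithmetic mean of the window correlations;
#' the combined index is the unweighted mean of the per-side summaries
#' available. A side is classified `impaired` when its nMxa is strictly
#' greater than the 0.4 dysfunction threshold, otherwise `intact`. If no
#' side has any valid window the result is the explicit "not obtainable"
#' outcome, not an error.
#'
#' @param windows Named list of per-side window tibbles (from
#'   [windowed_correlation()]), e.g. `list(left = ..., right = ...)`.
#' @param threshold Dysfunction threshold on nMxa (default 0.4; strict
#'   `>`).
#' @param window_s,step_s Window parameters echoed into the result.
#' @return A `ca_nmxa` object: list with `sides` tibble (side, nmxa,
#'   n_windows, classification), `combined`, `obtainable`, `windows`,
#'   and the parameters.
#' @export
nmxa_summary <- function(windows, threshold = 0.4,
                         window_s = 300, step_s = 10) {
  if (is.data.frame(windows)) windows <- list(combined = windows)
  sides <- purrr::imap(windows, function(w, nm) {
    n <- nrow(w)
    tibble(
      side = nm,
      nmxa = if (n > 0) mean(w$r) else NA_real_,
      n_windows = n,
      classification = dplyr::case_when(
        n == 0 ~ "not_obtainable",
        mean(w$r) > threshold ~ "impaired",
        TRUE ~ "intact"
      )
    )
  })
  sides <- dplyr::bind_rows(sides)
  have <- is.finite(sides$nmxa)
  combined <- if (any(have)) mean(sides$nmxa[have]) else NA_real_
  structure(list(
    sides = sides,
    combined = combined,
    combined_classification = if (!any(have)) "not_obtainable"
      else if (combined > threshold) "impaired" else "intact",
    obtainable = any(have),
    windows = windows,
    params = list(threshold = threshold, window_s = window_s, step_s = step_s)
  ), class = "ca_nmxa")
}

#' Compute nMxa from a waveform recording
#'
#' The full pipeline: artefact detection, 10-s block averaging of ABP
#' and each FV channel (mean velocity), moving 5-min-window Pearson
#' correlation, and per-side / combined summary with the >0.4
#' dysfunction classification. Thirty minutes of analyzable signal is
#' advisable (a warning is raised below that); below five minutes the
#' function refuses.
#'
#' @param rec A `ca_recording` with `abp` and at least one of
#'   `fvl`/`fvr`.
#' @param block_len_s Block length, seconds.
#' @param window_s,step_s,min_blocks See [windowed_correlation()].
#' @param threshold Dysfunction threshold.
#' @param min_valid_frac Minimum unmasked fraction for a valid block.
#' @param detect Run [detect_artefacts()] first (default TRUE).
#' @return A `ca_nmxa` object; `params$analyzable_s` records the
#'   effective analyzable duration.
#' @export
nmxa <- function(rec, block_len_s = 10, window_s = 300, step_s = 10,
                 min_blocks = 25, threshold = 0.4, min_valid_frac = 0.5,
                 detect = TRUE) {
  chans <- wf_channels(rec)
  if (!"abp" %in% chans) abort("recording has no `abp` channel")
  fv <- intersect(c("fvl", "fvr"), chans)
  if (length(fv) == 0) abort("recording has no flow-velocity channel")
  if (detect) rec <- detect_artefacts(rec)

  analyzable <- min(vapply(c("abp", fv), function(ch) {
    sum(!rec[[mask_col(ch)]]) / wf_fs(rec)
  }, numeric(1)))
  if (analyzable < 300) {
    abort(sprintf(
      "only %.1f min analyzable; at least 5 min required", analyzable / 60))
  }
  if (analyzable < 1800) {
    warn(sprintf(
      "only %.1f min analyzable; 30 min advisable for nMxa", analyzable / 60))
  }

  abp_blocks <- block_average(rec, "abp", block_len_s, min_valid_frac)
  side_name <- c(fvl = "left", fvr = "right")
  wins <- purrr::map(fv, function(ch) {
    fvb <- block_average(rec, ch, block_len_s, min_valid_frac)
    windowed_correlation(abp_blocks, fvb, window_s, step_s, min_blocks)
  })
  names(wins) <- side_name[fv]

  out <- nmxa_summary(wins, threshold, window_s, step_s)
  out$params$analyzable_s <- analyzable
  out$params$block_len_s <- block_len_s
  out
}

#' @export
print.ca_nmxa <- function(x, ...) {
  cat("<ca_nmxa>\n")
  if (!x$obtainable) {
    cat("  nMxa not obtainable (no valid windows)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$sides))) {
    s <- x$sides[i, ]
    cat(sprintf("  %s: nMxa = %.3f over %d windows [%s]\n",
                s$side, s$nmxa, s$n_windows, s$classification))
  }
  cat(sprintf("  combined: %.3f [%s] (threshold > %.2f)\n",
              x$combined, x$combined_classification, x$params$threshold))
  invisible(x)
}
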