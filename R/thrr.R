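#' Find carotid-compression episodes in a flow-velocity beat series
#'
#' With annotations supplied (the usual mode, mirroring manual marking
#' of the THRT stages), one episode is built around each annotated
#' interval. Without annotations, compressions are auto-detected as
#' maximal runs of beats whose systolic value stays at or below 70% of
#' the median of the preceding 10 beats, lasting 3–10 s; overlapping
#' detections are merged.
#'
#' Each episode carries validity flags:
#' * `drop_ok` — nadir systolic FV at most 70% of the baseline mean
#'   (the >30% systolic reduction a valid compression must cause),
#' * `duration_ok` — compression length within 5–7 s (+/- 1 s
#'   tolerance),
#' * `spacing_ok` — at least 60 s gap after the previous episode,
#' * `signal_ok` — enough valid baseline and post-release beats.
#'
#' @param beats A `ca_beats` tibble for the insonated side.
#' @param annotations Optional tibble of intervals: `start_s`, `end_s`
#'   (half-open), optionally `side`.
#' @param side Side label attached to episodes (used when annotations
#'   carry none).
#' @param baseline_n Baseline beats used for the drop test and THRR.
#' @param n_post Post-release systolic peaks retained.
#' @return Tibble of episodes: one row per compression, with list
#'   columns `baseline` and `post_peaks`, the nadir, flags and `source`.
#' @export
find_compressions <- function(beats, annotations = NULL, side = NA_character_,
                              baseline_n = 5, n_post = 8) {
  if (nrow(beats) == 0) {
    warn("empty beat series; no episodes")
    return(empty_episodes())
  }
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations)
    if (!all(c("start_s", "end_s") %in% names(ann))) {
      abort("annotations need columns start_s, end_s")
    }
    if (!"side" %in% names(ann)) ann$side <- side
    src <- "manual_annotation"
  } else {
    ann <- auto_detect_compressions(beats)
    ann$side <- side
    src <- "auto_detected"
    if (nrow(ann) == 0) {
      message("no compression episodes auto-detected")
      return(empty_episodes())
    }
  }
  ann <- dplyr::arrange(ann, .data$start_s)

  eps <- purrr::pmap(ann, function(start_s, end_s, side, ...) {
    build_episode(beats, start_s, end_s, side, baseline_n, n_post, src)
  })
  eps <- dplyr::bind_rows(eps)
  # spacing: gap from previous episode end to this start must be >= 60 s
  if (nrow(eps) > 1) {
    gap <- eps$start_s[-1] - eps$end_s[-nrow(eps)]
    eps$spacing_ok[-1] <- eps$spacing_ok[-1] & gap >= 60
  }
  eps
}

auto_detect_compressions <- function(beats, drop_ratio = 0.7,
                                     lookback = 10, min_s = 3, max_s = 10) {
  syst <- beats$systolic
  n <- length(syst)
  ref <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - lookback)
    if (lo >= i) return(NA_real_)
    median(syst[lo:(i - 1L)])
  }, numeric(1))
  low <- !is.na(ref) & syst <= drop_ratio * ref
  # extend runs: once in compression, compare to the pre-run reference
  runs <- true_runs(low)
  if (nrow(runs) == 0) return(tibble(start_s = numeric(0), end_s = numeric(0)))
  runs <- purrr::pmap(runs, function(start, end) {
    ref0 <- ref[start]
    while (end < n && syst[end + 1L] <= drop_ratio * ref0) end <- end + 1L
    tibble(start_s = beats$onset_s[start],
           end_s = beats$peak_s[end] + 0.5 * median(beats$interval_s, na.rm = TRUE))
  })
  runs <- dplyr::bind_rows(runs)
  # merge overlaps
  merged <- runs[0, ]
  for (i in seq_len(nrow(runs))) {
    if (nrow(merged) > 0 && runs$start_s[i] <= merged$end_s[nrow(merged)]) {
      merged$end_s[nrow(merged)] <- max(merged$end_s[nrow(merged)], runs$end_s[i])
    } else {
      merged <- dplyr::bind_rows(merged, runs[i, ])
    }
  }
  dur <- merged$end_s - merged$start_s
  merged[dur >= min_s & dur <= max_s, ]
}

build_episode <- function(beats, start_s, end_s, side,
                          baseline_n, n_post, src) {
  pre <- beats[beats$peak_s < start_s & beats$valid, ]
  base <- tail(pre$systolic, baseline_n)
  inside <- beats[beats$peak_s >= start_s & beats$peak_s < end_s, ]
  nadir <- if (nrow(inside) > 0) min(inside$systolic) else NA_real_
  post <- beats[beats$peak_s >= end_s, ]
  post_peaks <- head(post$systolic, n_post)
  post_valid <- head(post$valid, n_post)

  base_mean <- if (length(base) > 0) mean(base) else NA_real_
  drop_ok <- is.finite(nadir) && is.finite(base_mean) &&
    nadir <= 0.70 * base_mean
  duration_ok <- (end_s - start_s) >= 4 && (end_s - start_s) <= 8
  signal_ok <- length(base) >= baseline_n && length(post_peaks) >= 4 &&
    all(post_valid[1:min(4, length(post_valid))])
  tibble(
    side = side, start_s = start_s, end_s = end_s,
    baseline = list(base), nadir = nadir,
    post_peaks = list(post_peaks),
    drop_ok = drop_ok, duration_ok = duration_ok,
    spacing_ok = TRUE, signal_ok = signal_ok,
    source = src
  )
}

empty_episodes <- function() {
  tibble(side = character(0), start_s = numeric(0), end_s = numeric(0),
         baseline = list(), nadir = numeric(0), post_peaks = list(),
         drop_ok = logical(0), duration_ok = logical(0),
         spacing_ok = logical(0), signal_ok = logical(0),
         source = character(0))
}

#' Compute the transient hyperaemic response ratio of one episode
#'
#' Baseline is the mean systolic flow velocity of the `baseline_n` beats
#' immediately preceding compression onset. On restoration of flow the
#' first systolic peak is ignored and the next three are averaged; THRR
#' is that response over the baseline.
#'
#' @param episode One row of the episode tibble from
#'   [find_compressions()] (or a list with `baseline` and `post_peaks`).
#' @param baseline_n Number of baseline beats required and used.
#' @return The episode THRR (a positive ratio), or `NA` with a warning
#'   when beats are insufficient.
#' @export
compute_thrr <- function(episode, baseline_n = 5) {
  base <- episode$baseline[[1]]
  post <- episode$post_peaks[[1]]
  if (length(base) < baseline_n) {
    warn("episode excluded: fewer baseline beats than required")
    return(NA_real_)
  }
  if (length(post) < 4) {
    warn("episode excluded: fewer than 4 post-release beats")
    return(NA_real_)
  }
  baseline <- mean(tail(base, baseline_n))
  if (!is.finite(baseline) || baseline == 0) abort("zero or non-finite baseline")
  response <- mean(post[2:4])  # first post-release peak ignored
  response / baseline
}

#' Summarise THRT episodes into a session THRR result
#'
#' The per-side THRR is the mean over episodes with all validity flags
#' true; a side is classified `preserved` when its THRR is at least
#' 1.10 (a flow increase >9% of baseline systolic velocity), otherwise
#' `impaired`. Sides with no valid episode yield the explicit "not
#' obtainable" outcome, with the failed flags listed in the audit trail.
#'
#' @param episodes Episode tibble from [find_compressions()] (both sides
#'   may be mixed; grouped by `side`).
#' @param baseline_n Passed to [compute_thrr()].
#' @param threshold Preserved-CA threshold (default 1.10, inclusive).
#' @return A `ca_thrr` object: `episodes` (with per-episode `thrr` and
#'   `valid`), `sides` summary tibble, `obtainable`.
#' @export
session_thrr <- function(episodes, baseline_n = 5, threshold = 1.10) {
  if (nrow(episodes) == 0) {
    return(structure(list(episodes = episodes,
                          sides = tibble(side = character(0)),
                          obtainable = FALSE,
                          params = list(threshold = threshold)),
                     class = "ca_thrr"))
  }
  eps <- episodes
  eps$thrr <- vapply(seq_len(nrow(eps)), function(i) {
    tryCatch(suppressWarnings(compute_thrr(eps[i, ], baseline_n)),
             error = function(e) NA_real_)
  }, numeric(1))
  eps$valid <- eps$drop_ok & eps$duration_ok & eps$spacing_ok &
    eps$signal_ok & is.finite(eps$thrr)
  eps$failed_flags <- vapply(seq_len(nrow(eps)), function(i) {
    f <- c(drop_ok = eps$drop_ok[i], duration_ok = eps$duration_ok[i],
           spacing_ok = eps$spacing_ok[i], signal_ok = eps$signal_ok[i])
    paste(names(f)[!f], collapse = ",")
  }, character(1))

  sides <- dplyr::group_by(eps, .data$side)
  sides <- dplyr::summarise(
    sides,
    n_episodes = dplyr::n(),
    n_valid = sum(.data$valid),
    thrr = ifelse(sum(.data$valid) > 0, mean(.data$thrr[.data$valid]),
                  NA_real_),
    .groups = "drop"
  )
  sides$classification <- dplyr::case_when(
    sides$n_valid == 0 ~ "not_obtainable",
    sides$thrr >= threshold ~ "preserved",
    TRUE ~ "impaired"
  )
  structure(list(episodes = eps, sides = sides,
                 obtainable = any(sides$n_valid > 0),
                 params = list(threshold = threshold,
                               baseline_n = baseline_n)),
            class = "ca_thrr")
}

#' Compute THRR from a waveform recording
#'
#' Convenience wrapper: artefact detection, beat detection on each
#' flow-velocity channel, episode construction (from annotations when
#' given, else auto-detection), per-episode THRR and session summary.
#'
#' @param rec A `ca_recording`.
#' @param annotations Optional annotation tibble (`side`, `start_s`,
#'   `end_s`); `side` selects the channel (`left` = `fvl`).
#' @param auto Auto-detect compressions when no annotations are given.
#' @param baseline_n,threshold See [session_thrr()].
#' @param detect Run [detect_artefacts()] first.
#' @return A `ca_thrr` object.
#' @export
thrr <- function(rec, annotations = NULL, auto = TRUE, baseline_n = 5,
                 threshold = 1.10, detect = TRUE) {
  if (detect) rec <- detect_artefacts(rec)
  side_chan <- c(left = "fvl", right = "fvr")
  sides_present <- names(side_chan)[side_chan %in% wf_channels(rec)]

  all_eps <- purrr::map(sides_present, function(sd) {
    ch <- side_chan[[sd]]
    ann_side <- NULL
    if (!is.null(annotations)) {
      ann <- as_tibble(annotations)
      ann_side <- if ("side" %in% names(ann)) ann[ann$side == sd, ] else ann
      if (nrow(ann_side) == 0) return(empty_episodes())
    } else if (!auto) {
      return(empty_episodes())
    }
    beats <- detect_beats(rec, ch)
    find_compressions(beats, annotations = ann_side, side = sd,
                      baseline_n = baseline_n)
  })
  session_thrr(dplyr::bind_rows(all_eps), baseline_n, threshold)
}

#' @export
print.ca_thrr <- function(x, ...) {
  cat("<ca_thrr>\n")
  if (!x$obtainable) {
    cat("  THRR not obtainable (no valid episodes)\n")
    if (nrow(x$episodes) > 0) {
      cat("  failed flags:",
          paste(unique(x$episodes$failed_flags), collapse = "; "), "\n")
    }
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$sides))) {
    s <- x$sides[i, ]
    cat(sprintf("  %s: THRR = %.3f (%d/%d valid episodes) [%s]\n",
                s$side, s$thrr, s$n_valid, s$n_episodes, s$classification))
  }
  cat(sprintf("  threshold >= %.2f for preserved CA\n", x$params$threshold))
  invisible(x)
}
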