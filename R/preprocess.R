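#' Detect artefacts in a waveform recording
#'
#' Flags, per channel, samples that are physiologically implausible or
#' look like measurement failures:
#' * values outside the channel limits (defaults: ABP outside
#'   \[20, 300\] mm Hg; flow velocity not in (0, 150\] cm/s — the MCA
#'   velocity of healthy adults is about 55 +/- 12 cm/s, so these limits
#'   bracket physiology with wide margins),
#' * flatline runs of at least `flatline_s` seconds with zero variance,
#' * isolated spikes more than `spike_k` robust SDs from a 1-s rolling
#'   median.
#'
#' The returned mask is the union of these rules with any pre-existing
#' mask on the recording.
#'
#' @param rec A `ca_recording`.
#' @param limits Named list of `c(lo, hi)` per channel; FV limits are
#'   open at zero (a zero velocity is a dropout, not flow).
#' @param flatline_s Minimum zero-variance run length flagged, seconds.
#' @param spike_k Robust-SD multiple for the spike rule.
#' @return The recording with updated `*_art` mask columns.
#' @export
detect_artefacts <- function(rec,
                             limits = list(abp = c(20, 300),
                                           fvl = c(0, 150),
                                           fvr = c(0, 150)),
                             flatline_s = 2, spike_k = 5) {
  if (nrow(rec) == 0) abort("recording is empty")
  fs <- wf_fs(rec)
  for (ch in wf_channels(rec)) {
    x <- rec[[ch]]
    lim <- limits[[ch]] %||% c(-Inf, Inf)
    open_lo <- ch %in% c("fvl", "fvr")  # FV range is (0, hi]
    m <- if (open_lo) x <= lim[1] | x > lim[2] else x < lim[1] | x > lim[2]
    m <- m | !is.finite(x)

    # flatline: runs of identical consecutive values >= flatline_s
    same <- c(FALSE, diff(x) == 0)
    runs <- true_runs(same)
    min_run <- round(flatline_s * fs) - 1L
    for (j in which(runs$end - runs$start + 1L >= min_run)) {
      m[(runs$start[j] - 1L):runs$end[j]] <- TRUE
    }

    # isolated spikes vs 1-s rolling median
    k <- round(fs)
    if (k %% 2 == 0) k <- k + 1L
    if (length(x) > k) {
      med <- runmed(x, k, endrule = "median")
      resid <- x - med
      s <- mad(resid)
      if (s > 0) m <- m | abs(resid) > spike_k * s
    }
    rec[[mask_col(ch)]] <- rec[[mask_col(ch)]] | m
  }
  rec
}

#' Detect cardiac beats in a channel
#'
#' Locates systolic peaks as local maxima with prominence at least
#' `prominence_frac` of the rolling pulse amplitude, separated by a
#' refractory period of `refractory_s`. The diastolic value of a beat is
#' the minimum between consecutive systolic peaks; the per-beat mean is
#' the mean of samples within the beat interval. Beats whose interval
#' overlaps any masked sample are flagged invalid, as are beats with an
#' implausible interval (outside 0.3–2 s).
#'
#' @param rec A `ca_recording` (or plain tibble with a `time_s` column).
#' @param channel Channel name, e.g. `"fvl"`.
#' @param refractory_s Minimum spacing between systolic peaks, seconds.
#' @param prominence_frac Required peak prominence as a fraction of the
#'   local pulse amplitude.
#' @return A `ca_beats` tibble: `onset_s`, `peak_s`, `systolic`,
#'   `diastolic`, `mean`, `interval_s`, `valid`.
#' @export
detect_beats <- function(rec, channel, refractory_s = 0.3,
                         prominence_frac = 0.25) {
  fs <- wf_fs(rec)
  x <- rec[[channel]]
  if (is.null(x)) abort(paste0("no channel `", channel, "` in recording"))
  msk <- rec[[mask_col(channel)]] %||% rep(FALSE, length(x))
  if (all(msk)) {
    warn(paste0("channel `", channel, "` fully masked; no beats detected"))
    return(empty_beats())
  }
  if (sum(!msk) < 10 * fs) abort("need at least 10 s of unmasked signal")

  # local pulse amplitude on a coarse 2-s grid, linearly interpolated
  seg <- ceiling(2 * fs)
  n <- length(x)
  starts <- seq(1L, n, by = seg)
  amp <- vapply(starts, function(s) {
    w <- x[s:min(s + seg - 1L, n)]
    diff(range(w))
  }, numeric(1))
  centers <- pmin(starts + seg / 2, n)
  local_amp <- approx(centers, amp, xout = seq_len(n), rule = 2)$y

  # candidate local maxima
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  refr <- round(refractory_s * fs)

  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last < refr) {
      # within refractory: keep the higher of the two
      if (length(peaks) && x[i] > x[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        last <- i
      }
      next
    }
    peaks <- c(peaks, i)
    last <- i
  }
  if (length(peaks) < 2) return(empty_beats())

  # prominence: peak height above the higher of the minima to either side
  keep <- rep(TRUE, length(peaks))
  for (j in seq_along(peaks)) {
    lo_l <- if (j == 1) min(x[1:peaks[1]]) else min(x[peaks[j - 1]:peaks[j]])
    lo_r <- if (j == length(peaks)) min(x[peaks[j]:n])
            else min(x[peaks[j]:peaks[j + 1]])
    prom <- x[peaks[j]] - max(lo_l, lo_r)
    keep[j] <- prom >= prominence_frac * local_amp[peaks[j]]
  }
  peaks <- peaks[keep]
  if (length(peaks) < 2) return(empty_beats())

  t <- rec$time_s
  # beat interval: from one systolic peak's preceding trough to the next's
  troughs <- vapply(seq_len(length(peaks) - 1L), function(j) {
    seg_idx <- peaks[j]:peaks[j + 1]
    seg_idx[which.min(x[seg_idx])]
  }, integer(1))
  onset_idx <- c(max(1L, 2L * peaks[1] - troughs[1]), troughs)
  onset_idx[1] <- max(1L, min(onset_idx[1], peaks[1]))

  n_beats <- length(peaks)
  ends <- c(troughs, n)
  systolic <- x[peaks]
  diastolic <- x[ends]
  bmean <- vapply(seq_len(n_beats), function(j) {
    mean(x[onset_idx[j]:ends[j]])
  }, numeric(1))
  overlap_mask <- vapply(seq_len(n_beats), function(j) {
    any(msk[onset_idx[j]:ends[j]])
  }, logical(1))
  interval <- c(diff(t[peaks]), NA_real_)

  out <- tibble(
    onset_s = t[onset_idx], peak_s = t[peaks],
    systolic = systolic, diastolic = diastolic, mean = bmean,
    interval_s = interval,
    valid = !overlap_mask &
      (is.na(interval) | (interval >= 0.3 & interval <= 2.0))
  )
  class(out) <- c("ca_beats", class(out))
  out
}

empty_beats <- function() {
  out <- tibble(onset_s = numeric(0), peak_s = numeric(0),
                systolic = numeric(0), diastolic = numeric(0),
                mean = numeric(0), interval_s = numeric(0),
                valid = logical(0))
  class(out) <- c("ca_beats", class(out))
  out
}

#' Block-average a channel into a slow-wave surrogate
#'
#' Averages unmasked samples over consecutive non-overlapping blocks
#' (default 10 s) anchored at the recording start. Block means suppress
#' the cardiac and respiratory bands while retaining slow waves in
#' roughly the 0.005–0.05 Hz band; this is the conventional Mx-family
#' slow-wave surrogate. A block is invalid when its fraction of unmasked
#' samples falls below `min_valid_frac`.
#'
#' @param rec A `ca_recording`.
#' @param channel Channel name.
#' @param block_len_s Block length, seconds (default 10).
#' @param min_valid_frac Minimum unmasked fraction for a valid block.
#' @return A `ca_blocks` tibble: `start_s`, `mean`, `valid_frac`,
#'   `valid`; block length carried as attribute `block_len_s`.
#' @export
block_average <- function(rec, channel, block_len_s = 10,
                          min_valid_frac = 0.5) {
  if (!is.numeric(block_len_s) || block_len_s <= 0) {
    abort("`block_len_s` must be positive")
  }
  fs <- wf_fs(rec)
  if (fs * block_len_s < 1) abort("block shorter than one sample")
  x <- rec[[channel]]
  if (is.null(x)) abort(paste0("no channel `", channel, "` in recording"))
  msk <- rec[[mask_col(channel)]] %||% rep(FALSE, length(x))

  len <- round(block_len_s * fs)
  n_blocks <- floor(length(x) / len)
  idx <- factor(rep(seq_len(n_blocks), each = len), levels = seq_len(n_blocks))
  xs <- x[seq_len(n_blocks * len)]
  ms <- msk[seq_len(n_blocks * len)]
  xs[ms] <- NA_real_

  valid_n <- tapply(!ms, idx, sum)
  sums <- tapply(ifelse(is.na(xs), 0, xs), idx, sum)
  bmean <- as.numeric(sums) / as.numeric(valid_n)
  bmean[valid_n == 0] <- NA_real_
  valid_frac <- as.numeric(valid_n) / len

  out <- tibble(
    start_s = rec$time_s[1] + (seq_len(n_blocks) - 1) * block_len_s,
    mean = bmean,
    valid_frac = valid_frac,
    valid = valid_frac >= min_valid_frac & is.finite(bmean)
  )
  attr(out, "block_len_s") <- block_len_s
  class(out) <- c("ca_blocks", class(out))
  out
}
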