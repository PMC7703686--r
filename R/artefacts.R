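#' Artefact injection specification
#'
#' Describes the artefact load added to a synthetic recording: signal
#' dropouts (channel falls to zero, as when a TCD probe loses the
#' insonation window), isolated spikes, and an optional baseline
#' step-change. Event counts are deterministic — `round(rate *
#' minutes)` per channel — with only the placements drawn from the
#' artefact RNG substream, so a stated rate yields a reproducible,
#' enumerable artefact load at any seed.
#'
#' @param dropout_rate Dropout events per minute, per channel.
#' @param dropout_len_s Length of each dropout, seconds.
#' @param spike_rate Spike events per minute, per channel.
#' @param spike_amp Spike amplitude, multiples of the channel SD.
#' @param shift_prob Probability of one baseline step-change per
#'   recording (on the ABP channel).
#' @param shift_frac Step size as a fraction of the channel mean.
#' @return An `artefact_spec` list.
#' @export
artefact_spec <- function(dropout_rate = 0, dropout_len_s = 2,
                          spike_rate = 0, spike_amp = 8,
                          shift_prob = 0, shift_frac = 0.1) {
  check_num(dropout_rate, "dropout_rate", lo = 0)
  check_num(dropout_len_s, "dropout_len_s", lo = 0)
  check_num(spike_rate, "spike_rate", lo = 0)
  check_num(spike_amp, "spike_amp", lo = 0)
  check_num(shift_prob, "shift_prob", lo = 0, hi = 1)
  check_num(shift_frac, "shift_frac", lo = 0)
  structure(list(dropout_rate = dropout_rate, dropout_len_s = dropout_len_s,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 shift_prob = shift_prob, shift_frac = shift_frac),
            class = "artefact_spec")
}

#' Inject artefacts into a recording
#'
#' Returns a corrupted copy of the recording together with the boolean
#' truth mask of exactly the corrupted samples; uncorrupted samples are
#' bit-identical to the input. The truth mask is also OR-ed into the
#' recording's `*_art` mask columns and stored in `meta$artefact_truth`.
#'
#' @param rec A `ca_recording`.
#' @param spec An [artefact_spec()].
#' @param seed Seed for the artefact RNG substream (defaults to the
#'   simulation seed in `meta`, else 1).
#' @return List with elements `recording` (corrupted copy) and `truth`
#'   (tibble of logical mask columns, one per channel).
#' @export
inject_artefacts <- function(rec, spec = artefact_spec(), seed = NULL) {
  chans <- wf_channels(rec)
  if (length(chans) < 1) abort("recording has no channels")
  if (is.null(seed)) seed <- wf_meta(rec)$config$seed %||% 1L
  n <- nrow(rec)
  fs <- wf_fs(rec)
  minutes <- n / fs / 60

  truth <- as_tibble(stats::setNames(
    replicate(length(chans), rep(FALSE, n), simplify = FALSE), chans))
  out <- rec

  with_substream(seed, "artefacts", {
    for (ch in chans) {
      x <- out[[ch]]
      m <- truth[[ch]]
      n_drop <- round(spec$dropout_rate * minutes)
      if (n_drop > 0) {
        len <- round(spec$dropout_len_s * fs)
        # rejection-sample non-overlapping starts (dropouts are disjoint
        # events); deterministic under the substream seed
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < n_drop && tries < 1000L) {
          cand <- sample.int(max(n - len, 1L), 1L)
          if (!any(abs(cand - starts) < len)) starts <- c(starts, cand)
          tries <- tries + 1L
        }
        starts <- sort(starts)
        for (s in starts) {
          idx <- s:min(s + len - 1L, n)
          x[idx] <- 0
          m[idx] <- TRUE
        }
      }
      n_spike <- round(spec$spike_rate * minutes)
      if (n_spike > 0) {
        pos <- sample.int(n, n_spike)
        x[pos] <- x[pos] + spec$spike_amp * sd(rec[[ch]]) *
          sample(c(-1, 1), n_spike, replace = TRUE)
        m[pos] <- TRUE
      }
      out[[ch]] <- x
      truth[[ch]] <- m
    }
    if (spec$shift_prob > 0 && runif(1) < spec$shift_prob) {
      ch <- chans[[1]]
      from <- sample.int(n, 1)
      out[[ch]][from:n] <- out[[ch]][from:n] +
        spec$shift_frac * mean(rec[[ch]]) * sample(c(-1, 1), 1)
      truth[[ch]][from:n] <- TRUE
    }
  })

  for (ch in chans) {
    out[[mask_col(ch)]] <- out[[mask_col(ch)]] | truth[[ch]]
  }
  meta <- wf_meta(out)
  meta$artefact_truth <- truth
  attr(out, "meta") <- meta
  list(recording = out, truth = truth)
}
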