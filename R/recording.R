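#' Waveform recording container
#'
#' A recording is a tibble with one row per sample and columns `time_s`
#' (seconds from recording start, 0-based), one column per channel
#' (`abp` in mm Hg, `fvl` / `fvr` in cm/s), and one logical artefact-mask
#' column per channel (`abp_art`, `fvl_art`, `fvr_art`; `TRUE` marks a
#' corrupted sample). The sampling rate (Hz) and provenance metadata are
#' carried as attributes `fs` and `meta`.
#'
#' @param time_s Sample times, strictly increasing at `1/fs` spacing.
#' @param channels Named list of numeric channel vectors, all equal length.
#' @param fs Sampling rate in Hz.
#' @param masks Optional named list of logical artefact masks (default all
#'   `FALSE`); names must match `channels`.
#' @param meta List of provenance metadata (e.g. the simulation config).
#' @return A `ca_recording` tibble.
#' @export
new_recording <- function(time_s, channels, fs, masks = NULL, meta = list()) {
  check_num(fs, "fs", lo = 0, strict_lo = TRUE)
  n <- length(time_s)
  if (n == 0) abort("recording must contain at least one sample")
  lens <- vapply(channels, length, integer(1))
  if (any(lens != n)) abort("all channels must have the same length as `time_s`")
  if (is.null(masks)) masks <- lapply(channels, function(ch) rep(FALSE, n))
  if (!setequal(names(masks), names(channels))) {
    abort("mask names must match channel names")
  }
  if (any(vapply(masks, length, integer(1)) != n)) {
    abort("mask length must equal channel length")
  }
  out <- tibble(time_s = as.numeric(time_s))
  for (nm in names(channels)) out[[nm]] <- as.numeric(channels[[nm]])
  for (nm in names(channels)) out[[paste0(nm, "_art")]] <- as.logical(masks[[nm]])
  attr(out, "fs") <- fs
  attr(out, "meta") <- meta
  class(out) <- c("ca_recording", class(out))
  out
}

#' Sampling rate of a recording
#' @param rec A `ca_recording` (or any tibble with an `fs` attribute).
#' @return Sampling rate in Hz.
#' @export
wf_fs <- function(rec) {
  fs <- attr(rec, "fs", exact = TRUE)
  if (is.null(fs)) {
    if (nrow(rec) < 2) abort("cannot infer `fs`: recording has no `fs` attribute")
    fs <- 1 / median(diff(rec$time_s))
  }
  fs
}

wf_meta <- function(rec) attr(rec, "meta", exact = TRUE) %||% list()

# Channel names present in a recording (columns with a *_art companion).
wf_channels <- function(rec) {
  nms <- names(rec)
  art <- grep("_art$", nms, value = TRUE)
  sub("_art$", "", art)
}

mask_col <- function(channel) paste0(channel, "_art")

#' @export
print.ca_recording <- function(x, ...) {
  fs <- wf_fs(x)
  cat(sprintf("<ca_recording> %d samples @ %g Hz (%.1f s), channels: %s\n",
              nrow(x), fs, nrow(x) / fs,
              paste(wf_channels(x), collapse = ", ")))
  NextMethod()
}

#' Plot a waveform recording
#'
#' Channels are faceted on a common time axis; masked (artefact) samples
#' are drawn in red.
#'
#' @param object A `ca_recording`.
#' @param max_points Downsample to at most this many points per channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_recording
#' @export
autoplot.ca_recording <- function(object, max_points = 20000, ...) {
  chans <- wf_channels(object)
  df <- dplyr::select(as_tibble(object), "time_s", dplyr::all_of(chans),
                      dplyr::all_of(mask_col(chans)))
  thin <- max(1L, floor(nrow(df) / max_points))
  df <- df[seq(1L, nrow(df), by = thin), ]
  long <- tidyr::pivot_longer(df, dplyr::all_of(chans),
                              names_to = "channel", values_to = "value")
  long$masked <- purrr::map2_lgl(long$channel, seq_len(nrow(long)),
                                 function(ch, i) long[[mask_col(ch)]][i])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_point(data = function(d) d[d$masked, ],
                        colour = "red", size = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
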