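#' Write a waveform recording to a tabular text file
#'
#' The format is tab-separated text with a structured `#`-prefixed
#' header declaring sampling rate, start offset, channel names and
#' units, followed by columns `time_s`, `abp_mmHg`, `fvl_cms`,
#' `fvr_cms`. Masked samples are written as empty fields. Values are
#' written with 17 significant digits so a read/write round trip is
#' bit-exact for finite values.
#'
#' @param rec A `ca_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(rec, path) {
  chans <- wf_channels(rec)
  units <- c(abp = "mmHg", fvl = "cm/s", fvr = "cm/s")[chans]
  colnames_out <- paste0(chans, "_", sub("/", "", units))
  header <- c(
    "# caindex waveform v1",
    sprintf("# fs_hz: %.17g", wf_fs(rec)),
    sprintf("# start_s: %.17g", rec$time_s[1]),
    sprintf("# channels: %s", paste(colnames_out, collapse = ",")),
    sprintf("# units: %s", paste(units, collapse = ","))
  )
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  cols <- c(list(fmt(rec$time_s)),
            purrr::map(chans, function(ch) {
              v <- rec[[ch]]
              v[rec[[mask_col(ch)]]] <- NA_real_
              fmt(v)
            }))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, paste(c("time_s", colnames_out), collapse = "\t"), body),
             path)
  invisible(path)
}

#' Read a waveform recording from a tabular text file
#'
#' Reads the format written by [write_waveform()]. The artefact mask is
#' initialised from missing (empty) values; sampling rate is taken from
#' the header and verified against the time column (uniform `1/fs`
#' spacing within 1e-6 s).
#'
#' @param path File path.
#' @return A `ca_recording`.
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0 || !grepl("caindex waveform", hdr[1])) {
    abort(paste0("malformed header in ", path, ": missing format line"))
  }
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1) abort(paste0("malformed header: missing `", key, "`"))
    sub(paste0("^# ", key, ":\\s*"), "", ln)
  }
  fs <- as.numeric(get_field("fs_hz"))
  if (!is.finite(fs) || fs <= 0) abort("malformed header: bad fs_hz")

  # base strtod parsing: correctly rounded, so the %.17g round trip is
  # bit-exact
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          colClasses = "numeric")
  df <- as_tibble(df)
  if (!"time_s" %in% names(df)) abort("malformed file: no time_s column")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) abort("timestamps not strictly increasing")
  if (any(abs(dt - 1 / fs) > 1e-6)) {
    bad <- which(abs(dt - 1 / fs) > 1e-6)[1]
    abort(sprintf(
      "timestamps inconsistent with header fs=%g Hz near row %d", fs, bad + 1))
  }

  chan_cols <- setdiff(names(df), "time_s")
  short <- sub("_[^_]*$", "", chan_cols)
  channels <- purrr::map(chan_cols, function(cc) {
    v <- df[[cc]]
    v[is.na(v)] <- 0
    v
  })
  names(channels) <- short
  masks <- purrr::map(chan_cols, function(cc) is.na(df[[cc]]))
  names(masks) <- short
  new_recording(df$time_s, channels, fs, masks,
                meta = list(source = path))
}

#' Read / write THRT annotation files
#'
#' Annotations are tab-separated with columns `side` (`left`/`right`),
#' `start_s`, `end_s` — seconds from recording start, half-open
#' intervals.
#'
#' @param path File path.
#' @return For `read_annotations()`, a tibble of intervals.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("side", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    abort("annotation file needs columns side, start_s, end_s")
  }
  if (any(df$end_s <= df$start_s)) abort("annotation intervals must have end_s > start_s")
  df
}

#' @rdname read_annotations
#' @param annotations Tibble with columns `side`, `start_s`, `end_s`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("side", "start_s", "end_s")], path,
                   progress = FALSE)
  invisible(path)
}
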