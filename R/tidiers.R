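#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an nMxa result
#'
#' One row per moving window, with its side, placement, valid-block
#' count and Pearson correlation.
#'
#' @param x A `ca_nmxa` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ca_nmxa
#' @export
tidy.ca_nmxa <- function(x, ...) {
  dplyr::bind_rows(x$windows, .id = "side")
}

#' One-row summary of an nMxa result
#' @param x A `ca_nmxa` object.
#' @param ... Unused.
#' @return A one-row tibble: combined nMxa, classification, window
#'   counts, threshold.
#' @method glance ca_nmxa
#' @export
glance.ca_nmxa <- function(x, ...) {
  tibble(
    nmxa = x$combined,
    classification = x$combined_classification,
    obtainable = x$obtainable,
    n_windows = sum(x$sides$n_windows),
    n_sides = sum(is.finite(x$sides$nmxa)),
    threshold = x$params$threshold
  )
}

#' Tidy a THRR result
#'
#' One row per compression episode with its ratio and validity flags.
#' @param x A `ca_thrr` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ca_thrr
#' @export
tidy.ca_thrr <- function(x, ...) {
  eps <- x$episodes
  if (nrow(eps) == 0) return(as_tibble(eps))
  dplyr::select(eps, "side", "start_s", "end_s", "thrr", "valid",
                "drop_ok", "duration_ok", "spacing_ok", "signal_ok",
                "failed_flags", "source")
}

#' One-row-per-side summary of a THRR result
#' @param x A `ca_thrr` object.
#' @param ... Unused.
#' @return A tibble with per-side THRR and classification.
#' @method glance ca_thrr
#' @export
glance.ca_thrr <- function(x, ...) {
  if (nrow(x$sides) == 0) {
    return(tibble(side = NA_character_, thrr = NA_real_,
                  classification = "not_obtainable", n_episodes = 0L,
                  n_valid = 0L))
  }
  x$sides
}

#' Plot per-window nMxa correlations over time
#'
#' Window Pearson correlations per side against window start time, with
#' the dysfunction threshold and the per-side summary drawn as
#' reference lines.
#'
#' @param object A `ca_nmxa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_nmxa
#' @export
autoplot.ca_nmxa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_s, y = .data$r,
                                   colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(data = object$sides,
                        ggplot2::aes(yintercept = .data$nmxa,
                                     colour = .data$side),
                        alpha = 0.5) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "window start (s)", y = "window Pearson r",
                  title = "Moving-window ABP~CBFV correlation (nMxa)")
}

#' Plot THRT episodes
#'
#' Per-episode THRR by side with the preserved-autoregulation boundary.
#'
#' @param object A `ca_thrr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_thrr
#' @export
autoplot.ca_thrr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_s, y = .data$thrr,
                                   shape = .data$valid,
                                   colour = .data$side)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "compression start (s)", y = "episode THRR",
                  title = "Transient hyperaemic response ratios")
}
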