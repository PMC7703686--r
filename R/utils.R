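#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor median rnorm runif rpois sd mad qnorm approx runmed
#' @importFrom utils head tail
## usethis namespace: end
NULL

# Scalar validation helper: every validation error names the offending field.
check_num <- function(x, field, lo = -Inf, hi = Inf, len = 1L,
                      strict_lo = FALSE, strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric of length %d", field, len))
  }
  bad_lo <- if (strict_lo) any(x <= lo) else any(x < lo)
  bad_hi <- if (strict_hi) any(x >= hi) else any(x > hi)
  if (bad_lo || bad_hi) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s (got %s)", field,
      if (strict_lo) "(" else "[", lo, hi, if (strict_hi) ")" else "]",
      paste(signif(x, 6), collapse = ", ")
    ))
  }
  invisible(x)
}

# Named RNG substreams derived from one global seed, so toggling one
# component (artefacts, say) leaves the others' draws untouched.
substream_seed <- function(seed, stream) {
  offsets <- c(abp = 11L, fv_left = 23L, fv_right = 37L,
               artefacts = 53L, thrt = 71L)
  if (!stream %in% names(offsets)) abort(paste0("unknown RNG stream: ", stream))
  (as.integer(seed) %% 1000003L) * 1009L + offsets[[stream]]
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}

# Runs of TRUE in a logical vector, as a tibble of [start, end] indices.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}
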