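#' THRT session simulation specification
#'
#' Parameters of simulated transient-hyperaemic-response-test sessions:
#' brief unilateral carotid compressions (alternating left/right) that
#' drop systolic flow velocity on the compressed side, followed on
#' release by a transient hyperaemic overshoot decaying back to
#' baseline. Compressions last 5–7 s and are spaced at least a minute
#' apart so the autoregulatory system recovers between tests.
#'
#' @param n_compressions Number of compressions (default 4: two per side).
#' @param compression_len_s Compression length, seconds, in \[5, 7\].
#' @param spacing_s Gap between the end of one compression and the start
#'   of the next, seconds, at least 60.
#' @param drop_frac Fractional reduction of systolic flow velocity during
#'   compression (default 0.35, beyond the >30% validity requirement).
#' @param overshoot_frac Post-release hyperaemic excess `h`: systolic
#'   peaks immediately after release reach about `(1 + h) * baseline`.
#' @param recovery_tau_s Exponential decay constant of the overshoot,
#'   seconds. Long relative to a few beats, so the assessed peaks 2–4
#'   still carry close to the full overshoot.
#' @param lead_in_s Baseline recording before the first compression.
#' @return A `thrt_sim_spec` list.
#' @export
sim_thrt_spec <- function(n_compressions = 4, compression_len_s = 6,
                          spacing_s = 60, drop_frac = 0.35,
                          overshoot_frac = 0.15, recovery_tau_s = 60,
                          lead_in_s = 60) {
  check_num(n_compressions, "n_compressions", lo = 1)
  check_num(compression_len_s, "compression_len_s", lo = 0, strict_lo = TRUE)
  check_num(spacing_s, "spacing_s", lo = 60)
  check_num(drop_frac, "drop_frac", lo = 0, hi = 1,
            strict_lo = TRUE, strict_hi = TRUE)
  check_num(overshoot_frac, "overshoot_frac", lo = 0)
  check_num(recovery_tau_s, "recovery_tau_s", lo = 0)
  check_num(lead_in_s, "lead_in_s", lo = 0)
  structure(list(n_compressions = as.integer(n_compressions),
                 compression_len_s = compression_len_s,
                 spacing_s = spacing_s, drop_frac = drop_frac,
                 overshoot_frac = overshoot_frac,
                 recovery_tau_s = recovery_tau_s, lead_in_s = lead_in_s),
            class = "thrt_sim_spec")
}

#' Simulate a THRT compression session
#'
#' Generates a base recording with [sim_recording()] and modulates the
#' flow-velocity channel of the compressed side over each compression:
#' a smooth drop to `(1 - drop_frac)` of the running signal during the
#' compression, then a multiplicative overshoot
#' `1 + h * exp(-(t - release) / recovery_tau_s)` after release. Sides
#' alternate left, right, left, right. The contralateral channel is
#' untouched.
#'
#' @param config A [sim_config()]; its `duration_s` is overridden to fit
#'   the session if too short.
#' @param spec A [sim_thrt_spec()].
#' @return List with `recording` (a `ca_recording`) and `episodes`
#'   (tibble of truth intervals: `side`, `start_s`, `end_s`, half-open).
#' @export
sim_thrt_session <- function(config = sim_config(duration_s = 420),
                             spec = sim_thrt_spec()) {
  if (!inherits(spec, "thrt_sim_spec")) abort("`spec` must be a sim_thrt_spec()")
  need <- spec$lead_in_s +
    spec$n_compressions * (spec$compression_len_s + spec$spacing_s)
  if (config$duration_s < need) {
    config$duration_s <- need
  }
  rec <- sim_recording(config)
  t <- rec$time_s

  starts <- spec$lead_in_s +
    (seq_len(spec$n_compressions) - 1) * (spec$compression_len_s + spec$spacing_s)
  ends <- starts + spec$compression_len_s
  sides <- rep(c("left", "right"), length.out = spec$n_compressions)

  ramp_s <- 0.3  # compression onset/offset ramp
  for (i in seq_len(spec$n_compressions)) {
    ch <- if (sides[i] == "left") "fvl" else "fvr"
    mult <- rep(1, length(t))
    inside <- t >= starts[i] & t < ends[i]
    # cosine ramp down/up at the interval edges
    u <- pmin(pmax((t - starts[i]) / ramp_s, 0), 1)
    v <- pmin(pmax((ends[i] - t) / ramp_s, 0), 1)
    depth <- spec$drop_frac * (1 - cos(pi * pmin(u, v))) / 2
    mult[inside] <- 1 - depth[inside]
    # overshoot runs until the next compression starts: the 1-min spacing
    # exists precisely so the system has recovered by the next test
    recover_until <- if (i < spec$n_compressions) starts[i + 1] else max(t) + 1
    after <- t >= ends[i] & t < recover_until
    if (spec$overshoot_frac > 0) {
      dt <- t[after] - ends[i]
      decay <- if (spec$recovery_tau_s > 0) exp(-dt / spec$recovery_tau_s) else 0
      mult[after] <- mult[after] * (1 + spec$overshoot_frac * decay)
    }
    rec[[ch]] <- rec[[ch]] * mult
  }

  episodes <- tibble(side = sides, start_s = starts, end_s = ends)
  meta <- wf_meta(rec)
  meta$truth$thrt_episodes <- episodes
  meta$truth$overshoot_frac <- spec$overshoot_frac
  attr(rec, "meta") <- meta
  list(recording = rec, episodes = episodes)
}
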