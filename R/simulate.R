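#' Synthetic hemodynamic recording configuration
#'
#' Parameterises the synthetic generator for paired arterial blood
#' pressure (ABP) and bilateral middle-cerebral-artery flow-velocity
#' (FVL/FVR) waveforms. The generator writes down the ground truth the
#' analysis is later asked to recover: the coupling gain `g` sets how
#' pressure-passive the cerebral circulation is.
#'
#' The flow-velocity slow-wave component is
#' `g * (fv_mean / abp_mean) * ABP_slow + (1 - g) * intrinsic`, where
#' `intrinsic` is a slow fluctuation independent of pressure. `g = 1` is
#' fully pressure-passive (impaired autoregulation), `g = 0` fully
#' decoupled (intact autoregulation). Slow waves live in the
#' 0.005–0.05 Hz band; cardiac pulsatility rides on top of all channels.
#'
#' The default parameterisation is the package's "healthy" condition:
#' its coupling gain and noise were calibrated once so that the cohort
#' mean nMxa of default recordings matches the published healthy-adult
#' mean of 0.21 (SD 0.16).
#'
#' @param duration_s Recording length, seconds (default 2400 = 40 min).
#' @param fs Sampling rate, Hz (default 125).
#' @param hr_bpm Mean heart rate, beats/min.
#' @param hr_jitter Fractional i.i.d. perturbation of beat intervals.
#' @param abp_mean Mean arterial pressure, mm Hg.
#' @param abp_pulse_amp Systolic-minus-diastolic ABP excursion, mm Hg.
#' @param slow_waves Data frame with columns `freq_hz` (each in
#'   \[0.005, 0.05\]), `amp` (mm Hg) and `phase` (rad): the ABP slow-wave
#'   lines.
#' @param resp_wave Optional `c(freq_hz, amp)` respiratory line; `NULL`
#'   (default) disables it.
#' @param fv_mean Mean flow velocity, cm/s (default 55, the plausible MCA
#'   value).
#' @param fv_pulse_amp Systolic-minus-diastolic FV excursion, cm/s.
#' @param coupling_gain Pressure-passivity gain `g` in \[0, 1\].
#' @param intrinsic_slow_amp Standard deviation (cm/s) of the intrinsic
#'   (pressure-independent) slow fluctuation of each FV channel.
#' @param noise_sd White measurement noise SD on FV channels, cm/s.
#' @param artefact_spec An [artefact_spec()]; default injects nothing.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @seealso [sim_recording()], [sim_thrt_session()]
#' @export
sim_config <- function(duration_s = 2400, fs = 125,
                       hr_bpm = 70, hr_jitter = 0.03,
                       abp_mean = 90, abp_pulse_amp = 40,
                       slow_waves = default_slow_waves(),
                       resp_wave = NULL,
                       fv_mean = 55, fv_pulse_amp = 30,
                       coupling_gain = 0.15, intrinsic_slow_amp = 1.2,
                       noise_sd = 0.5,
                       artefact_spec = caindex::artefact_spec(),
                       seed = 1L) {
  check_num(duration_s, "duration_s", lo = 0, strict_lo = TRUE)
  check_num(fs, "fs", lo = 0, strict_lo = TRUE)
  check_num(hr_bpm, "hr_bpm", lo = 20, hi = 250)
  check_num(hr_jitter, "hr_jitter", lo = 0, hi = 0.5)
  check_num(abp_mean, "abp_mean", lo = 0, strict_lo = TRUE)
  check_num(abp_pulse_amp, "abp_pulse_amp", lo = 0)
  check_num(fv_mean, "fv_mean", lo = 0, strict_lo = TRUE)
  check_num(fv_pulse_amp, "fv_pulse_amp", lo = 0)
  check_num(coupling_gain, "coupling_gain", lo = 0, hi = 1)
  check_num(intrinsic_slow_amp, "intrinsic_slow_amp", lo = 0)
  check_num(noise_sd, "noise_sd", lo = 0)
  slow_waves <- as_tibble(slow_waves)
  if (!all(c("freq_hz", "amp", "phase") %in% names(slow_waves))) {
    abort("`slow_waves` needs columns freq_hz, amp, phase")
  }
  if (nrow(slow_waves) > 0) {
    check_num(slow_waves$freq_hz, "slow_waves$freq_hz",
              lo = 0.005, hi = 0.05, len = nrow(slow_waves))
    check_num(slow_waves$amp, "slow_waves$amp", lo = 0, len = nrow(slow_waves))
  }
  if (!is.null(resp_wave)) check_num(resp_wave, "resp_wave", len = 2, lo = 0)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer")
  }
  structure(list(
    duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, hr_jitter = hr_jitter,
    abp_mean = abp_mean, abp_pulse_amp = abp_pulse_amp,
    slow_waves = slow_waves, resp_wave = resp_wave,
    fv_mean = fv_mean, fv_pulse_amp = fv_pulse_amp,
    coupling_gain = coupling_gain, intrinsic_slow_amp = intrinsic_slow_amp,
    noise_sd = noise_sd, artefact_spec = artefact_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default ABP slow-wave lines
#'
#' Three incommensurate lines spread over the 0.005–0.05 Hz band with a
#' few mm Hg of amplitude, the scale of spontaneous slow waves in awake
#' adults.
#' @return Tibble with columns `freq_hz`, `amp`, `phase`.
#' @export
default_slow_waves <- function() {
  tibble(freq_hz = c(0.008, 0.021, 0.043),
         amp     = c(2.0, 1.5, 1.0),
         phase   = c(0, 0, 0))
}

# Asymmetric cardiac pulse template on beat phase u in [0, 1): gamma-like
# fast systolic upstroke, slow diastolic decay. Zero-mean over the cycle,
# unit peak-to-trough, so `mean + amp * template` has the requested mean
# and pulse amplitude.
pulse_template <- function(u) {
  shape <- 3; rate <- 12
  raw <- function(v) v^(shape - 1) * exp(-rate * v)
  grid <- seq(0, 1, length.out = 2049)[-2049]
  g <- raw(grid)
  g <- g - mean(g)
  g <- g / (max(g) - min(g))
  idx <- pmin(floor((u %% 1) * 2048) + 1L, 2048L)
  g[idx]
}

# Peak and mean offsets of the unit template (systolic value =
# mean + amp * pulse_peak_offset()).
pulse_peak_offset <- function() max(pulse_template(seq(0, 1, length.out = 2048)))
pulse_trough_offset <- function() min(pulse_template(seq(0, 1, length.out = 2048)))

# Beat-phase vector for all samples: draws jittered beat intervals, returns
# phase in [0,1) per sample plus the beat onset times.
beat_phase <- function(t, hr_bpm, hr_jitter) {
  t0 <- 60 / hr_bpm
  n_beats <- ceiling(max(t) / (t0 * (1 - min(hr_jitter * 4, 0.5)))) + 2L
  iv <- t0 * (1 + hr_jitter * rnorm(n_beats))
  iv <- pmax(iv, 0.3)
  onsets <- c(0, cumsum(iv))
  beat <- findInterval(t, onsets)
  u <- (t - onsets[beat]) / iv[beat]
  list(u = u, onsets = onsets[seq_len(max(beat) + 1L)])
}

# ABP slow-wave component (deterministic given config).
abp_slow_component <- function(t, config) {
  s <- rep(0, length(t))
  sw <- config$slow_waves
  for (i in seq_len(nrow(sw))) {
    s <- s + sw$amp[i] * sin(2 * pi * sw$freq_hz[i] * t + sw$phase[i])
  }
  if (!is.null(config$resp_wave)) {
    s <- s + config$resp_wave[2] * sin(2 * pi * config$resp_wave[1] * t)
  }
  s
}

# Intrinsic FV slow fluctuation: three sinusoids at random frequencies in
# the slow-wave band with random phases, scaled so the component's
# analytic SD equals `sd_target`.
intrinsic_slow <- function(t, sd_target) {
  if (sd_target <= 0) return(rep(0, length(t)))
  k <- 3
  f <- runif(k, 0.005, 0.05)
  ph <- runif(k, 0, 2 * pi)
  w <- runif(k, 0.5, 1)
  amp <- w * sd_target / sqrt(sum(w^2) / 2)  # sum(amp^2)/2 = sd_target^2
  s <- rep(0, length(t))
  for (i in seq_len(k)) s <- s + amp[i] * sin(2 * pi * f[i] * t + ph[i])
  s
}

#' Generate a synthetic ABP/FVL/FVR recording
#'
#' Builds pressure and bilateral flow-velocity waveforms sampled at
#' `config$fs`: ABP = mean + slow waves + cardiac pulse train; each FV
#' channel = mean + coupled slow component + independent intrinsic slow
#' fluctuation + white noise + cardiac pulsatility (same beat train as
#' ABP, as in one cardiac cycle). Artefacts from `config$artefact_spec`
#' are injected last; the truth mask is stored in the recording's mask
#' columns and in `meta$artefact_truth`.
#'
#' @param config A [sim_config()].
#' @return A `ca_recording`; `meta` carries the config (including the
#'   ground-truth coupling gain) and the artefact truth mask.
#' @export
sim_recording <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs

  bp <- with_substream(config$seed, "abp",
                       beat_phase(t, config$hr_bpm, config$hr_jitter))
  pulse <- pulse_template(bp$u)

  slow_a <- abp_slow_component(t, config)
  abp <- config$abp_mean + slow_a + config$abp_pulse_amp * pulse

  scale <- config$fv_mean / config$abp_mean
  coupled <- config$coupling_gain * scale * slow_a

  mk_fv <- function(stream) {
    with_substream(config$seed, stream, {
      intr <- intrinsic_slow(t, config$intrinsic_slow_amp)
      noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
      config$fv_mean + coupled + (1 - config$coupling_gain) * intr +
        noise + config$fv_pulse_amp * pulse
    })
  }
  fvl <- mk_fv("fv_left")
  fvr <- mk_fv("fv_right")

  rec <- new_recording(
    t, list(abp = abp, fvl = fvl, fvr = fvr), config$fs,
    meta = list(config = config, beat_onsets = bp$onsets,
                truth = list(coupling_gain = config$coupling_gain))
  )
  inject_artefacts(rec, config$artefact_spec, seed = config$seed)$recording
}
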