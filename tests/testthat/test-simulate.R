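test_that("identical config and seed give bit-identical recordings", {
  cfg <- quick_config(42, duration_s = 120)
  r1 <- sim_recording(cfg)
  r2 <- sim_recording(cfg)
  expect_identical(r1$abp, r2$abp)
  expect_identical(r1$fvl, r2$fvl)
  expect_identical(r1$fvr, r2$fvr)
  r3 <- sim_recording(quick_config(43, duration_s = 120))
  expect_false(identical(r1$fvl, r3$fvl))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(coupling_gain = 1.2), "coupling_gain")
  expect_error(sim_config(duration_s = -5), "duration_s")
  expect_error(sim_config(noise_sd = NaN), "noise_sd")
  expect_error(
    sim_config(slow_waves = tibble::tibble(freq_hz = 0.2, amp = 1, phase = 0)),
    "freq_hz")
})

test_that("noiseless pressure-passive limit gives window correlation 1", {
  # slow components only: FV slow is an exact affine image of ABP slow
  cfg <- quick_config(1, duration_s = 600, coupling_gain = 1,
                      intrinsic_slow_amp = 0, noise_sd = 0,
                      abp_pulse_amp = 0, fv_pulse_amp = 0)
  rec <- sim_recording(cfg)
  a <- block_average(rec, "abp")
  f <- block_average(rec, "fvl")
  wins <- windowed_correlation(a, f)
  expect_true(all(abs(wins$r - 1) < 1e-12))

  # with cardiac pulsatility riding on top the correlation stays near 1
  cfg2 <- quick_config(1, duration_s = 600, coupling_gain = 1,
                       intrinsic_slow_amp = 0, noise_sd = 0)
  rec2 <- sim_recording(cfg2)
  w2 <- windowed_correlation(block_average(rec2, "abp"),
                             block_average(rec2, "fvl"))
  expect_true(all(w2$r > 0.99))
})

test_that("generated FV channel has the configured plausible MCA mean", {
  rec <- sim_recording(quick_config(7, duration_s = 600, noise_sd = 0))
  expect_lt(abs(mean(rec$fvl) - 55), 1)
  expect_lt(abs(mean(rec$fvr) - 55), 1)
})

test_that("decoupled recordings have near-zero mean block correlation", {
  # 30-block recordings; the block series are narrowband, so individual
  # correlations spread wider than the iid 1/sqrt(n) null, but the mean
  # over seeds must sit near zero
  rs <- vapply(1:100, function(s) {
    rec <- sim_recording(quick_config(s, duration_s = 300, coupling_gain = 0))
    cor(block_average(rec, "abp")$mean, block_average(rec, "fvl")$mean)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
  expect_gt(mean(abs(rs) <= 2 / sqrt(30)), 0.85)
})

test_that("block correlation follows the closed-form mixing prediction", {
  g <- 0.5; A <- 2; si <- 1.2; sn <- 0.5
  sw <- tibble::tibble(freq_hz = 0.02, amp = A, phase = 0)
  rs <- vapply(1:100, function(s) {
    cfg <- sim_config(duration_s = 1200, fs = 25, coupling_gain = g, seed = s,
                      slow_waves = sw, abp_pulse_amp = 0, fv_pulse_amp = 0,
                      intrinsic_slow_amp = si, noise_sd = sn)
    rec <- sim_recording(cfg)
    cor(block_average(rec, "abp")$mean, block_average(rec, "fvl")$mean)
  }, numeric(1))
  sa <- g * (55 / 90) * A / sqrt(2)
  sib <- (1 - g) * si
  snb <- sn / sqrt(250)
  pred <- sa / sqrt(sa^2 + sib^2 + snb^2)
  expect_lt(abs(mean(rs) - pred), 0.03)
})

test_that("expected block correlation is non-decreasing in coupling gain", {
  gains <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(gains, function(g) {
    mean(vapply(1:50, function(s) {
      rec <- sim_recording(quick_config(s, duration_s = 600,
                                        coupling_gain = g))
      cor(block_average(rec, "abp")$mean, block_average(rec, "fvl")$mean)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("slow-wave energy of generated channels sits in the stated band", {
  cfg <- sim_config(duration_s = 1600, fs = 25, seed = 9, noise_sd = 0,
                    hr_jitter = 0)
  rec <- sim_recording(cfg)
  for (ch in c("abp", "fvl")) {
    x <- rec[[ch]] - mean(rec[[ch]])
    sp <- Mod(fft(x))^2
    freq <- (seq_along(x) - 1) / length(x) * 25
    sub_cardiac <- freq > 0 & freq < 0.5  # below cardiac/harmonic lines
    in_band <- freq >= 0.004 & freq <= 0.051
    frac <- sum(sp[sub_cardiac & in_band]) / sum(sp[sub_cardiac])
    expect_gt(frac, 0.95)
  }
})

test_that("THRT session produces disjoint truth intervals with 60 s gaps", {
  ses <- sim_thrt_session(quick_config(3, duration_s = 400),
                          sim_thrt_spec(n_compressions = 4, spacing_s = 60))
  eps <- ses$episodes
  expect_equal(nrow(eps), 4)
  expect_equal(eps$side, c("left", "right", "left", "right"))
  gaps <- eps$start_s[-1] - eps$end_s[-4]
  expect_true(all(gaps >= 60))
  expect_true(all(eps$end_s > eps$start_s))
})

test_that("no-hyperaemia session recovers THRR of exactly 1", {
  # no slow fluctuation on FV: post-release peaks equal baseline exactly
  ses <- sim_thrt_session(
    sim_config(duration_s = 400, fs = 50, seed = 11, noise_sd = 0,
               hr_jitter = 0, coupling_gain = 0, intrinsic_slow_amp = 0),
    sim_thrt_spec(overshoot_frac = 0, recovery_tau_s = 0))
  res <- thrr(ses$recording, annotations = ses$episodes)
  expect_true(res$obtainable)
  expect_true(all(abs(res$sides$thrr - 1) < 1e-3))

  # with spontaneous slow waves present the ratio still sits near 1
  ses2 <- sim_thrt_session(
    sim_config(duration_s = 400, fs = 50, seed = 11, noise_sd = 0,
               hr_jitter = 0),
    sim_thrt_spec(overshoot_frac = 0, recovery_tau_s = 0))
  res2 <- thrr(ses2$recording, annotations = ses2$episodes)
  expect_true(all(abs(res2$sides$thrr - 1) < 0.05))
})

test_that("overshoot with slow recovery yields THRR near 1 + h", {
  ses <- sim_thrt_session(
    sim_config(duration_s = 400, fs = 50, seed = 12, noise_sd = 0.2),
    sim_thrt_spec(overshoot_frac = 0.15, recovery_tau_s = 600))
  res <- thrr(ses$recording, annotations = ses$episodes)
  expect_true(all(abs(res$sides$thrr - 1.15) < 0.03))
})

test_that("zero artefact rates leave the recording untouched", {
  rec <- sim_recording(quick_config(5, duration_s = 120))
  out <- inject_artefacts(rec, artefact_spec())
  expect_identical(out$recording$fvl, rec$fvl)
  expect_false(any(unlist(out$truth)))
})

test_that("dropout injection covers the enumerated contiguous runs", {
  rec <- sim_recording(quick_config(6, duration_s = 120, fs = 125))
  spec <- artefact_spec(dropout_rate = 1.5, dropout_len_s = 2)
  out <- inject_artefacts(rec, spec, seed = 6)
  for (ch in c("abp", "fvl", "fvr")) {
    runs <- rle(out$truth[[ch]])
    tr <- runs$lengths[runs$values]
    expect_equal(length(tr), 3)  # 1.5/min over 2 min
    expect_true(all(tr == 250))  # 2 s at 125 Hz
    expect_true(all(out$recording[[ch]][out$truth[[ch]]] == 0))
  }
  # unmasked samples bit-identical
  keep <- !out$truth$fvl
  expect_identical(out$recording$fvl[keep], rec$fvl[keep])
})

test_that("large injected spikes are recovered by the artefact detector", {
  rec <- sim_recording(quick_config(8, duration_s = 120, fs = 125))
  out <- inject_artefacts(rec, artefact_spec(spike_rate = 2, spike_amp = 10),
                          seed = 8)
  det <- detect_artefacts(out$recording)
  hit <- det$fvl_art[out$truth$fvl]
  expect_gte(mean(hit), 0.95)
})
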