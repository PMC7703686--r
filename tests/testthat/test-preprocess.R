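make_rec <- function(x, fs = 125, channel = "fvl", mask = NULL) {
  n <- length(x)
  chans <- list(abp = rep(90, n), fvl = rep(55, n), fvr = rep(55, n))
  chans[[channel]] <- x
  masks <- NULL
  if (!is.null(mask)) {
    masks <- list(abp = rep(FALSE, n), fvl = rep(FALSE, n),
                  fvr = rep(FALSE, n))
    masks[[channel]] <- mask
  }
  new_recording((seq_len(n) - 1) / fs, chans, fs, masks)
}

test_that("clean synthetic recordings stay essentially unmasked", {
  rec <- sim_recording(quick_config(1, duration_s = 300, fs = 125))
  det <- detect_artefacts(rec)
  for (ch in c("abp", "fvl", "fvr")) {
    expect_lt(mean(det[[paste0(ch, "_art")]]), 0.001)
  }
})

test_that("physiological limits are enforced with the stated boundaries", {
  x <- rep(55, 2000)
  x[100] <- 150      # retained: FV limit is (0, 150]
  x[200] <- 150.1    # masked
  x[300] <- 0        # masked: zero flow is a dropout
  rec <- make_rec(x)
  det <- detect_artefacts(rec, spike_k = Inf, flatline_s = Inf)
  expect_false(det$fvl_art[100])
  expect_true(det$fvl_art[200])
  expect_true(det$fvl_art[300])

  a <- rep(90, 2000); a[50] <- 19.9; a[60] <- 20
  det2 <- detect_artefacts(make_rec(a, channel = "abp"),
                           spike_k = Inf, flatline_s = Inf)
  expect_true(det2$abp_art[50])
  expect_false(det2$abp_art[60])
})

test_that("dropout runs in a synthetic fixture are recalled", {
  rec <- sim_recording(quick_config(2, duration_s = 180, fs = 125))
  out <- inject_artefacts(rec, artefact_spec(dropout_rate = 1,
                                             dropout_len_s = 2), seed = 2)
  det <- detect_artefacts(out$recording)
  for (ch in c("abp", "fvl")) {
    truth <- out$truth[[ch]]
    expect_gte(sum(det[[paste0(ch, "_art")]] & truth) / sum(truth), 0.95)
  }
})

test_that("flatline runs of two seconds or more are masked", {
  rec <- sim_recording(quick_config(4, duration_s = 120, fs = 125))
  x <- rec$fvl
  x[3000:3300] <- x[3000]  # 2.4 s frozen at a plausible value
  rec$fvl <- x
  det <- detect_artefacts(rec)
  expect_gte(mean(det$fvl_art[3000:3300]), 0.99)
})

test_that("beat detection finds the expected beat count and values", {
  cfg <- sim_config(duration_s = 60, fs = 125, hr_bpm = 60, hr_jitter = 0,
                    noise_sd = 0, intrinsic_slow_amp = 0,
                    slow_waves = tibble::tibble(freq_hz = numeric(0),
                                                amp = numeric(0),
                                                phase = numeric(0)))
  rec <- sim_recording(cfg)
  beats <- detect_beats(rec, "fvl")
  expect_gte(nrow(beats), 59)
  expect_lte(nrow(beats), 61)

  # truth values from the generator's pulse template
  tpl <- caindex:::pulse_template(seq(0, 1, length.out = 2048))
  s_true <- 55 + 30 * max(tpl)
  d_true <- 55 + 30 * min(tpl)
  mid <- beats[5:50, ]
  expect_true(all(abs(mid$systolic - s_true) / s_true < 0.01))
  expect_true(all(abs(mid$diastolic - d_true) / d_true < 0.01))
})

test_that("beats spanning masked samples are flagged invalid", {
  cfg <- sim_config(duration_s = 60, fs = 125, hr_bpm = 60, hr_jitter = 0,
                    noise_sd = 0)
  rec <- sim_recording(cfg)
  mask <- rep(FALSE, nrow(rec))
  mask[3125:3375] <- TRUE  # 2 s dropout at t = 25 s
  rec$fvl_art <- mask
  beats <- detect_beats(rec, "fvl")
  spanned <- beats$onset_s < 27 & beats$peak_s > 24.5
  expect_true(any(!beats$valid[spanned]))
  expect_true(all(beats$valid[beats$peak_s < 20]))
})

test_that("fully masked channel yields empty beats with a warning", {
  rec <- make_rec(rep(55, 2000), mask = rep(TRUE, 2000))
  expect_warning(b <- detect_beats(rec, "fvl"), "masked")
  expect_equal(nrow(b), 0)
})

test_that("beat count times mean interval matches unmasked duration", {
  rec <- sim_recording(quick_config(10, duration_s = 120, fs = 125))
  beats <- detect_beats(rec, "fvl")
  dur <- mean(beats$interval_s, na.rm = TRUE) * nrow(beats)
  expect_lt(abs(dur - 120), 2 * mean(beats$interval_s, na.rm = TRUE))
})

test_that("block means reproduce constants and attenuate sines as sinc", {
  rec <- make_rec(rep(7.5, 12500))
  b <- block_average(rec, "fvl")
  expect_true(all(b$mean == 7.5))
  expect_true(all(b$valid))

  # pure 0.02 Hz sine of amplitude A: block means trace the sine with
  # attenuation sinc(pi f T) evaluated at block centres
  fs <- 125; f <- 0.02; A <- 3
  t <- (seq_len(500 * fs) - 1) / fs
  rec2 <- make_rec(55 + A * sin(2 * pi * f * t), fs = fs)
  b2 <- block_average(rec2, "fvl")
  att <- sin(pi * f * 10) / (pi * f * 10)
  centre <- b2$start_s + 5 - 1 / (2 * fs)
  pred <- 55 + A * att * sin(2 * pi * f * centre)
  expect_lt(max(abs(b2$mean - pred)), 1e-3)
  expect_equal(att, 0.9355, tolerance = 1e-3)
})

test_that("block validity follows the minimum valid fraction", {
  n <- 12500
  mask <- rep(FALSE, n)
  mask[1:625] <- TRUE                 # block 1: exactly half masked
  mask[1251:(1250 + 638)] <- TRUE     # block 2: 51% masked
  rec <- make_rec(rep(5, n), mask = mask)
  b <- block_average(rec, "fvl", min_valid_frac = 0.5)
  expect_true(b$valid[1])
  expect_false(b$valid[2])
})

test_that("block means are invariant to the sampling rate", {
  mk <- function(fs) {
    t <- (seq_len(500 * fs) - 1) / fs
    x <- 55 + 3 * sin(2 * pi * 0.01 * t) + 2 * sin(2 * pi * 0.8 * t)
    make_rec(x, fs = fs)
  }
  b125 <- block_average(mk(125), "fvl")
  b250 <- block_average(mk(250), "fvl")
  expect_lt(max(abs(b125$mean - b250$mean) / abs(b125$mean)), 0.005)
})

test_that("enlarging the mask never increases valid blocks or beats", {
  rec <- sim_recording(quick_config(11, duration_s = 300, fs = 125))
  mask1 <- rep(FALSE, nrow(rec)); mask1[5000:8000] <- TRUE
  mask2 <- mask1; mask2[15000:22000] <- TRUE
  r1 <- rec; r1$fvl_art <- mask1
  r2 <- rec; r2$fvl_art <- mask2
  b1 <- block_average(r1, "fvl"); b2 <- block_average(r2, "fvl")
  expect_lte(sum(b2$valid), sum(b1$valid))
  beats1 <- detect_beats(r1, "fvl"); beats2 <- detect_beats(r2, "fvl")
  expect_lte(sum(beats2$valid), sum(beats1$valid))
})
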