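test_that("high-pass filter attenuates below and preserves above cutoff", {
  low <- tone_wave(100, 0.3)
  hi <- tone_wave(2000, 0.3)
  out_low <- high_pass(low, "squeal")        # 500 Hz cutoff
  expect_lt(sqrt(mean(out_low$samples^2)), 0.01 * sqrt(mean(low$samples^2)))
  for (ty in c("snort", "soft_snort", "squeal", "quagga_quagga")) {
    out_hi <- high_pass(hi, ty)
    gain_db <- 20 * log10(sqrt(mean(out_hi$samples^2)) /
                            sqrt(mean(hi$samples^2)))
    expect_lt(abs(gain_db), 1)
  }
  expect_equal(unname(highpass_cutoffs[c("snort", "soft_snort", "squeal",
                                         "quagga_quagga")]),
               c(30, 30, 500, 600))
  expect_error(high_pass(tone_wave(100, 0.1, rate = 800), cutoff_hz = 500),
               "Nyquist")
})

test_that("pitch tracker recovers pure tones and rejects noise", {
  w <- tone_wave(800, 0.5)
  ctr <- f0_contour(w, 500, 2000)
  expect_true(all(ctr$voiced))
  expect_true(all(abs(ctr$f0 - 800) < 8))
  set.seed(1)
  noise <- waveform(rnorm(22050) * 0.3, 44100)
  ctr_n <- f0_contour(noise, 500, 2000)
  expect_gte(mean(!ctr_n$voiced), 0.9)
})

test_that("pitch statistics track a two-segment 600/900 Hz tone", {
  seg <- function(f) 0.5 * sin(2 * pi * f * seq_len(11025) / 44100)
  w <- waveform(c(seg(600), seg(900)), 44100)
  ctr <- f0_contour(w, 400, 2000)
  v <- ctr$f0[ctr$voiced]
  expect_lt(abs(min(v) - 600), 12)
  expect_lt(abs(max(v) - 900), 18)
  expect_lt(abs((max(v) - min(v)) - 300), 30)
})

test_that("spectral quartiles match the flat-spectrum closed form", {
  # brick-wall band-limited white noise on [0, 8000] Hz
  set.seed(2)
  n <- 44100
  x <- rnorm(n)
  X <- fft(x)
  f <- (0:(n - 1)) / n * 44100
  X[pmin(f, 44100 - f) > 8000] <- 0
  w <- waveform(Re(fft(X, inverse = TRUE)) / n, 44100)
  sp <- spectral_summary(w)
  expect_lt(abs(sp$q25 - 2000) / 2000, 0.05)
  expect_lt(abs(sp$q50 - 4000) / 4000, 0.05)
  expect_lt(abs(sp$q75 - 6000) / 6000, 0.05)
})

test_that("a pure tone concentrates all quartiles at its frequency", {
  sp <- spectral_summary(tone_wave(1000, 0.5))
  expect_equal(sp$q25, sp$q50)
  expect_equal(sp$q50, sp$q75)
  expect_lt(abs(sp$peak_frequency - 1000), 5)
  expect_lt(abs(sp$q50 - 1000), 5)
})

test_that("equal-power two-tone spectrum puts q50 between the tones", {
  w <- waveform(tone_wave(500, 0.5)$samples + tone_wave(1500, 0.5)$samples,
                44100)
  sp <- spectral_summary(w)
  # independent oracle: cumulative spectrum computed directly
  pw <- Mod(fft(w$samples))^2
  half <- pw[1:(length(pw) %/% 2 + 1)]
  freqs <- (seq_along(half) - 1) / length(w$samples) * 44100
  oracle_q50 <- freqs[which(cumsum(half) / sum(half) >= 0.5)[1]]
  expect_equal(sp$q50, oracle_q50)
  expect_gte(sp$q50, 495); expect_lte(sp$q50, 1505)
  expect_true(min(abs(sp$peak_frequency - c(500, 1500))) < 5)
  expect_error(spectral_summary(waveform(numeric(100), 44100)), "energy")
})

test_that("amplitude metrics recover a known sinusoidal modulation", {
  t <- seq_len(44100) / 44100
  carrier <- sin(2 * pi * 2000 * t)
  env <- 10^((20 * (-cos(2 * pi * 10 * t) - 1) / 2) / 20)  # 20 dB swings
  am <- amplitude_metrics(waveform(0.5 * carrier * env, 44100))
  expect_gte(am$am_rate, 9); expect_lte(am$am_rate, 11)
  expect_gt(am$am_extent, 18); expect_lt(am$am_extent, 22)
})

test_that("a constant envelope yields no modulation", {
  am <- amplitude_metrics(tone_wave(2000, 0.5))
  expect_equal(am$am_rate, 0)
  expect_true(is.na(am$am_extent))
  expect_lt(am$amplitude_variation, 5)
})

test_that("non-tonal calls get exactly 8 populated features", {
  set.seed(6)
  w <- synth_call("soft_snort", duration_s = 0.4, rate = 22050)
  fv <- extract_features(w, "soft_snort")
  f0_cols <- c("mean_f0", "max_f0", "min_f0", "range_f0")
  expect_true(all(is.na(fv[f0_cols])))
  expect_true(all(!is.na(fv[setdiff(names(fv), f0_cols)])))
})

test_that("duration comes from the annotated boundaries", {
  w <- tone_wave(1000, 0.5)
  fv <- extract_features(w, "squeal", onset_s = 0.2, offset_s = 0.7)
  expect_equal(fv$duration, 0.5)
})

test_that("a squeal without detectable modulation has missing am_extent", {
  set.seed(7)
  w <- synth_call("squeal", list(am_depth_db = 0, f0_mod_frac = 0),
                  0.4, 22050, snr_db = Inf)
  fv <- extract_features(w, "squeal")
  expect_true(is.na(fv$am_extent))
  expect_equal(fv$am_rate, 0)
})

test_that("feature invariants hold across random synthetic calls", {
  set.seed(8)
  types <- rep(c("snort", "soft_snort", "squeal", "quagga_quagga"), 3)
  for (ty in types) {
    w <- synth_call(ty, duration_s = runif(1, 0.3, 0.8), rate = 22050)
    fv <- extract_features(w, ty)
    expect_true(fv$q25 <= fv$q50 && fv$q50 <= fv$q75)
    expect_true(all(c(fv$q25, fv$q75, fv$peak_frequency) <= 22050 / 2))
    if (!is.na(fv$mean_f0)) {
      expect_true(fv$min_f0 <= fv$mean_f0 && fv$mean_f0 <= fv$max_f0)
      expect_equal(fv$range_f0, fv$max_f0 - fv$min_f0)
    }
    # scale invariance: a gain change leaves every feature unchanged
    w2 <- waveform(w$samples * 0.25, w$rate)
    fv2 <- extract_features(w2, ty)
    for (cn in names(fv))
      expect_equal(fv2[[cn]], fv[[cn]], tolerance = 1e-6)
  }
})

test_that("batch extraction records failures without aborting", {
  d <- small_dataset()
  ann <- d$ds$annotations[1:3, ]
  waves <- d$ds$waves[ann$call_id]
  waves[[2]] <- waveform(numeric(220), 22050)   # silent -> zero energy
  res <- extract_feature_table(ann, waves = waves)
  expect_equal(nrow(res$features), 2)
  expect_equal(nrow(res$failures), 1)
  expect_match(res$failures$reason, "energy|short")
})
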