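test_that("frame count follows the hop-based formula", {
  w <- tone_wave(1000, 1.25)            # 55125 samples
  sp <- mel_spectrogram(w)
  expect_equal(ncol(sp), ceiling(55125 / 256) + 1)
  expect_equal(nrow(sp), 128)
})

test_that("calls over the duration limit are rejected and logged", {
  expect_error(mel_spectrogram(tone_wave(500, 1.3)), "1.25")
  d <- data.frame(call_id = c("a", "b"), file = NA, onset_s = 0,
                  offset_s = c(0.4, 1.4), call_type = "snort",
                  individual_id = "i", sex = "F", location = "L")
  waves <- list(a = tone_wave(500, 0.4), b = tone_wave(500, 1.4))
  prep <- prepare_spectrograms(d, waves = waves)
  expect_equal(names(prep$specs), "a")
  expect_equal(prep$excluded$call_id, "b")
})

test_that("silence maps to a uniform floor-dB matrix", {
  w <- waveform(numeric(4410), 44100)
  sp <- mel_spectrogram(w)
  expect_true(all(sp == -80))
})

test_that("a pure tone energizes the mel band containing its frequency", {
  w <- tone_wave(1000, 0.3)
  sp <- mel_spectrogram(w)
  hot <- which.max(rowSums(10^(unclass(sp) / 10)))
  # oracle: band centres from the mel scale used by the filterbank
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centres <- imel(seq(mel(30), mel(22050), length.out = 130))[2:129]
  expect_lt(abs(centres[hot] - 1000), diff(centres[hot + c(-1, 1)]))
})

test_that("pad_and_align pads to the longest call and zeroes the onset", {
  p <- mel_params(44100)
  mk <- function(n_lead, n_sig) {
    w <- waveform(c(numeric(round(n_lead * 256)),
                    tone_wave(1000, n_sig * 256 / 44100)$samples), 44100)
    mel_spectrogram(w, p)
  }
  specs <- list(a = mk(0, 40), b = mk(20, 60), c = mk(0, 100))
  out <- pad_and_align(specs)
  widths <- vapply(out, ncol, 0L)
  expect_true(all(widths == max(widths)))
  # the call with 20 leading silent frames now starts at frame 1
  expect_gt(max(out$b[, 1]), -70)
  # aligned equal-length set passes through unchanged
  again <- pad_and_align(out)
  expect_equal(lapply(again, unclass), lapply(out, unclass),
               ignore_attr = TRUE)
  # padding preserves content: un-padded prefix equals the aligned matrix
  on_b <- which(apply(unclass(specs$b), 2, max) > -70)[1]
  content <- unclass(specs$b)[, on_b:ncol(specs$b)]
  expect_equal(unclass(out$b)[, seq_len(ncol(content))], content,
               ignore_attr = TRUE)
})

test_that("time-shift distance matches a brute-force oracle", {
  set.seed(11)
  p <- mel_params(44100)
  shift_oracle <- function(a, b, ms, fill = -80) {
    n <- ncol(a)
    best <- Inf
    for (s in (-ms):ms) {
      sb <- matrix(fill, nrow(b), n)
      src <- seq_len(n) - s
      okc <- src >= 1 & src <= n
      sb[, which(okc)] <- b[, src[okc]]
      best <- min(best, sqrt(sum((a - sb)^2)))
    }
    best
  }
  for (i in 1:20) {
    a <- matrix(runif(8 * 12, -80, 0), 8)
    b <- matrix(runif(8 * 12, -80, 0), 8)
    attr(a, "mel_params") <- p; attr(b, "mel_params") <- p
    ms <- sample(1:4, 1)
    expect_equal(timeshift_distance(a, b, ms),
                 shift_oracle(unclass(a), unclass(b), ms))
  }
})

test_that("time-shift distance absorbs shifts inside the window", {
  set.seed(12)
  p <- mel_params(44100)
  # a padded call: content then floor-dB tail, as pad_and_align produces
  a <- cbind(matrix(runif(10 * 25, -80, 0), 10), matrix(-80, 10, 5))
  attr(a, "mel_params") <- p
  b <- cbind(matrix(-80, 10, 5), unclass(a)[, 1:25])   # a shifted by 5
  attr(b, "mel_params") <- p
  expect_equal(timeshift_distance(a, a), 0)
  expect_equal(timeshift_distance(a, b, max_shift = 5), 0)
  expect_gt(timeshift_distance(a, b, max_shift = 2), 0)
  expect_error(timeshift_distance(a, matrix(0, 4, 4)), "mismatch")
})

test_that("spectrogram sets persist and reload", {
  d <- small_dataset()
  ann <- d$ds$annotations[d$ds$annotations$call_type == "snort", ][1:4, ]
  prep <- prepare_spectrograms(ann, waves = d$ds$waves,
                               params = within(mel_params(22050),
                                               n_mels <- 32))
  stem <- file.path(withr::local_tempdir(), "specs")
  save_spectrograms(prep, stem)
  back <- load_spectrograms(stem)
  expect_equal(back$index$call_id, prep$index$call_id)
  expect_equal(back$specs, prep$specs)
})
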