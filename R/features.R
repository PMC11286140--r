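#' Acoustic feature extraction
#'
#' Implements the twelve standard features used for zebra vocalizations:
#' four fundamental-frequency statistics (mean/max/min/range F0, tonal calls
#' only), the spectral energy quartiles Q25/Q50/Q75, peak frequency,
#' duration, and three amplitude metrics (amplitude variation in dB/s, AM
#' rate in cycles/s, AM extent in dB). Calls are high-pass filtered by type
#' before analysis.
#'
#' @name features
NULL

#' Per-type high-pass cutoffs (Hz)
#'
#' 30 Hz for snorts and soft snorts, 500 Hz for squeals and 600 Hz for
#' quagga quagga — just above the average minimum fundamental frequency of
#' the tonal types, so that low-frequency rumble never contaminates the
#' spectral statistics.
#' @export
highpass_cutoffs <- c(snort = 30, soft_snort = 30,
                      squeal = 500, quagga_quagga = 600)

#' High-pass filter a call by type
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass at the
#' per-type cutoff. Zero-phase filtering keeps the amplitude envelope
#' undistorted for the AM metrics.
#'
#' @param wave a [waveform()].
#' @param call_type call type label (selects the cutoff), or `NULL` to use
#'   `cutoff_hz` directly.
#' @param cutoff_hz explicit cutoff frequency in Hz.
#' @return the filtered [waveform()].
#' @export
high_pass <- function(wave, call_type = NULL, cutoff_hz = NULL) {
  stopifnot(inherits(wave, "zr_wave"), length(wave$samples) > 0)
  if (is.null(cutoff_hz)) {
    call_type <- match.arg(call_type, names(highpass_cutoffs))
    cutoff_hz <- highpass_cutoffs[[call_type]]
  }
  if (cutoff_hz >= wave$rate / 2)
    stop("high-pass cutoff at or above Nyquist frequency")
  bf <- signal::butter(4, cutoff_hz / (wave$rate / 2), type = "high")
  waveform(signal::filtfilt(bf, wave$samples), wave$rate)
}

#' Frame-wise fundamental-frequency contour
#'
#' Autocorrelation pitch tracker: the signal is cut into `frame_s` windows
#' every `hop_s` seconds; in each frame the normalized autocorrelation is
#' searched for its highest peak with lag in `[1/fmax, 1/fmin]`, refined by
#' parabolic interpolation. Frames whose periodicity strength (normalized
#' autocorrelation at the peak) falls below `voicing_threshold` are marked
#' unvoiced.
#'
#' @param wave a [waveform()] (already high-pass filtered).
#' @param fmin,fmax F0 search range in Hz, `0 < fmin < fmax < rate/2`.
#' @param frame_s analysis frame length in seconds (default 40 ms).
#' @param hop_s hop between frames in seconds (default 10 ms).
#' @param voicing_threshold minimum periodicity strength for a voiced frame.
#' @return data.frame with `time` (frame centre, s), `f0` (Hz, `NA` when
#'   unvoiced), `strength`, `voiced`.
#' @export
f0_contour <- function(wave, fmin, fmax, frame_s = 0.04, hop_s = 0.01,
                       voicing_threshold = 0.45) {
  stopifnot(inherits(wave, "zr_wave"))
  rate <- wave$rate
  if (!(fmin > 0 && fmin < fmax && fmax < rate / 2))
    stop("need 0 < fmin < fmax < rate/2")
  x <- wave$samples
  frame_n <- round(frame_s * rate)
  hop_n <- round(hop_s * rate)
  n_frames <- max(1L, ceiling(length(x) / hop_n))
  lag_min <- max(2L, floor(rate / fmax))
  lag_max <- ceiling(rate / fmin)
  if (lag_max >= frame_n) stop("frame too short for fmin")
  out <- data.frame(time = (seq_len(n_frames) - 1) * hop_s + frame_s / 2,
                    f0 = NA_real_, strength = 0, voiced = FALSE)
  for (i in seq_len(n_frames)) {
    s0 <- (i - 1L) * hop_n + 1L
    fr <- x[s0:min(s0 + frame_n - 1L, length(x))]
    if (length(fr) < lag_max + 2L) next
    fr <- fr - mean(fr)
    r0 <- sum(fr * fr)
    if (r0 < 1e-12) next
    lags <- lag_min:lag_max
    r <- vapply(lags, function(l)
      sum(fr[1:(length(fr) - l)] * fr[(l + 1):length(fr)]) / r0, 0)
    j <- which.max(r)
    strength <- r[j]
    out$strength[i] <- strength
    if (strength >= voicing_threshold) {
      lag <- lags[j]
      if (j > 1 && j < length(r)) {       # parabolic peak refinement
        d <- (r[j + 1] - r[j - 1]) / (2 * (2 * r[j] - r[j - 1] - r[j + 1]))
        if (is.finite(d) && abs(d) < 1) lag <- lag + d
      }
      out$f0[i] <- rate / lag
      out$voiced[i] <- TRUE
    }
  }
  out
}

#' Spectral energy quartiles and peak frequency
#'
#' A single DFT of the whole (filtered) call; `q_p` is the smallest
#' frequency at which the cumulative magnitude-squared spectrum reaches
#' `p` of the total energy, and `peak_frequency` the bin of maximum power.
#'
#' @param wave a [waveform()].
#' @return named list `q25`, `q50`, `q75`, `peak_frequency` (Hz).
#' @export
spectral_summary <- function(wave) {
  stopifnot(inherits(wave, "zr_wave"))
  x <- wave$samples
  if (length(x) == 0 || sum(x^2) < 1e-20) stop("zero-energy signal")
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  half <- pw[1:(n %/% 2L + 1L)]
  freqs <- (seq_along(half) - 1) / n * wave$rate
  cum <- cumsum(half) / sum(half)
  qat <- function(p) freqs[which(cum >= p)[1]]
  list(q25 = qat(0.25), q50 = qat(0.50), q75 = qat(0.75),
       peak_frequency = freqs[which.max(half)])
}

# RMS intensity contour in dB (relative to full scale)
.env_db <- function(x, rate, frame_s = 0.01, hop_s = 0.005) {
  frame_n <- max(2L, round(frame_s * rate))
  hop_n <- max(1L, round(hop_s * rate))
  starts <- seq(1L, max(1L, length(x) - frame_n + 1L), by = hop_n)
  rms <- vapply(starts, function(s)
    sqrt(mean(x[s:min(s + frame_n - 1L, length(x))]^2)), 0)
  20 * log10(pmax(rms, 1e-10))
}

# alternating envelope extrema with a dB hysteresis: an extremum is
# committed only once the contour has moved `prom` dB away from it, so
# small ripple never counts as modulation
.alt_extrema <- function(env, prom) {
  idx <- integer(0); val <- numeric(0); type <- integer(0)  # 1 max, -1 min
  cm_i <- 1L; cm_v <- env[1]     # running candidate maximum
  cn_i <- 1L; cn_v <- env[1]     # running candidate minimum
  dir <- 0L                      # -1: seeking min, 1: seeking max, 0: open
  for (i in seq_along(env)[-1]) {
    v <- env[i]
    if (dir != -1L) {
      if (v > cm_v) { cm_v <- v; cm_i <- i }
      if (cm_v - v >= prom) {
        idx <- c(idx, cm_i); val <- c(val, cm_v); type <- c(type, 1L)
        dir <- -1L; cn_v <- v; cn_i <- i
        next
      }
    }
    if (dir != 1L) {
      if (v < cn_v) { cn_v <- v; cn_i <- i }
      if (v - cn_v >= prom) {
        idx <- c(idx, cn_i); val <- c(val, cn_v); type <- c(type, -1L)
        dir <- 1L; cm_v <- v; cm_i <- i
      }
    }
  }
  # the trailing candidate already lies >= prom away from the last committed
  # extremum (commitment guarantees it); the contour ending completes it
  if (dir == -1L) {
    idx <- c(idx, cn_i); val <- c(val, cn_v); type <- c(type, -1L)
  } else if (dir == 1L) {
    idx <- c(idx, cm_i); val <- c(val, cm_v); type <- c(type, 1L)
  }
  data.frame(idx = idx, val = val, type = type)
}

#' Amplitude metrics: variation, AM rate, AM extent
#'
#' The intensity contour is the frame RMS in dB (10 ms frames, 5 ms hop).
#' `amplitude_variation` is the cumulative absolute dB change divided by the
#' call duration. Amplitude-modulation cycles are complete
#' extremum-to-extremum-to-extremum excursions of the contour in which every
#' swing exceeds a 3 dB prominence (hysteresis tracking, so ripple below the
#' threshold never counts); `am_rate` is the complete-cycle count over the
#' duration and `am_extent` the mean dB swing between consecutive committed
#' extrema. A contour with no complete cycle yields `am_rate = 0` and a
#' missing `am_extent`.
#'
#' @param wave a [waveform()].
#' @param frame_s,hop_s envelope frame and hop in seconds.
#' @param prominence_db minimum swing for an AM excursion (dB).
#' @return named list `amplitude_variation` (dB/s), `am_rate` (1/s),
#'   `am_extent` (dB, `NA` if no cycles).
#' @export
amplitude_metrics <- function(wave, frame_s = 0.01, hop_s = 0.005,
                              prominence_db = 3) {
  stopifnot(inherits(wave, "zr_wave"))
  dur <- wave_duration(wave)
  env <- .env_db(wave$samples, wave$rate, frame_s, hop_s)
  if (length(env) < 3) stop("waveform too short for an intensity contour")
  av <- sum(abs(diff(env))) / dur
  # onset/offset transients are not modulation: drop the edge frames that
  # overlap the first/last 10 ms before counting cycles
  core <- if (length(env) > 6) env[3:(length(env) - 2L)] else env
  ext <- .alt_extrema(core, prominence_db)
  cycles <- max(0L, (nrow(ext) - 1L) %/% 2L)
  if (cycles == 0L)
    return(list(amplitude_variation = av, am_rate = 0, am_extent = NA_real_))
  list(amplitude_variation = av,
       am_rate = cycles / dur,
       am_extent = mean(abs(diff(ext$val))))
}

#' F0 search ranges per tonal call type (Hz)
#' @export
f0_search_ranges <- list(squeal = c(400, 4000), quagga_quagga = c(400, 3000))

#' Extract the full feature vector for one call
#'
#' Applies the per-type high-pass filter and composes [f0_contour()] (tonal
#' types only), [spectral_summary()] and [amplitude_metrics()]. For snorts
#' and soft snorts the four F0 fields are `NA` by design (non-tonal calls
#' have no fundamental). `duration` is `offset_s - onset_s` when both are
#' given, else the waveform length.
#'
#' @param wave a [waveform()] trimmed to the call.
#' @param call_type call type label.
#' @param onset_s,offset_s optional annotated call boundaries (s).
#' @param f0_range optional F0 search range override `c(fmin, fmax)`.
#' @return one-row data.frame with columns `mean_f0`, `max_f0`, `min_f0`,
#'   `range_f0`, `q25`, `q50`, `q75`, `peak_frequency`, `duration`,
#'   `amplitude_variation`, `am_rate`, `am_extent`.
#' @export
extract_features <- function(wave, call_type, onset_s = NULL, offset_s = NULL,
                             f0_range = NULL) {
  call_type <- match.arg(call_type, .zr_call_types)
  filt <- high_pass(wave, call_type)
  tonal <- call_type %in% names(f0_search_ranges)
  f0s <- c(mean_f0 = NA_real_, max_f0 = NA_real_, min_f0 = NA_real_,
           range_f0 = NA_real_)
  if (tonal) {
    rng <- if (is.null(f0_range)) f0_search_ranges[[call_type]] else f0_range
    ctr <- f0_contour(filt, rng[1], rng[2])
    v <- ctr$f0[ctr$voiced]
    if (length(v) > 0) {
      f0s <- c(mean_f0 = mean(v), max_f0 = max(v), min_f0 = min(v),
               range_f0 = max(v) - min(v))
    }
  }
  sp <- spectral_summary(filt)
  am <- amplitude_metrics(filt)
  dur <- if (!is.null(onset_s) && !is.null(offset_s)) offset_s - onset_s
         else wave_duration(wave)
  data.frame(mean_f0 = f0s[["mean_f0"]], max_f0 = f0s[["max_f0"]],
             min_f0 = f0s[["min_f0"]], range_f0 = f0s[["range_f0"]],
             q25 = sp$q25, q50 = sp$q50, q75 = sp$q75,
             peak_frequency = sp$peak_frequency, duration = dur,
             amplitude_variation = am$amplitude_variation,
             am_rate = am$am_rate, am_extent = am$am_extent)
}

#' Names of the feature subsets
#'
#' `feature_names("all")` gives the full 12-feature set used by the
#' individuality analysis; `feature_names("repertoire")` the 8-feature
#' subset (everything except the F0 statistics, which non-tonal calls lack).
#'
#' @param subset `"all"` or `"repertoire"`.
#' @return character vector of column names.
#' @export
feature_names <- function(subset = c("all", "repertoire")) {
  subset <- match.arg(subset)
  all <- c("mean_f0", "max_f0", "min_f0", "range_f0", "q25", "q50", "q75",
           "peak_frequency", "duration", "amplitude_variation", "am_rate",
           "am_extent")
  if (subset == "all") all else setdiff(all, c("mean_f0", "max_f0", "min_f0",
                                               "range_f0"))
}

#' Extract a feature table for an annotated dataset
#'
#' Runs [extract_features()] for every annotation row, reading each call's
#' WAV from `audio_dir` (or taking it from `waves`). Per-call failures are
#' recorded in the returned `failures` table instead of aborting the batch.
#'
#' @param annotations annotation data.frame (see [load_annotations()]).
#' @param audio_dir directory containing the WAV files named in
#'   `annotations$file`.
#' @param waves optional named list of waveforms keyed by `call_id`,
#'   used instead of reading files.
#' @return list with `features` (annotation columns + 12 feature columns)
#'   and `failures` (call_id, reason).
#' @export
extract_feature_table <- function(annotations, audio_dir = NULL,
                                  waves = NULL) {
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    fv <- tryCatch({
      w <- if (!is.null(waves)) waves[[a$call_id]]
           else read_wav(file.path(audio_dir, a$file))
      extract_features(w, a$call_type, a$onset_s, a$offset_s)
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        call_id = a$call_id, reason = conditionMessage(fv),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- cbind(a, fv, row.names = NULL)
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(call_id = character(), reason = character()))
}
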