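#' Mel-spectrogram preparation
#'
#' Spectrogram-based repertoire analyses work on uniform-length,
#' time-aligned log-power mel-spectrograms: each call's STFT magnitude is
#' pooled through a mel filterbank, converted to dB relative to the call's
#' maximum, floored at `floor_db`; all matrices in a set are then shifted so
#' the energy onset sits at frame 0 and padded with the dB floor (zero
#' power) to the longest call. A time-shift-aware Euclidean distance
#' compensates for residual misalignment.
#'
#' @name specprep
NULL

#' Default mel-spectrogram parameters
#'
#' 128 mel bands, 512-sample window, 256-sample hop, 30 Hz to Nyquist.
#' @param rate sampling rate the spectrogram will be computed at.
#' @return named list of parameters.
#' @export
mel_params <- function(rate = 44100) {
  list(n_mels = 128L, n_fft = 512L, hop = 256L, fmin = 30,
       fmax = rate / 2, floor_db = -80)
}

# HTK mel scale
.hz2mel <- function(f) 2595 * log10(1 + f / 700)
.mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: n_mels x (n_fft/2 + 1)
.mel_filterbank <- function(n_mels, n_fft, rate, fmin, fmax) {
  pts <- .mel2hz(seq(.hz2mel(fmin), .hz2mel(fmax), length.out = n_mels + 2L))
  bins <- (0:(n_fft %/% 2L)) / n_fft * rate
  fb <- matrix(0, n_mels, length(bins))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; c0 <- pts[m + 1]; hi <- pts[m + 2]
    up <- (bins - lo) / (c0 - lo)
    dn <- (hi - bins) / (hi - c0)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Mel-spectrogram of a call
#'
#' Centre-padded STFT (Hann window) with frames starting every `hop`
#' samples, giving `ceil(n_samples / hop) + 1` frames; magnitude-squared
#' spectra are pooled through a triangular mel filterbank and expressed in
#' dB relative to the matrix maximum, floored at `params$floor_db`. Calls
#' longer than `max_duration_s` are rejected (the repertoire inclusion
#' rule).
#'
#' @param wave a [waveform()].
#' @param params parameter list, see [mel_params()].
#' @param call_id optional identifier stored on the result.
#' @param max_duration_s maximum allowed call length in seconds (default
#'   1.25; `Inf` disables the check).
#' @return an `n_mels x n_frames` matrix of class `zr_melspec` with
#'   attributes `mel_params`, `original_frames`, `call_id`.
#' @export
mel_spectrogram <- function(wave, params = mel_params(wave$rate),
                            call_id = NULL, max_duration_s = 1.25) {
  stopifnot(inherits(wave, "zr_wave"))
  if (wave_duration(wave) > max_duration_s)
    stop(sprintf("call longer than %.2f s excluded from spectrogram analysis",
                 max_duration_s))
  x <- wave$samples
  n <- length(x)
  n_fft <- params$n_fft; hop <- params$hop
  n_frames <- ceiling(n / hop) + 1L
  half <- n_fft %/% 2L
  xp <- c(numeric(half), x,
          numeric(max(0L, (n_frames - 1L) * hop + n_fft - half - n)))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n_fft - 1L)) / n_fft)
  fb <- .mel_filterbank(params$n_mels, n_fft, wave$rate,
                        params$fmin, params$fmax)
  pw <- matrix(0, n_fft %/% 2L + 1L, n_frames)
  for (k in seq_len(n_frames)) {
    fr <- xp[((k - 1L) * hop + 1L):((k - 1L) * hop + n_fft)] * win
    sp <- stats::fft(fr)[1:(n_fft %/% 2L + 1L)]
    pw[, k] <- Mod(sp)^2
  }
  melp <- fb %*% pw
  ref <- max(melp)
  m <- if (ref <= 1e-20) {
    matrix(params$floor_db, params$n_mels, n_frames)
  } else {
    pmax(10 * log10(pmax(melp / ref, 1e-20)), params$floor_db)
  }
  structure(m, class = "zr_melspec", mel_params = params,
            original_frames = n_frames, call_id = call_id)
}

# first frame whose per-frame maximum exceeds the floor by onset_margin dB
.onset_frame <- function(spec, onset_margin_db = 10) {
  floor_db <- attr(spec, "mel_params")$floor_db
  peaks <- apply(spec, 2, max)
  idx <- which(peaks > floor_db + onset_margin_db)
  if (length(idx) == 0) 1L else idx[1]
}

#' Pad and onset-align a set of mel-spectrograms
#'
#' Shifts each matrix so its energy onset (first frame more than 10 dB above
#' the dB floor) sits at frame 0, then pads every matrix on the right with
#' the dB floor (zero power) to the length of the longest one, so all calls
#' share one shape.
#'
#' @param specs list of [mel_spectrogram()] matrices.
#' @param onset_margin_db onset threshold above the floor (dB).
#' @return list of aligned, equal-width `zr_melspec` matrices;
#'   `original_frames` records each call's content length after alignment.
#' @export
pad_and_align <- function(specs, onset_margin_db = 10) {
  stopifnot(length(specs) > 0)
  shifted <- lapply(specs, function(s) {
    on <- .onset_frame(s, onset_margin_db)
    out <- s[, on:ncol(s), drop = FALSE]
    attributes(out) <- c(attributes(out),
                         attributes(s)[c("mel_params", "call_id")])
    attr(out, "original_frames") <- ncol(out)
    class(out) <- "zr_melspec"
    out
  })
  width <- max(vapply(shifted, ncol, 0L))
  lapply(shifted, function(s) {
    floor_db <- attr(s, "mel_params")$floor_db
    if (ncol(s) < width) {
      pad <- matrix(floor_db, nrow(s), width - ncol(s))
      out <- cbind(unclass(s), pad)
      attr(out, "mel_params") <- attr(s, "mel_params")
      attr(out, "call_id") <- attr(s, "call_id")
      attr(out, "original_frames") <- attr(s, "original_frames")
      class(out) <- "zr_melspec"
      out
    } else s
  })
}

#' Time-shift-aware spectrogram distance
#'
#' Minimum over integer frame shifts `s` in `[-max_shift, max_shift]` of the
#' Euclidean (Frobenius) distance between `a` and `b` shifted by `s` frames,
#' vacated frames filled with the dB floor. Compensates residual onset
#' misalignment: a call and its shifted copy are at distance 0 whenever the
#' shift is within the window.
#'
#' @param a,b equal-shape `zr_melspec` matrices.
#' @param max_shift maximum shift in frames (default 25% of the width).
#' @return non-negative scalar.
#' @export
timeshift_distance <- function(a, b, max_shift = NULL) {
  if (!all(dim(a) == dim(b))) stop("spectrogram shape mismatch")
  if (is.null(max_shift)) max_shift <- round(0.25 * ncol(a))
  floor_db <- attr(b, "mel_params")$floor_db
  if (is.null(floor_db)) floor_db <- min(b)
  am <- unclass(a); bm <- unclass(b)
  best <- Inf
  for (s in (-max_shift):max_shift) {
    shifted <- .shift_cols(bm, s, floor_db)
    d <- sqrt(sum((am - shifted)^2))
    if (d < best) best <- d
  }
  best
}

# shift matrix columns by s (positive = right), filling with `fill`
.shift_cols <- function(m, s, fill) {
  n <- ncol(m)
  out <- matrix(fill, nrow(m), n)
  if (s >= 0) {
    if (s < n) out[, (s + 1L):n] <- m[, 1L:(n - s), drop = FALSE]
  } else {
    if (-s < n) out[, 1L:(n + s)] <- m[, (1L - s):n, drop = FALSE]
  }
  out
}

#' Prepare an aligned spectrogram set for an annotated dataset
#'
#' Computes, aligns and pads the mel-spectrograms of every call shorter
#' than the repertoire duration limit; longer calls are recorded in the
#' exclusion table rather than aborting the batch.
#'
#' @param annotations annotation data.frame.
#' @param audio_dir directory of WAV files, or `NULL` when `waves` given.
#' @param waves optional named list of waveforms keyed by call_id.
#' @param params mel parameters, see [mel_params()].
#' @param max_duration_s repertoire duration limit in seconds.
#' @return list with `specs` (named list of aligned matrices), `index`
#'   (call_id, original_frames), `excluded` (call_id, reason).
#' @export
prepare_spectrograms <- function(annotations, audio_dir = NULL, waves = NULL,
                                 params = NULL, max_duration_s = 1.25) {
  specs <- list(); excl <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    res <- tryCatch({
      w <- if (!is.null(waves)) waves[[a$call_id]]
           else read_wav(file.path(audio_dir, a$file))
      p <- if (is.null(params)) mel_params(w$rate) else params
      mel_spectrogram(w, p, call_id = a$call_id,
                      max_duration_s = max_duration_s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        call_id = a$call_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else specs[[a$call_id]] <- res
  }
  aligned <- pad_and_align(specs)
  names(aligned) <- names(specs)
  index <- data.frame(
    call_id = names(aligned),
    original_frames = vapply(aligned, attr, 0L, which = "original_frames"),
    stringsAsFactors = FALSE)
  list(specs = aligned, index = index,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(call_id = character(), reason = character()))
}

#' Persist / reload a prepared spectrogram set
#'
#' Writes the aligned matrices as an R binary archive (`<stem>.rds`) next to
#' a plain-text index (`<stem>_index.csv` with call_id and original_frames).
#'
#' @param prep result of [prepare_spectrograms()].
#' @param stem output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
save_spectrograms <- function(prep, stem) {
  saveRDS(prep$specs, paste0(stem, ".rds"))
  utils::write.csv(prep$index, paste0(stem, "_index.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname save_spectrograms
#' @export
load_spectrograms <- function(stem) {
  list(specs = readRDS(paste0(stem, ".rds")),
       index = utils::read.csv(paste0(stem, "_index.csv"),
                               stringsAsFactors = FALSE))
}
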