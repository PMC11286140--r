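#' Synthetic zebra-call generator
#'
#' The four call types of the plains zebra repertoire are emulated with
#' simple source models whose generating parameters are known exactly, so
#' that every downstream stage (feature extraction, classification,
#' clustering, individuality testing) can be validated against ground truth:
#'
#' * `squeal` — a harmonic stack on a smoothly varying, high fundamental
#'   frequency with mild sinusoidal amplitude modulation.
#' * `quagga_quagga` — a series of alternating two-syllable tonal units
#'   ("a-ha") separated by silent gaps.
#' * `snort` — broadband tilted noise with periodic amplitude pulses at the
#'   AM rate (the visible vibration pulses).
#' * `soft_snort` — broadband noise with a smooth, non-pulsed envelope at a
#'   lower level.
#'
#' @name synth
NULL

.zr_call_types <- c("snort", "soft_snort", "squeal", "quagga_quagga")

#' Default generating parameters for a call type
#'
#' Base values of the per-call generating parameters: fundamental frequency
#' `f0` (Hz, tonal types), harmonic count and spectral rolloff (dB/octave),
#' amplitude-modulation rate `am_rate` (cycles/s) and depth (dB), noise
#' spectral tilt (dB/octave, noisy types), relative level (dB), and for
#' quagga quagga the unit count range and gap fraction.
#'
#' @param call_type one of `"snort"`, `"soft_snort"`, `"squeal"`,
#'   `"quagga_quagga"`.
#' @return named list of generating parameters.
#' @export
default_call_params <- function(call_type) {
  call_type <- match.arg(call_type, .zr_call_types)
  switch(call_type,
    squeal = list(f0 = 1200, n_harmonics = 6, rolloff_db_oct = -6,
                  f0_mod_frac = 0.04, am_rate = 20, am_depth_db = 8,
                  tilt_db_oct = 0, level_db = 0),
    quagga_quagga = list(f0 = 700, n_harmonics = 5, rolloff_db_oct = -6,
                         f0_mod_frac = 0.03, n_units_min = 3, n_units_max = 6,
                         gap_frac = 0.35, am_rate = 0, am_depth_db = 0,
                         tilt_db_oct = 0, level_db = 0),
    snort = list(am_rate = 25, am_depth_db = 20, tilt_db_oct = -3,
                 level_db = 0, f0 = NA_real_),
    soft_snort = list(am_rate = 0, am_depth_db = 0, tilt_db_oct = 0,
                      level_db = -12, f0 = NA_real_))
}

# dB -> linear amplitude
.db2lin <- function(db) 10^(db / 20)

# harmonic stack with smooth rise-fall F0 contour; returns raw samples
.tonal_stack <- function(f0, n_harm, rolloff_db_oct, f0_mod_frac, n, rate) {
  t <- seq_len(n) / rate
  dur <- n / rate
  f0_t <- f0 * (1 + f0_mod_frac * sin(pi * t / dur))   # rise-fall contour
  phase <- 2 * pi * cumsum(f0_t) / rate
  x <- numeric(n)
  for (k in seq_len(n_harm)) {
    if (k * max(f0_t) >= rate / 2) break
    x <- x + .db2lin(rolloff_db_oct * log2(k)) * sin(k * phase)
  }
  x
}

# tilted broadband noise via frequency-domain shaping (tilt in dB/octave
# relative to 500 Hz); uses the current RNG stream
.tilted_noise <- function(n, rate, tilt_db_oct) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                                # two-sided
  gain <- .db2lin(tilt_db_oct * log2(pmax(f, 20) / 500))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# linear attack/decay ramps (seconds) applied in place
.apply_ramps <- function(x, rate, ramp_s = 0.01) {
  n <- length(x)
  r <- min(n %/% 2L, max(1L, round(ramp_s * rate)))
  ramp <- seq(0, 1, length.out = r)
  x[1:r] <- x[1:r] * ramp
  x[(n - r + 1):n] <- x[(n - r + 1):n] * rev(ramp)
  x
}

#' Synthesize one vocalization
#'
#' Generates a waveform of exactly `round(duration_s * rate)` samples for the
#' requested call type, using the generating parameters in `params` (see
#' [default_call_params()] for the fields). Background pink-ish noise is added
#' at `snr_db` so that high-pass filtering is exercised; set
#' `snr_db = Inf` for a clean call. Uses the current RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param call_type call type label.
#' @param params generating parameters; missing fields are filled from
#'   [default_call_params()].
#' @param duration_s call duration in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param snr_db signal-to-background ratio in dB (default 30).
#' @return a [waveform()].
#' @export
synth_call <- function(call_type, params = list(), duration_s, rate = 44100,
                       snr_db = 30) {
  call_type <- match.arg(call_type, .zr_call_types)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a positive number")
  p <- utils::modifyList(default_call_params(call_type), params)
  n <- round(duration_s * rate)
  t <- seq_len(n) / rate

  x <- switch(call_type,
    squeal = {
      carrier <- .tonal_stack(p$f0, p$n_harmonics, p$rolloff_db_oct,
                              p$f0_mod_frac, n, rate)
      # sinusoidal AM from 0 dB down to -am_depth_db, starting at a trough
      # so the onset/offset ramps never clip a modulation peak
      env <- .db2lin(p$am_depth_db * (-cos(2 * pi * p$am_rate * t) - 1) / 2)
      .apply_ramps(carrier * env, rate)
    },
    quagga_quagga = {
      n_units <- if (!is.null(p$n_units)) p$n_units else
        sample(p$n_units_min:p$n_units_max, 1L)
      unit_n <- floor(n * (1 - p$gap_frac) / n_units)
      gap_n <- if (n_units > 1)
        floor((n - n_units * unit_n) / (n_units - 1)) else 0L
      x <- numeric(n)
      pos <- 1L
      for (u in seq_len(n_units)) {
        # alternating exhale/inhale: every second unit shifted up in F0
        f0_u <- p$f0 * if (u %% 2 == 0) 1.2 else 1.0
        unit <- .tonal_stack(f0_u, p$n_harmonics, p$rolloff_db_oct,
                             p$f0_mod_frac, unit_n, rate)
        win <- 0.5 - 0.5 * cos(2 * pi * seq_len(unit_n) / (unit_n + 1))
        x[pos:(pos + unit_n - 1L)] <- unit * win
        pos <- pos + unit_n + gap_n
        if (pos + unit_n - 1L > n) break
      }
      x
    },
    snort = {
      noise <- .tilted_noise(n, rate, p$tilt_db_oct)
      # pulsed envelope: raised-cosine pulses at the AM rate, trough-first
      env <- .db2lin(p$am_depth_db * (-cos(2 * pi * p$am_rate * t) - 1) / 2)
      .apply_ramps(noise * env, rate)
    },
    soft_snort = {
      noise <- .tilted_noise(n, rate, p$tilt_db_oct)
      env <- (0.5 - 0.5 * cos(2 * pi * t / duration_s))^0.5  # smooth swell
      noise * env
    })

  x <- x / max(abs(x), 1e-12) * 0.5 * .db2lin(p$level_db)
  if (is.finite(snr_db)) {
    bg <- .tilted_noise(n, rate, -3)
    sig_rms <- sqrt(mean(x^2))
    bg <- bg / sqrt(mean(bg^2)) * sig_rms * .db2lin(-snr_db)
    x <- x + bg
  }
  waveform(pmin(1, pmax(-1, x)), rate)
}

#' Synthetic dataset configuration
#'
#' Defines the population and recording structure the generator emulates:
#' individuals nested in locations, a sex per individual, a fixed number of
#' calls per individual and type, between-individual (`individual_sd`) and
#' within-individual (`within_sd`) standard deviations on the generating
#' parameters, and optional additive sex and location effects. Setting every
#' `individual_sd` to zero gives the null model with no individual vocal
#' signatures.
#'
#' @param n_individuals_per_location individuals simulated at each location.
#' @param locations character vector of location labels.
#' @param calls_per_individual_per_type calls per individual per call type.
#' @param type_set subset of the four call types to generate.
#' @param individual_sd named list of between-individual SDs: `f0` (Hz),
#'   `am_rate` (1/s), `tilt` (dB/octave).
#' @param within_sd named list of call-to-call SDs, same names.
#' @param sex_effect additive parameter shift for males (females are the
#'   reference), same names.
#' @param location_effect named list (one entry per location) of additive
#'   shifts, same names; default all zero.
#' @param duration_range_s named list of per-type duration ranges (s).
#' @param sample_rate sampling rate in Hz.
#' @param snr_db signal-to-background ratio per call (dB).
#' @param sex_assignment optional named character vector individual -> "F"/"M";
#'   by default sexes alternate within each location.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return a validated `zr_synth_config` list.
#' @export
synth_config <- function(n_individuals_per_location = 6,
                         locations = c("KSP", "PNP"),
                         calls_per_individual_per_type = 10,
                         type_set = .zr_call_types,
                         individual_sd = list(f0 = 120, am_rate = 4, tilt = 0.8),
                         within_sd = list(f0 = 40, am_rate = 1.5, tilt = 0.3),
                         sex_effect = list(f0 = 0, am_rate = 0, tilt = 0),
                         location_effect = NULL,
                         duration_range_s = list(
                           snort = c(0.3, 0.7), soft_snort = c(0.25, 0.6),
                           squeal = c(0.3, 0.8), quagga_quagga = c(0.7, 1.2)),
                         sample_rate = 44100, snr_db = 30,
                         sex_assignment = NULL, seed = 1L) {
  type_set <- match.arg(type_set, .zr_call_types, several.ok = TRUE)
  pn <- c("f0", "am_rate", "tilt")
  fill <- function(l) {
    out <- stats::setNames(as.list(rep(0, 3)), pn)
    if (!is.null(l)) out[names(l)] <- l
    out
  }
  individual_sd <- fill(individual_sd); within_sd <- fill(within_sd)
  sex_effect <- fill(sex_effect)
  if (is.null(location_effect))
    location_effect <- stats::setNames(
      replicate(length(locations), fill(NULL), simplify = FALSE), locations)
  else
    location_effect <- lapply(stats::setNames(location_effect[locations],
                                              locations), fill)
  if (any(unlist(individual_sd) < 0) || any(unlist(within_sd) < 0))
    stop("standard deviations must be >= 0")
  for (ty in type_set) {
    r <- duration_range_s[[ty]]
    if (is.null(r) || length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("invalid duration range for type ", ty)
  }
  if (sample_rate <= 2 * 1200 * 6 / 2)  # must resolve squeal harmonics
    stop("sample_rate too low for the synthesized frequencies")
  structure(list(
    n_individuals_per_location = n_individuals_per_location,
    locations = locations,
    calls_per_individual_per_type = calls_per_individual_per_type,
    type_set = type_set, individual_sd = individual_sd,
    within_sd = within_sd, sex_effect = sex_effect,
    location_effect = location_effect, duration_range_s = duration_range_s,
    sample_rate = sample_rate, snr_db = snr_db,
    sex_assignment = sex_assignment, seed = as.integer(seed)),
    class = "zr_synth_config")
}

#' Generate a synthetic annotated dataset
#'
#' Draws one random-effect offset vector per individual (its vocal
#' signature), then per-call parameters around it with the within-individual
#' SDs, plus sex and location shifts; synthesizes each call with
#' [synth_call()] and (optionally) writes one WAV file per call. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @param out_dir directory for WAV files and the two CSV tables; created if
#'   needed. Required when `write_audio = TRUE`.
#' @param write_audio write WAV files (and keep waveforms in memory when
#'   `keep_waves = TRUE`)? With `FALSE` only the annotation and ground-truth
#'   tables are produced, which is enough for simulations that work directly
#'   on the generating parameters.
#' @param keep_waves return the waveforms in the result (avoids re-reading
#'   the WAVs downstream).
#' @return list with `annotations` (call_id, file, onset_s, offset_s,
#'   call_type, individual_id, sex, location), `truth` (the per-call true
#'   generating parameters plus each individual's offsets), and `waves`
#'   (named list of waveforms, if kept).
#' @export
generate_dataset <- function(config, out_dir = NULL, write_audio = TRUE,
                             keep_waves = write_audio) {
  stopifnot(inherits(config, "zr_synth_config"))
  if (write_audio && is.null(out_dir))
    stop("out_dir is required when write_audio = TRUE")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  pn <- c("f0", "am_rate", "tilt")

  inds <- data.frame(
    individual_id = character(), sex = character(), location = character(),
    stringsAsFactors = FALSE)
  for (loc in config$locations) {
    ids <- sprintf("%s_I%02d", loc, seq_len(config$n_individuals_per_location))
    sex <- if (!is.null(config$sex_assignment)) {
      unname(config$sex_assignment[ids])
    } else rep(c("F", "M"), length.out = length(ids))
    inds <- rbind(inds, data.frame(individual_id = ids, sex = sex,
                                   location = loc, stringsAsFactors = FALSE))
  }
  # one signature draw per individual, shared across call types
  offs <- sapply(pn, function(p)
    stats::rnorm(nrow(inds), 0, config$individual_sd[[p]]))
  offs <- matrix(offs, nrow = nrow(inds),
                 dimnames = list(inds$individual_id, pn))

  ann <- list(); truth <- list(); waves <- list()
  k <- 0L
  for (i in seq_len(nrow(inds))) {
    ind <- inds[i, ]
    shift <- sapply(pn, function(p)
      offs[ind$individual_id, p] +
        (if (ind$sex == "M") config$sex_effect[[p]] else 0) +
        config$location_effect[[ind$location]][[p]])
    for (ty in config$type_set) {
      base <- default_call_params(ty)
      for (j in seq_len(config$calls_per_individual_per_type)) {
        k <- k + 1L
        call_id <- sprintf("C%05d", k)
        dr <- config$duration_range_s[[ty]]
        dur <- stats::runif(1, dr[1], dr[2])
        par <- base
        f0_true <- am_true <- tilt_true <- mean_f0_true <- NA_real_
        if (ty %in% c("squeal", "quagga_quagga")) {
          f0_true <- max(350, base$f0 + shift["f0"] +
                           stats::rnorm(1, 0, config$within_sd$f0))
          par$f0 <- f0_true
          # expected mean F0 of the generated contour: the rise-fall
          # modulation averages to 1 + 2*mod/pi; quagga units alternate
          # between f0 and 1.2*f0
          contour_mean <- 1 + 2 * base$f0_mod_frac / pi
          if (ty == "quagga_quagga") {
            par$n_units <- sample(base$n_units_min:base$n_units_max, 1L)
            unit_mean <- (ceiling(par$n_units / 2) +
                            floor(par$n_units / 2) * 1.2) / par$n_units
            mean_f0_true <- f0_true * unit_mean * contour_mean
          } else {
            mean_f0_true <- f0_true * contour_mean
          }
        }
        if (ty == "snort") {
          am_true <- max(5, base$am_rate + shift["am_rate"] +
                           stats::rnorm(1, 0, config$within_sd$am_rate))
          par$am_rate <- am_true
        }
        if (ty == "squeal") {
          am_true <- max(5, base$am_rate + shift["am_rate"] / 2 +
                           stats::rnorm(1, 0, config$within_sd$am_rate))
          par$am_rate <- am_true
        }
        if (ty %in% c("snort", "soft_snort")) {
          tilt_true <- base$tilt_db_oct + shift["tilt"] +
            stats::rnorm(1, 0, config$within_sd$tilt)
          par$tilt_db_oct <- tilt_true
        }
        fname <- paste0(call_id, ".wav")
        if (write_audio || keep_waves) {
          wav <- synth_call(ty, par, dur, config$sample_rate, config$snr_db)
          if (write_audio) write_wav(wav, file.path(out_dir, fname))
          if (keep_waves) waves[[call_id]] <- wav
        }
        ann[[k]] <- data.frame(
          call_id = call_id, file = fname, onset_s = 0,
          offset_s = round(dur, 6), call_type = ty,
          individual_id = ind$individual_id, sex = ind$sex,
          location = ind$location, stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(
          call_id = call_id, call_type = ty,
          individual_id = ind$individual_id, sex = ind$sex,
          location = ind$location, duration_s = dur, f0 = f0_true,
          mean_f0 = mean_f0_true, am_rate = am_true, tilt = tilt_true,
          ind_f0_offset = unname(offs[ind$individual_id, "f0"]),
          ind_am_offset = unname(offs[ind$individual_id, "am_rate"]),
          ind_tilt_offset = unname(offs[ind$individual_id, "tilt"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  annotations <- do.call(rbind, ann)
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    utils::write.csv(annotations, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(annotations = annotations, truth = truth,
       waves = if (keep_waves) waves else NULL, dir = out_dir)
}
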