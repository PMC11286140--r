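# shared fixtures, built lazily once per test run

.zr_cache <- new.env(parent = emptyenv())

zr_cached <- function(name, expr) {
  if (is.null(.zr_cache[[name]])) assign(name, force(expr), .zr_cache)
  get(name, .zr_cache)
}

tone_wave <- function(freq, dur, rate = 44100, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * seq_len(round(dur * rate)) / rate), rate)
}

# compact dataset for module-level tests (22.05 kHz keeps it fast)
small_dataset <- function() zr_cached("small", {
  cfg <- synth_config(n_individuals_per_location = 4, locations = "KSP",
                      calls_per_individual_per_type = 5,
                      sample_rate = 22050, seed = 101)
  ds <- generate_dataset(cfg, write_audio = FALSE, keep_waves = TRUE)
  ft <- extract_feature_table(ds$annotations, waves = ds$waves)
  list(ds = ds, features = ft$features)
})

# study-condition dataset: 12 individuals x 4 types x 15 calls at 44.1 kHz
acceptance_dataset <- function() zr_cached("acc", {
  cfg <- synth_config(n_individuals_per_location = 6,
                      locations = c("KSP", "PNP"),
                      calls_per_individual_per_type = 15, seed = 42)
  ds <- generate_dataset(cfg, write_audio = FALSE, keep_waves = TRUE)
  ft <- extract_feature_table(ds$annotations, waves = ds$waves)
  list(ds = ds, features = ft$features)
})

# four separable Gaussian blobs at generic (asymmetric) centres
blob_fixture <- function(n_per = 100, seed = 1) {
  set.seed(seed)
  centres <- matrix(c(0, 0, 9, 1, 3, 10, 12, 8), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(n_per) + centres[i, 1], rnorm(n_per) + centres[i, 2])))
  list(x = x, labels = rep(letters[1:4], each = n_per))
}

# regression-residual oracle for partial correlations: q_jk given all other
# variables, via residuals of least-squares fits
partial_cor_oracle <- function(X) {
  p <- ncol(X)
  Q <- diag(p)
  for (j in 1:(p - 1)) for (k in (j + 1):p) {
    others <- setdiff(1:p, c(j, k))
    rj <- if (length(others)) residuals(lm(X[, j] ~ X[, others])) else X[, j]
    rk <- if (length(others)) residuals(lm(X[, k] ~ X[, others])) else X[, k]
    Q[j, k] <- Q[k, j] <- cor(rj, rk)
  }
  Q
}

kmo_oracle <- function(X) {
  R <- cor(X); Q <- partial_cor_oracle(X)
  diag(R) <- 0; diag(Q) <- 0
  per <- rowSums(R^2) / (rowSums(R^2) + rowSums(Q^2))
  list(per = per, overall = sum(R^2) / (sum(R^2) + sum(Q^2)))
}

# mean silhouette width, computed directly from definitions
silhouette_mean <- function(x, labels) {
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(tapply(d[i, labels != labels[i]], labels[labels != labels[i]],
                    mean))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
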