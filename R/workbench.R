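#' Workbench: annotations, inclusion rules and the end-to-end pipeline
#'
#' Annotation tables are the single source of labels (one row per call:
#' call_id, file, onset/offset, call_type, individual, sex, location). Two
#' inclusion rules mirror the study design: the repertoire analyses drop
#' calls longer than 1.25 s (strictly longer; a 1.25 s call is kept), and
#' the individuality analysis drops, per call type, individuals with fewer
#' than 5 calls of that type.
#'
#' @name workbench
NULL

.zr_ann_cols <- c("call_id", "file", "onset_s", "offset_s", "call_type",
                  "individual_id", "sex", "location")

#' Load and validate an annotation CSV
#'
#' Required columns: `call_id, file, onset_s, offset_s, call_type,
#' individual_id, sex, location`. Rows with `offset_s <= onset_s` or an
#' unknown call type are flagged (attribute `"flagged"`) and dropped rather
#' than fatal; a missing column is fatal.
#'
#' @param path CSV file path.
#' @return data.frame of valid records with a `duration_s` column;
#'   attribute `"flagged"` holds the rejected rows with reasons.
#' @export
load_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.zr_ann_cols, names(ann))
  if (length(missing))
    stop("annotation file missing required column(s): ",
         paste(missing, collapse = ", "))
  bad_time <- !is.finite(ann$onset_s) | !is.finite(ann$offset_s) |
    ann$offset_s <= ann$onset_s
  bad_type <- !ann$call_type %in% .zr_call_types
  flagged <- rbind(
    if (any(bad_time)) cbind(ann[bad_time, ], reason = "offset <= onset"),
    if (any(bad_type & !bad_time))
      cbind(ann[bad_type & !bad_time, ], reason = "unknown call_type"))
  keep <- ann[!(bad_time | bad_type), , drop = FALSE]
  keep$duration_s <- keep$offset_s - keep$onset_s
  attr(keep, "flagged") <- flagged
  keep
}

#' Apply the study inclusion rules
#'
#' `mode = "repertoire"` drops calls strictly longer than `max_duration_s`
#' (default 1.25 s). `mode = "individuality"` drops, within each call type,
#' all calls of individuals with fewer than `min_calls` (default 5) calls
#' of that type. Every excluded call appears exactly once in the log.
#'
#' @param records annotation data.frame (see [load_annotations()]).
#' @param mode `"repertoire"` or `"individuality"`.
#' @param max_duration_s repertoire duration limit (s).
#' @param min_calls individuality minimum calls per individual per type.
#' @return list `kept` (records) and `exclusions` (call_id, rule, detail).
#' @export
apply_inclusion_rules <- function(records,
                                  mode = c("repertoire", "individuality"),
                                  max_duration_s = 1.25, min_calls = 5) {
  mode <- match.arg(mode)
  dur <- records$offset_s - records$onset_s
  if (mode == "repertoire") {
    drop <- dur > max_duration_s
    excl <- data.frame(call_id = records$call_id[drop],
                       rule = rep("too_long", sum(drop)),
                       detail = sprintf("%.3f s > %.2f s", dur[drop],
                                        max_duration_s),
                       stringsAsFactors = FALSE)
  } else {
    key <- interaction(records$individual_id, records$call_type, drop = TRUE)
    n_by <- ave(seq_along(key), key, FUN = length)
    drop <- n_by < min_calls
    excl <- data.frame(call_id = records$call_id[drop],
                       rule = rep("too_few_per_individual", sum(drop)),
                       detail = sprintf("%d calls of %s for %s", n_by[drop],
                                        records$call_type[drop],
                                        records$individual_id[drop]),
                       stringsAsFactors = FALSE)
  }
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0) stop("no calls survive the ", mode,
                            " inclusion rules")
  list(kept = kept, exclusions = excl)
}

#' Pipeline configuration
#'
#' Validates the per-stage parameter blocks before anything runs. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param output_dir where all artifacts are written.
#' @param synth a [synth_config()] (or `NULL` to analyse existing audio
#'   under `audio_dir` with `annotations_csv`).
#' @param audio_dir,annotations_csv input audio + annotations when no
#'   synthesis is requested.
#' @param feature_split,spectrogram_split split fractions for the two
#'   supervised analyses.
#' @param shap_threshold feature-screening cutoff.
#' @param n_trials gradient-boosting tuning budget.
#' @param cnn [cnn_config()] for the spectrogram classifier.
#' @param k_max elbow search limit for clustering.
#' @param pdfa list with `n_permutations`, `n_selections`,
#'   `restriction_col`, `call_type`.
#' @param seed global seed.
#' @return validated `zr_pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, synth = synth_config(),
                            audio_dir = NULL, annotations_csv = NULL,
                            feature_split = c(0.7, 0.3),
                            spectrogram_split = c(0.49, 0.21, 0.30),
                            shap_threshold = 1, n_trials = 20,
                            cnn = cnn_config(), k_max = 8,
                            pdfa = list(n_permutations = 1000,
                                        n_selections = 100,
                                        restriction_col = "sex",
                                        call_type = "snort"),
                            seed = 1L) {
  bad <- setdiff(names(pdfa), c("n_permutations", "n_selections",
                                "restriction_col", "call_type"))
  if (length(bad)) stop("unknown pdfa key(s): ", paste(bad, collapse = ", "))
  for (fr in list(feature_split, spectrogram_split))
    if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-8)
      stop("split fractions must be positive and sum to 1")
  if (is.null(synth) && (is.null(audio_dir) || is.null(annotations_csv)))
    stop("either a synth config or audio_dir + annotations_csv is required")
  structure(list(output_dir = output_dir, synth = synth,
                 audio_dir = audio_dir, annotations_csv = annotations_csv,
                 feature_split = feature_split,
                 spectrogram_split = spectrogram_split,
                 shap_threshold = shap_threshold, n_trials = n_trials,
                 cnn = cnn, k_max = k_max, pdfa = pdfa,
                 seed = as.integer(seed)),
            class = "zr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `synth`
#' block takes [synth_config()] arguments.
#'
#' @param path YAML file.
#' @return a `zr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$cnn)) y$cnn <- do.call(cnn_config, y$cnn)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Synthesis (optional) -> feature extraction and spectrogram preparation
#' -> supervised and unsupervised repertoire analyses -> individuality
#' chain; every artifact lands under `config$output_dir` together with a
#' JSON manifest of inputs, parameters and seeds. Deterministic for a fixed
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("features", "spectrograms", "supervised", "unsupervised",
#'   "individuality")` to run after the data stage.
#' @return list of stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(config,
                         stages = c("features", "spectrograms", "supervised",
                                    "unsupervised", "individuality")) {
  stopifnot(inherits(config, "zr_pipeline_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  result <- list()

  if (!is.null(config$synth)) {
    ds <- generate_dataset(config$synth, file.path(out, "audio"),
                           write_audio = TRUE, keep_waves = TRUE)
    ann <- ds$annotations
    waves <- ds$waves
    audio_dir <- file.path(out, "audio")
  } else {
    ann <- load_annotations(config$annotations_csv)
    waves <- NULL
    audio_dir <- config$audio_dir
  }
  ann$duration_s <- ann$offset_s - ann$onset_s
  result$n_calls <- nrow(ann)

  rep_rules <- apply_inclusion_rules(ann, "repertoire")
  utils::write.csv(rep_rules$exclusions,
                   file.path(out, "exclusions_repertoire.csv"),
                   row.names = FALSE)

  feats <- NULL
  if ("features" %in% stages) {
    ft <- extract_feature_table(rep_rules$kept, audio_dir, waves)
    feats <- ft$features
    utils::write.csv(feats, file.path(out, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(ft$failures, file.path(out, "feature_failures.csv"),
                     row.names = FALSE)
    result$features <- feats
  }

  prep <- NULL
  if ("spectrograms" %in% stages) {
    prep <- prepare_spectrograms(rep_rules$kept, audio_dir, waves)
    save_spectrograms(prep, file.path(out, "spectrograms"))
    result$spectrograms <- prep$index
  }

  if ("supervised" %in% stages && !is.null(feats)) {
    rf <- feature_names("repertoire")
    ok <- stats::complete.cases(feats[rf])
    sel <- select_features_by_importance(feats[ok, rf],
                                         feats$call_type[ok],
                                         threshold = config$shap_threshold,
                                         seed = config$seed)
    fc <- train_feature_classifier(feats[ok, sel$selected],
                                   feats$call_type[ok],
                                   fractions = config$feature_split,
                                   n_trials = config$n_trials,
                                   seed = config$seed)
    result$feature_classifier <- fc
    jsonlite::write_json(list(
      selected = sel$selected, importance = as.list(sel$importance),
      accuracy = fc$report$accuracy, per_class = fc$report$per_class,
      confusion = as.data.frame(fc$report$confusion)),
      file.path(out, "supervised_features.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(prep)) {
      ids <- intersect(names(prep$specs), feats$call_id[ok])
      labs <- feats$call_type[match(ids, feats$call_id)]
      sc <- train_spectrogram_classifier(prep$specs[ids], labs,
                                         fractions = config$spectrogram_split,
                                         config = config$cnn,
                                         seed = config$seed)
      result$spectrogram_classifier <- sc
      jsonlite::write_json(list(
        accuracy = sc$report$accuracy, per_class = sc$report$per_class),
        file.path(out, "supervised_spectrograms.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  if ("unsupervised" %in% stages && !is.null(feats)) {
    rf <- feature_names("repertoire")
    ok <- stats::complete.cases(feats[rf])
    emb <- embed_2d(feats[ok, rf], metric = "euclidean")
    cl <- cluster_and_diagnose(emb, feats$call_type[ok],
                               k_max = config$k_max, seed = config$seed)
    result$clustering <- cl
    utils::write.csv(data.frame(call_id = feats$call_id[ok], emb,
                                cluster = cl$assignments),
                     file.path(out, "clusters_features.csv"),
                     row.names = FALSE)
  }

  if ("individuality" %in% stages && !is.null(feats)) {
    pd_cfg <- config$pdfa
    ind_rules <- apply_inclusion_rules(ann, "individuality")
    keep_ids <- ind_rules$kept$call_id[
      ind_rules$kept$call_type == pd_cfg$call_type]
    fi <- feats[feats$call_id %in% keep_ids, , drop = FALSE]
    if (nrow(fi) > 0 && length(unique(fi$individual_id)) >= 2) {
      ia <- individuality_analysis(
        fi, restriction_col = pd_cfg$restriction_col,
        n_permutations = pd_cfg$n_permutations,
        n_selections = pd_cfg$n_selections, seed = config$seed)
      result$individuality <- ia
      jsonlite::write_json(list(
        call_type = pd_cfg$call_type,
        restriction = pd_cfg$restriction_col,
        observed_correct = ia$pdfa$observed_correct,
        expected_correct = ia$pdfa$expected_correct,
        percent_correct = ia$pdfa$percent_correct,
        chance_percent = ia$pdfa$chance_percent,
        p_value = ia$pdfa$p_value),
        file.path(out, "individuality.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed, stages = stages,
    synth_seed = if (!is.null(config$synth)) config$synth$seed else NULL,
    n_calls = nrow(ann),
    parameters = list(feature_split = config$feature_split,
                      spectrogram_split = config$spectrogram_split,
                      shap_threshold = config$shap_threshold,
                      n_trials = config$n_trials, k_max = config$k_max,
                      pdfa = config$pdfa))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}
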