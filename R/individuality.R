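#' Vocal-individuality analysis chain
#'
#' The individuality of a call type is quantified in four steps:
#' Kaiser-Meyer-Olkin screening of the acoustic features (keep features
#' with sampling adequacy MSA >= 0.5), principal component reduction of
#' the retained features (keep components with eigenvalue > 1), a
#' discriminant function analysis with individual identity as the grouping
#' factor (DF variance shares and DF-PC correlations, flagged at
#' |r| >= 0.5), and a nested permuted DFA that tests whether calls are
#' cross-classified to the correct individual above chance while permuting
#' identities only within levels of a restriction factor (sex or location).
#'
#' @name individuality
NULL

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Per-variable MSA compares squared Pearson correlations against squared
#' anti-image partial correlations (obtained from the inverse correlation
#' matrix): `MSA_j = sum r2_jk / (sum r2_jk + sum q2_jk)` over `k != j`;
#' the overall MSA pools both sums over all pairs. Variables with
#' MSA >= `threshold` are retained for factor-analytic reduction.
#'
#' @param X numeric matrix/data.frame, more rows than columns.
#' @param threshold retention cutoff on per-variable MSA (default 0.5).
#' @return `zr_kmo` list: `overall_msa`, `per_variable_msa` (named),
#'   `retained` (feature names).
#' @export
kmo <- function(X, threshold = 0.5) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more observations than variables")
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || !all(is.finite(Rinv)) || kappa(R) > 1e10) {
    cc <- which(abs(R) > 0.999 & upper.tri(R), arr.ind = TRUE)
    pairs <- if (nrow(cc)) paste(colnames(R)[cc[, 1]], colnames(R)[cc[, 2]],
                                 sep = "~", collapse = ", ") else "unknown"
    stop("correlation matrix is singular; collinear variables: ", pairs)
  }
  # anti-image partial correlations
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)
  diag(R) <- 0; diag(Q) <- 0
  r2 <- R^2; q2 <- Q^2
  per <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per) <- colnames(X)
  overall <- sum(r2) / (sum(r2) + sum(q2))
  structure(list(overall_msa = overall, per_variable_msa = per,
                 retained = names(per)[per >= threshold],
                 threshold = threshold),
            class = "zr_kmo")
}

#' @export
print.zr_kmo <- function(x, ...) {
  cat(sprintf("KMO overall MSA: %.3f\n", x$overall_msa))
  print(round(x$per_variable_msa, 3))
  cat("retained (MSA >=", x$threshold, "):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component reduction of the retained features
#'
#' Centers and unit-scales the variables, eigendecomposes the correlation
#' matrix, and retains components with eigenvalue > 1 (Kaiser criterion).
#' Loading signs are fixed so each component's largest-magnitude loading is
#' positive (a reporting convention only).
#'
#' @param X numeric matrix/data.frame of KMO-retained features (>= 2).
#' @return `zr_pca` list: `loadings` (variables x components),
#'   `eigenvalues`, `scores` (all components), `retained_components`
#'   (indices with eigenvalue > 1), `retained_scores`.
#' @export
pca_reduce <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 retained features")
  Z <- base::scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  L <- eg$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- Z %*% L
  keep <- which(eg$values > 1)
  if (length(keep) == 0) stop("no component with eigenvalue > 1")
  structure(list(loadings = L, eigenvalues = eg$values, scores = scores,
                 retained_components = keep,
                 retained_scores = scores[, keep, drop = FALSE]),
            class = "zr_pca")
}

# ---- internal pooled-covariance linear discriminant classifier ----------
# Classical LDA: pooled within-group covariance (ridge eps for numerical
# safety), equal priors; used inside dfa() and the pDFA permutation loop
# where speed matters. Ties broken by lowest group index.

.lda_fit <- function(X, g, ridge = 1e-8) {
  X <- as.matrix(X)
  groups <- sort(unique(as.character(g)))
  p <- ncol(X)
  M <- matrix(0, length(groups), p, dimnames = list(groups, NULL))
  Sw <- matrix(0, p, p)
  for (k in seq_along(groups)) {
    Xi <- X[g == groups[k], , drop = FALSE]
    ni <- nrow(Xi)
    if (ni < 2) stop("group '", groups[k],
                     "' has fewer than 2 observations")
    mu <- colMeans(Xi)
    M[k, ] <- mu
    Sw <- Sw + crossprod(Xi) - ni * outer(mu, mu)
  }
  Sw <- Sw / (nrow(X) - length(groups)) + diag(ridge, p)
  W <- solve(Sw)
  # linear scores: x' W m_k - 0.5 m_k' W m_k
  A <- W %*% t(M)
  c0 <- -0.5 * colSums(t(M) * A)
  list(groups = groups, A = A, c0 = c0, M = M, Sw = Sw, W = W)
}

# nested permutation: shuffle the call -> individual assignment only among
# calls sharing a restriction level, so every call keeps its level and each
# individual keeps its call count within the level
.permute_within <- function(ind, res) {
  out <- ind
  for (lev in unique(res)) {
    ix <- which(res == lev)
    out[ix] <- ind[ix][sample.int(length(ix))]
  }
  out
}

.lda_classify <- function(fit, X) {
  S <- as.matrix(X) %*% fit$A + matrix(fit$c0, nrow(X), length(fit$c0),
                                       byrow = TRUE)
  fit$groups[max.col(S, ties.method = "first")]
}

#' Discriminant function analysis of individual identity
#'
#' Linear discriminant functions with individual identity as the grouping
#' factor: eigendecomposition of the between-group relative to the pooled
#' within-group covariance gives `min(groups - 1, variables)` discriminant
#' functions, their percent of discriminative variance, and the correlation
#' of each DF score with each input (PC) score, flagged at
#' `|r| >= corr_flag`.
#'
#' @param scores numeric matrix of PC scores (columns named).
#' @param groups individual identity labels; every individual needs >= 2
#'   calls.
#' @param corr_flag threshold for flagging DF-PC correlations (default 0.5).
#' @param ridge ridge added to the pooled covariance.
#' @return `zr_dfa` list: `coefficients` (variables x DFs),
#'   `percent_variance`, `df_scores`, `correlations` (DF x PC), `flagged`
#'   (logical matrix `|r| >= corr_flag`), `fit` (internal classifier).
#' @export
dfa <- function(scores, groups, corr_flag = 0.5, ridge = 1e-8) {
  X <- as.matrix(scores)
  g <- as.character(groups)
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 individuals")
  if (any(tab < 2)) stop("individual(s) with a single call: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  fit <- .lda_fit(X, g, ridge)
  # between-group covariance of group means (weighted by group size)
  gm <- colMeans(X)
  Sb <- matrix(0, ncol(X), ncol(X))
  for (k in seq_along(fit$groups)) {
    d <- fit$M[k, ] - gm
    Sb <- Sb + tab[[fit$groups[k]]] * outer(d, d)
  }
  Sb <- Sb / (nrow(X) - 1)
  # whiten by Sw^{-1/2}, then symmetric eigenproblem
  es <- eigen(fit$Sw, symmetric = TRUE)
  Swi2 <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)),
                              ncol(X)) %*% t(es$vectors)
  eg <- eigen(Swi2 %*% Sb %*% Swi2, symmetric = TRUE)
  n_df <- min(length(fit$groups) - 1L, ncol(X))
  V <- Swi2 %*% eg$vectors[, seq_len(n_df), drop = FALSE]
  colnames(V) <- paste0("DF", seq_len(n_df))
  rownames(V) <- colnames(X)
  ev <- pmax(eg$values[seq_len(n_df)], 0)
  pct <- if (sum(ev) > 0) ev / sum(ev) * 100 else rep(100 / n_df, n_df)
  df_scores <- base::scale(X, center = gm, scale = FALSE) %*% V
  cors <- stats::cor(df_scores, X)
  rownames(cors) <- colnames(V)
  structure(list(coefficients = V, percent_variance = pct,
                 df_scores = df_scores, correlations = cors,
                 flagged = abs(cors) >= corr_flag, fit = fit),
            class = "zr_dfa")
}

#' @export
print.zr_dfa <- function(x, ...) {
  cat("Discriminant functions:", ncol(x$coefficients), "\n")
  cat("percent variance:", paste(sprintf("%.1f", x$percent_variance),
                                 collapse = ", "), "\n")
  cat("DF-PC correlations (| r | flagged at threshold):\n")
  print(round(x$correlations, 2))
  invisible(x)
}

#' Nested permuted discriminant function analysis
#'
#' Tests whether calls can be assigned to the correct individual above
#' chance, controlling for a restriction factor (e.g. sex or location)
#' under which identities are nested:
#'
#' 1. *Balanced cross-classification.* For each of `n_selections` draws, an
#'    equal number of calls per individual (the derivation set,
#'    `max(2, floor(derivation_frac * min per-individual count))` calls) is
#'    sampled; a linear DFA fitted on it classifies the withheld calls;
#'    `observed_correct` is the mean number classified to the correct
#'    individual over draws.
#' 2. *Nested null.* For each of `n_permutations - 1` permutations, the
#'    call-to-individual assignment is shuffled only among individuals
#'    sharing a restriction level (preserving per-individual call counts),
#'    and the selection-averaged correct count is recomputed. The observed
#'    dataset counts as one permutation, so the smallest attainable p-value
#'    is `1 / n_permutations`.
#' 3. `p_value` = share of permutations with a count >= the observed one;
#'    `expected_correct` = mean permuted count (the chance level); the
#'    percentage fields divide both counts by the number of withheld calls.
#'
#' @param scores numeric matrix of PC scores, one row per call.
#' @param individual individual identity per call; each individual must
#'   belong to exactly one restriction level.
#' @param restriction restriction-factor level per call (sex or location).
#'   A level containing a single individual contributes nothing to the
#'   null (warned); a single level overall reduces to an unrestricted pDFA.
#' @param n_permutations total permutations including the observed dataset
#'   (default 1000).
#' @param n_selections balanced derivation-set draws per dataset
#'   (default 100).
#' @param derivation_frac fraction of the minimum per-individual call count
#'   used for the derivation set (default 0.6).
#' @param seed integer seed.
#' @param ridge ridge for the internal LDA.
#' @return `zr_pdfa` list: `observed_correct`, `expected_correct`,
#'   `percent_correct`, `chance_percent`, `p_value`, `n_withheld`,
#'   `n_permutations`, `n_selections`, `restriction_factor`, `seed`,
#'   `permuted_counts`.
#' @export
nested_pdfa <- function(scores, individual, restriction,
                        n_permutations = 1000, n_selections = 100,
                        derivation_frac = 0.6, seed = 1L, ridge = 1e-8) {
  X <- as.matrix(scores)
  ind <- as.character(individual)
  res <- as.character(restriction)
  stopifnot(nrow(X) == length(ind), length(ind) == length(res))
  map <- unique(data.frame(ind, res, stringsAsFactors = FALSE))
  if (anyDuplicated(map$ind))
    stop("an individual maps to more than one restriction level")
  counts <- table(ind)
  if (any(counts < 3))
    stop("each individual needs >= 3 calls for derivation + withheld sets")
  singles <- names(which(table(map$res) == 1))
  if (length(singles))
    warning("restriction level(s) with a single individual contribute ",
            "nothing to the null: ", paste(singles, collapse = ", "))
  n_derive <- max(2L, floor(derivation_frac * min(counts)))
  n_withheld <- nrow(X) - n_derive * length(counts)
  if (n_withheld < 1) stop("derivation_frac leaves no withheld calls")

  set.seed(seed)
  n <- nrow(X)
  cross_count <- function(ind_vec) {
    by_ind <- split(seq_len(n), ind_vec)
    total <- 0
    for (s in seq_len(n_selections)) {
      der <- unlist(lapply(by_ind, function(ix) ix[sample.int(length(ix),
                                                              n_derive)]),
                    use.names = FALSE)
      fit <- .lda_fit(X[der, , drop = FALSE], ind_vec[der], ridge)
      held <- seq_len(n)[-der]
      pred <- .lda_classify(fit, X[held, , drop = FALSE])
      total <- total + sum(pred == ind_vec[held])
    }
    total / n_selections
  }

  observed <- cross_count(ind)
  permuted <- numeric(n_permutations - 1L)
  for (b in seq_len(n_permutations - 1L)) {
    permuted[b] <- cross_count(.permute_within(ind, res))
  }
  p <- (1 + sum(permuted >= observed)) / n_permutations
  structure(list(
    observed_correct = observed,
    expected_correct = mean(permuted),
    percent_correct = observed / n_withheld * 100,
    chance_percent = mean(permuted) / n_withheld * 100,
    p_value = p, n_withheld = n_withheld,
    n_permutations = n_permutations, n_selections = n_selections,
    n_derive = n_derive, restriction_factor = "restriction",
    seed = seed, permuted_counts = permuted),
    class = "zr_pdfa")
}

#' @export
print.zr_pdfa <- function(x, ...) {
  cat("Nested permuted DFA\n")
  cat(sprintf("  no. of correct cross-classified calls:          %.2f\n",
              x$observed_correct))
  cat(sprintf("  expected no. of correct cross-classified calls: %.2f\n",
              x$expected_correct))
  cat(sprintf("  correctly cross-classified percentage:          %.2f%%\n",
              x$percent_correct))
  cat(sprintf("  cross-classified chance level:                  %.2f%%\n",
              x$chance_percent))
  cat(sprintf("  p-value (%d permutations, %d selections):       %.3f\n",
              x$n_permutations, x$n_selections, x$p_value))
  invisible(x)
}

#' Run the full individuality chain for one call type
#'
#' KMO screening of the 12 features -> PCA (eigenvalue > 1) -> DFA with
#' individual identity as the grouping factor -> nested pDFA with the
#' requested restriction factor.
#'
#' @param features feature data.frame including the feature columns plus
#'   `individual_id` and the restriction column.
#' @param feature_cols feature columns to screen (default the full
#'   12-feature set present in the data without missing values).
#' @param restriction_col column name of the restriction factor
#'   (`"sex"` or `"location"`).
#' @param n_permutations,n_selections,seed passed to [nested_pdfa()].
#' @return list with `kmo`, `pca`, `dfa`, `pdfa`.
#' @export
individuality_analysis <- function(features, feature_cols = NULL,
                                   restriction_col = "sex",
                                   n_permutations = 1000,
                                   n_selections = 100, seed = 1L) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_names("all"), names(features))
    feature_cols <- feature_cols[colSums(is.na(features[feature_cols])) == 0]
  }
  km <- kmo(features[feature_cols])
  pc <- pca_reduce(features[km$retained])
  df <- dfa(pc$retained_scores, features$individual_id)
  pd <- nested_pdfa(pc$retained_scores, features$individual_id,
                    features[[restriction_col]],
                    n_permutations = n_permutations,
                    n_selections = n_selections, seed = seed)
  pd$restriction_factor <- restriction_col
  list(kmo = km, pca = pc, dfa = df, pdfa = pd)
}
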