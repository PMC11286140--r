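#' Unsupervised repertoire clustering
#'
#' Calls are embedded in two dimensions — from the acoustic features
#' (Euclidean metric on standardized features) or from the aligned
#' mel-spectrograms (the time-shift-aware distance) — then clustered with
#' k-means; the cluster count is picked by the elbow of the within-cluster
#' sum-of-squares curve. Diagnostics follow the repertoire study: a
#' type-by-cluster confusion table (row proportions) and the distributions
#' of pairwise distances within versus between call types.
#'
#' @name repertoire_unsupervised
NULL

#' Pairwise distance matrix for either representation
#'
#' @param x numeric matrix (feature mode, Euclidean on standardized
#'   columns) or a list of equal-shape spectrogram matrices (spectrogram
#'   mode, [timeshift_distance()]).
#' @param metric `"euclidean"` or `"timeshift"`.
#' @param max_shift shift window for the time-shift metric (frames).
#' @param scale standardize feature columns first (feature mode)?
#' @return a `dist` object.
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "timeshift"),
                               max_shift = NULL, scale = TRUE) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    x <- as.matrix(x)
    if (scale) x <- base::scale(x)
    stats::dist(x)
  } else {
    n <- length(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- timeshift_distance(x[[i]], x[[j]], max_shift)
    }
    stats::as.dist(d)
  }
}

#' Embed calls in two dimensions
#'
#' Neighbor-graph spectral embedding (Laplacian eigenmap): a k-nearest-
#' neighbor graph is built on the pairwise distances — Euclidean on
#' standardized features in feature mode, the time-shift spectrogram
#' distance in spectrogram mode — with locally adaptive Gaussian edge
#' weights (each call's kernel width is its median distance to its
#' neighbors), and the two leading non-trivial eigenvectors of the
#' symmetric normalized graph Laplacian give the coordinates. Like other
#' neighbor-based manifold embeddings, this equalizes the separation of
#' well-isolated groups, which is what makes the downstream elbow curve
#' interpretable. Deterministic: no stochastic optimization is involved.
#'
#' @param x feature matrix or list of spectrograms (see
#'   [pairwise_distances()]); alternatively a precomputed `dist`.
#' @param metric distance metric (ignored when `x` is a `dist`).
#' @param n_neighbors neighborhood size of the graph (default 50; it should
#'   stay below the expected size of a call-type group so neighborhoods do
#'   not bridge distinct types; clamped to n - 1 with a warning when the
#'   dataset is smaller).
#' @param max_shift shift window for the time-shift metric.
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(x, metric = c("euclidean", "timeshift"),
                     n_neighbors = 50, max_shift = NULL) {
  d <- if (inherits(x, "dist")) x
       else pairwise_distances(x, metric, max_shift)
  n <- attr(d, "Size")
  if (n < 10) stop("need at least 10 calls to embed")
  if (n_neighbors > n - 1) {
    warning("n_neighbors = ", n_neighbors, " clamped to n - 1 = ", n - 1)
    n_neighbors <- n - 1
  }
  dm <- as.matrix(d)
  nn <- t(apply(dm, 1, function(r) {
    ord <- order(r)[-1]          # drop self
    out <- rep(FALSE, n); out[ord[seq_len(n_neighbors)]] <- TRUE; out
  }))
  # locally adaptive kernel width: median distance to the k neighbors
  sig <- vapply(seq_len(n), function(i) stats::median(dm[i, nn[i, ]]), 0)
  sig <- pmax(sig, 1e-12)
  W <- exp(-dm^2 / outer(sig, sig))
  W[!(nn | t(nn))] <- 0          # union-of-neighborhoods graph
  # faint global affinity keeps the graph connected: with fully isolated
  # components the Laplacian null space is degenerate and two groups can
  # collapse onto one 2-D coordinate
  gsig <- stats::median(dm)
  W <- W + 1e-6 * exp(-dm^2 / gsig^2)
  diag(W) <- 0
  deg <- pmax(rowSums(W), 1e-12)
  L <- diag(n) - W / sqrt(outer(deg, deg))   # symmetric normalized Laplacian
  eg <- eigen(L, symmetric = TRUE)
  coords <- eg$vectors[, c(n - 1L, n - 2L)] / sqrt(deg)
  coords <- base::scale(coords)              # unit variance per axis
  colnames(coords) <- c("dim1", "dim2")
  coords
}

# elbow: k at the maximum discrete second difference of the log-inertia
# curve (scale-invariant, so a bend after an already-large drop still
# registers). A smooth structureless curve has elbow strength
# I(k-1)I(k+1)/I(k)^2 near 1; below `strength` the data are declared
# unclustered (k = 1).
.elbow_k <- function(inertia, strength = 3) {
  k_max <- length(inertia)
  if (k_max < 3) return(1L)
  li <- log(pmax(inertia, max(inertia[1], 1e-300) * 1e-12))
  d2 <- li[1:(k_max - 2)] - 2 * li[2:(k_max - 1)] + li[3:k_max]
  if (max(d2) < log(strength)) return(1L)
  which.max(d2) + 1L
}

#' Cluster calls and diagnose against the true types
#'
#' Runs k-means for k = 1..`k_max` on the clustering representation
#' (default: the 2-D embedding), selects k at the elbow (maximum discrete
#' second difference of the within-cluster sum of squares), and reports the
#' row-normalized type-by-cluster table plus sampled pairwise distances
#' within and between call types.
#'
#' @param x clustering representation: n x p numeric matrix (e.g. the 2-D
#'   embedding from [embed_2d()]).
#' @param types true call-type labels (diagnostics only; clustering never
#'   sees them).
#' @param k_max largest cluster count examined.
#' @param nstart k-means restarts per k.
#' @param max_pairs cap on sampled distance pairs per group.
#' @param seed integer seed (k-means starts, pair sampling).
#' @return `zr_clustering` list: `k`, `assignments`, `inertia_by_k`,
#'   `type_cluster_matrix` (rows = types, row proportions),
#'   `within_distances`, `between_distances`, `overlap_coefficient`,
#'   `embedding` (= `x`).
#' @export
cluster_and_diagnose <- function(x, types, k_max = 8, nstart = 10,
                                 max_pairs = 50000, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k_max) stop("need more calls than k_max")
  set.seed(seed)
  degenerate <- all(apply(x, 2, function(c) diff(range(c)) < 1e-12))
  if (degenerate) {
    k <- 1L
    inertia <- rep(0, k_max)
    assign <- rep(1L, n)
  } else {
    inertia <- numeric(k_max)
    fits <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      fits[[k]] <- stats::kmeans(x, centers = k, nstart = nstart,
                                 iter.max = 50)
      inertia[k] <- fits[[k]]$tot.withinss
    }
    inertia <- cummin(inertia)         # guard against local-optimum bumps
    k <- .elbow_k(inertia)
    assign <- fits[[k]]$cluster
  }
  tcm <- table(type = types, cluster = assign)
  tcm <- sweep(tcm, 1, pmax(rowSums(tcm), 1), `/`)
  d <- as.matrix(stats::dist(x))
  same <- outer(types, types, `==`)
  ut <- upper.tri(d)
  wd <- d[ut & same]; bd <- d[ut & !same]
  if (length(wd) > max_pairs) wd <- sample(wd, max_pairs)
  if (length(bd) > max_pairs) bd <- sample(bd, max_pairs)
  structure(list(k = k, assignments = assign, inertia_by_k = inertia,
                 type_cluster_matrix = tcm, within_distances = wd,
                 between_distances = bd,
                 overlap_coefficient = overlap_coefficient(wd, bd),
                 embedding = x),
            class = "zr_clustering")
}

#' @export
print.zr_clustering <- function(x, ...) {
  cat(sprintf("k-means elbow: k = %d (k_max = %d)\n", x$k,
              length(x$inertia_by_k)))
  cat("Type x cluster (row proportions):\n")
  print(round(x$type_cluster_matrix, 2))
  cat(sprintf("within/between distance overlap coefficient: %.3f\n",
              x$overlap_coefficient))
  invisible(x)
}

#' Histogram overlap coefficient of two distance samples
#'
#' Shared area of the two normalized histograms on a common grid; 0 means
#' fully disjoint distributions, 1 identical.
#'
#' @param a,b numeric samples.
#' @param nbins histogram bins over the pooled range.
#' @return overlap in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b, nbins = 50) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  breaks <- seq(min(a, b), max(a, b), length.out = nbins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[nbins + 1] <- breaks[nbins + 1] + 1e-9
  ha <- hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  hb <- hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(pmin(ha, hb))
}
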