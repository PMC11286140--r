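test_that("KMO equals the regression-residual partial-correlation oracle", {
  set.seed(51)
  for (rep in 1:20) {
    X <- matrix(rnorm(200 * 5), 200, 5)
    colnames(X) <- paste0("v", 1:5)
    got <- kmo(X)
    want <- kmo_oracle(X)
    expect_equal(unname(got$per_variable_msa), unname(want$per),
                 tolerance = 1e-6)
    expect_equal(got$overall_msa, want$overall, tolerance = 1e-6)
  }
})

test_that("KMO rejects collinear input and keeps adequate blocks", {
  set.seed(52)
  X <- matrix(rnorm(300), 100, 3)
  X <- cbind(X, X[, 1])
  colnames(X) <- c("a", "b", "c", "a2")
  expect_error(kmo(X), "singular|collinear")
  # block of strongly correlated variables with weak partials
  f <- rnorm(300)
  B <- sapply(1:4, function(i) f + rnorm(300, 0, 0.6))
  colnames(B) <- paste0("b", 1:4)
  res <- kmo(B)
  expect_true(all(res$per_variable_msa > 0.5))
  expect_setequal(res$retained, colnames(B))
})

test_that("PCA retention follows the eigenvalue > 1 rule", {
  set.seed(53)
  # two latent factors + noise -> two retained components
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, 0, 0.4), f1 + rnorm(n, 0, 0.4),
             f1 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.4),
             f2 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.4))
  colnames(X) <- paste0("x", 1:6)
  pc <- pca_reduce(X)
  expect_equal(length(pc$retained_components), 2)
  expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_identical(pc$retained_components,
                   which(pc$eigenvalues > 1))
  # full reconstruction from all components
  Z <- scale(X)
  expect_equal(pc$scores %*% t(pc$loadings), Z, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("DFA recovers a separation confined to one component", {
  set.seed(54)
  n <- 60
  scores <- cbind(PC1 = c(rnorm(n, -3, 0.5), rnorm(n, 3, 0.5)),
                  PC2 = rnorm(2 * n))
  g <- rep(c("i1", "i2"), each = n)
  d <- dfa(scores, g)
  expect_equal(ncol(d$coefficients), 1)       # 2 groups -> 1 DF
  expect_gt(abs(d$correlations["DF1", "PC1"]), 0.95)
  expect_true(d$flagged["DF1", "PC1"])
  expect_lt(abs(d$correlations["DF1", "PC2"]), 0.5)
})

test_that("DFA dimensionality and variance shares follow the rank rule", {
  set.seed(55)
  scores <- matrix(rnorm(300), 150, 2)
  colnames(scores) <- c("PC1", "PC2")
  g <- rep(c("a", "b", "c"), each = 50)
  scores[g == "b", 1] <- scores[g == "b", 1] + 4
  scores[g == "c", 2] <- scores[g == "c", 2] + 4
  d <- dfa(scores, g)
  expect_equal(ncol(d$coefficients), 2)       # min(3 - 1, 2)
  expect_equal(sum(d$percent_variance), 100)
  expect_error(dfa(scores[c(1, 51, 52, 101, 102), ],
                   c("a", "b", "b", "c", "c")), "single call")
})

test_that("DFA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(56)
  n <- 40
  scores <- cbind(PC1 = c(rnorm(n, 0), rnorm(n, 2), rnorm(n, 4)),
                  PC2 = c(rnorm(n, 1), rnorm(n, -1), rnorm(n, 0)))
  g <- rep(c("a", "b", "c"), each = n)
  ours <- dfa(scores, g)
  ref <- MASS::lda(scores, g)
  # discriminant directions collinear with the reference scalings
  for (j in 1:2) {
    cosang <- abs(sum(ours$coefficients[, j] * ref$scaling[, j])) /
      sqrt(sum(ours$coefficients[, j]^2) * sum(ref$scaling[, j]^2))
    expect_gt(cosang, 0.999)
  }
  expect_equal(ours$percent_variance / 100,
               ref$svd^2 / sum(ref$svd^2), tolerance = 1e-6)
  # classification of the internal classifier matches the reference
  ours_pred <- zebrarep:::.lda_classify(zebrarep:::.lda_fit(scores, g),
                                        scores)
  ref_pred <- as.character(predict(ref, scores)$class)
  expect_gt(mean(ours_pred == ref_pred), 0.99)
})

test_that("pDFA counts a perfectly separable toy exactly", {
  # two individuals, 5 calls each, far apart: every derivation DFA
  # classifies every withheld call correctly, under every selection
  scores <- cbind(c(rep(0, 5), rep(100, 5)) + (1:10) / 10)
  ind <- rep(c("i1", "i2"), each = 5)
  res <- rep("F", 10)
  pd <- suppressWarnings(
    nested_pdfa(scores, ind, res, n_permutations = 50, n_selections = 20,
                seed = 1))
  # derivation 3 per individual -> 4 withheld, all correct every time
  expect_equal(pd$n_withheld, 4)
  expect_equal(pd$observed_correct, 4)
  expect_equal(pd$percent_correct, 100)
})

test_that("pDFA p-value honors its permutation floor", {
  set.seed(57)
  n_ind <- 8; n_call <- 6
  ind <- rep(sprintf("i%02d", 1:n_ind), each = n_call)
  res <- rep(rep(c("F", "M"), each = n_call), n_ind / 2)
  centre <- rep(seq(0, 70, by = 10), each = n_call)
  scores <- cbind(centre + rnorm(n_ind * n_call, 0, 0.5),
                  rnorm(n_ind * n_call))
  pd <- nested_pdfa(scores, ind, res, n_permutations = 200,
                    n_selections = 5, seed = 2)
  expect_equal(pd$p_value, 1 / 200)
  expect_gt(pd$percent_correct, pd$chance_percent)
})

test_that("permutations never cross restriction levels", {
  # exact property of the permutation scheme: every permuted call keeps
  # its restriction label and per-individual call counts are preserved
  set.seed(58)
  ind <- rep(sprintf("i%d", 1:6), each = 5)
  res <- rep(c("F", "F", "M", "M", "F", "M"), each = 5)
  for (rep in 1:50) {
    perm <- zebrarep:::.permute_within(ind, res)
    for (lev in c("F", "M")) {
      expect_setequal(unique(perm[res == lev]), unique(ind[res == lev]))
      expect_equal(sort(table(perm[res == lev])),
                   sort(table(ind[res == lev])))
      expect_true(all(perm[res == lev] %in% ind[res == lev]))
    }
  }

  # one individual per level: within-level shuffles are identities; with
  # perfectly separated individuals every selection classifies all
  # withheld calls correctly, so all counts coincide and p = 1
  ind1 <- rep(c("i1", "i2", "i3"), each = 6)
  res1 <- ind1                                # level == individual
  scores <- cbind(rep(c(0, 100, 200), each = 6) + rnorm(18, 0, 0.1))
  pd <- suppressWarnings(
    nested_pdfa(scores, ind1, res1, n_permutations = 30, n_selections = 5,
                seed = 3))
  expect_true(all(abs(pd$permuted_counts - pd$observed_correct) < 1e-9))
  expect_equal(pd$p_value, 1)
})

test_that("pDFA is invariant to relabeling of individual identities", {
  set.seed(59)
  ind <- rep(sprintf("i%d", 1:6), each = 5)
  res <- rep(c("F", "M"), each = 15)
  scores <- cbind(rep(1:6, each = 5) + rnorm(30, 0, 0.4), rnorm(30))
  p1 <- nested_pdfa(scores, ind, res, n_permutations = 100,
                    n_selections = 5, seed = 4)
  relabel <- setNames(sprintf("z%d", 6:1), sprintf("i%d", 1:6))
  p2 <- nested_pdfa(scores, unname(relabel[ind]), res,
                    n_permutations = 100, n_selections = 5, seed = 4)
  expect_equal(p1$observed_correct, p2$observed_correct)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("pDFA validates its design", {
  scores <- cbind(rnorm(12)); ind <- rep(c("a", "b"), each = 6)
  expect_error(nested_pdfa(scores, ind, c(rep("F", 3), rep("M", 3),
                                          rep("F", 6)),
                           n_permutations = 10, n_selections = 2),
               "more than one restriction level")
  expect_error(nested_pdfa(cbind(rnorm(4)), rep(c("a", "b"), 2),
                           rep("F", 4), 10, 2), ">= 3 calls")
})

test_that("the full individuality chain runs on synthetic snorts", {
  d <- small_dataset()
  f <- d$features[d$features$call_type == "snort", ]
  ia <- individuality_analysis(f, restriction_col = "sex",
                               n_permutations = 100, n_selections = 5,
                               seed = 6)
  expect_true(ia$kmo$overall_msa >= 0 && ia$kmo$overall_msa <= 1)
  expect_gte(ia$pdfa$p_value, 1 / 100)
  expect_lte(ia$pdfa$p_value, 1)
  expect_equal(ia$pdfa$restriction_factor, "sex")
  expect_equal(sum(ia$dfa$percent_variance), 100)
})
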