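#' Compact convolutional network for spectrogram classification
#'
#' A small CNN — two 3x3 convolution + ReLU + 2x2 max-pool blocks, one dense
#' ReLU layer and a softmax head — trained with Adam and early stopping on a
#' validation split. Implemented directly on matrix operations (im2col
#' convolution), which is ample for the compact spectrogram inputs used
#' here and keeps training fully deterministic under a seed.
#'
#' @name cnn
NULL

#' CNN configuration
#'
#' @param input_shape target height/width the spectrograms are mean-pooled
#'   to before entering the network.
#' @param filters1,filters2 filters in the two convolution blocks.
#' @param dense width of the dense layer.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @return named list of hyperparameters.
#' @export
cnn_config <- function(input_shape = c(32, 32), filters1 = 8, filters2 = 16,
                       dense = 32, lr = 1e-3, epochs = 30, batch = 16,
                       patience = 6) {
  list(input_shape = input_shape, filters1 = filters1, filters2 = filters2,
       dense = dense, lr = lr, epochs = epochs, batch = batch,
       patience = patience, kernel = 3L)
}

# mean-pool an arbitrary matrix to h x w
.resize_mean <- function(m, h, w) {
  ri <- pmin(h, floor((seq_len(nrow(m)) - 1) / nrow(m) * h) + 1L)
  ci <- pmin(w, floor((seq_len(ncol(m)) - 1) / ncol(m) * w) + 1L)
  t(rowsum(t(rowsum(m, ri) / as.vector(table(ri))), ci) /
      as.vector(table(ci)))
}

# im2col cell-index matrix for an H x W grid (row-major cells), kernel k
.conv_index <- function(H, W, k) {
  Ho <- H - k + 1L; Wo <- W - k + 1L
  pos <- expand.grid(j = seq_len(Wo), i = seq_len(Ho))   # row-major positions
  idx <- matrix(0L, Ho * Wo, k * k)
  o <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    o <- o + 1L
    idx[, o] <- (pos$i + di - 1L) * W + (pos$j + dj)
  }
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# 2x2 max-pool cell-index matrix for an H x W grid
.pool_index <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  pos <- expand.grid(j = seq_len(Wo), i = seq_len(Ho))
  idx <- matrix(0L, Ho * Wo, 4L)
  o <- 0L
  for (di in 0:1) for (dj in 0:1) {
    o <- o + 1L
    idx[, o] <- (2L * (pos$i - 1L) + di) * W + (2L * (pos$j - 1L) + dj + 1L)
  }
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# grid activations are (H*W) x C matrices; cols = channel-blocked im2col
.im2col <- function(G, I) {
  C <- ncol(G)
  out <- matrix(0, nrow(I$idx), ncol(I$idx) * C)
  for (c in seq_len(C))
    out[, ((c - 1L) * ncol(I$idx) + 1L):(c * ncol(I$idx))] <-
      matrix(G[, c][I$idx], nrow(I$idx))
  out
}

.col2im <- function(dcols, I, H, W, C) {
  dG <- matrix(0, H * W, C)
  k2 <- ncol(I$idx)
  for (c in seq_len(C)) for (o in seq_len(k2)) {
    ix <- I$idx[, o]
    dG[ix, c] <- dG[ix, c] + dcols[, (c - 1L) * k2 + o]
  }
  dG
}

.he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                    nr, nc)

# build parameter list + cached geometry for one input shape
.cnn_init <- function(config, n_classes, seed) {
  set.seed(seed)
  h <- config$input_shape[1]; w <- config$input_shape[2]; k <- config$kernel
  c1 <- .conv_index(h, w, k)
  p1 <- .pool_index(c1$Ho, c1$Wo)
  c2 <- .conv_index(p1$Ho, p1$Wo, k)
  p2 <- .pool_index(c2$Ho, c2$Wo)
  flat <- p2$Ho * p2$Wo * config$filters2
  params <- list(
    W1 = .he_init(k * k, config$filters1), b1 = numeric(config$filters1),
    W2 = .he_init(k * k * config$filters1, config$filters2),
    b2 = numeric(config$filters2),
    W3 = .he_init(flat, config$dense), b3 = numeric(config$dense),
    W4 = .he_init(config$dense, n_classes), b4 = numeric(n_classes))
  list(params = params, geom = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                                    h = h, w = w, flat = flat),
       config = config, n_classes = n_classes)
}

# forward pass for one (H*W) x 1 grid; returns activations for backprop
.cnn_forward <- function(net, g0) {
  gm <- net$geom; P <- net$params
  cols1 <- .im2col(g0, gm$c1)
  z1 <- sweep(cols1 %*% P$W1, 2, P$b1, `+`)
  a1 <- pmax(z1, 0)
  np1 <- nrow(gm$p1$idx)
  a1p <- matrix(0, np1, ncol(a1)); amax1 <- matrix(0L, np1, ncol(a1))
  for (c in seq_len(ncol(a1))) {
    v <- matrix(a1[, c][gm$p1$idx], np1)
    amax1[, c] <- max.col(v, ties.method = "first")
    a1p[, c] <- v[cbind(seq_len(np1), amax1[, c])]
  }
  cols2 <- .im2col(a1p, gm$c2)
  z2 <- sweep(cols2 %*% P$W2, 2, P$b2, `+`)
  a2 <- pmax(z2, 0)
  np2 <- nrow(gm$p2$idx)
  a2p <- matrix(0, np2, ncol(a2)); amax2 <- matrix(0L, np2, ncol(a2))
  for (c in seq_len(ncol(a2))) {
    v <- matrix(a2[, c][gm$p2$idx], np2)
    amax2[, c] <- max.col(v, ties.method = "first")
    a2p[, c] <- v[cbind(seq_len(np2), amax2[, c])]
  }
  v <- as.vector(a2p)
  z3 <- drop(v %*% P$W3) + P$b3
  h <- pmax(z3, 0)
  logits <- drop(h %*% P$W4) + P$b4
  e <- exp(logits - max(logits))
  prob <- e / sum(e)
  list(g0 = g0, cols1 = cols1, z1 = z1, a1p = a1p, amax1 = amax1,
       cols2 = cols2, z2 = z2, a2p = a2p, amax2 = amax2, v = v, z3 = z3,
       h = h, prob = prob)
}

# gradient of cross-entropy loss for one sample; returns same shape as params
.cnn_backward <- function(net, fw, y) {
  gm <- net$geom; P <- net$params
  dlogits <- fw$prob
  dlogits[y] <- dlogits[y] - 1
  gW4 <- outer(fw$h, dlogits); gb4 <- dlogits
  dh <- drop(P$W4 %*% dlogits) * (fw$z3 > 0)
  gW3 <- outer(fw$v, dh); gb3 <- dh
  dv <- drop(P$W3 %*% dh)
  da2p <- matrix(dv, nrow(fw$a2p), ncol(fw$a2p))
  dz2 <- matrix(0, nrow(fw$z2), ncol(fw$z2))
  for (c in seq_len(ncol(dz2))) {
    ix <- gm$p2$idx[cbind(seq_len(nrow(fw$amax2)), fw$amax2[, c])]
    dz2[ix, c] <- dz2[ix, c] + da2p[, c]
  }
  dz2 <- dz2 * (fw$z2 > 0)
  gW2 <- t(fw$cols2) %*% dz2; gb2 <- colSums(dz2)
  da1p <- .col2im(dz2 %*% t(P$W2), gm$c2, gm$p1$Ho, gm$p1$Wo,
                  ncol(fw$a1p))
  dz1 <- matrix(0, nrow(fw$z1), ncol(fw$z1))
  for (c in seq_len(ncol(dz1))) {
    ix <- gm$p1$idx[cbind(seq_len(nrow(fw$amax1)), fw$amax1[, c])]
    dz1[ix, c] <- dz1[ix, c] + da1p[, c]
  }
  dz1 <- dz1 * (fw$z1 > 0)
  gW1 <- t(fw$cols1) %*% dz1; gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4)
}

# average loss + predictions over a list of grids
.cnn_eval <- function(net, grids, y) {
  loss <- 0; pred <- integer(length(grids))
  for (i in seq_along(grids)) {
    fw <- .cnn_forward(net, grids[[i]])
    loss <- loss - log(max(fw$prob[y[i]], 1e-12))
    pred[i] <- which.max(fw$prob)
  }
  list(loss = loss / length(grids), pred = pred)
}

# prepare model inputs: mean-pool to input_shape, min-max scale over the set
.cnn_prepare_inputs <- function(specs, input_shape) {
  small <- lapply(specs, function(s)
    .resize_mean(unclass(s), input_shape[1], input_shape[2]))
  lo <- min(vapply(small, min, 0)); hi <- max(vapply(small, max, 0))
  rng <- max(hi - lo, 1e-12)
  lapply(small, function(m) matrix((t(m) - lo) / rng, ncol = 1))
  # note: t(m) flattens row-major to match the conv index convention
}

#' Train and evaluate the spectrogram-based call-type classifier
#'
#' Splits the aligned spectrogram set 49/21/30 into train/validation/test
#' (stratified), mean-pools each matrix to the network input shape, scales
#' the whole set to \[0, 1\], trains the compact CNN with Adam and early
#' stopping on validation loss, and reports metrics on the held-out test
#' split only.
#'
#' @param specs list of equal-shape `zr_melspec` matrices (see
#'   [prepare_spectrograms()]).
#' @param labels call-type labels, one per spectrogram.
#' @param fractions train/validation/test fractions
#'   (default `c(0.49, 0.21, 0.30)`).
#' @param config hyperparameters, see [cnn_config()].
#' @param seed integer seed (weights, shuffling, split).
#' @return list: `net` (weights + geometry), `report` (test-split
#'   [evaluate()]), `history` (per-epoch losses), `split`, `classes`.
#' @export
train_spectrogram_classifier <- function(specs, labels,
                                         fractions = c(0.49, 0.21, 0.30),
                                         config = cnn_config(), seed = 1L) {
  dims <- vapply(specs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("spectrogram shape mismatch; run pad_and_align() first")
  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  grids <- .cnn_prepare_inputs(specs, config$input_shape)
  split <- split_data(labels, fractions, stratify = TRUE, seed = seed)
  net <- .cnn_init(config, length(classes), seed)
  adam <- list(m = lapply(net$params, function(p) p * 0),
               v = lapply(net$params, function(p) p * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best_params <- net$params; wait <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  set.seed(seed + 1L)
  for (ep in seq_len(config$epochs)) {
    order <- sample(split$train)
    tr_loss <- 0
    for (start in seq(1, length(order), by = config$batch)) {
      batch <- order[start:min(start + config$batch - 1L, length(order))]
      grads <- NULL
      for (i in batch) {
        fw <- .cnn_forward(net, grids[[i]])
        tr_loss <- tr_loss - log(max(fw$prob[y[i]], 1e-12))
        g <- .cnn_backward(net, fw, y[i])
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, length(batch))
      adam$t <- adam$t + 1
      for (nm in names(net$params)) {
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * grads[[nm]]
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2^adam$t)
        net$params[[nm]] <- net$params[[nm]] -
          config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val <- .cnn_eval(net, grids[split$validation], y[split$validation])
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = tr_loss / length(order),
      val_loss = val$loss))
    if (val$loss < best_loss - 1e-6) {
      best_loss <- val$loss; best_params <- net$params; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  net$params <- best_params
  te <- .cnn_eval(net, grids[split$test], y[split$test])
  net$classes <- classes
  list(net = net, report = evaluate(classes[te$pred], labels[split$test],
                                    classes),
       history = history, split = split, classes = classes)
}

#' Predict call types for spectrograms with a trained CNN
#'
#' @param net trained network from [train_spectrogram_classifier()].
#' @param specs list of spectrogram matrices (same shape as training).
#' @return character vector of predicted class labels.
#' @export
predict_cnn <- function(net, specs) {
  grids <- .cnn_prepare_inputs(specs, net$config$input_shape)
  pred <- vapply(grids, function(g) which.max(.cnn_forward(net, g)$prob), 0L)
  net$classes[pred]
}
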