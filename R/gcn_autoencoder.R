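#' Model hyperparameters
#'
#' The architecture is fixed at two graph-convolutional layers with a ReLU
#' non-linearity and dropout after the first layer, followed by an
#' inner-product decoder. The embedding dimension (`feature_size`) defaults
#' to 50 and dropout to p = 0.5, the configuration that performed best in the
#' feature-size sweep; the hidden layer defaults to twice the embedding width.
#'
#' @param feature_size Embedding dimension (columns of the latent matrix Z).
#' @param hidden_size Width of the first convolutional layer.
#' @param dropout_p Dropout probability in `[0, 1)` applied to the first-layer
#'   activations during training.
#' @param epochs Number of full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialization, dropout masks
#'   and per-epoch negative sampling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(feature_size = 50L, hidden_size = 2L * feature_size,
                         dropout_p = 0.5, epochs = 100L,
                         learning_rate = 0.01, seed = 42L) {
  if (feature_size < 1L) stop_usage("feature_size must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) stop_usage("need 0 <= dropout_p < 1")
  if (epochs < 1L) stop_usage("epochs must be >= 1")
  structure(
    list(n_layers = 2L, feature_size = as.integer(feature_size),
         hidden_size = as.integer(hidden_size), dropout_p = dropout_p,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Builds the graph-convolution operator of Kipf-style GCNs:
#' \deqn{\hat{A} = \tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2}}
#' where `A` holds the (weighted) training edges and \eqn{\tilde{D}} is the
#' degree matrix of `A + I`. Entry (i, j) equals
#' \eqn{w_{ij} / \sqrt{\tilde{d}_i \tilde{d}_j}}; isolated nodes keep a
#' self-loop entry of 1.
#'
#' @param graph A `bipartite_graph` (defines n and the node index).
#' @param train_edges Edge matrix (global indices) used for message passing;
#'   defaults to all graph edges. During training this must be the training
#'   positives only, so held-out edges never leak into the convolution.
#' @param weights Optional per-edge weights aligned with `train_edges`;
#'   default 1 (unweighted).
#' @return A sparse symmetric `dgCMatrix` of dimension n x n.
#' @export
normalize_adjacency <- function(graph, train_edges = graph$edges,
                                weights = NULL) {
  stopifnot(inherits(graph, "bipartite_graph"))
  n <- graph$n_genes + graph$n_diseases
  w <- weights %||% rep(1, nrow(train_edges))
  i <- c(train_edges[, 1L], train_edges[, 2L], seq_len(n))
  j <- c(train_edges[, 2L], train_edges[, 1L], seq_len(n))
  x <- c(w, w, rep(1, n))
  a_tilde <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  d <- Matrix::rowSums(a_tilde)
  dinv <- 1 / sqrt(d)
  Matrix::Diagonal(n, dinv) %*% a_tilde %*% Matrix::Diagonal(n, dinv)
}

#' Rectified linear unit
#'
#' @param x Numeric vector, matrix or Matrix.
#' @return Elementwise `max(0, x)`.
#' @export
relu <- function(x) {
  x * (x > 0)
}

#' Inverted dropout
#'
#' During training each element is zeroed independently with probability `p`
#' and survivors are scaled by `1/(1-p)`, so the expectation of the output
#' equals the input. Outside training the input passes through unchanged.
#'
#' @param x Numeric array.
#' @param p Drop probability in `[0, 1)`.
#' @param training Apply dropout (TRUE) or the identity (FALSE).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @export
dropout <- function(x, p, training = TRUE, seed = NULL) {
  if (p < 0 || p >= 1) stop_usage("dropout requires 0 <= p < 1")
  if (!training || p == 0) return(x)
  with_seed(seed, x * (dropout_mask(length(x), p)))
}

dropout_mask <- function(len, p) {
  (stats::runif(len) >= p) / (1 - p)
}

# Glorot-uniform initialization: U(-l, l), l = sqrt(6 / (fan_in + fan_out)).
init_weights <- function(input_dim, config) {
  l1 <- sqrt(6 / (input_dim + config$hidden_size))
  l2 <- sqrt(6 / (config$hidden_size + config$feature_size))
  list(
    W1 = matrix(stats::runif(input_dim * config$hidden_size, -l1, l1),
                input_dim, config$hidden_size),
    W2 = matrix(stats::runif(config$hidden_size * config$feature_size, -l2, l2),
                config$hidden_size, config$feature_size)
  )
}

# Forward pass. Input features are the identity (one-hot per node), so the
# first layer reduces to A_hat %*% W1. Returns intermediates for backprop.
gae_forward <- function(a_hat, weights, config, training = FALSE) {
  p1 <- as.matrix(a_hat %*% weights$W1)
  h1 <- relu(p1)
  mask <- NULL
  h1d <- h1
  if (training && config$dropout_p > 0) {
    mask <- matrix(dropout_mask(length(h1), config$dropout_p),
                   nrow(h1), ncol(h1))
    h1d <- h1 * mask
  }
  b <- as.matrix(a_hat %*% h1d)   # aggregated hidden features
  z <- b %*% weights$W2
  list(p1 = p1, h1d = h1d, mask = mask, b = b, z = z)
}

#' Encode the graph into node embeddings
#'
#' Computes \eqn{Z = \hat{A}\,\sigma(\hat{A} X W_1) W_2} with \eqn{\sigma}
#' ReLU (plus dropout when `training = TRUE`) and `X` the identity feature
#' matrix: with no node attributes available, each node starts from a one-hot
#' indicator, making the first layer a free per-node embedding.
#'
#' @param graph A `bipartite_graph`.
#' @param weights A list with matrices `W1` (n x hidden) and `W2`
#'   (hidden x feature_size).
#' @param config A [model_config()].
#' @param train_edges Edges used for message passing (default: all).
#' @param training Apply dropout stochastically (TRUE) or run deterministically
#'   (FALSE, the default).
#' @return An n x feature_size embedding matrix, rows aligned with the graph's
#'   node index.
#' @export
encode <- function(graph, weights, config, train_edges = graph$edges,
                   training = FALSE) {
  n <- graph$n_genes + graph$n_diseases
  if (nrow(weights$W1) != n || ncol(weights$W1) != nrow(weights$W2)) {
    stop_validation("weight shapes inconsistent with graph/config")
  }
  a_hat <- normalize_adjacency(graph, train_edges)
  gae_forward(a_hat, weights, config, training = training)$z
}

#' Inner-product decoder for a node pair
#'
#' The score of a candidate link (i, j) is the dot product of the two node
#' embeddings; the logistic of that score is the edge probability. Symmetric
#' in its arguments.
#'
#' @param z Embedding matrix (rows aligned with the node index).
#' @param i,j Node indices (vectorized; recycled to common length).
#' @return A list with `raw_score` and `probability` vectors.
#' @export
decode_pair <- function(z, i, j) {
  if (any(i < 1 | i > nrow(z)) || any(j < 1 | j > nrow(z))) {
    stop_validation("node index out of range")
  }
  s <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
  list(raw_score = s, probability = stats::plogis(s))
}

# raw scores for an m x 2 pair matrix
pair_scores <- function(z, pairs) {
  rowSums(z[pairs[, 1L], , drop = FALSE] * z[pairs[, 2L], , drop = FALSE])
}

PROB_EPS <- 1e-15

#' Reconstruction loss
#'
#' Binary cross-entropy of the decoded edge probabilities: the mean negative
#' log-probability over positive pairs plus the mean negative
#' log-complement over negative pairs. Probabilities are clamped to
#' `[1e-15, 1 - 1e-15]` to keep the loss finite.
#'
#' @param z Embedding matrix.
#' @param pos_edges,neg_edges Non-empty m x 2 pair matrices (global indices).
#' @return A non-negative scalar.
#' @export
reconstruction_loss <- function(z, pos_edges, neg_edges) {
  if (nrow(pos_edges) == 0L || nrow(neg_edges) == 0L) {
    stop_validation("both edge sets must be non-empty")
  }
  p_pos <- pmin(pmax(stats::plogis(pair_scores(z, pos_edges)), PROB_EPS),
                1 - PROB_EPS)
  p_neg <- pmin(pmax(stats::plogis(pair_scores(z, neg_edges)), PROB_EPS),
                1 - PROB_EPS)
  -mean(log(p_pos)) - mean(log(1 - p_neg))
}

# dL/dZ for the BCE loss above. g_s holds dL/ds per pair; contributions are
# scattered back onto both endpoint rows.
loss_grad_z <- function(z, pos_edges, neg_edges) {
  s_pos <- pair_scores(z, pos_edges)
  s_neg <- pair_scores(z, neg_edges)
  g <- c((stats::plogis(s_pos) - 1) / nrow(pos_edges),
         stats::plogis(s_neg) / nrow(neg_edges))
  ii <- c(pos_edges[, 1L], neg_edges[, 1L])
  jj <- c(pos_edges[, 2L], neg_edges[, 2L])
  contrib <- rbind(g * z[jj, , drop = FALSE], g * z[ii, , drop = FALSE])
  idx <- c(ii, jj)
  agg <- rowsum(contrib, idx)
  dz <- matrix(0, nrow(z), ncol(z))
  dz[as.integer(rownames(agg)), ] <- agg
  dz
}

# Backward pass for the BCE objective through decoder and both conv layers.
# With identity input features and symmetric A_hat, dW1 = A_hat %*% dP1.
gae_backward <- function(a_hat, fw, weights, pos, neg) {
  dz <- loss_grad_z(fw$z, pos, neg)
  d_w2 <- crossprod(fw$b, dz)
  d_h1d <- as.matrix(a_hat %*% (dz %*% t(weights$W2)))
  d_h1 <- if (is.null(fw$mask)) d_h1d else d_h1d * fw$mask
  d_p1 <- d_h1 * (fw$p1 > 0)
  list(W1 = as.matrix(a_hat %*% d_p1), W2 = d_w2)
}

adam_state <- function(weights) {
  lapply(weights, function(w) list(m = w * 0, v = w * 0))
}

adam_step <- function(weights, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(weights)) {
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[k]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[k]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    weights[[k]] <- weights[[k]] - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- st
  }
  list(weights = weights, state = state)
}

#' Train the graph autoencoder
#'
#' Full-batch training: each epoch runs a forward pass with dropout on the
#' train-edge adjacency, evaluates the binary cross-entropy on the training
#' positives plus freshly sampled training negatives (1:1), backpropagates,
#' and applies an Adam update. Validation AUC and AP are recorded every epoch
#' from a dropout-free forward pass; after the last epoch the final
#' embeddings are computed with dropout off and scored on the test set.
#' A fixed seed makes the whole run reproducible on a single thread.
#'
#' @param graph A `bipartite_graph`.
#' @param split An [split_edges()] result consistent with `graph`.
#' @param config A [model_config()].
#' @return A list of class `gae_fit` with `weights`, `embeddings`, `history`
#'   (data frame: epoch, loss, val_auc, val_ap), `test_auc`, `test_ap`,
#'   `config`, and `graph_hash` (fingerprint of the node index).
#' @export
train_gae <- function(graph, split, config = model_config()) {
  stopifnot(inherits(graph, "bipartite_graph"), inherits(split, "edge_split"))
  n <- graph$n_genes + graph$n_diseases
  a_hat <- normalize_adjacency(graph, split$train_pos)
  pos <- split$train_pos
  n_neg <- nrow(pos)

  val_pairs <- rbind(split$val_pos, split$val_neg)
  val_labels <- rep(1:0, c(nrow(split$val_pos), nrow(split$val_neg)))
  has_val <- nrow(split$val_pos) > 0L && nrow(split$val_neg) > 0L

  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        val_auc = NA_real_, val_ap = NA_real_)

  with_seed(config$seed, {
    weights <- init_weights(n, config)
    state <- adam_state(weights)
    for (epoch in seq_len(config$epochs)) {
      neg <- sample_training_negatives(graph, split, n_neg)
      fw <- gae_forward(a_hat, weights, config, training = TRUE)
      loss <- reconstruction_loss(fw$z, pos, neg)
      if (!is.finite(loss)) {
        stop_numerical("training diverged at epoch %d (loss = %s)",
                       epoch, format(loss))
      }

      grads <- gae_backward(a_hat, fw, weights, pos, neg)
      upd <- adam_step(weights, grads, state,
                       t = epoch, lr = config$learning_rate)
      weights <- upd$weights
      state <- upd$state

      history$loss[epoch] <- loss
      if (has_val) {
        z_eval <- gae_forward(a_hat, weights, config, training = FALSE)$z
        scores <- pair_scores(z_eval, val_pairs)
        history$val_auc[epoch] <- auc(scores, val_labels)
        history$val_ap[epoch] <- average_precision(scores, val_labels)
      }
    }
  })

  z_final <- gae_forward(a_hat, weights, config, training = FALSE)$z
  test_auc <- test_ap <- NA_real_
  if (nrow(split$test_pos) > 0L && nrow(split$test_neg) > 0L) {
    test_pairs <- rbind(split$test_pos, split$test_neg)
    test_labels <- rep(1:0, c(nrow(split$test_pos), nrow(split$test_neg)))
    scores <- pair_scores(z_final, test_pairs)
    test_auc <- auc(scores, test_labels)
    test_ap <- average_precision(scores, test_labels)
  }

  structure(
    list(weights = weights, embeddings = z_final, history = history,
         test_auc = test_auc, test_ap = test_ap, config = config,
         graph_hash = fnv1a_hash(graph$node_id)),
    class = "gae_fit"
  )
}

#' @export
print.gae_fit <- function(x, ...) {
  cat(sprintf(
    "Graph autoencoder fit: %d epochs, %d-d embeddings; final loss %.4f; test AUC %.4f, test AP %.4f\n",
    nrow(x$history), ncol(x$embeddings),
    x$history$loss[nrow(x$history)], x$test_auc, x$test_ap))
  invisible(x)
}

#' Serialize embeddings with a JSON sidecar
#'
#' Writes a TSV (node_id plus one column per latent dimension) and a JSON
#' sidecar recording the model configuration and a hash of the node index, so
#' later prediction can verify it is pairing embeddings with the right graph.
#'
#' @param fit A `gae_fit`.
#' @param graph The graph the model was trained on.
#' @param dir Output directory.
#' @export
write_embeddings <- function(fit, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- fit$embeddings
  df <- data.frame(node_id = graph$node_id, z, check.names = FALSE)
  names(df) <- c("node_id", paste0("h", seq_len(ncol(z))))
  utils::write.table(df, file.path(dir, "embeddings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sidecar <- c(unclass(fit$config), list(graph_hash = fit$graph_hash))
  jsonlite::write_json(sidecar, file.path(dir, "embeddings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param dir Directory holding `embeddings.tsv` and `embeddings.json`.
#' @param graph Optional graph to validate against; a node-index hash
#'   mismatch is a hard error.
#' @return A list with `embeddings` (matrix) and `sidecar` (list).
#' @export
read_embeddings <- function(dir, graph = NULL) {
  df <- utils::read.delim(file.path(dir, "embeddings.tsv"),
                          check.names = FALSE)
  sidecar <- jsonlite::read_json(file.path(dir, "embeddings.json"),
                                 simplifyVector = TRUE)
  z <- as.matrix(df[, -1L, drop = FALSE])
  rownames(z) <- df$node_id
  if (!is.null(graph) && fnv1a_hash(graph$node_id) != sidecar$graph_hash) {
    stop_validation("embeddings were trained on a different graph (hash mismatch)")
  }
  list(embeddings = z, sidecar = sidecar)
}
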