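test_that("normalized adjacency matches hand-computed values", {
  # two nodes, one edge: d_tilde = 2 for both -> all entries 1/2
  pair <- build_bipartite_graph(data.frame(gene_id = "g1", disease_id = "d1"))
  a <- as.matrix(normalize_adjacency(pair))
  expect_equal(a, matrix(0.5, 2, 2), ignore_attr = TRUE)

  # path g1 - d1 - g2: d_tilde(d1) = 3, d_tilde(g1) = 2
  path <- build_bipartite_graph(
    data.frame(gene_id = c("g1", "g2"), disease_id = c("d1", "d1")))
  a2 <- as.matrix(normalize_adjacency(path))
  d1 <- 3L  # node index: g1, g2, d1
  expect_equal(a2[d1, d1], 1 / 3)
  expect_equal(a2[1, d1], 1 / sqrt(6))
  expect_equal(a2, t(a2), ignore_attr = TRUE)

  # a node isolated by the train-edge restriction keeps a unit self-loop
  a3 <- as.matrix(normalize_adjacency(path, path$edges[1, , drop = FALSE]))
  expect_equal(a3[2, 2], 1)
})

test_that("normalized adjacency has spectral radius <= 1 on unweighted graphs", {
  g <- small_block_graph()
  a <- as.matrix(normalize_adjacency(g))
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(abs(ev)), 1 + 1e-10)
  expect_true(all(diag(a) > 0))
})

test_that("relu and dropout honor their contracts", {
  expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))

  x <- matrix(rnorm(20), 4)
  expect_identical(dropout(x, 0, training = TRUE), x)
  expect_identical(dropout(x, 0.5, training = FALSE), x)
  expect_error(dropout(x, 1), class = "gda_usage_error")

  # unbiasedness: E[dropout(1, 0.5)] = 1; per-draw variance is 1
  draws <- dropout(rep(1, 1e5), 0.5, training = TRUE, seed = 99)
  expect_lt(abs(mean(draws) - 1), 3 / sqrt(1e5))
  expect_setequal(unique(draws), c(0, 2))
})

test_that("encoder reduces to the documented linear algebra", {
  pair <- build_bipartite_graph(data.frame(gene_id = "g1", disease_id = "d1"))
  cfg <- model_config(feature_size = 2, hidden_size = 2, dropout_p = 0)
  # first-layer pre-activation with W1 = I is A_hat itself: rows [0.5, 0.5]
  a <- normalize_adjacency(pair)
  p1 <- as.matrix(a %*% diag(2))
  expect_equal(p1, matrix(0.5, 2, 2), ignore_attr = TRUE)

  w0 <- list(W1 = matrix(0, 2, 2), W2 = matrix(0, 2, 2))
  expect_equal(encode(pair, w0, cfg), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("encoder is equivariant under node relabeling", {
  set.seed(31)
  rec <- data.frame(gene_id = c("g1", "g2", "g3", "g1", "g2"),
                    disease_id = c("d1", "d2", "d3", "d2", "d3"))
  g <- build_bipartite_graph(rec)
  # same topology, different first-appearance order -> permuted node index
  rec_p <- rec[c(3, 5, 1, 4, 2), ]
  g_p <- build_bipartite_graph(rec_p)
  perm <- match(g_p$node_id, g$node_id)   # g_p index -> g index

  cfg <- model_config(feature_size = 3, hidden_size = 4, dropout_p = 0)
  w <- gdagae:::with_seed(1, gdagae:::init_weights(6, cfg))
  w_p <- list(W1 = w$W1[perm, , drop = FALSE], W2 = w$W2)

  z <- encode(g, w, cfg)
  z_p <- encode(g_p, w_p, cfg)
  expect_equal(z_p, z[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("encode is a pure function with dropout off", {
  g <- small_block_graph()
  cfg <- model_config(feature_size = 4, dropout_p = 0.5)
  w <- gdagae:::with_seed(2, gdagae:::init_weights(100, cfg))
  expect_identical(encode(g, w, cfg), encode(g, w, cfg))
})

test_that("inner-product decoder is symmetric with a logistic probability", {
  z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  d <- decode_pair(z, 1, 2)
  expect_equal(d$raw_score, 1)
  expect_equal(d$probability, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(decode_pair(z, 1, 3)$probability, 0.5)   # orthogonal
  expect_equal(decode_pair(z, 2, 1), decode_pair(z, 1, 2))
  expect_error(decode_pair(z, 1, 9), class = "gda_validation_error")
})

test_that("reconstruction loss has its closed-form values and limits", {
  z <- matrix(0, 4, 3)  # all dot products 0 -> all probabilities 0.5
  pos <- cbind(1L, 3L)
  neg <- cbind(2L, 4L)
  expect_equal(reconstruction_loss(z, pos, neg), 2 * log(2), tolerance = 1e-12)

  z2 <- rbind(c(20, 0), c(-20, 0), c(20, 0), c(0.05, 0))
  # positive pair (1,3): p ~ 1; negative pair (2,3): p ~ 0
  expect_lt(reconstruction_loss(z2, cbind(1L, 3L), cbind(2L, 3L)), 1e-8)
  expect_error(reconstruction_loss(z, pos[0, , drop = FALSE], neg),
               class = "gda_validation_error")
})

test_that("analytic gradients match finite differences", {
  g <- small_block_graph(seed = 21)
  split <- split_edges(g, 0.1, 0.1, seed = 1)
  cfg <- model_config(feature_size = 3, hidden_size = 4, dropout_p = 0)
  n <- g$n_genes + g$n_diseases
  w <- gdagae:::with_seed(3, gdagae:::init_weights(n, cfg))
  a_hat <- normalize_adjacency(g, split$train_pos)
  pos <- split$train_pos
  neg <- sample_training_negatives(g, split, nrow(pos), seed = 8)

  fw <- gdagae:::gae_forward(a_hat, w, cfg, training = FALSE)
  grads <- gdagae:::gae_backward(a_hat, fw, w, pos, neg)

  loss_at <- function(w) {
    gdagae:::with_seed(1, reconstruction_loss(
      gdagae:::gae_forward(a_hat, w, cfg, training = FALSE)$z, pos, neg))
  }
  eps <- 1e-6
  probe <- list(W1 = cbind(c(1, 2, 57), c(1, 3, 2)),
                W2 = cbind(c(1, 2, 4), c(1, 3, 2)))
  for (layer in c("W1", "W2")) {
    idx <- probe[[layer]]
    for (r in seq_len(nrow(idx))) {
      wp <- w; wp[[layer]][idx[r, 1], idx[r, 2]] <- wp[[layer]][idx[r, 1], idx[r, 2]] + eps
      wm <- w; wm[[layer]][idx[r, 1], idx[r, 2]] <- wm[[layer]][idx[r, 1], idx[r, 2]] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(grads[[layer]][idx[r, 1], idx[r, 2]], fd, tolerance = 1e-4)
    }
  }
})

test_that("training runs, records history, and is seed-reproducible", {
  g <- small_block_graph()
  split <- split_edges(g, 0.1, 0.15, seed = 4)
  cfg1 <- model_config(feature_size = 8, hidden_size = 16, epochs = 1, seed = 5)
  fit1 <- train_gae(g, split, cfg1)
  expect_equal(nrow(fit1$history), 1)

  cfg <- model_config(feature_size = 8, hidden_size = 16, epochs = 40, seed = 5)
  fit_a <- train_gae(g, split, cfg)
  fit_b <- train_gae(g, split, cfg)
  expect_identical(fit_a$history, fit_b$history)
  expect_identical(fit_a$embeddings, fit_b$embeddings)

  # loss decreases over training on a structured graph
  expect_lt(fit_a$history$loss[40], fit_a$history$loss[1])
  expect_true(all(is.finite(fit_a$embeddings)))
  expect_equal(dim(fit_a$embeddings), c(100, 8))
})

test_that("embeddings round-trip through serialization with a graph hash", {
  g <- small_block_graph()
  split <- split_edges(g, 0.1, 0.1, seed = 6)
  fit <- train_gae(g, split, model_config(feature_size = 4, epochs = 5, seed = 6))
  dir <- tempfile()
  write_embeddings(fit, g, dir)
  back <- read_embeddings(dir, g)
  expect_equal(unname(back$embeddings), unname(fit$embeddings),
               tolerance = 1e-12)
  other <- generate_er_bipartite(20, 15, 0.2, seed = 1)
  expect_error(read_embeddings(dir, other), "hash",
               class = "gda_validation_error")
})
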