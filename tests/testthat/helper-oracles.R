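# Independent oracles and small fixture builders, deliberately written as
# naive loops so they share no code path with the package implementation.

# Mann-Whitney pair counting: P(random positive outscores a random negative),
# ties credited 1/2. O(P*N).
auc_paircount <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (p in sp) {
    total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  }
  total / (length(sp) * length(sn))
}

# AP step-sum evaluated threshold by threshold with naive counting.
ap_stepsum <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Exhaustive Youden search over every candidate threshold (all distinct
# scores); ties in J resolved toward the larger threshold.
youden_exhaustive <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in thr) {
    pred <- scores >= t
    tpr <- sum(pred & labels == 1) / sum(labels == 1)
    fpr <- sum(pred & labels == 0) / sum(labels == 0)
    j <- tpr - fpr
    if (j > best_j) {  # descending thresholds: first max = largest threshold
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, J = best_j)
}

# Random scored instance with injected ties and both classes guaranteed.
random_scored_instance <- function(n = 200) {
  scores <- round(runif(n), 2)                  # 2 decimals force tied scores
  labels <- rbinom(n, 1, plogis(3 * (scores - 0.5)))
  labels[1] <- 1
  labels[2] <- 0
  list(scores = scores, labels = labels)
}

# Tiny deterministic association tables.
toy_records <- function() {
  data.frame(gene_id = c("g1", "g1", "g2"),
             disease_id = c("d1", "d2", "d1"),
             weight = 1, stringsAsFactors = FALSE)
}

toy_graph <- function() build_bipartite_graph(toy_records())

# Small structured graph that trains in well under a second.
small_block_graph <- function(seed = 5) {
  generate_block_bipartite(60, 40, 2, 0.30, 0.02, seed = seed)$graph
}

write_toy_tsv <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
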