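#' Split positive edges and sample held-out negatives
#'
#' Partitions the observed associations uniformly at random into train,
#' validation and test positives, and samples an equal number of negative
#' gene-disease pairs (non-edges) for the validation and test sets. Held-out
#' positives and negatives never enter training: the message-passing adjacency
#' is built from `train_pos` only, and per-epoch training negatives avoid the
#' held-out negatives (see [sample_training_negatives()]).
#'
#' @param graph A `bipartite_graph` with at least 10 edges.
#' @param val_frac,test_frac Fractions of edges held out for validation and
#'   test; must satisfy `val_frac + test_frac < 1`. Defaults 0.05 / 0.10.
#' @param seed Integer seed; the same seed reproduces the split exactly.
#' @return An object of class `edge_split`: list with `train_pos`, `val_pos`,
#'   `test_pos`, `val_neg`, `test_neg` (each an m x 2 matrix of global node
#'   indices, gene column first), plus `seed`, `val_frac`, `test_frac`.
#' @export
split_edges <- function(graph, val_frac = 0.05, test_frac = 0.10, seed = 42L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (val_frac < 0 || test_frac < 0 || val_frac + test_frac >= 1) {
    stop_usage("need val_frac, test_frac >= 0 and val_frac + test_frac < 1")
  }
  m <- nrow(graph$edges)
  if (m < 10L) stop_validation("graph has %d edges; need at least 10", m)

  n_val <- round(val_frac * m)
  n_test <- round(test_frac * m)
  n_pairs <- as.numeric(graph$n_genes) * graph$n_diseases
  if (n_pairs - m < n_val + n_test) {
    stop_validation(
      "graph too dense: %d non-edges available, %d negatives requested",
      n_pairs - m, n_val + n_test)
  }

  pos_codes <- edge_codes(graph, graph$edges)
  with_seed(seed, {
    perm <- sample.int(m)
    val_idx <- perm[seq_len(n_val)]
    test_idx <- perm[n_val + seq_len(n_test)]
    train_idx <- perm[-seq_len(n_val + n_test)]
    neg <- sample_nonedge_codes(graph, n_val + n_test, forbidden = pos_codes)
  })

  structure(
    list(train_pos = graph$edges[train_idx, , drop = FALSE],
         val_pos = graph$edges[val_idx, , drop = FALSE],
         test_pos = graph$edges[test_idx, , drop = FALSE],
         val_neg = code_to_pairs(graph, neg[seq_len(n_val)]),
         test_neg = code_to_pairs(graph, neg[n_val + seq_len(n_test)]),
         seed = seed, val_frac = val_frac, test_frac = test_frac),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(
    "Edge split (seed %d): %d train / %d val / %d test positives; %d val + %d test negatives\n",
    x$seed, nrow(x$train_pos), nrow(x$val_pos), nrow(x$test_pos),
    nrow(x$val_neg), nrow(x$test_neg)))
  invisible(x)
}

#' Sample fresh training negatives
#'
#' The reconstruction loss needs class-0 pairs every epoch. These are drawn
#' uniformly from gene-disease non-edges, excluding both the full positive
#' edge set and the held-out validation/test negatives, and are resampled on
#' each call so the model never memorizes one negative set.
#'
#' @param graph A `bipartite_graph`.
#' @param split The `edge_split` whose held-out negatives must be avoided.
#' @param count Number of pairs to draw; `count = 0` returns an empty set.
#' @param seed Optional seed; `NULL` (the default, used inside the training
#'   loop) draws from the current RNG stream.
#' @return A `count` x 2 matrix of global node indices (gene, disease).
#' @export
sample_training_negatives <- function(graph, split, count, seed = NULL) {
  stopifnot(inherits(graph, "bipartite_graph"), inherits(split, "edge_split"))
  if (count < 0) stop_usage("count must be >= 0")
  if (count == 0) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("gene", "disease"))))
  }
  forbidden <- c(edge_codes(graph, graph$edges),
                 edge_codes(graph, split$val_neg),
                 edge_codes(graph, split$test_neg))
  n_pairs <- as.numeric(graph$n_genes) * graph$n_diseases
  if (n_pairs - length(forbidden) < count) {
    stop_validation("not enough free non-edges to sample %d negatives", count)
  }
  codes <- with_seed(seed, sample_nonedge_codes(graph, count, forbidden))
  code_to_pairs(graph, codes)
}

# Rejection-sample `count` distinct pair codes avoiding `forbidden`.
# Uniform over the allowed non-edges; sparse GDA graphs make rejection cheap.
sample_nonedge_codes <- function(graph, count, forbidden) {
  n_pairs <- as.numeric(graph$n_genes) * graph$n_diseases
  free <- n_pairs - length(forbidden)
  if (free < count) {
    stop_validation("not enough non-edges: %d free, %d requested", free, count)
  }
  got <- numeric(0)
  while (length(got) < count) {
    need <- count - length(got)
    # oversample to absorb rejections; bounded retries keep this terminating
    draw <- ceiling(need / max(free / n_pairs, 1e-6)) + 16L
    gi <- sample.int(graph$n_genes, draw, replace = TRUE)
    dl <- sample.int(graph$n_diseases, draw, replace = TRUE)
    cand <- (gi - 1) * graph$n_diseases + dl
    cand <- cand[!(cand %in% forbidden) & !(cand %in% got)]
    cand <- cand[!duplicated(cand)]
    got <- c(got, cand)
  }
  got[seq_len(count)]
}

#' Serialize a split to TSV edge lists plus a JSON manifest
#'
#' @param graph The graph the split was drawn from (for identifier lookup).
#' @param split An `edge_split`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly. Writes `train_pos.tsv`, `val_pos.tsv`,
#'   `test_pos.tsv`, `val_neg.tsv`, `test_neg.tsv` and `split.json`.
#' @export
write_edge_split <- function(graph, split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("train_pos", "val_pos", "test_pos", "val_neg", "test_neg")
  for (p in parts) {
    pairs <- split[[p]]
    writeLines(paste(graph$node_id[pairs[, 1L]],
                     graph$node_id[pairs[, 2L]], sep = "\t"),
               file.path(dir, paste0(p, ".tsv")))
  }
  manifest <- list(seed = split$seed, val_frac = split$val_frac,
                   test_frac = split$test_frac,
                   counts = lapply(split[parts], nrow))
  jsonlite::write_json(manifest, file.path(dir, "split.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
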