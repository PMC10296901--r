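#' Score all unobserved gene-disease pairs
#'
#' Iterates the gene x disease candidate universe (never gene-gene or
#' disease-disease pairs), skipping known edges and any extra `exclude` set,
#' and scores each pair by the dot product of its node embeddings. Scores are
#' computed blockwise as gene-block x disease matrix products, so memory is
#' bounded by `block_genes` rows of the score matrix rather than the full
#' dense gene x disease matrix.
#'
#' @param graph A `bipartite_graph`.
#' @param z Embedding matrix aligned with the graph's node index.
#' @param exclude Optional extra m x 2 matrix of pairs (global indices) to
#'   skip in addition to the graph's own edges.
#' @param block_genes Number of gene rows scored per block.
#' @return A data frame with `gene_id`, `disease_id`, `raw_score`,
#'   `probability`, one row per candidate non-edge (unsorted).
#' @export
score_candidates <- function(graph, z, exclude = NULL, block_genes = 512L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  n <- graph$n_genes + graph$n_diseases
  if (nrow(z) != n) stop_validation("embeddings misaligned with graph")
  skip <- edge_codes(graph, graph$edges)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    skip <- c(skip, edge_codes(graph, exclude))
  }
  zg <- z[seq_len(graph$n_genes), , drop = FALSE]
  zd <- z[graph$n_genes + seq_len(graph$n_diseases), , drop = FALSE]

  out <- vector("list", ceiling(graph$n_genes / block_genes))
  bi <- 0L
  for (start in seq(1L, graph$n_genes, by = block_genes)) {
    rows <- start:min(start + block_genes - 1L, graph$n_genes)
    s <- zg[rows, , drop = FALSE] %*% t(zd)       # |rows| x n_diseases
    gi <- rep(rows, times = graph$n_diseases)
    dl <- rep(seq_len(graph$n_diseases), each = length(rows))
    code <- (gi - 1) * graph$n_diseases + dl
    keep <- !(code %in% skip)
    bi <- bi + 1L
    out[[bi]] <- data.frame(
      gene_id = graph$node_id[gi[keep]],
      disease_id = graph$node_id[graph$n_genes + dl[keep]],
      raw_score = as.vector(s)[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$probability <- stats::plogis(res$raw_score)
  rownames(res) <- NULL
  res
}

#' Top-k candidate associations
#'
#' Exact selection of the `k` highest raw dot-product scores; ties are broken
#' deterministically by (gene_id, disease_id) lexicographic order. If fewer
#' than `k` candidates exist, all are returned with a warning.
#'
#' @param candidates Scored candidate data frame from [score_candidates()].
#' @param k Number of candidates to keep (default 15).
#' @return The candidates with a `rank` column (1 = highest score), sorted.
#' @export
top_k <- function(candidates, k = 15L) {
  if (k < 1L) stop_usage("k must be >= 1")
  if (nrow(candidates) < k) {
    warning("only ", nrow(candidates), " candidates available (k = ", k, ")")
    k <- nrow(candidates)
  }
  ord <- order(-candidates$raw_score, candidates$gene_id,
               candidates$disease_id)
  out <- candidates[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out[, c("rank", "gene_id", "disease_id", "raw_score", "probability")]
}

#' Candidates above a probability threshold
#'
#' @param candidates Scored candidate data frame.
#' @param threshold Probability cut-off (e.g. the Youden best threshold);
#'   candidates with `probability >= threshold` are kept.
#' @return Passing candidates sorted by descending score, with ranks.
#' @export
apply_threshold <- function(candidates, threshold) {
  keep <- candidates[candidates$probability >= threshold, , drop = FALSE]
  if (nrow(keep) == 0L) {
    keep$rank <- integer(0)
    return(keep[, c("rank", "gene_id", "disease_id", "raw_score",
                    "probability")])
  }
  top_k(keep, nrow(keep))
}

#' Degree diagnostic for ranked candidates
#'
#' Graph convolutions favor well-connected nodes, so top-ranked candidates
#' tend to involve hubs. This reports the mean degree of the genes and
#' diseases appearing in a candidate list against the graph-wide means — a
#' diagnostic, not a test statistic.
#'
#' @param graph A `bipartite_graph`.
#' @param candidates A ranked candidate data frame (e.g. from [top_k()]).
#' @return A list with `mean_gene_degree`, `mean_disease_degree`,
#'   `graph_mean_gene_degree`, `graph_mean_disease_degree`.
#' @export
candidate_degree_bias <- function(graph, candidates) {
  deg <- node_degrees(graph)
  list(
    mean_gene_degree = mean(deg[candidates$gene_id]),
    mean_disease_degree = mean(deg[candidates$disease_id]),
    graph_mean_gene_degree = mean(deg[graph$partition == "gene"]),
    graph_mean_disease_degree = mean(deg[graph$partition == "disease"])
  )
}
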