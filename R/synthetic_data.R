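#' Planted-block bipartite graph generator
#'
#' Emulates the clustered, hub-dominated topology of curated gene-disease
#' networks: genes and diseases are each assigned uniformly to one of
#' `k_blocks` latent blocks, and a gene-disease pair becomes an edge
#' independently with probability `p_in` when their blocks match and `p_out`
#' otherwise. The block structure gives graph convolution a neighborhood
#' signal to learn; `p_in = p_out` degenerates to an Erdős–Rényi bipartite
#' null with uninformative labels.
#'
#' With `degree_skew` set, each node gets a propensity `u^(-1/(1+skew))`
#' (`u ~ U(0,1)`; a Pareto-like tail with index `1 + skew`, so larger values
#' give lighter tails), normalized to empirical mean 1; pair probabilities
#' are multiplied by both endpoint propensities and capped at 1. This mimics
#' hub genes such as TNF that dominate real degree tables.
#'
#' @param n_genes,n_diseases Partition sizes.
#' @param k_blocks Number of latent blocks; at most `min(n_genes, n_diseases)`.
#' @param p_in,p_out Within-/between-block edge probabilities, `p_out <= p_in`.
#' @param seed Integer seed; identical seeds give identical graphs.
#' @param degree_skew Optional non-negative skew parameter (default off).
#' @return A list with `graph` (a `bipartite_graph`), and `blocks` (data
#'   frame: node_id, partition, block).
#' @export
generate_block_bipartite <- function(n_genes, n_diseases, k_blocks,
                                     p_in, p_out, seed = 42L,
                                     degree_skew = NULL) {
  if (p_out > p_in) stop_usage("p_out must not exceed p_in")
  if (p_in < 0 || p_in > 1 || p_out < 0) stop_usage("probabilities in [0, 1]")
  if (k_blocks > min(n_genes, n_diseases)) {
    stop_usage("k_blocks must not exceed min(n_genes, n_diseases)")
  }
  p_match <- 1 / k_blocks
  expected_m <- n_genes * n_diseases * (p_match * p_in + (1 - p_match) * p_out)
  if (expected_m < 10) {
    stop_validation("expected edge count %.2f < 10: graph untrainable",
                    expected_m)
  }

  with_seed(seed, {
    gb <- sample.int(k_blocks, n_genes, replace = TRUE)
    db <- sample.int(k_blocks, n_diseases, replace = TRUE)
    prob <- matrix(p_out, n_genes, n_diseases)
    prob[outer(gb, db, `==`)] <- p_in
    if (!is.null(degree_skew)) {
      if (degree_skew < 0) stop_usage("degree_skew must be >= 0")
      pg <- propensity(n_genes, degree_skew)
      pd <- propensity(n_diseases, degree_skew)
      prob <- pmin(prob * outer(pg, pd), 1)
    }
    hit <- which(matrix(stats::runif(length(prob)), n_genes) < prob,
                 arr.ind = TRUE)
  })
  graph <- edges_to_graph(hit, n_genes, n_diseases)
  blocks <- data.frame(node_id = graph$node_id,
                       partition = graph$partition,
                       block = c(gb, db),
                       stringsAsFactors = FALSE)
  list(graph = graph, blocks = blocks)
}

propensity <- function(n, skew) {
  a <- stats::runif(n)^(-1 / (1 + skew))
  a / mean(a)
}

#' Erdős–Rényi bipartite graph generator
#'
#' Every gene-disease pair becomes an edge independently with probability
#' `p`. There is no latent structure, so held-out edges carry no learnable
#' signal beyond degree: the null model for leakage checks.
#'
#' @param n_genes,n_diseases Partition sizes.
#' @param p Edge probability in (0, 1).
#' @param seed Integer seed.
#' @return A `bipartite_graph`.
#' @export
generate_er_bipartite <- function(n_genes, n_diseases, p, seed = 42L) {
  if (p <= 0 || p >= 1) stop_usage("need 0 < p < 1")
  if (n_genes * n_diseases * p < 10) {
    stop_validation("expected edge count %.2f < 10: graph untrainable",
                    n_genes * n_diseases * p)
  }
  hit <- with_seed(seed,
    which(matrix(stats::runif(n_genes * n_diseases), n_genes) < p,
          arr.ind = TRUE))
  edges_to_graph(hit, n_genes, n_diseases)
}

# (gene_row, disease_col) index pairs -> bipartite_graph with synthetic ids.
# All nodes are materialized (including isolated ones) so partition sizes are
# exactly as requested.
edges_to_graph <- function(hit, n_genes, n_diseases) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  disease_ids <- sprintf("d%04d", seq_len(n_diseases))
  structure(
    list(node_id = c(gene_ids, disease_ids),
         partition = rep(c("gene", "disease"), c(n_genes, n_diseases)),
         n_genes = n_genes,
         n_diseases = n_diseases,
         edges = cbind(gene = as.integer(hit[, 1L]),
                       disease = as.integer(n_genes + hit[, 2L])),
         weights = rep(1, nrow(hit))),
    class = "bipartite_graph"
  )
}

#' Write ground-truth block assignments as TSV
#'
#' @param blocks Block data frame from [generate_block_bipartite()].
#' @param path Output file path.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
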