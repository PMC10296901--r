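#' Read a gene-disease association edge list
#'
#' Parses a delimited text file with one association per line: a gene
#' identifier (e.g. an Entrez GeneID or symbol), a disease identifier (e.g. a
#' UMLS CUI), and optionally an association score in `[0, 1]`. Identifiers are
#' kept verbatim as strings; any numeric encoding happens only inside the
#' model's arrays, never on the identifiers themselves.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator, default tab.
#' @param has_header Whether the first line is a header row.
#' @param weight_column Optional: name (when `has_header`) or integer position
#'   of the column holding the association weight. When `NULL`, the third
#'   column named `score` or `weight` is used if a header declares one;
#'   otherwise all weights default to 1.
#' @return A data frame of class `gda_records` with columns `gene_id`,
#'   `disease_id`, `weight`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("g1\td1", "g1\td2", "g2\td1"), tf)
#' read_edge_list(tf)
#' @export
read_edge_list <- function(path, delimiter = "\t", has_header = FALSE,
                           weight_column = NULL) {
  if (!file.exists(path)) {
    stop_validation("edge-list file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  header <- NULL
  first_data_line <- 1L
  if (has_header && length(lines) >= 1L) {
    header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
    lines <- lines[-1L]
    first_data_line <- 2L
  }
  keep <- nzchar(trimws(lines))
  line_no <- which(keep) + first_data_line - 1L
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("edge list '", basename(path), "' contains no data rows")
    return(new_gda_records(character(), character(), numeric()))
  }

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- line_no[which(nf < 2L)[1L]]
    stop_validation("line %d of '%s' has fewer than 2 columns", bad, path)
  }

  gene_id <- trimws(vapply(fields, `[[`, "", 1L))
  disease_id <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(gene_id)) || any(!nzchar(disease_id))) {
    bad <- line_no[which(!nzchar(gene_id) | !nzchar(disease_id))[1L]]
    stop_validation("line %d of '%s' has an empty identifier", bad, path)
  }

  wcol <- resolve_weight_column(weight_column, header)
  if (is.na(wcol)) {
    weight <- rep(1, length(gene_id))
  } else {
    if (any(nf < wcol)) {
      bad <- line_no[which(nf < wcol)[1L]]
      stop_validation("line %d of '%s' lacks the weight column", bad, path)
    }
    weight <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", wcol)))
    if (anyNA(weight)) {
      bad <- line_no[which(is.na(weight))[1L]]
      stop_validation("line %d of '%s' has a non-numeric weight", bad, path)
    }
    if (any(weight < 0 | weight > 1)) {
      bad <- line_no[which(weight < 0 | weight > 1)[1L]]
      stop_validation("line %d of '%s' has a weight outside [0, 1]", bad, path)
    }
  }
  new_gda_records(gene_id, disease_id, weight)
}

resolve_weight_column <- function(weight_column, header) {
  if (is.null(weight_column)) {
    if (!is.null(header) && length(header) >= 3L &&
        tolower(trimws(header[[3L]])) %in% c("score", "weight")) {
      return(3L)
    }
    return(NA_integer_)
  }
  if (is.numeric(weight_column)) return(as.integer(weight_column))
  if (is.null(header)) {
    stop_usage("weight_column given by name but the file has no header")
  }
  idx <- match(weight_column, trimws(header))
  if (is.na(idx)) stop_usage("weight column '%s' not in header", weight_column)
  idx
}

new_gda_records <- function(gene_id, disease_id, weight) {
  structure(
    data.frame(gene_id = as.character(gene_id),
               disease_id = as.character(disease_id),
               weight = as.numeric(weight),
               stringsAsFactors = FALSE),
    class = c("gda_records", "data.frame")
  )
}

#' Build the indexed undirected bipartite gene-disease graph
#'
#' Nodes are indexed deterministically: the gene block first, then the disease
#' block, each in order of first appearance in `records`. Duplicate
#' (gene, disease) pairs collapse to a single edge keeping the maximum weight
#' (association exports may repeat a pair across evidence sources). An
#' identifier appearing in both partitions is a hard error.
#'
#' @param records A `gda_records` data frame (see [read_edge_list()]), or any
#'   data frame with columns `gene_id`, `disease_id` and optionally `weight`.
#' @return An object of class `bipartite_graph`: a list with `node_id`,
#'   `partition` (`"gene"`/`"disease"` per node), `n_genes`, `n_diseases`,
#'   `edges` (an m x 2 integer matrix of global node indices, gene column
#'   first), and `weights`.
#' @export
build_bipartite_graph <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_validation("records must be a non-empty data frame of associations")
  }
  gene_id <- as.character(records$gene_id)
  disease_id <- as.character(records$disease_id)
  weight <- if ("weight" %in% names(records)) as.numeric(records$weight)
            else rep(1, nrow(records))
  if (any(!nzchar(gene_id)) || any(!nzchar(disease_id))) {
    stop_validation("empty identifiers in records")
  }
  if (any(weight < 0 | weight > 1)) {
    stop_validation("edge weights must lie in [0, 1]")
  }

  genes <- unique(gene_id)
  diseases <- unique(disease_id)
  both <- intersect(genes, diseases)
  if (length(both) > 0L) {
    stop_validation(
      "identifier(s) appear in both partitions (first: '%s')", both[[1L]])
  }

  n_genes <- length(genes)
  n_diseases <- length(diseases)
  gi <- match(gene_id, genes)                  # 1..n_genes
  di <- n_genes + match(disease_id, diseases)  # global disease index

  # collapse duplicates, keeping max weight and first-appearance edge order
  code <- (gi - 1) * n_diseases + (di - n_genes)
  first <- !duplicated(code)
  wmax <- vapply(split(weight, code), max, 0)
  keep_code <- code[first]
  edges <- cbind(gene = gi[first], disease = di[first])
  weights <- unname(wmax[match(as.character(keep_code), names(wmax))])

  structure(
    list(node_id = c(genes, diseases),
         partition = rep(c("gene", "disease"), c(n_genes, n_diseases)),
         n_genes = n_genes,
         n_diseases = n_diseases,
         edges = edges,
         weights = weights),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "Bipartite gene-disease graph: %d genes, %d diseases, %d edges\n",
    x$n_genes, x$n_diseases, nrow(x$edges)))
  invisible(x)
}

#' Graph summary
#'
#' @param graph A `bipartite_graph`.
#' @return A list with `n`, `n_genes`, `n_diseases`, `m`.
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  list(n = graph$n_genes + graph$n_diseases,
       n_genes = graph$n_genes,
       n_diseases = graph$n_diseases,
       m = nrow(graph$edges))
}

#' Node degrees
#'
#' @param graph A `bipartite_graph`.
#' @return Integer vector of degrees, one per node, aligned with the node
#'   index.
#' @export
node_degrees <- function(graph) {
  n <- graph$n_genes + graph$n_diseases
  deg <- tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = n)
  names(deg) <- graph$node_id
  deg
}

#' Top-degree nodes per partition
#'
#' Descriptive statistics of the association network: the `top_k`
#' highest-degree genes and diseases (hub genes like TNF dominate real
#' curated networks). Ties are broken lexicographically by node id.
#'
#' @param graph A `bipartite_graph`.
#' @param top_k Number of nodes to report per partition; if larger than a
#'   partition, the whole partition is returned.
#' @return A data frame with columns `node_id`, `partition`, `degree`, sorted
#'   by partition (genes first) then descending degree.
#' @export
degree_stats <- function(graph, top_k = 10L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (top_k < 1L) stop_usage("top_k must be >= 1")
  deg <- node_degrees(graph)
  out <- lapply(c("gene", "disease"), function(part) {
    sel <- graph$partition == part
    d <- deg[sel]
    ids <- graph$node_id[sel]
    ord <- order(-d, ids)
    k <- min(top_k, length(ord))
    data.frame(node_id = ids[ord[seq_len(k)]],
               partition = part,
               degree = unname(d[ord[seq_len(k)]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a graph back to an edge-list TSV
#'
#' Rows appear in the graph's deterministic edge order, so reading the file
#' back with [read_edge_list()] and [build_bipartite_graph()] reproduces the
#' same node indexing.
#'
#' @param graph A `bipartite_graph`.
#' @param path Output file path.
#' @param write_weights Include the weight column (default only when any
#'   weight differs from 1).
#' @export
write_edge_list <- function(graph, path,
                            write_weights = any(graph$weights != 1)) {
  stopifnot(inherits(graph, "bipartite_graph"))
  g <- graph$node_id[graph$edges[, 1L]]
  d <- graph$node_id[graph$edges[, 2L]]
  lines <- if (write_weights) {
    paste(g, d, format(graph$weights, trim = TRUE, digits = 15), sep = "\t")
  } else {
    paste(g, d, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# m x 2 matrix of (gene, disease) global indices -> scalar pair code.
# Codes are exact in doubles up to ~2^53 pairs, far beyond any GDA network.
edge_codes <- function(graph, pairs) {
  (pairs[, 1L] - 1) * graph$n_diseases + (pairs[, 2L] - graph$n_genes)
}

code_to_pairs <- function(graph, codes) {
  gi <- (codes - 1) %/% graph$n_diseases + 1
  dl <- (codes - 1) %% graph$n_diseases + 1
  cbind(gene = as.integer(gi), disease = as.integer(graph$n_genes + dl))
}
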