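#' Build the weighted background network
#'
#' Turns a raw interaction pair list into a simple undirected graph:
#' self-interactions are removed and duplicate edges (either orientation)
#' collapsed. Node weights are the gene z-scores. By default nodes without
#' a gene score are dropped together with their incident edges — a module
#' score averages member weights, so an unweighted member is meaningless —
#' and the removal counts are reported. Scored nodes that end up isolated
#' are retained (they can seed only singleton modules, which the minimum
#' size rule discards). Gene identifiers are opaque case-sensitive strings.
#'
#' @param pairs `data.frame` with columns `a`, `b` ([read_edge_list()]).
#' @param scores Gene score table ([score_genes()]) supplying weights.
#' @param drop_unscored Drop nodes with no score (default `TRUE`); when
#'   `FALSE`, unscored nodes get weight `z = 0`.
#' @return An [igraph][igraph::igraph-package] graph with vertex attributes
#'   `name` and `z`, plus attributes `n_nodes_removed`/`n_edges_removed`.
#' @export
build_network <- function(pairs, scores, drop_unscored = TRUE) {
  a <- as.character(pairs$a)
  b <- as.character(pairs$b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]
  nodes <- sort(unique(c(a, b, scores$gene_id)))
  z <- stats::setNames(rep(0, length(nodes)), nodes)
  z[scores$gene_id] <- scores$z
  n_nodes_rm <- n_edges_rm <- 0L
  if (drop_unscored) {
    scored <- nodes %in% scores$gene_id
    n_nodes_rm <- sum(!scored)
    edge_ok <- a %in% nodes[scored] & b %in% nodes[scored]
    n_edges_rm <- sum(!edge_ok)
    a <- a[edge_ok]; b <- b[edge_ok]
    nodes <- nodes[scored]
    z <- z[nodes]
  }
  if (!length(nodes)) validation_error("resulting network is empty")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, z = unname(z), stringsAsFactors = FALSE))
  assert_that(all(is.finite(igraph::V(g)$z)), "non-finite node weight")
  attr(g, "n_nodes_removed") <- n_nodes_rm
  attr(g, "n_edges_removed") <- n_edges_rm
  if (n_nodes_rm || n_edges_rm)
    message("build_network: removed ", n_nodes_rm, " unscored node(s) and ",
            n_edges_rm, " incident edge(s)")
  g
}

#' Summarize a weighted network
#'
#' @param net Network from [build_network()].
#' @return List with `n_nodes`, `n_edges` and the named `degree` vector.
#' @export
network_summary <- function(net) {
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       degree = igraph::degree(net))
}
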