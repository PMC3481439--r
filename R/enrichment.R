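#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` of observing at
#' least the seen overlap between the module genes (draws) and a gene set
#' (successes) within a finite gene universe. Gene-set members outside the
#' universe are discarded before testing.
#'
#' @param module_genes Character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param gene_set A gene set (list with `name`, `genes`).
#' @param universe Character vector: the gene universe (e.g. all network
#'   nodes).
#' @return List with `set_name`, `set_size_in_universe`, `overlap`, `p`.
#' @export
hypergeom_enrich <- function(module_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) validation_error("empty gene universe")
  module_genes <- unique(module_genes)
  assert_that(all(module_genes %in% universe),
              "module genes must be a subset of the universe")
  set_in <- intersect(unique(gene_set$genes), universe)
  ov <- length(intersect(module_genes, set_in))
  N <- length(universe)
  K <- length(set_in)
  n <- length(module_genes)
  p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  list(set_name = gene_set$name, set_size_in_universe = K, overlap = ov,
       p = p)
}

#' Bonferroni correction
#'
#' @param ps P-values.
#' @param m Total number of tests (must be >= `length(ps)`).
#' @return `min(1, p * m)` element-wise.
#' @export
bonferroni <- function(ps, m = length(ps)) {
  if (m < length(ps)) validation_error("m must be >= number of p-values")
  pmin(1, ps * m)
}

#' Enrichment of module genes across a pathway collection
#'
#' Applies [hypergeom_enrich()] to every pathway and Bonferroni-corrects
#' across the collection.
#'
#' @param module_genes Genes of interest.
#' @param sets List of pathway gene sets.
#' @param universe Gene universe (defaults to the union of all pathway
#'   genes and module genes only if not supplied — prefer passing the
#'   network node set explicitly).
#' @return `data.frame` with `set`, `size_in_universe`, `overlap`, `p`,
#'   `p_bonferroni`, ordered by `p`.
#' @export
enrich_gene_sets <- function(module_genes, sets, universe) {
  rows <- lapply(sets, function(s) {
    r <- hypergeom_enrich(module_genes, s, universe)
    data.frame(set = r$set_name, size_in_universe = r$set_size_in_universe,
               overlap = r$overlap, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bonferroni <- bonferroni(out$p, nrow(out))
  out[order(out$p, out$set), ]
}
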