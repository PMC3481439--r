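#' Significant genes from a SNP pool
#'
#' A gene is significant when at least one of its mapped SNPs has a
#' p-value strictly below `p_cut`.
#'
#' @param pool SNP association table (the full analyzed SNP collection).
#' @param map A `snp_gene_map` ([map_snps_to_genes()]).
#' @param p_cut SNP significance cut (default 0.05).
#' @return Sorted character vector of significant gene ids.
#' @export
significant_genes <- function(pool, map, p_cut = 0.05) {
  pv <- stats::setNames(pool$p_value, pool$snp_id)
  hit <- vapply(map$map, function(ids) {
    ps <- pv[ids]
    any(ps < p_cut, na.rm = TRUE)
  }, logical(1))
  sort(names(map$map)[hit])
}

# Internal: index structures reused across resamples. Flattens the SNP-gene
# incidence (every mapped SNP, whatever its p-value: in the resampling null
# a gene is hit by containing a drawn SNP, which is what corrects for gene
# length and SNP density).
build_resample_index <- function(pool, map) {
  genes <- names(map$map)
  snp_id <- stats::setNames(seq_len(nrow(pool)), pool$snp_id)
  pair_snp <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    si <- snp_id[map$map[[gi]]]
    pair_snp[[gi]] <- unname(si[!is.na(si)])
  }
  npairs <- lengths(pair_snp)
  list(genes = genes, n_snps = nrow(pool),
       pair_snp = unlist(pair_snp),
       pair_gene = rep.int(seq_along(genes), npairs))
}

#' One ALIGATOR resample
#'
#' Draws SNPs from the pool uniformly without replacement, maintaining the
#' running set of genes containing at least one drawn SNP, and stops as
#' soon as that set reaches `target_count` genes (a single SNP adding
#' several new genes may overshoot by the tie). Drawn SNPs hit their genes
#' regardless of their own p-value — the resampling null models which genes
#' a random SNP collection lands in, which is what corrects the real count
#' (defined through the `p < p_cut` rule) for gene length and SNP density.
#'
#' @param pool SNP association table.
#' @param map A `snp_gene_map`.
#' @param target_count Required number of hit genes (the real
#'   significant-gene count).
#' @param seed Optional integer seed for this resample.
#' @return Character vector of gene ids (size >= `target_count`).
#' @export
one_resample <- function(pool, map, target_count, seed = NULL) {
  idx <- build_resample_index(pool, map)
  gi <- with_seed(seed, resample_once(idx, target_count))
  sort(idx$genes[gi])
}

# Core of a single resample on the precomputed index; returns integer gene
# ids. Vectorized: ranks the (snp, gene) incidence pairs by the SNP's
# position in a random permutation and cuts at the first rank where the
# cumulative count of distinct genes reaches the target.
resample_once <- function(idx, target_count) {
  if (target_count == 0) return(integer(0))
  max_attain <- length(unique(idx$pair_gene))
  if (target_count > max_attain)
    validation_error("target_count (", target_count,
                     ") exceeds attainable significant genes (", max_attain, ")")
  rnk <- integer(idx$n_snps)
  rnk[sample.int(idx$n_snps)] <- seq_len(idx$n_snps)
  pr <- rnk[idx$pair_snp]
  o <- order(pr)
  pg <- idx$pair_gene[o]
  newg <- cumsum(!duplicated(pg))
  i_stop <- which(newg >= target_count)[1]
  stop_rank <- pr[o][i_stop]
  unique(pg[pr[o] <= stop_rank])
}

#' Build the resampling null for per-category significant-gene counts
#'
#' Runs `B` independent resamples ([one_resample()]) and records, for each
#' category, how many of its genes are significant in each resample. The
#' real-case target count is computed from the pool itself unless supplied.
#'
#' @param pool SNP association table.
#' @param map A `snp_gene_map`.
#' @param categories List of gene sets ([read_gmt()]).
#' @param B Number of resamples (default 10000).
#' @param p_cut SNP significance cut (default 0.05).
#' @param seed Master seed; resample `b` uses a substream derived from
#'   `(seed, b)`.
#' @param target_count Optional override of the real significant-gene count.
#' @return A `resample_null`: list with `B`, `counts` (B x categories
#'   integer matrix), `real_genes`, `target_count`.
#' @export
resample_null <- function(pool, map, categories, B = 10000L, p_cut = 0.05,
                          seed = NULL, target_count = NULL) {
  assert_that(B >= 1, "B must be >= 1")
  idx <- build_resample_index(pool, map)
  real <- significant_genes(pool, map, p_cut)
  if (is.null(target_count)) target_count <- length(real)
  gene_cats <- vector("list", length(idx$genes))
  for (ci in seq_along(categories)) {
    gis <- match(categories[[ci]]$genes, idx$genes)
    for (gi in gis[!is.na(gis)])
      gene_cats[[gi]] <- c(gene_cats[[gi]], ci)
  }
  counts <- matrix(0L, nrow = B, ncol = length(categories))
  colnames(counts) <- vapply(categories, `[[`, "", "name")
  for (b in seq_len(B)) {
    gi <- with_seed(derive_seed(seed, paste0("resample", b)),
                    resample_once(idx, target_count))
    hits <- unlist(gene_cats[gi])
    if (length(hits))
      counts[b, ] <- tabulate(hits, nbins = length(categories))
  }
  structure(list(B = B, counts = counts, real_genes = real,
                 target_count = target_count),
            class = "resample_null")
}

#' Empirical category P-values from the resampling null
#'
#' For category `C` with real significant-gene count `x_C`, the empirical
#' p-value is `max(1, #{b : count_b >= x_C}) / B`; the `1/B` floor applies
#' when no resample reaches the real count.
#'
#' @param categories List of gene sets.
#' @param real_set Character vector of genes significant in the real data.
#' @param nulls A `resample_null`.
#' @return `data.frame` with `set`, `size`, `real_count`, `p`.
#' @export
category_pvalues <- function(categories, real_set, nulls) {
  rows <- lapply(seq_along(categories), function(ci) {
    cat <- categories[[ci]]
    x <- length(intersect(cat$genes, real_set))
    p <- max(1L, sum(nulls$counts[, ci] >= x)) / nulls$B
    data.frame(set = cat$name, size = length(cat$genes), real_count = x,
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' `adj_i = min_{j >= i} p_(j) * m_total / j`, capped at 1, computed on the
#' ascending sort and mapped back to the input order. `m_total` may exceed
#' the number of supplied p-values when they are a subset of a larger
#' family of tests.
#'
#' @param ps P-values in `(0, 1]`.
#' @param m_total Total number of tests (default `length(ps)`).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(ps, m_total = length(ps)) {
  assert_that(all(ps > 0 & ps <= 1), "p-values must lie in (0, 1]")
  if (m_total < length(ps))
    validation_error("m_total must be >= number of p-values")
  n <- length(ps)
  if (!n) return(numeric(0))
  o <- order(ps)
  adj <- ps[o] * m_total / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Filter gene sets by size
#'
#' Keeps sets with `min_size <= |genes| <= max_size` (closed bounds).
#'
#' @param sets List of gene sets.
#' @param min_size,max_size Inclusive size bounds (defaults 5 and 300).
#' @return Filtered list.
#' @export
filter_gene_sets <- function(sets, min_size = 5L, max_size = 300L) {
  Filter(function(s) {
    n <- length(s$genes)
    n >= min_size && n <= max_size
  }, sets)
}

#' SNP-resampling evaluation of gene sets
#'
#' End-to-end ALIGATOR-style driver: size-filters the pathway sets, adds
#' the extra (module) gene sets unfiltered, builds the resampling null,
#' computes empirical category p-values and applies the BH correction
#' across all tested sets.
#'
#' @param pool SNP association table.
#' @param map A `snp_gene_map`.
#' @param sets Pathway gene sets (size-filtered).
#' @param extra_sets Additional gene sets tested as-is (e.g. pooled module
#'   genes); default none.
#' @param B Number of resamples.
#' @param p_cut SNP significance cut.
#' @param min_size,max_size Pathway size bounds.
#' @param m_total Total test count for BH (default: number of tested sets).
#' @param seed Master seed.
#' @return `data.frame` with `set`, `size`, `real_count`, `p`, `p_bh`.
#' @export
evaluate_gene_sets <- function(pool, map, sets, extra_sets = list(),
                               B = 10000L, p_cut = 0.05, min_size = 5L,
                               max_size = 300L, m_total = NULL, seed = NULL) {
  tested <- c(extra_sets, filter_gene_sets(sets, min_size, max_size))
  if (!length(tested)) validation_error("no gene sets to test")
  nulls <- resample_null(pool, map, tested, B = B, p_cut = p_cut, seed = seed)
  res <- category_pvalues(tested, nulls$real_genes, nulls)
  res$p_bh <- bh_adjust(res$p, m_total %||% nrow(res))
  res
}
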