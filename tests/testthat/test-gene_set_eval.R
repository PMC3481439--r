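# Small deterministic pool used across several blocks: 30 SNPs over 8 genes.
toy_pool <- function(seed = 50) {
  set.seed(seed)
  genes <- paste0("G", 1:8)
  loci <- data.frame(gene_id = genes, chrom = "1",
                     start = seq(1e5, by = 3e5, length.out = 8),
                     end = seq(1e5, by = 3e5, length.out = 8) + 1e4,
                     stringsAsFactors = FALSE)
  gi <- sample(1:8, 30, TRUE)
  pool <- data.frame(snp_id = paste0("s", 1:30), chrom = "1",
                     pos = as.integer(loci$start[gi] + sample(1e4, 30, TRUE) - 1),
                     p_value = runif(30), stringsAsFactors = FALSE)
  map <- map_snps_to_genes(pool, loci, flank_bp = 0L)
  list(pool = pool, map = map, loci = loci)
}

test_that("significant_genes uses a strict per-gene minimum rule", {
  loci <- data.frame(gene_id = c("A", "B", "C"), chrom = "1",
                     start = c(1e5, 5e5, 9e5), end = c(2e5, 6e5, 1e6))
  pool <- data.frame(snp_id = c("s1", "s2"), chrom = "1",
                     pos = c(150000L, 550000L), p_value = c(0.049, 0.05),
                     stringsAsFactors = FALSE)
  map <- map_snps_to_genes(pool, loci, flank_bp = 0L)
  sig <- significant_genes(pool, map)
  expect_true("A" %in% sig)    # 0.049 < 0.05
  expect_false("B" %in% sig)   # 0.05 is not < 0.05
  expect_false("C" %in% sig)   # no mapped SNPs

  tp <- toy_pool()
  got <- significant_genes(tp$pool, tp$map)
  pv <- setNames(tp$pool$p_value, tp$pool$snp_id)
  want <- names(tp$map$map)[vapply(tp$map$map, function(ids)
    min(pv[ids]) < 0.05, TRUE)]
  expect_setequal(got, sort(want))
})

test_that("one_resample draw mechanics match the construction cases", {
  tp <- toy_pool()
  expect_length(one_resample(tp$pool, tp$map, 0, seed = 1), 0)

  # every SNP maps to a distinct gene: reaching the target takes exactly
  # target_count distinct genes
  genes <- paste0("D", 1:10)
  loci <- data.frame(gene_id = genes, chrom = "1",
                     start = seq(1e5, by = 3e5, length.out = 10),
                     end = seq(1e5, by = 3e5, length.out = 10) + 100)
  pool <- data.frame(snp_id = paste0("t", 1:10), chrom = "1",
                     pos = as.integer(loci$start + 1), p_value = 0.01,
                     stringsAsFactors = FALSE)
  map <- map_snps_to_genes(pool, loci, flank_bp = 0L)
  got <- one_resample(pool, map, 4, seed = 9)
  expect_length(got, 4)

  expect_error(one_resample(pool, map, 11, seed = 1),
               class = "netdms_validation_error")
})

test_that("a gene hit by several drawn SNPs counts once", {
  # one gene contains every SNP: any draw yields exactly that gene
  loci <- data.frame(gene_id = "ONE", chrom = "1", start = 1e5, end = 2e5)
  pool <- data.frame(snp_id = paste0("u", 1:6), chrom = "1",
                     pos = seq(100001L, 100006L), p_value = 0.01,
                     stringsAsFactors = FALSE)
  map <- map_snps_to_genes(pool, loci, flank_bp = 0L)
  expect_equal(one_resample(pool, map, 1, seed = 3), "ONE")
})

test_that("vectorized resampler matches the plain-loop oracle distribution", {
  tp <- toy_pool(51)
  cats <- list(list(name = "C1", description = ".", genes = c("G1", "G2", "G3")),
               list(name = "C2", description = ".", genes = c("G4", "G8")),
               list(name = "C3", description = ".", genes = paste0("G", 3:7)))
  target <- length(significant_genes(tp$pool, tp$map))
  B <- 2000
  nulls <- resample_null(tp$pool, tp$map, cats, B = B, seed = 7)
  set.seed(77)
  oracle <- oracle_resample_counts(tp$pool, tp$map, cats, target, B)
  for (ci in 1:3) {
    lev <- 0:length(cats[[ci]]$genes)
    t1 <- tabulate(factor(nulls$counts[, ci], levels = lev), length(lev))
    t2 <- tabulate(factor(oracle[, ci], levels = lev), length(lev))
    keep <- t1 + t2 > 0
    suppressWarnings(gof <- stats::chisq.test(rbind(t1[keep], t2[keep])))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("category p-values apply the 1/B floor and counting rule", {
  cats <- list(list(name = "A", description = ".", genes = paste0("g", 1:4)))
  nulls <- structure(list(B = 10L,
                          counts = matrix(c(0, 1, 1, 2, 2, 2, 3, 3, 4, 5), 10, 1)),
                     class = "resample_null")
  # x = 0: every count >= 0
  expect_equal(category_pvalues(cats, character(0), nulls)$p, 1)
  # x = 4 (second largest of the hand-built null) -> 2/10
  nulls$counts <- matrix(c(0, 1, 1, 2, 2, 2, 3, 3, 4, 5), 10, 1)
  real <- paste0("g", 1:4)
  expect_equal(category_pvalues(cats, real, nulls)$p, 0.2)
  # x exceeds all counts -> floor 1/B
  nulls$counts <- matrix(rep(0L, 10), 10, 1)
  expect_equal(category_pvalues(cats, real, nulls)$p, 0.1)
})

test_that("bh_adjust implements the step-up definition with m_total", {
  expect_equal(bh_adjust(0.01, 1), 0.01)
  set.seed(52)
  ps <- runif(20)
  expect_equal(bh_adjust(ps), oracle_bh(ps, 20), tolerance = 1e-12)
  expect_equal(bh_adjust(ps, 100), oracle_bh(ps, 100), tolerance = 1e-12)
  expect_error(bh_adjust(ps, 10), class = "netdms_validation_error")
  expect_error(bh_adjust(c(0.5, 0)), class = "netdms_validation_error")
})

test_that("filter_gene_sets keeps the closed size bounds", {
  mk <- function(n) list(name = paste0("S", n), description = ".",
                         genes = paste0("g", seq_len(n)))
  sets <- lapply(c(4, 5, 300, 301), mk)
  kept <- filter_gene_sets(sets)
  expect_equal(vapply(kept, function(s) length(s$genes), 0), c(5, 300))
  expect_length(filter_gene_sets(list()), 0)

  set.seed(53)
  sizes <- sample(1:40, 10)
  sets10 <- lapply(sizes, mk)
  expect_equal(vapply(filter_gene_sets(sets10, 5, 20), function(s)
    length(s$genes), 0), sizes[sizes >= 5 & sizes <= 20])
})

test_that("evaluate_gene_sets runs end-to-end with BH across tested sets", {
  tp <- toy_pool(54)
  sets <- list(list(name = "P1", description = ".", genes = paste0("G", 1:5)),
               list(name = "tiny", description = ".", genes = "G1"))
  res <- evaluate_gene_sets(tp$pool, tp$map, sets,
                            extra_sets = list(list(name = "extra",
                                                   description = ".",
                                                   genes = paste0("G", 6:8))),
                            B = 200, min_size = 2, seed = 5)
  expect_setequal(res$set, c("extra", "P1"))  # 'tiny' filtered out
  expect_true(all(res$p >= 1 / 200 & res$p <= 1))
  expect_equal(res$p_bh, bh_adjust(res$p, 2))
})
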