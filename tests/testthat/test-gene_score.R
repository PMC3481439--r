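test_that("SNP-gene mapping honors the flank boundary", {
  loci <- data.frame(gene_id = "G1", chrom = "1", start = 100000L,
                     end = 110000L, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("in", "out"), chrom = "1",
                     pos = c(50000L, 49999L), p_value = 0.5,
                     stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, loci)
  expect_equal(m$map$G1, "in")   # distance 50,000 <= flank, 50,001 not
})

test_that("mapping equals the exhaustive pairwise oracle", {
  set.seed(10)
  loci <- data.frame(gene_id = paste0("G", 1:5), chrom = c("1", "1", "1", "2", "2"),
                     start = c(1e5, 1.4e5, 5e5, 1e5, 9e5),
                     end = c(1.3e5, 2.5e5, 6e5, 2e5, 9.5e5))  # G1/G2 overlap
  snps <- data.frame(snp_id = paste0("s", 1:20),
                     chrom = sample(c("1", "2"), 20, TRUE),
                     pos = sample(1e4:1e6, 20), p_value = runif(20),
                     stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, loci, flank_bp = 50000L)
  for (i in 1:5) {
    expected <- snps$snp_id[snps$chrom == loci$chrom[i] &
                              snps$pos >= loci$start[i] - 50000 &
                              snps$pos <= loci$end[i] + 50000]
    got <- m$map[[loci$gene_id[i]]]
    expect_setequal(got %||% character(0), expected)
  }
})

test_that("autosome restriction excludes X/Y and reports counts", {
  loci <- data.frame(gene_id = c("GA", "GX"), chrom = c("1", "X"),
                     start = 1000L, end = 2000L, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("a", "x"), chrom = c("1", "X"), pos = 1500L,
                     p_value = 0.5, stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, loci)
  expect_named(m$map, "GA")
  expect_equal(m$n_snps_excluded, 1L)
  expect_equal(m$n_genes_excluded, 1L)
  m2 <- map_snps_to_genes(snps, loci, autosomes_only = FALSE)
  expect_setequal(names(m2$map), c("GA", "GX"))
})

test_that("LD estimation matches hand-computed correlations and repairs PSD", {
  g <- genotype_ref(cbind(s1 = c(0, 1, 2, 1, 0, 2),
                          s2 = c(0, 1, 2, 1, 0, 2),
                          s3 = c(2, 1, 0, 2, 1, 0)))
  ld <- estimate_ld(g, c("s1", "s2", "s3"))
  expect_equal(ld["s1", "s2"], 1.0)
  # hand Pearson correlation for (s1, s3)
  x <- c(0, 1, 2, 1, 0, 2); y <- c(2, 1, 0, 2, 1, 0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld["s1", "s3"], r_hand, tolerance = 1e-12)
  expect_equal(diag(unclass(ld)), c(s1 = 1, s2 = 1, s3 = 1))
  expect_gte(min(eigen(unclass(ld), symmetric = TRUE)$values), -1e-10)

  # independent SNPs: |r| < 0.1 at n = 1000
  set.seed(11)
  gi <- genotype_ref(cbind(a = rbinom(1000, 2, 0.3), b = rbinom(1000, 2, 0.3)))
  expect_lt(abs(estimate_ld(gi, c("a", "b"))["a", "b"]), 0.1)

  # monomorphic SNPs dropped with report
  gm <- genotype_ref(cbind(a = rbinom(100, 2, 0.4), mono = rep(1, 100)))
  expect_warning(ld2 <- estimate_ld(gm, c("a", "mono")), "monomorphic")
  expect_equal(rownames(ld2), "a")

  # absent SNPs: drop by default, error on request
  expect_warning(estimate_ld(gi, c("a", "b", "zz")), "absent")
  expect_error(estimate_ld(gi, c("a", "zz"), on_missing = "error"),
               class = "netdms_validation_error")
})

test_that("gene_p_all matches chi-square closed forms", {
  r1 <- gene_p_all(0.01, matrix(1, 1, 1), n_sims = 1e4, seed = 5)
  mc <- 3 * sqrt(0.01 * 0.99 / r1$n_sims_used)
  expect_lt(abs(r1$p_gene - 0.01), mc)

  set.seed(12)
  ps <- c(0.02, 0.3, 0.5, 0.11, 0.77)
  r5 <- gene_p_all(ps, diag(5), n_sims = 1e4, seed = 5)
  exact <- pchisq(sum(qchisq(ps, 1, lower.tail = FALSE)), 5,
                  lower.tail = FALSE)
  expect_lt(abs(r5$p_gene - exact),
            3 * sqrt(exact * (1 - exact) / r5$n_sims_used))

  # perfect LD degenerates to the single-SNP case
  r2 <- gene_p_all(c(0.03, 0.03), matrix(1, 2, 2), n_sims = 1e4, seed = 9)
  expect_lt(abs(r2$p_gene - 0.03), 3 * sqrt(0.03 * 0.97 / r2$n_sims_used))
})

test_that("gene_p_all is monotone when all SNP p-values decrease", {
  set.seed(13)
  C <- repair_ld_for_test(0.5, 4)
  ps <- runif(4, 0.1, 0.9)
  p_hi <- gene_p_all(ps, C, n_sims = 1000, seed = 77)$p_gene
  p_lo <- gene_p_all(ps / 2, C, n_sims = 1000, seed = 77)$p_gene
  expect_lte(p_lo, p_hi)
})

test_that("gene_p_top selection statistic matches its closed forms", {
  set.seed(14)
  ps <- runif(5, 0.05, 0.9)
  # fraction = 1 reduces exactly to gene_p_all on the same draws
  expect_identical(gene_p_top(ps, diag(5), fraction = 1, n_sims = 1000,
                              seed = 3),
                   gene_p_all(ps, diag(5), n_sims = 1000, seed = 3))
  # k = 5, fraction 0.1 -> m = 1: equivalent to testing the max chi-square;
  # closed form for independent SNPs: P(max chi2 >= t) = 1 - F(t)^5
  t_obs <- max(qchisq(ps, 1, lower.tail = FALSE))
  exact <- 1 - pchisq(t_obs, 1)^5
  r <- gene_p_top(ps, diag(5), fraction = 0.1, n_sims = 1e4, seed = 21)
  expect_lt(abs(r$p_gene - exact),
            3 * sqrt(exact * (1 - exact) / r$n_sims_used) + 2e-3)
})

test_that("gene_p_top matches a brute-force plain-simulation oracle at k=20", {
  set.seed(15)
  k <- 20
  ps <- runif(k, 0.01, 0.99)
  C <- repair_ld_for_test(0.4, k)
  r <- gene_p_top(ps, C, fraction = 0.10, n_sims = 1e4, seed = 8,
                  max_sims = 1e4)
  # independent re-simulation: same statistic, separate plain code path
  m <- 2L  # ceiling(0.1 * 20)
  t_obs <- sum(sort(qchisq(ps, 1, lower.tail = FALSE), decreasing = TRUE)[1:m])
  L <- t(chol(C))
  B <- 1e5
  set.seed(99)
  tstar <- replicate(B, {
    z <- as.vector(L %*% rnorm(k))
    sum(sort(z^2, decreasing = TRUE)[1:m])
  })
  p_oracle <- (1 + sum(tstar >= t_obs)) / (1 + B)
  tol <- 3 * (sqrt(p_oracle * (1 - p_oracle) / 1e4) +
                sqrt(p_oracle * (1 - p_oracle) / B))
  expect_lt(abs(r$p_gene - p_oracle), tol)
})

test_that("gene_p_min is the exact minimum", {
  expect_equal(gene_p_min(c(0.2, 0.05, 0.8)), 0.05)
  expect_equal(gene_p_min(0.3), 0.3)
  set.seed(16)
  u <- runif(100)
  expect_equal(gene_p_min(u), sort(u)[1])
  expect_error(gene_p_min(numeric(0)), class = "netdms_validation_error")
  # expected value 1/(k+1) for k independent uniforms
  set.seed(17)
  k <- 9
  sims <- replicate(4000, gene_p_min(runif(k)))
  expect_equal(mean(sims), 1 / (k + 1), tolerance = 0.05)
})

test_that("p_to_z is the clamped upper-tail normal quantile", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.0227501), 2.000, tolerance = 1e-3)
  expect_true(is.finite(p_to_z(1)))
  expect_equal(p_to_z(1), qnorm(1e-12), tolerance = 1e-4)
  expect_error(p_to_z(0), class = "netdms_validation_error")
  expect_error(p_to_z(1.2), class = "netdms_validation_error")
})

test_that("length bias diagnostic bins by length and emits Q-Q coordinates", {
  loci <- data.frame(gene_id = paste0("G", 1:200), chrom = "1",
                     start = 1L, end = c(rep(1000L, 100), rep(100000L, 100)))
  sc <- make_scores(loci$gene_id, z = rep(0, 200), loci)
  sc$start <- loci$start; sc$end <- loci$end
  sc$p_gene <- 0.5
  d0 <- length_bias_diagnostic(sc, bin_size = 100)
  expect_equal(d0$bins$prop_significant, c(0, 0))

  sc$p_gene <- c(rep(0.01, 100), rep(0.5, 100))  # short genes significant
  d1 <- length_bias_diagnostic(sc, bin_size = 100)
  expect_equal(d1$bins$prop_significant, c(1, 0))
  expect_true(all(diff(d1$bins$mean_length) > 0))

  # uniform p-values stay inside the 95% order-statistic band for most points
  set.seed(18)
  sc$p_gene <- runif(200)
  qq <- length_bias_diagnostic(sc)$qq
  n <- nrow(qq)
  lo <- -log10(qbeta(0.975, seq_len(n), n:1))
  hi <- -log10(qbeta(0.025, seq_len(n), n:1))
  inside <- mean(qq$observed >= lo & qq$observed <= hi)
  expect_gte(inside, 0.9)
})

test_that("score_genes drives per-gene scoring with order-independent seeds", {
  cfg <- synthetic_config(n_samples = 300, n_genes = 30,
                          snps_per_gene = c(2L, 5L), background_null = TRUE,
                          seed = 19)
  d <- simulate_dataset(cfg)
  sc <- score_genes(d$assoc, d$loci, d$geno, method = "all", seed = 19,
                    max_sims = 1e3)
  expect_equal(nrow(sc), 30)
  expect_true(all(sc$p_gene > 0 & sc$p_gene <= 1))
  expect_equal(sc$z, p_to_z(sc$p_gene))
  # reversing the locus order leaves each gene's score unchanged
  sc2 <- score_genes(d$assoc, d$loci[rev(seq_len(30)), ], d$geno,
                     method = "all", seed = 19, max_sims = 1e3)
  expect_equal(sc$p_gene[match(sc2$gene_id, sc$gene_id)], sc2$p_gene)
})
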