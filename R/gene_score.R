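#' Map SNPs to genes with a flanking window
#'
#' Assigns every SNP to every gene whose extended interval
#' `[start - flank_bp, end + flank_bp]` (1-based, fully closed) on the same
#' chromosome contains the SNP position. A SNP may map to several genes.
#' With `autosomes_only = TRUE` (the default), SNPs and genes on the sex
#' chromosomes are excluded and their counts reported; the LD machinery
#' downstream only handles autosomal markers.
#'
#' @param snps SNP association table ([read_assoc()]).
#' @param loci Gene locus table ([read_gene_loci()]).
#' @param flank_bp Flank in base pairs added to both gene ends (default 50000).
#' @param autosomes_only Drop X/Y SNPs and genes before mapping.
#' @return A `snp_gene_map`: list with `map` (named list, gene id -> SNP ids
#'   ordered by genomic position), `flank_bp`, and exclusion counts.
#' @export
map_snps_to_genes <- function(snps, loci, flank_bp = 50000L,
                              autosomes_only = TRUE) {
  n_snp_excl <- n_gene_excl <- 0L
  if (autosomes_only) {
    keep_s <- snps$chrom %in% AUTOSOMES
    keep_g <- loci$chrom %in% AUTOSOMES
    n_snp_excl <- sum(!keep_s)
    n_gene_excl <- sum(!keep_g)
    snps <- snps[keep_s, , drop = FALSE]
    loci <- loci[keep_g, , drop = FALSE]
  }
  map <- vector("list", nrow(loci))
  names(map) <- loci$gene_id
  by_chr <- split(seq_len(nrow(snps)), snps$chrom)
  for (i in seq_len(nrow(loci))) {
    idx <- by_chr[[loci$chrom[i]]]
    if (is.null(idx)) next
    lo <- loci$start[i] - flank_bp
    hi <- loci$end[i] + flank_bp
    hit <- idx[snps$pos[idx] >= lo & snps$pos[idx] <= hi]
    if (length(hit)) map[[i]] <- snps$snp_id[hit[order(snps$pos[hit])]]
  }
  map <- map[!vapply(map, is.null, TRUE)]
  if (!length(map)) warning("no SNP maps to any gene")
  structure(list(map = map, flank_bp = flank_bp,
                 n_snps_excluded = n_snp_excl,
                 n_genes_excluded = n_gene_excl),
            class = "snp_gene_map")
}

#' Estimate an LD (correlation) matrix from reference genotypes
#'
#' Pairwise Pearson correlation of additive genotype codes over
#' pairwise-complete samples. Monomorphic SNPs (zero variance or fewer than
#' two non-missing samples) are dropped with a report, as are SNPs absent
#' from the reference (unless `on_missing = "error"`). Pairwise-complete
#' correlation matrices need not be positive semi-definite, so the estimate
#' is repaired by clipping negative eigenvalues at zero and re-normalizing
#' to a unit diagonal.
#'
#' @param geno A `genotype_ref`.
#' @param snp_ids SNP ids, in the order the matrix should follow.
#' @param on_missing `"drop"` (default, with warning) or `"error"` for SNPs
#'   absent from the reference.
#' @return An `ld_matrix`: correlation matrix with SNP-id dimnames and
#'   attribute `dropped` listing excluded SNPs.
#' @export
estimate_ld <- function(geno, snp_ids, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  absent <- setdiff(snp_ids, geno$snp_ids)
  if (length(absent)) {
    if (on_missing == "error")
      validation_error("SNP(s) absent from genotype reference: ",
                       paste(utils::head(absent, 5), collapse = ", "))
    warning("estimate_ld: dropping ", length(absent),
            " SNP(s) absent from the reference")
  }
  ids <- setdiff(snp_ids, absent)
  g <- geno$matrix[, ids, drop = FALSE]
  n_ok <- colSums(!is.na(g))
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  mono <- n_ok < 2 | is.na(v) | v == 0
  if (any(mono)) {
    warning("estimate_ld: dropping ", sum(mono), " monomorphic SNP(s)")
    ids <- ids[!mono]
    g <- g[, ids, drop = FALSE]
  }
  if (!length(ids)) validation_error("no usable SNPs for LD estimation")
  C <- stats::cor(g, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0
  diag(C) <- 1
  C <- repair_psd(C)
  dimnames(C) <- list(ids, ids)
  attr(C, "dropped") <- c(absent, names(mono)[mono])
  class(C) <- c("ld_matrix", class(C))
  C
}

# Clip eigenvalues at zero and rescale to a unit diagonal. Idempotent on PSD
# inputs up to numerical noise.
repair_psd <- function(C, tol = 1e-10) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -tol) return(C)
  lam <- pmax(e$values, 0)
  C2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(C2))
  d[d == 0] <- 1
  C2 <- C2 / tcrossprod(d)
  diag(C2) <- 1
  (C2 + t(C2)) / 2
}

# Square-root factor of a PSD correlation matrix (for MVN draws): returns L
# with L %*% t(L) = C.
mvn_factor <- function(C, tol = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop_netdms("LD matrix is not positive semi-definite after repair",
                class = "netdms_numerical_error")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
}

# Shared simulation core for the all-SNP and top-fraction statistics.
# m = NULL sums all k chi-squares; otherwise the m largest per draw.
simulate_gene_p <- function(snp_ps, ld, m, n_sims, seed, max_sims) {
  k <- length(snp_ps)
  assert_that(k >= 1, "empty SNP p-value list")
  assert_that(all(snp_ps > 0 & snp_ps < 1), "SNP p-values must lie in (0,1)")
  assert_that(nrow(ld) == k, "LD dimension does not match SNP count")
  if (!is.null(m) && m >= k) m <- NULL
  q <- stats::qchisq(snp_ps, df = 1, lower.tail = FALSE)
  t_obs <- if (is.null(m)) sum(q) else
    sum(sort.int(q, decreasing = TRUE, method = "quick")[seq_len(m)])
  L <- mvn_factor(unclass(ld))
  schedule <- c(n_sims, 1e4, 1e5)
  schedule <- unique(pmin(schedule[schedule >= n_sims], max_sims))
  p <- NA_real_
  used <- 0L
  for (si in seq_along(schedule)) {
    B <- as.integer(schedule[si])
    p <- with_seed(derive_seed(seed, paste0("B", B)), {
      hits <- 0L
      done <- 0L
      chunk <- 20000L
      while (done < B) {
        nb <- min(chunk, B - done)
        Z <- matrix(stats::rnorm(nb * k), nb, k) %*% t(L)
        Z2 <- Z * Z
        tstar <- if (is.null(m)) rowSums(Z2) else
          apply(Z2, 1, function(v)
            sum(sort.int(v, decreasing = TRUE, method = "quick")[seq_len(m)]))
        hits <- hits + sum(tstar >= t_obs)
        done <- done + nb
      }
      (1 + hits) / (1 + B)
    })
    used <- B
    # adaptive escalation: refine small p-values with more draws
    if (si < length(schedule)) {
      thr <- if (schedule[si + 1] <= 1e4) 0.1 else 0.01
      if (p >= thr) break
    }
  }
  list(p_gene = p, n_sims_used = used)
}

#' Gene-wise P-value from all mapped SNPs (simulation-based)
#'
#' The observed statistic is the sum over mapped SNPs of the upper-tail
#' 1-df chi-square quantiles of their p-values. Its null distribution is
#' estimated by drawing `z ~ MVN(0, ld)` and summing the squared
#' coordinates, which accounts for LD between markers. The empirical
#' p-value is `(1 + #{T* >= T}) / (1 + B)`. An adaptive schedule refines
#' small p-values: B starts at `n_sims` (default 1000) and is escalated to
#' 1e4 when p < 0.1 and to 1e5 when p < 0.01, capped at `max_sims`.
#'
#' @param snp_ps SNP p-values in `(0,1)`, in the LD matrix's SNP order.
#' @param ld LD matrix from [estimate_ld()] (or any PSD correlation matrix).
#' @param n_sims Initial number of null simulations.
#' @param seed Integer seed for the simulation stream (`NULL` = unseeded).
#' @param max_sims Cap on the adaptive escalation.
#' @return List with `p_gene` and `n_sims_used`.
#' @export
gene_p_all <- function(snp_ps, ld, n_sims = 1000L, seed = NULL, max_sims = 1e5) {
  simulate_gene_p(snp_ps, ld, m = NULL, n_sims = n_sims, seed = seed,
                  max_sims = max_sims)
}

#' Gene-wise P-value from the top fraction of mapped SNPs
#'
#' Uses the `m = max(1, ceiling(fraction * k))` largest chi-square values;
#' every null draw contributes the sum of its own `m` largest squared
#' coordinates, so the selection step is accounted for in the null.
#'
#' @inheritParams gene_p_all
#' @param fraction Fraction of SNPs to keep (default 0.10).
#' @return List with `p_gene` and `n_sims_used`.
#' @export
gene_p_top <- function(snp_ps, ld, fraction = 0.10, n_sims = 1000L,
                       seed = NULL, max_sims = 1e5) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0,1]")
  m <- max(1L, as.integer(ceiling(fraction * length(snp_ps))))
  simulate_gene_p(snp_ps, ld, m = m, n_sims = n_sims, seed = seed,
                  max_sims = max_sims)
}

#' Gene-wise P-value by the most significant SNP
#'
#' Returns `min(snp_ps)` exactly, with no multiplicity or LD correction:
#' the classical smallest-P strategy, included for comparison with the
#' simulation-based combinations.
#'
#' @param snp_ps Non-empty vector of SNP p-values.
#' @return The minimum p-value.
#' @export
gene_p_min <- function(snp_ps) {
  assert_that(length(snp_ps) >= 1, "empty SNP p-value list")
  min(snp_ps)
}

#' Transform a gene-wise P-value to a node weight
#'
#' `z = qnorm(1 - p)` after clamping `p` into `[1e-12, 1 - 1e-12]`, so the
#' weight is finite for every admissible input (including `p = 1`).
#'
#' @param p P-value(s) in `(0, 1]`.
#' @return Finite z-score(s).
#' @export
p_to_z <- function(p) {
  assert_that(all(p > 0 & p <= 1), "p must lie in (0, 1]")
  eps <- 1e-12
  stats::qnorm(pmin(pmax(p, eps), 1 - eps), lower.tail = FALSE)
}

#' Score all mapped genes
#'
#' Drives the per-gene combination over a SNP-gene map: estimates the LD
#' matrix of each gene's mapped SNPs from the reference panel, computes the
#' requested gene-wise p-value, and attaches the node weight `z`. Genes
#' whose mapped SNPs all fail LD QC produce no score (and are therefore
#' absent from the downstream network). Each gene gets its own RNG
#' substream derived from `(seed, gene id)`, so results do not depend on
#' processing order.
#'
#' @param assoc SNP association table.
#' @param loci Gene locus table.
#' @param geno `genotype_ref` reference panel for LD (not needed for
#'   `method = "minp"`).
#' @param map Optional precomputed [map_snps_to_genes()] result.
#' @param method One of `"all"`, `"top"`, `"minp"`.
#' @param fraction Top fraction for `method = "top"`.
#' @param flank_bp Flank used when `map` is not supplied.
#' @param n_sims,max_sims Simulation schedule (see [gene_p_all()]).
#' @param seed Master seed.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `p_gene`, `method`, `z`.
#' @export
score_genes <- function(assoc, loci, geno = NULL, map = NULL,
                        method = c("all", "top", "minp"), fraction = 0.10,
                        flank_bp = 50000L, n_sims = 1000L, max_sims = 1e5,
                        seed = NULL) {
  method <- match.arg(method)
  if (is.null(map)) map <- map_snps_to_genes(assoc, loci, flank_bp = flank_bp)
  if (method != "minp" && is.null(geno))
    validation_error("methods 'all' and 'top' require a genotype reference")
  pv <- stats::setNames(assoc$p_value, assoc$snp_id)
  rows <- lapply(names(map$map), function(g) {
    ids <- map$map[[g]]
    ps <- pv[ids]
    ps <- ps[!is.na(ps)]
    if (!length(ps)) return(NULL)
    if (method == "minp") {
      res <- list(p_gene = gene_p_min(ps), n = length(ps))
    } else {
      ld <- tryCatch(suppressWarnings(estimate_ld(geno, names(ps))),
                     netdms_validation_error = function(e) NULL)
      if (is.null(ld)) return(NULL)
      ps <- ps[rownames(ld)]
      # the MC statistic needs p strictly inside (0,1)
      ps <- pmin(pmax(ps, 1e-300), 1 - 1e-12)
      gseed <- derive_seed(seed, g)
      r <- if (method == "all")
        gene_p_all(ps, ld, n_sims = n_sims, seed = gseed, max_sims = max_sims)
      else
        gene_p_top(ps, ld, fraction = fraction, n_sims = n_sims,
                   seed = gseed, max_sims = max_sims)
      res <- list(p_gene = r$p_gene, n = length(ps))
    }
    li <- match(g, loci$gene_id)
    data.frame(gene_id = g, chrom = loci$chrom[li], start = loci$start[li],
               end = loci$end[li], n_snps = res$n, p_gene = res$p_gene,
               method = method, z = p_to_z(res$p_gene),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), p_gene = numeric(0),
                      method = character(0), z = numeric(0))
  rownames(out) <- NULL
  out
}

#' Gene-length bias diagnostic and Q-Q coordinates
#'
#' Sorts scored genes by length (`end - start + 1`), groups them into
#' consecutive bins of `bin_size` genes (the last bin may be smaller), and
#' reports per bin the mean length and the proportion of genes with
#' `p_gene < alpha`. A calibrated combination method shows no trend of that
#' proportion with length; the minimum-P strategy typically does. Also
#' returns Q-Q coordinates (`-log10` expected uniform order statistics vs
#' `-log10` observed p-values).
#'
#' @param scores Gene score table from [score_genes()].
#' @param loci Gene locus table (used when `scores` lacks coordinates).
#' @param bin_size Genes per length bin (default 100).
#' @param alpha Significance cut for the per-bin proportion (default 0.05).
#' @return List with `bins` (data.frame: `bin`, `n`, `mean_length`,
#'   `prop_significant`) and `qq` (data.frame: `expected`, `observed`).
#' @export
length_bias_diagnostic <- function(scores, loci = NULL, bin_size = 100L,
                                   alpha = 0.05) {
  if (!all(c("start", "end") %in% names(scores))) {
    li <- match(scores$gene_id, loci$gene_id)
    assert_that(!anyNA(li), "every scored gene needs a locus")
    scores$start <- loci$start[li]
    scores$end <- loci$end[li]
  }
  len <- scores$end - scores$start + 1L
  o <- order(len)
  p <- scores$p_gene[o]
  n <- length(p)
  bin <- ceiling(seq_len(n) / bin_size)
  bins <- data.frame(
    bin = unique(bin),
    n = as.integer(tapply(p, bin, length)),
    mean_length = as.numeric(tapply(len[o], bin, mean)),
    prop_significant = as.numeric(tapply(p < alpha, bin, mean)))
  ps <- sort(scores$p_gene)
  qq <- data.frame(expected = -log10(seq_len(n) / (n + 1)),
                   observed = -log10(ps))
  list(bins = bins, qq = qq)
}
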