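# Independent oracles and fixture builders. Everything here is deliberately
# written against different primitives than the package code paths it checks
# (adjacency matrices + hand BFS instead of igraph, plain loops instead of
# the vectorized resampler).

# Build a score table for a set of genes with given weights (coordinates are
# dummies unless supplied).
make_scores <- function(genes, z, loci = NULL) {
  n <- length(genes)
  data.frame(gene_id = genes,
             chrom = if (is.null(loci)) rep("1", n)
                     else loci$chrom[match(genes, loci$gene_id)],
             start = rep(1L, n), end = rep(1000L, n), n_snps = rep(1L, n),
             p_gene = stats::pnorm(z, lower.tail = FALSE),
             method = rep("all", n), z = z, stringsAsFactors = FALSE)
}

# Weighted network straight from an edge data.frame and named weight vector.
make_net <- function(edges, z) {
  build_network(edges, make_scores(names(z), unname(z)))
}

edges_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

# ---- module growth oracle -------------------------------------------------

# All-pairs shortest path lengths by repeated BFS on an adjacency list.
oracle_dists <- function(nodes, edges) {
  adj <- stats::setNames(lapply(nodes, function(n) character(0)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), nodes[is.finite(d[s, ])])
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

# Step-by-step greedy growth calculator, independent of igraph and of the
# package's grow_module internals.
oracle_grow <- function(nodes, edges, z, seed, d = 2, r = 0.1) {
  dist <- oracle_dists(nodes, edges)
  members <- seed
  zm <- sum(z[members]) / sqrt(length(members))
  trace <- zm
  repeat {
    outside <- setdiff(nodes, members)
    cand <- outside[vapply(outside, function(v)
      min(dist[v, members]) <= d, TRUE)]
    if (!length(cand)) break
    zm_new <- vapply(sort(cand), function(v)
      sum(z[c(members, v)]) / sqrt(length(members) + 1), 0)
    best <- names(zm_new)[which.max(zm_new)]
    if (!(zm_new[[best]] > zm + abs(zm) * r)) break
    members <- c(members, best)
    zm <- zm_new[[best]]
    trace <- c(trace, zm)
  }
  list(members = members, Zm = zm, trace = trace)
}

# Random small graph for parameterised growth checks.
random_graph_fixture <- function(n, p_edge = 0.35) {
  nodes <- paste0("n", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  z <- stats::setNames(stats::rnorm(n, 0, 1.5), nodes)
  list(nodes = nodes, edges = edges, z = z)
}

# ---- ALIGATOR oracle -------------------------------------------------------

# Plain-loop resampler: draws SNPs one at a time with sample(), maintains the
# hit-gene set by union, stops at the target, then counts per category.
oracle_resample_counts <- function(pool, map, categories, target, B) {
  snp_genes <- stats::setNames(vector("list", nrow(pool)), pool$snp_id)
  for (g in names(map$map)) for (s in map$map[[g]])
    snp_genes[[s]] <- c(snp_genes[[s]], g)
  out <- matrix(0L, B, length(categories))
  for (b in seq_len(B)) {
    ord <- sample(pool$snp_id)
    hit <- character(0)
    for (s in ord) {
      hit <- union(hit, snp_genes[[s]])
      if (length(hit) >= target) break
    }
    out[b, ] <- vapply(categories, function(cc)
      length(intersect(cc$genes, hit)), 0L)
  }
  out
}

# Direct-definition BH step-up.
oracle_bh <- function(ps, m_total) {
  n <- length(ps)
  o <- order(ps)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[o][i:n] * m_total / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# ---- misc ------------------------------------------------------------------

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A two-6-clique + null background fixture used by module search tests and
# the acceptance suite. Background: Erdos-Renyi over n_bg nodes, cliques
# attached to the background by one edge each.
planted_cliques_fixture <- function(n_bg = 188, p_edge = 0.02, z_clique = 3,
                                    bg_sd = 1) {
  bg <- sprintf("b%03d", seq_len(n_bg))
  cl1 <- paste0("c1_", 1:6)
  cl2 <- paste0("c2_", 1:6)
  pairs <- t(utils::combn(bg, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- rbind(
    data.frame(a = pairs[keep, 1], b = pairs[keep, 2], stringsAsFactors = FALSE),
    do.call(rbind, lapply(list(cl1, cl2), function(cl) {
      cp <- t(utils::combn(cl, 2))
      data.frame(a = cp[, 1], b = cp[, 2], stringsAsFactors = FALSE)
    })),
    data.frame(a = c(cl1[1], cl2[1]), b = bg[1:2], stringsAsFactors = FALSE))
  z <- c(stats::setNames(stats::rnorm(n_bg, 0, bg_sd), bg),
         stats::setNames(rep(z_clique, 12), c(cl1, cl2)))
  list(net = make_net(edges, z), cl1 = cl1, cl2 = cl2)
}

# Exchangeable correlation matrix.
repair_ld_for_test <- function(rho, k) {
  C <- matrix(rho, k, k)
  diag(C) <- 1
  C
}
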