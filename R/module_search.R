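#' Search parameters for dense module growth
#'
#' @param d Neighborhood radius: candidates lie within shortest-path
#'   distance `d` of the growing module (default 2).
#' @param r Score increment rate: a growth step is accepted only when the
#'   module score improves by more than a factor `1 + r` (default 0.1).
#' @param min_size Minimum member count for a module to be recorded by the
#'   restricted search (default 5).
#' @param anchor `"module"` (default) measures the distance-`d`
#'   neighborhood from the nearest current member; `"seed"` restricts
#'   candidates to the seed's own neighborhood for sensitivity analysis.
#' @param denominator `"sqrt_k"` (default) scores a module as
#'   `sum(z)/sqrt(k)` (Stouffer); `"k"` uses the plain mean, exposed only
#'   for comparison.
#' @return A `search_params` list.
#' @export
search_params <- function(d = 2L, r = 0.1, min_size = 5L,
                          anchor = c("module", "seed"),
                          denominator = c("sqrt_k", "k")) {
  assert_that(d >= 1, "d must be >= 1")
  assert_that(r > 0, "r must be > 0")
  assert_that(min_size >= 1, "min_size must be >= 1")
  structure(list(d = as.integer(d), r = r, min_size = as.integer(min_size),
                 anchor = match.arg(anchor),
                 denominator = match.arg(denominator)),
            class = "search_params")
}

#' Stouffer module score
#'
#' `Zm = sum(z_i) / sqrt(k)` for `k` member weights. Under independent
#' standard-normal member weights the score is again standard normal, which
#' is what makes module scores comparable across sizes.
#'
#' @param weights Non-empty numeric vector of member z-scores.
#' @param denominator `"sqrt_k"` (Stouffer, default) or `"k"` (mean).
#' @return The module score.
#' @export
score_module <- function(weights, denominator = c("sqrt_k", "k")) {
  denominator <- match.arg(denominator)
  assert_that(length(weights) >= 1, "empty weight list")
  assert_that(all(is.finite(weights)), "non-finite weight")
  s <- sum(weights)
  if (denominator == "sqrt_k") s / sqrt(length(weights)) else s / length(weights)
}

#' Candidate neighbors of a growing module
#'
#' All nodes not currently in the module whose shortest-path distance to
#' the nearest member (or to the seed, with `anchor = "seed"`) is at most
#' `d`.
#'
#' @param net Background network.
#' @param members Character vector of current member gene ids.
#' @param d Neighborhood radius.
#' @param anchor `"module"` or `"seed"`; with `"seed"` the first element of
#'   `members` is taken as the anchor.
#' @return Character vector of candidate gene ids (possibly empty).
#' @export
candidate_neighbors <- function(net, members, d, anchor = "module") {
  assert_that(length(members) >= 1, "members must be non-empty")
  from <- if (anchor == "seed") members[1] else members
  reach <- unique(unlist(lapply(igraph::ego(net, order = d, nodes = from),
                                names)))
  setdiff(reach, members)
}

# Growth acceptance rule. For Zm > 0 this is the proportional rule
# Zm1 > Zm * (1 + r); for Zm <= 0 the symmetric form Zm1 > Zm + |Zm| * r
# demands the same absolute improvement and avoids the pathology where any
# less-negative score would pass.
step_accepted <- function(zm_old, zm_new, r) {
  zm_new > zm_old + abs(zm_old) * r
}

#' Grow a dense module from a seed node
#'
#' Greedy growth: starting from `members = {seed}`, every candidate within
#' distance `d` of the module is evaluated, the candidate maximizing the
#' new module score is selected (ties broken by lexicographically smallest
#' gene id), and the step is accepted only when the score improves by more
#' than the rate `r`. Growth stops at the first rejected step, returning
#' the best module found.
#'
#' @param net Background network ([build_network()]).
#' @param seed Seed gene id (must be a network node).
#' @param params [search_params()].
#' @return A `netdms_module`: list with `seed`, `members`, `Zm`.
#' @export
grow_module <- function(net, seed, params = search_params()) {
  vnames <- igraph::V(net)$name
  if (!seed %in% vnames) validation_error("seed '", seed, "' not in network")
  zv <- stats::setNames(igraph::V(net)$z, vnames)
  members <- seed
  zm <- score_module(zv[members], params$denominator)
  repeat {
    cand <- candidate_neighbors(net, members, params$d, params$anchor)
    if (!length(cand)) break
    cand <- sort(cand)
    s <- sum(zv[members])
    k1 <- length(members) + 1L
    den <- if (params$denominator == "sqrt_k") sqrt(k1) else k1
    zm_new <- (s + zv[cand]) / den
    best <- which.max(zm_new)     # ties: first after sort = smallest id
    if (!step_accepted(zm, zm_new[best], params$r)) break
    members <- c(members, cand[best])
    zm <- zm_new[[best]]
  }
  structure(list(seed = seed, members = members, Zm = zm),
            class = "netdms_module")
}

#' Restricted whole-network module search
#'
#' Seeds are taken in descending weight order (ties by gene id). Each seed
#' grows a module with [grow_module()]; a module reaching `min_size`
#' members is recorded and all its members removed from the background
#' network (with their incident edges) before the next round, so recorded
#' modules are pairwise disjoint and every node belongs to at most one
#' module. A seed whose module stays below `min_size` is permanently
#' disqualified from seeding but remains available as a member of later
#' modules. The search ends when no seed-eligible node remains.
#'
#' @param net Background network.
#' @param params [search_params()].
#' @return List of recorded `netdms_module` objects, in discovery order.
#' @export
restricted_search <- function(net, params = search_params()) {
  g <- net
  modules <- list()
  disqualified <- character(0)
  repeat {
    vn <- igraph::V(g)$name
    eligible <- setdiff(vn, disqualified)
    if (!length(eligible)) break
    zv <- stats::setNames(igraph::V(g)$z, vn)[eligible]
    o <- order(-zv, eligible)
    seed <- eligible[o[1]]
    mod <- grow_module(g, seed, params)
    if (length(mod$members) >= params$min_size) {
      modules[[length(modules) + 1L]] <- mod
      g <- igraph::delete_vertices(g, mod$members)
      if (!igraph::vcount(g)) break
    } else {
      disqualified <- c(disqualified, seed)
    }
  }
  modules
}
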