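#' Fit the empirical null distribution of module scores
#'
#' Module scores produced by a greedy search are selection-biased, so their
#' null distribution is estimated from the data rather than assumed
#' standard normal. Scores are first centered at their median; a normal
#' `N(delta, sigma)` is then fitted by maximum likelihood to the central
#' `central_fraction` of the centered scores, with scores outside the
#' central quantile window entering the likelihood only through their
#' counts (censoring). The bulk of the scores drives the fit, so a
#' minority of truly enriched modules in the right tail cannot inflate
#' `sigma`: their magnitudes never enter, only the fact that they lie
#' above the window.
#'
#' @param scores Numeric vector of module scores `Zm` (at least 20).
#' @param central_fraction Fraction of the centered scores used for the
#'   truncated-normal fit (default 0.5).
#' @return A `null_fit`: list with `delta`, `sigma`, `center` (the median
#'   used for centering), `n_scores`, `central_fraction`.
#' @export
fit_empirical_null <- function(scores, central_fraction = 0.5) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20)
    validation_error("fit_empirical_null needs >= 20 scores; with fewer ",
                     "modules use the exact standard-normal null ",
                     "(null_fit_exact())")
  ctr <- stats::median(scores)
  x <- scores - ctr
  lohi <- stats::quantile(x, c((1 - central_fraction) / 2,
                               1 - (1 - central_fraction) / 2),
                          names = FALSE, type = 7)
  a <- lohi[1]; b <- lohi[2]
  w <- x[x >= a & x <= b]
  if (stats::sd(w) < 1e-6 || b - a < 1e-6)
    stop_netdms("degenerate module score distribution (sigma < 1e-6)",
                class = "netdms_numerical_error")
  n_below <- sum(x < a)
  n_above <- sum(x > b)
  # Censored-normal likelihood: scores inside the central window enter with
  # their density, scores outside only through their counts. Tail
  # magnitudes (where enriched modules live) therefore cannot distort the
  # fit, while the window-mass information keeps the scale estimate
  # efficient — a pure truncated likelihood is an order of magnitude
  # noisier and has spurious flat directions (distant mean, huge scale).
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    lo <- stats::pnorm(a, mu, sig, log.p = TRUE)
    hi <- stats::pnorm(b, mu, sig, lower.tail = FALSE, log.p = TRUE)
    v <- -sum(stats::dnorm(w, mu, sig, log = TRUE)) -
      n_below * lo - n_above * hi
    if (!is.finite(v)) 1e10 else v
  }
  wid <- b - a
  fit <- stats::optim(c(mean(w), log(max(stats::sd(x), wid / 10))), nll,
                      method = "L-BFGS-B",
                      lower = c(a, log(wid / 20)),
                      upper = c(b, log(wid * 10)),
                      control = list(maxit = 2000, factr = 1e4))
  sigma <- exp(fit$par[2])
  if (sigma < 1e-6)
    stop_netdms("degenerate null fit (sigma < 1e-6)",
                class = "netdms_numerical_error")
  structure(list(delta = fit$par[1], sigma = sigma, center = ctr,
                 n_scores = length(scores),
                 central_fraction = central_fraction),
            class = "null_fit")
}

#' Exact standard-normal null fallback
#'
#' For runs producing too few modules to fit an empirical null; uses
#' `delta = 0`, `sigma = 1` around the median (or 0 when fewer than 2
#' scores are available).
#'
#' @param scores Module scores (used only for the median center).
#' @return A `null_fit`.
#' @export
null_fit_exact <- function(scores = numeric(0)) {
  ctr <- if (length(scores) >= 2) stats::median(scores) else 0
  structure(list(delta = 0, sigma = 1, center = ctr,
                 n_scores = length(scores), central_fraction = NA_real_),
            class = "null_fit")
}

#' Standardize module scores and assign module P-values
#'
#' `ZS = (Zm' - delta) / sigma` with `Zm'` the median-centered score, and
#' `p_module = 1 - pnorm(ZS)`. P-values are strictly decreasing in `Zm`.
#'
#' @param modules List of `netdms_module` objects.
#' @param fit A `null_fit` from [fit_empirical_null()] (or
#'   [null_fit_exact()]), fitted on the same score population.
#' @return The module list with `ZS` and `p_module` added to each module.
#' @export
module_pvalues <- function(modules, fit) {
  lapply(modules, function(m) {
    zs <- (m$Zm - fit$center - fit$delta) / fit$sigma
    m$ZS <- zs
    m$p_module <- stats::pnorm(zs, lower.tail = FALSE)
    m
  })
}

#' Select significant modules and pool their genes
#'
#' Modules with `p_module < alpha` are kept; their member genes are pooled
#' into one gene set (disjointness of the restricted search makes the pool
#' a plain union without double counting).
#'
#' @param modules Module list from [module_pvalues()].
#' @param alpha Raw significance threshold (default 0.05; no
#'   multiple-testing correction at this step).
#' @return List with `modules` (the significant ones) and `genes` (sorted
#'   character vector of pooled member genes).
#' @export
select_significant <- function(modules, alpha = 0.05) {
  sig <- Filter(function(m) {
    if (is.null(m$p_module)) validation_error("modules lack p_module; run module_pvalues first")
    m$p_module < alpha
  }, modules)
  list(modules = sig,
       genes = sort(unique(unlist(lapply(sig, `[[`, "members")))))
}
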