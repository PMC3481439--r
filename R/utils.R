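# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_netdms <- function(..., class = "netdms_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

format_error <- function(...) stop_netdms(..., class = "netdms_format_error")
validation_error <- function(...) stop_netdms(..., class = "netdms_validation_error")

assert_that <- function(ok, ...) if (!isTRUE(ok)) validation_error(...)

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-gene / per-resample RNG substreams that do not depend on processing
# order. Kept below 2^31 so it is always a valid R integer.
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Substream seed from (master seed, label). Master seed may be NULL for
# non-reproducible runs.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + hash31(as.character(label))) %%
               2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 6 significant digits, scientific below 1e-4; used by all table writers so
# written files round-trip through the readers.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 1e-4) formatC(v, digits = 6, format = "e")
    else formatC(v, digits = 6, format = "g")
  }, character(1))
}

AUTOSOMES <- as.character(1:22)

norm_chrom <- function(x) sub("^chr", "", as.character(x))
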