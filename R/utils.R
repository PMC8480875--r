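#' @importFrom data.table data.table := .SD
NULL

.datatable.aware <- TRUE

# Format doubles so that a write/read text round-trip is bit-exact.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All randomness in the package is routed through this helper so
# every operation is reproducible from its `seed` argument alone.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pearson correlation that returns NA (without a warning) when either
# vector is constant.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}
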