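# Internal helpers shared across the package.

# Deterministic, locale-independent gene ordering.  All tie-breaks in the
# package go through this so results do not depend on the session locale.
gene_sort <- function(x) sort(x, method = "radix")

gene_rank <- function(x) match(x, gene_sort(unique(x)))

# Evaluate `code` under a temporary RNG state seeded with `seed`; a NULL
# seed just uses the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from the single run seed; keeps values in
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage * 7919) %% 2147483587)
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Binary entropy, natural log, with the 0 log 0 = 0 convention.
binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}
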