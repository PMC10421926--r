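#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# Deterministic sub-seed for a named random substream. A single master seed
# fans out to independent, order-insensitive streams (per feature, per stage)
# so that e.g. normalizing features in a different order cannot change results.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cp in utf8ToInt(as.character(name))) {
    h <- (h * 131 + cp) %% 2147483629
  }
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629) + 1L
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
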