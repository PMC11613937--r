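# internal helpers

# evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards (pure-function semantics for generators)
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# item metadata in spec order, as plain vectors
spec_item_info <- function(spec) {
  list(name = spec$items$name,
       ncat = as.integer(spec$items$n_categories),
       factor = spec$items$factor)
}
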