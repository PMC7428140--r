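## deterministic RNG scoping: save the caller's RNG state, seed locally,
## restore on exit
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## derive bounded per-component seeds from a master seed
derive_seeds <- function(master, n) {
  old <- local_seed(master)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}
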