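#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

## Derive a stream of 32-bit replication seeds from one base seed.
derive_seeds <- function(base_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
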