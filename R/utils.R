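# Internal helpers: scoped RNG and hierarchical seed derivation.

# Evaluate expr with a locally set seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a master seed and a path of non-negative indices,
# so that e.g. adding trials or flies never perturbs earlier ones. Plain
# multiplicative hash folded into the 32-bit signed integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 69069 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom Rcpp evalCpp
#' @useDynLib sensillum, .registration = TRUE
NULL
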