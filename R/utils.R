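#' @useDynLib viperImpute, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic seed derived from the run seed and a key. Character keys
# (cell identifiers) are hashed so that results travel with the cell, not
# with its position in the matrix. Kept below 2^31 so it is always a valid
# R integer.
derive_seed <- function(global_seed, key) {
  h <- if (is.character(key)) {
    acc <- 7
    for (v in utf8ToInt(key)) acc <- (acc * 31 + v) %% 2147483647
    acc
  } else as.double(key)
  as.integer((as.double(global_seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

vlog <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}
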