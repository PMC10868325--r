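# Deterministic seed derivation. Every stochastic module draws per-molecule
# randomness from a seed derived from (global seed, op name, molecule id), so
# module order and stream chunking never change outcomes.

.hash_env <- new.env(parent = emptyenv())
.hash_env$pows <- c(1)
.HASH_P <- 2147483647  # 2^31 - 1; derived seeds stay in 32-bit integer range

.hash_pows <- function(n) {
  pows <- .hash_env$pows
  while (length(pows) < n) {
    pows <- c(pows, (pows[length(pows)] * 33) %% .HASH_P)
  }
  .hash_env$pows <- pows
  pows
}

#' Derive a deterministic 32-bit seed from arbitrary components
#'
#' Polynomial string hash (base 33 modulo 2^31-1) over the concatenated
#' components. Used internally to give every (seed, op, molecule id) triple
#' its own reproducible RNG stream.
#'
#' @param ... components (coerced to character and joined).
#' @return a single integer in `[0, 2^31-2]`, usable with [set.seed()].
#' @export
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)), collapse = "\036")
  codes <- utf8ToInt(s)
  n <- length(codes)
  if (n == 0L) return(5381L)
  pows <- .hash_pows(n + 1L)
  h <- (5381 * pows[n + 1L]) %% .HASH_P
  h <- (h + sum(codes * pows[n:1L]) %% .HASH_P) %% .HASH_P
  as.integer(h)
}

# Vectorized over ids; prefix = already-hashed context components.
derive_seeds <- function(seed, op, ids) {
  vapply(ids, function(id) derive_seed(seed, op, id), integer(1), USE.NAMES = FALSE)
}

# Evaluate expr with the global RNG state preserved (ops never perturb the
# caller's RNG stream).
with_preserved_rng <- function(expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
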