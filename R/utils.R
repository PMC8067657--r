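#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so simulators are pure functions of their arguments.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix-free formatted message
abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# permutation p-value convention used throughout: (1 + #{null >= obs}) / (1 + n)
perm_pvalue <- function(null, observed) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# all permutations of 1..n as a matrix (n! rows); used for small exact tests
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, 1L] <- k
    rest <- seq_len(n)[-k]
    block[, -1L] <- matrix(rest[sub], nrow(sub))
    out[[k]] <- block
  }
  do.call(rbind, out)
}
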