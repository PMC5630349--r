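# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations do not perturb the
#' global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Derive a sub-seed from a master seed
#'
#' Deterministically folds integer tags into a master seed so that every
#' stage and subject of a simulation draws from an independent,
#' reproducible stream. Uses a multiplicative-congruential fold modulo
#' 2^31 - 1; all arithmetic stays exact in doubles.
#'
#' @param master integer master seed.
#' @param ... integer tags (stage codes, subject indices, replicate ids).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(master) %% m)
  for (tag in c(...)) {
    s <- (s * 69069 + (abs(tag) %% m) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
}

# Validate a binary undirected adjacency matrix, returning it with a
# zeroed diagonal.
check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop_input("adjacency must be a square matrix")
  if (any(adj != 0 & adj != 1))
    stop_input("adjacency must be binary (0/1)")
  if (any(adj != t(adj)))
    stop_input("adjacency must be symmetric (undirected graph)")
  diag(adj) <- 0
  storage.mode(adj) <- "double"
  adj
}
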