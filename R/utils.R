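# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Generators split one user-facing seed into independent sub-streams (e.g.
#' planted positions vs. residue draws) so that parts of a simulation can be
#' regenerated without disturbing the others. The map is a fixed affine hash
#' modulo the Mersenne prime 2^31 - 1, keeping results inside R's integer
#' range.
#'
#' @param seed Integer master seed.
#' @param offset Integer sub-stream index (>= 0).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * (offset + 1)) %% 2147483647)
}

# Evaluate expr with a locally-set RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# All pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

centroid <- function(x) colMeans(as.matrix(x))

stop_nodkey <- function(...) stop(..., call. = FALSE)
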