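# Internal numerical helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# random state afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible child seeds from one parent seed (kept < 2^31).
childSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withSeed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

#' Z-normalize matrix rows
#'
#' Scales each row to mean 0 and (sample) standard deviation 1 across
#' columns. This is the normalization applied to every scalp map before
#' clustering and before MLP input, making topographies amplitude
#' comparable. Idempotent on already-normalized rows.
#'
#' @param x numeric matrix.
#' @param tol rows with standard deviation below `tol` are considered
#'   degenerate; they are returned as-is and flagged in the
#'   `"degenerate"` attribute.
#' @return matrix of the same shape, with a logical `"degenerate"`
#'   attribute marking zero-variance rows.
#' @export
zNormalizeRows <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowSums(xc^2) / max(1L, ncol(x) - 1L))
  degenerate <- sdv < tol
  scale <- ifelse(degenerate, 1, sdv)
  out <- xc / scale
  attr(out, "degenerate") <- degenerate
  out
}

# Squared Euclidean distances between rows of X (N x C) and rows of C (k x C).
sqDistMatrix <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
    2 * tcrossprod(X, centers)
  d2[d2 < 0] <- 0   # numeric round-off
  d2
}

# Pearson correlation between every row of A and every row of B.
rowCorMatrix <- function(A, B) {
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  An <- sqrt(rowSums(Ac^2))
  Bn <- sqrt(rowSums(Bc^2))
  if (any(An == 0) || any(Bn == 0)) {
    stop("cannot correlate zero-variance maps")
  }
  tcrossprod(Ac / An, Bc / Bn)
}

# Exact linear assignment maximizing sum(score[i, perm[i]]) by depth-first
# branch and bound (exhaustive-equivalent; fast for the k used here).
solveAssignment <- function(score) {
  n <- nrow(score)
  stopifnot(ncol(score) == n)
  best <- list(value = -Inf, perm = integer(n))
  colMax <- apply(score, 2L, max)
  recurse <- function(row, used, acc, perm) {
    if (row > n) {
      if (acc > best$value) best <<- list(value = acc, perm = perm)
      return(invisible())
    }
    # optimistic bound: remaining rows each take the global column max
    bound <- acc + sum(sort(colMax[!used], decreasing = TRUE)[seq_len(n - row + 1L)])
    if (bound <= best$value) return(invisible())
    ord <- order(score[row, ], decreasing = TRUE)
    for (j in ord) {
      if (!used[j]) {
        used[j] <- TRUE
        perm[row] <- j
        recurse(row + 1L, used, acc + score[row, j], perm)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n), 0, integer(n))
  best
}

# Stable hash of an R object (provenance / caching).
configHash <- function(x) rlang::hash(x)

# Numerically stable row-wise softmax.
softmaxRows <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}
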