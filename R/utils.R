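# Small shared helpers: batch 3x3 tensor algebra on N x 9 matrices
# (row-major packing (11,12,13,21,...,33), one tensor per row), classed
# error constructors, and seed scoping.

#' @noRd
pack_idx <- function(i, j) 3L * (i - 1L) + j

#' Batch determinant of N x 9 packed 3x3 matrices
#' @noRd
det3_batch <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
  A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

#' Batch inverse; `detA` may be supplied to avoid recomputation
#' @noRd
inv3_batch <- function(A, detA = det3_batch(A)) {
  B <- matrix(0, nrow(A), 9L)
  B[, 1] <-  (A[, 5] * A[, 9] - A[, 6] * A[, 8])
  B[, 2] <- -(A[, 2] * A[, 9] - A[, 3] * A[, 8])
  B[, 3] <-  (A[, 2] * A[, 6] - A[, 3] * A[, 5])
  B[, 4] <- -(A[, 4] * A[, 9] - A[, 6] * A[, 7])
  B[, 5] <-  (A[, 1] * A[, 9] - A[, 3] * A[, 7])
  B[, 6] <- -(A[, 1] * A[, 6] - A[, 3] * A[, 4])
  B[, 7] <-  (A[, 4] * A[, 8] - A[, 5] * A[, 7])
  B[, 8] <- -(A[, 1] * A[, 8] - A[, 2] * A[, 7])
  B[, 9] <-  (A[, 1] * A[, 5] - A[, 2] * A[, 4])
  B / detA
}

#' Batch matrix product C = A %*% B on packed rows
#' @noRd
mul3_batch <- function(A, B) {
  C <- matrix(0, nrow(A), 9L)
  for (i in 1:3) for (k in 1:3) {
    acc <- 0
    for (j in 1:3)
      acc <- acc + A[, pack_idx(i, j)] * B[, pack_idx(j, k)]
    C[, pack_idx(i, k)] <- acc
  }
  C
}

#' Batch symmetric part
#' @noRd
sym3_batch <- function(A) {
  S <- A
  for (i in 1:2) for (j in (i + 1):3) {
    m <- 0.5 * (A[, pack_idx(i, j)] + A[, pack_idx(j, i)])
    S[, pack_idx(i, j)] <- m
    S[, pack_idx(j, i)] <- m
  }
  S
}

#' Pack a single 3x3 matrix into the row-major 9-vector convention
#' @noRd
pack3 <- function(M) as.numeric(t(M))

#' @noRd
unpack3 <- function(v) matrix(v, 3L, 3L, byrow = TRUE)

#' Classed condition helpers: config errors exit 2 at the CLI, numerical
#' failures exit 3.
#' @noRd
config_error <- function(msg, ...) {
  stop(structure(class = c("gravfm_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @noRd
numeric_error <- function(msg, ...) {
  stop(structure(class = c("gravfm_numeric_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
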