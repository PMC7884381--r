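# ---------------------------------------------------------------------------
# Affine-invariant (Fisher-Rao) geometry on symmetric positive definite
# matrices.  All matrix functions go through one symmetric
# eigendecomposition so results are bit-reproducible across calls.
# ---------------------------------------------------------------------------

# eigendecomposition with a positive-definiteness guard: the smallest
# eigenvalue must exceed 1e-12 times the largest.  Rank deficiency is
# meaningful here (it marks degenerate forests), so failure is an error,
# never a silent regularization.
.sym_eigen <- function(S, what = "matrix") {
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop(what, " is not symmetric")
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values)) {
    stop(what, " is not positive definite (eigenvalue below floor)")
  }
  ev
}

.spd_fun <- function(S, fun, what = "matrix") {
  ev <- .sym_eigen(S, what)
  ev$vectors %*% (fun(ev$values) * t(ev$vectors))
}

.spd_inverse <- function(S) .spd_fun(S, function(x) 1 / x)

#' Matrix square root, inverse square root and logarithm
#'
#' All three functions of a symmetric positive definite matrix from a
#' single symmetric eigendecomposition.
#'
#' @param S symmetric positive definite matrix.
#' @return list with components `sqrt`, `inv_sqrt` and `log`.
#' @export
matrix_sqrt_log <- function(S) {
  ev <- .sym_eigen(S)
  V <- ev$vectors
  list(sqrt = V %*% (sqrt(ev$values) * t(V)),
       inv_sqrt = V %*% ((1 / sqrt(ev$values)) * t(V)),
       log = V %*% (log(ev$values) * t(V)))
}

# symmetric matrix exponential (used for geodesic points)
.spd_exp <- function(X) {
  ev <- eigen((X + t(X)) / 2, symmetric = TRUE)
  ev$vectors %*% (exp(ev$values) * t(ev$vectors))
}

#' Affine-invariant distance between covariance matrices
#'
#' \eqn{d(S_1, S_2)^2 = \mathrm{tr}\,\log^2(S_1^{-1/2} S_2 S_1^{-1/2})/2}.
#' The distance is symmetric, zero iff the matrices agree, and invariant
#' under congruence \eqn{S \mapsto G S G^T} by any invertible `G`.
#'
#' @param S1,S2 symmetric positive definite matrices.
#' @return non-negative numeric scalar.
#' @export
spd_distance <- function(S1, S2) {
  m <- matrix_sqrt_log(S1)
  W <- m$inv_sqrt %*% S2 %*% m$inv_sqrt
  L <- .spd_fun(W, log, "whitened matrix")
  sqrt(sum(L * L) / 2)
}

#' Point along the affine-invariant geodesic
#'
#' \eqn{\Gamma_{S_1,S_2}(t) = S_1^{1/2} \exp(t\,U) S_1^{1/2}} with
#' \eqn{U = \log(S_1^{-1/2} S_2 S_1^{-1/2})}; the unique geodesic of the
#' globally non-positively curved affine-invariant geometry, traversed at
#' constant speed with endpoints \eqn{\Gamma(0) = S_1},
#' \eqn{\Gamma(1) = S_2}.
#'
#' @inheritParams spd_distance
#' @param t proportion(s) along the geodesic, typically in `[0, 1]`.
#' @return the interpolating matrix, or a list of matrices when `t` has
#'   length greater than one.
#' @export
spd_geodesic_point <- function(S1, S2, t) {
  m <- matrix_sqrt_log(S1)
  W <- m$inv_sqrt %*% S2 %*% m$inv_sqrt
  U <- .spd_fun(W, log, "whitened matrix")
  one <- function(tt) {
    G <- m$sqrt %*% .spd_exp(tt * U) %*% m$sqrt
    (G + t(G)) / 2
  }
  if (length(t) == 1L) one(t) else lapply(t, one)
}

#' Read / write whitespace-delimited square matrices
#'
#' Plain-text exchange format for covariance and metric matrices: one row
#' per line, entries separated by whitespace.
#'
#' @param file path.
#' @param S matrix to write.
#' @return `read_matrix()` returns a numeric matrix.
#' @export
read_matrix <- function(file) {
  as.matrix(utils::read.table(file, header = FALSE))
}

#' @rdname read_matrix
#' @export
write_matrix <- function(S, file) {
  utils::write.table(format(S, digits = 12, trim = TRUE), file,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
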