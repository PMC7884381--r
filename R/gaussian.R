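# ---------------------------------------------------------------------------
# Gaussian (Ornstein-Uhlenbeck) process on forests: covariance embedding,
# closed-form Fisher metric, analytic metric derivatives, Christoffel
# symbols and curvature.
#
# Throughout, S is the leaf covariance matrix exp(-l_uv), A = S^{-1}, and
# sigma_i the split matrix of edge i.  Because d S / d l_k = -(S o sigma_k),
# every matrix of the form S o m (m a 0/1 mask, o the Hadamard product)
# differentiates to -(S o m o sigma_k): the family is closed under
# differentiation, which the term engine below exploits to produce exact
# first and second derivatives of the metric tensor.
# ---------------------------------------------------------------------------

#' Covariance matrix of the Gaussian process on a forest
#'
#' Entry (u, v) is \eqn{e^{-\ell_{uv}}}: unit diagonal, zero across
#' components, positive definite for every valid forest.
#'
#' @param forest a `wald_forest`.
#' @return `n_leaves x n_leaves` symmetric positive definite matrix.
#' @export
covariance_matrix <- function(forest) {
  exp(-leaf_distance_matrix(forest))
}

# coordinate context for a resolved tree: covariance, inverse, split masks
.gauss_context <- function(tree) {
  co <- tree_coords(tree)
  E <- length(co$ell)
  masks <- lapply(co$edge_index, function(e) split_matrix(tree, e))
  S <- covariance_matrix(tree)
  A <- .spd_inverse(S)
  list(co = co, E = E, S = S, A = A, masks = masks)
}

#' Derivative of the covariance matrix in an edge length
#'
#' \eqn{\partial S / \partial \ell^i = -(S \circ \sigma^i)} where
#' \eqn{\sigma^i} is the split matrix of coordinate `i` (the sign follows
#' from differentiating the product-over-edges form of the covariance).
#'
#' @param tree a single fully resolved `wald_forest` with finite lengths.
#' @param i coordinate index in the order of [tree_coords()].
#' @return symmetric `N x N` matrix.
#' @export
covariance_derivative <- function(tree, i) {
  co <- tree_coords(tree)
  if (!(i %in% seq_along(co$ell))) stop("unknown edge coordinate: ", i)
  S <- covariance_matrix(tree)
  -(S * split_matrix(tree, co$edge_index[i]))
}

#' Fisher information inner product for zero-mean Gaussians
#'
#' At a covariance matrix `S`, the inner product of two symmetric tangent
#' matrices is \eqn{\langle X, Y\rangle = \mathrm{tr}(S^{-1} X S^{-1} Y)/2}.
#'
#' @param S symmetric positive definite matrix.
#' @param X,Y symmetric matrices of the same dimension.
#' @return numeric scalar.
#' @export
gaussian_inner_product <- function(S, X, Y) {
  A <- .spd_inverse(S)
  sum((A %*% X) * t(A %*% Y)) / 2
}

#' Fisher information metric of the Gaussian model on a tree
#'
#' For a resolved tree, \eqn{g_{ij} =
#' \mathrm{tr}(S^{-1}(S\circ\sigma^i) S^{-1}(S\circ\sigma^j))/2} over the
#' canonical edge coordinates.
#'
#' @inheritParams covariance_derivative
#' @return symmetric positive definite `(2N-3) x (2N-3)` matrix.
#' @export
fisher_information_gaussian <- function(tree) {
  ctx <- .gauss_context(tree)
  AD <- lapply(ctx$masks, function(m) ctx$A %*% (ctx$S * m))
  E <- ctx$E
  g <- matrix(0, E, E)
  for (i in seq_len(E)) {
    for (j in i:E) {
      v <- sum(AD[[i]] * t(AD[[j]])) / 2
      g[i, j] <- v; g[j, i] <- v
    }
  }
  g
}

# --- term engine ------------------------------------------------------------
# A term is coef * tr(F1 F2 ... Fm) where each factor is either the inverse
# covariance A (encoded integer(0)) or S o sigma_{m1} o sigma_{m2} ...
# (encoded as the sorted vector of mask indices).  Differentiation:
#   d A / d l_k = A (S o sigma_k) A
#   d (S o m) / d l_k = -(S o m o sigma_k)

.term <- function(coef, factors) list(coef = coef, factors = factors)

.deriv_terms <- function(terms, k) {
  out <- list()
  for (tm in terms) {
    for (pos in seq_along(tm$factors)) {
      fct <- tm$factors[[pos]]
      if (length(fct) == 0L) {                   # factor A
        nf <- append(tm$factors[-pos], list(integer(0), k, integer(0)),
                     after = pos - 1L)
        out[[length(out) + 1L]] <- .term(tm$coef, nf)
      } else {
        nf <- tm$factors
        nf[[pos]] <- sort(unique(c(fct, k)))
        out[[length(out) + 1L]] <- .term(-tm$coef, nf)
      }
    }
  }
  out
}

# evaluate sum of terms under a context; mask-product matrices are cached
.eval_terms <- function(terms, ctx, cache) {
  total <- 0
  for (tm in terms) {
    M <- NULL
    for (fct in tm$factors) {
      Fm <- if (length(fct) == 0L) {
        ctx$A
      } else {
        key <- paste(fct, collapse = ".")
        val <- get0(key, envir = cache, inherits = FALSE)
        if (is.null(val)) {
          m <- ctx$masks[[fct[[1L]]]]
          for (q in fct[-1L]) m <- m * ctx$masks[[q]]
          val <- ctx$S * m
          assign(key, val, envir = cache)
        }
        val
      }
      M <- if (is.null(M)) Fm else M %*% Fm
    }
    total <- total + tm$coef * sum(diag(M))
  }
  total
}

# metric with analytic first (and optionally second) derivatives:
# dg[k, i, j] = d g_ij / d l_k;  d2g[k, l, i, j] = d^2 g_ij / d l_k d l_l.
# First derivatives expand, with D_i = S o sigma_i, D_ik = S o sigma_i o
# sigma_k and A = S^{-1} (so dA/dl_k = A D_k A, dD_i/dl_k = -D_ik):
#   2 dg_ij/dl_k = tr(A D_k A D_i A D_j) + tr(A D_i A D_k A D_j)
#               - tr(A D_ik A D_j) - tr(A D_i A D_jk)
# and are evaluated from cached products; second derivatives are produced
# by the term engine (only needed for curvature).
.gaussian_metric_derivatives <- function(tree, second = FALSE) {
  ctx <- .gauss_context(tree)
  E <- ctx$E
  AD <- lapply(ctx$masks, function(m) ctx$A %*% (ctx$S * m))
  ADt <- lapply(AD, t)
  # ADD[[i]][[k]] = A (S o sigma_i o sigma_k) A D-free product A D_ik
  ADD <- vector("list", E)
  for (i in seq_len(E)) {
    ADD[[i]] <- vector("list", E)
    for (k in i:E) {
      M <- ctx$A %*% (ctx$S * (ctx$masks[[i]] * ctx$masks[[k]]))
      ADD[[i]][[k]] <- M
    }
  }
  getADD <- function(i, k) if (i <= k) ADD[[i]][[k]] else ADD[[k]][[i]]
  P2 <- vector("list", E)              # P2[[k]][[i]] = AD_k %*% AD_i
  for (k in seq_len(E)) {
    P2[[k]] <- lapply(seq_len(E), function(i) AD[[k]] %*% AD[[i]])
  }
  g <- matrix(0, E, E)
  dg <- array(0, c(E, E, E))
  for (i in seq_len(E)) {
    for (j in i:E) {
      v <- sum(AD[[i]] * ADt[[j]]) / 2
      g[i, j] <- v; g[j, i] <- v
      for (k in seq_len(E)) {
        v <- (sum(P2[[k]][[i]] * ADt[[j]]) + sum(P2[[i]][[k]] * ADt[[j]]) -
                sum(getADD(i, k) * ADt[[j]]) -
                sum(AD[[i]] * t(getADD(j, k)))) / 2
        dg[k, i, j] <- v; dg[k, j, i] <- v
      }
    }
  }
  d2g <- NULL
  if (second) {
    cache <- new.env(parent = emptyenv())
    d2g <- array(0, c(E, E, E, E))
    for (i in seq_len(E)) {
      for (j in i:E) {
        base <- list(.term(0.5, list(integer(0), i, integer(0), j)))
        for (k in seq_len(E)) {
          dk <- .deriv_terms(base, k)
          for (l in k:E) {
            v2 <- .eval_terms(.deriv_terms(dk, l), ctx, cache)
            d2g[k, l, i, j] <- v2; d2g[l, k, i, j] <- v2
            d2g[k, l, j, i] <- v2; d2g[l, k, j, i] <- v2
          }
        }
      }
    }
  }
  list(g = g, dg = dg, d2g = d2g)
}

#' Christoffel symbols of the Gaussian geometry
#'
#' \eqn{\Gamma^k_{ij}} over a resolved tree's edge-length coordinates,
#' assembled from the analytic first derivatives of the Gaussian Fisher
#' metric.
#'
#' @inheritParams covariance_derivative
#' @return array `Gamma` with `Gamma[k, i, j]` \eqn{= \Gamma^k_{ij}}.
#' @export
christoffel_gaussian <- function(tree) {
  md <- .gaussian_metric_derivatives(tree)
  .christoffel_from_metric(md$g, md$dg)
}

# Christoffels and their analytic coordinate derivatives
# dGamma[l, k, i, j] = d Gamma^k_ij / d x_l
.christoffel_with_derivatives <- function(g, dg, d2g) {
  E <- nrow(g)
  ginv <- solve(g)
  Gamma <- .christoffel_from_metric(g, dg)
  dGamma <- array(0, c(E, E, E, E))
  for (l in seq_len(E)) {
    dginv_l <- -ginv %*% dg[l, , ] %*% ginv
    for (k in seq_len(E)) {
      for (i in seq_len(E)) {
        for (j in i:E) {
          v <- 0
          for (m in seq_len(E)) {
            v <- v + dginv_l[k, m] * (dg[i, m, j] + dg[j, m, i] - dg[m, i, j]) +
              ginv[k, m] * (d2g[l, i, m, j] + d2g[l, j, m, i] - d2g[l, m, i, j])
          }
          dGamma[l, k, i, j] <- v / 2; dGamma[l, k, j, i] <- v / 2
        }
      }
    }
  }
  list(Gamma = Gamma, dGamma = dGamma)
}

# lowered Riemann tensor R[r, s, m, n] = <R(d_m, d_n) d_s, d_r> from the
# standard coordinate formula
.riemann_from_christoffel <- function(g, Gamma, dGamma) {
  E <- nrow(g)
  Rup <- array(0, c(E, E, E, E))     # Rup[r, s, m, n] = R^r_{s m n}
  for (r in seq_len(E)) {
    for (s in seq_len(E)) {
      for (m in seq_len(E)) {
        for (n in seq_len(E)) {
          v <- dGamma[m, r, n, s] - dGamma[n, r, m, s]
          for (lam in seq_len(E)) {
            v <- v + Gamma[r, m, lam] * Gamma[lam, n, s] -
              Gamma[r, n, lam] * Gamma[lam, m, s]
          }
          Rup[r, s, m, n] <- v
        }
      }
    }
  }
  Rlow <- array(0, c(E, E, E, E))
  for (r in seq_len(E)) {
    for (s in seq_len(E)) {
      for (m in seq_len(E)) {
        for (n in seq_len(E)) {
          Rlow[r, s, m, n] <- sum(g[r, ] * Rup[, s, m, n])
        }
      }
    }
  }
  Rlow
}

#' Sectional curvatures of coordinate planes in the Gaussian geometry
#'
#' Computes the sectional curvature of the plane spanned by the coordinate
#' directions `(i, j)` at a resolved tree, from the Riemann tensor
#' assembled out of the metric and its analytic first and second
#' derivatives.  With `i` and `j` missing, returns the full matrix of
#' coordinate-plane curvatures.
#'
#' @inheritParams covariance_derivative
#' @param i,j distinct coordinate indices, or both missing.
#' @return numeric scalar, or a symmetric matrix with `NA` diagonal.
#' @export
sectional_curvature <- function(tree, i = NULL, j = NULL) {
  md <- .gaussian_metric_derivatives(tree, second = TRUE)
  cd <- .christoffel_with_derivatives(md$g, md$dg, md$d2g)
  R <- .riemann_from_christoffel(md$g, cd$Gamma, cd$dGamma)
  g <- md$g
  sec <- function(a, b) {
    denom <- g[a, a] * g[b, b] - g[a, b]^2
    if (denom <= 0) stop("degenerate coordinate plane")
    R[a, b, a, b] / denom
  }
  if (is.null(i) && is.null(j)) {
    E <- nrow(g)
    K <- matrix(NA_real_, E, E)
    for (a in seq_len(E)) for (b in seq_len(E)) if (a != b) K[a, b] <- sec(a, b)
    return(K)
  }
  if (i == j) stop("degenerate coordinate plane: i == j")
  sec(i, j)
}

# full lowered Riemann tensor (exported for tests of the tensor symmetries)
#' @rdname sectional_curvature
#' @export
riemann_tensor <- function(tree) {
  md <- .gaussian_metric_derivatives(tree, second = TRUE)
  cd <- .christoffel_with_derivatives(md$g, md$dg, md$d2g)
  .riemann_from_christoffel(md$g, cd$Gamma, cd$dGamma)
}
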