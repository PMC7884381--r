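# ---------------------------------------------------------------------------
# Two-state symmetric Markov model on forests: character distributions with
# exact first and second derivatives, f-divergences, Fisher information
# metric and Christoffel symbols.
# ---------------------------------------------------------------------------

#' Probability that the two-state chain is unchanged over a path
#'
#' For the symmetric two-state substitution process, the probability that
#' the states at two points a path length `ell` apart agree is
#' \eqn{(1 + e^{-\ell})/2}; the complement is the change probability.
#'
#' @param ell non-negative (possibly infinite) path length(s).
#' @return numeric vector of probabilities in `[1/2, 1]`.
#' @export
transition_same_prob <- function(ell) {
  if (any(ell < 0, na.rm = TRUE)) stop("path lengths must be non-negative")
  0.5 * (1 + exp(-ell))
}

# 2x2 transition matrix over an edge of length ell, and its first two
# derivatives in ell
.trans_matrix <- function(ell) {
  s <- 0.5 * (1 + exp(-ell)); d <- 0.5 * (1 - exp(-ell))
  matrix(c(s, d, d, s), 2L, 2L)
}
.trans_matrix_d1 <- function(ell) {
  h <- 0.5 * exp(-ell)
  matrix(c(-h, h, h, -h), 2L, 2L)
}
.trans_matrix_d2 <- function(ell) -.trans_matrix_d1(ell)

# global character index bits: leaf 1 is the most significant bit, so a
# character s in {0,1}^N has 1-based index 1 + sum_i s_i 2^(N-i)
.char_bits <- function(n) {
  idx <- 0:(2L^n - 1L)
  vapply(seq_len(n), function(i) idx %/% 2L^(n - i) %% 2L, numeric(2L^n))
}

#' Exact character distribution of a forest
#'
#' Computes the probability mass function on the \eqn{2^N} binary
#' characters induced by the two-state symmetric model on a forest, by
#' post-order pruning on each component (stationary Bernoulli(1/2) root
#' marginal, transition probabilities from the path-length formula);
#' components are independent, so their distributions multiply.  Characters
#' are indexed with leaf 1 as the most significant bit.
#'
#' @param forest a `wald_forest` with `n_leaves <= 16`.
#' @return numeric vector of length `2^n_leaves` summing to one.
#' @export
character_pmf <- function(forest) {
  f <- forest
  n <- f$n_leaves
  if (n > 16L) stop("character distributions are guarded at 16 leaves")
  adj <- .adjacency(f)
  comp <- .components(f)
  leaf_comp <- comp[seq_len(n)]
  B <- .char_bits(n)
  total <- rep(1, 2L^n)
  for (cid in unique(leaf_comp)) {
    leaves <- which(leaf_comp == cid)
    r <- min(leaves)
    if (is.null(adj[[r]])) {                    # isolated leaf
      pcomp <- c(0.5, 0.5); ord <- r
    } else {
      node <- function(v, parent) {
        if (v <= n) {
          return(list(leaves = v, val = diag(2)))
        }
        nb <- adj[[v]]
        res <- NULL
        for (i in seq_len(nrow(nb))) {
          w <- nb[i, 1L]
          if (w == parent) next
          ch <- node(w, v)
          chv <- .trans_matrix(f$lengths[nb[i, 2L]]) %*% ch$val
          if (is.null(res)) {
            res <- list(leaves = ch$leaves, val = chv)
          } else {
            P1 <- ncol(res$val); P2 <- ncol(chv)
            val <- matrix(0, 2L, P1 * P2)
            for (s in 1:2) val[s, ] <- as.vector(outer(res$val[s, ], chv[s, ]))
            res <- list(leaves = c(res$leaves, ch$leaves), val = val)
          }
        }
        res
      }
      nb <- adj[[r]]
      sub <- node(nb[1L, 1L], r)
      m <- .trans_matrix(f$lengths[nb[1L, 2L]]) %*% sub$val
      pcomp <- 0.5 * c(m[1L, ], m[2L, ])        # root bit most significant
      ord <- c(sub$leaves, r)                   # position j -> weight 2^(j-1)
    }
    sub_idx <- as.vector(B[, ord, drop = FALSE] %*% 2^(seq_along(ord) - 1L))
    total <- total * pcomp[sub_idx + 1L]
  }
  total
}

#' Character distribution of a resolved tree with exact derivatives
#'
#' Runs the pruning recursion with forward-mode differentiation, carrying
#' exact first and second derivatives of every character probability with
#' respect to the edge lengths in canonical coordinate order (see
#' [tree_coords()]).
#'
#' @param tree a single fully resolved `wald_forest` with finite lengths.
#' @return list with `p` (vector of length `2^N`), `grad`
#'   (`2^N x (2N-3)` matrix of first derivatives) and `hess`
#'   (`2^N x (2N-3) x (2N-3)` array of second derivatives).
#' @export
character_pmf_derivatives <- function(tree) {
  f <- tree
  n <- f$n_leaves
  if (any(is.infinite(f$lengths))) stop("tree must have finite edge lengths")
  co <- tree_coords(f)
  E <- length(co$ell)
  coord_of_edge <- integer(nrow(f$edges))
  coord_of_edge[co$edge_index] <- seq_len(E)
  adj <- .adjacency(f)

  trans <- function(state, e) {
    ci <- coord_of_edge[e]
    ell <- f$lengths[e]
    Tm <- .trans_matrix(ell); dT <- .trans_matrix_d1(ell)
    d2T <- .trans_matrix_d2(ell)
    P <- ncol(state$val)
    val <- Tm %*% state$val
    grad <- array(0, c(2L, P, E)); hess <- array(0, c(2L, P, E, E))
    for (j in seq_len(E)) {
      grad[, , j] <- Tm %*% state$grad[, , j]
      for (l in seq_len(E)) hess[, , j, l] <- Tm %*% state$hess[, , j, l]
    }
    grad[, , ci] <- grad[, , ci] + dT %*% state$val
    for (l in seq_len(E)) {
      hess[, , ci, l] <- hess[, , ci, l] + dT %*% state$grad[, , l]
      hess[, , l, ci] <- hess[, , l, ci] + dT %*% state$grad[, , l]
    }
    hess[, , ci, ci] <- hess[, , ci, ci] + d2T %*% state$val
    list(leaves = state$leaves, val = val, grad = grad, hess = hess)
  }

  combine <- function(a, b) {
    P1 <- ncol(a$val); P2 <- ncol(b$val); P <- P1 * P2
    val <- matrix(0, 2L, P)
    grad <- array(0, c(2L, P, E)); hess <- array(0, c(2L, P, E, E))
    for (s in 1:2) {
      val[s, ] <- as.vector(outer(a$val[s, ], b$val[s, ]))
      for (j in seq_len(E)) {
        grad[s, , j] <- as.vector(outer(a$grad[s, , j], b$val[s, ])) +
          as.vector(outer(a$val[s, ], b$grad[s, , j]))
        for (l in j:E) {
          h <- as.vector(outer(a$hess[s, , j, l], b$val[s, ])) +
            as.vector(outer(a$grad[s, , j], b$grad[s, , l])) +
            as.vector(outer(a$grad[s, , l], b$grad[s, , j])) +
            as.vector(outer(a$val[s, ], b$hess[s, , j, l]))
          hess[s, , j, l] <- h
          if (l != j) hess[s, , l, j] <- h
        }
      }
    }
    list(leaves = c(a$leaves, b$leaves), val = val, grad = grad, hess = hess)
  }

  node <- function(v, parent) {
    if (v <= n) {
      return(list(leaves = v, val = diag(2),
                  grad = array(0, c(2L, 2L, E)),
                  hess = array(0, c(2L, 2L, E, E))))
    }
    nb <- adj[[v]]
    res <- NULL
    for (i in seq_len(nrow(nb))) {
      w <- nb[i, 1L]
      if (w == parent) next
      ch <- trans(node(w, v), nb[i, 2L])
      res <- if (is.null(res)) ch else combine(res, ch)
    }
    res
  }

  r <- 1L
  nb <- adj[[r]]
  top <- trans(node(nb[1L, 1L], r), nb[1L, 2L])
  P <- ncol(top$val)
  pcomp <- 0.5 * c(top$val[1L, ], top$val[2L, ])
  gcomp <- matrix(0, 2L * P, E); hcomp <- array(0, c(2L * P, E, E))
  for (j in seq_len(E)) {
    gcomp[, j] <- 0.5 * c(top$grad[1L, , j], top$grad[2L, , j])
    for (l in seq_len(E)) {
      hcomp[, j, l] <- 0.5 * c(top$hess[1L, , j, l], top$hess[2L, , j, l])
    }
  }
  ord <- c(top$leaves, r)
  B <- .char_bits(n)
  sub_idx <- as.vector(B[, ord, drop = FALSE] %*% 2^(seq_along(ord) - 1L)) + 1L
  list(p = pcomp[sub_idx],
       grad = gcomp[sub_idx, , drop = FALSE],
       hess = hcomp[sub_idx, , , drop = FALSE])
}

#' Covariance of the leaf states
#'
#' Under the two-state symmetric model the states at leaves `u`, `v`
#' satisfy \eqn{\mathrm{Cov}(X_u, X_v) = e^{-\ell_{uv}}/4}, which is zero
#' across components and 1/4 (the Bernoulli(1/2) variance) for `u == v`.
#'
#' @param forest a `wald_forest`.
#' @param u,v leaf labels.
#' @return numeric scalar.
#' @export
leaf_covariance <- function(forest, u, v) {
  D <- leaf_distance_matrix(forest)
  0.25 * exp(-D[u, v])
}

#' Simulate aligned binary characters on a forest
#'
#' Draws i.i.d. characters from the two-state symmetric model by sampling
#' the state at the smallest leaf of each component from Bernoulli(1/2) and
#' propagating along the edges with the change probability
#' \eqn{(1 - e^{-\ell})/2}; infinite edges yield independent sides.
#'
#' @param forest a `wald_forest`.
#' @param n_sites number of characters to draw.
#' @param seed optional integer seed.
#' @return `n_sites x n_leaves` 0/1 integer matrix.
#' @export
simulate_characters <- function(forest, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- forest
  n <- f$n_leaves
  adj <- .adjacency(f)
  comp <- .components(f)
  states <- matrix(0L, n_sites, f$n_vertices)
  leaf_comp <- comp[seq_len(n)]
  for (cid in unique(leaf_comp)) {
    r <- min(which(leaf_comp == cid))
    states[, r] <- stats::rbinom(n_sites, 1L, 0.5)
    if (is.null(adj[[r]])) next
    queue <- r
    seen <- logical(f$n_vertices); seen[r] <- TRUE
    while (length(queue)) {
      w <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[w]]
      if (is.null(nb)) next
      for (i in seq_len(nrow(nb))) {
        x <- nb[i, 1L]
        if (seen[x]) next
        seen[x] <- TRUE
        pflip <- 0.5 * (1 - exp(-f$lengths[nb[i, 2L]]))
        flip <- stats::rbinom(n_sites, 1L, pflip)
        states[, x] <- (states[, w] + flip) %% 2L
        queue <- c(queue, x)
      }
    }
  }
  states[, seq_len(n), drop = FALSE]
}

#' f-divergence between two character distributions
#'
#' \eqn{D_f(p; q) = \sum_s q(s) f(p(s)/q(s))} for a convex `f` with
#' `f(1) = 0`.  The usual specializations are provided:
#' [kl_divergence()] (`f(t) = t log t`), the Jensen-Shannon metric
#' [js_metric()] and the Hellinger metric [hellinger_metric()].
#'
#' @param p,q probability vectors of equal length; `q` strictly positive.
#' @param f convex function with `f(1) = 0`.
#' @return numeric scalar.
#' @export
f_divergence <- function(p, q, f) {
  if (length(p) != length(q)) stop("distributions of unequal length")
  if (any(q <= 0)) stop("q must be strictly positive")
  sum(q * f(p / q))
}

#' @rdname f_divergence
#' @export
kl_divergence <- function(p, q) {
  f_divergence(p, q, function(t) ifelse(t > 0, t * log(t), 0))
}

#' @rdname f_divergence
#' @export
js_metric <- function(p, q) {
  m <- (p + q) / 2
  sqrt(0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m))
}

#' @rdname f_divergence
#' @export
hellinger_metric <- function(p, q) {
  sqrt(sum((sqrt(p) - sqrt(q))^2))
}

#' Fisher information metric of the two-state model
#'
#' The metric tensor over a resolved tree's edge-length coordinates,
#' \eqn{g_{ij} = \sum_s p(s) \partial_i \log p(s) \partial_j \log p(s)},
#' computed from the exact derivatives of the character distribution.
#' Coordinates follow [tree_coords()].
#'
#' @param tree a single fully resolved `wald_forest` with finite lengths
#'   and positive pendant lengths.
#' @return symmetric positive definite `(2N-3) x (2N-3)` matrix.
#' @export
fisher_information_two_state <- function(tree) {
  d <- character_pmf_derivatives(tree)
  if (any(d$p <= 0)) stop("degenerate character distribution")
  g <- t(d$grad) %*% (d$grad / d$p)
  (g + t(g)) / 2
}

# first derivatives of the two-state metric: dg[k, i, j] = d g_ij / d l_k
.two_state_metric_derivatives <- function(tree) {
  d <- character_pmf_derivatives(tree)
  p <- d$p; gr <- d$grad; he <- d$hess
  E <- ncol(gr)
  g <- t(gr) %*% (gr / p)
  dg <- array(0, c(E, E, E))
  for (k in seq_len(E)) {
    for (i in seq_len(E)) {
      for (j in i:E) {
        v <- sum((he[, k, i] * gr[, j] + gr[, i] * he[, k, j]) / p) -
          sum(gr[, i] * gr[, j] * gr[, k] / p^2)
        dg[k, i, j] <- v; dg[k, j, i] <- v
      }
    }
  }
  list(g = (g + t(g)) / 2, dg = dg)
}

# Christoffel symbols of the second kind from a metric and its first
# derivatives; dg[k, i, j] = d g_ij / d x_k.  Gamma[k, i, j] = Gamma^k_ij.
.christoffel_from_metric <- function(g, dg) {
  E <- nrow(g)
  ginv <- solve(g)
  Gamma <- array(0, c(E, E, E))
  for (k in seq_len(E)) {
    for (i in seq_len(E)) {
      for (j in i:E) {
        v <- 0
        for (l in seq_len(E)) {
          v <- v + ginv[k, l] * (dg[i, l, j] + dg[j, l, i] - dg[l, i, j])
        }
        Gamma[k, i, j] <- v / 2; Gamma[k, j, i] <- v / 2
      }
    }
  }
  Gamma
}

#' Christoffel symbols of the two-state Fisher geometry
#'
#' \eqn{\Gamma^k_{ij}} over a resolved tree's edge-length coordinates,
#' assembled from exact first derivatives of the Fisher information metric
#' (which require first and second derivatives of the character
#' probabilities).
#'
#' @inheritParams fisher_information_two_state
#' @return array `Gamma` with `Gamma[k, i, j]` \eqn{= \Gamma^k_{ij}},
#'   symmetric in `(i, j)`.
#' @export
christoffel_two_state <- function(tree) {
  md <- .two_state_metric_derivatives(tree)
  .christoffel_from_metric(md$g, md$dg)
}

#' Read / write binary character matrices and character distributions
#'
#' Characters are exchanged as whitespace-delimited 0/1 matrices with one
#' site per row and one column per leaf; character distributions as
#' two-column text (character bitstring, probability), with leaf 1 the
#' leading bit.
#'
#' @param x 0/1 matrix of simulated characters.
#' @param p probability vector of length `2^N`.
#' @param file path.
#' @return the read object, or (for writers) the path invisibly.
#' @export
write_characters <- function(x, file) {
  utils::write.table(x, file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_characters
#' @export
read_characters <- function(file) {
  m <- as.matrix(utils::read.table(file, header = FALSE))
  storage.mode(m) <- "integer"
  if (any(m != 0L & m != 1L)) stop("characters must be 0/1")
  unname(m)
}

#' @rdname write_characters
#' @export
write_pmf <- function(p, file) {
  n <- round(log2(length(p)))
  if (2^n != length(p)) stop("length of p must be a power of two")
  bits <- vapply(0:(length(p) - 1L), function(k) {
    paste(k %/% 2^((n - 1):0) %% 2, collapse = "")
  }, "")
  utils::write.table(data.frame(bits, format(p, digits = 15)), file,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_characters
#' @export
read_pmf <- function(file) {
  d <- utils::read.table(file, header = FALSE,
                         colClasses = c("character", "numeric"))
  idx <- strtoi(d[[1]], base = 2L)
  p <- numeric(nrow(d))
  p[idx + 1L] <- d[[2]]
  p
}
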