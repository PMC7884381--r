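# ---------------------------------------------------------------------------
# Named fixture trees for the worked examples, random tree generation and
# tree-comparison metrics.
# ---------------------------------------------------------------------------

#' Named fixture forests
#'
#' Deterministic constructors for the worked-example trees:
#' \describe{
#'   \item{`F1`}{`((1:p, 2:p):l6, 3:p, (4:p, 5:p):l7)`}
#'   \item{`F2`}{`((2:p, 3:p):l6, 1:p, (4:p, 5:p):l7)` (one NNI from `F1`)}
#'   \item{`F3`}{`((2:p, 3:p):l6, 5:p, (1:p, 4:p):l7)` (two NNIs from `F1`)}
#'   \item{`G_lambda0`}{the resolved 4-taxon tree
#'     `((1:a, 2:a):a, (3:a, 4:a))` with every edge weight `a = lambda`
#'     (weights, not lengths)}
#'   \item{`F_star_lambda`}{the 4-taxon star `(1:a, 2:a, 3:a, 4:a)` with
#'     pendant weights `a = lambda`}
#'   \item{`fig4_orthant`}{the 5-taxon orthant tree
#'     `((1:p, 2:p):l6, 3:p, (4:p, 5:p):l7)` with common pendant length
#'     `pendant`}
#' }
#'
#' @param name one of `"F1"`, `"F2"`, `"F3"`, `"G_lambda0"`,
#'   `"F_star_lambda"`, `"fig4_orthant"`.
#' @param l6,l7 internal edge lengths for `F1`/`F2`/`F3`/`fig4_orthant`.
#' @param pendant common pendant edge length (default 0.1).
#' @param lambda edge weight in (0, 1] for the 4-taxon fixtures.
#' @return a `wald_forest`.
#' @export
fixture_forest <- function(name, l6 = 0.3, l7 = 0.2, pendant = 0.1,
                           lambda = 0.5) {
  p <- pendant
  switch(name,
    F1 = parse_newick(sprintf("((1:%g,2:%g):%g,3:%g,(4:%g,5:%g):%g);",
                              p, p, l6, p, p, p, l7)),
    F2 = parse_newick(sprintf("((2:%g,3:%g):%g,1:%g,(4:%g,5:%g):%g);",
                              p, p, l6, p, p, p, l7)),
    F3 = parse_newick(sprintf("((2:%g,3:%g):%g,5:%g,(1:%g,4:%g):%g);",
                              p, p, l6, p, p, p, l7)),
    fig4_orthant = parse_newick(
      sprintf("((1:%g,2:%g):%g,3:%g,(4:%g,5:%g):%g);",
              p, p, l6, p, p, p, l7)),
    G_lambda0 = {
      ell <- weight_to_length(lambda)
      parse_newick(sprintf("((1:%.15g,2:%.15g):%.15g,(3:%.15g,4:%.15g));",
                           ell, ell, ell, ell, ell))
    },
    F_star_lambda = {
      if (lambda == 1) {
        parse_newick(c("1;", "2;", "3;", "4;"))
      } else {
        ell <- weight_to_length(lambda)
        parse_newick(sprintf("(1:%.15g,2:%.15g,3:%.15g,4:%.15g);",
                             ell, ell, ell, ell))
      }
    },
    stop("unknown fixture name: ", name)
  )
}

#' Random resolved tree
#'
#' Draws a uniformly random resolved topology (from the full enumeration
#' for up to 6 leaves, by random sequential leaf insertion above) and
#' i.i.d. exponential edge lengths with mean 0.5.
#'
#' @param n_leaves number of leaves (at least 3).
#' @param seed optional integer seed.
#' @param mean_length mean of the exponential edge-length law.
#' @return a `wald_forest`.
#' @export
random_tree <- function(n_leaves, seed = NULL, mean_length = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_leaves)
  if (n < 3L) stop("need at least 3 leaves")
  E <- 2L * n - 3L
  ell <- stats::rexp(E, rate = 1 / mean_length)
  if (n <= 6L) {
    tops <- enumerate_topologies(n)
    top <- tops[[sample.int(length(tops), 1L)]]
    return(tree_from_topology(top, pmax(ell, 1e-6)))
  }
  # random sequential insertion: uniform over resolved topologies
  tr <- cbind(1:3, rep(4L, 3L))
  for (k in 3L:(n - 1L)) {
    tr[tr > k] <- tr[tr > k] + 1L
    e <- sample.int(nrow(tr), 1L)
    w <- max(tr) + 1L
    u <- tr[e, 1L]; v <- tr[e, 2L]
    tr[e, ] <- c(u, w)
    tr <- rbind(tr, c(w, v), c(k + 1L, w))
  }
  wald_forest(n, tr, pmax(ell, 1e-6))
}

#' Path-difference metric between two trees
#'
#' The Euclidean norm of the difference of the two leaf path-length
#' matrices over unordered leaf pairs,
#' \eqn{(\sum_{u<v} (\ell_{uv} - \ell'_{uv})^2)^{1/2}}.
#'
#' @param t1,t2 single trees on the same leaf set with finite lengths.
#' @return numeric scalar.
#' @export
path_difference_metric <- function(t1, t2) {
  if (t1$n_leaves != t2$n_leaves) stop("trees are on different leaf sets")
  D1 <- leaf_distance_matrix(t1); D2 <- leaf_distance_matrix(t2)
  if (any(is.infinite(D1)) || any(is.infinite(D2))) {
    stop("path-difference metric requires connected trees")
  }
  sqrt(sum((D1[upper.tri(D1)] - D2[upper.tri(D2)])^2))
}

# Euclidean (BHV-style) distance for two trees sharing one resolved
# topology: the norm of the difference of their coordinate vectors
.bhv_shared_orthant <- function(t1, t2) {
  c1 <- tree_coords(t1); c2 <- tree_coords(t2)
  if (.topology_key(c1$topology) != .topology_key(c2$topology)) {
    stop("trees do not share a topology")
  }
  sqrt(sum((c1$ell - c2$ell)^2))
}

#' Pairwise metric tables for a list of forests
#'
#' Computes, for every pair, any of: the ambient covariance metric
#' (`"d_cov"`), the Jensen-Shannon (`"d_JS"`) and Hellinger (`"d_H"`)
#' metrics of the induced character distributions (exact sums over the
#' \eqn{2^N} characters, feasible for up to 16 leaves), and the
#' path-difference metric (`"path_difference"`).
#'
#' @param forests list of `wald_forest` objects on a common leaf set.
#' @param metrics character vector of metric names.
#' @return named list of symmetric zero-diagonal matrices.
#' @export
pairwise_metric_table <- function(forests,
                                  metrics = c("d_cov", "d_JS", "d_H")) {
  n <- unique(vapply(forests, `[[`, 0L, "n_leaves"))
  if (length(n) != 1L) stop("forests are on different leaf sets")
  m <- length(forests)
  need_pmf <- any(metrics %in% c("d_JS", "d_H"))
  pmfs <- if (need_pmf) lapply(forests, character_pmf) else NULL
  covs <- if ("d_cov" %in% metrics) {
    lapply(forests, covariance_matrix)
  } else {
    NULL
  }
  out <- lapply(metrics, function(met) {
    M <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i < j) {
          M[i, j] <- M[j, i] <- switch(met,
            d_cov = spd_distance(covs[[i]], covs[[j]]),
            d_JS = js_metric(pmfs[[i]], pmfs[[j]]),
            d_H = hellinger_metric(pmfs[[i]], pmfs[[j]]),
            path_difference = path_difference_metric(forests[[i]],
                                                     forests[[j]]),
            stop("unknown metric: ", met))
        }
      }
    }
    M
  })
  names(out) <- metrics
  out
}
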