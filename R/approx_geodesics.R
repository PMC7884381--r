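# ---------------------------------------------------------------------------
# Boundary-value approximate geodesics between forests: project points of
# the ambient affine-invariant geodesic into the embedded forest space,
# either recursively from one end or symmetrically from both ends, and
# measure discrete path lengths; plus the star-stratum distance
# experiment.
# ---------------------------------------------------------------------------

.new_discrete_path <- function(forests, k, symmetrized) {
  S <- lapply(forests, covariance_matrix)
  lens <- vapply(seq_len(length(S) - 1L), function(i) {
    spd_distance(S[[i]], S[[i + 1L]])
  }, 0)
  structure(list(forests = forests, k = k, lengths = lens,
                 symmetrized = symmetrized),
            class = "wald_discrete_path")
}

#' @export
print.wald_discrete_path <- function(x, ...) {
  cat(sprintf("wald_discrete_path: %d points (k = %d, %s), length %.6g\n",
              length(x$forests), x$k,
              if (x$symmetrized) "symmetrized" else "recursive",
              discrete_length(x)))
  invisible(x)
}

# a projection initialization must be a resolved tree; when a path point
# has collapsed internal edges (an unresolved tree), refine it into the
# first resolved topology compatible with its splits, opening the missing
# internal edges to a hair above zero
.as_resolved_init <- function(forest, reference = NULL) {
  co <- try(tree_coords(forest), silent = TRUE)
  if (!inherits(co, "try-error")) {
    return(tree_from_topology(co$topology, pmax(co$ell, 1e-8)))
  }
  .resolve_tree(forest)
}

# refine an unresolved single tree into a resolved one with tiny new
# internal edges (deterministic: first compatible enumerated topology)
.resolve_tree <- function(forest, eps = 1e-8) {
  n <- forest$n_leaves
  have <- vapply(forest_splits(forest), .split_key, "")
  lens <- forest$lengths
  for (top in enumerate_topologies(n)) {
    keys <- vapply(top$splits, .split_key, "")
    if (all(have %in% keys)) {
      ord <- .coord_split_order(top)
      ell <- rep(eps, length(keys))
      m <- match(have, keys[ord])
      ell[m] <- lens
      return(tree_from_topology(top, pmax(ell, eps)))
    }
  }
  stop("could not resolve forest into a tree topology")
}

#' Approximate geodesic by one-ended recursive projection
#'
#' Produces points `G_0 = F1, G_1, ..., G_k = F2`: at iteration
#' `i = 1..k-1` the ambient affine-invariant geodesic from the covariance
#' of `G_{i-1}` to that of `F2` is computed, the point at proportion
#' `1/(k-i+1)` along it is taken, and that matrix is projected into the
#' forest space with the boundary-crossing projection initialized at
#' `G_{i-1}`.  The construction is deliberately not symmetric under
#' swapping the end points; see [symmetrized_path()].
#'
#' @param f1 starting forest; must be a resolved tree (it seeds the
#'   projections).
#' @param f2 target forest (any valid forest).
#' @param k number of subdivisions (`k >= 2`).
#' @param control optimizer controls passed to the projections.
#' @return object of class `wald_discrete_path` with fields `forests`,
#'   `k` and `lengths` (consecutive ambient distances).
#' @export
recursive_path <- function(f1, f2, k = 64, control = list()) {
  if (k < 2) stop("k must be at least 2")
  S2 <- covariance_matrix(f2)
  forests <- vector("list", k + 1L)
  forests[[1L]] <- f1
  forests[[k + 1L]] <- f2
  cur <- f1
  for (i in seq_len(k - 1L)) {
    S <- spd_geodesic_point(covariance_matrix(cur), S2, 1 / (k - i + 1))
    pr <- project_crossing(S, .as_resolved_init(cur, f1), control = control)
    cur <- pr$forest
    forests[[i + 1L]] <- cur
  }
  .new_discrete_path(forests, k, symmetrized = FALSE)
}

#' Approximate geodesic by symmetrized two-ended projection
#'
#' Runs the projection construction simultaneously from both ends:
#' `G_0 = F1`, `H_0 = F2`, and at iteration `i = 1..k-1` the points at
#' proportions `1/(k-i+1)` and `1 - 1/(k-i+1)` of the ambient geodesic
#' from the covariance of `G_{i-1}` to that of `H_{i-1}` are projected to
#' give `G_i` and `H_i`.  The output is the concatenation
#' `G_0, ..., G_{k-1}, H_{k-1}, ..., H_0`; the seam between the two
#' half-sequences is an ordinary segment of the discrete path.
#'
#' @inheritParams recursive_path
#' @param f1,f2 end forests; both must be resolved trees (each seeds the
#'   projections from its end).
#' @return a `wald_discrete_path`.
#' @export
symmetrized_path <- function(f1, f2, k = 64, control = list()) {
  if (k < 2) stop("k must be at least 2")
  G <- vector("list", k); H <- vector("list", k)
  G[[1L]] <- f1; H[[1L]] <- f2
  for (i in seq_len(k - 1L)) {
    SG <- covariance_matrix(G[[i]])
    SH <- covariance_matrix(H[[i]])
    prop <- 1 / (k - i + 1)
    R <- spd_geodesic_point(SG, SH, prop)
    S <- spd_geodesic_point(SG, SH, 1 - prop)
    G[[i + 1L]] <- project_crossing(R, .as_resolved_init(G[[i]], f1),
                                    control = control)$forest
    H[[i + 1L]] <- project_crossing(S, .as_resolved_init(H[[i]], f2),
                                    control = control)$forest
  }
  .new_discrete_path(c(G, rev(H)), k, symmetrized = TRUE)
}

#' Discrete length of an approximate geodesic
#'
#' Sum of the ambient affine-invariant distances between consecutive path
#' points; always at least the ambient chordal distance between the end
#' points.
#'
#' @param path a `wald_discrete_path`.
#' @return numeric scalar.
#' @export
discrete_length <- function(path) {
  sum(path$lengths)
}

#' Distance profile from a tree to the star stratum
#'
#' Reproduces the star-stratum experiment: for a fully resolved 4-taxon
#' tree `G(lambda0)` with all five edge weights equal to `lambda0`, the
#' approximate intrinsic distance to the star tree `F(lambda)` with all
#' pendant weights `lambda` is computed with [symmetrized_path()] over a
#' grid of `lambda` values.  The distance blows up as `lambda` tends to 0
#' (the limiting covariance matrix loses rank) and its minimizer sits
#' slightly above `lambda0`.
#'
#' @param lambda0 weight in (0, 1) of every edge of the resolved source
#'   tree.
#' @param lambda_grid weights in (0, 1] for the target star trees.
#' @param k subdivision count for the symmetrized paths.
#' @param control optimizer controls passed to the projections.
#' @return data frame with columns `lambda` and `distance`.
#' @export
star_stratum_curve <- function(lambda0, lambda_grid, k = 16,
                               control = list()) {
  if (lambda0 <= 0 || lambda0 >= 1) stop("lambda0 must lie in (0, 1)")
  if (any(lambda_grid <= 0)) {
    stop("lambda = 0 is rejected: the star covariance degenerates")
  }
  G1 <- fixture_forest("G_lambda0", lambda = lambda0)
  dist <- vapply(lambda_grid, function(lam) {
    Fk <- fixture_forest("F_star_lambda", lambda = lam)
    discrete_length(symmetrized_path(G1, Fk, k = k, control = control))
  }, 0)
  data.frame(lambda = lambda_grid, distance = dist)
}
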