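# Independent oracles used across the suite.

# character distribution by brute-force enumeration over all internal-state
# assignments (single-tree forests), independent of the pruning recursion
brute_force_pmf <- function(f) {
  n <- f$n_leaves
  V <- f$n_vertices
  p <- numeric(2^n)
  for (conf in 0:(2^V - 1)) {
    st <- (conf %/% 2^(0:(V - 1))) %% 2
    pr <- 0.5                                  # root marginal, one per tree
    for (e in seq_len(nrow(f$edges))) {
      u <- f$edges[e, 1]; v <- f$edges[e, 2]
      pr <- pr * if (st[u] == st[v]) {
        0.5 * (1 + exp(-f$lengths[e]))
      } else {
        0.5 * (1 - exp(-f$lengths[e]))
      }
    }
    idx <- sum(st[1:n] * 2^(n - (1:n))) + 1
    p[idx] <- p[idx] + pr
  }
  p
}

# covariance of two leaf states summed directly from a pmf
moment_covariance <- function(p, n, u, v) {
  idx <- 0:(2^n - 1)
  bu <- idx %/% 2^(n - u) %% 2
  bv <- idx %/% 2^(n - v) %% 2
  sum(p * bu * bv) - sum(p * bu) * sum(p * bv)
}

random_spd <- function(n) {
  G <- matrix(stats::rnorm(n * n), n)
  crossprod(G) + diag(n) * 0.5
}

topo_key <- function(top) {
  paste(vapply(top$splits, function(s) paste(s, collapse = ","), ""),
        collapse = "|")
}

expect_tree_equal <- function(f1, f2, tol = 1e-6) {
  expect_true(forests_equivalent(f1, f2, tol = tol))
}
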