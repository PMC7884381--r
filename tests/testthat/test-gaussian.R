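# Gaussian (OU) model: covariance embedding, metric, Christoffel symbols
# and curvature.

test_that("covariance matrix has the exponential path-length form", {
  iso <- parse_newick(c("1;", "2;", "3;", "4;"))
  expect_equal(covariance_matrix(iso), diag(4))

  f <- parse_newick("((1:0.1,2:0.1):0.1,3:0.1,(4:0.1,5:0.1):0.1);")
  S <- covariance_matrix(f)
  expect_equal(S[1, 2], exp(-0.2))
  expect_equal(S[1, 4], exp(-0.4))
  expect_equal(diag(S), rep(1, 5))

  set.seed(13)
  for (rep in 1:100) {
    f <- random_tree(5)
    # push some weights near the boundary
    if (rep %% 3 == 0) f$lengths[1] <- 12
    expect_gt(min(eigen(covariance_matrix(f), symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # equivalent forests share one covariance matrix
  x <- parse_newick("((1:0.1,2:0.1):0.2,3:inf,(4:0.1,5:0.1):0.3);")
  expect_equal(covariance_matrix(x), covariance_matrix(canonicalize(x)),
               tolerance = 1e-14)
})

test_that("the embedding separates distinct canonical forests", {
  set.seed(14)
  mats <- list(); forests <- list()
  for (tp in enumerate_topologies(4)) {
    for (l6 in c(0.2, 0.7)) {
      f <- tree_from_topology(tp, c(0.3, 0.3, 0.3, 0.3, l6))
      forests[[length(forests) + 1L]] <- f
      mats[[length(mats) + 1L]] <- covariance_matrix(f)
    }
  }
  for (i in seq_along(mats)) {
    for (j in seq_along(mats)) {
      if (i < j) expect_gt(max(abs(mats[[i]] - mats[[j]])), 1e-6)
    }
  }
})

test_that("covariance derivative is the negative masked Hadamard product", {
  f <- parse_newick("((1:0.2,2:0.3):0.25,3:0.15,(4:0.3,5:0.2):0.35);")
  co <- tree_coords(f)
  h <- 1e-6
  for (i in c(1, 3, 6, 7)) {
    dS <- covariance_derivative(f, i)
    expect_equal(dS, t(dS))
    expect_gt(max(abs(dS)), 0)
    lp <- co$ell; lp[i] <- lp[i] + h
    lm <- co$ell; lm[i] <- lm[i] - h
    fd <- (covariance_matrix(tree_from_topology(co$topology, lp)) -
             covariance_matrix(tree_from_topology(co$topology, lm))) / (2 * h)
    expect_equal(dS, fd, tolerance = 1e-8)
  }
  expect_error(covariance_derivative(f, 99), "unknown")
})

test_that("Gaussian inner product is positive and congruence invariant", {
  set.seed(15)
  S <- random_spd(4)
  X <- matrix(rnorm(16), 4); X <- X + t(X)
  Y <- matrix(rnorm(16), 4); Y <- Y + t(Y)
  expect_gt(gaussian_inner_product(S, X, X), 0)
  expect_equal(gaussian_inner_product(diag(4), X, Y), sum(X * t(Y)) / 2)
  G <- matrix(rnorm(16), 4)
  expect_equal(gaussian_inner_product(G %*% S %*% t(G),
                                      G %*% X %*% t(G), G %*% Y %*% t(G)),
               gaussian_inner_product(S, X, Y), tolerance = 1e-9)
})

test_that("Gaussian Fisher metric matches its defining properties", {
  f <- parse_newick("((1:0.2,2:0.3):0.25,3:0.15,(4:0.3,5:0.2):0.35);")
  g <- fisher_information_gaussian(f)
  expect_equal(g, t(g))
  expect_gt(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), 0)

  # pullback identity g_ij = <dS_i, dS_j>_S
  S <- covariance_matrix(f)
  for (ij in list(c(1, 1), c(2, 6), c(6, 7))) {
    expect_equal(g[ij[1], ij[2]],
                 gaussian_inner_product(S, covariance_derivative(f, ij[1]),
                                        covariance_derivative(f, ij[2])),
                 tolerance = 1e-10)
  }

  # scaling the covariance leaves the metric unchanged
  X <- covariance_derivative(f, 6)
  expect_equal(gaussian_inner_product(3.7 * S, 3.7 * X, 3.7 * X),
               gaussian_inner_product(S, X, X), tolerance = 1e-12)

  # N = 2 closed form from S = [[1, r], [r, 1]]
  ell <- 0.6; r <- exp(-ell)
  f2 <- parse_newick(sprintf("(1:%g,2:%g);", ell / 2, ell / 2))
  g2 <- fisher_information_gaussian(f2)
  expect_equal(g2[1, 1], r^2 * (1 + r^2) / (1 - r^2)^2, tolerance = 1e-10)
})

test_that("Gaussian metric matches Monte-Carlo score covariance", {
  # score integral evaluated by simulation on a 4-leaf tree
  f <- parse_newick("((1:0.4,2:0.3):0.3,3:0.5,4:0.4);")
  S <- covariance_matrix(f)
  A <- solve(S)
  g <- fisher_information_gaussian(f)
  set.seed(16)
  nmc <- 2e5
  Z <- matrix(rnorm(nmc * 4), nmc, 4) %*% chol(S)
  E <- length(tree_coords(f)$ell)
  scores <- matrix(0, nmc, E)
  for (i in seq_len(E)) {
    dS <- covariance_derivative(f, i)
    M <- A %*% dS %*% A
    scores[, i] <- 0.5 * rowSums((Z %*% M) * Z) - 0.5 * sum(diag(A %*% dS))
  }
  for (i in seq_len(E)) {
    for (j in i:E) {
      prod_ij <- scores[, i] * scores[, j]
      se <- stats::sd(prod_ij) / sqrt(nmc)
      expect_lt(abs(mean(prod_ij) - g[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("Gaussian Christoffels match finite differences of the metric", {
  f <- parse_newick("((1:0.2,2:0.3):0.25,3:0.15,(4:0.3,5:0.2):0.35);")
  G <- christoffel_gaussian(f)
  expect_equal(G, aperm(G, c(1, 3, 2)))
  co <- tree_coords(f)
  h <- 1e-5
  dg_fd <- array(0, c(7, 7, 7))
  for (k in 1:7) {
    lp <- co$ell; lp[k] <- lp[k] + h
    lm <- co$ell; lm[k] <- lm[k] - h
    dg_fd[k, , ] <-
      (fisher_information_gaussian(tree_from_topology(co$topology, lp)) -
       fisher_information_gaussian(tree_from_topology(co$topology, lm))) /
      (2 * h)
  }
  g <- fisher_information_gaussian(f)
  ginv <- solve(g)
  G_fd <- array(0, c(7, 7, 7))
  for (k in 1:7) for (i in 1:7) for (j in 1:7) {
    G_fd[k, i, j] <- 0.5 * sum(ginv[k, ] *
      (dg_fd[i, , j] + dg_fd[j, , i] - dg_fd[, i, j]))
  }
  expect_equal(G, G_fd, tolerance = 1e-6)
})

test_that("the two inner products converge as the edge saturates", {
  # N = 2 grid: the discrete and Gaussian metrics differ for short edges
  # and agree in the saturation limit
  rel <- vapply(c(0.5, 1.5, 3, 5), function(ell) {
    f2 <- parse_newick(sprintf("(1:%g,2:%g);", ell / 2, ell / 2))
    a <- fisher_information_two_state(f2)[1, 1]
    b <- fisher_information_gaussian(f2)[1, 1]
    abs(a - b) / b
  }, 0)
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[length(rel)], 1e-2)
  expect_gt(rel[1], 0.1)
})

test_that("Riemann tensor has its symmetries and FD-consistent assembly", {
  f <- parse_newick("((1:0.3,2:0.25):0.3,3:0.35,4:0.3);")
  R <- riemann_tensor(f)
  expect_equal(R, -aperm(R, c(2, 1, 3, 4)), tolerance = 1e-9)
  expect_equal(R, -aperm(R, c(1, 2, 4, 3)), tolerance = 1e-9)
  expect_equal(R, aperm(R, c(3, 4, 1, 2)), tolerance = 1e-9)

  # independent route: finite differences of the analytic Christoffels
  co <- tree_coords(f)
  E <- length(co$ell)
  h <- 1e-5
  Gm <- christoffel_gaussian(f)
  dG <- array(0, c(E, E, E, E))
  for (l in seq_len(E)) {
    lp <- co$ell; lp[l] <- lp[l] + h
    lm <- co$ell; lm[l] <- lm[l] - h
    dG[l, , , ] <-
      (christoffel_gaussian(tree_from_topology(co$topology, lp)) -
       christoffel_gaussian(tree_from_topology(co$topology, lm))) / (2 * h)
  }
  g <- fisher_information_gaussian(f)
  Rup <- array(0, c(E, E, E, E))
  for (r in 1:E) for (s in 1:E) for (m in 1:E) for (n in 1:E) {
    Rup[r, s, m, n] <- dG[m, r, n, s] - dG[n, r, m, s] +
      sum(Gm[r, m, ] * Gm[, n, s]) - sum(Gm[r, n, ] * Gm[, m, s])
  }
  R_fd <- array(0, c(E, E, E, E))
  for (r in 1:E) for (s in 1:E) for (m in 1:E) for (n in 1:E) {
    R_fd[r, s, m, n] <- sum(g[r, ] * Rup[, s, m, n])
  }
  expect_equal(R, R_fd, tolerance = 1e-4)
})

test_that("sectional curvatures have mixed signs over the 5-leaf space", {
  set.seed(18)
  signs <- c()
  for (rep in 1:6) {
    f <- random_tree(5)
    K <- sectional_curvature(f)
    signs <- c(signs, range(K, na.rm = TRUE))
  }
  expect_gt(max(signs), 0)
  expect_lt(min(signs), 0)
  f <- random_tree(5)
  k67 <- sectional_curvature(f, 6, 7)
  expect_equal(k67, sectional_curvature(f, 7, 6))
  expect_error(sectional_curvature(f, 3, 3), "degenerate")
})
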