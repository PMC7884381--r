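# Two-state symmetric model: character distributions, exact derivatives,
# divergences, Fisher metric and Christoffel symbols.

test_that("transition probability follows the closed form", {
  expect_equal(transition_same_prob(0), 1)
  expect_equal(transition_same_prob(Inf), 0.5)
  expect_equal(transition_same_prob(log(2)), 0.75)
  expect_error(transition_same_prob(-1), "non-negative")
})

test_that("character distribution matches closed forms and brute force", {
  # N = 2, single edge: enumerate the chain by hand
  ell <- 0.8
  f2 <- parse_newick(sprintf("(1:%g,2:%g);", ell / 2, ell / 2))
  p <- character_pmf(f2)
  expect_equal(p, c((1 + exp(-ell)) / 4, (1 - exp(-ell)) / 4,
                    (1 - exp(-ell)) / 4, (1 + exp(-ell)) / 4))

  set.seed(5)
  for (rep in 1:5) {
    f <- random_tree(5)
    p <- character_pmf(f)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(p, brute_force_pmf(f), tolerance = 1e-12)
  }
  # a 4-leaf check of the enumeration oracle as well
  f4 <- random_tree(4)
  expect_equal(character_pmf(f4), brute_force_pmf(f4), tolerance = 1e-12)
})

test_that("equivalent forests induce identical character distributions", {
  a <- parse_newick("((1:0.1,2:0.1):0.0,3:0.1,(4:0.1,5:0.1):0.2);")
  b <- parse_newick("(1:0.1,2:0.1,3:0.1,(4:0.1,5:0.1):0.2);")
  expect_equal(character_pmf(a), character_pmf(b), tolerance = 1e-14)

  x <- parse_newick("((1:0.1,2:0.1):0.2,3:inf,(4:0.1,5:0.1):0.3);")
  expect_equal(character_pmf(x), character_pmf(canonicalize(x)),
               tolerance = 1e-14)
  # independence across components: the infinite pendant makes leaf 3
  # marginally Bernoulli(1/2) independent of the rest
  p <- character_pmf(x)
  idx <- 0:31
  b3 <- idx %/% 2^2 %% 2
  expect_equal(sum(p[b3 == 1]), 0.5, tolerance = 1e-12)
})

test_that("derivatives of the character distribution are exact", {
  # N = 2 closed form: dp(00)/dl = -e^{-l}/4
  f2 <- parse_newick("(1:0.35,2:0.35);")
  d2 <- character_pmf_derivatives(f2)
  expect_equal(d2$grad[1, 1], -exp(-0.7) / 4, tolerance = 1e-12)

  set.seed(6)
  f <- random_tree(5)
  co <- tree_coords(f)
  d <- character_pmf_derivatives(f)
  expect_equal(colSums(d$grad), rep(0, 7), tolerance = 1e-12)
  # finite-difference oracle on the gradient
  h <- 1e-5
  for (j in c(1, 4, 6, 7)) {
    lp <- co$ell; lp[j] <- lp[j] + h
    lm <- co$ell; lm[j] <- lm[j] - h
    fd <- (character_pmf(tree_from_topology(co$topology, lp)) -
             character_pmf(tree_from_topology(co$topology, lm))) / (2 * h)
    expect_equal(d$grad[, j], fd, tolerance = 1e-7)
  }
  # finite-difference oracle on the Hessian slices
  h <- 1e-4
  for (jl in list(c(2, 6), c(6, 6), c(3, 7))) {
    lp <- co$ell; lp[jl[1]] <- lp[jl[1]] + h
    lm <- co$ell; lm[jl[1]] <- lm[jl[1]] - h
    fd <- (character_pmf_derivatives(
             tree_from_topology(co$topology, lp))$grad[, jl[2]] -
           character_pmf_derivatives(
             tree_from_topology(co$topology, lm))$grad[, jl[2]]) / (2 * h)
    expect_equal(d$hess[, jl[1], jl[2]], fd, tolerance = 1e-6)
  }
})

test_that("leaf covariance matches the closed form and the pmf moments", {
  set.seed(8)
  f <- random_tree(5)
  D <- leaf_distance_matrix(f)
  p <- character_pmf(f)
  for (u in 1:5) {
    for (v in 1:5) {
      expect_equal(leaf_covariance(f, u, v), exp(-D[u, v]) / 4,
                   tolerance = 1e-12)
      expect_equal(leaf_covariance(f, u, v), moment_covariance(p, 5, u, v),
                   tolerance = 1e-10)
    }
  }
  expect_equal(leaf_covariance(f, 2, 2), 0.25)
  f2 <- parse_newick(c("(1:0.3,2:0.4);", "(3:0.1,4:0.2);"))
  expect_equal(leaf_covariance(f2, 1, 3), 0)
})

test_that("simulated characters reproduce the model's moments and pmf", {
  f <- parse_newick("((1:0.3,2:0.2):0.4,3:0.3,(4:0.25,5:0.35):0.15);")
  n <- 1e5
  X <- simulate_characters(f, n, seed = 42)
  expect_identical(dim(X), c(1e5L, 5L))
  expect_identical(X, simulate_characters(f, n, seed = 42))
  # stationary marginals within a 3-sigma binomial band
  expect_true(all(abs(colMeans(X) - 0.5) < 3 * sqrt(0.25 / n)))
  # pair covariance vs Lemma-style closed form
  for (pair in list(c(1, 2), c(1, 4), c(3, 5))) {
    expect_equal(stats::cov(X[, pair[1]], X[, pair[2]]),
                 leaf_covariance(f, pair[1], pair[2]),
                 tolerance = 8 / sqrt(n))
  }
  # chi-square goodness of fit against the exact pmf (N = 4)
  f4 <- parse_newick("((1:0.3,2:0.2):0.4,3:0.3,4:0.25);")
  X4 <- simulate_characters(f4, 1e5, seed = 7)
  idx <- as.vector(X4 %*% 2^(3:0)) + 1
  obs <- tabulate(idx, nbins = 16)
  expect_gt(stats::chisq.test(obs, p = character_pmf(f4))$p.value, 0.01)
})

test_that("f-divergences satisfy their defining identities", {
  set.seed(9)
  p <- character_pmf(random_tree(4))
  q <- character_pmf(random_tree(4))
  expect_equal(f_divergence(p, p, function(t) t * log(t)), 0)
  expect_equal(kl_divergence(p, p), 0)
  expect_gt(kl_divergence(p, q), 0)
  # Hellinger: f-divergence route equals the direct formula
  hel_f <- f_divergence(p, q, function(t) (sqrt(t) - 1)^2)
  expect_equal(sqrt(hel_f), hellinger_metric(p, q), tolerance = 1e-12)
  expect_equal(js_metric(p, q), js_metric(q, p))
  expect_error(f_divergence(p, c(q[-1], 0), function(t) t), "positive")
})

test_that("Fisher metric is positive definite and matches the KL expansion", {
  set.seed(10)
  for (rep in 1:25) {
    f <- random_tree(5)
    g <- fisher_information_two_state(f)
    expect_gt(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  f <- parse_newick("((1:0.2,2:0.3):0.25,3:0.15,(4:0.3,5:0.2):0.35);")
  g <- fisher_information_two_state(f)
  co <- tree_coords(f)
  p0 <- character_pmf(f)
  dl <- c(0.4, -0.2, 0.3, 0.1, -0.3, 0.5, -0.25)
  dl <- dl / sqrt(sum(dl^2)) * 1e-3
  p1 <- character_pmf(tree_from_topology(co$topology, co$ell + dl))
  quad <- as.numeric(t(dl) %*% g %*% dl)
  # 2 D_KL approximates the quadratic form to third order
  expect_equal(2 * kl_divergence(p1, p0), quad, tolerance = 1e-2)
  # any f-divergence gives the same normalized quadratic form
  # (f = -log t has f''(1) = 1 as well)
  rkl <- f_divergence(p1, p0, function(t) -log(t))
  expect_equal(2 * rkl, quad, tolerance = 1e-2)

  # N = 2: metric matches the hand-derived scalar from the 4-entry pmf
  ell <- 0.9
  f2 <- parse_newick(sprintf("(1:%g,2:%g);", ell / 2, ell / 2))
  g2 <- fisher_information_two_state(f2)
  # four pmf entries (1 +/- r)/4 with derivatives -/+ r/4:
  # g = sum (dp)^2 / p = r^2 / (1 - r^2)
  r <- exp(-ell)
  expect_equal(g2[1, 1], r^2 / (1 - r^2), tolerance = 1e-10)
})

test_that("metric saturates as an edge grows long", {
  gs <- vapply(c(0.5, 1, 2, 4, 6), function(l6) {
    f <- parse_newick(sprintf(
      "((1:0.2,2:0.2):%g,3:0.2,(4:0.2,5:0.2):0.3);", l6))
    co <- tree_coords(f)
    fisher_information_two_state(f)[6, 6]
  }, 0)
  expect_true(all(diff(gs) < 0))
  expect_lt(gs[length(gs)], 1e-3)
})

test_that("two-state Christoffel symbols match finite differences of g", {
  f <- parse_newick("((1:0.2,2:0.3):0.25,3:0.15,(4:0.3,5:0.2):0.35);")
  G <- christoffel_two_state(f)
  expect_equal(G, aperm(G, c(1, 3, 2)))
  co <- tree_coords(f)
  h <- 1e-4
  dg_fd <- array(0, c(7, 7, 7))
  for (k in 1:7) {
    lp <- co$ell; lp[k] <- lp[k] + h
    lm <- co$ell; lm[k] <- lm[k] - h
    dg_fd[k, , ] <-
      (fisher_information_two_state(tree_from_topology(co$topology, lp)) -
       fisher_information_two_state(tree_from_topology(co$topology, lm))) /
      (2 * h)
  }
  g <- fisher_information_two_state(f)
  ginv <- solve(g)
  G_fd <- array(0, c(7, 7, 7))
  for (k in 1:7) for (i in 1:7) for (j in 1:7) {
    G_fd[k, i, j] <- 0.5 * sum(ginv[k, ] *
      (dg_fd[i, , j] + dg_fd[j, , i] - dg_fd[, i, j]))
  }
  expect_equal(G, G_fd, tolerance = 1e-5)
})

test_that("character matrices and distributions round trip as text", {
  f <- parse_newick("((1:0.3,2:0.2):0.4,3:0.3,4:0.25);")
  X <- simulate_characters(f, 50, seed = 1)
  tf <- tempfile()
  write_characters(X, tf)
  expect_identical(read_characters(tf), X)
  p <- character_pmf(f)
  write_pmf(p, tf)
  expect_equal(read_pmf(tf), p, tolerance = 1e-12)
  unlink(tf)
})
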