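# Forest construction, Newick round trips, splits, canonical reductions,
# topology combinatorics.

test_that("Newick parsing matches the documented worked examples", {
  f <- parse_newick("((1:0.1,2:0.1):0.3,3:0.1,(4:0.1,5:0.1):0.2);")
  expect_equal(f$n_leaves, 5L)
  expect_equal(nrow(f$edges), 7L)
  expect_setequal(f$lengths[f$lengths > 0.15], c(0.3, 0.2))

  # degree-2 suppression sums lengths
  f2 <- parse_newick("(1:0.5,2:0.5);")
  expect_equal(nrow(f2$edges), 1L)
  expect_equal(f2$lengths, 1.0)
  expect_equal(write_newick(f2), "(1:0.5,2:0.5);")

  # forests as one statement per component; isolated leaves allowed
  f3 <- parse_newick(c("1;", "2;", "3;"))
  expect_equal(write_newick(f3), c("1;", "2;", "3;"))

  # infinite lengths survive the round trip
  f4 <- parse_newick("((1:0.1,2:0.1):inf,3:0.1,(4:0.1,5:0.1):0.2);")
  expect_true(any(is.infinite(f4$lengths)))
  expect_true(forests_equivalent(f4, parse_newick(write_newick(f4))))
})

test_that("invalid Newick input is rejected with informative errors", {
  expect_error(parse_newick("((1:0.1,2:0.1):0.3,3:0.1,(4:0.1,2:0.1):0.2);"),
               "duplicate")
  expect_error(parse_newick("(1:-0.5,2:0.5);"), "negative")
  expect_error(parse_newick("(1:0.0,2:0.0);"), "pendant|coincident")
})

test_that("write o parse o write is idempotent and deterministic", {
  txts <- c("((1:0.1,2:0.1):0.3,3:0.1,(4:0.1,5:0.1):0.2);",
            "((2:0.4,3:0.1):0.25,1:0.3,(4:0.2,5:0.1):0.2);",
            "(1:0.2,2:0.3,3:0.4,4:0.5);")
  for (txt in txts) {
    s <- write_newick(parse_newick(txt))
    expect_identical(write_newick(parse_newick(paste(s, collapse = "\n"))), s)
    expect_tree_equal(parse_newick(txt),
                      parse_newick(paste(s, collapse = "\n")))
  }
})

test_that("leaf distance matrix sums path lengths, Inf across components", {
  f <- parse_newick("((1:0.1,2:0.1):0.1,3:0.1,(4:0.1,5:0.1):0.1);")
  D <- leaf_distance_matrix(f)
  expect_equal(D[1, 2], 0.2)
  expect_equal(D[1, 4], 0.4)
  expect_equal(diag(D), rep(0, 5))
  expect_true(isSymmetric(D))

  f2 <- parse_newick(c("(1:0.3,2:0.4);", "(3:0.1,4:0.2);"))
  D2 <- leaf_distance_matrix(f2)
  expect_true(all(is.infinite(D2[1:2, 3:4])))
  expect_equal(D2[1, 2], 0.7)
})

test_that("split matrices follow the path-indicator definition", {
  f3 <- parse_newick("(1:0.2,2:0.3,3:0.4);")
  e1 <- which(apply(f3$edges, 1, function(r) 1 %in% r))
  sm <- split_matrix(f3, e1)
  expect_equal(sm[1, 2], 1L); expect_equal(sm[1, 3], 1L)
  expect_equal(sm[2, 3], 0L); expect_equal(diag(sm), rep(0L, 3))

  f <- parse_newick("((1:0.1,2:0.2):0.3,3:0.1,(4:0.1,5:0.1):0.2);")
  splits <- forest_splits(f)
  eint <- which(vapply(splits, function(s) identical(s, c(3L, 4L, 5L)), TRUE))
  sm2 <- split_matrix(f, eint)
  for (u in 1:5) for (v in 1:5) {
    expect_equal(sm2[u, v],
                 as.integer((u %in% 1:2) != (v %in% 1:2) && u != v))
  }
  # sum of length-weighted split matrices is the distance matrix
  S <- Reduce(`+`, lapply(seq_len(nrow(f$edges)),
                          function(e) f$lengths[e] * split_matrix(f, e)))
  expect_equal(S, leaf_distance_matrix(f))
  expect_error(split_matrix(f, 99), "unknown")
})

test_that("canonicalize applies both reduction rules and is idempotent", {
  # zero-length internal edge contracts to a degree-4 vertex
  a <- parse_newick("((1:0.1,2:0.1):0.0,3:0.1,(4:0.1,5:0.1):0.2);")
  b <- parse_newick("(1:0.1,2:0.1,3:0.1,(4:0.1,5:0.1):0.2);")
  expect_true(forests_equivalent(a, b))

  # infinite pendant edge: leaf splits off, flanking edges merge with
  # weight lambda_A + lambda_B - lambda_A lambda_B (= summed lengths)
  x <- parse_newick("((1:0.1,2:0.1):0.2,3:inf,(4:0.1,5:0.1):0.3);")
  y <- parse_newick(c("((1:0.1,2:0.1):0.5,4:0.1,5:0.1);", "3;"))
  expect_true(forests_equivalent(x, y))

  # infinite internal edge disconnects
  z <- parse_newick("((1:0.1,2:0.1):inf,3:0.1,(4:0.1,5:0.1):0.2);")
  cz <- canonicalize(z)
  comps <- write_newick(cz)
  expect_length(comps, 2L)

  for (f in list(a, x, z)) {
    expect_tree_equal(canonicalize(f), canonicalize(canonicalize(f)),
                      tol = 1e-12)
  }
})

test_that("equivalence agrees with the character-distribution oracle", {
  set.seed(11)
  base <- parse_newick("((1:0.2,2:0.4):0.3,3:0.1,(4:0.5,5:0.2):0.6);")
  variants <- list(
    base,
    parse_newick("((1:0.2,2:0.4):0.3,3:0.1,(4:0.5,5:0.2):0.6);"),
    parse_newick("((1:0.2,2:0.4):0.31,3:0.1,(4:0.5,5:0.2):0.6);"),
    parse_newick("((2:0.4,3:0.1):0.3,1:0.2,(4:0.5,5:0.2):0.6);"),
    parse_newick("((1:0.2,2:0.4):0.0,3:0.1,(4:0.5,5:0.2):0.6);"),
    parse_newick("(1:0.2,2:0.4,3:0.1,(4:0.5,5:0.2):0.6);"))
  for (i in seq_along(variants)) {
    for (j in seq_along(variants)) {
      same_pmf <- max(abs(character_pmf(variants[[i]]) -
                            character_pmf(variants[[j]]))) < 1e-12
      expect_identical(forests_equivalent(variants[[i]], variants[[j]],
                                          tol = 1e-9),
                       same_pmf)
    }
  }
  expect_true(forests_equivalent(base, base))
})

test_that("topology enumeration gives the double-factorial counts", {
  expect_length(enumerate_topologies(4), 3L)
  expect_length(enumerate_topologies(5), 15L)
  t6 <- enumerate_topologies(6)
  expect_length(t6, 105L)
  expect_length(unique(vapply(t6, topo_key, "")), 105L)
  expect_error(enumerate_topologies(10), "guard")

  # each resolved topology has 2N-3 splits, N of them pendant
  for (tp in enumerate_topologies(5)) {
    expect_true(tp$resolved)
    expect_length(tp$splits, 7L)
    sizes <- vapply(tp$splits, length, 1L)
    expect_equal(sum(sizes == 1L | sizes == 4L), 5L)
  }
})

test_that("NNI neighbours resolve a contracted edge in the two other ways", {
  tp <- tree_topology(parse_newick(
    "((1:1,2:1):1,3:1,(4:1,5:1):1);"))
  internal <- tp$splits[[which(vapply(tp$splits, length, 1L) == 3L)]]
  nb <- nni_neighbors(tp, internal)
  keys <- c(topo_key(tp), vapply(nb, topo_key, ""))
  expect_length(unique(keys), 3L)
  for (x in nb) {
    shared <- intersect(vapply(x$splits, paste, collapse = ",", ""),
                        vapply(tp$splits, paste, collapse = ",", ""))
    expect_length(shared, 6L)
  }
  expect_error(nni_neighbors(tp, c(4L)), "pendant")

  # the NNI graph on 5 leaves is connected and covers all 15 topologies
  seen <- character(0)
  frontier <- list(tp)
  while (length(frontier)) {
    cur <- frontier[[1L]]; frontier <- frontier[-1L]
    k <- topo_key(cur)
    if (k %in% seen) next
    seen <- c(seen, k)
    for (s in cur$splits[vapply(cur$splits, length, 1L) %in% 2:3]) {
      frontier <- c(frontier, nni_neighbors(cur, s))
    }
  }
  expect_setequal(seen, vapply(enumerate_topologies(5), topo_key, ""))
})

test_that("length/weight conversion is the exact exponential map", {
  expect_equal(length_to_weight(0), 0)
  expect_equal(length_to_weight(Inf), 1)
  expect_equal(length_to_weight(log(2)), 0.5)
  expect_equal(weight_to_length(0.5), log(2))
  grid <- seq(0.01, 5, length.out = 100)
  expect_equal(weight_to_length(length_to_weight(grid)), grid,
               tolerance = 1e-12)
  expect_error(weight_to_length(1.2), "weights")
  expect_error(length_to_weight(-1), "non-negative")
})

test_that("tree metrics satisfy the four-point condition on random trees", {
  set.seed(21)
  for (rep in 1:10) {
    f <- random_tree(6)
    D <- leaf_distance_matrix(f)
    for (q in utils::combn(6, 4, simplify = FALSE)) {
      s <- c(D[q[1], q[2]] + D[q[3], q[4]],
             D[q[1], q[3]] + D[q[2], q[4]],
             D[q[1], q[4]] + D[q[2], q[3]])
      s <- sort(s, decreasing = TRUE)
      expect_lt(s[1] - s[2], 1e-10)
    }
  }
})
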