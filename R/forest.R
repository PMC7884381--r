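# ---------------------------------------------------------------------------
# Forests: labelled-leaf graphs with per-edge lengths in [0, Inf].
#
# A `wald_forest` stores an undirected graph on vertices 1..n_vertices where
# vertices 1..n_leaves are the labelled leaves and the remaining vertices are
# unlabelled internal vertices.  Edge lengths live on the scale of expected
# substitutions; the equivalent edge weight is lambda = 1 - exp(-length).
# ---------------------------------------------------------------------------

#' Construct a phylogenetic forest
#'
#' Builds a forest on `n_leaves` labelled leaves from an edge list.  Vertices
#' `1..n_leaves` are the leaves; higher-numbered vertices are unlabelled
#' internal vertices.  Edge lengths may be `Inf` (an infinitely long edge,
#' weight 1); internal edges may have length 0 (weight 0), but pendant edges
#' of a directly constructed forest must have strictly positive length.
#'
#' @param n_leaves number of labelled leaves (\eqn{N \ge 1}).
#' @param edges two-column integer matrix of vertex pairs (may have 0 rows).
#' @param lengths numeric vector of non-negative (possibly infinite) edge
#'   lengths, one per row of `edges`.
#' @param allow_zero_pendant logical; permit pendant edges of length zero.
#'   Zero-length pendant edges only arise transiently (boundary clamping in
#'   the geodesic integrator) or from equivalence-rule reductions, so the
#'   default is `FALSE`.
#' @return an object of class `wald_forest`.
#' @export
wald_forest <- function(n_leaves, edges, lengths, allow_zero_pendant = FALSE) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  lengths <- as.numeric(lengths)
  n_vertices <- max(n_leaves, if (nrow(edges)) max(edges) else 0L)
  f <- structure(list(n_leaves = as.integer(n_leaves),
                      n_vertices = as.integer(n_vertices),
                      edges = edges, lengths = lengths),
                 class = "wald_forest")
  validate_wald_forest(f, allow_zero_pendant = allow_zero_pendant)
  f
}

#' Validate the structural invariants of a forest
#'
#' Checks leaf degrees, internal vertex degrees, non-negative lengths,
#' pendant-edge positivity and the no-coincident-leaves condition (every
#' leaf pair in a component is separated by at least one edge of positive
#' weight).
#'
#' @inheritParams wald_forest
#' @param forest a `wald_forest`.
#' @return `forest`, invisibly; errors on violation.
#' @export
validate_wald_forest <- function(forest, allow_zero_pendant = FALSE) {
  f <- forest
  stopifnot(f$n_leaves >= 1L, nrow(f$edges) == length(f$lengths))
  if (any(is.na(f$lengths)) || any(f$lengths < 0)) {
    stop("edge lengths must be non-negative (possibly Inf)")
  }
  if (nrow(f$edges) && any(f$edges[, 1L] == f$edges[, 2L])) {
    stop("self-loop edge")
  }
  ek <- pmin(f$edges[, 1L], f$edges[, 2L]) * (f$n_vertices + 1) +
    pmax(f$edges[, 1L], f$edges[, 2L])
  if (anyDuplicated(ek)) stop("duplicated edge")
  deg <- .degrees(f)
  if (any(deg[seq_len(f$n_leaves)] > 1L)) {
    stop("leaves must have degree at most 1")
  }
  if (f$n_vertices > f$n_leaves) {
    internal <- seq.int(f$n_leaves + 1L, f$n_vertices)
    if (any(deg[internal] <= 2L)) {
      stop("unlabelled vertices must have degree >= 3")
    }
  }
  pend <- .pendant_edges(f)
  if (!allow_zero_pendant && any(f$lengths[pend] == 0)) {
    stop("pendant edges must have positive length")
  }
  .check_coincident_leaves(f)
  invisible(forest)
}

.degrees <- function(f) {
  tabulate(f$edges, nbins = f$n_vertices)
}

# edges incident to at least one leaf
.pendant_edges <- function(f) {
  which(f$edges[, 1L] <= f$n_leaves | f$edges[, 2L] <= f$n_leaves)
}

# adjacency list: for each vertex, matrix with columns (nbr, edge)
.adjacency <- function(f) {
  adj <- vector("list", f$n_vertices)
  if (nrow(f$edges)) {
    for (e in seq_len(nrow(f$edges))) {
      u <- f$edges[e, 1L]; v <- f$edges[e, 2L]
      adj[[u]] <- rbind(adj[[u]], c(v, e))
      adj[[v]] <- rbind(adj[[v]], c(u, e))
    }
  }
  adj
}

# component id per vertex
.components <- function(f) {
  comp <- integer(f$n_vertices)
  adj <- .adjacency(f)
  cid <- 0L
  for (v in seq_len(f$n_vertices)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      queue <- v; comp[v] <- cid
      while (length(queue)) {
        w <- queue[[1L]]; queue <- queue[-1L]
        nb <- adj[[w]]
        if (!is.null(nb)) {
          new <- nb[comp[nb[, 1L]] == 0L, 1L]
          comp[new] <- cid
          queue <- c(queue, new)
        }
      }
    }
  }
  comp
}

# edge indices on the unique path between vertices u and v (NULL if
# disconnected); forests are acyclic so BFS paths are unique
.path_edges <- function(f, u, v, adj = .adjacency(f)) {
  if (u == v) return(integer(0))
  parent <- integer(f$n_vertices); parent_edge <- integer(f$n_vertices)
  seen <- logical(f$n_vertices); seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    w <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[w]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      x <- nb[i, 1L]
      if (!seen[x]) {
        seen[x] <- TRUE; parent[x] <- w; parent_edge[x] <- nb[i, 2L]
        if (x == v) {
          path <- integer(0); cur <- v
          while (cur != u) { path <- c(path, parent_edge[cur]); cur <- parent[cur] }
          return(path)
        }
        queue <- c(queue, x)
      }
    }
  }
  NULL
}

.check_coincident_leaves <- function(f) {
  adj <- .adjacency(f)
  comp <- .components(f)
  wts <- forest_weights(f)
  for (u in seq_len(f$n_leaves)) {
    for (v in seq_len(f$n_leaves)) {
      if (u < v && comp[u] == comp[v]) {
        p <- .path_edges(f, u, v, adj)
        if (all(wts[p] == 0)) {
          stop(sprintf("leaves %d and %d are coincident (all-zero-weight path)",
                       u, v))
        }
      }
    }
  }
  invisible(NULL)
}

#' Edge weights of a forest
#'
#' The weight of an edge of length \eqn{\ell} is
#' \eqn{\lambda = 1 - e^{-\ell} \in [0, 1]}.
#'
#' @param forest a `wald_forest`.
#' @return numeric vector of weights, one per edge.
#' @export
forest_weights <- function(forest) {
  length_to_weight(forest$lengths)
}

#' Convert between edge lengths and edge weights
#'
#' `length_to_weight()` maps a length \eqn{\ell \in [0,\infty]} to the weight
#' \eqn{\lambda = 1 - e^{-\ell} \in [0,1]}; `weight_to_length()` is the
#' inverse \eqn{\ell = -\log(1-\lambda)}.
#'
#' @param ell lengths in `[0, Inf]`.
#' @param lambda weights in `[0, 1]`.
#' @return numeric vector.
#' @export
length_to_weight <- function(ell) {
  if (any(ell < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  -expm1(-ell)
}

#' @rdname length_to_weight
#' @export
weight_to_length <- function(lambda) {
  if (any(lambda < 0 | lambda > 1, na.rm = TRUE)) {
    stop("weights must lie in [0, 1]")
  }
  -log1p(-lambda)
}

#' @export
print.wald_forest <- function(x, ...) {
  comp <- .components(x)
  ncomp <- length(unique(comp[seq_len(x$n_leaves)]))
  cat(sprintf("wald_forest: %d leaves, %d edges, %d component(s)\n",
              x$n_leaves, nrow(x$edges), ncomp))
  cat(write_newick(x), sep = "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Newick I/O
# ---------------------------------------------------------------------------

# Large finite stand-in used so that standard Newick readers accept the
# "inf" token; restored to Inf immediately after parsing.
.INF_SENTINEL <- 1e300

#' Parse Newick text into a forest
#'
#' Reads one or more semicolon-terminated Newick statements (one statement
#' per forest component) into a single `wald_forest`.  Leaf labels must be
#' distinct positive integers and are taken to label the leaves `1..N`
#' jointly across statements.  Branch lengths are non-negative numbers or
#' the token `inf` for an infinitely long edge; a missing length is read
#' as 0.  Rooted statements are read as unrooted: any unlabelled degree-2
#' vertex is suppressed and the adjacent lengths summed.  An isolated leaf
#' is written as the bare statement `"k;"`.
#'
#' @param text character scalar (or vector of lines) of Newick statements.
#' @return a `wald_forest`.
#' @export
parse_newick <- function(text) {
  txt <- paste(text, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)            # strip comments
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) stop("no Newick statements found")

  comp_edges <- list()   # per component: list(labels, edges, lengths)
  for (s in stmts) {
    if (grepl("^[0-9]+$", s)) {
      comp_edges[[length(comp_edges) + 1L]] <-
        list(labels = as.integer(s),
             edges = matrix(integer(0), ncol = 2L), lengths = numeric(0))
      next
    }
    s2 <- gsub("(?i)\\binf(inity)?\\b", format(.INF_SENTINEL), s, perl = TRUE)
    ph <- ape::read.tree(text = paste0(s2, ";"))
    if (is.null(ph)) stop("could not parse Newick statement: ", s)
    labs <- suppressWarnings(as.integer(ph$tip.label))
    if (any(is.na(labs))) stop("leaf labels must be integers")
    ntip <- length(labs)
    len <- ph$edge.length
    if (is.null(len)) len <- rep(0, nrow(ph$edge))
    len[is.na(len) | is.nan(len)] <- 0
    if (any(len < 0)) stop("negative branch length in: ", s)
    len[len >= .INF_SENTINEL / 2] <- Inf
    comp_edges[[length(comp_edges) + 1L]] <-
      list(labels = labs, edges = ph$edge, lengths = len, ntip = ntip)
  }

  all_labels <- unlist(lapply(comp_edges, `[[`, "labels"))
  if (anyDuplicated(all_labels)) {
    stop("duplicate leaf labels: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  if (any(all_labels < 1L)) stop("leaf labels must be positive integers")
  n <- length(all_labels)
  if (!setequal(all_labels, seq_len(n))) {
    stop("leaf labels must be exactly 1..N")
  }

  edges <- matrix(integer(0), ncol = 2L)
  lengths <- numeric(0)
  next_internal <- n
  for (ce in comp_edges) {
    if (!nrow(ce$edges)) next                    # isolated leaf
    ntip <- ce$ntip
    nnode <- max(ce$edges) - ntip
    vmap <- integer(ntip + nnode)
    vmap[seq_len(ntip)] <- ce$labels
    if (nnode > 0L) {
      vmap[ntip + seq_len(nnode)] <- next_internal + seq_len(nnode)
      next_internal <- next_internal + nnode
    }
    edges <- rbind(edges, cbind(vmap[ce$edges[, 1L]], vmap[ce$edges[, 2L]]))
    lengths <- c(lengths, ce$lengths)
  }

  f <- structure(list(n_leaves = n,
                      n_vertices = max(n, if (nrow(edges)) max(edges) else 0L),
                      edges = edges, lengths = lengths),
                 class = "wald_forest")
  f <- .suppress_degree2(f)
  validate_wald_forest(f)
  f
}

#' @rdname parse_newick
#' @param file path to a Newick (`.nwk`) file.
#' @export
read_newick <- function(file) {
  parse_newick(readLines(file, warn = FALSE))
}

# remove unlabelled degree-2 vertices, summing the two adjacent lengths
.suppress_degree2 <- function(f) {
  repeat {
    deg <- .degrees(f)
    cand <- which(deg == 2L)
    cand <- cand[cand > f$n_leaves]
    if (!length(cand)) break
    v <- cand[[1L]]
    inc <- which(f$edges[, 1L] == v | f$edges[, 2L] == v)
    e1 <- inc[[1L]]; e2 <- inc[[2L]]
    a <- setdiff(as.integer(f$edges[e1, ]), v)
    b <- setdiff(as.integer(f$edges[e2, ]), v)
    newlen <- f$lengths[e1] + f$lengths[e2]
    f$edges <- f$edges[-inc, , drop = FALSE]
    f$lengths <- f$lengths[-inc]
    f$edges <- rbind(f$edges, c(a, b))
    f$lengths <- c(f$lengths, newlen)
    f <- .compact_vertices(f)
  }
  # unlabelled isolated / degree-0 vertices cannot be represented; drop them
  .compact_vertices(f)
}

# renumber vertices so that internal vertices are contiguous after the
# leaves; drops unlabelled vertices of degree 0
.compact_vertices <- function(f) {
  used <- sort(unique(c(seq_len(f$n_leaves),
                        if (nrow(f$edges)) as.integer(f$edges))))
  vmap <- integer(max(used, 0L))
  vmap[used] <- seq_along(used)
  if (nrow(f$edges)) {
    f$edges <- cbind(vmap[f$edges[, 1L]], vmap[f$edges[, 2L]])
  }
  f$n_vertices <- length(used)
  f
}

.format_len <- function(x) {
  ifelse(is.infinite(x), "inf",
         trimws(formatC(x, digits = 12, format = "g")))
}

#' Serialize a forest to Newick text
#'
#' Writes one semicolon-terminated statement per component, components
#' ordered by smallest leaf label.  Each tree component is serialized from
#' a virtual root placed at the midpoint of the pendant edge of its
#' smallest leaf, with children ordered by smallest descendant leaf, which
#' makes the output deterministic; an isolated leaf `k` is written `"k;"`.
#' Lengths are printed with 12 significant digits, infinite lengths as
#' `inf`.
#'
#' @param forest a `wald_forest`.
#' @param file optional path; when given the statements are written there.
#' @return character vector of Newick statements (invisibly when `file`
#'   is given).
#' @export
write_newick <- function(forest, file = NULL) {
  f <- forest
  adj <- .adjacency(f)
  comp <- .components(f)
  leaf_comp <- comp[seq_len(f$n_leaves)]
  stmts <- character(0)
  for (cid in unique(leaf_comp[order(seq_len(f$n_leaves))])) {
    leaves <- which(leaf_comp == cid)
    r <- min(leaves)
    if (length(leaves) == 1L && is.null(adj[[r]])) {
      stmts <- c(stmts, paste0(r, ";"))
      next
    }
    # subtree serialization away from vertex `from`
    ser <- function(v, from) {
      nb <- adj[[v]]
      kids <- nb[nb[, 1L] != from, , drop = FALSE]
      parts <- character(nrow(kids))
      keys <- integer(nrow(kids))
      for (i in seq_len(nrow(kids))) {
        w <- kids[i, 1L]; e <- kids[i, 2L]
        if (w <= f$n_leaves) {
          parts[i] <- paste0(w, ":", .format_len(f$lengths[e]))
          keys[i] <- w
        } else {
          sub <- ser(w, v)
          parts[i] <- paste0("(", sub$text, "):", .format_len(f$lengths[e]))
          keys[i] <- sub$minleaf
        }
      }
      o <- order(keys)
      list(text = paste(parts[o], collapse = ","), minleaf = min(keys))
    }
    # virtual root on the midpoint of r's pendant edge
    nb <- adj[[r]]
    e <- nb[1L, 2L]; v <- nb[1L, 1L]
    half <- .format_len(f$lengths[e] / 2)
    if (v <= f$n_leaves) {
      right <- paste0(v, ":", half)
    } else {
      right <- paste0("(", ser(v, r)$text, "):", half)
    }
    stmts <- c(stmts, paste0("(", r, ":", half, ",", right, ");"))
  }
  if (!is.null(file)) {
    writeLines(stmts, file)
    return(invisible(stmts))
  }
  stmts
}

# ---------------------------------------------------------------------------
# Splits and path-length matrices
# ---------------------------------------------------------------------------

# leaf labels on the side of edge `e` containing vertex `side_vertex`
.edge_side_leaves <- function(f, e, side_vertex, adj = .adjacency(f)) {
  u <- f$edges[e, 1L]; v <- f$edges[e, 2L]
  seen <- logical(f$n_vertices)
  seen[c(u, v)] <- TRUE
  queue <- side_vertex
  out <- integer(0)
  if (side_vertex <= f$n_leaves) out <- side_vertex
  while (length(queue)) {
    w <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[w]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      if (nb[i, 2L] == e) next
      x <- nb[i, 1L]
      if (!seen[x]) {
        seen[x] <- TRUE
        if (x <= f$n_leaves) out <- c(out, x)
        queue <- c(queue, x)
      }
    }
  }
  sort(out)
}

#' Splits of a forest
#'
#' The split of an edge is the bipartition of the leaf labels of its
#' component obtained by cutting the edge.  Each split is reported as the
#' side not containing the smallest leaf of the component.
#'
#' @param forest a `wald_forest`.
#' @return list (one element per edge) of sorted integer vectors.
#' @export
forest_splits <- function(forest) {
  f <- forest
  adj <- .adjacency(f)
  comp <- .components(f)
  out <- vector("list", nrow(f$edges))
  for (e in seq_len(nrow(f$edges))) {
    u <- f$edges[e, 1L]
    side_u <- .edge_side_leaves(f, e, u, adj)
    cl <- which(comp[seq_len(f$n_leaves)] == comp[u])
    if (min(cl) %in% side_u) out[[e]] <- sort(setdiff(cl, side_u))
    else out[[e]] <- side_u
  }
  out
}

#' Split matrix of an edge
#'
#' The split matrix \eqn{\sigma^e} is the \eqn{N \times N} 0/1 matrix with
#' \eqn{\sigma^e_{uv} = 1} iff edge `e` lies on the path between leaves `u`
#' and `v`.
#'
#' @param forest a `wald_forest`.
#' @param edge edge index (row of `forest$edges`).
#' @return integer matrix of dimension `n_leaves` x `n_leaves`.
#' @export
split_matrix <- function(forest, edge) {
  f <- forest
  if (!(edge %in% seq_len(nrow(f$edges)))) stop("unknown edge index: ", edge)
  adj <- .adjacency(f)
  u <- f$edges[edge, 1L]; v <- f$edges[edge, 2L]
  A <- .edge_side_leaves(f, edge, u, adj)
  B <- .edge_side_leaves(f, edge, v, adj)
  m <- matrix(0L, f$n_leaves, f$n_leaves)
  m[A, B] <- 1L
  m[B, A] <- 1L
  m
}

#' Matrix of leaf-to-leaf path lengths
#'
#' Entry (u, v) is the sum of edge lengths on the path between leaves u and
#' v, and `Inf` when the leaves lie in different components.
#'
#' @param forest a `wald_forest`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
leaf_distance_matrix <- function(forest) {
  f <- forest
  n <- f$n_leaves
  comp <- .components(f)
  D <- matrix(0, n, n)
  lc <- comp[seq_len(n)]
  D[outer(lc, lc, "!=")] <- Inf
  adj <- .adjacency(f)
  for (e in seq_len(nrow(f$edges))) {
    u <- f$edges[e, 1L]
    A <- .edge_side_leaves(f, e, u, adj)
    B <- .edge_side_leaves(f, e, f$edges[e, 2L], adj)
    if (length(A) && length(B)) {
      D[A, B] <- D[A, B] + f$lengths[e]
      D[B, A] <- D[B, A] + f$lengths[e]
    }
  }
  D
}

# ---------------------------------------------------------------------------
# Canonical representatives and equivalence
# ---------------------------------------------------------------------------

#' Canonical representative of a forest's equivalence class
#'
#' Applies the two reduction rules of wald space until a fixed point is
#' reached: internal edges of weight 0 are contracted (their endpoints
#' merged), and edges of weight 1 (infinite length) are deleted, splitting
#' the component; any unlabelled degree-2 vertex left behind has its two
#' incident edges `e`, `ee` merged into one with weight
#' \eqn{\lambda^e + \lambda^{ee} - \lambda^e\lambda^{ee}} (i.e. summed
#' lengths), and unlabelled vertices of degree 0 or 1 are pruned away.
#' The result is the unique reduced representative of the input class.
#'
#' @param forest a `wald_forest`.
#' @return a reduced `wald_forest`.
#' @export
canonicalize <- function(forest) {
  f <- forest
  repeat {
    changed <- FALSE
    # rule 1: contract zero-weight internal edges
    pend <- .pendant_edges(f)
    zero_int <- setdiff(which(f$lengths == 0), pend)
    if (length(zero_int)) {
      e <- zero_int[[1L]]
      u <- f$edges[e, 1L]; v <- f$edges[e, 2L]
      keep <- min(u, v); drop <- max(u, v)
      f$edges <- f$edges[-e, , drop = FALSE]
      f$lengths <- f$lengths[-e]
      f$edges[f$edges == drop] <- keep
      f <- .compact_vertices(f)
      changed <- TRUE
    } else {
      # rule 2: delete weight-one (infinite) edges
      infe <- which(is.infinite(f$lengths))
      if (length(infe)) {
        e <- infe[[1L]]
        f$edges <- f$edges[-e, , drop = FALSE]
        f$lengths <- f$lengths[-e]
        f <- .prune_unlabelled(f)
        f <- .suppress_degree2(f)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  f <- .relabel_internal(f)
  validate_wald_forest(f, allow_zero_pendant = TRUE)
  f
}

# delete unlabelled vertices of degree 0 or 1 (with their incident edge),
# cascading
.prune_unlabelled <- function(f) {
  repeat {
    deg <- .degrees(f)
    bad <- which(deg <= 1L)
    bad <- bad[bad > f$n_leaves]
    if (!length(bad)) break
    v <- bad[[1L]]
    inc <- which(f$edges[, 1L] == v | f$edges[, 2L] == v)
    if (length(inc)) {
      f$edges <- f$edges[-inc, , drop = FALSE]
      f$lengths <- f$lengths[-inc]
    }
    # vertex becomes degree-0 and is dropped on compaction
    f <- .compact_vertices(f)
  }
  f
}

# deterministic internal-vertex numbering: BFS order from the smallest leaf
# of each component, components in order of their smallest leaf
.relabel_internal <- function(f) {
  if (!nrow(f$edges)) return(.compact_vertices(f))
  adj <- .adjacency(f)
  comp <- .components(f)
  order_internal <- integer(0)
  leaf_comp <- comp[seq_len(f$n_leaves)]
  for (cid in unique(leaf_comp)) {
    r <- min(which(leaf_comp == cid))
    seen <- logical(f$n_vertices); seen[r] <- TRUE
    queue <- r
    while (length(queue)) {
      w <- queue[[1L]]; queue <- queue[-1L]
      if (w > f$n_leaves) order_internal <- c(order_internal, w)
      nb <- adj[[w]]
      if (is.null(nb)) next
      nxt <- sort(nb[!seen[nb[, 1L]], 1L])
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  vmap <- integer(f$n_vertices)
  vmap[seq_len(f$n_leaves)] <- seq_len(f$n_leaves)
  vmap[order_internal] <- f$n_leaves + seq_along(order_internal)
  f$edges <- cbind(vmap[f$edges[, 1L]], vmap[f$edges[, 2L]])
  f
}

# canonical comparable summary: per component (ordered by min leaf) the leaf
# set and the (split, weight) pairs
.forest_key <- function(f) {
  comp <- .components(f)
  leaf_comp <- comp[seq_len(f$n_leaves)]
  splits <- forest_splits(f)
  wts <- forest_weights(f)
  out <- list()
  for (cid in unique(leaf_comp[order(seq_len(f$n_leaves))])) {
    leaves <- which(leaf_comp == cid)
    es <- which(comp[f$edges[, 1L]] == cid)
    keys <- vapply(splits[es], function(s) paste(s, collapse = ","), "")
    o <- order(keys)
    out[[length(out) + 1L]] <-
      list(leaves = leaves, split_keys = keys[o], weights = wts[es][o])
  }
  names(out) <- vapply(out, function(cc) as.character(min(cc$leaves)), "")
  out[order(as.integer(names(out)))]
}

#' Test whether two forests are equivalent in wald space
#'
#' Two forests are equivalent iff their canonical representatives are
#' label-respecting isomorphic with equal edge weights (compared with
#' absolute tolerance `tol` on the weight scale).  By a characterization of
#' the equivalence, this holds iff the two forests induce the same
#' character distribution.
#'
#' @param f1,f2 `wald_forest` objects on the same leaf set.
#' @param tol absolute tolerance for weight comparison.
#' @return logical.
#' @export
forests_equivalent <- function(f1, f2, tol = 1e-12) {
  if (f1$n_leaves != f2$n_leaves) stop("forests have different leaf sets")
  k1 <- .forest_key(canonicalize(f1))
  k2 <- .forest_key(canonicalize(f2))
  if (length(k1) != length(k2)) return(FALSE)
  for (i in seq_along(k1)) {
    a <- k1[[i]]; b <- k2[[i]]
    if (!identical(a$leaves, b$leaves)) return(FALSE)
    if (!identical(a$split_keys, b$split_keys)) return(FALSE)
    if (length(a$weights) && max(abs(a$weights - b$weights)) > tol) {
      return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Topologies, enumeration, NNI
# ---------------------------------------------------------------------------

.split_key <- function(s) paste(s, collapse = ",")

#' Topology (split set) of a tree
#'
#' The topology of a single tree on leaves `1..N` is its set of splits,
#' stored canonically as the side of each split not containing leaf 1.
#'
#' @param forest a single-component `wald_forest` on leaves `1..N`.
#' @return an object of class `wald_topology` with fields `n_leaves`,
#'   `splits` (list of sorted integer vectors) and `resolved` (TRUE iff the
#'   tree has `2N - 3` edges).
#' @export
tree_topology <- function(forest) {
  f <- forest
  comp <- .components(f)
  if (length(unique(comp)) != 1L) stop("topology requires a single tree")
  splits <- forest_splits(f)          # sides not containing leaf 1
  .new_topology(f$n_leaves, splits)
}

.new_topology <- function(n, splits) {
  keys <- vapply(splits, .split_key, "")
  o <- order(keys)
  splits <- splits[o]
  structure(list(n_leaves = n, splits = splits,
                 resolved = length(splits) == 2L * n - 3L),
            class = "wald_topology")
}

#' @export
print.wald_topology <- function(x, ...) {
  cat(sprintf("wald_topology on %d leaves (%s): ", x$n_leaves,
              if (x$resolved) "resolved" else "unresolved"))
  cat(paste(vapply(x$splits, .split_key, ""), collapse = " | "), "\n")
  invisible(x)
}

.topology_key <- function(top) {
  paste(vapply(top$splits, .split_key, ""), collapse = "|")
}

# internal splits = non-singleton sides whose complement is also
# non-singleton
.internal_split_idx <- function(top) {
  n <- top$n_leaves
  which(vapply(top$splits,
               function(s) length(s) >= 2L && length(s) <= n - 2L, TRUE))
}

#' Build a tree realizing a topology
#'
#' Constructs the `wald_forest` with the given resolved topology and edge
#' lengths in canonical coordinate order (see [tree_coords()]): entries
#' `1..N` are the pendant lengths of leaves `1..N` and the remaining
#' entries are the internal lengths in lexicographic order of the splits'
#' canonical sides.
#'
#' @param topology a resolved `wald_topology`.
#' @param lengths numeric vector of `2N - 3` edge lengths.
#' @return a `wald_forest`.
#' @export
tree_from_topology <- function(topology, lengths) {
  top <- topology
  n <- top$n_leaves
  if (n == 2L) {
    return(wald_forest(2L, cbind(1L, 2L), lengths[[1L]],
                       allow_zero_pendant = TRUE))
  }
  ord <- .coord_split_order(top)
  if (length(lengths) != length(top$splits)) {
    stop("lengths must have one entry per split")
  }
  # build unlengthed tree from the laminar family of sides not containing 1
  idx_int <- .internal_split_idx(top)
  sides <- top$splits[idx_int]
  sizes <- vapply(sides, length, 1L)
  center <- n + 1L
  attach <- rep(center, n)        # current attachment vertex of each leaf
  # edges as (vertex, vertex, split_key); pendant edges first
  edges <- cbind(seq_len(n), rep(center, n))
  ekeys <- vapply(seq_len(n), function(k) {
    .split_key(if (k == 1L) sort(seq_len(n)[-1L]) else k)
  }, "")
  # subtree roots adjacent to each hub vertex; track leafsets per adjacent
  # subtree by recording, for each edge, the leaf set away from the hub
  nextv <- center
  for (i in order(sizes, decreasing = TRUE)) {
    A <- sides[[i]]
    v <- unique(attach[A])
    if (length(v) != 1L) stop("incompatible split set")
    nextv <- nextv + 1L
    w <- nextv
    # reattach: every edge at v whose far leaf set is a subset of A
    for (e in seq_len(nrow(edges))) {
      uu <- edges[e, 1L]; vv <- edges[e, 2L]
      if (uu == v || vv == v) {
        far <- if (uu == v) vv else uu
        farset <- .subtree_leafset(edges, far, v, n)
        if (length(farset) && all(farset %in% A)) {
          edges[e, ] <- c(far, w)
        }
      }
    }
    edges <- rbind(edges, c(v, w))
    ekeys <- c(ekeys, .split_key(A))
    attach[A] <- w
  }
  len <- numeric(nrow(edges))
  want <- vapply(top$splits[ord], .split_key, "")
  for (j in seq_along(want)) {
    len[match(want[j], ekeys)] <- lengths[j]
  }
  f <- structure(list(n_leaves = n, n_vertices = max(edges),
                      edges = edges, lengths = len),
                 class = "wald_forest")
  f <- .relabel_internal(.compact_vertices(f))
  validate_wald_forest(f, allow_zero_pendant = TRUE)
  f
}

# leaf set of the subtree hanging from `v` away from `from`, given a raw
# edge matrix
.subtree_leafset <- function(edges, v, from, n) {
  out <- integer(0)
  queue <- v; prev <- from
  seen <- c(from)
  while (length(queue)) {
    w <- queue[[1L]]; queue <- queue[-1L]
    seen <- c(seen, w)
    if (w <= n) out <- c(out, w)
    nbr <- c(edges[edges[, 1L] == w, 2L], edges[edges[, 2L] == w, 1L])
    queue <- c(queue, setdiff(nbr, seen))
  }
  sort(out)
}

# canonical coordinate order of splits: pendant splits of leaves 1..N first,
# then internal splits sorted lexicographically by canonical side
.coord_split_order <- function(top) {
  n <- top$n_leaves
  if (n == 2L) return(1L)
  keys <- vapply(top$splits, .split_key, "")
  pend_keys <- vapply(seq_len(n), function(k) {
    .split_key(if (k == 1L) sort(seq_len(n)[-1L]) else k)
  }, "")
  pend <- match(pend_keys, keys)
  if (any(is.na(pend))) stop("topology lacks a pendant split")
  int <- setdiff(seq_along(top$splits), pend)
  int <- int[order(keys[int])]
  c(pend, int)
}

#' Coordinates of a resolved tree
#'
#' Returns the edge lengths of a resolved tree in the canonical coordinate
#' order used throughout the package: coordinates `1..N` are the pendant
#' edges of leaves `1..N`, coordinates `N+1 .. 2N-3` the internal edges in
#' lexicographic order of the splits' sides not containing leaf 1.
#'
#' @param forest a single resolved tree.
#' @return list with `topology` (`wald_topology`), `ell` (numeric vector of
#'   length `2N-3`) and `edge_index` (mapping from coordinates to rows of
#'   `forest$edges`).
#' @export
tree_coords <- function(forest) {
  f <- forest
  top <- tree_topology(f)
  if (!top$resolved) stop("tree is not fully resolved")
  splits <- forest_splits(f)
  keys <- vapply(splits, .split_key, "")
  ord <- .coord_split_order(top)
  want <- vapply(top$splits[ord], .split_key, "")
  idx <- match(want, keys)
  list(topology = top, ell = f$lengths[idx], edge_index = idx)
}

#' Enumerate all fully resolved unrooted topologies
#'
#' Generates the \eqn{(2N-5)!!} resolved topologies on `N` leaves by
#' sequential insertion of leaf `k+1` onto every edge of each tree on `k`
#' leaves, giving a deterministic ordering.
#'
#' @param n_leaves number of leaves, `3 <= n_leaves <= 9`.
#' @return list of `wald_topology` objects.
#' @export
enumerate_topologies <- function(n_leaves) {
  n <- as.integer(n_leaves)
  if (n < 3L) stop("need at least 3 leaves")
  if (n > 9L) stop("enumeration guarded at n_leaves <= 9")
  # trees as edge matrices over vertices (1..k leaves, then internals)
  trees <- list(cbind(1:3, rep(4L, 3L)))
  for (k in 3L:(n - 1L)) {
    if (k == n) break
    newtrees <- list()
    for (tr in trees) {
      # renumber internal vertices up by one to free label k+1
      trv <- tr
      trv[trv > k] <- trv[trv > k] + 1L
      for (e in seq_len(nrow(trv))) {
        w <- max(trv) + 1L
        t2 <- trv
        u <- t2[e, 1L]; v <- t2[e, 2L]
        t2[e, ] <- c(u, w)
        t2 <- rbind(t2, c(w, v), c(k + 1L, w))
        newtrees[[length(newtrees) + 1L]] <- t2
      }
    }
    trees <- newtrees
  }
  lapply(trees, function(tr) {
    f <- structure(list(n_leaves = n, n_vertices = max(tr),
                        edges = tr, lengths = rep(1, nrow(tr))),
                   class = "wald_forest")
    tree_topology(f)
  })
}

#' The two nearest-neighbour-interchange alternatives of an internal split
#'
#' Contracting an internal split of a resolved topology yields a degree-4
#' vertex with four hanging subtrees; the two alternative resolutions give
#' the two NNI-neighbour topologies.
#'
#' @param topology a resolved `wald_topology`.
#' @param split an internal split of `topology` (integer vector, either
#'   side).
#' @return list of two `wald_topology` objects.
#' @export
nni_neighbors <- function(topology, split) {
  top <- topology
  if (!top$resolved) stop("topology must be resolved")
  n <- top$n_leaves
  side <- sort(as.integer(split))
  if (1L %in% side) side <- sort(setdiff(seq_len(n), side))
  key <- .split_key(side)
  keys <- vapply(top$splits, .split_key, "")
  pos <- match(key, keys)
  if (is.na(pos)) stop("split does not belong to the topology")
  if (length(side) < 2L || length(side) > n - 2L) {
    stop("split is pendant, not internal")
  }
  f <- tree_from_topology(top, rep(1, 2L * n - 3L))
  splits <- forest_splits(f)
  fkeys <- vapply(splits, .split_key, "")
  e <- match(key, fkeys)
  u <- f$edges[e, 1L]; v <- f$edges[e, 2L]
  adj <- .adjacency(f)
  group_sets <- list(); group_of_1 <- NA_integer_
  for (vert in c(u, v)) {
    nb <- adj[[vert]]
    for (i in seq_len(nrow(nb))) {
      if (nb[i, 2L] == e) next
      gs <- .edge_side_leaves(f, nb[i, 2L], nb[i, 1L], adj)
      group_sets[[length(group_sets) + 1L]] <-
        list(leaves = gs, end = vert)
    }
  }
  has1 <- vapply(group_sets, function(g) 1L %in% g$leaves, TRUE)
  g1 <- group_sets[[which(has1)]]
  others <- group_sets[!has1]
  # the group on the same side as the leaf-1 group
  same_side <- vapply(others, function(g) g$end == g1$end, TRUE)
  p2 <- others[same_side][[1L]]$leaves
  qs <- lapply(others[!same_side], `[[`, "leaves")
  alt_sides <- list(sort(c(p2, qs[[1L]])), sort(c(p2, qs[[2L]])))
  lapply(alt_sides, function(newside) {
    sp <- top$splits
    sp[[pos]] <- newside
    .new_topology(n, sp)
  })
}
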