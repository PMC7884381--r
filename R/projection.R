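# ---------------------------------------------------------------------------
# Projection of an ambient covariance matrix onto the embedded forest
# space: gradient descent on the squared affine-invariant distance
# d(S0, S_F)^2 over the edge lengths of a tree, with Barzilai-Borwein step
# sizes.  Three variants: constrained to one orthant, crossing orthant
# boundaries by nearest-neighbour interchange, and a global search over
# all orthants.
# ---------------------------------------------------------------------------

# default optimizer controls
.proj_control <- function(control = list()) {
  utils::modifyList(list(
    grad_tol = 1e-8,      # convergence: gradient infinity norm
    max_iter = 5000L,
    alpha_min = 1e-8,     # Barzilai-Borwein safeguards
    alpha_max = 1e2,
    alpha0 = 1e-2,
    ell_cap = 50,         # length cap (weight within 2e-22 of 1)
    pendant_floor = 1e-10,
    max_backtrack = 30L
  ), control)
}

# context holding the whitening of S0
.proj_target <- function(S0) {
  m <- matrix_sqrt_log(S0)
  list(S0 = S0, half = m$sqrt, ihalf = m$inv_sqrt)
}

# per-topology context (split matrices in coordinate order), memoized:
# the descent evaluates the objective thousands of times per orthant, and
# the splits never change within one
.orthant_cache <- new.env(parent = emptyenv())

.orthant_context <- function(topology) {
  key <- .topology_key(topology)
  ctx <- get0(key, envir = .orthant_cache, inherits = FALSE)
  if (is.null(ctx)) {
    tree1 <- tree_from_topology(topology, rep(1, length(topology$splits)))
    co <- tree_coords(tree1)
    sigmas <- lapply(co$edge_index, function(e) split_matrix(tree1, e))
    ctx <- list(topology = topology, sigmas = sigmas)
    assign(key, ctx, envir = .orthant_cache)
  }
  ctx
}

# squared distance and gradient at edge lengths `ell` in `topology`
.proj_objective <- function(tg, topology, ell, gradient = TRUE) {
  ctx <- .orthant_context(topology)
  D <- 0
  for (i in seq_along(ell)) D <- D + ell[i] * ctx$sigmas[[i]]
  SF <- exp(-D)
  W <- tg$ihalf %*% SF %*% tg$ihalf
  L <- .spd_fun(W, log, "whitened matrix")
  obj <- sum(L * L) / 2
  if (!gradient) return(list(objective = obj))
  SFinv <- .spd_inverse(SF)
  pre <- tg$ihalf %*% L %*% tg$half %*% SFinv     # S0^{-1/2} moved by trace cyclicity
  tpre <- t(pre)
  gr <- vapply(seq_along(ell), function(i) {
    -sum(tpre * (SF * ctx$sigmas[[i]]))
  }, 0)
  list(objective = obj, gradient = gr)
}

#' Gradient of the squared ambient distance to a tree
#'
#' For a resolved tree `F` with covariance \eqn{S_F}, returns
#' \eqn{\partial_i\, d(S_0, S_F)^2 =
#' \mathrm{tr}(\log(S_0^{-1/2} S_F S_0^{-1/2})\, S_0^{1/2} S_F^{-1}
#' (\partial_i S_F)\, S_0^{-1/2})} with
#' \eqn{\partial_i S_F = -(S_F \circ \sigma^i)}, over the canonical edge
#' coordinates.
#'
#' @param S0 symmetric positive definite target matrix.
#' @param tree a fully resolved `wald_forest` with finite lengths.
#' @return numeric gradient vector with attribute `objective` (the squared
#'   distance).
#' @export
grad_sq_dist <- function(S0, tree) {
  co <- tree_coords(tree)
  res <- .proj_objective(.proj_target(S0), co$topology, co$ell)
  structure(res$gradient, objective = res$objective)
}

.new_projection_result <- function(forest, objective, status, trace,
                                   iterations) {
  structure(list(forest = forest, objective = objective, status = status,
                 trace = trace, iterations = iterations),
            class = "wald_projection")
}

#' @export
print.wald_projection <- function(x, ...) {
  cat(sprintf("wald_projection: objective %.6g after %d iterations (%s)\n",
              x$objective, x$iterations, x$status))
  print(x$forest)
  invisible(x)
}

# core Barzilai-Borwein descent; `on_negative_internal` decides what to do
# with a proposal carrying a negative internal length:
#   "halt"  - stop with status boundary_halt (orthant-constrained variant)
#   "cross" - switch to the closer NNI reinterpretation and continue
#
# A projection target can sit exactly on an orthant boundary, in which
# case a crossing descent alternates between the two adjacent orthants
# with ever smaller overshoots.  Such a coordinate is pinned at zero (an
# unresolved tree) and released only if its gradient later pushes it back
# into the interior; at a pinned zero the one-sided optimality condition
# is gradient >= 0.
.bb_descent <- function(tg, topology, ell, ctl, on_negative_internal) {
  n <- topology$n_leaves
  E <- length(ell)
  internal_ix <- if (E > n) seq.int(n + 1L, E) else integer(0)
  ev <- .proj_objective(tg, topology, ell)
  obj <- ev$objective; gr <- ev$gradient
  alpha <- ctl$alpha0 / max(1, max(abs(gr)))
  tracel <- list(c(0, obj, NA_real_, max(abs(gr))))
  events <- character(0)
  pinned <- logical(E)
  last_cross <- ""; cross_run <- 0L
  status <- "max_iter"
  iter <- 0L
  kkt_ok <- function(gr) {
    free <- !pinned
    (max(abs(gr[free])) < ctl$grad_tol) &&
      (!any(pinned) || min(gr[pinned]) > -ctl$grad_tol)
  }
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    release <- pinned & (gr < -ctl$grad_tol)
    if (any(release)) pinned[release] <- FALSE
    if (kkt_ok(gr)) { status <- "converged"; break }
    accepted <- FALSE
    a <- alpha
    for (bt in seq_len(ctl$max_backtrack)) {
      step <- gr; step[pinned] <- 0
      prop <- ell - a * step
      prop[seq_len(n)] <- pmax(prop[seq_len(n)], ctl$pendant_floor)
      prop <- pmin(prop, ctl$ell_cap)
      prop[pinned] <- 0
      neg <- internal_ix[prop[internal_ix] < 0]
      if (length(neg)) {
        if (on_negative_internal == "halt") {
          return(list(topology = topology, ell = ell, objective = obj,
                      status = "boundary_halt",
                      trace = .trace_df(tracel), iter = iter,
                      events = events))
        }
        viol <- neg[which.min(prop[neg])]
        if (abs(prop[viol]) < 1e-9 || cross_run >= 2L) {
          # converged onto the boundary: pin and continue unresolved
          prop[viol] <- 0
          pinned[viol] <- TRUE
          cross_run <- 0L
        } else {
          cross <- .nni_reinterpret(topology, prop, internal_ix, tg)
          cross_run <- if (identical(cross$key, last_cross)) {
            cross_run + 1L
          } else {
            0L
          }
          last_cross <- cross$key
          events <- c(events, cross$event)
          topology <- cross$topology
          ell <- cross$ell
          ev <- .proj_objective(tg, topology, ell)
          obj <- ev$objective; gr <- ev$gradient
          alpha <- ctl$alpha0 / max(1, max(abs(gr)))
          accepted <- TRUE
          tracel[[length(tracel) + 1L]] <- c(iter, obj, a, max(abs(gr)))
          break
        }
      }
      ev2 <- .proj_objective(tg, topology, prop)
      if (ev2$objective <= obj || bt == ctl$max_backtrack) {
        s <- prop - ell
        y <- ev2$gradient - gr
        sy <- sum(s * y)
        alpha <- if (sy > 0) {
          min(max(sum(s * s) / sy, ctl$alpha_min), ctl$alpha_max)
        } else {
          ctl$alpha0
        }
        ell <- prop; obj <- ev2$objective; gr <- ev2$gradient
        accepted <- TRUE
        tracel[[length(tracel) + 1L]] <- c(iter, obj, a, max(abs(gr)))
        # numerically stationary iterate: the objective is at its floating
        # point floor even though the gradient norm sits above grad_tol
        if (max(abs(s)) < 1e-12) { status <- "converged"; accepted <- FALSE }
        break
      }
      a <- a / 2
    }
    if (!accepted) break
  }
  list(topology = topology, ell = ell, objective = obj, status = status,
       trace = .trace_df(tracel), iter = iter, events = events)
}

.trace_df <- function(tracel) {
  m <- do.call(rbind, tracel)
  data.frame(iter = as.integer(m[, 1L]), objective = m[, 2L],
             alpha = m[, 3L], grad_norm = m[, 4L])
}

# given a proposal with negative internal entries, evaluate the two
# NNI-neighbour reinterpretations (absolute values as lengths) across the
# most violated boundary and return the closer one
.nni_reinterpret <- function(topology, prop, internal_ix, tg) {
  n <- topology$n_leaves
  viol <- internal_ix[which.min(prop[internal_ix])]
  ord <- .coord_split_order(topology)
  old_split <- topology$splits[[ord[viol]]]
  neighbors <- nni_neighbors(topology, old_split)
  absprop <- abs(prop)
  cands <- lapply(neighbors, function(nb) {
    # map lengths by split identity; the replaced split takes |prop[viol]|
    ell2 <- .map_lengths_between_topologies(topology, absprop, nb)
    list(topology = nb, ell = ell2,
         objective = .proj_objective(tg, nb, ell2,
                                     gradient = FALSE)$objective)
  })
  objs <- vapply(cands, `[[`, 0, "objective")
  tie <- abs(objs[1] - objs[2]) < 1e-14
  pick <- if (tie) {
    # genuine tie: lexicographically smaller split set
    order(vapply(neighbors, .topology_key, ""))[1L]
  } else {
    which.min(objs)
  }
  key <- .split_key(old_split)
  list(topology = cands[[pick]]$topology, ell = cands[[pick]]$ell,
       key = key,
       event = sprintf("crossed %s to %s%s", key,
                       .topology_key(cands[[pick]]$topology),
                       if (tie) " (tie)" else ""))
}

# transfer coordinate lengths between two topologies sharing all but one
# split; the new split inherits the length at the replaced coordinate
.map_lengths_between_topologies <- function(top_from, ell_from, top_to) {
  ord_f <- .coord_split_order(top_from)
  ord_t <- .coord_split_order(top_to)
  keys_f <- vapply(top_from$splits[ord_f], .split_key, "")
  keys_t <- vapply(top_to$splits[ord_t], .split_key, "")
  ell_to <- numeric(length(keys_t))
  for (j in seq_along(keys_t)) {
    m <- match(keys_t[j], keys_f)
    ell_to[j] <- if (is.na(m)) {
      ell_from[[which(is.na(match(keys_f, keys_t)))]]
    } else {
      ell_from[[m]]
    }
  }
  ell_to
}

# ordinary-least-squares branch lengths for a topology against the
# path-distance matrix -log(S0): the standard least-squares edge-length
# fit, used as the default descent initialization.  Entries of S0 at or
# below zero correspond to infinite distances and are capped.
.ols_lengths <- function(S0, topology, floor = 0.05) {
  n <- topology$n_leaves
  D <- -log(pmax(S0, 1e-12))
  tree1 <- tree_from_topology(topology, rep(1, length(topology$splits)))
  co <- tree_coords(tree1)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  X <- vapply(seq_along(co$ell), function(i) {
    sm <- split_matrix(tree1, co$edge_index[i])
    sm[pairs]
  }, numeric(nrow(pairs)))
  ell <- qr.solve(X, D[pairs])
  pmax(ell, floor)
}

#' Project an SPD matrix into a fixed orthant
#'
#' Barzilai-Borwein gradient descent on the squared affine-invariant
#' distance \eqn{d(S_0, S_\ell)^2} over the edge lengths of trees with the
#' given resolved topology.  The iteration halts with status
#' `"boundary_halt"` as soon as a proposal assigns a negative internal
#' length; otherwise it stops when the gradient infinity norm drops below
#' `control$grad_tol` (status `"converged"`) or after `control$max_iter`
#' iterations.
#'
#' @param S0 symmetric positive definite target matrix.
#' @param topology a resolved `wald_topology`.
#' @param ell_init positive initial edge lengths (canonical coordinate
#'   order) or a single number recycled to all edges; the default `NULL`
#'   uses the least-squares branch-length fit to the path-distance matrix
#'   `-log(S0)`.
#' @param control named list overriding the optimizer defaults (gradient
#'   tolerance `grad_tol = 1e-8`, `max_iter = 5000`, Barzilai-Borwein
#'   safeguards `alpha_min`, `alpha_max`, length cap `ell_cap = 50`,
#'   pendant floor `1e-10`).
#' @return a `wald_projection`: list with the projected `forest`, final
#'   `objective` (squared distance), `status`, iteration `trace` and
#'   `iterations`.
#' @export
project_within_orthant <- function(S0, topology, ell_init = NULL,
                                   control = list()) {
  ctl <- .proj_control(control)
  E <- length(topology$splits)
  ell <- if (is.null(ell_init)) {
    .ols_lengths(S0, topology)
  } else {
    rep_len(as.numeric(ell_init), E)
  }
  res <- .bb_descent(.proj_target(S0), topology, ell, ctl, "halt")
  .new_projection_result(tree_from_topology(res$topology, res$ell),
                         res$objective, res$status, res$trace, res$iter)
}

#' Project an SPD matrix, crossing orthant boundaries
#'
#' Like [project_within_orthant()], but when a proposal assigns a negative
#' internal length the two trees in the neighbouring orthants across that
#' boundary are evaluated (taking absolute values of the proposal as
#' lengths) and the descent continues from whichever is closer to `S0`;
#' the gradient is recomputed after the switch.  Ties are broken toward
#' the lexicographically smaller split set and recorded in the result's
#' `events`.
#'
#' @param S0 symmetric positive definite target matrix.
#' @param tree_init a fully resolved `wald_forest` giving the starting
#'   orthant and lengths.
#' @inheritParams project_within_orthant
#' @return a `wald_projection` (with crossing `events` attached).
#' @export
project_crossing <- function(S0, tree_init, control = list()) {
  ctl <- .proj_control(control)
  co <- tree_coords(tree_init)
  ell <- pmax(co$ell, ctl$pendant_floor)
  res <- .bb_descent(.proj_target(S0), co$topology, ell, ctl, "cross")
  out <- .new_projection_result(tree_from_topology(res$topology, res$ell),
                                res$objective, res$status, res$trace,
                                res$iter)
  out$events <- res$events
  out
}

#' Global projection over all maximal orthants
#'
#' Runs the orthant-constrained projection once per fully resolved
#' topology on `n_leaves` leaves ((2N-5)!! runs) and returns the best
#' result; the objectives of all runs are attached as attribute
#' `all_objectives`.
#'
#' @inheritParams project_within_orthant
#' @param n_leaves number of leaves (guarded at 6).
#' @return the best `wald_projection` across orthants.
#' @export
project_global <- function(S0, n_leaves, ell_init = NULL, control = list()) {
  if (n_leaves > 6L) stop("global projection guarded at 6 leaves")
  tops <- enumerate_topologies(n_leaves)
  runs <- lapply(tops, function(tp) {
    project_within_orthant(S0, tp, ell_init = ell_init, control = control)
  })
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- runs[[which.min(objs)]]
  attr(best, "all_objectives") <- objs
  best
}
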