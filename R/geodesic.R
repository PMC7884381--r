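# ---------------------------------------------------------------------------
# Numerical integration of the geodesic equation
#   d2x^k/dt2 + Gamma^k_ij dx^i/dt dx^j/dt = 0
# inside a maximal orthant, for either the two-state or the Gaussian
# metric, in length or weight coordinates, with boundary handling:
# integration stops when an internal coordinate reaches zero (a BHV
# boundary) or, in weight coordinates, when a weight reaches one (the
# boundary at infinity); a pendant coordinate hitting zero is clamped to
# zero with its velocity zeroed, and integration continues.
# ---------------------------------------------------------------------------

# weights within this tolerance of 1 count as having reached the boundary
# at infinity: the metric in weight coordinates loses rank like (1-lambda)^4
# as a disconnection boundary is approached, so the last representable
# interior points sit about 1e-3 away from the face
.INFINITY_TOL <- 1e-3

# metric tensor and Christoffel symbols at a coordinate point.
# coords = "length": x is ell.  coords = "weight": x is lambda; the
# length-coordinate data are pulled back through ell_k = -log(1 - x_k)
# (diagonal change of variables).
.metric_at <- function(x, topology, model, coords) {
  if (coords == "weight") {
    # trial evaluations of an RK4 stage may step slightly outside the unit
    # cube before the boundary check sees them; clamp for evaluation only.
    # The clamp matches the boundary-at-infinity stopping tolerance: at the
    # boundary itself the metric degenerates (disconnected components lose
    # Fisher information in their pendant directions).
    x <- pmin(pmax(x, 0), 1 - .INFINITY_TOL)
    phi1 <- 1 / (1 - x)                 # d ell / d lambda
    ell <- weight_to_length(x)
  } else {
    ell <- pmax(x, 0)
  }
  tree <- tree_from_topology(topology, ell)
  md <- if (model == "two_state") {
    .two_state_metric_derivatives(tree)
  } else {
    .gaussian_metric_derivatives(tree)
  }
  g <- md$g; dg <- md$dg
  if (coords == "weight") {
    # pull back through the diagonal map ell = -log(1 - lambda):
    # phi' = 1/(1-lambda), phi'' = phi'^2, so
    #   g~_ab      = g_ab phi'_a phi'_b
    #   dg~_c(ab)  = dg_c(ab) phi'_c phi'_a phi'_b
    #              + g_ab phi'_a phi'_b (d_ca phi'_a + d_cb phi'_b)
    # (working in the transformed coordinates keeps the linear solve well
    # conditioned near the boundary at infinity, where g in length
    # coordinates degenerates)
    E <- length(x)
    pp <- outer(phi1, phi1)
    gt <- g * pp
    dgt <- array(0, c(E, E, E))
    for (k in seq_len(E)) {
      dgt[k, , ] <- dg[k, , ] * phi1[k] * pp
      dgt[k, k, ] <- dgt[k, k, ] + gt[k, ] * phi1[k]
      dgt[k, , k] <- dgt[k, , k] + gt[, k] * phi1[k]
    }
    g <- gt; dg <- dgt
  }
  list(g = g, Gamma = .christoffel_from_metric(g, dg))
}

.geo_accel <- function(x, v, topology, model, coords) {
  Gamma <- .metric_at(x, topology, model, coords)$Gamma
  -vapply(seq_along(x), function(k) sum(Gamma[k, , ] * outer(v, v)), 0)
}

# one classical RK4 step of the first-order system (x, v)
.rk4_step <- function(x, v, h, topology, model, coords) {
  a1 <- .geo_accel(x, v, topology, model, coords)
  k1x <- v; k1v <- a1
  a2 <- .geo_accel(x + h / 2 * k1x, v + h / 2 * k1v, topology, model, coords)
  k2x <- v + h / 2 * k1v; k2v <- a2
  a3 <- .geo_accel(x + h / 2 * k2x, v + h / 2 * k2v, topology, model, coords)
  k3x <- v + h / 2 * k2v; k3v <- a3
  a4 <- .geo_accel(x + h * k3x, v + h * k3v, topology, model, coords)
  k4x <- v + h * k3v; k4v <- a4
  list(x = x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x),
       v = v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
}

#' Shoot a geodesic from a tree
#'
#' Integrates the geodesic differential equation of the chosen model with
#' a fourth-order Runge-Kutta scheme, starting at `tree` with initial
#' coordinate velocity `v0` (canonical coordinate order of
#' [tree_coords()]).  Integration stops when an internal coordinate
#' reaches zero (status `"boundary"`, with the crossing located by
#' bisection) or, in weight coordinates, when any weight reaches one
#' (status `"infinity"`); a pendant coordinate that hits zero is set to
#' zero, its velocity zeroed, and integration continues.
#'
#' @param tree a fully resolved `wald_forest` (finite lengths).
#' @param v0 numeric initial velocity of length `2N - 3`.
#' @param t_max integration horizon.
#' @param step RK4 time step.
#' @param model `"gaussian"` or `"two_state"`.
#' @param coords `"length"` to integrate edge lengths, `"weight"` to
#'   integrate edge weights.
#' @param normalize logical; rescale `v0` to unit Riemannian speed so that
#'   time equals arc length.
#' @return object of class `wald_geodesic`: a list with the sample times
#'   `t`, coordinate matrix `x`, velocity matrix `v`, `status`
#'   (`"completed"`, `"boundary"` or `"infinity"`), `clamped` flags and the
#'   originating `topology`, `model`, `coords`.
#' @export
shoot_geodesic <- function(tree, v0, t_max = 1, step = 5e-3,
                           model = c("gaussian", "two_state"),
                           coords = c("length", "weight"),
                           normalize = TRUE) {
  model <- match.arg(model)
  coords <- match.arg(coords)
  co <- tree_coords(tree)
  E <- length(co$ell)
  if (length(v0) != E) stop("v0 must have length 2N - 3")
  n <- tree$n_leaves
  x <- if (coords == "weight") length_to_weight(co$ell) else co$ell
  v <- as.numeric(v0)
  if (normalize && any(v != 0)) {
    g0 <- .metric_at(x, co$topology, model, coords)$g
    v <- v / sqrt(as.numeric(t(v) %*% g0 %*% v))
  }
  pend <- seq_len(n)
  internal <- if (E > n) seq.int(n + 1L, E) else integer(0)
  clamped <- logical(E)
  ts <- 0; xs <- matrix(x, 1L); vs <- matrix(v, 1L)
  status <- "completed"
  t <- 0
  while (t < t_max - 1e-12) {
    h <- min(step, t_max - t)
    stp <- .rk4_step(x, v, h, co$topology, model, coords)
    xn <- stp$x; vn <- stp$v
    if (any(!is.finite(xn)) || any(!is.finite(vn))) {
      stop("non-finite state during geodesic integration")
    }
    hit_internal <- internal[xn[internal] <= 0]
    hit_inf <- if (coords == "weight") {
      which(xn >= 1 - .INFINITY_TOL)
    } else {
      integer(0)
    }
    if (length(hit_internal) || length(hit_inf)) {
      # bisect the step fraction to land on the boundary
      lo <- 0; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        sm <- .rk4_step(x, v, h * mid, co$topology, model, coords)
        crossed <- any(sm$x[internal] <= 0) ||
          (coords == "weight" && any(sm$x >= 1 - .INFINITY_TOL))
        if (crossed) hi <- mid else lo <- mid
        if (hi - lo < 1e-10) break
      }
      sm <- .rk4_step(x, v, h * hi, co$topology, model, coords)
      t <- t + h * hi
      ts <- c(ts, t); xs <- rbind(xs, sm$x); vs <- rbind(vs, sm$v)
      status <- if (length(hit_inf)) "infinity" else "boundary"
      break
    }
    zero_pend <- pend[xn[pend] <= 0]
    if (length(zero_pend)) {
      xn[zero_pend] <- 0
      vn[zero_pend] <- 0
      clamped[zero_pend] <- TRUE
    }
    xn[clamped] <- 0; vn[clamped] <- 0
    t <- t + h
    x <- xn; v <- vn
    ts <- c(ts, t); xs <- rbind(xs, x); vs <- rbind(vs, v)
  }
  structure(list(t = ts, x = xs, v = vs, status = status,
                 clamped = clamped, topology = co$topology,
                 model = model, coords = coords),
            class = "wald_geodesic")
}

#' @export
print.wald_geodesic <- function(x, ...) {
  cat(sprintf(
    "wald_geodesic (%s model, %s coordinates): %d samples, t in [0, %.4g], status %s\n",
    x$model, x$coords, length(x$t), max(x$t), x$status))
  invisible(x)
}

#' Forest at a sample of a shot geodesic
#'
#' @param path a `wald_geodesic`.
#' @param i sample index (row of `path$x`).
#' @return a `wald_forest`.
#' @export
path_forest <- function(path, i) {
  x <- path$x[i, ]
  ell <- if (path$coords == "weight") weight_to_length(x) else x
  tree_from_topology(path$topology, ell)
}

#' Fan of geodesics fired in many directions
#'
#' Shoots unit-speed geodesics from `tree` in `directions` equally spaced
#' angles of the plane of the two internal coordinates (initial pendant
#' velocity zero), as used to draw distance contours around a starting
#' tree.  Time equals cumulative arc length.
#'
#' @inheritParams shoot_geodesic
#' @param directions number of equally spaced directions.
#' @return data frame with columns `direction`, `angle`, `t`, `status` and
#'   one column `x1 ... x(2N-3)` per coordinate.
#' @export
distance_field <- function(tree, directions = 24, t_max = 1, step = 5e-3,
                           model = c("gaussian", "two_state"),
                           coords = c("length", "weight")) {
  model <- match.arg(model)
  coords <- match.arg(coords)
  co <- tree_coords(tree)
  E <- length(co$ell)
  n <- tree$n_leaves
  if (E != n + 2L) stop("distance_field expects two internal coordinates")
  out <- NULL
  for (d in seq_len(directions)) {
    ang <- 2 * pi * (d - 1) / directions
    v0 <- numeric(E)
    v0[n + 1L] <- cos(ang); v0[n + 2L] <- sin(ang)
    gp <- shoot_geodesic(tree, v0, t_max = t_max, step = step,
                         model = model, coords = coords)
    df <- data.frame(direction = d, angle = ang, t = gp$t,
                     status = gp$status)
    colnames(gp$x) <- paste0("x", seq_len(E))
    out <- rbind(out, cbind(df, gp$x))
  }
  out
}

#' Riemannian length of a sampled path
#'
#' Riemann-sum length \eqn{\sum_k \sqrt{\delta x^T g(x_{mid}) \delta x}}
#' over consecutive samples, with the metric evaluated at segment
#' midpoints; refines under subdivision and is invariant under
#' reparametrization of the sample times.
#'
#' @param path a `wald_geodesic`, or a coordinate matrix (one row per
#'   sample) if `topology` is supplied.
#' @param topology,model,coords required when `path` is a plain matrix.
#' @return numeric scalar.
#' @export
riemannian_path_length <- function(path, topology = NULL,
                                   model = c("gaussian", "two_state"),
                                   coords = c("length", "weight")) {
  if (inherits(path, "wald_geodesic")) {
    x <- path$x; topology <- path$topology
    model <- path$model; coords <- path$coords
  } else {
    x <- as.matrix(path)
    model <- match.arg(model); coords <- match.arg(coords)
    if (is.null(topology)) stop("topology required for a coordinate matrix")
  }
  total <- 0
  for (k in seq_len(nrow(x) - 1L)) {
    dx <- x[k + 1L, ] - x[k, ]
    mid <- (x[k + 1L, ] + x[k, ]) / 2
    g <- .metric_at(mid, topology, model, coords)$g
    total <- total + sqrt(max(0, as.numeric(t(dx) %*% g %*% dx)))
  }
  total
}
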