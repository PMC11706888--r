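#' Spring-chain state on an interface
#'
#' The state of a chain of \eqn{M = N m} springs at one instant, stored as
#' strictly increasing node arc-length coordinates. With fixed boundaries
#' (open interface) the state holds \eqn{M + 1} nodes with \eqn{s_0 = 0} and
#' \eqn{s_M = L} pinned at the curve end points. With periodic boundaries
#' (closed interface) it holds the \eqn{M} distinct nodes in \eqn{[0, L)};
#' the seam spring connects the last node back to the first across \eqn{s=L}.
#'
#' @param s numeric vector of node arc-length coordinates (length \code{M + 1}
#'   fixed, \code{M} periodic).
#' @param L interface length.
#' @param N number of cells.
#' @param m springs per cell.
#' @param boundary \code{"fixed"} or \code{"periodic"}.
#' @param t time stamp of the state.
#' @return An object of class \code{"spring_chain_state"}.
#' @export
spring_chain_state <- function(s, L, N, m, boundary = c("fixed", "periodic"), t = 0) {
  boundary <- match.arg(boundary)
  N <- as.integer(N); m <- as.integer(m)
  M <- N * m
  if (boundary == "fixed") {
    if (length(s) != M + 1L) stop("fixed boundary state needs M + 1 = ", M + 1L, " nodes")
    if (abs(s[1L]) > 1e-12 * L || abs(s[M + 1L] - L) > 1e-12 * L) {
      stop("fixed boundary nodes must sit at s = 0 and s = L")
    }
    s[1L] <- 0; s[M + 1L] <- L
  } else {
    if (length(s) != M) stop("periodic state needs M = ", M, " distinct nodes")
    if (any(s < 0 | s >= L)) stop("periodic node coordinates must lie in [0, L)")
  }
  st <- structure(list(s = as.numeric(s), L = L, N = N, m = m, M = M,
                       boundary = boundary, t = t),
                  class = "spring_chain_state")
  ell <- spring_lengths(st)
  if (any(ell <= 0)) {
    stop("node ordering violated: spring ", which(ell <= 0)[1L],
         " has non-positive length")
  }
  st
}

#' @export
print.spring_chain_state <- function(x, ...) {
  cat(sprintf("Spring chain: N=%d cells x m=%d springs (%s), t=%g, L=%g\n",
              x$N, x$m, x$boundary, x$t, x$L))
  ell <- spring_lengths(x)
  cat(sprintf("  spring lengths: min %.4g, mean %.4g, max %.4g\n",
              min(ell), mean(ell), max(ell)))
  invisible(x)
}

#' Spring lengths of a chain state
#'
#' Arc lengths \eqn{\ell_i = s_i - s_{i-1}} for the curved-spring model, or
#' Euclidean chord lengths \eqn{\lVert r(s_i) - r(s_{i-1}) \rVert} for the
#' straight-spring model (chord is never longer than arc). For periodic
#' states spring 1 is the seam spring.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param model \code{"curved"} (arc lengths) or \code{"straight"} (chords).
#' @param curve an \code{"arclength_curve"}; required for \code{"straight"}.
#' @return Numeric vector of \code{M} spring lengths.
#' @export
spring_lengths <- function(state, model = c("curved", "straight"), curve = NULL) {
  model <- match.arg(model)
  s <- state$s
  if (model == "curved") {
    if (state$boundary == "fixed") diff(s)
    else c(s[1L] + state$L - s[state$M], diff(s))
  } else {
    if (is.null(curve)) stop("straight spring lengths require the curve")
    p <- curve$position(s)
    if (state$boundary == "periodic") p <- rbind(p[state$M, , drop = FALSE], p)
    sqrt(rowSums(diff(p)^2))
  }
}

#' Discrete per-spring cell density
#'
#' \eqn{q_i = 1/(m \ell_i)} using the model's own notion of spring length.
#' For a uniform chain this equals the mean density \eqn{N/L}.
#'
#' @inheritParams spring_lengths
#' @return Numeric vector of \code{M} densities (cells/length).
#' @export
cell_density_discrete <- function(state, model = c("curved", "straight"), curve = NULL) {
  1 / (state$m * spring_lengths(state, model, curve))
}

#' Node velocities, curved-spring model
#'
#' Overdamped dynamics \eqn{\eta \, ds_i/dt = f(s_{i+1} - s_i) - f(s_i -
#' s_{i-1})}: each node is pulled by the imbalance of its two neighbouring
#' spring forces along the interface. The dynamics is independent of the
#' curve's shape. Fixed boundary nodes have zero velocity.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param law a \code{"force_law"} (its \code{m} should match the state).
#' @return Velocities \eqn{ds_i/dt} for every stored node.
#' @export
rhs_curved <- function(state, law) {
  p <- .spring_params(law)
  ell <- spring_lengths(state, "curved")
  f <- spring_force(law, ell)
  if (state$boundary == "fixed") {
    c(0, (f[-1L] - f[-state$M]) / p$eta, 0)
  } else {
    # node i sits between springs i (left) and i+1 (right); seam is spring 1
    fl <- f
    fr <- c(f[-1L], f[1L])
    (fr - fl) / p$eta
  }
}

#' Node velocities, straight-spring model
#'
#' Spring forces act along the secant between node positions in the plane; a
#' normal substrate reaction keeps nodes on the curve, so the velocity is the
#' tangential projection \eqn{\eta\, ds_i/dt = [f(\lVert d_+\rVert)\hat d_+ -
#' f(\lVert d_-\rVert)\hat d_-] \cdot \tau_i}. Reduces exactly to
#' [rhs_curved()] on a straight interface.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param curve an \code{"arclength_curve"}.
#' @param law a \code{"force_law"}.
#' @return Velocities \eqn{ds_i/dt} for every stored node.
#' @export
rhs_straight <- function(state, curve, law) {
  p <- .spring_params(law)
  s <- state$s
  r <- curve$position(s)
  tau <- curve$tangent(s)
  if (state$boundary == "fixed") {
    n <- length(s)
    d <- diff(r)
    len <- sqrt(rowSums(d^2))
    if (any(len <= 0)) stop("collapsed spring: coincident node positions")
    fhat <- spring_force(law, len) / len
    Fplus <- d * fhat                      # force from right spring, rows 1..M at nodes 0..M-1
    v <- rowSums((Fplus[-1L, , drop = FALSE] - Fplus[-(n - 1L), , drop = FALSE]) *
                   tau[2:(n - 1L), , drop = FALSE]) / p$eta
    c(0, v, 0)
  } else {
    M <- state$M
    rr <- rbind(r, r[1L, ])
    d <- diff(rr)                          # spring i+1 vector from node i to node i+1 (wrap)
    len <- sqrt(rowSums(d^2))
    if (any(len <= 0)) stop("collapsed spring: coincident node positions")
    fhat <- spring_force(law, len) / len
    Fr <- d * fhat                         # right spring force at node i (row i)
    Fl <- rbind(Fr[M, ], Fr[-M, , drop = FALSE])  # left spring force at node i
    rowSums((Fr - Fl) * tau) / p$eta
  }
}

# largest stable Euler step about the initial state: dt <= 0.5 eta / max f'(ell)
.euler_dt_max <- function(state, law, model = "curved", curve = NULL) {
  p <- .spring_params(law)
  ell <- spring_lengths(state, model, curve)
  0.5 * p$eta / max(spring_force_deriv(law, ell))
}

#' One forward Euler step
#'
#' \eqn{s_i(t + \Delta t) = s_i(t) + \Delta t \, v_i}, then boundary conditions
#' are re-imposed: fixed nodes are pinned, periodic coordinates wrapped modulo
#' \eqn{L}. A step that destroys the node ordering raises an error naming the
#' offending spring.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param velocity node velocities (e.g. from [rhs_curved()]).
#' @param dt time step, > 0.
#' @return The updated \code{"spring_chain_state"} at \code{t + dt}.
#' @export
step_euler <- function(state, velocity, dt) {
  stopifnot(dt > 0, length(velocity) == length(state$s))
  s <- state$s + dt * velocity
  if (state$boundary == "fixed") {
    s[1L] <- 0
    s[length(s)] <- state$L
    if (any(diff(s) <= 0)) {
      stop("unstable step: spring ", which(diff(s) <= 0)[1L],
           " collapsed; reduce dt")
    }
  } else {
    # wrap while keeping the stored ordering: shift by whole L only
    s <- s - state$L * floor(s / state$L)
    s[s >= state$L] <- s[s >= state$L] - state$L  # fp edge: tiny negatives wrap to L
    s[s < 0] <- 0
    # restore increasing order if the origin node crossed the seam
    o <- order(s)
    if (!all(o == seq_along(o))) {
      # a cyclic rotation is fine; anything else means a genuine crossing
      k <- which.min(s)
      s2 <- c(s[k:length(s)], s[seq_len(k - 1L)])
      if (any(diff(s2) <= 0)) stop("unstable step: node ordering violated; reduce dt")
      s <- s2
    }
  }
  spring_chain_state(s, state$L, state$N, state$m, state$boundary, state$t + dt)
}

#' Offset initial condition
#'
#' The standard perturbed start used throughout: cell boundaries evenly spaced
#' along the interface except one, displaced forward by
#' \code{offset_fraction} of a resting cell length \eqn{L/N}, so that exactly
#' one cell is elongated and its neighbour equally compressed; the \code{m}
#' spring nodes inside each cell are evenly spaced. With
#' \code{offset_fraction = 1/2}, the elongated cell is stretched 50\% and its
#' neighbour compressed 50\%.
#'
#' @param N cells (>= 2).
#' @param m springs per cell (>= 1).
#' @param L interface length.
#' @param boundary \code{"fixed"} or \code{"periodic"}.
#' @param offset_fraction displacement in units of a cell rest length, in
#'   (-0.5, 0.5].
#' @return A \code{"spring_chain_state"} at \code{t = 0}.
#' @export
initial_condition_offset <- function(N, m, L, boundary = c("fixed", "periodic"),
                                     offset_fraction = 0.5) {
  boundary <- match.arg(boundary)
  N <- as.integer(N); m <- as.integer(m)
  if (N < 2L || m < 1L) stop("need N >= 2 cells and m >= 1 springs per cell")
  if (offset_fraction <= -0.5 || offset_fraction > 0.5) {
    stop("offset_fraction must lie in (-0.5, 0.5]")
  }
  cell <- L / N
  bnd <- (0:N) * cell
  bnd[3L] <- bnd[3L] + offset_fraction * cell  # boundary between 2nd and 3rd cells
  s <- unlist(lapply(seq_len(N), function(j) {
    seq(bnd[j], bnd[j + 1L], length.out = m + 1L)[-(m + 1L)]
  }))
  if (boundary == "fixed") {
    spring_chain_state(c(s, L), L, N, m, "fixed", t = 0)
  } else {
    spring_chain_state(s, L, N, m, "periodic", t = 0)
  }
}

#' Simulate the spring-chain dynamics
#'
#' Integrates the overdamped node dynamics with explicit forward Euler
#' (default \eqn{\Delta t = 0.001}) and returns states at the requested save
#' times (linear interpolation in time between the bracketing Euler steps).
#' A guard rejects time steps beyond the linear stability limit
#' \eqn{0.5\,\eta / \max_i f'(\ell_i)} estimated at \eqn{t = 0}.
#'
#' The curved-spring model runs in compiled code; the straight-spring model
#' needs curve positions each step and runs in R.
#'
#' @param initial a \code{"spring_chain_state"}.
#' @param law a \code{"force_law"}.
#' @param model \code{"curved"} or \code{"straight"}.
#' @param curve an \code{"arclength_curve"}; required for the straight model.
#' @param dt Euler time step.
#' @param t_end final time.
#' @param save_times times at which to store states; default 21 evenly spaced.
#' @param use_compiled use the C++ kernel for the curved model.
#' @return A \code{"spring_trajectory"}: list with \code{times}, \code{states}
#'   (list of \code{"spring_chain_state"}), \code{model}, \code{law}.
#' @examples
#' law <- force_law("hookean", k_star = 1, a_star = 2 * pi / 8, eta_star = 1, m = 1)
#' ic <- initial_condition_offset(8, 1, 2 * pi, "periodic")
#' tr <- simulate_chain(ic, law, "curved", t_end = 2)
#' range(spring_lengths(tr$states[[length(tr$states)]]))  # relaxed to L/M
#' @export
simulate_chain <- function(initial, law, model = c("curved", "straight"),
                           curve = NULL, dt = 1e-3, t_end, save_times = NULL,
                           use_compiled = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(initial, "spring_chain_state"), t_end > 0, dt > 0)
  if (model == "straight" && is.null(curve)) stop("straight model requires the curve")
  if (is.null(save_times)) save_times <- seq(0, t_end, length.out = 21L)
  save_times <- sort(unique(pmin(pmax(save_times, 0), t_end)))
  dt_max <- .euler_dt_max(initial, law, model, curve)
  if (dt > dt_max) {
    stop(sprintf(paste0("dt = %g exceeds the forward-Euler stability guard %.3g ",
                        "(0.5 eta / max f'(ell) at t = 0); reduce dt"), dt, dt_max))
  }
  n_total <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  lower <- pmin(as.integer(floor(save_times / dt + 1e-9)), n_total)
  record <- sort(unique(c(lower, pmin(lower + 1L, n_total), 0L)))

  if (model == "curved" && use_compiled) {
    p <- .spring_params(law)
    code <- match(law$kind, c("hookean", "inverse_density", "inverse_density_sq"))
    S <- euler_curved_cpp(initial$s, initial$L, initial$boundary == "periodic",
                          p$k, p$a, p$eta, code, dt, record)
  } else {
    S <- matrix(NA_real_, length(record), length(initial$s))
    st <- initial
    idx <- 1L
    if (record[1L] == 0L) { S[1L, ] <- st$s; idx <- 2L }
    for (n in seq_len(max(record))) {
      v <- if (model == "curved") rhs_curved(st, law) else rhs_straight(st, curve, law)
      st <- step_euler(st, v, dt)
      if (idx <= length(record) && n == record[idx]) {
        S[idx, ] <- st$s
        idx <- idx + 1L
      }
    }
  }

  states <- lapply(seq_along(save_times), function(i) {
    tt <- save_times[i]
    n0 <- lower[i]
    if (n0 >= n_total || abs(tt - n0 * dt) < 1e-12 * max(dt, 1)) {
      s <- S[match(n0, record), ]
    } else {
      w <- tt / dt - n0
      s0 <- S[match(n0, record), ]
      s1 <- S[match(n0 + 1L, record), ]
      if (initial$boundary == "periodic") {
        d <- s1 - s0   # unwrap seam crossings before interpolating
        d <- d - initial$L * round(d / initial$L)
        s <- (s0 + w * d) %% initial$L
        k <- which.min(s)
        if (k > 1L) s <- c(s[k:length(s)], s[seq_len(k - 1L)])
      } else {
        s <- s0 + w * (s1 - s0)
      }
    }
    spring_chain_state(s, initial$L, initial$N, initial$m, initial$boundary, t = tt)
  })
  structure(list(times = save_times, states = states, model = model,
                 law = law, dt = dt),
            class = "spring_trajectory")
}

#' @export
print.spring_trajectory <- function(x, ...) {
  st <- x$states[[1L]]
  cat(sprintf("Spring-chain trajectory (%s model): N=%d, m=%d, %s boundaries\n",
              x$model, st$N, st$m, st$boundary),
      sprintf("  %d saved states, t in [%g, %g], Euler dt=%g\n",
              length(x$times), min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' @export
plot.spring_trajectory <- function(x, ...) {
  S <- t(vapply(x$states, function(st) st$s, numeric(length(x$states[[1L]]$s))))
  graphics::matplot(x$times, S, type = "l", lty = 1, col = "grey40",
                    xlab = "time", ylab = "arc length s_i", ...)
  invisible(x)
}

#' @export
as.data.frame.spring_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$states, function(st) {
    data.frame(time = st$t, node_index = seq_along(st$s) - 1L, s = st$s)
  }))
}

#' Stress-free rest length
#'
#' The spring rest length that makes the evenly spaced steady state force-free.
#' For curved springs this is exactly \eqn{a = L/M}. For straight springs it is
#' the common chord length of the equal-chord \eqn{M}-gon inscribed in the
#' closed curve that closes after one loop (on a circle, \eqn{2R\sin(\pi/M)});
#' on an open curve, the equal-chord polyline joining the two pinned end
#' points in \eqn{M} chords. The straight case is solved by a shooting method:
#' for a trial chord \eqn{a}, march \eqn{M} chords along the curve (each
#' advance by safeguarded Newton on \eqn{\lVert r(s') - r(s)\rVert = a}) and
#' adjust \eqn{a} until the total arc equals \eqn{L} (closure gap below
#' \code{1e-10 L}).
#'
#' @param curve an \code{"arclength_curve"} (or \code{"parametric_curve"},
#'   which is reparametrised first).
#' @param M number of springs.
#' @param model \code{"curved"} or \code{"straight"}.
#' @param s0 arc-length start of the chord march (straight model).
#' @return The rest length \eqn{a}.
#' @examples
#' circ <- arc_length_curve(circle_curve(1))
#' rest_length_stress_free(circ, 4, "straight")  # sqrt(2)
#' rest_length_stress_free(circ, 4, "curved")    # 2*pi/4
#' @export
rest_length_stress_free <- function(curve, M, model = c("curved", "straight"), s0 = 0) {
  model <- match.arg(model)
  if (inherits(curve, "parametric_curve")) curve <- arc_length_curve(curve)
  stopifnot(inherits(curve, "arclength_curve"), M >= 2)
  L <- curve$L
  if (model == "curved") return(L / M)
  total <- function(a) .march_chords(curve, a, M, s0) - L
  # chord <= arc, so the stress-free chord lies in (0, L/M]
  lo <- 0.5 * L / M
  while (total(lo) > 0 && lo > 1e-6 * L / M) lo <- lo / 2
  f_lo <- total(lo); f_hi <- total(L / M)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo > 0 || f_hi < 0) {
    stop("no closing equal-chord polygon found for M = ", M)
  }
  r <- stats::uniroot(total, c(lo, L / M), f.lower = f_lo, f.upper = f_hi,
                      tol = 1e-13 * L)
  if (abs(r$f.root) > 1e-10 * L) stop("equal-chord shooting did not converge")
  r$root
}

# march M chords of length a starting at arc position s0; return total arc swept.
# open curves are extended linearly beyond their end points so that trial marches
# overshooting s = L stay well defined (the root of the closure equation does not).
.march_chords <- function(curve, a, M, s0 = 0) {
  pos <- if (curve$closed) curve$position else function(s) {
    if (s > curve$L) curve$position(curve$L) + (s - curve$L) * curve$tangent(curve$L)
    else if (s < 0) curve$position(0) + s * curve$tangent(0)
    else curve$position(s)
  }
  tang <- if (curve$closed) curve$tangent else function(s) {
    curve$tangent(min(max(s, 0), curve$L))
  }
  s <- s0
  ds <- a * 1.02
  for (i in seq_len(M)) {
    p <- pos(s)
    g <- function(d) sqrt(sum((pos(s + d) - p)^2)) - a
    # safeguarded Newton on the chord-length equation
    d <- max(ds, a)
    ok <- FALSE
    for (it in 1:40) {
      q <- pos(s + d)
      v <- q - p
      nv <- sqrt(sum(v^2))
      res <- nv - a
      if (abs(res) < 1e-13 * max(a, 1)) { ok <- TRUE; break }
      slope <- sum(tang(s + d) * v) / nv
      if (!is.finite(slope) || abs(slope) < 1e-8) break
      d_new <- d - res / slope
      if (!is.finite(d_new) || d_new <= a * 0.999 || d_new > 4 * a) break
      d <- d_new
    }
    if (!ok) {
      hi <- a * 1.05
      while (g(hi) < 0 && hi < 0.45 * curve$L) hi <- hi * 1.3
      if (g(hi) < 0) stop("chord march failed: chord a = ", format(a), " too long")
      d <- stats::uniroot(g, c(a * (1 - 1e-12), hi), tol = 1e-14 * max(a, 1))$root
    }
    s <- s + d
    ds <- d
  }
  s - s0
}
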