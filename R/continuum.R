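#' Continuum cell-density field
#'
#' Cell density \eqn{q(s, t)} sampled on the uniform arc-length grid
#' \eqn{s_j = j\,\delta s}, \eqn{j = 0, \dots, J}, \eqn{\delta s = L/J}. For
#' periodic boundaries the last grid value duplicates the first
#' (\eqn{q_J = q_0}).
#'
#' @param q numeric vector of \code{J + 1} positive densities.
#' @param L interface length.
#' @param boundary \code{"fixed"} (no-flux) or \code{"periodic"}.
#' @param t time stamp.
#' @return An object of class \code{"density_field"} with fields \code{s},
#'   \code{q}, \code{L}, \code{J}, \code{ds}, \code{boundary}, \code{t}.
#' @export
density_field <- function(q, L, boundary = c("fixed", "periodic"), t = 0) {
  boundary <- match.arg(boundary)
  J <- length(q) - 1L
  if (J < 2L) stop("need at least 3 grid values")
  if (any(q <= 0)) stop("cell density must be positive everywhere")
  if (boundary == "periodic" && abs(q[1L] - q[J + 1L]) > 1e-12 * max(q)) {
    stop("periodic density field must have q[0] == q[J]")
  }
  structure(list(s = seq(0, L, length.out = J + 1L), q = as.numeric(q),
                 L = L, J = J, ds = L / J, boundary = boundary, t = t),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("Density field (%s): J=%d intervals on [0, %g], t=%g\n",
              x$boundary, x$J, x$L, x$t),
      sprintf("  q in [%.5g, %.5g], mass = %.8g cells\n",
              min(x$q), max(x$q), field_mass(x)))
  invisible(x)
}

#' @export
plot.density_field <- function(x, ...) {
  graphics::plot(x$s, x$q, type = "l", xlab = "arc length s",
                 ylab = "cell density q", ...)
  invisible(x)
}

#' Total cell number of a density field (trapezoid rule)
#' @param field a \code{"density_field"}.
#' @return \eqn{\int_0^L q \, ds}.
#' @export
field_mass <- function(field) {
  q <- field$q
  field$ds * (sum(q) - (q[1L] + q[length(q)]) / 2)
}

#' Density field of a discrete chain state
#'
#' The piecewise-constant field equal to \eqn{q_i = 1/(m \ell_i)} over each
#' spring's arc interval, sampled on the uniform grid; it matches the discrete
#' density exactly at spring midpoints. Total mass equals \eqn{N} up to one
#' grid cell of discretisation.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param J number of grid intervals (default 1000).
#' @return A \code{"density_field"}.
#' @export
density_from_state <- function(state, J = 1000L) {
  s <- state$s
  L <- state$L
  q_spring <- cell_density_discrete(state)
  grid <- seq(0, L, length.out = J + 1L)
  if (state$boundary == "fixed") {
    idx <- pmin(pmax(findInterval(grid, s, rightmost.closed = TRUE), 1L), state$M)
    q <- q_spring[idx]
  } else {
    # springs: seam (index 1) covers [s_M, L) U [0, s_1); spring i covers [s_{i-1}, s_i)
    idx <- findInterval(grid %% L, s) + 1L        # 1 when below s_1 -> seam
    idx[idx > state$M] <- 1L                       # at/above s_M -> seam
    q <- q_spring[idx]
    q[J + 1L] <- q[1L]
  }
  density_field(q, L, state$boundary, t = state$t)
}

# conservative flux-form right-hand side (R reference implementation)
.pde_rhs_r <- function(q, ds, Dfun, periodic) {
  J1 <- length(q)
  if (periodic) {
    qp <- c(q[-1L], q[1L])
    qm <- c(q[J1], q[-J1])
  } else {
    qp <- c(q[-1L], q[J1 - 1L])   # mirror ghosts
    qm <- c(q[2L], q[-J1])
  }
  Dp <- Dfun((q + qp) / 2)
  Dm <- Dfun((qm + q) / 2)
  (Dp * (qp - q) - Dm * (q - qm)) / ds^2
}

#' Solve the continuum mechanical-relaxation PDE
#'
#' Integrates the conservation law \deqn{\partial_t q = \partial_s \left(
#' D(q)\, \partial_s q \right)} on \eqn{[0, L]} with no-flux
#' (\code{"fixed"}) or periodic boundaries, by the method of lines: a
#' conservative flux-form central difference in space (face diffusivities at
#' arithmetic-mean densities, mirror ghost values at no-flux boundaries) and
#' an adaptive Dormand-Prince 5(4) Runge-Kutta pair in time. Mass is conserved
#' to solver tolerance and constant fields are exact fixed points.
#'
#' @param q0 initial \code{"density_field"}.
#' @param law a \code{"force_law"} supplying \eqn{D(q)} via [diffusivity()].
#' @param t_eval increasing times at which to report the solution (the first
#'   may be 0).
#' @param rtol,atol relative/absolute time-integration tolerances.
#' @param use_compiled use the C++ kernel (all three built-in laws).
#' @return A \code{"pde_solution"}: list with \code{times} and \code{fields}
#'   (list of \code{"density_field"}).
#' @examples
#' law <- force_law("hookean", k_star = 1, a_star = 2 * pi / 8, eta_star = 1)
#' ic <- density_from_state(initial_condition_offset(8, 1, 2 * pi, "periodic"), J = 200)
#' sol <- solve_pde(ic, law, t_eval = c(0.05, 2))
#' range(sol$fields[[2]]$q)  # nearly uniform at t = 2
#' @export
solve_pde <- function(q0, law, t_eval, rtol = 1e-8, atol = 1e-8,
                      use_compiled = TRUE) {
  stopifnot(inherits(q0, "density_field"), inherits(law, "force_law"))
  t_eval <- sort(t_eval)
  if (any(t_eval < 0)) stop("t_eval must be non-negative")
  periodic <- q0$boundary == "periodic"
  q_work <- if (periodic) q0$q[-(q0$J + 1L)] else q0$q

  if (use_compiled) {
    code <- match(law$kind, c("hookean", "inverse_density", "inverse_density_sq"))
    coef <- switch(law$kind,
      hookean = law$k_star / law$eta_star,
      inverse_density = law$alpha_star / law$eta_star,
      inverse_density_sq = 2 * law$beta_star / law$eta_star)
    Q <- pde_rk45_cpp(q_work, q0$ds, t_eval, code, coef, periodic, rtol, atol)
  } else {
    Dfun <- function(q) diffusivity(law, q)
    Q <- .solve_pde_r(q_work, q0$ds, t_eval, Dfun, periodic, rtol, atol)
  }
  fields <- lapply(seq_along(t_eval), function(i) {
    q <- Q[i, ]
    if (periodic) q <- c(q, q[1L])
    density_field(q, q0$L, q0$boundary, t = t_eval[i])
  })
  structure(list(times = t_eval, fields = fields, law = law),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  f <- x$fields[[length(x$fields)]]
  cat(sprintf("PDE solution (%s, %s): J=%d, %d output times in [%g, %g]\n",
              x$law$kind, f$boundary, f$J, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# pure-R Dormand-Prince 5(4); reference path and generic-D fallback
.solve_pde_r <- function(q, ds, t_eval, Dfun, periodic, rtol, atol) {
  A <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200, 187 / 2100, 1 / 40)
  out <- matrix(NA_real_, length(t_eval), length(q))
  t <- 0
  dt <- ds^2 / (2 * max(Dfun(q))) # initial guess at the explicit stability scale
  k <- vector("list", 7L)
  for (i in seq_along(t_eval)) {
    tf <- t_eval[i]
    while (t < tf - 1e-14 * max(tf, 1)) {
      h <- min(dt, tf - t)
      k[[1L]] <- .pde_rhs_r(q, ds, Dfun, periodic)
      for (st in 1:6) {
        qs <- q
        for (j in seq_along(A[[st]])) qs <- qs + h * A[[st]][j] * k[[j]]
        if (any(qs <= 0)) { qs <- NULL; break }
        k[[st + 1L]] <- .pde_rhs_r(qs, ds, Dfun, periodic)
      }
      if (is.null(qs)) { dt <- h / 2; next }
      q5 <- q
      for (j in 1:7) if (b5[j] != 0) q5 <- q5 + h * b5[j] * k[[j]]
      qe <- numeric(length(q))
      for (j in 1:7) qe <- qe + h * (b5[j] - b4[j]) * k[[j]]
      sc <- atol + rtol * pmax(abs(q), abs(q5))
      err <- sqrt(mean((qe / sc)^2))
      if (err <= 1 && all(q5 > 0)) {
        q <- q5
        t <- t + h
        dt <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
      } else {
        if (h < 1e-14) stop("solver failure: step size underflow (negative density?); reduce tolerance")
        dt <- h * max(0.1, 0.9 * max(err, 1)^(-0.2))
        if (!all(q5 > 0) || !is.finite(err)) dt <- h / 2
      }
    }
    out[i, ] <- q
  }
  out
}
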