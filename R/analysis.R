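#' Relaxation spectrum of the linearised spring chain
#'
#' Eigenvalues of the dimensionless coupling matrix of the linearised node
#' dynamics \eqn{\eta \, d\xi/dt = k B \xi} (second-difference stencil
#' \eqn{[1, -2, 1]}): with periodic boundaries (circulant \eqn{M \times M}
#' matrix) \eqn{\lambda_p = -2 + 2\cos(2\pi p/M)}, \eqn{p = 0, \dots, M-1},
#' whose zero mode is the evenly spaced steady state; with fixed boundaries
#' (tridiagonal \eqn{(M-1)\times(M-1)} matrix over interior nodes)
#' \eqn{\lambda_p = -2 + 2\cos(\pi p/M)}, \eqn{p = 1, \dots, M-1}, all
#' negative. Mode \eqn{p} decays at rate \eqn{(k/\eta)|\lambda_p|}.
#'
#' @param M number of springs (>= 2).
#' @param boundary \code{"periodic"} or \code{"fixed"}.
#' @return Numeric vector of eigenvalues (length \code{M} periodic,
#'   \code{M - 1} fixed).
#' @export
chain_eigenvalues <- function(M, boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  stopifnot(M >= 2)
  if (boundary == "periodic") {
    -2 + 2 * cos(2 * pi * (0:(M - 1)) / M)
  } else {
    -2 + 2 * cos(pi * (1:(M - 1)) / M)
  }
}

#' Coupling matrix of the linearised chain
#'
#' The matrix whose spectrum [chain_eigenvalues()] gives in closed form:
#' circulant with rows \eqn{[1, -2, 1]} (periodic) or Toeplitz tridiagonal
#' over the \eqn{M - 1} interior nodes (fixed). Used as the numerical oracle
#' for the closed-form spectrum.
#'
#' @inheritParams chain_eigenvalues
#' @return A numeric matrix.
#' @export
chain_matrix <- function(M, boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  stopifnot(M >= 2)
  n <- if (boundary == "periodic") M else M - 1L
  B <- diag(-2, n)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    B[cbind(idx, idx + 1L)] <- 1
    B[cbind(idx + 1L, idx)] <- 1
  }
  if (boundary == "periodic") {
    B[1L, n] <- B[1L, n] + 1
    B[n, 1L] <- B[n, 1L] + 1
  }
  B
}

#' Characteristic mechanical relaxation time
#'
#' Timescale of the slowest decaying mode in the many-spring limit:
#' \eqn{T_{relax} = \eta^* N^2 / (4 k^* \pi^2)} with periodic boundaries and
#' \eqn{\eta^* N^2 / (k^* \pi^2)} with fixed boundaries — four times slower,
#' because the slowest half-wave fits the open chain rather than a full wave.
#' Independent of the number of springs per cell under the cell-level
#' scalings.
#'
#' @param N number of cells.
#' @param k_star,eta_star cell-level stiffness and drag.
#' @param boundary \code{"periodic"} or \code{"fixed"}.
#' @return Relaxation time, time units.
#' @export
relaxation_time <- function(N, k_star = 1, eta_star = 1,
                            boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  stopifnot(N >= 2)
  base <- eta_star * N^2 / (k_star * pi^2)
  if (boundary == "periodic") base / 4 else base
}

#' Linear stability of the evenly spaced state
#'
#' The evenly spaced configuration is linearly stable iff the effective
#' stiffness \eqn{k = f'(L/M)} is positive (all three built-in laws), unstable
#' if negative (aggregating potentials), marginal at zero.
#'
#' @param law a \code{"force_law"}, or directly a numeric effective stiffness
#'   \eqn{f'(L/M)} for laws outside the built-in family.
#' @param L interface length.
#' @param M number of springs.
#' @return \code{"stable"}, \code{"unstable"} or \code{"marginal"}.
#' @export
stability_flag <- function(law, L, M) {
  k <- if (is.numeric(law)) law else effective_stiffness(law, L / M)
  if (k > 0) "stable" else if (k < 0) "unstable" else "marginal"
}

#' Discrete-to-continuum convergence order
#'
#' Empirically estimates how fast the discrete cell density converges to the
#' continuum PDE solution as the number of springs per cell grows. For each
#' \code{m}, the standard offset protocol (N cells on a closed loop of length
#' \eqn{2\pi}, one cell boundary displaced by half a resting cell length) is
#' simulated with curved springs under the cell-level scalings, and the error
#' \eqn{\max_i |q_i - q(s_{sample}, t)|} is measured against a fine-grid
#' continuum reference at the comparison time. Sampling the continuum field at
#' spring \emph{midpoints} gives second-order convergence \eqn{O(1/m^2)};
#' sampling at quarter-points degrades it to first order.
#'
#' The Euler step of the discrete runs is taken well below the accuracy
#' needed so time-stepping error does not pollute the spatial slope, and the
#' continuum reference uses a refined grid (default \code{J_ref = 4000}).
#'
#' @param m_values at least 3 spring counts, e.g. \code{c(2, 4, 8, 16)}.
#' @param sample \code{"midpoint"} or \code{"quarterpoint"}.
#' @param N number of cells (default 8).
#' @param kind force-law kind (default \code{"hookean"}).
#' @param k_star,eta_star cell-level parameters (default 1).
#' @param t_compare comparison time (default 0.05, mid-relaxation).
#' @param J_ref continuum reference grid intervals.
#' @param dt Euler step of the discrete runs.
#' @return A \code{"convergence_fit"}: list with \code{order} (least-squares
#'   slope of log error against log(1/m)), \code{errors}, \code{m_values},
#'   \code{sample}.
#' @export
convergence_order <- function(m_values, sample = c("midpoint", "quarterpoint"),
                              N = 8L, kind = "hookean", k_star = 1, eta_star = 1,
                              t_compare = 0.05, J_ref = 4000L, dt = 2e-5) {
  sample <- match.arg(sample)
  if (length(m_values) < 3L) stop("need at least 3 values of m")
  L <- 2 * pi
  a_star <- L / N
  ic1 <- initial_condition_offset(N, 1L, L, "periodic", 0.5)
  law1 <- force_law(kind, k_star = k_star, a_star = a_star, eta_star = eta_star, m = 1L)
  ref <- solve_pde(density_from_state(ic1, J = J_ref), law1, t_eval = t_compare,
                   rtol = 1e-10, atol = 1e-10)$fields[[1L]]

  errors <- vapply(m_values, function(m) {
    law <- force_law(kind, k_star = k_star, a_star = a_star,
                     eta_star = eta_star, m = as.integer(m))
    ic <- initial_condition_offset(N, as.integer(m), L, "periodic", 0.5)
    tr <- simulate_chain(ic, law, "curved", dt = dt, t_end = t_compare,
                         save_times = t_compare)
    st <- tr$states[[length(tr$states)]]
    q_i <- cell_density_discrete(st)
    s <- st$s
    lo <- c(s[st$M] - st$L, s[-st$M])
    frac <- if (sample == "midpoint") 0.5 else 0.25
    pts <- (lo + frac * (s - lo)) %% st$L
    q_ref <- stats::approx(ref$s, ref$q, xout = pts, rule = 2)$y
    max(abs(q_i - q_ref))
  }, numeric(1L))

  if (any(errors < 1e-9)) {
    warning("ill-conditioned fit: some errors are at the solver tolerance floor")
  }
  fit <- stats::lm.fit(cbind(1, log(1 / m_values)), log(errors))
  structure(list(order = unname(fit$coefficients[2L]), errors = errors,
                 m_values = m_values, sample = sample),
            class = "convergence_fit")
}

#' @export
print.convergence_fit <- function(x, ...) {
  cat(sprintf("Discrete-to-continuum convergence (%s sampling): order %.3f\n",
              x$sample, x$order))
  print(data.frame(m = x$m_values, max_error = signif(x$errors, 4)))
  invisible(x)
}
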