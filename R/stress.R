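#' Normalised tangential stress of a spring
#'
#' \eqn{\sigma_{\tau\tau}/E = -f(\ell)/(k a)}: compressive stress is positive,
#' tensile negative. The normalisation \eqn{k a = k^* a^*} is independent of
#' the number of springs per cell. For Hookean springs this is minus the
#' strain, e.g. a spring stretched 50\% has \eqn{\sigma_{\tau\tau}/E = -0.5}.
#'
#' @param law a \code{"force_law"}.
#' @param ell spring length(s), > 0.
#' @return Dimensionless stress \eqn{\sigma_{\tau\tau}/E}.
#' @export
tangential_stress <- function(law, ell) {
  -spring_force(law, ell) / (law$k_star * law$a_star)
}

#' Normalised tangential stress at a cell density
#'
#' Continuum form of [tangential_stress()], exact at every finite \code{m}
#' under the cell-level scalings: Hookean \eqn{1 - 1/(q a^*)}; inverse-density
#' \eqn{a^* q - 1}; inverse-density-squared \eqn{-(1 - (a^* q)^2)/2}.
#'
#' @param law a \code{"force_law"}.
#' @param q cell density (cells/length), > 0.
#' @return Dimensionless stress \eqn{\sigma_{\tau\tau}/E}.
#' @export
tangential_stress_density <- function(law, q) {
  if (any(q <= 0)) stop("cell density must be positive")
  a <- law$a_star
  switch(law$kind,
    hookean = 1 - 1 / (q * a),
    inverse_density = a * q - 1,
    inverse_density_sq = -(1 - (a * q)^2) / 2)
}

#' Surface tension of the cell layer
#'
#' \eqn{\gamma(s, t) = \tilde f(\rho)/w}: the tangential spring force per unit
#' out-of-plane width \code{w}. Positive (true tension) where springs are
#' stretched (\eqn{\rho < 1/a}).
#'
#' @param law a \code{"force_law"}.
#' @param rho spring density (springs/length), > 0.
#' @param w out-of-plane cell width, > 0.
#' @return Surface tension, units force/length.
#' @export
surface_tension <- function(law, rho, w) {
  if (w <= 0) stop("width w must be positive")
  density_force(law, rho) / w
}

#' Curvature-induced normal stress of a discrete chain state
#'
#' On curved substrate regions the tangential spring tension induces a normal
#' substrate reaction, as in the Young-Laplace law \eqn{\sigma_{nn} = \gamma
#' \kappa}. Normalised by Young's modulus and layer height,
#' \eqn{\sigma_{nn}/(Eh) = \kappa(s) f(\ell_i)/(k a) =
#' -\kappa(s)\,\sigma_{\tau\tau}/E}, reported as a piecewise profile over each
#' spring's arc interval with the continuous curvature sampled at
#' \code{points_per_spring} locations. It vanishes wherever the curvature is
#' zero or the springs are at rest, and is compressive (positive) on convex
#' regions carrying stretched cells.
#'
#' @param state a \code{"spring_chain_state"}.
#' @param curve an \code{"arclength_curve"}.
#' @param law a \code{"force_law"}.
#' @param points_per_spring curvature samples per spring (default 20).
#' @return A data frame with columns \code{s}, \code{spring}, \code{kappa},
#'   \code{sigma_tt_over_E}, \code{sigma_nn_over_Eh}.
#' @export
normal_stress_discrete <- function(state, curve, law, points_per_spring = 20L) {
  ell <- spring_lengths(state)
  stt <- tangential_stress(law, ell)
  s <- state$s
  if (state$boundary == "fixed") {
    lo <- s[-length(s)]; hi <- s[-1L]
  } else {
    lo <- c(s[state$M] - state$L, s[-state$M])  # seam spring first
    hi <- s
  }
  out <- lapply(seq_along(ell), function(i) {
    ss <- seq(lo[i], hi[i], length.out = points_per_spring)
    kap <- curve$curvature(if (state$boundary == "periodic") ss %% state$L else ss)
    data.frame(s = if (state$boundary == "periodic") ss %% state$L else ss,
               spring = i, kappa = kap,
               sigma_tt_over_E = stt[i],
               sigma_nn_over_Eh = -kap * stt[i])
  })
  do.call(rbind, out)
}

#' Curvature-induced normal stress of a continuum density field
#'
#' Grid-point profile \eqn{\sigma_{nn}(s)/(Eh) = -\kappa(s)\,
#' \sigma_{\tau\tau}(q(s))/E}; see [normal_stress_discrete()].
#'
#' @param field a \code{"density_field"}.
#' @param curve an \code{"arclength_curve"} of matching length.
#' @param law a \code{"force_law"}.
#' @return A data frame with columns \code{s}, \code{q}, \code{kappa},
#'   \code{sigma_tt_over_E}, \code{sigma_nn_over_Eh}.
#' @export
normal_stress_continuum <- function(field, curve, law) {
  if (abs(field$L - curve$L) > 1e-6 * field$L) {
    stop("field and curve lengths disagree")
  }
  stt <- tangential_stress_density(law, field$q)
  kap <- curve$curvature(field$s)
  data.frame(s = field$s, q = field$q, kappa = kap,
             sigma_tt_over_E = stt, sigma_nn_over_Eh = -kap * stt)
}
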