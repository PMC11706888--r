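#' Spring restoring-force laws
#'
#' A force law describes the signed restoring force \eqn{f(\ell)} of one spring
#' of length \eqn{\ell}: positive when elongated, negative when compressed,
#' zero at the rest length \eqn{a}. Three laws are supported, all sharing the
#' same linearisation \eqn{f(\ell) \approx k(\ell - a)} about the rest length:
#' \describe{
#'   \item{\code{hookean}}{\eqn{f(\ell) = k(\ell - a)}; continuum limit is
#'     fast diffusion \eqn{D(q) = (k^*/\eta^*) q^{-2}}.}
#'   \item{\code{inverse_density}}{\eqn{f(\ell) = k a^2 (1/a - 1/\ell)};
#'     diverges on compression, saturates at \eqn{ka} on extension; continuum
#'     limit is linear diffusion with \eqn{D_0 = k^* (a^*)^2/\eta^*}.}
#'   \item{\code{inverse_density_sq}}{\eqn{f(\ell) = (k a^3/2)(1/a^2 -
#'     1/\ell^2)}; continuum limit is porous-medium (Boussinesq) diffusion
#'     \eqn{D(q) = D_0^* q} with \eqn{D_0^* = k^* (a^*)^3/\eta^*}.}
#' }
#'
#' Parameters are stored at cell level (\code{k_star}, \code{a_star},
#' \code{eta_star}): the stiffness, rest length and drag of a whole cell made
#' of \code{m} springs in series. Spring-level values follow the scalings
#' \eqn{a = a^*/m}, \eqn{k = k^* m}, \eqn{\eta = \eta^*/m}, which keep the
#' collective dynamics independent of \code{m}. Spring-level input is accepted
#' via \code{k}, \code{a}, \code{eta} and converted.
#'
#' @param kind one of \code{"hookean"}, \code{"inverse_density"},
#'   \code{"inverse_density_sq"}.
#' @param k_star,a_star,eta_star cell-level stiffness (force/length), rest
#'   length (length) and drag (force·time/length). All positive.
#' @param m springs per cell (positive integer).
#' @param k,a,eta alternative spring-level parametrisation; converted to cell
#'   level using \code{m}.
#' @return An object of class \code{"force_law"}.
#' @examples
#' law <- force_law("hookean", k_star = 1, a_star = 2 * pi / 8, eta_star = 1)
#' spring_force(law, 2 * pi / 8)  # zero at rest length
#' diffusivity(law, 8 / (2 * pi)) # fast diffusion k*/(eta* q^2)
#' @export
force_law <- function(kind = c("hookean", "inverse_density", "inverse_density_sq"),
                      k_star = NULL, a_star = NULL, eta_star = NULL, m = 1L,
                      k = NULL, a = NULL, eta = NULL) {
  kind <- match.arg(kind)
  m <- as.integer(m)
  if (m < 1L) stop("m must be a positive integer")
  if (is.null(k_star)) k_star <- if (!is.null(k)) k / m else 1
  if (is.null(a_star)) {
    if (is.null(a)) stop("a rest length is required (a_star or a)")
    a_star <- a * m
  }
  if (is.null(eta_star)) eta_star <- if (!is.null(eta)) eta * m else 1
  if (k_star <= 0 || a_star <= 0 || eta_star <= 0) {
    stop("force-law parameters k_star, a_star, eta_star must be strictly positive")
  }
  structure(list(kind = kind, k_star = k_star, a_star = a_star,
                 eta_star = eta_star, m = m,
                 # scale-factor limits: alpha* = lim m alpha^(m), beta* = lim m^2 beta^(m)
                 alpha_star = k_star * a_star^2,
                 beta_star = k_star * a_star^3 / 2),
            class = "force_law")
}

#' @export
print.force_law <- function(x, ...) {
  sp <- scale_parameters(x$a_star, x$k_star, x$eta_star, x$m)
  cat(sprintf("Force law '%s': cell level k*=%g, a*=%g, eta*=%g; m=%d springs/cell",
              x$kind, x$k_star, x$a_star, x$eta_star, x$m),
      sprintf("\n  spring level k=%g, a=%g, eta=%g\n", sp$k, sp$a, sp$eta))
  invisible(x)
}

#' Cell-to-spring parameter scalings
#'
#' Maps cell-level mechanical parameters to the parameters of each of the
#' \code{m} springs making up the cell: \eqn{a = a^*/m} (springs shrink),
#' \eqn{k = k^* m} (stiffness of springs in series), \eqn{\eta = \eta^*/m}
#' (constant total drag per cell). These scalings make the chain dynamics
#' converge as \eqn{m \to \infty} and give \eqn{k/\eta = O(m^2)}.
#'
#' @param a_star,k_star,eta_star cell-level parameters.
#' @param m springs per cell.
#' @return list with elements \code{a}, \code{k}, \code{eta}.
#' @export
scale_parameters <- function(a_star, k_star, eta_star, m) {
  stopifnot(m >= 1)
  list(a = a_star / m, k = k_star * m, eta = eta_star / m)
}

#' Re-scale a force law to a different number of springs per cell
#' @param law a \code{"force_law"}.
#' @param m new springs-per-cell count.
#' @return A \code{"force_law"} with the same cell-level parameters.
#' @export
with_m <- function(law, m) {
  force_law(law$kind, k_star = law$k_star, a_star = law$a_star,
            eta_star = law$eta_star, m = m)
}

# spring-level parameters of a law
.spring_params <- function(law) {
  scale_parameters(law$a_star, law$k_star, law$eta_star, law$m)
}

#' Spring restoring force f(ell)
#'
#' @param law a \code{"force_law"}.
#' @param ell spring length(s), > 0.
#' @return Signed force: positive when elongated (\code{ell > a}), negative
#'   when compressed.
#' @export
spring_force <- function(law, ell) {
  stopifnot(inherits(law, "force_law"))
  if (any(ell <= 0)) stop("collapsed spring: non-positive length")
  p <- .spring_params(law)
  switch(law$kind,
    hookean = p$k * (ell - p$a),
    inverse_density = p$k * p$a^2 * (1 / p$a - 1 / ell),
    inverse_density_sq = p$k * p$a^3 / 2 * (1 / p$a^2 - 1 / ell^2))
}

#' Derivative f'(ell) of the restoring force
#' @inheritParams spring_force
#' @return \eqn{df/d\ell} at \code{ell}; equals \code{k} at the rest length for
#'   all three laws.
#' @export
spring_force_deriv <- function(law, ell) {
  stopifnot(inherits(law, "force_law"))
  if (any(ell <= 0)) stop("collapsed spring: non-positive length")
  p <- .spring_params(law)
  switch(law$kind,
    hookean = rep(p$k, length(ell)),
    inverse_density = p$k * p$a^2 / ell^2,
    inverse_density_sq = p$k * p$a^3 / ell^3)
}

#' Restoring force as a function of spring density
#'
#' \eqn{\tilde f(\rho) = f(1/\rho)} where \eqn{\rho} is the local spring
#' density (springs per unit length).
#' @param law a \code{"force_law"}.
#' @param rho spring density, > 0.
#' @export
density_force <- function(law, rho) {
  if (any(rho <= 0)) stop("spring density must be positive")
  spring_force(law, 1 / rho)
}

#' Cell-level flux potential F(q)
#'
#' The continuum limit \eqn{F(q) = \lim_{m\to\infty} \tilde f(mq)/(\eta m)} of
#' the scaled restoring force as a function of cell density \eqn{q}. With the
#' cell-level scalings the limit is attained exactly at every finite \code{m}.
#' \eqn{F(1/a^*) = 0} for all laws: the resting cell density is stress-free.
#' The continuum cell-density flux is \eqn{-\partial F(q)/\partial s}.
#'
#' @param law a \code{"force_law"}.
#' @param q cell density (cells/length), > 0.
#' @return \eqn{F(q)}, units length^2/time.
#' @export
cell_force_limit <- function(law, q) {
  stopifnot(inherits(law, "force_law"))
  if (any(q <= 0)) stop("cell density must be positive")
  q0 <- 1 / law$a_star
  switch(law$kind,
    hookean = (law$k_star / law$eta_star) * (1 / q - law$a_star),
    inverse_density = {
      D0 <- law$alpha_star / law$eta_star
      D0 * (q0 - q)
    },
    inverse_density_sq = {
      D0s <- 2 * law$beta_star / law$eta_star
      (D0s / 2) * (q0^2 - q^2)
    })
}

#' Continuum diffusivity D(q)
#'
#' \eqn{D(q) = -dF/dq}: fast diffusion \eqn{(k^*/\eta^*) q^{-2}} for the
#' Hookean law, constant \eqn{D_0 = k^*(a^*)^2/\eta^*} for the inverse-density
#' law, and porous-medium \eqn{D_0^* q} with \eqn{D_0^* = k^*(a^*)^3/\eta^*}
#' for the inverse-density-squared law. Positive for all three laws.
#'
#' @param law a \code{"force_law"}.
#' @param q cell density (cells/length), > 0.
#' @return Diffusivity, units length^2/time.
#' @export
diffusivity <- function(law, q) {
  stopifnot(inherits(law, "force_law"))
  if (any(q <= 0)) stop("cell density must be positive")
  switch(law$kind,
    hookean = (law$k_star / law$eta_star) / q^2,
    inverse_density = rep(law$alpha_star / law$eta_star, length(q)),
    inverse_density_sq = (2 * law$beta_star / law$eta_star) * q)
}

#' Effective stiffness about an evenly spaced state
#'
#' The linearised stiffness \eqn{k = f'(L/M)} of the chain about the steady
#' state with uniform spring length \code{mean_spacing}. Its sign decides the
#' linear stability of the evenly spaced configuration: positive means stable.
#'
#' @param law a \code{"force_law"}.
#' @param mean_spacing uniform spring length \eqn{L/M}, > 0.
#' @return \eqn{f'(L/M)}, units force/length.
#' @export
effective_stiffness <- function(law, mean_spacing) {
  spring_force_deriv(law, mean_spacing)
}
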