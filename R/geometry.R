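#' Planar parametric curve
#'
#' Constructs a smooth planar curve \eqn{u \mapsto (x(u), y(u))} on a parameter
#' interval, together with its first and second derivatives. The curve is the
#' substrate ("interface") along which cell chains are simulated; it must be
#' regular (non-vanishing speed) so that a unit tangent exists everywhere.
#'
#' Derivative functions may be omitted, in which case they are approximated by
#' central finite differences. All functions must be vectorised over \code{u}
#' and return a 2-column matrix (or a length-2 vector for scalar input).
#'
#' @param position function \code{u -> cbind(x, y)}.
#' @param derivative optional function \code{u -> cbind(x', y')}.
#' @param second_derivative optional function \code{u -> cbind(x'', y'')}.
#' @param u_range numeric length-2, the parameter interval \code{c(u_lo, u_hi)}.
#' @param closed logical; if \code{TRUE} the curve is a closed loop and
#'   \code{position(u_lo)} must equal \code{position(u_hi)}.
#' @param n_check number of sample points used to verify regularity.
#' @return An object of class \code{"parametric_curve"}.
#' @seealso [builtin_curve()], [arc_length_curve()], [curvature()]
#' @export
parametric_curve <- function(position, derivative = NULL, second_derivative = NULL,
                             u_range, closed = FALSE, n_check = 200L) {
  stopifnot(is.function(position), is.numeric(u_range), length(u_range) == 2L,
            u_range[2] > u_range[1])
  pos <- function(u) {
    p <- position(u)
    if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
    p
  }
  h <- (u_range[2] - u_range[1]) * 1e-6
  d1 <- if (is.null(derivative)) {
    function(u) (pos(u + h) - pos(u - h)) / (2 * h)
  } else {
    function(u) {
      p <- derivative(u)
      if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
      p
    }
  }
  d2 <- if (is.null(second_derivative)) {
    function(u) (pos(u + h) - 2 * pos(u) + pos(u - h)) / h^2
  } else {
    function(u) {
      p <- second_derivative(u)
      if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
      p
    }
  }
  uu <- seq(u_range[1], u_range[2], length.out = n_check)
  dv <- d1(uu)
  if (any(!is.finite(dv))) {
    stop("invalid curve: non-finite derivative values on the parameter interval")
  }
  spd <- sqrt(rowSums(dv^2))
  if (any(spd <= 1e-12)) {
    stop("invalid curve: the parametrisation is not regular (vanishing speed at u = ",
         format(uu[which.min(spd)]), ")")
  }
  if (closed) {
    gap <- sqrt(sum((pos(u_range[1]) - pos(u_range[2]))^2))
    if (gap > 1e-8 * diff(u_range)) {
      stop("closed curve does not close: |r(u_lo) - r(u_hi)| = ", format(gap))
    }
  }
  structure(list(position = pos, d1 = d1, d2 = d2,
                 u_lo = u_range[1], u_hi = u_range[2], closed = closed),
            class = "parametric_curve")
}

#' @export
print.parametric_curve <- function(x, ...) {
  cat(sprintf("Planar parametric curve (%s), u in [%g, %g]\n",
              if (x$closed) "closed" else "open", x$u_lo, x$u_hi))
  invisible(x)
}

#' Built-in substrate curves
#'
#' Curves used throughout the package's examples and tests:
#' \describe{
#'   \item{\code{circle}}{counter-clockwise circle of radius \code{R}, closed.}
#'   \item{\code{sinusoid}}{graph \eqn{(u, R\sin u)} on \eqn{[0, 2\pi]}, open.}
#'   \item{\code{polar_cross}}{four-lobed closed curve with polar radius
#'     \eqn{R(\theta) = R_0(\cos^4\theta + \sin^4\theta)}.}
#'   \item{\code{polar_generic}}{closed polar curve \eqn{R(\theta)} supplied as
#'     an arithmetic expression string in \code{theta} (see [polar_curve()]).}
#' }
#'
#' @param name one of \code{"circle"}, \code{"sinusoid"}, \code{"polar_cross"},
#'   \code{"polar_generic"}.
#' @param R radius (circle) or amplitude (sinusoid). Default 1 and 0.8.
#' @param R0 scale of the polar cross. Default 1.
#' @param expr polar-radius expression string for \code{polar_generic},
#'   e.g. \code{"1 + 0.2*cos(3*theta)"}.
#' @return A \code{"parametric_curve"}.
#' @export
builtin_curve <- function(name = c("circle", "sinusoid", "polar_cross", "polar_generic"),
                          R = NULL, R0 = 1, expr = NULL) {
  name <- match.arg(name)
  switch(name,
    circle = circle_curve(if (is.null(R)) 1 else R),
    sinusoid = sinusoid_curve(if (is.null(R)) 0.8 else R),
    polar_cross = polar_cross_curve(R0),
    polar_generic = {
      if (is.null(expr)) stop("polar_generic requires an 'expr' string for R(theta)")
      polar_curve(expr)
    })
}

#' @rdname builtin_curve
#' @export
circle_curve <- function(R = 1) {
  if (!is.numeric(R) || R <= 0) stop("circle requires R > 0")
  parametric_curve(
    position = function(u) cbind(R * cos(u), R * sin(u)),
    derivative = function(u) cbind(-R * sin(u), R * cos(u)),
    second_derivative = function(u) cbind(-R * cos(u), -R * sin(u)),
    u_range = c(0, 2 * pi), closed = TRUE)
}

#' @rdname builtin_curve
#' @export
sinusoid_curve <- function(R = 0.8) {
  parametric_curve(
    position = function(u) cbind(u, R * sin(u)),
    derivative = function(u) cbind(rep(1, length(u)), R * cos(u)),
    second_derivative = function(u) cbind(rep(0, length(u)), -R * sin(u)),
    u_range = c(0, 2 * pi), closed = FALSE)
}

#' @rdname builtin_curve
#' @export
polar_cross_curve <- function(R0 = 1) {
  if (!is.numeric(R0) || R0 <= 0) stop("polar_cross requires R0 > 0")
  # cos^4 + sin^4 = 3/4 + cos(4 theta)/4
  polar_curve(r = function(th) R0 * (0.75 + 0.25 * cos(4 * th)),
              rp = function(th) -R0 * sin(4 * th),
              rpp = function(th) -4 * R0 * cos(4 * th))
}

#' Closed polar curve R(theta)
#'
#' Builds a closed curve \eqn{(R(\theta)\cos\theta, R(\theta)\sin\theta)} for
#' \eqn{\theta \in [0, 2\pi]}. The radius may be given as vectorised functions
#' (with optional analytic derivatives) or as an arithmetic expression string
#' in \code{theta}, which is differentiated symbolically where possible and by
#' central differences otherwise. The expression is evaluated in a restricted
#' environment exposing only arithmetic and standard mathematical functions.
#'
#' @param r radius: a function of \code{theta} or an expression string.
#' @param rp,rpp optional first/second derivative functions of the radius.
#' @return A \code{"parametric_curve"} (closed).
#' @export
polar_curve <- function(r, rp = NULL, rpp = NULL) {
  if (is.character(r)) {
    e <- str2lang(r)
    safe <- c("+", "-", "*", "/", "^", "(", "sin", "cos", "tan", "exp", "log",
              "sqrt", "abs", "pi", "theta")
    vars <- all.names(e, unique = TRUE)
    bad <- setdiff(vars, safe)
    if (length(bad)) stop("disallowed symbols in polar expression: ",
                          paste(bad, collapse = ", "))
    env <- new.env(parent = baseenv())
    rfun <- function(th) eval(e, list(theta = th), env)
    dpe <- tryCatch(stats::D(e, "theta"), error = function(err) NULL)
    if (!is.null(dpe)) {
      rpfun <- function(th) eval(dpe, list(theta = th), env) + 0 * th
      dppe <- tryCatch(stats::D(dpe, "theta"), error = function(err) NULL)
      rppfun <- if (!is.null(dppe)) {
        function(th) eval(dppe, list(theta = th), env) + 0 * th
      } else NULL
    } else {
      rpfun <- NULL
      rppfun <- NULL
    }
    return(polar_curve(rfun, rpfun, rppfun))
  }
  stopifnot(is.function(r))
  h <- 2 * pi * 1e-6
  if (is.null(rp)) rp <- function(th) (r(th + h) - r(th - h)) / (2 * h)
  if (is.null(rpp)) rpp <- function(th) (r(th + h) - 2 * r(th) + r(th - h)) / h^2
  parametric_curve(
    position = function(u) cbind(r(u) * cos(u), r(u) * sin(u)),
    derivative = function(u) {
      R <- r(u); Rp <- rp(u)
      cbind(Rp * cos(u) - R * sin(u), Rp * sin(u) + R * cos(u))
    },
    second_derivative = function(u) {
      R <- r(u); Rp <- rp(u); Rpp <- rpp(u)
      cbind(Rpp * cos(u) - 2 * Rp * sin(u) - R * cos(u),
            Rpp * sin(u) + 2 * Rp * cos(u) - R * sin(u))
    },
    u_range = c(0, 2 * pi), closed = TRUE)
}

# cached cumulative arc-length table: composite Simpson's 1/3 rule on each of
# n_panels grid intervals (midpoint-refined), giving s at every grid node
.arc_table <- function(curve, n_panels = 10000L) {
  u <- seq(curve$u_lo, curve$u_hi, length.out = n_panels + 1L)
  h <- u[2L] - u[1L]
  spd <- function(t) sqrt(rowSums(curve$d1(t)^2))
  v <- spd(u)
  vm <- spd(u[-length(u)] + h / 2)
  ds <- (h / 6) * (v[-length(v)] + 4 * vm + v[-1L])
  list(u = u, s = c(0, cumsum(ds)), h = h, speed = spd)
}

.curve_table <- function(curve, n_panels = 10000L) {
  tab <- attr(curve, "arc_table")
  if (is.null(tab) || length(tab$u) != n_panels + 1L) tab <- .arc_table(curve, n_panels)
  tab
}

#' Cumulative arc length of a parametric curve
#'
#' Computes \eqn{s(u) = \int_{u_{lo}}^{u} \lVert r'(v) \rVert \, dv} by the
#' composite Simpson 1/3 rule on a cached fine grid (10,001 parameter samples
#' by default), with a final Simpson panel from the nearest grid node to
#' \code{u}. Monotone non-decreasing in \code{u}.
#'
#' @param curve a \code{"parametric_curve"}.
#' @param u parameter value(s) in the curve's interval.
#' @return Arc length(s) from the start of the curve, in curve length units.
#' @export
cumulative_arc_length <- function(curve, u) {
  stopifnot(inherits(curve, "parametric_curve"))
  tab <- .curve_table(curve)
  eps <- 1e-12 * (curve$u_hi - curve$u_lo)
  if (any(u < curve$u_lo - eps | u > curve$u_hi + eps)) {
    stop("parameter u outside the curve interval [",
         format(curve$u_lo), ", ", format(curve$u_hi), "]")
  }
  u <- pmin(pmax(u, curve$u_lo), curve$u_hi)
  j <- pmin(pmax(findInterval(u, tab$u), 1L), length(tab$u) - 1L)
  u0 <- tab$u[j]
  d <- u - u0
  v0 <- tab$speed(u0)
  vm <- tab$speed(u0 + d / 2)
  v1 <- tab$speed(u)
  tab$s[j] + (d / 6) * (v0 + 4 * vm + v1)
}

#' Total length of a parametric curve
#' @param curve a \code{"parametric_curve"}.
#' @return The curve length \eqn{L}.
#' @export
curve_length <- function(curve) {
  tab <- .curve_table(curve)
  tab$s[length(tab$s)]
}

#' Invert the arc-length map
#'
#' Finds the parameter \code{u} such that \code{cumulative_arc_length(curve, u)
#' == s}, by bracketed lookup in the cached Simpson table followed by safeguarded
#' Newton iteration (tolerance 1e-12 in \code{u}). On a closed curve \code{s}
#' is taken modulo the total length; on an open curve values outside
#' \eqn{[0, L]} are an error.
#'
#' @param curve a \code{"parametric_curve"}.
#' @param s arc length value(s).
#' @return Parameter value(s) \code{u}.
#' @export
invert_arc_length <- function(curve, s) {
  stopifnot(inherits(curve, "parametric_curve"))
  tab <- .curve_table(curve)
  L <- tab$s[length(tab$s)]
  if (curve$closed) {
    s <- s %% L
  } else if (any(s < -1e-9 * L | s > L * (1 + 1e-9))) {
    stop("arc length s outside [0, L] on an open curve (L = ", format(L), ")")
  }
  s <- pmin(pmax(s, 0), L)
  j <- pmin(pmax(findInterval(s, tab$s), 1L), length(tab$s) - 1L)
  # linear interpolation start, then Newton on s(u) - s with analytic slope
  u <- tab$u[j] + (s - tab$s[j]) / pmax(tab$s[j + 1L] - tab$s[j], 1e-300) * tab$h
  lo <- tab$u[j]
  hi <- tab$u[j + 1L]
  for (iter in 1:6) {
    res <- cumulative_arc_length(curve, u) - s
    u_new <- u - res / tab$speed(u)
    u <- pmin(pmax(u_new, lo), hi)
    if (max(abs(res)) < 1e-13 * max(L, 1)) break
  }
  u
}

#' Signed curvature of a parametric curve
#'
#' Evaluates \deqn{\kappa(u) = \frac{y''x' - x''y'}{\left[(x')^2 +
#' (y')^2\right]^{3/2}},} positive where the substrate is convex (e.g. a
#' counter-clockwise circle has \eqn{\kappa = 1/R}) and negative where it is
#' concave. With the package's normal convention (\code{n} is the tangent
#' rotated by \eqn{-\pi/2}, outward on counter-clockwise loops) the Frenet-type
#' relation \eqn{\tau'(s) = -\kappa n} holds.
#'
#' @param curve a \code{"parametric_curve"}.
#' @param u parameter value(s).
#' @return Signed curvature(s), units 1/length.
#' @export
curvature <- function(curve, u) {
  stopifnot(inherits(curve, "parametric_curve"))
  d1 <- curve$d1(u)
  d2 <- curve$d2(u)
  spd2 <- rowSums(d1^2)
  if (any(spd2 <= 1e-24)) stop("singular point: vanishing speed")
  (d2[, 2L] * d1[, 1L] - d2[, 1L] * d1[, 2L]) / spd2^1.5
}

#' Arc-length parametrisation of a curve
#'
#' Reparametrises a \code{"parametric_curve"} by arc length, returning an
#' object queryable at any \eqn{s \in [0, L]} for position, unit tangent,
#' outward normal and signed curvature. On closed curves all queries wrap
#' \code{s} modulo \code{L}.
#'
#' @param curve a \code{"parametric_curve"}.
#' @param n_panels Simpson panels for the cached cumulative table.
#' @return An object of class \code{"arclength_curve"} with fields
#'   \code{L}, \code{closed}, and vectorised functions \code{position(s)},
#'   \code{tangent(s)}, \code{normal(s)}, \code{curvature(s)}, \code{u_of_s(s)}.
#' @examples
#' circ <- arc_length_curve(circle_curve(2))
#' circ$position(pi)          # quarter turn: (0, 2)
#' circ$curvature(1)          # 1/R = 0.5
#' @export
arc_length_curve <- function(curve, n_panels = 10000L) {
  stopifnot(inherits(curve, "parametric_curve"))
  tab <- .curve_table(curve, n_panels)
  attr(curve, "arc_table") <- tab
  L <- tab$s[length(tab$s)]
  u_of_s <- function(s) invert_arc_length(curve, s)
  obj <- list(
    L = L,
    closed = curve$closed,
    base = curve,
    u_of_s = u_of_s,
    position = function(s) curve$position(u_of_s(s)),
    tangent = function(s) {
      d <- curve$d1(u_of_s(s))
      d / sqrt(rowSums(d^2))
    },
    normal = function(s) {
      d <- curve$d1(u_of_s(s))
      d <- d / sqrt(rowSums(d^2))
      cbind(d[, 2L], -d[, 1L])  # tangent rotated by -pi/2
    },
    curvature = function(s) curvature(curve, u_of_s(s)))
  class(obj) <- "arclength_curve"
  obj
}

#' @export
print.arclength_curve <- function(x, ...) {
  cat(sprintf("Arc-length curve (%s), total length L = %.6g\n",
              if (x$closed) "closed" else "open", x$L))
  invisible(x)
}
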