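# shared fixtures: curves are cheap to build but reused across many tests
unit_circle <- arc_length_curve(circle_curve(1))
std_sinusoid <- arc_length_curve(sinusoid_curve(0.8))
std_cross <- arc_length_curve(polar_cross_curve(1))

# a straight horizontal segment of length 10, as a degenerate "curve"
flat_line <- arc_length_curve(parametric_curve(
  position = function(u) cbind(u, 0 * u),
  derivative = function(u) cbind(rep(1, length(u)), rep(0, length(u))),
  second_derivative = function(u) cbind(rep(0, length(u)), rep(0, length(u))),
  u_range = c(0, 10)))

hookean_cell <- function(N = 8, L = 2 * pi, m = 1L, k_star = 1, eta_star = 1) {
  force_law("hookean", k_star = k_star, a_star = L / N, eta_star = eta_star, m = m)
}

all_law_kinds <- c("hookean", "inverse_density", "inverse_density_sq")
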