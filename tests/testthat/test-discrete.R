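test_that("chain states validate ordering, boundaries and lengths", {
  expect_error(spring_chain_state(c(0, 0.6, 0.5, 1), 1, 3, 1, "fixed"),
               "non-positive")
  expect_error(spring_chain_state(c(0.1, 0.5, 1), 1, 2, 1, "fixed"), "s = 0")
  expect_error(spring_chain_state(c(0, 2, 5), 2 * pi, 4, 1, "periodic"), "M = 4")
  st <- spring_chain_state(c(0, 1, 2.5, 4), 2 * pi, 4, 1, "periodic")
  ell <- spring_lengths(st)
  expect_equal(ell, c(2 * pi - 4, 1, 1.5, 1.5))  # seam spring first
  expect_equal(sum(ell), 2 * pi)

  # chord <= arc always; equal on a flat interface
  stc <- spring_chain_state(c(0, pi / 2, pi, 3 * pi / 2), 2 * pi, 4, 1, "periodic")
  expect_equal(spring_lengths(stc, "straight", unit_circle), rep(sqrt(2), 4),
               tolerance = 1e-8)
  expect_true(all(spring_lengths(stc, "straight", unit_circle) <=
                    spring_lengths(stc, "curved")))
  stf <- spring_chain_state(c(0, 3, 7, 10), 10, 3, 1, "fixed")
  expect_equal(spring_lengths(stf, "straight", flat_line),
               spring_lengths(stf, "curved"), tolerance = 1e-9)

  # uniform density equals N/L
  u <- initial_condition_offset(4, 4, 2 * pi, "periodic", 0)
  expect_equal(cell_density_discrete(u), rep(4 / (2 * pi), 16))
})

test_that("curved-spring velocities match hand-computed cases", {
  law <- hookean_cell(N = 2, L = 1, m = 1)  # k* = 1, a* = 0.5
  st <- spring_chain_state(c(0, 0.25, 1), 1, 2, 1, "fixed")
  v <- rhs_curved(st, law)
  expect_equal(v, c(0, 1 * (1 - 2 * 0.25), 0))  # eta ds/dt = k (L - 2 s1)

  # evenly spaced: zero velocity for every law
  for (kind in all_law_kinds) {
    lawk <- force_law(kind, k_star = 1, a_star = 2 * pi / 8, eta_star = 1)
    u <- initial_condition_offset(8, 1, 2 * pi, "periodic", 0)
    expect_equal(rhs_curved(u, lawk), rep(0, 8), tolerance = 1e-13)
  }

  # periodic pair: equal and opposite velocities (action-reaction around the loop)
  st2 <- spring_chain_state(c(0.2, 2.2), 2 * pi, 2, 1, "periodic")
  v2 <- rhs_curved(st2, hookean_cell(N = 2))
  expect_equal(v2[1], -v2[2])
  # total drift vanishes on any closed loop (telescoping)
  st3 <- spring_chain_state(c(0, 0.8, 2.9, 4.4), 2 * pi, 4, 1, "periodic")
  expect_equal(sum(rhs_curved(st3, hookean_cell(N = 4))), 0, tolerance = 1e-14)
})

test_that("straight-spring velocities project chords onto tangents", {
  law <- hookean_cell(N = 4)
  # flat interface: straight and curved dynamics coincide exactly
  stf <- spring_chain_state(c(0, 2, 4.5, 6.5, 10), 10, 4, 1, "fixed")
  lawf <- force_law("hookean", k_star = 1, a_star = 10 / 4, eta_star = 1)
  expect_equal(rhs_straight(stf, flat_line, lawf), rhs_curved(stf, lawf),
               tolerance = 1e-9)
  # evenly spaced nodes on the circle: zero by rotational symmetry
  stc <- spring_chain_state(c(0, pi / 2, pi, 3 * pi / 2), 2 * pi, 4, 1, "periodic")
  laws <- force_law("hookean", k_star = 1, a_star = sqrt(2), eta_star = 1)
  expect_equal(rhs_straight(stc, unit_circle, laws), rep(0, 4), tolerance = 1e-9)
})

test_that("straight-spring forces and trajectories converge to curved ones as O(1/m^2)", {
  # per-node force imbalance between the two models (the velocities carry an
  # extra factor m through the drag scaling eta = eta*/m)
  ms <- c(2, 4, 8, 16, 32)
  errs <- sapply(ms, function(m) {
    law <- hookean_cell(N = 4, m = m)
    st <- initial_condition_offset(4, m, 2 * pi, "periodic", 0.5)
    (1 / m) * max(abs(rhs_straight(st, unit_circle, law) - rhs_curved(st, law)))
  })
  slope <- unname(lm.fit(cbind(1, log(1 / ms)), log(errs))$coefficients[2])
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)

  # max-over-time node discrepancy between full trajectories, each model with
  # its own stress-free rest length
  ms2 <- c(2, 4, 8, 16)
  tsave <- seq(0.05, 1, by = 0.05)
  terr <- sapply(ms2, function(m) {
    lc <- force_law("hookean", k_star = 1, a_star = 2 * pi / 4, eta_star = 1, m = m)
    ic <- initial_condition_offset(4, m, 2 * pi, "periodic", 0.5)
    trc <- simulate_chain(ic, lc, "curved", t_end = 1, save_times = tsave)
    a_s <- rest_length_stress_free(unit_circle, 4 * m, "straight")
    ls <- force_law("hookean", k_star = 1, a_star = a_s * m, eta_star = 1, m = m)
    trs <- simulate_chain(ic, ls, "straight", curve = unit_circle, t_end = 1,
                          save_times = tsave)
    max(sapply(seq_along(tsave), function(i) {
      max(abs(trc$states[[i]]$s - trs$states[[i]]$s))
    }))
  })
  tslope <- unname(lm.fit(cbind(1, log(1 / ms2)), log(terr))$coefficients[2])
  expect_gt(tslope, 1.7)
  expect_lt(tslope, 2.3)
})

test_that("forward Euler stepping honours boundaries and detects crossings", {
  law <- hookean_cell(N = 2, L = 1, m = 1)
  st <- spring_chain_state(c(0, 0.25, 1), 1, 2, 1, "fixed")
  st1 <- step_euler(st, rhs_curved(st, law), 0.001)
  expect_equal(st1$s[2], 0.2505)
  expect_equal(st1$t, 0.001)
  # zero-velocity state unchanged
  expect_equal(step_euler(st, rep(0, 3), 0.01)$s, st$s)
  # a violent step must fail loudly, naming the collapsed spring
  expect_error(step_euler(st, c(0, 1e4, 0), 0.001), "spring")

  # fixed end nodes stay pinned through a full simulation
  tr <- simulate_chain(spring_chain_state(c(0, 0.25, 1), 1, 2, 1, "fixed"),
                       law, "curved", t_end = 0.5, save_times = c(0.1, 0.37, 0.5))
  for (s in tr$states) {
    expect_identical(s$s[1], 0)
    expect_identical(s$s[3], 1)
  }
  # the stability guard rejects over-long steps
  expect_error(simulate_chain(st, force_law("hookean", k = 1000, a = 0.5, eta = 1, m = 1),
                              "curved", t_end = 1, dt = 0.01), "stability")
})

test_that("offset initial condition stretches one cell and compresses its neighbour", {
  expect_error(initial_condition_offset(4, 1, 1, "periodic", 0.7), "offset_fraction")
  ic0 <- initial_condition_offset(4, 2, 2 * pi, "fixed", 0)
  expect_equal(spring_lengths(ic0), rep(2 * pi / 8, 8))

  ic <- initial_condition_offset(8, 1, 2 * pi, "periodic", 0.5)
  ell <- spring_lengths(ic)
  a_cell <- 2 * pi / 8
  expect_equal(sort(unique(round(ell, 12))),
               sort(unique(round(c(1.5 * a_cell, 0.5 * a_cell, a_cell), 12))))
  expect_equal(ell[3], 1.5 * a_cell)  # second cell elongated
  expect_equal(ell[4], 0.5 * a_cell)  # third cell compressed

  ic44 <- initial_condition_offset(4, 4, 2 * pi, "fixed", 0.5)
  ell44 <- spring_lengths(ic44)
  cell_len <- sapply(1:4, function(j) sum(ell44[(4 * j - 3):(4 * j)]))
  expect_equal(cell_len, (2 * pi / 4) * c(1, 1.5, 0.5, 1))
  # springs uniform within each cell
  for (j in 1:4) expect_lt(diff(range(ell44[(4 * j - 3):(4 * j)])), 1e-12)
})

test_that("compiled and R Euler paths agree exactly, both boundary kinds", {
  law <- hookean_cell(N = 4, m = 2)
  icp <- initial_condition_offset(4, 2, 2 * pi, "periodic", 0.5)
  icf <- initial_condition_offset(4, 2, 2 * pi, "fixed", 0.5)
  for (ic in list(icp, icf)) {
    a <- simulate_chain(ic, law, "curved", t_end = 0.2, save_times = c(0.07, 0.2))
    b <- simulate_chain(ic, law, "curved", t_end = 0.2, save_times = c(0.07, 0.2),
                        use_compiled = FALSE)
    expect_equal(a$states[[1]]$s, b$states[[1]]$s, tolerance = 1e-14)
    expect_equal(a$states[[2]]$s, b$states[[2]]$s, tolerance = 1e-14)
  }
})

test_that("chains relax to the evenly spaced, stress-free steady state", {
  # open sinusoid, N=4 cells of m=4 Hookean springs, spring-level k=4, eta=0.25
  L <- std_sinusoid$L
  law <- force_law("hookean", k = 4, a = L / 16, eta = 0.25, m = 4)
  ic <- initial_condition_offset(4, 4, L, "fixed", 0.5)
  Tr <- relaxation_time(4, law$k_star, law$eta_star, "fixed")
  tr <- simulate_chain(ic, law, "curved", t_end = 15 * Tr,
                       save_times = Tr * c(4, 8, 15))
  final <- tr$states[[3]]
  ell <- spring_lengths(final)
  expect_lt(max(abs(ell - mean(ell))), 1e-6)
  expect_lt(max(abs(ell - L / 16)), 1e-5)           # all springs at rest length
  expect_lt(max(abs(tangential_stress(law, ell))), 1e-4)
  # energy decreases monotonically along the trajectory
  en <- sapply(tr$states, function(s) sum((spring_lengths(s) - L / 16)^2))
  expect_true(all(diff(en) <= 1e-15))
  # the stress amplitude decays by one e-fold per T_relax
  st8 <- tangential_stress(law, spring_lengths(tr$states[[2]]))
  st4 <- tangential_stress(law, spring_lengths(tr$states[[1]]))
  expect_equal(max(abs(st8)) / max(abs(st4)), exp(-4), tolerance = 0.05)

  # steady state reached for every law with its stress-free rest length
  for (kind in all_law_kinds) {
    lawp <- force_law(kind, k_star = 1, a_star = 2 * pi / 8, eta_star = 1, m = 1)
    trp <- simulate_chain(initial_condition_offset(8, 1, 2 * pi, "periodic", 0.5),
                          lawp, "curved", t_end = 25, save_times = 25)
    ellp <- spring_lengths(trp$states[[1]])
    expect_lt(max(abs(ellp - mean(ellp))), 1e-6)
  }
})

test_that("periodic curved dynamics conserves the mean coordinate", {
  law <- hookean_cell(N = 8)
  ic <- initial_condition_offset(8, 1, 2 * pi, "periodic", 0.5)
  tr <- simulate_chain(ic, law, "curved", t_end = 1, save_times = c(0, 0.5, 1))
  sums <- sapply(tr$states, function(s) sum(s$s))
  expect_lt(max(abs(sums - sums[1])), 1e-9)
})

test_that("stress-free rest lengths reproduce circle, sinusoid and cross geometry", {
  expect_equal(rest_length_stress_free(unit_circle, 4, "curved"), 2 * pi / 4)
  expect_equal(rest_length_stress_free(unit_circle, 4, "straight"), sqrt(2),
               tolerance = 1e-9)
  expect_equal(rest_length_stress_free(unit_circle, 64, "straight"),
               2 * sin(pi / 64), tolerance = 1e-9)
  expect_equal(rest_length_stress_free(std_sinusoid, 16, "curved"),
               std_sinusoid$L / 16, tolerance = 1e-12)
  # open-curve straight polyline: 16 equal chords from end to end
  a_open <- rest_length_stress_free(std_sinusoid, 16, "straight")
  expect_lt(a_open, std_sinusoid$L / 16)
  expect_gt(a_open, 0.4)
  # on the 4-fold cross the closing 64-gon depends on its phase: the polygon
  # with a node on the symmetry axis and the one with a chord midpoint there
  # have genuinely different chords (both below the arc spacing L/64)
  a_node <- rest_length_stress_free(std_cross, 64, "straight")
  a_mid <- rest_length_stress_free(std_cross, 64, "straight",
                                   s0 = std_cross$L / 128)
  expect_gt(abs(a_node - a_mid), 1e-5)
  expect_lt(max(a_node, a_mid), std_cross$L / 64)
})

test_that("straight and curved equilibria coincide on the circle, differ transiently", {
  ic <- initial_condition_offset(4, 1, 2 * pi, "periodic", 0.5)
  lc <- force_law("hookean", k_star = 1, a_star = 2 * pi / 4, eta_star = 1)
  ls <- force_law("hookean", k_star = 1, a_star = sqrt(2), eta_star = 1)
  trc <- simulate_chain(ic, lc, "curved", t_end = 20, save_times = c(0.5, 20))
  trs <- simulate_chain(ic, ls, "straight", curve = unit_circle, t_end = 20,
                        save_times = c(0.5, 20))
  expect_gt(max(abs(trc$states[[1]]$s - trs$states[[1]]$s)), 1e-3)
  expect_lt(max(abs(trc$states[[2]]$s - trs$states[[2]]$s)), 1e-6)
})

test_that("cross-curve straight/curved differences shrink rapidly with m", {
  # each model runs with its own stress-free rest length; their equilibria are
  # the equal-chord and equal-arc polygons, whose node positions converge as m grows
  L <- std_cross$L
  diffs <- sapply(c(1L, 8L), function(m) {
    M <- 8L * m
    ac <- rest_length_stress_free(std_cross, M, "curved")
    as <- rest_length_stress_free(std_cross, M, "straight")
    lc <- force_law("hookean", k_star = 1, a_star = ac * m, eta_star = 1, m = m)
    ls <- force_law("hookean", k_star = 1, a_star = as * m, eta_star = 1, m = m)
    ic <- initial_condition_offset(8, m, L, "periodic", 0.5)
    trc <- simulate_chain(ic, lc, "curved", t_end = 12, save_times = 12)
    trs <- simulate_chain(ic, ls, "straight", curve = std_cross, t_end = 12,
                          save_times = 12)
    max(abs(trc$states[[1]]$s - trs$states[[1]]$s))
  })
  expect_gt(diffs[1], 1e-3)          # m = 1: visibly different states
  expect_lt(diffs[2], 1e-2)          # m = 8: below plotting resolution
  expect_lt(diffs[2], diffs[1] / 4)  # and shrinking fast with m
})
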