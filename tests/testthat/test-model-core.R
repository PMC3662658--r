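test_that("channel currents vanish at the reversal potential and at gbar 0", {
  hh <- build_hh()
  na <- hh$channels[[1]]
  gv <- steady_gate_values(hh, -40)
  expect_equal(channel_current(na, V = na$E, gv), 0)
  na0 <- na
  na0$gbar <- 0
  expect_equal(channel_current(na0, V = -55, gv), 0)
  leak <- channel("leak", gbar = 0.3, E = -54.4)
  expect_equal(channel_current(leak, V = -64.4), -3)
})

test_that("missing gate values raise an error naming the gate", {
  hh <- build_hh()
  expect_error(channel_current(hh$channels[[1]], -60, list(m = 0.1)),
               "'h'")
  expect_error(net_current(hh, -60, gate_values = list(m = 0.1, h = 0.5)),
               "'n'")
})

test_that("net current reduces to I_app and to leak algebra", {
  hh <- build_hh(gbar_Na = 0, gbar_K = 0, g_L = 0, I_app = 3.5)
  expect_equal(net_current(hh, -60), 3.5)
  lk <- leak_only(g_L = 0.25, E_L = -60, I_app = 2)
  expect_equal(net_current(lk, -60 + 2 / 0.25), 0, tolerance = 1e-12)
})

test_that("the RHS vanishes at fixed points and for gates at steady state", {
  hh <- build_hh()
  st <- c(V = -70, unlist(steady_gate_values(hh, -70)))
  d <- model_rhs(hh, st)
  expect_equal(unname(d[c("m", "h", "n")]), c(0, 0, 0))
  expect_equal(unname(d[["V"]]),
               net_current(hh, -70) / hh$capacitance)

  fp <- fixed_points(hh)
  st_fp <- c(V = fp$V[1], unlist(fp$gate_values[[1]]))
  expect_lt(max(abs(model_rhs(hh, st_fp))), 1e-9)
  # unit-tau mode only rescales the gate rows
  d_unit <- model_rhs(hh, st, tau_mode = "unit")
  expect_equal(unname(d_unit[["V"]]), unname(d[["V"]]))
})

test_that("fixed-point search finds the leak root exactly and HH rest", {
  lk <- leak_only(g_L = 0.25, E_L = -60, I_app = 2)
  fp <- fixed_points(lk)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$V, -60 + 2 / 0.25, tolerance = 1e-9)
  expect_true(fp$stable)

  hh <- build_hh()
  fp_hh <- fixed_points(hh)
  expect_equal(nrow(fp_hh), 1)
  expect_true(fp_hh$stable)
  expect_lt(abs(fp_hh$V - (-65)), 1)
  # dense-grid oracle at 1e5 points finds the same single sign change
  grid <- seq(-100, 20, length.out = 1e5)
  Fg <- tcswitch:::net_current_steady_vec(hh, grid)
  expect_equal(sum(sign(Fg[-1]) * sign(Fg[-1e5]) < 0), 1)
  i <- which(sign(Fg[-1]) * sign(Fg[-1e5]) < 0)
  expect_lt(abs(fp_hh$V - grid[i]), diff(grid[1:2]) * 1.5)
})

test_that("fixed-point residuals meet the solver tolerance", {
  for (seed in 0:4) {
    m <- seeded_random_model(seed)
    fp <- fixed_points(m)
    for (v in fp$V)
      expect_lt(abs(net_current(m, v)), 1e-9 * (1 + abs(m$I_app)))
  }
})

test_that("the Jacobian is an arrowhead and matches finite differences", {
  hh <- build_hh()
  st <- c(V = -63, unlist(steady_gate_values(hh, -63)))
  J <- model_jacobian(hh, st)
  # off-arrowhead entries exactly zero
  gn <- c("m", "h", "n")
  for (a in gn) for (b in gn)
    if (a != b) expect_identical(J[a, b], 0)
  # full central finite-difference oracle on the RHS
  h_fd <- 1e-6
  nm <- names(st)
  J_fd <- matrix(0, length(st), length(st), dimnames = list(nm, nm))
  for (j in seq_along(st)) {
    up <- st; up[j] <- up[j] + h_fd
    dn <- st; dn[j] <- dn[j] - h_fd
    J_fd[, j] <- (model_rhs(hh, up) - model_rhs(hh, dn)) / (2 * h_fd)
  }
  expect_equal(J, J_fd, tolerance = 1e-6)

  lk <- leak_only(g_L = 0.3, C = 2)
  J_lk <- model_jacobian(lk, c(V = -60))
  expect_equal(unname(J_lk[1, 1]), -0.3 / 2)
})

test_that("reduced slope degenerates correctly on simple models", {
  lk <- leak_only(g_L = 0.4)
  for (sub in list("fast", "fast_slow", character()))
    expect_equal(reduced_slope(lk, -60, sub), -0.4)
  hh <- build_hh()
  gv <- steady_gate_values(hh, -60)
  expect_equal(reduced_slope(hh, -60, character()),
               tcswitch:::dF_dV(hh, -60, gv))
  expect_error(reduced_slope(hh, -60, "nope"), "unknown gate")
})

test_that("arrowhead determinant identity holds across seeded models", {
  # det J(unit tau) = (1/C) (-1)^m * s(V; fast+slow) -- the identity that
  # makes the balance and singularity conditions time-constant free
  for (seed in 0:9) {
    m <- seeded_random_model(seed)
    n_gates <- nrow(model_gates(m))
    for (V in seq(-80, -30, length.out = 5)) {
      st <- c(V = V, unlist(steady_gate_values(m, V)))
      d <- det(model_jacobian(m, st, tau_mode = "unit"))
      s <- reduced_slope(m, V, "fast_slow")
      rhs <- (1 / m$capacitance) * (-1)^n_gates * s
      expect_equal(d, rhs, tolerance = 1e-10)
    }
  }
})

test_that("algebraic quantities are invariant to tau rescaling", {
  hh <- build_hh()
  hh_rt <- with_random_taus(hh, seed = 11)
  fp <- fixed_points(hh)
  fp_rt <- fixed_points(hh_rt)
  expect_equal(fp$V, fp_rt$V, tolerance = 1e-12)
  for (V in c(-70, -55)) {
    expect_equal(reduced_slope(hh, V, "fast"),
                 reduced_slope(hh_rt, V, "fast"), tolerance = 1e-12)
    expect_equal(slow_balance(hh, V), slow_balance(hh_rt, V),
                 tolerance = 1e-12)
  }
  # eigenvalues do change (stability analysis sees the taus)
  expect_false(isTRUE(all.equal(fp$eigenvalues[[1]],
                                fp_rt$eigenvalues[[1]])))
})

test_that("frozen adaptation gates act as constants with no state", {
  m <- conductance_model(list(
    channel("leak", 0.3, -60),
    channel("CaT", 1.2, 120, gates = list(
      gate_boltzmann("s", "activation", "slow", V_half = -55, k = 6,
                     tau = tau_constant(5)),
      gate_boltzmann("u", "inactivation", "ultraslow", V_half = -70,
                     k = -5, tau = tau_constant(500))))),
    frozen = c(u = 0.4))
  expect_equal(state_gate_names(m), "s")
  st <- c(V = -60, s = gate_steady(find_gate(m, "s")$gate, -60))
  expect_equal(dim(model_jacobian(m, st)), c(2L, 2L))
  # current scales linearly in the frozen value
  i1 <- net_current(m, -60)
  m2 <- m
  m2$frozen[["u"]] <- 0.8
  i2 <- net_current(m2, -60)
  leak_i <- 0.3 * (-60 - -60)
  expect_equal(i2 - leak_i, 2 * (i1 - leak_i), tolerance = 1e-12)
  # ultraslow gates must be frozen
  expect_error(conductance_model(list(
    channel("CaT", 1.2, 120, gates = list(
      gate_boltzmann("u", "inactivation", "ultraslow", V_half = -70,
                     k = -5)))), frozen = c()),
    "must be frozen")
})
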