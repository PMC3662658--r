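test_that("a leak branch against current is straight and event-free", {
  lk <- leak_only(g_L = 0.25, E_L = -60)
  sw <- sweep_current(lk, range = c(-2, 4))
  br <- continue_fixed_points(sw, start = c(-60, 0))
  expect_gte(nrow(br), 10)
  expect_equal(br$V, -60 + br$param / 0.25, tolerance = 1e-8)
  expect_true(all(br$stable))
  expect_identical(nrow(attr(br, "events")), 0L)
})

test_that("branch voltages agree with the direct fixed-point oracle", {
  lk <- leak_only(g_L = 0.25, E_L = -60)
  sw <- sweep_current(lk, range = c(-2, 4))
  br <- continue_fixed_points(sw, start = c(-60, 0))
  for (i in seq(1, nrow(br), length.out = 5)) {
    p <- br$param[i]
    fp <- fixed_points(sw$model_at(p), V_range = c(-100, 20))
    expect_lt(min(abs(fp$V - br$V[i])), 1e-8)
  }
  # same check on a curved HH branch against applied current
  hh <- build_hh()
  swI <- sweep_current(hh, range = c(0, 6))
  fp0 <- fixed_points(hh, I_app = 0)
  brI <- continue_fixed_points(swI, start = c(fp0$V[1], 0))
  for (i in seq(2, nrow(brI) - 1, length.out = 5)) {
    p <- brI$param[round(i)]
    fp <- fixed_points(swI$model_at(p), V_range = c(-100, 20))
    expect_lt(min(abs(fp$V - brI$V[round(i)])), 1e-8)
  }
})

test_that("the HH E_K diagram carries the SN, TC, HB event sequence", {
  fx <- hh_tc_fixture()
  sw <- sweep_bif_param(fx$hh, fx$bp, fx$primary, range = c(-90, -20))
  dg <- bifurcation_diagram(sw, n_seeds = 5, V_range = c(-100, 0))
  expect_true(all(c("SN", "TC", "HB") %in% dg$events$type))
  tc_ev <- dg$events[dg$events$type == "TC", ]
  expect_gte(nrow(tc_ev), 1)
  expect_lt(min(abs(tc_ev$param - fx$primary$lambda_star)), 1e-4)
  expect_lt(min(abs(tc_ev$V - fx$primary$V_star)), 1e-4)
  # the saddle-node lies on the hyperpolarized side of the crossing and
  # precedes it in the parameter, as the branch geometry requires
  sn <- dg$events[dg$events$type == "SN", ]
  expect_lt(min(sn$param), fx$primary$lambda_star)
})

test_that("stability flips only at detected events", {
  fx <- hh_tc_fixture()
  sw <- sweep_bif_param(fx$hh, fx$bp, fx$primary, range = c(-90, -20))
  br <- continue_fixed_points(sw, start = c(fx$primary$V_star, -85),
                              direction = 1)
  ev <- attr(br, "events")
  flips <- which(br$stable[-1] != br$stable[-nrow(br)])
  for (f in flips)
    expect_true(any(ev$idx_lo <= f + 1 & ev$idx_hi >= f))
})

test_that("an applied-current sweep of restorative HH shows a Hopf onset", {
  hh <- build_hh()
  sw <- sweep_current(hh, range = c(0, 20))
  fp0 <- fixed_points(hh, I_app = 0)
  br <- continue_fixed_points(sw, start = c(fp0$V[1], 0))
  ev <- attr(br, "events")
  hb <- ev[ev$type == "HB", ]
  expect_gte(nrow(hb), 1)
  # eigenvalue-scan oracle on a dense current grid
  grid <- seq(0, 20, length.out = 400)
  re_max <- vapply(grid, function(I) {
    fp <- fixed_points(hh, I_app = I, V_range = c(-80, -40), n_grid = 100)
    ev_ <- fp$eigenvalues[[which.min(fp$V)]]
    cc <- ev_[abs(Im(ev_)) > 1e-9]
    max(Re(cc))
  }, numeric(1))
  cross <- grid[which(sign(re_max[-1]) * sign(re_max[-400]) < 0)]
  expect_lt(abs(hb$param[1] - cross[1]), diff(grid[1:2]) * 1.5)
})

test_that("event refinement is converged in the step size", {
  fx <- hh_tc_fixture()
  sw <- sweep_bif_param(fx$hh, fx$bp, fx$primary, range = c(-62, -55))
  ev1 <- attr(continue_fixed_points(sw, start = c(fx$primary$V_star, -62),
                                    max_step = 0.5), "events")
  ev2 <- attr(continue_fixed_points(sw, start = c(fx$primary$V_star, -62),
                                    max_step = 0.25), "events")
  shared <- intersect(ev1$type, ev2$type)
  expect_gte(length(shared), 1)
  for (tp in shared) {
    p1 <- ev1$param[ev1$type == tp][1]
    p2 <- ev2$param[ev2$type == tp][1]
    expect_lt(abs(p1 - p2), 1e-6)
  }
})

test_that("det-zero classification separates folds from crossings", {
  fx <- hh_tc_fixture()
  sw <- sweep_bif_param(fx$hh, fx$bp, fx$primary, range = c(-90, -20))
  dg <- bifurcation_diagram(sw, n_seeds = 5, V_range = c(-100, 0))
  ev <- dg$events
  sn <- ev[ev$type == "SN", ][1, ]
  tc <- ev[ev$type == "TC", ][1, ]
  expect_gt(abs(sn$slow_balance), 1e-4)   # fold away from balance
  expect_lt(abs(tc$slow_balance), 1e-6)   # crossing on the balance
})

test_that("an artificially balanced fold is labelled degenerate", {
  # base: leak + fast sodium-like gate gives an S-shaped current sweep with
  # genuine folds; two feather-weight slow gates are then tuned to cancel
  # exactly at the fold voltage, so the balance vanishes there although the
  # det-zero is a fold, not a crossing
  base <- conductance_model(list(
    channel("leak", 1, -60),
    channel("fastNa", 1, 50, gates = list(
      gate_boltzmann("mf", "activation", "fast", V_half = -40, k = 5,
                     tau = tau_constant(0.3))))))
  swb <- sweep_current(base, range = c(-10, 5))
  fp <- fixed_points(base, I_app = 0)
  br <- continue_fixed_points(swb, start = c(min(fp$V), 0))
  evb <- attr(br, "events")
  fold <- evb[evb$type == "SN", ][1, ]
  expect_false(is.na(fold$V))
  V_f <- fold$V
  # tune the regenerative feather so the two tiny slow weights cancel at V_f
  xs <- function(V, Vh, k) 1 / (1 + exp(-(V - Vh) / k))
  dxs <- function(V, Vh, k) xs(V, Vh, k) * (1 - xs(V, Vh, k)) / k
  w_r_unit <- -(V_f + 95) * dxs(V_f, -50, 8)
  w_g_unit <- -(V_f - 30) * dxs(V_f, -55, 7)
  eps_g <- 1e-3
  g_regen <- -eps_g * w_r_unit / w_g_unit
  tuned <- conductance_model(list(
    base$channels[[1]], base$channels[[2]],
    channel("resto", eps_g, -95, gates = list(
      gate_boltzmann("sr", "activation", "slow", V_half = -50, k = 8,
                     tau = tau_constant(5)))),
    channel("regen", g_regen, 30, gates = list(
      gate_boltzmann("sg", "activation", "slow", V_half = -55, k = 7,
                     tau = tau_constant(6))))))
  swt <- sweep_current(tuned, range = c(-10, 5))
  fp_t <- fixed_points(tuned, I_app = 0)
  br_t <- continue_fixed_points(swt, start = c(min(fp_t$V), 0))
  ev_t <- attr(br_t, "events")
  deg <- ev_t[ev_t$type == "degenerate", ]
  expect_gte(nrow(deg), 1)
  expect_lt(abs(deg$slow_balance[1]), 1e-4)
  expect_match(deg$flagged[1], "crossing probe failed")
})
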