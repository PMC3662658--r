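test_that("residuals are the balance and the fast-subsystem slope", {
  hh <- build_hh()
  bp <- hh_ek_param()
  r <- tc_residuals(hh, -60, bp, -50)
  m50 <- build_hh(E_K = -50)
  expect_equal(r$balance, slow_balance(m50, -60))
  expect_equal(r$fast, reduced_slope(m50, -60, "fast"))
  # for HH the fast singularity does not involve E_K at all
  r2 <- tc_residuals(hh, -60, bp, -80)
  expect_equal(r$fast, r2$fast)
  expect_false(isTRUE(all.equal(r$balance, r2$balance)))
})

test_that("a vanished regenerative current leaves the balance negative", {
  m <- toy_tc_model(g_regen = 0)
  bp <- bif_param("max_conductance", "regen", c(0, 10))
  for (V in seq(-80, -40, by = 10))
    expect_lt(tc_residuals(m, V, bp, 0)$balance, 0)
})

test_that("the HH transcritical point matches the brute-force oracle", {
  fx <- hh_tc_fixture()
  orc <- tc_brute_force_oracle(fx$hh, fx$bp, c(-90, 0))
  expect_gte(length(orc), 1)
  for (o in orc) {
    d_V <- min(abs(fx$tc$V_star - o[["V"]]))
    d_l <- min(abs(fx$tc$lambda_star - o[["lambda"]]))
    expect_lt(d_V, 1e-6)
    expect_lt(d_l, 1e-6)
  }
  # residual postconditions and root ordering
  expect_lt(max(abs(c(fx$tc$res_balance, fx$tc$res_fast))), 1e-9)
  expect_identical(fx$tc$V_star, sort(fx$tc$V_star))
  # the balance point sits where the potassium driving force inverts:
  # E_K* above V*
  expect_gt(fx$primary$lambda_star, fx$primary$V_star)
})

test_that("conductance roots match the closed-form affine elimination", {
  m <- toy_tc_model()
  bp <- bif_param("max_conductance", "regen", c(0, 12))
  tc <- solve_tc(m, bp, V_range = c(-90, -20), verify = FALSE)
  expect_gte(nrow(tc), 1)
  # independent oracle: both residuals are affine in the conductance, so
  # lambda can be eliminated through two evaluations (gbar = 0 and 1) of
  # hand-written Boltzmann algebra
  xs <- function(V, Vh, k) 1 / (1 + exp(-(V - Vh) / k))
  dxs <- function(V, Vh, k) xs(V, Vh, k) * (1 - xs(V, Vh, k)) / k
  w_resto <- function(V) -2 * (V - -95) * dxs(V, -50, 8)
  w_regen_unit <- function(V) -(V - 30) * dxs(V, -55, 7)
  lam_of_V <- function(V) -w_resto(V) / w_regen_unit(V)
  # fast slope: conductance sum at steady state plus the fast-gate term
  s_fast <- function(V, lam) {
    gsum <- 0.2 + 4 * xs(V, -40, 6) + 2 * xs(V, -50, 8) +
      lam * xs(V, -55, 7)
    -gsum + (-4 * (V - 50)) * dxs(V, -40, 6)
  }
  g <- function(V) s_fast(V, lam_of_V(V))
  # the eliminated residual crosses zero twice in the window; bracket each
  # crossing from a fine sign scan
  vg <- seq(-90, -20, length.out = 2001)
  gs <- vapply(vg, g, numeric(1))
  idx <- which(sign(gs[-1]) * sign(gs[-2001]) < 0)
  expect_gte(length(idx), 1)
  for (i0 in idx) {
    root <- stats::uniroot(g, c(vg[i0], vg[i0 + 1]), tol = 1e-13)$root
    lam <- lam_of_V(root)
    if (lam < 0 || lam > 12) next
    i <- which.min(abs(tc$V_star - root))
    expect_equal(tc$V_star[i], root, tolerance = 1e-8)
    expect_equal(tc$lambda_star[i], lam, tolerance = 1e-8)
  }
})

test_that("models with no regenerative mass report the sign obstruction", {
  m <- conductance_model(list(
    channel("leak", 0.3, -60),
    channel("K", 3, -90, gates = list(
      gate_boltzmann("s", "activation", "slow", V_half = -50, k = 8,
                     tau = tau_constant(5))))))
  bp <- bif_param("max_conductance", "leak", c(0.01, 5))
  err <- tryCatch(solve_tc(m, bp, V_range = c(-85, -30)),
                  error = function(e) e)
  expect_s3_class(err, "tcs_no_balance_root")
  expect_match(conditionMessage(err), "strictly negative")
})

test_that("the applied current completes the fixed-point equation", {
  fx <- hh_tc_fixture()
  tcp <- fx$primary
  I_TC <- i_app_at_tc(fx$hh, tcp, fx$bp)
  m_star <- set_bif_param(fx$hh, fx$bp, tcp$lambda_star)
  m_star$I_app <- I_TC
  expect_lt(abs(net_current(m_star, tcp$V_star)), 1e-9)
  # degenerate leak-only call: the current is just the leak current
  lk <- leak_only(g_L = 0.3, E_L = -54.4)
  bp_lk <- bif_param("max_conductance", "leak", c(0.1, 1))
  fake <- tibble::tibble(V_star = -40, lambda_star = 0.3)
  expect_equal(i_app_at_tc(lk, fake, bp_lk), 0.3 * (-40 + 54.4))
  # a model already at equilibrium at V* with I_app = 0 needs no current
  fake0 <- tibble::tibble(V_star = -54.4, lambda_star = 0.3)
  expect_equal(i_app_at_tc(lk, fake0, bp_lk), 0)
})

test_that("the affine current law anchors V* across the whole sweep", {
  fx <- hh_tc_fixture()
  tcp <- fx$primary
  expect_equal(affine_current(fx$hh, tcp, fx$bp, tcp$lambda_star),
               tcp$I_TC, tolerance = 1e-12)
  # closed form of the E_K dependence: the n^4 driving-force term
  n_inf <- gate_steady(find_gate(fx$hh, "n")$gate, tcp$V_star)
  for (ek in c(-80, -65, -50, -40)) {
    expect_equal(affine_current(fx$hh, tcp, fx$bp, ek) - tcp$I_TC,
                 -36 * n_inf^4 * (ek - tcp$lambda_star), tolerance = 1e-9)
    m <- set_bif_param(fx$hh, fx$bp, ek)
    m$I_app <- affine_current(fx$hh, tcp, fx$bp, ek)
    fp <- fixed_points(m, V_range = tcp$V_star + c(-1, 1), n_grid = 50)
    expect_lt(min(abs(fp$V - tcp$V_star)), 1e-9)
  }
})

test_that("verification passes at the root and fails off it", {
  fx <- hh_tc_fixture()
  tcp <- fx$primary
  v_ok <- verify_tc(fx$hh, tcp, fx$bp)
  expect_true(v_ok$verified)
  bad <- tcp
  bad$lambda_star <- bad$lambda_star + 1e-2
  v_bad <- verify_tc(fx$hh, bad, fx$bp)
  expect_false(v_bad$verified)
  expect_false(v_bad$checks[["det_zero"]])
})

test_that("the condition chain closes at every transcritical point", {
  fx <- hh_tc_fixture()
  for (i in seq_len(nrow(fx$tc))) {
    m <- set_bif_param(fx$hh, fx$bp, fx$tc$lambda_star[i])
    V <- fx$tc$V_star[i]
    expect_lt(abs(slow_balance(m, V)), 1e-9)
    expect_lt(abs(reduced_slope(m, V, "fast")), 1e-9)
    expect_lt(abs(reduced_slope(m, V, "fast_slow")), 2e-9)
    st <- c(V = V, unlist(steady_gate_values(m, V)))
    expect_lt(abs(det(model_jacobian(m, st, tau_mode = "unit"))), 2e-9)
  }
})

test_that("the transcritical location ignores the time constants", {
  fx <- hh_tc_fixture()
  hh_rt <- with_random_taus(fx$hh, seed = 7)
  tc_rt <- solve_tc(hh_rt, fx$bp, V_range = c(-90, 0), verify = FALSE)
  expect_equal(nrow(tc_rt), nrow(fx$tc))
  expect_equal(tc_rt$V_star, fx$tc$V_star, tolerance = 1e-10)
  expect_equal(tc_rt$lambda_star, fx$tc$lambda_star, tolerance = 1e-10)
})

test_that("tidy and glance expose the solved roots", {
  fx <- hh_tc_fixture()
  td <- tidy(fx$tc)
  expect_identical(nrow(td), nrow(fx$tc))
  expect_true(all(c("V_star", "lambda_star", "I_TC") %in% names(td)))
  g <- glance(fx$tc)
  expect_identical(g$n_roots, nrow(fx$tc))
  expect_lt(g$max_residual, 1e-9)
})
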