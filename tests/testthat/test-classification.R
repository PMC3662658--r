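test_that("HH slow gates are restorative at physiological E_K", {
  hh <- build_hh()
  rest <- fixed_points(hh)$V[1]
  expect_lt(feedback_weight(hh, rest, "h"), 0)
  expect_lt(feedback_weight(hh, rest, "n"), 0)
  expect_lt(slow_balance(hh, rest), 0)
  ex <- excitability_at_rest(hh)
  expect_identical(ex$label, "restorative")
  expect_false(ex$mixed)
})

test_that("raising E_K above the operating voltage flips the n feedback", {
  hh_hi <- build_hh(E_K = -50)
  expect_gt(feedback_weight(hh_hi, -60, "n"), 0)
  expect_lt(feedback_weight(hh_hi, -60, "h"), 0)
})

test_that("feedback weights are linear in gbar and zero at gbar 0", {
  m1 <- toy_tc_model(g_regen = 1)
  m2 <- toy_tc_model(g_regen = 2)
  m0 <- toy_tc_model(g_regen = 0)
  for (V in c(-70, -55, -40)) {
    expect_equal(feedback_weight(m2, V, "sg"),
                 2 * feedback_weight(m1, V, "sg"), tolerance = 1e-12)
    expect_identical(feedback_weight(m0, V, "sg"), 0)
  }
  set.seed(42)
  for (seed in 0:4) {
    m <- seeded_random_model(seed)
    gt <- model_gates(m)
    slow <- gt$gate[gt$tclass == "slow"]
    i <- which(vapply(m$channels, function(ch)
      any(vapply(ch$gates, `[[`, character(1), "name") %in% slow),
      logical(1)))[1]
    m2 <- m
    m2$channels[[i]]$gbar <- 2 * m2$channels[[i]]$gbar
    g_in_ch <- intersect(
      vapply(m$channels[[i]]$gates, `[[`, character(1), "name"), slow)
    V <- runif(1, -75, -45)
    expect_equal(feedback_weight(m2, V, g_in_ch[1]),
                 2 * feedback_weight(m, V, g_in_ch[1]), tolerance = 1e-12)
  }
})

test_that("weight signs follow the role and driving-force logic", {
  # inward current (V < E): inactivation gives negative feedback
  # (transient-sodium logic), activation positive (calcium logic)
  mk <- function(role, k) conductance_model(list(
    channel("leak", 0.3, -60),
    channel("test", 2, 60, gates = list(
      gate_boltzmann("s", role, "slow", V_half = -50, k = k,
                     tau = tau_constant(5))))))
  inact <- mk("inactivation", -8)
  act <- mk("activation", 8)
  for (V in seq(-80, -30, by = 5)) {
    expect_lt(feedback_weight(inact, V, "s"), 0)
    expect_gt(feedback_weight(act, V, "s"), 0)
  }
  # outward current (V > E): the signs flip
  mk_out <- function(role, k) conductance_model(list(
    channel("leak", 0.3, -60),
    channel("test", 2, -95, gates = list(
      gate_boltzmann("s", role, "slow", V_half = -50, k = k,
                     tau = tau_constant(5))))))
  expect_gt(feedback_weight(mk_out("inactivation", -8), -60, "s"), 0)
  expect_lt(feedback_weight(mk_out("activation", 8), -60, "s"), 0)
})

test_that("slow balance decomposes the reduced slope exactly", {
  for (seed in 0:9) {
    m <- seeded_random_model(seed)
    V <- seq(-80, -40, length.out = 7)
    lhs <- reduced_slope(m, V, "fast_slow")
    rhs <- reduced_slope(m, V, "fast") + slow_balance(m, V)
    expect_identical(lhs, rhs)
  }
  # no slow gates: balance is exactly zero
  lk <- leak_only()
  expect_identical(slow_balance(lk, -60), 0)
})

test_that("a single slow restorative gate gives restorative excitability", {
  for (g in c(0.5, 2, 8)) {
    m <- conductance_model(list(
      channel("leak", 0.3, -60),
      channel("K", g, -90, gates = list(
        gate_boltzmann("s", "activation", "slow", V_half = -50, k = 8,
                       tau = tau_constant(5))))))
    expect_identical(excitability_at_rest(m)$label, "restorative")
  }
})

test_that("errors and edge labels are as documented", {
  hh <- build_hh()
  expect_error(feedback_weight(hh, -60, "m"), "slow")
  expect_error(feedback_weight(hh, -60, "zz"), "unknown gate")
  lk <- leak_only()
  expect_identical(excitability_at_rest(lk)$label, "neutral")
  # no stable fixed point in the window
  expect_error(excitability_at_rest(lk, V_range = c(19, 20)),
               "no stable fixed point")
})

test_that("archetype lookups reproduce the printed classification", {
  resto <- c("transient", "delayed rectifier", "BK", "HCN")
  regen <- c("resurgent", "L-type", "T-type", "N-type", "P/Q-type",
             "R-type", "A-type")
  neutral <- c("persistent", "KCNQ", "eag/erg")
  for (a in resto) expect_identical(table1_class(a), "slow restorative")
  for (a in regen) expect_identical(table1_class(a), "slow regenerative")
  for (a in neutral) expect_identical(table1_class(a), "neutral")
  expect_error(table1_class("M-current"), "known archetypes")
})

test_that("static/dynamic disagreement raises a warning, not silence", {
  # an 'L-type' label on a channel whose kinetics are restorative here
  m <- conductance_model(list(
    channel("leak", 0.3, -60),
    channel("Ca", 2, -95, archetype = "L-type", gates = list(
      gate_boltzmann("s", "activation", "slow", V_half = -50, k = 8,
                     tau = tau_constant(5))))))
  expect_warning(feedback_report(m, -60), "disagrees")
  # agreement stays silent
  m_ok <- conductance_model(list(
    channel("leak", 0.3, -60),
    channel("Ca", 2, 60, archetype = "L-type", gates = list(
      gate_boltzmann("s", "activation", "slow", V_half = -50, k = 8,
                     tau = tau_constant(5))))))
  expect_silent(rep_ok <- feedback_report(m_ok, -60))
  expect_identical(attr(rep_ok, "model_label"), "regenerative")
})

test_that("the report tibble and its summaries are coherent", {
  hh <- build_hh()
  rep <- feedback_report(hh, -65)
  expect_setequal(rep$gate, c("h", "n"))
  g <- glance(rep)
  expect_equal(g$balance,
               g$total_regenerative + g$total_restorative)
  expect_identical(g$label, "restorative")
  td <- tidy(rep)
  expect_false(inherits(td, "feedback_report"))
  expect_identical(nrow(td), 2L)
})
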