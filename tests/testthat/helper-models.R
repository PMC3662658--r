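# shared fixture builders; everything is constructed in code at test time

leak_only <- function(g_L = 0.3, E_L = -54.4, I_app = 0, C = 1) {
  conductance_model(list(channel("leak", gbar = g_L, E = E_L)),
                    capacitance = C, I_app = I_app)
}

# leak + one fast activation + one slow restorative + one slow regenerative
# Boltzmann gate; lambda = the regenerative gbar is the canonical toy sweep
toy_tc_model <- function(g_regen = 1) {
  conductance_model(list(
    channel("leak", gbar = 0.2, E = -60),
    channel("fastNa", gbar = 4, E = 50, gates = list(
      gate_boltzmann("mf", "activation", "fast", V_half = -40, k = 6,
                     tau = tau_constant(0.3)))),
    channel("resto", gbar = 2, E = -95, gates = list(
      gate_boltzmann("sr", "activation", "slow", V_half = -50, k = 8,
                     tau = tau_constant(5)))),
    channel("regen", gbar = g_regen, E = 30, gates = list(
      gate_boltzmann("sg", "activation", "slow", V_half = -55, k = 7,
                     tau = tau_constant(6))))))
}

# swap every gate's time-constant spec for a random positive constant;
# purely-algebraic quantities must not notice
with_random_taus <- function(model, seed) {
  set.seed(seed)
  for (i in seq_along(model$channels)) {
    for (j in seq_along(model$channels[[i]]$gates)) {
      g <- model$channels[[i]]$gates[[j]]
      model$channels[[i]]$gates[[j]] <-
        if (g$kinetics$type == "boltzmann")
          gate_boltzmann(g$name, g$role, g$tclass, g$kinetics$V_half,
                         g$kinetics$k, exponent = g$exponent,
                         tau = tau_constant(runif(1, 0.05, 50)))
        else
          gate_alphabeta(g$name, g$role, g$tclass, g$kinetics$alpha,
                         g$kinetics$beta, exponent = g$exponent,
                         tau = tau_constant(runif(1, 0.05, 50)))
    }
  }
  # rebuild to refresh the cached gate table
  conductance_model(model$channels, capacitance = model$capacitance,
                    frozen = model$frozen, I_app = model$I_app,
                    aux = model$aux)
}

# the mix of gate counts used for seeded property sweeps
random_model_counts <- function(seed) {
  counts <- list(c(1, 1, 0), c(1, 2, 0), c(1, 1, 1), c(2, 1, 1),
                 c(1, 2, 1))
  counts[[seed %% length(counts) + 1]]
}

seeded_random_model <- function(seed) {
  ct <- random_model_counts(seed)
  random_model(ct[1], ct[2], ct[3], seed = seed)
}

# HH transcritical fixture, solved once per test run
hh_tc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hh <- build_hh()
      bp <- hh_ek_param()
      tc <- solve_tc(hh, bp, V_range = c(-90, 0), verify = FALSE)
      cache <<- list(hh = hh, bp = bp, tc = tc,
                     primary = tc[which.min(abs(tc$V_star - (-65))), ])
    }
    cache
  }
})

# dense-grid + bisection oracle for the transcritical point: for each
# voltage on a fine grid, bracket the lambda root of the balance by scanning
# a lambda grid and bisecting; then bisect in V on the fast-singularity
# residual evaluated along that balance curve. Independent root-finding
# path from solve_tc's interpolation-seeded Newton.
tc_brute_force_oracle <- function(model, bp, V_range, n_V = 2000,
                                  n_lambda = 200, n_bisect = 40) {
  lg <- seq(bp$range[1], bp$range[2], length.out = n_lambda)
  Vg <- seq(V_range[1], V_range[2], length.out = n_V)
  Bm <- matrix(NA_real_, n_V, n_lambda)
  Sm <- matrix(NA_real_, n_V, n_lambda)
  for (j in seq_len(n_lambda)) {
    r <- tc_residuals(model, Vg, bp, lg[j])
    Bm[, j] <- r$balance
    Sm[, j] <- r$fast
  }
  # coarse balance curve per grid row (first bracket), with the
  # fast-singularity residual interpolated along it
  lam_c <- rep(NA_real_, n_V)
  s_c <- rep(NA_real_, n_V)
  for (i in seq_len(n_V)) {
    b <- Bm[i, ]
    sc <- which(sign(b[-1]) * sign(b[-n_lambda]) < 0)
    if (!length(sc)) next
    j <- sc[1]
    w <- b[j] / (b[j] - b[j + 1])
    lam_c[i] <- lg[j] + w * (lg[j + 1] - lg[j])
    s_c[i] <- Sm[i, j] * (1 - w) + Sm[i, j + 1] * w
  }
  # exact bisection refinement: inner bisection in lambda on the balance,
  # outer bisection in V on the fast residual along the balance curve
  lambda_of_V <- function(v, l_lo, l_hi) {
    b_lo <- tc_residuals(model, v, bp, l_lo)$balance
    for (k in seq_len(n_bisect)) {
      mid <- (l_lo + l_hi) / 2
      bm <- tc_residuals(model, v, bp, mid)$balance
      if (sign(bm) == sign(b_lo)) { l_lo <- mid; b_lo <- bm } else
        l_hi <- mid
    }
    (l_lo + l_hi) / 2
  }
  g <- function(v, l_guess) {
    dl <- diff(range(lg)) / (n_lambda - 1)
    l <- lambda_of_V(v, max(lg[1], l_guess - 2 * dl),
                     min(lg[n_lambda], l_guess + 2 * dl))
    list(s = tc_residuals(model, v, bp, l)$fast, lambda = l)
  }
  out <- list()
  for (i in which(!is.na(s_c[-1]) & !is.na(s_c[-n_V]) &
                  sign(s_c[-1]) * sign(s_c[-n_V]) < 0)) {
    v_lo <- Vg[i]; v_hi <- Vg[i + 1]
    s_lo <- g(v_lo, lam_c[i])$s
    lam <- lam_c[i]
    for (k in seq_len(n_bisect)) {
      mid <- (v_lo + v_hi) / 2
      gm <- g(mid, lam)
      lam <- gm$lambda
      if (sign(gm$s) == sign(s_lo)) { v_lo <- mid; s_lo <- gm$s } else
        v_hi <- mid
    }
    v <- (v_lo + v_hi) / 2
    out[[length(out) + 1]] <- c(V = v, lambda = g(v, lam)$lambda)
  }
  out
}
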