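#' Built-in Hodgkin-Huxley model
#'
#' The squid-giant-axon model in its modern-voltage parameterization:
#' transient sodium (`gbar` 120 mS/cm^2, `E_Na` 50 mV, gates `m^3 h`),
#' delayed-rectifier potassium (`gbar` 36, `E_K` -77, gate `n^4`), leak
#' (`gbar` 0.3, `E_L` -54.4), `C` = 1 uF/cm^2, with the classic alpha/beta
#' rate functions. Timescale classes follow the physiological grouping: the
#' sodium activation `m` is fast, while the sodium inactivation `h` and the
#' potassium activation `n` are the slow gates. Both slow gates give negative
#' feedback at physiological `E_K` (the model is restorative), but raising
#' `E_K` above the operating voltage turns the `n` feedback positive, which
#' is what makes `E_K` the canonical bifurcation parameter for the
#' excitability switch in this model.
#'
#' @param E_K potassium reversal potential override, mV.
#' @param I_app applied current, uA/cm^2.
#' @param gbar_Na,gbar_K,g_L maximal conductances, mS/cm^2.
#' @param E_Na,E_L reversal potentials, mV.
#' @param capacitance membrane capacitance, uF/cm^2.
#' @return a [conductance_model()].
#' @examples
#' hh <- build_hh()
#' fixed_points(hh)            # one stable resting point near -65 mV
#' @export
build_hh <- function(E_K = -77, I_app = 0, gbar_Na = 120, gbar_K = 36,
                     g_L = 0.3, E_Na = 50, E_L = -54.4, capacitance = 1) {
  m <- gate_alphabeta("m", "activation", "fast", exponent = 3L,
                      alpha = "0.1 * vtrap(V + 40, 10)",
                      beta = "4 * exp(-(V + 65) / 18)")
  h <- gate_alphabeta("h", "inactivation", "slow",
                      alpha = "0.07 * exp(-(V + 65) / 20)",
                      beta = "1 / (1 + exp(-(V + 35) / 10))")
  n <- gate_alphabeta("n", "activation", "slow", exponent = 4L,
                      alpha = "0.01 * vtrap(V + 55, 10)",
                      beta = "0.125 * exp(-(V + 65) / 80)")
  conductance_model(
    channels = list(
      channel("Na", gbar = gbar_Na, E = E_Na, gates = list(m, h),
              archetype = "transient"),
      channel("K", gbar = gbar_K, E = E_K, gates = list(n),
              archetype = "delayed rectifier"),
      channel("leak", gbar = g_L, E = E_L)),
    capacitance = capacitance, I_app = I_app)
}

#' The canonical bifurcation parameter of the built-in HH model
#'
#' `E_K` swept over a window that brackets the balance point.
#' @param range search interval for `E_K`, mV.
#' @export
hh_ek_param <- function(range = c(-90, -20)) {
  bif_param("reversal_potential", "K", range)
}

#' Planar caricature of the excitability switch
#'
#' A two-variable model with a cubic fast (voltage) nullcline and a sigmoidal
#' slow nullcline:
#' \deqn{\dot v = v - v^3/3 - w^2 + I}
#' \deqn{\dot w = \epsilon\,(w_\infty(v - v_0) + w_0 - w)}
#' with `w_inf(x) = 6 / (1 + exp(-x))`. `epsilon` sets the timescale
#' separation, `v0` is the half-activation of the slow sigmoid, and `w0`
#' shifts the slow nullcline vertically: positive `w0` puts the resting point
#' at `w > 0`, where the cross-derivative product `dv'/dw * dw'/dv =
#' -2 w epsilon w_inf'` is negative (restorative excitability); sufficiently
#' negative `w0` moves the rest to `w < 0` (regenerative excitability, with
#' the bistable saddle-separatrix phase portrait). The transition between the
#' two regimes is a transcritical bifurcation at the self-intersection of the
#' `v`-nullcline, computed in closed form by [planar_tc_point()].
#'
#' @param epsilon timescale-separation parameter (> 0).
#' @param v0 half-activation of the slow sigmoid.
#' @param w0 slow-nullcline offset.
#' @param I applied current.
#' @return an object of class `"planar_model"`.
#' @export
planar_model <- function(epsilon = 0.1, v0 = 0, w0 = 0, I = 0) {
  stopifnot(epsilon > 0)
  structure(list(epsilon = epsilon, v0 = v0, w0 = w0, I = I),
            class = "planar_model")
}

# slow-nullcline sigmoid: amplitude 6, unit gain, so its rise spans the
# whole lasso of the v-nullcline -- this keeps the phase portrait at three
# or fewer equilibria in the physiological window
planar_winf <- function(x) 6 * stats::plogis(x)
planar_winf_slope <- function(x) {
  s <- stats::plogis(x)
  6 * s * (1 - s)
}

#' Planar vector field and Jacobian
#'
#' @param pm a [planar_model()].
#' @param v,w state.
#' @param I applied current override.
#' @return `planar_rhs()` a numeric `c(dv, dw)`; `planar_jacobian()` a 2x2
#'   matrix.
#' @export
planar_rhs <- function(pm, v, w, I = pm$I) {
  c(dv = v - v^3 / 3 - w^2 + I,
    dw = pm$epsilon * (planar_winf(v - pm$v0) + pm$w0 - w))
}

#' @rdname planar_rhs
#' @export
planar_jacobian <- function(pm, v, w) {
  matrix(c(1 - v^2, -2 * w,
           pm$epsilon * planar_winf_slope(v - pm$v0), -pm$epsilon),
         2, 2, byrow = TRUE, dimnames = list(c("v", "w"), c("v", "w")))
}

#' Analytic transcritical point of the planar model
#'
#' The planar transcritical point satisfies, at a fixed point, (i) vanishing
#' cross-derivative product `(dv'/dw)(dw'/dv) = 0`, which forces `w = 0`
#' since the slow sigmoid is strictly increasing, and (ii) vanishing Jacobian
#' determinant, which with `w = 0` forces `1 - v^2 = 0`. The self-intersection
#' of the `v`-nullcline `w^2 = v - v^3/3 + I` is the branch point at
#' `v = -1` (where the cubic has a double root and the nullcline crosses
#' itself as `w = +/-(v + 1)`), giving the closed-form critical values
#' `v* = -1`, `w* = 0`, `I* = 2/3`, and the critical offset
#' `w0* = -w_inf(-1 - v0)` that places the fixed point there.
#'
#' @param pm a [planar_model()]; only `v0` matters for `w0*`.
#' @return a list with `v_star`, `w_star`, `I_star`, `w0_star`.
#' @export
planar_tc_point <- function(pm) {
  v_star <- -1
  w_star <- 0
  I_star <- v_star^3 / 3 - v_star   # v - v^3/3 + I = 0 at w = 0
  w0_star <- -planar_winf(v_star - pm$v0)
  list(v_star = v_star, w_star = w_star, I_star = I_star, w0_star = w0_star)
}

#' Fixed points of the planar model
#'
#' Roots of the reduced scalar equation
#' `v - v^3/3 - (w_inf(v - v0) + w0)^2 + I = 0` by sign-change bracketing,
#' with stability from the planar Jacobian.
#'
#' @param pm a [planar_model()].
#' @param v_range search window.
#' @param n_grid grid resolution.
#' @return tibble with `v`, `w`, `stable`, `saddle`, `det`, `tr`.
#' @export
planar_fixed_points <- function(pm, v_range = c(-5, 3), n_grid = 2000) {
  red <- function(v) {
    w <- planar_winf(v - pm$v0) + pm$w0
    v - v^3 / 3 - w^2 + pm$I
  }
  g <- seq(v_range[1], v_range[2], length.out = n_grid)
  f <- red(g)
  sc <- which(sign(f[-1]) * sign(f[-n_grid]) < 0)
  vs <- c(g[f == 0],
          vapply(sc, function(i)
            stats::uniroot(red, lower = g[i], upper = g[i + 1],
                           tol = 1e-13)$root, numeric(1)))
  vs <- sort(vs)
  if (length(vs) > 1) vs <- vs[c(TRUE, diff(vs) > 1e-8)]
  purrr::map_dfr(vs, function(v) {
    w <- planar_winf(v - pm$v0) + pm$w0
    J <- planar_jacobian(pm, v, w)
    d <- det(J)
    tr <- sum(diag(J))
    tibble::tibble(v = v, w = w,
                   stable = d > 0 & tr < 0,
                   saddle = d < 0, det = d, tr = tr)
  })
}

#' Integrate the planar model
#'
#' @param pm a [planar_model()].
#' @param protocol a [protocol()] (applied-current schedule for `I`).
#' @param x0 initial state `c(v, w)`; defaults to the most hyperpolarized
#'   stable fixed point at the first segment's current.
#' @param sample_dt output sampling step.
#' @return a tibble `time`, `v`, `w`.
#' @export
planar_simulate <- function(pm, protocol, x0 = NULL, sample_dt = 0.5) {
  if (is.null(x0)) {
    pm0 <- pm
    pm0$I <- protocol$I[1]
    fp <- planar_fixed_points(pm0)
    fp <- fp[fp$stable, , drop = FALSE]
    if (!nrow(fp)) stop("no stable planar fixed point at the holding current")
    x0 <- c(v = fp$v[1], w = fp$w[1])
  }
  deriv <- function(t, y, parms) {
    list(unname(planar_rhs(pm, y[1], y[2], I = parms$I)))
  }
  pieces <- purrr::map(seq_len(nrow(protocol)), function(i) {
    times <- seq(protocol$t_start[i], protocol$t_end[i], by = sample_dt)
    if (utils::tail(times, 1) < protocol$t_end[i])
      times <- c(times, protocol$t_end[i])
    out <- deSolve::lsoda(y = x0, times = times, func = deriv,
                          parms = list(I = protocol$I[i]),
                          rtol = 1e-8, atol = 1e-10)
    x0 <<- out[nrow(out), -1]
    tibble::tibble(time = out[, 1], v = out[, 2], w = out[, 3])
  })
  out <- dplyr::distinct(dplyr::bind_rows(pieces), time, .keep_all = TRUE)
  out
}

#' Pulse-based bistability test for the planar model
#'
#' Analogue of [bistability_test()] for the planar caricature: a transient
#' depolarizing pulse must leave the model on an attractor distinct from the
#' most hyperpolarized rest, persistently, and a subsequent hyperpolarizing
#' pulse must return it to rest. On the regenerative side of the critical
#' offset `w0*` the model has a depolarized up-attractor coexisting with the
#' hyperpolarized rest at the same current; on the restorative side it is
#' monostable and every pulse relaxes back.
#'
#' @param pm a [planar_model()].
#' @param pulse_amps pulse amplitudes scanned (current units).
#' @param pulse_dur pulse duration.
#' @param persist persistence horizon after pulse offset.
#' @return list with `bistable`, `amp_up`, `amp_down`, `v_rest`, `v_up`.
#' @export
planar_bistability_test <- function(pm, pulse_amps = c(4, 8, 12, 16),
                                    pulse_dur = 5, persist = 400) {
  fp <- planar_fixed_points(pm)
  st <- fp[fp$stable, , drop = FALSE]
  if (!nrow(st))
    return(list(bistable = FALSE, amp_up = NA_real_, amp_down = NA_real_,
                v_rest = NA_real_, v_up = NA_real_))
  rest <- st[which.min(st$v), , drop = FALSE]
  x0 <- c(v = rest$v, w = rest$w)
  for (amp in pulse_amps) {
    tr <- planar_simulate(pm, protocol_steps(c(50, pulse_dur, persist + 100),
                                             c(pm$I, pm$I + amp, pm$I)),
                          x0 = x0, sample_dt = 0.5)
    late <- tr[tr$time > 50 + pulse_dur + persist, , drop = FALSE]
    if (max(abs(late$v - rest$v)) < 0.2) next  # relaxed back: no latch
    v_up <- late$v[nrow(late)]
    x1 <- c(v = tr$v[nrow(tr)], w = tr$w[nrow(tr)])
    for (amp_dn in pulse_amps) {
      tr2 <- planar_simulate(pm, protocol_steps(c(pulse_dur, persist + 100),
                                                c(pm$I - amp_dn, pm$I)),
                             x0 = x1, sample_dt = 0.5)
      late2 <- tr2[tr2$time > pulse_dur + persist, , drop = FALSE]
      if (max(abs(late2$v - rest$v)) < 0.2)
        return(list(bistable = TRUE, amp_up = amp, amp_down = amp_dn,
                    v_rest = rest$v, v_up = v_up))
    }
  }
  list(bistable = FALSE, amp_up = NA_real_, amp_down = NA_real_,
       v_rest = rest$v, v_up = NA_real_)
}

#' Seeded generator of synthetic conductance-based models
#'
#' Draws a random but well-posed conductance model for property testing:
#' always a leak channel, `n_fast` fast activation gates on depolarizing
#' (high-reversal) channels, `n_slow_resto` slow gates constructed to give
#' negative feedback over the -80..-40 mV operating band (delayed-rectifier-
#' or transient-inactivation-like), and `n_slow_regen` slow gates with
#' positive feedback there (calcium-activation-like). Boltzmann kinetics
#' with `V_half` in \[-70, -20\] mV, `|k|` in \[3, 15\] mV, `gbar` in
#' \[0.1, 10\] mS/cm^2; fast taus 0.1-1 ms, slow taus 3-10 ms. Candidates
#' are rejection-sampled until the declared feedback signs hold across the
#' operating band and at least one fixed point lies in \[-100, 0\] mV.
#' Deterministic in `seed`.
#'
#' @param n_fast,n_slow_resto,n_slow_regen gate counts.
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return a [conductance_model()].
#' @export
random_model <- function(n_fast = 1, n_slow_resto = 1, n_slow_regen = 0,
                         seed = 0, max_tries = 200) {
  stopifnot(n_fast >= 0, n_slow_resto >= 0, n_slow_regen >= 0)
  rng <- local_rng(seed)
  band <- seq(-80, -40, length.out = 41)
  for (try in seq_len(max_tries)) {
    chans <- list(channel("leak", gbar = rng$unif(0.05, 0.5),
                          E = rng$unif(-70, -50)))
    k_id <- 0
    ok <- TRUE
    add <- function(ch) chans[[length(chans) + 1]] <<- ch
    for (i in seq_len(n_fast)) {
      g <- gate_boltzmann(paste0("mf", i), "activation", "fast",
                          V_half = rng$unif(-70, -20), k = rng$unif(3, 15),
                          tau = tau_constant(rng$unif(0.1, 1)))
      add(channel(paste0("fastNa", i), gbar = rng$unif(0.1, 10),
                  E = rng$unif(40, 60), gates = list(g)))
    }
    for (i in seq_len(n_slow_resto)) {
      # negative feedback on the band: either an activation gate on an
      # outward (low-reversal) current or an inactivation gate on an inward
      # (high-reversal) current
      if (rng$unif(0, 1) < 0.5) {
        g <- gate_boltzmann(paste0("sr", i), "activation", "slow",
                            V_half = rng$unif(-70, -20), k = rng$unif(3, 15),
                            tau = tau_constant(rng$unif(3, 10)))
        E <- rng$unif(-110, -90)
      } else {
        g <- gate_boltzmann(paste0("sr", i), "inactivation", "slow",
                            V_half = rng$unif(-70, -20), k = -rng$unif(3, 15),
                            tau = tau_constant(rng$unif(3, 10)))
        E <- rng$unif(20, 60)
      }
      add(channel(paste0("resto", i), gbar = rng$unif(0.1, 10), E = E,
                  gates = list(g)))
    }
    for (i in seq_len(n_slow_regen)) {
      # positive feedback on the band: activation gate on an inward current
      g <- gate_boltzmann(paste0("sg", i), "activation", "slow",
                          V_half = rng$unif(-70, -20), k = rng$unif(3, 15),
                          tau = tau_constant(rng$unif(3, 10)))
      add(channel(paste0("regen", i), gbar = rng$unif(0.1, 10),
                  E = rng$unif(0, 60), gates = list(g)))
    }
    m <- conductance_model(channels = chans)
    gt <- model_gates(m)
    signs_ok <- TRUE
    for (g in gt$gate[startsWith(gt$gate, "sr")])
      signs_ok <- signs_ok && all(feedback_weight(m, band, g) < 0)
    for (g in gt$gate[startsWith(gt$gate, "sg")])
      signs_ok <- signs_ok && all(feedback_weight(m, band, g) > 0)
    if (!signs_ok) next
    fp <- fixed_points(m, V_range = c(-100, 0), n_grid = 200)
    if (!nrow(fp) || !any(fp$stable)) next
    return(m)
  }
  stop("random_model: rejection budget exhausted (seed = ", seed,
       ", counts = ", n_fast, "/", n_slow_resto, "/", n_slow_regen, ")")
}

# Self-contained uniform RNG stream so model generation is deterministic in
# its seed and leaves the global RNG untouched.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  draw <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    x
  }
  list(unif = function(a, b) a + (b - a) * draw(1))
}
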