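#' @keywords internal
# Partial derivative of F = I_app - sum(I_ion) with respect to V at fixed
# gate values: minus the instantaneous conductance sum. Vectorized over V
# when gate_values entries are aligned vectors.
dF_dV <- function(model, V, gate_values) {
  tot <- 0
  for (ch in model$channels) {
    prod_x <- 1
    for (g in ch$gates)
      prod_x <- prod_x * gate_value_of(model, g, gate_values)^g$exponent
    tot <- tot + ch$gbar * prod_x
  }
  -tot
}

# Partial derivative of F with respect to one live gate value.
dF_dx <- function(model, V, gate_values, gate_name) {
  hit <- find_gate(model, gate_name)
  ch <- hit$channel
  g <- hit$gate
  prod_other <- 1
  for (gg in ch$gates) {
    if (gg$name == gate_name) next
    prod_other <- prod_other * gate_value_of(model, gg, gate_values)^gg$exponent
  }
  x <- gate_value_of(model, g, gate_values)
  -ch$gbar * g$exponent * x^(g$exponent - 1) * prod_other * (V - ch$E)
}

# Steady-state evaluation, vectorized over V: for each live gate, x_inf(V).
steady_gate_values_vec <- function(model, V) {
  out <- list()
  for (ch in model$channels)
    for (g in ch$gates)
      if (g$tclass != "ultraslow") out[[g$name]] <- gate_steady(g, V)
  out
}

# Voltage-feedback weight of a gate at steady state:
# w(V) = dF/dx * dx_inf/dV, in mS/cm^2. Vectorized over V.
gate_weight_steady <- function(model, V, gate_name,
                               gate_values = steady_gate_values_vec(model, V)) {
  g <- find_gate(model, gate_name)$gate
  dF_dx(model, V, gate_values, gate_name) * gate_steady_slope(g, V)
}

#' Reduced voltage slope over a gate subset
#'
#' The slope of the net current along the steady-state manifold of a gate
#' subset S:
#' `s(V; S) = dF/dV + sum_{x in S} (dF/dx) * (dx_inf/dV)`,
#' in mS/cm^2, with all gates evaluated at `x_inf(V)`. With S = all fast
#' gates this is the fast-subsystem singularity test function; with S = all
#' fast and slow gates its zero set coincides (up to a positive factor and a
#' sign of known parity) with the vanishing of the unit-tau Jacobian
#' determinant. The sum is accumulated fast-gates-first so that
#' `reduced_slope(fast + slow) == reduced_slope(fast) + slow_balance(...)`
#' holds exactly in floating point.
#'
#' @param model a [conductance_model()].
#' @param V membrane potential, mV (vectorized).
#' @param gates character vector of live-gate names, or one of the shortcuts
#'   `"fast"` (all fast gates), `"fast_slow"` (all fast and slow gates),
#'   `"none"`.
#' @return slope in mS/cm^2.
#' @export
reduced_slope <- function(model, V, gates = "fast_slow") {
  gt <- gate_table_live(model)
  if (identical(gates, "fast")) gates <- gt$gate[gt$tclass == "fast"]
  else if (identical(gates, "fast_slow")) gates <- gt$gate
  else if (identical(gates, "none")) gates <- character()
  unknown <- setdiff(gates, gt$gate)
  if (length(unknown))
    stop("unknown gate(s) in subset: ", paste(unknown, collapse = ", "))
  gv <- steady_gate_values_vec(model, V)
  # keep model gate order, fast before slow, for exact decomposability
  fast <- gt$gate[gt$tclass == "fast" & gt$gate %in% gates]
  slow <- gt$gate[gt$tclass == "slow" & gt$gate %in% gates]
  s <- dF_dV(model, V, gv)
  for (g in fast) s <- s + gate_weight_steady(model, V, g, gv)
  slow_sum <- 0
  for (g in slow) slow_sum <- slow_sum + gate_weight_steady(model, V, g, gv)
  s + slow_sum
}

#' Jacobian of a conductance model at a state
#'
#' The Jacobian has arrowhead structure: the V row holds `(1/C) dF/dV` and
#' `(1/C) dF/dx_i`; each gate row has `d(dx/dt)/dV` in the first column and
#' `-1/tau_i` on the diagonal, and zeros elsewhere. Away from steady state
#' the first-column entry carries the full derivative
#' `(dx_inf/dV - (x_inf - x) dtau/dV / tau) / tau`, which reduces to
#' `(dx_inf/dV)/tau` at fixed points.
#'
#' @param model a [conductance_model()].
#' @param state named numeric vector `c(V = ..., <gates> = ...)`.
#' @param tau_mode see [gate_tau()].
#' @return a square matrix (1/ms) with dimnames `c("V", gates)`.
#' @export
model_jacobian <- function(model, state, tau_mode = "physiological") {
  V <- unname(state[["V"]])
  gnames <- state_gate_names(model)
  gates <- as.list(state[gnames])
  n <- 1 + length(gnames)
  J <- matrix(0, n, n, dimnames = list(c("V", gnames), c("V", gnames)))
  C <- model$capacitance
  J["V", "V"] <- dF_dV(model, V, gates) / C
  for (nm in gnames) {
    g <- find_gate(model, nm)$gate
    J["V", nm] <- dF_dx(model, V, gates, nm) / C
    tau <- gate_tau(g, V, tau_mode)
    dtau <- gate_tau_slope(g, V, tau_mode)
    J[nm, "V"] <- (gate_steady_slope(g, V) -
                     (gate_steady(g, V) - gates[[nm]]) * dtau / tau) / tau
    J[nm, nm] <- -1 / tau
  }
  J
}

#' Locate all fixed points of a model in a voltage window
#'
#' Fixed points satisfy `x = x_inf(V)` componentwise, so the search reduces
#' to the scalar equation `F(V, x_inf(V); I_app) = 0`: sign changes are
#' bracketed on a voltage grid, polished by bisection ([stats::uniroot]) and
#' a final Newton step using the exact reduced slope. Each root is returned
#' with its full-Jacobian eigenvalues (physiological tau), stability flag and
#' slow balance.
#'
#' @param model a [conductance_model()].
#' @param I_app applied current (defaults to the model's).
#' @param V_range search window, mV.
#' @param n_grid number of grid points (>= 50).
#' @param dedup_tol roots closer than this (mV) are merged.
#' @return a tibble with one row per fixed point: `V`, `I_app`, `stable`,
#'   `slow_balance`, `max_re`, `n_unstable`, and list-columns `gate_values`,
#'   `eigenvalues`. Zero rows if no equilibrium lies in the window.
#' @export
fixed_points <- function(model, I_app = model$I_app, V_range = c(-100, 20),
                         n_grid = 400, dedup_tol = 1e-6) {
  stopifnot(n_grid >= 50, all(is.finite(V_range)))
  grid <- seq(V_range[1], V_range[2], length.out = n_grid)
  Fg <- net_current_steady_vec(model, grid, I_app)
  roots <- numeric()
  zero_hits <- grid[Fg == 0]
  roots <- c(roots, zero_hits)
  sgn <- sign(Fg)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(function(v) net_current(model, v, I_app = I_app),
                     lower = grid[i], upper = grid[i + 1],
                     tol = 1e-12)$root,
      error = function(e) {
        warning("fixed-point bracket [", signif(grid[i], 6), ", ",
                signif(grid[i + 1], 6), "] failed to converge: ",
                conditionMessage(e))
        NA_real_
      })
    if (!is.na(r)) roots <- c(roots, newton_polish_fp(model, r, I_app))
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > dedup_tol)]
  purrr::map_dfr(roots, function(v) fixed_point_record(model, v, I_app))
}

# One or two Newton steps on F(V, x_inf(V)) = 0 using s(V; fast+slow) as the
# exact derivative; keeps |F| at the 1e-9*(1+|I_app|) residual scale.
newton_polish_fp <- function(model, V, I_app, n = 3) {
  for (i in seq_len(n)) {
    f <- net_current(model, V, I_app = I_app)
    s <- reduced_slope(model, V, "fast_slow")
    if (abs(s) < 1e-14) break
    step <- f / s
    if (!is.finite(step) || abs(step) > 1) break
    V <- V - step
  }
  V
}

fixed_point_record <- function(model, V, I_app = model$I_app) {
  gv <- steady_gate_values(model, V)
  st <- c(V = V, unlist(gv))
  J <- model_jacobian(model, st, tau_mode = "physiological")
  ev <- eigen(J, only.values = TRUE)$values
  tibble::tibble(
    V = V,
    I_app = I_app,
    stable = all(Re(ev) < 0),
    slow_balance = slow_balance(model, V),
    max_re = max(Re(ev)),
    n_unstable = sum(Re(ev) > 0),
    gate_values = list(gv),
    eigenvalues = list(ev))
}

# F(V, x_inf(V); I_app) vectorized over a voltage grid.
net_current_steady_vec <- function(model, V, I_app = model$I_app) {
  gv <- steady_gate_values_vec(model, V)
  tot <- 0
  for (ch in model$channels)
    tot <- tot + channel_current(ch, V, gv, model = model)
  I_app - tot
}
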