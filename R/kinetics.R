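#' Gating-variable kinetics
#'
#' A gate is one Hodgkin-Huxley-style gating variable: a state in \[0, 1\]
#' relaxing to a voltage-dependent steady state `x_inf(V)` with time constant
#' `tau(V)`. Gates are declared with a `role` (activation gates have strictly
#' increasing `x_inf`, inactivation gates strictly decreasing) and a timescale
#' class (`fast`, `slow`, or `ultraslow`); the timescale class drives the
#' restorative/regenerative analysis and is declared, never inferred.
#'
#' Two kinetics dialects are supported:
#' \describe{
#'   \item{Boltzmann}{`x_inf(V) = 1 / (1 + exp(-(V - V_half) / k))` with a
#'     signed slope factor `k` (mV); negative `k` gives a decreasing sigmoid.}
#'   \item{alpha/beta}{forward and backward rate expressions (per ms) in the
#'     variable `V`, giving `x_inf = alpha / (alpha + beta)` and, when the
#'     time constant is declared as `tau_alphabeta()`, `tau = 1/(alpha+beta)`.}
#' }
#'
#' Rate and time-constant expressions are plain R expressions of `V` given as
#' strings, e.g. `"0.1 * vtrap(V + 40, 10)"`. They are evaluated in a sealed
#' environment exposing `exp`, `log`, `vtrap` and arithmetic only, so model
#' files stay declarative.
#'
#' @param name gate identifier, unique within the model.
#' @param role `"activation"` or `"inactivation"`.
#' @param tclass `"fast"`, `"slow"`, or `"ultraslow"`.
#' @param exponent positive integer power in the current law.
#' @param V_half,k Boltzmann half-activation (mV) and signed slope (mV).
#' @param alpha,beta rate expressions in `V` (strings, per ms).
#' @param tau time-constant spec from [tau_constant()], [tau_expression()] or
#'   [tau_alphabeta()].
#' @return an object of class `"tcs_gate"`.
#' @examples
#' n <- gate_boltzmann("n", "activation", "slow", V_half = -53, k = 15,
#'                     tau = tau_constant(5))
#' gate_steady(n, -53)  # 0.5 at the half-activation potential
#' @name gate
NULL

#' @rdname gate
#' @export
gate_boltzmann <- function(name, role, tclass, V_half, k, exponent = 1L,
                           tau = tau_constant(1)) {
  stopifnot(is.numeric(V_half), is.numeric(k), k != 0)
  new_gate(name, role, tclass, exponent,
           kinetics = list(type = "boltzmann", V_half = as.numeric(V_half),
                           k = as.numeric(k)),
           tau = tau)
}

#' @rdname gate
#' @export
gate_alphabeta <- function(name, role, tclass, alpha, beta, exponent = 1L,
                           tau = tau_alphabeta()) {
  stopifnot(is.character(alpha), is.character(beta))
  new_gate(name, role, tclass, exponent,
           kinetics = list(type = "alphabeta", alpha = alpha, beta = beta),
           tau = tau)
}

#' Time-constant specifications
#'
#' @param value positive constant (ms).
#' @param expr expression in `V` (string, ms).
#' @return a tagged list consumed by the gate constructors.
#' @export
tau_constant <- function(value) {
  stopifnot(is.numeric(value), value > 0)
  list(type = "constant", value = as.numeric(value))
}

#' @rdname tau_constant
#' @export
tau_expression <- function(expr) {
  stopifnot(is.character(expr))
  list(type = "expression", expr = expr)
}

#' @rdname tau_constant
#' @export
tau_alphabeta <- function() list(type = "alphabeta")

new_gate <- function(name, role, tclass, exponent, kinetics, tau) {
  role <- match.arg(role, c("activation", "inactivation"))
  tclass <- match.arg(tclass, c("fast", "slow", "ultraslow"))
  stopifnot(is.character(name), nchar(name) > 0,
            exponent >= 1, exponent == as.integer(exponent))
  if (identical(tau$type, "alphabeta") && !identical(kinetics$type, "alphabeta"))
    stop("tau_alphabeta() requires alpha/beta kinetics (gate '", name, "')")
  # compile rate/tau expressions once; the strings stay authoritative for
  # serialization, the closures are evaluation caches
  if (identical(kinetics$type, "alphabeta")) {
    kinetics$alpha_fun <- compile_rate(kinetics$alpha)
    kinetics$beta_fun <- compile_rate(kinetics$beta)
  }
  if (identical(tau$type, "expression"))
    tau$fun <- compile_rate(tau$expr)
  g <- structure(
    list(name = name, role = role, tclass = tclass,
         exponent = as.integer(exponent), kinetics = kinetics, tau = tau),
    class = "tcs_gate")
  validate_gate(g)
  g
}

# Sealed evaluation scope for kinetics expressions. `vtrap(x, y)` is the
# overflow- and singularity-safe form of x / (1 - exp(-x/y)) that appears in
# the classic rate laws; near x = 0 the removable 0/0 is replaced by its
# series value y + x/2 + O(x^2).
kin_env <- function() {
  e <- new.env(parent = baseenv())
  e$vtrap <- vtrap
  e
}

#' Singularity-safe rational-exponential rate helper
#'
#' `vtrap(x, y)` evaluates `x / (1 - exp(-x / y))`, replacing the removable
#' singularity at `x = 0` by its limit `y` (second-order series within
#' `|x/y| < 1e-6`). Used by the standard sodium/potassium activation rates.
#'
#' @param x,y numeric vectors (mV).
#' @export
vtrap <- function(x, y) {
  z <- x / y
  out <- ifelse(abs(z) < 1e-6, y * (1 + z / 2), x / (1 - exp(-z)))
  out
}

compile_rate <- function(expr) {
  fn_env <- kin_env()
  body <- str2lang(expr)
  function(V) {
    env <- new.env(parent = fn_env)
    env$V <- V
    eval(body, env)
  }
}

gate_rates <- function(gate, V) {
  list(alpha = gate$kinetics$alpha_fun(V),
       beta = gate$kinetics$beta_fun(V))
}

#' Steady-state value of a gate
#'
#' Overflow-safe evaluation of `x_inf(V)`; saturates to the 0/1 limits for
#' large `|V|`. Vectorized over `V`.
#'
#' @param gate a [gate] object.
#' @param V membrane potential(s), mV.
#' @return values in (0, 1).
#' @export
gate_steady <- function(gate, V) {
  k <- gate$kinetics
  if (identical(k$type, "boltzmann")) {
    stats::plogis((V - k$V_half) / k$k)
  } else {
    r <- gate_rates(gate, V)
    r$alpha / (r$alpha + r$beta)
  }
}

#' Voltage derivative of the gate steady state
#'
#' Analytic for Boltzmann kinetics (`x_inf (1 - x_inf) / k`); for alpha/beta
#' kinetics a Richardson-extrapolated central difference with base step
#' 1e-3 mV is used (relative accuracy ~1e-10 on smooth rates).
#'
#' @inheritParams gate_steady
#' @return `dx_inf/dV` in 1/mV, vectorized over `V`.
#' @export
gate_steady_slope <- function(gate, V) {
  k <- gate$kinetics
  if (identical(k$type, "boltzmann")) {
    x <- gate_steady(gate, V)
    x * (1 - x) / k$k
  } else {
    richardson_deriv(function(v) gate_steady(gate, v), V)
  }
}

# Richardson-extrapolated five-point central difference, base step h.
richardson_deriv <- function(f, x, h = 1e-3) {
  (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) / (12 * h)
}

#' Gate time constant
#'
#' @inheritParams gate_steady
#' @param tau_mode `"physiological"` (declared time constants) or `"unit"`
#'   (all taus set to 1 ms; the algebraic conditions for the excitability
#'   switch are unaffected by this substitution).
#' @return tau in ms, vectorized over `V`.
#' @export
gate_tau <- function(gate, V, tau_mode = c("physiological", "unit")) {
  tau_mode <- match.arg(tau_mode)
  if (tau_mode == "unit") return(rep(1, length(V)))
  tt <- gate$tau
  switch(tt$type,
    constant = rep(tt$value, length(V)),
    expression = tt$fun(V),
    alphabeta = {
      r <- gate_rates(gate, V)
      1 / (r$alpha + r$beta)
    },
    stop("unknown tau type: ", tt$type))
}

gate_tau_slope <- function(gate, V, tau_mode = "physiological") {
  if (tau_mode == "unit" || identical(gate$tau$type, "constant"))
    return(rep(0, length(V)))
  richardson_deriv(function(v) gate_tau(gate, v, tau_mode), V)
}

# Load-time checks on a 201-point grid over [-120, 60] mV: x_inf in (0,1),
# monotone with the sign declared by the role, tau positive.
validate_gate <- function(gate, grid = seq(-120, 60, length.out = 201)) {
  x <- gate_steady(gate, grid)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1) ||
      all(x < 1e-12) || all(x > 1 - 1e-12))
    stop("gate '", gate$name, "': x_inf must lie in (0,1) on [-120, 60] mV")
  # strict monotonicity enforced away from numerical saturation; steep
  # sigmoids legitimately flatline to 0/1 in double precision at the edges
  d <- diff(x)
  interior <- x[-1] > 1e-12 & x[-1] < 1 - 1e-12 &
    x[-length(x)] > 1e-12 & x[-length(x)] < 1 - 1e-12
  if (gate$role == "activation" && (any(d < 0) || !any(d[interior] > 0) ||
                                    any(d[interior] <= 0)))
    stop("gate '", gate$name,
         "': declared activation but x_inf is not strictly increasing")
  if (gate$role == "inactivation" && (any(d > 0) || !any(d[interior] < 0) ||
                                      any(d[interior] >= 0)))
    stop("gate '", gate$name,
         "': declared inactivation but x_inf is not strictly decreasing")
  tau <- gate_tau(gate, grid)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("gate '", gate$name, "': tau(V) must be positive on [-120, 60] mV")
  invisible(gate)
}

#' @export
print.tcs_gate <- function(x, ...) {
  cat(sprintf("<gate %s: %s, %s, p=%d, %s kinetics>\n",
              x$name, x$role, x$tclass, x$exponent, x$kinetics$type))
  invisible(x)
}
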