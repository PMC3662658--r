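#' Ionic channels and conductance-based models
#'
#' A channel is a maximal conductance `gbar` (mS/cm^2), a reversal potential
#' `E` (mV) and an ordered set of [gate]s; its current is
#' `gbar * prod(x^p) * (V - E)` (uA/cm^2). A conductance model couples the
#' membrane equation `C dV/dt = I_app - sum(I_ion)` to first-order gate
#' relaxation `dx/dt = (x_inf(V) - x) / tau_x(V)`. Ultraslow (adaptation)
#' gates are frozen: they enter the algebra as constant parameters taken from
#' the model's `frozen` mapping and contribute no state.
#'
#' Units throughout: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2.
#'
#' @param name channel identifier.
#' @param gbar maximal conductance, mS/cm^2 (>= 0).
#' @param E reversal potential, mV.
#' @param gates list of [gate] objects (possibly empty, e.g. a leak).
#' @param archetype optional channel-archetype label (see [table1_class()]).
#' @return `channel()` returns a `"tcs_channel"`; `conductance_model()` a
#'   `"conductance_model"`.
#' @examples
#' leak <- channel("leak", gbar = 0.3, E = -54.4)
#' mod <- conductance_model(channels = list(leak))
#' net_current(mod, V = -44.4)  # -3 uA/cm^2 of leak at I_app = 0
#' @name conductance_model
NULL

#' @rdname conductance_model
#' @export
channel <- function(name, gbar, E, gates = list(), archetype = NULL) {
  stopifnot(is.character(name), is.numeric(gbar), gbar >= 0, is.numeric(E))
  nm <- vapply(gates, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("channel '", name, "': duplicate gate names")
  structure(list(name = name, gbar = as.numeric(gbar), E = as.numeric(E),
                 gates = gates, archetype = archetype),
            class = "tcs_channel")
}

#' @rdname conductance_model
#' @param capacitance membrane capacitance C, uF/cm^2 (> 0).
#' @param channels list of [channel()] objects (at least one).
#' @param frozen named numeric vector fixing every ultraslow gate (and any
#'   declared auxiliary scalar) at a constant value.
#' @param I_app applied current, uA/cm^2.
#' @param aux character vector of auxiliary scalar names that `frozen` may
#'   reference (e.g. an intracellular calcium level a rate expression uses).
#' @export
conductance_model <- function(channels, capacitance = 1, frozen = c(),
                              I_app = 0, aux = character()) {
  stopifnot(is.numeric(capacitance), capacitance > 0, length(channels) >= 1)
  frozen <- unlist(frozen)
  if (length(frozen) && is.null(names(frozen)))
    stop("frozen values must be named")
  frozen <- stats::setNames(as.numeric(frozen), names(frozen))
  m <- structure(
    list(capacitance = as.numeric(capacitance), channels = channels,
         frozen = frozen, I_app = as.numeric(I_app), aux = aux),
    class = "conductance_model")
  m$gate_table <- build_gate_table(m)  # cached; structure never mutates
  validate_model(m)
  m
}

build_gate_table <- function(m) {
  rows <- lapply(m$channels, function(ch) {
    if (!length(ch$gates)) return(NULL)
    data.frame(
      channel = ch$name,
      gate = vapply(ch$gates, `[[`, character(1), "name"),
      role = vapply(ch$gates, `[[`, character(1), "role"),
      tclass = vapply(ch$gates, `[[`, character(1), "tclass"),
      exponent = vapply(ch$gates, `[[`, integer(1), "exponent"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(channel = character(), gate = character(),
                      role = character(), tclass = character(),
                      exponent = integer())
  out
}

validate_model <- function(m) {
  gt <- model_gates(m, frozen_too = TRUE)
  if (anyDuplicated(gt$gate)) stop("gate names must be unique across the model")
  ultras <- gt$gate[gt$tclass == "ultraslow"]
  missing_frozen <- setdiff(ultras, names(m$frozen))
  if (length(missing_frozen))
    stop("ultraslow gates must be frozen: ", paste(missing_frozen, collapse = ", "))
  unknown <- setdiff(names(m$frozen), c(ultras, m$aux))
  if (length(unknown))
    stop("frozen names do not resolve to ultraslow gates or declared ",
         "auxiliaries: ", paste(unknown, collapse = ", "))
  bad <- m$frozen[names(m$frozen) %in% ultras]
  if (length(bad) && (any(bad < 0) || any(bad > 1)))
    stop("frozen gate values must lie in [0, 1]")
  invisible(m)
}

#' Tabulate the gates of a model
#'
#' @param model a [conductance_model()].
#' @param frozen_too include frozen (ultraslow) gates.
#' @return a tibble with one row per gate: `channel`, `gate`, `role`,
#'   `tclass`, `exponent`.
#' @export
model_gates <- function(model, frozen_too = FALSE) {
  rows <- model$gate_table
  if (is.null(rows)) rows <- build_gate_table(model)
  if (!frozen_too) rows <- rows[rows$tclass != "ultraslow", , drop = FALSE]
  tibble::as_tibble(rows)
}

# internal fast path: cached base data.frame, live gates only
gate_table_live <- function(model) {
  rows <- model$gate_table
  if (is.null(rows)) rows <- build_gate_table(model)
  rows[rows$tclass != "ultraslow", , drop = FALSE]
}

#' Names of the live (state-carrying) gates, in model order
#'
#' Frozen ultraslow gates are excluded; these names, prefixed by `"V"`, are
#' the state coordinates of the model ODE.
#'
#' @param model a [conductance_model()].
#' @export
state_gate_names <- function(model) gate_table_live(model)$gate

#' Look up a gate and its owning channel by name
#'
#' @param model a [conductance_model()].
#' @param name gate name.
#' @return a list with elements `channel` and `gate`.
#' @export
find_gate <- function(model, name) {
  for (ch in model$channels)
    for (g in ch$gates) if (g$name == name) return(list(channel = ch, gate = g))
  stop("unknown gate: ", name)
}

# gate value inside a current product: frozen gates read from model$frozen,
# live gates from the supplied mapping.
gate_value_of <- function(model, gate, gate_values) {
  if (gate$tclass == "ultraslow") return(unname(model$frozen[[gate$name]]))
  if (!gate$name %in% names(gate_values))
    stop("missing value for gate '", gate$name, "'")
  v <- gate_values[[gate$name]]
  if (is.null(v)) stop("missing value for gate '", gate$name, "'")
  v
}

#' Ionic current through one channel
#'
#' @param channel a [channel()].
#' @param V membrane potential, mV (vectorized).
#' @param gate_values named list/vector of gate values (live gates only);
#'   each entry may be a vector aligned with `V`.
#' @param model optional owning model, needed to resolve frozen gates.
#' @return current in uA/cm^2.
#' @export
channel_current <- function(channel, V, gate_values = c(), model = NULL) {
  prod_x <- 1
  for (g in channel$gates) {
    x <- if (g$tclass == "ultraslow") {
      if (is.null(model)) stop("frozen gate '", g$name,
                               "' needs the owning model to resolve its value")
      gate_value_of(model, g, gate_values)
    } else {
      if (!g$name %in% names(gate_values))
        stop("missing value for gate '", g$name, "'")
      gate_values[[g$name]]
    }
    prod_x <- prod_x * x^g$exponent
  }
  channel$gbar * prod_x * (V - channel$E)
}

#' Steady-state gate values at a voltage
#'
#' @param model a [conductance_model()].
#' @param V membrane potential, mV (scalar).
#' @return named list of `x_inf(V)` for every live (non-frozen) gate.
#' @export
steady_gate_values <- function(model, V) {
  out <- list()
  for (ch in model$channels)
    for (g in ch$gates)
      if (g$tclass != "ultraslow") out[[g$name]] <- gate_steady(g, V)
  out
}

#' Net membrane current F(V, x)
#'
#' `F = I_app - sum of channel currents`; the membrane equation is
#' `dV/dt = F / C`.
#'
#' @inheritParams steady_gate_values
#' @param gate_values named list of live-gate values; defaults to steady state
#'   at `V`.
#' @param I_app applied current; defaults to the model's.
#' @return F in uA/cm^2.
#' @export
net_current <- function(model, V, gate_values = steady_gate_values(model, V),
                        I_app = model$I_app) {
  tot <- 0
  for (ch in model$channels)
    tot <- tot + channel_current(ch, V, gate_values, model = model)
  I_app - tot
}

#' Right-hand side of the model ODE
#'
#' @inheritParams net_current
#' @param state named numeric vector `c(V = ..., <gate> = ...)` over the live
#'   gates.
#' @param tau_mode see [gate_tau()].
#' @return named numeric vector of time derivatives (mV/ms and 1/ms).
#' @export
model_rhs <- function(model, state, I_app = model$I_app,
                      tau_mode = "physiological") {
  V <- unname(state[["V"]])
  gates <- as.list(state[setdiff(names(state), "V")])
  dV <- net_current(model, V, gates, I_app) / model$capacitance
  d <- c(V = dV)
  for (ch in model$channels) for (g in ch$gates) {
    if (g$tclass == "ultraslow") next
    x <- gates[[g$name]]
    d[[g$name]] <- (gate_steady(g, V) - x) / gate_tau(g, V, tau_mode)
  }
  d
}

#' Install a bifurcation parameter value in a model
#'
#' Returns a copy of the model with `lambda` written into the target named by
#' `bif_param`: a channel's maximal conductance, a channel's reversal
#' potential, or a frozen (adaptation) value.
#'
#' @param model a [conductance_model()].
#' @param bif_param a [bif_param()].
#' @param lambda new parameter value.
#' @export
set_bif_param <- function(model, bif_param, lambda) {
  kind <- bif_param$kind
  target <- bif_param$target
  if (kind %in% c("max_conductance", "reversal_potential")) {
    idx <- which(vapply(model$channels, `[[`, character(1), "name") == target)
    if (!length(idx)) stop("unknown channel: ", target)
    field <- if (kind == "max_conductance") "gbar" else "E"
    model$channels[[idx]][[field]] <- lambda
  } else if (kind == "frozen_value") {
    if (!target %in% names(model$frozen)) stop("unknown frozen value: ", target)
    model$frozen[[target]] <- lambda
  } else stop("unknown bif_param kind: ", kind)
  model
}

#' Declare a bifurcation parameter
#'
#' @param kind `"max_conductance"`, `"reversal_potential"`, or
#'   `"frozen_value"`.
#' @param target channel name (for conductance/reversal) or frozen-variable
#'   name.
#' @param range closed finite interval searched by [solve_tc()].
#' @export
bif_param <- function(kind = c("max_conductance", "reversal_potential",
                               "frozen_value"),
                      target, range) {
  kind <- match.arg(kind)
  stopifnot(is.character(target), length(range) == 2, all(is.finite(range)),
            range[1] < range[2])
  structure(list(kind = kind, target = target, range = as.numeric(range)),
            class = "tcs_bif_param")
}

bif_param_value <- function(model, bif_param) {
  if (bif_param$kind == "frozen_value")
    return(unname(model$frozen[[bif_param$target]]))
  idx <- which(vapply(model$channels, `[[`, character(1), "name") ==
                 bif_param$target)
  field <- if (bif_param$kind == "max_conductance") "gbar" else "E"
  model$channels[[idx]][[field]]
}

#' @export
print.conductance_model <- function(x, ...) {
  gt <- model_gates(x, frozen_too = TRUE)
  cat(sprintf(
    "<conductance model: %d channel(s), %d gate(s) (%d frozen), C = %g uF/cm^2, I_app = %g uA/cm^2>\n",
    length(x$channels), nrow(gt), sum(gt$tclass == "ultraslow"),
    x$capacitance, x$I_app))
  for (ch in x$channels) {
    gs <- if (length(ch$gates))
      paste(vapply(ch$gates, function(g)
        sprintf("%s^%d[%s,%s]", g$name, g$exponent,
                substr(g$role, 1, 4), g$tclass), character(1)), collapse = " ")
    else "(no gates)"
    cat(sprintf("  %-10s gbar = %6.3g  E = %7.3g  %s\n", ch$name, ch$gbar,
                ch$E, gs))
  }
  invisible(x)
}
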