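#' Voltage-feedback weight of a slow gate
#'
#' For a slow gating variable x the weight
#' `w = (dF/dx) * (dx_inf/dV)` (mS/cm^2), with all gates at steady state,
#' measures the feedback the gate exerts on voltage perturbations around an
#' operating point: negative weight is negative feedback (the gate is
#' restorative there), positive weight is positive feedback (regenerative).
#' The weight is linear in the owning channel's maximal conductance.
#'
#' @param model a [conductance_model()].
#' @param V operating voltage, mV (vectorized).
#' @param gate name of a slow gate.
#' @return weight in mS/cm^2.
#' @export
feedback_weight <- function(model, V, gate) {
  g <- find_gate(model, gate)$gate
  if (g$tclass != "slow")
    stop("feedback_weight is defined for slow gates; '", gate, "' is ",
         g$tclass)
  gate_weight_steady(model, V, gate)
}

#' Slow balance of a model at a voltage
#'
#' The signed sum of the feedback weights of all slow gates. Its zero set is
#' the balance condition separating restorative (negative balance) from
#' regenerative (positive balance) excitability; it equals
#' `reduced_slope(model, V, "fast_slow") - reduced_slope(model, V, "fast")`
#' exactly.
#'
#' @inheritParams feedback_weight
#' @return balance B in mS/cm^2 (0 for a model with no slow gates).
#' @export
slow_balance <- function(model, V) {
  gt <- gate_table_live(model)
  slow <- gt$gate[gt$tclass == "slow"]
  gv <- steady_gate_values_vec(model, V)
  b <- 0
  for (g in slow) b <- b + gate_weight_steady(model, V, g, gv)
  if (length(V) > 1 && length(b) == 1) b <- rep(b, length(V))
  b
}

sign_label <- function(x, tol_B) {
  dplyr::case_when(x < -tol_B ~ "restorative",
                   x > tol_B ~ "regenerative",
                   TRUE ~ "balanced")
}

#' Per-gate feedback report at an operating voltage
#'
#' Tabulates every slow gate's feedback weight and restorative/regenerative
#' label at `V`, plus channel membership. Channels that declare a Table-style
#' archetype are cross-checked against the dynamic sign of their summed slow
#' weights; a disagreement raises a warning (kinetic parameterizations of
#' some channel subtypes legitimately flip the static class).
#'
#' @inheritParams feedback_weight
#' @param V operating voltage, mV (scalar).
#' @param tol_B absolute balance tolerance (mS/cm^2) below which a weight or
#'   balance counts as `"balanced"`.
#' @return a tibble of class `"feedback_report"` with columns `channel`,
#'   `gate`, `role`, `weight`, `label`; the voltage, the restorative and
#'   regenerative totals, the net balance and the model-level label are
#'   attached as attributes and summarized by [glance.feedback_report()].
#' @export
feedback_report <- function(model, V, tol_B = 1e-8) {
  gt <- gate_table_live(model)
  slow <- gt[gt$tclass == "slow", , drop = FALSE]
  w <- vapply(slow$gate, function(g) feedback_weight(model, V, g), numeric(1))
  rep_tbl <- tibble::tibble(
    channel = slow$channel, gate = slow$gate, role = slow$role,
    weight = unname(w), label = sign_label(unname(w), tol_B))
  total_regen <- sum(rep_tbl$weight[rep_tbl$weight > 0])
  total_resto <- sum(rep_tbl$weight[rep_tbl$weight < 0])
  balance <- slow_balance(model, V)
  check_archetypes(model, rep_tbl, tol_B)
  # a model with no slow gate at all is neutral, not balanced: there is
  # nothing to balance
  model_label <- if (!nrow(rep_tbl)) "neutral" else sign_label(balance, tol_B)
  structure(rep_tbl,
            class = c("feedback_report", class(rep_tbl)),
            V = V, tol_B = tol_B,
            total_regenerative = total_regen,
            total_restorative = total_resto,
            balance = balance,
            model_label = model_label)
}

#' @rdname feedback_report
#' @param x a `feedback_report`.
#' @param ... unused.
#' @export
glance.feedback_report <- function(x, ...) {
  tibble::tibble(
    V = attr(x, "V"),
    total_regenerative = attr(x, "total_regenerative"),
    total_restorative = attr(x, "total_restorative"),
    balance = attr(x, "balance"),
    label = attr(x, "model_label"))
}

check_archetypes <- function(model, rep_tbl, tol_B) {
  for (ch in model$channels) {
    if (is.null(ch$archetype)) next
    static <- tryCatch(table1_class(ch$archetype), error = function(e) NA)
    if (is.na(static)) next
    wsum <- sum(rep_tbl$weight[rep_tbl$channel == ch$name])
    dynamic <- switch(sign_label(wsum, tol_B),
                      restorative = "slow restorative",
                      regenerative = "slow regenerative",
                      balanced = "neutral")
    if (!length(rep_tbl$weight[rep_tbl$channel == ch$name]))
      dynamic <- "neutral"
    if (!identical(static, dynamic))
      warning("channel '", ch$name, "' (archetype '", ch$archetype,
              "'): static class '", static,
              "' disagrees with dynamic sign '", dynamic,
              "' at this operating point", call. = FALSE)
  }
  invisible(NULL)
}

#' Excitability type at the resting point
#'
#' Locates the model's stable fixed points at `I_app`, takes the most
#' hyperpolarized stable one as the resting point, and labels the model from
#' the sign of the slow balance there. If another stable equilibrium carries
#' the opposite balance sign the model is additionally flagged `mixed`
#' (coexistence of a regenerative down-state with a restorative up-state).
#'
#' @param model a [conductance_model()].
#' @param I_app holding current, uA/cm^2.
#' @param V_range,n_grid fixed-point search controls, see [fixed_points()].
#' @param tol_B balance tolerance, mS/cm^2.
#' @return a list with `label` (`"restorative"`, `"regenerative"`,
#'   `"balanced"`, or `"neutral"` for a model with no slow gates), `mixed`
#'   flag, `rest` (one-row fixed-point tibble) and
#'   `report` (the [feedback_report()] at the resting voltage).
#' @export
excitability_at_rest <- function(model, I_app = model$I_app,
                                 V_range = c(-100, 20), n_grid = 400,
                                 tol_B = 1e-8) {
  fp <- fixed_points(model, I_app, V_range, n_grid)
  stable <- fp[fp$stable, , drop = FALSE]
  if (!nrow(stable))
    stop("no stable fixed point in [", V_range[1], ", ", V_range[2],
         "] mV at I_app = ", I_app)
  rest <- stable[which.min(stable$V), , drop = FALSE]
  has_slow <- any(gate_table_live(model)$tclass == "slow")
  label <- if (!has_slow) "neutral" else
    sign_label(rest$slow_balance, tol_B)
  others <- stable[-which.min(stable$V), , drop = FALSE]
  mixed <- any(sign_label(others$slow_balance, tol_B) != label &
                 sign_label(others$slow_balance, tol_B) != "balanced")
  list(label = label, mixed = mixed, rest = rest,
       report = feedback_report(model, rest$V, tol_B))
}

.table1 <- c(
  "transient"         = "slow restorative",
  "persistent"        = "neutral",
  "resurgent"         = "slow regenerative",
  "l-type"            = "slow regenerative",
  "t-type"            = "slow regenerative",
  "n-type"            = "slow regenerative",
  "p/q-type"          = "slow regenerative",
  "r-type"            = "slow regenerative",
  "delayed rectifier" = "slow restorative",
  "delayed rectifiers" = "slow restorative",
  "kcnq"              = "neutral",
  "eag/erg"           = "neutral",
  "a-type"            = "slow regenerative",
  "bk"                = "slow restorative",
  "hcn"               = "slow restorative")

#' Static channel classification by archetype
#'
#' Lookup of the standard gating-kinetics classification of named channel
#' archetypes: channels whose slow gate provides negative feedback are slow
#' restorative (transient Na, delayed rectifier, BK, HCN), channels whose
#' slow gate provides positive feedback are slow regenerative (resurgent Na,
#' L/T/N/P-Q/R-type Ca, A-type K), and channels with no slow gate are neutral
#' (persistent Na, KCNQ, eag/erg). The static class can disagree with the
#' dynamic sign for particular kinetic parameterizations of a subtype; the
#' dynamic check in [feedback_report()] warns in that case.
#'
#' @param archetype archetype label (case-insensitive), e.g. `"L-type"`,
#'   `"delayed rectifier"`, `"A-type"`, `"HCN"`.
#' @return `"slow restorative"`, `"slow regenerative"`, or `"neutral"`.
#' @export
table1_class <- function(archetype) {
  key <- tolower(trimws(archetype))
  if (!key %in% names(.table1))
    stop("unknown archetype '", archetype, "'; known archetypes: ",
         paste(sort(unique(names(.table1))), collapse = ", "))
  unname(.table1[[key]])
}
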