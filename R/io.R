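#' Read and write model specification files
#'
#' Models are stored as declarative JSON (canonical) or YAML (accepted on
#' input only) documents with the schema
#' `{capacitance, I_app, channels: [{name, gbar, E, archetype?, gates:
#' [{name, role, tclass, exponent, kinetics, tau}]}], frozen: {...},
#' aux: [...]}`, where `kinetics` is either
#' `{type: "boltzmann", V_half, k}` or `{type: "alphabeta", alpha, beta}`
#' (rate expressions in `V`), and `tau` is `{type: "constant", value}`,
#' `{type: "expression", expr}`, or `{type: "alphabeta"}`. All structural
#' and kinetic invariants (gate monotonicity on a voltage grid, positive
#' taus, frozen-name resolution) are validated at load time; violations are
#' reported with the offending channel and gate named.
#'
#' Numbers are written at full precision so that decimal literals survive a
#' save/load round trip bit-exactly.
#'
#' @param path file path; `.yaml`/`.yml` files are parsed as YAML.
#' @return `load_model()` a [conductance_model()]; `write_model()` the path,
#'   invisibly.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  model_from_list(spec)
}

#' @rdname load_model
#' @param model a [conductance_model()].
#' @export
write_model <- function(model, path) {
  # 17 significant digits: enough for any double to round-trip bit-exactly
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname load_model
#' @param spec a nested list following the schema above.
#' @export
model_from_list <- function(spec) {
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("model spec: missing '", field, "' in ", where)
    x[[field]]
  }
  channels <- lapply(seq_along(spec$channels), function(i) {
    ch <- spec$channels[[i]]
    where <- paste0("channels[", i, "]")
    gates <- lapply(seq_along(ch$gates), function(j) {
      g <- ch$gates[[j]]
      gwhere <- paste0(where, "$gates[", j, "] ('",
                       if (is.null(g$name)) "?" else g$name, "')")
      kin <- need(g, "kinetics", gwhere)
      tau <- if (is.null(g$tau)) NULL else g$tau
      tau_spec <- if (is.null(tau)) {
        if (identical(kin$type, "alphabeta")) tau_alphabeta() else
          tau_constant(1)
      } else switch(as.character(tau$type),
        constant = tau_constant(need(tau, "value", gwhere)),
        expression = tau_expression(need(tau, "expr", gwhere)),
        alphabeta = tau_alphabeta(),
        stop("unknown tau type '", tau$type, "' in ", gwhere))
      ex <- if (is.null(g$exponent)) 1L else as.integer(g$exponent)
      tryCatch(
        switch(as.character(kin$type),
          boltzmann = gate_boltzmann(
            need(g, "name", gwhere), need(g, "role", gwhere),
            need(g, "tclass", gwhere),
            V_half = need(kin, "V_half", gwhere),
            k = need(kin, "k", gwhere), exponent = ex, tau = tau_spec),
          alphabeta = gate_alphabeta(
            need(g, "name", gwhere), need(g, "role", gwhere),
            need(g, "tclass", gwhere),
            alpha = need(kin, "alpha", gwhere),
            beta = need(kin, "beta", gwhere), exponent = ex,
            tau = tau_spec),
          stop("unknown kinetics type '", kin$type, "'")),
        error = function(e)
          stop("in ", gwhere, ": ", conditionMessage(e), call. = FALSE))
    })
    channel(need(ch, "name", where), need(ch, "gbar", where),
            need(ch, "E", where), gates = gates,
            archetype = ch$archetype)
  })
  conductance_model(
    channels = channels,
    capacitance = if (is.null(spec$capacitance)) 1 else spec$capacitance,
    frozen = if (length(spec$frozen)) unlist(spec$frozen) else c(),
    I_app = if (is.null(spec$I_app)) 0 else spec$I_app,
    aux = if (length(spec$aux)) unlist(spec$aux) else character())
}

#' @rdname load_model
#' @export
model_to_list <- function(model) {
  list(
    capacitance = model$capacitance,
    I_app = model$I_app,
    channels = lapply(model$channels, function(ch) {
      out <- list(name = ch$name, gbar = ch$gbar, E = ch$E)
      if (!is.null(ch$archetype)) out$archetype <- ch$archetype
      out$gates <- lapply(ch$gates, function(g) {
        kin <- g$kinetics[setdiff(names(g$kinetics),
                                  c("alpha_fun", "beta_fun"))]
        tau <- g$tau[setdiff(names(g$tau), "fun")]
        list(name = g$name, role = g$role, tclass = g$tclass,
             exponent = g$exponent, kinetics = kin, tau = tau)
      })
      out
    }),
    frozen = as.list(model$frozen),
    aux = as.list(model$aux))
}

#' Provenance metadata embedded in result files
#'
#' @param seed integer seed recorded in the output.
#' @param tolerances numeric tolerances recorded in the output.
#' @param input optional input file whose md5 digest is embedded.
#' @return a named list consumed by [save_results()].
#' @export
result_meta <- function(seed = NULL, tolerances = NULL, input = NULL) {
  meta <- list(
    tool = "tcswitch",
    version = as.character(utils::packageVersion("tcswitch")),
    seed = seed,
    tolerances = tolerances)
  if (!is.null(input) && file.exists(input))
    meta$input_digest <- unname(tools::md5sum(input))
  meta
}

#' Serialize analysis results
#'
#' Branch tables go to CSV ('.' decimal, comma separator, header row, no
#' index column; columns `s`, `param`, `I_app`, `V`, `stable`,
#' `n_unstable`, `re_lambda_max`, `slow_balance`, `event`) with the refined
#' event list in a JSON sidecar; transcritical points and signature reports
#' go to JSON. Every output embeds the tool version plus any seed,
#' tolerances, and input-file digest passed in `meta`, so identical
#' configurations produce identical bytes.
#'
#' @param x a `branch_table`, `tc_points` table, or [signature_report()]
#'   row.
#' @param path output file path (for a branch table, the `.csv`; events are
#'   written next to it as `<path>.events.json`).
#' @param meta optional list from `result_meta()`-style plumbing (seed,
#'   tolerances, input digest).
#' @return `path`, invisibly.
#' @export
save_results <- function(x, path, meta = result_meta()) {
  if (inherits(x, "branch_table")) {
    ev <- attr(x, "events")
    tab <- as.data.frame(x[, c("s", "param", "I_app", "V", "stable",
                               "n_unstable", "re_lambda_max",
                               "slow_balance")])
    tab$event <- ""
    if (!is.null(ev) && nrow(ev))
      for (i in seq_len(nrow(ev)))
        tab$event[ev$idx_lo[i]] <- paste0(tab$event[ev$idx_lo[i]],
                                          ev$type[i])
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(meta = meta,
           events = if (is.null(ev)) list() else
             as.list(ev[, c("type", "param", "V", "I_app",
                            "slow_balance")])),
      paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "tc_points")) {
    jsonlite::write_json(
      list(meta = meta,
           tc_points = lapply(seq_len(nrow(x)), function(i) {
             out <- list(
               V_star = x$V_star[i], lambda_star = x$lambda_star[i],
               I_TC = x$I_TC[i],
               residuals = list(balance = x$res_balance[i],
                                fast = x$res_fast[i]),
               verified = x$verified[i])
             if (!is.null(x$primary)) out$primary <- x$primary[i]
             out
           })),
      path, auto_unbox = TRUE, digits = NA)
  } else if (is.data.frame(x)) {
    cols <- x[vapply(x, function(col) !is.list(col), logical(1))]
    jsonlite::write_json(list(meta = meta, report = as.list(cols)),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("don't know how to save an object of class ",
              paste(class(x), collapse = "/"))
  invisible(path)
}

#' Read a branch CSV back
#'
#' @param path CSV written by [save_results()].
#' @return a tibble.
#' @export
read_branch_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(event = "character")))
}

#' Load a piecewise-constant protocol from JSON
#'
#' Accepts either `{durations: [...], currents: [...]}` or
#' `{segments: [{t_start, t_end, I}, ...]}`.
#'
#' @param path JSON file.
#' @return a [protocol_steps()] tibble.
#' @export
load_protocol <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(spec$durations))
    return(protocol_steps(spec$durations, spec$currents))
  seg <- spec$segments
  stopifnot(!is.null(seg))
  seg <- seg[order(seg$t_start), , drop = FALSE]
  protocol_steps(seg$t_end - seg$t_start, seg$I)
}
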