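#' Piecewise-constant current protocols
#'
#' A protocol is an ordered set of contiguous segments, each holding the
#' applied current constant. `protocol_steps()` builds one from segment
#' durations and currents; the integrator is restarted at every segment
#' boundary so discontinuities are handled exactly.
#'
#' @param durations segment lengths, ms.
#' @param currents applied current per segment, uA/cm^2 (recycled).
#' @return a tibble of class `"tcs_protocol"` with `t_start`, `t_end`, `I`.
#' @examples
#' protocol_steps(c(100, 200, 300), c(0, 10, 0))  # hold, step, release
#' @export
protocol_steps <- function(durations, currents) {
  stopifnot(all(durations > 0))
  currents <- rep_len(currents, length(durations))
  ends <- cumsum(durations)
  structure(tibble::tibble(t_start = c(0, ends[-length(ends)]),
                           t_end = ends, I = currents),
            class = c("tcs_protocol", class(tibble::tibble())))
}

#' Integrate a conductance model under a protocol
#'
#' Stiff-capable adaptive integration (lsoda) of the full model with
#' physiological time constants, sampled densely (default 10 samples/ms) and
#' restarted at each protocol discontinuity. Gate values are clipped to
#' \[0, 1\] inside the RHS to guard against tolerance-level overshoot.
#'
#' @param model a [conductance_model()].
#' @param protocol a [protocol_steps()] schedule.
#' @param x0 named initial state `c(V = ..., <gates> = ...)`; defaults to the
#'   steady state at the most hyperpolarized stable fixed point under the
#'   first segment's current.
#' @param sample_dt output sampling interval, ms.
#' @param rtol,atol integrator tolerances.
#' @return a tibble of class `"neuron_trace"`: `time`, `V`, one column per
#'   gate; the protocol and integrator settings are attached as attributes.
#' @export
integrate_model <- function(model, protocol, x0 = NULL, sample_dt = 0.1,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "tcs_protocol"))
  if (is.null(x0)) {
    fp <- fixed_points(model, I_app = protocol$I[1])
    fp <- fp[fp$stable, , drop = FALSE]
    if (!nrow(fp))
      stop("no stable fixed point at the holding current; supply x0")
    i <- which.min(fp$V)
    x0 <- c(V = fp$V[i], unlist(fp$gate_values[[i]]))
  }
  gnames <- state_gate_names(model)
  deriv <- function(t, y, parms) {
    y[gnames] <- pmin(pmax(y[gnames], 0), 1)
    list(unname(model_rhs(model, y, I_app = parms$I)))
  }
  state <- x0
  pieces <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    times <- seq(protocol$t_start[i], protocol$t_end[i], by = sample_dt)
    if (utils::tail(times, 1) < protocol$t_end[i])
      times <- c(times, protocol$t_end[i])
    out <- deSolve::lsoda(y = state, times = times, func = deriv,
                          parms = list(I = protocol$I[i]),
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop("integrator failed near t = ", utils::tail(out[, 1], 1), " ms")
    state <- out[nrow(out), -1]
    pieces[[i]] <- tibble::as_tibble(as.data.frame(out))
  }
  tr <- dplyr::distinct(dplyr::bind_rows(pieces), time, .keep_all = TRUE)
  structure(tr, class = c("neuron_trace", class(tr)),
            protocol = protocol, rtol = rtol, atol = atol)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold`, separated by at least `refractory` ms;
#' crossing times are linearly interpolated between samples.
#'
#' @param trace a `neuron_trace` (or any tibble with `time` and `V`).
#' @param threshold spike threshold, mV.
#' @param refractory minimum inter-spike interval, ms.
#' @return numeric vector of spike times, ms (possibly empty).
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2) {
  V <- trace$V
  t <- trace$time
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (!length(up)) return(numeric())
  times <- t[up] + (threshold - V[up]) / (V[up + 1] - V[up]) *
    (t[up + 1] - t[up])
  out <- times[1]
  for (s in times[-1]) if (s - utils::tail(out, 1) >= refractory)
    out <- c(out, s)
  out
}

#' Electrophysiological signature report
#'
#' Runs the standardized two-protocol battery distinguishing restorative
#' from regenerative excitability and quantifies its markers:
#' \describe{
#'   \item{latency}{time from depolarizing-step onset to the first spike
#'     (hold, step `I_step` for `t_step`, release);}
#'   \item{plateau}{after the depolarizing step is released, `V` stays above
#'     `V_rest + 20` mV for more than 50 ms while emitting at least 2
#'     spikes;}
#'   \item{ADP}{after release from a hyperpolarizing step (`I_hyper`), the
#'     peak depolarization above rest within 200 ms, reported when it
#'     exceeds 2 mV without reaching spike threshold; if the release
#'     triggers spikes they are reported as rebound instead;}
#'   \item{bistable}{the pulse test of [bistability_test()].}
#' }
#' All thresholds are operational definitions and configurable.
#'
#' @param model a [conductance_model()].
#' @param I_hold holding current, uA/cm^2.
#' @param I_step depolarizing step amplitude above hold.
#' @param I_hyper hyperpolarizing step amplitude below hold (positive
#'   number).
#' @param t_hold,t_step,t_post phase durations, ms.
#' @param spike_threshold,refractory see [detect_spikes()].
#' @param adp_threshold minimal post-release hump counted as ADP, mV.
#' @param run_bistability include the pulse-based bistability test.
#' @return one-row tibble: `V_rest`, `n_spikes_step`, `latency`,
#'   `plateau`, `adp`, `rebound_spikes`, `bistable`, plus the two traces in
#'   list-columns `trace_depol`, `trace_hyper`.
#' @export
signature_report <- function(model, I_hold = 0, I_step = 15, I_hyper = 5,
                             t_hold = 100, t_step = 400, t_post = 300,
                             spike_threshold = 0, refractory = 2,
                             adp_threshold = 2, run_bistability = TRUE) {
  fp <- fixed_points(model, I_app = I_hold)
  fp <- fp[fp$stable, , drop = FALSE]
  if (!nrow(fp)) stop("no stable resting point at the holding current")
  V_rest <- min(fp$V)

  dep <- integrate_model(model,
    protocol_steps(c(t_hold, t_step, t_post),
                   c(I_hold, I_hold + I_step, I_hold)))
  on <- t_hold
  off <- t_hold + t_step
  spikes <- detect_spikes(dep, spike_threshold, refractory)
  sp_step <- spikes[spikes >= on & spikes < off]
  latency <- if (length(sp_step)) sp_step[1] - on else NA_real_

  post <- dep[dep$time >= off, , drop = FALSE]
  sp_post <- detect_spikes(post, spike_threshold, refractory)
  above <- post$time[post$V > V_rest + 20]
  plateau <- length(sp_post) >= 2 && length(above) > 1 &&
    (max(above) - min(above)) > 50

  hyp <- integrate_model(model,
    protocol_steps(c(t_hold, t_step, t_post),
                   c(I_hold, I_hold - I_hyper, I_hold)))
  rel <- hyp[hyp$time >= off & hyp$time <= off + 200, , drop = FALSE]
  sp_rel <- detect_spikes(rel, spike_threshold, refractory)
  adp <- NA_real_
  if (!length(sp_rel)) {
    hump <- max(rel$V) - V_rest
    if (hump > adp_threshold) adp <- hump
  }

  bist <- if (run_bistability) bistability_test(model, I_hold)$bistable else NA

  tibble::tibble(
    V_rest = V_rest, n_spikes_step = length(sp_step), latency = latency,
    plateau = plateau, adp = adp, rebound_spikes = length(sp_rel),
    bistable = bist,
    trace_depol = list(dep), trace_hyper = list(hyp))
}

#' Pulse-based bistability test
#'
#' Tests for the robust coexistence of a stable resting potential and a
#' stable spiking limit cycle at the same holding current: a transient
#' depolarizing pulse must leave the model spiking periodically at least
#' `persist` ms after the pulse ends, and a subsequent hyperpolarizing pulse
#' must return it to rest. Pulse amplitudes are scanned over a decade; the
#' test passes if any (depolarizing, hyperpolarizing) pair switches the
#' model between the two attractors.
#'
#' @param model a [conductance_model()].
#' @param I_hold holding current, uA/cm^2.
#' @param pulse_amps depolarizing pulse amplitudes scanned, uA/cm^2.
#' @param pulse_dur pulse duration, ms.
#' @param persist persistence horizon after pulse offset, ms.
#' @param spike_threshold,refractory see [detect_spikes()].
#' @return list with `bistable`, the successful `amp_up`/`amp_down` (NA when
#'   none), and the evidence `trace`.
#' @export
bistability_test <- function(model, I_hold = 0,
                             pulse_amps = c(2, 5, 10, 20),
                             pulse_dur = 5, persist = 500,
                             spike_threshold = 0, refractory = 2) {
  fp <- fixed_points(model, I_app = I_hold)
  fp <- fp[fp$stable, , drop = FALSE]
  if (!nrow(fp))
    return(list(bistable = FALSE, amp_up = NA_real_, amp_down = NA_real_,
                trace = NULL, reason = "no stable resting point"))
  i <- which.min(fp$V)
  x0 <- c(V = fp$V[i], unlist(fp$gate_values[[i]]))
  settle <- 50
  for (amp in pulse_amps) {
    prot_up <- protocol_steps(c(settle, pulse_dur, persist + 100),
                              c(I_hold, I_hold + amp, I_hold))
    tr_up <- integrate_model(model, prot_up, x0 = x0)
    t_off <- settle + pulse_dur
    late <- tr_up[tr_up$time >= t_off + persist, , drop = FALSE]
    sp_late <- detect_spikes(late, spike_threshold, refractory)
    if (length(sp_late) < 2) next  # pulse did not latch spiking
    # attractor latched; try to switch back with a hyperpolarizing pulse of
    # each scanned amplitude
    x_latched <- unlist(tr_up[nrow(tr_up),
                              setdiff(names(tr_up), "time")])
    for (amp_dn in pulse_amps) {
      prot_dn <- protocol_steps(c(pulse_dur, persist + 100),
                                c(I_hold - amp_dn, I_hold))
      tr_dn <- integrate_model(model, prot_dn, x0 = x_latched)
      late_dn <- tr_dn[tr_dn$time >= pulse_dur + persist, , drop = FALSE]
      if (!length(detect_spikes(late_dn, spike_threshold, refractory)) &&
          max(late_dn$V) < spike_threshold) {
        return(list(bistable = TRUE, amp_up = amp, amp_down = amp_dn,
                    trace = tr_up, reason = NA_character_))
      }
    }
  }
  list(bistable = FALSE, amp_up = NA_real_, amp_down = NA_real_,
       trace = NULL, reason = "no pulse pair latched and released spiking")
}
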