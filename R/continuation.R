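#' Sweep specifications for fixed-point continuation
#'
#' A sweep defines the one-parameter family of reduced fixed-point problems
#' `Phi(V, p) = 0` that [continue_fixed_points()] traces, where gates are
#' eliminated at steady state (`x = x_inf(V)` holds exactly at every fixed
#' point, so nothing is lost):
#' \describe{
#'   \item{`sweep_bif_param()`}{`p` is a [bif_param()] value; the applied
#'     current follows the [affine_current()] law anchored at a transcritical
#'     point, so the net steady current at the critical voltage is constant
#'     along the sweep.}
#'   \item{`sweep_current()`}{`p` is the applied current itself at fixed
#'     model parameters.}
#' }
#'
#' @param model a [conductance_model()].
#' @param bif_param a [bif_param()].
#' @param tc anchor transcritical point (one row of [solve_tc()] output).
#' @param range parameter interval swept.
#' @return an object of class `"tcs_sweep"` with elements `phi(V, p)`,
#'   `phi_V(V, p)`, `model_at(p)` (model with parameter and current
#'   installed), `range`, `label`.
#' @export
sweep_bif_param <- function(model, bif_param, tc, range = bif_param$range) {
  model_at <- function(p) {
    m <- set_bif_param(model, bif_param, p)
    m$I_app <- affine_current(model, tc, bif_param, p)
    m
  }
  structure(list(
    phi = function(V, p) net_current(model_at(p), V),
    phi_V = function(V, p) reduced_slope(model_at(p), V, "fast_slow"),
    model_at = model_at,
    range = range,
    label = paste0(bif_param$target, ":", bif_param$kind),
    bif_param = bif_param, tc = tc, base = model),
    class = "tcs_sweep")
}

#' @rdname sweep_bif_param
#' @export
sweep_current <- function(model, range) {
  model_at <- function(p) {
    m <- model
    m$I_app <- p
    m
  }
  structure(list(
    phi = function(V, p) net_current(model, V, I_app = p),
    phi_V = function(V, p) reduced_slope(model, V, "fast_slow"),
    model_at = model_at,
    range = range,
    label = "I_app", base = model),
    class = "tcs_sweep")
}

sweep_phi_p <- function(sweep, V, p, h = NULL) {
  if (is.null(h)) h <- 1e-6 * (1 + abs(p))
  (sweep$phi(V, p + h) - sweep$phi(V, p - h)) / (2 * h)
}

# Newton corrector on (Phi = 0, hyperplane through z_ref normal to t_hat)
sweep_corrector <- function(sweep, z, t_hat, z_ref = z, max_iter = 12,
                            tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    r <- c(sweep$phi(z[1], z[2]), sum((z - z_ref) * t_hat))
    if (all(abs(r) < c(tol, 1e-12))) return(list(z = z, iters = it - 1,
                                                 converged = TRUE))
    J <- rbind(c(sweep$phi_V(z[1], z[2]), sweep_phi_p(sweep, z[1], z[2])),
               t_hat)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(z = z, iters = it, converged = FALSE))
    z <- z + step
  }
  r <- c(sweep$phi(z[1], z[2]), sum((z - z_ref) * t_hat))
  list(z = z, iters = max_iter, converged = all(abs(r) < c(1e-8, 1e-8)))
}

branch_record <- function(sweep, V, p, s_arc) {
  m <- sweep$model_at(p)
  rec <- fixed_point_record(m, V)
  det_test <- reduced_slope(m, V, "fast_slow")
  tibble::tibble(
    s = s_arc, param = p, I_app = m$I_app, V = V,
    stable = rec$stable, n_unstable = rec$n_unstable,
    re_lambda_max = rec$max_re,
    has_complex = any(abs(Im(rec$eigenvalues[[1]])) > 1e-9),
    max_re_complex = {
      ev <- rec$eigenvalues[[1]]
      cc <- ev[abs(Im(ev)) > 1e-9]
      if (length(cc)) max(Re(cc)) else NA_real_
    },
    det_test = det_test,
    slow_balance = rec$slow_balance,
    gate_values = rec$gate_values,
    eigenvalues = rec$eigenvalues)
}

#' Continue a fixed-point branch
#'
#' Pseudo-arclength continuation of the reduced fixed-point equation with a
#' secant predictor and a 2-by-2 Newton corrector on `(V, p)`. Folds are
#' traversed, not terminated; the step length adapts to the corrector
#' iteration count within `[min_step, max_step]`. Each accepted record is
#' annotated with the full-Jacobian eigenvalues at physiological time
#' constants (Hopf positions depend on the taus; the determinant test and
#' the balance do not), the unit-tau determinant test function (the reduced
#' slope over all fast and slow gates), and the slow balance.
#'
#' @param sweep a [sweep_bif_param()] or [sweep_current()].
#' @param start numeric `c(V, p)`: a fixed point on the branch (polished
#'   internally).
#' @param direction +1/-1: initial sense of increasing/decreasing `p`.
#' @param initial_step,min_step,max_step arclength step controls (natural
#'   units).
#' @param max_records safety cap on branch length.
#' @param V_range voltage window outside which the branch is truncated.
#' @param events run [detect_events()] before returning.
#' @return a `branch_table`: a tibble of records ordered by arclength
#'   (columns `s`, `param`, `I_app`, `V`, `stable`, `n_unstable`,
#'   `re_lambda_max`, `det_test`, `slow_balance`, plus eigenvalue
#'   list-columns), with the refined `events` tibble and the sweep attached
#'   as attributes (`attr(x, "events")`).
#' @export
continue_fixed_points <- function(sweep, start, direction = 1,
                                  initial_step = 1e-2, min_step = 1e-6,
                                  max_step = 0.5, max_records = 2000,
                                  V_range = c(-120, 40), events = TRUE) {
  V0 <- start[1]
  p0 <- start[2]
  if (!is.finite(V0) || !is.finite(p0))
    stop("start point must be a finite (V, parameter) pair")
  # polish the start onto the branch at fixed p
  for (i in 1:5) {
    f <- sweep$phi(V0, p0)
    d <- sweep$phi_V(V0, p0)
    if (abs(d) < 1e-14) break
    V0 <- V0 - f / d
  }
  if (abs(sweep$phi(V0, p0)) > 1e-6)
    stop("start point is not a converged fixed point of the sweep")
  z <- c(V0, p0)
  # initial tangent from the implicit function: (-Phi_p, Phi_V) rotated so
  # dp has the requested sign; fall back to pure-p direction at a singular
  # start (e.g. starting exactly on a transcritical point)
  tv <- c(-sweep_phi_p(sweep, z[1], z[2]), sweep$phi_V(z[1], z[2]))
  if (sqrt(sum(tv^2)) < 1e-12) tv <- c(0, 1)
  t_hat <- tv / sqrt(sum(tv^2))
  if (sign(t_hat[2]) != sign(direction)) t_hat <- -t_hat
  if (t_hat[2] == 0) t_hat[2] <- direction * 1e-3

  recs <- list(branch_record(sweep, z[1], z[2], 0))
  h <- initial_step
  s_arc <- 0
  truncated <- NULL
  while (length(recs) < max_records) {
    pred <- z + h * t_hat
    cor <- sweep_corrector(sweep, pred, t_hat, z_ref = pred)
    if (!cor$converged || sqrt(sum((cor$z - z)^2)) > 4 * h) {
      h <- h / 2
      if (h < min_step) {
        truncated <- "corrector failed at minimum step"
        break
      }
      next
    }
    z_new <- cor$z
    s_arc <- s_arc + sqrt(sum((z_new - z)^2))
    t_hat <- (z_new - z) / sqrt(sum((z_new - z)^2))
    recs[[length(recs) + 1]] <- branch_record(sweep, z_new[1], z_new[2], s_arc)
    z <- z_new
    if (cor$iters <= 3 && h < max_step) h <- min(max_step, h * 1.5)
    if (cor$iters >= 8) h <- max(min_step, h / 2)
    if (z[2] < sweep$range[1] - 1e-9 || z[2] > sweep$range[2] + 1e-9 ||
        z[1] < V_range[1] || z[1] > V_range[2]) break
  }
  tb <- dplyr::bind_rows(recs)
  tb <- structure(tb, class = c("branch_table", class(tb)),
                  sweep = sweep, truncated = truncated)
  attr(tb, "events") <- if (events && nrow(tb) >= 3) detect_events(tb) else
    empty_events()
  tb
}

empty_events <- function() {
  tibble::tibble(type = character(), param = numeric(), V = numeric(),
                 I_app = numeric(), slow_balance = numeric(),
                 idx_lo = integer(), idx_hi = integer(),
                 flagged = character())
}

#' Detect and refine bifurcation events along a branch
#'
#' Scans consecutive records for sign changes of the test functions and
#' refines each bracket by corrector-based bisection along the branch to a
#' parameter tolerance of 1e-8:
#' \describe{
#'   \item{SN / TC}{sign change of the unit-tau determinant test; a fold in
#'     the parameter (`|dPhi/dp|` large, parameter direction reverses) is a
#'     saddle-node, a det-zero crossed without a fold is classified by
#'     [classify_det_zero()] (transcritical when the slow balance also
#'     vanishes and the branch-crossing probe passes).}
#'   \item{HB}{the real part of a complex eigenvalue pair (physiological
#'     taus) crosses zero with nonzero imaginary part.}
#' }
#'
#' @param branch a `branch_table` from [continue_fixed_points()].
#' @return events tibble (`type`, `param`, `V`, `I_app`, `slow_balance`,
#'   bracketing record indices, `flagged`).
#' @export
detect_events <- function(branch) {
  sweep <- attr(branch, "sweep")
  stopifnot(!is.null(sweep), nrow(branch) >= 3)
  evs <- list()
  add <- function(e) evs[[length(evs) + 1]] <<- e

  det_sgn <- sign(branch$det_test)
  hb_val <- ifelse(branch$has_complex, branch$max_re_complex, NA_real_)
  for (i in seq_len(nrow(branch) - 1)) {
    if (det_sgn[i] * det_sgn[i + 1] < 0) {
      z <- refine_on_branch(sweep, branch, i,
                            function(V, p) sweep$phi_V(V, p))
      m <- sweep$model_at(z[2])
      cls <- classify_det_zero_point(sweep, z[1], z[2])
      add(tibble::tibble(type = cls$type, param = z[2], V = z[1],
                         I_app = m$I_app,
                         slow_balance = slow_balance(m, z[1]),
                         idx_lo = i, idx_hi = i + 1L,
                         flagged = cls$flag))
    }
    if (!is.na(hb_val[i]) && !is.na(hb_val[i + 1]) &&
        sign(hb_val[i]) * sign(hb_val[i + 1]) < 0) {
      z <- refine_on_branch(sweep, branch, i, function(V, p) {
        st <- c(V = V, unlist(steady_gate_values(sweep$model_at(p), V)))
        ev <- eigen(model_jacobian(sweep$model_at(p), st), only.values = TRUE)$values
        cc <- ev[abs(Im(ev)) > 1e-9]
        if (length(cc)) max(Re(cc)) else NA_real_
      })
      if (!any(is.na(z))) {
        m <- sweep$model_at(z[2])
        add(tibble::tibble(type = "HB", param = z[2], V = z[1],
                           I_app = m$I_app,
                           slow_balance = slow_balance(m, z[1]),
                           idx_lo = i, idx_hi = i + 1L,
                           flagged = NA_character_))
      }
    }
  }
  if (!length(evs)) return(empty_events())
  out <- dplyr::bind_rows(evs)
  # overlapping brackets: report both, flagged
  dup <- duplicated(out$idx_lo) | duplicated(out$idx_lo, fromLast = TRUE)
  out$flagged[dup & is.na(out$flagged)] <- "overlapping bracket"
  out[order(out$param), , drop = FALSE]
}

# Bisection along the branch segment [i, i+1] on test(V, p), points kept on
# the branch by the corrector; refined to 1e-8 in the parameter.
refine_on_branch <- function(sweep, branch, i, test, tol_p = 1e-8,
                             max_iter = 60) {
  z_a <- c(branch$V[i], branch$param[i])
  z_b <- c(branch$V[i + 1], branch$param[i + 1])
  seg <- z_b - z_a
  t_hat <- seg / sqrt(sum(seg^2))
  at <- function(t) {
    z <- sweep_corrector(sweep, z_a + t * seg, t_hat)$z
    z
  }
  f_a <- test(z_a[1], z_a[2])
  t_lo <- 0
  t_hi <- 1
  f_lo <- f_a
  for (k in seq_len(max_iter)) {
    t_mid <- (t_lo + t_hi) / 2
    z_mid <- at(t_mid)
    f_mid <- test(z_mid[1], z_mid[2])
    if (is.na(f_mid)) return(c(NA_real_, NA_real_))
    if (sign(f_mid) == sign(f_lo)) {
      t_lo <- t_mid
      f_lo <- f_mid
    } else t_hi <- t_mid
    if (abs(seg[2]) * (t_hi - t_lo) < tol_p && k > 5) break
  }
  at((t_lo + t_hi) / 2)
}

#' Classify a determinant-zero event
#'
#' A det-zero event along a branch is transcritical iff the slow balance also
#' vanishes there (within `tol_B`) and a branch-crossing probe finds fixed
#' points on both sides of the event parameter near the event voltage,
#' with an exchange of stability; a det-zero with a genuine fold and nonzero
#' balance is a saddle-node; a balanced point whose crossing probe fails is
#' labelled degenerate, never silently classified.
#'
#' @param branch a `branch_table`.
#' @param event one row of its events tibble.
#' @param tol_B balance tolerance, mS/cm^2.
#' @return `"TC"`, `"SN"`, or `"degenerate"`.
#' @export
classify_det_zero <- function(branch, event, tol_B = 1e-4) {
  sweep <- attr(branch, "sweep")
  classify_det_zero_point(sweep, event$V[1], event$param[1], tol_B)$type
}

classify_det_zero_point <- function(sweep, V, p, tol_B = 1e-4) {
  m <- sweep$model_at(p)
  if (!any(gate_table_live(m)$tclass == "slow"))
    return(list(type = "SN", flag = NA_character_))  # no balance in play
  B <- slow_balance(m, V)
  balanced <- abs(B) < tol_B
  crossing <- crossing_probe(sweep, V, p)
  if (balanced && crossing) return(list(type = "TC", flag = NA_character_))
  if (!balanced) return(list(type = "SN", flag = NA_character_))
  list(type = "degenerate",
       flag = "balance vanishes but branch-crossing probe failed")
}

# two fixed points within (V +/- dV) on both sides of p <=> crossing
crossing_probe <- function(sweep, V, p, delta = 0.5) {
  for (dl in delta * c(1, 1 / 5, 1 / 25, 1 / 125)) {
    n_lo <- nrow(fixed_points(sweep$model_at(p - dl),
                              V_range = c(V - delta, V + delta),
                              n_grid = 200, dedup_tol = 1e-7))
    n_hi <- nrow(fixed_points(sweep$model_at(p + dl),
                              V_range = c(V - delta, V + delta),
                              n_grid = 200, dedup_tol = 1e-7))
    if (n_lo >= 2 && n_hi >= 2) return(TRUE)
  }
  FALSE
}

#' Full bifurcation diagram over a sweep
#'
#' Seeds continuation from every fixed point found at a few parameter values
#' across the sweep range, de-duplicates branches (a seed lying within
#' tolerance of an already-traced branch is skipped), and merges the event
#' tables.
#'
#' @param sweep a sweep specification.
#' @param n_seeds number of parameter values scanned for starting points.
#' @param V_range voltage window for fixed-point seeding.
#' @param ... passed to [continue_fixed_points()].
#' @return a list with `branches` (list of `branch_table`s), `records` (all
#'   records with a `branch` id column), `events` (merged, with `branch`).
#' @export
bifurcation_diagram <- function(sweep, n_seeds = 5, V_range = c(-100, 20),
                                ...) {
  p_seeds <- seq(sweep$range[1], sweep$range[2], length.out = n_seeds)
  branches <- list()
  on_existing <- function(V, p) {
    for (b in branches) {
      d <- sqrt((b$V - V)^2 + (b$param - p)^2)
      if (min(d) < 0.25) return(TRUE)
    }
    FALSE
  }
  for (p in p_seeds) {
    fp <- fixed_points(sweep$model_at(p), V_range = V_range, n_grid = 400)
    for (V in fp$V) {
      if (on_existing(V, p)) next
      for (dir in c(1, -1)) {
        br <- tryCatch(
          continue_fixed_points(sweep, c(V, p), direction = dir, ...),
          error = function(e) NULL)
        if (!is.null(br) && nrow(br) >= 3)
          branches[[length(branches) + 1]] <- br
      }
    }
  }
  records <- purrr::imap_dfr(branches, function(b, i)
    dplyr::mutate(tibble::as_tibble(b), branch = i))
  events <- purrr::imap_dfr(branches, function(b, i) {
    ev <- attr(b, "events")
    if (nrow(ev)) dplyr::mutate(ev, branch = i) else ev
  })
  # de-duplicate events found from both sweep directions / shared branches;
  # a branch crossing is seen from both branches through it, and the copy
  # refined on the transversal branch can land a hair off the exact crossing
  # -- within a family of coincident det-zero events the TC label wins
  if (nrow(events)) {
    fam <- function(type) ifelse(type == "HB", "HB", "det")
    pref <- c(TC = 1, SN = 2, degenerate = 3, HB = 1)
    events <- events[order(pref[events$type], abs(events$slow_balance)), ,
                     drop = FALSE]
    keep <- rep(TRUE, nrow(events))
    for (i in seq_len(nrow(events))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(events))) {
        if (j <= i || !keep[j]) next
        if (fam(events$type[j]) == fam(events$type[i]) &&
            abs(events$param[j] - events$param[i]) < 2e-3 &&
            abs(events$V[j] - events$V[i]) < 2e-2) keep[j] <- FALSE
      }
    }
    events <- events[keep, , drop = FALSE]
    events <- events[order(events$param), , drop = FALSE]
  }
  list(branches = branches, records = records, events = events)
}

#' @export
print.branch_table <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<branch: %d records, param in [%g, %g], %d event(s)%s>\n",
              nrow(x), min(x$param), max(x$param),
              if (is.null(ev)) 0L else nrow(ev),
              if (!is.null(attr(x, "truncated")))
                paste0("; truncated: ", attr(x, "truncated")) else ""))
  NextMethod()
}
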