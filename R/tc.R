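#' Balance and fast-singularity residuals
#'
#' The transcritical point of the excitability switch is pinned by two
#' algebraic conditions evaluated with all gates at steady state and the
#' bifurcation parameter `lambda` installed:
#' \describe{
#'   \item{balance `B(V, lambda)`}{the summed feedback weights of all slow
#'     gates vanish ([slow_balance()]);}
#'   \item{fast singularity `s_fast(V, lambda)`}{the reduced voltage slope
#'     over the fast gates alone vanishes ([reduced_slope()]).}
#' }
#' Together they imply that the full reduced slope, and hence the unit-tau
#' Jacobian determinant, vanish — the bifurcation condition. Neither residual
#' involves any time constant, which is what makes the detection robust to
#' the model's kinetics.
#'
#' @param model a [conductance_model()].
#' @param V voltage, mV (vectorized).
#' @param bif_param a [bif_param()].
#' @param lambda parameter value to install.
#' @return a list with numeric components `balance` and `fast` (mS/cm^2).
#' @export
tc_residuals <- function(model, V, bif_param, lambda) {
  m <- set_bif_param(model, bif_param, lambda)
  list(balance = slow_balance(m, V),
       fast = reduced_slope(m, V, "fast"))
}

#' Solve for transcritical points
#'
#' Finds all roots `(V*, lambda*)` of the two-residual system
#' `B = 0, s_fast = 0` inside the search box `V_range x bif_param$range`.
#' The balance is first eliminated: on a voltage grid, every `lambda` root of
#' `B(V, .)` is located by sign-change bracketing and bisection, tracing the
#' balance curve(s) `lambda_B(V)`; sign changes of `s_fast` along each curve
#' seed a damped Newton iteration on the full 2-residual system. Roots are
#' polished to residuals below `tol`, deduplicated, ordered by `V*`, and each
#' is completed with the applied current `I_TC` that makes `V*` a fixed point
#' and a numerical branch-crossing verification ([verify_tc()]).
#'
#' @param model a [conductance_model()].
#' @param bif_param a [bif_param()].
#' @param V_range voltage search window, mV.
#' @param n_V,n_lambda coarse grid resolutions.
#' @param tol residual tolerance, mS/cm^2.
#' @param verify run [verify_tc()] on each root.
#' @return a tibble of class `"tc_points"`, one row per root, ordered by
#'   `V_star`: columns `V_star`, `lambda_star`, `I_TC`, `res_balance`,
#'   `res_fast`, `verified`.
#' @export
solve_tc <- function(model, bif_param, V_range = c(-100, 20),
                     n_V = 161, n_lambda = 81, tol = 1e-9, verify = TRUE) {
  lr <- bif_param$range
  Vg <- seq(V_range[1], V_range[2], length.out = n_V)
  lg <- seq(lr[1], lr[2], length.out = n_lambda)

  # residual matrices on the (V, lambda) grid; one vectorized-V evaluation
  # per lambda column
  Bm <- matrix(NA_real_, n_V, n_lambda)
  Sm <- matrix(NA_real_, n_V, n_lambda)
  for (j in seq_len(n_lambda)) {
    r <- tc_residuals(model, Vg, bif_param, lg[j])
    Bm[, j] <- r$balance
    Sm[, j] <- r$fast
  }
  if (all(Bm > 0) || all(Bm < 0)) {
    side <- if (all(Bm < 0)) "strictly negative (restorative)" else
      "strictly positive (regenerative)"
    stop(structure(class = c("tcs_no_balance_root", "error", "condition"),
                   list(message = paste0(
                     "the slow balance is ", side,
                     " over the whole search box; no balance root for '",
                     bif_param$target, "' in [", lr[1], ", ", lr[2], "]"),
                     call = NULL)))
  }

  # balance-root curves lambda_B(V) by linear interpolation within each
  # sign-change bracket of a grid row
  bal_roots <- vector("list", n_V)
  for (i in seq_len(n_V)) {
    b <- Bm[i, ]
    if (all(b == 0)) {  # degenerate row (e.g. zero driving force)
      bal_roots[[i]] <- numeric()
      next
    }
    roots <- lg[b == 0]
    sc <- which(sign(b[-1]) * sign(b[-n_lambda]) < 0)
    if (length(sc))
      roots <- c(roots, lg[sc] + (lg[sc + 1] - lg[sc]) *
                   b[sc] / (b[sc] - b[sc + 1]))
    bal_roots[[i]] <- sort(roots)
  }

  # s_fast along each balance curve (interpolated in lambda), sign changes
  # seed the Newton iteration
  s_on_curve <- function(i, l) {
    j <- findInterval(l, lg, all.inside = TRUE)
    w <- (l - lg[j]) / (lg[j + 1] - lg[j])
    Sm[i, j] * (1 - w) + Sm[i, j + 1] * w
  }
  seeds <- list()
  jump_tol <- diff(lr) / 4
  for (i in seq_len(n_V - 1)) {
    for (l1 in bal_roots[[i]]) {
      nxt <- bal_roots[[i + 1]]
      if (!length(nxt)) next
      l2 <- nxt[which.min(abs(nxt - l1))]
      if (abs(l2 - l1) > jump_tol) next
      s1 <- s_on_curve(i, l1)
      s2 <- s_on_curve(i + 1, l2)
      if (sign(s1) * sign(s2) < 0 || s1 == 0)
        seeds[[length(seeds) + 1]] <- c(V = mean(Vg[i:(i + 1)]),
                                        lambda = mean(c(l1, l2)))
    }
  }
  roots <- purrr::compact(purrr::map(seeds, function(s)
    tc_newton(model, bif_param, s[["V"]], s[["lambda"]],
              V_range, lr, tol = tol)))
  if (!length(roots)) {
    return(structure(tibble::tibble(
      V_star = numeric(), lambda_star = numeric(), I_TC = numeric(),
      res_balance = numeric(), res_fast = numeric(), verified = logical()),
      class = c("tc_points", class(tibble::tibble())),
      bif_param = bif_param))
  }
  tb <- purrr::map_dfr(roots, function(r)
    tibble::tibble(V_star = r[1], lambda_star = r[2]))
  # dedupe to 1e-6 in both coordinates
  keep <- rep(TRUE, nrow(tb))
  for (i in seq_len(nrow(tb))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tb))) {
      if (j <= i || !keep[j]) next
      if (abs(tb$V_star[j] - tb$V_star[i]) < 1e-6 &&
          abs(tb$lambda_star[j] - tb$lambda_star[i]) < 1e-6) keep[j] <- FALSE
    }
  }
  tb <- tb[keep, , drop = FALSE]
  tb <- tb[order(tb$V_star), , drop = FALSE]
  res <- purrr::map2(tb$V_star, tb$lambda_star, function(v, l)
    tc_residuals(model, v, bif_param, l))
  tb$I_TC <- purrr::map2_dbl(tb$V_star, tb$lambda_star, function(v, l)
    i_app_at_state(model, bif_param, v, l))
  tb$res_balance <- purrr::map_dbl(res, "balance")
  tb$res_fast <- purrr::map_dbl(res, "fast")
  tb$verified <- FALSE
  out <- structure(tb, class = c("tc_points", class(tb)),
                   bif_param = bif_param)
  if (verify) {
    out$verified <- vapply(seq_len(nrow(out)), function(i)
      verify_tc(model, out[i, , drop = FALSE], bif_param)$verified,
      logical(1))
  }
  out
}

# damped Newton (step halving) on r(V, lambda) = (balance, s_fast),
# numeric central-difference Jacobian; max 50 iterations, convergence at
# max|r| < tol and step < 1e-10.
tc_newton <- function(model, bif_param, V, lambda, V_box, l_box,
                      tol = 1e-9, max_iter = 50) {
  z <- c(V, lambda)
  rfun <- function(z) {
    r <- tc_residuals(model, z[1], bif_param, z[2])
    c(r$balance, r$fast)
  }
  r <- rfun(z)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) return(z)
    hV <- 1e-6 * (1 + abs(z[1]))
    hl <- 1e-6 * (1 + abs(z[2]))
    J <- cbind((rfun(z + c(hV, 0)) - rfun(z - c(hV, 0))) / (2 * hV),
               (rfun(z + c(0, hl)) - rfun(z - c(0, hl))) / (2 * hl))
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    damp <- 1
    repeat {
      z_new <- z + damp * step
      r_new <- tryCatch(rfun(z_new), error = function(e) rep(Inf, 2))
      if (all(is.finite(r_new)) && max(abs(r_new)) < max(abs(r))) break
      damp <- damp / 2
      if (damp < 1e-8) return(NULL)
    }
    converged_step <- max(abs(damp * step)) < 1e-10
    z <- z_new
    r <- r_new
    if (converged_step && max(abs(r)) < tol) return(z)
  }
  if (max(abs(r)) < tol) z else NULL
}

i_app_at_state <- function(model, bif_param, V, lambda) {
  m <- set_bif_param(model, bif_param, lambda)
  m$I_app - net_current(m, V)  # = sum of ionic currents at (V, x_inf(V))
}

#' Applied current at a transcritical point
#'
#' The unique applied current making `V*` a fixed point of the model with
#' `lambda*` installed: the sum of all ionic currents at
#' `(V*, x_inf(V*))`.
#'
#' @param model a [conductance_model()].
#' @param tc one row of a [solve_tc()] result (or any list with `V_star`,
#'   `lambda_star`).
#' @param bif_param the [bif_param()] used to solve.
#' @return I_TC in uA/cm^2.
#' @export
i_app_at_tc <- function(model, tc, bif_param) {
  i_app_at_state(model, bif_param, tc$V_star[1], tc$lambda_star[1])
}

#' Net-current-preserving affine current law
#'
#' As the bifurcation parameter moves away from `lambda*`, the applied
#' current is co-varied so that the net steady-state current at the critical
#' voltage stays constant: `I_app(lambda)` is the sum of ionic currents at
#' the frozen anchor `(V*, x_inf(V*))` with `lambda` installed. This keeps
#' `V*` a fixed point for every `lambda` (one of the defining conditions of
#' the transcritical crossing) and is affine in `lambda` for conductance,
#' reversal-potential and frozen-value parameters alike; the observed switch
#' in excitability therefore does not rely on changes in the net membrane
#' current, only on its dynamical properties.
#'
#' @inheritParams i_app_at_tc
#' @param lambda parameter value(s); vectorized.
#' @return applied current(s) in uA/cm^2; equals `I_TC` at
#'   `lambda = lambda*`.
#' @export
affine_current <- function(model, tc, bif_param, lambda) {
  vapply(lambda, function(l)
    i_app_at_state(model, bif_param, tc$V_star[1], l), numeric(1))
}

#' Numerically verify a transcritical candidate
#'
#' Three checks at a candidate point `(V*, lambda*)` with the affine current
#' law installed: (a) the unit-tau Jacobian determinant vanishes there (via
#' the reduced slope over all fast and slow gates); (b) fixed-point branches
#' exist on both sides of `lambda*` within a window around `V*` — two
#' transversally crossing branches, as opposed to a fold, which has solutions
#' on one side only; (c) the stability pattern of the crossing branches is
#' exchanged across `lambda*`.
#'
#' @inheritParams i_app_at_tc
#' @param delta probe offsets (natural parameter units / mV) for the
#'   branch-crossing test.
#' @param tol_det absolute tolerance (mS/cm^2) on the reduced slope for
#'   check (a).
#' @param current_law function of `lambda` giving the applied current for the
#'   probe solves; defaults to the affine law anchored at the candidate
#'   itself.
#' @return a list with `verified` and the named logical `checks`
#'   (`det_zero`, `both_sides`, `exchange`); on failure `failed` names the
#'   first failed check.
#' @export
verify_tc <- function(model, tc, bif_param, delta = 0.5, tol_det = 1e-6,
                      current_law = NULL) {
  V0 <- tc$V_star[1]
  l0 <- tc$lambda_star[1]
  if (is.null(current_law))
    current_law <- function(l) affine_current(model, tc, bif_param, l)

  m_star <- set_bif_param(model, bif_param, l0)
  s_all <- reduced_slope(m_star, V0, "fast_slow")
  det_zero <- abs(s_all) < tol_det

  probe <- function(l, dV) {
    m <- set_bif_param(model, bif_param, l)
    m$I_app <- current_law(l)
    fixed_points(m, V_range = c(V0 - dV, V0 + dV), n_grid = 200,
                 dedup_tol = 1e-7)
  }
  # the crossing branch may be steep in lambda; shrink the parameter offset
  # until both branches fall inside the voltage window
  both_sides <- FALSE
  lo <- hi <- NULL
  for (dl in delta * c(1, 1 / 5, 1 / 25, 1 / 125)) {
    lo <- probe(l0 - dl, delta)
    hi <- probe(l0 + dl, delta)
    if (nrow(lo) >= 2 && nrow(hi) >= 2) {
      both_sides <- TRUE
      break
    }
  }
  exchange <- FALSE
  if (both_sides) {
    # the branch through V* must flip stability across the crossing
    near_lo <- lo$stable[which.min(abs(lo$V - V0))]
    near_hi <- hi$stable[which.min(abs(hi$V - V0))]
    pat_lo <- lo$stable[order(lo$V)][c(1, nrow(lo))]
    pat_hi <- hi$stable[order(hi$V)][c(1, nrow(hi))]
    exchange <- (near_lo != near_hi) || any(pat_lo != pat_hi)
  }
  checks <- c(det_zero = det_zero, both_sides = both_sides,
              exchange = exchange)
  failed <- names(checks)[!checks]
  list(verified = all(checks), checks = checks,
       failed = if (length(failed)) failed[1] else NA_character_,
       probes = list(lower = lo, upper = hi))
}

#' @export
print.tc_points <- function(x, ...) {
  cat("<transcritical points>\n")
  NextMethod()
}

#' @rdname solve_tc
#' @param x a `tc_points` table.
#' @param ... unused.
#' @export
glance.tc_points <- function(x, ...) {
  tibble::tibble(n_roots = nrow(x), n_verified = sum(x$verified),
                 max_residual = if (nrow(x))
                   max(abs(c(x$res_balance, x$res_fast))) else NA_real_)
}
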