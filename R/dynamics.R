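# Independent oracles for the catalog: the defining recursion on the
# integer scale and an adaptive ODE integrator on the reals. The
# recursion, not any printed closed form, is the ground truth for the
# discrete curves — it is the definition of the delta derivative and
# immune to typesetting errors.

#' Construct a linear dynamic equation
#'
#' Represents \eqn{x^\Delta = p(t)x + h(t)} (forward form) or
#' \eqn{x^\Delta = -p(t)x^\sigma + h(t)} (sigma form) with initial value
#' `x0` at `t0`. Catalog models expose their registered equation through
#' `model$dyn(pars)`, including the state transform (identity, `exp` for
#' log-population models, reciprocal for the 3-parameter logistic).
#'
#' @param form `"forward"` or `"sigma"`.
#' @param p,h Coefficient functions of time.
#' @param x0 Initial state.
#' @param t0 Initial time.
#' @param transform,inv_transform Map between the solved state and the
#'   observable curve.
#' @return An object of class `dynamic_equation`.
#' @export
dynamic_equation <- function(form = c("forward", "sigma"), p, h, x0, t0 = 0,
                             transform = identity, inv_transform = identity) {
  form <- match.arg(form)
  stopifnot(is.function(p), is.function(h))
  structure(list(form = form, p = p, h = h, x0 = x0, t0 = t0,
                 transform = transform, inv_transform = inv_transform),
            class = "dynamic_equation")
}

as_dyneq <- function(eq) {
  if (inherits(eq, "dynamic_equation")) return(eq)
  do.call(dynamic_equation, eq[c("form", "p", "h", "x0", "t0",
                                 "transform", "inv_transform")])
}

#' Solve a dynamic equation exactly on the integer scale
#'
#' Steps the defining recursion of the delta derivative:
#' forward form \eqn{x(t+1) = (1 + p(t))x(t) + h(t)}, sigma form
#' \eqn{x(t+1) = (x(t) + h(t))/(1 + p(t))}. Exact up to floating-point
#' rounding.
#'
#' @param eq A [dynamic_equation()] (or a list with its fields).
#' @param horizon Number of steps (`>= 0`).
#' @return Numeric state trajectory of length `horizon + 1`, starting at
#'   `x0`, with times `t0 + 0:horizon` as names.
#' @examples
#' eq <- dynamic_equation("forward", function(t) 0.5, function(t) 0, x0 = 1)
#' recursion_solve(eq, 3)  # 1, 1.5, 2.25, 3.375
#' @export
recursion_solve <- function(eq, horizon) {
  eq <- as_dyneq(eq)
  stopifnot(horizon >= 0)
  x <- numeric(horizon + 1)
  x[1] <- eq$x0
  if (horizon > 0) {
    for (i in seq_len(horizon)) {
      tau <- eq$t0 + i - 1
      pv <- eq$p(tau)
      hv <- eq$h(tau)
      if (eq$form == "forward") {
        x[i + 1] <- (1 + pv) * x[i] + hv
      } else {
        if (1 + pv == 0) {
          stop(sprintf("sigma-form step at tau = %g divides by 1 + p = 0", tau),
               call. = FALSE)
        }
        x[i + 1] <- (x[i] + hv) / (1 + pv)
      }
    }
  }
  stats::setNames(x, eq$t0 + 0:horizon)
}

#' Solve a dynamic equation numerically on the continuous scale
#'
#' Integrates \eqn{x' = p(t)x + h(t)} (forward) or \eqn{x' = -p(t)x + h(t)}
#' (sigma; on the reals \eqn{x^\sigma = x}) with an adaptive solver at
#' local tolerance `tol`.
#'
#' @inheritParams recursion_solve
#' @param grid Strictly increasing output times starting at `t0`.
#' @param tol Relative integration tolerance (absolute tolerance is
#'   `tol / 100`). The internal step is additionally capped at the output
#'   spacing so that dense-output interpolation cannot dominate the
#'   error budget through the fast transient of lag-phase curves.
#' @return Numeric state trajectory on `grid`.
#' @export
ode_solve <- function(eq, grid, tol = 1e-12) {
  eq <- as_dyneq(eq)
  stopifnot(abs(grid[1] - eq$t0) < 1e-12, !is.unsorted(grid, strictly = TRUE))
  sgn <- if (eq$form == "forward") 1 else -1
  deriv <- function(t, y, parms) list(sgn * eq$p(t) * y[1] + eq$h(t))
  out <- deSolve::lsoda(y = c(x = eq$x0), times = grid, func = deriv,
                        rtol = tol, atol = tol / 100, hmax = max(diff(grid)))
  if (nrow(out) < length(grid)) stop("integration failed before the horizon end")
  stats::setNames(out[, "x"], grid)
}

#' Verify a closed-form curve against its dynamic equation
#'
#' Solves the model's registered dynamic equation independently (exact
#' recursion on the integers, adaptive integration on the reals) and
#' compares it with the closed-form evaluator over the horizon. The
#' comparison is made in the equation's own state space (log-population
#' for second-type Gompertz, reciprocal for the 3-parameter logistic) and
#' the deviation is the scaled sup norm
#' \eqn{\max_t |x_{closed}(t) - x_{solved}(t)| / \max(1, \max_t |x_{solved}|)}.
#'
#' @inheritParams growth_eval
#' @param pars Named parameter vector.
#' @param horizon Integer-scale horizon (steps past the anchor).
#' @param t_max Continuous-scale window length past the anchor.
#' @param n_grid Continuous-scale grid size.
#' @param tol Pass threshold on the deviation.
#' @param as_printed Verify the literal typeset discrete 4-parameter
#'   logistic product instead of the registered evaluator (expected to
#'   fail for shape `b != 1`).
#' @return A list with `model_id`, `max_abs_dev`, `tol` and logical
#'   `pass`.
#' @examples
#' verify_solution("G1D4", c(K = 1, B = 0.5, w0 = 1, t0 = 0), horizon = 30)
#' @export
verify_solution <- function(model, pars, horizon = 30, t_max = 10,
                            n_grid = 200, tol = 1e-8, as_printed = FALSE) {
  model <- growth_model(model)
  pars <- complete_pars(model, pars)
  eq <- as_dyneq(model$dyn(pars))
  if (model$scale == "integer") {
    times <- eq$t0 + 0:horizon
    solved <- recursion_solve(eq, horizon)
  } else {
    times <- seq(eq$t0, eq$t0 + t_max, length.out = n_grid)
    solved <- ode_solve(eq, times)
  }
  closed <- if (as_printed) {
    if (model$family != "logistic4" || model$scale != "integer") {
      stop("as_printed applies to the discrete 4-parameter logistic only")
    }
    eval_logistic4(times, k = pars[["k"]], f = pars[["f"]], s = pars[["s"]],
                   b = if ("b" %in% names(pars)) pars[["b"]] else 1,
                   scale = "integer", variant = "primary", as_printed = TRUE)
  } else {
    model$eval(times, pars)
  }
  closed_state <- eq$inv_transform(closed)
  dev <- max(abs(closed_state - solved)) / max(1, max(abs(solved)))
  list(model_id = model$id, max_abs_dev = dev, tol = tol, pass = dev < tol)
}

#' Verify the whole catalog over random admissible draws
#'
#' Runs [verify_solution()] for every catalog model over `n_draws`
#' seeded admissible parameter draws and reports the worst deviation per
#' model.
#'
#' @param n_draws Draws per model.
#' @param seed Seed for the draws.
#' @inheritParams verify_solution
#' @return A data.frame with one row per model id: worst deviation and
#'   pass flag.
#' @export
verify_catalog <- function(n_draws = 100, seed = 1, horizon = 30,
                           t_max = 10, n_grid = 200, tol = 1e-8) {
  set.seed(seed)
  models <- growth_catalog()
  rows <- lapply(models, function(m) {
    draws <- m$sample(n_draws)
    worst <- 0
    for (i in seq_len(nrow(draws))) {
      r <- verify_solution(m, draws[i, ], horizon = horizon, t_max = t_max,
                           n_grid = n_grid, tol = tol)
      worst <- max(worst, r$max_abs_dev)
    }
    data.frame(model_id = m$id, n_draws = n_draws, max_abs_dev = worst,
               pass = worst < tol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
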