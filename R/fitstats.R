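# Nonlinear least-squares fitting of catalog curves with seeded
# multi-start initialization, Wald-type parameter inference, the six
# forecast-error metrics, and the model-ranking rule.

#' Validated time series
#'
#' A two-column growth time series: strictly increasing times and the
#' observed measurements. Integer-scale models additionally require
#' integer time offsets at fitting time.
#'
#' @param t Strictly increasing numeric times.
#' @param y Observed values, same length.
#' @return A data.frame of class `growth_series` with columns `t`, `y`.
#' @export
growth_series <- function(t, y) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 2) stop("a time series needs at least 2 observations")
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop("non-finite value in the time series")
  }
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf("times must be strictly increasing; violation at row %d (t = %s)",
                 bad[1] + 1, format(t[bad[1] + 1])))
  }
  structure(data.frame(t = t, y = y),
            class = c("growth_series", "data.frame"))
}

as_growth_series <- function(data) {
  if (inherits(data, "growth_series")) return(data)
  if (is.list(data) && all(c("t", "y") %in% names(data))) {
    return(growth_series(data$t, data$y))
  }
  stop("data must be a growth_series or have components t and y")
}

#' Six forecast-error metrics
#'
#' Computes, for observations `y` and fitted values `yhat` with residuals
#' \eqn{e_t = y_t - \hat y_t} over \eqn{T} observations:
#' \deqn{RMSE = \sqrt{\textstyle\sum e_t^2 / T},\quad
#'       RRMSE = \sqrt{\textstyle\sum |e_t/y_t|^2 / T},\quad
#'       MAE = \textstyle\sum |e_t| / T,}
#' \deqn{MAPE = \textstyle\sum (|e_t|/y_t) / T,\quad
#'       U_1 = \frac{\sqrt{\sum e_t^2/T}}{\sqrt{\sum y_t^2/T} +
#'             \sqrt{\sum \hat y_t^2/T}},\quad
#'       U_2 = \frac{\sqrt{\sum e_t^2/T}}{\sqrt{\sum y_t^2/T}}.}
#' MAPE and RRMSE are stored as fractions (no x100). The relative metrics
#' require every observation nonzero.
#'
#' @param y Observed values.
#' @param yhat Fitted/predicted values.
#' @return A list of class `gof_report` with fields `rmse`, `rrmse`,
#'   `mae`, `mape`, `u1`, `u2`.
#' @examples
#' gof(c(1, 2), c(1, 1))  # rmse sqrt(0.5), mae 0.5, mape 0.25, ...
#' @export
gof <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (any(y == 0)) {
    stop(sprintf("y[%d] = 0: relative metrics (RRMSE, MAPE) are undefined",
                 which(y == 0)[1]))
  }
  e <- y - yhat
  Tn <- length(y)
  rms <- function(v) sqrt(sum(v^2) / Tn)
  structure(list(
    rmse = rms(e),
    rrmse = rms(e / y),
    mae = sum(abs(e)) / Tn,
    mape = sum(abs(e) / y) / Tn,
    u1 = rms(e) / (rms(y) + rms(yhat)),
    u2 = rms(e) / rms(y)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, digits = 6, ...) {
  v <- unlist(x)
  cat("Goodness of fit:\n")
  print(signif(v, digits))
  invisible(x)
}

# numeric Jacobian of the residual vector, central differences
num_jacobian <- function(resfun, theta) {
  r0 <- resfun(theta)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (j in seq_along(theta)) {
    hj <- 1e-6 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + hj
    dn <- theta; dn[j] <- dn[j] - hj
    J[, j] <- (resfun(up) - resfun(dn)) / (2 * hj)
  }
  J
}

#' Fit a catalog curve by bounded least squares
#'
#' Minimizes \eqn{\sum_t (y_t - \omega(t;\theta))^2} over the model's
#' parameter bounds with the Levenberg-Marquardt algorithm, started from
#' one data-driven heuristic (asymptote from the data maximum, initial
#' value from the first observation, rate from the time span) plus
#' `n_starts` seeded random initializations, keeping the best local
#' optimum. Standard errors come from the Jacobian-based covariance
#' \eqn{s^2 (J^\top J)^{-1}} with \eqn{s^2 = SSE/(n - p)}; p-values are
#' two-sided from the t-distribution with \eqn{n - p} degrees of freedom;
#' adjusted \eqn{R^2 = 1 - (SSE/(n-p))/(SST/(n-1))}.
#'
#' `t0`-type anchor parameters are fitted only for continuous-scale
#' first/second-type Gompertz models; on the integer scale (where the
#' curve is a product over integer offsets) and for the 3-parameter
#' logistic they are fixed, by default at the first observation time
#' (override via `fixed`).
#'
#' @inheritParams growth_eval
#' @param data A [growth_series()] or data.frame with columns `t`, `y`.
#' @param n_starts Number of random initializations beyond the heuristic.
#' @param seed Seed for the random starts (reproducibility contract:
#'   identical seed, data and options give identical results).
#' @param fixed Named vector of parameters to hold fixed at given values.
#' @param bounds_override Named list with optional `lower`/`upper` named
#'   vectors replacing registry bounds.
#' @return An object of class `growth_fit`: estimates (full parameter
#'   vector), `se`, `tstat`, `pvalue` and `covariance` for the free
#'   parameters, `sse`, `adj_r2`, `fitted`, `residuals`, `converged`,
#'   `n_starts`, `seed`.
#' @export
fit_growth <- function(model, data, n_starts = 50, seed = NULL,
                       fixed = NULL, bounds_override = NULL) {
  model <- growth_model(model)
  data <- as_growth_series(data)
  t <- data$t; y <- data$y; n <- length(y)
  if (!is.null(seed)) set.seed(seed)

  if (model$scale == "integer") check_integer_times(t)

  free <- model$free
  fixed_vals <- numeric(0)
  # default values for registry-fixed parameters: anchor at the first
  # observation (except the alpha = 0 sub-family, hard-anchored at 1)
  for (pn in model$par_names[!free]) {
    fixed_vals[pn] <- if (pn == "t0") t[1] else model$defaults[[pn]]
  }
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% model$par_names)) {
      stop("fixed must be a named vector of model parameters")
    }
    free[names(fixed)] <- FALSE
    fixed_vals[names(fixed)] <- fixed
  }
  p_free <- sum(free)
  if (p_free == 0) stop("no free parameters left to fit")
  if (n <= p_free) {
    stop(sprintf("n = %d observations cannot identify %d free parameters",
                 n, p_free))
  }

  lower <- model$lower; upper <- model$upper
  if (!is.null(bounds_override)) {
    for (side in c("lower", "upper")) {
      ov <- bounds_override[[side]]
      if (!is.null(ov)) {
        b <- get(side); b[names(ov)] <- ov; assign(side, b)
      }
    }
  }
  lo <- lower[free]; hi <- upper[free]
  free_names <- model$par_names[free]

  full_pars <- function(theta) {
    pars <- stats::setNames(numeric(model$n_params), model$par_names)
    pars[free_names] <- theta
    if (length(fixed_vals)) pars[names(fixed_vals)] <- fixed_vals
    pars
  }
  resfun <- function(theta) {
    r <- tryCatch(y - model$eval(t, full_pars(theta)), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(rep(1e6, n))
    r
  }

  clip <- function(v) pmin(pmax(v, lo + 1e-10), hi - 1e-10)
  heur <- model$heuristic(t, y)[free_names]
  heur[is.na(heur)] <- 1
  starts <- list(clip(heur))
  if (n_starts > 0) {
    for (r in seq_len(n_starts)) {
      th <- vapply(seq_along(free_names), function(j) {
        h <- heur[j]
        if (is.finite(lo[j]) && lo[j] >= 0 && h > 0) {
          exp(stats::runif(1, log(h / 5), log(h * 5)))
        } else {
          d <- max(1, abs(h))
          stats::runif(1, h - d, h + d)
        }
      }, numeric(1))
      starts[[r + 1]] <- clip(stats::setNames(th, free_names))
    }
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lo, upper = hi, fn = resfun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best) || best$deviance >= 1e6) {
    stop(sprintf("fit of %s failed to converge from any start", model$id))
  }

  theta <- stats::setNames(unlist(best$par), free_names)
  resid <- resfun(theta)
  sse <- sum(resid^2)
  dfree <- n - p_free
  s2 <- sse / dfree
  J <- num_jacobian(resfun, theta)
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, p_free, p_free)
  })
  se <- sqrt(pmax(diag(covm), 0))
  tstat <- theta / se
  pvalue <- 2 * stats::pt(-abs(tstat), df = dfree)
  sst <- sum((y - mean(y))^2)
  adj_r2 <- 1 - s2 / (sst / (n - 1))

  structure(list(
    model_id = model$id, estimates = full_pars(theta), free = free_names,
    se = se, tstat = tstat, pvalue = pvalue, covariance = covm,
    sse = sse, adj_r2 = adj_r2, df = dfree,
    fitted = y - resid, residuals = resid, data = data,
    converged = best$info %in% 1:4, info = best$info,
    n_starts = n_starts, seed = seed
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 5, ...) {
  cat(sprintf("Fit of %s (n = %d, SSE = %.6g, adj R^2 = %.6f)\n",
              x$model_id, nrow(x$data), x$sse, x$adj_r2))
  tab <- data.frame(
    estimate = signif(x$estimates[x$free], digits),
    se = signif(x$se, digits),
    t = signif(x$tstat, digits),
    p = paste0(signif(x$pvalue, 3), p_stars(x$pvalue))
  )
  fixed <- setdiff(names(x$estimates), x$free)
  print(tab)
  if (length(fixed)) {
    cat("fixed:", paste(sprintf("%s = %g", fixed, x$estimates[fixed]),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(object$fitted)
  growth_eval(object$model_id, t, object$estimates)
}

#' Rank competing fitted models
#'
#' Implements the comparison rule used to decide which growth family
#' models a data set better. A fit is *admissible* when every free
#' parameter has a two-sided p-value below `alpha`. Among admissible
#' fits, each is scored by the number of the six error metrics (RMSE,
#' RRMSE, MAE, MAPE, U1, U2) on which it attains the minimum (ties share
#' the credit); ranking is by score descending with ascending RMSE as the
#' tie-break, and a model is flagged well-fitting when it is admissible
#' and attains the minimum on at least three metrics. Inadmissible fits
#' are listed after all admissible ones with their failing parameters
#' named.
#'
#' @param fits A nonempty list of [fit_growth()] results (fitted to the
#'   same series for the comparison to be meaningful).
#' @param alpha Significance level for parameter admissibility.
#' @return A data.frame of class `growth_ranking`, one row per fit in
#'   rank order, with the six metrics, adjusted R-squared, score,
#'   admissibility and failing parameters.
#' @export
rank_models <- function(fits, alpha = 0.05) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  if (!length(fits)) stop("rank_models needs at least one fit")
  metrics <- c("rmse", "rrmse", "mae", "mape", "u1", "u2")
  rows <- lapply(fits, function(f) {
    g <- gof(f$data$y, f$fitted)
    fail <- f$free[!(f$pvalue < alpha) | !is.finite(f$pvalue)]
    data.frame(model_id = f$model_id,
               admissible = length(fail) == 0,
               failing_params = paste(fail, collapse = ","),
               adj_r2 = f$adj_r2,
               as.data.frame(unclass(g)[metrics]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  M <- as.matrix(tab[metrics])
  score <- numeric(nrow(tab))
  adm <- tab$admissible
  if (any(adm)) {
    for (m in metrics) {
      mn <- min(M[adm, m])
      hit <- adm & (M[, m] <= mn * (1 + 1e-12) + 1e-300)
      score <- score + hit
    }
  }
  tab$score <- score
  tab$well_fitting <- adm & score >= 3
  ord <- order(!tab$admissible, -tab$score, tab$rmse)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[c("rank", "model_id", "admissible", "score", "well_fitting",
               "adj_r2", metrics, "failing_params")]
  class(tab) <- c("growth_ranking", "data.frame")
  tab
}
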