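# The model registry. Each entry links a catalog id to its closed-form
# evaluator, the linear dynamic equation it solves (used by the
# independent solvers in dynamics.R), an admissible-parameter sampler for
# property tests, the derived carrying capacity, and the metadata the
# fitting layer needs (bounds, free-parameter mask, start heuristic).

new_growth_model <- function(id, family, variant, scale, par_names,
                             lower, upper, free, defaults, evalf, init,
                             anchor, dyn, sample, capacity, heuristic) {
  structure(list(
    id = id, family = family, variant = variant, scale = scale,
    par_names = par_names, n_params = length(par_names),
    lower = lower, upper = upper, free = free, defaults = defaults,
    eval = evalf, init = init, anchor = anchor, dyn = dyn,
    sample = sample, capacity = capacity, heuristic = heuristic
  ), class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model %s: %s/%s on the %s scale; parameters %s>\n",
              x$id, x$family, x$variant, x$scale,
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

# -- samplers ---------------------------------------------------------------
# Draws are uniform over boxes chosen so that every draw is admissible
# (regressive rates, pole-free windows, bounded trajectories over the
# verification horizons) and produces growth-scaled values.

ru <- function(n, lo, hi) stats::runif(n, lo, hi)

sample_g1 <- function(three_par) function(n) {
  K <- ru(n, 0.1, 1.2)
  B <- if (three_par) rep(0, n) else ru(n, 0, 0.6)
  w0 <- B + ru(n, 0.1, 1.5)
  out <- cbind(K = K, w0 = w0, t0 = 0)
  if (!three_par) out <- cbind(K = K, B = B, w0 = w0, t0 = 0)
  out
}

sample_zw <- function(n) {
  cbind(A = ru(n, 1, 3), Kz = ru(n, 0.05, 0.3), T_lag = ru(n, 0, 2))
}

sample_lr <- function(n) {
  cbind(w0 = ru(n, 0.1, 1), L = ru(n, 0.2, 0.8), K = ru(n, 0.1, 0.6))
}

sample_g2 <- function(variant, a0) function(n) {
  beta <- if (variant == "forward") ru(n, -0.8, -0.05) else ru(n, 0.05, 0.8)
  g0 <- ru(n, -1.5, 0.5)
  if (a0) cbind(beta = beta, g0 = g0)
  else cbind(alpha = ru(n, 0.01, 0.5), beta = beta, g0 = g0, t0 = 0)
}

sample_l3 <- function(variant) function(n) {
  if (variant == "first") {
    cbind(alpha = ru(n, 0.2, 1), beta = ru(n, -0.6, -0.1),
          l0 = ru(n, 0.05, 0.5), t0 = 1)
  } else {
    cap <- ru(n, 0.5, 3)
    beta <- ru(n, 0.1, 0.8)
    cbind(alpha = beta / cap, beta = beta, l0 = ru(n, 0.1, 0.8) * cap, t0 = 1)
  }
}

sample_l4 <- function(b1) function(n) {
  f <- ru(n, 1, 4)
  s <- ru(n, 0.05, 0.7) * f
  k <- ru(n, 0.1, 0.8)
  b <- if (b1) rep(1, n) else ru(n, 0.1, 0.9) * f / (f - s)
  if (b1) cbind(k = k, f = f, s = s) else cbind(k = k, f = f, s = s, b = b)
}

# -- dynamic-equation builders ----------------------------------------------
# Each returns list(form, p, h, x0, t0, transform, inv_transform) where the
# state solves x^Delta = p x + h (forward) or x^Delta = -p x^sigma + h
# (sigma) and transform maps the state to the curve (exp for the
# log-population second-type Gompertz, reciprocal for the 3-parameter
# logistic).

dyn_identity <- list(transform = identity, inv_transform = identity)

dyn_g1 <- function(pars, mu, variant) {
  K <- pars[["K"]]; B <- if ("B" %in% names(pars)) pars[["B"]] else 0
  t0 <- pars[["t0"]]
  if (variant == "standard") {
    p <- function(tau) odot(K, ominus(exp_const(ominus(K, mu), tau, t0, mu), mu), mu)
    list(form = "sigma", p = p, h = function(tau) B * p(tau),
         x0 = pars[["w0"]], t0 = t0,
         transform = identity, inv_transform = identity)
  } else {
    p <- function(tau) ominus(odot(K, exp_const(ominus(K, mu), tau, t0, mu), mu), mu)
    list(form = "forward", p = p, h = function(tau) B * p(tau),
         x0 = pars[["w0"]], t0 = t0,
         transform = identity, inv_transform = identity)
  }
}

dyn_zw <- function(pars, mu) {
  A <- pars[["A"]]; Kz <- pars[["Kz"]]; T_lag <- pars[["T_lag"]]
  KK <- exp(1) * Kz / A
  cc <- KK * T_lag + 1
  p <- function(tau) {
    odot(exp(cc), odot(KK, exp_const(ominus(KK, mu), tau, 0, mu), mu), mu)
  }
  list(form = "forward", p = p, h = function(tau) 0,
       x0 = A * exp(-exp(cc)), t0 = 0,
       transform = identity, inv_transform = identity)
}

dyn_lr <- function(pars, mu) {
  w0 <- pars[["w0"]]; L <- pars[["L"]]; K <- pars[["K"]]
  p <- function(tau) {
    odot(L / K, odot(K, exp_const(ominus(K, mu), tau, 0, mu), mu), mu)
  }
  list(form = "forward", p = p, h = function(tau) 0, x0 = w0, t0 = 0,
       transform = identity, inv_transform = identity)
}

dyn_g2 <- function(pars, mu, variant) {
  alpha <- if ("alpha" %in% names(pars)) pars[["alpha"]] else 0
  t0 <- if ("t0" %in% names(pars)) pars[["t0"]] else 1
  beta <- pars[["beta"]]
  list(form = if (variant == "forward") "forward" else "sigma",
       p = function(tau) beta, h = function(tau) alpha,
       x0 = pars[["g0"]], t0 = t0,
       transform = exp, inv_transform = log)
}

dyn_l3 <- function(pars, mu, variant) {
  list(form = if (variant == "first") "forward" else "sigma",
       p = function(tau) pars[["beta"]], h = function(tau) pars[["alpha"]],
       x0 = 1 / pars[["l0"]], t0 = pars[["t0"]],
       transform = function(u) 1 / u, inv_transform = function(w) 1 / w)
}

dyn_l4 <- function(pars, mu, variant) {
  k <- pars[["k"]]; f <- pars[["f"]]; s <- pars[["s"]]
  b <- if ("b" %in% names(pars)) pars[["b"]] else 1
  c0 <- f / (f - s) - b
  if (variant == "primary") {
    p <- function(tau) k * (1 - b / (b + c0 * exp_const(k, tau, 0, mu)))
    list(form = "sigma", p = p, h = function(tau) f * p(tau), x0 = s, t0 = 0,
         transform = identity, inv_transform = identity)
  } else {
    q <- function(tau) 1 - b / (b + c0 * exp_const(k, tau + mu, 0, mu))
    p <- function(tau) ominus(k, mu) * q(tau)
    list(form = "forward", p = p, h = function(tau) -f * p(tau), x0 = s,
         t0 = 0, transform = identity, inv_transform = identity)
  }
}

# -- start heuristics --------------------------------------------------------
# Crude data-driven initial values for the optimizer; the multi-start
# layer explores a box around them.

heur_g1 <- function(three_par, variant) function(t, y) {
  r <- max(diff(range(y)), 1e-6)
  Bh <- if (three_par) 0 else min(y) - 0.02 * r
  Ah <- max(y) + 0.02 * r - Bh
  w0 <- Bh + Ah / exp(1)
  K <- 5 / max(diff(range(t)), 1)
  u <- min(max((y[1] - Bh) / Ah, 0.01), 0.99)
  t0 <- t[1] + log(-log(u)) / K
  out <- c(K = K, B = Bh, w0 = w0, t0 = t0)
  if (three_par) out <- out[c("K", "w0", "t0")]
  out
}

heur_zw <- function(t, y) {
  A <- max(y) * 1.02
  sl <- diff(y) / diff(t)
  i <- which.max(sl)
  Kz <- max(sl[i], 1e-3)
  T_lag <- max(t[1], t[i] - y[i] / Kz)
  c(A = A, Kz = Kz, T_lag = T_lag)
}

heur_lr <- function(t, y) {
  w0 <- max(y[1], 1e-3)
  K <- 3 / max(diff(range(t)), 1)
  L <- K * log(max(max(y) / w0, 1.05))
  c(w0 = w0, L = L, K = K)
}

heur_g2 <- function(variant, a0) function(t, y) {
  Tspan <- max(diff(range(t)), 1)
  lcap <- log(max(max(y), 1e-3) * 1.02)
  g0 <- log(max(y[1], 1e-6))
  if (variant == "mirror") {
    beta <- 3 / Tspan
    alpha <- beta * lcap
  } else {
    beta <- -3 / Tspan
    alpha <- -beta * lcap
  }
  if (a0) c(beta = beta, g0 = g0)
  else c(alpha = alpha, beta = beta, g0 = g0, t0 = t[1])
}

heur_l3 <- function(variant) function(t, y) {
  Tspan <- max(diff(range(t)), 1)
  cap <- max(y) * 1.02
  l0 <- max(y[1], 1e-3)
  if (variant == "second") {
    beta <- 4 / Tspan
    c(alpha = beta / cap, beta = beta, l0 = l0, t0 = t[1])
  } else {
    beta <- -4 / Tspan
    c(alpha = -beta / cap, beta = beta, l0 = l0, t0 = t[1])
  }
}

heur_l4 <- function(b1) function(t, y) {
  f <- max(y) * 1.02
  s <- min(max(y[1], 0.01 * f), 0.95 * f)
  k <- 4 / max(diff(range(t)), 1)
  if (b1) c(k = k, f = f, s = s) else c(k = k, f = f, s = s, b = 1)
}

# -- registry ---------------------------------------------------------------

build_catalog <- function() {
  eps <- 1e-8
  models <- list()
  add <- function(m) models[[m$id]] <<- m

  scales <- c(C = "continuous", D = "integer")

  # first-type Gompertz: standard/alternative x 3/4-parameter x scale
  for (sc in names(scales)) {
    for (variant in c("standard", "alternative")) {
      for (three in c(FALSE, TRUE)) {
        id <- paste0("G1", sc, if (three) "3" else "4",
                     if (variant == "alternative") "A" else "")
        pn <- if (three) c("K", "w0", "t0") else c("K", "B", "w0", "t0")
        scale <- scales[[sc]]
        lo <- c(K = eps, B = -Inf, w0 = eps, t0 = -Inf)[pn]
        hi <- c(K = Inf, B = Inf, w0 = Inf, t0 = Inf)[pn]
        free <- stats::setNames(pn != "t0" | scale == "continuous", pn)
        local({
          scale <- scale; variant <- variant; three <- three
          add(new_growth_model(
            id = id, family = "gompertz1", variant = variant, scale = scale,
            par_names = pn, lower = lo, upper = hi, free = free,
            defaults = c(t0 = 0),
            evalf = function(t, pars) {
              eval_gompertz1(t, K = pars[["K"]],
                             B = if (three) 0 else pars[["B"]],
                             w0 = pars[["w0"]], t0 = pars[["t0"]],
                             scale = scale, variant = variant)
            },
            init = function(pars) pars[["w0"]],
            anchor = function(pars) pars[["t0"]],
            dyn = function(pars) {
              p <- c(pars, if (three) c(B = 0))
              dyn_g1(p, if (scale == "integer") 1 else 0, variant)
            },
            sample = sample_g1(three),
            capacity = function(pars) {
              B <- if (three) 0 else pars[["B"]]
              if (variant == "standard") B + exp(1) * (pars[["w0"]] - B)
              else (pars[["w0"]] + B) / exp(1) - B
            },
            heuristic = heur_g1(three, variant)
          ))
        })
      }
    }
  }

  for (sc in names(scales)) {
    scale <- scales[[sc]]
    local({
      scale <- scale
      add(new_growth_model(
        id = paste0("ZW", sc), family = "zwietering", variant = "standard",
        scale = scale, par_names = c("A", "Kz", "T_lag"),
        lower = c(A = eps, Kz = eps, T_lag = -Inf),
        upper = c(A = Inf, Kz = Inf, T_lag = Inf),
        free = c(A = TRUE, Kz = TRUE, T_lag = TRUE), defaults = numeric(),
        evalf = function(t, pars) {
          eval_zwietering(t, A = pars[["A"]], Kz = pars[["Kz"]],
                          T_lag = pars[["T_lag"]], scale = scale)
        },
        init = function(pars) {
          cc <- exp(1) * pars[["Kz"]] * pars[["T_lag"]] / pars[["A"]] + 1
          pars[["A"]] * exp(-exp(cc))
        },
        anchor = function(pars) 0,
        dyn = function(pars) dyn_zw(pars, if (scale == "integer") 1 else 0),
        sample = sample_zw,
        capacity = function(pars) pars[["A"]],
        heuristic = heur_zw
      ))
      add(new_growth_model(
        id = paste0("LR", sc), family = "laird", variant = "standard",
        scale = scale, par_names = c("w0", "L", "K"),
        lower = c(w0 = eps, L = -Inf, K = eps),
        upper = c(w0 = Inf, L = Inf, K = Inf),
        free = c(w0 = TRUE, L = TRUE, K = TRUE), defaults = numeric(),
        evalf = function(t, pars) {
          eval_laird(t, w0 = pars[["w0"]], L = pars[["L"]], K = pars[["K"]],
                     scale = scale)
        },
        init = function(pars) pars[["w0"]],
        anchor = function(pars) 0,
        dyn = function(pars) dyn_lr(pars, if (scale == "integer") 1 else 0),
        sample = sample_lr,
        capacity = function(pars) pars[["w0"]] * exp(pars[["L"]] / pars[["K"]]),
        heuristic = heur_lr
      ))
    })
  }

  # second-type Gompertz (log-population), full and alpha = 0 sub-family
  for (sc in names(scales)) {
    for (variant in c("forward", "mirror")) {
      for (a0 in c(FALSE, TRUE)) {
        scale <- scales[[sc]]
        id <- paste0("G2", sc, if (variant == "mirror") "M" else "",
                     if (a0) "-a0" else "")
        pn <- if (a0) c("beta", "g0") else c("alpha", "beta", "g0", "t0")
        blo <- if (scale == "integer") -1 + 1e-6 else -Inf
        lo <- c(alpha = -Inf, beta = blo, g0 = -Inf, t0 = -Inf)[pn]
        hi <- c(alpha = Inf, beta = Inf, g0 = Inf, t0 = Inf)[pn]
        free <- stats::setNames(pn != "t0" | scale == "continuous", pn)
        local({
          scale <- scale; variant <- variant; a0 <- a0
          add(new_growth_model(
            id = id, family = "gompertz2", variant = variant, scale = scale,
            par_names = pn, lower = lo, upper = hi, free = free,
            defaults = c(t0 = if (a0) 1 else 0),
            evalf = function(t, pars) {
              eval_gompertz2(t,
                             alpha = if (a0) 0 else pars[["alpha"]],
                             beta = pars[["beta"]], g0 = pars[["g0"]],
                             t0 = if (a0) 1 else pars[["t0"]],
                             scale = scale, variant = variant)
            },
            init = function(pars) exp(pars[["g0"]]),
            anchor = function(pars) if (a0) 1 else pars[["t0"]],
            dyn = function(pars) {
              p <- if (a0) c(pars, alpha = 0, t0 = 1) else pars
              dyn_g2(p, if (scale == "integer") 1 else 0, variant)
            },
            sample = sample_g2(variant, a0),
            capacity = function(pars) {
              r <- if (a0) 0 else pars[["alpha"]] / pars[["beta"]]
              if (variant == "mirror") exp(r) else exp(-r)
            },
            heuristic = heur_g2(variant, a0)
          ))
        })
      }
    }
  }

  # 3-parameter logistic, both dynamic-equation variants
  for (sc in names(scales)) {
    for (variant in c("first", "second")) {
      scale <- scales[[sc]]
      id <- paste0("L3", sc, if (variant == "second") "2" else "")
      blo <- if (scale == "integer") -1 + 1e-6 else -Inf
      local({
        scale <- scale; variant <- variant
        add(new_growth_model(
          id = id, family = "logistic3", variant = variant, scale = scale,
          par_names = c("alpha", "beta", "l0", "t0"),
          lower = c(alpha = -Inf, beta = blo, l0 = eps, t0 = -Inf),
          upper = c(alpha = Inf, beta = Inf, l0 = Inf, t0 = Inf),
          free = c(alpha = TRUE, beta = TRUE, l0 = TRUE, t0 = FALSE),
          defaults = c(t0 = 1),
          evalf = function(t, pars) {
            eval_logistic3(t, alpha = pars[["alpha"]], beta = pars[["beta"]],
                           l0 = pars[["l0"]], t0 = pars[["t0"]],
                           scale = scale, variant = variant)
          },
          init = function(pars) pars[["l0"]],
          anchor = function(pars) pars[["t0"]],
          dyn = function(pars) dyn_l3(pars, if (scale == "integer") 1 else 0,
                                      variant),
          sample = sample_l3(variant),
          capacity = function(pars) {
            r <- pars[["beta"]] / pars[["alpha"]]
            if (variant == "second") r else -r
          },
          heuristic = heur_l3(variant)
        ))
      })
    }
  }

  # 4-parameter logistic and its b = 1 reductions
  l4_ids <- list(
    list(id = "L4C", scale = "continuous", variant = "primary", b1 = FALSE),
    list(id = "L4D", scale = "integer", variant = "primary", b1 = FALSE),
    list(id = "L4DA", scale = "integer", variant = "alternative", b1 = FALSE),
    list(id = "L4D-b1", scale = "integer", variant = "primary", b1 = TRUE),
    list(id = "L4DA-b1", scale = "integer", variant = "alternative", b1 = TRUE)
  )
  for (cfg in l4_ids) {
    pn <- if (cfg$b1) c("k", "f", "s") else c("k", "f", "s", "b")
    lo <- c(k = eps, f = eps, s = eps, b = -Inf)[pn]
    hi <- c(k = Inf, f = Inf, s = Inf, b = Inf)[pn]
    local({
      cfg <- cfg
      add(new_growth_model(
        id = cfg$id, family = "logistic4", variant = cfg$variant,
        scale = cfg$scale, par_names = pn, lower = lo, upper = hi,
        free = stats::setNames(rep(TRUE, length(pn)), pn),
        defaults = numeric(),
        evalf = function(t, pars) {
          eval_logistic4(t, k = pars[["k"]], f = pars[["f"]], s = pars[["s"]],
                         b = if (cfg$b1) 1 else pars[["b"]],
                         scale = cfg$scale, variant = cfg$variant)
        },
        init = function(pars) pars[["s"]],
        anchor = function(pars) 0,
        dyn = function(pars) {
          p <- if (cfg$b1) c(pars, b = 1) else pars
          dyn_l4(p, if (cfg$scale == "integer") 1 else 0, cfg$variant)
        },
        sample = sample_l4(cfg$b1),
        capacity = function(pars) pars[["f"]],
        heuristic = heur_l4(cfg$b1)
      ))
    })
  }

  models
}

catalog_env <- new.env(parent = emptyenv())

#' The growth-curve catalog
#'
#' `growth_catalog()` returns every registered curve model, optionally
#' filtered by family and/or time scale; `growth_model(id)` looks up a
#' single entry; `catalog_ids()` lists the stable id strings.
#'
#' Ids follow a compact scheme: family prefix (`G1` first-type Gompertz,
#' `ZW` Zwietering, `LR` Gompertz-Laird, `G2` second-type Gompertz, `L3`/
#' `L4` logistic), `C`/`D` for the continuous/integer scale, then variant
#' markers (`A` alternative, `M` mirror, `3`/`4` parameter count, `2`
#' second logistic variant, `-a0` the 2-parameter alpha = 0 sub-family,
#' `-b1` the b = 1 logistic reduction).
#'
#' @param family Optional family filter (e.g. `"gompertz1"`).
#' @param scale Optional scale filter (`"continuous"` or `"integer"`).
#' @param id A catalog id string.
#' @return `growth_catalog()`: a named list of `growth_model` objects;
#'   `growth_model()`: one `growth_model`; `catalog_ids()`: character
#'   vector.
#' @examples
#' length(growth_catalog(family = "gompertz1"))  # 8
#' growth_model("L4D")
#' @export
growth_catalog <- function(family = NULL, scale = NULL) {
  if (is.null(catalog_env$models)) catalog_env$models <- build_catalog()
  models <- catalog_env$models
  if (!is.null(family)) {
    models <- Filter(function(m) m$family %in% family, models)
  }
  if (!is.null(scale)) {
    models <- Filter(function(m) m$scale %in% scale, models)
  }
  models
}

#' @rdname growth_catalog
#' @export
growth_model <- function(id) {
  models <- growth_catalog()
  if (inherits(id, "growth_model")) return(id)
  if (!id %in% names(models)) {
    stop(sprintf("unknown model id '%s'; see catalog_ids()", id))
  }
  models[[id]]
}

#' @rdname growth_catalog
#' @export
catalog_ids <- function() names(growth_catalog())

#' Evaluate a catalog model
#'
#' Evaluates the closed-form curve of a catalog entry at times `t` with a
#' full named parameter vector (fixed parameters such as `t0` take their
#' registry defaults when omitted).
#'
#' @param model A catalog id or `growth_model`.
#' @param t Evaluation times.
#' @param pars Named parameter vector.
#' @return Curve values at `t`.
#' @examples
#' growth_eval("G1C3", 0:5, c(K = 0.5, w0 = 0.3, t0 = 0))
#' @export
growth_eval <- function(model, t, pars) {
  model <- growth_model(model)
  pars <- complete_pars(model, pars)
  model$eval(t, pars)
}

complete_pars <- function(model, pars) {
  pars <- unlist(pars)
  missing <- setdiff(model$par_names, names(pars))
  fillable <- intersect(missing, names(model$defaults))
  if (length(fillable)) {
    pars <- c(pars, model$defaults[fillable])
  }
  missing <- setdiff(model$par_names, names(pars))
  if (length(missing)) {
    stop(sprintf("model %s is missing parameter(s): %s",
                 model$id, paste(missing, collapse = ", ")))
  }
  pars[model$par_names]
}

#' Admissible random parameter draws
#'
#' Draws parameter vectors from a box in which the model's regressivity
#' and pole conditions hold over the standard verification horizons.
#' Used by the property tests and the verification harness; uses R's
#' global random stream (seed with [set.seed()]).
#'
#' @param model Catalog id or `growth_model`.
#' @param n Number of draws.
#' @return A matrix with one named row per draw.
#' @export
sample_admissible <- function(model, n = 1) {
  model <- growth_model(model)
  model$sample(n)
}

#' Derived carrying capacity
#'
#' The finite asymptotic size implied by a fitted parameter vector. The
#' families parameterize it differently, so it is reported as a derived
#' quantity: \eqn{B + e(\omega_0 - B)} (first-type Gompertz, standard),
#' `A` (Zwietering), \eqn{\omega_0 e^{L/K}} (Laird),
#' \eqn{e^{\alpha/\beta}} (second-type Gompertz, mirror),
#' \eqn{\beta/\alpha} (3-parameter logistic, second variant), `f`
#' (4-parameter logistic).
#'
#' @inheritParams growth_eval
#' @param pars Named parameter vector.
#' @return The derived carrying capacity.
#' @export
carrying_capacity <- function(model, pars) {
  model <- growth_model(model)
  model$capacity(complete_pars(model, pars))
}
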