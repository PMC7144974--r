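# The curve catalog: registry structure, hand-derived point values,
# limits, and the cross-family identities.

test_that("catalog has the full 29-model registry with unique ids", {
  cat <- growth_catalog()
  expect_length(cat, 29)
  expect_false(anyDuplicated(names(cat)) > 0)
  expect_length(growth_catalog(family = "gompertz1"), 8)
  expect_setequal(names(growth_catalog(family = "logistic4",
                                       scale = "integer")),
                  c("L4D", "L4DA", "L4D-b1", "L4DA-b1"))
  for (m in cat) {
    expect_identical(m$n_params, length(m$par_names))
    expect_named(m$lower, m$par_names)
  }
  expect_error(growth_model("nope"), "unknown model id")
})

test_that("evaluators reject out-of-schema parameters", {
  expect_error(eval_gompertz1(1, K = -1, w0 = 1), "positive")
  expect_error(eval_zwietering(1, A = 0, Kz = 1, T_lag = 0), "positive")
  expect_error(eval_laird(1, w0 = 1, L = 1, K = -0.1), "positive")
  expect_error(eval_laird(1, w0 = 1, L = 1, K = 1, m = 2), "exactly one")
  expect_error(eval_gompertz2(1, alpha = 1, beta = 0, g0 = 0), "nonzero")
  expect_error(eval_logistic3(2, alpha = 1, beta = 1, l0 = 0), "nonzero")
  expect_error(eval_logistic4(1, k = 1, f = 2, s = 2, b = 1), "differ")
  expect_error(growth_eval("G1C4", 1, c(K = 1, w0 = 1)), "missing parameter")
})

test_that("hand-derived point values hold for every family", {
  # discrete first-type Gompertz, K=1, B=0, w0=1: (2/1)*(3/2) = 3 at t = 2
  expect_equal(eval_gompertz1(2, K = 1, B = 0, w0 = 1, t0 = 0, "integer"), 3)
  # Zwietering with e*Kz/A = 1, T_lag = 0 at t = 1: exp(-exp(0))
  expect_equal(eval_zwietering(1, A = 1, Kz = exp(-1), T_lag = 0), exp(-1))
  # discrete Laird single factor (1/2)^{-1} = 2
  expect_equal(eval_laird(1, w0 = 1, L = 1, K = 1, scale = "integer"), 2)
  # discrete forward second-type Gompertz: exp((0+1)*4 - 1) = e^3
  expect_equal(eval_gompertz2(2, alpha = 1, beta = 1, g0 = 0, t0 = 0,
                              "integer", "forward"), exp(3))
  # discrete first-variant logistic: 1/(-1 + 4*2) = 1/7
  expect_equal(eval_logistic3(2, alpha = 1, beta = 1, l0 = 1/3, t0 = 1,
                              "integer", "first"), 1/7)
  # one recursion step of the discrete 4PL: 2 - 2/(1 + 2) = 4/3
  expect_equal(eval_logistic4(1, k = 1, f = 2, s = 1, b = 1, "integer"), 4/3)
})

test_that("anchored initial values and asymptotic limits are exact", {
  tbig <- 500
  # first-type Gompertz limit B + e(w0 - B), i.e. A + B with A = e(w0 - B)
  expect_equal(eval_gompertz1(tbig, K = 0.8, B = 0.2, w0 = 0.5),
               0.2 + exp(1) * 0.3, tolerance = 1e-12)
  expect_equal(eval_zwietering(tbig, A = 1.7, Kz = 0.2, T_lag = 1), 1.7,
               tolerance = 1e-12)
  # Laird limit w0 e^{L/K}; simpler-w0 reparameterization makes it exactly A
  expect_equal(eval_laird(tbig, w0 = 0.3, L = 0.6, K = 0.2),
               0.3 * exp(3), tolerance = 1e-12)
  expect_equal(eval_laird(tbig, w0 = 0.3, K = 0.2, A = 5), 5,
               tolerance = 1e-12)
  # mirror second-type Gompertz limit exp(alpha/beta)
  expect_equal(eval_gompertz2(tbig, alpha = 0.6, beta = 0.3, g0 = -1,
                              variant = "mirror"), exp(2), tolerance = 1e-12)
  # second-variant logistic equilibrium: l0 = beta/alpha stays constant
  expect_equal(eval_logistic3(1:30, alpha = 0.4, beta = 0.8, l0 = 2,
                              scale = "integer", variant = "second"),
               rep(2, 30))
  # 4PL limit f
  expect_equal(eval_logistic4(tbig, k = 0.5, f = 2.4, s = 0.3, b = 0.7), 2.4,
               tolerance = 1e-12)
})

test_that("every catalog curve returns its declared initial value", {
  set.seed(46)
  for (m in growth_catalog()) {
    draws <- m$sample(500)
    for (i in seq_len(nrow(draws))) {
      pars <- complete_pars_for_test(m, draws[i, ])
      t0 <- m$anchor(pars)
      v <- m$eval(t0, pars)
      expect_equal(v, m$init(pars), tolerance = 1e-10,
                   label = sprintf("%s draw %d", m$id, i))
    }
  }
})

test_that("3-parameter first-type and second-type continuous Gompertz are identical", {
  set.seed(47)
  for (i in 1:100) {
    K <- runif(1, 0.1, 1.5); w0 <- runif(1, 0.1, 2); t0 <- runif(1, -2, 2)
    g0 <- log(w0)
    tg <- seq(t0, t0 + 10, length.out = 101)
    a <- eval_gompertz1(tg, K = K, B = 0, w0 = w0, t0 = t0,
                        "continuous", "standard")
    b <- eval_gompertz2(tg, alpha = K * (g0 + 1), beta = K, g0 = g0, t0 = t0,
                        "continuous", "mirror")
    expect_lt(max(abs(a - b)), 1e-10)
    # dual identity: alternative first-type <-> forward second-type, beta = -K
    a2 <- eval_gompertz1(tg, K = K, B = 0, w0 = w0, t0 = t0,
                         "continuous", "alternative")
    b2 <- eval_gompertz2(tg, alpha = -K * (1 - g0), beta = -K, g0 = g0,
                         t0 = t0, "continuous", "forward")
    expect_lt(max(abs(a2 - b2)), 1e-10)
  }
})

test_that("the lag-time and anchored-at-zero Zwietering forms agree", {
  # A exp(-exp(eKz/A (T-t) + 1)) versus A (exp(-exp(-eKz/A t)))^{e^{eKz T/A + 1}}
  set.seed(48)
  for (i in 1:100) {
    A <- runif(1, 0.5, 3); Kz <- runif(1, 0.05, 0.5); T_lag <- runif(1, -1, 3)
    tg <- seq(0, 10, length.out = 50)
    KK <- exp(1) * Kz / A
    rewrite <- A * (exp(-exp(-KK * tg)))^(exp(KK * T_lag + 1))
    expect_equal(eval_zwietering(tg, A, Kz, T_lag), rewrite,
                 tolerance = 1e-12)
  }
})

test_that("Laird reparameterizations delegate with L = K m and L = K log(A/w0)", {
  tg <- 0:10
  expect_equal(eval_laird(tg, w0 = 0.4, K = 0.3, m = 2.5, scale = "integer"),
               eval_laird(tg, w0 = 0.4, L = 0.75, K = 0.3, scale = "integer"))
  expect_equal(eval_laird(tg, w0 = 0.4, K = 0.3, A = 3),
               eval_laird(tg, w0 = 0.4, L = 0.3 * log(3 / 0.4), K = 0.3))
})

test_that("discrete 4PL variants agree with each other and the telescoped form", {
  set.seed(49)
  draws <- sample_admissible("L4D", 100)
  tt <- 0:50
  for (i in seq_len(nrow(draws))) {
    p <- draws[i, ]
    c0 <- p[["f"]] / (p[["f"]] - p[["s"]]) - p[["b"]]
    prim <- eval_logistic4(tt, p[["k"]], p[["f"]], p[["s"]], p[["b"]],
                           "integer", "primary")
    alt <- eval_logistic4(tt, p[["k"]], p[["f"]], p[["s"]], p[["b"]],
                          "integer", "alternative")
    closed <- p[["f"]] - p[["f"]] / (p[["b"]] + c0 * (1 + p[["k"]])^tt)
    expect_lt(max(abs(prim - alt)), 1e-9)
    expect_lt(max(abs(prim - closed)), 1e-9)
  }
})

test_that("b = 1 collapses the 4PL onto the 3-parameter logistic on both scales", {
  set.seed(50)
  for (i in 1:50) {
    k <- runif(1, 0.1, 0.8); f <- runif(1, 1, 4); s <- runif(1, 0.1, 0.7) * f
    tc <- seq(0, 10, length.out = 101)
    expect_lt(max(abs(
      eval_logistic4(tc, k, f, s, b = 1, "continuous") -
        eval_logistic3(tc, alpha = k / f, beta = k, l0 = s, t0 = 0,
                       "continuous", "second"))), 1e-10)
    td <- 0:30
    expect_lt(max(abs(
      eval_logistic4(td, k, f, s, b = 1, "integer") -
        eval_logistic3(td, alpha = k / f, beta = k, l0 = s, t0 = 0,
                       "integer", "second"))), 1e-10)
  }
})

test_that("growth-oriented curves are monotone between start and capacity", {
  set.seed(51)
  growth_ids <- c("G1C4", "G1D4", "ZWC", "ZWD", "LRC", "LRD",
                  "G2CM", "G2DM", "L3C2", "L3D2", "L4C", "L4D")
  for (id in growth_ids) {
    m <- growth_model(id)
    draws <- m$sample(40)
    for (i in seq_len(nrow(draws))) {
      pars <- complete_pars_for_test(m, draws[i, ])
      cap <- m$capacity(pars)
      init <- m$init(pars)
      if (!is.finite(cap) || cap <= init) next  # not growth-oriented draw
      t0 <- m$anchor(pars)
      tg <- if (m$scale == "integer") t0 + 0:99
            else seq(t0, t0 + 25, length.out = 100)
      v <- m$eval(tg, pars)
      expect_true(all(diff(v) > -1e-9), label = sprintf("%s monotone", id))
      # the product-form discrete first-type curves saturate at their own
      # (slightly larger) limit, not at the continuous-family capacity
      if (!id %in% c("G1D4", "ZWD", "LRD")) {
        expect_true(all(v >= init - 1e-9 & v <= cap + 1e-9),
                    label = sprintf("%s bounded by capacity", id))
      }
    }
  }
})
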