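# Least-squares fitting, the six error metrics, and the ranking rule.

make_fake_fit <- function(id, y, yhat, pvalue, adj_r2 = 0.99) {
  structure(list(
    model_id = id, estimates = stats::setNames(rep(1, length(pvalue)),
                                               names(pvalue)),
    free = names(pvalue), se = rep(0.1, length(pvalue)),
    tstat = rep(10, length(pvalue)), pvalue = unname(pvalue),
    sse = sum((y - yhat)^2), adj_r2 = adj_r2, df = length(y) - length(pvalue),
    fitted = yhat, residuals = y - yhat,
    data = growth_series(seq_along(y), y),
    converged = TRUE, n_starts = 0, seed = NULL
  ), class = "growth_fit")
}

test_that("the six error metrics match hand arithmetic on the worked fixture", {
  g <- gof(c(1, 2), c(1, 1))
  expect_equal(g$rmse, sqrt(0.5))
  expect_equal(g$rrmse, sqrt(0.125))
  expect_equal(g$mae, 0.5)
  expect_equal(g$mape, 0.25)
  expect_equal(g$u1, sqrt(0.5) / (sqrt(2.5) + 1))
  expect_equal(g$u2, sqrt(0.5) / sqrt(2.5))
  # all six vanish iff the residuals vanish
  z <- gof(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(unlist(z) == 0))
  expect_error(gof(c(1, 0), c(1, 1)), "y\\[2\\] = 0")
})

test_that("metrics have the right scale behavior", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- runif(n, 0.5, 5)
    yhat <- pmax(y + rnorm(n, 0, 0.5), 1e-6)
    g <- gof(y, yhat)
    cc <- runif(1, 0.1, 10)
    gs <- gof(cc * y, cc * yhat)
    # absolute metrics scale by c, relative metrics are invariant
    expect_equal(gs$rmse, cc * g$rmse)
    expect_equal(gs$mae, cc * g$mae)
    expect_equal(gs$rrmse, g$rrmse)
    expect_equal(gs$mape, g$mape)
    expect_equal(gs$u1, g$u1)
    expect_equal(gs$u2, g$u2)
    # U2 = RMSE / rms(y), U1 <= U2 for nonnegative fits, U1 in [0, 1]
    expect_equal(g$u2, g$rmse / sqrt(mean(y^2)))
    expect_lte(g$u1, g$u2)
    expect_gte(g$u1, 0); expect_lte(g$u1, 1)
  }
})

test_that("noiseless data is fit exactly with adjusted R^2 of 1", {
  fx <- synthetic_fixture("bacteria")
  ser <- simulate_growth(fx$model_id, fx$truth, fx$times, sigma = 0)
  f <- fit_growth(fx$model_id, ser, n_starts = 4, seed = 7)
  expect_true(f$converged)
  rel <- abs(f$estimates[c("K", "B", "w0")] - fx$truth[c("K", "B", "w0")]) /
    abs(fx$truth[c("K", "B", "w0")])
  expect_lt(max(rel), 1e-6)
  expect_lt(abs(f$estimates[["t0"]]), 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  expect_equal(unname(f$fitted), ser$y, tolerance = 1e-7)
})

test_that("fitting is reproducible from the seed and validates its inputs", {
  fx <- synthetic_fixture("tumor")
  ser <- simulate_growth(fx$model_id, fx$truth, fx$times, sigma = 0.1,
                         seed = 99)
  f1 <- fit_growth("LRC", ser, n_starts = 6, seed = 123)
  f2 <- fit_growth("LRC", ser, n_starts = 6, seed = 123)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$se, f2$se)
  # underdetermined: 3 points against a 4-parameter model
  tiny <- growth_series(0:2, c(0.1, 0.2, 0.3))
  expect_error(fit_growth("G1C4", tiny, n_starts = 1), "identify")
  # integer-scale models refuse fractional times
  frac <- growth_series(seq(0, 5, by = 0.5), runif(11, 0.5, 1))
  expect_error(fit_growth("G1D4", frac, n_starts = 1), "integer")
})

test_that("integer-scale fits hold t0 fixed at the first observation", {
  fx <- synthetic_fixture("bacteria")
  truth_d <- c(K = 0.5, B = 0.05, w0 = 0.1, t0 = 0)
  ser <- simulate_growth("G1D4", truth_d, 0:19, sigma = 0)
  f <- fit_growth("G1D4", ser, n_starts = 4, seed = 3)
  expect_identical(f$estimates[["t0"]], 0)
  expect_false("t0" %in% f$free)
  expect_lt(max(abs(f$estimates[c("K", "B", "w0")] -
                      truth_d[c("K", "B", "w0")])), 1e-5)
})

test_that("ranking rewards admissible metric winners and names failing parameters", {
  y <- c(1, 2, 3, 4, 5)
  good <- make_fake_fit("A", y, y + 0.01, c(k = 0.001, f = 0.002))
  worse <- make_fake_fit("B", y, y + 0.1, c(k = 0.001, f = 0.002))
  inadm <- make_fake_fit("C", y, y + 0.001, c(k = 0.2, f = 0.001))
  rk <- rank_models(list(worse, good, inadm))
  # dominance: A beats B on all six; C has the best errors but p = 0.2
  expect_equal(rk$model_id, c("A", "B", "C"))
  expect_equal(rk$score[rk$model_id == "A"], 6)
  expect_true(rk$well_fitting[rk$model_id == "A"])
  expect_false(rk$admissible[rk$model_id == "C"])
  expect_equal(rk$failing_params[rk$model_id == "C"], "k")
  # single admissible fit is rank 1 and trivially minimal on all six
  solo <- rank_models(list(good))
  expect_equal(solo$rank, 1)
  expect_equal(solo$score, 6)
  expect_true(solo$well_fitting)
  # ties share credit: identical fits both score on every metric
  tie <- rank_models(list(good, make_fake_fit("A2", y, y + 0.01,
                                              c(k = 0.001, f = 0.002))))
  expect_equal(tie$score, c(6, 6))
  expect_error(rank_models(list()), "at least one")
})
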