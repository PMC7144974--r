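# Calculus primitives: circle operations, generalized exponentials,
# delta derivative, and their group/semigroup laws on both scales.

test_that("circle operations reproduce the defining arithmetic", {
  # continuous case degenerates to ordinary arithmetic
  expect_equal(ominus(0.5, 0), -0.5)
  expect_equal(oplus(2, 3, 0), 5)
  expect_equal(ominus_binary(3, 1, 0), 2)
  expect_equal(odot(2, 3, 0), 6)
  # integer case
  expect_equal(ominus(1, 1), -0.5)
  expect_equal(oplus(1, 1, 1), 3)
  expect_equal(ominus_binary(3, 1, 1), 1)
  expect_equal(ominus_binary(5, 5, 1), 0)
  expect_equal(odot(2, 1, 1), 3)
  # hand arithmetic: 0.7 - 7/17 + 0.7 * (-7/17) = 0
  expect_equal(oplus(0.7, ominus(0.7, 1), 1), 0, tolerance = 1e-15)
})

test_that("non-regressive inputs raise domain errors naming the value", {
  expect_error(ominus(-1, 1), "not regressive")
  expect_error(ominus_binary(3, -1, 1), "not regressive")
  expect_error(odot(0.5, -1.5, 1), "not positively regressive")
  expect_error(exp_const(-1, 3, 0, "integer"), "not regressive")
})

test_that("odot matches the numerical quadrature of its defining integral", {
  # alpha * p * int_0^1 (1 + h mu p)^(alpha-1) dh, the form odot closes
  odot_quad <- function(alpha, p, mu) {
    alpha * p * stats::integrate(function(h) (1 + h * mu * p)^(alpha - 1),
                                 0, 1, rel.tol = 1e-12)$value
  }
  set.seed(41)
  for (i in 1:50) {
    alpha <- runif(1, -2, 3)
    p <- runif(1, -0.9, 4)   # positively regressive at mu = 1
    expect_equal(odot(alpha, p, 1), odot_quad(alpha, p, 1), tolerance = 1e-9)
    expect_equal(odot(alpha, p, 0), odot_quad(alpha, p, 0), tolerance = 1e-9)
  }
  # power identity 1 + mu (a (.) p) = (1 + mu p)^a
  expect_equal(1 + 1 * odot(0.5, 3, 1), (1 + 3)^0.5)
})

test_that("circle plus is a commutative group with ominus as inverse", {
  set.seed(42)
  for (mu in c(0, 1)) {
    p <- runif(1000, -0.9, 5)
    q <- runif(1000, -0.9, 5)
    r <- runif(1000, -0.9, 5)
    expect_lt(max(abs(oplus(p, ominus(p, mu), mu))), 1e-12)
    expect_equal(oplus(p, q, mu), oplus(q, p, mu))
    expect_equal(oplus(oplus(p, q, mu), r, mu),
                 oplus(p, oplus(q, r, mu), mu), tolerance = 1e-12)
    expect_equal(oplus(p, 0, mu), p)
  }
})

test_that("exp_const solves x^Delta = p x and obeys the semigroup law", {
  expect_equal(exp_const(1, 2, 0, "integer"), 4)
  expect_equal(exp_const(0.5, 2, 0, "continuous"), exp(1))
  expect_equal(exp_const(0.3, 5, 5, "integer"), 1)
  expect_equal(exp_const(0.3, 2.5, 2.5, "continuous"), 1)
  set.seed(43)
  for (i in 1:200) {
    p <- runif(1, -0.9, 3)
    ts <- sort(sample(-10:20, 3))
    expect_equal(exp_const(p, ts[3], ts[2], 1) * exp_const(p, ts[2], ts[1], 1),
                 exp_const(p, ts[3], ts[1], 1), tolerance = 1e-12)
    tc <- sort(runif(3, -5, 5))
    expect_equal(exp_const(p, tc[3], tc[2], 0) * exp_const(p, tc[2], tc[1], 0),
                 exp_const(p, tc[3], tc[1], 0), tolerance = 1e-12)
    # positivity for positively regressive rates
    expect_gt(exp_const(p, ts[3], ts[1], 1), 0)
    # reciprocal law e_{(-)p} = 1/e_p
    expect_equal(exp_const(ominus(p, 1), ts[3], ts[1], 1),
                 1 / exp_const(p, ts[3], ts[1], 1), tolerance = 1e-12)
  }
})

test_that("exp_fun handles time-varying rates on both scales", {
  # constant rate reduces to exp_const
  expect_equal(exp_fun(function(tau) 0.7, 5, 1, "integer"),
               exp_const(0.7, 5, 1, "integer"))
  expect_equal(exp_fun(function(tau) 0.7, 2.3, 1, "continuous"),
               exp_const(0.7, 2.3, 1, "continuous"), tolerance = 1e-10)
  # product of (1 + (1+K)^{-tau}) with K = 1: (1+1)(1+1/2) = 3
  p <- function(tau) exp_const(ominus(1, 1), tau, 0, 1)
  expect_equal(exp_fun(p, 2, 0, "integer"), 3)
  expect_equal(exp_fun(p, 0, 0, "integer"), 1)  # empty product
  # reciprocal law for a genuinely time-varying rate
  set.seed(44)
  for (i in 1:20) {
    K <- runif(1, 0.2, 1.5)
    pf <- function(tau) exp_const(ominus(K, 1), tau, 0, 1)
    pm <- function(tau) ominus(pf(tau), 1)
    expect_equal(exp_fun(pf, 6, 0, "integer") * exp_fun(pm, 6, 0, "integer"),
                 1, tolerance = 1e-12)
  }
  expect_error(exp_fun(function(tau) -1, 3, 0, "integer"), "tau = 0")
})

test_that("circle-dot powers commute with the exponential (both scales)", {
  set.seed(45)
  for (i in 1:50) {
    p <- runif(1, -0.8, 2)
    a <- runif(1, -1.5, 2.5)
    for (ts in c("integer", "continuous")) {
      mu <- if (ts == "integer") 1 else 0
      lhs <- exp_fun(function(tau) odot(a, p, mu), 4, 0, ts)
      rhs <- exp_fun(function(tau) p, 4, 0, ts)^a
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("delta derivative is the forward difference / ordinary derivative", {
  expect_equal(delta_derivative(function(t) t^2, 3, "integer"), 7)
  expect_equal(delta_derivative(function(t) t^2, 3, "continuous"), 6,
               tolerance = 1e-7)
  # e_p is the solution of x^Delta = p x: delta derivative equals p * f
  for (p in c(-0.4, 0.3, 1.2)) {
    f <- function(t) exp_const(p, t, 0, "integer")
    for (tt in 0:5) {
      expect_equal(delta_derivative(f, tt, "integer"), p * f(tt),
                   tolerance = 1e-12)
    }
    fc <- function(t) exp_const(p, t, 0, "continuous")
    expect_equal(delta_derivative(fc, 1.5, "continuous"), p * fc(1.5),
                 tolerance = 1e-6)
  }
})
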