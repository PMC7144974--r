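# Closed-form evaluators for the growth-curve catalog. Every curve exists
# on both the real and the integer time scale; the discrete forms are the
# generalized-exponential products, accumulated in log space where the
# factors are positive so that terms like (1+K)^tau cannot overflow the
# running product.

# Sum_{j=0}^{n-1} log1p((1+K)^-j), vectorized over nonnegative integers n.
# This is the log of the product at the heart of every first-type discrete
# Gompertz curve: e_{K (.) e_{(-)K}}(t, t0) = exp(K * g1_logsum(t - t0, K)).
g1_logsum <- function(n, K) {
  m <- max(n, 0)
  cs <- c(0, cumsum(log1p((1 + K)^-(seq_len(m) - 1))))
  cs[n + 1]
}

# The discrete products are defined for nonnegative integer offsets from
# the anchor; the continuous closed forms are global in t (needed when t0
# is a free parameter during fitting).
check_horizon <- function(t, t0, scale) {
  if (scale == "integer") {
    if (any(t < t0 - 1e-9)) {
      stop(sprintf("t = %s lies before the anchor time t0 = %s",
                   format(min(t)), format(t0)), call. = FALSE)
    }
    check_integer_times(t - t0, "t - t0")
  }
  invisible(TRUE)
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0) {
      stop(sprintf("parameter %s must be positive, got %s",
                   nm, format(vals[[nm]])), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' First-type Gompertz curves (4- and 3-parameter)
#'
#' The standard curve solves the sigma-form dynamic equation
#' \eqn{\omega^\Delta = -(K \odot \ominus e_{\ominus K})\,\omega^\sigma +
#' B\,(K \odot \ominus e_{\ominus K})} and the alternative curve the
#' forward-form companion. On the reals the standard curve is
#' \eqn{B + e\,(\omega_0 - B) \exp(-\exp(-K(t - t_0)))} — the classical
#' 4-parameter Gompertz with asymptote offset \eqn{B} and amplitude
#' \eqn{A = e(\omega_0 - B)}; on the integers it is the product form
#' \eqn{B + (\omega_0 - B)\left[\prod_{\tau=t_0}^{t-1}
#' \frac{1 + (1+K)^{\tau-t_0}}{(1+K)^{\tau-t_0}}\right]^{K}}.
#' The alternative (decay-oriented) curve is
#' \eqn{(\omega_0 + B)e^{-1}\exp(\exp(-K(t - t_0))) - B} and its discrete
#' analogue. `B = 0` gives the 3-parameter sub-family. All four variants
#' take the value \eqn{\omega_0} at \eqn{t = t_0}.
#'
#' @param t Evaluation times (`t >= t0`; integer offsets on the integer
#'   scale).
#' @param K Growth (standard) or decay (alternative) rate, `K > 0`.
#' @param B Carrying-capacity offset; 0 selects the 3-parameter curve.
#' @param w0 Value of the curve at the anchor time.
#' @param t0 Anchor time.
#' @param scale `"continuous"` or `"integer"`.
#' @param variant `"standard"` or `"alternative"`.
#' @return Curve values at `t`.
#' @examples
#' eval_gompertz1(0:3, K = 1, B = 0, w0 = 1, scale = "integer")  # 1 2 3 ...
#' @export
eval_gompertz1 <- function(t, K, B = 0, w0, t0 = 0,
                           scale = c("continuous", "integer"),
                           variant = c("standard", "alternative")) {
  scale <- match.arg(scale); variant <- match.arg(variant)
  check_positive(K = K)
  check_horizon(t, t0, scale)
  if (scale == "continuous") {
    E <- exp(-exp(-K * (t - t0)))
    if (variant == "standard") B + exp(1) * (w0 - B) * E
    else (w0 + B) * exp(-1) / E - B
  } else {
    S <- g1_logsum(round(t - t0), K)
    if (variant == "standard") B + (w0 - B) * exp(K * S)
    else (w0 + B) * exp(-K * S) - B
  }
}

#' Zwietering-modified Gompertz curve
#'
#' Gompertz growth reparameterized by the quantities a microbiologist
#' reads off a growth curve: the asymptote `A`, the maximal absolute
#' growth rate `Kz`, and the lag time `T_lag` before a transferred
#' population resumes appreciable division. The continuous form is
#' \eqn{A \exp(-\exp(\frac{e K_z}{A}(T_{lag} - t) + 1))}; the discrete
#' form is the generalized-exponential product with base rate
#' \eqn{e K_z / A}, anchored at 0 with initial value
#' \eqn{A\exp(-\exp(e K_z T_{lag}/A + 1))}.
#'
#' @param t Evaluation times, `t >= 0`.
#' @param A Asymptote, `A > 0`.
#' @param Kz Maximal absolute growth rate, `Kz > 0`.
#' @param T_lag Lag time.
#' @inheritParams eval_gompertz1
#' @return Curve values at `t`.
#' @examples
#' eval_zwietering(1, A = 1, Kz = exp(-1), T_lag = 0)  # exp(-1)
#' @export
eval_zwietering <- function(t, A, Kz, T_lag,
                            scale = c("continuous", "integer")) {
  scale <- match.arg(scale)
  check_positive(A = A, Kz = Kz)
  check_horizon(t, 0, scale)
  KK <- exp(1) * Kz / A
  cc <- KK * T_lag + 1
  if (scale == "continuous") {
    A * exp(-exp(KK * (T_lag - t) + 1))
  } else {
    S <- g1_logsum(round(t), KK)
    A * exp(-exp(cc) + KK * exp(cc) * S)
  }
}

#' Gompertz-Laird curve
#'
#' The Laird parameterization, the form most often fitted to tumor growth:
#' initial size `w0`, initial specific growth rate `L`, and exponential
#' rate of growth deceleration `K`, with carrying capacity
#' \eqn{\omega_0 e^{L/K}}. The continuous curve is
#' \eqn{\omega_0 \exp(-\frac{L}{K}(e^{-Kt} - 1))}; the discrete curve is
#' \eqn{\omega_0 \left[\prod_{\tau=0}^{t-1}
#' \frac{(1+K)^\tau}{1 + (1+K)^\tau}\right]^{-L}}.
#' Instead of `L` you may give the Zweifel-Lasker shape `m` (`L = K m`) or
#' the simpler-w0 asymptote `A` (`L = K log(A/w0)`, making the carrying
#' capacity exactly `A`).
#'
#' @param t Evaluation times, `t >= 0`.
#' @param w0 Initial value, `w0 > 0`.
#' @param L Initial specific growth rate (give exactly one of `L`, `m`,
#'   `A`).
#' @param K Decay rate of the specific growth rate, `K > 0`.
#' @param m Zweifel-Lasker reparameterization, `L = K * m`.
#' @param A Simpler-w0 reparameterization, `L = K * log(A / w0)`.
#' @inheritParams eval_gompertz1
#' @return Curve values at `t`.
#' @examples
#' eval_laird(1, w0 = 1, L = 1, K = 1, scale = "integer")  # 2
#' @export
eval_laird <- function(t, w0, L = NULL, K,
                       scale = c("continuous", "integer"),
                       m = NULL, A = NULL) {
  scale <- match.arg(scale)
  check_positive(w0 = w0, K = K)
  given <- c(L = !is.null(L), m = !is.null(m), A = !is.null(A))
  if (sum(given) != 1) {
    stop("give exactly one of L, m (Zweifel-Lasker), or A (simpler-w0)")
  }
  if (!is.null(m)) L <- K * m
  if (!is.null(A)) { check_positive(A = A); L <- K * log(A / w0) }
  check_horizon(t, 0, scale)
  if (scale == "continuous") {
    w0 * exp(-(L / K) * (exp(-K * t) - 1))
  } else {
    w0 * exp(L * g1_logsum(round(t), K))
  }
}

#' Second-type Gompertz curves (through the log-population)
#'
#' Second-type curves act on \eqn{u = \ln G}: the forward variant solves
#' \eqn{u^\Delta = \alpha + \beta u} and the mirror variant
#' \eqn{u^\Delta = \alpha - \beta u^\sigma}, both from \eqn{u(t_0) = g_0}.
#' Closed forms: forward
#' \eqn{G = \exp((g_0 + \alpha/\beta)e_\beta(t,t_0) - \alpha/\beta)},
#' mirror
#' \eqn{G = \exp((g_0 - \alpha/\beta)e_{\ominus\beta}(t,t_0) +
#' \alpha/\beta)}, with \eqn{e_\beta(t,t_0) = e^{\beta(t-t_0)}} on the
#' reals and \eqn{(1+\beta)^{t-t_0}} on the integers. `alpha = 0` gives
#' the 2-parameter sub-family (the mirror continuous member is the Mirror
#' Gompertz model of human-lifespan work).
#'
#' @param t Evaluation times.
#' @param alpha Intercept rate of the log-population equation.
#' @param beta Rate; must be nonzero (and `> -1` on the integer scale).
#' @param g0 Initial log-population.
#' @inheritParams eval_gompertz1
#' @param variant `"forward"` or `"mirror"`.
#' @return Curve values at `t` (positive).
#' @examples
#' eval_gompertz2(2, alpha = 1, beta = 1, g0 = 0, scale = "integer")  # e^3
#' @export
eval_gompertz2 <- function(t, alpha, beta, g0, t0 = 0,
                           scale = c("continuous", "integer"),
                           variant = c("forward", "mirror")) {
  scale <- match.arg(scale); variant <- match.arg(variant)
  if (beta == 0) stop("beta must be nonzero (alpha/beta enters the closed form)")
  if (scale == "integer" && 1 + beta <= 0) {
    stop(sprintf("beta = %s is not positively regressive on the integer scale",
                 format(beta)))
  }
  check_horizon(t, t0, scale)
  r <- alpha / beta
  E <- if (scale == "continuous") exp(beta * (t - t0)) else (1 + beta)^(t - t0)
  if (variant == "forward") exp((g0 + r) * E - r)
  else exp((g0 - r) / E + r)
}

#' 3-parameter logistic curves
#'
#' The two logistic dynamic equations arise from the two linear forms for
#' the reciprocal \eqn{u = 1/L}: the first variant solves
#' \eqn{u^\Delta = \beta u + \alpha} and the second
#' \eqn{u^\Delta = \alpha - \beta u^\sigma}, from \eqn{u(t_0) = 1/l_0}.
#' Closed forms: first
#' \eqn{L = 1/(-\alpha/\beta + (1/l_0 + \alpha/\beta)e_\beta(t,t_0))},
#' second
#' \eqn{L = 1/(\alpha/\beta + (1/l_0 - \alpha/\beta)e_{\ominus\beta}(t,t_0))}.
#' The second variant grows toward the carrying capacity \eqn{\beta/\alpha}
#' when \eqn{\alpha, \beta > 0}; starting at \eqn{l_0 = \beta/\alpha} it
#' stays at that equilibrium.
#'
#' @param t Evaluation times.
#' @param alpha Forcing rate (nonzero sign convention per variant).
#' @param beta Rate; nonzero, `> -1` on the integer scale.
#' @param l0 Initial value, nonzero.
#' @param t0 Anchor time (default 1).
#' @inheritParams eval_gompertz1
#' @param variant `"first"` or `"second"`.
#' @return Curve values at `t`.
#' @examples
#' eval_logistic3(2, alpha = 1, beta = 1, l0 = 1/3, scale = "integer")  # 1/7
#' @export
eval_logistic3 <- function(t, alpha, beta, l0, t0 = 1,
                           scale = c("continuous", "integer"),
                           variant = c("first", "second")) {
  scale <- match.arg(scale); variant <- match.arg(variant)
  if (l0 == 0) stop("l0 must be nonzero")
  if (beta == 0) stop("beta must be nonzero (alpha/beta enters the closed form)")
  if (scale == "integer" && 1 + beta <= 0) {
    stop(sprintf("beta = %s is not positively regressive on the integer scale",
                 format(beta)))
  }
  check_horizon(t, t0, scale)
  r <- alpha / beta
  E <- if (scale == "continuous") exp(beta * (t - t0)) else (1 + beta)^(t - t0)
  den <- if (variant == "first") -r + (1 / l0 + r) * E else r + (1 / l0 - r) / E
  if (any(abs(den) < 1e-12)) {
    stop(sprintf("logistic denominator vanishes at t = %s (pole)",
                 format(t[abs(den) < 1e-12][1])), call. = FALSE)
  }
  1 / den
}

#' 4-parameter logistic curves
#'
#' The 4-parameter logistic \eqn{\omega = f - f/(b + c\,e_k(t, 0))} with
#' \eqn{c = f/(f-s) - b}, asymptote `f`, initial value \eqn{\omega(0) = s}
#' and shape `b` (`b = 1` recovers the classical logistic). Two dynamic
#' equations generate it: the primary sigma form
#' \eqn{\omega^\Delta = -p(t)\omega^\sigma + f\,p(t)} with
#' \eqn{p(t) = k[1 - b/(b + c\,e_k(t,0))]}, evaluated through
#' \eqn{e_{\ominus p}}, and the alternative forward form
#' \eqn{\omega^\Delta = (\ominus k)q\,\omega - f(\ominus k)q} with
#' \eqn{q(t) = 1 - b/(b + c\,e_k(\sigma(t),0))}. On the integers both
#' products telescope to \eqn{f - f/(b + c(1+k)^t)}; on the reals the two
#' variants coincide exactly.
#'
#' `as_printed = TRUE` (primary, integer scale) evaluates instead the
#' literal product \eqn{f + (s-f)/\prod_{\tau=0}^{t-1}
#' [1 - kb/(b + c(1+k)^{\tau+1})]}, a typeset variant circulating for this
#' curve that does *not* solve the defining dynamic equation; it is kept
#' for comparison only and deviates from the recursion (see
#' [verify_solution()]).
#'
#' @param t Evaluation times, `t >= 0`.
#' @param k Rate, `k > 0`.
#' @param f Asymptote, `f > 0`.
#' @param s Initial value, `s > 0`, `s != f`.
#' @param b Shape; the curve needs \eqn{b + c\,e_k(\tau,0) \neq 0} over
#'   the evaluation window.
#' @inheritParams eval_gompertz1
#' @param variant `"primary"` or `"alternative"` (identical on the
#'   continuous scale).
#' @param as_printed Evaluate the literal typeset product (integer,
#'   primary only).
#' @return Curve values at `t`.
#' @examples
#' eval_logistic4(1, k = 1, f = 2, s = 1, b = 1, scale = "integer")  # 4/3
#' @export
eval_logistic4 <- function(t, k, f, s, b,
                           scale = c("continuous", "integer"),
                           variant = c("primary", "alternative"),
                           as_printed = FALSE) {
  scale <- match.arg(scale); variant <- match.arg(variant)
  check_positive(k = k, f = f, s = s)
  if (s == f) stop("s must differ from f (c = f/(f-s) - b is undefined)")
  check_horizon(t, 0, scale)
  c0 <- f / (f - s) - b
  if (scale == "continuous") {
    den <- b + c0 * exp(k * t)
    if (any(abs(den) < 1e-12)) {
      stop(sprintf("denominator b + c*e^{kt} vanishes at t = %s (pole)",
                   format(t[abs(den) < 1e-12][1])), call. = FALSE)
    }
    return(f - f / den)
  }
  tt <- round(t)
  mx <- max(tt, 0)
  taus <- seq_len(mx) - 1
  den <- b + c0 * (1 + k)^taus
  if (as_printed) {
    if (variant != "primary") stop("as_printed applies to the primary variant")
    fac <- 1 - k * b / (b + c0 * (1 + k)^(taus + 1))
    if (any(fac == 0)) stop("printed-form factor vanishes", call. = FALSE)
    cp <- c(1, cumprod(fac))
    return(f + (s - f) / cp[tt + 1])
  }
  if (variant == "primary") {
    if (any(den == 0)) {
      stop(sprintf("denominator b + c(1+k)^tau vanishes at tau = %d (pole)",
                   taus[den == 0][1]), call. = FALSE)
    }
    p <- k * (1 - b / den)
    if (any(1 + p == 0)) stop("1 + p(tau) = 0: dynamic equation not regressive")
    cp <- c(1, cumprod(1 / (1 + p)))          # e_{(-)p}(t, 0)
    f + (s - f) * cp[tt + 1]
  } else {
    den1 <- b + c0 * (1 + k)^(taus + 1)
    if (any(den1 == 0)) {
      stop(sprintf("denominator b + c(1+k)^(tau+1) vanishes at tau = %d (pole)",
                   taus[den1 == 0][1]), call. = FALSE)
    }
    q <- 1 - b / den1
    fac <- 1 - (k / (1 + k)) * q              # 1 + (circle-minus k) q
    cp <- c(1, cumprod(fac))                  # e_{((-)k) q}(t, 0)
    f + (s - f) * cp[tt + 1]
  }
}
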