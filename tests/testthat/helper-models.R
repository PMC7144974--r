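# Shared helpers for the test suite.

complete_pars_for_test <- function(model, pars) {
  tsgrowth:::complete_pars(tsgrowth::growth_model(model), pars)
}

# Direct implementation of the variation-of-constants formulas on the
# integer scale, used as the independent oracle against recursion_solve.
# forward: x(t) = e_p(t,t0) x0 + sum_{tau} e_p(t, tau+1) f(tau)
# sigma:   x(t) = e_{(-)p}(t,t0) x0 + sum_{tau} e_{(-)p}(t, tau) f(tau)
voc_solve_integer <- function(form, pseq, fseq, x0) {
  n <- length(pseq)
  ep <- function(ti, si) {               # e_p(t, s) = prod_{u=s}^{t-1} (1+p(u))
    if (ti == si) return(1)
    prod(1 + pseq[(si + 1):ti])          # pseq[j] is p at tau = j-1
  }
  x <- numeric(n + 1)
  for (step in 0:n) {
    if (form == "forward") {
      acc <- ep(step, 0) * x0
      if (step > 0) {
        for (tau in 0:(step - 1)) acc <- acc + ep(step, tau + 1) * fseq[tau + 1]
      }
    } else {
      em <- function(ti, si) 1 / ep(ti, si)   # e_{(-)p}(t,s) = 1/e_p(t,s)
      acc <- em(step, 0) * x0
      if (step > 0) {
        for (tau in 0:(step - 1)) acc <- acc + em(step, tau) * fseq[tau + 1]
      }
    }
    x[step + 1] <- acc
  }
  x
}
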