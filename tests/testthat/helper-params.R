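# Shared fixture parameter sets (the figure-caption regimes of the study)
# and small independent oracles used across test files.

# Free-mean noise-scan parameter sets (four colored curves)
fig2b_sets <- list(
  green = gene_params(gamma1 = 0.1, gamma0 = 0.1, f = 0.01, lambda1 = 40, lambda0 = 0),
  red   = gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0,    lambda1 = 40, lambda0 = 0),
  black = gene_params(gamma1 = 0.1, gamma0 = 0.2, f = 0,    lambda1 = 40, lambda0 = 0),
  blue  = gene_params(gamma1 = 0.1, gamma0 = 0.1, f = 0,    lambda1 = 30, lambda0 = 0)
)

# Fixed-mean compensation base (all four modes anchored at zero leakage)
fig2a_base <- gene_params(gamma1 = 0.1, gamma0 = 0.1, f = 0, lambda1 = 40, lambda0 = 0)

# Modality-analysis bases: no feedback, negative feedback, positive feedback
fig3a_base <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0,   lambda1 = 40, lambda0 = 0)
fig3b_base <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0.1, lambda1 = 40, lambda0 = 0)
fig3c_base <- gene_params(gamma1 = 0.5, gamma0 = 0.1, f = 0.1, lambda1 = 0,  lambda0 = 40)

# Independent reference evaluation of Kummer's function: plain-R series with
# the reflection to a positive argument, coded without package internals.
kummer_ref <- function(a, b, z, max_iter = 5000L) {
  if (z < 0) return(exp(z) * kummer_ref(b - a, b, -z, max_iter))
  term <- 1; s <- 1
  for (k in 0:(max_iter - 1L)) {
    term <- term * (a + k) * z / ((b + k) * (k + 1))
    s <- s + term
    if (abs(term) < 1e-17 * abs(s) && k > z) break
  }
  s
}

# Independent evaluation of the classical (no-leakage, no-feedback)
# two-state stationary law: P(n) = lambda^n/n! (g1)_n/(g0+g1)_n *
# 1F1(g1 + n, g0 + g1 + n; -lambda), normalized.
classical_two_state_pmf <- function(gamma1, gamma0, lambda, n_max) {
  logp <- vapply(0:n_max, function(n) {
    n * log(lambda) - lgamma(n + 1) +
      (lgamma(gamma1 + n) - lgamma(gamma1)) -
      (lgamma(gamma0 + gamma1 + n) - lgamma(gamma0 + gamma1)) +
      log(kummer_ref(gamma1 + n, gamma0 + gamma1 + n, -lambda))
  }, numeric(1))
  p <- exp(logp)
  p / sum(p)
}

# parameter grid spanning the caption regimes with lambda > 0 (where the
# closed form is on its proven domain)
caption_grid <- local({
  grid <- list()
  for (ps in fig2b_sets) {
    for (l0 in c(0, 1, 2, 5, 10, 15, 20)) {
      grid[[length(grid) + 1L]] <- set_leakage(ps, l0)
    }
  }
  for (l0 in c(0, 10, 25)) grid[[length(grid) + 1L]] <- set_leakage(fig3a_base, l0)
  for (l0 in c(2, 5, 10)) grid[[length(grid) + 1L]] <- set_leakage(fig3b_base, l0)
  grid
})
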