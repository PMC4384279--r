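test_that("no-leakage limit reproduces the classical two-state law pointwise", {
  p <- gene_params(0.2, 0.1, 0, 40, 0)
  pmf <- stationary_pmf(p, n_max = 120)
  ref <- classical_two_state_pmf(0.2, 0.1, 40, 120)
  expect_lt(max(abs(as.numeric(pmf) - ref)), 1e-8)
})

test_that("leaky and feedback regimes agree with the master-equation solve", {
  p <- gene_params(0.2, 0.1, 0, 40, 5)
  expect_lt(total_variation(stationary_pmf(p),
                            marginal_pmf(cme_steady_state(p, 200))), 1e-6)
  p2 <- gene_params(0.2, 0.1, 0.1, 40, 10)
  expect_lt(total_variation(stationary_pmf(p2),
                            marginal_pmf(cme_steady_state(p2))), 1e-6)
})

test_that("constitutive limit is an exact Poisson law", {
  p <- gene_params(0.7, 0.3, 0, 5, 5)
  pmf <- stationary_pmf(p)
  expect_lt(total_variation(pmf, poisson_pmf(5, support_max(pmf))), 1e-10)
  expect_equal(pmf[["0"]], exp(-5), tolerance = 1e-12)
})

test_that("generating-function mean matches its no-feedback closed form", {
  gd <- generating_derivatives(gene_params(0.2, 0.1, 0, 40, 0))
  expect_equal(gd$gprime, 40 * 0.2 / 0.3, tolerance = 1e-10)
  gd2 <- generating_derivatives(gene_params(0.1, 0.1, 0, 40, 10))
  expect_equal(gd2$gprime, 10 + 30 * 0.5, tolerance = 1e-10)
  # with feedback, against the master-equation moments
  p <- gene_params(0.2, 0.1, 0.1, 40, 10)
  ref <- pmf_moments(marginal_pmf(cme_steady_state(p)))
  expect_equal(generating_derivatives(p)$gprime, ref$mean, tolerance = 1e-6)
})

test_that("noise intensity matches Poisson, classical and master-equation references", {
  expect_equal(moments(gene_params(0.2, 0.1, 0, 5, 5))$noise, 0.2,
               tolerance = 1e-12)
  m <- moments(gene_params(0.2, 0.1, 0, 40, 0))
  expect_equal(m$noise, 1 / m$mean + 0.1 / (0.2 * 1.3), tolerance = 1e-10)
  p <- gene_params(0.2, 0.1, 0.1, 40, 10)
  ref <- pmf_moments(marginal_pmf(cme_steady_state(p)))
  expect_equal(moments(p)$noise, ref$noise, tolerance = 1e-6)
  expect_error(moments(gene_params(0.2, 0.1, 0, 0, 0)), "mean is zero")
})

test_that("series normalization and moment consistency hold across the caption grid", {
  for (p in caption_grid) {
    pmf <- stationary_pmf(p)
    expect_lt(abs(attr(pmf, "residual")), 1e-6)
    mom <- moments(p)
    num <- pmf_moments(pmf)
    expect_equal(num$mean, mom$mean, tolerance = 1e-6)
    expect_equal(num$variance, mom$variance, tolerance = 1e-6)
  }
})

test_that("fast-switching limit converges to the Poisson law of the ON rate", {
  p <- gene_params(gamma1 = 1000, gamma0 = 0, f = 0, lambda1 = 40, lambda0 = 0)
  pmf <- stationary_pmf(p)
  expect_lt(total_variation(pmf, poisson_pmf(40, support_max(pmf))), 1e-3)
})

test_that("mean is strictly increasing in the leakage rate", {
  grid <- seq(0, 20, length.out = 10)
  for (base in fig2b_sets) {
    means <- vapply(grid, function(l0) moments(set_leakage(base, l0))$mean,
                    numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("the unproven positive-feedback regime is validated or replaced", {
  pm <- product_pmf(fig3c_base)
  expect_true(attr(pm, "path") %in% c("analytic", "cme"))
  ref <- marginal_pmf(cme_steady_state(fig3c_base))
  expect_lt(total_variation(pm, ref), 1e-6)
  mm <- model_moments(fig3c_base)
  expect_equal(mm$mean, pmf_moments(ref)$mean, tolerance = 1e-6)
})
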