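test_that("degradation-rate normalization rescales and is idempotent", {
  p <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0, lambda1 = 40, lambda0 = 0, d = 1)
  expect_equal(normalize_params(p), p)

  q <- gene_params(gamma1 = 0.4, gamma0 = 0.2, f = 0, lambda1 = 80, lambda0 = 0, d = 2)
  qn <- normalize_params(q)
  expect_equal(unclass(qn),
               unclass(gene_params(0.2, 0.1, 0, 40, 0, d = 1)))
  expect_equal(normalize_params(qn), qn)
  # dimensionless ratios unchanged
  expect_equal(qn$lambda1 / qn$gamma0, q$lambda1 / q$gamma0)

  expect_error(gene_params(0.2, 0.1, 0, 40, 0, d = 0), "positive")
  expect_error(gene_params(-0.1, 0.1, 0, 40, 0), "nonnegative")
})

test_that("feedback labeling identifies the ON state", {
  expect_identical(feedback_labeling(gene_params(0.2, 0.1, 0.1, 40, 1)), "negative")
  expect_identical(feedback_labeling(gene_params(0.5, 0.1, 0.1, 1, 40)), "positive")
  expect_identical(feedback_labeling(gene_params(0.2, 0.1, 0, 5, 5)), "constitutive")
})

test_that("derived constants match direct substitution in the caption regimes", {
  # f = 0, lambda0 = 0 collapses to the classical two-state constants
  dc <- derived_constants(gene_params(0.2, 0.1, 0, 40, 0))
  expect_equal(dc$lam, 40)
  expect_equal(dc$R, 40)
  expect_equal(dc$Q, 40)
  expect_equal(dc$alpha, 1.2)
  expect_equal(dc$beta, 1.3)
  expect_equal(dc$alpha - 1, 0.2)   # gamma1
  expect_equal(dc$beta - 1, 0.3)    # gamma0 + gamma1

  # negative-feedback regime with leakage
  dc2 <- derived_constants(gene_params(0.2, 0.1, 0.1, 40, 10))
  expect_equal(dc2$lam, 30)
  expect_equal(dc2$R, 29)
  expect_equal(dc2$Q, 29 / 1.21)

  # positive-feedback labeled regime flags lambda < 0
  dc3 <- derived_constants(gene_params(0.5, 0.1, 0.1, 10, 40))
  expect_equal(dc3$lam, -30)
  expect_equal(dc3$R, -34)
})

test_that("Q * (f+1)^2 = R self-consistency holds across random parameter sets", {
  set.seed(42)
  for (i in 1:25) {
    p <- gene_params(gamma1 = runif(1, 0.05, 2), gamma0 = runif(1, 0.05, 2),
                     f = runif(1, 0, 0.5), lambda1 = runif(1, 1, 60),
                     lambda0 = runif(1, 0, 30))
    dc <- tryCatch(derived_constants(p), error = function(e) NULL)
    if (is.null(dc)) next
    expect_equal(dc$Q * (p$f + 1)^2, dc$R, tolerance = 1e-12)
    expect_true(is.finite(dc$A) && dc$A != 0)
  }
})

test_that("near-singular R is refused and routed to the master-equation path", {
  # lambda = f * lambda0 exactly
  p <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0.5, lambda1 = 15, lambda0 = 10)
  expect_error(derived_constants(p), "cme_steady_state")
  # but the routed distribution still works
  pm <- product_pmf(p)
  expect_identical(attr(pm, "path"), "cme")
  expect_equal(sum(pm), 1, tolerance = 1e-12)
})

test_that("parameter sets round-trip through YAML and JSON config files", {
  p <- gene_params(0.2, 0.1, 0.1, 40, 10, d = 2)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gamma1: 0.2", "gamma0: 0.1", "f: 0.1",
               "lambda1: 40", "lambda0: 10", "d: 2"), yml)
  expect_equal(unclass(read_params(yml)), unclass(p))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(p), js, auto_unbox = TRUE)
  expect_equal(unclass(read_params(js)), unclass(p))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("gamma1: 0.2", bad)
  expect_error(read_params(bad), "missing keys")
})
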