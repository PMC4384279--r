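test_that("zero leakage is the fixed point of every compensation mode", {
  base <- fig2a_base
  for (mode in c("gamma1_down", "gamma0_up", "f_up", "lambda1_down")) {
    ps <- solve_compensation(base, 0, mode)
    target <- switch(mode, gamma1_down = "gamma1", gamma0_up = "gamma0",
                     f_up = "f", lambda1_down = "lambda1")
    expect_equal(attr(ps, "comp_value"), base[[target]], tolerance = 1e-7)
  }
})

test_that("the gamma1 compensation agrees with the algebraic no-feedback solution", {
  base <- fig2a_base
  fixed_mean <- moments(base)$mean          # 20
  for (l0 in c(2, 5, 10)) {
    ps <- solve_compensation(base, l0, "gamma1_down")
    closed <- base$gamma0 * (fixed_mean - l0) / (base$lambda1 - fixed_mean)
    expect_equal(attr(ps, "comp_value"), closed, tolerance = 1e-8)
    expect_equal(moments(ps)$mean, fixed_mean, tolerance = 1e-8)
  }
})

test_that("the feedback-strength compensation holds the master-equation mean fixed", {
  ps <- solve_compensation(fig2a_base, 8, "f_up")
  ref <- pmf_moments(marginal_pmf(cme_steady_state(ps)))
  expect_equal(ref$mean, 20, tolerance = 1e-6)
})

test_that("unattainable targets raise an infeasible-point error", {
  # once the leakage alone exceeds the target mean, no gamma0 can lower the
  # mean back to it (the mean is bounded below by the leakage rate)
  expect_error(solve_compensation(fig2a_base, 30, "gamma0_up"),
               "infeasible")
})

test_that("a single-point free scan reduces to the base-model moments", {
  sc <- noise_vs_leakage_scan(fig2a_base, 5)
  expect_equal(nrow(sc), 1L)
  ref <- moments(set_leakage(fig2a_base, 5))
  expect_equal(sc$mean, ref$mean)
  expect_equal(sc$noise, ref$noise)
  expect_identical(sc$path, "analytic")
})

test_that("compensated scans pin the mean and decrease the noise", {
  sc <- noise_vs_leakage_scan(fig2a_base, seq(0, 15, length.out = 8),
                              mode = "gamma0_up")
  expect_true(all(sc$feasible))
  expect_equal(sc$mean, rep(20, 8), tolerance = 1e-7)
  expect_true(all(diff(sc$noise) < 0))
  # infeasible grid points are recorded as gaps, not failures
  sc2 <- noise_vs_leakage_scan(fig2a_base, c(0, 10, 30), mode = "gamma0_up")
  expect_identical(sc2$feasible, c(TRUE, TRUE, FALSE))
  expect_true(is.na(sc2$noise[3]))
})

test_that("analytic scan rows are spot-audited against the master equation", {
  sc <- noise_vs_leakage_scan(fig2b_sets$red, seq(0, 20, length.out = 12))
  audit <- attr(sc, "audit")
  expect_gt(nrow(audit), 0)
  expect_true(all(audit$rel_err < 1e-6))
})

test_that("modality scans reproduce the three feedback scenarios", {
  expect_equal(modality_scan(fig3a_base, c(0, 25))$n_modes, c(2L, 1L))
  expect_equal(modality_scan(fig3c_base, c(0, 10))$n_modes, c(2L, 1L))
  scb <- modality_scan(fig3b_base, c(0, 10))
  expect_equal(scb$n_modes, c(1L, 1L))
  # the single peak moves away from the origin as leakage rises
  loc <- as.integer(scb$mode_locations)
  expect_lte(loc[1], 2)
  expect_gte(loc[2], 8)
  expect_gt(loc[2], loc[1])
})

test_that("burst scans aggregate seeds reproducibly", {
  sc1 <- burst_scan(fig3a_base, c(0, 10), seeds = 1:2, t_end = 2e4)
  sc2 <- burst_scan(fig3a_base, c(0, 10), seeds = 1:2, t_end = 2e4)
  expect_identical(sc1, sc2)
  expect_equal(sc1$n_seeds, c(2L, 2L))
  expect_true(all(is.finite(sc1$bf_se)))
  # without feedback both summaries are flat within their 3 s.e. bands
  expect_lt(abs(sc1$bf[2] - sc1$bf[1]),
            3 * sqrt(sc1$bf_se[1]^2 + sc1$bf_se[2]^2))
  expect_lt(abs(sc1$bs[2] - sc1$bs[1]),
            3 * sqrt(sc1$bs_se[1]^2 + sc1$bs_se[2]^2))
})

test_that("tables round-trip through the TSV format with headers", {
  pmf <- stationary_pmf(fig3a_base)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(pmf, f, params = fig3a_base)
  back <- read_tsv_table(f)
  expect_equal(back$probability, as.numeric(pmf), tolerance = 1e-12)
  expect_true(any(grepl("gamma1=0.2", attr(back, "header"))))

  ss <- cme_steady_state(fig3a_base, 100)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_promoter_pmf_tsv(ss, f2)
  back2 <- read_tsv_table(f2)
  expect_equal(back2$P0 + back2$P1, as.numeric(marginal_pmf(ss)),
               tolerance = 1e-12)
})
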