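test_that("simulations are bit-identical under the same seed and differ across seeds", {
  p <- fig3a_base
  a <- simulate_gene(p, t_end = 500, seed = 11, store_path = TRUE)
  b <- simulate_gene(p, t_end = 500, seed = 11, store_path = TRUE)
  expect_identical(a$times, b$times)
  expect_identical(a$counts, b$counts)
  expect_identical(a$promoter_states, b$promoter_states)
  c <- simulate_gene(p, t_end = 500, seed = 12, store_path = TRUE)
  expect_false(identical(a$times, c$times))
})

test_that("counts stay nonnegative and change by unit steps along a path", {
  a <- simulate_gene(fig3b_base, t_end = 300, seed = 5, store_path = TRUE)
  expect_true(all(a$counts >= 0))
  dn <- diff(a$counts)
  ds <- diff(a$promoter_states)
  expect_true(all(abs(dn) <= 1))
  # product count moves only on synthesis/degradation, promoter only on switching
  expect_true(all(dn == 0 | ds == 0))
})

test_that("constitutive simulation recovers the Poisson mean", {
  tr <- simulate_gene(gene_params(0.2, 0.1, 0, 5, 5), t_end = 2e4, seed = 3)
  m <- pmf_moments(stationary_histogram(tr))
  # ~1.8e4 product lifetimes of stationary data: 3 s.e. is ~0.05 molecules
  expect_lt(abs(m$mean - 5), 0.15)
})

test_that("a silent gene stays at zero", {
  tr <- simulate_gene(gene_params(0.2, 0.1, 0, 0, 0), t_end = 1000, seed = 1,
                      store_path = TRUE)
  expect_true(all(tr$counts == 0))
  expect_equal(sum(tr$channel_counts[c("synth_on", "synth_off", "degrade")]), 0)
})

test_that("stationary histogram is time-weighted, not event-weighted", {
  # constant count: point mass
  tr <- new_trajectory(times = c(0, 1, 2), promoter_states = c(1, 1, 1),
                       counts = c(3, 3, 3), t_end = 10)
  h <- stationary_histogram(tr, burn_in = 0)
  expect_equal(as.numeric(h), c(0, 0, 0, 1))
  # 25% of time at n = 0, 75% at n = 1
  tr2 <- new_trajectory(times = c(0, 2.5), promoter_states = c(0, 0),
                        counts = c(0, 1), t_end = 10)
  h2 <- stationary_histogram(tr2, burn_in = 0)
  expect_equal(as.numeric(h2), c(0.25, 0.75))
  # event-dense excursions must not distort the time weighting
  tr3 <- new_trajectory(times = c(0, 1, 1.1, 1.2, 1.3, 1.4), rep(0, 6),
                        counts = c(0, 1, 0, 1, 0, 1), t_end = 2)
  h3 <- stationary_histogram(tr3, burn_in = 0)
  expect_equal(as.numeric(h3), c(1.2, 0.8) / 2)
  expect_error(stationary_histogram(tr, burn_in = 20), "empty")
})

test_that("long-run histogram matches the analytic stationary law", {
  p <- set_leakage(fig3a_base, 25)
  tr <- simulate_gene(p, t_end = 1e5, seed = 21)
  expect_lt(total_variation(stationary_histogram(tr), stationary_pmf(p)), 0.02)
})

test_that("fast binding/dissociation recovers the catalytic-feedback model", {
  p <- fig3b_base
  tr <- simulate_gene(p, t_end = 3e4, seed = 8, variant = "slow_binding",
                      variant_params = list(k_off = 500))
  expect_lt(total_variation(stationary_histogram(tr), stationary_pmf(p)), 0.03)
})

test_that("two-stage transcription/translation preserves the mean product level", {
  p <- fig3a_base
  tr <- simulate_gene(p, t_end = 3e4, seed = 9, variant = "two_stage")
  m <- pmf_moments(stationary_histogram(tr))
  target <- moments(p)$mean
  expect_lt(abs(m$mean - target) / target, 0.1)
})

test_that("leakage reduces noise and unimodalizes in the sequestration variant", {
  # qualitative check of the robustness claim for slow transcription-factor
  # binding: raising leakage lowers the histogram noise
  lo <- simulate_gene(set_leakage(fig3b_base, 0), t_end = 3e4, seed = 14,
                      variant = "slow_binding", variant_params = list(k_off = 0.5))
  hi <- simulate_gene(set_leakage(fig3b_base, 10), t_end = 3e4, seed = 14,
                      variant = "slow_binding", variant_params = list(k_off = 0.5))
  expect_gt(pmf_moments(stationary_histogram(lo))$noise,
            pmf_moments(stationary_histogram(hi))$noise)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulate_gene(fig3a_base, t_end = 100, seed = 1,
                             variant = "nonsense"))
  expect_error(simulate_gene(fig3a_base, t_end = 100, seed = 1,
                             variant_params = list(k_off = 2)),
               "only meaningful")
  expect_error(simulate_gene(fig3a_base, t_end = 100, burn_in = 200, seed = 1))
})
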