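test_that("expected null damaging count is linear arithmetic", {
  rt <- rate_table(c("A", "B"), c(4e-5, 4e-5), c(2e-6, 2e-6),
                   c(8e-6, 8e-6))
  expect_equal(expected_null_damaging(rt, 100), 0.004)
  expect_equal(expected_null_damaging(rt, 200),
               2 * expected_null_damaging(rt, 100))
  expect_equal(expected_null_damaging(rt, 100, exposure = 0.5), 0.002)
  expect_error(expected_null_damaging(rt[0, ], 100), "empty")
})

test_that("a calibrated default-size table gives cohort-scale expectations", {
  rates <- make_rate_table(scenario_config(seed = 1))
  E0 <- expected_null_damaging(rates, 750)
  expect_equal(E0, 750 * 0.42, tolerance = 0.02)
})

test_that("degenerate recurrence cases follow pigeonhole logic", {
  rt <- rate_table(c("A", "B", "C"), rep(1e-9, 3), rep(2.5e-10, 3),
                   rep(2.5e-10, 3))
  # no mutations: never a recurrent gene
  expect_true(all(simulate_recurrence(2, 0, rt, 10, n_reps = 50,
                                      seed = 1) == 0))
  # k = 1 with two forced risk mutations: always at least one
  expect_true(all(simulate_recurrence(1, 2, rt, 1, n_reps = 200,
                                      seed = 2) >= 1))
})

test_that("tiny-instance enumeration oracle: 2 risk mutations, k=2 of G=3", {
  # equal rates, E0 ~ 0 so both mutations are risk-mediating; they land in
  # the same gene with probability 1/2 by enumeration
  rt <- rate_table(c("A", "B", "C"), rep(1e-9, 3), rep(2.5e-10, 3),
                   rep(2.5e-10, 3))
  R <- simulate_recurrence(2, 2, rt, 1, n_reps = 4000, seed = 33)
  p1 <- mean(R == 1)
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(p1 - 0.5), 3 * se)
})

test_that("equal-rate occupancy matches the closed-form expectation", {
  # M null mutations over G equal-weight genes: E[#genes with >= 2] =
  # G * (1 - (1-1/G)^M - M/G * (1-1/G)^(M-1))
  G <- 400; M <- 54
  rt <- rate_table(sprintf("g%03d", 1:G), rep(4e-5, G), rep(1e-5, G),
                   rep(1e-5, G))
  # huge E0 so that no mutation is risk-mediating (pure null placement)
  R <- simulate_recurrence(5, M, rt, 5000, n_reps = 3000, seed = 12)
  expected <- G * (1 - (1 - 1 / G)^M - (M / G) * (1 - 1 / G)^(M - 1))
  se <- stats::sd(R) / sqrt(length(R))
  expect_lt(abs(mean(R) - expected), 3 * se)
})

test_that("mean recurrence decreases as risk spreads over more genes", {
  cfg <- small_scenario(seed = 6)
  rates <- make_rate_table(cfg)
  # exposure chosen so roughly 15 of 54 mutations are risk-mediating
  means <- vapply(c(10, 100, 1000), function(k) {
    mean(simulate_recurrence(k, 54, rates, 118, exposure = 0.79,
                             n_reps = 600, seed = 100 + k))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the likelihood curve is seeded-reproducible and flags misuse", {
  cfg <- small_scenario(seed = 4)
  rates <- make_rate_table(cfg)
  mc <- mle_config(M_obs = 30, R_obs = 1, n_trios = 60,
                   k_grid = c(10, 50, 200, 1000), n_sims_per_k = 300,
                   exposure = 0.5, refine = FALSE, seed = 77)
  r1 <- mle_risk_genes(mc, rates)
  r2 <- mle_risk_genes(mc, rates)
  expect_equal(r1$likelihood, r2$likelihood)
  expect_true(r1$k_hat %in% mc$k_grid)
  expect_true(all(r1$likelihood$L >= 0 & r1$likelihood$L <= 1))
  expect_error(mle_config(M_obs = 1, R_obs = 1, n_trios = 10),
               "too small")
  expect_error(mle_config(M_obs = 10, R_obs = 1, n_trios = 10,
                          profile = c(1)), "hit count")
})

test_that("count statistic is degenerate at k = 1 but profile is not", {
  # with a large excess, k = 1 stacks all risk mutations in one gene:
  # the scalar count still reports one recurrent gene, the profile
  # (one gene hit exactly twice) rejects the pile-up
  cfg <- small_scenario(seed = 9)
  rates <- make_rate_table(cfg)
  base <- list(M_obs = 40, R_obs = 1, n_trios = 60,
               k_grid = c(1, 50, 500), n_sims_per_k = 400,
               exposure = 0.2, refine = FALSE, seed = 5)
  count_res <- mle_risk_genes(do.call(mle_config, c(base,
                                                    statistic = "count")),
                              rates)
  prof_res <- mle_risk_genes(do.call(mle_config, c(base,
                                                   statistic = "profile")),
                             rates)
  Lc <- count_res$likelihood
  Lp <- prof_res$likelihood
  expect_gt(Lc$L[Lc$k == 1], 0.8)   # degenerate maximum
  expect_lt(Lp$L[Lp$k == 1], 0.02)  # profile rules it out
})

test_that("non-identifiable configuration (R=0, no excess) warns", {
  cfg <- small_scenario(seed = 10, G = 200)
  rates <- make_rate_table(cfg)
  mc <- mle_config(M_obs = 2, R_obs = 0, n_trios = 1,
                   k_grid = c(5, 50), n_sims_per_k = 200, exposure = 50,
                   refine = FALSE, seed = 3)
  expect_warning(mle_risk_genes(mc, rates), "non-identifiable")
})
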