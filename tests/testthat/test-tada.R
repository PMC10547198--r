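test_that("class Bayes factor matches the quadrature oracle", {
  # spot grid; the full acceptance grid lives in test-acceptance.R
  for (x in c(0, 2, 4)) {
    for (q0 in c(1e-4, 1e-2)) {
      for (gbar in c(1, 20)) {
        bf <- class_bayes_factor(x, n_trios = 1, mu = q0 / 2, gbar)
        expect_equal(bf, bf_quadrature_oracle(x, q0, gbar, 1),
                     tolerance = 1e-6)
      }
    }
  }
  expect_equal(class_bayes_factor(2, 1, 0.005, 20, 1), 340.8,
               tolerance = 1e-3)
})

test_that("Bayes factor limits behave: flat prior, no data, large beta", {
  # gamma_bar = 1 with large beta: prior degenerates at relative risk 1
  expect_equal(class_bayes_factor(3, 100, 1e-5, 1, beta = 1e6), 1,
               tolerance = 1e-3)
  # x = 0 with small q0: slightly below 1, tending to 1 as q0 -> 0
  b1 <- class_bayes_factor(0, 100, 1e-5, 20)
  b2 <- class_bayes_factor(0, 100, 1e-8, 20)
  expect_lt(b1, 1)
  expect_lt(b1, b2)
  expect_equal(b2, 1, tolerance = 1e-3)
  # zero rate: BF 1 at x = 0, error when a count was observed
  expect_equal(class_bayes_factor(0, 100, 0, 20), 1)
  expect_error(class_bayes_factor(1, 100, 0, 20), "rate table")
  expect_error(class_bayes_factor(51, 100, 1e-5, 20), "exceeds 50")
})

test_that("Bayes factor increases with the observed count when gbar > 1", {
  for (q0 in c(1e-4, 1e-2, 1e-1)) {
    bf <- class_bayes_factor(0:6, n_trios = 1, mu = q0 / 2, 20)
    expect_true(all(diff(bf) > 0))
  }
})

test_that("gene Bayes factor is the product of class Bayes factors", {
  params <- tada_params(100, 20, 5, pi = 0.01)
  bf <- gene_bayes_factor(2, 1, 1e-5, 3e-5, params)
  expect_equal(bf,
               class_bayes_factor(2, 100, 1e-5, 20) *
                 class_bayes_factor(1, 100, 3e-5, 5))
  expect_equal(gene_bayes_factor(0, 0, 1e-9, 1e-9, params), 1,
               tolerance = 1e-4)
})

test_that("direct-posterior q is the running mean with tie sharing", {
  # posteriors 0.9 and 0.5 at pi = 0.5 require BFs 9 and 1
  res <- direct_posterior_fdr(c(9, 1), pi = 0.5)
  expect_equal(res$posterior, c(0.9, 0.5))
  expect_equal(res$q, c(0.1, 0.3))
  # all BFs equal: every gene shares the worst q
  res2 <- direct_posterior_fdr(rep(4, 5), pi = 0.1)
  expect_true(all(res2$q == res2$q[1]))
  # q at rank 1 equals 1 - max posterior (when untied)
  withr::local_seed(1)
  bf <- stats::rlnorm(50, 1, 2)
  res3 <- direct_posterior_fdr(bf, pi = 0.05)
  expect_equal(min(res3$q), 1 - max(res3$posterior))
  # non-decreasing along the BF-descending ranking
  o <- order(-res3$bf)
  expect_true(all(diff(res3$q[o]) >= -1e-12))
  # invariant to input order
  perm <- sample(50)
  res4 <- direct_posterior_fdr(bf[perm], pi = 0.05)
  expect_equal(res4$q, res3$q[perm])
})

test_that("burden-calibrated gamma matches plug-in arithmetic", {
  expect_equal(estimate_gamma_from_burden(10, 10, 5, 100), 1)
  expect_equal(estimate_gamma_from_burden(20, 10, 10, 1000), 101)
  expect_equal(estimate_gamma_from_burden(12, 6.15, 184, 18665), 97,
               tolerance = 0.01)
  expect_equal(estimate_gamma_from_burden(1, 10, 5, 100), 1) # floor at 1
  expect_error(estimate_gamma_from_burden(10, 10, 0, 100), "positive")
})

test_that("null simulation p-values behave at the extremes", {
  cfg <- small_scenario(seed = 5, G = 300)
  rates <- make_rate_table(cfg)
  params <- tada_params(60, 20, 5, pi = 0.02, n_null_sims = 150, seed = 8)
  obs0 <- gene_bayes_factor(rep(0L, 300), rep(0L, 300), rates$mu_lgd,
                            rates$mu_misd, params)
  # against each gene's own null, a zero count is never exceeded: p ~ 1
  p0 <- null_pvalues(obs0, rates, params, pooled = FALSE)
  expect_true(all(p0 > 0.5))
  # a planted doubly-hit gene at tiny q0 is never matched under the null
  obs <- obs0
  obs[1] <- gene_bayes_factor(2L, 0L, rates$mu_lgd[1], rates$mu_misd[1],
                              params)
  p <- null_pvalues(obs, rates, params)
  expect_lt(p[1], 1e-3)
  expect_equal(p, null_pvalues(obs, rates, params)) # seeded: reproducible
})

test_that("run_tada flags the doubly hit gene and reports skipped genes", {
  cfg <- small_scenario(seed = 2, G = 500)
  rates <- make_rate_table(cfg)
  genes <- c(rates$gene[10], rates$gene[10], rates$gene[20], "NOT_IN_TABLE")
  tb <- denovo_table(data.frame(
    proband_id = c("a", "b", "c", "d"), cohort = "case", gene = genes,
    effect = "stopgain", polyphen_hdiv = NA_real_, pop_freq = NA_real_))
  params <- tada_params(118, 90, 25, pi = 0.01)
  res <- run_tada(tb, rates, params)
  expect_equal(attr(res, "skipped"), "NOT_IN_TABLE")
  expect_equal(res$gene[1], rates$gene[10])
  expect_lt(res$q[1], 0.1)
  expect_equal(sum(res$high_confidence), 1)
  # doubling pi weakly decreases every q
  params2 <- tada_params(118, 90, 25, pi = 0.02)
  res2 <- run_tada(tb, rates, params2)
  expect_true(all(res2$q <= res$q + 1e-12))
  # no variants: nothing flagged
  res0 <- run_tada(tb[0, ], rates, params)
  expect_equal(sum(res0$high_confidence), 0)
  expect_equal(sum(res0$probable), 0)
})

test_that("TADA writer emits the conventional column layout", {
  cfg <- small_scenario(seed = 2, G = 50)
  rates <- make_rate_table(cfg)
  tb <- denovo_table(data.frame(
    proband_id = "a", cohort = "case", gene = rates$gene[1],
    effect = "stopgain", polyphen_hdiv = NA_real_, pop_freq = NA_real_))
  res <- run_tada(tb, rates, tada_params(50, 10, 5, pi = 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tada(res, rates, path)
  out <- utils::read.delim(path, check.names = FALSE)
  expect_true(all(c("gene", "mut.cls1", "mut.cls2", "dn.cls1", "dn.cls2",
                    "BF", "qval") %in% names(out)))
  expect_equal(out$dn.cls1[out$gene == rates$gene[1]], 1)
})
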