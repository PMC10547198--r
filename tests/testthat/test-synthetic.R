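test_that("rate tables are calibrated to the per-individual targets", {
  cfg <- scenario_config(seed = 21)
  rates <- make_rate_table(cfg)
  expect_equal(nrow(rates), 18665)
  expect_equal(2 * sum(rates$mu_total), 1.18, tolerance = 1e-9)
  expect_equal(2 * sum(rates$mu_damaging), 0.42, tolerance = 0.02)
  # deterministic given the seed
  expect_equal(make_rate_table(cfg), rates)
  expect_false(isTRUE(all.equal(make_rate_table(scenario_config(seed = 22)),
                                rates)))
})

test_that("an explicit log-mean shifts total rates multiplicatively", {
  a <- make_rate_table(small_scenario(seed = 30, rate_log_mean = -12))
  b <- make_rate_table(small_scenario(seed = 30,
                                      rate_log_mean = -12 + log(2)))
  expect_equal(sum(b$mu_total), 2 * sum(a$mu_total), tolerance = 1e-9)
})

test_that("null cohorts reproduce the calibrated per-individual load", {
  cfg <- scenario_config(seed = 23, k_true = 1, gamma_bar_lgd = 1,
                         gamma_bar_misd = 1, freq_common_fraction = 0)
  rates <- make_rate_table(cfg)
  sim <- simulate_trio_cohort(cfg, rates)
  ct <- tabulate_counts(sim$variants, "control")
  sum_e <- sum(sim$trios$callable_bp[sim$trios$phenotype == "control"]) /
    (2 * 33828798)
  expected <- 1.18 * sum_e
  expect_lt(abs(ct[["coding"]] - expected), 3 * sqrt(expected))
  # null scenario: case and control per-bp rates agree
  bt <- burden_table(sim$variants[sim$variants$cohort == "case", ],
                     sim$variants[sim$variants$cohort == "control", ],
                     sim$trios)
  rr <- bt$rr[bt$variant_class == "coding"]
  expect_gt(bt$p[bt$variant_class == "coding"], 0.001)
  expect_lt(abs(log(rr)), 0.5)
})

test_that("common-variant fraction feeds the frequency filter", {
  cfg <- small_scenario(seed = 24, freq_common_fraction = 0.3)
  sim <- simulate_trio_cohort(cfg, make_rate_table(cfg))
  n_common <- sum(!is.na(sim$variants$pop_freq) &
                    sim$variants$pop_freq >= 0.001)
  expect_gt(n_common, 0)
  kept <- frequency_filter(sim$variants)
  expect_equal(nrow(kept), nrow(sim$variants) - n_common)
})

test_that("the pCMS-like scenario lands near its calibration anchors", {
  # ~54 damaging case variants and a recurrently hit gene in most seeds
  stats <- vapply(1:10, function(s) {
    cfg <- scenario_config(seed = s)
    sim <- simulate_trio_cohort(cfg, make_rate_table(cfg))
    v <- frequency_filter(sim$variants)
    fine <- classify_variant(v$effect, v$polyphen_hdiv)
    dmg <- v$gene[v$cohort == "case" &
                    fine %in% c("lgd_stopgain", "lgd_splice",
                                "lgd_frameshift", "mis_d")]
    c(M = length(dmg), recurrent = sum(table(dmg) >= 2))
  }, numeric(2))
  expect_lt(abs(mean(stats["M", ]) - 54), 10)
  expect_gte(mean(stats["recurrent", ] >= 1), 0.6)
})

test_that("gene sets have the requested sizes and risk overlap", {
  cfg <- small_scenario(seed = 25)
  rates <- make_rate_table(cfg)
  risk <- rates$gene[1:50]
  sets <- make_gene_sets(rates, risk, sizes = c(20, 40),
                         overlap_with_risk = c(1, 0),
                         names = c("hit", "null"), seed = 9)
  expect_equal(length(sets$hit$genes), 20)
  expect_equal(length(sets$null$genes), 40)
  expect_true(all(sets$hit$genes %in% risk))
  expect_false(any(sets$null$genes %in% risk))
})

test_that("planted-overlap sets are detected, disjoint sets are not", {
  cfg <- small_scenario(seed = 26, G = 1500, k_true = 40)
  rates <- make_rate_table(cfg)
  sim <- simulate_trio_cohort(cfg, rates)
  v <- frequency_filter(sim$variants)
  fine <- classify_variant(v$effect, v$polyphen_hdiv)
  keep <- v$cohort == "case" & fine %in% c("lgd_stopgain", "lgd_splice",
                                           "lgd_frameshift", "mis_d")
  muts <- data.frame(gene = v$gene[keep])
  sets <- make_gene_sets(rates, sim$risk_genes, sizes = c(40, 40),
                         overlap_with_risk = c(1, 0),
                         names = c("risk", "none"), seed = 2)
  scan <- cross_disorder_scan(muts, sets, rates, n_perm = 2000, seed = 3)
  expect_gt(scan$fold[scan$set_name == "risk"], 2)
  expect_lt(scan$p[scan$set_name == "risk"], 0.05)
  expect_gt(scan$p[scan$set_name == "none"], 0.05)
})

test_that("a scenario writes a complete, re-readable input directory", {
  dir <- withr::local_tempdir()
  paths <- write_scenario(small_scenario(seed = 27, G = 300), dir)
  expect_true(all(file.exists(unlist(paths))))
  expect_equal(nrow(read_rate_table(paths$rates)), 300)
  expect_gt(nrow(read_denovo_table(paths$variants)), 0)
  expect_equal(nrow(read_cohort_table(paths$trios)), 180)
})

test_that("the whole generator is a pure function of the scenario seed", {
  cfg <- small_scenario(seed = 28)
  r1 <- make_rate_table(cfg)
  s1 <- simulate_trio_cohort(cfg, r1)
  s2 <- simulate_trio_cohort(cfg, make_rate_table(cfg))
  expect_equal(as.data.frame(s1$variants), as.data.frame(s2$variants))
  expect_equal(s1$risk_genes, s2$risk_genes)
})
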