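test_that("reading a well-formed table preserves rows, order, and genes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "proband_id\tcohort\tgene\teffect\tpolyphen_hdiv\tpop_freq",
    "p1\tcase\tKDM5B\tstopgain\t\t",
    "p2\tcase\tCHD8\tnonsynonymous SNV\t0.99\t0.0001",
    "p3\tcontrol\tTTN\tsynonymous SNV\t\t0.2"
  ), path)
  tb <- read_denovo_table(path)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$gene, c("KDM5B", "CHD8", "TTN"))
  expect_equal(tb$effect[1], "stopgain")
  expect_true(is.na(tb$polyphen_hdiv[1]))
  expect_equal(tb$effect[2], "missense_snv")
  expect_equal(tb$pop_freq[3], 0.2)
})

test_that("unrecognized effects map to unknown and dialects remap columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "fam\tgrp\tGene.refGene\tExonicFunc.refGene",
    "f1\tcase\tFOXP1\texotic annotation"
  ), path)
  tb <- read_denovo_table(path, denovo_dialect(
    proband_id = "fam", cohort = "grp", gene = "Gene.refGene",
    effect = "ExonicFunc.refGene"))
  expect_equal(tb$effect, "unknown")
})

test_that("schema and parse errors name the offending column / row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("proband_id\tcohort\tgene", "p1\tcase\tA"), path)
  expect_error(read_denovo_table(path), "effect")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "proband_id\tcohort\tgene\teffect\tpolyphen_hdiv\tpop_freq",
    "p1\tcase\tA\tstopgain\tnot_a_number\t"
  ), path2)
  expect_error(read_denovo_table(path2), "row.*1")
})

test_that("generator output round-trips through the writer and reader", {
  cfg <- small_scenario(seed = 42)
  sim <- simulate_trio_cohort(cfg, make_rate_table(cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_denovo_table(sim$variants, path)
  back <- read_denovo_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$variants),
               tolerance = 1e-12)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(sim$trios, tpath)
  expect_equal(as.data.frame(read_cohort_table(tpath)),
               as.data.frame(sim$trios))
})

test_that("missense variants split on the PolyPhen2-HDIV cutpoints", {
  expect_equal(classify_variant("missense_snv", 0.96), "mis_d")
  expect_equal(classify_variant("missense_snv", 0.957), "mis_d")
  expect_equal(classify_variant("missense_snv", 0.50), "mis_p")
  expect_equal(classify_variant("missense_snv", 0.453), "mis_p")
  expect_equal(classify_variant("missense_snv", 0.10), "mis_b")
  expect_equal(classify_variant("missense_snv", NA), "missense_all")
  expect_equal(classify_variant("synonymous_snv", NA), "synonymous")
  expect_equal(classify_variant("stoploss", NA), "lgd_stopgain")
})

test_that("frequency filter keeps rare and unobserved variants, idempotently", {
  tb <- denovo_table(data.frame(
    proband_id = "p", cohort = "case", gene = letters[1:5],
    effect = "missense_snv", polyphen_hdiv = 0.5,
    pop_freq = c(0.05, NA, 0.0005, 0.01, NA)
  ))
  kept <- frequency_filter(tb)
  expect_equal(kept$gene, c("b", "c", "e"))
  expect_equal(frequency_filter(kept), kept)
  one <- frequency_filter(tb[1, ])
  expect_equal(nrow(one), 0)
})

test_that("class-hierarchy identities hold on random variant tables", {
  for (seed in 1:20) {
    counts <- tabulate_counts(random_denovo_table(200, seed))
    expect_equal(counts[["nonsynonymous"]],
                 counts[["missense_all"]] + counts[["lgd"]])
    expect_equal(counts[["damaging"]], counts[["lgd"]] + counts[["mis_d"]])
    expect_equal(counts[["lgd"]],
                 counts[["lgd_snv"]] + counts[["lgd_frameshift"]])
    expect_equal(counts[["lgd_snv"]],
                 counts[["lgd_stopgain"]] + counts[["lgd_splice"]])
    expect_equal(counts[["coding"]],
                 counts[["synonymous"]] + counts[["nonsynonymous"]] +
                   counts[["nonframeshift"]] + counts[["unknown"]])
  }
})

test_that("each variant contributes to exactly one finest class", {
  tb <- random_denovo_table(300, 7)
  fine <- classify_variant(tb$effect, tb$polyphen_hdiv)
  expect_equal(length(fine), nrow(tb))
  expect_true(all(nzchar(fine)))
  counts <- tabulate_counts(tb)
  expect_equal(counts[["all"]], nrow(tb))
})

test_that("empty tables tabulate to all-zero counts", {
  tb <- random_denovo_table(10, 1)[0, ]
  expect_true(all(tabulate_counts(tb) == 0))
})

test_that("case-exclusive damaging genes are set arithmetic on symbols", {
  mk <- function(genes, cohort, effect = "stopgain") {
    denovo_table(data.frame(proband_id = "p", cohort = cohort,
                            gene = genes, effect = effect,
                            polyphen_hdiv = NA_real_, pop_freq = NA_real_))
  }
  res <- case_exclusive_damaging_genes(mk(c("G1", "G1", "G2", "G3"), "case"),
                                       mk("G3", "control"))
  expect_equal(res$genes, c("G1", "G2"))
  res2 <- case_exclusive_damaging_genes(mk(c("G1", "G2"), "case"),
                                        mk("ZZ", "control"))
  expect_equal(res2$genes, c("G1", "G2"))
  # non-damaging control hits do not exclude
  res3 <- case_exclusive_damaging_genes(
    mk("G1", "case"), mk("G1", "control", effect = "synonymous_snv"))
  expect_equal(res3$genes, "G1")
})

test_that("rate table validation computes mu_damaging and rejects bad input", {
  rt <- rate_table(c("A", "B", "C"), c(1e-5, 2e-5, 3e-5),
                   c(1e-6, 2e-6, 3e-6), c(3e-6, 6e-6, 9e-6))
  expect_equal(rt$mu_damaging, rt$mu_lgd + rt$mu_misd)
  expect_error(rate_table(c("A", "A"), c(1, 1), c(0, 0), c(0, 0)),
               "duplicate.*A")
  expect_error(rate_table("A", 1e-5, -1e-6, 1e-6), "non-negative")
  expect_error(rate_table("A", 1e-6, 1e-6, 1e-6), "exceeds")
})

test_that("rate tables and gene sets round-trip through files", {
  cfg <- small_scenario(seed = 3, G = 100)
  rates <- make_rate_table(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rates, path)
  expect_equal(as.data.frame(read_rate_table(path)),
               as.data.frame(rates), tolerance = 1e-12)

  gpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# curated list", "KDM5B", "CHD8", " FOXP1 "), gpath)
  gs <- read_gene_set(gpath, "asd")
  expect_equal(gs$genes, c("KDM5B", "CHD8", "FOXP1"))

  sets <- make_gene_sets(rates, rates$gene[1:10], sizes = c(5, 8),
                         overlap_with_risk = c(0.4, 0), seed = 1)
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_gene_sets_tsv(sets, spath)
  back <- read_gene_sets_tsv(spath)
  expect_equal(sort(back[[1]]$genes), sort(sets[[1]]$genes))
})
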