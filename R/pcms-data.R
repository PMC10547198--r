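# Published summary data from the pCMS de novo exome study (118 case and
# 750 control trios after quality control) and deterministic synthetic
# reconstructions of its input tables from those printed marginals. The
# study's individual-level supplementary tables are not redistributed;
# everything here is rebuilt from the published per-class counts, rates,
# and gene lists, and is labelled synthetic accordingly.

#' Published per-class de novo variant counts for the pCMS study
#'
#' @return matrix with one row per variant class ([variant_classes()]) and
#'   columns `case` (118 trios) and `control` (750 trios).
#' @export
pcms_class_counts <- function() {
  m <- cbind(
    case = c(all = 134, coding = 128, synonymous = 30, nonsynonymous = 96,
             missense_all = 84, mis_d = 42, mis_p = 15, mis_b = 25,
             lgd = 12, damaging = 54, lgd_snv = 10, lgd_stopgain = 6,
             lgd_splice = 4, lgd_frameshift = 2, nonframeshift = 1,
             unknown = 1),
    control = c(all = 666, coding = 628, synonymous = 171,
                nonsynonymous = 446, missense_all = 411, mis_d = 190,
                mis_p = 79, mis_b = 137, lgd = 35, damaging = 225,
                lgd_snv = 19, lgd_stopgain = 16, lgd_splice = 3,
                lgd_frameshift = 16, nonframeshift = 3, unknown = 8)
  )
  m[variant_classes(), ]
}

#' Cohort haploid callable-base totals for the pCMS study
#'
#' Recovered from the published coding counts and per-bp coding rates
#' (count divided by rate): 128 / 2.02e-8 for cases, 628 / 1.74e-8 for
#' controls.
#'
#' @return named numeric vector (`case`, `control`) of haploid callable
#'   bases summed over each cohort's trios.
#' @export
pcms_callable_totals <- function() {
  c(case = 128 / 2.02e-8, control = 628 / 1.74e-8)
}

#' Trio counts of the pCMS study cohorts
#' @return named vector (`case` = 118, `control` = 750).
#' @export
pcms_n_trios <- function() c(case = 118L, control = 750L)

#' Published case-exclusive damaging gene list of the pCMS study
#'
#' The published table of genes harboring de novo damaging variants in
#' cases and not in controls lists 52 entries, one per damaging mutation in
#' a case-exclusive gene; the recurrently hit gene KDM5B appears twice, so
#' there are 51 unique genes.
#'
#' @param unique drop the duplicated recurrent-gene entry (default TRUE).
#' @return character vector of gene symbols.
#' @export
pcms_damaging_gene_list <- function(unique = TRUE) {
  entries <- c(
    "ACACB", "BBX", "DESI1", "GUCA1B", "MRAS", "SLC7A7", "ZNF195",
    "ADGRF2", "C16orf87", "DLG5", "HERC1", "NAV3", "TET3", "ZNF461",
    "ADRBK1", "CCDC25", "DNAH6", "ITSN1", "PHIP", "TNFRSF10B", "ZNF74",
    "AGO4", "CENPP", "DPPA5", "KDM3B", "PPP1R14C", "TRIM55", "ZNF862",
    "ALG8", "COG8", "FAM65B", "KDM5B", "PRRG4", "TRPM1",
    "ANKRD39", "COL21A1", "FEZ2", "KDM5B", "RAB11FIP3", "TRPV4",
    "ARVCF", "CORO6", "GGCX", "LY9", "RHAG", "UVSSA",
    "ATP2B2", "DDR1", "GLYR1", "MASP2", "RRBP1", "WNT5A"
  )
  if (unique) unique(entries) else entries
}

#' Burden-calibrated prior relative risks for the pCMS study
#'
#' The expected null class count in cases is the control count scaled by
#' the callable-base ratio; the excess over that expectation is spread over
#' `k` risk genes via [estimate_gamma_from_burden()].
#'
#' @param k assumed number of risk genes.
#' @param G gene-universe size.
#' @return named vector (`lgd`, `misd`) of prior mean relative risks.
#' @export
pcms_gamma <- function(k = 184, G = 18665) {
  cc <- pcms_class_counts()
  B <- pcms_callable_totals()
  scale <- B[["case"]] / B[["control"]]
  E0_lgd <- cc["lgd", "control"] * scale
  E0_misd <- cc["mis_d", "control"] * scale
  c(lgd = estimate_gamma_from_burden(cc["lgd", "case"], E0_lgd, k, G),
    misd = estimate_gamma_from_burden(cc["mis_d", "case"], E0_misd, k, G))
}

#' Mean callable exposure of the pCMS case cohort
#'
#' Fraction of the diploid coding exome callable in an average case trio,
#' `B_case / (n_case * 2 * coding_exome_bp)`; scales full-exome null
#' expectations onto the study's callable territory.
#'
#' @return scalar in (0, 1].
#' @export
pcms_case_exposure <- function() {
  pcms_callable_totals()[["case"]] /
    (pcms_n_trios()[["case"]] * 2 * exome_constants()$coding_exome_bp)
}

# Deterministic round-robin assignment of variants to trios.
assign_probands <- function(n, ids, offset = 0) {
  ids[(offset + seq_len(n) - 1L) %% length(ids) + 1L]
}

#' Synthetic reconstruction of the pCMS study's variant and cohort tables
#'
#' Rebuilds case and control annotated de novo variant tables whose
#' per-class tabulations equal the published counts exactly, together with
#' a per-trio callable-base table whose cohort totals equal the published
#' callable totals. Damaging case variants are placed in the published
#' case-exclusive gene list (with the recurrent gene KDM5B carrying two
#' stopgain variants in different probands) plus two genes shared with
#' damaged control genes; all other gene assignments, PolyPhen scores, and
#' proband assignments are synthetic.
#'
#' @param rates a [rate_table()] defining the gene universe; its first
#'   genes are renamed to the published symbols so that every observed gene
#'   has a rate. Typically `pcms_rate_table()`.
#' @param seed RNG seed for the synthetic score draws and gene fill-ins.
#' @return list with `case_variants`, `control_variants` (each a
#'   [denovo_table()]), `trios` (a [cohort_table()]), `rates` (the renamed
#'   [rate_table()]), and `shared_genes` (the two control-overlap genes).
#' @export
pcms_fixture <- function(rates = pcms_rate_table(), seed = 1L) {
  cc <- pcms_class_counts()
  B <- pcms_callable_totals()
  n <- pcms_n_trios()

  t2 <- pcms_damaging_gene_list(unique = TRUE)          # 51 unique
  stopifnot(all(t2 %in% rates$gene))
  other <- setdiff(rates$gene, t2)
  shared <- other[1:2]        # damaged in both cohorts
  pool <- other[-(1:2)]       # background gene pool

  with_seed(seed, {
    case_ids <- sprintf("pCMS_%03d", seq_len(n[["case"]]))
    ctrl_ids <- sprintf("SSC_%04d", seq_len(n[["control"]]))

    exclusive <- setdiff(t2, "KDM5B")                   # 50 genes
    lgd_genes <- exclusive[1:10]
    misd_genes <- c(exclusive[11:50], shared)           # 42 Mis-D
    case_rows <- list(
      data.frame(gene = c("KDM5B", "KDM5B", lgd_genes[1:4]),
                 effect = "stopgain", stringsAsFactors = FALSE),
      data.frame(gene = lgd_genes[5:8], effect = "splice_site",
                 stringsAsFactors = FALSE),
      data.frame(gene = lgd_genes[9:10], effect = "frameshift_indel",
                 stringsAsFactors = FALSE),
      data.frame(gene = misd_genes, effect = "missense_snv",
                 stringsAsFactors = FALSE)
    )
    # remaining case classes drawn from the background pool
    fill <- function(k, effect, pool_offset) {
      data.frame(gene = pool[pool_offset + seq_len(k)], effect = effect,
                 stringsAsFactors = FALSE)
    }
    case_rows <- c(case_rows, list(
      fill(cc["mis_p", "case"], "missense_snv", 0),
      fill(cc["mis_b", "case"], "missense_snv", 15),
      fill(2, "missense_snv", 40),                      # unscored missense
      fill(cc["synonymous", "case"], "synonymous_snv", 42),
      fill(cc["nonframeshift", "case"], "nonframeshift_indel", 72),
      fill(cc["unknown", "case"], "unknown", 73),
      fill(cc["all", "case"] - cc["coding", "case"], "noncoding", 74)
    ))
    case <- do.call(rbind, case_rows)
    # PolyPhen scores: damaging for Mis-D, class-typical for the rest,
    # missing for the two unscored missense calls
    case$polyphen_hdiv <- NA_real_
    is_mis <- case$effect == "missense_snv"
    mis_idx <- which(is_mis)
    n_misd <- length(misd_genes)
    n_misp <- cc["mis_p", "case"]
    n_misb <- cc["mis_b", "case"]
    case$polyphen_hdiv[mis_idx[seq_len(n_misd)]] <-
      stats::runif(n_misd, 0.96, 1)
    case$polyphen_hdiv[mis_idx[n_misd + seq_len(n_misp)]] <-
      stats::runif(n_misp, 0.46, 0.95)
    case$polyphen_hdiv[mis_idx[n_misd + n_misp + seq_len(n_misb)]] <-
      stats::runif(n_misb, 0, 0.45)
    case$proband_id <- assign_probands(nrow(case), case_ids)
    case$cohort <- "case"
    case$pop_freq <- NA_real_

    ctrl_pool <- pool[200 + seq_len(cc["all", "control"])]
    ctrl_rows <- list(
      data.frame(gene = c(shared,
                          ctrl_pool[seq_len(cc["mis_d", "control"] - 2)]),
                 effect = "missense_snv", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[190 + seq_len(cc["lgd_stopgain",
                                                   "control"])],
                 effect = "stopgain", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[206 + seq_len(cc["lgd_splice",
                                                   "control"])],
                 effect = "splice_site", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[209 + seq_len(cc["lgd_frameshift",
                                                   "control"])],
                 effect = "frameshift_indel", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[225 + seq_len(cc["mis_p", "control"])],
                 effect = "missense_snv", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[304 + seq_len(cc["mis_b", "control"])],
                 effect = "missense_snv", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[441 + seq_len(5)],
                 effect = "missense_snv", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[446 + seq_len(cc["synonymous",
                                                   "control"])],
                 effect = "synonymous_snv", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[617 + seq_len(cc["nonframeshift",
                                                   "control"])],
                 effect = "nonframeshift_indel", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[620 + seq_len(cc["unknown", "control"])],
                 effect = "unknown", stringsAsFactors = FALSE),
      data.frame(gene = ctrl_pool[628 + seq_len(cc["all", "control"] -
                                                  cc["coding", "control"])],
                 effect = "noncoding", stringsAsFactors = FALSE)
    )
    ctrl <- do.call(rbind, ctrl_rows)
    ctrl$polyphen_hdiv <- NA_real_
    mis_idx <- which(ctrl$effect == "missense_snv")
    n_misd <- cc["mis_d", "control"]
    n_misp <- cc["mis_p", "control"]
    n_misb <- cc["mis_b", "control"]
    ctrl$polyphen_hdiv[mis_idx[seq_len(n_misd)]] <-
      stats::runif(n_misd, 0.96, 1)
    ctrl$polyphen_hdiv[mis_idx[n_misd + seq_len(n_misp)]] <-
      stats::runif(n_misp, 0.46, 0.95)
    ctrl$polyphen_hdiv[mis_idx[n_misd + n_misp + seq_len(n_misb)]] <-
      stats::runif(n_misb, 0, 0.45)
    ctrl$proband_id <- assign_probands(nrow(ctrl), ctrl_ids)
    ctrl$cohort <- "control"
    ctrl$pop_freq <- NA_real_

    cols <- c("proband_id", "cohort", "gene", "effect", "polyphen_hdiv",
              "pop_freq")
    # per-trio callable bases: equal split, remainder on the first trio so
    # cohort totals match the published values exactly
    split_callable <- function(total, n_trios) {
      base <- floor(total / n_trios)
      out <- rep(base, n_trios)
      out[1] <- out[1] + round(total) - base * n_trios
      out
    }
    trios <- cohort_table(
      c(case_ids, ctrl_ids),
      rep(c("case", "control"), n),
      c(split_callable(B[["case"]], n[["case"]]),
        split_callable(B[["control"]], n[["control"]]))
    )
    list(case_variants = denovo_table(case[cols]),
         control_variants = denovo_table(ctrl[cols]),
         trios = trios, rates = rates, shared_genes = shared)
  })
}

#' Synthetic pCMS-calibrated rate table with published gene symbols
#'
#' A [make_rate_table()] universe in which the genes observed in the
#' reconstructed pCMS tables carry the published symbols (assigned to
#' median-mutability genes, deterministically given the seed).
#'
#' @param config a [scenario_config()].
#' @return a [rate_table()].
#' @export
pcms_rate_table <- function(config = scenario_config()) {
  rates <- make_rate_table(config)
  t2 <- pcms_damaging_gene_list(unique = TRUE)
  # rename genes of middling mutability to the published symbols so the
  # fixture genes exist in the universe with unexceptional rates
  ord <- order(rates$mu_total)
  mid <- ord[seq(floor(nrow(rates) / 2) - 2000,
                 length.out = length(t2), by = 7)]
  rates$gene[mid] <- t2
  rates
}

#' Mutation list for gene-set overlap analysis of the pCMS fixture
#'
#' One row per damaging de novo mutation in a case-exclusive gene (the
#' recurrent gene contributes two rows), mirroring the published overlap
#' analysis input.
#'
#' @param fixture result of [pcms_fixture()].
#' @return data.frame with columns `gene` and `class` (`lgd` / `mis_d`).
#' @export
pcms_mutation_list <- function(fixture) {
  cv <- fixture$case_variants
  fine <- classify_variant(cv$effect, cv$polyphen_hdiv)
  damaging <- fine %in% .damaging_finest
  excl <- case_exclusive_damaging_genes(cv, fixture$control_variants)
  keep <- damaging & cv$gene %in% excl$genes
  data.frame(
    gene = cv$gene[keep],
    class = ifelse(fine[keep] == "mis_d", "mis_d", "lgd"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cross-disorder gene sets calibrated to the published overlaps
#'
#' The study's curated disorder gene lists are not redistributed; these
#' stand-ins reproduce their reported structure: set sizes typical of the
#' source literature and planted overlaps with the pCMS case-exclusive
#' damaging genes chosen so that the analytic fold enrichment matches the
#' published values (Tourette's disorder 4.5x, ASD 2.2x, ASD with high
#' stereotypy scores 5.8x via the two recurrent-gene mutations, and no
#' enrichment for OCD, schizophrenia, intellectual disability,
#' developmental disorders, or epileptic encephalopathy).
#'
#' @param rates the [rate_table()] used by the fixture.
#' @param seed RNG seed for the synthetic member draws.
#' @return named list of [gene_set()]s.
#' @export
pcms_gene_sets <- function(rates = pcms_rate_table(), seed = 1L) {
  t2 <- pcms_damaging_gene_list(unique = TRUE)
  singles <- setdiff(t2, "KDM5B")
  spec <- list(
    TD = list(size = 400, overlap = c("KDM5B", singles[1:3])),
    ASD = list(size = 1500, overlap = c("KDM5B", singles[4:10])),
    ASD_high_stereotypy = list(size = 124, overlap = "KDM5B"),
    ASD_low_stereotypy = list(size = 124, overlap = character(0)),
    OCD = list(size = 60, overlap = character(0)),
    SCZ = list(size = 1000, overlap = singles[11:13]),
    ID = list(size = 200, overlap = singles[14]),
    DD = list(size = 600, overlap = singles[15:16]),
    EE = list(size = 100, overlap = character(0))
  )
  other <- setdiff(rates$gene, t2)
  with_seed(seed, {
    out <- lapply(names(spec), function(nm) {
      s <- spec[[nm]]
      gene_set(nm, c(s$overlap,
                     sample(other, s$size - length(s$overlap))))
    })
    stats::setNames(out, names(spec))
  })
}
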