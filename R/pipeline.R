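# Orchestration: run the full analysis (filter -> burden -> TADA -> MLE ->
# projection -> enrichment) from a single validated configuration, with
# line-delimited JSON logging and a machine-readable report.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks threshold ranges and consistency, and rejects
#' unknown keys. Inputs may be given as file paths (`variants`, `trios`,
#' `rates`, `gene_sets`) or as in-memory objects (`case_variants`,
#' `control_variants`, `trios`, `rates`, `gene_sets`).
#'
#' @param config named list; recognized keys: `variants`, `case_variants`,
#'   `control_variants`, `trios`, `rates`, `gene_sets`, `freq_threshold`
#'   (default 0.001), `q_hc` (0.1), `q_prob` (0.3), `p_sig` (0.05), `k`
#'   (risk-gene count for TADA priors; default from the MLE stage), `pi`,
#'   `exposure`, `mle` (logical or [mle_config()] fields), `projection`
#'   (logical or [projection_config()] fields), `n_perm` (10000), `seed`,
#'   `out_dir`.
#' @return normalized config with class `run_config`.
#' @export
validate_config <- function(config) {
  known <- c("variants", "case_variants", "control_variants", "trios",
             "rates", "gene_sets", "freq_threshold", "q_hc", "q_prob",
             "p_sig", "k", "pi", "exposure", "mle", "projection",
             "n_perm", "seed", "out_dir", "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(freq_threshold = 0.001, q_hc = 0.1, q_prob = 0.3,
                   p_sig = 0.05, mle = TRUE,
                   projection = FALSE, n_perm = 10000, verbose = FALSE)
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  thr <- unlist(config[c("freq_threshold", "q_hc", "q_prob", "p_sig")])
  if (any(thr <= 0 | thr >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (config$q_hc >= config$q_prob) {
    stop("q_hc must be smaller than q_prob", call. = FALSE)
  }
  needs_mc <- isTRUE(config$mle) || is.list(config$mle) ||
    isTRUE(config$projection) || is.list(config$projection)
  if (needs_mc && is.null(config$seed)) {
    stop("seed is required when Monte-Carlo stages are enabled",
         call. = FALSE)
  }
  if (is.null(config$rates)) stop("rates input is required", call. = FALSE)
  has_tables <- !is.null(config$case_variants) ||
    !is.null(config$variants)
  if (!has_tables) {
    stop("variant input is required (variants path or case_variants/",
         "control_variants tables)", call. = FALSE)
  }
  if (is.null(config$trios)) stop("trios input is required", call. = FALSE)
  class(config) <- c("run_config", "list")
  config
}

log_stage <- function(verbose, stage, t0, ...) {
  if (!verbose) return(invisible())
  rec <- c(list(stage = stage,
                elapsed = round(as.numeric(Sys.time()) - t0, 3)),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE))
}

#' Run the full de novo analysis pipeline
#'
#' Stages: read inputs, rare-variant frequency filter, per-class burden
#' table, TADA-Denovo gene table with high-confidence/probable flags,
#' risk-gene-number MLE, optional discovery projection, and optional
#' gene-set enrichment scan. Every stochastic stage receives its own
#' sub-seed derived from `config$seed`, so the report is a pure function of
#' (inputs, config, seed). When `config$out_dir` is set, tables are written
#' as TSV alongside a JSON `report.json`.
#'
#' @param config a [validate_config()]-ready list.
#' @return list with class `run_report`: `burden`, `tada`, `hc_genes`,
#'   `probable_genes`, `case_exclusive`, `mle`, `projection`, `enrichment`,
#'   `params`, `seeds`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  t0 <- as.numeric(Sys.time())
  v <- config$verbose
  seeds <- if (!is.null(config$seed)) split_seed(config$seed, 8) else rep(NA, 8)

  # --- inputs -------------------------------------------------------------
  rates <- if (is.character(config$rates)) {
    read_rate_table(config$rates)
  } else config$rates
  trios <- if (is.character(config$trios)) {
    read_cohort_table(config$trios)
  } else config$trios
  if (!is.null(config$variants)) {
    all_vs <- if (is.character(config$variants)) {
      read_denovo_table(config$variants)
    } else config$variants
    case_vs <- all_vs[all_vs$cohort == "case", , drop = FALSE]
    ctrl_vs <- all_vs[all_vs$cohort == "control", , drop = FALSE]
  } else {
    case_vs <- config$case_variants
    ctrl_vs <- config$control_variants
  }
  log_stage(v, "read", t0, n_case_variants = nrow(case_vs),
            n_ctrl_variants = nrow(ctrl_vs), n_genes = nrow(rates))

  # --- frequency filter ---------------------------------------------------
  case_vs <- frequency_filter(case_vs, config$freq_threshold)
  ctrl_vs <- frequency_filter(ctrl_vs, config$freq_threshold)
  log_stage(v, "frequency_filter", t0, threshold = config$freq_threshold,
            n_case = nrow(case_vs), n_ctrl = nrow(ctrl_vs))

  # --- burden -------------------------------------------------------------
  burden <- burden_table(case_vs, ctrl_vs, trios,
                         sig_level = config$p_sig)
  excl <- case_exclusive_damaging_genes(case_vs, ctrl_vs)
  log_stage(v, "burden", t0,
            damaging_rr = burden$rr[burden$variant_class == "damaging"])

  n_case <- sum(trios$phenotype == "case")
  G <- nrow(rates)
  cc <- tabulate_counts(case_vs)
  ct <- tabulate_counts(ctrl_vs)
  B_case <- sum(trios$callable_bp[trios$phenotype == "case"])
  B_ctrl <- sum(trios$callable_bp[trios$phenotype == "control"])
  scale <- B_case / B_ctrl

  # --- MLE ----------------------------------------------------------------
  mle <- NULL
  if (isTRUE(config$mle) || is.list(config$mle)) {
    fine <- classify_variant(case_vs$effect, case_vs$polyphen_hdiv)
    dmg_genes <- case_vs$gene[fine %in% .damaging_finest]
    hits <- table(dmg_genes)
    profile <- sort(as.integer(hits[hits >= 2]))
    exposure <- config$exposure %||%
      (B_case / (n_case * 2 * exome_constants()$coding_exome_bp))
    args <- list(M_obs = cc[["damaging"]], R_obs = length(profile),
                 profile = profile, n_trios = n_case, exposure = exposure,
                 seed = seeds[1])
    if (is.list(config$mle)) args[names(config$mle)] <- config$mle
    mle <- mle_risk_genes(do.call(mle_config, args), rates)
    log_stage(v, "mle", t0, k_hat = mle$k_hat)
  }
  k <- config$k %||% (if (!is.null(mle)) mle$k_hat else 184L)
  pi <- config$pi %||% (k / G)

  # --- TADA ---------------------------------------------------------------
  E0_lgd <- max(ct[["lgd"]] * scale, 0.5)
  E0_misd <- max(ct[["mis_d"]] * scale, 0.5)
  params <- tada_params(
    n_trios = n_case,
    gamma_bar_lgd = estimate_gamma_from_burden(cc[["lgd"]], E0_lgd, k, G),
    gamma_bar_misd = estimate_gamma_from_burden(cc[["mis_d"]], E0_misd, k,
                                                G),
    pi = pi, seed = seeds[2]
  )
  tada <- run_tada(case_vs, rates, params, q_hc = config$q_hc,
                   q_prob = config$q_prob)
  log_stage(v, "tada", t0, n_hc = sum(tada$high_confidence),
            n_probable = sum(tada$probable))

  # --- projection ---------------------------------------------------------
  projection <- NULL
  if (isTRUE(config$projection) || is.list(config$projection)) {
    args <- list(k = k, gamma_bar_lgd = params$gamma_bar_lgd,
                 gamma_bar_misd = params$gamma_bar_misd, pi = pi,
                 q_hc = config$q_hc, q_prob = config$q_prob,
                 seed = seeds[3])
    if (is.list(config$projection)) {
      args[names(config$projection)] <- config$projection
    }
    projection <- project_discovery(do.call(projection_config, args),
                                    rates)
    log_stage(v, "projection", t0)
  }

  # --- enrichment ---------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- if (is.character(config$gene_sets)) {
      read_gene_sets_tsv(config$gene_sets)
    } else config$gene_sets
    fine <- classify_variant(case_vs$effect, case_vs$polyphen_hdiv)
    keep <- fine %in% .damaging_finest & case_vs$gene %in% excl$genes
    mutations <- data.frame(gene = case_vs$gene[keep],
                            class = ifelse(fine[keep] == "mis_d", "mis_d",
                                           "lgd"),
                            stringsAsFactors = FALSE)
    enrichment <- cross_disorder_scan(mutations, sets, rates,
                                      n_perm = config$n_perm,
                                      seed = seeds[4])
    log_stage(v, "enrichment", t0, n_sets = length(sets))
  }

  report <- structure(list(
    burden = burden, tada = tada,
    hc_genes = tada$gene[tada$high_confidence],
    probable_genes = tada$gene[tada$probable],
    case_exclusive = excl, mle = mle, projection = projection,
    enrichment = enrichment, params = params,
    seeds = seeds, config = config
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk (TSV tables + JSON summary)
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisible path of the JSON report.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_burden_table(report$burden, file.path(dir, "burden.tsv"))
  utils::write.table(as.data.frame(report$tada),
                     file.path(dir, "tada.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$mle)) {
    utils::write.table(report$mle$likelihood,
                       file.path(dir, "mle_likelihood.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$projection)) {
    utils::write.table(as.data.frame(report$projection),
                       file.path(dir, "projection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$enrichment)) {
    utils::write.table(as.data.frame(report$enrichment),
                       file.path(dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    hc_genes = report$hc_genes,
    probable_genes = report$probable_genes,
    case_exclusive_genes = report$case_exclusive$genes,
    k_hat = if (!is.null(report$mle)) report$mle$k_hat else NULL,
    gamma_bar_lgd = report$params$gamma_bar_lgd,
    gamma_bar_misd = report$params$gamma_bar_misd,
    pi = report$params$pi,
    seeds = as.integer(report$seeds)
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
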