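# Synthetic trio-cohort generator: emulates every input the pipeline
# consumes (per-gene mutation-rate tables, annotated de novo variant tables,
# per-trio callable-base tables, curated gene sets) with the statistical
# structure the analysis assumes: Poisson de novo counts at 2*N*mu scaled by
# per-trio callable exposure, with planted relative risks in a hidden set of
# risk genes in the case cohort.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a pCMS-like pilot study: 118 case and 750 control
#' trios, a coding gene universe of 18,665 genes, 184 planted risk genes,
#' and per-class rates calibrated so that an average fully callable
#' individual carries the published per-individual de novo load (1.18
#' coding, 0.42 damaging). Per-trio callable bases enter as an exposure
#' multiplier `callable_bp / (2 * coding_exome_bp)` on all per-gene rates.
#'
#' @param G gene-universe size.
#' @param n_case,n_ctrl trio counts.
#' @param k_true number of planted risk genes.
#' @param gamma_bar_lgd,gamma_bar_misd planted relative risks in risk genes
#'   (defaults: burden-calibrated pCMS values from [pcms_gamma()]).
#' @param rate_log_sd log-scale standard deviation of per-gene rates
#'   (lognormal); 0.8 spans roughly the half-order-of-magnitude spread of
#'   coding-sequence lengths that drives per-gene mutability.
#' @param rate_log_mean optional lognormal log-mean. `NULL` (default)
#'   rescales rates so that `2 * sum(mu_total) = coding_per_individual`;
#'   a numeric value is used as-is without rescaling.
#' @param coding_per_individual calibration target: expected coding de novo
#'   variants per fully callable individual.
#' @param class_fractions named fractions splitting the coding rate into
#'   finest classes (must sum to 1); defaults follow the published control
#'   class distribution.
#' @param noncoding_per_individual expected non-coding (capture) de novo
#'   variants per individual.
#' @param callable_mean_case,callable_mean_ctrl,callable_sd per-trio haploid
#'   callable-base model (normal, truncated at 1 Mb); defaults reproduce the
#'   published cohort callable totals.
#' @param freq_common_fraction fraction of extra variants given a population
#'   frequency above the rare-variant filter, to exercise filtering.
#' @param seed master seed; every stream in the generator derives from it.
#' @return validated list with class `scenario_config`.
#' @export
scenario_config <- function(G = 18665L, n_case = 118L, n_ctrl = 750L,
                            k_true = 184L,
                            gamma_bar_lgd = NULL, gamma_bar_misd = NULL,
                            rate_log_sd = 0.8, rate_log_mean = NULL,
                            coding_per_individual = 1.18,
                            class_fractions = NULL,
                            noncoding_per_individual = 0.071,
                            callable_mean_case = NULL,
                            callable_mean_ctrl = NULL,
                            callable_sd = 4e6,
                            freq_common_fraction = 0.05,
                            seed = 1L) {
  gam <- pcms_gamma(k = k_true, G = G)
  cal <- pcms_callable_totals()
  cfg <- list(
    G = as.integer(G), n_case = as.integer(n_case),
    n_ctrl = as.integer(n_ctrl), k_true = as.integer(k_true),
    gamma_bar_lgd = gamma_bar_lgd %||% gam[["lgd"]],
    gamma_bar_misd = gamma_bar_misd %||% gam[["misd"]],
    rate_log_sd = rate_log_sd, rate_log_mean = rate_log_mean,
    coding_per_individual = coding_per_individual,
    class_fractions = class_fractions %||% default_class_fractions(),
    noncoding_per_individual = noncoding_per_individual,
    callable_mean_case = callable_mean_case %||% (cal[["case"]] / 118),
    callable_mean_ctrl = callable_mean_ctrl %||% (cal[["control"]] / 750),
    callable_sd = callable_sd,
    freq_common_fraction = freq_common_fraction,
    seed = as.integer(seed)
  )
  stopifnot(cfg$k_true <= cfg$G, cfg$n_case >= 0, cfg$n_ctrl >= 0,
            cfg$gamma_bar_lgd >= 1, cfg$gamma_bar_misd >= 1,
            cfg$rate_log_sd >= 0, cfg$coding_per_individual > 0,
            cfg$freq_common_fraction >= 0, cfg$freq_common_fraction < 1,
            abs(sum(cfg$class_fractions) - 1) < 1e-6)
  class(cfg) <- "scenario_config"
  cfg
}

# Finest-class fractions of the coding de novo rate, anchored to the
# published control class distribution (171 synonymous, 190 Mis-D, 79
# Mis-P, 137 Mis-B, 5 unscored missense, 16 stopgain, 3 splice, 16
# frameshift, 3 nonframeshift, 8 unknown of 628 coding variants).
default_class_fractions <- function() {
  x <- c(synonymous = 171, mis_d = 190, mis_p = 79, mis_b = 137,
         missense_unscored = 5, lgd_stopgain = 16, lgd_splice = 3,
         lgd_frameshift = 16, nonframeshift = 3, unknown = 8)
  x / sum(x)
}

# finest generator class -> canonical effect annotation
.class_effect <- c(
  synonymous = "synonymous_snv", mis_d = "missense_snv",
  mis_p = "missense_snv", mis_b = "missense_snv",
  missense_unscored = "missense_snv", lgd_stopgain = "stopgain",
  lgd_splice = "splice_site", lgd_frameshift = "frameshift_indel",
  nonframeshift = "nonframeshift_indel", unknown = "unknown",
  noncoding = "noncoding"
)

draw_polyphen <- function(class, n) {
  switch(class,
    mis_d = stats::runif(n, 0.957, 1),
    mis_p = stats::runif(n, 0.453, 0.957 - 1e-6),
    mis_b = stats::runif(n, 0, 0.453 - 1e-6),
    rep(NA_real_, n))
}

#' Generate a per-gene mutation-rate table
#'
#' Per-gene coding rates are lognormal; unless an explicit
#' `rate_log_mean` is given they are rescaled so that
#' `2 * sum(mu_total)` equals the scenario's coding-per-individual target.
#' Class rates are fixed fractions of the coding rate.
#'
#' @param config a [scenario_config()].
#' @return a [rate_table()] of `config$G` genes.
#' @export
make_rate_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(split_seed(config$seed, 8)[1], {
    raw <- stats::rlnorm(config$G, config$rate_log_mean %||% 0,
                         config$rate_log_sd)
    mu_total <- if (is.null(config$rate_log_mean)) {
      raw * (config$coding_per_individual / 2) / sum(raw)
    } else raw
    f <- config$class_fractions
    rate_table(sprintf("G%05d", seq_len(config$G)), mu_total,
               mu_lgd = (f[["lgd_stopgain"]] + f[["lgd_splice"]] +
                           f[["lgd_frameshift"]]) * mu_total,
               mu_misd = f[["mis_d"]] * mu_total)
  })
}

# Expand per-gene totals drawn for one finest class into variant rows.
materialize_class <- function(x_g, genes, class, trio_ids, trio_prob) {
  total <- sum(x_g)
  if (total == 0) return(NULL)
  idx <- rep.int(seq_along(x_g), x_g)
  data.frame(
    proband_id = trio_ids[sample_cumw(trio_prob, total)],
    gene = genes[idx],
    effect = unname(.class_effect[class]),
    polyphen_hdiv = draw_polyphen(class, total),
    pop_freq = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a trio cohort with annotated de novo variant tables
#'
#' Per trio, haploid callable bases are drawn from the callable model and
#' enter as an exposure multiplier on all rates. Per gene and finest class,
#' cohort-level counts are Poisson with mean
#' `2 * mu_class * sum(exposure) * gamma`, where `gamma` is the planted
#' relative risk for LGD / damaging-missense classes in case-cohort risk
#' genes and 1 otherwise; variants are then assigned to trios with
#' probability proportional to exposure. A configurable fraction of extra
#' variants receives a population frequency above the rare-variant filter.
#'
#' @param config a [scenario_config()].
#' @param rates a [rate_table()] from [make_rate_table()].
#' @return list with elements `variants` (a [denovo_table()], cases and
#'   controls pooled), `trios` (a [cohort_table()]), and `risk_genes`
#'   (character vector of planted risk genes).
#' @export
simulate_trio_cohort <- function(config, rates) {
  stopifnot(inherits(config, "scenario_config"),
            nrow(rates) == config$G)
  seeds <- split_seed(config$seed, 8)
  exome2 <- 2 * exome_constants()$coding_exome_bp
  f <- config$class_fractions

  with_seed(seeds[2], {
    n_all <- config$n_case + config$n_ctrl
    trio_ids <- c(sprintf("case_%04d", seq_len(config$n_case)),
                  sprintf("ctrl_%04d", seq_len(config$n_ctrl)))
    phenotype <- rep(c("case", "control"),
                     c(config$n_case, config$n_ctrl))
    callable <- round(stats::rnorm(
      n_all,
      mean = ifelse(phenotype == "case", config$callable_mean_case,
                    config$callable_mean_ctrl),
      sd = config$callable_sd))
    callable <- pmax(callable, 1e6)
    trios <- cohort_table(trio_ids, phenotype, callable)
    exposure <- callable / exome2

    risk_idx <- sample.int(config$G, config$k_true)
    risk_genes <- rates$gene[risk_idx]

    out <- list()
    for (ph in c("case", "control")) {
      sel <- phenotype == ph
      sum_e <- sum(exposure[sel])
      ids <- trio_ids[sel]
      prob <- cumsum(exposure[sel]) / sum(exposure[sel])
      for (cl in names(f)) {
        gamma <- rep(1, config$G)
        if (ph == "case") {
          if (cl %in% c("lgd_stopgain", "lgd_splice", "lgd_frameshift")) {
            gamma[risk_idx] <- config$gamma_bar_lgd
          } else if (cl == "mis_d") {
            gamma[risk_idx] <- config$gamma_bar_misd
          }
        }
        lambda <- 2 * rates$mu_total * f[[cl]] * sum_e * gamma
        rows <- materialize_class(stats::rpois(config$G, lambda),
                                  rates$gene, cl, ids, prob)
        if (!is.null(rows)) {
          rows$cohort <- ph
          out[[length(out) + 1]] <- rows
        }
      }
      # non-coding capture territory: flat rate over the universe
      n_nc <- stats::rpois(1, config$noncoding_per_individual * sum_e)
      if (n_nc > 0) {
        out[[length(out) + 1]] <- data.frame(
          proband_id = ids[sample_cumw(prob, n_nc)],
          gene = rates$gene[sample.int(config$G, n_nc, replace = TRUE)],
          effect = "noncoding", polyphen_hdiv = NA_real_,
          pop_freq = NA_real_, cohort = ph, stringsAsFactors = FALSE
        )
      }
      # extra common (filterable) variants on top of the rare calibration
      fr <- config$freq_common_fraction
      if (fr > 0) {
        n_rare <- sum(vapply(out, nrow, 0L)[
          vapply(out, function(d) d$cohort[1] == ph, TRUE)])
        n_common <- stats::rpois(1, n_rare * fr / (1 - fr))
        if (n_common > 0) {
          cls <- names(f)[sample_cumw(cumsum(f) / sum(f), n_common)]
          cumw_g <- cumsum(rates$mu_total) / sum(rates$mu_total)
          rows <- data.frame(
            proband_id = ids[sample_cumw(prob, n_common)],
            gene = rates$gene[sample_cumw(cumw_g, n_common)],
            effect = unname(.class_effect[cls]),
            polyphen_hdiv = vapply(cls, function(cl) draw_polyphen(cl, 1),
                                   0),
            pop_freq = stats::runif(n_common, 0.001, 0.05),
            cohort = ph, stringsAsFactors = FALSE
          )
          out[[length(out) + 1]] <- rows
        }
      }
    }
    variants <- do.call(rbind, out)
    variants <- variants[, c("proband_id", "cohort", "gene", "effect",
                             "polyphen_hdiv", "pop_freq")]
    rownames(variants) <- NULL
    list(variants = denovo_table(variants), trios = trios,
         risk_genes = risk_genes)
  })
}

#' Generate gene sets with controlled overlap with the planted risk genes
#'
#' @param rates a [rate_table()] defining the universe.
#' @param risk_genes character vector of planted risk genes.
#' @param sizes integer vector of set sizes.
#' @param overlap_with_risk fraction of each set drawn from `risk_genes`
#'   (recycled over sets).
#' @param names optional set names.
#' @param seed RNG seed.
#' @return list of [gene_set()]s.
#' @export
make_gene_sets <- function(rates, risk_genes, sizes, overlap_with_risk,
                           names = NULL, seed = NULL) {
  stopifnot(all(overlap_with_risk >= 0), all(overlap_with_risk <= 1))
  overlap_with_risk <- rep_len(overlap_with_risk, length(sizes))
  names <- names %||% sprintf("set%02d", seq_along(sizes))
  other <- setdiff(rates$gene, risk_genes)
  with_seed(seed, {
    out <- lapply(seq_along(sizes), function(i) {
      n_risk <- min(round(sizes[i] * overlap_with_risk[i]),
                    length(risk_genes))
      genes <- c(sample(risk_genes, n_risk),
                 sample(other, sizes[i] - n_risk))
      gene_set(names[i], genes)
    })
    stats::setNames(out, names)
  })
}

#' Write a full synthetic scenario to a directory
#'
#' Emits `variants.tsv`, `trios.tsv`, `rates.tsv`, and `risk_genes.txt`,
#' ready for the file-based pipeline entry points.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rates <- make_rate_table(config)
  sim <- simulate_trio_cohort(config, rates)
  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    trios = file.path(dir, "trios.tsv"),
    rates = file.path(dir, "rates.tsv"),
    risk_genes = file.path(dir, "risk_genes.txt")
  )
  write_denovo_table(sim$variants, paths$variants)
  write_cohort_table(sim$trios, paths$trios)
  write_rate_table(rates, paths$rates)
  writeLines(sim$risk_genes, paths$risk_genes)
  invisible(paths)
}
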