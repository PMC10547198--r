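# TADA-Denovo: gene-level Bayesian test of de novo recurrence.
#
# Per variant class c, the count in gene g over N trios is Poisson with mean
# q0 = 2 N mu_gc under the null. Under the alternative the rate is inflated
# by a relative risk gamma with a Gamma(gamma_bar * beta, beta) prior, so the
# marginal likelihood is negative binomial and the Bayes factor has a closed
# form, evaluated in log space.

#' Parameter bundle for the TADA-Denovo test
#'
#' @param n_trios number of case trios N.
#' @param gamma_bar_lgd,gamma_bar_misd prior mean relative risks (>= 1) for
#'   the LGD and damaging-missense classes.
#' @param beta_lgd,beta_misd Gamma prior rate parameters (> 0).
#' @param pi prior fraction of risk genes, in (0, 1).
#' @param n_null_sims Monte-Carlo replicates for empirical p-values (0
#'   disables them).
#' @param seed RNG seed for the null simulations.
#' @return validated list with class `tada_params`.
#' @export
tada_params <- function(n_trios, gamma_bar_lgd, gamma_bar_misd,
                        beta_lgd = 1, beta_misd = 1, pi,
                        n_null_sims = 0, seed = NULL) {
  stopifnot(n_trios > 0, gamma_bar_lgd >= 1, gamma_bar_misd >= 1,
            beta_lgd > 0, beta_misd > 0, pi > 0, pi < 1)
  if (n_null_sims > 0 && n_null_sims < 100) {
    stop("n_null_sims must be 0 or >= 100", call. = FALSE)
  }
  structure(list(n_trios = n_trios, gamma_bar_lgd = gamma_bar_lgd,
                 gamma_bar_misd = gamma_bar_misd, beta_lgd = beta_lgd,
                 beta_misd = beta_misd, pi = pi, n_null_sims = n_null_sims,
                 seed = seed),
            class = "tada_params")
}

# Vectorized log Bayes factor for one variant class.
# q0 = 2 N mu;  a = gamma_bar * beta.
# log BF = lgamma(x+a) - lgamma(a) + a log(beta/(beta+q0))
#          - x log(beta+q0) + q0
log_class_bf <- function(x, q0, gamma_bar, beta) {
  a <- gamma_bar * beta
  lgamma(x + a) - lgamma(a) + a * (log(beta) - log(beta + q0)) -
    x * log(beta + q0) + q0
}

#' Per-class Poisson-Gamma Bayes factor
#'
#' Marginal likelihood ratio of the observed de novo count `x` in one gene
#' and class under the risk-gene model (relative risk gamma ~
#' Gamma(`gamma_bar * beta`, `beta`)) versus the null (gamma = 1).
#'
#' @param x observed count (0 <= x <= 50; larger counts indicate an input
#'   error).
#' @param n_trios number of trios N.
#' @param mu per-gene class mutation rate (haploid, per generation).
#' @param gamma_bar prior mean relative risk (>= 1).
#' @param beta Gamma prior rate parameter.
#' @param log return the log Bayes factor.
#' @return Bayes factor (vectorized over `x` / `mu`).
#' @export
class_bayes_factor <- function(x, n_trios, mu, gamma_bar, beta = 1,
                               log = FALSE) {
  stopifnot(all(x >= 0), n_trios > 0, all(mu >= 0), gamma_bar >= 1, beta > 0)
  if (any(x > 50)) {
    stop("per-gene class count exceeds 50; likely an input error",
         call. = FALSE)
  }
  if (any(mu == 0 & x > 0)) {
    stop("undefined Bayes factor: observed count with zero mutation rate ",
         "(rate table inconsistency)", call. = FALSE)
  }
  q0 <- 2 * n_trios * mu
  lbf <- log_class_bf(x, q0, gamma_bar, beta)
  lbf[mu == 0 & x == 0] <- 0
  if (log) lbf else exp(lbf)
}

#' Gene-level Bayes factor as the product of class Bayes factors
#'
#' @param x_lgd,x_misd observed counts in the two classes.
#' @param mu_lgd,mu_misd per-gene class rates.
#' @param params a [tada_params()].
#' @param log return the log Bayes factor.
#' @return total Bayes factor (vectorized).
#' @export
gene_bayes_factor <- function(x_lgd, x_misd, mu_lgd, mu_misd, params,
                              log = FALSE) {
  lbf <- class_bayes_factor(x_lgd, params$n_trios, mu_lgd,
                            params$gamma_bar_lgd, params$beta_lgd,
                            log = TRUE) +
    class_bayes_factor(x_misd, params$n_trios, mu_misd,
                       params$gamma_bar_misd, params$beta_misd, log = TRUE)
  if (log) lbf else exp(lbf)
}

#' Posterior probabilities and direct-posterior FDR q-values
#'
#' The posterior probability of association is
#' `pi * BF / (pi * BF + 1 - pi)`. Genes are ranked by decreasing Bayes
#' factor (ties broken by gene symbol) and the q-value at rank i is the
#' running mean of `1 - posterior` over the top i genes; tied Bayes factors
#' share the q of the worst tied rank. q is non-decreasing along the
#' ranking and invariant to input order.
#'
#' @param bf per-gene Bayes factors.
#' @param pi prior fraction of risk genes.
#' @param gene optional gene symbols used for stable tie-breaking.
#' @return data.frame (`gene`, `bf`, `posterior`, `q`) in input order.
#' @export
direct_posterior_fdr <- function(bf, pi, gene = NULL) {
  stopifnot(length(bf) >= 1, pi > 0, pi < 1, all(bf >= 0))
  if (is.null(gene)) gene <- sprintf("g%06d", seq_along(bf))
  posterior <- pi * bf / (pi * bf + 1 - pi)
  q <- rep(NA_real_, length(bf))
  o <- order(-bf, gene)
  qs <- cumsum(1 - posterior[o]) / seq_along(bf)
  # tied BFs share the q of the worst tied rank
  r <- rle(bf[o])
  ends <- cumsum(r$lengths)
  qs <- rep(qs[ends], r$lengths)
  q[o] <- qs
  data.frame(gene = gene, bf = bf, posterior = posterior, q = q,
             stringsAsFactors = FALSE)
}

# Fast path used in simulations: q-values only, given a bare BF vector.
dp_fdr_q <- function(bf, pi) {
  posterior <- pi * bf / (pi * bf + 1 - pi)
  o <- order(bf, decreasing = TRUE)
  qs <- cumsum(1 - posterior[o]) / seq_along(bf)
  r <- rle(bf[o])
  ends <- cumsum(r$lengths)
  qs <- rep(qs[ends], r$lengths)
  q <- numeric(length(bf))
  q[o] <- qs
  q
}

#' Empirical p-values from simulated null mutational data
#'
#' Draws per-gene class counts from Poisson(2 N mu_c), recomputes gene
#' Bayes factors, and compares observed Bayes factors against the null
#' distribution, pooled across genes (default) or gene by gene. The add-one
#' estimator `(1 + #null >= obs) / (n_null + 1)` is used. Pooled p-values
#' rank a gene's Bayes factor in the genome-wide null distribution, so even
#' a zero-count gene with a small mutation rate can receive p < 1; with
#' `pooled = FALSE` each gene is compared only against its own null and
#' zero counts give p near 1.
#'
#' @param obs_bf observed per-gene Bayes factors (aligned with `rates`).
#' @param rates a [rate_table()] (or subset) supplying `mu_lgd`, `mu_misd`.
#' @param params a [tada_params()]; `n_null_sims` must be >= 100.
#' @param pooled pool simulated Bayes factors across genes (default TRUE).
#' @return numeric vector of empirical p-values.
#' @export
null_pvalues <- function(obs_bf, rates, params, pooled = TRUE) {
  stopifnot(params$n_null_sims >= 100, length(obs_bf) == nrow(rates))
  G <- nrow(rates)
  with_seed(params$seed, {
    if (pooled) {
      exceed <- numeric(length(obs_bf))
      srt <- sort(obs_bf)
      total <- 0
      for (s in seq_len(params$n_null_sims)) {
        x1 <- stats::rpois(G, 2 * params$n_trios * rates$mu_lgd)
        x2 <- stats::rpois(G, 2 * params$n_trios * rates$mu_misd)
        bf <- gene_bayes_factor(pmin(x1, 50), pmin(x2, 50),
                                rates$mu_lgd, rates$mu_misd, params)
        # count null BFs >= each observed BF via the sorted observed vector
        cnt <- length(bf) - findInterval(srt, sort(bf),
                                         left.open = TRUE)
        exceed <- exceed + cnt[match(obs_bf, srt)]
        total <- total + length(bf)
      }
      (1 + exceed) / (total + 1)
    } else {
      exceed <- numeric(length(obs_bf))
      for (s in seq_len(params$n_null_sims)) {
        x1 <- stats::rpois(G, 2 * params$n_trios * rates$mu_lgd)
        x2 <- stats::rpois(G, 2 * params$n_trios * rates$mu_misd)
        bf <- gene_bayes_factor(pmin(x1, 50), pmin(x2, 50),
                                rates$mu_lgd, rates$mu_misd, params)
        exceed <- exceed + (bf >= obs_bf)
      }
      (1 + exceed) / (params$n_null_sims + 1)
    }
  })
}

#' Calibrate the prior mean relative risk from cohort burden
#'
#' Spreads the excess class burden (observed minus expected-null count)
#' uniformly over `k` risk genes out of `G`:
#' `gamma_bar = max(1, 1 + (x_case - E0) * G / (E0 * k))`.
#'
#' @param x_case observed case count in the class.
#' @param E0 expected null count `2 N sum(mu)` (> 0), optionally scaled by
#'   callable exposure.
#' @param k assumed number of risk genes (> 0).
#' @param G size of the gene universe.
#' @return prior mean relative risk (>= 1).
#' @export
estimate_gamma_from_burden <- function(x_case, E0, k, G) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  stopifnot(E0 > 0, G >= k)
  max(1, 1 + (x_case - E0) * G / (E0 * k))
}

#' Run the TADA-Denovo gene-level test
#'
#' Counts LGD and damaging-missense de novo variants per gene in the case
#' cohort, computes per-class and total Bayes factors for every gene in the
#' rate table, and attaches posterior probabilities and direct-posterior
#' FDR q-values. Genes observed in the variant table but absent from the
#' rate table are collected in the `skipped` attribute rather than silently
#' dropped.
#'
#' @param case_variants a classified [denovo_table()] (case cohort).
#' @param rates a [rate_table()] defining the gene universe.
#' @param params a [tada_params()].
#' @param q_hc,q_prob q-value thresholds flagging high-confidence and
#'   probable risk genes.
#' @return data.frame with class `tada_result`: `gene`, `x_lgd`, `x_misd`,
#'   `bf_lgd`, `bf_misd`, `bf_total`, `posterior`, `q`, `high_confidence`,
#'   `probable`, plus `p_empirical` when `params$n_null_sims > 0`.
#' @export
run_tada <- function(case_variants, rates, params, q_hc = 0.1,
                     q_prob = 0.3) {
  fine <- classify_variant(case_variants$effect,
                           case_variants$polyphen_hdiv)
  lgd_genes <- case_variants$gene[fine %in%
                                    c("lgd_stopgain", "lgd_splice",
                                      "lgd_frameshift")]
  misd_genes <- case_variants$gene[fine == "mis_d"]
  observed <- unique(c(lgd_genes, misd_genes))
  skipped <- setdiff(observed, rates$gene)

  x_lgd <- as.integer(table(factor(lgd_genes, levels = rates$gene)))
  x_misd <- as.integer(table(factor(misd_genes, levels = rates$gene)))

  bf_lgd <- class_bayes_factor(x_lgd, params$n_trios, rates$mu_lgd,
                               params$gamma_bar_lgd, params$beta_lgd)
  bf_misd <- class_bayes_factor(x_misd, params$n_trios, rates$mu_misd,
                                params$gamma_bar_misd, params$beta_misd)
  bf_total <- bf_lgd * bf_misd
  fdr <- direct_posterior_fdr(bf_total, params$pi, gene = rates$gene)

  out <- data.frame(
    gene = rates$gene, x_lgd = x_lgd, x_misd = x_misd,
    bf_lgd = bf_lgd, bf_misd = bf_misd, bf_total = bf_total,
    posterior = fdr$posterior, q = fdr$q,
    high_confidence = fdr$q < q_hc, probable = fdr$q < q_prob,
    stringsAsFactors = FALSE
  )
  if (params$n_null_sims > 0) {
    out$p_empirical <- null_pvalues(bf_total, rates, params)
  }
  out <- out[order(-out$bf_total, out$gene), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "params") <- params
  class(out) <- c("tada_result", "data.frame")
  out
}

#' Write a TADA result table as TSV (conventional column names)
#'
#' Columns mirror the conventional TADA-Denovo layout: `mut.cls1`/`mut.cls2`
#' are the class rates, `dn.cls1`/`dn.cls2` the observed counts, `BF` the
#' total Bayes factor, and `qval` the direct-posterior q-value.
#'
#' @param res a [run_tada()] result.
#' @param rates the [rate_table()] used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tada <- function(res, rates, path) {
  mu <- rates[match(res$gene, rates$gene), ]
  out <- data.frame(
    gene = res$gene,
    mut.cls1 = mu$mu_lgd, mut.cls2 = mu$mu_misd,
    dn.cls1 = res$x_lgd, dn.cls2 = res$x_misd,
    BF.cls1 = res$bf_lgd, BF.cls2 = res$bf_misd, BF = res$bf_total,
    pp = res$posterior, qval = res$q,
    stringsAsFactors = FALSE
  )
  if (!is.null(res$p_empirical)) out$pval <- res$p_empirical
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
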