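# Projection of risk-gene discovery versus cohort size: simulate de novo
# counts for cohorts of increasing size and count genes crossing the
# high-confidence (q < 0.1) and probable (q < 0.3) thresholds after the
# TADA-Denovo test.

#' Configuration for discovery projection
#'
#' @param k assumed number of risk genes.
#' @param gamma_bar_lgd,gamma_bar_misd relative risks planted in risk genes
#'   (and used as the TADA priors).
#' @param trio_grid increasing cohort sizes to evaluate.
#' @param n_sims replicates per cohort size (>= 50).
#' @param beta_lgd,beta_misd TADA prior rate parameters.
#' @param pi prior risk-gene fraction used in the TADA step; default `k / G`
#'   resolved at run time.
#' @param q_hc,q_prob discovery thresholds.
#' @param seed RNG seed.
#' @return validated list with class `projection_config`.
#' @export
projection_config <- function(k, gamma_bar_lgd, gamma_bar_misd,
                              trio_grid = c(100, 250, 500, 1000),
                              n_sims = 200, beta_lgd = 1, beta_misd = 1,
                              pi = NULL, q_hc = 0.1, q_prob = 0.3,
                              seed = NULL) {
  stopifnot(k >= 1, gamma_bar_lgd >= 1, gamma_bar_misd >= 1,
            all(diff(trio_grid) > 0), all(trio_grid >= 0), n_sims >= 50,
            q_hc < q_prob)
  structure(list(k = as.integer(k), gamma_bar_lgd = gamma_bar_lgd,
                 gamma_bar_misd = gamma_bar_misd,
                 trio_grid = as.integer(trio_grid), n_sims = n_sims,
                 beta_lgd = beta_lgd, beta_misd = beta_misd, pi = pi,
                 q_hc = q_hc, q_prob = q_prob, seed = seed),
            class = "projection_config")
}

#' Simulate per-gene de novo class counts for one cohort
#'
#' Draws `k` risk genes uniformly from the gene universe, then per-gene
#' class counts `Poisson(2 n mu_c gamma_c)` with `gamma_c` equal to the
#' planted relative risk in risk genes and 1 elsewhere. With
#' `gamma_bar = 1` this is exactly the TADA null generator.
#'
#' @param n_trios cohort size.
#' @param k number of risk genes.
#' @param rates a [rate_table()].
#' @param gamma_bar_lgd,gamma_bar_misd planted relative risks.
#' @param seed RNG seed (NULL = current stream).
#' @return list with integer vectors `x_lgd`, `x_misd` (length G) and
#'   `risk_idx`, the planted risk-gene indices.
#' @export
simulate_cohort_counts <- function(n_trios, k, rates, gamma_bar_lgd,
                                   gamma_bar_misd, seed = NULL) {
  stopifnot(k <= nrow(rates), n_trios >= 0)
  G <- nrow(rates)
  with_seed(seed, {
    risk_idx <- sample.int(G, k)
    g_lgd <- rep(1, G); g_lgd[risk_idx] <- gamma_bar_lgd
    g_misd <- rep(1, G); g_misd[risk_idx] <- gamma_bar_misd
    list(
      x_lgd = stats::rpois(G, 2 * n_trios * rates$mu_lgd * g_lgd),
      x_misd = stats::rpois(G, 2 * n_trios * rates$mu_misd * g_misd),
      risk_idx = risk_idx
    )
  })
}

#' Project risk-gene discovery as a function of cohort size
#'
#' At each cohort size, simulates `n_sims` cohorts with
#' [simulate_cohort_counts()], applies the TADA-Denovo Bayes factors and
#' direct-posterior FDR, and averages the number of genes crossing each
#' q-value threshold. The true-positive fraction is the share of flagged
#' probable genes that are planted risk genes.
#'
#' @param config a [projection_config()].
#' @param rates a [rate_table()].
#' @return data.frame with class `projection_table`: `n_trios`,
#'   `mean_probable`, `se_probable`, `mean_high_confidence`,
#'   `se_high_confidence`, `tp_fraction`.
#' @export
project_discovery <- function(config, rates) {
  stopifnot(inherits(config, "projection_config"))
  G <- nrow(rates)
  pi <- config$pi %||% (config$k / G)
  seeds <- split_seed(config$seed %||% 1L, length(config$trio_grid))
  rows <- lapply(seq_along(config$trio_grid), function(i) {
    n <- config$trio_grid[i]
    hc <- prob <- tp <- numeric(config$n_sims)
    with_seed(seeds[i], {
      for (s in seq_len(config$n_sims)) {
        sim <- simulate_cohort_counts(n, config$k, rates,
                                      config$gamma_bar_lgd,
                                      config$gamma_bar_misd)
        lbf <- log_class_bf(pmin(sim$x_lgd, 50), 2 * n * rates$mu_lgd,
                            config$gamma_bar_lgd, config$beta_lgd) +
          log_class_bf(pmin(sim$x_misd, 50), 2 * n * rates$mu_misd,
                       config$gamma_bar_misd, config$beta_misd)
        q <- dp_fdr_q(exp(lbf), pi)
        flagged <- which(q < config$q_prob)
        hc[s] <- sum(q < config$q_hc)
        prob[s] <- length(flagged)
        tp[s] <- if (length(flagged)) {
          mean(flagged %in% sim$risk_idx)
        } else NA_real_
      }
    })
    data.frame(
      n_trios = n,
      mean_probable = mean(prob),
      se_probable = stats::sd(prob) / sqrt(config$n_sims),
      mean_high_confidence = mean(hc),
      se_high_confidence = stats::sd(hc) / sqrt(config$n_sims),
      tp_fraction = mean(tp, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("projection_table", "data.frame")
  out
}
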