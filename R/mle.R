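# Simulation-based maximum-likelihood estimation of the number of risk
# genes k, from the observed count of damaging de novo variants (M) and the
# observed recurrence among genes (genes hit two or more times).

#' Expected null count of damaging de novo variants in a cohort
#'
#' @param rates a [rate_table()].
#' @param n_trios number of trios N.
#' @param exposure mean fraction of the diploid coding exome that is
#'   callable in the cohort (1 = fully callable). Observed counts from
#'   partially callable exomes should be compared against an
#'   exposure-scaled expectation.
#' @return `E0 = 2 * N * exposure * sum(mu_damaging)`.
#' @export
expected_null_damaging <- function(rates, n_trios, exposure = 1) {
  if (!nrow(rates)) stop("empty rate table", call. = FALSE)
  stopifnot(n_trios > 0, exposure > 0)
  2 * n_trios * exposure * sum(rates$mu_damaging)
}

#' Configuration for the risk-gene-number MLE
#'
#' The likelihood at each candidate k is the simulated probability of
#' reproducing the observed recurrence. Two statistics are available:
#' `"profile"` (default) matches the multiset of per-gene hit counts among
#' recurrently hit genes (e.g. "one gene hit exactly twice"), which uses
#' the multiplicity information in the data; `"count"` matches only the
#' number of genes hit at least twice. The count statistic is degenerate
#' when the excess burden is large: very small k concentrates all excess
#' mutations in a few genes, which still yields a small count of recurrent
#' genes while predicting hit multiplicities far beyond anything observed.
#'
#' @param M_obs observed number of damaging de novo variants in cases.
#' @param R_obs observed number of genes with >= 2 damaging de novo
#'   variants.
#' @param n_trios number of case trios.
#' @param profile integer vector of observed per-gene hit counts among the
#'   recurrently hit genes; default `rep(2, R_obs)` (each recurrent gene
#'   hit exactly twice). Ignored by the `"count"` statistic.
#' @param statistic `"profile"` (default) or `"count"`.
#' @param k_grid increasing integer grid of candidate risk-gene numbers.
#' @param n_sims_per_k Monte-Carlo replicates per grid point (>= 100).
#' @param exposure callable-exposure scaling for the null expectation (see
#'   [expected_null_damaging()]).
#' @param placement `"rate_weighted"` (default) or `"uniform"` placement of
#'   risk-mediating mutations within the sampled risk-gene set.
#' @param refine refine the grid around the coarse argmax.
#' @param seed RNG seed.
#' @return validated list with class `mle_config`.
#' @export
mle_config <- function(M_obs, R_obs, n_trios, profile = NULL,
                       statistic = c("profile", "count"),
                       k_grid = c(1, 2, 5, 10, 25, 50, 75, 100, 150, 200,
                                  250, 300, 400, 500, 750, 1000, 1500,
                                  2000, 2500),
                       n_sims_per_k = 2000, exposure = 1,
                       placement = c("rate_weighted", "uniform"),
                       refine = TRUE, seed = NULL) {
  placement <- match.arg(placement)
  statistic <- match.arg(statistic)
  k_grid <- as.integer(k_grid)
  profile <- as.integer(profile %||% rep(2L, R_obs))
  stopifnot(M_obs >= 0, R_obs >= 0, n_trios > 0,
            all(diff(k_grid) > 0), all(k_grid >= 1),
            n_sims_per_k >= 100)
  if (length(profile) != R_obs || (R_obs > 0 && any(profile < 2))) {
    stop("profile must list one hit count (>= 2) per recurrent gene",
         call. = FALSE)
  }
  if (M_obs < sum(profile)) {
    stop("M_obs is too small to produce the observed recurrence",
         call. = FALSE)
  }
  structure(list(M_obs = M_obs, R_obs = R_obs, n_trios = n_trios,
                 profile = sort(profile), statistic = statistic,
                 k_grid = k_grid, n_sims_per_k = n_sims_per_k,
                 exposure = exposure, placement = placement,
                 refine = refine, seed = seed),
            class = "mle_config")
}

# Multiset of per-gene hit counts (>= 2) for one replicate's placements.
recurrence_multiplicities <- function(idx) {
  r <- rle(sort(idx))
  sort(r$lengths[r$lengths >= 2L])
}

# One replicate of mutation placement: C ~ Binomial(M, C_bar / M)
# risk-mediating mutations among k risk genes sampled uniformly from the
# universe (rate-weighted within the set unless `uniform`), M - C null
# mutations over all genes with probability proportional to mu_damaging.
place_mutations <- function(k, M, p_risk, mu, cumw_all, placement) {
  C <- stats::rbinom(1, M, p_risk)
  idx <- if (M - C > 0) sample_cumw(cumw_all, M - C) else integer(0)
  if (C > 0) {
    risk_set <- sample.int(length(mu), k)
    if (placement == "rate_weighted") {
      w <- mu[risk_set]
      if (sum(w) <= 0) w <- rep(1, k)
      idx <- c(idx, risk_set[sample_cumw(cumsum(w) / sum(w), C)])
    } else {
      idx <- c(idx, risk_set[sample.int(k, C, replace = TRUE)])
    }
  }
  idx
}

#' Simulate the number of recurrently hit genes under k risk genes
#'
#' @param k number of risk genes (<= number of genes in `rates`).
#' @param M total damaging de novo variants to place.
#' @param rates a [rate_table()].
#' @param n_trios,exposure define the expected null count used to split `M`
#'   into risk-mediating and background mutations.
#' @param n_reps number of replicates.
#' @param placement see [mle_config()].
#' @param seed RNG seed (NULL = current stream).
#' @return integer vector of length `n_reps`: genes with >= 2 mutations.
#' @export
simulate_recurrence <- function(k, M, rates, n_trios, exposure = 1,
                                n_reps = 1, placement = "rate_weighted",
                                seed = NULL) {
  stopifnot(k >= 1, k <= nrow(rates), M >= 0)
  E0 <- expected_null_damaging(rates, n_trios, exposure)
  p_risk <- if (M > 0) min(1, max(0, M - E0) / M) else 0
  mu <- rates$mu_damaging
  cumw <- cumsum(mu) / sum(mu)
  with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      if (M == 0) return(0L)
      length(recurrence_multiplicities(
        place_mutations(k, M, p_risk, mu, cumw, placement)))
    }, integer(1))
  })
}

#' Maximum-likelihood estimate of the number of risk genes
#'
#' For each candidate k the likelihood `L(k)` is the Monte-Carlo
#' probability of reproducing the observed recurrence (see [mle_config()]
#' for the two statistics); the MLE is the grid argmax (smallest k on
#' ties). When `refine = TRUE` the grid is refined once around the coarse
#' argmax. The support interval collects grid points with
#' `L(k) >= max(L) / e^2`; the plateau interval collects points within two
#' Monte-Carlo standard errors of the maximum and measures how flat the
#' likelihood is around the argmax at the configured simulation depth.
#'
#' @param config an [mle_config()].
#' @param rates a [rate_table()].
#' @return list with class `mle_result`: `k_hat`, `likelihood` (data.frame
#'   `k`, `L`, `se`), `support` (range), `plateau` (range), `C_bar`, `E0`,
#'   and `identifiable`.
#' @export
mle_risk_genes <- function(config, rates) {
  stopifnot(inherits(config, "mle_config"))
  G <- nrow(rates)
  E0 <- expected_null_damaging(rates, config$n_trios, config$exposure)
  C_bar <- max(0, config$M_obs - E0)
  p_risk <- if (config$M_obs > 0) min(1, C_bar / config$M_obs) else 0
  mu <- rates$mu_damaging
  cumw <- cumsum(mu) / sum(mu)
  grid <- config$k_grid[config$k_grid <= G]
  M <- config$M_obs

  matches <- if (config$statistic == "profile") {
    function(idx) identical(recurrence_multiplicities(idx), config$profile)
  } else {
    function(idx) {
      length(recurrence_multiplicities(idx)) == config$R_obs
    }
  }
  eval_grid <- function(ks, seeds) {
    L <- se <- numeric(length(ks))
    for (i in seq_along(ks)) {
      hit <- with_seed(seeds[i], {
        n_ok <- 0L
        for (r in seq_len(config$n_sims_per_k)) {
          idx <- if (M > 0) {
            place_mutations(ks[i], M, p_risk, mu, cumw, config$placement)
          } else integer(0)
          n_ok <- n_ok + matches(idx)
        }
        n_ok
      })
      L[i] <- hit / config$n_sims_per_k
      se[i] <- sqrt(L[i] * (1 - L[i]) / config$n_sims_per_k)
    }
    data.frame(k = ks, L = L, se = se)
  }

  seeds <- split_seed(config$seed %||% 1L, length(grid) + 64L)
  lik <- eval_grid(grid, seeds[seq_along(grid)])

  if (config$refine && nrow(lik) > 2) {
    i <- which.max(lik$L)
    lo <- lik$k[max(1, i - 1)]
    hi <- lik$k[min(nrow(lik), i + 1)]
    step <- max(2L, as.integer(round((hi - lo) / 20)))
    ks2 <- setdiff(seq(lo, hi, by = step), lik$k)
    if (length(ks2)) {
      lik2 <- eval_grid(ks2, seeds[length(grid) + seq_along(ks2)])
      lik <- rbind(lik, lik2)
      lik <- lik[order(lik$k), ]
    }
  }
  rownames(lik) <- NULL

  if (all(lik$L == 0)) {
    stop("likelihood is zero over the whole grid; increase n_sims_per_k ",
         "or extend k_grid", call. = FALSE)
  }
  Lmax <- max(lik$L)
  k_hat <- lik$k[which.max(lik$L)]
  support <- range(lik$k[lik$L >= Lmax / exp(2)])
  plateau <- range(lik$k[lik$L >= Lmax - 2 * max(lik$se)])
  identifiable <- !(config$R_obs == 0 && C_bar == 0)
  if (!identifiable) {
    warning("R_obs = 0 with no excess burden: likelihood is flat in k ",
            "(non-identifiable)", call. = FALSE)
  }
  structure(list(k_hat = k_hat, likelihood = lik, support = support,
                 plateau = plateau, C_bar = C_bar, E0 = E0,
                 identifiable = identifiable, config = config),
            class = "mle_result")
}

#' @export
print.mle_result <- function(x, ...) {
  cat(sprintf(paste0("<mle_result> k_hat = %d (support %d-%d, ",
                     "plateau %d-%d), E0 = %.2f, C_bar = %.2f\n"),
              x$k_hat, x$support[1], x$support[2], x$plateau[1],
              x$plateau[2], x$E0, x$C_bar))
  invisible(x)
}
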