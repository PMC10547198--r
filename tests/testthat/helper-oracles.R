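# Independent numerical oracles and small fixture builders used across the
# test files.

# Poisson-Gamma Bayes factor by direct numerical quadrature of
#   integral Pois(x; q0 * gamma) Gamma(gamma; shape = gbar * beta,
#                                      rate = beta) dgamma / Pois(x; q0).
# The integrand's mass can sit far from the prior when x / q0 is large, so
# the peak region is located by a coarse scan before a fine Simpson rule on
# the log scale. Accuracy ~1e-7 relative.
bf_quadrature_oracle <- function(x, q0, gbar, beta) {
  li <- function(lg) {
    gam <- exp(lg)
    stats::dpois(x, q0 * gam, log = TRUE) +
      stats::dgamma(gam, shape = gbar * beta, rate = beta, log = TRUE) + lg
  }
  coarse <- seq(-30, log(max(1, x / q0)) + 30, length.out = 20001)
  lv <- li(coarse)
  keep <- range(coarse[lv > max(lv) - 80])
  lg <- seq(keep[1] - 2, keep[2] + 2, length.out = 200001)
  h <- lg[2] - lg[1]
  lh <- li(lg)
  m <- max(lh)
  w <- rep(c(4, 2), length.out = length(lg))
  w[c(1, length(lg))] <- 1
  num <- m + log(sum(w * exp(lh - m)) * h / 3)
  exp(num - stats::dpois(x, q0, log = TRUE))
}

# Exact conditional binomial tail by explicit summation (independent of
# stats::pbinom), for small totals.
binom_tail_oracle <- function(x_case, Tt, p0) {
  j <- x_case:Tt
  sum(choose(Tt, j) * p0^j * (1 - p0)^(Tt - j))
}

# Small random annotated variant table exercising every effect class.
random_denovo_table <- function(n, seed) {
  withr::local_seed(seed)
  effects <- c("synonymous_snv", "missense_snv", "stopgain", "stoploss",
               "splice_site", "frameshift_indel", "nonframeshift_indel",
               "unknown", "noncoding")
  eff <- sample(effects, n, replace = TRUE)
  pp <- ifelse(eff == "missense_snv",
               ifelse(stats::runif(n) < 0.15, NA_real_, stats::runif(n)),
               NA_real_)
  denovo_table(data.frame(
    proband_id = sprintf("p%03d", sample.int(50, n, replace = TRUE)),
    cohort = sample(c("case", "control"), n, replace = TRUE),
    gene = sprintf("G%04d", sample.int(500, n, replace = TRUE)),
    effect = eff, polyphen_hdiv = pp,
    pop_freq = ifelse(stats::runif(n) < 0.1, stats::runif(n, 0, 0.05),
                      NA_real_),
    stringsAsFactors = FALSE
  ))
}

# Compact synthetic scenario for fast Monte-Carlo tests.
small_scenario <- function(seed = 1, G = 2000, k_true = 50, ...) {
  scenario_config(G = G, n_case = 60, n_ctrl = 120, k_true = k_true,
                  seed = seed, ...)
}
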