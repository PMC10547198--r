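# Callable-base-normalized de novo mutation-rate burden analysis:
# per-class rates, per-individual estimates, and one-tailed exact
# rate-ratio tests comparing case versus control cohorts.

#' Coding-exome constants used for per-individual estimates
#'
#' `coding_exome_bp` is the RefSeq hg19 coding exome size. The per-individual
#' estimate multiplies a per-haploid-bp rate by the exome size and by
#' `ploidy_factor = 2`, so that it counts expected de novo coding variants
#' per diploid individual.
#'
#' @param coding_exome_bp coding exome size in bp.
#' @param ploidy_factor haploid-to-diploid factor.
#' @return named list of the two constants.
#' @export
exome_constants <- function(coding_exome_bp = 33828798L, ploidy_factor = 2L) {
  stopifnot(coding_exome_bp > 0, ploidy_factor > 0)
  list(coding_exome_bp = coding_exome_bp, ploidy_factor = ploidy_factor)
}

#' De novo mutation rate per haploid callable base
#'
#' @param x variant count (non-negative).
#' @param B haploid callable bases summed over the cohort's trios (positive).
#' @return rate `x / B` per bp.
#' @export
mutation_rate <- function(x, B) {
  if (any(B <= 0)) stop("callable base total B must be positive", call. = FALSE)
  if (any(x < 0)) stop("count x must be non-negative", call. = FALSE)
  x / B
}

#' Expected de novo coding variants per individual
#'
#' @param rate per-haploid-bp mutation rate.
#' @param consts constants from [exome_constants()].
#' @return `rate * coding_exome_bp * ploidy_factor`.
#' @export
per_individual_estimate <- function(rate, consts = exome_constants()) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  rate * consts$coding_exome_bp * consts$ploidy_factor
}

#' Exact conditional rate-ratio test for two Poisson rates
#'
#' Compares the case rate `x_case / B_case` against the control rate
#' `x_ctrl / B_ctrl`. Conditional on the total count `T = x_case + x_ctrl`,
#' the case count is Binomial(`T`, `p0`) with
#' `p0 = B_case / (B_case + B_ctrl)` under the null of equal rates; the
#' p-value is the exact binomial tail in the direction of `alternative`.
#'
#' The default confidence interval is the log-normal (Katz) interval
#' `exp(log rr +/- z * sqrt(1/x_case + 1/x_ctrl))`; `"exact_conditional"`
#' inverts the exact binomial interval for `p0` instead. With `x_ctrl = 0`
#' the ratio is reported as `Inf` and only the exact interval is available;
#' with `x_case = 0` the ratio is 0 and the one-sided (greater) p-value is 1.
#'
#' @param x_case,x_ctrl observed counts.
#' @param B_case,B_ctrl haploid callable base totals.
#' @param alternative `"greater"` (case rate higher; default), `"less"`, or
#'   `"two_sided"`.
#' @param ci_method `"log_normal"` (default) or `"exact_conditional"`.
#' @param conf_level confidence level for the interval.
#' @param adjust p-value discreteness adjustment: `"none"` (exact,
#'   conservative), `"mid"` (mid-p), or `"randomized"` (uniform on \[0,1\]
#'   under the null; useful for calibration checks only).
#' @return list with `rr`, `ci_low`, `ci_high`, `p`.
#' @export
rate_ratio_test <- function(x_case, B_case, x_ctrl, B_ctrl,
                            alternative = c("greater", "less", "two_sided"),
                            ci_method = c("log_normal", "exact_conditional"),
                            conf_level = 0.95,
                            adjust = c("none", "mid", "randomized")) {
  alternative <- match.arg(alternative)
  ci_method <- match.arg(ci_method)
  adjust <- match.arg(adjust)
  stopifnot(B_case > 0, B_ctrl > 0, x_case >= 0, x_ctrl >= 0)
  if (x_case + x_ctrl == 0) stop("no events in either cohort", call. = FALSE)

  Tt <- x_case + x_ctrl
  p0 <- B_case / (B_case + B_ctrl)
  upper <- stats::pbinom(x_case - 1, Tt, p0, lower.tail = FALSE) # P(X >= x)
  lower <- stats::pbinom(x_case, Tt, p0)                         # P(X <= x)
  point <- stats::dbinom(x_case, Tt, p0)
  tail <- function(side) {
    switch(adjust,
      none = side,
      mid = side - point / 2,
      randomized = side - stats::runif(1) * point)
  }
  p <- switch(alternative,
    greater = tail(upper),
    less = tail(lower),
    two_sided = min(1, 2 * min(tail(upper), tail(lower))))
  p <- min(max(p, 0), 1)
  if (adjust == "none" && alternative != "two_sided") p <- max(p, point)

  rr <- if (x_ctrl == 0) Inf else (x_case / B_case) / (x_ctrl / B_ctrl)
  if (ci_method == "log_normal" && x_case > 0 && x_ctrl > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / x_case + 1 / x_ctrl)
    ci <- rr * exp(c(-1, 1) * z * se)
  } else {
    # invert the exact binomial CI for the conditional proportion
    bt <- stats::binom.test(x_case, Tt, p0, conf.level = conf_level)
    th <- bt$conf.int
    odds <- th / (1 - th)
    ci <- odds * B_ctrl / B_case
  }
  list(rr = rr, ci_low = ci[1], ci_high = ci[2], p = p)
}

#' Per-class burden table comparing case and control de novo rates
#'
#' Builds one row per variant class with counts, per-bp rates,
#' per-individual estimates, the rate ratio with confidence interval, and
#' the one-sided exact p-value (case rate greater). The `all` row can use
#' whole-capture callable totals supplied via the `callable_all_bp` column
#' of the cohort table; coding rows use `callable_bp`.
#'
#' @param case_vs,ctrl_vs classified, frequency-filtered [denovo_table()]s.
#' @param cohorts a [cohort_table()] covering both phenotypes.
#' @param consts constants from [exome_constants()].
#' @param sig_level flag threshold for the `significant` column.
#' @param ci_method passed to [rate_ratio_test()].
#' @return data.frame with class `burden_table`, one row per class.
#' @export
burden_table <- function(case_vs, ctrl_vs, cohorts,
                         consts = exome_constants(), sig_level = 0.05,
                         ci_method = "log_normal") {
  stopifnot(inherits(cohorts, "cohort_table") || is.data.frame(cohorts))
  if (!all(c("case", "control") %in% cohorts$phenotype)) {
    stop("configuration error: cohort table must contain both phenotypes",
         call. = FALSE)
  }
  B_case <- sum(cohorts$callable_bp[cohorts$phenotype == "case"])
  B_ctrl <- sum(cohorts$callable_bp[cohorts$phenotype == "control"])
  has_all <- "callable_all_bp" %in% names(cohorts)
  B_case_all <- if (has_all) {
    sum(cohorts$callable_all_bp[cohorts$phenotype == "case"])
  } else B_case
  B_ctrl_all <- if (has_all) {
    sum(cohorts$callable_all_bp[cohorts$phenotype == "control"])
  } else B_ctrl

  n_case <- sum(cohorts$phenotype == "case")
  n_ctrl <- sum(cohorts$phenotype == "control")
  cc <- tabulate_counts(case_vs)
  ct <- tabulate_counts(ctrl_vs)

  rows <- lapply(variant_classes(), function(cl) {
    Bc <- if (cl == "all") B_case_all else B_case
    Bt <- if (cl == "all") B_ctrl_all else B_ctrl
    x_case <- cc[[cl]]
    x_ctrl <- ct[[cl]]
    rate_case <- mutation_rate(x_case, Bc)
    rate_ctrl <- mutation_rate(x_ctrl, Bt)
    if (x_case + x_ctrl > 0) {
      tst <- rate_ratio_test(x_case, Bc, x_ctrl, Bt, ci_method = ci_method)
    } else {
      tst <- list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p = NA_real_)
    }
    data.frame(
      variant_class = cl, x_case = x_case, x_ctrl = x_ctrl,
      B_case = Bc, B_ctrl = Bt,
      rate_case = rate_case, rate_ctrl = rate_ctrl,
      per_ind_case = per_individual_estimate(rate_case, consts),
      per_ind_ctrl = per_individual_estimate(rate_ctrl, consts),
      rr = tst$rr, ci_low = tst$ci_low, ci_high = tst$ci_high, p = tst$p,
      significant = !is.na(tst$p) & tst$p < sig_level,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_trios") <- c(case = n_case, control = n_ctrl)
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Write a burden table as TSV
#' @param bt a [burden_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(bt, path) {
  utils::write.table(as.data.frame(bt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
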