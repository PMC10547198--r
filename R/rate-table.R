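# Per-gene expected de novo mutation-rate tables (haploid rate per gene per
# generation, split by variant class).

#' Construct / validate a per-gene mutation rate table
#'
#' @param gene unique gene symbols.
#' @param mu_total per-gene total coding de novo rate (haploid, per
#'   generation).
#' @param mu_lgd,mu_misd class rates for likely-gene-disrupting and probably
#'   damaging missense variants; their sum must not exceed `mu_total`.
#' @return data.frame (`gene`, `mu_total`, `mu_lgd`, `mu_misd`,
#'   `mu_damaging`) with class `rate_table`; `mu_damaging = mu_lgd + mu_misd`.
#' @export
rate_table <- function(gene, mu_total, mu_lgd, mu_misd) {
  gene <- trimws(as.character(gene))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup)) {
    stop("duplicate gene symbol(s) in rate table: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  mu_total <- as.numeric(mu_total)
  mu_lgd <- as.numeric(mu_lgd)
  mu_misd <- as.numeric(mu_misd)
  if (any(c(mu_total, mu_lgd, mu_misd) < 0)) {
    stop("mutation rates must be non-negative", call. = FALSE)
  }
  if (any(mu_lgd + mu_misd > mu_total * (1 + 1e-8))) {
    stop("mu_lgd + mu_misd exceeds mu_total for some genes", call. = FALSE)
  }
  structure(
    data.frame(gene = gene, mu_total = mu_total, mu_lgd = mu_lgd,
               mu_misd = mu_misd, mu_damaging = mu_lgd + mu_misd,
               stringsAsFactors = FALSE),
    class = c("rate_table", "data.frame")
  )
}

#' Default column-name mapping for rate tables
#'
#' The defaults mirror the conventional TADA-Denovo input layout: overall
#' rate `mut.rate`, LGD rate `mut.cls1`, damaging-missense rate `mut.cls2`.
#'
#' @param gene,mu_total,mu_lgd,mu_misd column names in the file.
#' @return named character vector for [read_rate_table()].
#' @export
rate_dialect <- function(gene = "gene", mu_total = "mut.rate",
                         mu_lgd = "mut.cls1", mu_misd = "mut.cls2") {
  c(gene = gene, mu_total = mu_total, mu_lgd = mu_lgd, mu_misd = mu_misd)
}

#' Read a per-gene mutation rate table from TSV
#'
#' @param path TSV with one gene per row.
#' @param dialect column mapping from [rate_dialect()].
#' @return a [rate_table()].
#' @export
read_rate_table <- function(path, dialect = rate_dialect()) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- dialect[!dialect %in% names(df)]
  if (length(miss)) {
    stop("schema error: required column(s) not found: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rate_table(df[[dialect[["gene"]]]],
             parse_numeric_column(df[[dialect[["mu_total"]]]], "mu_total"),
             parse_numeric_column(df[[dialect[["mu_lgd"]]]], "mu_lgd"),
             parse_numeric_column(df[[dialect[["mu_misd"]]]], "mu_misd"))
}

#' Write a rate table as TSV (conventional TADA-style column names)
#' @param rates a [rate_table()].
#' @param path output path.
#' @param dialect column mapping from [rate_dialect()].
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path, dialect = rate_dialect()) {
  out <- data.frame(rates$gene, rates$mu_total, rates$mu_lgd, rates$mu_misd,
                    stringsAsFactors = FALSE)
  names(out) <- dialect[c("gene", "mu_total", "mu_lgd", "mu_misd")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
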