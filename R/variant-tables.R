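# Annotated de novo variant tables: reading, validation, classification,
# frequency filtering, and class tabulation.

# Canonical functional-effect vocabulary (finest annotation level).
.effects <- c(
  "synonymous_snv", "missense_snv", "stopgain", "stoploss", "splice_site",
  "frameshift_indel", "nonframeshift_indel", "unknown", "noncoding"
)

#' Variant-class hierarchy used in burden tabulations
#'
#' The sixteen classes form a hierarchy: `nonsynonymous = missense_all + lgd`,
#' `damaging = lgd + mis_d`, `lgd = lgd_snv + lgd_frameshift`,
#' `lgd_snv = lgd_stopgain + lgd_splice`, and
#' `coding = synonymous + nonsynonymous + nonframeshift + unknown`.
#' `all` additionally counts non-coding calls.
#'
#' @return character vector of the sixteen class names.
#' @export
variant_classes <- function() {
  c("all", "coding", "synonymous", "nonsynonymous", "missense_all",
    "mis_d", "mis_p", "mis_b", "lgd", "damaging", "lgd_snv",
    "lgd_stopgain", "lgd_splice", "lgd_frameshift", "nonframeshift",
    "unknown")
}

# PolyPhen2-HDIV cutpoints separating probably/possibly damaging/benign
# missense calls.
.pp2_damaging <- 0.957
.pp2_possible <- 0.453

#' Default column-name mapping for annotated de novo variant tables
#'
#' Maps the package's field names to the column headers expected in a
#' tab-separated, ANNOVAR-style annotated de novo variant table. Override
#' individual entries to read tables with different headers, e.g.
#' `denovo_dialect(gene = "Gene.refGene", effect = "ExonicFunc.refGene")`.
#'
#' @param proband_id,cohort,gene,effect,polyphen_hdiv,pop_freq column names.
#' @return named character vector usable as the `dialect` argument of
#'   [read_denovo_table()].
#' @export
denovo_dialect <- function(proband_id = "proband_id", cohort = "cohort",
                           gene = "gene", effect = "effect",
                           polyphen_hdiv = "polyphen_hdiv",
                           pop_freq = "pop_freq") {
  c(proband_id = proband_id, cohort = cohort, gene = gene, effect = effect,
    polyphen_hdiv = polyphen_hdiv, pop_freq = pop_freq)
}

# Normalize free-text effect annotations (ANNOVAR exonic-function strings and
# close variants) onto the canonical vocabulary. Unrecognized strings map to
# "unknown" so that a table with exotic annotations still tabulates.
normalize_effect <- function(x) {
  key <- gsub("[ .]+", "_", tolower(trimws(x)))
  map <- c(
    synonymous_snv = "synonymous_snv", synonymous = "synonymous_snv",
    missense_snv = "missense_snv", missense = "missense_snv",
    nonsynonymous_snv = "missense_snv",
    stopgain = "stopgain", stopgain_snv = "stopgain", stop_gain = "stopgain",
    stoploss = "stoploss", stoploss_snv = "stoploss", stop_loss = "stoploss",
    splice_site = "splice_site", splicing = "splice_site", splice = "splice_site",
    frameshift_indel = "frameshift_indel",
    frameshift_insertion = "frameshift_indel",
    frameshift_deletion = "frameshift_indel",
    frameshift_substitution = "frameshift_indel",
    nonframeshift_indel = "nonframeshift_indel",
    nonframeshift_insertion = "nonframeshift_indel",
    nonframeshift_deletion = "nonframeshift_indel",
    nonframeshift_substitution = "nonframeshift_indel",
    unknown = "unknown",
    noncoding = "noncoding", intronic = "noncoding", intergenic = "noncoding",
    upstream = "noncoding", downstream = "noncoding",
    utr3 = "noncoding", utr5 = "noncoding",
    ncrna_exonic = "noncoding", ncrna_intronic = "noncoding"
  )
  out <- unname(map[key])
  out[is.na(out)] <- "unknown"
  out
}

# Parse a numeric column, reporting 1-based row indices of unparsable entries.
parse_numeric_column <- function(x, column) {
  if (is.numeric(x)) return(as.numeric(x))
  raw <- trimws(as.character(x))
  raw[raw %in% c("", ".", "NA", "na", "N/A")] <- NA_character_
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(val))
  if (length(bad)) {
    stop(sprintf("column '%s': unparsable numeric value in row(s) %s",
                 column, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  val
}

#' Construct / validate an annotated de novo variant table
#'
#' @param df data.frame with columns `proband_id`, `cohort` (`"case"` or
#'   `"control"`), `gene`, `effect` (canonical vocabulary), and optionally
#'   `polyphen_hdiv` and `pop_freq` (both in `[0, 1]`, `NA` allowed).
#' @return the validated data.frame with class `denovo_table`.
#' @export
denovo_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("proband_id", "cohort", "gene", "effect")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$proband_id <- as.character(df$proband_id)
  df$cohort <- tolower(trimws(as.character(df$cohort)))
  if (!all(df$cohort %in% c("case", "control"))) {
    stop("cohort must be 'case' or 'control'", call. = FALSE)
  }
  df$gene <- trimws(as.character(df$gene))
  df$effect <- as.character(df$effect)
  if (!all(df$effect %in% .effects)) df$effect <- normalize_effect(df$effect)
  if (is.null(df$polyphen_hdiv)) df$polyphen_hdiv <- NA_real_
  if (is.null(df$pop_freq)) df$pop_freq <- NA_real_
  ok <- is.na(df$polyphen_hdiv) |
    (df$polyphen_hdiv >= 0 & df$polyphen_hdiv <= 1)
  if (!all(ok)) stop("polyphen_hdiv outside [0, 1]", call. = FALSE)
  ok <- is.na(df$pop_freq) | (df$pop_freq >= 0 & df$pop_freq <= 1)
  if (!all(ok)) stop("pop_freq outside [0, 1]", call. = FALSE)
  class(df) <- unique(c("denovo_table", class(df)))
  df
}

#' Read an annotated de novo variant table
#'
#' Reads a tab-separated, header-bearing table of annotated de novo calls
#' (one row per variant). Effect strings are normalized onto the canonical
#' vocabulary; unrecognized effects become `"unknown"`. Row order is
#' preserved.
#'
#' @param path path to a UTF-8 TSV file.
#' @param dialect column-name mapping from [denovo_dialect()].
#' @return a [denovo_table()] data.frame.
#' @export
read_denovo_table <- function(path, dialect = denovo_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  req <- c("proband_id", "cohort", "gene", "effect")
  missing_cols <- req[!dialect[req] %in% names(raw)]
  if (length(missing_cols)) {
    stop(sprintf("schema error: required column(s) not found: %s",
                 paste(dialect[missing_cols], collapse = ", ")),
         call. = FALSE)
  }
  df <- data.frame(
    proband_id = raw[[dialect[["proband_id"]]]],
    cohort = raw[[dialect[["cohort"]]]],
    gene = raw[[dialect[["gene"]]]],
    effect = normalize_effect(raw[[dialect[["effect"]]]]),
    stringsAsFactors = FALSE
  )
  pp <- dialect[["polyphen_hdiv"]]
  df$polyphen_hdiv <- if (pp %in% names(raw)) {
    parse_numeric_column(raw[[pp]], pp)
  } else NA_real_
  pf <- dialect[["pop_freq"]]
  df$pop_freq <- if (pf %in% names(raw)) {
    parse_numeric_column(raw[[pf]], pf)
  } else NA_real_
  denovo_table(df)
}

#' Write an annotated de novo variant table as TSV
#'
#' @param df a [denovo_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_denovo_table <- function(df, path) {
  cols <- c("proband_id", "cohort", "gene", "effect", "polyphen_hdiv",
            "pop_freq")
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign each variant to its finest variant class
#'
#' Missense calls are split by PolyPhen2-HDIV score: probably damaging
#' (`mis_d`, score >= 0.957), possibly damaging (`mis_p`, in [0.453, 0.957)),
#' benign (`mis_b`, < 0.453). A missense call without a score counts toward
#' `missense_all` (and hence `nonsynonymous`/`coding`) but toward no
#' sub-class. Stopgain, stoploss, and canonical splice-site variants are
#' likely gene disrupting (stoploss also alters a stop codon and is treated
#' as `lgd_stopgain`).
#'
#' @param effect character vector of canonical effects (or a
#'   [denovo_table()], from which both arguments are taken).
#' @param polyphen_hdiv numeric vector of PolyPhen2-HDIV scores (`NA`
#'   allowed).
#' @return character vector of finest classes: one of `synonymous`, `mis_d`,
#'   `mis_p`, `mis_b`, `missense_all` (unscored missense), `lgd_stopgain`,
#'   `lgd_splice`, `lgd_frameshift`, `nonframeshift`, `unknown`,
#'   `noncoding`.
#' @export
classify_variant <- function(effect, polyphen_hdiv = NULL) {
  if (is.data.frame(effect)) {
    polyphen_hdiv <- effect$polyphen_hdiv
    effect <- effect$effect
  }
  if (is.null(polyphen_hdiv)) polyphen_hdiv <- rep(NA_real_, length(effect))
  stopifnot(all(effect %in% .effects))
  out <- character(length(effect))
  out[effect == "synonymous_snv"] <- "synonymous"
  out[effect %in% c("stopgain", "stoploss")] <- "lgd_stopgain"
  out[effect == "splice_site"] <- "lgd_splice"
  out[effect == "frameshift_indel"] <- "lgd_frameshift"
  out[effect == "nonframeshift_indel"] <- "nonframeshift"
  out[effect == "unknown"] <- "unknown"
  out[effect == "noncoding"] <- "noncoding"
  mis <- effect == "missense_snv"
  out[mis & is.na(polyphen_hdiv)] <- "missense_all"
  out[mis & !is.na(polyphen_hdiv) & polyphen_hdiv >= .pp2_damaging] <- "mis_d"
  out[mis & !is.na(polyphen_hdiv) & polyphen_hdiv < .pp2_damaging &
        polyphen_hdiv >= .pp2_possible] <- "mis_p"
  out[mis & !is.na(polyphen_hdiv) & polyphen_hdiv < .pp2_possible] <- "mis_b"
  out
}

# Finest classes contributing to the damaging (LGD + Mis-D) aggregate.
.damaging_finest <- c("lgd_stopgain", "lgd_splice", "lgd_frameshift", "mis_d")

#' Filter variants on population allele frequency
#'
#' Keeps variants rarer than `threshold` in the reference population. A
#' missing frequency means the call is absent from the reference database and
#' is treated as novel (kept). Order is preserved; the operation is
#' idempotent.
#'
#' @param vs a [denovo_table()].
#' @param threshold frequency cutoff in `(0, 1]`; default 0.001.
#' @return the filtered table.
#' @export
frequency_filter <- function(vs, threshold = 0.001) {
  stopifnot(is.data.frame(vs), threshold > 0, threshold <= 1)
  keep <- is.na(vs$pop_freq) | vs$pop_freq < threshold
  vs[keep, , drop = FALSE]
}

#' Tabulate variant counts over the full class hierarchy
#'
#' @param vs a [denovo_table()].
#' @param cohort optional `"case"` or `"control"` to restrict the tabulation.
#' @return named integer vector over [variant_classes()]; hierarchy
#'   identities hold by construction.
#' @export
tabulate_counts <- function(vs, cohort = NULL) {
  if (!is.null(cohort)) vs <- vs[vs$cohort == cohort, , drop = FALSE]
  fine <- classify_variant(vs$effect, vs$polyphen_hdiv)
  n <- function(...) sum(fine %in% c(...))
  counts <- integer(0)
  counts["synonymous"] <- n("synonymous")
  counts["mis_d"] <- n("mis_d")
  counts["mis_p"] <- n("mis_p")
  counts["mis_b"] <- n("mis_b")
  counts["missense_all"] <- n("mis_d", "mis_p", "mis_b", "missense_all")
  counts["lgd_stopgain"] <- n("lgd_stopgain")
  counts["lgd_splice"] <- n("lgd_splice")
  counts["lgd_frameshift"] <- n("lgd_frameshift")
  counts["lgd_snv"] <- counts["lgd_stopgain"] + counts["lgd_splice"]
  counts["lgd"] <- counts["lgd_snv"] + counts["lgd_frameshift"]
  counts["nonsynonymous"] <- counts["missense_all"] + counts["lgd"]
  counts["damaging"] <- counts["lgd"] + counts["mis_d"]
  counts["nonframeshift"] <- n("nonframeshift")
  counts["unknown"] <- n("unknown")
  counts["coding"] <- counts["synonymous"] + counts["nonsynonymous"] +
    counts["nonframeshift"] + counts["unknown"]
  counts["all"] <- counts["coding"] + n("noncoding")
  counts[variant_classes()]
}

#' Genes with damaging de novo variants in cases but not in controls
#'
#' Returns the unique gene symbols carrying at least one damaging (LGD or
#' probably damaging missense) de novo variant in cases, minus any symbol
#' also carrying a damaging de novo variant in controls. A recurrently hit
#' gene contributes a single symbol; published gene lists that count each
#' mutation as a row can therefore exceed the unique-gene count.
#'
#' @param case_vs,control_vs [denovo_table()]s for each cohort.
#' @param name name given to the resulting set.
#' @return a [gene_set()].
#' @export
case_exclusive_damaging_genes <- function(case_vs, control_vs,
                                          name = "case_exclusive_damaging") {
  fine_case <- classify_variant(case_vs$effect, case_vs$polyphen_hdiv)
  fine_ctrl <- classify_variant(control_vs$effect, control_vs$polyphen_hdiv)
  g_case <- unique(case_vs$gene[fine_case %in% .damaging_finest])
  g_ctrl <- unique(control_vs$gene[fine_ctrl %in% .damaging_finest])
  gene_set(name, sort(setdiff(g_case, g_ctrl)))
}

#' Gene set constructor
#'
#' @param name set label.
#' @param genes character vector of gene symbols; whitespace is trimmed,
#'   symbols are compared case-sensitively, duplicates are dropped.
#' @return list with elements `name` and `genes`, class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a one-symbol-per-line gene set file
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @param name set label (default: file base name).
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(name %||% sub("\\.[^.]+$", "", basename(path)), lines)
}

#' Read a two-column (set, gene) TSV into a list of gene sets
#'
#' @param path TSV with header columns `set` and `gene`.
#' @return named list of [gene_set()]s.
#' @export
read_gene_sets_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("set", "gene") %in% names(df))) {
    stop("schema error: required column(s) not found: set, gene",
         call. = FALSE)
  }
  sets <- split(df$gene, df$set)
  out <- lapply(names(sets), function(nm) gene_set(nm, sets[[nm]]))
  names(out) <- names(sets)
  out
}

#' Write a list of gene sets as a two-column TSV
#'
#' @param sets list of [gene_set()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_tsv <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set = s$name, gene = s$genes, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort table constructor
#'
#' One row per sequenced trio with its phenotype and total haploid callable
#' bases (the denominator of per-base-pair de novo rates).
#'
#' @param trio_id character ids, unique.
#' @param phenotype `"case"` or `"control"` per trio.
#' @param callable_bp positive haploid callable base count per trio.
#' @return data.frame with class `cohort_table`.
#' @export
cohort_table <- function(trio_id, phenotype, callable_bp) {
  trio_id <- as.character(trio_id)
  if (anyDuplicated(trio_id)) stop("trio ids must be unique", call. = FALSE)
  phenotype <- tolower(as.character(phenotype))
  stopifnot(all(phenotype %in% c("case", "control")))
  callable_bp <- as.numeric(callable_bp)
  if (any(callable_bp <= 0)) stop("callable_bp must be positive", call. = FALSE)
  structure(
    data.frame(trio_id = trio_id, phenotype = phenotype,
               callable_bp = callable_bp, stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame")
  )
}

#' Read a per-trio cohort table (trio_id, phenotype, callable_bp) from TSV
#' @param path TSV with header `trio_id`, `phenotype`, `callable_bp`.
#' @return a [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("trio_id", "phenotype", "callable_bp")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("schema error: required column(s) not found: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cohort_table(df$trio_id, df$phenotype,
               parse_numeric_column(df$callable_bp, "callable_bp"))
}

#' Write a cohort table as TSV
#' @param cohorts a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohorts, path) {
  utils::write.table(as.data.frame(cohorts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
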