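# Mutability-weighted permutation test of overlap between an observed de
# novo damaging mutation list and curated gene sets. Each permutation
# reassigns every mutation independently to a gene with probability
# proportional to its placement weight (by default the per-gene damaging
# mutation rate, which subsumes gene length and sequence context).

#' Closed-form expected overlap under weighted random placement
#'
#' @param weights named non-negative per-gene placement weights spanning
#'   the gene universe.
#' @param gene_set a [gene_set()] or character vector of symbols.
#' @param n_mutations number of mutations placed.
#' @return `n_mutations * sum(weights in set) / sum(weights)`.
#' @export
expected_overlap <- function(weights, gene_set, n_mutations) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  stopifnot(all(weights >= 0), sum(weights) > 0, n_mutations >= 0)
  in_set <- names(weights) %in% genes
  if (!any(in_set)) {
    warning("gene set has no overlap with the weighted universe",
            call. = FALSE)
    return(0)
  }
  n_mutations * sum(weights[in_set]) / sum(weights)
}

# Build the matrix of permuted gene indices (n_perm x n_mut), optionally
# with class-specific weights. `weights` is a named vector, or a named list
# of named vectors keyed by mutation class.
permute_placements <- function(mutation_genes, mutation_class, weights,
                               n_perm) {
  if (is.list(weights)) {
    universe <- names(weights[[1]])
    idx <- matrix(0L, n_perm, length(mutation_genes))
    for (cl in unique(mutation_class)) {
      if (is.null(weights[[cl]])) {
        stop("no placement weights supplied for class '", cl, "'",
             call. = FALSE)
      }
      w <- weights[[cl]]
      stopifnot(identical(names(w), universe))
      cols <- which(mutation_class == cl)
      cumw <- cumsum(w) / sum(w)
      idx[, cols] <- sample_cumw(cumw, n_perm * length(cols))
    }
  } else {
    universe <- names(weights)
    cumw <- cumsum(weights) / sum(weights)
    idx <- matrix(sample_cumw(cumw, n_perm * length(mutation_genes)),
                  nrow = n_perm)
  }
  attr(idx, "universe") <- universe
  idx
}

count_stat <- function(idx, set_mask, statistic) {
  if (statistic == "mutations") {
    hits <- matrix(set_mask[idx], nrow = nrow(idx))
    rowSums(hits)
  } else {
    set_ids <- which(set_mask)
    apply(idx, 1, function(r) length(unique(r[r %in% set_ids])))
  }
}

observed_stat <- function(mutation_genes, genes, statistic) {
  if (statistic == "mutations") {
    sum(mutation_genes %in% genes)
  } else {
    length(unique(mutation_genes[mutation_genes %in% genes]))
  }
}

#' Permutation gene-set enrichment of de novo mutations
#'
#' @param mutations data.frame with columns `gene` and optionally `class`,
#'   one row per de novo damaging mutation, or a bare character vector of
#'   gene symbols.
#' @param gene_set a [gene_set()].
#' @param weights named per-gene placement weights (default: use
#'   `mu_damaging` from a [rate_table()] passed here), or a named list of
#'   such vectors keyed by mutation class for class-specific placement.
#' @param n_perm number of permutations (>= 1000 recommended for reported
#'   p-values).
#' @param statistic `"mutations"` (count of permuted mutations landing in
#'   the set; default) or `"genes"` (count of distinct set genes hit).
#' @param seed RNG seed.
#' @return list with class `enrichment_result`: `set_name`, `n_mutations`,
#'   `observed`, `expected` (permutation mean), `expected_analytic`,
#'   `fold`, `p` (add-one estimator), `n_perm`, `seed`.
#' @export
permutation_enrichment <- function(mutations, gene_set, weights,
                                   n_perm = 10000,
                                   statistic = c("mutations", "genes"),
                                   seed = NULL) {
  statistic <- match.arg(statistic)
  if (inherits(weights, "rate_table")) {
    weights <- stats::setNames(weights$mu_damaging, weights$gene)
  }
  mut_genes <- if (is.data.frame(mutations)) mutations$gene else mutations
  mut_class <- if (is.data.frame(mutations) && !is.null(mutations$class)) {
    mutations$class
  } else rep("all", length(mut_genes))
  universe <- if (is.list(weights)) names(weights[[1]]) else names(weights)
  missing_genes <- setdiff(mut_genes, universe)
  if (length(missing_genes)) {
    stop("mutation gene(s) missing from the weighted universe: ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- permute_placements(mut_genes, mut_class, weights, n_perm)
    summarize_enrichment(idx, mut_genes, gene_set, weights, statistic,
                         seed)
  })
}

# Shared by permutation_enrichment and cross_disorder_scan.
summarize_enrichment <- function(idx, mut_genes, gene_set, weights,
                                 statistic, seed) {
  universe <- attr(idx, "universe")
  set_mask <- universe %in% gene_set$genes
  perm <- count_stat(idx, set_mask, statistic)
  obs <- observed_stat(mut_genes, gene_set$genes, statistic)
  expected <- mean(perm)
  w <- if (is.list(weights)) Reduce(`+`, weights) else weights
  expected_analytic <- expected_overlap(w, gene_set, length(mut_genes))
  structure(list(
    set_name = gene_set$name, n_mutations = length(mut_genes),
    observed = obs, expected = expected,
    expected_analytic = expected_analytic,
    fold = if (expected > 0) obs / expected else NA_real_,
    p = (1 + sum(perm >= obs)) / (length(perm) + 1),
    n_perm = length(perm), seed = seed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> %s: observed %d, expected %.2f, fold %.2f, p = %.4g\n",
    x$set_name, x$observed, x$expected, x$fold, x$p))
  invisible(x)
}

#' Scan several gene sets against one mutation list
#'
#' All sets share a single permutation stream (the mutation placements are
#' generated once), so results across sets are comparable and the scan is
#' deterministic given the seed. Nominal p-values are reported without
#' multiplicity correction.
#'
#' @inheritParams permutation_enrichment
#' @param sets list of [gene_set()]s.
#' @return data.frame with class `enrichment_table`, one row per set.
#' @export
cross_disorder_scan <- function(mutations, sets, weights, n_perm = 10000,
                                statistic = c("mutations", "genes"),
                                seed = NULL) {
  statistic <- match.arg(statistic)
  if (!length(sets)) {
    return(structure(data.frame(), class = c("enrichment_table",
                                             "data.frame")))
  }
  if (inherits(weights, "rate_table")) {
    weights <- stats::setNames(weights$mu_damaging, weights$gene)
  }
  mut_genes <- if (is.data.frame(mutations)) mutations$gene else mutations
  mut_class <- if (is.data.frame(mutations) && !is.null(mutations$class)) {
    mutations$class
  } else rep("all", length(mut_genes))
  universe <- if (is.list(weights)) names(weights[[1]]) else names(weights)
  missing_genes <- setdiff(mut_genes, universe)
  if (length(missing_genes)) {
    stop("mutation gene(s) missing from the weighted universe: ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         call. = FALSE)
  }
  res <- with_seed(seed, {
    idx <- permute_placements(mut_genes, mut_class, weights, n_perm)
    lapply(sets, function(s) {
      summarize_enrichment(idx, mut_genes, s, weights, statistic, seed)
    })
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(set_name = r$set_name, n_mutations = r$n_mutations,
               observed = r$observed, expected = r$expected,
               expected_analytic = r$expected_analytic, fold = r$fold,
               p = r$p, n_perm = r$n_perm, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
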