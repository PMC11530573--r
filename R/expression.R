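#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are ranked ascending,
#' each multiplied by `m / rank`, monotonicity enforced from the largest rank
#' down, capped at 1, and returned in the original order. A thin, validated
#' wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Genes linked to condition-specific regions
#'
#' Convenience accessor: the unique genes that fall in the `window_kb` window
#' of regions labelled specific to `condition` in a specificity call.
#'
#' @param labels Specificity tibble from [call_specificity()].
#' @param gene_links Window-gene tibble from [assign_window_genes()].
#' @param condition Condition whose specific regions to use.
#' @param window_kb Window size to use (must be present in `gene_links`).
#' @return Character vector of gene ids.
#' @export
linked_genes <- function(labels, gene_links, condition, window_kb = 400) {
  ids <- labels$region_id[labels$label == "specific" & labels$condition == condition]
  sort(unique(gene_links$gene_id[gene_links$region_id %in% ids &
                                   gene_links$window_kb == window_kb]))
}

#' Concordant target genes of cell-specific regions
#'
#' Integrates region specificity with differential expression: a window gene
#' of a region specific to the numerator condition of the comparison is kept
#' when its `log2fc >= +log2fc_threshold`; a gene of a denominator-specific
#' region when `log2fc <= -log2fc_threshold`; in both cases
#' `padj < padj_threshold` is required. Defaults follow the class-specific
#' fold-change thresholds (1.5 for enhancer-linked genes, 1.0 for
#' super-enhancer-linked genes) with BH-adjusted p < 0.05. The fold-change
#' gate is inclusive (`>=`), the padj gate strict (`<`).
#'
#' The DE table's `log2fc` must be oriented as numerator over denominator in
#' the order the specificity comparison was run (`A_vs_B`: positive log2fc =
#' higher in A). Genes linked by several specific regions are reported once.
#' Linked genes absent from the DE table are excluded and counted in the
#' `missing_genes` attribute.
#'
#' @param labels Specificity tibble from [call_specificity()].
#' @param gene_links Window-gene tibble from [assign_window_genes()] (for the
#'   matching regions: enhancers or stitched super-enhancers).
#' @param de DE tibble (`gene_id`, `log2fc`, `padj`; see [read_de_table()]).
#' @param region_class `"enhancer"` or `"SE"`; sets the default fold-change
#'   threshold.
#' @param window_kb Which gene window to integrate; default 400.
#' @param log2fc_threshold Absolute log2 fold-change threshold; default 1.5
#'   for enhancers, 1.0 for SEs.
#' @param padj_threshold Adjusted-p threshold (strict `<`); default 0.05.
#' @return Tibble `comparison`, `region_class`, `window_kb`, `condition`,
#'   `gene_id`, `log2fc`, `padj`, one row per retained gene per condition,
#'   ordered by condition, descending `|log2fc|`, then `gene_id`. Attribute
#'   `missing_genes`: linked genes absent from the DE table.
#' @export
concordant_genes <- function(labels, gene_links, de,
                             region_class = c("enhancer", "SE"),
                             window_kb = 400, log2fc_threshold = NULL,
                             padj_threshold = 0.05) {
  region_class <- match.arg(region_class)
  if (is.null(log2fc_threshold)) {
    log2fc_threshold <- if (region_class == "enhancer") 1.5 else 1.0
  }
  stopifnot(log2fc_threshold > 0, padj_threshold > 0)
  comparison <- unique(labels$comparison)
  stopifnot(length(comparison) == 1)
  conds <- strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
  stopifnot(length(conds) == 2)

  linked <- labels |>
    dplyr::filter(.data$label == "specific") |>
    dplyr::inner_join(gene_links[gene_links$window_kb == window_kb, ],
                      by = "region_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$condition, .data$gene_id)
  missing <- sort(setdiff(linked$gene_id, de$gene_id))
  out <- linked |>
    dplyr::inner_join(de[, c("gene_id", "log2fc", "padj")], by = "gene_id") |>
    dplyr::filter(
      !is.na(.data$log2fc), !is.na(.data$padj),
      .data$padj < padj_threshold,
      dplyr::if_else(.data$condition == conds[1],
                     .data$log2fc >= log2fc_threshold,
                     .data$log2fc <= -log2fc_threshold)
    ) |>
    dplyr::mutate(comparison = comparison, region_class = region_class,
                  window_kb = as.integer(window_kb)) |>
    dplyr::arrange(.data$condition, dplyr::desc(abs(.data$log2fc)), .data$gene_id) |>
    dplyr::select("comparison", "region_class", "window_kb", "condition",
                  "gene_id", "log2fc", "padj")
  attr(out, "missing_genes") <- missing
  out
}

rank_test_result <- function(ht, extra) {
  res <- c(list(
    statistic = unname(ht$statistic), p.value = ht$p.value,
    method = ht$method, alternative = ht$alternative
  ), extra)
  structure(res, class = "regland_ranktest")
}

#' @export
print.regland_ranktest <- function(x, ...) {
  cat(x$method, "\n")
  cat("statistic =", format(x$statistic), ", p =", format.pval(x$p.value), "\n")
  nums <- x[vapply(x, is.numeric, logical(1))]
  nums <- nums[setdiff(names(nums), c("statistic", "p.value"))]
  for (nm in names(nums)) cat(nm, "=", format(nums[[nm]]), "\n")
  invisible(x)
}

# exact Wilcoxon path only when both groups are small and rank ties are absent
use_exact <- function(x, y, n_exact = 8) {
  length(x) <= n_exact && length(y) <= n_exact && !any(duplicated(c(x, y)))
}

#' Expression of region-linked genes versus the rest of the genome
#'
#' One-sided two-sample Wilcoxon rank-sum test comparing the within-condition
#' mean normalized expression of region-linked genes against all remaining
#' genes. The exact null distribution is used when both groups have at most 8
#' genes (and no ties); otherwise the normal approximation with continuity
#' correction.
#'
#' @param expr Long expression tibble (`gene_id`, `sample_id`, `condition`,
#'   `expr`; see [read_expression()]).
#' @param region_genes Character vector of gene ids linked to the regions of
#'   interest (e.g. from [linked_genes()]).
#' @param condition Condition whose samples to average within.
#' @param alternative `"greater"` (default: linked genes more expressed) or
#'   `"two.sided"`/`"less"`.
#' @return A `regland_ranktest`: statistic, p-value, group medians and sizes.
#'   Use [generics::tidy()] / [generics::glance()] for a tibble.
#' @export
near_vs_global_expression <- function(expr, region_genes, condition,
                                      alternative = "greater") {
  stopifnot(length(region_genes) > 0)
  means <- expr |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_expr = mean(.data$expr), .groups = "drop")
  x <- means$mean_expr[means$gene_id %in% region_genes]
  y <- means$mean_expr[!means$gene_id %in% region_genes]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("need at least 2 genes in each group")
  }
  ht <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = use_exact(x, y), correct = TRUE)
  rank_test_result(ht, list(
    median_region = stats::median(x), median_global = stats::median(y),
    n_region = length(x), n_global = length(y), condition = condition
  ))
}

#' Linked-gene expression in the matching versus the other condition
#'
#' Paired one-sided Wilcoxon signed-rank test of per-gene mean normalized
#' expression in condition A minus condition B, over the genes linked to
#' A-specific regions: validates that cell-specific regulatory regions sit
#' near genes more expressed in their own cell population.
#'
#' @inheritParams near_vs_global_expression
#' @param cond_a Condition the regions are specific to (expected higher).
#' @param cond_b The other condition of the comparison.
#' @return A `regland_ranktest` with the median paired difference.
#' @export
cross_population_validation <- function(expr, region_genes, cond_a, cond_b,
                                        alternative = "greater") {
  means <- expr |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b),
                  .data$gene_id %in% region_genes) |>
    dplyr::group_by(.data$gene_id, .data$condition) |>
    dplyr::summarise(mean_expr = mean(.data$expr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_expr") |>
    tidyr::drop_na()
  if (nrow(means) < 2) {
    rlang::abort("need at least 2 linked genes with expression in both conditions")
  }
  xa <- means[[cond_a]]; xb <- means[[cond_b]]
  d <- xa - xb
  # the exact signed-rank null requires no zero and no tied |differences|
  exact <- length(d) <= 8 && all(d != 0) && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(xa, xb, paired = TRUE, alternative = alternative,
                       exact = exact, correct = TRUE))
  rank_test_result(ht, list(
    median_diff = stats::median(xa - xb), n_genes = nrow(means),
    cond_a = cond_a, cond_b = cond_b
  ))
}

#' @exportS3Method generics::tidy
tidy.regland_ranktest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p.value,
    median_region = x$median_region %||% NA_real_,
    median_global = x$median_global %||% NA_real_,
    median_diff = x$median_diff %||% NA_real_,
    method = x$method, alternative = x$alternative
  )
}

#' @exportS3Method generics::glance
glance.regland_ranktest <- function(x, ...) tidy.regland_ranktest(x)

#' Export concordant gene lists for downstream enrichment tools
#'
#' Writes one ranked TSV (`gene_id`, `log2fc`, `padj`) and one plain-text
#' gene-id list per (comparison, class, window, condition) set, ordered by
#' descending `|log2fc|` then `gene_id` so output is stable across runs.
#' Duplicate genes within a set are written once.
#'
#' @param gene_sets Tibble from [concordant_genes()] (several may be
#'   row-bound).
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_gene_lists <- function(gene_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- gene_sets |>
    dplyr::distinct(.data$comparison, .data$region_class,
                    .data$window_kb, .data$condition)
  written <- character(0)
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- gene_sets |>
      dplyr::semi_join(k, by = names(k)) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
      dplyr::arrange(dplyr::desc(abs(.data$log2fc)), .data$gene_id)
    stem <- paste0("concordant_", k$region_class, "_", k$comparison, "_",
                   k$condition, "_", k$window_kb, "kb")
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    txt <- file.path(dir, paste0(stem, ".txt"))
    readr::write_tsv(sub[, c("gene_id", "log2fc", "padj")], tsv, progress = FALSE)
    writeLines(sub$gene_id, txt)
    written <- c(written, tsv, txt)
  }
  if (nrow(keys) == 0) {
    empty <- gene_sets[0, c("gene_id", "log2fc", "padj")]
    tsv <- file.path(dir, "concordant_empty.tsv")
    readr::write_tsv(empty, tsv, progress = FALSE)
    written <- tsv
  }
  invisible(written)
}
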