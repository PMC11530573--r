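#' Score a pipeline run against the planted ground truth
#'
#' For a simulated landscape and the pipeline result computed from it,
#' measures how much of the planted structure the workflow recovered:
#'
#' * `specific_recovery` — fraction of planted condition-specific enhancer
#'   regions overlapped by a consensus region labelled specific to the same
#'   condition;
#' * `se_recovery` — fraction of (planted super-enhancer-flagged region,
#'   condition-where-present) pairs overlapped by a called super-enhancer in
#'   that condition;
#' * `link_recovery` — fraction of planted region-to-gene links whose gene
#'   appears among the enhancer-class concordant genes of the matching
#'   condition;
#' * `cross_population_p` — the enhancer-class cross-population validation
#'   p-values, one per condition.
#'
#' @param sim A [simulate_landscape()] result.
#' @param result The [run_pipeline()] result computed from `sim`'s data.
#' @return A list with the four elements above.
#' @export
evaluate_recovery <- function(sim, result) {
  truth <- sim$truth
  conds <- sim$config$conditions
  overlaps_any <- function(tr_row, tab) {
    any(tab$chrom == tr_row$chrom & tab$start < tr_row$end & tab$end > tr_row$start)
  }

  lab <- dplyr::left_join(result$specificity,
                          result$regions[, c("region_id", "chrom", "start", "end")],
                          by = "region_id")
  spec_tr <- truth$regions[truth$regions$specificity %in% conds, ]
  specific_recovery <- if (nrow(spec_tr) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(spec_tr)), function(i) {
      overlaps_any(spec_tr[i, ],
                   lab[lab$class == "enhancer" & lab$label == "specific" &
                         lab$condition == spec_tr$specificity[i], ])
    }, logical(1)))
  }

  se_tr <- truth$regions[truth$regions$is_se, ]
  sup <- result$se_calls[result$se_calls$is_super, ]
  se_pairs <- purrr::map_dfr(seq_len(nrow(se_tr)), function(i) {
    cs <- if (se_tr$specificity[i] == "shared") conds else se_tr$specificity[i]
    tibble::tibble(i = i, condition = cs)
  })
  se_recovery <- if (nrow(se_pairs) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(se_pairs)), function(k) {
      overlaps_any(se_tr[se_pairs$i[k], ],
                   sup[sup$condition == se_pairs$condition[k], ])
    }, logical(1)))
  }

  links <- truth$links
  conc <- result$concordant[result$concordant$region_class == "enhancer", ]
  link_recovery <- if (nrow(links) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(links)), function(k) {
      any(conc$condition == links$condition[k] &
            conc$gene_id == links$gene_id[k])
    }, logical(1)))
  }

  cp <- result$validation[result$validation$test == "cross_population" &
                            result$validation$class == "enhancer", ]
  list(specific_recovery = specific_recovery,
       se_recovery = se_recovery,
       link_recovery = link_recovery,
       cross_population_p = stats::setNames(cp$p.value, cp$condition))
}
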