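#' Label regions as cell-specific or shared between two conditions
#'
#' A region is *shared* when some region of the other condition reciprocally
#' overlaps it: in the default `mode = "both"` the overlap must cover at least
#' `min_fraction` of BOTH intervals (the `bedtools intersect -f 0.3 -r`
#' reading of "reciprocal overlap"); `mode = "any"` relaxes this to either
#' direction. Regions with no such partner are *specific* to their own
#' condition. When a region overlaps several partners, each candidate pair is
#' evaluated on its own and the best pair (largest minimum of the two
#' fractions) decides and is recorded as the partner.
#'
#' @param regions_a,regions_b Classified region tibbles for the two
#'   conditions (columns `region_id`, `chrom`, `start`, `end`, `condition`);
#'   each set must be internally disjoint.
#' @param min_fraction Reciprocal-overlap fraction threshold in (0, 1\];
#'   overlap `>=` this fraction makes a pair shared. Default 0.3.
#' @param mode `"both"` (default) requires the fraction on both intervals,
#'   `"any"` on at least one.
#' @return Tibble with one row per input region (A rows first):
#'   `region_id`, `condition`, `comparison`, `label` (`"specific"` or
#'   `"shared"`), `partner_id`, `frac_self`, `frac_partner`.
#' @export
call_specificity <- function(regions_a, regions_b, min_fraction = 0.3,
                             mode = c("both", "any")) {
  mode <- match.arg(mode)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  for (nm in list(list(regions_a, "regions_a"), list(regions_b, "regions_b"))) {
    x <- nm[[1]]
    validate_intervals(x, nm[[2]])
    stopifnot(all(c("region_id", "condition") %in% names(x)))
    if (nrow(x) > 1 && !is_disjoint(x)) {
      rlang::abort(paste0(nm[[2]], ": regions within one set must be disjoint"))
    }
  }
  cond_a <- if (nrow(regions_a)) unique(regions_a$condition) else "A"
  cond_b <- if (nrow(regions_b)) unique(regions_b$condition) else "B"
  stopifnot(length(cond_a) == 1, length(cond_b) == 1)
  comparison <- paste0(cond_a, "_vs_", cond_b)

  pairs <- dplyr::inner_join(
    dplyr::rename(regions_a[, c("region_id", "chrom", "start", "end")],
                  id_a = "region_id", start_a = "start", end_a = "end"),
    dplyr::rename(regions_b[, c("region_id", "chrom", "start", "end")],
                  id_b = "region_id", start_b = "start", end_b = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      ov = pmax(0, pmin(.data$end_a, .data$end_b) - pmax(.data$start_a, .data$start_b)),
      frac_a = .data$ov / (.data$end_a - .data$start_a),
      frac_b = .data$ov / (.data$end_b - .data$start_b)
    ) |>
    dplyr::filter(.data$ov > 0) |>
    dplyr::mutate(score = if (mode == "both") pmin(.data$frac_a, .data$frac_b)
                  else pmax(.data$frac_a, .data$frac_b))

  best_for <- function(id_col, other_col, frac_self_col, frac_other_col) {
    if (nrow(pairs) == 0) {
      return(tibble::tibble(region_id = character(), partner_id = character(),
                            frac_self = double(), frac_partner = double(),
                            score = double()))
    }
    pairs |>
      dplyr::group_by(region_id = .data[[id_col]]) |>
      dplyr::arrange(dplyr::desc(.data$score), .data[[other_col]], .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$region_id, partner_id = .data[[other_col]],
                       frac_self = .data[[frac_self_col]],
                       frac_partner = .data[[frac_other_col]],
                       score = .data$score)
  }
  label_side <- function(regions, cond, best) {
    out <- dplyr::left_join(regions[, "region_id", drop = FALSE], best, by = "region_id")
    shared <- !is.na(out$score) & out$score >= min_fraction
    tibble::tibble(
      region_id = out$region_id,
      condition = rep(cond, nrow(out)),
      comparison = rep(comparison, nrow(out)),
      label = as.character(ifelse(shared, "shared", "specific")),
      partner_id = as.character(ifelse(shared, out$partner_id, NA_character_)),
      frac_self = as.numeric(ifelse(is.na(out$frac_self), 0, out$frac_self)),
      frac_partner = as.numeric(ifelse(is.na(out$frac_partner), 0, out$frac_partner))
    )
  }
  dplyr::bind_rows(
    label_side(regions_a, cond_a, best_for("id_a", "id_b", "frac_a", "frac_b")),
    label_side(regions_b, cond_b, best_for("id_b", "id_a", "frac_b", "frac_a"))
  )
}
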