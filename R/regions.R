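#' Build replicate-consensus regions for one condition
#'
#' Merges all replicate peaks of a condition into connected components
#' (gap 0: overlapping or abutting peaks join) and keeps components supported
#' by at least `min_replicates` distinct replicates. Support is evaluated on
#' the merged component as a whole — a chain rep1/rep2/rep3 counts every
#' replicate touching the chain even where single bases are covered by only
#' one replicate. The aggregated `net_signal` is the sum of the
#' input-subtracted signals of all contributing peaks.
#'
#' @param peaks Peak tibble (see [read_peaks()]); all rows must share one
#'   condition.
#' @param condition Optional condition label to assert against the peaks.
#' @param min_replicates Minimum number of distinct replicates (`>= 1`) that
#'   must contribute a peak for a region to be kept. Default 2.
#' @return Tibble of consensus regions: `region_id`, `chrom`, `start`, `end`,
#'   `condition`, `support`, `net_signal`, sorted and pairwise disjoint.
#' @export
consensus_regions <- function(peaks, condition = NULL, min_replicates = 2) {
  stopifnot(min_replicates >= 1)
  validate_intervals(peaks, "peaks")
  stopifnot(all(c("replicate_id", "condition", "net_signal") %in% names(peaks)))
  conds <- unique(peaks$condition)
  if (length(conds) > 1) {
    rlang::abort(paste0("peaks mix conditions: ", paste(conds, collapse = ", ")))
  }
  if (!is.null(condition) && length(conds) == 1 && conds != condition) {
    rlang::abort(paste0("peaks are labelled '", conds, "', not '", condition, "'"))
  }
  cond <- if (length(conds) == 1) conds else condition
  if (nrow(peaks) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          condition = character(), support = integer(),
                          net_signal = double()))
  }
  peaks$.cluster <- interval_cluster(peaks, gap = 0)
  out <- peaks |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      support = dplyr::n_distinct(.data$replicate_id),
      net_signal = sum(.data$net_signal),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$support >= min_replicates) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      condition = cond,
      region_id = paste0(cond, ":", .data$chrom, ":", .data$start, "-", .data$end)
    ) |>
    dplyr::select("region_id", "chrom", "start", "end", "condition",
                  "support", "net_signal")
  out
}

#' Nearest TSS for each region centre
#'
#' For each region, finds the annotated TSS on the same chromosome nearest to
#' the region centre (`floor((start + end) / 2)`). Ties in distance are broken
#' by the lexicographically smallest `gene_id` so the result is deterministic.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param tss TSS tibble (see [read_tss()]).
#' @return Tibble aligned with `regions`: `nearest_gene` (NA when the
#'   chromosome has no TSS) and `dist_tss` (absolute bp distance, NA likewise).
#' @export
annotate_nearest_tss <- function(regions, tss) {
  validate_intervals(regions, "regions")
  tss <- validate_tss(tss)
  n <- nrow(regions)
  out <- tibble::tibble(nearest_gene = rep(NA_character_, n),
                        dist_tss = rep(NA_real_, n))
  if (n == 0 || nrow(tss) == 0) return(out)
  centre <- floor((regions$start + regions$end) / 2)
  # collapse TSS records sharing a position to the lexicographically smallest
  # gene id: any distance tie within a position resolves to that gene anyway
  by_pos <- tss |>
    dplyr::group_by(.data$chrom, .data$tss) |>
    dplyr::summarise(gene_id = min(.data$gene_id), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$tss)
  for (c in unique(regions$chrom)) {
    idx <- which(regions$chrom == c)
    tc <- by_pos[by_pos$chrom == c, ]
    if (nrow(tc) == 0) next
    pos <- tc$tss
    i <- findInterval(centre[idx], pos)
    left_ok <- i >= 1
    right_ok <- i < length(pos)
    d_left <- ifelse(left_ok, centre[idx] - pos[pmax(i, 1)], Inf)
    d_right <- ifelse(right_ok, pos[pmin(i + 1, length(pos))] - centre[idx], Inf)
    g_left <- ifelse(left_ok, tc$gene_id[pmax(i, 1)], NA_character_)
    g_right <- ifelse(right_ok, tc$gene_id[pmin(i + 1, length(pos))], NA_character_)
    take_left <- d_left < d_right |
      (d_left == d_right & !is.na(g_left) & !is.na(g_right) & g_left <= g_right)
    out$nearest_gene[idx] <- ifelse(take_left, g_left, g_right)
    out$dist_tss[idx] <- ifelse(take_left, d_left, d_right)
  }
  out
}

#' Classify consensus regions as promoters or enhancers
#'
#' A region is a promoter when its centre lies strictly within
#' `promoter_dist` bp of the nearest TSS on the same chromosome, an enhancer
#' otherwise (the centre-to-TSS distance exactly equal to `promoter_dist`
#' counts as enhancer, matching the strict "< 2 kb" / "> 2 kb" convention).
#' Promoters are annotated to the gene whose TSS is nearest their centre.
#' Regions on chromosomes with no annotated TSS are classified as enhancers
#' and flagged.
#'
#' @param regions Consensus-region tibble (see [consensus_regions()]).
#' @param tss TSS tibble.
#' @param promoter_dist Promoter distance threshold in bp; default 2000.
#' @return `regions` with added columns `class` (`"promoter"`/`"enhancer"`),
#'   `anchor_gene` (promoters only, else NA), `dist_tss`, and `no_tss_chrom`.
#' @export
classify_regions <- function(regions, tss, promoter_dist = 2000) {
  tss <- validate_tss(tss)
  if (nrow(tss) == 0) rlang::abort("TSS annotation is empty")
  nearest <- annotate_nearest_tss(regions, tss)
  regions |>
    dplyr::mutate(
      dist_tss = nearest$dist_tss,
      no_tss_chrom = is.na(nearest$dist_tss),
      class = dplyr::if_else(!is.na(nearest$dist_tss) & nearest$dist_tss < promoter_dist,
                             "promoter", "enhancer"),
      anchor_gene = dplyr::if_else(.data$class == "promoter",
                                   nearest$nearest_gene, NA_character_)
    )
}

#' Genes whose TSS falls in windows around regions
#'
#' For each region (typically an enhancer or stitched super-enhancer) and
#' each window size, returns the genes whose TSS lies within
#' `[start - window_kb * 1000, end + window_kb * 1000)` on the same
#' chromosome — the linear-proximity candidate target genes. The lower bound
#' is closed, the upper open, mirroring half-open coordinates. Gene sets are
#' nested across windows: every 100 kb gene is also a 200 kb and 400 kb gene.
#'
#' @param regions Data frame with `region_id`, `chrom`, `start`, `end`.
#' @param tss TSS tibble.
#' @param windows_kb Integer vector of window sizes in kb; default
#'   `c(100, 200, 400)`.
#' @return Tibble `region_id`, `window_kb`, `gene_id`, `distance` (bp from
#'   TSS to the nearest region boundary, 0 inside the region), ordered by
#'   region, window, then increasing distance.
#' @export
assign_window_genes <- function(regions, tss, windows_kb = c(100, 200, 400)) {
  validate_intervals(regions, "regions")
  stopifnot("region_id" %in% names(regions), all(windows_kb > 0))
  tss <- validate_tss(tss)
  empty <- tibble::tibble(region_id = character(), window_kb = integer(),
                          gene_id = character(), distance = integer())
  if (nrow(regions) == 0 || nrow(tss) == 0) return(empty)
  wmax <- max(windows_kb) * 1000
  pairs <- dplyr::inner_join(
    regions[, c("region_id", "chrom", "start", "end")],
    tss[, c("gene_id", "chrom", "tss")],
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = pmax(.data$start - .data$tss,
                                  .data$tss - (.data$end - 1L), 0L)) |>
    dplyr::filter(.data$distance <= wmax)
  if (nrow(pairs) == 0) return(empty)
  # duplicated gene_ids (one record per transcript) collapse to the nearest TSS
  pairs <- pairs |>
    dplyr::group_by(.data$region_id, .data$gene_id) |>
    dplyr::summarise(distance = min(.data$distance), .groups = "drop")
  purrr::map_dfr(sort(windows_kb), function(w) {
    pairs |>
      dplyr::filter(.data$distance <= w * 1000) |>
      dplyr::mutate(window_kb = as.integer(w))
  }) |>
    dplyr::arrange(.data$region_id, .data$window_kb, .data$distance, .data$gene_id) |>
    dplyr::select("region_id", "window_kb", "gene_id", "distance")
}
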