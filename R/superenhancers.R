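#' Drop enhancers wholly inside a TSS exclusion zone
#'
#' Before stitching, enhancers wholly contained in a window of
#' `half_window` bp on each side of any annotated TSS are removed — a
#' promoter exclusion zone of `2 * half_window` bp in total. Enhancers that
#' only partially overlap the zone are retained.
#'
#' @param enhancers Region tibble (`region_id`, `chrom`, `start`, `end`, ...).
#' @param tss TSS tibble.
#' @param half_window Half-width of the exclusion zone in bp; default 2500
#'   (a 5000 bp promoter exclusion zone).
#' @return `enhancers` without the wholly-contained rows.
#' @export
exclude_promoter_proximal <- function(enhancers, tss, half_window = 2500) {
  stopifnot(half_window >= 0)
  validate_intervals(enhancers, "enhancers")
  tss <- validate_tss(tss)
  if (nrow(enhancers) == 0 || nrow(tss) == 0) return(enhancers)
  contained <- dplyr::inner_join(
    enhancers[, c("region_id", "chrom", "start", "end")],
    tss[, c("chrom", "tss")],
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start >= .data$tss - half_window,
                  .data$end <= .data$tss + half_window) |>
    dplyr::pull("region_id") |>
    unique()
  enhancers[!enhancers$region_id %in% contained, ]
}

#' Stitch enhancers into clusters
#'
#' Enhancers separated by at most `distance` bp (boundary to boundary) are
#' merged into one stitched enhancer whose interval spans its constituents
#' and whose signal is the sum of constituent input-subtracted signals.
#' Idempotent and independent of input row order.
#'
#' @param enhancers Region tibble with `region_id`, `chrom`, `start`, `end`,
#'   `net_signal` (and optionally `condition`); internally disjoint.
#' @param distance Maximum stitching gap in bp; default 12500.
#' @return Tibble of stitched enhancers: `region_id` (new, `SE:`-prefixed),
#'   `chrom`, `start`, `end`, `condition` (if present), `n_constituents`,
#'   `constituents` (list column of input region ids), `net_signal`.
#' @export
stitch_enhancers <- function(enhancers, distance = 12500) {
  stopifnot(distance >= 0)
  validate_intervals(enhancers, "enhancers")
  stopifnot(all(c("region_id", "net_signal") %in% names(enhancers)))
  if (nrow(enhancers) > 1 && !is_disjoint(enhancers)) {
    rlang::abort("enhancers must be internally disjoint before stitching")
  }
  cond <- if ("condition" %in% names(enhancers) && nrow(enhancers) > 0) {
    unique(enhancers$condition)
  } else NA_character_
  stopifnot(length(cond) == 1)
  if (nrow(enhancers) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          condition = character(), n_constituents = integer(),
                          constituents = list(), net_signal = double()))
  }
  enhancers$.cluster <- interval_cluster(enhancers, gap = distance)
  enhancers |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_constituents = dplyr::n(),
      constituents = list(sort(.data$region_id)),
      net_signal = sum(.data$net_signal),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      condition = cond,
      region_id = paste0("SE:", .data$chrom, ":", .data$start, "-", .data$end)
    ) |>
    dplyr::select("region_id", "chrom", "start", "end", "condition",
                  "n_constituents", "constituents", "net_signal")
}

#' Separate super-enhancers from typical enhancers
#'
#' Stitched enhancers are ranked by ascending input-subtracted signal and
#' both rank and signal are scaled to \[0, 1\]. On the convex "hockey-stick"
#' curve this produces, the cutoff is the point where the tangent to the
#' curve has slope 1 — found, parameter-free, as the point lying furthest
#' below the diagonal (the maximum of `scaled_rank - scaled_signal`; ties go
#' to the higher-signal point, a conservative cutoff). Every stitched
#' enhancer whose signal is strictly above the signal at the cutoff point is
#' a super-enhancer, so super-enhancers occupy the top ranks contiguously.
#'
#' With fewer than 3 stitched enhancers, or when all signals are identical
#' (a flat curve has no slope-1 tangent), no super-enhancers are called.
#'
#' @param stitched Stitched-enhancer tibble (see [stitch_enhancers()]); any
#'   region tibble with `region_id` and `net_signal` works.
#' @return The input with added columns `rank` (1-based, ascending signal;
#'   signal ties broken by `(chrom, start)`), `scaled_rank` (`rank / n`),
#'   `scaled_signal`, `is_super`, `cutoff_signal` (unscaled signal at the
#'   cutoff), ordered by rank. Class `"regland_se"` for [autoplot()].
#' @examples
#' x <- tibble::tibble(
#'   region_id = paste0("e", 1:5), chrom = "chr1",
#'   start = seq(0, 4e5, 1e5), end = seq(0, 4e5, 1e5) + 1000,
#'   net_signal = c(1, 1, 1, 1, 10)
#' )
#' call_superenhancers(x) # only the signal-10 element is a super-enhancer
#' @export
call_superenhancers <- function(stitched) {
  validate_intervals(stitched, "stitched")
  stopifnot(all(c("region_id", "net_signal") %in% names(stitched)))
  stopifnot(all(stitched$net_signal >= 0))
  n <- nrow(stitched)
  out <- stitched |>
    dplyr::arrange(.data$net_signal, .data$chrom, .data$start) |>
    dplyr::mutate(rank = dplyr::row_number(), scaled_rank = .data$rank / n)
  if (n == 0) {
    out$scaled_signal <- double(0); out$is_super <- logical(0)
    out$cutoff_signal <- double(0)
    return(structure(out, class = c("regland_se", class(out))))
  }
  smin <- min(out$net_signal); smax <- max(out$net_signal)
  degenerate <- n < 3 || smax == smin
  if (n < 3) rlang::warn("fewer than 3 stitched enhancers: all called typical")
  if (degenerate) {
    out$scaled_signal <- if (smax == smin) rep(0, n) else
      (out$net_signal - smin) / (smax - smin)
    out$cutoff_signal <- smax
    out$is_super <- FALSE
    return(structure(out, class = c("regland_se", class(out))))
  }
  out$scaled_signal <- (out$net_signal - smin) / (smax - smin)
  below <- out$scaled_rank - out$scaled_signal
  cutoff_idx <- max(which(below == max(below)))
  out$cutoff_signal <- out$net_signal[cutoff_idx]
  out$is_super <- out$net_signal > out$cutoff_signal
  structure(out, class = c("regland_se", class(out)))
}

#' Hockey-stick plot of ranked enhancer signal
#'
#' Rank versus input-subtracted signal for a set of super-enhancer calls,
#' with the cutoff signal as a horizontal reference line and super-enhancers
#' highlighted.
#'
#' @param object A `regland_se` tibble from [call_superenhancers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regland_se <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$net_signal,
                                       colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = unique(object$cutoff_signal),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 name = "super-enhancer") +
    ggplot2::labs(x = "enhancer rank (ascending signal)",
                  y = "input-subtracted H3K27ac signal") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.regland_se
#' @param se_calls A `regland_se` tibble.
#' @export
plot_se_curve <- function(se_calls) autoplot.regland_se(se_calls)
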