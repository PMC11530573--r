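#' Validate a table of genomic intervals
#'
#' Checks the invariants every interval table in the package relies on:
#' `chrom` is character, coordinates are non-negative integers in the 0-based
#' half-open convention, and `end > start` row-wise.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly, with `start`/`end` coerced to integer (or double
#'   when they exceed integer range).
#' @keywords internal
validate_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(what, " is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    rlang::abort(paste0(what, ": non-finite coordinates"))
  }
  if (any(x$start < 0)) {
    rlang::abort(paste0(what, ": negative start coordinate (0-based half-open expected)"))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      what, ": end <= start on row(s) ", paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) " ..." else ""
    ))
  }
  invisible(x)
}

#' Pairwise overlap length between intervals
#'
#' Intervals are 0-based half-open, so abutting intervals (`a$end == b$start`)
#' overlap by 0. The two tables are recycled row-wise like arithmetic vectors.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (one row each, or
#'   equal-length / length-1 recycling).
#' @return Integer vector of overlap lengths in base pairs; 0 for intervals on
#'   different chromosomes.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_length(a, b) # 50
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(integer(0))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov[a$chrom[ai] != b$chrom[bi]] <- 0L
  as.integer(pmax(ov, 0))
}

#' Reciprocal overlap fractions between two interval sets
#'
#' For each row pair, the overlap length expressed as a fraction of each
#' interval's own length — the quantity a `bedtools intersect -f ... -r`
#' comparison thresholds when deciding whether two regions are "the same"
#' region in two conditions.
#'
#' @inheritParams overlap_length
#' @return A tibble with columns `frac_a`, `frac_b`, both in \[0, 1\].
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 90, end = 200)
#' reciprocal_overlap(a, b) # 0.10 and 0.0909...
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- overlap_length(a, b)
  n <- length(ov)
  ai <- rep_len(seq_len(max(nrow(a), 1L)), n); bi <- rep_len(seq_len(max(nrow(b), 1L)), n)
  tibble::tibble(
    frac_a = ov / (a$end[ai] - a$start[ai]),
    frac_b = ov / (b$end[bi] - b$start[bi])
  )
}

# Assign a cluster id to every interval such that intervals whose gap
# (start2 - end1 on the sorted sequence) is <= gap share a cluster.
# Row order of the input is preserved in the output column.
interval_cluster <- function(x, gap = 0) {
  validate_intervals(x)
  stopifnot(gap >= 0)
  if (nrow(x) == 0) return(integer(0))
  ord <- order(x$chrom, x$start, x$end)
  xs <- x[ord, ]
  new_cluster <- logical(nrow(xs))
  new_cluster[1] <- TRUE
  if (nrow(xs) > 1) {
    run_end <- xs$end # running max end within the current cluster
    for (i in 2:nrow(xs)) {
      if (xs$chrom[i] != xs$chrom[i - 1]) {
        new_cluster[i] <- TRUE
      } else {
        new_cluster[i] <- xs$start[i] > run_end[i - 1] + gap
        if (!new_cluster[i]) run_end[i] <- max(run_end[i], run_end[i - 1])
      }
    }
  }
  cl_sorted <- cumsum(new_cluster)
  cl <- integer(nrow(x))
  cl[ord] <- cl_sorted
  cl
}

# TRUE when no two intervals in x overlap (abutting is fine: half-open)
is_disjoint <- function(x) {
  if (nrow(x) < 2) return(TRUE)
  ord <- order(x$chrom, x$start, x$end)
  xs <- x[ord, ]
  ok <- TRUE
  for (c in unique(xs$chrom)) {
    sub <- xs[xs$chrom == c, ]
    if (nrow(sub) > 1 &&
        any(sub$start[-1] < cummax(sub$end)[-nrow(sub)])) ok <- FALSE
  }
  ok
}

#' Merge genomic intervals within a gap distance
#'
#' Connected-component merge under the rule "two intervals belong together if
#' the distance between them (`start2 - end1` on the sorted sequence) is at
#' most `gap`". With `gap = 0` only overlapping or abutting intervals merge.
#' This is the primitive behind both replicate-consensus region building
#' (gap 0) and ROSE-style enhancer stitching (gap 12,500 bp).
#'
#' The result is sorted, pairwise separated by more than `gap`, idempotent
#' under re-application, and independent of input row order.
#'
#' @param x Data frame with `chrom`, `start`, `end`.
#' @param gap Maximum separating distance in bp (`>= 0`) for two intervals to
#'   be merged.
#' @return Tibble with `chrom`, `start`, `end`, and `n_constituents`, the
#'   number of input intervals contained in each merged interval.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0, 150), end = c(100, 250))
#' merge_intervals(x, gap = 50)  # one interval [0, 250)
#' merge_intervals(x, gap = 49)  # unchanged
#' @export
merge_intervals <- function(x, gap = 0) {
  cl <- interval_cluster(x, gap)
  if (length(cl) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_constituents = integer()))
  }
  x |>
    dplyr::mutate(.cluster = cl) |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_constituents = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "n_constituents")
}

#' Input-subtracted signal
#'
#' IP read density minus matched input (control) density, floored at zero:
#' densities below control noise carry no evidence of an active region.
#'
#' @param ip_signal,input_signal Numeric vectors, both `>= 0`.
#' @return Numeric vector `pmax(ip_signal - input_signal, 0)`.
#' @export
net_signal <- function(ip_signal, input_signal) {
  stopifnot(all(ip_signal >= 0), all(input_signal >= 0))
  pmax(ip_signal - input_signal, 0)
}
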