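#' Read a BED5+ peak file
#'
#' Peak files are header-less, tab-separated, BED-like: `chrom`, `start`,
#' `end`, `ip_signal`, `input_signal`, and optionally `replicate_id` as a
#' sixth column. Coordinates must already be 0-based half-open (the BED
#' convention); signals are per-peak read densities summarised upstream of
#' this package.
#'
#' @param path Path to a tab-separated peak file.
#' @param condition Condition (cell population) label attached to every peak.
#' @param replicate_id Replicate label; required when the file has no sixth
#'   column, ignored (with a warning) when it has one.
#' @return A tibble of peaks sorted by `(chrom, start, end)` with columns
#'   `chrom`, `start`, `end`, `ip_signal`, `input_signal`, `replicate_id`,
#'   `condition`, `net_signal` (input-subtracted, floored at 0).
#' @seealso [write_peaks()] for the inverse, [net_signal()].
#' @export
read_peaks <- function(path, condition, replicate_id = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("peak file not found: ", path))
  raw <- readr::read_tsv(
    path, col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "#"
  )
  if (nrow(raw) == 0) {
    rlang::warn(paste0("empty peak file: ", path))
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      ip_signal = double(), input_signal = double(),
      replicate_id = character(), condition = character(), net_signal = double()
    ))
  }
  if (ncol(raw) < 5) {
    rlang::abort(paste0(path, ": expected >= 5 tab-separated columns ",
                        "(chrom, start, end, ip_signal, input_signal), got ", ncol(raw)))
  }
  parse_num <- function(col, name) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out) & !is.na(col))
    if (length(bad) > 0) {
      rlang::abort(paste0(path, ": non-numeric ", name, " on line(s) ",
                          paste(utils::head(bad, 5), collapse = ", ")))
    }
    out
  }
  peaks <- tibble::tibble(
    chrom = raw[[1]],
    start = parse_num(raw[[2]], "start"),
    end = parse_num(raw[[3]], "end"),
    ip_signal = parse_num(raw[[4]], "ip_signal"),
    input_signal = parse_num(raw[[5]], "input_signal")
  )
  if (ncol(raw) >= 6) {
    if (!is.null(replicate_id)) {
      rlang::warn(paste0(path, ": replicate_id column present in file; ",
                         "ignoring the replicate_id argument"))
    }
    peaks$replicate_id <- raw[[6]]
  } else {
    if (is.null(replicate_id)) {
      rlang::abort(paste0(path, ": no replicate_id column; pass replicate_id="))
    }
    peaks$replicate_id <- replicate_id
  }
  bad <- which(peaks$start < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0(path, ": negative start on line(s) ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(peaks$end <= peaks$start)
  if (length(bad) > 0) {
    rlang::abort(paste0(path, ": end <= start on line(s) ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(peaks$ip_signal < 0) || any(peaks$input_signal < 0)) {
    rlang::abort(paste0(path, ": negative signal values"))
  }
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  peaks$condition <- condition
  peaks$net_signal <- net_signal(peaks$ip_signal, peaks$input_signal)
  dplyr::arrange(peaks, .data$chrom, .data$start, .data$end)
}

#' Write peaks back to a BED5+ file
#'
#' Writes the six columns [read_peaks()] consumes, so read/write round-trips
#' are the identity on well-formed records.
#'
#' @param peaks A peak tibble as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  validate_intervals(peaks, "peaks")
  out <- peaks[, c("chrom", "start", "end", "ip_signal", "input_signal", "replicate_id")]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' A tab-separated file with header columns `gene_id`, `chrom`, `tss`,
#' `strand`. `tss` is a 0-based position; `strand` is `+` or `-`. Gene ids
#' must be unique. For interval-style gene annotations use
#' [tss_from_features()] first.
#'
#' @param path Path to the TSV.
#' @return Tibble with `gene_id`, `chrom`, `tss` (integer), `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("TSS file not found: ", path))
  tss <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_double(), strand = readr::col_character()
  ), progress = FALSE)
  validate_tss(tss)
}

validate_tss <- function(tss) {
  missing_cols <- setdiff(c("gene_id", "chrom", "tss", "strand"), names(tss))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("TSS table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(tss$tss < 0)) rlang::abort("TSS table: negative positions")
  if (!all(tss$strand %in% c("+", "-"))) rlang::abort("TSS table: strand must be + or -")
  tss$tss <- as.integer(tss$tss)
  tibble::as_tibble(tss)
}

#' Derive TSS positions from gene feature intervals
#'
#' For GTF-style gene records (half-open `start`/`end` with strand), the TSS
#' is `start` for `+`-strand genes and `end - 1` for `-`-strand genes.
#' Duplicate `gene_id`s (e.g. one record per transcript) are kept; downstream
#' nearest-TSS logic collapses them to the nearest record.
#'
#' @param features Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
tss_from_features <- function(features) {
  validate_intervals(features, "features")
  stopifnot(all(c("gene_id", "strand") %in% names(features)))
  tibble::tibble(
    gene_id = features$gene_id,
    chrom = features$chrom,
    tss = as.integer(ifelse(features$strand == "+", features$start, features$end - 1L)),
    strand = features$strand
  )
}

#' Read a differential-expression table
#'
#' Expects header columns `gene_id`, `log2fc`, `pvalue`, and optionally
#' `padj`. When `padj` is absent it is recomputed from the raw p-values with
#' [bh_adjust()].
#'
#' @param path Path to the TSV.
#' @return Tibble with `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("DE table not found: ", path))
  de <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("gene_id", "log2fc", "pvalue"), names(de))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("DE table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"padj" %in% names(de)) de$padj <- bh_adjust(de$pvalue)
  tibble::as_tibble(de[, c("gene_id", "log2fc", "pvalue", "padj")])
}

#' Read a long-format normalized expression table
#'
#' Header columns `gene_id`, `sample_id`, `condition`, `expr`. Values are
#' assumed already normalized (e.g. a regularised-log transform); this
#' package performs no count normalization.
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per gene x sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("expression table not found: ", path))
  expr <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), sample_id = readr::col_character(),
    condition = readr::col_character(), expr = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("gene_id", "sample_id", "condition", "expr"), names(expr))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("expression table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(expr$expr))) rlang::abort("expression table: non-finite values")
  expr
}
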