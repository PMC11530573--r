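#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable parameter of the workflow with its default, plus
#' the inputs, into one validated object. Inputs can be given as file paths
#' (`peak_files`: a named list, one character vector of BED5+ files per
#' condition; `tss_file`, `de_file`, `expr_file`) or as in-memory tibbles
#' (`peaks`, `tss`, `de`, `expr`). A YAML or JSON document with the same
#' fields can be loaded with `pipeline_config_from_file()`.
#'
#' Parameter defaults: `min_replicates` 2, `promoter_dist` 2000 bp,
#' `min_fraction` 0.3, `stitch_distance` 12500 bp, `tss_exclusion` 2500 bp
#' (half-window), `windows_kb` 100/200/400, `enhancer_log2fc` 1.5,
#' `se_log2fc` 1.0, `padj` 0.05, `integration_window_kb` 400,
#' `reciprocal_mode` "both".
#'
#' @param conditions Two condition labels, numerator first: the DE table's
#'   log2fc must be oriented `conditions[1]` over `conditions[2]`.
#' @param peaks,tss,de,expr In-memory inputs (tibbles), or NULL to read from
#'   the corresponding `*_file`/`peak_files` fields at run time.
#' @param peak_files Named list (by condition) of character vectors of peak
#'   file paths; replicate ids are taken from the files' sixth column or
#'   derived from file order.
#' @param tss_file,de_file,expr_file Input file paths.
#' @param out_dir Output directory for stage TSVs and `report.json`.
#' @param min_replicates,promoter_dist,min_fraction,stitch_distance,tss_exclusion,windows_kb,enhancer_log2fc,se_log2fc,padj,integration_window_kb,reciprocal_mode
#'   Workflow parameters; see above.
#' @return A validated `regland_config` list.
#' @export
pipeline_config <- function(conditions,
                            peaks = NULL, tss = NULL, de = NULL, expr = NULL,
                            peak_files = NULL, tss_file = NULL,
                            de_file = NULL, expr_file = NULL,
                            out_dir = NULL,
                            min_replicates = 2, promoter_dist = 2000,
                            min_fraction = 0.3, stitch_distance = 12500,
                            tss_exclusion = 2500,
                            windows_kb = c(100, 200, 400),
                            enhancer_log2fc = 1.5, se_log2fc = 1.0,
                            padj = 0.05, integration_window_kb = 400,
                            reciprocal_mode = c("both", "any")) {
  reciprocal_mode <- match.arg(reciprocal_mode)
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(conditions) == 2 && !anyDuplicated(conditions),
      "conditions must be two distinct labels")
  chk(min_replicates >= 1, "min_replicates must be >= 1")
  chk(promoter_dist > 0, "promoter_dist must be > 0")
  chk(min_fraction > 0 && min_fraction <= 1, "min_fraction must be in (0, 1]")
  chk(stitch_distance >= 0, "stitch_distance must be >= 0")
  chk(tss_exclusion >= 0, "tss_exclusion must be >= 0")
  chk(length(windows_kb) > 0 && all(windows_kb > 0), "windows_kb must be positive")
  chk(enhancer_log2fc > 0, "enhancer_log2fc must be > 0")
  chk(se_log2fc > 0, "se_log2fc must be > 0")
  chk(padj > 0 && padj <= 1, "padj must be in (0, 1]")
  chk(integration_window_kb %in% windows_kb,
      "integration_window_kb must be one of windows_kb")
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid pipeline configuration:\n- ",
                        paste(problems, collapse = "\n- ")))
  }
  structure(cfg, class = "regland_config")
}

#' @rdname pipeline_config
#' @param path YAML (or JSON) file whose top-level fields match the
#'   `pipeline_config()` arguments.
#' @export
pipeline_config_from_file <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  raw$conditions <- unlist(raw$conditions)
  if (!is.null(raw$windows_kb)) raw$windows_kb <- unlist(raw$windows_kb)
  do.call(pipeline_config, raw)
}

load_pipeline_inputs <- function(config) {
  conds <- config$conditions
  peaks <- config$peaks
  if (is.null(peaks)) {
    if (is.null(config$peak_files)) rlang::abort("no peaks or peak_files given")
    stopifnot(all(conds %in% names(config$peak_files)))
    peaks <- purrr::map_dfr(conds, function(cn) {
      files <- config$peak_files[[cn]]
      purrr::imap_dfr(files, function(f, i) {
        has_rep_col <- ncol(utils::read.table(f, sep = "\t", nrows = 1)) >= 6
        if (has_rep_col) read_peaks(f, condition = cn)
        else read_peaks(f, condition = cn, replicate_id = paste0("rep", i))
      })
    })
  }
  tss <- config$tss %||% read_tss(config$tss_file %||%
                                    rlang::abort("no tss or tss_file given"))
  de <- config$de %||% read_de_table(config$de_file %||%
                                       rlang::abort("no de or de_file given"))
  expr <- config$expr %||% read_expression(config$expr_file %||%
                                             rlang::abort("no expr or expr_file given"))
  list(peaks = peaks, tss = validate_tss(tss), de = de, expr = expr)
}

run_stage <- function(name, fn) {
  tryCatch(fn(), error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)), parent = e)
  })
}

safe_test <- function(fn) {
  tryCatch({
    r <- fn()
    tibble::tibble(statistic = r$statistic, p.value = r$p.value,
                   median_region = r$median_region %||% NA_real_,
                   median_global = r$median_global %||% NA_real_,
                   median_diff = r$median_diff %||% NA_real_,
                   n = r$n_region %||% r$n_genes, note = NA_character_)
  }, error = function(e) {
    tibble::tibble(statistic = NA_real_, p.value = NA_real_,
                   median_region = NA_real_, median_global = NA_real_,
                   median_diff = NA_real_, n = NA_integer_,
                   note = conditionMessage(e))
  })
}

#' Run the full regulatory-region workflow
#'
#' Executes, for a two-condition comparison: replicate-consensus region
#' building, promoter/enhancer classification, per-class specificity calls,
#' promoter-proximal exclusion, enhancer stitching, super-enhancer
#' separation, window-gene assignment, concordance filtering against the DE
#' table, and the two expression validations (linked genes vs the rest of
#' the genome; linked-gene expression in the matching vs the other
#' condition). Every stage is a pure function of the inputs and the config,
#' so reruns reproduce the same outputs byte for byte.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON config).
#' @return Invisibly, a list with all stage tables (`regions`,
#'   `specificity`, `stitched`, `se_calls`, `gene_links`, `se_gene_links`,
#'   `concordant`, `validation`) and `report`, the count summary written to
#'   `report.json`. When `out_dir` is set, stage TSVs, gene lists,
#'   `report.json` and `pipeline.log` are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config_from_file(config)
  stopifnot(inherits(config, "regland_config"))
  conds <- config$conditions
  inputs <- run_stage("load_inputs", function() load_pipeline_inputs(config))

  regions <- run_stage("consensus_and_classify", function() {
    purrr::map_dfr(conds, function(cn) {
      classify_regions(
        consensus_regions(inputs$peaks[inputs$peaks$condition == cn, ],
                          condition = cn,
                          min_replicates = config$min_replicates),
        inputs$tss, promoter_dist = config$promoter_dist)
    })
  })
  by_class <- function(cn, cl) {
    regions[regions$condition == cn & regions$class == cl, ]
  }
  specificity <- run_stage("specificity", function() {
    dplyr::bind_rows(
      dplyr::mutate(call_specificity(by_class(conds[1], "promoter"),
                                     by_class(conds[2], "promoter"),
                                     config$min_fraction, config$reciprocal_mode),
                    class = "promoter"),
      dplyr::mutate(call_specificity(by_class(conds[1], "enhancer"),
                                     by_class(conds[2], "enhancer"),
                                     config$min_fraction, config$reciprocal_mode),
                    class = "enhancer")
    )
  })

  se <- run_stage("superenhancers", function() {
    per_cond <- purrr::map(conds, function(cn) {
      enh <- exclude_promoter_proximal(by_class(cn, "enhancer"), inputs$tss,
                                       half_window = config$tss_exclusion)
      stitched <- stitch_enhancers(enh, distance = config$stitch_distance)
      calls <- suppressWarnings(call_superenhancers(stitched))
      list(stitched = stitched, calls = calls)
    })
    names(per_cond) <- conds
    per_cond
  })
  se_calls <- dplyr::bind_rows(purrr::map(se, "calls"))
  se_only <- se_calls[se_calls$is_super, ]
  se_specificity <- run_stage("se_specificity", function() {
    dplyr::mutate(
      call_specificity(se_only[se_only$condition == conds[1], ],
                       se_only[se_only$condition == conds[2], ],
                       config$min_fraction, config$reciprocal_mode),
      class = "SE")
  })
  specificity <- dplyr::bind_rows(specificity, se_specificity)

  gene_links <- run_stage("window_genes", function() {
    assign_window_genes(regions[regions$class == "enhancer", ], inputs$tss,
                        windows_kb = config$windows_kb)
  })
  se_gene_links <- run_stage("se_window_genes", function() {
    assign_window_genes(se_only, inputs$tss, windows_kb = config$windows_kb)
  })

  concordant <- run_stage("concordance", function() {
    dplyr::bind_rows(
      concordant_genes(specificity[specificity$class == "enhancer", ],
                       gene_links, inputs$de, region_class = "enhancer",
                       window_kb = config$integration_window_kb,
                       log2fc_threshold = config$enhancer_log2fc,
                       padj_threshold = config$padj),
      concordant_genes(specificity[specificity$class == "SE", ],
                       se_gene_links, inputs$de, region_class = "SE",
                       window_kb = config$integration_window_kb,
                       log2fc_threshold = config$se_log2fc,
                       padj_threshold = config$padj)
    )
  })

  validation <- run_stage("validation", function() {
    purrr::map_dfr(c("enhancer", "SE"), function(cl) {
      labels <- specificity[specificity$class == cl, ]
      links <- if (cl == "enhancer") gene_links else se_gene_links
      purrr::map_dfr(seq_along(conds), function(i) {
        cn <- conds[i]; other <- conds[-i]
        genes <- linked_genes(labels, links, cn,
                              window_kb = config$integration_window_kb)
        dplyr::bind_rows(
          dplyr::mutate(safe_test(function()
            near_vs_global_expression(inputs$expr, genes, cn)),
            test = "near_vs_global", .before = 1),
          dplyr::mutate(safe_test(function()
            cross_population_validation(inputs$expr, genes, cn, other)),
            test = "cross_population", .before = 1)
        ) |> dplyr::mutate(class = cl, condition = cn, .before = 1)
      })
    })
  })

  count_labels <- function(cl) {
    lab <- specificity[specificity$class == cl, ]
    stats::setNames(lapply(conds, function(cn) {
      list(specific = sum(lab$condition == cn & lab$label == "specific"),
           shared = sum(lab$condition == cn & lab$label == "shared"))
    }), conds)
  }
  report <- list(
    package_version = as.character(utils::packageVersion("regland")),
    conditions = as.list(conds),
    parameters = config[c("min_replicates", "promoter_dist", "min_fraction",
                          "stitch_distance", "tss_exclusion", "windows_kb",
                          "enhancer_log2fc", "se_log2fc", "padj",
                          "integration_window_kb", "reciprocal_mode")],
    counts = list(
      regions = stats::setNames(lapply(conds, function(cn) {
        list(consensus = sum(regions$condition == cn),
             promoters = sum(regions$condition == cn & regions$class == "promoter"),
             enhancers = sum(regions$condition == cn & regions$class == "enhancer"),
             stitched = nrow(se[[cn]]$stitched),
             superenhancers = sum(se_calls$condition == cn & se_calls$is_super))
      }), conds),
      specificity = list(promoter = count_labels("promoter"),
                         enhancer = count_labels("enhancer"),
                         SE = count_labels("SE")),
      concordant_genes = stats::setNames(lapply(conds, function(cn) {
        list(enhancer = sum(concordant$condition == cn &
                              concordant$region_class == "enhancer"),
             SE = sum(concordant$condition == cn &
                        concordant$region_class == "SE"))
      }), conds)
    ),
    validation = purrr::pmap(
      validation[, c("class", "condition", "test", "statistic", "p.value")],
      function(class, condition, test, statistic, p.value) {
        list(class = class, condition = condition, test = test,
             statistic = statistic, p.value = p.value)
      })
  )

  result <- list(regions = regions, specificity = specificity,
                 stitched = dplyr::bind_rows(purrr::map(se, "stitched")),
                 se_calls = se_calls, gene_links = gene_links,
                 se_gene_links = se_gene_links, concordant = concordant,
                 validation = validation, report = report, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(config$out_dir, f),
                                         progress = FALSE)
    w(regions, "regions.tsv")
    w(specificity, "specificity.tsv")
    se_flat <- result$se_calls |>
      dplyr::mutate(constituents = purrr::map_chr(
        .data$constituents, paste, collapse = ","))
    w(se_flat, "superenhancers.tsv")
    w(gene_links, "enhancer_genes.tsv")
    w(se_gene_links, "superenhancer_genes.tsv")
    w(validation, "validation_report.tsv")
    export_gene_lists(concordant, file.path(config$out_dir, "gene_lists"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      paste0("regland ", report$package_version, " run at ", format(Sys.time())),
      paste0("conditions: ", paste(conds, collapse = " vs ")),
      paste0("parameters: ", jsonlite::toJSON(report$parameters, auto_unbox = TRUE))
    ), file.path(config$out_dir, "pipeline.log"))
  }
  invisible(result)
}
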