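#' Configuration for the synthetic regulatory-landscape generator
#'
#' The generator plants a known regulatory structure — shared and
#' condition-specific H3K27ac regions, promoter regions at gene TSSs, a
#' long-tailed signal distribution with a super-enhancer upper tail, and
#' expression effects on genes near condition-specific regions — and then
#' emits replicate peak sets, a TSS annotation, a normalized expression table
#' and a differential-expression table, all deterministic given `seed`.
#'
#' Regions and genes are laid out on regular genomic slots (`slot_spacing`
#' apart, order shuffled) so planted elements never collide: distinct
#' regions stay farther apart than the stitching distance, linked genes sit
#' 10-80 kb from their region (inside the 100 kb window but outside the
#' promoter zone), and every TSS pair is separated by at least
#' `tss_min_spacing`. With the default 500 kb spacing, neighbouring slots
#' also fall outside each other's largest (400 kb) gene window, so the
#' window genes of a planted region are exactly its own planted gene(s) and
#' every region-to-gene link is identifiable.
#'
#' @param seed Integer RNG seed. Sub-streams are derived per component so the
#'   annotation, peak and expression draws do not perturb one another.
#' @param conditions Two condition labels; default `c("condA", "condB")`.
#' @param n_chromosomes,chrom_length Genome shape. `chrom_length = NULL`
#'   (default) sizes chromosomes to fit the slots; an explicit value that is
#'   too small for the requested element counts is an error.
#' @param n_genes Total genes; must cover linked genes (one per specific
#'   region) plus promoter genes.
#' @param n_shared_regions Enhancer regions planted in both conditions.
#' @param n_specific_regions Enhancer regions planted per condition,
#'   condition-specific.
#' @param n_promoters Regions planted centred on a gene TSS (shared).
#' @param n_replicates Replicates per condition (>= 3 recommended); default 4.
#' @param replicate_reproducibility Probability a planted region yields a
#'   peak in a given replicate; default 0.9.
#' @param peak_jitter_bp SD of Gaussian boundary jitter in bp; default 50.
#' @param signal_meanlog,signal_sdlog Log-normal parameters of the typical
#'   region net signal (long-tailed, giving a convex rank-signal curve).
#'   Super-enhancer-flagged regions draw from the upper tail with
#'   `signal_sdlog / 2` dispersion. Setting `signal_sdlog = 0` gives
#'   deterministic region signals (flat body plus the SE outliers).
#' @param signal_noise_sd SD of the per-peak multiplicative log-normal IP
#'   noise around the region's base signal; default 0.2, 0 for noiseless.
#' @param input_fraction_range Range of the per-peak input/IP signal ratio;
#'   default `c(0.05, 0.2)`. A zero-width range makes it deterministic.
#' @param se_fraction Fraction of enhancer regions flagged super-enhancer and
#'   drawn from the upper signal tail; default 0.1.
#' @param se_signal_factor Multiplicative separation of the SE signal tail;
#'   default 25.
#' @param effect_log2fc Planted expression effect (log2) for genes linked to
#'   condition-specific regions, in the matching condition; default 2.
#' @param expr_noise_sd Gaussian noise SD on log2 expression; default 0.5.
#' @param background_fp_rate Spurious single-replicate peaks per Mb per
#'   condition; default 0.5.
#' @param region_width_range Planted region width range in bp.
#' @param slot_spacing Genomic slot spacing in bp; default 120000.
#' @param tss_min_spacing Minimum distance between any two TSSs; default 5000.
#' @return A `regland_sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              conditions = c("condA", "condB"),
                              n_chromosomes = 2,
                              chrom_length = NULL,
                              n_genes = 500,
                              n_shared_regions = 40,
                              n_specific_regions = 30,
                              n_promoters = 30,
                              n_replicates = 4,
                              replicate_reproducibility = 0.9,
                              peak_jitter_bp = 50,
                              signal_meanlog = 2.5,
                              signal_sdlog = 0.8,
                              signal_noise_sd = 0.2,
                              input_fraction_range = c(0.05, 0.2),
                              se_fraction = 0.1,
                              se_signal_factor = 25,
                              effect_log2fc = 2,
                              expr_noise_sd = 0.5,
                              background_fp_rate = 0.5,
                              region_width_range = c(800, 2000),
                              slot_spacing = 500000,
                              tss_min_spacing = 5000) {
  cfg <- as.list(environment())
  stopifnot(
    length(conditions) == 2, !anyDuplicated(conditions),
    n_chromosomes >= 1, n_genes >= 0, n_shared_regions >= 0,
    n_specific_regions >= 0, n_promoters >= 0, n_replicates >= 1,
    replicate_reproducibility >= 0, replicate_reproducibility <= 1,
    peak_jitter_bp >= 0, se_fraction >= 0, se_fraction <= 1,
    signal_sdlog >= 0, signal_noise_sd >= 0,
    length(input_fraction_range) == 2, input_fraction_range[1] >= 0,
    input_fraction_range[2] < 1, diff(input_fraction_range) >= 0,
    expr_noise_sd >= 0, background_fp_rate >= 0,
    length(region_width_range) == 2, region_width_range[1] > 0,
    diff(region_width_range) >= 0, slot_spacing > 0, tss_min_spacing >= 0
  )
  n_linked <- 2 * n_specific_regions
  if (n_genes < n_linked + n_promoters) {
    rlang::abort("n_genes must be at least 2 * n_specific_regions + n_promoters")
  }
  n_slots <- n_shared_regions + n_linked + n_promoters + (n_genes - n_linked - n_promoters)
  slots_per_chrom <- ceiling(n_slots / n_chromosomes)
  needed <- 2L * 50000L + (slots_per_chrom + 1L) * as.integer(slot_spacing)
  if (is.null(chrom_length)) {
    cfg$chrom_length <- needed
  } else if (chrom_length < needed) {
    rlang::abort(paste0("infeasible spacing: chrom_length ", chrom_length,
                        " cannot hold ", slots_per_chrom,
                        " slots at spacing ", slot_spacing,
                        " (need >= ", needed, ")"))
  }
  structure(cfg, class = "regland_sim_config")
}

# component sub-streams: one master seed, stable small offsets
derive_seed <- function(seed, k) as.integer((abs(seed) + 7919 * k) %% 2147483647)

#' Plant the ground-truth regulatory structure
#'
#' Places genes and regions on the genome and decides every latent property
#' the generator will realise: region specificity (shared / one condition),
#' promoter vs enhancer type, super-enhancer flags, base net signals, and
#' region-to-gene links carrying the planted expression effect.
#'
#' @param config A [simulation_config()].
#' @return A `regland_truth` list: `regions` (truth_id, chrom, start, end,
#'   specificity, type, is_se, base_signal), `tss`, `links` (truth_id,
#'   gene_id, condition, effect_log2fc), and `config`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "regland_sim_config"))
  set.seed(derive_seed(config$seed, 1))
  cond <- config$conditions
  n_spec <- config$n_specific_regions
  n_linked <- 2 * n_spec
  n_free_genes <- config$n_genes - n_linked - config$n_promoters

  roles <- c(rep("shared_enh", config$n_shared_regions),
             rep("specific_A", n_spec), rep("specific_B", n_spec),
             rep("promoter", config$n_promoters),
             rep("free_gene", n_free_genes))
  roles <- sample(roles)
  n_slots <- length(roles)
  chrom <- paste0("chr", ((seq_len(n_slots) - 1) %% config$n_chromosomes) + 1)
  idx_on_chrom <- ceiling(seq_len(n_slots) / config$n_chromosomes)
  pos <- 50000L + idx_on_chrom * as.integer(config$slot_spacing) +
    as.integer(floor(stats::runif(n_slots, 0, config$slot_spacing / 4)))

  widths <- as.integer(round(stats::runif(
    n_slots, config$region_width_range[1], config$region_width_range[2])))

  regions <- list(); genes <- list(); links <- list()
  gene_counter <- 0; region_counter <- 0
  new_gene_id <- function() sprintf("gene%04d", gene_counter)
  for (i in seq_len(n_slots)) {
    role <- roles[i]
    if (role == "free_gene") {
      gene_counter <- gene_counter + 1
      genes[[length(genes) + 1]] <- tibble::tibble(
        gene_id = new_gene_id(), chrom = chrom[i], tss = pos[i],
        strand = sample(c("+", "-"), 1))
      next
    }
    region_counter <- region_counter + 1
    truth_id <- sprintf("truth%04d", region_counter)
    if (role == "promoter") {
      gene_counter <- gene_counter + 1
      gid <- new_gene_id()
      tss_pos <- pos[i]
      genes[[length(genes) + 1]] <- tibble::tibble(
        gene_id = gid, chrom = chrom[i], tss = tss_pos,
        strand = sample(c("+", "-"), 1))
      start <- tss_pos - widths[i] %/% 2L
      regions[[length(regions) + 1]] <- tibble::tibble(
        truth_id = truth_id, chrom = chrom[i], start = start,
        end = start + widths[i], specificity = "shared", type = "promoter")
    } else {
      start <- pos[i]
      spec <- switch(role, shared_enh = "shared",
                     specific_A = cond[1], specific_B = cond[2])
      regions[[length(regions) + 1]] <- tibble::tibble(
        truth_id = truth_id, chrom = chrom[i], start = start,
        end = start + widths[i], specificity = spec, type = "enhancer")
      if (spec != "shared") {
        gene_counter <- gene_counter + 1
        gid <- new_gene_id()
        offset <- as.integer(round(stats::runif(1, 10000, 80000)))
        genes[[length(genes) + 1]] <- tibble::tibble(
          gene_id = gid, chrom = chrom[i], tss = start + widths[i] + offset,
          strand = sample(c("+", "-"), 1))
        links[[length(links) + 1]] <- tibble::tibble(
          truth_id = truth_id, gene_id = gid, condition = spec,
          effect_log2fc = config$effect_log2fc)
      }
    }
  }
  regions <- dplyr::bind_rows(regions)
  genes <- dplyr::bind_rows(genes)
  links <- if (length(links)) dplyr::bind_rows(links) else
    tibble::tibble(truth_id = character(), gene_id = character(),
                   condition = character(), effect_log2fc = double())

  if (nrow(genes) > 1) {
    d <- genes |> dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$tss, .by_group = TRUE) |>
      dplyr::summarise(min_d = if (dplyr::n() > 1) min(diff(.data$tss)) else Inf,
                       .groups = "drop")
    if (min(d$min_d) < config$tss_min_spacing) {
      rlang::abort("infeasible spacing: generated TSSs closer than tss_min_spacing")
    }
  }

  # super-enhancer flags and long-tailed signals (enhancer-type regions only)
  enh_idx <- which(regions$type == "enhancer")
  n_se <- floor(config$se_fraction * length(enh_idx))
  se_idx <- if (n_se > 0) sample(enh_idx, n_se) else integer(0)
  regions$is_se <- FALSE
  regions$is_se[se_idx] <- TRUE
  regions$base_signal <- stats::rlnorm(nrow(regions), config$signal_meanlog,
                                       config$signal_sdlog)
  if (n_se > 0) {
    regions$base_signal[se_idx] <- stats::rlnorm(
      n_se, config$signal_meanlog + log(config$se_signal_factor),
      config$signal_sdlog / 2)
  }
  structure(list(regions = regions, tss = genes, links = links, config = config),
            class = "regland_truth")
}

#' Synthetic TSS annotation
#'
#' The gene annotation of a simulated landscape (deterministic given the
#' config seed).
#'
#' @param config A [simulation_config()].
#' @return TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_annotation <- function(config) simulate_ground_truth(config)$tss

#' Realise replicate peak sets from planted regions
#'
#' Every planted region present in a condition emits a peak in each replicate
#' with probability `replicate_reproducibility`, with Gaussian boundary
#' jitter and multiplicative signal noise (IP ~ base signal, input a small
#' fraction of IP). Spurious background peaks land in single replicates at
#' `background_fp_rate` per Mb, placed clear of planted regions so they can
#' only ever form single-replicate components.
#'
#' @param config A [simulation_config()].
#' @param truth A [simulate_ground_truth()] result for the same config.
#' @return Peak tibble across all conditions and replicates (same columns as
#'   [read_peaks()]).
#' @export
simulate_peaks <- function(config, truth) {
  stopifnot(inherits(truth, "regland_truth"))
  set.seed(derive_seed(config$seed, 2))
  cond <- config$conditions
  regions <- truth$regions
  out <- list()
  for (ci in seq_along(cond)) {
    present <- regions[regions$specificity %in% c("shared", cond[ci]), ]
    for (rep_i in seq_len(config$n_replicates)) {
      emit <- stats::runif(nrow(present)) <= config$replicate_reproducibility
      sub <- present[emit, ]
      if (nrow(sub) > 0) {
        j1 <- as.integer(round(stats::rnorm(nrow(sub), 0, config$peak_jitter_bp)))
        j2 <- as.integer(round(stats::rnorm(nrow(sub), 0, config$peak_jitter_bp)))
        start <- pmax(0L, sub$start + j1)
        end <- pmax(start + 50L, sub$end + j2)
        ip <- sub$base_signal *
          exp(stats::rnorm(nrow(sub), 0, config$signal_noise_sd))
        input <- ip * stats::runif(nrow(sub), config$input_fraction_range[1],
                                   config$input_fraction_range[2])
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = sub$chrom, start = start, end = end,
          ip_signal = ip, input_signal = input,
          replicate_id = paste0("rep", rep_i), condition = cond[ci])
      }
    }
    # background false positives, one replicate each
    genome_mb <- config$n_chromosomes * config$chrom_length / 1e6
    n_fp <- stats::rpois(1, config$background_fp_rate * genome_mb)
    if (n_fp > 0) {
      placed <- regions[, c("chrom", "start", "end")]
      fp <- list()
      tries <- 0
      while (length(fp) < n_fp && tries < n_fp * 50) {
        tries <- tries + 1
        w <- as.integer(round(stats::runif(1, 300, 800)))
        ch <- paste0("chr", sample.int(config$n_chromosomes, 1))
        s <- as.integer(floor(stats::runif(1, 0, config$chrom_length - w)))
        cand <- tibble::tibble(chrom = ch, start = s, end = s + w)
        margin <- tibble::tibble(chrom = placed$chrom,
                                 start = pmax(0L, placed$start - 5000L),
                                 end = placed$end + 5000L)
        if (any(overlap_length(cand, margin) > 0)) next
        placed <- dplyr::bind_rows(placed, cand)
        ip <- stats::rlnorm(1, config$signal_meanlog - 1, 0.5)
        fp[[length(fp) + 1]] <- tibble::tibble(
          chrom = ch, start = s, end = s + w,
          ip_signal = ip,
          input_signal = ip * stats::runif(1, config$input_fraction_range[1],
                                           config$input_fraction_range[2]),
          replicate_id = paste0("rep", sample.int(config$n_replicates, 1)),
          condition = cond[ci])
      }
      if (length(fp)) out[[length(out) + 1]] <- dplyr::bind_rows(fp)
    }
  }
  peaks <- dplyr::bind_rows(out)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          ip_signal = double(), input_signal = double(),
                          replicate_id = character(), condition = character(),
                          net_signal = double()))
  }
  peaks$net_signal <- net_signal(peaks$ip_signal, peaks$input_signal)
  dplyr::arrange(peaks, .data$condition, .data$replicate_id,
                 .data$chrom, .data$start, .data$end)
}

#' Simulate normalized expression and a differential-expression table
#'
#' Per-gene baseline log2 expression plus the planted `effect_log2fc` in the
#' matching condition for linked genes, plus Gaussian noise per sample. The
#' DE table compares the two conditions (first condition as numerator):
#' `log2fc` is the difference of condition means and the p-value a moderated
#' two-sample t-statistic (limma `lmFit`/`eBayes` on the normalized matrix),
#' mirroring how the consumed DE tables are produced in practice by
#' variance-moderated count models, which this package does not fit itself.
#' P-values are BH-adjusted with [bh_adjust()]. When the residual variance is
#' zero for every gene (a noiseless simulation), p is 1 for genes with equal
#' condition means and 0 otherwise, so noiseless runs stay well-defined.
#'
#' @inheritParams simulate_peaks
#' @return List with `expr` (long tibble: gene_id, sample_id, condition,
#'   expr) and `de` (gene_id, log2fc, pvalue, padj).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(truth, "regland_truth"))
  set.seed(derive_seed(config$seed, 3))
  cond <- config$conditions
  genes <- truth$tss$gene_id
  n_g <- length(genes)
  baseline <- stats::rnorm(n_g, 6, 1.5)
  effect <- matrix(0, nrow = n_g, ncol = 2, dimnames = list(genes, cond))
  if (nrow(truth$links) > 0) {
    for (k in seq_len(nrow(truth$links))) {
      effect[truth$links$gene_id[k], truth$links$condition[k]] <-
        effect[truth$links$gene_id[k], truth$links$condition[k]] +
        truth$links$effect_log2fc[k]
    }
  }
  n_rep <- config$n_replicates
  expr <- tidyr::expand_grid(
    gene_id = genes,
    tibble::tibble(condition = rep(cond, each = n_rep),
                   sample_id = paste0(rep(cond, each = n_rep), "_s",
                                      rep(seq_len(n_rep), 2)))
  )
  gi <- match(expr$gene_id, genes)
  expr$expr <- baseline[gi] +
    effect[cbind(gi, match(expr$condition, cond))] +
    stats::rnorm(nrow(expr), 0, config$expr_noise_sd)

  wide <- tidyr::pivot_wider(expr[, c("gene_id", "sample_id", "expr")],
                             names_from = "sample_id", values_from = "expr")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$gene_id
  mat <- mat[genes, , drop = FALSE]
  sample_cond <- expr$condition[match(colnames(mat), expr$sample_id)]
  ma <- rowMeans(mat[, sample_cond == cond[1], drop = FALSE])
  mb <- rowMeans(mat[, sample_cond == cond[2], drop = FALSE])
  resid_var <- apply(mat, 1, function(r) {
    sum(stats::var(r[sample_cond == cond[1]]), stats::var(r[sample_cond == cond[2]]))
  })
  if (all(resid_var == 0)) {
    p <- ifelse(ma == mb, 1, 0)
  } else {
    design <- cbind(intercept = 1, diff = as.numeric(sample_cond == cond[1]))
    fit <- limma::eBayes(limma::lmFit(mat, design))
    p <- fit$p.value[, "diff"]
  }
  de <- tibble::tibble(gene_id = genes, log2fc = unname(ma - mb),
                       pvalue = unname(p), padj = bh_adjust(unname(p))) |>
    dplyr::arrange(.data$gene_id)
  list(expr = dplyr::arrange(expr, .data$gene_id, .data$sample_id), de = de)
}

#' Simulate a full landscape in one call
#'
#' @param config A [simulation_config()].
#' @return List: `truth`, `peaks`, `expr`, `de`, `config`.
#' @export
simulate_landscape <- function(config) {
  truth <- simulate_ground_truth(config)
  peaks <- simulate_peaks(config, truth)
  ex <- simulate_expression(config, truth)
  list(truth = truth, peaks = peaks, expr = ex$expr, de = ex$de, config = config)
}

#' Write a simulated landscape to disk
#'
#' Emits the file formats the readers consume: one BED5+ file per condition x
#' replicate (`peaks_<condition>_<replicate>.bed`), `tss.tsv`, `expr.tsv`,
#' `de_table.tsv`, and `truth.json`.
#'
#' @param sim A [simulate_landscape()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- sim$peaks |> dplyr::distinct(.data$condition, .data$replicate_id)
  for (i in seq_len(nrow(combos))) {
    sub <- sim$peaks |>
      dplyr::filter(.data$condition == combos$condition[i],
                    .data$replicate_id == combos$replicate_id[i])
    write_peaks(sub, file.path(dir, paste0(
      "peaks_", combos$condition[i], "_", combos$replicate_id[i], ".bed")))
  }
  readr::write_tsv(sim$truth$tss, file.path(dir, "tss.tsv"), progress = FALSE)
  readr::write_tsv(sim$expr, file.path(dir, "expr.tsv"), progress = FALSE)
  readr::write_tsv(sim$de, file.path(dir, "de_table.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(regions = sim$truth$regions, links = sim$truth$links),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
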