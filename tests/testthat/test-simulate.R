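small_cfg <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_genes = 60, n_shared_regions = 8,
                    n_specific_regions = 6, n_promoters = 5,
                    n_replicates = 3, ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  s1 <- simulate_landscape(small_cfg())
  s2 <- simulate_landscape(small_cfg())
  expect_identical(s1$truth$regions, s2$truth$regions)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$de, s2$de)
  s3 <- simulate_landscape(small_cfg(seed = 8))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("annotation respects the minimum TSS spacing and gene count", {
  cfg <- small_cfg()
  tss <- simulate_annotation(cfg)
  expect_equal(nrow(tss), cfg$n_genes)
  expect_false(anyDuplicated(tss$gene_id) > 0)
  d <- tss |>
    dplyr::group_by(chrom) |>
    dplyr::arrange(tss, .by_group = TRUE) |>
    dplyr::summarise(min_d = min(diff(tss)), .groups = "drop")
  expect_true(all(d$min_d >= cfg$tss_min_spacing))
  # zero genes is a valid degenerate configuration
  cfg0 <- simulation_config(seed = 1, n_genes = 0, n_shared_regions = 2,
                            n_specific_regions = 0, n_promoters = 0)
  expect_equal(nrow(simulate_annotation(cfg0)), 0)
})

test_that("an explicit chromosome length that cannot hold the slots errors", {
  expect_error(simulation_config(seed = 1, chrom_length = 1e6),
               "infeasible spacing")
})

test_that("a noiseless simulation reproduces the planted regions exactly", {
  cfg <- small_cfg(replicate_reproducibility = 1, peak_jitter_bp = 0,
                   background_fp_rate = 0, expr_noise_sd = 0,
                   signal_sdlog = 0, signal_noise_sd = 0,
                   input_fraction_range = c(0.1, 0.1))
  sim <- simulate_landscape(cfg)
  for (cn in cfg$conditions) {
    planted <- sim$truth$regions[sim$truth$regions$specificity %in%
                                   c("shared", cn), ]
    planted <- dplyr::arrange(planted, chrom, start)
    cons <- consensus_regions(sim$peaks[sim$peaks$condition == cn, ],
                              min_replicates = 2)
    expect_equal(cons$start, planted$start)
    expect_equal(cons$end, planted$end)
    expect_true(all(cons$support == cfg$n_replicates))
  }
  # noiseless expression: estimated log2fc equals the planted effect exactly
  linked <- sim$de[sim$de$gene_id %in% sim$truth$links$gene_id, ]
  dirs <- ifelse(sim$truth$links$condition[match(linked$gene_id,
                                                 sim$truth$links$gene_id)] ==
                   cfg$conditions[1], 1, -1)
  expect_equal(linked$log2fc, dirs * cfg$effect_log2fc)
  expect_true(all(linked$padj == 0))
  unlinked <- sim$de[!sim$de$gene_id %in% sim$truth$links$gene_id, ]
  expect_true(all(unlinked$log2fc == 0))
})

test_that("replicate dropout follows the binomial support model", {
  # reproducibility = 1/n_replicates: P(support >= 2) = 1 - (1-p)^n - n p (1-p)^(n-1)
  cfg <- simulation_config(seed = 12, n_genes = 80, n_shared_regions = 150,
                           n_specific_regions = 0, n_promoters = 0,
                           n_replicates = 4, replicate_reproducibility = 0.25,
                           background_fp_rate = 0)
  sim <- simulate_landscape(cfg)
  cons <- consensus_regions(sim$peaks[sim$peaks$condition == "condA", ],
                            min_replicates = 2)
  p <- 0.25; n <- 4
  expected_keep <- 1 - (1 - p)^n - n * p * (1 - p)^(n - 1)
  kept <- nrow(cons) / cfg$n_shared_regions
  # binomial Monte-Carlo slack: ~4 SDs at 150 trials
  expect_lt(abs(kept - expected_keep), 4 * sqrt(expected_keep *
                                                  (1 - expected_keep) / 150))
  # most planted regions are discarded at this reproducibility
  expect_lt(kept, 0.5)
})

test_that("background false-positive peaks never reach consensus support", {
  cfg <- small_cfg(replicate_reproducibility = 1, peak_jitter_bp = 0,
                   background_fp_rate = 2)
  sim <- simulate_landscape(cfg)
  peaks_a <- sim$peaks[sim$peaks$condition == "condA", ]
  planted <- sim$truth$regions[sim$truth$regions$specificity %in%
                                 c("shared", "condA"), ]
  n_fp <- sum(!vapply(seq_len(nrow(peaks_a)), function(i) {
    any(planted$chrom == peaks_a$chrom[i] &
          planted$start < peaks_a$end[i] & planted$end > peaks_a$start[i])
  }, logical(1)))
  expect_gt(n_fp, 0)
  cons <- consensus_regions(peaks_a, min_replicates = 2)
  expect_equal(nrow(cons), nrow(planted))
})

test_that("planted super-enhancer signals sit in the upper tail", {
  cfg <- small_cfg(se_fraction = 0.25)
  truth <- simulate_ground_truth(cfg)
  enh <- truth$regions[truth$regions$type == "enhancer", ]
  expect_gt(min(enh$base_signal[enh$is_se]),
            stats::quantile(enh$base_signal[!enh$is_se], 0.9))
})

test_that("simulation files round-trip through the package readers", {
  sim <- simulate_landscape(small_cfg())
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tss <- read_tss(file.path(dir, "tss.tsv"))
  expect_equal(tss, sim$truth$tss)
  de <- read_de_table(file.path(dir, "de_table.tsv"))
  expect_equal(de, sim$de)
  expr <- read_expression(file.path(dir, "expr.tsv"))
  expect_equal(expr, sim$expr)
  f <- file.path(dir, "peaks_condA_rep1.bed")
  expect_true(file.exists(f))
  p <- read_peaks(f, condition = "condA")
  ref <- sim$peaks[sim$peaks$condition == "condA" &
                     sim$peaks$replicate_id == "rep1", ]
  expect_equal(dplyr::arrange(p, chrom, start, end)[, c("chrom", "start", "end")],
               dplyr::arrange(ref, chrom, start, end)[, c("chrom", "start", "end")])
})
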