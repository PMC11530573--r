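test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(401)
  for (i in 1:50) {
    p <- stats::runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

mk_labels <- function(ids, conds, labels, comparison = "nsc_vs_ipsc") {
  tibble::tibble(region_id = ids, condition = conds, comparison = comparison,
                 label = labels, partner_id = NA_character_,
                 frac_self = 0, frac_partner = 0)
}

test_that("concordance filtering gates on direction, magnitude and padj", {
  labels <- mk_labels(c("r1", "r2"), c("nsc", "ipsc"), c("specific", "specific"))
  links <- tibble::tibble(region_id = c("r1", "r1", "r1", "r2"),
                          window_kb = 400L,
                          gene_id = c("gUp", "gWeak", "gNoisy", "gDown"),
                          distance = c(1000L, 2000L, 3000L, 500L))
  de <- tibble::tibble(
    gene_id = c("gUp", "gWeak", "gNoisy", "gDown"),
    log2fc = c(2.0, 1.2, 2.0, -2.5),
    pvalue = c(0.001, 0.001, 0.15, 0.001),
    padj = c(0.01, 0.01, 0.2, 0.01)
  )
  enh <- concordant_genes(labels, links, de, region_class = "enhancer")
  # +2.0 with padj 0.01 kept for the numerator condition
  expect_true("gUp" %in% enh$gene_id[enh$condition == "nsc"])
  # padj 0.2 fails the strict < 0.05 gate
  expect_false("gNoisy" %in% enh$gene_id)
  # +1.2 fails the enhancer threshold 1.5 but passes the SE threshold 1.0
  expect_false("gWeak" %in% enh$gene_id)
  se <- concordant_genes(labels, links, de, region_class = "SE")
  expect_true("gWeak" %in% se$gene_id[se$condition == "nsc"])
  # denominator-specific region keeps the down-regulated gene
  expect_true("gDown" %in% enh$gene_id[enh$condition == "ipsc"])
})

test_that("concordant sets shrink as thresholds tighten and dedupe genes", {
  set.seed(411)
  labels <- mk_labels(paste0("r", 1:12),
                      rep(c("nsc", "ipsc"), each = 6), "specific")
  links <- tibble::tibble(
    region_id = sample(paste0("r", 1:12), 60, replace = TRUE),
    window_kb = 400L,
    gene_id = sample(sprintf("g%02d", 1:25), 60, replace = TRUE),
    distance = 1000L
  )
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:25),
                       log2fc = stats::rnorm(25, 0, 2),
                       pvalue = stats::runif(25)^2,
                       padj = NA_real_)
  de$padj <- bh_adjust(de$pvalue)
  sizes <- vapply(c(0.5, 1, 1.5, 2.5), function(thr) {
    nrow(concordant_genes(labels, links, de, "enhancer", log2fc_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  sizes_p <- vapply(c(0.2, 0.05, 0.01), function(a) {
    nrow(concordant_genes(labels, links, de, "enhancer", padj_threshold = a))
  }, numeric(1))
  expect_true(all(diff(sizes_p) <= 0))
  out <- concordant_genes(labels, links, de, "enhancer", log2fc_threshold = 0.1,
                          padj_threshold = 1)
  expect_false(any(duplicated(out[, c("condition", "gene_id")])))
})

test_that("linked genes missing from the DE table are excluded and reported", {
  labels <- mk_labels("r1", "nsc", "specific")
  links <- tibble::tibble(region_id = "r1", window_kb = 400L,
                          gene_id = c("gKnown", "gUnknown"), distance = 0L)
  de <- tibble::tibble(gene_id = "gKnown", log2fc = 3, pvalue = 1e-5,
                       padj = 1e-4)
  out <- concordant_genes(labels, links, de, "enhancer")
  expect_equal(out$gene_id, "gKnown")
  expect_equal(attr(out, "missing_genes"), "gUnknown")
})

mk_expr <- function(values, genes = sprintf("g%03d", seq_along(values)),
                    condition = "X") {
  tibble::tibble(gene_id = genes, sample_id = "s1", condition = condition,
                 expr = values)
}

test_that("small-sample rank-sum p equals exhaustive enumeration", {
  x <- c(8.1, 9.4, 10.2)          # region genes
  y <- c(5.0, 6.3, 7.7, 8.9)      # the rest
  expr <- mk_expr(c(x, y))
  res <- near_vs_global_expression(expr, sprintf("g%03d", 1:3), "X")
  # 3 of 7 ranks: choose(7, 3) = 35 assignments enumerated by the oracle
  expect_equal(res$p.value, bf_wilcox_greater(x, y))
  expect_equal(res$median_region, median(x))
  expect_equal(res$median_global, median(y))
})

test_that("exact and approximate rank-sum branches agree near the switch point", {
  set.seed(421)
  for (i in 1:20) {
    x <- stats::rnorm(8, 1, 1)
    y <- stats::rnorm(8, 0, 1)
    p_exact <- stats::wilcox.test(x, y, alternative = "greater",
                                  exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(x, y, alternative = "greater",
                                   exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("near-vs-global detects planted upward shifts and needs 2+ genes", {
  set.seed(431)
  vals <- stats::rnorm(200, 5, 1)
  vals[1:20] <- vals[1:20] + 3
  expr <- mk_expr(vals)
  res <- near_vs_global_expression(expr, sprintf("g%03d", 1:20), "X")
  expect_lt(res$p.value, 1e-6)
  expect_gt(res$median_region, res$median_global)
  expect_error(near_vs_global_expression(expr, "g001", "X"), "at least 2")
})

test_that("cross-population validation is null on equal expression, powered on shifts", {
  set.seed(441)
  genes <- sprintf("g%03d", 1:30)
  base <- stats::rnorm(30, 5, 1)
  expr_equal <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, sample_id = "a1", condition = "A", expr = base),
    tibble::tibble(gene_id = genes, sample_id = "b1", condition = "B", expr = base)
  )
  res <- cross_population_validation(expr_equal, genes, "A", "B")
  expect_equal(res$median_diff, 0)
  expect_gt(res$p.value, 0.5)

  expr_shift <- expr_equal
  expr_shift$expr[expr_shift$condition == "A"] <-
    expr_shift$expr[expr_shift$condition == "A"] + 2
  res2 <- cross_population_validation(expr_shift, genes, "A", "B")
  expect_lt(res2$p.value, 1e-4)
  expect_equal(res2$median_diff, 2)
  expect_error(cross_population_validation(expr_equal, "g001", "A", "B"),
               "at least 2")
})

test_that("rank-test results tidy into one-row tibbles", {
  expr <- mk_expr(stats::rnorm(50))
  res <- near_vs_global_expression(expr, sprintf("g%03d", 1:5), "X")
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p.value", "median_region") %in% names(td)))
  expect_equal(td$p.value, res$p.value)
})

test_that("gene-list export is deterministic, unique and handles empty sets", {
  sets <- tibble::tibble(
    comparison = "nsc_vs_ipsc", region_class = "enhancer", window_kb = 400L,
    condition = "nsc",
    gene_id = c("gB", "gA", "gB"), log2fc = c(2, 3, 2), padj = c(0.01, 0.001, 0.01)
  )
  d1 <- withr::local_tempdir()
  f1 <- export_gene_lists(sets, d1)
  tsv <- readr::read_tsv(f1[1], show_col_types = FALSE)
  expect_equal(tsv$gene_id, c("gA", "gB")) # |log2fc| desc, unique
  d2 <- withr::local_tempdir()
  f2 <- export_gene_lists(sets, d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))

  empty <- sets[0, ]
  d3 <- withr::local_tempdir()
  f3 <- export_gene_lists(empty, d3)
  expect_true(file.exists(f3))
  expect_equal(nrow(readr::read_tsv(f3, show_col_types = FALSE)), 0)
})
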