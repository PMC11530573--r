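mk_peaks <- function(starts, ends, reps, cond = "A", ip = 10, input = 2) {
  tibble::tibble(chrom = "chr1", start = starts, end = ends,
                 ip_signal = ip, input_signal = input,
                 replicate_id = reps, condition = cond,
                 net_signal = pmax(ip - input, 0))
}

test_that("consensus regions merge replicate peaks and apply the support filter", {
  # two overlapping replicates -> one region, support 2, kept
  p <- mk_peaks(c(100, 150), c(200, 250), c("rep1", "rep2"))
  r <- consensus_regions(p, min_replicates = 2)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(100, 250))
  expect_equal(r$support, 2L)
  expect_equal(r$net_signal, 16) # 8 + 8

  # single-replicate region discarded at min_replicates = 2
  p1 <- mk_peaks(100, 200, "rep1")
  expect_equal(nrow(consensus_regions(p1, min_replicates = 2)), 0)
  expect_equal(nrow(consensus_regions(p1, min_replicates = 1)), 1)

  # chained component counts every replicate touching it
  p3 <- mk_peaks(c(0, 90, 170), c(100, 180, 260), c("rep1", "rep2", "rep3"))
  r3 <- consensus_regions(p3, min_replicates = 2)
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$start, r3$end), c(0, 260))
  expect_equal(r3$support, 3L)

  # mixed conditions are an error
  pm <- dplyr::bind_rows(mk_peaks(0, 10, "rep1", "A"), mk_peaks(0, 10, "rep1", "B"))
  expect_error(consensus_regions(pm), "mix conditions")
})

test_that("consensus regions are disjoint and match a brute-force build", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_peaks(sample(5:50, 1))
    minr <- sample(1:3, 1)
    r <- consensus_regions(p, min_replicates = minr)
    if (nrow(r) > 1) {
      for (c in unique(r$chrom)) {
        sub <- r[r$chrom == c, ]
        if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
      }
    }
    bf <- bf_consensus(p, minr)
    expect_equal(r[, c("chrom", "start", "end")],
                 bf[, c("chrom", "start", "end")], ignore_attr = TRUE)
    expect_equal(r$support, bf$support)
    expect_equal(r$net_signal, bf$net_signal)
  }
})

tss3 <- tibble::tibble(
  gene_id = c("geneA", "geneB", "geneC"),
  chrom = c("chr1", "chr1", "chr2"),
  tss = c(10000L, 40000L, 5000L),
  strand = c("+", "-", "+")
)

mk_region <- function(start, end, chrom = "chr1", cond = "A") {
  tibble::tibble(region_id = paste0(cond, ":", chrom, ":", start, "-", end),
                 chrom = chrom, start = start, end = end, condition = cond,
                 support = 2L, net_signal = 10)
}

test_that("promoter/enhancer classification uses a strict centre distance", {
  # centre 1,500 bp from a TSS -> promoter
  r <- classify_regions(mk_region(11000, 12000), tss3) # centre 11500, d = 1500
  expect_equal(r$class, "promoter")
  expect_equal(r$anchor_gene, "geneA")
  # centre exactly 2,000 bp away -> enhancer (strict <)
  r2 <- classify_regions(mk_region(11500, 12500), tss3) # centre 12000
  expect_equal(r2$dist_tss, 2000)
  expect_equal(r2$class, "enhancer")
  expect_true(is.na(r2$anchor_gene))
  # centre on the TSS -> promoter anchored to that gene
  r3 <- classify_regions(mk_region(9500, 10500), tss3)
  expect_equal(r3$dist_tss, 0)
  expect_equal(r3$anchor_gene, "geneA")
  # chromosome with no TSS -> enhancer, flagged
  r4 <- classify_regions(mk_region(100, 600, chrom = "chr9"), tss3)
  expect_equal(r4$class, "enhancer")
  expect_true(r4$no_tss_chrom)
  # classification partitions the input
  many <- dplyr::bind_rows(mk_region(11000, 12000), mk_region(11500, 12500),
                           mk_region(100000, 101000))
  cl <- classify_regions(many, tss3)
  expect_equal(sum(cl$class == "promoter") + sum(cl$class == "enhancer"), 3)
})

test_that("nearest-TSS annotation minimises distance and breaks ties lexicographically", {
  tss <- tibble::tibble(gene_id = c("geneA", "geneB"), chrom = "chr1",
                        tss = c(900L, 1300L), strand = c("+", "+"))
  r <- mk_region(990, 1010) # centre 1000
  expect_equal(annotate_nearest_tss(r, tss)$nearest_gene, "geneA") # 100 < 300
  tss$tss <- c(900L, 1100L) # tie at distance 100
  expect_equal(annotate_nearest_tss(r, tss)$nearest_gene, "geneA")
  expect_equal(annotate_nearest_tss(r, tss[2, ])$nearest_gene, "geneB")
})

test_that("nearest-TSS annotation matches exhaustive search on random instances", {
  set.seed(111)
  for (i in 1:30) {
    tss <- random_tss(sample(1:20, 1))
    r <- random_peaks(sample(1:30, 1))[, c("chrom", "start", "end")]
    got <- annotate_nearest_tss(r, tss)
    for (j in seq_len(nrow(r))) {
      bf <- bf_nearest_tss(r$chrom[j], floor((r$start[j] + r$end[j]) / 2), tss)
      expect_identical(got$nearest_gene[j], bf$gene)
      expect_equal(got$dist_tss[j], bf$dist)
    }
  }
})

test_that("window genes respect boundaries and nest across window sizes", {
  enh <- mk_region(1000000, 1001000)
  tss <- tibble::tibble(
    gene_id = c("g_at_lower", "g_inside", "g_above", "g_far"),
    chrom = "chr1",
    tss = c(600000L, 1000500L, 1400999L, 1401000L),
    strand = "+"
  )
  w <- assign_window_genes(enh, tss, windows_kb = c(100, 200, 400))
  w400 <- w$gene_id[w$window_kb == 400]
  # closed lower bound at start - 400 kb; open upper bound at end + 400 kb
  expect_true("g_at_lower" %in% w400)
  expect_true("g_above" %in% w400)
  expect_false("g_far" %in% w400)
  expect_equal(w$distance[w$gene_id == "g_inside" & w$window_kb == 100], 0)
  # monotone nesting
  g <- function(k) sort(w$gene_id[w$window_kb == k])
  expect_true(all(g(100) %in% g(200)))
  expect_true(all(g(200) %in% g(400)))
  # no TSS in range -> empty
  far_tss <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 9000000L,
                            strand = "+")
  expect_equal(nrow(assign_window_genes(enh, far_tss)), 0)
})

test_that("duplicate gene records collapse to the nearest TSS", {
  enh <- mk_region(1000000, 1001000)
  tss <- tibble::tibble(gene_id = "gX", chrom = "chr1",
                        tss = c(990000L, 1200000L), strand = "+")
  w <- assign_window_genes(enh, tss, windows_kb = 400)
  expect_equal(nrow(w), 1)
  expect_equal(w$distance, 10000L)
})

test_that("TSS derivation from stranded features uses start or end - 1", {
  feats <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          start = c(100L, 500L), end = c(300L, 900L),
                          strand = c("+", "-"))
  tss <- tss_from_features(feats)
  expect_equal(tss$tss, c(100L, 899L))
})
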