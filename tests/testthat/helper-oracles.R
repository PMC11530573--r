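# Brute-force reference implementations, kept deliberately naive and
# independent of the package's sweep-line / vectorised code paths.

bf_merge <- function(x, gap = 0) {
  rows <- lapply(seq_len(nrow(x)), function(i)
    list(chrom = x$chrom[i], start = x$start[i], end = x$end[i]))
  dead <- rep(FALSE, length(rows))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(rows)) {
      if (dead[i]) next
      for (j in seq_along(rows)) {
        if (i == j || dead[j] || dead[i]) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= gap) {
          rows[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                            end = max(a$end, b$end))
          dead[j] <- TRUE
          merged_any <- TRUE
        }
      }
    }
    if (!merged_any) break
  }
  rows <- rows[!dead]
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  tibble::as_tibble(out)
}

bf_consensus <- function(peaks, min_replicates = 2) {
  merged <- bf_merge(peaks, gap = 0)
  res <- lapply(seq_len(nrow(merged)), function(i) {
    inside <- peaks$chrom == merged$chrom[i] &
      peaks$start >= merged$start[i] & peaks$end <= merged$end[i]
    list(chrom = merged$chrom[i], start = merged$start[i], end = merged$end[i],
         support = length(unique(peaks$replicate_id[inside])),
         net_signal = sum(peaks$net_signal[inside]))
  })
  out <- tibble::as_tibble(do.call(rbind, lapply(res, as.data.frame)))
  out[out$support >= min_replicates, ]
}

bf_nearest_tss <- function(chrom, centre, tss) {
  cand <- tss[tss$chrom == chrom, ]
  if (nrow(cand) == 0) return(list(gene = NA_character_, dist = NA_real_))
  d <- abs(cand$tss - centre)
  at_min <- cand$gene_id[d == min(d)]
  list(gene = sort(at_min)[1], dist = min(d))
}

bf_specificity <- function(regions_a, regions_b, min_fraction = 0.3) {
  shared_a <- vapply(seq_len(nrow(regions_a)), function(i) {
    any(vapply(seq_len(nrow(regions_b)), function(j) {
      if (regions_a$chrom[i] != regions_b$chrom[j]) return(FALSE)
      ov <- max(0, min(regions_a$end[i], regions_b$end[j]) -
                  max(regions_a$start[i], regions_b$start[j]))
      fa <- ov / (regions_a$end[i] - regions_a$start[i])
      fb <- ov / (regions_b$end[j] - regions_b$start[j])
      fa >= min_fraction && fb >= min_fraction
    }, logical(1)))
  }, logical(1))
  ifelse(shared_a, "shared", "specific")
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact one-sided (greater) rank-sum p by enumeration of all assignments of
# the pooled values to group x
bf_wilcox_greater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(w_all >= w_obs)
}

# slope-1 tangent index on the scaled rank/signal curve, found by scanning
# consecutive secant slopes (strictly convex curves: slopes increase)
bf_se_cutoff_index <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- seq_len(n) / n
  y <- (s - min(s)) / (max(s) - min(s))
  slopes <- diff(y) / diff(x)
  le1 <- which(slopes <= 1)
  if (length(le1) == 0) 1L else max(le1) + 1L
}

# --- random-instance generators -------------------------------------------

random_peaks <- function(n, n_chrom = 2, n_reps = 3, span = 10000) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(20:400, n, replace = TRUE)
  ip <- stats::runif(n, 0, 50)
  tibble::tibble(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + width,
    ip_signal = ip, input_signal = ip * stats::runif(n, 0, 0.5),
    replicate_id = paste0("rep", sample.int(n_reps, n, replace = TRUE)),
    condition = "A"
  ) |>
    dplyr::mutate(net_signal = pmax(ip_signal - input_signal, 0))
}

random_tss <- function(n, n_chrom = 2, span = 10000) {
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    tss = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# internally disjoint random region set
random_disjoint_regions <- function(n, condition, n_chrom = 2, span = 20000) {
  per_chrom <- split(seq_len(n), sample.int(n_chrom, n, replace = TRUE))
  out <- lapply(names(per_chrom), function(ci) {
    k <- length(per_chrom[[ci]])
    gaps <- sample.int(200, k, replace = TRUE)
    widths <- sample(30:300, k, replace = TRUE)
    start <- cumsum(gaps + widths) - widths + sample.int(span, 1)
    tibble::tibble(chrom = paste0("chr", ci), start = start,
                   end = start + widths)
  })
  x <- dplyr::bind_rows(out)
  x$condition <- condition
  x$region_id <- paste0(condition, ":", x$chrom, ":", x$start, "-", x$end)
  x$net_signal <- stats::runif(nrow(x), 0, 100)
  x
}

random_convex_se_curve <- function(n) {
  inc <- sort(stats::rexp(n - 1)) + 1e-9
  y <- c(0, cumsum(inc))
  y <- y / max(y)
  smin <- stats::runif(1, 0, 5)
  srange <- stats::runif(1, 10, 1000)
  signals <- smin + y * srange
  start <- seq_len(n) * 100000L
  tibble::tibble(
    region_id = sprintf("e%04d", sample.int(n)), chrom = "chr1",
    start = start, end = start + 1000L,
    net_signal = sample(signals) # shuffled: order must not matter
  )
}
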