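mk_peaks <- function(categories, chrom = "chr1") {
  n <- length(categories)
  start <- seq(0L, by = 1000L, length.out = n)
  genomic_intervals(rep(chrom, n), start, start + 500L,
                    peak_category = categories)
}

test_that("category table counts match a manual tally", {
  peaks <- list(
    HTN = mk_peaks(c("Promoter", "Promoter", "Distal", "Intronic",
                     "Intronic", "Exonic")),
    normal = mk_peaks(c("Distal", "Distal", "Intronic", "Promoter")))
  ct <- category_table(peaks)
  expect_equal(unname(ct$counts["HTN", ]), c(2L, 1L, 1L, 2L))
  expect_equal(unname(ct$counts["normal", ]), c(1L, 2L, 0L, 1L))
  expect_equal(unname(rowSums(ct$proportions)), c(1, 1))
  # single-category condition puts proportion 1 in that cell
  ct1 <- category_table(list(x = mk_peaks(rep("Distal", 3)),
                             y = mk_peaks("Promoter")))
  expect_equal(ct1$proportions["x", "Distal"], 1)
})

test_that("uncategorised peaks go to 'unassigned' and empty rows flag", {
  p <- genomic_intervals("chr1", c(0L, 1000L), c(500L, 1500L),
                         peak_category = c("Promoter", NA))
  ct <- category_table(list(z = p))
  expect_equal(unname(ct$counts[, "unassigned"]), 1L)
  expect_warning(
    category_table(list(
      a = mk_peaks("Promoter"),
      b = genomic_intervals("chr1", 0L, 10L, peak_category = NA))),
    "zero categorised")
})

test_that("chi-squared matches the closed form on 2x2 tables", {
  m <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  res <- chisq_independence(m)
  expect_equal(res$statistic, 100 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  # identical rows: statistic 0, p = 1
  res0 <- chisq_independence(matrix(c(5, 7, 5, 7), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # doubling all counts doubles the statistic
  res2 <- chisq_independence(2 * m)
  expect_equal(res2$statistic, 2 * res$statistic, tolerance = 1e-12)
})

test_that("chi-squared agrees with an independent Pearson formula", {
  set.seed(29)
  for (i in 1:100) {
    m <- matrix(rpois(8, lambda = 40) + 1L, nrow = 2)
    got <- chisq_independence(m)
    want <- oracle_chisq(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value,
                 pchisq(want$statistic, want$df, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  deg <- matrix(c(0, 0, 5, 7), 2, byrow = TRUE)
  expect_error(chisq_independence(deg), "degenerate row")
  deg2 <- matrix(c(0, 3, 0, 7), 2, byrow = TRUE)
  expect_error(chisq_independence(deg2), "degenerate column")
})

test_that("histone match fractions behave at the extremes and sum to 1", {
  peaks <- mk_peaks(rep("Distal", 10))
  empty <- histone_track("H3K4me1",
                         genomic_intervals(character(), integer(),
                                           integer()))
  r0 <- histone_match_fraction(peaks, empty)
  expect_equal(r0$matched_fraction, 0)
  full <- histone_track("H3K4me1",
                        genomic_intervals("chr1", 0L, 100000L))
  r1 <- histone_match_fraction(peaks, full)
  expect_equal(r1$matched_fraction, 1)
  set.seed(31)
  iv <- random_intervals(200L)
  tr <- histone_track("H3K27ac",
                      genomic_intervals(iv$chrom, iv$start, iv$end))
  q <- random_intervals(150L)
  qp <- genomic_intervals(q$chrom, q$start, q$end,
                          peak_category = "Distal")
  r <- histone_match_fraction(qp, tr)
  want <- sum(oracle_match_any(q$chrom, q$start, q$end,
                               iv$chrom, iv$start, iv$end))
  expect_equal(r$matched, want)
  expect_equal(r$matched_fraction + r$unmatched_fraction, 1)
  expect_warning(
    histone_match_fraction(genomic_intervals(character(), integer(),
                                             integer()), tr),
    "undefined")
})

test_that("gene coverage equals an exhaustive set enumeration", {
  set.seed(37)
  ann <- data.frame(gene = sprintf("g%02d", 1:50),
                    chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                    tss = sample.int(100000L, 50),
                    strand = sample(c("+", "-"), 50, replace = TRUE))
  iv <- random_intervals(300L, chroms = c("chr1", "chr2"),
                         max_pos = 120000L)
  peaks <- genomic_intervals(iv$chrom, iv$start, iv$end,
                             peak_category = sample(
                               c("Promoter", "Distal", "Exonic",
                                 "Intronic"), 300L, replace = TRUE))
  w <- 5000L
  cov <- gene_coverage(peaks, ann, gene_window_bp = w)
  # oracle: per (gene, category) peak counts by double loop
  cats <- c("Promoter", "Distal", "Exonic", "Intronic")
  counts <- matrix(0L, 50, 4, dimnames = list(ann$gene, cats))
  for (i in seq_len(300)) for (j in seq_len(50)) {
    ws <- max(ann$tss[j] - w, 0L); we <- ann$tss[j] + w
    if (iv$chrom[i] == ann$chrom[j] &&
        min(iv$end[i], we) - max(iv$start[i], ws) >= 1)
      counts[j, S4Vectors::mcols(peaks)$peak_category[i]] <-
        counts[j, S4Vectors::mcols(peaks)$peak_category[i]] + 1L
  }
  covered <- counts[rowSums(counts) > 0, , drop = FALSE]
  for (cc in cats)
    expect_setequal(cov$gene_sets[[cc]],
                    rownames(covered)[covered[, cc] > 0])
  expect_equal(unname(cov$max_per_category[cats]),
               unname(apply(counts, 2, max)))
  expect_setequal(cov$genes_all_categories,
                  rownames(covered)[rowSums(covered > 0) == 4])
  # powerset oracle over the four gene sets
  sets <- lapply(cats, function(cc) rownames(covered)[covered[, cc] > 0])
  names(sets) <- cats
  universe <- unique(unlist(sets))
  for (r in seq_len(nrow(cov$venn))) {
    members <- strsplit(cov$venn$region[r], "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[members], universe)
    outside <- unique(unlist(sets[setdiff(cats, members)]))
    expect_equal(cov$venn$count[r], length(setdiff(inside, outside)),
                 info = cov$venn$region[r])
  }
  expect_equal(sum(cov$venn$count), length(universe))
  # no-overlap case
  far <- genomic_intervals("chr9", 0L, 100L, peak_category = "Distal")
  # disjoint seqlevels legitimately mean zero coverage
  cov0 <- suppressWarnings(gene_coverage(far, ann, gene_window_bp = w))
  expect_equal(lengths(cov0$gene_sets), c(Promoter = 0L, Distal = 0L,
                                          Exonic = 0L, Intronic = 0L))
})
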