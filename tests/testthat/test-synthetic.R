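test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(shared_genes = 25L, k_top = 20L),
               "shared_genes")
  expect_error(synthetic_config(n_inferred = 10L,
                                n_curated_supported = 20L),
               "link-overlap")
  expect_error(synthetic_config(n_triple = 90L,
                                n_curated_supported = 60L),
               "link-overlap")
  expect_error(synthetic_config(condition_fractions = c(
    Hepatocytes_1 = 1.2, Hepatocytes_2 = 0.1, outlier = 0.5)),
    "fractions")
  expect_error(synthetic_config(
    blocks = list(A = c("C0", "C1"), B = c("C1", "C2"))), "distinct")
})

test_that("DEG fixture forces the planted Jaccard block structure", {
  # shared = k: within-block similarity 1, between-block 0
  cfg1 <- small_config(seed = 2, shared_genes = 20L)
  d1 <- generate_deg_tables(cfg1)
  J1 <- jaccard_matrix(d1$top_sets)
  expect_equal(J1["C0", "C3"], 1)
  expect_equal(J1["C0", "C1"], 0)

  # shared = 10 of k = 20, disjoint remainders: within-block 1/3
  cfg2 <- small_config(seed = 2)
  d2 <- generate_deg_tables(cfg2)
  J2 <- jaccard_matrix(d2$top_sets)
  expect_equal(J2["C0", "C8"], 1 / 3)
  expect_equal(J2["C1", "C4"], 1 / 3)
  expect_equal(J2["C0", "C4"], 0)
  # the outlier shares nothing with anyone
  expect_equal(unname(J2["C9", setdiff(rownames(J2), "C9")]),
               rep(0, nrow(J2) - 1L))

  # the planted top sets are exactly what top_upregulated recovers
  sets <- cluster_gene_sets(d2$degs, k = cfg2$k_top)
  for (cl in names(sets))
    expect_setequal(sets[[cl]], d2$top_sets[[cl]])
  # filler rows fail at least one filter
  extra <- d2$degs[!paste(d2$degs$gene, d2$degs$cluster) %in%
                     unlist(lapply(names(d2$top_sets), function(cl)
                       paste(d2$top_sets[[cl]], cl))), ]
  expect_true(all(extra$avg_log2FC <= 0 | extra$p_val >= 0.05))
})

test_that("cell metadata matches the configured condition skew", {
  cfg <- synthetic_config(seed = 4, cells_per_cluster = 2000L)
  cells <- generate_cells(cfg)
  expect_false(anyDuplicated(cells$cell_id) > 0)
  h1 <- cells[cells$cluster %in% cfg$blocks$Hepatocytes_1, ]
  frac <- mean(h1$condition == "HTN")
  # binomial 3-sigma bound at n = 7 * 2000
  expect_lt(abs(frac - 0.853), 3 * sqrt(0.853 * 0.147 / nrow(h1)))
  # extreme fraction is exact
  cfg1 <- small_config(seed = 4, condition_fractions = c(
    A = 1.0, B = 0, outlier = 0.5))
  cells1 <- generate_cells(cfg1)
  expect_true(all(cells1$condition[cells1$cluster == "C0"] == "HTN"))
  expect_true(all(cells1$condition[cells1$cluster == "C1"] == "normal"))
})

test_that("planted CRE truth is recoverable by brute-force rule check", {
  cfg <- small_config(seed = 9)
  ph <- generate_peaks_and_histone(cfg)
  for (cond in c("HTN", "normal")) {
    gr <- ph$peaks[[cond]]
    cats <- S4Vectors::mcols(gr)$peak_category
    ids <- S4Vectors::mcols(gr)$name
    chk <- function(track) oracle_match_any(
      as.character(GenomicRanges::seqnames(gr)), bed_start(gr),
      bed_end(gr),
      as.character(GenomicRanges::seqnames(track$intervals)),
      bed_start(track$intervals), bed_end(track$intervals))
    me3 <- chk(ph$tracks[[cond]]$H3K4me3)
    me1 <- chk(ph$tracks[[cond]]$H3K4me1)
    ac <- chk(ph$tracks[[cond]]$H3K27ac)
    expect_setequal(ids[cats == "Promoter" & me3],
                    ph$truth$true_promoters[[cond]])
    expect_setequal(ids[cats != "Promoter" & me1 & ac],
                    ph$truth$true_enhancers[[cond]])
  }
  # every planted promoter hosts exactly one annotated TSS inside it
  pg <- ph$promoter_gene$HTN
  gr <- ph$peaks$HTN
  ids <- S4Vectors::mcols(gr)$name
  for (pid in names(pg)) {
    i <- match(pid, ids)
    ann <- ph$annotation
    inside <- ann$chrom == as.character(GenomicRanges::seqnames(gr))[i] &
      ann$tss >= bed_start(gr)[i] & ann$tss < bed_end(gr)[i]
    expect_identical(ann$gene[inside], unname(pg[[pid]]))
  }
  expect_error(
    generate_peaks_and_histone(small_config(
      seed = 9, chrom_lengths = c(chr1 = 2e5, chr2 = 2e5, chr3 = 1e5))),
    "genome too small")
})

test_that("link tables realise the configured three-way agreement", {
  cfg <- small_config(seed = 13)
  ph <- generate_peaks_and_histone(cfg)
  enh <- ph$peaks$HTN[S4Vectors::mcols(ph$peaks$HTN)$name %in%
                        ph$truth$true_enhancers$HTN]
  lt <- generate_link_tables(cfg, enh, gene_pool = sprintf("G%04d", 1:400))
  expect_equal(nrow(lt$inferred), 40L)
  expect_equal(nrow(lt$true_edges), 15L)
  # brute-force filter: curated overlap + same gene + histone overlap
  inf <- lt$inferred
  cur <- lt$curated
  survive <- vapply(seq_len(nrow(inf)), function(i) {
    cur_ok <- any(cur$chrom == inf$chrom[i] & cur$gene == inf$gene[i] &
                    pmin(cur$end, inf$end[i]) -
                    pmax(cur$start, inf$start[i]) >= 1)
    his_ok <- any(oracle_match_any(inf$chrom[i], inf$start[i], inf$end[i],
                                   as.character(GenomicRanges::seqnames(enh)),
                                   bed_start(enh), bed_end(enh)))
    cur_ok && his_ok
  }, logical(1))
  expect_equal(sum(survive), 15L)
  expect_setequal(
    sprintf("%s|%s", inf$chrom[survive], inf$gene[survive]),
    sprintf("%s|%s",
            sub(":.*", "", lt$true_edges$cre_id), lt$true_edges$gene))
})

test_that("fixture bundles are byte-identical under a fixed seed", {
  cfg <- small_config(seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixtures(cfg, d1)
  make_fixtures(cfg, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  # and a different seed changes the content
  d3 <- withr::local_tempdir()
  make_fixtures(small_config(seed = 7), d3)
  expect_false(identical(readLines(file.path(d1, "deg_clusters.tsv")),
                         readLines(file.path(d3, "deg_clusters.tsv"))))
})

test_that("generated files parse cleanly through the package readers", {
  cfg <- small_config(seed = 8)
  outdir <- withr::local_tempdir()
  fx <- make_fixtures(cfg, outdir)
  degs <- read_deg_table(fx$paths$deg_clusters)
  expect_true(all(c("gene", "cluster", "avg_log2FC", "p_val") %in%
                    names(degs)))
  peaks <- read_bed(fx$paths$peaks_HTN, category_column = 7L)
  expect_length(peaks, cfg$n_atac_peaks %/% 2L)
  expect_false(any(is.na(S4Vectors::mcols(peaks)$peak_category)))
  hist <- read_bed(fx$paths$histone_HTN_H3K4me3, format = "narrowPeak")
  expect_gt(length(hist), 0L)
  ann <- read_gene_annotation(fx$paths$genes)
  expect_gt(nrow(ann), 0L)
  pw <- read_pathways(fx$paths$pathways)
  expect_named(pw, c("GO:0006631", "GO:0044282"))
  links <- read_links(fx$paths$links_inferred, "inferred")
  expect_equal(nrow(links), cfg$n_inferred)
})
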