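test_that("hypergeometric enrichment matches the exact tail sum", {
  bg <- sprintf("pk%02d", 1:10)
  occ <- data.frame(peak_id = bg[1:4], motif = "TFX")
  res <- motif_enrichment(bg[1:5], bg, occ)
  # N=10, K=4, n=5, k=4 -> C(4,4) C(6,1) / C(10,5) = 6/252
  row <- res[res$motif == "TFX", ]
  expect_equal(row$k, 4L)
  expect_equal(row$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(row$p_value, oracle_hyper_tail(4, 4, 10, 5),
               tolerance = 1e-15)
  # motif in every background peak -> p = 1
  occ_all <- data.frame(peak_id = bg, motif = "TFY")
  resY <- motif_enrichment(bg[1:3], bg, occ_all)
  expect_equal(resY$p_value, 1)
  # target = background -> k = K, fold = 1
  resT <- motif_enrichment(bg, bg, occ)
  expect_equal(resT$k, resT$K)
  expect_equal(resT$fold, 1)
  expect_error(motif_enrichment(c(bg, "extra"), bg, occ), "subset")
  expect_error(
    motif_enrichment(bg[1], bg,
                     data.frame(peak_id = "alien", motif = "T")),
    "outside")
})

test_that("enrichment p-values equal the oracle on random tables and BH is monotone", {
  set.seed(43)
  bg <- sprintf("pk%03d", 1:60)
  tg <- sample(bg, 25)
  occ <- expand.grid(peak_id = bg, motif = sprintf("M%02d", 1:12),
                     stringsAsFactors = FALSE)
  occ <- occ[runif(nrow(occ)) < 0.3, ]
  res <- motif_enrichment(tg, bg, occ)
  for (r in seq_len(nrow(res)))
    expect_equal(res$p_value[r],
                 oracle_hyper_tail(res$k[r], res$K[r], 60, 25),
                 tolerance = 1e-12)
  # BH q-values non-decreasing in p-rank (result is sorted by p)
  expect_true(all(diff(res$q_value) >= -1e-15))
  expect_identical(res$q_value,
                   p.adjust(res$p_value, "BH")[order(order(res$p_value))])
})

test_that("promoter network enumerates motif-bearing promoters of upregulated genes", {
  prom <- genomic_intervals("chr1", c(0L, 2000L), c(500L, 2500L),
                            name = c("pkA", "pkB"),
                            peak_category = "Promoter")
  S4Vectors::mcols(prom)$cre_class <- "promoter"
  S4Vectors::mcols(prom)$gene <- c("CYP3A4", "OTHER")
  tfs <- sprintf("TF%d", 1:5)
  occ <- data.frame(peak_id = "pkA", motif = tfs)
  net <- build_promoter_network(
    upregulated = c("CYP3A4"), promoter_calls = prom,
    occurrences = occ, tf_universe = tfs)
  # one promoter bearing five TF motifs -> 5 edges into the gene
  expect_equal(nrow(net), 5L)
  expect_setequal(net$tf, tfs)
  expect_true(all(net$gene == "CYP3A4"))
  # gene upregulated but no promoter call -> no edges
  net0 <- build_promoter_network("GENE_X", prom, occ, tfs)
  expect_equal(nrow(net0), 0L)
  # TF outside the universe is dropped; self-loops flagged
  occ2 <- rbind(occ, data.frame(peak_id = "pkA",
                                motif = c("ALIEN", "CYP3A4")))
  net2 <- build_promoter_network("CYP3A4", prom, occ2,
                                 c(tfs, "CYP3A4"))
  expect_false("ALIEN" %in% net2$tf)
  expect_true(net2$self_loop[net2$tf == "CYP3A4"])
  expect_error(build_promoter_network("g", prom[, setdiff(
    names(S4Vectors::mcols(prom)), "gene")], occ, tfs), "gene")
})

test_that("promoter network equals planted truth on generator fixtures", {
  cfg <- small_config(seed = 19)
  outdir <- withr::local_tempdir()
  fx <- make_fixtures(cfg, outdir)
  prom <- call_promoters(fx$peaks_histone$peaks$HTN,
                         fx$peaks_histone$tracks$HTN$H3K4me3)
  prom <- assign_gene(prom, fx$peaks_histone$annotation)
  net <- build_promoter_network(fx$cond$upregulated, prom, fx$motifs,
                                attr(fx$motifs, "tfs"))
  want <- fx$truth$promoter_edges
  expect_setequal(paste(net$tf, net$cre_id, net$gene),
                  paste(want$tf, want$cre_id, want$gene))
})

test_that("triple-evidence filter keeps exactly the supported links", {
  enh <- genomic_intervals("chr1", c(0L, 5000L), c(1000L, 6000L),
                           name = c("e1", "e2"),
                           peak_category = "Distal")
  inferred <- data.frame(
    tf = c("T1", "T2", "T3"),
    chrom = "chr1", start = c(100L, 5100L, 9000L),
    end = c(900L, 5900L, 9500L),
    gene = c("gA", "gB", "gC"), source = "inferred")
  curated <- data.frame(chrom = "chr1",
                        start = c(50L, 5100L), end = c(950L, 5900L),
                        gene = c("gA", "gZ"), source = "curated")
  res <- build_enhancer_network(inferred, curated, enh)
  # link 1: curated (overlap + gene) and histone -> kept
  # link 2: curated overlap but wrong gene -> dropped
  # link 3: no curated, no histone -> dropped
  expect_equal(nrow(res$edges), 1L)
  expect_identical(res$edges$gene, "gA")
  # overlap-only support admits link 2 (histone also present)
  res2 <- build_enhancer_network(inferred, curated, enh,
                                 require_gene_match = FALSE)
  expect_setequal(res2$edges$gene, c("gA", "gB"))
  # curated support without histone support is still removed
  res3 <- build_enhancer_network(inferred, curated, enh[0])
  expect_equal(nrow(res3$edges), 0L)
  # all three evidence sources identical -> everything survives
  cur_all <- data.frame(chrom = inferred$chrom, start = inferred$start,
                        end = inferred$end, gene = inferred$gene,
                        source = "curated")
  enh_all <- genomic_intervals(inferred$chrom, inferred$start,
                               inferred$end, peak_category = "Distal")
  res4 <- build_enhancer_network(inferred, cur_all, enh_all)
  expect_equal(nrow(res4$edges), 3L)
})

test_that("surviving edges equal the brute-force three-way filter on fixtures", {
  for (seed in c(2, 11, 23)) {
    cfg <- small_config(seed = seed)
    ph <- generate_peaks_and_histone(cfg)
    enh_calls <- call_enhancers(ph$peaks$HTN, ph$tracks$HTN$H3K4me1,
                                ph$tracks$HTN$H3K27ac)
    lt <- generate_link_tables(cfg, enh_calls,
                               gene_pool = sprintf("G%04d", 1:400))
    res <- build_enhancer_network(lt$inferred, lt$curated, enh_calls)
    expect_equal(nrow(res$edges), cfg$n_triple)
    expect_setequal(paste(res$edges$cre_id, res$edges$gene),
                    paste(lt$true_edges$cre_id, lt$true_edges$gene))
    # Venn regions satisfy inclusion-exclusion over the inferred links
    expect_equal(sum(res$venn_pairs$count), cfg$n_inferred)
    triple <- res$venn_pairs$count[
      res$venn_pairs$region == "inferred&curated&histone"]
    expect_equal(triple, cfg$n_triple)
  }
})
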