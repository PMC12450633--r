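#' Configuration for the synthetic-data generator
#'
#' Fixes every knob of the generator: the planted subtype block structure
#' of the hepatocyte clusters, the condition skew of each subtype, the
#' genome and peak layout, the rates of histone-supported regulatory
#' elements, motif density and the three-way agreement of the
#' enhancer-link evidence sources. Defaults emulate the study conditions
#' at roughly 1/10 scale: 12 hepatocyte clusters in two blocks
#' (C0/C3/C8/C11/C12/C13/C15 and C1/C4/C7/C14) plus the zero-similarity
#' outlier C9; disease fractions 0.853 and 0.12; top-20 gene sets sharing
#' 10 genes within a block; ~2,000 genes and ~2,000 accessible peaks.
#'
#' @param seed Master random seed (integer); every stage derives a
#'   documented sub-seed from it.
#' @param blocks Named list of character vectors partitioning the cluster
#'   ids into planted subtypes.
#' @param outlier Optional singleton cluster sharing no top genes with
#'   any other cluster.
#' @param k_top Top-gene set size per cluster.
#' @param shared_genes Number of top genes shared within a block
#'   (remainders are cluster-private), must be <= `k_top`.
#' @param n_genes Size of the gene universe.
#' @param condition_fractions Named numeric: disease-cell fraction per
#'   subtype (plus `outlier`).
#' @param cells_per_cluster Cells generated per cluster.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp);
#'   the last chromosome is reserved for enhancer-link decoys.
#' @param n_atac_peaks Total accessible peaks (split evenly across the
#'   two conditions).
#' @param category_probs Named list (per condition) of probabilities over
#'   the four peak categories.
#' @param planted_promoter_rate Named numeric per condition: fraction of
#'   Promoter-category peaks given H3K4me3 support.
#' @param planted_enhancer_rate Named numeric per condition: fraction of
#'   non-Promoter peaks given both H3K4me1 and H3K27ac support.
#' @param n_tfs Number of TF motifs.
#' @param motif_density Per-(peak, TF) occurrence probability.
#' @param n_inferred,n_curated_supported,n_triple Enhancer-link counts:
#'   inferred links, those with curated support, and those additionally
#'   histone-supported (the planted surviving edges); must be
#'   non-increasing.
#' @param slot_bp Width of the exclusive genomic slot holding one peak
#'   and its histone evidence.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    blocks = list(
      Hepatocytes_1 = c("C0", "C3", "C8", "C11", "C12", "C13", "C15"),
      Hepatocytes_2 = c("C1", "C4", "C7", "C14")),
    outlier = "C9",
    k_top = 20L,
    shared_genes = 10L,
    n_genes = 2000L,
    condition_fractions = c(Hepatocytes_1 = 0.853, Hepatocytes_2 = 0.12,
                            outlier = 0.5),
    cells_per_cluster = 150L,
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
    n_atac_peaks = 2000L,
    category_probs = list(
      HTN = c(Promoter = 0.168, Distal = 0.20, Exonic = 0.15,
              Intronic = 0.482),
      normal = c(Promoter = 0.083, Distal = 0.30, Exonic = 0.15,
                 Intronic = 0.467)),
    planted_promoter_rate = c(HTN = 0.5, normal = 0.5),
    planted_enhancer_rate = c(HTN = 0.15, normal = 0.02),
    n_tfs = 30L,
    motif_density = 0.05,
    n_inferred = 100L,
    n_curated_supported = 60L,
    n_triple = 40L,
    slot_bp = 2000L) {
  cfg <- list(seed = as.integer(seed), blocks = blocks, outlier = outlier,
              k_top = as.integer(k_top),
              shared_genes = as.integer(shared_genes),
              n_genes = as.integer(n_genes),
              condition_fractions = condition_fractions,
              cells_per_cluster = as.integer(cells_per_cluster),
              chrom_lengths = chrom_lengths,
              n_atac_peaks = as.integer(n_atac_peaks),
              category_probs = category_probs,
              planted_promoter_rate = planted_promoter_rate,
              planted_enhancer_rate = planted_enhancer_rate,
              n_tfs = as.integer(n_tfs), motif_density = motif_density,
              n_inferred = as.integer(n_inferred),
              n_curated_supported = as.integer(n_curated_supported),
              n_triple = as.integer(n_triple),
              slot_bp = as.integer(slot_bp))
  all_clusters <- c(unlist(blocks, use.names = FALSE), outlier)
  if (anyDuplicated(all_clusters))
    stop("blocks and outlier must partition distinct cluster ids")
  if (cfg$shared_genes > cfg$k_top)
    stop("shared_genes must not exceed k_top")
  need_fr <- c(names(blocks), if (length(outlier)) "outlier")
  if (!all(need_fr %in% names(condition_fractions)))
    stop("condition_fractions must name every block (",
         paste(need_fr, collapse = ", "), ")")
  fr <- c(condition_fractions, motif_density,
          unlist(category_probs), planted_promoter_rate,
          planted_enhancer_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!(cfg$n_inferred >= cfg$n_curated_supported &&
        cfg$n_curated_supported >= cfg$n_triple))
    stop("inconsistent link-overlap counts: need ",
         "n_inferred >= n_curated_supported >= n_triple")
  if (cfg$n_atac_peaks < 2L) stop("need at least 2 peaks")
  structure(cfg, class = "synthetic_config")
}

# Documented sub-seed derivation: one master seed, fixed offsets per stage.
sub_seed <- function(seed, stage) {
  stages <- c(degs = 1L, condition = 2L, cells = 3L, peaks = 4L,
              motifs = 5L, links = 6L)
  as.integer((abs(as.numeric(seed)) * 97 + stages[[stage]] * 1009) %%
               2147483647)
}

# sample() that never expands a length-1 vector into 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

gene_universe <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

#' Generate per-cluster differential-expression tables
#'
#' Plants the subtype structure: clusters of the same block share exactly
#' `shared_genes` of their `k_top` top upregulated genes and nothing with
#' other blocks; the outlier cluster shares no genes with anyone. Planted
#' top genes get positive `avg_log2FC` and `p_val < 0.05`; each cluster
#' also carries filler records that fail exactly one of the two filters,
#' so the top-gene selection is forced to equal the planted set.
#'
#' @param config A [synthetic_config()].
#' @return List with `degs` (data frame: gene, cluster, avg_log2FC,
#'   p_val, contrast), `top_sets` (planted per-cluster gene sets) and
#'   `true_subtype` (named cluster -> subtype label or `"excluded"`).
#' @export
generate_deg_tables <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "degs"))
  k <- config$k_top
  sh <- config$shared_genes
  universe <- sample(gene_universe(config))
  clusters <- c(unlist(config$blocks, use.names = FALSE), config$outlier)
  need <- sum(vapply(config$blocks, function(b)
    sh + length(b) * (k - sh), integer(1))) +
    length(config$outlier) * k
  if (need > length(universe))
    stop("gene universe too small for the requested block structure")
  cursor <- 0L
  take <- function(m) {
    out <- universe[cursor + seq_len(m)]
    cursor <<- cursor + m
    out
  }
  top_sets <- list()
  true_subtype <- character()
  for (bn in names(config$blocks)) {
    pool <- take(sh)
    for (cl in config$blocks[[bn]]) {
      top_sets[[cl]] <- c(pool, take(k - sh))
      true_subtype[cl] <- bn
    }
  }
  for (cl in config$outlier) {
    top_sets[[cl]] <- take(k)
    true_subtype[cl] <- "excluded"
  }
  rows <- lapply(clusters, function(cl) {
    genes <- top_sets[[cl]]
    planted <- data.frame(
      gene = genes, cluster = cl,
      avg_log2FC = round(sort(stats::runif(k, 0.5, 3),
                              decreasing = TRUE), 4),
      p_val = round(stats::runif(k, 1e-6, 0.049), 6),
      contrast = "cluster_vs_rest", stringsAsFactors = FALSE)
    filler_genes <- sample(setdiff(gene_universe(config), genes), 30L)
    filler <- data.frame(
      gene = filler_genes, cluster = cl,
      avg_log2FC = c(round(stats::runif(15L, -3, -0.1), 4),
                     round(stats::runif(15L, 0.1, 5), 4)),
      p_val = c(round(stats::runif(15L, 1e-6, 0.049), 6),
                round(stats::runif(15L, 0.05, 1), 6)),
      contrast = "cluster_vs_rest", stringsAsFactors = FALSE)
    rbind(planted, filler)
  })
  list(degs = do.call(rbind, rows), top_sets = top_sets,
       true_subtype = true_subtype)
}

#' Generate the disease-vs-normal contrast and pathway gene sets
#'
#' Emulates the condition contrast within the disease-skewed subtype plus
#' two pathway gene sets (fatty-acid metabolic process and small-molecule
#' catabolic process analogues) constructed so that the intersection of
#' the condition-upregulated genes with the pathway union is exactly the
#' planted marker set (by default UPB1, SDS, PCCA, CYP3A4, PPARGC1A).
#'
#' @param config A [synthetic_config()].
#' @return List with `degs` (contrast `"HTN_vs_normal"`), `pathways`
#'   (named list of two gene sets), `upregulated` and `marker_genes`.
#' @export
generate_condition_degs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "condition"))
  markers <- c("UPB1", "SDS", "PCCA", "CYP3A4", "PPARGC1A")
  universe <- sample(gene_universe(config))
  up_other <- universe[1:200]
  not_up <- universe[201:400]
  upregulated <- c(markers, up_other)
  pathways <- list(
    "GO:0006631" = c(markers[1:3], not_up[1:40]),
    "GO:0044282" = c(markers[3:5], not_up[31:80]))
  up_rows <- data.frame(
    gene = upregulated, cluster = "Hepatocytes_1",
    avg_log2FC = round(stats::runif(length(upregulated), 0.3, 4), 4),
    p_val = round(stats::runif(length(upregulated), 1e-6, 0.049), 6),
    contrast = "HTN_vs_normal", stringsAsFactors = FALSE)
  dn <- universe[401:500]
  dn_rows <- data.frame(
    gene = dn, cluster = "Hepatocytes_1",
    avg_log2FC = round(stats::runif(100L, -4, 0), 4),
    p_val = round(stats::runif(100L, 0, 1), 6),
    contrast = "HTN_vs_normal", stringsAsFactors = FALSE)
  list(degs = rbind(up_rows, dn_rows), pathways = pathways,
       upregulated = sort(upregulated), marker_genes = markers)
}

#' Generate cell metadata with planted condition skew
#'
#' Each cluster receives `cells_per_cluster` cells; the number of
#' disease-condition cells is binomial with the fraction configured for
#' the cluster's subtype, so empirical fractions match within sampling
#' error.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `cell_id`, `cluster`, `condition`.
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "cells"))
  clusters <- c(unlist(config$blocks, use.names = FALSE), config$outlier)
  subtype_of <- character()
  for (bn in names(config$blocks))
    subtype_of[config$blocks[[bn]]] <- bn
  subtype_of[config$outlier] <- "outlier"
  n <- config$cells_per_cluster
  rows <- lapply(clusters, function(cl) {
    frac <- config$condition_fractions[[subtype_of[[cl]]]]
    n_htn <- stats::rbinom(1L, n, frac)
    data.frame(cluster = cl,
               condition = c(rep("HTN", n_htn),
                             rep("normal", n - n_htn)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(cell_id = sprintf("cell_%06d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  out
}

#' Generate accessible peaks, histone tracks and gene annotation
#'
#' Peaks are laid out in exclusive genomic slots (one peak per slot, with
#' its histone evidence confined to the same slot), so every histone
#' overlap is planted, never accidental. Per condition: a configured
#' fraction of Promoter-category peaks get an overlapping H3K4me3
#' interval (the planted promoters); a fraction of non-Promoter peaks get
#' both H3K4me1 and H3K27ac (the planted enhancers); the remaining peaks
#' are decoys carrying no mark, a single enhancer mark, or both enhancer
#' marks on a Promoter-category peak — all of which must be rejected by
#' the calling rules. Each planted promoter hosts exactly one gene TSS
#' inside the peak (drawn from the condition-upregulated set when
#' supplied), fixing the promoter-to-gene truth; additional gene TSSs are
#' placed in unused slots far enough from every peak to be outside the
#' promoter window.
#'
#' @param config A [synthetic_config()].
#' @param upregulated Optional character vector of condition-upregulated
#'   genes to use for promoter target genes.
#' @return List with `peaks` (named list of `GRanges` per condition),
#'   `tracks` (per condition, named list of [histone_track()]s),
#'   `annotation` (gene annotation data frame), `promoter_gene` (named
#'   list per condition: planted promoter id -> gene) and `truth`
#'   (`true_promoters`, `true_enhancers` id sets per condition).
#' @export
generate_peaks_and_histone <- function(config, upregulated = character()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "peaks"))
  S <- config$slot_bp
  conds <- names(config$category_probs)
  n_cond <- config$n_atac_peaks %/% length(conds)
  peak_chroms <- utils::head(names(config$chrom_lengths), -1L)
  slots_per_chrom <- floor(config$chrom_lengths[peak_chroms] / S)
  n_slots <- sum(slots_per_chrom)
  if (n_cond * length(conds) + 400L > n_slots)
    stop("genome too small to place the requested peaks in exclusive ",
         "slots")
  slot_coord <- function(idx) {
    chrom <- character(length(idx)); off <- integer(length(idx))
    bounds <- cumsum(slots_per_chrom)
    prev <- c(0L, utils::head(bounds, -1L))
    for (ci in seq_along(peak_chroms)) {
      inb <- idx > prev[ci] & idx <= bounds[ci]
      chrom[inb] <- peak_chroms[ci]
      off[inb] <- (idx[inb] - prev[ci] - 1L) * S
    }
    list(chrom = chrom, start = off)
  }
  next_slot <- 0L
  peaks <- list(); tracks <- list(); truth_p <- list(); truth_e <- list()
  promoter_gene <- list()
  ann_rows <- list()
  used_genes <- character()
  gene_pool <- sample(gene_universe(config))
  pick_gene <- function(prefer) {
    cand <- setdiff(prefer, used_genes)
    if (length(cand) == 0L) cand <- setdiff(gene_pool, used_genes)
    g <- cand[[1L]]
    used_genes <<- c(used_genes, g)
    g
  }
  for (cond in conds) {
    idx <- next_slot + seq_len(n_cond)
    next_slot <- next_slot + n_cond
    sc <- slot_coord(idx)
    w <- sample(300:700, n_cond, replace = TRUE)
    p_start <- sc$start + 600L
    p_end <- p_start + w
    cat_p <- config$category_probs[[cond]]
    categories <- sample(PEAK_CATEGORIES, n_cond, replace = TRUE,
                         prob = cat_p[PEAK_CATEGORIES])
    ids <- sprintf("%s_peak_%04d", cond, seq_len(n_cond))
    gr <- genomic_intervals(sc$chrom, p_start, p_end, name = ids,
                            score = round(stats::runif(n_cond, 1, 100), 2),
                            peak_category = categories,
                            summit_offset = as.integer(w %/% 2L))
    prom_idx <- which(categories == "Promoter")
    nonprom_idx <- which(categories != "Promoter")
    n_tp <- round(config$planted_promoter_rate[[cond]] * length(prom_idx))
    n_te <- round(config$planted_enhancer_rate[[cond]] *
                    length(nonprom_idx))
    tp <- sort(resample(prom_idx, n_tp))
    te <- sort(resample(nonprom_idx, n_te))
    rest_prom <- setdiff(prom_idx, tp)
    rest_non <- setdiff(nonprom_idx, te)
    # decoys: Promoter-category peaks with both enhancer marks;
    # non-Promoter peaks with exactly one of the two enhancer marks
    dec_both <- resample(rest_prom, round(0.3 * length(rest_prom)))
    one_mark <- resample(rest_non, round(0.4 * length(rest_non)))
    dec_me1 <- one_mark[seq_len(length(one_mark) %/% 2L)]
    dec_ac <- setdiff(one_mark, dec_me1)
    hist_iv <- function(i) {
      hs <- p_start[i] - 100L + sample(0:100, length(i), replace = TRUE)
      genomic_intervals(sc$chrom[i], hs, hs + 300L,
                        name = sprintf("h_%s_%d", cond, i))
    }
    empty_gr <- genomic_intervals(character(), integer(), integer())
    me3 <- if (length(tp)) hist_iv(tp) else empty_gr
    me1_idx <- sort(c(te, dec_both, dec_me1))
    ac_idx <- sort(c(te, dec_both, dec_ac))
    me1 <- if (length(me1_idx)) hist_iv(me1_idx) else empty_gr
    ac <- if (length(ac_idx)) hist_iv(ac_idx) else empty_gr
    peaks[[cond]] <- gr
    tracks[[cond]] <- list(
      H3K4me3 = histone_track("H3K4me3", me3),
      H3K4me1 = histone_track("H3K4me1", me1),
      H3K27ac = histone_track("H3K27ac", ac))
    truth_p[[cond]] <- ids[tp]
    truth_e[[cond]] <- ids[te]
    pg <- character()
    for (i in tp) {
      g <- pick_gene(upregulated)
      pg[ids[i]] <- g
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene = g, chrom = sc$chrom[i],
        tss = as.integer(p_start[i] + w[i] %/% 2L),
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    promoter_gene[[cond]] <- pg
  }
  # background genes in unused slots, > 2 kb from every peak
  n_bg <- 300L
  bg_idx <- next_slot + seq_len(n_bg)
  sc <- slot_coord(bg_idx)
  for (j in seq_len(n_bg)) {
    g <- pick_gene(character())
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene = g, chrom = sc$chrom[j],
      tss = as.integer(sc$start[j] + 1800L),
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann_rows)
  list(peaks = peaks, tracks = tracks, annotation = annotation,
       promoter_gene = promoter_gene,
       truth = list(true_promoters = truth_p, true_enhancers = truth_e))
}

#' Generate a motif-occurrence table
#'
#' Every (peak, TF) pair occurs independently with probability
#' `motif_density`; in addition each listed promoter peak is guaranteed
#' at least one motif so the promoter network is non-trivial.
#'
#' @param config A [synthetic_config()].
#' @param peak_ids Character vector of peak ids to cover.
#' @param ensure_peaks Peak ids guaranteed to carry >= 1 motif.
#' @return Data frame with `peak_id`, `motif` (unique pairs) and the TF
#'   name vector as attribute `tfs`.
#' @export
generate_motifs <- function(config, peak_ids, ensure_peaks = character()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "motifs"))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  hit <- matrix(stats::runif(length(peak_ids) * config$n_tfs) <
                  config$motif_density,
                nrow = length(peak_ids))
  for (p in intersect(ensure_peaks, peak_ids)) {
    i <- match(p, peak_ids)
    if (!any(hit[i, ])) hit[i, sample(config$n_tfs, 1L)] <- TRUE
  }
  idx <- which(hit, arr.ind = TRUE)
  occ <- data.frame(peak_id = peak_ids[idx[, 1L]],
                    motif = tfs[idx[, 2L]], stringsAsFactors = FALSE)
  occ <- occ[order(occ$peak_id, occ$motif), , drop = FALSE]
  rownames(occ) <- NULL
  attr(occ, "tfs") <- tfs
  occ
}

#' Generate enhancer-gene link tables with controlled evidence agreement
#'
#' Builds `n_inferred` inference-style links over distinct genes:
#' `n_triple` of them sit on true (histone-supported) enhancer intervals
#' and carry a matching curated annotation; `n_curated_supported -
#' n_triple` carry curated support but lie on the reserved decoy
#' chromosome where no enhancer is ever called; the remainder lack
#' curated support (no curated row, or a curated row naming a different
#' gene). The triple-supported links are the planted surviving edges.
#'
#' @param config A [synthetic_config()].
#' @param true_enhancers `GRanges` of histone-supported enhancer
#'   intervals (e.g. the planted disease-condition enhancers).
#' @param gene_pool Character vector of target gene symbols to draw from.
#' @return List with `inferred`, `curated` (link data frames) and
#'   `true_edges` (data frame `tf`, `cre_id`, `gene`).
#' @export
generate_link_tables <- function(config, true_enhancers, gene_pool) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "links"))
  n_inf <- config$n_inferred
  n_cur <- config$n_curated_supported
  n_tri <- config$n_triple
  if (length(true_enhancers) < 1L && n_tri > 0L)
    stop("no true enhancers available to anchor triple-supported links")
  decoy_chrom <- utils::tail(names(config$chrom_lengths), 1L)
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  genes <- sample(gene_pool, n_inf)
  tf_of <- sample(tfs, n_inf, replace = TRUE)
  anchor <- sample(length(true_enhancers), n_tri,
                   replace = n_tri > length(true_enhancers))
  inf <- data.frame(tf = tf_of, chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, gene = genes,
                    score = round(stats::runif(n_inf), 3),
                    stringsAsFactors = FALSE)
  if (n_tri > 0L) {
    inf$chrom[1:n_tri] <-
      as.character(GenomicRanges::seqnames(true_enhancers))[anchor]
    inf$start[1:n_tri] <- bed_start(true_enhancers)[anchor]
    inf$end[1:n_tri] <- bed_end(true_enhancers)[anchor]
  }
  n_decoy <- n_inf - n_tri
  if (n_decoy > 0L) {
    pos <- (seq_len(n_decoy) - 1L) * 2000L + 1000L
    inf$chrom[(n_tri + 1L):n_inf] <- decoy_chrom
    inf$start[(n_tri + 1L):n_inf] <- pos
    inf$end[(n_tri + 1L):n_inf] <- pos + 500L
  }
  supported <- seq_len(n_cur)
  cur <- data.frame(chrom = inf$chrom[supported],
                    start = pmax(inf$start[supported] - 50L, 0L),
                    end = inf$end[supported] + 50L,
                    gene = inf$gene[supported], stringsAsFactors = FALSE)
  unsupported <- setdiff(seq_len(n_inf), supported)
  wrong_gene <- unsupported[seq_len(length(unsupported) %/% 2L)]
  if (length(wrong_gene)) {
    other <- setdiff(gene_pool, inf$gene)
    cur <- rbind(cur, data.frame(
      chrom = inf$chrom[wrong_gene], start = inf$start[wrong_gene],
      end = inf$end[wrong_gene],
      gene = sample(other, length(wrong_gene)),
      stringsAsFactors = FALSE))
  }
  true_edges <- if (n_tri > 0L) data.frame(
    tf = inf$tf[1:n_tri],
    cre_id = sprintf("%s:%d-%d", inf$chrom[1:n_tri], inf$start[1:n_tri],
                     inf$end[1:n_tri]),
    gene = inf$gene[1:n_tri], stringsAsFactors = FALSE)
  else data.frame(tf = character(), cre_id = character(),
                  gene = character())
  inf$source <- "inferred"
  cur$source <- "curated"
  list(inferred = inf, curated = cur, true_edges = true_edges)
}

#' Write a complete fixture bundle with planted truth
#'
#' Runs every generator stage under the config's master seed and writes
#' the exact file dialects the pipeline consumes, plus a `truth.json`
#' sidecar recording the planted ground truth (subtype partition, marker
#' genes, true promoter/enhancer ids, promoter target genes and the
#' surviving enhancer edges). Identical configs produce byte-identical
#' bundles.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects, the `truth`
#'   list and `paths` to every file written.
#' @export
make_fixtures <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deg <- generate_deg_tables(config)
  cond <- generate_condition_degs(config)
  cells <- generate_cells(config)
  ph <- generate_peaks_and_histone(config,
                                   upregulated = cond$upregulated)
  all_peak_ids <- unlist(lapply(ph$peaks, function(g)
    S4Vectors::mcols(g)$name), use.names = FALSE)
  occ <- generate_motifs(config, all_peak_ids,
                         ensure_peaks = ph$truth$true_promoters$HTN)
  links <- generate_link_tables(
    config,
    true_enhancers = ph$peaks$HTN[S4Vectors::mcols(ph$peaks$HTN)$name
                                  %in% ph$truth$true_enhancers$HTN],
    gene_pool = gene_universe(config))
  # planted promoter-network edges, re-derived by brute-force rule check
  pg <- ph$promoter_gene$HTN
  tfs <- attr(occ, "tfs")
  prom_edges <- list()
  for (pid in names(pg)) {
    g <- pg[[pid]]
    if (!(g %in% cond$upregulated)) next
    for (tf in occ$motif[occ$peak_id == pid]) {
      if (!(tf %in% tfs)) next
      prom_edges[[length(prom_edges) + 1L]] <-
        data.frame(tf = tf, cre_id = pid, gene = g,
                   stringsAsFactors = FALSE)
    }
  }
  prom_edges <- if (length(prom_edges)) do.call(rbind, prom_edges)
  else data.frame(tf = character(), cre_id = character(),
                  gene = character())
  p <- function(f) file.path(outdir, f)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p(f)
  }
  paths <- list(
    deg_clusters = wt(deg$degs, "deg_clusters.tsv"),
    deg_condition = wt(cond$degs, "deg_condition.tsv"),
    cells = wt(cells, "cells.tsv"),
    genes = wt(ph$annotation, "genes.tsv"),
    motifs = wt(occ, "motifs.tsv"),
    links_inferred = wt(links$inferred, "links_inferred.tsv"),
    links_curated = wt(links$curated, "links_curated.tsv"))
  gmt <- vapply(names(cond$pathways), function(id)
    paste(c(id, id, cond$pathways[[id]]), collapse = "\t"), character(1))
  writeLines(gmt, p("pathways.gmt"))
  paths$pathways <- p("pathways.gmt")
  for (cn in names(ph$peaks)) {
    f <- sprintf("peaks_%s.bed", cn)
    write_bed(ph$peaks[[cn]], p(f))
    paths[[paste0("peaks_", cn)]] <- p(f)
    for (mk in names(ph$tracks[[cn]])) {
      f <- sprintf("histone_%s_%s.narrowPeak", cn, mk)
      write_bed(ph$tracks[[cn]][[mk]]$intervals, p(f),
                format = "narrowPeak")
      paths[[sprintf("histone_%s_%s", cn, mk)]] <- p(f)
    }
  }
  truth <- list(
    true_subtype = as.list(deg$true_subtype),
    marker_genes = cond$marker_genes,
    upregulated = cond$upregulated,
    true_promoters = ph$truth$true_promoters,
    true_enhancers = ph$truth$true_enhancers,
    promoter_gene = lapply(ph$promoter_gene, as.list),
    promoter_edges = prom_edges,
    enhancer_edges = links$true_edges)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$truth <- p("truth.json")
  invisible(list(config = config, deg = deg, cond = cond, cells = cells,
                 peaks_histone = ph, motifs = occ, links = links,
                 truth = truth, paths = paths))
}
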