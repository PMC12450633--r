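#' Build a pipeline configuration
#'
#' Collects input paths, stage toggles and thresholds into a validated
#' run configuration. `pipeline_config_from_fixtures()` wires one up
#' directly from a [make_fixtures()] bundle directory.
#'
#' @param inputs Named list of input file paths (see Details).
#' @param outdir Output directory.
#' @param stages Character subset of
#'   `c("subtypes", "markers", "cre", "peak_stats", "grn")`.
#' @param conditions Condition labels, first one treated as the disease
#'   state (default `c("HTN", "normal")`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param k,fc_min,p_max Top-gene selection thresholds (20, 0, 0.05).
#' @param n_subtypes Number of subtypes to cut (2).
#' @param min_bp Minimum overlap in bp (1).
#' @param promoter_window_bp,enhancer_max_distance_bp,gene_window_bp
#'   Distance parameters (2000, 100000, 50000 bp).
#' @param condition_contrast Contrast label of the disease-vs-normal DEG
#'   table (`"HTN_vs_normal"`).
#'
#' @details Expected `inputs` entries (a stage is checked only when
#' enabled): `deg_clusters`, `deg_condition`, `pathways`, `genes`,
#' `motifs`, `links_inferred`, `links_curated`, and per condition
#' `peaks_<cond>` plus `histone_<cond>_<mark>` for the three marks.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, outdir,
                            stages = c("subtypes", "markers", "cre",
                                       "peak_stats", "grn"),
                            conditions = c("HTN", "normal"),
                            seed = 1L, k = 20L, fc_min = 0,
                            p_max = 0.05, n_subtypes = 2L, min_bp = 1L,
                            promoter_window_bp = 2000L,
                            enhancer_max_distance_bp = 100000L,
                            gene_window_bp = 50000L,
                            condition_contrast = "HTN_vs_normal") {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(inputs = inputs, outdir = outdir, stages = stages,
              conditions = conditions, seed = as.integer(seed),
              k = as.integer(k), fc_min = fc_min, p_max = p_max,
              n_subtypes = as.integer(n_subtypes),
              min_bp = as.integer(min_bp),
              promoter_window_bp = as.integer(promoter_window_bp),
              enhancer_max_distance_bp =
                as.integer(enhancer_max_distance_bp),
              gene_window_bp = as.integer(gene_window_bp),
              condition_contrast = condition_contrast)
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must be in (0, 1]")
  if (cfg$min_bp < 1L) stop("min_bp must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param fixture_dir Directory written by [make_fixtures()].
#' @param ... Passed on to `pipeline_config()`.
#' @export
pipeline_config_from_fixtures <- function(fixture_dir, outdir, ...) {
  conds <- c("HTN", "normal")
  inputs <- list(
    deg_clusters = file.path(fixture_dir, "deg_clusters.tsv"),
    deg_condition = file.path(fixture_dir, "deg_condition.tsv"),
    cells = file.path(fixture_dir, "cells.tsv"),
    genes = file.path(fixture_dir, "genes.tsv"),
    pathways = file.path(fixture_dir, "pathways.gmt"),
    motifs = file.path(fixture_dir, "motifs.tsv"),
    links_inferred = file.path(fixture_dir, "links_inferred.tsv"),
    links_curated = file.path(fixture_dir, "links_curated.tsv"))
  for (cn in conds) {
    inputs[[paste0("peaks_", cn)]] <-
      file.path(fixture_dir, sprintf("peaks_%s.bed", cn))
    for (mk in HISTONE_MARKS)
      inputs[[sprintf("histone_%s_%s", cn, mk)]] <-
        file.path(fixture_dir, sprintf("histone_%s_%s.narrowPeak", cn, mk))
  }
  pipeline_config(inputs = inputs, outdir = outdir, conditions = conds,
                  ...)
}

require_inputs <- function(config, stage, keys) {
  for (key in keys) {
    path <- config$inputs[[key]]
    if (is.null(path))
      stop("stage '", stage, "': input '", key, "' not configured")
    if (!file.exists(path))
      stop("stage '", stage, "': missing input file '", key,
           "' (", path, ")")
  }
  invisible(TRUE)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — subtype merge,
#' condition markers, promoter/enhancer calling, peak statistics,
#' regulatory networks — writing each stage's artifacts under the
#' configured output directory plus a `manifest.json` recording the
#' configuration, seed, package version and MD5 checksum of every input
#' and output. The manifest carries no timestamps, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus
#'   `output_files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  out <- character()
  p <- function(f) file.path(config$outdir, f)
  emit <- function(path) out <<- c(out, path)
  disease <- config$conditions[[1L]]

  if ("subtypes" %in% config$stages) {
    require_inputs(config, "subtypes", "deg_clusters")
    degs <- read_deg_table(config$inputs$deg_clusters)
    sets <- cluster_gene_sets(degs, k = config$k, fc_min = config$fc_min,
                              p_max = config$p_max)
    J <- jaccard_matrix(sets)
    assignment <- merge_subtypes(J, n_subtypes = config$n_subtypes)
    utils::write.table(data.frame(cluster = rownames(J), J,
                                  check.names = FALSE),
                       p("jaccard_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(cluster = names(assignment),
                                  subtype = unname(assignment)),
                       p("subtype_assignment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("jaccard_matrix.tsv")); emit(p("subtype_assignment.tsv"))
    res$subtypes <- list(jaccard = J, assignment = assignment)
    if (!is.null(config$inputs$cells) &&
        file.exists(config$inputs$cells)) {
      cells <- utils::read.table(config$inputs$cells, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
      cells$subtype <- unname(assignment[cells$cluster])
      comp <- condition_composition(cells, group = "subtype")
      utils::write.table(comp, p("condition_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p("condition_composition.tsv"))
      res$subtypes$composition <- comp
    }
  }

  if ("markers" %in% config$stages) {
    require_inputs(config, "markers", c("deg_condition", "pathways"))
    cdeg <- read_deg_table(config$inputs$deg_condition)
    up <- upregulated_in_condition(cdeg, config$condition_contrast,
                                   fc_min = config$fc_min,
                                   p_max = config$p_max)
    pathways <- read_pathways(config$inputs$pathways, format = "gmt")
    mk <- intersect_with_pathways(up, pathways)
    writeLines(mk$markers, p("markers.tsv"))
    jsonlite::write_json(mk$venn, p("marker_venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(p("markers.tsv")); emit(p("marker_venn.json"))
    res$markers <- c(mk, list(upregulated = up))
  }

  peaks <- tracks <- list()
  need_peaks <- any(c("cre", "peak_stats", "grn") %in% config$stages)
  if (need_peaks) {
    for (cn in config$conditions) {
      require_inputs(config, "cre", paste0("peaks_", cn))
      peaks[[cn]] <- read_bed(config$inputs[[paste0("peaks_", cn)]],
                              category_column = 7L)
      tracks[[cn]] <- list()
      for (mk in HISTONE_MARKS) {
        key <- sprintf("histone_%s_%s", cn, mk)
        require_inputs(config, "cre", key)
        tracks[[cn]][[mk]] <- histone_track(
          mk, read_bed(config$inputs[[key]], format = "narrowPeak"))
      }
    }
  }

  if (any(c("cre", "grn") %in% config$stages)) {
    require_inputs(config, "cre", "genes")
    annotation <- read_gene_annotation(config$inputs$genes)
    res$cre <- list()
    summary <- list()
    for (cn in config$conditions) {
      prom <- call_promoters(peaks[[cn]], tracks[[cn]]$H3K4me3,
                             min_bp = config$min_bp)
      enh <- call_enhancers(peaks[[cn]], tracks[[cn]]$H3K4me1,
                            tracks[[cn]]$H3K27ac, min_bp = config$min_bp)
      prom <- assign_gene(prom, annotation,
                          promoter_window_bp = config$promoter_window_bp,
                          enhancer_max_distance_bp =
                            config$enhancer_max_distance_bp)
      enh <- assign_gene(enh, annotation,
                         promoter_window_bp = config$promoter_window_bp,
                         enhancer_max_distance_bp =
                           config$enhancer_max_distance_bp)
      f <- sprintf("cre_calls_%s.bed", cn)
      write_cre_calls(c(prom, enh), p(f))
      emit(p(f))
      res$cre[[cn]] <- list(promoters = prom, enhancers = enh)
      summary[[cn]] <- list(n_promoters = length(prom),
                            n_enhancers = length(enh))
    }
    jsonlite::write_json(summary, p("cre_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(p("cre_summary.json"))
    res$cre_summary <- summary
  }

  if ("peak_stats" %in% config$stages) {
    require_inputs(config, "peak_stats", "genes")
    annotation <- read_gene_annotation(config$inputs$genes)
    ct <- category_table(peaks)
    test <- chisq_independence(ct$counts)
    utils::write.table(data.frame(condition = rownames(ct$counts),
                                  ct$counts, check.names = FALSE),
                       p("category_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(test[c("statistic", "df", "p_value")],
                         p("category_chisq.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    emit(p("category_counts.tsv")); emit(p("category_chisq.json"))
    hm <- list()
    cov <- list()
    for (cn in config$conditions) {
      hm[[cn]] <- lapply(tracks[[cn]], function(tr)
        histone_match_fraction(peaks[[cn]], tr, min_bp = config$min_bp))
      gc <- gene_coverage(peaks[[cn]], annotation,
                          gene_window_bp = config$gene_window_bp)
      f <- sprintf("gene_coverage_venn_%s.json", cn)
      jsonlite::write_json(
        list(venn = gc$venn, max_per_category = gc$max_per_category,
             genes_all_categories = gc$genes_all_categories),
        p(f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit(p(f))
      cov[[cn]] <- gc
    }
    jsonlite::write_json(hm, p("histone_match.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    emit(p("histone_match.json"))
    res$peak_stats <- list(category = ct, chisq = test,
                           histone_match = hm, gene_coverage = cov)
  }

  if ("grn" %in% config$stages) {
    require_inputs(config, "grn", c("deg_condition", "motifs",
                                    "links_inferred", "links_curated"))
    cdeg <- read_deg_table(config$inputs$deg_condition)
    up <- upregulated_in_condition(cdeg, config$condition_contrast,
                                   fc_min = config$fc_min,
                                   p_max = config$p_max)
    occ <- utils::read.table(config$inputs$motifs, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    prom_calls <- res$cre[[disease]]$promoters
    enh_calls <- res$cre[[disease]]$enhancers
    pk_names <- S4Vectors::mcols(peaks[[disease]])$name
    tf_universe <- sort(unique(occ$motif))
    pnet <- build_promoter_network(up, prom_calls, occ, tf_universe)
    utils::write.table(pnet, p("promoter_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("promoter_edges.tsv"))
    enr <- list(
      promoter = motif_enrichment(
        S4Vectors::mcols(prom_calls)$name, pk_names,
        occ[occ$peak_id %in% pk_names, , drop = FALSE]),
      enhancer = motif_enrichment(
        S4Vectors::mcols(enh_calls)$name, pk_names,
        occ[occ$peak_id %in% pk_names, , drop = FALSE]))
    for (cls in names(enr)) {
      f <- sprintf("motif_enrichment_%s.tsv", cls)
      utils::write.table(enr[[cls]], p(f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(p(f))
    }
    inferred <- read_links(config$inputs$links_inferred, "inferred")
    curated <- read_links(config$inputs$links_curated, "curated")
    enet <- build_enhancer_network(inferred, curated, enh_calls,
                                   min_bp = config$min_bp)
    utils::write.table(enet$edges, p("enhancer_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(pairs = enet$venn_pairs,
                              regions = enet$venn_regions),
                         p("enhancer_venn.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    emit(p("enhancer_edges.tsv")); emit(p("enhancer_venn.json"))
    res$grn <- list(promoter_network = pnet, enrichment = enr,
                    enhancer_network = enet)
  }

  manifest <- list(
    package = "hepcre",
    version = as.character(utils::packageVersion("hepcre")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("inputs", "outdir"))],
    inputs = lapply(config$inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = lapply(stats::setNames(out, basename(out)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$output_files <- c(out, p("manifest.json"))
  invisible(res)
}
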