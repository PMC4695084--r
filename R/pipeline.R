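# End-to-end pipeline: simulate (or ingest) per-tissue alignments, build
# the junction catalog, filter, classify, quantify, and summarise tissue
# specificity, writing every intermediate with a manifest.

#' Run the full multi-tissue junction pipeline
#'
#' Composes the whole analysis: per-tissue junction extraction and
#' statistics, per-tissue per-library filtering, classification against
#' annotation, junction/gene expression with cross-tissue normalization,
#' presence calls, tissue-count distributions, junction-gene pairing and
#' the specificity matrix (paired-end data), single-end/paired-end
#' concordance, tissue-specific lists confirmed in both libraries, and
#' BED12 tracks. Every table is written under `out_dir` and recorded in a
#' manifest with md5 checksums; stage counters are logged via `message()`.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Either a `simulation` block (arguments for
#'   [simulation_config()]) or a `samples` table (fields `tissue`,
#'   `library` (`SE`/`PE`), `path` to SAM/BAM) together with `annotation`
#'   (intron BED or GTF path) and `genes` (GTF path). Optional fields:
#'   `threshold` (presence threshold, default 10), `entropy_min`,
#'   `mismatch_max_se`, `mismatch_max_pe`, `intron_min`, `log_base`.
#' @param out_dir output directory.
#' @return invisibly, a list with the principal in-memory results
#'   (reference, catalogs, reports, matrices, distributions, pairs,
#'   specificity matrix, concordance, tissue-specific lists, manifest).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tau <- config$threshold %||% 10
  log_base <- config$log_base %||% 2
  taus <- c(5, 10, 50, 100, 500, 1000)

  # ---- inputs: simulate or ingest -----------------------------------------
  reference <- NULL
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_cfg <- do.call(simulation_config, sim_args)
    message("simulating reference: ", sim_cfg$n_genes, " genes, ",
            sim_cfg$n_tissues, " tissues (seed ", sim_cfg$seed, ")")
    reference <- generate_reference(sim_cfg)
    sim_dir <- file.path(out_dir, "alignments")
    manifest_sam <- simulate_tissue_panel(reference, sim_dir)
    export_truth(reference$truth, file.path(out_dir, "truth.tsv"))
    samples <- manifest_sam[, c("tissue", "library", "path")]
    annotation <- reference$annotation
    gene_models <- reference$genes
  } else {
    samples <- as.data.frame(config$samples)
    stopifnot(all(c("tissue", "library", "path") %in% names(samples)))
    if (!all(file.exists(samples$path)))
      stop("stage input: missing alignment file(s): ",
           paste(samples$path[!file.exists(samples$path)], collapse = ", "))
    if (is.null(config$annotation) || !file.exists(config$annotation))
      stop("stage annotation: intron annotation file missing")
    if (is.null(config$genes) || !file.exists(config$genes))
      stop("stage genes: gene model GTF missing")
    introns <- if (grepl("\\.bed$", config$annotation, ignore.case = TRUE))
      read_intron_bed(config$annotation) else
      read_gtf_introns(config$annotation)
    annotation <- build_annotation_index(introns)
    gene_models <- read_gtf_gene_models(config$genes)
  }

  libs <- intersect(c("SE", "PE"), unique(samples$library))
  thr_for <- function(lib) filter_thresholds(
    entropy_min = config$entropy_min %||% 0.75,
    mismatch_max = if (lib == "SE") config$mismatch_max_se %||% 1.5
                   else config$mismatch_max_pe %||% 1.0,
    intron_min = config$intron_min %||% 50
  )

  res <- list(reference = reference, samples = samples)
  per_lib <- list()
  for (lib in libs) {
    sub <- samples[samples$library == lib, , drop = FALSE]
    tissues <- sub$tissue
    stats_by_tissue <- list()
    retained_by_tissue <- list()
    sizes <- numeric(0)
    cov_by_tissue <- list()
    thr <- thr_for(lib)
    for (i in seq_len(nrow(sub))) {
      t <- sub$tissue[i]
      aln <- read_alignments(sub$path[i])
      ev <- extract_junctions(aln)
      st <- compute_stats(ev, log_base = log_base)
      cls <- classify_junction(st, annotation)
      flt <- apply_filters(st, thr, classes = cls)
      message(sprintf(
        "[%s %s] %d alignments, %d junctions, %d retained (ann %.1f%% / novel %.1f%%)",
        lib, t, length(aln), nrow(st), nrow(flt$retained),
        100 * flt$report$retention_annotated,
        100 * flt$report$retention_novel))
      stats_by_tissue[[t]] <- st
      retained_by_tissue[[t]] <- flt$retained
      sizes[[t]] <- length(aln)
      cov_by_tissue[[t]] <- gene_expression(
        exonic_coverage(aln, gene_models), gene_models)
    }
    if (any(sizes == 0)) {
      message("tissue(s) with 0 aligned reads: ",
              paste(names(sizes)[sizes == 0], collapse = ", "),
              " (library size set to 1 for normalization)")
      sizes[sizes == 0] <- 1
    }
    lib_sizes <- library_sizes(sizes)
    pooled <- sort(unique(unlist(lapply(retained_by_tissue,
                                        function(x) x$junction_id))))
    pooled_unfiltered <- sort(unique(unlist(lapply(stats_by_tissue,
                                                   function(x) x$junction_id))))
    cls_pooled <- classify_junction(parse_junction_id(pooled), annotation)
    mat_j <- normalize_expression(
      junction_counts(retained_by_tissue, junctions = pooled), lib_sizes)
    gm <- do.call(cbind, cov_by_tissue)
    colnames(gm) <- names(cov_by_tissue)
    mat_g <- normalize_expression(
      new_expression_matrix(gm, "gene", FALSE), lib_sizes)
    dist_j <- lapply(taus, function(x)
      tissue_distribution(presence_calls(mat_j, x)))
    names(dist_j) <- as.character(taus)
    dist_g <- lapply(taus, function(x)
      tissue_distribution(presence_calls(mat_g, x)))
    names(dist_g) <- as.character(taus)
    per_lib[[lib]] <- list(
      thresholds = thr, sizes = lib_sizes,
      stats_by_tissue = stats_by_tissue,
      junctions_filtered = pooled, junctions_unfiltered = pooled_unfiltered,
      classes = stats::setNames(as.character(cls_pooled), pooled),
      classification = classification_table(cls_pooled),
      matrix_junction = mat_j, matrix_gene = mat_g,
      presence_junction = presence_calls(mat_j, tau),
      presence_gene = presence_calls(mat_g, tau),
      dist_junction = dist_j, dist_gene = dist_g,
      ratio = junction_gene_ratio(mat_j, mat_g, taus)
    )
    message(sprintf("[%s] pooled: %d filtered / %d unfiltered junctions",
                    lib, length(pooled), length(pooled_unfiltered)))
  }
  res$per_lib <- per_lib

  # ---- cross-library analyses ---------------------------------------------
  files <- list()
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    files[[name]] <<- p
    p
  }
  for (lib in libs) {
    pl <- per_lib[[lib]]
    put(sprintf("classification_%s.tsv", lib), function(p)
      utils::write.table(data.frame(class = names(pl$classification),
                                    count = pl$classification),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    put(sprintf("junction_matrix_%s.tsv", lib), function(p)
      write_expression_matrix(pl$matrix_junction, p))
    put(sprintf("gene_matrix_%s.tsv", lib), function(p)
      write_expression_matrix(pl$matrix_gene, p))
    put(sprintf("tissue_distribution_%s.tsv", lib), function(p) {
      d <- do.call(rbind, lapply(names(pl$dist_junction), function(tx)
        data.frame(tau = tx, kind = "junction",
                   n_tissues = names(pl$dist_junction[[tx]]),
                   count = pl$dist_junction[[tx]])))
      g <- do.call(rbind, lapply(names(pl$dist_gene), function(tx)
        data.frame(tau = tx, kind = "gene",
                   n_tissues = names(pl$dist_gene[[tx]]),
                   count = pl$dist_gene[[tx]])))
      utils::write.table(rbind(d, g), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    put(sprintf("junction_gene_ratio_%s.tsv", lib), function(p)
      utils::write.table(pl$ratio, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  if (all(c("SE", "PE") %in% libs)) {
    se <- per_lib$SE; pe <- per_lib$PE
    res$concordance <- concordance_by_class(
      se$junctions_filtered, pe$junctions_filtered,
      classes = c(se$classes, pe$classes))
    res$filtered_unfiltered <- list(
      pe_in_se = filtered_vs_unfiltered_overlap(pe$junctions_filtered,
                                                se$junctions_unfiltered),
      se_in_pe = filtered_vs_unfiltered_overlap(se$junctions_filtered,
                                                pe$junctions_unfiltered))
    message(sprintf(
      "concordance SE/PE: all %.1f%%, annotated %.1f%%, novel %.1f%%",
      100 * res$concordance$all$fraction,
      100 * res$concordance$annotated$fraction,
      100 * res$concordance$novel$fraction))
    message(sprintf(
      "filtered-vs-unfiltered overlap: PE-in-SE %.1f%%, SE-in-PE %.1f%%",
      100 * res$filtered_unfiltered$pe_in_se,
      100 * res$filtered_unfiltered$se_in_pe))
    res$specific_junctions <- tissue_specific_lists(se$presence_junction,
                                                    pe$presence_junction)
    res$specific_genes <- tissue_specific_lists(se$presence_gene,
                                                pe$presence_gene)
  } else {
    one <- per_lib[[libs[1L]]]
    res$specific_junctions <- tissue_specific_lists(
      one$presence_junction, require_both = FALSE)
    res$specific_genes <- tissue_specific_lists(
      one$presence_gene, require_both = FALSE)
  }

  pair_lib <- if ("PE" %in% libs) "PE" else libs[1L]
  pl <- per_lib[[pair_lib]]
  res$pairs <- pair_junctions_to_genes(
    parse_junction_id(pl$junctions_filtered), gene_models)
  res$specificity <- specificity_matrix(res$pairs$pairs,
                                        pl$presence_junction,
                                        pl$presence_gene)
  res$gene_summary <- genes_with_specific_junctions(
    res$pairs$pairs, pl$presence_junction, pl$presence_gene, gene_models)
  message(sprintf(
    "junction-gene pairs: %d paired, %d multi-gene excluded, %d unpaired",
    nrow(res$pairs$pairs), length(res$pairs$multi_gene),
    length(res$pairs$unpaired)))

  put("specificity_matrix.tsv", function(p)
    utils::write.table(as.data.frame(unclass(res$specificity)), p,
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA))
  put("gene_summary.tsv", function(p)
    utils::write.table(data.frame(row = rownames(res$gene_summary),
                                  res$gene_summary),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  put("tissue_specific_junctions.tsv", function(p) {
    df <- data.frame(
      tissue = rep(names(res$specific_junctions),
                   lengths(res$specific_junctions)),
      junction_id = unlist(res$specific_junctions, use.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # novel-junction track and tissue-specific track
  novel_ids <- pl$junctions_filtered[pl$classes[pl$junctions_filtered] !=
                                       "annotated"]
  if (length(novel_ids))
    put("novel_junctions.bed", function(p)
      write_junction_bed(parse_junction_id(novel_ids), p))
  spec_df <- data.frame(
    tissue = rep(names(res$specific_junctions),
                 lengths(res$specific_junctions)),
    junction_id = unlist(res$specific_junctions, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(spec_df)) {
    pal <- tissue_palette(length(res$specific_junctions))
    names(pal) <- names(res$specific_junctions)
    put("tissue_specific_junctions.bed", function(p)
      write_junction_bed(parse_junction_id(spec_df$junction_id), p,
                         name = spec_df$tissue,
                         itemRgb = pal[spec_df$tissue]))
  }

  manifest <- data.frame(
    file = names(files),
    md5 = as.character(tools::md5sum(unlist(files))),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
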