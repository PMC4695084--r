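# Synthetic multi-tissue spliced-alignment generator with planted ground
# truth. Emulates a 16-tissue body-map style design: one individual per
# tissue, one 75 bp single-end and one 2x50 bp paired-end library
# (insert ~210 bp) per tissue, annotated and novel junctions, ubiquitous
# and tissue-restricted genes and junctions.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 16 tissues, 75 bp single-end
#' and 2x50 bp paired-end reads with ~210 bp inserts, intron lengths
#' between 50 and 100,000 bp. Reads are emitted pre-aligned (no sequence
#' content or base-level errors); per-read mismatch counts are drawn
#' Poisson and carried in the `NM` tag only.
#'
#' @param n_tissues number of tissues (>= 2).
#' @param n_genes number of genes to plant.
#' @param frac_tissue_specific_genes fraction of genes expressed in exactly
#'   one tissue; all remaining genes are ubiquitous (expressed everywhere).
#' @param frac_ubiquitous_genes_with_specific_junction fraction of
#'   ubiquitous genes that receive one extra exon-skipping junction
#'   expressed in exactly one tissue.
#' @param frac_novel_junctions target fraction of all planted junctions
#'   withheld from the annotation, planted in equal thirds as new
#'   combinations of annotated sites, one-site-novel, and
#'   neither-site-novel.
#' @param frac_single_exon_genes fraction of genes planted with a single
#'   exon (they host no junctions and are excluded from multi-exon
#'   summaries).
#' @param frac_artifact_junctions fraction (relative to the true junction
#'   count) of planted low-entropy artifact junctions whose spanning reads
#'   stack at few offsets (geometric offset mode); used to exercise the
#'   entropy filter.
#' @param novel_depth_factor depth multiplier for novel junctions (< 1
#'   plants them at lower, threshold-bordering expression, as observed for
#'   unannotated junctions).
#' @param read_length_se,read_length_pe read lengths in bp.
#' @param insert_size_pe paired-end insert size in bp.
#' @param depth_per_tissue mean spanning reads per expressed junction per
#'   tissue (Poisson).
#' @param gene_body_depth_factor target mean exonic depth of unspliced
#'   gene-body reads, as a multiple of `depth_per_tissue`.
#' @param mismatch_rate mean mismatches per read (Poisson, `NM` tag).
#' @param intron_length_range intron length bounds in bp (min >= 50);
#'   lengths are drawn log-uniformly.
#' @param exon_length_range,exons_per_gene_range gene architecture bounds.
#' @param genes_per_chrom genes laid per synthetic chromosome
#'   (`chrS1`, `chrS2`, ...).
#' @param chrom_length optional fixed chromosome length in bp; an error is
#'   raised if the genes do not fit.
#' @param offset_geom_prob success probability of the geometric offset
#'   distribution used for artifact junctions.
#' @param tissues tissue names; defaults to the 16 human body-map tissue
#'   labels (or `tissue01..` beyond 16).
#' @param seed integer seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_tissues = 16L,
                              n_genes = 200L,
                              frac_tissue_specific_genes = 0.2,
                              frac_ubiquitous_genes_with_specific_junction = 0.25,
                              frac_novel_junctions = 0.1,
                              frac_single_exon_genes = 0.1,
                              frac_artifact_junctions = 0,
                              novel_depth_factor = 0.25,
                              read_length_se = 75L,
                              read_length_pe = 50L,
                              insert_size_pe = 210L,
                              depth_per_tissue = 50,
                              gene_body_depth_factor = 0.5,
                              mismatch_rate = 0.5,
                              intron_length_range = c(50L, 100000L),
                              exon_length_range = c(120L, 260L),
                              exons_per_gene_range = c(3L, 6L),
                              genes_per_chrom = 50L,
                              chrom_length = NULL,
                              offset_geom_prob = 0.95,
                              tissues = NULL,
                              seed = 1L) {
  fr <- c(frac_tissue_specific_genes,
          frac_ubiquitous_genes_with_specific_junction,
          frac_novel_junctions, frac_single_exon_genes,
          frac_artifact_junctions)
  stopifnot(all(fr >= 0), all(fr <= 1), frac_novel_junctions < 1,
            n_tissues >= 2L, n_genes >= 1L,
            intron_length_range[1L] >= 50L,
            intron_length_range[2L] >= intron_length_range[1L],
            read_length_se > 2L, read_length_pe > 2L,
            insert_size_pe >= 2L * read_length_pe,
            depth_per_tissue > 0, mismatch_rate >= 0,
            exon_length_range[1L] > max(read_length_se, read_length_pe) + 40L,
            exons_per_gene_range[1L] >= 2L,
            offset_geom_prob > 0, offset_geom_prob < 1,
            length(seed) == 1L, is.finite(seed))
  if (is.null(tissues)) tissues <- default_tissue_names(n_tissues)
  stopifnot(length(tissues) == n_tissues, !anyDuplicated(tissues))
  structure(list(
    n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
    frac_tissue_specific_genes = frac_tissue_specific_genes,
    frac_ubiquitous_genes_with_specific_junction =
      frac_ubiquitous_genes_with_specific_junction,
    frac_novel_junctions = frac_novel_junctions,
    frac_single_exon_genes = frac_single_exon_genes,
    frac_artifact_junctions = frac_artifact_junctions,
    novel_depth_factor = novel_depth_factor,
    read_length_se = as.integer(read_length_se),
    read_length_pe = as.integer(read_length_pe),
    insert_size_pe = as.integer(insert_size_pe),
    depth_per_tissue = depth_per_tissue,
    gene_body_depth_factor = gene_body_depth_factor,
    mismatch_rate = mismatch_rate,
    intron_length_range = as.integer(intron_length_range),
    exon_length_range = as.integer(exon_length_range),
    exons_per_gene_range = as.integer(exons_per_gene_range),
    genes_per_chrom = as.integer(genes_per_chrom),
    chrom_length = if (is.null(chrom_length)) NULL else as.numeric(chrom_length),
    offset_geom_prob = offset_geom_prob,
    tissues = tissues, seed = as.integer(seed)
  ), class = "simulation_config")
}

default_tissue_names <- function(n) {
  body <- c("adipose", "adrenal", "brain", "breast", "colon", "kidney",
            "heart", "liver", "lung", "lymph_node", "prostate",
            "skeletal_muscle", "white_blood_cell", "ovary", "testes",
            "thyroid")
  if (n <= length(body)) body[seq_len(n)] else
    c(body, sprintf("tissue%02d", seq.int(length(body) + 1L, n)))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d tissues, %d genes, seed %d\n",
              x$n_tissues, x$n_genes, x$seed))
  cat(sprintf("  SE %dbp / PE 2x%dbp (insert %d), depth %g reads/junction\n",
              x$read_length_se, x$read_length_pe, x$insert_size_pe,
              x$depth_per_tissue))
  invisible(x)
}

# stable per-(tissue, library) stream seed derived from the master seed
derive_seed <- function(seed, tissue_idx, library) {
  pe <- if (library == "PE") 1L else 0L
  as.integer((abs(as.numeric(seed)) * 3571 + tissue_idx * 97 + pe * 31) %%
               2147483629)
}

#' Generate a reference genome layout, annotation, and planted truth
#'
#' Lays out non-overlapping genes on synthetic chromosomes
#' (`chrS1..chrSn`), assigns each gene a tissue profile (tissue-specific or
#' ubiquitous), plants constitutive introns plus extra junctions
#' (tissue-specific exon skips inside ubiquitous genes, novel junctions in
#' the three boundary sub-classes, optional low-entropy artifacts), builds
#' the annotation index containing every annotated intron while omitting
#' the junctions planted as novel, and records the full ground truth.
#'
#' @param config a [simulation_config()].
#' @return a `juncspect_reference`: list with `genes`
#'   ([gene_model_set()]), `annotation` ([build_annotation_index()]),
#'   `truth` (a `truth_set`), `chrom_lengths`, and the `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  tissues <- config$tissues

  # gene architectures
  n_single <- round(config$frac_single_exon_genes * n)
  single <- seq_len(n) %in% sample.int(n, n_single)
  n_ex <- ifelse(single, 1L,
                 sample(seq.int(config$exons_per_gene_range[1L],
                                config$exons_per_gene_range[2L]),
                        n, replace = TRUE))
  gene_ids <- sprintf("G%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  exon_rows <- vector("list", n)
  gene_span <- numeric(n)
  layout <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_ex[i]
    elen <- sample(seq.int(config$exon_length_range[1L],
                           config$exon_length_range[2L]), k, replace = TRUE)
    ilen <- if (k >= 2L) {
      lo <- log(config$intron_length_range[1L])
      hi <- log(config$intron_length_range[2L])
      pmin(pmax(round(exp(runif(k - 1L, lo, hi))),
                config$intron_length_range[1L]),
           config$intron_length_range[2L])
    } else integer()
    starts <- cumsum(c(0L, head(elen, -1L) + ilen))
    layout[[i]] <- list(start = starts, end = starts + elen)
    gene_span[i] <- starts[k] + elen[k]
  }

  # placement on chromosomes
  gap <- 5000
  n_chrom <- max(1L, ceiling(n / config$genes_per_chrom))
  chrom_of <- sprintf("chrS%d", ((seq_len(n) - 1L) %/% config$genes_per_chrom) + 1L)
  offsets <- numeric(n)
  cursor <- stats::setNames(rep(1000, n_chrom), sprintf("chrS%d", seq_len(n_chrom)))
  for (i in seq_len(n)) {
    offsets[i] <- cursor[[chrom_of[i]]]
    cursor[[chrom_of[i]]] <- offsets[i] + gene_span[i] + gap
  }
  chrom_lengths <- ceiling(cursor + 1000)
  if (!is.null(config$chrom_length)) {
    if (any(chrom_lengths > config$chrom_length))
      stop("genome too small: chromosome length ", config$chrom_length,
           " cannot hold ", config$genes_per_chrom, " genes per chromosome",
           " (need up to ", max(chrom_lengths), " bp)")
    chrom_lengths[] <- config$chrom_length
  }
  for (i in seq_len(n)) {
    exon_rows[[i]] <- data.frame(
      gene_id = gene_ids[i],
      start = as.integer(offsets[i] + layout[[i]]$start),
      end = as.integer(offsets[i] + layout[[i]]$end),
      stringsAsFactors = FALSE
    )
  }
  exons <- do.call(rbind, exon_rows)
  genes_df <- data.frame(gene_id = gene_ids, chrom = chrom_of,
                         strand = strand, biotype = "protein_coding",
                         stringsAsFactors = FALSE)
  genes <- gene_model_set(genes_df, exons)

  # tissue profiles: specific genes get one tissue, the rest all tissues
  n_spec_genes <- round(config$frac_tissue_specific_genes * n)
  spec_genes <- sample(gene_ids, n_spec_genes)
  profile <- stats::setNames(rep(list(tissues), n), gene_ids)
  profile[spec_genes] <- as.list(sample(tissues, n_spec_genes, replace = TRUE))

  # constitutive introns: annotated, gene-wide profile
  jrows <- list()
  used <- new.env(parent = emptyenv())
  add_j <- function(gene_id, chrom, s, e, status, tiss, depth_factor,
                    offset_mode, is_artifact, lflank, rflank) {
    key <- paste0(chrom, ":", s, "-", e)
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    jrows[[length(jrows) + 1L]] <<- data.frame(
      junction_id = key, gene_id = gene_id, chrom = chrom,
      intron_start = as.integer(s), intron_end = as.integer(e),
      strand = genes_df$strand[match(gene_id, gene_ids)],
      status = status, tissues = paste(tiss, collapse = ","),
      depth_factor = depth_factor, offset_mode = offset_mode,
      is_artifact = is_artifact,
      left_flank_start = as.integer(lflank),
      right_flank_end = as.integer(rflank),
      stringsAsFactors = FALSE
    )
    TRUE
  }
  exon_of <- split(genes$exons, genes$exons$gene_id)
  for (gid in gene_ids) {
    ex <- exon_of[[gid]]
    if (is.null(ex) || nrow(ex) < 2L) next
    chr <- genes_df$chrom[match(gid, gene_ids)]
    for (k in seq_len(nrow(ex) - 1L)) {
      add_j(gid, chr, ex$end[k], ex$start[k + 1L], "annotated",
            profile[[gid]], 1, "uniform", FALSE, ex$start[k],
            ex$end[k + 1L])
    }
  }

  # tissue-specific exon-skip junctions inside ubiquitous genes (annotated)
  ubiq <- setdiff(gene_ids, spec_genes)
  elig <- ubiq[n_ex[match(ubiq, gene_ids)] >= 3L]
  n_skip <- min(round(config$frac_ubiquitous_genes_with_specific_junction *
                        length(ubiq)), length(elig))
  skip_hosts <- sample(elig, n_skip)
  for (gid in skip_hosts) {
    ex <- exon_of[[gid]]
    chr <- genes_df$chrom[match(gid, gene_ids)]
    k <- sample.int(nrow(ex) - 2L, 1L)
    add_j(gid, chr, ex$end[k], ex$start[k + 2L], "annotated",
          sample(tissues, 1L), 1, "uniform", FALSE, ex$start[k],
          ex$end[k + 2L])
  }

  n_base <- length(jrows)
  # novel junctions, three boundary sub-classes in equal proportions
  n_novel <- round(config$frac_novel_junctions /
                     (1 - config$frac_novel_junctions) * n_base)
  novel_classes <- rep(c("novel_both_sites", "novel_one_site",
                         "novel_neither"), length.out = n_novel)
  multi <- gene_ids[n_ex >= 2L]
  plant_novel <- function(cls, depth_factor, offset_mode, is_artifact) {
    for (try in seq_len(40L)) {
      gid <- sample(if (cls == "novel_both_sites")
        gene_ids[n_ex >= 3L] else multi, 1L)
      ex <- exon_of[[gid]]
      chr <- genes_df$chrom[match(gid, gene_ids)]
      if (cls == "novel_both_sites") {
        k <- sample.int(nrow(ex) - 2L, 1L)
        s <- ex$end[k]; e <- ex$start[k + 2L]
        lf <- ex$start[k]; rf <- ex$end[k + 2L]
      } else if (cls == "novel_one_site") {
        k <- sample.int(nrow(ex) - 1L, 1L)
        d <- sample(10:30, 1L)
        s <- ex$end[k]; e <- ex$start[k + 1L] + d
        lf <- ex$start[k]; rf <- ex$end[k + 1L]
      } else {
        k <- sample.int(nrow(ex) - 1L, 1L)
        d1 <- sample(10:30, 1L); d2 <- sample(10:30, 1L)
        s <- ex$end[k] - d1; e <- ex$start[k + 1L] + d2
        lf <- ex$start[k]; rf <- ex$end[k + 1L]
      }
      if (add_j(gid, chr, s, e, cls, profile[[gid]], depth_factor,
                offset_mode, is_artifact, lf, rf)) return(TRUE)
    }
    FALSE
  }
  for (cls in novel_classes)
    plant_novel(cls, config$novel_depth_factor, "uniform", FALSE)

  # low-entropy artifacts (unannotated, stacked read offsets)
  n_art <- round(config$frac_artifact_junctions * n_base)
  for (i in seq_len(n_art))
    plant_novel("novel_one_site", 1, "geometric", TRUE)

  junctions <- do.call(rbind, jrows)
  rownames(junctions) <- NULL
  truth <- structure(list(
    tissues = tissues,
    gene_profiles = data.frame(
      gene_id = gene_ids,
      tissues = vapply(profile, paste, "", collapse = ","),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    junctions = junctions
  ), class = "truth_set")

  ann <- junctions[junctions$status == "annotated", , drop = FALSE]
  annotation <- build_annotation_index(ann[, c("chrom", "intron_start",
                                               "intron_end", "strand")])
  structure(list(genes = genes, annotation = annotation, truth = truth,
                 chrom_lengths = chrom_lengths, config = config),
            class = "juncspect_reference")
}

#' @export
print.juncspect_reference <- function(x, ...) {
  jt <- table(x$truth$junctions$status)
  cat(sprintf("juncspect_reference: %d genes on %d chromosomes, %d junctions\n",
              nrow(x$genes$genes), length(x$chrom_lengths),
              nrow(x$truth$junctions)))
  cat("  junction status:",
      paste(sprintf("%s=%d", names(jt), as.integer(jt)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d tissues, %d genes, %d junctions\n",
              length(x$tissues), nrow(x$gene_profiles), nrow(x$junctions)))
  invisible(x)
}

#' Tissue profiles recorded in a truth set
#'
#' @param truth a `truth_set`.
#' @param what `"junction"` or `"gene"`.
#' @return named list mapping entity id to its expressing tissues.
#' @export
truth_profiles <- function(truth, what = c("junction", "gene")) {
  what <- match.arg(what)
  if (what == "junction") {
    stats::setNames(strsplit(truth$junctions$tissues, ",", fixed = TRUE),
                    truth$junctions$junction_id)
  } else {
    stats::setNames(strsplit(truth$gene_profiles$tissues, ",", fixed = TRUE),
                    truth$gene_profiles$gene_id)
  }
}

#' Simulate a tissue's spliced alignments as SAM
#'
#' Emits pre-aligned reads for every junction and gene whose truth profile
#' includes the tissue: junction-spanning reads with spliced CIGARs whose
#' skip equals the intron length, plus unspliced gene-body reads inside
#' exons. Spanning-read start offsets are uniform over all positions
#' leaving >= 1 aligned bp on each side of the junction within its
#' flanking exons (geometric for planted artifact junctions); per-read
#' mismatch counts are Poisson and carried in the `NM` tag. Paired-end
#' mode emits proper pairs at the configured insert size, the spliced read
#' first. Junctions whose flanking exons cannot hold a read are skipped
#' with a warning.
#'
#' @param truth a `truth_set` (or a `juncspect_reference`, from which
#'   truth, genes and chromosome lengths are taken).
#' @param genes a [gene_model_set()]; ignored when `truth` is a reference.
#' @param tissue tissue name present in the truth set.
#' @param library `"SE"` or `"PE"`.
#' @param config the [simulation_config()] used to build the reference.
#' @param path output SAM path; `NULL` keeps the lines in memory.
#' @return a `sim_alignments` list: `path`, `lines` (when not written),
#'   `n_records`, and `junction_read_counts` (named integer: planted
#'   spanning-read count per junction — the simulator's bookkeeping).
#' @export
simulate_alignments <- function(truth, genes = NULL, tissue,
                                library = c("SE", "PE"), config,
                                path = NULL) {
  library <- match.arg(library)
  if (inherits(truth, "juncspect_reference")) {
    ref <- truth
    truth <- ref$truth
    genes <- ref$genes
    chrom_lengths <- ref$chrom_lengths
    if (missing(config)) config <- ref$config
  } else {
    stopifnot(inherits(genes, "gene_model_set"))
    chrom_lengths <- NULL
  }
  stopifnot(inherits(truth, "truth_set"),
            inherits(config, "simulation_config"))
  t_idx <- match(tissue, truth$tissues)
  if (is.na(t_idx)) stop("tissue '", tissue, "' not in truth set")
  set.seed(derive_seed(config$seed, t_idx, library))

  R <- if (library == "SE") config$read_length_se else config$read_length_pe
  jt <- truth$junctions
  in_tissue <- vapply(strsplit(jt$tissues, ",", fixed = TRUE),
                      function(x) tissue %in% x, logical(1L))
  jt <- jt[in_tissue, , drop = FALSE]
  gp <- truth_profiles(truth, "gene")
  expressed_genes <- names(gp)[vapply(gp, function(x) tissue %in% x,
                                      logical(1L))]

  # --- junction-spanning reads (vectorised over junctions) ---
  flank_l <- jt$intron_start - jt$left_flank_start
  flank_r <- jt$right_flank_end - jt$intron_end
  l_min <- pmax(1L, R - flank_r)
  l_max <- pmin(R - 1L, flank_l)
  feasible <- l_min <= l_max
  if (any(!feasible))
    warning(sum(!feasible), " junction(s) skipped: flanking exons shorter",
            " than the read length")
  nj <- integer(nrow(jt))
  nj[feasible] <- rpois(sum(feasible),
                        config$depth_per_tissue * jt$depth_factor[feasible])
  counts <- stats::setNames(integer(nrow(truth$junctions)),
                            truth$junctions$junction_id)
  counts[jt$junction_id] <- nj
  idx <- rep(seq_len(nrow(jt)), nj)
  n_span <- length(idx)
  if (n_span) {
    geom <- jt$offset_mode[idx] == "geometric"
    span <- (l_max - l_min)[idx]
    l <- integer(n_span)
    u_n <- sum(!geom)
    if (u_n) l[!geom] <- l_min[idx][!geom] +
        floor(runif(u_n) * (span[!geom] + 1L))
    g_n <- sum(geom)
    if (g_n) l[geom] <- l_min[idx][geom] +
        pmin(stats::rgeom(g_n, config$offset_geom_prob), span[geom])
    jstart <- jt$intron_start[idx] - l
    ilen <- (jt$intron_end - jt$intron_start)[idx]
    cig <- sprintf("%dM%dN%dM", l, ilen, R - l)
    nm <- rpois(n_span, config$mismatch_rate)
    qname <- sprintf("%s_%s_j%s_%d", tissue, library, idx,
                     seq_len(n_span))
    chrom <- jt$chrom[idx]
  }

  # --- unspliced gene-body reads per exon ---
  ex <- genes$exons[genes$exons$gene_id %in% expressed_genes, , drop = FALSE]
  ex <- ex[(ex$end - ex$start) >= R, , drop = FALSE]
  w <- ex$end - ex$start
  d_body <- config$depth_per_tissue * config$gene_body_depth_factor
  per_read_bases <- if (library == "PE") 2L * R else R
  nb <- rpois(nrow(ex), d_body * w / per_read_bases)
  bidx <- rep(seq_len(nrow(ex)), nb)
  n_body <- length(bidx)
  if (n_body) {
    bstart <- ex$start[bidx] +
      floor(runif(n_body) * (w[bidx] - R + 1L))
    bchrom <- genes$genes$chrom[match(ex$gene_id[bidx], genes$genes$gene_id)]
    bnm <- rpois(n_body, config$mismatch_rate)
    bqname <- sprintf("%s_%s_b%d", tissue, library, seq_len(n_body))
  }

  seq_str <- strrep("A", R)
  qual_str <- strrep("I", R)
  recs <- character()
  if (library == "SE") {
    if (n_span)
      recs <- c(recs, sprintf(
        "%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
        qname, chrom, jstart + 1L, cig, seq_str, qual_str, nm))
    if (n_body)
      recs <- c(recs, sprintf(
        "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
        bqname, bchrom, bstart + 1L, R, seq_str, qual_str, bnm))
    n_records <- n_span + n_body
  } else {
    gap <- config$insert_size_pe - 2L * R
    if (n_span) {
      # mate 2 sits in the downstream flanking exon, clamped to fit
      m1_end <- jstart + R + ilen
      m2s <- pmin(pmax(m1_end + gap, jt$intron_end[idx]),
                  jt$right_flank_end[idx] - R)
      tlen <- (m2s + R) - jstart
      nm2 <- rpois(n_span, config$mismatch_rate)
      recs <- c(recs,
        sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                qname, chrom, jstart + 1L, cig, m2s + 1L, tlen,
                seq_str, qual_str, nm),
        sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                qname, chrom, m2s + 1L, R, jstart + 1L, -tlen,
                seq_str, qual_str, nm2))
    }
    if (n_body) {
      m2s <- pmin(bstart + config$insert_size_pe - R, ex$end[bidx] - R)
      m2s <- pmax(m2s, ex$start[bidx])
      tlen <- (m2s + R) - bstart
      bnm2 <- rpois(n_body, config$mismatch_rate)
      recs <- c(recs,
        sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                bqname, bchrom, bstart + 1L, R, m2s + 1L, tlen,
                seq_str, qual_str, bnm),
        sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                bqname, bchrom, m2s + 1L, R, bstart + 1L, -tlen,
                seq_str, qual_str, bnm2))
    }
    n_records <- 2L * (n_span + n_body)
  }

  if (is.null(chrom_lengths)) {
    top <- tapply(c(genes$exons$end, truth$junctions$intron_end),
                  c(genes$genes$chrom[match(genes$exons$gene_id,
                                            genes$genes$gene_id)],
                    truth$junctions$chrom), max)
    chrom_lengths <- top + 1000
  }
  chroms <- sort(names(chrom_lengths))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      as.integer(chrom_lengths[chroms])))
  lines <- c(header, recs)
  out <- structure(list(path = path, lines = if (is.null(path)) lines,
                        n_records = n_records,
                        junction_read_counts = counts),
                   class = "sim_alignments")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(out))
  }
  out
}

#' @export
print.sim_alignments <- function(x, ...) {
  cat(sprintf("sim_alignments: %d records, %d junctions with reads\n",
              x$n_records, sum(x$junction_read_counts > 0L)))
  invisible(x)
}

#' Simulate the full tissue panel
#'
#' Writes one SAM file per tissue per library type.
#'
#' @param reference a [generate_reference()] result.
#' @param dir output directory (created if needed).
#' @param libraries library types to emit.
#' @return data.frame manifest with `tissue`, `library`, `path`,
#'   `n_records`, plus an attribute `bookkeeping`: the per-file
#'   `junction_read_counts`.
#' @export
simulate_tissue_panel <- function(reference, dir,
                                  libraries = c("SE", "PE")) {
  stopifnot(inherits(reference, "juncspect_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  book <- list()
  for (lib in libraries) {
    for (tissue in reference$truth$tissues) {
      p <- file.path(dir, sprintf("%s_%s.sam", tissue, lib))
      sim <- simulate_alignments(reference, tissue = tissue, library = lib,
                                 path = p)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tissue, library = lib, path = p,
        n_records = sim$n_records, stringsAsFactors = FALSE)
      book[[sprintf("%s_%s", tissue, lib)]] <- sim$junction_read_counts
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bookkeeping") <- book
  out
}

#' Export / load a truth set as TSV
#'
#' The export is lossless: `read_truth(export_truth(x)) == x`.
#'
#' @param truth a `truth_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  jt <- truth$junctions
  empty <- character(0)
  df <- rbind(
    if (length(truth$tissues)) data.frame(
      record_type = "tissue", id = truth$tissues, chrom = NA_character_,
      intron_start = NA_integer_, intron_end = NA_integer_,
      strand = NA_character_, gene_id = NA_character_,
      status = NA_character_, tissues = NA_character_,
      depth_factor = NA_real_, offset_mode = NA_character_,
      is_artifact = NA, left_flank_start = NA_integer_,
      right_flank_end = NA_integer_, stringsAsFactors = FALSE),
    if (nrow(truth$gene_profiles)) data.frame(
      record_type = "gene", id = truth$gene_profiles$gene_id,
      chrom = NA_character_, intron_start = NA_integer_,
      intron_end = NA_integer_, strand = NA_character_,
      gene_id = NA_character_, status = NA_character_,
      tissues = truth$gene_profiles$tissues, depth_factor = NA_real_,
      offset_mode = NA_character_, is_artifact = NA,
      left_flank_start = NA_integer_, right_flank_end = NA_integer_,
      stringsAsFactors = FALSE),
    if (nrow(jt)) data.frame(
      record_type = "junction", id = jt$junction_id, chrom = jt$chrom,
      intron_start = jt$intron_start, intron_end = jt$intron_end,
      strand = jt$strand, gene_id = jt$gene_id, status = jt$status,
      tissues = jt$tissues, depth_factor = jt$depth_factor,
      offset_mode = jt$offset_mode, is_artifact = jt$is_artifact,
      left_flank_start = jt$left_flank_start,
      right_flank_end = jt$right_flank_end, stringsAsFactors = FALSE)
  )
  if (is.null(df)) df <- data.frame(
    record_type = empty, id = empty, chrom = empty,
    intron_start = integer(0), intron_end = integer(0), strand = empty,
    gene_id = empty, status = empty, tissues = empty,
    depth_factor = numeric(0), offset_mode = empty,
    is_artifact = logical(0), left_flank_start = integer(0),
    right_flank_end = integer(0), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = "character")
  as_int <- function(x) as.integer(x)
  jt <- df[df$record_type == "junction", , drop = FALSE]
  junctions <- data.frame(
    junction_id = jt$id, gene_id = jt$gene_id, chrom = jt$chrom,
    intron_start = as_int(jt$intron_start),
    intron_end = as_int(jt$intron_end), strand = jt$strand,
    status = jt$status, tissues = jt$tissues,
    depth_factor = as.numeric(jt$depth_factor),
    offset_mode = jt$offset_mode,
    is_artifact = as.logical(jt$is_artifact),
    left_flank_start = as_int(jt$left_flank_start),
    right_flank_end = as_int(jt$right_flank_end),
    stringsAsFactors = FALSE, row.names = NULL
  )
  gp <- df[df$record_type == "gene", , drop = FALSE]
  structure(list(
    tissues = df$id[df$record_type == "tissue"],
    gene_profiles = data.frame(gene_id = gp$id, tissues = gp$tissues,
                               stringsAsFactors = FALSE, row.names = NULL),
    junctions = junctions
  ), class = "truth_set")
}
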