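# Annotation: known-intron index, donor/acceptor site sets, junction
# classification, and gene models.

#' Build an index of known introns and their splice sites
#'
#' The donor site is the 5' intron boundary with respect to strand (the
#' `intron_start` position on `+`, `intron_end` on `-`); the acceptor is the
#' 3' boundary. Duplicate introns from multiple annotation sources collapse
#' to one entry. Zero- or negative-length intervals are rejected and
#' counted.
#'
#' @param introns data.frame with columns `chrom`, `intron_start`,
#'   `intron_end` (0-based half-open) and `strand` (`+`/`-`; anything else
#'   is treated as unstranded and indexed with the `+` convention), e.g.
#'   from [read_intron_bed()] or [read_gtf_introns()].
#' @return an `annotation_index`: list with data.tables `known_introns`,
#'   `donor_sites`, `acceptor_sites` and a QC count `n_rejected`.
#' @export
build_annotation_index <- function(introns) {
  introns <- as.data.frame(introns)
  need <- c("chrom", "intron_start", "intron_end")
  stopifnot(all(need %in% names(introns)))
  if (is.null(introns$strand)) introns$strand <- "+"
  bad <- introns$intron_end <= introns$intron_start
  n_rejected <- sum(bad)
  if (n_rejected) introns <- introns[!bad, , drop = FALSE]
  ki <- unique(data.table::data.table(
    chrom = as.character(introns$chrom),
    intron_start = as.integer(introns$intron_start),
    intron_end = as.integer(introns$intron_end)
  ))
  strand <- ifelse(introns$strand == "-", "-", "+")
  minus <- strand == "-"
  donors <- data.table::data.table(
    chrom = as.character(introns$chrom),
    pos = as.integer(ifelse(minus, introns$intron_end, introns$intron_start)),
    strand = strand
  )
  acceptors <- data.table::data.table(
    chrom = as.character(introns$chrom),
    pos = as.integer(ifelse(minus, introns$intron_start, introns$intron_end)),
    strand = strand
  )
  structure(list(
    known_introns = data.table::setkey(ki, chrom, intron_start, intron_end),
    donor_sites = unique(donors),
    acceptor_sites = unique(acceptors),
    n_rejected = n_rejected
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d introns, %d donor sites, %d acceptor sites\n",
              nrow(x$known_introns), nrow(x$donor_sites),
              nrow(x$acceptor_sites)))
  invisible(x)
}

#' Classify junctions against known intron annotation
#'
#' A junction is `annotated` when its intron interval is itself a known
#' intron. Otherwise the two boundary positions are looked up in the union
#' of annotated donor and acceptor sites: both found means a new combination
#' of known sites (`novel_both_sites`), exactly one found is
#' `novel_one_site`, none is `novel_neither`. The four classes partition any
#' input set. Site lookups ignore strand when the junction strand is
#' unknown (`"*"`) and respect it otherwise.
#'
#' @param junctions data.frame with `chrom`, `intron_start`, `intron_end`
#'   and optionally `strand` (e.g. a `junction_stats`).
#' @param index an [build_annotation_index()] result.
#' @return factor with levels `annotated`, `novel_both_sites`,
#'   `novel_one_site`, `novel_neither`, one per input row.
#' @export
classify_junction <- function(junctions, index) {
  stopifnot(inherits(index, "annotation_index"))
  junctions <- as.data.frame(junctions)
  n <- nrow(junctions)
  lv <- c("annotated", "novel_both_sites", "novel_one_site", "novel_neither")
  if (n == 0L) return(factor(character(), levels = lv))
  strand <- if (is.null(junctions$strand)) rep("*", n) else
    as.character(junctions$strand)
  key <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end)
  known <- paste(index$known_introns$chrom, index$known_introns$intron_start,
                 index$known_introns$intron_end)
  is_ann <- key %in% known
  sites <- rbind(index$donor_sites, index$acceptor_sites)
  site_any <- unique(paste(sites$chrom, sites$pos))
  site_str <- unique(paste(sites$chrom, sites$pos, sites$strand))
  hit <- function(chrom, pos) {
    ifelse(strand == "*",
           paste(chrom, pos) %in% site_any,
           paste(chrom, pos, strand) %in% site_str)
  }
  start_hit <- hit(junctions$chrom, junctions$intron_start)
  end_hit <- hit(junctions$chrom, junctions$intron_end)
  cls <- ifelse(is_ann, "annotated",
         ifelse(start_hit & end_hit, "novel_both_sites",
         ifelse(start_hit | end_hit, "novel_one_site", "novel_neither")))
  factor(cls, levels = lv)
}

#' Tabulate junction classes
#'
#' @param classes factor from [classify_junction()], or a junctions
#'   data.frame together with `index`.
#' @param index optional `annotation_index` when `classes` is a data.frame.
#' @return named integer vector over the four classes; sums to the input
#'   size.
#' @export
classification_table <- function(classes, index = NULL) {
  if (!is.factor(classes)) classes <- classify_junction(classes, index)
  tab <- table(classes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model set
#'
#' Exons of each gene are reduced to their union; gene length is the union
#' length in bp and a gene is multi-exon when the union has >= 2 intervals.
#' The gaps between consecutive union exons are the gene's annotated introns
#' and provide its donor/acceptor sites for junction-gene pairing.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` and optionally
#'   `biotype` (default `"protein_coding"`).
#' @param exons data.frame with `gene_id`, `start`, `end` (0-based
#'   half-open).
#' @return a `gene_model_set`: list with `genes` (adds `n_exons`,
#'   `gene_length`, `multi_exon`) and `exons` (reduced unions, sorted).
#' @export
gene_model_set <- function(genes, exons) {
  genes <- as.data.frame(genes)
  exons <- as.data.frame(exons)
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)),
            all(exons$end > exons$start),
            all(exons$gene_id %in% genes$gene_id))
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  # per-gene exon union via IRanges::reduce
  ex <- data.table::as.data.table(exons)
  red <- ex[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = gene_id]
  data.table::setorder(red, gene_id, start)
  stats <- red[, list(n_exons = .N, gene_length = sum(end - start)),
               by = gene_id]
  genes <- merge(genes, as.data.frame(stats), by = "gene_id", sort = TRUE)
  genes$multi_exon <- genes$n_exons >= 2L
  structure(list(genes = genes, exons = as.data.frame(red)),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes (%d multi-exon), %d exon-union intervals\n",
              nrow(x$genes), sum(x$genes$multi_exon), nrow(x$exons)))
  invisible(x)
}

#' Donor/acceptor splice sites owned by each gene
#'
#' Sites are the boundaries of the gaps between consecutive union exons
#' (the gene's annotated introns): on `+` genes the gap start is the donor
#' and the gap end the acceptor, reversed on `-` genes.
#'
#' @param gene_models a [gene_model_set()].
#' @return data.frame with `gene_id`, `chrom`, `pos`, `site_type`
#'   (donor/acceptor), `strand`.
#' @export
gene_sites <- function(gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  introns <- gene_introns(gene_models)
  if (nrow(introns) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), site_type = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  minus <- introns$strand == "-"
  rbind(
    data.frame(gene_id = introns$gene_id, chrom = introns$chrom,
               pos = ifelse(minus, introns$intron_end, introns$intron_start),
               site_type = "donor", strand = introns$strand,
               stringsAsFactors = FALSE),
    data.frame(gene_id = introns$gene_id, chrom = introns$chrom,
               pos = ifelse(minus, introns$intron_start, introns$intron_end),
               site_type = "acceptor", strand = introns$strand,
               stringsAsFactors = FALSE)
  )
}

#' Introns implied by each gene's exon union
#'
#' @param gene_models a [gene_model_set()].
#' @return data.frame with `gene_id`, `chrom`, `intron_start`,
#'   `intron_end`, `strand` (0-based half-open).
#' @export
gene_introns <- function(gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  ex <- data.table::as.data.table(gene_models$exons)
  data.table::setorder(ex, gene_id, start)
  gaps <- ex[, if (.N >= 2L)
    list(intron_start = end[-.N], intron_end = start[-1L]), by = gene_id]
  if (nrow(gaps) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      intron_start = integer(), intron_end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  g <- gene_models$genes
  out <- as.data.frame(gaps)
  out$chrom <- g$chrom[match(out$gene_id, g$gene_id)]
  out$strand <- g$strand[match(out$gene_id, g$gene_id)]
  out[, c("gene_id", "chrom", "intron_start", "intron_end", "strand")]
}

# ---- readers ---------------------------------------------------------------

#' Read intron intervals from a BED file
#'
#' @param path BED file of introns (0-based half-open, as BED is defined).
#' @return data.frame with `chrom`, `intron_start`, `intron_end`, `strand`.
#' @export
read_intron_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    intron_start = GenomicRanges::start(gr) - 1L,
    intron_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Derive introns from a GTF annotation
#'
#' Introns are the gaps between consecutive exons of each transcript
#' (GTF coordinates are 1-based inclusive and converted to the package's
#' 0-based half-open convention).
#'
#' @param path GTF file with exon features carrying `transcript_id`.
#' @return data.frame with `chrom`, `intron_start`, `intron_end`, `strand`.
#' @export
read_gtf_introns <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "exon"]
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx = gr$transcript_id
  )
  data.table::setorder(dt, tx, start)
  gaps <- dt[, if (.N >= 2L) list(
    chrom = chrom[-.N], intron_start = end[-.N], intron_end = start[-1L],
    strand = strand[-.N]), by = tx]
  unique(as.data.frame(gaps)[, c("chrom", "intron_start", "intron_end",
                                 "strand")])
}

#' Read gene models from a GTF annotation
#'
#' @param path GTF file with exon features carrying `gene_id`.
#' @param biotype keep only genes of this biotype (via the `gene_biotype`
#'   attribute) — default `"protein_coding"`; `NULL` keeps all.
#' @return a [gene_model_set()].
#' @export
read_gtf_gene_models <- function(path, biotype = "protein_coding") {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "exon"]
  bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
    rep(NA_character_, length(gr))
  if (!is.null(biotype) && any(!is.na(bt))) gr <- gr[!is.na(bt) & bt %in% biotype]
  genes <- unique(data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype else "protein_coding",
    stringsAsFactors = FALSE
  ))
  exons <- data.frame(
    gene_id = gr$gene_id,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  gene_model_set(genes, exons)
}
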