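# Expression: junction spanning-read counts, gene expression as mean
# exonic coverage, and the cross-tissue library-size normalization.

#' Per-tissue library sizes
#'
#' Total aligned reads per tissue (each paired-end mate counted as a
#' separate read), used by [normalize_expression()].
#'
#' @param x named numeric vector of total aligned read counts, one per
#'   tissue; all > 0.
#' @return a `library_sizes` object (named vector with mean attribute).
#' @export
library_sizes <- function(x) {
  stopifnot(is.numeric(x), !is.null(names(x)), all(nzchar(names(x))),
            !anyDuplicated(names(x)))
  if (any(x <= 0)) stop("library sizes must be positive")
  structure(x, mean_size = mean(x), class = "library_sizes")
}

#' @export
print.library_sizes <- function(x, ...) {
  cat(sprintf("library_sizes: %d tissues, mean %.1f reads\n",
              length(x), attr(x, "mean_size")))
  invisible(x)
}

new_expression_matrix <- function(m, kind, normalized) {
  structure(m, kind = kind, normalized = normalized,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s, %s): %d entities x %d tissues\n",
              attr(x, "kind"),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Raw junction expression: spanning-read counts per tissue
#'
#' Raw junction expression in a tissue is the number of reads aligning
#' across the junction; junctions unobserved in a tissue get 0.
#'
#' @param evidence_by_tissue named list (one element per tissue) of
#'   `junction_evidence` or `junction_stats` objects.
#' @param junctions optional character vector of junction ids fixing the
#'   row universe (e.g. the filtered catalog); default is the union of all
#'   observed junctions.
#' @return an `expression_matrix` (raw, junction): junctions x tissues.
#' @export
junction_counts <- function(evidence_by_tissue, junctions = NULL) {
  stopifnot(is.list(evidence_by_tissue), !is.null(names(evidence_by_tissue)))
  if (anyDuplicated(names(evidence_by_tissue)))
    stop("duplicate tissue id in evidence list")
  counts <- lapply(evidence_by_tissue, function(x) {
    if (inherits(x, "junction_evidence")) x <- compute_stats(x)
    stats::setNames(x$read_count, x$junction_id)
  })
  ids <- if (is.null(junctions)) sort(unique(unlist(lapply(counts, names))))
         else junctions
  m <- matrix(0, nrow = length(ids), ncol = length(counts),
              dimnames = list(ids, names(counts)))
  for (t in names(counts)) {
    ct <- counts[[t]]
    ct <- ct[names(ct) %in% ids]
    m[names(ct), t] <- ct
  }
  new_expression_matrix(m, kind = "junction", normalized = FALSE)
}

#' Total aligned bases over each gene's exon union
#'
#' Computes per-base read depth from the alignments (skip/`N` segments of
#' spliced reads contribute no depth) and sums it over the exon-union
#' positions of every gene. Alignments on chromosomes absent from the gene
#' models are skipped and counted in the `qc` attribute.
#'
#' @param aln a `GAlignments` from [read_alignments()], or a file path.
#' @param gene_models a [gene_model_set()].
#' @return named numeric vector of total exonic aligned bases per gene,
#'   with attribute `qc` (list with `n_unknown_chrom`).
#' @export
exonic_coverage <- function(aln, gene_models) {
  if (is.character(aln)) aln <- read_alignments(aln)
  stopifnot(inherits(gene_models, "gene_model_set"))
  cov <- GenomicAlignments::coverage(aln)
  g <- gene_models$genes
  ex <- gene_models$exons
  chrom_of <- stats::setNames(g$chrom, g$gene_id)
  n_unknown <- sum(!(as.character(GenomicRanges::seqnames(aln)) %in% g$chrom))
  totals <- stats::setNames(numeric(nrow(g)), g$gene_id)
  ex_chrom <- chrom_of[ex$gene_id]
  for (chr in intersect(unique(ex_chrom), names(cov))) {
    rle <- cov[[chr]]
    sub <- ex[ex_chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    ok <- IRanges::start(ir) <= length(rle)
    ir <- IRanges::restrict(ir[ok], start = 1L, end = length(rle))
    if (length(ir) == 0L) next
    vs <- as.numeric(sum(IRanges::Views(rle, ir)))
    agg <- tapply(vs, sub$gene_id[ok], sum)
    totals[names(agg)] <- totals[names(agg)] + as.numeric(agg)
  }
  attr(totals, "qc") <- list(n_unknown_chrom = n_unknown)
  totals
}

#' Raw gene expression: mean exonic read depth
#'
#' Raw gene expression is the total number of aligned bases over the exon
#' union divided by the gene length (the exon-union length), i.e. the mean
#' read depth over exonic positions.
#'
#' @param coverage_totals named vector from [exonic_coverage()].
#' @param gene_models a [gene_model_set()].
#' @return named numeric vector of per-gene expression values.
#' @export
gene_expression <- function(coverage_totals, gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  g <- gene_models$genes
  len <- stats::setNames(g$gene_length, g$gene_id)
  ids <- names(coverage_totals)
  stopifnot(all(ids %in% names(len)))
  if (any(len[ids] <= 0)) stop("zero-length gene in model set")
  stats::setNames(as.numeric(coverage_totals) / as.numeric(len[ids]), ids)
}

#' Gene expression matrix across tissues
#'
#' @param aln_by_tissue named list of `GAlignments` or file paths, one per
#'   tissue.
#' @param gene_models a [gene_model_set()].
#' @param biotype restrict to genes of this biotype (default
#'   `"protein_coding"`); `NULL` keeps all.
#' @return an `expression_matrix` (raw, gene): genes x tissues.
#' @export
gene_expression_matrix <- function(aln_by_tissue, gene_models,
                                   biotype = "protein_coding") {
  stopifnot(is.list(aln_by_tissue), !is.null(names(aln_by_tissue)))
  if (anyDuplicated(names(aln_by_tissue)))
    stop("duplicate tissue id in alignment list")
  if (!is.null(biotype)) {
    keep <- gene_models$genes$biotype %in% biotype
    gene_models <- structure(list(
      genes = gene_models$genes[keep, , drop = FALSE],
      exons = gene_models$exons[
        gene_models$exons$gene_id %in% gene_models$genes$gene_id[keep], ,
        drop = FALSE]
    ), class = "gene_model_set")
  }
  cols <- lapply(aln_by_tissue, function(a)
    gene_expression(exonic_coverage(a, gene_models), gene_models))
  m <- do.call(cbind, cols)
  colnames(m) <- names(aln_by_tissue)
  new_expression_matrix(m, kind = "gene", normalized = FALSE)
}

#' Cross-tissue library-size normalization
#'
#' Each tissue's raw values are multiplied by the mean total read count
#' across all tissues and divided by that tissue's total read count:
#' \eqn{\tilde c(e, t) = c(e, t) \cdot \bar N / N_t}. The same scheme
#' applies to junction counts and gene coverage values, which makes the two
#' directly comparable; it resembles RPKM but normalizes to the mean
#' library rather than per million reads.
#'
#' @param matrix an `expression_matrix` (raw).
#' @param sizes a [library_sizes()] covering every tissue in `matrix`.
#' @return the normalized `expression_matrix`.
#' @examples
#' ev <- list(
#'   heart = data.frame(junction_id = "chr1:100-200", read_count = 15),
#'   liver = data.frame(junction_id = "chr1:100-200", read_count = 15))
#' m <- junction_counts(ev)
#' normalize_expression(m, library_sizes(c(heart = 300, liver = 100)))
#' @export
normalize_expression <- function(matrix, sizes) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(sizes, "library_sizes"))
  tissues <- colnames(matrix)
  if (!all(tissues %in% names(sizes)))
    stop("library sizes missing for tissue(s): ",
         paste(setdiff(tissues, names(sizes)), collapse = ", "))
  nt <- as.numeric(sizes[tissues])
  nbar <- attr(sizes, "mean_size")
  out <- sweep(unclass(matrix), 2L, nbar / nt, `*`)
  new_expression_matrix(out, kind = attr(matrix, "kind"), normalized = TRUE)
}

#' Write per-base coverage as bedGraph
#'
#' @param aln a `GAlignments` (or SAM/BAM path); coverage excludes skipped
#'   intronic segments of spliced reads.
#' @param path output bedGraph file.
#' @export
write_bedgraph <- function(aln, path) {
  if (is.character(aln)) aln <- read_alignments(aln)
  cov <- GenomicAlignments::coverage(aln)
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

#' Write / read an expression matrix as TSV (entities x tissues)
#'
#' @param matrix an `expression_matrix`.
#' @param path output file.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(entity = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param kind entity kind flag restored on read.
#' @param normalized normalized flag restored on read.
#' @export
read_expression_matrix <- function(path, kind = "junction",
                                   normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$entity
  new_expression_matrix(m, kind = kind, normalized = normalized)
}
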