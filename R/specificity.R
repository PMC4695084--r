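# Tissue specificity: presence calls, tissue-count distributions,
# junction-gene pairing, the junction x gene specificity matrix,
# SE/PE concordance, and tissue-specific entity lists.

#' Presence calls at an expression threshold
#'
#' An entity is called expressed in a tissue when its (normalized) value is
#' strictly greater than the threshold. The thresholds surveyed in the
#' tissue-distribution analysis are 5, 10, 50, 100, 500 and 1000 reads;
#' downstream specificity analyses use 10.
#'
#' @param matrix an `expression_matrix`, normally normalized
#'   ([normalize_expression()]); raw matrices are accepted for simulator
#'   tests.
#' @param tau nonnegative expression threshold.
#' @return a `presence_matrix`: logical entities x tissues matrix with
#'   attributes `tau` and `kind`.
#' @export
presence_calls <- function(matrix, tau) {
  stopifnot(inherits(matrix, "expression_matrix"), length(tau) == 1L)
  if (tau < 0) stop("threshold must be nonnegative")
  m <- unclass(matrix) > tau
  structure(m, tau = tau, kind = attr(matrix, "kind"),
            class = c("presence_matrix", "matrix", "array"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix (%s, tau=%g): %d entities x %d tissues, %d present cells\n",
              attr(x, "kind"), attr(x, "tau"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Tissue-count distribution of expressed entities
#'
#' Histogram over 1..T of entities by the number of tissues they are
#' expressed in; entities expressed nowhere are excluded. Bin 1 holds the
#' tissue-specific entities and bin T the ubiquitous ones — across
#' thresholds the distribution is typically U-shaped.
#'
#' @param presence a `presence_matrix`.
#' @return named integer vector over `1..T`; sums to the number of
#'   expressed entities.
#' @export
tissue_distribution <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  nt <- rowSums(unclass(presence))
  tt <- ncol(presence)
  counts <- tabulate(nt[nt > 0L], nbins = tt)
  stats::setNames(as.integer(counts), as.character(seq_len(tt)))
}

#' Pair junctions to genes by annotated splice-site ownership
#'
#' A junction is paired to a gene when its intron start and/or end matches
#' one of the gene's annotated donor/acceptor sites ([gene_sites()]). A
#' junction whose boundaries match sites of two or more distinct genes
#' (overlapping genes, or a donor of one gene with an acceptor of another)
#' is excluded as multi-gene; a junction matching no site stays unpaired.
#'
#' @param junctions data.frame with `chrom`, `intron_start`, `intron_end`
#'   (e.g. `junction_stats`).
#' @param gene_models a [gene_model_set()].
#' @return list with `pairs` (data.frame `junction_id`, `gene_id`),
#'   `multi_gene` and `unpaired` (character vectors of junction ids).
#' @export
pair_junctions_to_genes <- function(junctions, gene_models) {
  junctions <- as.data.frame(junctions)
  sites <- gene_sites(gene_models)
  jid <- junction_id(junctions$chrom, junctions$intron_start,
                     junctions$intron_end)
  site_key <- paste(sites$chrom, sites$pos)
  owners <- split(sites$gene_id, site_key)
  g_of <- function(chrom, pos) owners[paste(chrom, pos)]
  start_g <- g_of(junctions$chrom, junctions$intron_start)
  end_g <- g_of(junctions$chrom, junctions$intron_end)
  genes_per_j <- mapply(function(a, b) unique(c(a, b)), start_g, end_g,
                        SIMPLIFY = FALSE)
  ngen <- lengths(genes_per_j)
  paired <- ngen == 1L
  list(
    pairs = data.frame(
      junction_id = jid[paired],
      gene_id = as.character(unlist(genes_per_j[paired], use.names = FALSE)),
      stringsAsFactors = FALSE
    ),
    multi_gene = jid[ngen >= 2L],
    unpaired = jid[ngen == 0L]
  )
}

#' Junction x gene tissue-breadth specificity matrix
#'
#' For each junction-gene pair, counts the number of tissues the junction
#' is expressed in (x) and the number its gene is expressed in (y), and
#' tallies pairs in a T x T grid. Pairs whose junction or gene is expressed
#' in zero tissues are dropped. Cell (1, T) is the headline class: a
#' tissue-specific junction inside a ubiquitously expressed gene. Cells
#' above the diagonal (junction in more tissues than gene) are rare and
#' arise only from threshold effects.
#'
#' @param pairs data.frame `junction_id`, `gene_id` from
#'   [pair_junctions_to_genes()].
#' @param presence_j junction `presence_matrix`.
#' @param presence_g gene `presence_matrix` at the same threshold.
#' @return a `specificity_matrix`: T x T integer matrix, rows = junction
#'   tissue count, cols = gene tissue count; total equals the number of
#'   retained pairs.
#' @export
specificity_matrix <- function(pairs, presence_j, presence_g) {
  stopifnot(inherits(presence_j, "presence_matrix"),
            inherits(presence_g, "presence_matrix"),
            ncol(presence_j) == ncol(presence_g))
  tt <- ncol(presence_j)
  keep <- pairs$junction_id %in% rownames(presence_j) &
    pairs$gene_id %in% rownames(presence_g)
  pairs <- pairs[keep, , drop = FALSE]
  nj <- rowSums(unclass(presence_j))[pairs$junction_id]
  ng <- rowSums(unclass(presence_g))[pairs$gene_id]
  ok <- nj > 0L & ng > 0L
  m <- table(factor(nj[ok], levels = seq_len(tt)),
             factor(ng[ok], levels = seq_len(tt)))
  m <- matrix(as.integer(m), nrow = tt, ncol = tt,
              dimnames = list(junction_tissues = as.character(seq_len(tt)),
                              gene_tissues = as.character(seq_len(tt))))
  structure(m, n_pairs = sum(ok),
            class = c("specificity_matrix", "matrix", "array"))
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("specificity_matrix: %d junction-gene pairs over %d tissues\n",
              attr(x, "n_pairs"), nrow(x)))
  cat(sprintf("  (1,%d) specific junction in ubiquitous gene: %d pairs\n",
              ncol(x), x[1L, ncol(x)]))
  cat(sprintf("  (1,1): %d, (%d,%d): %d\n", x[1L, 1L], nrow(x), ncol(x),
              x[nrow(x), ncol(x)]))
  invisible(x)
}

#' Concordance between two junction sets
#'
#' Exact-key overlap between, e.g., the junctions discovered in single-end
#' and paired-end libraries of the same tissues.
#'
#' @param set_a,set_b character vectors of junction ids (same coordinate
#'   convention).
#' @return list with `n_both`, `n_a_only`, `n_b_only`, and `fraction`
#'   (= |A and B| / |A or B|).
#' @export
concordance <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  both <- length(intersect(a, b))
  un <- length(union(a, b))
  list(n_both = both, n_a_only = length(a) - both,
       n_b_only = length(b) - both,
       fraction = if (un == 0L) NA_real_ else both / un)
}

#' @rdname concordance
#' @param classes named character/factor vector mapping junction ids to
#'   classification values; ids absent from it count as novel.
#' @return for `concordance_by_class`: list of [concordance()] results for
#'   `all`, `annotated`, `novel`.
#' @export
concordance_by_class <- function(set_a, set_b, classes) {
  is_ann <- function(ids) {
    cl <- classes[ids]
    !is.na(cl) & cl == "annotated"
  }
  list(all = concordance(set_a, set_b),
       annotated = concordance(set_a[is_ann(set_a)], set_b[is_ann(set_b)]),
       novel = concordance(set_a[!is_ann(set_a)], set_b[!is_ann(set_b)]))
}

#' Overlap of a filtered junction set with an unfiltered one
#'
#' Fraction of the filtered junctions from one library found anywhere
#' (no threshold) in the other library; always at least the
#' filtered-vs-filtered concordance on the same sets.
#'
#' @param filtered_a character vector of filtered junction ids (non-empty).
#' @param unfiltered_b character vector of unfiltered junction ids.
#' @return fraction in `[0, 1]`.
#' @export
filtered_vs_unfiltered_overlap <- function(filtered_a, unfiltered_b) {
  filtered_a <- unique(filtered_a)
  if (length(filtered_a) == 0L) stop("empty filtered set")
  mean(filtered_a %in% unique(unfiltered_b))
}

#' Tissue-specific entities confirmed in both library types
#'
#' An entity is tissue-specific for tissue t when it is expressed in
#' exactly {t} in the single-end data AND exactly {t} in the paired-end
#' data. Requiring both libraries treats them as technical replicates.
#'
#' @param presence_se,presence_pe `presence_matrix` objects over the same
#'   tissue universe.
#' @param require_both set `FALSE` to call specificity from `presence_se`
#'   alone (single-library mode for simulator tests).
#' @return named list: for each tissue, the character vector of entity ids
#'   specific to it.
#' @export
tissue_specific_lists <- function(presence_se, presence_pe = NULL,
                                  require_both = TRUE) {
  stopifnot(inherits(presence_se, "presence_matrix"))
  tissues <- colnames(presence_se)
  specific_tissue <- function(p, ids) {
    m <- unclass(p)[ids, , drop = FALSE]
    one <- rowSums(m) == 1L
    out <- rep(NA_character_, length(ids))
    out[one] <- tissues[max.col(m[one, , drop = FALSE])]
    stats::setNames(out, ids)
  }
  if (require_both && !is.null(presence_pe)) {
    stopifnot(inherits(presence_pe, "presence_matrix"))
    if (!identical(sort(colnames(presence_se)), sort(colnames(presence_pe))))
      stop("tissue universes differ between libraries")
    ids <- intersect(rownames(presence_se), rownames(presence_pe))
    se <- specific_tissue(presence_se, ids)
    pe <- specific_tissue(presence_pe[, tissues, drop = FALSE], ids)
    hit <- !is.na(se) & !is.na(pe) & se == pe
    spec <- se[hit]
  } else {
    ids <- rownames(presence_se)
    se <- specific_tissue(presence_se, ids)
    spec <- se[!is.na(se)]
  }
  lapply(stats::setNames(tissues, tissues),
         function(t) names(spec)[spec == t])
}

#' Multi-exon genes containing tissue-restricted junctions
#'
#' Summary of how widespread tissue-restricted splicing is: for multi-exon
#' genes expressed at all, expressed in more than one tissue, and expressed
#' in every tissue, counts how many contain at least one paired junction
#' expressed in exactly one tissue.
#'
#' @param pairs data.frame from [pair_junctions_to_genes()].
#' @param presence_j,presence_g `presence_matrix` objects at the same
#'   threshold.
#' @param gene_models a [gene_model_set()] (provides the multi-exon flag).
#' @return data.frame with rows `expressed`, `expressed_gt1`,
#'   `expressed_all`, columns `n_genes`, `n_with_specific_junction`,
#'   `percent`.
#' @export
genes_with_specific_junctions <- function(pairs, presence_j, presence_g,
                                          gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  tt <- ncol(presence_g)
  multi <- gene_models$genes$gene_id[gene_models$genes$multi_exon]
  gids <- intersect(rownames(presence_g), multi)
  ng <- rowSums(unclass(presence_g))[gids]
  nj <- rowSums(unclass(presence_j))
  pairs <- pairs[pairs$gene_id %in% gids &
                 pairs$junction_id %in% rownames(presence_j), , drop = FALSE]
  spec_j <- pairs$junction_id[nj[pairs$junction_id] == 1L]
  genes_with <- unique(pairs$gene_id[pairs$junction_id %in% spec_j])
  row_for <- function(sel) {
    sel_ids <- gids[sel]
    n <- length(sel_ids)
    w <- length(intersect(sel_ids, genes_with))
    data.frame(n_genes = n, n_with_specific_junction = w,
               percent = if (n) 100 * w / n else NA_real_)
  }
  out <- rbind(expressed = row_for(ng >= 1L),
               expressed_gt1 = row_for(ng > 1L),
               expressed_all = row_for(ng == tt))
  out
}

#' Ratio of detectable junctions to detectable genes per threshold
#'
#' Detection-bias control: if low expression favoured detecting gene bodies
#' over junction-spanning reads, this ratio would rise with the threshold;
#' a stable ratio indicates no such artifact.
#'
#' @param matrix_j,matrix_g normalized junction and gene
#'   `expression_matrix` objects.
#' @param taus thresholds to survey.
#' @return data.frame with `tau`, `n_junctions`, `n_genes`, `ratio`.
#' @export
junction_gene_ratio <- function(matrix_j, matrix_g,
                                taus = c(5, 10, 50, 100, 500, 1000)) {
  rows <- lapply(taus, function(tau) {
    nj <- sum(rowSums(unclass(matrix_j) > tau) > 0L)
    ng <- sum(rowSums(unclass(matrix_g) > tau) > 0L)
    data.frame(tau = tau, n_junctions = nj, n_genes = ng,
               ratio = if (ng > 0L) nj / ng else NA_real_)
  })
  do.call(rbind, rows)
}
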