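# Reporting: the BED12 junction-track dialect (one thick base on each
# flanking exon joined by a thin line), and concept-score normalization
# for text-mining association matrices.

#' A fixed 16-colour palette for per-tissue track colouring
#'
#' @param n number of colours (recycled beyond 16).
#' @return character vector of `R,G,B` strings for the BED `itemRgb` field.
#' @export
tissue_palette <- function(n = 16L) {
  base <- c(
    "230,25,75", "60,180,75", "255,225,25", "0,130,200",
    "245,130,48", "145,30,180", "70,240,240", "240,50,230",
    "210,245,60", "250,190,190", "0,128,128", "230,190,255",
    "170,110,40", "255,250,200", "128,0,0", "0,0,128"
  )
  rep_len(base, n)
}

#' Write junctions as a BED12 track
#'
#' Each junction becomes one 12-column BED line showing the last base of
#' the upstream exon and the first base of the downstream exon as 1-bp
#' thick blocks connected by a thin line across the intron: `chromStart =
#' intron_start - 1`, `chromEnd = intron_end + 1`, `blockCount = 2`,
#' `blockSizes = "1,1"`, `blockStarts = "0,<intron_length + 1>"`. The
#' resulting file is loadable as a UCSC Genome Browser custom track.
#' Junctions with `intron_start = 0` have no representable upstream exonic
#' base and are skipped with a warning.
#'
#' @param junctions data.frame with `chrom`, `intron_start`, `intron_end`
#'   and optionally `strand` and `read_count`.
#' @param path output file; `NULL` returns the lines only.
#' @param name per-junction name field; for a tissue-specific track pass
#'   the tissue label. Default is the junction id.
#' @param score per-junction score; default `read_count` (0 when absent),
#'   capped at 1000 as BED requires.
#' @param itemRgb per-junction `R,G,B` colour string (default black).
#' @param track_line optional `track name=...` header (some strict BED
#'   consumers reject one, so none is written by default).
#' @return the BED lines, invisibly when written to `path`.
#' @export
write_junction_bed <- function(junctions, path = NULL, name = NULL,
                               score = NULL, itemRgb = "0,0,0",
                               track_line = NULL) {
  junctions <- as.data.frame(junctions)
  n <- nrow(junctions)
  keep <- junctions$intron_start >= 1L
  if (any(!keep)) {
    warning(sum(!keep), " junction(s) at intron_start 0 skipped: no upstream",
            " exonic base representable")
  }
  if (is.null(name))
    name <- junction_id(junctions$chrom, junctions$intron_start,
                        junctions$intron_end)
  if (is.null(score))
    score <- if (!is.null(junctions$read_count)) junctions$read_count else 0L
  score <- pmin(as.integer(round(rep_len(score, n))), 1000L)
  strand <- if (!is.null(junctions$strand)) {
    ifelse(junctions$strand %in% c("+", "-"), junctions$strand, ".")
  } else rep(".", n)
  name <- rep_len(name, n)
  itemRgb <- rep_len(itemRgb, n)
  j <- junctions[keep, , drop = FALSE]
  len <- j$intron_end - j$intron_start
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t%s\t2\t1,1\t0,%d",
                   j$chrom, j$intron_start - 1L, j$intron_end + 1L,
                   name[keep], score[keep], strand[keep],
                   j$intron_start - 1L, j$intron_end + 1L,
                   itemRgb[keep], len + 1L)
  if (!is.null(track_line)) lines <- c(track_line, lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a BED12 junction track back into junction coordinates
#'
#' Inverse of [write_junction_bed()] for files in its dialect.
#'
#' @param path BED12 file; `track` header lines are ignored.
#' @return data.frame with `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `name`, `score`.
#' @export
read_junction_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      name = character(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 12L)) stop("not a 12-column BED file")
  m <- do.call(rbind, f)
  data.frame(
    chrom = m[, 1L],
    intron_start = as.integer(m[, 2L]) + 1L,
    intron_end = as.integer(m[, 3L]) - 1L,
    strand = ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*"),
    name = m[, 4L],
    score = as.integer(m[, 5L]),
    stringsAsFactors = FALSE
  )
}

#' Normalize concept association scores against a random-gene background
#'
#' Generic normalization for externally produced text-mining association
#' matrices (concepts x gene sets): each set's sum scores are divided by
#' its set size, the equivalently normalized background (random-gene) score
#' is subtracted per concept, and negative values are clipped to 0.
#'
#' @param scores numeric matrix, concepts x gene sets, of sum scores.
#' @param set_sizes positive numeric vector of set sizes, one per column.
#' @param background per-concept background sum scores (length nrow), from
#'   a random gene set.
#' @param n_background size of the background set (> 0).
#' @return normalized matrix, same dimensions, all values >= 0.
#' @export
normalize_concept_scores <- function(scores, set_sizes, background,
                                     n_background) {
  scores <- as.matrix(scores)
  stopifnot(length(set_sizes) == ncol(scores),
            length(background) == nrow(scores),
            length(n_background) == 1L)
  if (any(set_sizes <= 0) || n_background <= 0)
    stop("set sizes must be positive")
  out <- sweep(scores, 2L, as.numeric(set_sizes), `/`) -
    as.numeric(background) / as.numeric(n_background)
  pmax(out, 0)
}
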