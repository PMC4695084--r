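# Junction catalog: extract putative splice junctions from spliced SAM
# alignments and compute per-junction supporting-read statistics.

#' Read spliced alignments from a SAM or BAM file
#'
#' Loads primary, mapped alignments together with the per-read edit-distance
#' (`NM`) and splice-strand (`XS`) tags. SAM input is converted to BAM in a
#' temporary directory. Records with malformed CIGAR strings or truncated
#' fields are skipped and counted in the `qc` attribute rather than aborting
#' the run.
#'
#' @param path path to a SAM (`.sam`) or BAM file.
#' @param include_secondary count secondary alignments as supporting
#'   evidence (default `FALSE`: primary alignments only).
#' @return a [GenomicAlignments::GAlignments] object with metadata columns
#'   `flag`, `NM` and `XS`, and an attribute `qc` (list with
#'   `n_alignments` and `n_skipped_malformed`).
#' @export
read_alignments <- function(path, include_secondary = FALSE) {
  stopifnot(length(path) == 1L, file.exists(path))
  n_skipped <- 0L
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) NA_character_
    )
    if (is.na(bam)) {
      clean <- sanitize_sam(path)
      n_skipped <- clean$n_skipped
      bam <- Rsamtools::asBam(clean$path, dest, overwrite = TRUE,
                              indexDestination = FALSE)
    }
  } else {
    bam <- path
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(what = "flag", tag = c("NM", "XS"),
                                   flag = flag)
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  attr(ga, "qc") <- list(n_alignments = length(ga),
                         n_skipped_malformed = n_skipped)
  ga
}

# Drop SAM records that a strict parser would reject: wrong field count,
# non-numeric POS, or CIGAR not matching the grammar. Returns the cleaned
# temp file and the number of records removed.
sanitize_sam <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  body <- lines[!hdr]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 11L &&
      grepl("^[0-9]+$", f[4L]) &&
      (f[6L] == "*" || grepl("^([0-9]+[MIDNSHP=X])+$", f[6L]))
  }, logical(1L))
  out <- tempfile(fileext = ".sam")
  writeLines(c(lines[hdr], body[ok]), out)
  list(path = out, n_skipped = sum(!ok))
}

#' Extract putative splice junctions with supporting-read evidence
#'
#' Every `N` (skip) operation in an alignment CIGAR defines a putative
#' intron. A read with k skip operations contributes evidence to k
#' junctions. For each incidence the read's start offset (leftmost aligned
#' reference position minus the intron start, 0-based) and its whole-read
#' mismatch count (`NM` tag) are recorded; these drive the entropy and
#' average-mismatch junction filters.
#'
#' @param x a `GAlignments` object from [read_alignments()], or a file path.
#' @param include_secondary passed to [read_alignments()] when `x` is a path.
#' @return a `junction_evidence` object: a data.table with one row per
#'   (read, junction) incidence and columns `chrom`, `intron_start`,
#'   `intron_end` (0-based half-open), `strand`, `offset`, `mismatches`.
#'   Carries the reader's `qc` attribute.
#' @export
extract_junctions <- function(x, include_secondary = FALSE) {
  if (is.character(x)) x <- read_alignments(x, include_secondary)
  stopifnot(methods::is(x, "GAlignments"))
  qc <- attr(x, "qc")
  spliced <- GenomicAlignments::njunc(x) > 0L
  ga <- x[spliced]
  if (length(ga) == 0L) {
    ev <- data.table::data.table(
      chrom = character(), intron_start = integer(), intron_end = integer(),
      strand = character(), offset = integer(), mismatches = integer()
    )
    return(new_junction_evidence(ev, qc))
  }
  skips <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicRanges::start(ga), ops = "N"
  )
  nper <- S4Vectors::elementNROWS(skips)
  idx <- rep(seq_along(ga), nper)
  flat <- unlist(skips, use.names = FALSE)
  nm <- S4Vectors::mcols(ga)$NM
  if (is.null(nm)) nm <- rep(0L, length(ga))
  nm[is.na(nm)] <- 0L
  xs <- S4Vectors::mcols(ga)$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(ga))
  ev <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(ga))[idx],
    intron_start = GenomicRanges::start(flat) - 1L,
    intron_end = GenomicRanges::end(flat),
    strand = ifelse(is.na(xs[idx]), "*", as.character(xs[idx])),
    offset = (GenomicRanges::start(ga)[idx] - 1L) -
      (GenomicRanges::start(flat) - 1L),
    mismatches = as.integer(nm[idx])
  )
  new_junction_evidence(ev, qc)
}

new_junction_evidence <- function(ev, qc = NULL) {
  data.table::setattr(ev, "class",
                      c("junction_evidence", class(data.table::data.table())))
  data.table::setattr(ev, "qc", qc)
  ev
}

#' @export
print.junction_evidence <- function(x, ...) {
  nj <- nrow(unique(x[, c("chrom", "intron_start", "intron_end")]))
  cat(sprintf("junction_evidence: %d spanning-read incidences over %d junctions\n",
              nrow(x), nj))
  invisible(x)
}

#' Merge supporting-read evidence from several alignment sets
#'
#' Evidence is additive: merging the evidence of two SAM files equals
#' extracting from their concatenation.
#'
#' @param ... `junction_evidence` objects.
#' @return a combined `junction_evidence`.
#' @export
merge_evidence <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "junction_evidence")))
  new_junction_evidence(data.table::rbindlist(parts))
}

#' Shannon entropy of a read-offset histogram
#'
#' For counts \eqn{c_i} over distinct read start offsets around a junction,
#' with \eqn{p_i = c_i / \sum c_i}, returns \eqn{S = -\sum p_i \log p_i} in
#' the requested log base. A junction supported by reads stacked at a single
#' offset has entropy 0 and is a likely alignment artifact; well-supported
#' junctions accumulate reads at many offsets.
#'
#' @param counts numeric vector of per-offset read counts (all >= 1), or a
#'   named table. Offsets themselves are irrelevant: entropy is invariant
#'   under relabeling.
#' @param base logarithm base; default 2 (bits).
#' @return nonnegative entropy, at most `log(length(counts), base)`.
#' @examples
#' junction_entropy(c(10))        # all reads at one offset: 0
#' junction_entropy(rep(1, 4))    # uniform over 4 offsets: 2 bits
#' junction_entropy(c(3, 1))      # skewed: ~0.811
#' @export
junction_entropy <- function(counts, base = 2) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty offset histogram")
  if (any(counts < 1)) stop("offset counts must be >= 1")
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Average mismatches per spanning read
#'
#' @param mismatch_counts integer vector of per-read mismatch counts (the
#'   whole-read edit distance of every read spanning the junction).
#' @return arithmetic mean.
#' @export
average_mismatches <- function(mismatch_counts) {
  if (length(mismatch_counts) == 0L) stop("no spanning reads")
  mean(as.numeric(mismatch_counts))
}

#' Per-junction filtering statistics
#'
#' Aggregates spanning-read evidence into the junction catalog: read count,
#' offset entropy, average mismatches, and intron length — the variables the
#' junction filters act on.
#'
#' @param evidence a `junction_evidence` from [extract_junctions()].
#' @param log_base entropy log base (default 2).
#' @return a `junction_stats` data.frame with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `read_count`, `entropy`,
#'   `avg_mismatch`, `intron_length`, plus a `junction_id` key column.
#'   Junctions are keyed without strand, so evidence from both strands of an
#'   unstranded library merges; the reported strand is the consensus or
#'   `"*"` when mixed.
#' @export
compute_stats <- function(evidence, log_base = 2) {
  stopifnot(inherits(evidence, "junction_evidence"))
  if (nrow(evidence) == 0L) {
    out <- data.frame(
      junction_id = character(), chrom = character(),
      intron_start = integer(), intron_end = integer(), strand = character(),
      read_count = integer(), entropy = numeric(), avg_mismatch = numeric(),
      intron_length = integer(), stringsAsFactors = FALSE
    )
    class(out) <- c("junction_stats", "data.frame")
    return(out)
  }
  ev <- data.table::as.data.table(evidence)
  # offset histogram per junction, then entropy over it
  hist <- ev[, list(n = .N),
             by = list(chrom, intron_start, intron_end, offset)]
  ent <- hist[, list(entropy = junction_entropy(n, base = log_base)),
              by = list(chrom, intron_start, intron_end)]
  agg <- ev[, list(
    strand = if (data.table::uniqueN(strand) == 1L) strand[1L] else "*",
    read_count = .N,
    avg_mismatch = mean(as.numeric(mismatches))
  ), by = list(chrom, intron_start, intron_end)]
  out <- merge(agg, ent, by = c("chrom", "intron_start", "intron_end"))
  out[, intron_length := intron_end - intron_start]
  data.table::setorder(out, chrom, intron_start, intron_end)
  out <- as.data.frame(out)
  out$junction_id <- junction_id(out$chrom, out$intron_start, out$intron_end)
  out <- out[, c("junction_id", "chrom", "intron_start", "intron_end",
                 "strand", "read_count", "entropy", "avg_mismatch",
                 "intron_length")]
  class(out) <- c("junction_stats", "data.frame")
  out
}

#' @export
print.junction_stats <- function(x, ...) {
  cat(sprintf("junction_stats: %d junctions\n", nrow(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write / read a junction catalog as TSV
#'
#' @param stats a `junction_stats` data.frame.
#' @param path output file.
#' @export
write_junction_catalog <- function(stats, path) {
  stopifnot(inherits(stats, "junction_stats"))
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_catalog
#' @export
read_junction_catalog <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(junction_id = "character",
                                          chrom = "character",
                                          strand = "character"),
                           stringsAsFactors = FALSE)
  class(out) <- c("junction_stats", "data.frame")
  out
}
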