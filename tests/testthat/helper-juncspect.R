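# Shared fixtures, all built in code at test time.

# junction evidence built directly (bypassing SAM) for unit tests
make_evidence <- function(offsets, mismatches, chrom = "chr1",
                          intron_start = 100L, intron_end = 200L,
                          strand = "*") {
  stopifnot(length(offsets) == length(mismatches))
  ev <- data.table::data.table(
    chrom = chrom, intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end), strand = strand,
    offset = as.integer(offsets), mismatches = as.integer(mismatches)
  )
  juncspect:::new_junction_evidence(ev)
}

# minimal SAM writer: records are lists/data.frames of fields
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           chroms = c(chr1 = 100000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, chrom, pos, cigar, nm = 0L, flag = 0L,
                       len = NULL) {
  if (is.null(len)) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1]]
    len <- sum(as.integer(sub("[MIS=X]", "", ops)))
  }
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
          qname, flag, chrom, pos, cigar, strrep("A", len),
          strrep("I", len), nm)
}

# small annotation index: three + introns, one - intron
toy_index <- function() {
  build_annotation_index(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    intron_start = c(100L, 300L, 700L, 50L),
    intron_end = c(200L, 500L, 900L, 120L),
    strand = c("+", "+", "+", "-")
  ))
}

# memoised small simulated reference shared across test files
.juncspect_cache <- new.env(parent = emptyenv())
small_reference <- function() {
  if (is.null(.juncspect_cache$ref)) {
    cfg <- simulation_config(n_tissues = 4, n_genes = 30, seed = 42,
                             depth_per_tissue = 30,
                             frac_novel_junctions = 0.15,
                             frac_artifact_junctions = 0.1)
    .juncspect_cache$ref <- generate_reference(cfg)
  }
  .juncspect_cache$ref
}

# tiny two-gene GTF fixture written to a temp file
write_test_gtf <- function(path = tempfile(fileext = ".gtf")) {
  attr_of <- function(g) sprintf(
    'gene_id "%s"; transcript_id "%s.t1"; gene_biotype "protein_coding";', g, g)
  lines <- c(
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t+\t.\t%s", 101, 200, attr_of("gA")),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t+\t.\t%s", 301, 400, attr_of("gA")),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t+\t.\t%s", 601, 700, attr_of("gA")),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t-\t.\t%s", 2001, 2150, attr_of("gB")),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t-\t.\t%s", 2401, 2550, attr_of("gB"))
  )
  writeLines(lines, path)
  path
}
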