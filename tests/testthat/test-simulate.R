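test_that("planted gene fractions are exact and forced by the config", {
  cfg <- simulation_config(n_tissues = 4, n_genes = 10,
                           frac_tissue_specific_genes = 0.3,
                           frac_single_exon_genes = 0, seed = 1)
  ref <- generate_reference(cfg)
  prof <- truth_profiles(ref$truth, "gene")
  expect_equal(sum(lengths(prof) == 1L), 3L)
  expect_equal(sum(lengths(prof) == 4L), 7L)
})

test_that("frac_novel_junctions = 0 plants only annotated junctions", {
  cfg <- simulation_config(n_tissues = 3, n_genes = 12,
                           frac_novel_junctions = 0, seed = 2)
  ref <- generate_reference(cfg)
  expect_true(all(ref$truth$junctions$status == "annotated"))
  # and the annotation index then contains every planted junction
  cls <- classify_junction(ref$truth$junctions, ref$annotation)
  expect_true(all(cls == "annotated"))
})

test_that("novel junctions are withheld from the annotation index", {
  ref <- small_reference()
  jt <- ref$truth$junctions
  known <- paste(ref$annotation$known_introns$chrom,
                 ref$annotation$known_introns$intron_start,
                 ref$annotation$known_introns$intron_end)
  planted <- paste(jt$chrom, jt$intron_start, jt$intron_end)
  expect_true(all(planted[jt$status == "annotated"] %in% known))
  expect_false(any(planted[jt$status != "annotated"] %in% known))
  # classification by construction reproduces the planted status
  expect_equal(as.character(classify_junction(jt, ref$annotation)),
               jt$status)
})

test_that("generation and simulation are deterministic under a fixed seed", {
  cfg <- simulation_config(n_tissues = 3, n_genes = 8, seed = 7)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$truth, r2$truth)
  s1 <- simulate_alignments(r1, tissue = "brain", library = "SE")
  s2 <- simulate_alignments(r2, tissue = "brain", library = "SE")
  expect_identical(s1$lines, s2$lines)
  expect_identical(s1$junction_read_counts, s2$junction_read_counts)
  # different tissue or library gives a different stream
  s3 <- simulate_alignments(r1, tissue = "adrenal", library = "SE")
  expect_false(identical(s1$lines, s3$lines))
})

test_that("junction tissue profiles are subsets of their gene's profile", {
  ref <- small_reference()
  jp <- truth_profiles(ref$truth, "junction")
  gp <- truth_profiles(ref$truth, "gene")
  gene_of <- setNames(ref$truth$junctions$gene_id,
                      ref$truth$junctions$junction_id)
  for (j in names(jp)) {
    expect_true(all(jp[[j]] %in% gp[[gene_of[[j]]]]))
  }
  # every junction maps to exactly one gene
  expect_false(anyDuplicated(ref$truth$junctions$junction_id) > 0)
})

test_that("no reads are emitted for junctions outside the tissue profile", {
  ref <- small_reference()
  jt <- ref$truth$junctions
  spec <- jt[!grepl(",", jt$tissues), , drop = FALSE]
  expect_gt(nrow(spec), 0L)
  other <- setdiff(ref$truth$tissues, spec$tissues[1L])[1L]
  sim <- simulate_alignments(ref, tissue = other, library = "SE")
  expect_equal(unname(sim$junction_read_counts[spec$junction_id[1L]]), 0L)
  # and every emitted skip interval is a truth junction
  p <- tempfile(fileext = ".sam")
  writeLines(sim$lines, p)
  ev <- extract_junctions(p)
  ids <- unique(junction_id(ev$chrom, ev$intron_start, ev$intron_end))
  expect_true(all(ids %in% jt$junction_id))
})

test_that("deep uniform junctions occupy many distinct offsets", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 3, seed = 5,
                           depth_per_tissue = 500,
                           frac_tissue_specific_genes = 0,
                           frac_single_exon_genes = 0,
                           frac_novel_junctions = 0)
  ref <- generate_reference(cfg)
  p <- tempfile(fileext = ".sam")
  simulate_alignments(ref, tissue = "adipose", library = "SE", path = p)
  ev <- extract_junctions(p)
  per_j <- tapply(ev$offset, junction_id(ev$chrom, ev$intron_start,
                                         ev$intron_end),
                  function(x) length(unique(x)))
  expect_true(all(per_j > 1L))
})

test_that("spanning-read depth is Poisson-consistent across >= 100 junctions", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 60, seed = 9,
                           depth_per_tissue = 30,
                           frac_tissue_specific_genes = 0,
                           frac_ubiquitous_genes_with_specific_junction = 0,
                           frac_single_exon_genes = 0,
                           frac_novel_junctions = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_alignments(ref, tissue = "adipose", library = "SE")
  counts <- sim$junction_read_counts
  expect_gte(length(counts), 100L)
  within <- abs(counts - 30) <= 4 * sqrt(30)
  expect_gte(mean(within), 0.99)
})

test_that("paired-end mode emits proper pairs at the configured insert size", {
  ref <- small_reference()
  p <- tempfile(fileext = ".sam")
  sim <- simulate_alignments(ref, tissue = "brain", library = "PE", path = p)
  aln <- read_alignments(p)
  flags <- S4Vectors::mcols(aln)$flag
  expect_equal(sum(flags == 99L), sum(flags == 147L))
  expect_equal(length(aln), sim$n_records)
  expect_true(all(bitwAnd(flags, 1L) == 1L))  # all reads paired
  qw <- unique(GenomicAlignments::qwidth(aln))
  expect_equal(qw, ref$config$read_length_pe)
})

test_that("truth export round-trips losslessly", {
  ref <- small_reference()
  f <- tempfile(fileext = ".tsv")
  export_truth(ref$truth, f)
  expect_equal(read_truth(f), ref$truth)

  # empty truth -> header-only file
  empty <- structure(list(
    tissues = character(),
    gene_profiles = data.frame(gene_id = character(), tissues = character(),
                               stringsAsFactors = FALSE),
    junctions = ref$truth$junctions[0, ]), class = "truth_set")
  f2 <- tempfile(fileext = ".tsv")
  export_truth(empty, f2)
  expect_equal(length(readLines(f2)), 1L)
  back <- read_truth(f2)
  expect_equal(length(back$tissues), 0L)
  expect_equal(nrow(back$junctions), 0L)

  # randomized subset round-trip
  set.seed(10)
  sub <- ref$truth
  keep <- sample(nrow(sub$junctions), 5)
  sub$junctions <- sub$junctions[keep, ]
  rownames(sub$junctions) <- NULL
  f3 <- tempfile(fileext = ".tsv")
  export_truth(sub, f3)
  expect_equal(read_truth(f3), sub)
})

test_that("a fixed chromosome length too small for the genes errors", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 10, seed = 3,
                           chrom_length = 10000)
  expect_error(generate_reference(cfg), "genome too small")
})
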