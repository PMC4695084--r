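pm <- function(m, tau = 10, kind = "junction") {
  presence_calls(juncspect:::new_expression_matrix(m, kind, TRUE), tau)
}

test_that("presence is a strict inequality over the threshold", {
  m <- matrix(c(10, 10.5, 0), 3, 1,
              dimnames = list(c("a", "b", "c"), "heart"))
  p <- pm(m, 10)
  expect_false(p["a", "heart"])  # exactly at threshold: not expressed
  expect_true(p["b", "heart"])
  expect_false(p["c", "heart"])
  expect_error(pm(m, -1), "nonnegative")
})

test_that("presence counts are monotone non-increasing in the threshold", {
  set.seed(60)
  m <- matrix(rexp(400, 1 / 50), 40, 10,
              dimnames = list(sprintf("e%02d", 1:40), sprintf("t%02d", 1:10)))
  taus <- c(5, 10, 50, 100, 500, 1000)
  present <- vapply(taus, function(x) sum(pm(m, x)), numeric(1))
  expect_true(all(diff(present) <= 0))
  # and mass shifts toward the tissue-specific bin as tau grows
  d5 <- tissue_distribution(pm(m, 5))
  d500 <- tissue_distribution(pm(m, 500))
  frac1 <- function(d) if (sum(d) == 0) 0 else d[["1"]] / sum(d)
  expect_gte(frac1(d500), frac1(d5))
})

test_that("tissue distribution bins entities by breadth and drops absent ones", {
  m <- matrix(0, 3, 4, dimnames = list(c("ubiq", "spec", "off"),
                                       paste0("t", 1:4)))
  m["ubiq", ] <- 100
  m["spec", "t2"] <- 100
  d <- tissue_distribution(pm(m, 10))
  expect_equal(unname(d), c(1L, 0L, 0L, 1L))
  expect_equal(sum(d), 2L)  # 'off' is excluded
})

test_that("junction-gene pairing follows site ownership and the multi-gene rule", {
  gm <- gene_model_set(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       strand = "+"),
    exons = data.frame(gene_id = c("gA", "gA", "gB", "gB"),
                       start = c(0L, 500L, 450L, 1500L),
                       end = c(100L, 600L, 550L, 1600L)))
  # gA sites: 100 (donor), 500 (acceptor); gB sites: 550, 1500
  j <- data.frame(
    chrom = "chr1",
    intron_start = c(100L, 100L, 7777L),
    intron_end = c(333L, 1500L, 8888L))
  out <- pair_junctions_to_genes(j, gm)
  expect_equal(out$pairs$junction_id, "chr1:100-333")  # donor of gA only
  expect_equal(out$pairs$gene_id, "gA")
  expect_equal(out$multi_gene, "chr1:100-1500")  # gA donor + gB acceptor
  expect_equal(out$unpaired, "chr1:7777-8888")

  # brute force on fuzzed junctions against explicit site ownership
  set.seed(61)
  sites <- gene_sites(gm)
  n <- 300L
  jf <- data.frame(
    chrom = "chr1",
    intron_start = sample(c(sites$pos, sample(1:2000, 30)), n, TRUE))
  jf$intron_end <- jf$intron_start +
    sample(c(60L, 400L, 1400L, sample(51:900, 20)), n, TRUE)
  jf <- unique(jf)
  res <- pair_junctions_to_genes(jf, gm)
  for (i in seq_len(nrow(jf))) {
    own <- unique(sites$gene_id[sites$pos %in%
                                  c(jf$intron_start[i], jf$intron_end[i])])
    id <- junction_id(jf$chrom[i], jf$intron_start[i], jf$intron_end[i])
    if (length(own) == 1L) {
      expect_equal(res$pairs$gene_id[res$pairs$junction_id == id], own)
    } else if (length(own) >= 2L) {
      expect_true(id %in% res$multi_gene)
    } else {
      expect_true(id %in% res$unpaired)
    }
  }
})

test_that("specificity matrix tallies pairs by tissue breadth", {
  tiss <- paste0("t", 1:16)
  mj <- matrix(0, 2, 16, dimnames = list(c("j1", "j2"), tiss))
  mg <- matrix(100, 2, 16, dimnames = list(c("g1", "g2"), tiss))
  mj["j1", "t3"] <- 100          # junction in one tissue, gene in 16
  mj["j2", ] <- 100              # both ubiquitous
  pairs <- data.frame(junction_id = c("j1", "j2"), gene_id = c("g1", "g2"))
  sm <- specificity_matrix(pairs, pm(mj), pm(mg, kind = "gene"))
  expect_equal(sm["1", "16"], 1L)
  expect_equal(sm["16", "16"], 1L)
  expect_equal(sum(sm), 2L)
  expect_equal(attr(sm, "n_pairs"), 2L)
  # identical profiles land on the diagonal
  mj2 <- mg
  rownames(mj2) <- c("j1", "j2")
  smd <- specificity_matrix(pairs, pm(mj2), pm(mg, kind = "gene"))
  expect_equal(sum(diag(smd)), 2L)
  # a pair absent everywhere is dropped
  mj["j2", ] <- 0
  mg["g2", ] <- 0
  sm0 <- specificity_matrix(pairs, pm(mj), pm(mg, kind = "gene"))
  expect_equal(sum(sm0), 1L)
})

test_that("concordance counts exact-key overlaps", {
  expect_equal(concordance(c("x", "y"), c("x", "y"))$fraction, 1.0)
  cc <- concordance(c("x", "y"), c("y", "z"))
  expect_equal(cc$n_both, 1L)
  expect_equal(cc$n_a_only, 1L)
  expect_equal(cc$n_b_only, 1L)
  expect_equal(cc$fraction, 1 / 3)
  cls <- c(x = "annotated", y = "annotated", z = "novel_neither")
  by_cls <- concordance_by_class(c("x", "y", "z"), c("x", "z"), cls)
  expect_equal(by_cls$annotated$fraction, 1 / 2)
  expect_equal(by_cls$novel$fraction, 1)
})

test_that("filtered-vs-unfiltered overlap bounds filtered concordance", {
  expect_equal(filtered_vs_unfiltered_overlap(c("a", "b"),
                                              c("a", "b", "c")), 1.0)
  expect_equal(filtered_vs_unfiltered_overlap(c("a"), c("z")), 0.0)
  expect_error(filtered_vs_unfiltered_overlap(character(), "a"), "empty")
  set.seed(62)
  for (i in 1:20) {
    univ <- sprintf("j%03d", 1:80)
    unf_a <- sample(univ, 60); unf_b <- sample(univ, 60)
    fa <- sample(unf_a, 30); fb <- sample(unf_b, 30)
    expect_gte(filtered_vs_unfiltered_overlap(fa, unf_b),
               concordance(fa, fb)$fraction)
  }
})

test_that("tissue-specific lists require agreement between the libraries", {
  tiss <- c("heart", "liver", "testes")
  se <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), tiss))
  pe <- se
  se["a", "heart"] <- 100; pe["a", "liver"] <- 100   # disagree: dropped
  se["b", "testes"] <- 100; pe["b", "testes"] <- 100 # agree: listed
  se["c", ] <- 100; pe["c", ] <- 100                 # ubiquitous: not specific
  out <- tissue_specific_lists(pm(se), pm(pe))
  expect_equal(out$testes, "b")
  expect_equal(out$heart, character(0))
  expect_equal(out$liver, character(0))
  # single-library mode
  solo <- tissue_specific_lists(pm(se), require_both = FALSE)
  expect_setequal(solo$heart, "a")
  expect_error(
    tissue_specific_lists(pm(se), pm(pe[, 1:2, drop = FALSE])),
    "universes differ")
})

test_that("gene summary restricts to multi-exon genes", {
  gm <- gene_model_set(
    genes = data.frame(gene_id = c("multi", "mono"), chrom = "chr1",
                       strand = "+"),
    exons = data.frame(gene_id = c("multi", "multi", "mono"),
                       start = c(0L, 500L, 2000L),
                       end = c(100L, 600L, 2300L)))
  tiss <- paste0("t", 1:4)
  mg <- matrix(100, 2, 4, dimnames = list(c("multi", "mono"), tiss))
  mj <- matrix(0, 1, 4, dimnames = list("chr1:100-500", tiss))
  mj[1, "t1"] <- 100
  pairs <- data.frame(junction_id = "chr1:100-500", gene_id = "multi")
  out <- genes_with_specific_junctions(pairs, pm(mj), pm(mg, kind = "gene"),
                                       gm)
  # the single-exon gene is never counted even though expressed everywhere
  expect_equal(out["expressed", "n_genes"], 1L)
  expect_equal(out["expressed", "n_with_specific_junction"], 1L)
  expect_equal(out["expressed_all", "n_with_specific_junction"], 1L)
  expect_equal(out["expressed", "percent"], 100)
})

test_that("junction/gene detection ratio is finite and positive", {
  set.seed(63)
  mj <- juncspect:::new_expression_matrix(
    matrix(rexp(200, 1 / 30), 20, 10), "junction", TRUE)
  rownames(mj) <- sprintf("j%d", 1:20); colnames(mj) <- sprintf("t%d", 1:10)
  mg <- juncspect:::new_expression_matrix(
    matrix(rexp(100, 1 / 30), 10, 10), "gene", TRUE)
  rownames(mg) <- sprintf("g%d", 1:10); colnames(mg) <- sprintf("t%d", 1:10)
  r <- junction_gene_ratio(mj, mg, taus = c(5, 10, 20))
  detected <- r$n_genes > 0
  expect_true(all(is.finite(r$ratio[detected])))
  expect_true(all(r$ratio[detected] > 0))
})
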