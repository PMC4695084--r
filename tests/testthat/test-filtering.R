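fake_stats <- function(entropy, avg_mismatch, intron_length) {
  n <- max(length(entropy), length(avg_mismatch), length(intron_length))
  df <- data.frame(
    junction_id = sprintf("chr1:%d-%d", seq_len(n) * 1000L,
                          seq_len(n) * 1000L + rep_len(intron_length, n)),
    chrom = "chr1", intron_start = seq_len(n) * 1000L,
    intron_end = seq_len(n) * 1000L + rep_len(intron_length, n),
    strand = "*", read_count = 10L,
    entropy = rep_len(entropy, n),
    avg_mismatch = rep_len(avg_mismatch, n),
    intron_length = rep_len(intron_length, n))
  class(df) <- c("junction_stats", "data.frame")
  df
}

test_that("boundary semantics are >= entropy, <= mismatch, >= intron length", {
  thr <- filter_thresholds()
  keep <- function(s, m, l)
    nrow(apply_filters(fake_stats(s, m, l), thr)$retained) == 1L
  expect_true(keep(0.8, 0.5, 100))
  expect_false(keep(0.8, 0.5, 49))   # shorter than 50 nt: likely deletion
  expect_true(keep(0.75, 1.5, 50))   # all three exactly at threshold pass
  expect_false(keep(0.74, 0.5, 100))
  expect_false(keep(0.8, 1.51, 100))
  # paired-end default tightens the mismatch rule to 1.0
  expect_equal(default_thresholds("PE")$mismatch_max, 1.0)
  expect_equal(default_thresholds("SE")$mismatch_max, 1.5)
})

test_that("filtering equals brute-force predicate evaluation on random stats", {
  set.seed(55)
  n <- 10000L
  st <- fake_stats(runif(n, 0, 3), runif(n, 0, 3), sample(1:500, n, TRUE))
  thr <- filter_thresholds()
  out <- apply_filters(st, thr)
  brute <- st$entropy >= 0.75 & st$avg_mismatch <= 1.5 & st$intron_length >= 50
  expect_equal(out$retained$junction_id, st$junction_id[brute])
  expect_equal(out$report$n_retained, sum(brute))
  expect_equal(out$report$n_input, n)
  expect_equal(out$report$n_retained + out$report$n_removed, n)
  # first-fail attribution partitions the removed set
  expect_equal(sum(out$report$removed_first_fail), out$report$n_removed)
  # any-fail tallies each failed rule
  expect_equal(unname(out$report$removed_any_fail),
               c(sum(st$entropy < 0.75), sum(st$avg_mismatch > 1.5),
                 sum(st$intron_length < 50)))
})

test_that("loosening thresholds never shrinks the retained set", {
  set.seed(56)
  st <- fake_stats(runif(500, 0, 3), runif(500, 0, 3),
                   sample(1:500, 500, TRUE))
  for (i in 1:100) {
    e <- runif(1, 0, 2); m <- runif(1, 0, 2); l <- sample(1:200, 1)
    tight <- filter_thresholds(e, m, l)
    loose <- filter_thresholds(e * runif(1), m + runif(1, 0, 2),
                               l - sample(0:l, 1))
    a <- apply_filters(st, tight)$retained$junction_id
    b <- apply_filters(st, loose)$retained$junction_id
    expect_true(all(a %in% b))
  }
})

test_that("filter then merge equals merge then filter", {
  set.seed(57)
  st <- fake_stats(runif(200, 0, 2), runif(200, 0, 2),
                   sample(1:200, 200, TRUE))
  thr <- filter_thresholds()
  half <- seq_len(100)
  merged_then <- apply_filters(st, thr)$retained$junction_id
  then_merged <- c(apply_filters(st[half, ], thr)$retained$junction_id,
                   apply_filters(st[-half, ], thr)$retained$junction_id)
  expect_setequal(merged_then, then_merged)
})

test_that("retention fractions split by class and artifacts are removed", {
  ref <- small_reference()
  p <- tempfile(fileext = ".sam")
  simulate_alignments(ref, tissue = "brain", library = "SE", path = p)
  st <- compute_stats(extract_junctions(p))
  cls <- classify_junction(st, ref$annotation)
  out <- apply_filters(st, default_thresholds("SE"), classes = cls)
  rep <- out$report
  expect_true(rep$retention_annotated > rep$retention_novel)
  # planted low-entropy artifacts mostly fall below the entropy threshold;
  # true junctions are retained at a (strictly) higher rate
  art <- ref$truth$junctions$junction_id[ref$truth$junctions$is_artifact]
  observed_art <- intersect(art, st$junction_id)
  expect_gt(length(observed_art), 0L)
  art_rate <- mean(observed_art %in% out$retained$junction_id)
  true_ids <- setdiff(st$junction_id, art)
  expect_lt(art_rate, 0.5)
  expect_gt(mean(true_ids %in% out$retained$junction_id), art_rate)
})

test_that("calibration profiles conserve points and histogram mass", {
  set.seed(58)
  st <- fake_stats(runif(40, 0, 2), runif(40, 0, 2), sample(1:400, 40, TRUE))
  cls <- factor(sample(c("annotated", "novel_neither"), 40, TRUE),
                levels = c("annotated", "novel_both_sites",
                           "novel_one_site", "novel_neither"))
  prof <- calibration_profiles(st, cls)
  expect_equal(nrow(prof$points), 40L)
  expect_equal(sum(prof$hist_annotated$count), sum(cls == "annotated"))
  expect_equal(sum(prof$hist_novel$count), sum(cls != "annotated"))
  # all-annotated input: novel point set empty
  all_ann <- calibration_profiles(st, factor(rep("annotated", 40),
    levels = levels(cls)))
  expect_equal(sum(all_ann$points$class == "novel"), 0L)
  expect_equal(sum(all_ann$hist_novel$count), 0L)
})

test_that("suggested thresholds follow the nearest-rank quantile rule", {
  st <- fake_stats(c(0.4, 0.8, 1.2, 1.6), c(0.2, 0.4, 0.6, 0.8), 100L)
  # full retention: min entropy, max mismatch
  full <- suggest_thresholds(st, 1.0)
  expect_equal(full$entropy_min, 0.4)
  expect_equal(full$mismatch_max, 0.8)
  expect_equal(full$intron_min, 50)
  # retention 0.75: nearest-rank index floor(0.25 * 3) = 0 -> first value
  q <- suggest_thresholds(st, 0.75)
  expect_equal(q$entropy_min, 0.4)
  # mismatch side rounds the rank up so the criterion keeps >= 3 of 4
  expect_equal(q$mismatch_max, 0.8)
  expect_error(suggest_thresholds(st[0, ], 0.9), "no annotated")
})

test_that("suggested thresholds retain the target fraction on each criterion", {
  set.seed(59)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    st <- fake_stats(runif(n, 0, 4), runif(n, 0, 2), sample(50:500, n, TRUE))
    r <- runif(1, 0.05, 1)
    thr <- suggest_thresholds(st, r)
    expect_gte(sum(st$entropy >= thr$entropy_min), r * n)
    expect_gte(sum(st$avg_mismatch <= thr$mismatch_max), r * n)
  }
})
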