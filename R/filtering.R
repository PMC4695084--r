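# Junction filtering: entropy / average-mismatch / intron-length rules and
# empirical threshold calibration against the annotated junction set.

#' Junction filter thresholds
#'
#' Defaults follow the empirically chosen operating point: offset entropy
#' >= 0.75, average mismatches <= 1.5 (single-end) or <= 1.0 (paired-end),
#' and intron length >= 50 bp (shorter putative introns are more likely
#' small deletions than real splices).
#'
#' @param entropy_min minimum offset entropy (same log base as the catalog).
#' @param mismatch_max maximum mean mismatches per spanning read.
#' @param intron_min minimum intron length in bp.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(entropy_min = 0.75, mismatch_max = 1.5,
                              intron_min = 50) {
  stopifnot(entropy_min >= 0, mismatch_max >= 0, intron_min >= 0)
  structure(list(entropy_min = entropy_min, mismatch_max = mismatch_max,
                 intron_min = intron_min), class = "filter_thresholds")
}

#' @rdname filter_thresholds
#' @param library library type: mismatch default is 1.5 for `"SE"` and 1.0
#'   for `"PE"`.
#' @export
default_thresholds <- function(library = c("SE", "PE")) {
  library <- match.arg(library)
  filter_thresholds(mismatch_max = if (library == "SE") 1.5 else 1.0)
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("filter_thresholds: entropy >= %g, avg mismatches <= %g, intron >= %g bp\n",
              x$entropy_min, x$mismatch_max, x$intron_min))
  invisible(x)
}

#' Apply the three junction filters
#'
#' A junction is retained iff `entropy >= entropy_min` AND
#' `avg_mismatch <= mismatch_max` AND `intron_length >= intron_min`
#' (boundary semantics taken literally from the published thresholds).
#'
#' @param stats a `junction_stats` data.frame ([compute_stats()]).
#' @param thresholds a [filter_thresholds()]; default single-end values.
#' @param classes optional factor from [classify_junction()] aligned with
#'   `stats` rows, used to report annotated/novel retention fractions.
#' @return list with `retained` (the surviving `junction_stats` rows) and
#'   `report` (a `filter_report`: input/retained counts, per-rule removal
#'   tallies both as a first-failing-rule partition and as any-rule-failed
#'   counts, and retention fractions by class when `classes` is given).
#' @export
apply_filters <- function(stats, thresholds = filter_thresholds(),
                          classes = NULL) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  stats <- as.data.frame(stats)
  pass_e <- stats$entropy >= thresholds$entropy_min
  pass_m <- stats$avg_mismatch <= thresholds$mismatch_max
  pass_l <- stats$intron_length >= thresholds$intron_min
  keep <- pass_e & pass_m & pass_l
  first_fail <- ifelse(keep, NA_character_,
                ifelse(!pass_e, "entropy",
                ifelse(!pass_m, "mismatch", "intron_length")))
  report <- structure(list(
    n_input = nrow(stats),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    removed_first_fail = c(entropy = sum(first_fail == "entropy", na.rm = TRUE),
                           mismatch = sum(first_fail == "mismatch", na.rm = TRUE),
                           intron_length = sum(first_fail == "intron_length",
                                               na.rm = TRUE)),
    removed_any_fail = c(entropy = sum(!pass_e), mismatch = sum(!pass_m),
                         intron_length = sum(!pass_l)),
    retention_annotated = NA_real_,
    retention_novel = NA_real_
  ), class = "filter_report")
  if (!is.null(classes)) {
    stopifnot(length(classes) == nrow(stats))
    ann <- classes == "annotated"
    if (any(ann)) report$retention_annotated <- mean(keep[ann])
    if (any(!ann)) report$retention_novel <- mean(keep[!ann])
  }
  retained <- stats[keep, , drop = FALSE]
  class(retained) <- c("junction_stats", "data.frame")
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d junctions in, %d retained, %d removed\n",
              x$n_input, x$n_retained, x$n_removed))
  cat("  first-failing rule:",
      paste(sprintf("%s=%d", names(x$removed_first_fail),
                    x$removed_first_fail), collapse = ", "), "\n")
  cat("  any-rule failures: ",
      paste(sprintf("%s=%d", names(x$removed_any_fail), x$removed_any_fail),
            collapse = ", "), "\n")
  if (!is.na(x$retention_annotated))
    cat(sprintf("  retention: annotated %.1f%%, novel %.1f%%\n",
                100 * x$retention_annotated, 100 * x$retention_novel))
  invisible(x)
}

#' Calibration view: annotated vs novel entropy/mismatch scatter and
#' intron-length histograms
#'
#' Splits the catalog into annotated and novel junctions, returning the
#' (entropy, average mismatch) point sets and intron-length histograms used
#' to choose filter thresholds by inspection.
#'
#' @param stats a `junction_stats` data.frame.
#' @param classes factor from [classify_junction()] aligned with `stats`.
#' @param breaks histogram breaks for intron lengths (passed to
#'   [graphics::hist]); default 50-bp bins up to the observed maximum.
#' @return list with `points` (data.frame entropy, avg_mismatch, class
#'   annotated/novel) and `hist_annotated` / `hist_novel` (data.frames of
#'   bin mids and counts; counts per class sum to the class size).
#' @export
calibration_profiles <- function(stats, classes, breaks = NULL) {
  stats <- as.data.frame(stats)
  stopifnot(length(classes) == nrow(stats))
  grp <- ifelse(classes == "annotated", "annotated", "novel")
  points <- data.frame(entropy = stats$entropy,
                       avg_mismatch = stats$avg_mismatch,
                       class = grp, stringsAsFactors = FALSE)
  if (is.null(breaks)) {
    top <- max(stats$intron_length, 50L)
    breaks <- seq(0L, 50L * ceiling(top / 50L), by = 50L)
  }
  hist_of <- function(x) {
    if (length(x) == 0L) return(data.frame(mid = numeric(), count = integer()))
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  list(points = points,
       hist_annotated = hist_of(stats$intron_length[grp == "annotated"]),
       hist_novel = hist_of(stats$intron_length[grp == "novel"]))
}

#' Mechanised threshold selection from annotated junctions
#'
#' Treats annotated junctions as the gold standard and picks thresholds
#' that retain at least the requested fraction of them on each criterion:
#' `entropy_min` is the lower (1 - retention) nearest-rank quantile of the
#' annotated entropies and `mismatch_max` the retention nearest-rank
#' quantile of the annotated average mismatches. The minimum intron length
#' stays at 50 bp. Nearest rank on the ascending sample of size n uses
#' 0-based index `floor(q * (n - 1))` for the entropy cut and
#' `ceiling(q * (n - 1))` for the mismatch cut; the ceiling on the
#' mismatch side guarantees that each criterion alone retains at least
#' `retention * n` annotated junctions.
#'
#' @param annotated_stats `junction_stats` rows classified as annotated
#'   (>= 2 rows).
#' @param retention target fraction of annotated junctions to keep, in
#'   (0, 1].
#' @return a [filter_thresholds()].
#' @export
suggest_thresholds <- function(annotated_stats, retention) {
  annotated_stats <- as.data.frame(annotated_stats)
  n <- nrow(annotated_stats)
  if (n == 0L) stop("no annotated junctions to calibrate on")
  stopifnot(n >= 2L, retention > 0, retention <= 1)
  filter_thresholds(
    entropy_min = sort(annotated_stats$entropy)[
      floor((1 - retention) * (n - 1L)) + 1L],
    mismatch_max = sort(annotated_stats$avg_mismatch)[
      ceiling(retention * (n - 1L)) + 1L],
    intron_min = 50
  )
}
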