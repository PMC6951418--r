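# High-confidence elincRNA / canonical labels from a permutation null on
# the H3K4me1/H3K4me3 read-count ratio in TSS windows.
#
# The null is built by independently shuffling each mark's count vector
# across transcripts and pooling the recomputed per-transcript ratios over
# all rounds; this breaks the within-transcript pairing of the two marks,
# which is exactly the association the test interrogates.

#' Pseudocounted H3K4me1/H3K4me3 ratio
#'
#' @param me1,me3 non-negative read counts (vectors).
#' @param pseudocount added to both numerator and denominator (default 1) so
#'   zero-count transcripts yield finite ratios.
#' @return numeric vector of ratios.
#' @export
observed_ratio <- function(me1, me3, pseudocount = 1) {
  if (any(me1 < 0) || any(me3 < 0)) stopf("mark counts must be non-negative")
  (me1 + pseudocount) / (me3 + pseudocount)
}

#' Build the permutation null of mark-count ratios
#'
#' For each of `n_perm` rounds the me1 and me3 count vectors are shuffled
#' independently across transcripts and per-transcript ratios are recomputed;
#' the pooled ratios over all rounds form the empirical null. The caller is
#' expected to pass the same signal-filtered transcript universe that will be
#' labeled.
#'
#' @param counts data.frame(transcript_id, me1, me3).
#' @param n_perm permutation rounds (default 10000).
#' @param seed RNG seed (mandatory; the null is deterministic given it).
#' @param pseudocount see [observed_ratio()].
#' @param hi_pct,lo_pct percentiles stored as thresholds (defaults 95 / 5).
#' @return object of class `permutation_null` with sorted `ratios`,
#'   `hi_threshold` and `lo_threshold` (nearest-rank percentiles), `n_perm`
#'   and `seed`.
#' @export
build_null <- function(counts, n_perm = 10000, seed, pseudocount = 1,
                       hi_pct = 95, lo_pct = 5) {
  if (is.null(counts) || nrow(counts) < 2)
    stopf("need at least 2 transcripts to build a permutation null")
  if (missing(seed)) stopf("seed is required")
  me1 <- counts$me1; me3 <- counts$me3
  if (any(me1 < 0) || any(me3 < 0)) stopf("mark counts must be non-negative")
  # canonicalize order so the null realization (given the seed) depends only
  # on the multiset of counts, not on input row order
  me1 <- sort(me1); me3 <- sort(me3)
  n <- length(me1)
  set.seed(seed)
  ratios <- numeric(n * n_perm)
  for (r in seq_len(n_perm)) {
    p1 <- me1[sample.int(n)]
    p3 <- me3[sample.int(n)]
    ratios[((r - 1L) * n + 1L):(r * n)] <- (p1 + pseudocount) / (p3 + pseudocount)
  }
  ratios <- sort(ratios)
  structure(list(ratios = ratios, n_perm = n_perm, seed = seed,
                 pseudocount = pseudocount,
                 hi_threshold = nearest_rank_quantile(ratios, hi_pct),
                 lo_threshold = nearest_rank_quantile(ratios, lo_pct)),
            class = "permutation_null")
}

#' Nearest-rank percentile of a sorted sample
#' @param sorted_x ascending numeric vector.
#' @param pct percentile in (0, 100).
#' @return the value at rank ceiling(pct/100 * n).
#' @export
nearest_rank_quantile <- function(sorted_x, pct) {
  if (pct <= 0 || pct >= 100) stopf("percentile must lie in (0, 100)")
  sorted_x[ceiling(pct / 100 * length(sorted_x))]
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(paste0("<permutation_null> %d pooled ratios (%d rounds), ",
                     "thresholds lo=%.4g hi=%.4g\n"),
              length(x$ratios), x$n_perm, x$lo_threshold, x$hi_threshold))
  invisible(x)
}

#' Label transcripts against the permutation null
#'
#' Transcripts with `max(me1, me3) < min_signal` are `excluded`. Among the
#' rest, a transcript is `elinc` when its observed ratio lies strictly above
#' the `hi_pct` null percentile, `canonical` when strictly below the `lo_pct`
#' percentile, and `unlabeled` otherwise.
#'
#' @param counts data.frame(transcript_id, me1, me3).
#' @param null a `permutation_null` built from the same filtered universe.
#' @param min_signal minimum of the larger mark count (default 10).
#' @param hi_pct,lo_pct percentile thresholds (defaults 95 / 5).
#' @return data.frame(transcript_id, label, observed_ratio, percentile);
#'   percentile is the percent of null ratios strictly below the observed
#'   ratio (NA for excluded transcripts).
#' @export
label_transcripts <- function(counts, null, min_signal = 10,
                              hi_pct = 95, lo_pct = 5) {
  stopifnot(inherits(null, "permutation_null"))
  if (hi_pct <= 0 || hi_pct >= 100 || lo_pct <= 0 || lo_pct >= 100 ||
      hi_pct <= lo_pct)
    stopf("need 0 < lo_pct < hi_pct < 100")
  r <- observed_ratio(counts$me1, counts$me3, null$pseudocount)
  excluded <- pmax(counts$me1, counts$me3) < min_signal
  hi <- nearest_rank_quantile(null$ratios, hi_pct)
  lo <- nearest_rank_quantile(null$ratios, lo_pct)
  # findInterval with left.open counts null values strictly below r
  pct <- 100 * findInterval(r, null$ratios, left.open = TRUE) / length(null$ratios)
  label <- ifelse(excluded, "excluded",
                  ifelse(r > hi, "elinc",
                         ifelse(r < lo, "canonical", "unlabeled")))
  data.frame(transcript_id = counts$transcript_id, label = label,
             observed_ratio = r,
             percentile = ifelse(excluded, NA_real_, pct),
             stringsAsFactors = FALSE)
}

#' Compute TSS mark counts for the two H3K4 marks
#'
#' @param ts transcript table.
#' @param me1_track,me3_track `signal_track`s of kind "reads" for H3K4me1
#'   and H3K4me3.
#' @param flank TSS window half-width (bp).
#' @param chrom_lengths named chromosome lengths.
#' @return data.frame(transcript_id, me1, me3).
#' @export
tss_mark_counts <- function(ts, me1_track, me3_track, flank = 500,
                            chrom_lengths) {
  tssiv <- tss_interval(ts, flank = flank, chrom_lengths = chrom_lengths)
  data.frame(transcript_id = ts$transcript_id,
             me1 = count_reads(me1_track, tssiv),
             me3 = count_reads(me3_track, tssiv),
             stringsAsFactors = FALSE)
}

#' Write confidence labels as TSV
#' @param labels output of [label_transcripts()].
#' @param path file.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
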