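# Independent test-set labels from enhancer/promoter overlap, and the
# chromatin-state randomization check for the high-confidence sets.

#' Label transcripts by annotation-element overlap
#'
#' A transcript is `elinc` when it covers more than `min_frac` of some
#' enhancer element, `canonical` when it covers more than `min_frac` of some
#' promoter element, `conflict` when both (such transcripts are excluded
#' from test sets), and `none` otherwise. The fraction is of the annotation
#' element's length, and the inequality is strict.
#'
#' @param ts transcript table.
#' @param enhancers,promoters interval data.frames.
#' @param min_frac coverage fraction threshold (default 0.5).
#' @return data.frame(transcript_id, label, best_fraction) where
#'   best_fraction is the largest element fraction covered by the
#'   transcript across both annotation sets.
#' @export
label_by_overlap <- function(ts, enhancers, promoters, min_frac = 0.5) {
  validate_transcripts(ts)
  if (nrow(enhancers) == 0 && nrow(promoters) == 0)
    stopf("annotation sets are empty")
  txgr <- intervals_to_granges(ts)
  best_frac <- function(elements) {
    if (nrow(elements) == 0) return(numeric(nrow(ts)))
    h <- harmonize_seqlevels(txgr, intervals_to_granges(elements))
    el <- h$b
    hits <- GenomicRanges::findOverlaps(h$a, el, ignore.strand = TRUE)
    out <- numeric(nrow(ts))
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(h$a)[S4Vectors::queryHits(hits)],
        IRanges::ranges(el)[S4Vectors::subjectHits(hits)]))
      frac <- w / IRanges::width(el)[S4Vectors::subjectHits(hits)]
      agg <- tapply(frac, S4Vectors::queryHits(hits), max)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  fe <- best_frac(enhancers)
  fp <- best_frac(promoters)
  is_e <- fe > min_frac
  is_p <- fp > min_frac
  label <- ifelse(is_e & is_p, "conflict",
                  ifelse(is_e, "elinc", ifelse(is_p, "canonical", "none")))
  data.frame(transcript_id = ts$transcript_id, label = label,
             best_fraction = pmax(fe, fp), stringsAsFactors = FALSE)
}

#' Chromatin-state overlap enrichment by randomization
#'
#' Counts the transcripts whose span is covered over `cov_threshold` of its
#' length by the given chromatin-state intervals, then compares against a
#' null in which each transcript is replaced by a random same-length
#' interval placed uniformly on its own chromosome (so placements never run
#' off the end). The empirical p-value uses the add-one correction
#' `(1 + #{null >= observed}) / (1 + n_perm)` and is therefore never 0.
#'
#' @param ts transcript table.
#' @param states interval data.frame of chromatin-state segments.
#' @param cov_threshold transcript-fraction threshold, strict (default 0.3).
#' @param n_perm randomization rounds (default 10000).
#' @param seed RNG seed.
#' @param chrom_lengths named chromosome lengths.
#' @return list(observed, null_counts, n_perm, empirical_p, seed).
#' @export
chromstate_enrichment <- function(ts, states, cov_threshold = 0.3,
                                  n_perm = 10000, seed, chrom_lengths) {
  validate_transcripts(ts)
  if (missing(seed)) stopf("seed is required")
  len <- ts$end - ts$start
  clen <- chrom_lengths[ts$chrom]
  if (anyNA(clen)) stopf("chromosome length missing for some transcripts")
  if (any(len > clen))
    stopf("transcript longer than its chromosome: %s",
          paste(ts$transcript_id[len > clen], collapse = ", "))
  frac_covered <- function(iv) {
    if (nrow(states) == 0) return(numeric(nrow(iv)))
    coverage_ratio(states, iv)
  }
  observed <- sum(frac_covered(ts[, c("chrom", "start", "end")]) > cov_threshold)
  set.seed(seed)
  n <- nrow(ts)
  # all rounds placed at once: one interval per (transcript, round)
  starts <- floor(runif(n * n_perm, min = 0, max = rep(clen - len, n_perm) + 1))
  placed <- data.frame(chrom = rep(ts$chrom, n_perm),
                       start = starts,
                       end = starts + rep(len, n_perm))
  fr <- frac_covered(placed)
  round_id <- rep(seq_len(n_perm), each = n)
  null_counts <- as.integer(rowsum(as.integer(fr > cov_threshold), round_id))
  empirical_p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  list(observed = observed, null_counts = null_counts, n_perm = n_perm,
       empirical_p = empirical_p, seed = seed)
}
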