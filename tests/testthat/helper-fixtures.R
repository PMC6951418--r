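# Shared in-code fixtures: a tiny deterministic transcript set, chromosome
# lengths, and generators for random regression problems.

toy_chrom_lengths <- c(chrA = 100000, chrB = 50000)

toy_transcripts <- function() {
  data.frame(
    transcript_id = c("txPlus", "txMinus", "txEdge", "txShort"),
    chrom = c("chrA", "chrA", "chrA", "chrB"),
    start = c(10000, 30000, 300, 1000),
    end = c(14000, 36000, 2300, 1400),
    strand = c("+", "-", "+", "+"),
    fpkm = c(2.0, 0.5, 0.4, 7.1),
    stringsAsFactors = FALSE)
}

interval_df <- function(chrom, start, end, strand = ".") {
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep_len(strand, length(chrom)),
             stringsAsFactors = FALSE)
}

# random two-class regression problem with named columns
random_problem <- function(n, p, seed, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- sign(X[, 1] - X[, min(2, p)] + rnorm(n) * noise)
  y[y == 0] <- 1
  list(X = X, y = y)
}

# design whose columns are mean-zero and orthonormal under the 1/n inner
# product, so internal standardization is the identity
orthonormal_design <- function(n, p) {
  P <- stats::poly(seq_len(n), p)        # columns: mean 0, sum of squares 1
  X <- P * sqrt(n)                       # now colMeans 0, colMeans(X^2) = 1
  colnames(X) <- paste0("f", seq_len(p))
  unclass(X)[, , drop = FALSE]
}

planted_feature_signs <- c(
  TSS_DNAme = 1, TSS_H3K4me1 = 1, Body_DNAme = 1, Body_H3K122ac = 1,
  Body_H3K36me3 = -1, TSS_H3K9ac = -1, TSS_H3K4me3 = -1)

feature_tracks_of <- function(sim) {
  sim$tracks[setdiff(names(sim$tracks), c("H3K4me1_reads", "H3K4me3_reads"))]
}

sim_classes <- function(sim, m) {
  sim$truth$class[match(rownames(m), sim$truth$transcript_id)]
}
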