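# Transcripts x features table. One column per (region, assay) pair, named
# "<Region>_<Assay>" with Region in {TSS, Body}. Histone marks, TFs and
# annotation sets (CGI, repeats) contribute base-coverage fractions; the
# DNA-methylation track contributes mean beta. All values lie in [0,1].

#' Build the feature matrix
#'
#' For every assay two columns are produced: the statistic over the 1 kb TSS
#' window and over the gene body. Transcripts with an empty body (length <=
#' `flank`) are dropped with a message, since body features are half the
#' columns. Regions without any methylation measurement are imputed to 0 and
#' counted in a message.
#'
#' @param ts transcript table.
#' @param tracks named list of `signal_track`s (name = assay). Beta tracks
#'   yield mean-beta columns, reads/coverage tracks coverage-ratio columns.
#' @param annotations named list of interval data.frames (CGI, repeat
#'   classes, ...), each yielding coverage-ratio columns.
#' @param flank TSS half-width / body offset in bp (default 500).
#' @param chrom_lengths named chromosome lengths.
#' @return numeric matrix, rownames = transcript ids, colnames =
#'   "TSS_<assay>" / "Body_<assay>" in the order the assays were supplied
#'   (tracks first, then annotations).
#' @export
build_features <- function(ts, tracks = list(), annotations = list(),
                           flank = 500, chrom_lengths) {
  validate_transcripts(ts)
  if (length(tracks) == 0 && length(annotations) == 0)
    stopf("no assays supplied")
  if (length(tracks)) {
    nm <- names(tracks)
    if (is.null(nm) || any(!nzchar(nm))) stopf("tracks must be a named list")
  }
  if (length(annotations)) {
    nm <- names(annotations)
    if (is.null(nm) || any(!nzchar(nm))) stopf("annotations must be a named list")
  }
  keep <- has_body(ts, flank)
  if (any(!keep)) {
    message(sum(!keep), " transcript(s) without a gene body dropped: ",
            paste(utils::head(ts$transcript_id[!keep], 5), collapse = ", "))
    ts <- ts[keep, , drop = FALSE]
  }
  if (nrow(ts) == 0) stopf("no transcripts with a gene body remain")
  tssiv <- tss_interval(ts, flank, chrom_lengths)
  bodyiv <- body_region(ts, flank)

  cols <- list()
  for (a in names(tracks)) {
    tr <- tracks[[a]]
    if (!inherits(tr, "signal_track")) stopf("track '%s' is not a signal_track", a)
    if (tr$kind == "beta") {
      v_tss <- mean_beta(tr, tssiv); v_body <- mean_beta(tr, bodyiv)
      n_imp <- sum(is.na(v_tss)) + sum(is.na(v_body))
      if (n_imp > 0)
        message("assay '", a, "': ", n_imp,
                " region(s) without methylation data imputed to 0")
      v_tss[is.na(v_tss)] <- 0; v_body[is.na(v_body)] <- 0
    } else {
      v_tss <- coverage_ratio(tr, tssiv); v_body <- coverage_ratio(tr, bodyiv)
    }
    cols[[paste0("TSS_", a)]] <- v_tss
    cols[[paste0("Body_", a)]] <- v_body
  }
  for (a in names(annotations)) {
    cols[[paste0("TSS_", a)]] <- coverage_ratio(annotations[[a]], tssiv)
    cols[[paste0("Body_", a)]] <- coverage_ratio(annotations[[a]], bodyiv)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ts$transcript_id
  stopifnot(all(is.finite(m)), all(m >= 0), all(m <= 1))
  m
}

#' Column-subset a feature matrix
#'
#' @param m feature matrix.
#' @param names feature names to keep (all must exist).
#' @return the sub-matrix, row order preserved.
#' @export
subset_features <- function(m, names) {
  if (length(names) == 0) stopf("no feature names given")
  missing_cols <- setdiff(names, colnames(m))
  if (length(missing_cols))
    stopf("unknown feature(s): %s", paste(missing_cols, collapse = ", "))
  m[, names, drop = FALSE]
}

#' Write a feature matrix as TSV (first column transcript_id)
#' @param m feature matrix.
#' @param path file.
#' @export
write_features_tsv <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_tsv()]
#' @param path file.
#' @return numeric matrix with transcript-id rownames.
#' @export
read_features_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
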