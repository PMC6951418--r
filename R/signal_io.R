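# Per-assay signal tracks and the three primitive region statistics:
# read counts, base-coverage fraction, and mean methylation beta.

#' Construct a signal track
#'
#' A track couples an assay name with interval data of one of three kinds:
#' \describe{
#'   \item{reads}{read alignment intervals; supports [count_reads()] and
#'     [coverage_ratio()].}
#'   \item{coverage}{covered intervals (e.g. peak calls or bedGraph segments
#'     with signal); supports [coverage_ratio()].}
#'   \item{beta}{per-position DNA-methylation levels in \[0,1\]; supports
#'     [mean_beta()]. Positions are width-1 intervals with a `beta` value.}
#' }
#'
#' @param assay assay name, e.g. "H3K4me1".
#' @param kind one of "reads", "coverage", "beta".
#' @param intervals interval data.frame (chrom, start, end); for kind "beta"
#'   also a numeric `beta` column.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(assay, kind = c("coverage", "reads", "beta"), intervals) {
  kind <- match.arg(kind)
  if (nrow(intervals)) {
    if (any(intervals$start < 0 | intervals$start >= intervals$end))
      stopf("track '%s': invalid interval coordinates", assay)
  }
  if (kind == "beta") {
    b <- intervals$beta
    if (is.null(b)) stopf("beta track '%s' needs a beta column", assay)
    if (any(b < 0 | b > 1, na.rm = TRUE) || anyNA(b))
      stopf("track '%s': beta values must lie in [0,1]", assay)
  }
  gr <- intervals_to_granges(intervals)
  if (kind == "beta") S4Vectors::mcols(gr)$beta <- intervals$beta
  structure(list(assay = assay, kind = kind, data = gr),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s [%s], %d interval(s)\n",
              x$assay, x$kind, length(x$data)))
  invisible(x)
}

#' Count reads overlapping regions
#'
#' A read is counted when it overlaps the region by at least one base.
#'
#' @param track a `signal_track` of kind "reads".
#' @param regions interval data.frame (one or more rows).
#' @return integer vector, one count per region.
#' @export
count_reads <- function(track, regions) {
  if (!inherits(track, "signal_track") || track$kind != "reads")
    stopf("count_reads requires a track of kind 'reads'")
  h <- harmonize_seqlevels(intervals_to_granges(regions), track$data)
  GenomicRanges::countOverlaps(h$a, h$b, minoverlap = 1L,
                               ignore.strand = TRUE)
}

#' Base-coverage fraction of regions by a track
#'
#' Fraction of each region's bases overlapped by at least one track interval
#' (depth is ignored; abutting or overlapping track intervals are merged
#' first, so the statistic is invariant to how the track is segmented).
#'
#' @param track a `signal_track` (reads or coverage), or a plain interval
#'   data.frame used as an annotation set (CGI, repeats, ...).
#' @param regions interval data.frame.
#' @return numeric vector in \[0,1\], one value per region.
#' @export
coverage_ratio <- function(track, regions) {
  iv <- if (inherits(track, "signal_track")) {
    if (track$kind == "beta")
      stopf("coverage_ratio is undefined for beta tracks; use mean_beta")
    track$data
  } else intervals_to_granges(track)
  reg <- intervals_to_granges(regions)
  if (any(IRanges::width(reg) <= 0)) stopf("regions must have positive width")
  h <- harmonize_seqlevels(reg, GenomicRanges::reduce(iv, ignore.strand = TRUE))
  reg <- h$a; red <- h$b
  hits <- GenomicRanges::findOverlaps(reg, red, ignore.strand = TRUE)
  covered <- numeric(length(reg))
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(reg)[S4Vectors::queryHits(hits)],
      IRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    covered[as.integer(rownames(agg))] <- agg[, 1]
  }
  covered / IRanges::width(reg)
}

#' Mean methylation beta over regions
#'
#' Arithmetic mean of the per-position beta values falling inside each
#' region; `NA` where a region contains no measured position (downstream
#' feature assembly imputes 0 and reports how many regions were imputed).
#'
#' @param track a `signal_track` of kind "beta".
#' @param regions interval data.frame.
#' @return numeric vector in \[0,1\] with NA for empty regions.
#' @export
mean_beta <- function(track, regions) {
  if (!inherits(track, "signal_track") || track$kind != "beta")
    stopf("mean_beta requires a track of kind 'beta'")
  h <- harmonize_seqlevels(intervals_to_granges(regions), track$data)
  reg <- h$a
  hits <- GenomicRanges::findOverlaps(reg, h$b, ignore.strand = TRUE)
  out <- rep(NA_real_, length(reg))
  if (length(hits)) {
    b <- S4Vectors::mcols(h$b)$beta[S4Vectors::subjectHits(hits)]
    q <- S4Vectors::queryHits(hits)
    s <- rowsum(b, q); n <- rowsum(rep(1, length(q)), q)
    out[as.integer(rownames(s))] <- s[, 1] / n[, 1]
  }
  out
}

# ---- readers ----------------------------------------------------------------

#' Read a 4-column bedGraph as a coverage track
#'
#' Intervals with value >= `min_value` are treated as covered. Malformed
#' lines are skipped with a message.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param assay assay name.
#' @param min_value minimum value for a segment to count as covered.
#' @return `signal_track` of kind "coverage".
#' @export
read_bedgraph_track <- function(path, assay, min_value = 1) {
  x <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                         data.table = FALSE,
                         col.names = c("chrom", "start", "end", "value")[1:4])
  bad <- is.na(x$start) | is.na(x$end) | is.na(suppressWarnings(as.numeric(x$value))) |
    x$start < 0 | x$start >= x$end
  if (any(bad)) message(sum(bad), " malformed bedGraph line(s) skipped in ", path)
  x <- x[!bad, , drop = FALSE]
  x <- x[as.numeric(x$value) >= min_value, , drop = FALSE]
  signal_track(assay, "coverage",
               data.frame(chrom = x$chrom, start = x$start, end = x$end))
}

#' Read a BED6 file of read intervals as a reads track
#'
#' @param path BED file.
#' @param assay assay name.
#' @return `signal_track` of kind "reads".
#' @export
read_reads_bed <- function(path, assay) {
  gr <- rtracklayer::import(path, format = "bed")
  signal_track(assay, "reads", granges_to_intervals(gr))
}

#' Read per-position methylation beta values
#'
#' Expects a headerless TSV of (chrom, pos, beta) with pos 0-based; beta
#' values outside \[0,1\] are an error at load time.
#'
#' @param path file.
#' @param assay assay name, default "DNAme".
#' @return `signal_track` of kind "beta".
#' @export
read_beta_track <- function(path, assay = "DNAme") {
  x <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                         col.names = c("chrom", "pos", "beta"))
  bad <- is.na(x$pos) | is.na(suppressWarnings(as.numeric(x$beta)))
  if (any(bad)) message(sum(bad), " malformed methylation line(s) skipped in ", path)
  x <- x[!bad, , drop = FALSE]
  signal_track(assay, "beta",
               data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1,
                          beta = as.numeric(x$beta)))
}

#' Read a BED file as an annotation interval set
#' @param path BED file.
#' @return interval data.frame.
#' @export
read_annotation_bed <- function(path) {
  granges_to_intervals(rtracklayer::import(path, format = "bed"))
}

#' Write a track's intervals as bedGraph (value 1 per covered interval)
#' @param track `signal_track`.
#' @param path output file.
#' @export
write_bedgraph_track <- function(track, path) {
  iv <- granges_to_intervals(track$data)
  df <- data.frame(iv$chrom, iv$start, iv$end, 1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
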