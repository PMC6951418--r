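# Coordinate model: transcripts and their TSS / gene-body regions.
#
# A transcript table is a plain data.frame with columns
#   transcript_id, chrom, start, end, strand  (+ optional fpkm)
# in 0-based half-open coordinates. Exon structure, when present, is carried
# as a list column `exons` of data.frames (chrom, start, end) but is not used
# by any feature computation: all region statistics are interval-based.

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open (BED convention). This is the common
#' currency for regions, annotation sets and signal-track intervals.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (any(!nzchar(chrom))) stopf("chrom must be non-empty")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stopf("invalid interval: need 0 <= start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stopf("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Validate a transcript table
#'
#' @param ts data.frame with transcript_id, chrom, start, end, strand
#'   (and optionally fpkm).
#' @param require_fpkm require a complete fpkm column.
#' @return the table, invisibly checked.
#' @export
validate_transcripts <- function(ts, require_fpkm = FALSE) {
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(ts))
  if (length(miss)) stopf("transcript table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(ts$start < 0 | ts$start >= ts$end))
    stopf("invalid transcript coordinates (need 0 <= start < end)")
  if (!all(ts$strand %in% c("+", "-")))
    stopf("transcript strand must be '+' or '-'")
  if (require_fpkm) {
    if (is.null(ts$fpkm) || anyNA(ts$fpkm))
      stopf("fpkm missing for one or more transcripts")
  }
  invisible(ts)
}

#' Strand-aware TSS positions
#'
#' The TSS of a + strand transcript is its start coordinate; for a - strand
#' transcript it is the end coordinate (the maximal genomic position).
#'
#' @param ts transcript table.
#' @return numeric vector of TSS positions (0-based axis).
#' @export
tss_position <- function(ts) {
  validate_transcripts(ts)
  ifelse(ts$strand == "+", ts$start, ts$end)
}

#' TSS intervals: +/- flank bp around the transcription start site
#'
#' The window `[TSS - flank, TSS + flank)` is clipped to the chromosome
#' bounds rather than discarded, so the transcript universe is stable at
#' chromosome edges.
#'
#' @param ts transcript table.
#' @param flank half-width in bp (default 500, giving a 1 kb window).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return interval data.frame, one row per transcript, rownames dropped;
#'   carries transcript_id.
#' @export
tss_interval <- function(ts, flank = 500, chrom_lengths) {
  validate_transcripts(ts)
  if (flank <= 0) stopf("flank must be positive")
  if (missing(chrom_lengths) || is.null(chrom_lengths))
    stopf("chrom_lengths required")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  unknown <- setdiff(unique(ts$chrom), names(chrom_lengths))
  if (length(unknown)) stopf("no length for chromosome(s): %s",
                             paste(unknown, collapse = ", "))
  tss <- tss_position(ts)
  len <- chrom_lengths[ts$chrom]
  out <- data.frame(chrom = ts$chrom,
                    start = pmax(0, tss - flank),
                    end = pmin(len, tss + flank),
                    strand = ts$strand,
                    transcript_id = ts$transcript_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-body regions: flank bp downstream of the TSS through the TTS
#'
#' On the + strand the body is `[start + flank, end)`; on the - strand it is
#' `[start, end - flank)`. Transcripts no longer than `flank` have an empty
#' body and raise an error (use [has_body()] to pre-filter).
#'
#' @inheritParams tss_interval
#' @return interval data.frame with transcript_id.
#' @export
body_region <- function(ts, flank = 500) {
  validate_transcripts(ts)
  if (flank <= 0) stopf("flank must be positive")
  short <- ts$end - ts$start <= flank
  if (any(short))
    stopf("empty body region (length <= %d bp) for transcript(s): %s",
          flank, paste(ts$transcript_id[short], collapse = ", "))
  out <- data.frame(chrom = ts$chrom,
                    start = ifelse(ts$strand == "+", ts$start + flank, ts$start),
                    end = ifelse(ts$strand == "+", ts$end, ts$end - flank),
                    strand = ts$strand,
                    transcript_id = ts$transcript_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Which transcripts have a non-empty gene body?
#' @inheritParams body_region
#' @return logical vector.
#' @export
has_body <- function(ts, flank = 500) ts$end - ts$start > flank

#' Filter transcripts by expression level
#'
#' @param ts transcript table with a complete fpkm column.
#' @param min_fpkm retain transcripts with `fpkm >= min_fpkm` (default 0.5).
#' @return the retained rows, input order preserved.
#' @export
expressed_filter <- function(ts, min_fpkm = 0.5) {
  validate_transcripts(ts, require_fpkm = TRUE)
  out <- ts[ts$fpkm >= min_fpkm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- interval <-> GRanges conversion (internal) -----------------------------

#' @keywords internal
intervals_to_granges <- function(iv, chrom_lengths = NULL) {
  strand <- if (is.null(iv$strand)) "*" else ifelse(iv$strand == ".", "*", iv$strand)
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(start = iv$start + 1, end = iv$end),
                               strand = strand)
  if (!is.null(chrom_lengths)) {
    sl <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
    if (!anyNA(sl)) GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

# give two GRanges a common seqlevel universe so overlap ops on disjoint
# chromosome sets return empty results instead of warning
#' @keywords internal
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' @keywords internal
granges_to_intervals <- function(gr) {
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = st, stringsAsFactors = FALSE)
}

# ---- readers / writers ------------------------------------------------------

#' Read transcripts from a GTF file
#'
#' Uses rtracklayer; 1-based inclusive GTF coordinates are converted to the
#' internal 0-based half-open convention. Each `transcript` record becomes one
#' row; `exon` records are collected into the `exons` list column.
#'
#' @param path GTF file.
#' @return transcript table.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id)) stopf("GTF lacks transcript_id attributes")
  is_tx <- !is.null(md$type) & as.character(md$type) == "transcript"
  tx <- gr[is_tx]
  if (length(tx) == 0) stopf("no transcript records in %s", path)
  iv <- granges_to_intervals(tx)
  out <- data.frame(transcript_id = as.character(S4Vectors::mcols(tx)$transcript_id),
                    iv, stringsAsFactors = FALSE)
  ex <- gr[as.character(md$type) == "exon"]
  if (length(ex)) {
    eiv <- cbind(granges_to_intervals(ex),
                 transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id))
    out$exons <- lapply(out$transcript_id, function(id) {
      e <- eiv[eiv$transcript_id == id, c("chrom", "start", "end")]
      e[order(e$start), , drop = FALSE]
    })
  }
  validate_transcripts(out)
  out
}

#' Read transcripts from BED (BED6 or BED12)
#'
#' BED12 blocks become the `exons` column.
#'
#' @param path BED file.
#' @return transcript table.
#' @export
read_transcripts_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  iv <- granges_to_intervals(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("tx", seq_along(gr))
  out <- data.frame(transcript_id = as.character(nm), iv,
                    stringsAsFactors = FALSE)
  blocks <- S4Vectors::mcols(gr)$blocks
  if (!is.null(blocks)) {
    out$exons <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]  # block ranges relative coords are already absolute here
      data.frame(chrom = out$chrom[i],
                 start = out$start[i] + IRanges::start(b) - 1,
                 end = out$start[i] + IRanges::end(b))
    })
  }
  validate_transcripts(out)
  out
}

#' Write transcripts to BED
#'
#' Writes BED12 when an `exons` column is present, BED6 otherwise.
#'
#' @param ts transcript table.
#' @param path output file.
#' @export
write_transcripts_bed <- function(ts, path) {
  validate_transcripts(ts)
  gr <- intervals_to_granges(ts)
  S4Vectors::mcols(gr)$name <- ts$transcript_id
  S4Vectors::mcols(gr)$score <- 0L
  if (!is.null(ts$exons)) {
    S4Vectors::mcols(gr)$thick <- IRanges::ranges(gr)
    S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(ts)), function(i) {
      e <- ts$exons[[i]]
      IRanges::IRanges(start = e$start - ts$start[i] + 1, end = e$end - ts$start[i])
    }))
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read an expression table (transcript_id, fpkm)
#'
#' @param path two-column TSV with header.
#' @return data.frame(transcript_id, fpkm).
#' @export
read_expression_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(x) < 2) stopf("expression table needs columns transcript_id, fpkm")
  names(x)[1:2] <- c("transcript_id", "fpkm")
  x$fpkm <- as.numeric(x$fpkm)
  x[, c("transcript_id", "fpkm")]
}

#' Attach expression values to a transcript table
#' @param ts transcript table.
#' @param expr data.frame(transcript_id, fpkm).
#' @return ts with an fpkm column; transcripts absent from expr get NA.
#' @export
add_expression <- function(ts, expr) {
  ts$fpkm <- expr$fpkm[match(ts$transcript_id, expr$transcript_id)]
  ts
}
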