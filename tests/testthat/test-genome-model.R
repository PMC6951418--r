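test_that("TSS windows are strand-aware, symmetric, and boundary-clipped", {
  ts <- toy_transcripts()
  iv <- tss_interval(ts, flank = 500, chrom_lengths = toy_chrom_lengths)
  # + strand: window centred on the start coordinate
  expect_equal(unlist(iv[iv$transcript_id == "txPlus", c("start", "end")]),
               c(start = 9500, end = 10500))
  # - strand: TSS is the maximal coordinate (end)
  expect_equal(unlist(iv[iv$transcript_id == "txMinus", c("start", "end")]),
               c(start = 35500, end = 36500))
  # clipped at the chromosome start, not discarded
  expect_equal(unlist(iv[iv$transcript_id == "txEdge", c("start", "end")]),
               c(start = 0, end = 800))
  # width = min(2*flank, clipped span) and the window contains the TSS
  tss <- tss_position(ts)
  expect_true(all(iv$end - iv$start <= 1000))
  expect_true(all(iv$start <= tss & tss <= iv$end))
})

test_that("TSS windows reject bad inputs", {
  ts <- toy_transcripts()
  bad <- ts; bad$strand[1] <- "."
  expect_error(tss_interval(bad, 500, toy_chrom_lengths), "strand")
  expect_error(tss_interval(ts, 500, c(chrA = -1, chrB = 1)), "positive")
  expect_error(tss_interval(ts, 500, c(chrA = 1e5)), "chromosome")
  expect_error(tss_interval(ts, 0, toy_chrom_lengths), "flank")
})

test_that("body regions run from TSS+flank to the TTS and abut the TSS window", {
  ts <- toy_transcripts()[1:2, ]
  body <- body_region(ts, 500)
  expect_equal(unlist(body[1, c("start", "end")]), c(start = 10500, end = 14000))
  # minus strand: body is [start, end - flank)
  expect_equal(unlist(body[2, c("start", "end")]), c(start = 30000, end = 35500))
  tssw <- tss_interval(ts, 500, toy_chrom_lengths)
  # zero-base overlap: the regions abut at TSS+500 on the transcript axis
  ov <- pmax(0, pmin(tssw$end, body$end) - pmax(tssw$start, body$start))
  expect_equal(ov, c(0, 0))
  # a transcript of length 100 over a 500 bp flank has an empty body
  short <- data.frame(transcript_id = "s", chrom = "chrA", start = 0,
                      end = 400, strand = "+")
  expect_error(body_region(short, 500), "empty body")
  # length exactly flank+100 gives a 100 bp body
  b <- body_region(data.frame(transcript_id = "t", chrom = "chrA",
                              start = 1000, end = 1600, strand = "+"), 500)
  expect_equal(b$end - b$start, 100)
})

test_that("strand flip mirrors regions under coordinate reflection", {
  L <- 50000
  fwd <- data.frame(transcript_id = "f", chrom = "chrA",
                    start = 12000, end = 18000, strand = "+")
  # reflect x -> L - x: the mirrored transcript sits on the minus strand
  rev <- data.frame(transcript_id = "r", chrom = "chrA",
                    start = L - 18000, end = L - 12000, strand = "-")
  cl <- c(chrA = L)
  for (maker in list(function(t) tss_interval(t, 500, cl),
                     function(t) body_region(t, 500))) {
    a <- maker(fwd); b <- maker(rev)
    expect_equal(b$start, L - a$end)
    expect_equal(b$end, L - a$start)
  }
})

test_that("expression filter keeps fpkm >= threshold, order preserved", {
  ts <- toy_transcripts()
  kept <- expressed_filter(ts, 0.5)
  expect_equal(kept$transcript_id, c("txPlus", "txMinus", "txShort"))
  expect_equal(nrow(expressed_filter(ts, 100)), 0)
  expect_equal(expressed_filter(ts, 0)$transcript_id, ts$transcript_id)
  ts$fpkm[2] <- NA
  expect_error(expressed_filter(ts), "fpkm")
})

test_that("BED12 round trip preserves coordinates and exon structure", {
  ts <- toy_transcripts()[1:2, c("transcript_id", "chrom", "start", "end", "strand")]
  ts$exons <- list(
    data.frame(chrom = "chrA", start = c(10000, 12000), end = c(10800, 14000)),
    data.frame(chrom = "chrA", start = c(30000, 33000), end = c(31000, 36000)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_transcripts_bed(ts, path)
  back <- read_transcripts_bed(path)
  expect_equal(back$transcript_id, ts$transcript_id)
  expect_equal(back$start, ts$start)
  expect_equal(back$end, ts$end)
  expect_equal(back$strand, ts$strand)
  expect_equal(back$exons[[1]]$start, ts$exons[[1]]$start)
  expect_equal(back$exons[[2]]$end, ts$exons[[2]]$end)
})

test_that("GTF input (1-based inclusive) converts to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrA", "test", "transcript", "1001", "2000", ".", "+", ".",
          'transcript_id "tx1";', sep = "\t"),
    paste("chrA", "test", "exon", "1001", "1200", ".", "+", ".",
          'transcript_id "tx1";', sep = "\t"),
    paste("chrA", "test", "exon", "1501", "2000", ".", "+", ".",
          'transcript_id "tx1";', sep = "\t")), path)
  ts <- read_transcripts_gtf(path)
  expect_equal(ts$start, 1000)
  expect_equal(ts$end, 2000)
  expect_equal(ts$exons[[1]]$start, c(1000, 1500))
  expect_equal(ts$exons[[1]]$end, c(1200, 2000))
})
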