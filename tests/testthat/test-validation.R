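test_that("overlap labels follow the strict more-than-half rule", {
  ts <- data.frame(
    transcript_id = c("spans", "half", "both", "misses"),
    chrom = "chrA",
    start = c(1000, 5000, 9000, 20000),
    end = c(3000, 5500, 12000, 21000),
    strand = "+", stringsAsFactors = FALSE)
  enhancers <- interval_df("chrA", c(1500, 4900, 9500), c(1900, 5900, 10000))
  promoters <- interval_df("chrA", 11000, 11800)
  lab <- label_by_overlap(ts, enhancers, promoters)
  get <- function(id, col) lab[lab$transcript_id == id, col]
  # transcript fully containing an enhancer
  expect_equal(get("spans", "label"), "elinc")
  expect_equal(get("spans", "best_fraction"), 1.0)
  # covering exactly half of an enhancer does not qualify
  expect_equal(get("half", "label"), "none")
  expect_equal(get("half", "best_fraction"), 0.5)
  # qualifying for both annotation sets is a conflict
  expect_equal(get("both", "label"), "conflict")
  expect_equal(get("misses", "label"), "none")
  expect_error(label_by_overlap(ts, enhancers[0, ], promoters[0, ]), "empty")
})

test_that("overlap labeling is invariant to splitting the annotation set", {
  ts <- data.frame(transcript_id = paste0("t", 1:3), chrom = "chrA",
                   start = c(100, 4000, 8000), end = c(2000, 6000, 8700),
                   strand = "+", stringsAsFactors = FALSE)
  enh <- interval_df("chrA", c(150, 4500, 8100), c(450, 5400, 8600))
  prom <- interval_df("chrA", 1, 2)
  whole <- label_by_overlap(ts, enh, prom)
  parts <- rbind(enh[1, ], enh[2:3, ])  # same elements, regrouped
  expect_equal(label_by_overlap(ts, parts, prom), whole)
})

test_that("chromatin-state randomization: saturated and empty states", {
  ts <- data.frame(transcript_id = paste0("t", 1:5), chrom = "chrA",
                   start = seq(1000, 41000, by = 10000),
                   end = seq(3000, 43000, by = 10000),
                   strand = "+", stringsAsFactors = FALSE)
  cl <- c(chrA = 100000)
  whole <- chromstate_enrichment(ts, interval_df("chrA", 0, 100000),
                                 n_perm = 200, seed = 91, chrom_lengths = cl)
  expect_equal(whole$observed, 5)
  expect_true(all(whole$null_counts == 5))
  expect_equal(whole$empirical_p, 1)
  none <- chromstate_enrichment(ts, interval_df(character(0), numeric(0), numeric(0)),
                                n_perm = 50, seed = 92, chrom_lengths = cl)
  expect_equal(none$observed, 0)
  expect_gt(none$empirical_p, 0)  # add-one correction forbids p = 0
})

test_that("footprint-matched states: observed count far exceeds the exact
           null mean", {
  # 20 transcripts of length 1000, footprints 50 kb apart on a 1 Mb chrom
  n <- 20; L <- 1000; C <- 1e6
  starts <- seq(10000, by = 50000, length.out = n)
  ts <- data.frame(transcript_id = sprintf("t%02d", 1:n), chrom = "chrA",
                   start = starts, end = starts + L, strand = "+",
                   stringsAsFactors = FALSE)
  states <- interval_df("chrA", starts, starts + L)
  res <- chromstate_enrichment(ts, states, cov_threshold = 0.3,
                               n_perm = 2000, seed = 93,
                               chrom_lengths = c(chrA = C))
  expect_equal(res$observed, n)
  # a placement is covered > 0.3 iff its start is within 0.7L of a
  # footprint start: 2*700 - 1 positions per footprint, exactly
  p_hit <- n * (2 * 0.7 * L - 1) / (C - L + 1)
  null_mean_exact <- n * p_hit
  expect_equal(mean(res$null_counts), null_mean_exact, tolerance = 0.15)
  expect_gt(res$observed, 10 * mean(res$null_counts))
  expect_equal(res$empirical_p, 1 / (res$n_perm + 1))
})

test_that("the empirical p-value is super-uniform under the null itself", {
  set.seed(94)
  C <- 200000; n <- 10; L <- 800
  states <- interval_df("chrA", seq(5000, 195000, by = 20000),
                        seq(5000, 195000, by = 20000) + 2000)
  pvals <- replicate(60, {
    s <- sample.int(C - L, n)
    ts <- data.frame(transcript_id = paste0("t", 1:n), chrom = "chrA",
                     start = s, end = s + L, strand = "+",
                     stringsAsFactors = FALSE)
    chromstate_enrichment(ts, states, n_perm = 99,
                          seed = sample.int(1e6, 1),
                          chrom_lengths = c(chrA = C))$empirical_p
  })
  expect_true(all(pvals > 0))
  for (a in c(0.1, 0.25, 0.5))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 60))
})

test_that("a transcript longer than its chromosome is rejected", {
  ts <- data.frame(transcript_id = "big", chrom = "chrA", start = 0,
                   end = 5000, strand = "+", stringsAsFactors = FALSE)
  expect_error(chromstate_enrichment(ts, interval_df("chrA", 0, 10),
                                     n_perm = 10, seed = 1,
                                     chrom_lengths = c(chrA = 2000)),
               "longer than")
})
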