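# Synthetic toy genomes with the statistical structure the classifier
# assumes: two transcript classes whose TSS/body chromatin features differ
# in the directions of the published coefficients, uninformative assays,
# and raw H3K4me1/H3K4me3 read intervals so the permutation labeler can be
# exercised end to end.

#' Default simulation configuration
#'
#' Class effects follow the published coefficient signs: elincRNAs are high
#' in TSS/body DNA methylation, TSS H3K4me1 and body H3K122ac; canonical
#' lincRNAs are high in body H3K36me3, TSS H3K9ac and TSS H3K4me3. Each
#' informative (region, assay) has Beta-distributed per-transcript coverage
#' with mean `mean_hi` (0.8) in the enriched class and `mean_lo` (0.2) in
#' the other (concentration 20); the paired region of the same assay and all
#' noise assays use the mid mean 0.5 in both classes. H3K4me1/H3K4me3 TSS
#' read depths are Poisson with means 100/25 for elincRNAs and 25/100 for
#' canonical lincRNAs, giving planted count ratios of about 4 and 1/4.
#'
#' @param seed RNG seed.
#' @param n_per_class transcripts per class (default 200).
#' @param chrom_lengths named chromosome lengths (default two 10 Mb
#'   chromosomes).
#' @param n_noise_assays uninformative coverage assays (default 5, i.e. 10
#'   noise feature columns).
#' @param mean_hi,mean_lo,mean_null Beta means for enriched / depleted /
#'   uninformative (region, assay) pairs.
#' @param concentration Beta concentration (default 20).
#' @param depth_me1_elinc,depth_me3_elinc Poisson TSS read depths for the
#'   two H3K4 marks in elincRNAs (defaults 100 / 25); canonical lincRNAs use
#'   the reverse.
#' @param flank region flank in bp (default 500).
#' @param tx_len_range transcript length range in bp (default 2000-6000).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_per_class = 200,
                       chrom_lengths = c(chrS1 = 1e7, chrS2 = 1e7),
                       n_noise_assays = 5,
                       mean_hi = 0.8, mean_lo = 0.2, mean_null = 0.5,
                       concentration = 20,
                       depth_me1_elinc = 100, depth_me3_elinc = 25,
                       flank = 500, tx_len_range = c(2000, 6000)) {
  stopifnot(mean_hi > 0, mean_hi < 1, mean_lo > 0, mean_lo < 1,
            mean_null > 0, mean_null < 1, concentration > 0,
            depth_me1_elinc > 0, depth_me3_elinc > 0)
  structure(list(seed = seed, n_per_class = n_per_class,
                 chrom_lengths = chrom_lengths,
                 n_noise_assays = n_noise_assays,
                 mean_hi = mean_hi, mean_lo = mean_lo, mean_null = mean_null,
                 concentration = concentration,
                 depth_me1_elinc = depth_me1_elinc,
                 depth_me3_elinc = depth_me3_elinc,
                 flank = flank, tx_len_range = tx_len_range),
            class = "sim_config")
}

# The informative (region, assay) pairs and the class they mark.
#' @keywords internal
planted_effects <- function() {
  data.frame(
    feature = c("TSS_DNAme", "TSS_H3K4me1", "Body_DNAme", "Body_H3K122ac",
                "Body_H3K36me3", "TSS_H3K9ac", "TSS_H3K4me3"),
    hi_class = c("elinc", "elinc", "elinc", "elinc",
                 "canonical", "canonical", "canonical"),
    stringsAsFactors = FALSE)
}

#' Simulate a toy dataset
#'
#' Transcripts are placed without overlap by slotting them (with their
#' flanks and an inter-transcript gap) along the chromosomes in random
#' order; an error is raised if the genome cannot hold the requested number.
#' For every assay and region a per-transcript target fraction is drawn from
#' the class's Beta distribution and realized as a single contiguous covered
#' interval at the region start (a contiguous block makes the realized
#' coverage ratio exact up to rounding). The methylation track places a
#' probe every 100 bp carrying the region's drawn beta. The two H3K4 marks
#' are additionally emitted as read-interval tracks with class-dependent
#' Poisson TSS counts.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (incl. fpkm), `tracks` (named
#'   `signal_track` list: DNAme beta track, coverage tracks per mark/noise
#'   assay, and `H3K4me1_reads`/`H3K4me3_reads`), `truth`
#'   (transcript_id, class), `expression` (transcript_id, fpkm) and the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2 * config$n_per_class
  flank <- config$flank
  max_len <- config$tx_len_range[2]
  slot <- max_len + 2 * flank + 1000  # transcript + flanks + gap
  slots_per_chrom <- floor((config$chrom_lengths - flank) / slot)
  if (sum(slots_per_chrom) < n)
    stopf("cannot place %d non-overlapping transcripts on this genome", n)
  slot_chrom <- rep(names(config$chrom_lengths), slots_per_chrom)
  slot_offset <- unlist(lapply(slots_per_chrom, function(k) (seq_len(k) - 1) * slot))
  pick <- sort(sample.int(length(slot_chrom), n))
  lens <- round(runif(n, config$tx_len_range[1], config$tx_len_range[2]))
  start <- slot_offset[pick] + flank + floor(runif(n, 0, max_len - lens + 1))
  cls <- sample(rep(c("elinc", "canonical"), config$n_per_class))
  ts <- data.frame(transcript_id = sprintf("SIMT%04d", seq_len(n)),
                   chrom = slot_chrom[pick], start = start,
                   end = start + lens,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  ts$fpkm <- round(rlnorm(n, meanlog = 1.5, sdlog = 1), 3) + 0.5
  truth <- data.frame(transcript_id = ts$transcript_id, class = cls,
                      stringsAsFactors = FALSE)

  tssiv <- tss_interval(ts, flank, config$chrom_lengths)
  bodyiv <- body_region(ts, flank)
  regions <- list(TSS = tssiv, Body = bodyiv)
  planted <- planted_effects()
  assays <- unique(sub("^(TSS|Body)_", "", planted$feature))
  noise_assays <- if (config$n_noise_assays > 0)
    sprintf("noise%02d", seq_len(config$n_noise_assays)) else character(0)

  draw_fraction <- function(feature) {
    mu <- rep(config$mean_null, n)
    hit <- planted$feature == feature
    if (any(hit)) {
      hi <- planted$hi_class[hit]
      mu <- ifelse(cls == hi, config$mean_hi, config$mean_lo)
    }
    stats::rbeta(n, mu * config$concentration,
                 (1 - mu) * config$concentration)
  }

  tracks <- list()
  beta_rows <- list()
  for (a in c(assays, noise_assays)) {
    iv_rows <- list()
    for (reg in names(regions)) {
      rv <- regions[[reg]]
      frac <- draw_fraction(paste0(reg, "_", a))
      if (a == "DNAme") {
        # probes every 100 bp carrying the drawn beta for the region
        for (i in seq_len(n)) {
          pos <- seq(rv$start[i], rv$end[i] - 1, by = 100)
          beta_rows[[length(beta_rows) + 1]] <-
            data.frame(chrom = rv$chrom[i], start = pos, end = pos + 1,
                       beta = frac[i])
        }
      } else {
        w <- round(frac * (rv$end - rv$start))
        keep <- w > 0
        iv_rows[[reg]] <- data.frame(chrom = rv$chrom[keep],
                                     start = rv$start[keep],
                                     end = rv$start[keep] + w[keep])
      }
    }
    if (a != "DNAme") {
      iv <- do.call(rbind, iv_rows)
      tracks[[a]] <- signal_track(a, "coverage", iv)
    }
  }
  tracks[["DNAme"]] <- signal_track("DNAme", "beta", do.call(rbind, beta_rows))

  # raw read intervals for the two H3K4 marks (50 bp reads inside the TSS
  # window so each read is counted exactly once)
  for (mk in c("H3K4me1", "H3K4me3")) {
    mu_e <- if (mk == "H3K4me1") config$depth_me1_elinc else config$depth_me3_elinc
    mu_c <- if (mk == "H3K4me1") config$depth_me3_elinc else config$depth_me1_elinc
    counts <- rpois(n, ifelse(cls == "elinc", mu_e, mu_c))
    idx <- rep(seq_len(n), counts)
    rstart <- floor(runif(sum(counts), tssiv$start[idx],
                          pmax(tssiv$start[idx] + 1, tssiv$end[idx] - 50)))
    tracks[[paste0(mk, "_reads")]] <-
      signal_track(paste0(mk, "_reads"), "reads",
                   data.frame(chrom = tssiv$chrom[idx], start = rstart,
                              end = rstart + 50))
  }

  list(transcripts = ts, tracks = tracks, truth = truth,
       expression = data.frame(transcript_id = ts$transcript_id,
                               fpkm = ts$fpkm, stringsAsFactors = FALSE),
       config = config)
}

#' Exchangeable null mark counts
#'
#' me1 and me3 are drawn iid Poisson(`mean`) per transcript: both marks have
#' identical count distributions, so the permutation labeler should assign
#' each confident class at its nominal percentile rate.
#'
#' @param n transcripts.
#' @param mean Poisson mean (> 0).
#' @param seed RNG seed.
#' @return data.frame(transcript_id, me1, me3).
#' @export
make_null_markcounts <- function(n, mean, seed) {
  if (mean <= 0) stopf("mean must be positive")
  set.seed(seed)
  data.frame(transcript_id = sprintf("NULLT%05d", seq_len(n)),
             me1 = rpois(n, mean), me3 = rpois(n, mean),
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset in the formats the readers consume
#'
#' Transcripts as BED, coverage tracks as bedGraph, reads as BED, the
#' methylation track as a (chrom, pos, beta) TSV, expression and truth as
#' TSV.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts_bed(sim$transcripts, file.path(dir, "transcripts.bed"))
  utils::write.table(sim$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (a in names(sim$tracks)) {
    tr <- sim$tracks[[a]]
    if (tr$kind == "beta") {
      iv <- granges_to_intervals(tr$data)
      utils::write.table(data.frame(iv$chrom, iv$start,
                                    S4Vectors::mcols(tr$data)$beta),
                         file.path(dir, paste0(a, ".beta.tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else if (tr$kind == "reads") {
      iv <- granges_to_intervals(tr$data)
      gr <- tr$data
      S4Vectors::mcols(gr)$name <- paste0("r", seq_along(gr))
      rtracklayer::export(gr, file.path(dir, paste0(a, ".bed")), format = "bed")
    } else {
      write_bedgraph_track(tr, file.path(dir, paste0(a, ".bedGraph")))
    }
  }
  invisible(dir)
}
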