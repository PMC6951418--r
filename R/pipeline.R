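# End-to-end workflow: expression filter -> permutation labeling -> feature
# extraction -> regularized model training -> cross-validated evaluation ->
# genome-wide prediction. All randomness flows from one top-level seed via
# fixed per-stage offsets, so a rerun with the same inputs and config
# reproduces every artifact.

#' Pipeline configuration
#'
#' @param seed top-level RNG seed; stages derive their own seeds from it.
#' @param flank TSS half-width / body offset (bp, default 500).
#' @param min_fpkm expression cutoff (default 0.5).
#' @param min_signal minimum of the larger H3K4 mark count (default 10).
#' @param hi_pct,lo_pct permutation percentile thresholds (default 95 / 5).
#' @param n_perm permutation rounds (default 10000).
#' @param alphas elastic-net mixing grid searched by CV.
#' @param folds CV folds (default 10).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, flank = 500, min_fpkm = 0.5,
                       min_signal = 10, hi_pct = 95, lo_pct = 5,
                       n_perm = 10000, alphas = c(0, 0.5, 1), folds = 10) {
  stopifnot(flank > 0, min_fpkm >= 0, min_signal >= 0,
            lo_pct > 0, hi_pct < 100, lo_pct < hi_pct, n_perm > 0,
            all(alphas >= 0 & alphas <= 1), folds >= 2)
  structure(list(seed = seed, flank = flank, min_fpkm = min_fpkm,
                 min_signal = min_signal, hi_pct = hi_pct, lo_pct = lo_pct,
                 n_perm = n_perm, alphas = alphas, folds = folds),
            class = "run_config")
}

#' @keywords internal
stage_seed <- function(config, stage) {
  # fixed offsets keep stage RNG streams independent and reproducible
  offsets <- c(label = 101L, model = 202L, eval = 303L)
  (config$seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full classification pipeline
#'
#' Stages, in order: filter expressed transcripts; count the two H3K4 marks
#' in TSS windows and label high-confidence elincRNA / canonical sets by the
#' permutation test; build the feature matrix; select (alpha, lambda) by CV
#' and fit the final model; cross-validate it; score and classify every
#' transcript outside the high-confidence set. Artifacts are written under
#' `outdir` together with a manifest recording the config and its hash.
#'
#' @param transcripts transcript table with fpkm.
#' @param tracks named `signal_track` list; must contain reads tracks named
#'   `H3K4me1_reads` and `H3K4me3_reads` plus the feature assays.
#' @param annotations named list of annotation interval sets (may be empty).
#' @param chrom_lengths named chromosome lengths.
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return list with `labels`, `features`, `model`, `alpha`, `lambda`,
#'   `evaluation`, `predictions`, `manifest_path` (invisibly also on disk).
#' @export
run_pipeline <- function(transcripts, tracks, annotations = list(),
                         chrom_lengths, config = run_config(),
                         outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  expressed <- stage("filter",
                     expressed_filter(transcripts, config$min_fpkm))

  labels <- stage("label", {
    me1 <- tracks[["H3K4me1_reads"]]; me3 <- tracks[["H3K4me3_reads"]]
    if (is.null(me1) || is.null(me3))
      stopf("tracks H3K4me1_reads and H3K4me3_reads are required")
    counts <- tss_mark_counts(expressed, me1, me3, config$flank,
                              chrom_lengths)
    passing <- counts[pmax(counts$me1, counts$me3) >= config$min_signal, ]
    null <- build_null(passing, n_perm = config$n_perm,
                       seed = stage_seed(config, "label"),
                       hi_pct = config$hi_pct, lo_pct = config$lo_pct)
    label_transcripts(counts, null, config$min_signal,
                      config$hi_pct, config$lo_pct)
  })
  write_labels_tsv(labels, file.path(outdir, "labels.tsv"))

  feature_tracks <- tracks[setdiff(names(tracks),
                                   c("H3K4me1_reads", "H3K4me3_reads"))]
  features <- stage("features",
                    build_features(expressed, feature_tracks, annotations,
                                   config$flank, chrom_lengths))
  write_features_tsv(features, file.path(outdir, "features.tsv"))

  hc <- labels[labels$label %in% c("elinc", "canonical"), ]
  hc <- hc[hc$transcript_id %in% rownames(features), ]
  if (nrow(hc) < config$folds)
    stopf("pipeline stage 'train' failed: only %d high-confidence transcripts",
          nrow(hc))
  Xhc <- features[hc$transcript_id, , drop = FALSE]
  yhc <- hc$label

  model_seed <- stage_seed(config, "model")
  sel <- stage("train", select_alpha(Xhc, yhc, config$alphas,
                                     k = config$folds, seed = model_seed))
  model <- stage("train", regnet_fit(Xhc, yhc, sel$alpha, sel$path$chosen))
  write_regnet(model, file.path(outdir, "model.json"))

  eval_res <- stage("evaluate",
                    cross_validate(Xhc, yhc, sel$alpha, sel$path$chosen,
                                   k = config$folds,
                                   seed = stage_seed(config, "eval")))
  write_eval(eval_res, file.path(outdir, "cv"))

  rest <- setdiff(rownames(features), hc$transcript_id)
  predictions <- stage("predict", {
    if (length(rest)) {
      Xr <- features[rest, , drop = FALSE]
      data.frame(transcript_id = rest,
                 score = regnet_score(model, Xr),
                 class = regnet_classify(model, Xr),
                 stringsAsFactors = FALSE)
    } else data.frame(transcript_id = character(0), score = numeric(0),
                      class = character(0))
  })
  utils::write.table(predictions, file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest_path <- write_manifest(config, outdir)
  invisible(list(labels = labels, features = features, model = model,
                 alpha = sel$alpha, lambda = sel$path$chosen,
                 evaluation = eval_res, predictions = predictions,
                 manifest_path = manifest_path))
}

#' @keywords internal
write_manifest <- function(config, outdir) {
  cfg_path <- file.path(outdir, "config.txt")
  kv <- vapply(names(unclass(config)), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1))
  writeLines(sort(kv), cfg_path)
  manifest <- file.path(outdir, "manifest.txt")
  writeLines(c(paste0("config_md5=", unname(tools::md5sum(cfg_path))),
               paste0("seed=", config$seed)), manifest)
  manifest
}
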