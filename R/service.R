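# Coordinate-level prediction front-end: enumerate the three alternate
# alleles at a genomic coordinate, map them onto every covering acceptor
# window, featurize and score.

#' Predict splicing effects of all alternate alleles at a coordinate
#'
#' For each of the three non-reference alleles and each transcript whose
#' Int-50..Int-3 acceptor window covers the position, computes the
#' probability of aberrant splicing and the 0.5-threshold call. The
#' reference allele itself is never emitted.
#'
#' @param chrom,pos Genomic coordinate (1-based).
#' @param genome A `genome_store`.
#' @param windows Acceptor windows over all transcripts (see
#'   [acceptor_windows()]).
#' @param clf A fitted `gbdt_classifier`.
#' @param config A [feature_config()] matching the training configuration.
#' @return data.frame with columns `chrom, pos, ref, alt, transcript_id,
#'   int_position, probability, call`; zero rows (with a message) when no
#'   window covers the position.
#' @export
predict_at <- function(chrom, pos, genome, windows, clf,
                       config = feature_config()) {
  if (length(windows) == 0L) stop("no transcripts / acceptor windows loaded")
  ref <- fetch_seq(genome, chrom, pos, pos, "+")
  rows <- list()
  for (alt in setdiff(BASES, ref)) {
    for (iv in map_variant(chrom, pos, ref, alt, windows, genome)) {
      if (!iv$in_scope) next
      p <- predict_proba(clf, featurize(iv$ctx, iv, config))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        transcript_id = iv$transcript_id, int_position = iv$int_position,
        probability = unname(p), call = classify_proba(p, clf$threshold),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    message(chrom, ":", pos, " is not inside the Int-50..Int-3 window of ",
            "any loaded transcript; nothing to predict")
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      transcript_id = character(0), int_position = integer(0),
                      probability = numeric(0), call = character(0)))
  }
  do.call(rbind, rows)
}

#' Batch prediction over a variant file or table
#'
#' One prediction row per (variant, transcript) pair; variants that cannot
#' be scored (reference mismatch, outside every window, non-SNV) are
#' reported in a skipped list with the reason, never silently dropped.
#'
#' @param variants A `variant_table`, or a path readable by
#'   [read_variants()].
#' @param genome A `genome_store`.
#' @param windows Acceptor windows over all transcripts.
#' @param clf A fitted `gbdt_classifier`.
#' @param config A [feature_config()].
#' @return List with `predictions` (data.frame as in [predict_at()]) and
#'   `skipped` (data.frame `chrom, pos, ref, alt, reason`).
#' @export
batch_predict <- function(variants, genome, windows, clf,
                          config = feature_config()) {
  if (is.character(variants)) variants <- read_variants(variants)
  preds <- list(); skipped <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    res <- tryCatch({
      ivs <- map_variant(v$chrom, v$pos, v$ref, v$alt, windows, genome)
      ivs <- Filter(function(iv) iv$in_scope, ivs)
      if (length(ivs) == 0L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          reason = "outside every Int-50..Int-3 window",
          stringsAsFactors = FALSE)
      } else {
        for (iv in ivs) {
          p <- predict_proba(clf, featurize(iv$ctx, iv, config))
          preds[[length(preds) + 1L]] <- data.frame(
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            transcript_id = iv$transcript_id,
            int_position = iv$int_position, probability = unname(p),
            call = classify_proba(p, clf$threshold), stringsAsFactors = FALSE)
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        reason = res, stringsAsFactors = FALSE)
    }
  }
  empty_pred <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           transcript_id = character(0),
                           int_position = integer(0),
                           probability = numeric(0), call = character(0))
  empty_skip <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           reason = character(0))
  list(predictions = if (length(preds)) do.call(rbind, preds) else empty_pred,
       skipped = if (length(skipped)) do.call(rbind, skipped) else empty_skip)
}

#' Write a prediction report
#' @param report Output of [batch_predict()] or [predict_at()].
#' @param path Output path; `format` `"tsv"` (default) or `"json"`.
#' @param format Output format.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.data.frame(report)) report <- list(predictions = report,
                                            skipped = data.frame())
  if (format == "tsv") {
    utils::write.table(report$predictions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (nrow(report$skipped) > 0L) {
      utils::write.table(report$skipped, paste0(path, ".skipped.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
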