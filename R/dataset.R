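# Labeled datasets: curation filters, class balancing, and circularity-free
# train/test splitting.
#
# A dataset row is one (variant, transcript) pair. Keys therefore include the
# transcript id, but all rows of one genomic SNV are held out atomically (a
# genomic variant never straddles a train/test or fold boundary).

#' MAF filter for common variants
#'
#' Keeps common records with `lo <= maf < hi` (half-open interval; 0.01 is
#' kept, 0.50 is dropped under the defaults). Pathogenic records pass
#' unfiltered. Records with MAF outside `[0, 1]` are rejected with a warning.
#' The alternative upper bound `hi = 0.99` is supported for the
#' major-allele-inclusive curation arm.
#'
#' @param variants A `variant_table`.
#' @param lo,hi MAF bounds; defaults 0.01 and 0.50.
#' @return The filtered `variant_table`.
#' @export
maf_filter <- function(variants, lo = 0.01, hi = 0.50) {
  maf <- variants$maf
  invalid <- !is.na(maf) & (maf < 0 | maf > 1)
  if (any(invalid)) {
    warning(sum(invalid), " record(s) with MAF outside [0,1] rejected")
  }
  is_path <- variants$label == "pathogenic"
  keep <- !invalid & (is_path | (!is.na(maf) & maf >= lo & maf < hi))
  variants[keep, , drop = FALSE]
}

#' Balance classes by downsampling commons
#'
#' Draws a uniform random sample, without replacement, of as many common
#' rows as there are pathogenic rows; every pathogenic row is kept exactly.
#' Deterministic given `seed`.
#'
#' @param variants A `variant_table` with pathogenic and common rows.
#' @param seed Integer RNG seed.
#' @return A `variant_table` with equal class counts.
#' @export
balance_sample <- function(variants, seed) {
  path <- variants[variants$label == "pathogenic", , drop = FALSE]
  comm <- variants[variants$label == "common", , drop = FALSE]
  if (nrow(comm) < nrow(path)) {
    stop("fewer common (", nrow(comm), ") than pathogenic (", nrow(path),
         ") records; downsample the pathogenic set instead")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- sample.int(nrow(comm), nrow(path))
  out <- rbind(path, comm[sort(pick), , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

# Save/restore the global RNG state so package functions with their own seed
# never perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a labeled feature dataset
#'
#' Maps every variant onto every acceptor window covering it (one row per
#' (variant, transcript) pair, Int-50..Int-3 only) and featurizes each pair.
#'
#' @param variants A `variant_table` with labels.
#' @param windows List of `acceptor_context`s over all transcripts.
#' @param genome A `genome_store`.
#' @param config A [feature_config()].
#' @return A `labeled_dataset`: data.frame with identifier columns
#'   (`key`, `chrom`, `pos`, `ref`, `alt`, `transcript_id`, `int_position`),
#'   `label` (1 pathogenic / 0 common) and one column per feature.
#' @export
build_dataset <- function(variants, windows, genome, config = feature_config()) {
  rows <- vector("list", nrow(variants) * 2L)
  n <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ivs <- map_variant(v$chrom, v$pos, v$ref, v$alt, windows, genome)
    for (iv in ivs) {
      if (!iv$in_scope) next
      fv <- featurize(iv$ctx, iv, config)
      n <- n + 1L
      rows[[n]] <- data.frame(
        key = variant_key(iv), chrom = iv$chrom, pos = iv$pos,
        ref = iv$ref, alt = iv$alt, transcript_id = iv$transcript_id,
        int_position = iv$int_position,
        label = if (v$label == "pathogenic") 1L else 0L,
        t(fv), stringsAsFactors = FALSE)
    }
  }
  if (n == 0L) stop("no variant mapped into any acceptor window")
  ds <- do.call(rbind, rows[seq_len(n)])
  if (anyDuplicated(ds$key)) {
    stop("duplicate (variant, transcript) keys in dataset: ",
         ds$key[duplicated(ds$key)][1L])
  }
  rownames(ds) <- NULL
  structure(ds, class = c("labeled_dataset", "data.frame"),
            feature_names = FEATURE_NAMES)
}

#' Feature matrix / label vector of a dataset
#' @param ds A `labeled_dataset`.
#' @return `dataset_matrix`: numeric matrix (rows = pairs, columns =
#'   features); `dataset_labels`: integer 0/1 vector.
#' @export
dataset_matrix <- function(ds) {
  m <- as.matrix(as.data.frame(ds)[, attr(ds, "feature_names")])
  rownames(m) <- ds$key
  m
}

#' @rdname dataset_matrix
#' @export
dataset_labels <- function(ds) as.integer(ds$label)

#' Persist / load a labeled dataset (TSV + JSON sidecar)
#' @param ds A `labeled_dataset`.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `read_dataset`: the restored `labeled_dataset`.
#' @export
write_dataset <- function(ds, path) {
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(schema = "acceptorvar-dataset-1",
         feature_names = attr(ds, "feature_names"), n_rows = nrow(ds)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$schema, "acceptorvar-dataset-1")) {
    stop("unknown dataset schema in ", path, ".json")
  }
  structure(df, class = c("labeled_dataset", "data.frame"),
            feature_names = side$feature_names)
}

# ---- splits ------------------------------------------------------------------

# Stratified fold assignment at the level of genomic variants.
.stratified_folds <- function(gkeys, labels, n_folds, seed) {
  u <- !duplicated(gkeys)
  ug <- gkeys[u]; ul <- labels[u]
  fold_of <- stats::setNames(integer(length(ug)), ug)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in unique(ul)) {
    ks <- sample(ug[ul == cl])
    fold_of[ks] <- rep_len(seq_len(n_folds), length(ks))
  }
  unname(fold_of[gkeys])
}

#' Build a benchmark split with a circularity guard
#'
#' Holds out the given keys as the test set, assigns the remaining rows to
#' `n_folds` label-stratified CV folds, and *aborts* if any key ends up on
#' both sides. All rows sharing a genomic variant (`chrom:pos:ref:alt`) are
#' kept on the same side of every boundary, so a variant seen in training can
#' never be evaluated in test under another transcript.
#'
#' @param ds A `labeled_dataset`.
#' @param held_out_keys Character vector of row keys (or genomic keys) to
#'   hold out; empty for a plain CV plan.
#' @param seed Integer RNG seed for fold shuffling.
#' @param n_folds Number of CV folds, default 5.
#' @return A `split_plan`: list with `train_keys`, `test_keys`, `fold`
#'   (named integer fold id per train key), `n_folds`, `seed`.
#' @export
benchmark_split <- function(ds, held_out_keys = character(0), seed = 1L,
                            n_folds = 5L) {
  keys <- ds$key
  if (!all(held_out_keys %in% keys | held_out_keys %in%
             genomic_key(ds$chrom, ds$pos, ds$ref, ds$alt))) {
    stop("held-out keys must be dataset row keys or genomic keys")
  }
  gk <- genomic_key(ds$chrom, ds$pos, ds$ref, ds$alt)
  held_gk <- unique(gk[keys %in% held_out_keys | gk %in% held_out_keys])
  is_test <- gk %in% held_gk
  test_keys <- keys[is_test]
  train_keys <- keys[!is_test]
  if (length(intersect(train_keys, test_keys)) > 0L) {
    stop("circularity guard: ", length(intersect(train_keys, test_keys)),
         " key(s) present in both train and test")
  }
  fold <- .stratified_folds(gk[!is_test], ds$label[!is_test], n_folds, seed)
  plan <- structure(list(train_keys = train_keys, test_keys = test_keys,
                         fold = stats::setNames(fold, train_keys),
                         n_folds = as.integer(n_folds), seed = as.integer(seed)),
                    class = "split_plan")
  assert_no_circularity(plan)
  plan
}

#' Assert a split plan has no train/test overlap
#'
#' The absolute circularity guard: any key appearing on both sides raises an
#' error (non-zero exit in scripts).
#'
#' @param plan A `split_plan`.
#' @return `plan`, invisibly, if clean.
#' @export
assert_no_circularity <- function(plan) {
  overlap <- intersect(plan$train_keys, plan$test_keys)
  if (length(overlap) > 0L) {
    stop("circularity detected: ", length(overlap),
         " key(s) in both train and test (first: ", overlap[1L], ")")
  }
  folds <- plan$fold[plan$train_keys]
  if (anyNA(folds)) stop("train keys without fold assignment")
  invisible(plan)
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$train_keys), " train / ",
      length(x$test_keys), " test keys, ", x$n_folds,
      " folds, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Persist / load a split plan as JSON
#' @param plan A `split_plan`.
#' @param path JSON path.
#' @return `read_split_plan`: the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(schema = "acceptorvar-split-1", train_keys = plan$train_keys,
         test_keys = plan$test_keys, fold = as.list(plan$fold),
         n_folds = plan$n_folds, seed = plan$seed),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "acceptorvar-split-1")) {
    stop("unknown split-plan schema in ", path)
  }
  structure(list(train_keys = j$train_keys, test_keys = j$test_keys,
                 fold = unlist(j$fold), n_folds = j$n_folds, seed = j$seed),
            class = "split_plan")
}
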