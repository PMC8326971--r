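# Transcript models and acceptor-window extraction.
#
# Coordinates: external files keep their native conventions (GTF 1-based
# closed); internally exons are stored as a genomically-ascending matrix of
# 1-based closed intervals. Int-k numbering is 1-based counting upstream from
# the intron's 3' terminus: Int-1 is the last intronic base (the G of the
# canonical AG), Int-3 the third-from-last.

#' Construct a transcript model
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon (start, end), 1-based
#'   closed genomic coordinates, any order; must be non-overlapping.
#' @param coding Logical; is this a coding transcript?
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, coding = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) stop("exon end < start in ", transcript_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, coding = isTRUE(coding)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " ", x$chrom, ":",
      min(x$exons), "-", max(x$exons), "(", x$strand, "), ",
      nrow(x$exons), " exon(s), coding=", x$coding, "\n", sep = "")
  invisible(x)
}

#' Number of exons
#' @param tm A `transcript_model`.
#' @return Integer.
#' @export
n_exons <- function(tm) nrow(tm$exons)

# Exon intervals ordered 5'->3' in transcript orientation.
exons_in_transcript_order <- function(tm) {
  if (tm$strand == "+") tm$exons else tm$exons[rev(seq_len(nrow(tm$exons))), , drop = FALSE]
}

#' Read transcript models from a GTF/GFF annotation
#'
#' Uses [rtracklayer::import()]; exon features are grouped by
#' `transcript_id` (GTF) or `Parent`/`ID` (GFF3). A transcript is flagged
#' coding when it has CDS features or a `protein_coding` biotype attribute.
#'
#' @param path GTF or GFF3 file (optionally gzipped).
#' @param coding_only Keep only coding transcripts (default `TRUE`).
#' @return Named list of `transcript_model` objects.
#' @export
read_annotation <- function(path, coding_only = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(gr$type) & gr$type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  tx_of <- function(sel) {
    if ("transcript_id" %in% names(md)) {
      as.character(md$transcript_id[sel])
    } else if ("Parent" %in% names(md)) {
      vapply(md$Parent[sel], function(p) as.character(p)[1L], character(1))
    } else stop("annotation lacks transcript_id/Parent attributes")
  }
  ex_tx <- tx_of(is_exon)
  biotype <- rep(NA_character_, length(gr))
  for (col in c("transcript_biotype", "gene_biotype", "transcript_type")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  }
  cds_tx <- if (any(!is.na(gr$type) & gr$type == "CDS")) {
    unique(tx_of(!is.na(gr$type) & gr$type == "CDS"))
  } else character(0)
  coding_bio <- unique(ex_tx[!is.na(biotype[is_exon]) &
                               biotype[is_exon] == "protein_coding"])

  out <- list()
  for (tx in unique(ex_tx)) {
    sel <- which(is_exon)[ex_tx == tx]
    if (length(sel) == 0L) {
      warning("transcript ", tx, " has zero exons; skipped")
      next
    }
    coding <- tx %in% cds_tx || tx %in% coding_bio
    tm <- transcript_model(
      transcript_id = tx,
      chrom = as.character(GenomicRanges::seqnames(gr)[sel][1L]),
      strand = as.character(BiocGenerics::strand(gr)[sel][1L]),
      exons = cbind(GenomicRanges::start(gr)[sel], GenomicRanges::end(gr)[sel]),
      coding = coding
    )
    if (!coding_only || tm$coding) out[[tx]] <- tm
  }
  if (length(out) == 0L) warning("no ", if (coding_only) "coding " else "",
                                 "transcripts found in ", path)
  out
}

# ---- acceptor windows -------------------------------------------------------

WINDOW_LEN <- 50L   # Int-50 .. Int-1
INT_MIN <- 3L       # predictable range Int-50..Int-3; Int-1/Int-2 out of scope
INT_MAX <- 50L

#' Acceptor windows of a transcript
#'
#' For every internal exon (neither first nor last in transcript orientation)
#' of a coding transcript, extracts the 50-nt intronic window Int-50..Int-1
#' ending at the upstream intron's 3' terminus, in transcript-sense
#' orientation, together with the downstream-exon context needed for
#' featurization. Introns shorter than 50 nt yield no window.
#'
#' @param tm A `transcript_model` with at least 3 exons.
#' @param genome A `genome_store`.
#' @return List of `acceptor_context` objects (possibly empty).
#' @export
acceptor_windows <- function(tm, genome) {
  if (n_exons(tm) < 3L) return(list())
  ex <- exons_in_transcript_order(tm)
  n <- nrow(ex)
  clen <- contig_lengths(genome)[[tm$chrom]]
  out <- list()
  for (i in 2L:(n - 1L)) {                      # internal exons
    e <- ex[i, ]
    exon_len <- e[["end"]] - e[["start"]] + 1L
    if (tm$strand == "+") {
      int1 <- e[["start"]] - 1L                  # last intronic base
      prev_end <- ex[i - 1L, "end"]
      intron_len <- int1 - prev_end
      win_ok <- intron_len >= WINDOW_LEN && int1 - WINDOW_LEN + 1L >= 1L
      if (!win_ok) { message("intron upstream of exon ", i, " of ",
                             tm$transcript_id, " shorter than 50 nt; window skipped"); next }
      window_seq <- fetch_seq(genome, tm$chrom, int1 - WINDOW_LEN + 1L, int1, "+")
      exon_first3 <- fetch_seq(genome, tm$chrom, e[["start"]],
                               min(e[["start"]] + 2L, e[["end"]]), "+")
      donor_ok <- e[["end"]] - 2L >= e[["start"]] && e[["end"]] + 6L <= clen
      donor_seq <- if (donor_ok)
        fetch_seq(genome, tm$chrom, e[["end"]] - 2L, e[["end"]] + 6L, "+") else NA_character_
    } else {
      int1 <- e[["end"]] + 1L
      nxt_start <- ex[i - 1L, "start"]           # upstream exon, genomically right
      intron_len <- nxt_start - int1
      win_ok <- intron_len >= WINDOW_LEN && int1 + WINDOW_LEN - 1L <= clen
      if (!win_ok) { message("intron upstream of exon ", i, " of ",
                             tm$transcript_id, " shorter than 50 nt; window skipped"); next }
      window_seq <- fetch_seq(genome, tm$chrom, int1, int1 + WINDOW_LEN - 1L, "-")
      exon_first3 <- fetch_seq(genome, tm$chrom,
                               max(e[["end"]] - 2L, e[["start"]]), e[["end"]], "-")
      donor_ok <- e[["start"]] + 2L <= e[["end"]] && e[["start"]] - 6L >= 1L
      donor_seq <- if (donor_ok)
        fetch_seq(genome, tm$chrom, e[["start"]] - 6L, e[["start"]] + 2L, "-") else NA_character_
    }
    ctx <- structure(list(
      transcript_id = tm$transcript_id,
      chrom = tm$chrom,
      strand = tm$strand,
      exon_index = i,                 # transcript-orientation exon number
      intron_index = i - 1L,          # upstream intron, transcript orientation
      window_seq = window_seq,        # Int-50..Int-1, transcript sense
      exon_first_nt = substr(exon_first3, 1L, 1L),
      exon_first3 = exon_first3,
      exon_length = exon_len,
      donor_site_seq = donor_seq,     # Ex-3..Int+6 of this exon's 5'ss
      int1_genomic = unname(int1),
      canonical_ag = substr(window_seq, 49L, 50L) == "AG"
    ), class = "acceptor_context")
    out[[length(out) + 1L]] <- ctx
  }
  out
}

#' @export
print.acceptor_context <- function(x, ...) {
  cat("<acceptor_context> ", x$transcript_id, " intron ", x$intron_index,
      " (", x$chrom, ":", x$int1_genomic, x$strand, ")",
      if (!x$canonical_ag) " [non-canonical 3'ss]", "\n",
      "  window: ", x$window_seq, "\n", sep = "")
  invisible(x)
}

#' Genomic coordinate of an Int-k position within a window
#'
#' @param ctx An `acceptor_context`.
#' @param k Int-k position, 1-based from the intron's 3' end.
#' @return 1-based genomic coordinate.
#' @export
int_k_genomic <- function(ctx, k) {
  stopifnot(k >= 1L, k <= WINDOW_LEN)
  if (ctx$strand == "+") ctx$int1_genomic - (k - 1L) else ctx$int1_genomic + (k - 1L)
}

# Character index of Int-k within the 50-nt window string (1-based).
int_k_index <- function(k) WINDOW_LEN + 1L - as.integer(k)

# Replace the Int-k base of a window with the given (sense) allele.
mutate_window <- function(window_seq, k, sense_alt) {
  i <- int_k_index(k)
  paste0(substr(window_seq, 1L, i - 1L), sense_alt,
         substr(window_seq, i + 1L, WINDOW_LEN))
}
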