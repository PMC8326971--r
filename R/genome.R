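#' Reverse-complement a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read a reference genome from FASTA
#'
#' Loads a (optionally gzip-compressed) FASTA file into an in-memory sequence
#' store. Non-ACGTN characters are replaced by `N` with a warning. Contig
#' names are truncated at the first whitespace, as aligners do.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_store` object; subset sequences with [fetch_seq()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  genome_store(dss)
}

#' Build a sequence store from named sequences
#'
#' @param x A named `DNAStringSet` or named character vector of sequences.
#' @return A `genome_store` object.
#' @export
genome_store <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named by contig")
    bad <- grepl("[^ACGTNacgtn]", x)
    if (any(bad)) {
      warning("non-ACGTN characters in contig(s) ",
              paste(names(x)[bad], collapse = ", "), "; replaced by N")
      x <- vapply(x, function(s) gsub("[^ACGTNacgtn]", "N", s), character(1))
    }
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  stopifnot(methods::is(x, "DNAStringSet"))
  structure(list(seqs = x), class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("<genome_store> ", length(x$seqs), " contig(s), ",
      sum(Biostrings::width(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}

#' Contig lengths of a sequence store
#' @param genome A `genome_store`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

.check_contig <- function(genome, chrom) {
  idx <- match(chrom, names(genome$seqs))
  if (is.na(idx)) {
    stop("contig not found in genome: '", chrom, "' (available: ",
         paste(utils::head(names(genome$seqs), 10), collapse = ", "), ")")
  }
  idx
}

#' Fetch a genomic sub-sequence
#'
#' 1-based closed coordinates (GTF/VCF convention). On the minus strand the
#' slice is reverse-complemented, i.e. returned 5'->3' on that strand.
#'
#' @param genome A `genome_store`.
#' @param chrom Contig name.
#' @param start,end 1-based closed interval.
#' @param strand `"+"` (default) or `"-"`.
#' @return A single character string.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  idx <- .check_contig(genome, chrom)
  len <- Biostrings::width(genome$seqs)[idx]
  if (start < 1L || end > len || start > end) {
    stop("interval [", start, ",", end, "] out of bounds for contig '",
         chrom, "' (length ", len, ")")
  }
  s <- as.character(Biostrings::subseq(genome$seqs[[idx]], start, end))
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

#' Write a sequence store to FASTA
#' @param genome A `genome_store`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome$seqs, path, width = width)
  invisible(path)
}
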