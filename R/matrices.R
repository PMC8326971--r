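# Position frequency matrices: the parameters of the splice-signal scores.

#' Construct a position frequency matrix
#'
#' @param mat Numeric matrix, one row per position, columns `A,C,G,T`;
#'   rows must each sum to 1 (tolerance 1e-9).
#' @param name Optional short name recorded on the object.
#' @return A `frequency_matrix`.
#' @export
frequency_matrix <- function(mat, name = NULL) {
  mat <- as.matrix(mat)
  if (!identical(colnames(mat), BASES)) {
    if (all(BASES %in% colnames(mat))) mat <- mat[, BASES, drop = FALSE]
    else stop("frequency matrix needs columns A, C, G, T")
  }
  if (any(mat < 0)) stop("negative frequencies")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) {
    stop("each position's frequencies must sum to 1 (max deviation ",
         format(max(abs(rowSums(mat) - 1))), ")")
  }
  rownames(mat) <- NULL
  structure(mat, class = c("frequency_matrix", "matrix"), name = name)
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("<frequency_matrix> ", attr(x, "name") %||% "", " L=", nrow(x), "\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a frequency matrix as TSV
#'
#' The TSV has columns `pos, A, C, G, T`, one row per window position.
#'
#' @param path File path.
#' @return `read_frequency_matrix`: a `frequency_matrix`.
#' @export
read_frequency_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  frequency_matrix(as.matrix(df[, BASES]), name = basename(path))
}

#' @rdname read_frequency_matrix
#' @param fm A `frequency_matrix`.
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- data.frame(pos = seq_len(nrow(fm)), unclass(fm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "acceptorvar")
  if (p == "") p <- file.path("inst", "extdata", file)   # pre-install fallback
  if (!file.exists(p)) stop("bundled data file not found: ", file)
  p
}

#' Bundled default frequency matrices
#'
#' Consensus-derived synthetic defaults shipped with the package (they encode
#' the textbook acceptor / donor / branch-point consensus, not frequencies
#' estimated from any genome): a 15-position acceptor matrix
#' (Int-14..Int-1 + Ex+1), a 9-position donor matrix (Ex-3..Int+6) and a
#' 7-position branch-point matrix with the branch A at position 4. Matrices
#' estimated from a real annotation via [estimate_frequency_matrix()] can be
#' used anywhere these defaults are accepted.
#'
#' @param which One of `"acceptor15"`, `"donor9"`, `"bps7"`, `"acceptor23"`.
#' @return A `frequency_matrix`.
#' @export
default_matrix <- function(which = c("acceptor15", "donor9", "bps7", "acceptor23")) {
  which <- match.arg(which)
  file <- switch(which,
                 acceptor15 = "ss_acceptor15_synthetic.tsv",
                 donor9     = "ss_donor9_synthetic.tsv",
                 bps7       = "bps_heptamer7_synthetic.tsv",
                 acceptor23 = "acceptor_signal23_synthetic.tsv")
  read_frequency_matrix(.extdata(file))
}

#' Estimate a frequency matrix from aligned sequences
#'
#' @param seqs Character vector of equal-length sequences (e.g. acceptor
#'   15-mers collected from [acceptor_windows()] over an annotation).
#' @param pseudocount Added to every cell before normalization.
#' @return A `frequency_matrix` of the common sequence length.
#' @export
estimate_frequency_matrix <- function(seqs, pseudocount = 0.5) {
  stopifnot(length(seqs) >= 1L, pseudocount >= 0)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must share one length")
  m <- matrix(pseudocount, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  for (s in seqs) {
    b <- strsplit(s, "")[[1L]]
    ok <- b %in% BASES
    idx <- cbind(which(ok), match(b[ok], BASES))
    m[idx] <- m[idx] + 1
  }
  frequency_matrix(m / rowSums(m), name = "estimated")
}
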