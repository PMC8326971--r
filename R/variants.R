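# Variant records and mapping onto acceptor windows.

#' Construct a table of variant records
#'
#' Validates and normalizes a data.frame of single-nucleotide variants.
#'
#' @param chrom,pos,ref,alt Vectors of contig, 1-based position, reference and
#'   alternate alleles (single bases, A/C/G/T).
#' @param maf Minor allele fraction in `[0,1]`, or `NA` when unknown
#'   (pathogenic records typically have no MAF).
#' @param label `"pathogenic"`, `"common"` or `"unlabeled"`.
#' @return A data.frame with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, maf = NA_real_,
                          label = "unlabeled") {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = ref, alt = alt,
                   maf = rep_len(as.numeric(maf), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  bad_allele <- !(df$ref %in% BASES) | !(df$alt %in% BASES)
  if (any(bad_allele)) {
    stop(sum(bad_allele), " record(s) are not single-nucleotide A/C/G/T ",
         "substitutions (indels and ambiguity codes are not supported); ",
         "first offender: ", df$chrom[bad_allele][1L], ":",
         df$pos[bad_allele][1L], " ", df$ref[bad_allele][1L], ">",
         df$alt[bad_allele][1L])
  }
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (!all(df$label %in% c("pathogenic", "common", "unlabeled"))) {
    stop("labels must be 'pathogenic', 'common' or 'unlabeled'")
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read variants from VCF or TSV
#'
#' VCF v4.x files are read with \pkg{vcfR}; multi-allelic records are split
#' into one row per alternate allele. A `MAF` or `AF` INFO key populates the
#' `maf` column when present. TSV files must carry columns
#' `chrom, pos, ref, alt` and optionally `maf`, `label`. Both formats may be
#' gzip-compressed.
#'
#' @param path Input file; format chosen by extension (`.vcf[.gz]` vs other).
#' @param label Default label for records without one.
#' @return A `variant_table`.
#' @export
read_variants <- function(path, label = "unlabeled") {
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) {
      return(variant_table(character(0), integer(0), character(0), character(0)))
    }
    info <- vcfR::extract.info(v, element = "MAF")
    if (all(is.na(info))) info <- vcfR::extract.info(v, element = "AF")
    rows <- list()
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
      for (a in alts) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = a,
          maf = suppressWarnings(as.numeric(info[i])),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    variant_table(df$chrom, df$pos, df$ref, df$alt, df$maf, label)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df))) {
      stop("TSV must have columns chrom, pos, ref, alt (got: ",
           paste(names(df), collapse = ", "), ")")
    }
    variant_table(df$chrom, df$pos, df$ref, df$alt,
                  if ("maf" %in% names(df)) df$maf else NA_real_,
                  if ("label" %in% names(df)) df$label else label)
  }
}

#' Write variants as TSV
#' @param variants A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(
    variants[, c("chrom", "pos", "ref", "alt", "maf", "label")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variants as a minimal VCF
#'
#' Emits a VCF v4.2 file with MAF and LABEL INFO fields, one record per row.
#'
#' @param variants A `variant_table`.
#' @param path Output path.
#' @param genome Optional `genome_store`, used for contig header lines.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
           '##INFO=<ID=LABEL,Number=1,Type=String,Description="Curation label">')
  if (!is.null(genome)) {
    cl <- contig_lengths(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(cl), cl))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(variants$maf),
                 paste0("LABEL=", variants$label),
                 sprintf("MAF=%.6g;LABEL=%s", variants$maf, variants$label))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Map a variant onto acceptor windows
#'
#' Returns one `intronic_variant` per transcript whose Int-50..Int-1 acceptor
#' window covers the variant position. Alleles are re-expressed in
#' transcript-sense orientation (reverse-complemented for minus-strand
#' transcripts). Variants at Int-1/Int-2 are mappable (`in_scope = FALSE`);
#' only Int-50..Int-3 is the predictable range.
#'
#' @param chrom,pos,ref,alt A single variant (1-based genomic coordinates).
#' @param windows List of `acceptor_context` objects (e.g. from
#'   [acceptor_windows()] over all transcripts).
#' @param genome A `genome_store`, used to verify the reference allele.
#' @return List of `intronic_variant` objects (possibly empty).
#' @export
map_variant <- function(chrom, pos, ref, alt, windows, genome) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(chrom) == 1L, length(pos) == 1L)
  if (!(ref %in% BASES) || !(alt %in% BASES) || ref == alt) {
    stop("only single-nucleotide substitutions are supported: got ",
         ref, ">", alt)
  }
  genome_base <- fetch_seq(genome, chrom, pos, pos, "+")
  if (genome_base != ref) {
    stop("reference allele mismatch at ", chrom, ":", pos,
         ": variant says '", ref, "', genome has '", genome_base, "'")
  }
  out <- list()
  for (ctx in windows) {
    if (ctx$chrom != chrom) next
    k <- if (ctx$strand == "+") ctx$int1_genomic - pos + 1L else pos - ctx$int1_genomic + 1L
    if (k < 1L || k > WINDOW_LEN) next
    sense_ref <- if (ctx$strand == "+") ref else revcomp(ref)
    sense_alt <- if (ctx$strand == "+") alt else revcomp(alt)
    stopifnot(substr(ctx$window_seq, int_k_index(k), int_k_index(k)) == sense_ref)
    out[[length(out) + 1L]] <- structure(list(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      transcript_id = ctx$transcript_id,
      int_position = as.integer(k),
      sense_ref = sense_ref, sense_alt = sense_alt,
      in_scope = k >= INT_MIN && k <= INT_MAX,
      ctx = ctx
    ), class = "intronic_variant")
  }
  out
}

#' @export
print.intronic_variant <- function(x, ...) {
  cat("<intronic_variant> ", x$chrom, ":", x$pos, " ", x$ref, ">", x$alt,
      " -> ", x$transcript_id, " Int-", x$int_position,
      if (!x$in_scope) " [out of predictable range]", "\n", sep = "")
  invisible(x)
}

#' Unique key of a (variant, transcript) pair
#' @param iv An `intronic_variant`, or vectors via the `...` form below.
#' @return Character key `chrom:pos:ref:alt:transcript`.
#' @export
variant_key <- function(iv) {
  paste(iv$chrom, iv$pos, iv$ref, iv$alt, iv$transcript_id, sep = ":")
}

# Genomic (transcript-free) key; used for atomic train/test splitting.
genomic_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
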