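# Splice cis-element features for one (variant, transcript) pair.
#
# Window string convention: character 1 = Int-50, character 50 = Int-1, so
# Int-k lives at index 51-k. The predictable range Int-50..Int-3 is indices
# 1..48; the canonical AG occupies indices 49-50 and never enters the
# AG-gain/loss comparison.

# ---- AG dinucleotide gain / loss -------------------------------------------

# Start indices (window coords) of AG dinucleotides fully inside Int-50..Int-3.
.ag_positions <- function(window_seq) {
  hits <- gregexpr("(?=AG)", window_seq, perl = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  hits[hits + 1L <= WINDOW_LEN - INT_MIN + 1L]   # both bases at index <= 48
}

#' Detect creation or destruction of an AG dinucleotide
#'
#' Compares the AG-dinucleotide positions of the reference window with those
#' of the mutated window, restricted to positions fully inside Int-50..Int-3;
#' the canonical Int-2/Int-1 AG is excluded. A newly created upstream AG is a
#' candidate cryptic acceptor, the single most important signal for
#' splicing-pathogenicity in this position range.
#'
#' @param ctx An `acceptor_context`.
#' @param iv An `intronic_variant` mapping into `ctx`'s window.
#' @return Named integer vector `c(ag_gain = 0/1, ag_loss = 0/1)`.
#' @export
detect_ag_gain <- function(ctx, iv) {
  stopifnot(iv$transcript_id == ctx$transcript_id)
  ref_ag <- .ag_positions(ctx$window_seq)
  alt_ag <- .ag_positions(mutate_window(ctx$window_seq, iv$int_position, iv$sense_alt))
  c(ag_gain = as.integer(length(setdiff(alt_ag, ref_ag)) > 0L),
    ag_loss = as.integer(length(setdiff(ref_ag, alt_ag)) > 0L))
}

# ---- Shapiro-Senapathy-style percentile score ------------------------------

#' Shapiro-Senapathy percentile score
#'
#' Scores a sequence against a position frequency matrix on the classical
#' 0-100 percentile scale: `100 * (t - t_min) / (t_max - t_min)`, where `t`
#' is the sum over positions of the observed base's frequency and
#' `t_min`/`t_max` are the sums of per-position minimum/maximum frequencies.
#' The acceptor window is Int-14..Ex+1 (15 nt), the donor window Ex-3..Int+6
#' (9 nt); `N` bases contribute the position's mean frequency.
#'
#' @param seq Sequence whose length equals `nrow(fm)`.
#' @param fm A `frequency_matrix`.
#' @return Score in `[0, 100]`.
#' @export
shapiro_senapathy_score <- function(seq, fm) {
  b <- strsplit(toupper(seq), "")[[1L]]
  if (length(b) != nrow(fm)) {
    stop("sequence length ", length(b), " does not match matrix length ", nrow(fm))
  }
  col <- match(b, BASES)
  f <- ifelse(is.na(col), rowMeans(fm), fm[cbind(seq_along(b), col)])
  tmin <- sum(apply(fm, 1L, min))
  tmax <- sum(apply(fm, 1L, max))
  100 * (sum(f) - tmin) / (tmax - tmin)
}

# ---- weight-matrix log-odds acceptor strength ------------------------------

#' Train a weight-matrix log-odds model of acceptor strength
#'
#' A position weight-matrix model: per-position base frequencies with
#' pseudocount smoothing for the signal (and, optionally, the background)
#' class. Scoring is the sum over positions of
#' `log2(p_signal(base) / p_background(base))` — the classical PWM log-odds
#' in bits. This is the package's pluggable acceptor-strength scorer; any
#' per-position probability tables in the same TSV/JSON schema (e.g. derived
#' from an external acceptor-strength model) can be loaded in its place via
#' [read_wmm()].
#'
#' @param positives Character vector (>= 10) of equal-length signal sequences
#'   (the acceptor 23-mer Int-20..Int-1 + Ex+1..Ex+3 in the default pipeline).
#' @param background Optional character vector of background sequences; when
#'   `NULL` a uniform background is used.
#' @param pseudocount Positive smoothing constant.
#' @return A `wmm_model`.
#' @export
train_wmm <- function(positives, background = NULL, pseudocount = 0.5) {
  if (length(positives) < 10L) stop("need at least 10 positive sequences")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  sig <- estimate_frequency_matrix(positives, pseudocount)
  bg <- if (is.null(background)) {
    frequency_matrix(matrix(0.25, nrow(sig), 4L, dimnames = list(NULL, BASES)),
                     name = "uniform")
  } else {
    if (unique(nchar(background)) != nrow(sig)) {
      stop("background sequences must match positive length")
    }
    estimate_frequency_matrix(background, pseudocount)
  }
  wmm_model(sig, bg, pseudocount)
}

#' Assemble a weight-matrix model from frequency tables
#' @param signal,background `frequency_matrix` objects of equal length.
#' @param pseudocount Smoothing constant recorded for provenance.
#' @return A `wmm_model`.
#' @export
wmm_model <- function(signal, background, pseudocount = 0.5) {
  stopifnot(nrow(signal) == nrow(background))
  structure(list(signal = signal, background = background,
                 L = nrow(signal), pseudocount = pseudocount),
            class = "wmm_model")
}

#' @export
print.wmm_model <- function(x, ...) {
  cat("<wmm_model> L=", x$L, ", pseudocount=", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Per-position log-odds contributions of a sequence under a WMM
#' @param seq Sequence of length `model$L`.
#' @param model A `wmm_model`.
#' @return Numeric vector of per-position bits; `N` contributes 0.
#' @export
wmm_contributions <- function(seq, model) {
  b <- strsplit(toupper(seq), "")[[1L]]
  if (length(b) != model$L) {
    stop("sequence length ", length(b), " does not match model length ", model$L)
  }
  col <- match(b, BASES)
  idx <- cbind(seq_along(b), col)
  out <- numeric(length(b))
  ok <- !is.na(col)
  out[ok] <- log2(model$signal[idx[ok, , drop = FALSE]] /
                    model$background[idx[ok, , drop = FALSE]])
  out
}

#' Acceptor-strength log-odds score
#'
#' @param seq A 23-mer (Int-20..Int-1 plus the first 3 exonic nt) in the
#'   default pipeline; any sequence of the model's length is accepted.
#' @param model A `wmm_model` (see [train_wmm()], [default_wmm()]).
#' @return Log-odds score in bits.
#' @export
acceptor_wmm_score <- function(seq, model) {
  if (!inherits(model, "wmm_model")) {
    stop("unknown acceptor-strength model; supply a 'wmm_model' ",
         "(train_wmm(), default_wmm(), or read_wmm() on a JSON/TSV table)")
  }
  sum(wmm_contributions(seq, model))
}

#' The bundled default acceptor-strength model
#'
#' Consensus-derived synthetic 23-position signal frequencies over a uniform
#' background; see [default_matrix()] for provenance.
#' @return A `wmm_model`.
#' @export
default_wmm <- function() {
  wmm_model(default_matrix("acceptor23"),
            frequency_matrix(matrix(0.25, 23L, 4L, dimnames = list(NULL, BASES)),
                             name = "uniform"))
}

#' Serialize / load a weight-matrix model (JSON)
#' @param model A `wmm_model`.
#' @param path File path.
#' @return `read_wmm`: a `wmm_model` scoring bit-identically to the saved one.
#' @export
write_wmm <- function(model, path) {
  jsonlite::write_json(
    list(schema = "acceptorvar-wmm-1", L = model$L,
         pseudocount = model$pseudocount,
         signal = unclass(model$signal), background = unclass(model$background)),
    path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_wmm
#' @export
read_wmm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "acceptorvar-wmm-1")) {
    stop("unknown model format in ", path,
         "; accepted formats: acceptorvar-wmm-1 JSON")
  }
  mk <- function(m) frequency_matrix(matrix(as.numeric(m), ncol = 4L,
                                            dimnames = list(NULL, BASES)))
  wmm_model(mk(j$signal), mk(j$background), j$pseudocount)
}

# ---- branch point prediction -----------------------------------------------

#' Predict the branch point of an acceptor window
#'
#' Scans candidate branch-A positions in a configurable region (default
#' Int-44..Int-15) with a 7-position frequency matrix centred on the branch
#' adenosine (position 4 of the heptamer; yUnAy-like consensus). The score of
#' a candidate is the log2 likelihood ratio of its heptamer versus a uniform
#' background. Ties are broken toward the 3' splice site (smaller Int-k).
#'
#' @param window_seq 50-nt window string (or an `acceptor_context`).
#' @param bps_matrix 7-row `frequency_matrix`; default [default_matrix("bps7")].
#' @param region Integer `c(from, to)` of branch-A Int-k positions scanned,
#'   from the 5'-most (largest k) to the 3'-most.
#' @return List with `bps_position` (Int-k of the branch A, or `NA` when the
#'   region is infeasible), `bps_score` and `bps_heptamer`.
#' @export
predict_bps <- function(window_seq, bps_matrix = default_matrix("bps7"),
                        region = c(44L, 15L)) {
  if (inherits(window_seq, "acceptor_context")) window_seq <- window_seq$window_seq
  stopifnot(nrow(bps_matrix) == 7L)
  ks <- seq(max(region), min(region))            # large k -> small k
  # heptamer spans Int-(k+3)..Int-(k-3); keep candidates fully inside window
  ks <- ks[ks + 3L <= WINDOW_LEN & ks - 3L >= 1L]
  if (length(ks) == 0L) {
    return(list(bps_position = NA_integer_, bps_score = NA_real_,
                bps_heptamer = NA_character_, feasible = FALSE))
  }
  best_k <- NA_integer_; best_s <- -Inf; best_h <- NA_character_
  for (k in ks) {
    i <- int_k_index(k)
    hept <- substr(window_seq, i - 3L, i + 3L)
    s <- sum(wmm_contributions(hept, wmm_model(
      bps_matrix,
      frequency_matrix(matrix(0.25, 7L, 4L, dimnames = list(NULL, BASES))))))
    if (s > best_s || (s == best_s && k < best_k)) {   # tie -> closer to 3'ss
      best_k <- k; best_s <- s; best_h <- hept
    }
  }
  list(bps_position = best_k, bps_score = best_s, bps_heptamer = best_h,
       feasible = TRUE)
}

# ---- polypyrimidine tract ---------------------------------------------------

#' Count pyrimidines in the polypyrimidine tract
#'
#' Counts C/T in the window Int-25..Int-3 (configurable) of the reference
#' window, or of the mutated window when an `intronic_variant` is supplied.
#'
#' @param ctx An `acceptor_context` (or a 50-nt window string).
#' @param iv Optional `intronic_variant`; `NULL` scores the reference.
#' @param ppt_range Integer `c(from, to)` Int-k range, default `c(25, 3)`.
#' @return Integer pyrimidine count.
#' @export
count_ppt_pyrimidines <- function(ctx, iv = NULL, ppt_range = c(25L, 3L)) {
  w <- if (inherits(ctx, "acceptor_context")) ctx$window_seq else ctx
  if (!is.null(iv)) w <- mutate_window(w, iv$int_position, iv$sense_alt)
  i1 <- int_k_index(max(ppt_range)); i2 <- int_k_index(min(ppt_range))
  b <- strsplit(substr(w, i1, i2), "")[[1L]]
  sum(b %in% c("C", "T"))
}

# ---- RNA-binding-protein motif gain / loss ----------------------------------

#' Read an RBP motif table
#'
#' TSV with columns `motif` (4-10 nt, ACGT) and `protein`. A small synthetic
#' table ships with the package (`rbp_motifs_synthetic.tsv`) as a stand-in
#' for curated RBP motif databases, which are not redistributable.
#'
#' @param path TSV path; default the bundled synthetic table.
#' @return data.frame with columns `motif`, `protein`.
#' @export
read_motif_table <- function(path = .extdata("rbp_motifs_synthetic.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif", "protein") %in% names(df))) {
    stop("motif table needs columns 'motif' and 'protein'")
  }
  df$motif <- toupper(df$motif)
  bad <- nchar(df$motif) < 4L | nchar(df$motif) > 10L | grepl("[^ACGT]", df$motif)
  if (any(bad)) stop("motifs must be 4-10 nt of A/C/G/T; offender: ",
                     df$motif[bad][1L])
  df
}

# All start indices of `motif` in `seq` (overlapping occurrences).
.motif_starts <- function(seq, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  hits[hits > 0L]
}

#' Gain/loss of RBP motif occurrences at a variant
#'
#' Counts motif occurrences overlapping the variant position in the reference
#' versus the mutated window: gained occurrences are (motif, start) pairs
#' present only with the alternate allele, lost ones only with the reference.
#'
#' @param ctx An `acceptor_context`.
#' @param iv An `intronic_variant`.
#' @param motif_table data.frame from [read_motif_table()].
#' @return Named integer vector `c(rbp_gain = n, rbp_loss = m)`.
#' @export
rbp_motif_delta <- function(ctx, iv, motif_table = read_motif_table()) {
  if (nrow(motif_table) == 0L) {
    warning("empty motif table; motif features are 0")
    return(c(rbp_gain = 0L, rbp_loss = 0L))
  }
  pos <- int_k_index(iv$int_position)
  wref <- ctx$window_seq
  walt <- mutate_window(wref, iv$int_position, iv$sense_alt)
  gain <- 0L; loss <- 0L
  for (m in unique(motif_table$motif)) {
    L <- nchar(m)
    overlaps <- function(starts) starts[starts <= pos & starts + L - 1L >= pos]
    r <- overlaps(.motif_starts(wref, m))
    a <- overlaps(.motif_starts(walt, m))
    gain <- gain + length(setdiff(a, r))
    loss <- loss + length(setdiff(r, a))
  }
  c(rbp_gain = gain, rbp_loss = loss)
}

# ---- full feature vector -----------------------------------------------------

#' Feature configuration
#'
#' Bundles the score parameters used by [featurize()]: the acceptor and donor
#' percentile-score matrices, the acceptor-strength WMM, the branch-point
#' matrix and scan region, the PPT range, and the RBP motif table. Defaults
#' are the package's bundled consensus-derived synthetic parameters.
#'
#' @param acceptor_matrix,donor_matrix,bps_matrix `frequency_matrix` objects.
#' @param wmm A `wmm_model` acceptor-strength scorer.
#' @param bps_region,ppt_range Int-k ranges `c(from, to)`.
#' @param motif_table data.frame of RBP motifs.
#' @return A `feature_config` list.
#' @export
feature_config <- function(acceptor_matrix = default_matrix("acceptor15"),
                           donor_matrix = default_matrix("donor9"),
                           bps_matrix = default_matrix("bps7"),
                           wmm = default_wmm(),
                           bps_region = c(44L, 15L),
                           ppt_range = c(25L, 3L),
                           motif_table = read_motif_table()) {
  structure(list(acceptor_matrix = acceptor_matrix, donor_matrix = donor_matrix,
                 bps_matrix = bps_matrix, wmm = wmm, bps_region = bps_region,
                 ppt_range = ppt_range, motif_table = motif_table),
            class = "feature_config")
}

# Fixed feature schema; order is part of the classifier contract.
FEATURE_NAMES <- c(
  "int_position", "exon_length",
  "ag_gain", "ag_loss",
  "ss_acceptor_ref", "ss_acceptor_alt", "ss_acceptor_delta",
  "wmm_acceptor_ref", "wmm_acceptor_alt", "wmm_acceptor_delta",
  "ss_donor",
  "bps_position", "bps_score_ref", "bps_score_alt", "bps_score_delta",
  "ppt_count_ref", "ppt_count_alt", "ppt_count_delta",
  paste0("nt_int3_ref_", BASES), paste0("nt_int3_alt_", BASES),
  paste0("nt_ex1_", BASES),
  "rbp_gain", "rbp_loss"
)

#' Feature schema
#' @return Character vector of feature names in their fixed column order.
#' @export
feature_names <- function() FEATURE_NAMES

.one_hot <- function(base, prefix) {
  stats::setNames(as.numeric(BASES == base), paste0(prefix, BASES))
}

#' Compute the full feature vector of a (variant, transcript) pair
#'
#' Assembles every cis-element feature for the reference and alternate
#' alleles plus their deltas, in the fixed order of [feature_names()]:
#' AG gain/loss, acceptor percentile and log-odds strengths, the flanking
#' 5'ss donor percentile score, branch-point position/score, PPT pyrimidine
#' counts, Int-3 and Ex+1 nucleotide identities (one-hot), RBP motif
#' gain/loss, exon length and the Int-k position itself.
#'
#' @param ctx An `acceptor_context`.
#' @param iv An `intronic_variant` mapping into `ctx`.
#' @param config A [feature_config()].
#' @return Named numeric vector of length `length(feature_names())`.
#' @export
featurize <- function(ctx, iv, config = feature_config()) {
  stopifnot(inherits(ctx, "acceptor_context"), inherits(iv, "intronic_variant"),
            iv$transcript_id == ctx$transcript_id)
  wref <- ctx$window_seq
  walt <- mutate_window(wref, iv$int_position, iv$sense_alt)

  ag <- detect_ag_gain(ctx, iv)

  acc15 <- function(w) paste0(substr(w, 37L, 50L), ctx$exon_first_nt)
  ss_ref <- shapiro_senapathy_score(acc15(wref), config$acceptor_matrix)
  ss_alt <- shapiro_senapathy_score(acc15(walt), config$acceptor_matrix)

  acc23 <- function(w) paste0(substr(w, 31L, 50L), ctx$exon_first3)
  wmm_ref <- acceptor_wmm_score(acc23(wref), config$wmm)
  wmm_alt <- acceptor_wmm_score(acc23(walt), config$wmm)

  ss_donor <- if (is.na(ctx$donor_site_seq)) NA_real_ else
    shapiro_senapathy_score(ctx$donor_site_seq, config$donor_matrix)

  bref <- predict_bps(wref, config$bps_matrix, config$bps_region)
  # alt allele rescored at the reference branch position's heptamer
  balt <- predict_bps(walt, config$bps_matrix, config$bps_region)

  ppt_ref <- count_ppt_pyrimidines(ctx, NULL, config$ppt_range)
  ppt_alt <- count_ppt_pyrimidines(ctx, iv, config$ppt_range)

  nt_at <- function(w, k) substr(w, int_k_index(k), int_k_index(k))
  rbp <- rbp_motif_delta(ctx, iv, config$motif_table)

  fv <- c(
    int_position = as.numeric(iv$int_position),
    exon_length = as.numeric(ctx$exon_length),
    ag_gain = as.numeric(ag[["ag_gain"]]), ag_loss = as.numeric(ag[["ag_loss"]]),
    ss_acceptor_ref = ss_ref, ss_acceptor_alt = ss_alt,
    ss_acceptor_delta = ss_alt - ss_ref,
    wmm_acceptor_ref = wmm_ref, wmm_acceptor_alt = wmm_alt,
    wmm_acceptor_delta = wmm_alt - wmm_ref,
    ss_donor = ss_donor,
    bps_position = as.numeric(bref$bps_position %||% NA_real_),
    bps_score_ref = bref$bps_score, bps_score_alt = balt$bps_score,
    bps_score_delta = balt$bps_score - bref$bps_score,
    ppt_count_ref = as.numeric(ppt_ref), ppt_count_alt = as.numeric(ppt_alt),
    ppt_count_delta = as.numeric(ppt_alt - ppt_ref),
    .one_hot(nt_at(wref, 3L), "nt_int3_ref_"),
    .one_hot(nt_at(walt, 3L), "nt_int3_alt_"),
    .one_hot(ctx$exon_first_nt, "nt_ex1_"),
    rbp_gain = as.numeric(rbp[["rbp_gain"]]),
    rbp_loss = as.numeric(rbp[["rbp_loss"]])
  )
  stopifnot(identical(names(fv), FEATURE_NAMES))
  fv
}
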