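# Synthetic genome / annotation / variant fixtures with planted acceptor-site
# biology: terminal AG, pyrimidine-rich PPT, a branch-point heptamer with its
# branch A in a realistic upstream range, donor GT at each intron start.
# Pathogenic variants are drawn from effect classes that mirror the known
# determinants of acceptor-proximal pathogenicity (AG creation, PPT
# disruption, branch-A destruction, Int-3 pyrimidine-to-purine substitution);
# common variants are conservative pyrimidine swaps or deep substitutions
# that leave every planted element and the AG-dinucleotide set untouched.

PLANTED_HEPTAMER <- "TTTACTT"   # branch A at position 4; consensus-optimal

#' Simulation configuration
#'
#' @param n_genes Number of genes (one contig each).
#' @param exons_per_gene Exons per gene (>= 3, so internal exons exist).
#' @param intron_length Integer range of intron lengths; minimum 60 nt so a
#'   full 50-nt acceptor window plus the donor GT region always fits.
#' @param exon_length Integer range of exon lengths.
#' @param frac_minus Fraction of genes placed on the minus strand.
#' @param n_pathogenic,n_common Variant counts per class.
#' @param effect_mix Named fractions (summing to 1) of pathogenic effect
#'   classes `ag_gain`, `ppt`, `bps`, `int3`.
#' @param maf_range MAF range for common variants (uniform draw); MAFs are
#'   simulated only to exercise the MAF filter and carry no biology.
#' @param seed Integer seed (mandatory; the whole fixture is deterministic).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 60L, exons_per_gene = 4L,
                              intron_length = c(80L, 120L),
                              exon_length = c(60L, 150L),
                              frac_minus = 0.5,
                              n_pathogenic = 400L, n_common = 400L,
                              effect_mix = c(ag_gain = 0.40, ppt = 0.25,
                                             bps = 0.15, int3 = 0.20),
                              maf_range = c(0.01, 0.50),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible fixtures")
  if (exons_per_gene < 3L) stop("need >= 3 exons per gene for internal exons")
  if (min(intron_length) < 60L) stop("introns must be >= 60 nt")
  if (abs(sum(effect_mix) - 1) > 1e-9) stop("effect_mix fractions must sum to 1")
  if (!all(sort(names(effect_mix)) == c("ag_gain", "bps", "int3", "ppt"))) {
    stop("effect_mix needs fractions ag_gain, ppt, bps, int3")
  }
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 intron_length = as.integer(intron_length),
                 exon_length = as.integer(exon_length),
                 frac_minus = frac_minus,
                 n_pathogenic = as.integer(n_pathogenic),
                 n_common = as.integer(n_common),
                 effect_mix = effect_mix, maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# 50-nt acceptor tail, window coords (index 1 = Int-50 .. 50 = Int-1).
.build_tail50 <- function(branch_k) {
  b <- sample(BASES, 50L, replace = TRUE)
  ppt_idx <- 26:48                                  # Int-25..Int-3
  b[ppt_idx] <- sample(c("C", "T"), length(ppt_idx), replace = TRUE)
  hep_idx <- (48L - branch_k):(54L - branch_k)      # Int-(k+3)..Int-(k-3)
  b[hep_idx] <- strsplit(PLANTED_HEPTAMER, "")[[1L]]
  b[49:50] <- c("A", "G")
  paste(b, collapse = "")
}

#' Simulate a genome and annotation with planted acceptor biology
#'
#' Each gene sits on its own contig (half on each strand) with 100-nt flanks.
#' Every intron starts with the donor GTAAGT and ends with a 50-nt acceptor
#' tail carrying a pyrimidine-rich PPT (Int-25..Int-3, >= 70 percent C/T by
#' construction), one planted branch-point heptamer (branch A within
#' Int-30..Int-22) and the terminal AG.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` (`genome_store`), `models` (transcript models),
#'   `meta` (data.frame of planted element positions per acceptor window) and
#'   `cfg`.
#' @export
simulate_genome <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  seqs <- character(cfg$n_genes)
  names(seqs) <- sprintf("ctg%03d", seq_len(cfg$n_genes))
  models <- list()
  meta <- list()
  minus <- rep(c(FALSE, TRUE), length.out = cfg$n_genes)
  minus <- minus[sample.int(cfg$n_genes)]          # strand mix, deterministic
  if (cfg$frac_minus == 0) minus[] <- FALSE
  if (cfg$frac_minus == 1) minus[] <- TRUE
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- cfg$exons_per_gene
    ex_len <- sample(cfg$exon_length[1]:cfg$exon_length[2], n_ex, replace = TRUE)
    in_len <- sample(cfg$intron_length[1]:cfg$intron_length[2], n_ex - 1L,
                     replace = TRUE)
    branch_k <- sample(22:30, n_ex - 1L, replace = TRUE)
    parts <- character(0)
    sense_exons <- matrix(0L, n_ex, 2L)            # sense-gene coordinates
    cursor <- 100L
    parts <- c(parts, .rand_dna(100L))
    for (e in seq_len(n_ex)) {
      sense_exons[e, ] <- c(cursor + 1L, cursor + ex_len[e])
      parts <- c(parts, .rand_dna(ex_len[e]))
      cursor <- cursor + ex_len[e]
      if (e < n_ex) {
        filler <- in_len[e] - 6L - 50L
        parts <- c(parts, "GTAAGT", .rand_dna(filler), .build_tail50(branch_k[e]))
        cursor <- cursor + in_len[e]
      }
    }
    parts <- c(parts, .rand_dna(100L))
    sense_seq <- paste(parts, collapse = "")
    L <- nchar(sense_seq)
    tx <- sprintf("TX%03d", g)
    ctg <- names(seqs)[g]
    if (!minus[g]) {
      seqs[g] <- sense_seq
      exons <- sense_exons
      strand <- "+"
    } else {
      seqs[g] <- revcomp(sense_seq)
      exons <- cbind(L - sense_exons[, 2L] + 1L, L - sense_exons[, 1L] + 1L)
      strand <- "-"
    }
    models[[tx]] <- transcript_model(tx, ctg, strand, exons, coding = TRUE)
    for (e in 2L:(n_ex - 1L)) {                    # internal exons
      meta[[length(meta) + 1L]] <- data.frame(
        transcript_id = tx, chrom = ctg, strand = strand,
        intron_index = e - 1L, branch_k = branch_k[e - 1L],
        stringsAsFactors = FALSE)
    }
  }
  list(genome = genome_store(seqs), models = models,
       meta = do.call(rbind, meta), cfg = cfg)
}

#' Write transcript models as GTF
#'
#' Emits gene, transcript, exon and CDS lines with `gene_id`,
#' `transcript_id` and a `protein_coding` biotype, 1-based closed
#' coordinates.
#'
#' @param models List of `transcript_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (tm in models) {
    gid <- sub("^TX", "G", tm$transcript_id)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";',
                     gid, tm$transcript_id)
    span <- c(min(tm$exons), max(tm$exons))
    lines <- c(lines,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       tm$chrom, span[1], span[2], tm$strand,
                       sprintf('gene_id "%s"; gene_biotype "protein_coding";', gid)),
               sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tm$chrom, span[1], span[2], tm$strand, attrs))
    for (e in seq_len(nrow(tm$exons))) {
      for (type in c("exon", "CDS")) {
        lines <- c(lines, sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                                  tm$chrom, type, tm$exons[e, 1], tm$exons[e, 2],
                                  tm$strand, if (type == "CDS") "0" else ".",
                                  attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Build an intronic_variant directly from a window context and sense alleles.
.make_iv <- function(ctx, k, sense_alt) {
  pos <- int_k_genomic(ctx, k)
  sense_ref <- substr(ctx$window_seq, int_k_index(k), int_k_index(k))
  flip <- ctx$strand == "-"
  structure(list(
    chrom = ctx$chrom, pos = pos,
    ref = if (flip) revcomp(sense_ref) else sense_ref,
    alt = if (flip) revcomp(sense_alt) else sense_alt,
    transcript_id = ctx$transcript_id, int_position = as.integer(k),
    sense_ref = sense_ref, sense_alt = sense_alt,
    in_scope = k >= INT_MIN && k <= INT_MAX, ctx = ctx
  ), class = "intronic_variant")
}

# Window indices occupied by the planted heptamer for a given branch k.
.hep_idx <- function(branch_k) (48L - branch_k):(54L - branch_k)

#' Plant labeled variants on a simulated genome
#'
#' Pathogenic variants are drawn from the configured effect classes:
#' creation of an upstream AG dinucleotide, purine substitution in the PPT,
#' destruction of the planted branch A, or an Int-3 pyrimidine-to-G/A
#' substitution. Common variants are pyrimidine-to-pyrimidine swaps in the
#' PPT or deep (Int-50..Int-26) substitutions chosen to leave the
#' AG-dinucleotide set and all planted elements unchanged, with MAFs drawn
#' uniformly from the configured range. Every variant lies in Int-50..Int-3
#' of an internal exon, and every (chrom, pos) is used at most once.
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [simulate_genome()] (must carry the same config).
#' @return A `variant_table` with an extra `effect` column.
#' @export
plant_variants <- function(cfg, sim) {
  windows <- unlist(lapply(sim$models, acceptor_windows, genome = sim$genome),
                    recursive = FALSE)
  if (length(windows) == 0L) stop("simulated annotation yields no windows")
  wmeta <- sim$meta
  branch_of <- stats::setNames(
    wmeta$branch_k, paste(wmeta$transcript_id, wmeta$intron_index))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1000003L)

  n_eff <- round(cfg$n_pathogenic * cfg$effect_mix)
  n_eff[1L] <- cfg$n_pathogenic - sum(n_eff[-1L])   # rounding remainder
  effects <- rep(names(n_eff), n_eff)
  used_pos <- character(0)
  rows <- list()

  emit <- function(iv, label, effect) {
    maf <- if (label == "common") stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
           else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = iv$chrom, pos = iv$pos, ref = iv$ref, alt = iv$alt,
      maf = maf, label = label, effect = effect,
      transcript_id = iv$transcript_id, int_position = iv$int_position,
      stringsAsFactors = FALSE)
    used_pos <<- c(used_pos, paste(iv$chrom, iv$pos))
  }
  pos_free <- function(ctx, k) {
    !(paste(ctx$chrom, int_k_genomic(ctx, k)) %in% used_pos)
  }
  draw <- function(make_candidate, label, effect, max_tries = 2000L) {
    for (t in seq_len(max_tries)) {
      ctx <- windows[[sample.int(length(windows), 1L)]]
      hk <- branch_of[[paste(ctx$transcript_id, ctx$intron_index)]]
      cand <- make_candidate(ctx, hk)
      if (is.null(cand)) next
      if (!pos_free(ctx, cand$k)) next
      iv <- .make_iv(ctx, cand$k, cand$alt)
      if (!is.null(cand$check) && !cand$check(iv)) next
      emit(iv, label, effect)
      return(invisible(TRUE))
    }
    stop("could not place a ", effect, " variant after ", max_tries,
         " tries; reduce variant counts or enlarge the genome")
  }
  w_at <- function(ctx, idx) substr(ctx$window_seq, idx, idx)

  for (eff in effects) {
    make <- switch(eff,
      ag_gain = function(ctx, hk) {
        hep <- .hep_idx(hk)
        i <- sample(1:47, 1L)                       # AG start, fully in-scope
        a <- w_at(ctx, i); b <- w_at(ctx, i + 1L)
        if (a == "A" && b != "G" && !((i + 1L) %in% hep)) {
          list(k = 51L - (i + 1L), alt = "G",
               check = function(iv) detect_ag_gain(iv$ctx, iv)[["ag_gain"]] == 1L)
        } else if (b == "G" && a != "A" && !(i %in% hep)) {
          list(k = 51L - i, alt = "A",
               check = function(iv) detect_ag_gain(iv$ctx, iv)[["ag_gain"]] == 1L)
        } else NULL
      },
      ppt = function(ctx, hk) {
        idx <- setdiff(26:47, .hep_idx(hk))         # spare Int-3 for int3 class
        i <- sample(idx, 1L)
        if (!w_at(ctx, i) %in% c("C", "T")) return(NULL)
        list(k = 51L - i, alt = "A",
             check = function(iv) all(detect_ag_gain(iv$ctx, iv) == 0L))
      },
      bps = function(ctx, hk) {
        i <- int_k_index(hk)                        # the branch A
        if (w_at(ctx, i) != "A") return(NULL)
        list(k = hk, alt = sample(c("C", "T"), 1L),
             check = function(iv) all(detect_ag_gain(iv$ctx, iv) == 0L))
      },
      int3 = function(ctx, hk) {
        if (!w_at(ctx, 48L) %in% c("C", "T")) return(NULL)
        list(k = 3L, alt = sample(c("G", "A"), 1L),
             check = function(iv) all(detect_ag_gain(iv$ctx, iv) == 0L))
      })
    draw(make, "pathogenic", eff)
  }
  for (i in seq_len(cfg$n_common)) {
    deep <- stats::runif(1) < 0.5
    make <- if (deep) {
      function(ctx, hk) {
        i <- sample(setdiff(1:25, .hep_idx(hk)), 1L)
        alt <- sample(setdiff(BASES, w_at(ctx, i)), 1L)
        list(k = 51L - i, alt = alt,
             check = function(iv) all(detect_ag_gain(iv$ctx, iv) == 0L))
      }
    } else {
      function(ctx, hk) {
        idx <- setdiff(26:48, .hep_idx(hk))
        i <- sample(idx, 1L)
        b <- w_at(ctx, i)
        if (!b %in% c("C", "T")) return(NULL)
        list(k = 51L - i, alt = if (b == "C") "T" else "C",
             check = function(iv) all(detect_ag_gain(iv$ctx, iv) == 0L))
      }
    }
    draw(make, "common", "neutral")
  }
  df <- do.call(rbind, rows)
  vt <- variant_table(df$chrom, df$pos, df$ref, df$alt, df$maf, df$label)
  vt$effect <- df$effect
  vt$transcript_id <- df$transcript_id
  vt$int_position <- df$int_position
  vt
}

#' Simulate a complete fixture
#'
#' Convenience wrapper: genome + annotation + planted labeled variants,
#' optionally written to disk as FASTA, GTF, VCF and a TSV label sidecar.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory.
#' @return List with `genome`, `models`, `windows`, `variants`, `meta`,
#'   `cfg`, and (when `dir` is given) the file `paths`.
#' @export
simulate_fixture <- function(cfg, dir = NULL) {
  sim <- simulate_genome(cfg)
  variants <- plant_variants(cfg, sim)
  windows <- unlist(lapply(sim$models, acceptor_windows, genome = sim$genome),
                    recursive = FALSE)
  out <- list(genome = sim$genome, models = sim$models, windows = windows,
              variants = variants, meta = sim$meta, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  vcf = file.path(dir, "variants.vcf"),
                  tsv = file.path(dir, "variants.tsv"))
    write_genome(sim$genome, paths$fasta)
    write_gtf(sim$models, paths$gtf)
    write_variants_vcf(variants, paths$vcf, sim$genome)
    write_variants_tsv(variants, paths$tsv)
    out$paths <- paths
  }
  out
}
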