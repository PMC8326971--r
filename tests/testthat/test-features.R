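# Cis-element features: AG gain/loss, percentile and log-odds splice-site
# scores, branch point, PPT, RBP motifs, and the assembled feature vector.

# Build an acceptor_context + intronic_variant pair around an explicit
# window string, bypassing genome plumbing.
mock_pair <- function(window_seq, k, sense_alt, exon_first3 = "GCA",
                      donor = "CAGGTAAGT", exon_length = 90L) {
  ctx <- structure(list(
    transcript_id = "TXM", chrom = "cm", strand = "+", exon_index = 2L,
    intron_index = 1L, window_seq = window_seq,
    exon_first_nt = substr(exon_first3, 1, 1), exon_first3 = exon_first3,
    exon_length = exon_length, donor_site_seq = donor,
    int1_genomic = 1000L,
    canonical_ag = substr(window_seq, 49, 50) == "AG"),
    class = "acceptor_context")
  i <- 51L - k
  sense_ref <- substr(window_seq, i, i)
  iv <- structure(list(
    chrom = "cm", pos = 1000L - (k - 1L), ref = sense_ref, alt = sense_alt,
    transcript_id = "TXM", int_position = as.integer(k),
    sense_ref = sense_ref, sense_alt = sense_alt, in_scope = TRUE, ctx = NULL),
    class = "intronic_variant")
  list(ctx = ctx, iv = iv)
}

rand_window <- function() {
  w <- paste(sample(c("A", "C", "G", "T"), 48, TRUE), collapse = "")
  paste0(w, "AG")
}

test_that("AG creation and destruction are detected by definition", {
  base <- paste(rep("T", 48), collapse = "")
  # plant 'A' at index 20; mutate index 21 T->G  => new AG at 20
  w <- paste0(substr(base, 1, 19), "A", substr(base, 21, 48), "AG")
  p <- mock_pair(w, 51 - 21, "G")
  expect_equal(detect_ag_gain(p$ctx, p$iv),
               c(ag_gain = 1L, ag_loss = 0L))
  # T->C inside a poly-T run cannot create an AG
  p2 <- mock_pair(w, 51 - 30, "C")
  expect_equal(detect_ag_gain(p2$ctx, p2$iv), c(ag_gain = 0L, ag_loss = 0L))
  # destroying an existing AG is a loss
  w3 <- paste0(substr(base, 1, 19), "AG", substr(base, 22, 48), "AG")
  p3 <- mock_pair(w3, 51 - 21, "T")
  expect_equal(detect_ag_gain(p3$ctx, p3$iv), c(ag_gain = 0L, ag_loss = 1L))
  # the canonical Int-2/Int-1 AG never counts: destroying it is no 'loss'
  p4 <- mock_pair(w, 2, "C")
  expect_equal(detect_ag_gain(p4$ctx, p4$iv), c(ag_gain = 0L, ag_loss = 0L))
})

test_that("AG gain/loss agrees with an exhaustive string-scan oracle", {
  set.seed(101)
  for (rep in 1:200) {
    w <- rand_window()
    k <- sample(3:50, 1)
    i <- 51 - k
    ref <- substr(w, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      p <- mock_pair(w, k, alt)
      got <- detect_ag_gain(p$ctx, p$iv)
      walt <- paste0(substr(w, 1, i - 1), alt, substr(w, i + 1, 50))
      ref_set <- ag_scan_oracle(w); alt_set <- ag_scan_oracle(walt)
      expect_equal(unname(got), c(
        as.integer(length(setdiff(alt_set, ref_set)) > 0),
        as.integer(length(setdiff(ref_set, alt_set)) > 0)))
    }
  }
})

test_that("percentile score hits its bounds and a hand-computed value", {
  fm <- frequency_matrix(rbind(c(A = 0.4, C = 0.3, G = 0.2, T = 0.1),
                               c(A = 0.1, C = 0.2, G = 0.3, T = 0.4)))
  expect_equal(shapiro_senapathy_score("AT", fm), 100)   # max base everywhere
  expect_equal(shapiro_senapathy_score("TA", fm), 0)     # min base everywhere
  # "CA": t = 0.3 + 0.1 = 0.4; tmin = 0.2, tmax = 0.8 -> 100*(0.2)/(0.6)
  expect_equal(shapiro_senapathy_score("CA", fm), 100 * 0.2 / 0.6)
  expect_error(shapiro_senapathy_score("CAT", fm), "length")
})

test_that("percentile score is monotone in per-position base frequency", {
  fm <- default_matrix("acceptor15")
  set.seed(7)
  for (rep in 1:50) {
    s <- sample(c("A", "C", "G", "T"), 15, TRUE)
    sc <- shapiro_senapathy_score(paste(s, collapse = ""), fm)
    i <- sample(15, 1)
    higher <- names(which(fm[i, ] >= fm[i, s[i]]))
    s2 <- s; s2[i] <- sample(higher, 1)
    expect_gte(shapiro_senapathy_score(paste(s2, collapse = ""), fm), sc)
  }
})

test_that("WMM log-odds has the closed-form and additivity properties", {
  seqs <- rep(paste(rep("ACGT", 6), collapse = ""), 12)  # 24-mers, identical
  m <- train_wmm(seqs, pseudocount = 0.5)
  # observed base frequency (12+0.5)/(12+4*0.5) per position, uniform bg
  expected <- 24 * log2((12.5 / 14) / 0.25)
  expect_equal(acceptor_wmm_score(seqs[1], m), expected, tolerance = 1e-12)
  # per-position contributions sum to the total
  s <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
  expect_equal(sum(wmm_contributions(s, m)), acceptor_wmm_score(s, m))
  # signal == background => 0 for every sequence
  m0 <- wmm_model(m$signal, m$signal)
  expect_equal(acceptor_wmm_score(s, m0), 0)
  # pseudocount -> 0 limit: observed base frequency -> 1
  m_tiny <- train_wmm(seqs, pseudocount = 1e-9)
  expect_equal(max(m_tiny$signal), 1, tolerance = 1e-8)
})

test_that("WMM mean score over its own background is near zero", {
  set.seed(31)
  bg <- replicate(400, paste(sample(c("A", "C", "G", "T"), 23, TRUE,
                                    prob = c(0.2, 0.3, 0.3, 0.2)), collapse = ""))
  m <- train_wmm(bg[1:200], background = bg[1:200], pseudocount = 0.5)
  scores <- vapply(bg[201:400], acceptor_wmm_score, numeric(1), model = m)
  expect_lt(abs(mean(scores)), 0.5)   # 0 +/- sampling error
})

test_that("WMM serialization round-trips bit-identically", {
  fx <- small_fixture()
  seqs <- vapply(fx$windows[1:20], function(w)
    paste0(substr(w$window_seq, 31, 50), w$exon_first3), character(1))
  m <- train_wmm(seqs, pseudocount = 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_wmm(m, f)
  m2 <- read_wmm(f)
  s <- seqs[1]
  expect_identical(acceptor_wmm_score(s, m), acceptor_wmm_score(s, m2))
  expect_error(read_wmm(withr::local_tempfile(lines = '{"schema":"x"}',
                                              fileext = ".json")),
               "unknown model format")
})

test_that("branch point is recovered where planted, ties break 3'-ward", {
  set.seed(5)
  # plant the consensus-optimal heptamer with branch A at Int-25 in an
  # otherwise pyrimidine-poor background
  b <- rep("G", 50)
  b[(48 - 25):(54 - 25)] <- strsplit("TTTACTT", "")[[1]]
  b[49:50] <- c("A", "G")
  w <- paste(b, collapse = "")
  res <- predict_bps(w)
  expect_equal(res$bps_position, 25L)
  expect_equal(res$bps_heptamer, "TTTACTT")
  # identical heptamers at Int-30 and Int-20: tie goes toward the 3'ss
  b2 <- rep("G", 50)
  b2[(48 - 30):(54 - 30)] <- strsplit("TTTACTT", "")[[1]]
  b2[(48 - 20):(54 - 20)] <- strsplit("TTTACTT", "")[[1]]
  w2 <- paste(b2, collapse = "")
  expect_equal(predict_bps(w2)$bps_position, 20L)
  # all-purine window scores below any planted-motif window
  expect_lt(predict_bps(paste(rep("A", 50), collapse = ""))$bps_score,
            res$bps_score)
  # region shorter than the motif -> none-result with flag
  none <- predict_bps(w, region = c(2L, 1L))
  expect_false(none$feasible)
  expect_true(is.na(none$bps_position))
})

test_that("PPT pyrimidine counting covers Int-25..Int-3 with single-base deltas", {
  all_t <- paste(rep("T", 50), collapse = "")
  all_a <- paste(rep("A", 50), collapse = "")
  expect_equal(count_ppt_pyrimidines(all_t), 23L)
  expect_equal(count_ppt_pyrimidines(all_a), 0L)
  p <- mock_pair(all_t, 10, "A")   # T->A at Int-10
  expect_equal(count_ppt_pyrimidines(p$ctx, NULL) -
                 count_ppt_pyrimidines(p$ctx, p$iv), 1L)
  p2 <- mock_pair(all_t, 40, "A")  # outside the PPT window
  expect_equal(count_ppt_pyrimidines(p2$ctx, p2$iv), 23L)
})

test_that("RBP motif deltas match a brute-force scanner", {
  tab <- data.frame(motif = c("TTTT", "GAAG"), protein = c("P1", "P2"))
  # A->T completing a TTTT run overlapping the variant
  w <- paste0(paste(rep("C", 20), collapse = ""), "TTATT",
              paste(rep("C", 23), collapse = ""), "AG")
  p <- mock_pair(w, 51 - 23, "T")   # index 23 is the 'A' in TTATT
  d <- rbp_motif_delta(p$ctx, p$iv, tab)
  expect_gte(d[["rbp_gain"]], 1L)
  expect_equal(d[["rbp_loss"]], 0L)
  # variant not overlapping any occurrence
  p2 <- mock_pair(w, 51 - 5, "T")
  expect_equal(unname(rbp_motif_delta(p2$ctx, p2$iv, tab)),
               c(0L, 0L))
  # randomized agreement with an exhaustive occurrence scanner
  set.seed(77)
  scan <- function(seq, motif) {
    out <- integer(0)
    for (i in 1:(nchar(seq) - nchar(motif) + 1)) {
      if (substr(seq, i, i + nchar(motif) - 1) == motif) out <- c(out, i)
    }
    out
  }
  motifs <- c("TTTT", "CTCT", "GGAG", "ATTTA")
  tab2 <- data.frame(motif = motifs, protein = motifs)
  for (rep in 1:60) {
    w <- rand_window()
    k <- sample(3:50, 1)
    i <- 51 - k
    alt <- sample(setdiff(c("A", "C", "G", "T"), substr(w, i, i)), 1)
    p <- mock_pair(w, k, alt)
    got <- rbp_motif_delta(p$ctx, p$iv, tab2)
    walt <- paste0(substr(w, 1, i - 1), alt, substr(w, i + 1, 50))
    gain <- 0L; loss <- 0L
    for (m in motifs) {
      ov <- function(st) st[st <= i & st + nchar(m) - 1 >= i]
      r <- ov(scan(w, m)); a <- ov(scan(walt, m))
      gain <- gain + length(setdiff(a, r)); loss <- loss + length(setdiff(r, a))
    }
    expect_equal(unname(got), c(gain, loss))
  }
})

test_that("featurize assembles a stable, deterministic schema", {
  fx <- small_fixture()
  v <- fx$variants[fx$variants$label == "common", ][1, ]
  iv <- map_variant(v$chrom, v$pos, v$ref, v$alt, fx$windows, fx$genome)[[1]]
  fv <- featurize(iv$ctx, iv)
  expect_identical(names(fv), feature_names())
  expect_identical(fv, featurize(iv$ctx, iv))       # bit-identical repeats
  # one-hot groups each sum to exactly 1
  for (g in c("nt_int3_ref_", "nt_int3_alt_", "nt_ex1_")) {
    expect_equal(sum(fv[paste0(g, c("A", "C", "G", "T"))]), 1)
  }
  # schema identical across many variants
  ds <- fx$dataset
  expect_identical(colnames(dataset_matrix(ds)), feature_names())
})

test_that("planted canonical acceptors score high and deep variants are quiet", {
  fx <- small_fixture()
  deep <- fx$variants[fx$variants$effect == "neutral" &
                        fx$variants$int_position > 25, ][1, ]
  iv <- map_variant(deep$chrom, deep$pos, deep$ref, deep$alt,
                    fx$windows, fx$genome)[[1]]
  fv <- featurize(iv$ctx, iv)
  expect_equal(unname(fv["ag_gain"]), 0)
  expect_gte(unname(fv["ppt_count_ref"]), 16)
  expect_gt(unname(fv["ss_acceptor_ref"]), 50)       # planted signal is strong
  # alt-allele G at Int-3 flips the one-hot
  int3 <- fx$variants[fx$variants$effect == "int3" & fx$variants$alt != "", ]
  int3 <- int3[1, ]
  iv3 <- map_variant(int3$chrom, int3$pos, int3$ref, int3$alt,
                     fx$windows, fx$genome)[[1]]
  fv3 <- featurize(iv3$ctx, iv3)
  expect_equal(unname(fv3[paste0("nt_int3_alt_", iv3$sense_alt)]), 1)
})

test_that("featurization is strand symmetric", {
  fx <- small_fixture()
  flipped <- flip_fixture(fx$genome, fx$models)
  w2 <- unlist(lapply(flipped$models, acceptor_windows, genome = flipped$genome),
               recursive = FALSE)
  idx <- seq(1, nrow(fx$variants), by = 17)
  for (i in idx) {
    v <- fx$variants[i, ]
    iv1 <- map_variant(v$chrom, v$pos, v$ref, v$alt, fx$windows, fx$genome)[[1]]
    L <- contig_lengths(fx$genome)[[v$chrom]]
    pos2 <- L - v$pos + 1L
    iv2 <- map_variant(v$chrom, pos2, rc_oracle(v$ref), rc_oracle(v$alt),
                       w2, flipped$genome)[[1]]
    expect_equal(featurize(iv2$ctx, iv2), featurize(iv1$ctx, iv1))
  }
})
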