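# Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# Independent reverse-complement oracle (no Biostrings).
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# Hand-built toy genome: two '+' transcripts sharing exons 2..3 on one
# contig (so one acceptor window is covered by both), plus a '-' transcript
# on a second contig. Layout is explicit so tests can slice strings directly.
toy_fixture <- function() memo("toy", {
  set.seed(42)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # contig c1 ('+'): flank20 ex1(30) in1(60) ex2(40) in2(60) ex3(30) flank20
  tail50 <- function() {
    b <- sample(c("A", "C", "G", "T"), 50, TRUE)
    b[26:48] <- sample(c("C", "T"), 23, TRUE)
    b[18:24] <- strsplit("TTTACTT", "")[[1]]   # branch A at Int-30
    b[49:50] <- c("A", "G")
    paste(b, collapse = "")
  }
  intron <- function() paste0("GTAAGT", rand(4), tail50())
  c1 <- paste0(rand(20), rand(30), intron(), rand(40), intron(), rand(30), rand(20))
  ex <- rbind(c(21, 50), c(111, 150), c(211, 240))
  tma <- transcript_model("TXA", "c1", "+", ex)
  tmb <- transcript_model("TXB", "c1", "+", rbind(c(31, 50), ex[2:3, ]))
  # contig c2 ('-'): mirror of a sense gene
  sense <- paste0(rand(20), rand(30), intron(), rand(40), intron(), rand(30), rand(20))
  c2 <- rc_oracle(sense)
  L <- nchar(sense)
  flip <- function(ival) c(L - ival[2] + 1, L - ival[1] + 1)
  tmc <- transcript_model("TXC", "c2", "-", t(apply(ex, 1, flip)))
  genome <- genome_store(c(c1 = c1, c2 = c2))
  models <- list(TXA = tma, TXB = tmb, TXC = tmc)
  windows <- unlist(lapply(models, acceptor_windows, genome = genome),
                    recursive = FALSE)
  list(genome = genome, models = models, windows = windows,
       c1 = c1, c2 = c2, sense = sense, exons = ex)
})

# Small simulated fixture for module-level tests (fast).
small_fixture <- function() memo("small", {
  cfg <- simulation_config(n_genes = 30L, n_pathogenic = 100L,
                           n_common = 100L, seed = 11L)
  fx <- simulate_fixture(cfg)
  fx$dataset <- build_dataset(fx$variants, fx$windows, fx$genome)
  fx
})

# Full-size fixture under the study conditions (n = 400+400, seed 17).
full_fixture <- function() memo("full", {
  cfg <- simulation_config(seed = 17L)
  fx <- simulate_fixture(cfg)
  fx$dataset <- build_dataset(fx$variants, fx$windows, fx$genome)
  fx
})

# Reverse-complement an entire fixture: flip every contig and annotation.
flip_fixture <- function(genome, models) {
  lens <- contig_lengths(genome)
  seqs <- vapply(names(lens), function(ct)
    rc_oracle(fetch_seq(genome, ct, 1, lens[[ct]], "+")), character(1))
  genome2 <- genome_store(seqs)
  models2 <- lapply(models, function(tm) {
    L <- lens[[tm$chrom]]
    ex <- cbind(L - tm$exons[, 2] + 1L, L - tm$exons[, 1] + 1L)
    transcript_model(tm$transcript_id, tm$chrom,
                     if (tm$strand == "+") "-" else "+", ex, tm$coding)
  })
  list(genome = genome2, models = models2)
}

# Brute-force AG-position scan of a window (string oracle).
ag_scan_oracle <- function(w) {
  idx <- integer(0)
  for (i in 1:(nchar(w) - 1)) {
    if (substr(w, i, i + 1) == "AG" && i + 1 <= 48) idx <- c(idx, i)
  }
  idx
}

# Independent implementations of the seven guideline measures.
metrics_oracle <- function(tp, fp, fn, tn) {
  tot <- tp + fp + fn + tn
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(
    accuracy = if (tot > 0) (tp + tn) / tot else NA_real_,
    precision = prec,
    recall = rec,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    mcc = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    })
}

# Mann-Whitney pair-counting AUROC oracle.
auroc_pairs_oracle <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
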