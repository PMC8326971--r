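# Genome/annotation reading, acceptor-window extraction, Int-k mapping.

test_that("fetch_seq slices and reverse-complements correctly", {
  g <- genome_store(c(t1 = "ACGTAC"))
  expect_equal(fetch_seq(g, "t1", 1, 4, "+"), "ACGT")
  expect_equal(fetch_seq(g, "t1", 1, 4, "-"), "ACGT")  # palindromic 4-mer
  expect_equal(fetch_seq(g, "t1", 2, 4, "-"), rc_oracle("CGT"))
  expect_equal(fetch_seq(g, "t1", 2, 4, "-"), "ACG")
  expect_error(fetch_seq(g, "nope", 1, 2), "contig not found.*nope")
  expect_error(fetch_seq(g, "t1", 0, 3), "out of bounds")
  expect_warning(genome_store(c(x = "ACXT")), "non-ACGTN")
})

test_that("FASTA round-trips through read_genome", {
  fx <- toy_fixture()
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(fx$genome, fa)
  g2 <- read_genome(fa)
  expect_equal(contig_lengths(g2), contig_lengths(fx$genome))
  expect_equal(fetch_seq(g2, "c1", 5, 60), fetch_seq(fx$genome, "c1", 5, 60))
})

test_that("read_annotation recovers transcript structure from GTF", {
  fx <- toy_fixture()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fx$models, gtf)
  models <- read_annotation(gtf)
  expect_setequal(names(models), c("TXA", "TXB", "TXC"))
  expect_true(all(vapply(models, function(m) m$coding, logical(1))))
  expect_equal(models$TXA$exons, fx$models$TXA$exons, ignore_attr = TRUE)
  expect_equal(models$TXC$strand, "-")
  # exon order is genomically ascending; transcript order reverses on '-'
  ex_tx <- acceptorvar:::exons_in_transcript_order(models$TXC)
  expect_true(ex_tx[1, "start"] > ex_tx[3, "start"])
})

test_that("simulated annotation has the configured number of coding models", {
  fx <- small_fixture()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fx$models, gtf)
  models <- read_annotation(gtf)
  expect_length(models, 30L)
  expect_true(all(vapply(models, function(m) m$coding, logical(1))))
})

test_that("acceptor_windows yields one context per internal exon", {
  fx <- toy_fixture()
  expect_length(acceptor_windows(fx$models$TXA, fx$genome), 1L)  # 3 exons
  # 5-exon transcript -> 3 internal exons
  sim <- simulate_genome(simulation_config(n_genes = 2L, exons_per_gene = 5L,
                                           n_pathogenic = 1L, n_common = 1L,
                                           seed = 3L))
  expect_length(acceptor_windows(sim$models[[1]], sim$genome), 3L)
  # fewer than 3 exons -> no internal exon
  tm2 <- transcript_model("T2", "c1", "+", fx$exons[1:2, ])
  expect_length(acceptor_windows(tm2, fx$genome), 0L)
})

test_that("window sequence matches a direct string slice on both strands", {
  fx <- toy_fixture()
  wa <- acceptor_windows(fx$models$TXA, fx$genome)[[1]]
  # '+': exon 2 starts at 111; window is genomic [61, 110]
  expect_equal(wa$window_seq, substr(fx$c1, 61, 110))
  expect_equal(wa$exon_first_nt, substr(fx$c1, 111, 111))
  expect_equal(wa$exon_length, 40L)
  expect_true(wa$canonical_ag)
  expect_equal(wa$int1_genomic, 110L)
  # '-': window equals revcomp of the genomic 50-mer downstream of exon end
  wc <- acceptor_windows(fx$models$TXC, fx$genome)[[1]]
  e2 <- fx$models$TXC$exons[2, ]
  expect_equal(wc$window_seq,
               rc_oracle(fetch_seq(fx$genome, "c2", e2[["end"]] + 1,
                                   e2[["end"]] + 50, "+")))
  # and equals the sense-gene construction directly
  expect_equal(wc$window_seq, substr(fx$sense, 61, 110))
})

test_that("introns shorter than 50 nt are skipped", {
  g <- genome_store(c(s = paste(rep("ACGT", 70), collapse = "")))
  tm <- transcript_model("TS", "s", "+",
                         rbind(c(1, 30), c(61, 90), c(171, 200), c(231, 260)))
  expect_message(w <- acceptor_windows(tm, g), "shorter than 50")
  expect_length(w, 1L)   # exon 2's 30-nt intron skipped; exon 3's 80-nt kept
  expect_equal(w[[1]]$exon_index, 3L)
})

test_that("map_variant computes Int-k and sense alleles", {
  fx <- toy_fixture()
  # TXB's window (exon2 upstream intron) coincides with TXA's
  wa <- Filter(function(w) w$transcript_id == "TXA", fx$windows)[[1]]
  # Int-3 by definition: 3 nt upstream of the internal exon start
  pos <- 111 - 3
  ref <- substr(fx$c1, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ivs <- map_variant("c1", pos, ref, alt, fx$windows, fx$genome)
  expect_length(ivs, 2L)   # overlapping TXA and TXB transcripts
  expect_setequal(vapply(ivs, function(iv) iv$transcript_id, character(1)),
                  c("TXA", "TXB"))
  expect_true(all(vapply(ivs, function(iv) iv$int_position, integer(1)) == 3L))
  # 51 nt upstream is outside every window
  pos51 <- 111 - 51
  ref51 <- substr(fx$c1, pos51, pos51)
  expect_length(map_variant("c1", pos51, ref51,
                            setdiff(c("A", "C", "G", "T"), ref51)[1],
                            fx$windows, fx$genome), 0L)
  # reference mismatch is an error naming both bases
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[2]
  expect_error(map_variant("c1", pos, wrong, ref, fx$windows, fx$genome),
               "mismatch")
  # minus strand: genomic alleles are reverse-complemented to sense
  wc <- Filter(function(w) w$transcript_id == "TXC", fx$windows)[[1]]
  posm <- int_k_genomic(wc, 10L)
  refm <- fetch_seq(fx$genome, "c2", posm, posm)
  altm <- setdiff(c("A", "C", "G", "T"), refm)[1]
  ivm <- map_variant("c2", posm, refm, altm, fx$windows, fx$genome)
  expect_length(ivm, 1L)
  expect_equal(ivm[[1]]$int_position, 10L)
  expect_equal(ivm[[1]]$sense_ref, rc_oracle(refm))
  expect_equal(ivm[[1]]$sense_alt, rc_oracle(altm))
})

test_that("indels and ambiguity codes are rejected", {
  fx <- toy_fixture()
  expect_error(map_variant("c1", 100, "AT", "A", fx$windows, fx$genome),
               "single-nucleotide")
  expect_error(variant_table("c1", 100, "A", "AT"), "single-nucleotide")
})

test_that("Int-k round-trip: every window position maps back to its k", {
  fx <- small_fixture()
  for (ctx in fx$windows[seq(1, length(fx$windows), by = 7)]) {
    for (k in c(3L, 17L, 50L)) {
      pos <- int_k_genomic(ctx, k)
      ref <- fetch_seq(fx$genome, ctx$chrom, pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      ivs <- map_variant(ctx$chrom, pos, ref, alt, fx$windows, fx$genome)
      own <- Filter(function(iv) iv$transcript_id == ctx$transcript_id &&
                      identical(iv$ctx$intron_index, ctx$intron_index), ivs)
      expect_length(own, 1L)
      expect_equal(own[[1]]$int_position, k)
      # window_seq at index 51-k equals the sense ref allele
      expect_equal(substr(ctx$window_seq, 51 - k, 51 - k), own[[1]]$sense_ref)
    }
  }
})

test_that("strand symmetry: flipping the whole fixture preserves windows", {
  fx <- small_fixture()
  flipped <- flip_fixture(fx$genome, fx$models)
  w2 <- unlist(lapply(flipped$models, acceptor_windows, genome = flipped$genome),
               recursive = FALSE)
  key <- function(w) paste(w$transcript_id, w$intron_index)
  w1 <- fx$windows[order(vapply(fx$windows, key, character(1)))]
  w2 <- w2[order(vapply(w2, key, character(1)))]
  expect_equal(length(w1), length(w2))
  for (i in seq_along(w1)) {
    expect_equal(w2[[i]]$window_seq, w1[[i]]$window_seq)
    expect_equal(w2[[i]]$exon_first3, w1[[i]]$exon_first3)
    expect_equal(w2[[i]]$donor_site_seq, w1[[i]]$donor_site_seq)
  }
})

test_that("variant files round-trip through TSV and VCF", {
  fx <- small_fixture()
  v <- fx$variants
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_tsv(v, tsv)
  write_variants_vcf(v, vcf, fx$genome)
  vt <- read_variants(tsv)
  vv <- read_variants(vcf)
  for (rv in list(vt, vv)) {
    expect_equal(nrow(rv), nrow(v))
    expect_equal(rv$pos, v$pos)
    expect_equal(rv$ref, v$ref)
    expect_equal(rv$alt, v$alt)
  }
  expect_equal(vt$label, v$label)
  expect_equal(vt$maf, v$maf, tolerance = 1e-6)
  expect_equal(vv$maf, v$maf, tolerance = 1e-6)
})
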