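---
title: "Predicting splicing effects of acceptor-proximal intronic SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting splicing effects of acceptor-proximal intronic SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acceptorvar)
```

## Scope and model

`acceptorvar` classifies single-nucleotide variants at intronic positions
Int-50 through Int-3 upstream of the splice acceptors of internal coding
exons as splicing-pathogenic or splicing-neutral. The model is a
gradient-boosted decision-tree (GBDT) ensemble over hand-crafted splice
cis-element features; its output is a probability of aberrant splicing for
one (variant, transcript) pair, thresholded at 0.5 (inclusive) for the
"splicing-affecting" call.

The biological rationale: in this window lie the branch point sequence
(BPS, bound by SF1), the polypyrimidine tract (PPT, bound by U2AF65), and
the AG-exclusion zone in which a newly created AG dinucleotide can act as a
cryptic acceptor. A variant can therefore be pathogenic by strengthening a
decoy (AG gain), weakening a real element (PPT purine substitution, branch-A
destruction), or corrupting the U2AF35 contact at Int-3. These mechanisms
are exactly the feature families the package computes.

Positions Int-1/Int-2 (the canonical AG itself) are mappable but excluded
from datasets and predictions: variants there are classical splice-site
mutations with established annotation, and the model's scope is the harder
acceptor-proximal range. First and last exons are excluded because they have
no upstream acceptor within the transcript or no downstream donor; "internal"
is judged per transcript independently.

## Coordinate conventions

External files keep their native conventions (GTF 1-based closed, VCF
1-based). The window string holds Int-50..Int-1 in transcript-sense
orientation, so Int-*k* is character `51 - k`; all alleles are expressed in
sense orientation, reverse-complemented from genomic alleles on minus-strand
transcripts. Introns shorter than 50 nt yield no window: all feature
definitions are fixed-length, and truncated windows would silently change
their meaning. A message records each skip.

## Features

For each (variant, transcript) pair the reference window, the mutated
window, and their contrast are featurized (34 columns, fixed order from
`feature_names()`):

- **AG gain/loss** (`ag_gain`, `ag_loss`): set comparison of AG
  dinucleotide start positions fully inside Int-50..Int-3 between reference
  and mutated windows; the canonical Int-2/Int-1 AG never participates.
- **Acceptor percentile score** (`ss_acceptor_{ref,alt,delta}`): the
  classical percentile form `100 (t - t_min) / (t_max - t_min)` over a
  15-position frequency matrix spanning Int-14..Ex+1 — the classical
  acceptor definition; the window is a package constant, since only the
  matrix is configurable.
- **Acceptor log-odds strength** (`wmm_acceptor_{ref,alt,delta}`): a
  position-weight-matrix log-odds score in bits over the 23-mer
  Int-20..Int-1 + Ex+1..Ex+3, signal over background. This is a pluggable
  seam: `train_wmm()` fits the tables from any collection of acceptor
  23-mers, `read_wmm()` loads external per-position probability tables in
  the documented JSON schema. The bundled default is consensus-derived
  (see *Bundled parameters*).
- **Donor score** (`ss_donor`): percentile score of the internal exon's own
  5'ss 9-mer (Ex-3..Int+6), reference only — an acceptor-window variant
  cannot touch it, but a weak flanking donor modulates exon recognition.
- **Branch point** (`bps_position`, `bps_score_{ref,alt,delta}`): scan of
  branch-A candidates over Int-44..Int-15 with a 7-position matrix centred
  on the branch adenosine (yUnAy-like consensus), log2 likelihood ratio
  against uniform background, argmax with ties broken toward the 3'ss
  (the proximal candidate is the biologically preferred one).
- **PPT** (`ppt_count_{ref,alt,delta}`): pyrimidine count in Int-25..Int-3,
  the canonical PPT span; configurable.
- **Nucleotide identities**: one-hot Int-3 (reference and alternate) and
  Ex+1, because single-base identity at these positions carries known
  signal (G at Int-3 weakens U2AF35 binding).
- **RBP motifs** (`rbp_gain`, `rbp_loss`): counts of motif occurrences
  overlapping the variant present only in the alternate / only in the
  reference window, over a user-supplied motif table.
- **Context**: `int_position` (k) and `exon_length`.

Featurization is deterministic (two calls are bit-identical) and strand
symmetric: reverse-complementing the genome and flipping the annotation
leaves every feature unchanged, which the test suite asserts over whole
fixtures.

## Bundled parameters

The frequency matrices under `inst/extdata/` (acceptor 15-mer, donor 9-mer,
branch-point 7-mer, acceptor-strength 23-mer signal) are **consensus-derived
synthetic defaults**: they encode the textbook base preferences of each
element, not frequencies estimated from any particular genome, and their
filenames say so. For real-genome work, estimate matrices from your own
annotation with `estimate_frequency_matrix()` over sequences collected from
`acceptor_windows()`, or load external tables. The bundled RBP motif table
is likewise a small synthetic stand-in — curated RBP motif databases are not
redistributable — and exists to exercise the motif-delta seam.

## Datasets and splits

Common variants pass the MAF filter `lo <= MAF < hi` with defaults 0.01 and
0.50 (half-open: 0.01 kept, 0.50 dropped); `hi = 0.99` is available for the
major-allele-inclusive arm. Pathogenic records pass unfiltered.
`balance_sample()` downsamples commons to the pathogenic count uniformly
without replacement, keeping every pathogenic row.

A dataset row is one (variant, transcript) pair — a variant hitting the
windows of several transcripts contributes one row per transcript, matching
the per-transcript prediction interface. To prevent leakage, all rows of one
*genomic* variant are moved atomically: `benchmark_split()` assigns whole
genomic variants to test, train, and folds. Folds are label-stratified
(per-class fold sizes differ by at most one); with a balanced dataset this
stabilizes per-fold measures. The circularity guard is absolute: any key on
both sides of a split raises an error, so a script using it exits non-zero.

## Classifier

The GBDT backend is xgboost with `binary:logistic`, exact greedy tree
construction, and a single thread. These choices make training
deterministic given (data, config, seed) and invariant under row
permutation when bagging is off — both are asserted in tests. The
hyperparameter vocabulary follows the GBDT literature and maps onto the
backend: `learning_rate` (eta, default 0.1), `n_estimators` (200 trees),
`max_depth` (6), `min_child_samples` (minimum child weight, 5),
`feature_fraction` (column subsampling, 1), `bagging_fraction` (row
subsampling, 1), `reg_lambda` (L2, 1), `reg_alpha` (L1, 0).

`tune_hyperparameters()` is a seeded randomized search over the documented
space in `GBDT_SEARCH_SPACE` (learning rate and regularization sampled
log-uniformly). The default configuration is always evaluated alongside the
sampled trials, so the returned configuration is never worse than the
default under the same folds — a deliberate design choice that makes
"tuning cannot hurt" a property rather than a hope, at the cost of one extra
trial.

Feature importances are gain-based by default (split counts optional),
descending with lexicographic tie-break; features unused by every tree
report 0.

## Evaluation

The seven guideline measures are computed exactly from the confusion
matrix; any zero denominator yields an explicit `NA` plus an entry in
`undefined`, and undefined fold values are excluded (and counted) when
averaging across folds — silent NaN propagation is never allowed. MCC is
computed with a factored square root to avoid integer overflow at large
counts. Reported values round to 3 decimals with round-half-even.

ROC curves sweep unique score thresholds with tied scores grouped; AUROC is
trapezoidal and equals the Mann–Whitney U statistic normalized by
positive×negative pairs (asserted against brute-force pair counting). AUPR
uses right-continuous step integration rather than trapezoids, avoiding the
documented optimism of linear interpolation in PR space. Fold curves are
vertically averaged on a fixed 101-point grid with linear interpolation
within folds.

## The synthetic fixture generator

`simulate_genome()` builds one gene per contig (half per strand, flanks of
100 nt) whose introns carry the planted acceptor biology: donor `GTAAGT`,
a 50-nt acceptor tail with terminal AG, a pyrimidine-rich PPT (Int-25..Int-3
drawn from C/T, guaranteeing a pyrimidine count of at least 16 even where
the branch-point heptamer overlaps), and one planted consensus-optimal
branch heptamer (`TTTACTT`, branch A between Int-30 and Int-22).

`plant_variants()` draws pathogenic variants from four effect classes
mirroring the known determinants of acceptor-proximal pathogenicity — AG
creation (40%), PPT purine substitution (25%), branch-A destruction (15%),
Int-3 pyrimidine→G/A (20%) — and common variants as PPT C↔T swaps or deep
substitutions verified to leave the AG set and all planted elements
untouched. Common MAFs are Uniform(0.01, 0.50) and exist only to exercise
the MAF filter; they carry no biology. Default sizes are 60 genes × 4 exons
(120 acceptor windows) and 400+400 variants with seed 17 as the reference
run — large enough for stable fold metrics, small enough that the full
suite and the acceptance script run in well under a minute each.

**What passing these tests shows — and does not.** The fixture's classes
are separable by construction, so near-perfect cross-validated AUROC on it
demonstrates that mapping, featurization, training and evaluation are wired
correctly end-to-end (and the label-shuffle control, AUROC ≤ 0.6,
demonstrates the absence of leakage). It says nothing about accuracy on
real human variation, where effect sizes are smaller, elements degenerate,
and labels noisy; real-data performance must be established with curated
pathogenic/common sets, which are deliberately out of the package's
shipped data.

## Numerical and degenerate-input choices

- `N` bases contribute the position-mean frequency to percentile scores and
  0 bits to log-odds scores.
- Branch-point scans whose region cannot hold the 7-mer return a flagged
  none-result rather than an error.
- Windows with a non-AG terminus are processed but flagged
  (`canonical_ag = FALSE`); enforcement is left to the caller because real
  annotations contain non-canonical acceptors.
- Indels and ambiguity codes are rejected with a clear error; the method is
  defined for SNVs only.
- Model persistence keeps the ensemble in the backend's native format plus
  JSON schema/config sidecars; the weight-matrix JSON serializes at 17
  significant digits so reloaded models score bit-identically.
- Package functions that consume randomness take an explicit seed and
  restore the caller's RNG state on exit.

## Known limitations

- The acceptor-strength scorer is a first-order position weight matrix; it
  ignores inter-position dependence that maximum-entropy models capture.
  The seam accepts externally fitted tables but not arbitrary scoring code.
- The bundled matrices are consensus-derived, not genome-estimated; scores
  from them are meaningful relatively (ref vs alt, ranked candidates) but
  are not calibrated against any genome-wide distribution.
- One classifier is trained per dataset; no cross-assembly handling or
  liftover is provided — the tool trusts the FASTA+GTF pair it is given.
- The RBP motif feature counts exact string matches; degenerate motifs
  (IUPAC codes, motif PWMs) are out of scope.
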