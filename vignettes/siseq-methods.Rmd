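---
title: "Serial structured 16S sequencing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial structured 16S sequencing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Serial Illumina sequencing (SI-Seq) profiles bacterial communities by
reading three hypervariable regions of the 16S rRNA gene — V5, V6 and V7 —
from a single ~300 bp amplicon, instead of sequencing one long stretch that
is dominated by conserved positions. Each template is sequenced serially
with four sequencing primers, producing two mates per template:

```
mate 1:  barcode(8) :: V5(36) :: V6a(36)
mate 2:  barcode(8) :: V7(36) :: V6b(36)
```

for a total of 144 nt from the 16S locus (plus the 8 nt sample barcode read
twice). Because a template can attach to the flowcell in either direction,
the mate carrying V5 is unknown a priori; orientation must be resolved
computationally. Downstream analysis (classification, OTU clustering)
operates on the concatenation `V5::V6a::V7::V6b`.

`siseq` implements the full desk-scale computational pipeline:

1. **Structured reference construction** (`build_structured_db()`): the four
   sequencing primers are aligned to full-length reference sequences by
   local alignment with an EDNAFULL-like scoring (+5 compatible pair, -4
   otherwise, gap opening 15, extension 1) in which an IUPAC ambiguity code
   matches any base it denotes. Fragments 3' of each primer (36 nt) are
   extracted in sequencing direction and concatenated. Reverse primers are
   aligned as their reverse complements, and their fragments emitted
   reverse-complemented, so the reference matches what the sequencer reads;
   without this convention a `V5::V6a::V7::V6b` reference cannot match real
   reads. Both strands of each reference are searched, so records deposited
   in flipped orientation structure identically.
2. **Read simulation** (`simulate_reads()`, `generate_fixture_db()`): the
   fixture generator and error model described below.
3. **Read processing** (`run_frontend()`): dual-barcode demultiplexing
   (13-of-16 matching-site rule over the concatenated 8-mers, both
   concatenation orders tested), Phred quality filtering (discard when more
   than 6 of the 144 16S bases fall below Q20), and orientation resolution
   (both concatenation orders compared to the structured reference; best
   identity wins if it reaches 0.8).
4. **Taxonomic classification** (`train_classifier()`, `classify_reads()`):
   a word-based naive Bayes classifier in the style of the RDP Classifier,
   with 8-mer words, the smoothed conditional estimator
   `(n_g(w) + 0.5 prior(w)) / (N_g + 1)` with
   `prior(w) = (n(w) + 0.5) / (N + 1)`, presence/absence word evidence, and
   bootstrap confidence from 100 resamples of `floor(W/8)` of the query's
   `W` distinct words. Per-rank support is the rollup (fraction of
   resamples landing inside the taxon), which makes supports monotone
   non-increasing from domain to genus.
5. **OTU clustering** (`cluster_otus()`, `calibrate_cutoff()`): greedy
   centroid clustering — dereplicate, sort by abundance, first-fit at the
   identity cutoff — with the cutoff calibrated on single-species controls
   over the sweep 97/95/93/90/87/85/83/80%. The run-specific control
   misclassification rate doubles as the minimum OTU relative abundance
   (`abundance_threshold()`).
6. **Diversity summaries** (`rarefaction_curve()`, `chao1()`,
   `bray_curtis()`, `species_accumulation()`), delegating the standard
   computations to `vegan`.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `segment_length` | 36 nt | bases sequenced per serial step |
| `identity_floor` | 0.6 | minimum degenerate-aware primer identity to structure a record |
| `min_matches` | 13 / 16 | barcode matching sites required for assignment |
| `phred_threshold`, `max_low_quality_bases` | Q20, 6 | discard reads with **more than** 6 bases below Q20 (strict inequality) |
| `identity_cutoff` (orientation) | 0.8 | minimum best-hit identity to call an orientation |
| `word_size` | 8 nt | classifier word length |
| `n_boot` | 100 | bootstrap trials per read |
| acceptance threshold | 0.7 (`>=`) or 0.8 (`>`) | the simulation convention vs the per-read assignment convention; both are exposed because both are used in validation practice |
| `identity_cutoff` (clustering) | 0.87 | the calibrated OTU cutoff, anchored at the mean within-genus identity of structured sequences |

## The synthetic data generator

No reference database is bundled; every test input is generated in code.
`generate_fixture_db()` builds ~1400 nt 16S-like genes containing exact
(instantiated) sites for the four sequencing primers at realistic spacing,
conserved blocks, and hypervariable windows — the four sequenced 36-nt
segments plus two additional blocks standing in for other variable regions.
Divergence is imposed only in the hypervariable windows: genus ancestors
are mutated from a common root at half the between-genus divergence, and
species from their ancestor at half the within-genus divergence, so
pairwise divergences approximate the requested values. Defaults: 8 genera,
5 species each, between-genus divergence 0.25, within-genus divergence 0.11
— the latter chosen so the mean within-genus identity of structured
sequences is ~89%, the empirical anchor used for cutoff calibration in the
genus *Pseudomonas*.

The default mock community holds five taxa from five genera with genomic
DNA masses in 10-fold steps (five orders of magnitude, lowest 1.2 pg) and
equal rRNA operon counts and genome sizes, so the operon-corrected expected
template proportions are exact 10-fold steps. Expected proportions follow
`(mass x operons / genome size)`, normalized.

The error model is substitution-only: Illumina's dominant error mode, and
the pipeline contains no indel handling. Per-cycle mean Phred is 38 for
cycles 1–18 of each 36-cycle step, declining linearly to 30 at cycle 36,
with Gaussian jitter (sd 3) clamped to [2, 41]; each base's substitution
probability is derived from its emitted quality (`10^(-Q/10)`) unless a
flat rate is requested. Orientation is Bernoulli(0.5).

What the simulator does **not** emulate: PCR bias and chimeras (the
published pipeline delegates chimera removal to its clustering tool; the
simulator generates none, so that contract is untested here), indels,
flowcell cluster-density effects, and real within-genus phylogenetic
structure. Passing tests therefore demonstrate the pipeline's arithmetic,
boundary behavior and statistical contracts on substitution-dominated
reads from well-separated genera — not performance on real community data
or real reference databases.

## Numerical and design choices

- **Identity of structured sequences** is computed ungapped (matching
  columns / max length): reads and references share one fixed 144-nt layout
  and the error model is substitution-only. Unequal-length comparisons fall
  back to Needleman–Wunsch. Orientation resolution, demultiplexing and
  clustering all use compiled kernels for throughput.
- **Primer placement ties** are resolved deterministically by the alignment
  engine's traceback; the reference databases in scope do not contain
  repeated primer sites.
- **Orientation ties** (both concatenations equally good) keep the
  Read1::Read2 interpretation and are flagged; they arise only for
  pathological inputs.
- **Demultiplex ties** at or above 13 matches leave the read unassigned as
  "ambiguous"; the barcode-map loader rejects maps in which two reference
  16-mers are closer than 7 mismatches, which makes such ties impossible
  for compliant barcode sets.
- **Stage order** is demultiplex, then quality filter, then orientation;
  per-read outcomes are order-independent, only the report attribution
  changes.
- **Cutoff calibration objective**: "most closely recapitulating the
  single-species input" is operationalized as minimizing the fraction of
  reads in clusters whose accepted taxonomy conflicts with the control,
  breaking ties toward the candidate nearest the mean within-genus identity
  of the control genus, then toward the larger cutoff. This is a stated
  choice; the original description gives no formula.
- **Cross-sample OTU matching** clusters the per-sample centroids at the
  clustering cutoff; merged OTUs with conflicting member taxonomies keep
  the deepest common ancestor and are logged.
- **Chao1** uses the bias-corrected `(n2 + 1)` form so zero doubletons are
  defined; rarefaction subsamples without replacement.
- **Bootstrap RNG**: one seeded stream per call (`seed` is mandatory
  wherever randomness enters), giving bit-reproducible results; this
  implementation has no parallelism, so per-read seeding schemes are
  unnecessary.
- **All-N queries** yield no words and are reported unclassified at every
  rank rather than erroring.
- **Degenerate inputs**: empty reference sets structure to an empty
  reference with a warning; empty read sets cluster to an empty partition;
  all-zero count vectors have Chao1 0, and Bray–Curtis on two all-zero
  vectors is an error (undefined).

## Problem sizes

The test-suite and validation experiments run at desk scale, chosen as
the smallest sizes at which the statistical contracts are sharp: 40
reference records (8 genera x 5 species); single-species controls of
10,000–50,000 read pairs; mock-community runs of 50,000 reads for
classification fractions and 200,000 reads for the five-decade
dynamic-range check (the lowest-abundance taxon then receives ~18 read
pairs in expectation, comfortably above detection); brute-force clustering
oracles on <= 200 reads; 100 bootstrap trials, rarefactions, and sample
orderings, matching validation practice.

## Known limitations

- The classifier and clustering are validated on synthetic references with
  idealized genus structure; real databases bring unclassified lineages,
  uneven genus sizes, and chimeric records that this package does not
  model.
- No chimera detection; no phylogeny-dependent diversity metrics (UniFrac,
  Faith's PD), ordination, or tree inference — Bray–Curtis is the supported
  beta metric.
- Orientation resolution scores against every structured reference; for
  databases of ~10^5 records a k-mer prefilter would be needed.
- The CF-like saturation property uses geometric communities (ratio 0.7,
  5–15 taxa) whose minor members sit at detectable (>= ~0.1%) abundance;
  steeper communities with members far below the detection threshold will
  not saturate at 1,000 reads, nor should they.
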