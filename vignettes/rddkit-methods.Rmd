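---
title: "rddkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rddkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `rddkit`, the statistical
definitions it fixes, the synthetic data its tests rest on, and the design
decisions that were genuinely open.

## The model

RNA editing detection from RNA-seq reduces to a classification problem:
given raw RNA/DNA difference (RDD) candidates — sites where the aligned
RNA consensus differs from the genome — separate genuine editing (A-to-I,
presenting as A>G on the edited strand; C-to-U as C>T) from systematic
artefacts, the reproducible false variants created by short-read
mis-alignment among repeats, across splice junctions and at polymorphisms.
Because mis-alignment is a deterministic property of genome, read length
and aligner, replication does not remove these artefacts; a classifier
can, if it is trained on examples from the *same condition*.

`rddkit` compiles its training set from the input itself:

* **Positives**: candidates matching the consensus (intersection on
  `(chrom, pos, strand)`) of two curated editing-site databases. By
  default a match additionally requires substitution-class compatibility —
  an A-to-I row on `+` matches a forward A>G candidate, on `-` a forward
  T>C candidate (likewise C>T / G>A for C-to-U). A position-only mode
  exists because curated exports do not always carry usable strand
  information; the class-aware mode is the default since it is the
  stricter join and editing databases publish strands.
* **Negatives**: candidates at **error-prone sites** computed by the MES
  simulation: plant SNVs at rate 1 % (allele fraction 1) over the
  transcribed positions, simulate reads, align them with the method under
  study, call variants permissively, and record every called-but-unplanted
  position. Site identity is *position-level*: a planted site recalled
  with a wrong allele is still "intended". Trials are pooled with a
  recurrence threshold `k` (default `k = 1`, the union — the most
  conservative artefact mask; a vote is available but no principled
  default exists for one).
* Candidates matching both sources are dropped as label conflicts
  (ambiguous labels poison training; neither source outranks the other).
  Candidates on a supplied test-exclusion list are withheld from training
  only and remain prediction targets, so evaluation data never leak into
  the model; an optional ±w-base exclusion window generalises exact site
  identity (default w = 0).

A Random Forest (100 trees, unlimited depth, `floor(sqrt(15))` features
per split, fixed seed) is trained on the 15 attributes and applied to the
remaining candidates; a site is accepted as true editing when its
positive-class probability reaches the threshold (default 0.5, exposed as
a parameter — no calibration is attempted).

## The 15 attributes

The attribute *names* and category structure follow the
samtools/bcftools tradition; their exact formulas are fixed here so every
value is reproducible:

| Category | Attributes | Definition |
|---|---|---|
| Read depth | ReadDepth | observations passing the base-quality filter |
| Allele segregation | VAF, SGB, FQ, CallQual | see below |
| Mapping quality | PV3, MQB, MQ0F, MQ | rank-sum p/z on MAPQ; MAPQ-0 fraction; RMS MAPQ |
| Read position | VDB, RPB, PV4 | Monte-Carlo clustering; rank-sum z on relative offset; rank-sum p on tail distance |
| Base quality | PV2, BQB | rank-sum p/z on base quality |
| Read strand | PV1 | two-sided Fisher exact on (allele × strand) |

**Rank-sum tests** compare the alt-supporting against the ref-supporting
observations with the tie-corrected Mann-Whitney normal approximation and
continuity correction: `z = sign(U - μ)·max(0, |U - μ| - ½)/σ`,
`p = 2Φ(-|z|)`; identical values or an empty group yield the sentinel
`z = 0, p = 1`. Exhaustive enumeration over all rank assignments at group
sizes ≤ 6 shows the approximation deviates from the exact two-sided tail
by at most ≈ 0.13 (the tests assert 0.15); at the depths where candidates
are actually called the approximation error is negligible.

**Fisher strand** is the fixed-margin hypergeometric tail sum with the
customary 1e-7 relative slack on "≤ observed probability". Being an exact
discrete test its null distribution is super-uniform, not uniform — the
test suite therefore checks the rank-based p-values against U(0,1) by
Kolmogorov–Smirnov on a near-continuous null fixture, and checks PV1
against its exact enumerated null instead (P(p ≤ p(x)) = p(x) under the
hypergeometric null).

**Allele segregation** uses a three-hypothesis genotype-likelihood model
with per-base error `e = 10^(-Q/10)` (an erroneous base hits one specific
wrong base with probability `e/3`): hom-ref, het (a 50/50 allele draw) and
hom-alt. `SGB = ln P(hom-ref) − ln P(het)` (negative when the het model
beats the error-only explanation), and with a uniform prior,
`FQ = −10·log10` posterior of the best monomorphic hypothesis and
`CallQual = −10·log10` posterior of hom-ref, both capped at 9999.

**VDB** estimates, with `m = 1000` seeded Monte-Carlo draws, the
probability that the variance of the alt-base 5' offsets under uniform
placement over each read's valid offsets is at most the observed variance,
reported as `(1 + #{≤})/(m + 1)` so it stays in (0, 1]. Small VDB flags
alt bases clustered at one read position — the signature of splice-site
mis-alignment. Fewer than two alt observations returns the sentinel 1.

Candidate calling uses depth ≥ 10, alt reads ≥ 2, base quality ≥ 13 —
stated, configurable defaults in the spirit of a standard caller;
positions where two non-reference bases each reach the alt threshold are
dropped as multi-allelic (and counted). PV3/MQB and PV2/BQB are the p- and
z-statistics of the *same* test and are deliberately both emitted, since
both appear as distinct attributes in the tradition this follows. PV4 is
read here as a single tail-distance p-value (the historical bundling of
four p-values under one name is not reproduced).

## The synthetic data generator

The generator exists to make every downstream claim *exactly* testable:

* **Genome**: random chromosomes carrying repeat families planted as
  near-identical copies of a template, each copy diverging at exactly
  `round(divergence × length)` recorded positions. The inter-copy
  difference positions are recoverable — they are the complete truth set
  of potential mis-alignment variant columns.
* **Transcripts**: non-overlapping spliced models (1–3 exons, both
  strands), plus one transcript per repeat copy so repeats are
  transcribed.
* **Variants**: planted uniformly over transcribed positions; DNA-level
  SNVs carry allele fraction 1, RNA edits a configurable editing level
  (default 0.5, a typical editing ratio).
* **Reads**: single-end, uniform over transcripts and positions,
  independent per-base substitution errors, base qualities encoding the
  true error model (`Q = −10·log10 e`, capped at Q40). Stored in
  forward-genome orientation with exact per-base origin.
* **Alignments**: *no aligner is implemented.* Reads are placed at their
  true locus (MAPQ 60) except that a configurable fraction of reads lying
  wholly within a repeat copy is placed at the homologous offset of
  another copy with reduced MAPQ (default 20; a configurable fraction at
  MAPQ 0), and a truth table records every placement. The claims under
  test concern what happens *after* alignment, and only a truth-controlled
  fabricator makes artefact columns known by construction. A FASTQ export
  hook exists for driving a real external aligner.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: realistic expression-level distributions
(sampling is uniform; a per-transcript weight hook exists), quality decay
along reads, homopolymer and PCR/library artefacts, indels, paired-end
information, genuine aligner behaviour (soft-clipping, partial repeat
overlap, mismatch-dependent placement), and polymorphism between sample
and reference beyond the planted sets.

## Reference study conditions and problem sizes

The shipped end-to-end study (`simulate_rdd_study()` defaults) uses: two
chromosomes (12 kb + 9 kb), one 2-copy repeat family of 1200 bp at 2 %
divergence, 14 spliced transcripts plus the repeat transcripts, 80 planted
A-to-I sites at editing level 0.5, a decoy pool of 40 editable-but-unedited
database rows split across two database files (their overlap survives the
consensus), 20,000 reads of 75 bp at error rate 0.005, 50 % repeat-read
mis-placement (20 % of those at MAPQ 0), and an error-prone-site stage of
3 trials × 12,000 reads at 1 % planted SNVs. Half the edit sites and half
the truth artefact columns form the validation list, which is also the
test-exclusion list. These sizes give ~70× coverage — deep enough that
essentially every planted site becomes a candidate — while keeping a full
run in a few minutes on one CPU; they are the package's reference
conditions, not tuning knobs. The trial count of the *shipped count table*
used for the worked-example arithmetic is ten, matching the scale at which
such simulations are customarily reported.

## Numerical choices and degenerate inputs

* Percentages round half-up to two decimals everywhere (matching how such
  rates are customarily printed); `round_half_up()` is exported.
* Candidate/prediction tables serialize floats at `%.17g`, so
  write-then-read is the identity and repeated runs are byte-comparable.
* BED is written 0-based half-open and merged/sorted on write; in memory
  all coordinates are 1-based (the editing-database convention), and the
  conversion is exact at the boundary.
* Alphabetical tie-break for the modal alt allele; sentinel-plus-flag
  (never missing values) for degenerate statistics; empty training classes
  are an error naming both class counts, since no classifier can be fit.
* Every stochastic step takes an explicit seed; library functions save and
  restore the caller's RNG state.

## Known limitations

Single-sample, single-end, substitution-only by design. The MES stage in
the shipped pipeline relies on the truth-controlled fabricator unless an
external aligner hook is supplied, so its error-prone set reflects
engineered, not empirical, mis-alignment. Validation sites that never
reach candidate status are reported as unmatched rather than imputed,
which makes reproduction rates conditional on candidate discovery. The
information-gain category ranking fixes equal-frequency binning (10 bins)
and max-aggregation per category; these are stated conventions — mean
aggregation is available — and only the ranking's structural properties
(six categories, tie-averaged rank permutation, mean-rank column) should
be compared across implementations, not raw IG values, which depend on
the discretization.
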