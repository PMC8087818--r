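---
title: "Isoform discovery by grouped self-correction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform discovery by grouped self-correction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-read (nanopore) sequencing of a full-length amplicon can, in principle,
read out every exon of every transcript isoform in a single molecule. In
practice 1D nanopore reads carry roughly 10% combined
substitution/insertion/deletion error, which is far too high to call exon
boundaries at base-pair resolution from individual reads: a spliced
alignment of a raw read jitters by several bases at every splice junction,
and the exact-boundary information that distinguishes, say, a 3'-truncated
exon variant from its representative form is lost in the noise.

`isoscope` implements a *grouped self-correction* strategy for exactly this
setting — one amplified locus, deep read coverage, many co-amplified
isoforms:

1. **Loose grouping.** Raw reads are spliced-aligned to the locus. All
   aligned exons are merged into non-overlapping *blocks* (connected
   components of the interval union), and each read is assigned a
   *signature*: the ordered set of blocks its exon chain touches. Reads
   with identical signatures share, approximately, an exon structure.
2. **Within-group consensus.** Each multi-member group elects a medoid
   template; every member is aligned to it with a banded affine-gap
   aligner, and a per-template-column majority vote over
   match/substitution/deletion events (insertions voted per gap) produces a
   consensus. Each member's corrected sequence follows the consensus
   *except* across the member's own structural indels (longer than
   `max_correct_event`, default 10 bp), which are preserved verbatim — so
   a minority isoform that happens to share a group is corrected without
   being collapsed into the majority structure.
3. **Second round.** The corrected sequences are re-aligned; blocks and
   groups are re-derived — now boundary-accurate — and the *original raw
   reads* are re-corrected inside the refined groups. Re-correcting raw
   reads (rather than polishing round-1 output again) avoids locking in any
   bias introduced by coarse round-1 grouping. Reads alone in a group, or
   whose round-1 output fails round-2 alignment, are dropped from the
   corrected output: correction is partial by design, and downstream
   analysis uses corrected reads only.
4. **Catalog and exact matching.** Per block, the most frequent corrected
   (start, end) pair is elected the *representative exon* (`rex01`,
   `rex02`, ...); alternative pairs supported by more than `variant_frac`
   (default 5%) of the block's exon-containing reads are admitted as
   *boundary variants*, encoded as `"L{d5}:R{d3}"` patterns relative to the
   representative. A corrected read is counted toward an isoform only when
   its entire exon chain matches catalog elements base-pair exactly, one
   element per successive block.

## Coordinates and conventions

All coordinates are 0-based half-open on the forward genome strand, so
`length = end - start` everywhere, including the shipped published tables.
Reverse-strand reads are reverse-complemented into forward orientation
immediately after alignment; isoform identity is orientation-invariant.
Exon chains are strictly ascending; book-ended intervals (end of one equals
start of the next) are merged during block construction, matching the
per-base interval-union definition of a block.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `variant_frac` | 0.05 | a boundary pair must strictly exceed this fraction of the block's exon-containing reads to become a variant |
| `variable_frac` | 0.10 | exon frequency above which an exon is *variable* rather than *rare* |
| `stable_frac` | 0.90 | exon frequency above which an exon is *stable* ("nearly all" reads; the class boundary is not sharp in nature, 0.90 separates the published classes cleanly and is configurable) |
| `rare_min_frac` | 1e-4 | exons below this frequency are excluded from the catalog |
| `high_conf_reads` | 20 | pooled read support from which an isoform is *high-confidence* |
| `min_evidence_reads` | 3 | pooled read support from which an isoform has *minimum evidence* |
| `anchor_k` | 12 | aligner k-mer size (also the second-round alignment setting of the original analysis) |
| `intron_min_gap` | 30 bp | genomic gap, in excess of the read gap, at which the aligner opens an intron |
| `min_anchor_cov` | 0.25 | minimum chained-anchor coverage of a read; below it the read is unaligned (off-target reads fail here) |
| `band_frac` | 0.12 | banded-alignment width as a fraction of the longer sequence — comfortably above the ~10% error rate, so true paths stay in band |
| `max_correct_event` | 10 bp | indels longer than this are treated as structural (true exon differences) during correction |
| `match_tolerance` | 0 bp | isoform matching is base-pair exact; a nonzero tolerance exists but exactness is what makes boundary-level claims meaningful |

Two distinct denominators are used deliberately and both are logged on the
catalog: variant support is measured against the block's *exon-containing*
reads, while exon frequency (hence the stable/variable/rare state) is
measured against the reads whose *whole chain* matches the catalog.

## The built-in aligner

The aligner is intentionally minimal — a single-locus spliced aligner for
desk-scale work, not a genome aligner. Exact k-mer anchors are chained
colinearly (gap-difference penalty within exons, flat cost for opening a
genomic gap ≥ `intron_min_gap`); reads are tried in both orientations and
the better chain wins; chains covering less than `min_anchor_cov` of the
read are rejected. Between the segments separated by an intron, the exact
junction placement maximizes diagonal base matches over the unanchored
window, with a bonus (worth 2.5 matches) for a canonical `GT..AG` intron.
The window is widened 6 bp into the anchored flanks on both sides: at
junctions where the sequence is locally ambiguous (the exon end repeats the
intron end), several placements match equally and only the motif bonus
identifies the true one. Terminal exon ends are extended diagonally to the
read ends. For real multi-locus data, external spliced alignments
(minimap2-style SAM/BAM, PAF with `cg:Z` CIGARs, or BED12) can be imported
instead; the two sources are never mixed within a run.

## Numerical choices in the consensus

The member-to-template aligner uses affine gap costs (mismatch 4, gap open
6, gap extend 1). Affine costs are essential for two distinct reasons:

* a *structural* indel (a read lacking or carrying an exon relative to its
  template) must surface as one contiguous gap run, not fragment into
  sub-threshold pieces through chance matches inside the indel;
* a member's single-base insertion must not be *absorbed* into a cascade of
  cheap substitutions that re-synchronizes at the member's own nearest
  indel error — under cost ratios that allow such absorption, the votes
  that should restore a missing homopolymer base scatter and the consensus
  stays wrong no matter how deep the group is.

Consensus is computed iteratively (template → vote → new template, two
polish rounds on an evenly spaced subsample of up to 30 members, then one
final vote with all members). A single pass against an error-laden raw-read
template leaves a residue of indel-placement vote splits; re-voting against
the improved consensus removes it. Insertion consensus requires more than a
third of members to insert at the same gap (the most common inserted string
wins); column consensus is a plurality over the four bases and deletion,
with ties resolved toward the template. Structural events are excluded from
all votes. Medoid selection (highest mean pairwise identity; ties to the
longer member, then the lexicographically smaller read id) runs on a
deterministic, evenly spaced subsample of at most 12 members so the
quadratic pairwise stage stays cheap; the template only needs to be a
typical member, the voting does the accuracy work.

Degenerate inputs: groups of size 1 are returned uncorrected and flagged;
members whose banded alignment to the template fails (band breach) are
passed through untouched; an empty insertion vote keeps the template's
bases.

## What the simulator emulates — and what it does not

`simulate_dataset()` builds a multi-exon locus with canonical `GT..AG`
introns, an isoform mixture over stable/variable/rare exon classes
(stable exons always included, variable included with probability 0.5,
rare with 0.1; mixture frequencies from a symmetric Dirichlet), and
error-laden barcoded reads with i.i.d. per-base substitutions, insertions
and deletions, a configurable fraction of random off-target reads
(emulating non-specific priming), and both read orientations. Its defaults
define the package's standard desk-scale benchmark: a 20-exon locus
(14 stable including both primer-side exons, 3 variable, 3 rare), 12
isoforms, 2,000 reads across 2 replicate samples at 7% combined error with
5% off-target — small enough to run in minutes on one CPU, large enough
that every isoform above 2% frequency must be recovered exactly.

The error model is deliberately i.i.d.: it reproduces the overall ~10%
error magnitude of 1D nanopore reads but not their homopolymer-length
biases, nor PCR chimeras, nor reverse-transcription template switching.
Passing the recovery benchmark therefore demonstrates that the grouping,
consensus, election and exact-matching machinery is correct — it does not
by itself guarantee the same boundary-exactness on real nanopore data,
where systematic homopolymer errors can survive a majority vote. The
original analysis this package models handled the same risk by clamping
the outer boundaries of the first and last exon regions to known gene
models (the amplicon's outer ends are primer-defined, not splice-defined);
`pipeline_config(outer_boundaries = ...)` reproduces that convention.

## Design choices where the design was open

* **Correction output.** One corrected sequence per input read, preserving
  read ids, rather than one consensus per group: read-level output is what
  makes the two-round scheme meaningful, since reads of distinct isoforms
  that share a coarse round-1 group can only separate in round 2 if their
  structural differences survive round 1. This is also why structural
  indels are preserved per member instead of being outvoted.
* **Variant admission** does not require the variant to share a boundary
  with its representative; sharing is recorded as a QC flag
  (`shares_boundary`). The published variants all share one boundary, but
  that is an observation, not a rule of the method.
* **Variant threshold** is strict (`>` 5%), reading "more than 5%"
  literally; the same strictness applies to the stable/variable boundary.
* **Variant symmetry** is defined on the *length change* (|Δ| divisible by
  3 preserves the reading frame downstream of the variant boundary), which
  is also the only definition consistent with the published variant tables.
* **Exon frequency denominator.** The published exon table prints a
  frequency column whose denominator is not stated; the exact-match read
  set is used here, because it is the only population for which exon
  presence is unambiguous.
* **Isoform ranking** pools counts across samples ("total of corrected
  reads"), with per-sample counts retained as columns; ties break toward
  the lexicographically smaller key so ranking is deterministic.
* **Reads skipping interior blocks** are valid isoforms — exon skipping is
  the phenomenon under study — but a chain may use at most one element per
  block, in ascending block order.
* **Partial-exon trimming.** How alignments that cover only part of a
  terminal exon were trimmed before block merging is not specified in the
  source analysis; chains are used as aligned, and the primer filter plus
  outer-boundary clamping absorb the resulting edge effects.

## Known limitations

* The built-in aligner assumes one locus of at most a few hundred kb and
  has no notion of chromosomes, paralogs or split mappings; import external
  alignments for anything larger.
* Consensus correction can erase *true* boundary variants smaller than
  `max_correct_event` when they are in the minority within a group (a
  3-bp variant at 40% support inside one group is voted away). The
  published catalog contains variants as small as 3 bp; on real data this
  argues for lowering `max_correct_event` or raising sequencing depth so
  such variants form their own groups after round 2.
* Simulated problem sizes in the test suite (typically 6–20 exons, 80–2,000
  reads) were chosen so the whole suite runs in minutes on a single CPU;
  they are stated in each test and in `simulate_dataset()`'s defaults.
* `replicate_correlation()` needs at least 3 isoforms observed in either
  sample; below that it reports `NA` rather than a meaningless coefficient.
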