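---
title: "Calling mobile element insertions from read-pair and split-read evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mobile element insertions from read-pair and split-read evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meicall)
```

## The model

A non-reference mobile element insertion (MEI) at reference position *p*
leaves two junctions in the sampled genome. During target-primed reverse
transcription the endonuclease usually nicks the two strands at offset
positions, so the reference segment between the nicks is duplicated on
both sides of the insert (a target site duplication, TSD), occasionally
deleted (target site deletion), or neither (blunt). Writing *R* for the
reference coordinate where reads stop aligning on the 5′ side and *L* for
the coordinate where alignment resumes on the 3′ side, the signed
difference `R − L` is positive for a TSD, negative for a deletion and zero
for a blunt insertion — this quantity is estimated directly from the modal
clip positions of the 5′ and 3′ clipped read clusters and reported as
`tsd_bp`.

The caller consumes two evidence streams from a coordinate-sorted BAM:

1. **Discordant pairs.** A pair is discordant when, in order of
   precedence: one end is unmapped; ends map to different chromosomes; the
   orientation is not forward–reverse with the forward read upstream; or
   the absolute template length falls outside `median ± k·sd` of the
   insert-size distribution. The distribution is estimated from the first
   10,000 properly-paired records with template lengths above the sample's
   99.5th percentile trimmed first (one gross outlier would otherwise
   inflate the sd arbitrarily). "Differs significantly from the median"
   has no canonical *k*; we default to the conventional `k = 4` and expose
   it (`insert_size_sd_multiplier`).
2. **Soft-clipped reads.** Clips of a uniquely mapped read are accepted
   when the clip is at least `min_clip_length` (35 bp paired-end, 20 bp
   single-end), the clipped bases average at least Q20, and the opposite
   end is clipped at most 7 bp. "Uniquely mapped" is approximated
   portably as MAPQ ≥ 20 (`min_anchor_mapq`).

Candidate sequences (mates of discordant anchors, clipped tails) are
aligned against the mobilome — a small library of family consensus
sequences — accepting placements with mismatch fraction ≤ 0.10 over the
query length; queries shorter than 18 bp never map, matching the length at
which random sequence stops mapping uniquely. Sequences without a family
hit are tested for a terminal homopolymer: a terminal window longer than
8 bp that is ≥ 90% A (polyA) or T (polyT). The 8 bp length is from the
observed polyA-tail detection limit; the 90% purity and end-anchored
scanning are our choices (a pure-run definition would be destroyed by a
single sequencing error inside a long tail).

### The internal mobilome aligner

Because the mobilome is tiny (tens of kilobases), exactness is affordable.
The aligner hashes all 11-mers of both strands of every entry; a query's
11-mers vote for candidate diagonals, which are scored by C-level Hamming
comparison. A placement with *m* mismatches over length *n* is certain to
contain a clean *k*-mer when `n ≥ (k+1)m + k`, which yields a staged,
exact search: if the 11-mer-seeded best satisfies the bound it is provably
optimal; otherwise a 6-mer position index supplies the candidate
diagonals — at the 10% budget every qualifying placement contains a clean
6-mer for all query lengths ≥ 18 bp, so this stage is complete — and only
an explicit mismatch allowance that violates the 6-mer bound triggers a
blind scan of every offset. The reported best mismatch count is therefore
always exact (the test suite checks this against an independent
sliding-window oracle on random instances), while random reference-derived
mates, whose chance 11-mer collisions with the mobilome would otherwise
force full scans, cost only one short C-level pass. An 8-mer presence
screen additionally rules out homopolymer tails before any scoring. A banded
(band 3) gapped rescue via `pairwiseAlignment` catches clipped tails that
span a small indel; it only runs when no ungapped placement meets the
budget. Ties within a family resolve to the first FASTA entry (+ strand
first); ties across families mark the hit ambiguous and the read is
dropped, keeping only unambiguously assignable evidence.

## Clustering and event assembly

Discordant anchors cluster per (chromosome, strand, family) by single
linkage on start positions with a 200 bp neighborhood; forward-strand
clusters flank the insertion 5′, reverse-strand 3′. A 5′/3′ pair joins
when the spans overlap by ≤ 50 bp (TSD allowance) or gap by ≤ 600 bp.
Clipped anchors cluster per (chromosome, side, tag) around the modal clip
position with a 3 bp tolerance — the source material says only "within a
few bp"; 3 bp matches the single-end rule and is exposed as
`clip_position_tolerance`. Joining a 5′ clipped cluster (position *R*)
with a 3′ one (position *L*) requires compatible tags (same family, or
one family plus one homopolymer) and `R − L ∈ [−20, +50]`.

Cluster pairing is greedy nearest-first with a leftmost tie-break, each
cluster used at most once; the same rule attaches clipped events to
discordant events whose inner interval lies within the neighborhood
distance. These pairing rules are ours — no pairing procedure is specified
beyond the join predicates — and greedy-nearest is the conservative choice
(it can only split, never merge, distinct insertions ≥ 2 kb apart).
Anchors whose mate is unmapped and maps to nothing are tagged `unmapped`;
they cannot name a family and therefore never seed a cluster, but attach
to the nearest same-strand family cluster within the neighborhood,
contributing support. A joined clipped pair whose two sides are both
homopolymer-tagged names no family and is dropped rather than promoted to
a prediction.

Breakpoints, in decreasing precision: both clipped clusters →
`[min(R,L), max(R,L))` exactly (the window equals it); one clipped cluster
→ its clip position ± the clip tolerance; double discordant → the inner
borders of the two clusters (their overlap if a TSD inverts them), with
the midpoint as nominal breakpoint; single discordant cluster → the
window implied by the maximal template span, e.g.
`[cluster_end, cluster_start + median + k·sd − read_length)` for a 5′
cluster.

## Filters, merging, annotation

Filters set flags and never delete rows, so they commute and the audit
file preserves every candidate: `low_support` (< 5 reads),
`reference_mei` (window within 90 bp, edge-to-edge, of a same-family
reference element — we read the 90 bp rule as window-edge to
annotation-edge since no anchor point is specified), `satellite` (window
overlaps satellite DNA), `single_cluster` (no evidence on one side;
enforced for WGS, off for the WES presets so border-of-capture insertions
survive). Unflagged predictions of the same family within 50 bp merge
transitively; merging is family-scoped to avoid conflating co-located Alu
and L1 calls — a documented divergence risk against merging final call
sets family-blind. Gene-component annotation uses an internal refFlat
interval lookup with priority exonic/splice > ncRNA > UTR > intron >
1 kb flanks > intergenic, replacing an external annotator.

## The simulator: a stated world

The generator emulates, from a fixed seed (R's Mersenne Twister; all
randomness flows from `sim_config$seed`):

* a random reference with embedded, 2%-diverged copies of the consensus
  library (the "reference mobile elements" the 90 bp filter needs) and one
  satellite-like tandem repeat;
* planted insertions ≥ 2 kb apart and ≥ 500 bp from any decoy: family mix
  85.4% Alu / 11.4% L1 / 3.2% SVA (the observed family distribution; no
  HERV-K insertions were observed so none are planted, though HERV-K is in
  the library), random strand, TSD structure 93% duplications (5–20 bp,
  mode 13) / 6% deletions (1–15 bp, median 7) / 1% blunt, polyA tails of
  10–40 bp, and 5′ truncation for 70% of L1 copies;
* paired-end reads (100 bp, fragment N(400, 30), base error 0.1% — typical
  Illumina-era values; coverage, length and error are parameters) whose
  alignments are derived from the truth: fully-reference fragments become
  proper FR pairs; junction reads with ≥ 20 bp of reference anchor are
  soft-clipped exactly at the junction; reads inside the element
  multi-map to a reference decoy copy (MAPQ 0) when one exists, else come
  out unmapped — reproducing the dominant evidence class of real data,
  where most supporting mates are multi-mapped. The mobilome itself is
  *synthetic* (random sequences with family-labelled headers): planted and
  detected against the same library, detection is self-consistent without
  bundling third-party consensus data.

What the simulator does **not** emulate — and what a green test therefore
does not establish: alignment ambiguity in repetitive reference context
(clips are placed perfectly; real aligners scatter clip positions and
misplace anchors near low-complexity sequence), indels and structured
error profiles, chimeric artefacts, heterozygous-haplotype linkage (het
insertions are emulated by sampling half the fragments from a
pure-reference haplotype, which preserves local evidence but not
cross-insertion phase), and capture-efficiency gradients in WES mode
(reads start strictly on-target). Accuracy numbers on this world are
accordingly upper bounds on real-data performance.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; conversion happens only at
  the Rsamtools/VCF boundaries (VCF POS is 1-based).
* Modal clip position ties break toward the smallest coordinate;
  family-tie hits take the first FASTA entry; greedy pairings break ties
  leftmost. All tie-breaks are deterministic, so identical seeds give
  byte-identical outputs.
* An insert-size sample under 1,000 pairs sets a `low_sample` flag rather
  than failing; zero proper pairs in paired mode is fatal.
* A both-ends-unmapped pair has no coordinates and is dropped with a
  count; hard clips carry no sequence and are counted but never used.
* `estimate_breakpoint` clamps single-cluster windows to be non-empty;
  breakpoint-context extraction near contig edges N-pads to keep the
  13 bp width.

## Known limitations

Single-end mode requires soft clips in the BAM (hard-clipping aligners
would need the clipped sequence retained in an auxiliary tag, which is not
implemented). No local assembly of the inserted sequence, no subfamily
resolution, no population-database annotation. The 160X acceptance
simulation writes a ~800 MB temporary SAM; `tempdir()` must have the
space.
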