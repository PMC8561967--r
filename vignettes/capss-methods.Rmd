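---
title: "Methods: CAPSS-based BAC end profiling and genome anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAPSS-based BAC end profiling and genome anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pooling model

A BAC library stores a genome as tens of thousands of 50–300 kb inserts,
one clone per well of 384-well plates. Knowing where each clone sits on a
reference genome turns the library into a physical map — for gap filling,
FISH probe selection, or targeted re-sequencing — but Sanger-sequencing two
ends per clone is prohibitive at library scale. Clone-array pooled shotgun
sequencing (CAPSS) replaces per-clone sequencing with per-pool sequencing:
plates are arranged in a grid (here 6 plate-grid rows by 4 plate-grid
columns of 16 x 24-well plates), every physical row of wells across a
plate-grid row is pooled (96 row pools) and every column across a
plate-grid column likewise (96 column pools). Each well then lies at the
intersection of exactly one row pool and one column pool, so any sequence
found in one row pool *and* one column pool — but implied by no other pool
combination — identifies a single well. The package implements this
geometry as explicit integer arithmetic (`pools_for_well()`,
`well_at_intersection()`), which the test suite verifies to be mutually
inverse over all 9216 wells.

The quantity sequenced per pool is the clone *molecule*: the insert plus
the ~7 kb single-copy vector. Pool depth accounting therefore uses an
effective clone size of insert estimate + vector length
(`effective_clone_size_kb()`, 132 + 7 = 139 kb with the gel-based insert
estimate).

## End-sequence recovery: two pathways

Every insert is bounded by HindIII sites (AAGCTT — the partial-digest
cloning site), and the vector sequence flanking the cloning site is known.
A *forward* end sequence is the insert's first stretch read away from the
left vector flank, a *reverse* end sequence the same on the
reverse-complement side; both therefore start with AAGCTT, which the
package asserts on every emitted sequence.

**Short pathway** (`extract_short_bes()`): reads containing at least
`min_vector_anchor` (20) terminal bases of a vector flank immediately
followed by AAGCTT span a junction. Because all junction reads of one clone
end share the AAGCTT anchor at position one, clustering is anchored prefix
comparison (agreement ≥ 0.95 over ≥ 50 bp) rather than general overlap
assembly; each cluster of ≥ 3 reads yields a majority-vote consensus, which
grows only while ≥ 3 reads cover a column. Mates of clustered reads extend
the consensus where they overlap it by an exact 30-mer. The 20 bp anchor is
long enough to occur once in a 7 kb vector by chance; depth 3 suppresses
singleton chimeras.

**Long pathway** (`assemble_pool()` + `extract_long_bes()`): each pool's
reads are assembled and junction-bearing contigs are trimmed so the
retained sequence runs from AAGCTT into the insert, with vector sequence at
the contig's far end trimmed off as well. The built-in assembler is a
greedy overlap-merger intended for desk-scale data: reads are sorted
lexicographically (radix order, locale-independent — this plus a single
seed order makes assembly deterministic), contigs extend rightwards through
reads whose prefix overlaps the contig suffix by ≥ 40 bp at ≥ 0.98
identity, and the appended extension is the majority vote over all
candidate reads. A strictly-unique-extension rule would truncate a contig
at every sequencing error carried by a single read, so ambiguity is instead
declared when the *second-best* extension variant has support ≥ 2 — a
genuine branch (for example the three different inserts hanging off the
shared vector flank in one pool) — and extension stops there. Because the
frontier vote can outrun the reads that know better (two clones of one pool
overlapping on the genome share sequence, and the far junction's reads may
not yet be anchored when the vote crosses it), the assembler also treats a
read that anchors, matches the contig well and then diverges at ≥ 30%
beyond one coordinate as a *breakpoint witness*; two witnesses within 3 bp
truncate the contig at that coordinate. The same rule breaks contigs at
assembly gaps and at dispersed-repeat edges, where continuation is equally
unsupported.
Production-scale contigs from an external assembler can be substituted: the
extraction step only needs contig FASTA.

## Assignment and its conflict policies

Row-pool and column-pool end sequences "share" when they agree at ≥ 0.99
identity over their common AAGCTT-anchored prefix (`match_pools()`);
candidate pairs are pre-screened by the exact 24-mer following the anchor.
Forward and reverse ends, and short- and long-source sequences, flow
through assignment fully independently — removing all reverse sequences
provably leaves forward assignments unchanged.

Overlapping clones are the dominant failure mode: a sequence present in two
row pools and two column pools implies four wells. Under the default
`STRICT` policy any sequence implying more than one well is dropped
entirely (counted as filtered); the affected wells usually still anchor via
their other end. A well that accumulates two *different* sequences for one
end keeps both marked `AMBIGUOUS` — resolution is deferred to genome
mapping, where cross-source sequence agreement picks the candidate
consistent with the other pathway (two long
forward candidates, only one matching the short forward consensus).

## Genome anchoring

Aligned placement uses a seed-and-extend nucleotide aligner written for the
strict contract the method requires: identity ≥ 0.99 *and* query coverage
≥ 0.99 (the blastn `perc_identity`/`qcov_hsp_perc` convention as
fractions). Exact 21-mers tiled across the query (both strands) propose
diagonals; the full query is compared ungapped on each diagonal. Ungapped
extension is sufficient here because the simulator's error model is
substitution-only and the coverage contract leaves no room for gapped
placements; any qualifying alignment with fewer mismatches than tiled seeds
is found by pigeonhole, and the test suite checks exact hit-set equality
against a brute-force sliding aligner on hundreds of random instances.
Repeat-derived query bases are soft-masked beforehand: a base is masked
when every covering genome 21-mer occurs more than once (strand-combined);
masked bases neither seed nor count in identity or coverage denominators.
Hits are culled blastn-style — a hit dominated over ≥ 50% of its query
interval by a strictly higher-scoring hit is removed — and queries are
classed `NONE`/`SINGLE`/`MULTI` by surviving hits; only `SINGLE` placements
anchor clones.

A clone is `PAIRED` when its two end placements share a chromosome on
opposite strands *facing inward* with a span under 250 kb; "opposite
orientation" alone would admit outward-facing pairs with no coherent
interval, so inward-facing is required. The clone interval is the hull of
the two end placements. Failed pairs fall back to single-end records
(configurable to discard). Integration keeps wells present in one source
as-is; where both sources place a well, agreement (same chromosome,
boundaries within 1 kb) keeps the long-source coordinates (long sequences
are an order of magnitude longer, hence more specific); disagreement is
arbitrated by cross-source sequence identity of an end (≥ 0.99 over the
shorter), and irreconcilable wells are dropped and counted. GFF3 output
writes exactly three lines per paired clone (parent + two end children) and
two per single-end clone, 1-based inclusive — the only 1-based surface of
the package; everything internal is 0-based half-open, and the round-trip
test pins the conversion.

Gap statistics treat a gap (maximal N-run) as covered only when a `PAIRED`
clone interval strictly contains it: a single-end placement bounds the
clone on one side only, so strict spanning is the conservative definition
useful for gap filling.

## What the simulator emulates — and what it does not

`simulate_genome()`/`place_clones()`/`simulate_pool_reads()` generate a
random-background genome with planted N-run gaps and near-identical
dispersed repeats, one HindIII-bounded clone per well (insert lengths from
a truncated normal snapped to the nearest feasible site pair, either
insertion orientation), and indexed paired-end pool reads with
substitution errors, E. coli-style host contamination and optional
organelle-derived wells. All randomness flows from one seed; identical
seeds give identical reads.

Deliberate simplifications: substitution-only errors (no indels, hence the
ungapped aligner is exact on simulated data), flat quality strings except
at errored bases, fragment sampling from the linearised molecule (only the
two junctions matter; circularity is ignored), uniform pool depth, and a
repeat landscape far simpler than a real plant genome's. Passing tests
therefore demonstrate the pipeline's logic — deconvolution, thresholds,
coordinate bookkeeping — not robustness to real Illumina artefacts,
indel-rich alignments, or the repeat content of an 850 Mb genome, where the
external-assembler path and a production aligner would carry more of the
load.

Clone placement samples forward (start) sites without replacement and
prefers unused reverse (end) sites, because the two end types are matched
in independent flows: a shared start site would make two clones' forward
sequences identical and cost both wells that end under `STRICT`. At the toy
scale (96 clones, ~140 HindIII sites per 500 kb) occasional end-site reuse
is tolerated and degrades the two wells to single-end placements rather
than failing the run. The insert-length truncation band is symmetric about
the mean (toy preset 1.5–8.5 kb around 5 kb) so that site snapping — which
runs out of short-side candidates at the band floor — leaves the realized
mean unbiased; the production-scale preset keeps the published 50–300 kb
band around 123.48 kb.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `min_vector_anchor` | 20 bp | vector evidence required at a junction |
| `short_min_overlap` / `short_min_identity` / `short_min_depth` | 50 bp / 0.95 / 3 | junction-read clustering and consensus depth |
| `asm_min_overlap` / `asm_min_identity` | 40 bp / 0.98 | assembler merge rule |
| `share_min_identity` / `share_min_cov` | 0.99 / 0.9 | row-column sequence sharing |
| `map_min_identity` / `map_min_qcov` | 0.99 / 0.99 | genome placement contract |
| `seed_k` | 21 | alignment seed and masking k-mer length |
| `culling_overlap` | 0.5 | hit-domination fraction |
| `max_span` | 250 kb | paired-placement interval cap |
| `min_agreement_identity` | 0.99 | cross-source integration evidence |
| `max_mismatch` (demux) | 0 | exact 7-bp index matching |
| `host_k` / `host_hit_fraction` | 21 / 0.5 | host k-mer screen |

The thresholds the source method left unstated (anchor length, clustering
and assembler parameters, sharing thresholds) are package defaults chosen
as described above and are all exposed through `capss_config()`.

## Verification scale

The test suite runs the whole pipeline on the toy preset — a 2 x 2 plate
grid of 4 x 6-well plates (96 clones), a 500 kb single-chromosome genome
with three 500 bp gaps, 5 kb mean inserts, depth 30 per pool, 0.1%
substitution error, 2% host reads — and on a 6-well variant for the module
tests; these sizes exercise every stage (a few hundred thousand read pairs,
~20 assemblies) in a few minutes on one core. Alignment is additionally
checked against a brute-force oracle on 200 random genome/query instances
and the N50 statistic against its exhaustive definition on 1000 random
lists.

## Known limitations

* The built-in assembler is contractually adequate for simulated pools,
  not competitive with production assemblers on real data; pool-scale
  contig FASTA from an external assembler is the intended production path.
* The aligner is ungapped; indel-containing end sequences would need a
  banded gapped extension to place under the 0.99/0.99 contract.
* The whole genome k-mer index lives in memory, which suits the simulated
  scale; chromosome-scale production genomes would require an on-disk
  index or an external aligner behind the same placement contract.
* The two-overlapping-clone rectification from earlier array-pooling work
  is not implemented; `STRICT` filtering (with genome-level rescue through
  integration) stands in for it.
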