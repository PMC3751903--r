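---
title: "Detecting chimeric transcripts from assembly contigs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chimeric transcripts from assembly contigs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimdetect)
```

## The problem

De novo transcriptome assembly reconstructs transcripts without a
reference, so contigs derived from chimeric RNAs — gene fusions, partial
tandem duplications (PTDs, duplications of whole exon runs whose edges
coincide with annotated exon boundaries), and internal tandem
duplications (ITDs, duplications with at least one sub-exonic edge, the
FLT3 pattern in leukemia being the canonical example) — survive assembly
as first-class sequences. Aligning such a contig back to the genome with
a long-read spliced aligner produces a characteristic *non-collinear*
signature: the contig either splits into two alignments, or aligns once
with an unalignable query gap. `chimdetect` detects these signatures,
quantifies the read evidence directly supporting each putative junction,
filters common artifact classes, types the surviving candidates, and
estimates the expression of the chimera relative to its co-expressed
wild-type transcripts.

The input contract is deliberately aligner-agnostic: contig-to-genome
alignments in PSL, read-to-contig (and optionally read-to-genome)
alignments in SAM/BAM, gene models in UCSC genePredExt, and annotation
tracks in BED. All internal coordinates are 0-based half-open; reports
are written 1-based inclusive.

## Stage 1: choosing the alignments that explain a contig

For a contig $C$ with alignment set $A(C)$, each subset $A^*(C)$ is
scored as

$$\mathrm{score} = \mathrm{quality} + \mathrm{inclusion} -
  \mathrm{overlap} - \mathrm{size},$$

where *inclusion* is the fraction of contig positions aligned by at
least one member, *overlap* the fraction aligned by more than one,
*size* the member count, and *quality* the sum of per-alignment
qualities.

**Per-alignment quality.** We normalize quality as
$(\mathrm{matches}-\mathrm{mismatches})/(\mathrm{matches}+\mathrm{mismatches})$,
clamped to $[0,1]$: monotone in both the aligner score and percent
identity, and independent of how much of the contig the alignment
covers. The independence matters: if quality were instead scaled by
covered fraction, any piece covering less than half the contig would
contribute `quality + marginal inclusion − 1 < 0` to the set score, and
score maximization would always discard the smaller piece of a genuine
two-piece fusion contig. Coverage belongs to the inclusion term, not to
quality.

**Selection.** If one gap-free alignment already has inclusion above
`case1_inclusion_min` (0.95), the contig is non-chimeric and skipped.
Otherwise alignments are grouped transitively by pairwise
contig-coordinate overlap (threshold 0.10 of the contig), and the chosen
subset takes at most one member per group. Because groups are tiny, we
solve this selection exactly by enumeration (score-maximizing, quality
as tie-break) rather than greedily by quality; within a group the
quality term dominates, so the two almost always coincide, but the exact
form makes the optimality property testable. Members whose quality lies
within 0.05 of their group's best are kept as alternates and flagged
multi-mapping.

The subset's cardinality classifies the contig: one clean alignment
(done), one gapped alignment (gap-candidate), a pair (split-candidate),
or three and more (left uncharacterized). Alignments to mitochondrial
sequence (`chrM`, `chrMT`, `MT`, `M`; configurable) are discarded by
default.

**Topology.** An ordered pair of alignments is labeled
`interchromosomal`, `inversion` (same chromosome, different strands),
`duplication` (same chromosome and strand, overlapping genomic
intervals), or `eversion` (same chromosome and strand, genomic order
reversed relative to contig order). A fifth label, `read_through`, covers
the same-strand in-order disjoint configuration, which fits none of the
four non-collinear classes but is still a legitimate (deletion-type)
fusion signature; without it the labeling would not be total.

**Gap realignment.** A query gap $C[i,j]$ (minimum 4 nt, the smallest
duplication unit worth realigning) is explained by Smith–Waterman
realignment (match +1, mismatch −1, gap open −2, gap extend −1, via
`Biostrings::pairwiseAlignment`): first against the contig with the gap
masked out (tandem duplication), then — for internal gaps — against the
genomic window between the gap-flanking bases' mates, in both
orientations (inversion). Success requires ≥ 90% of the gap aligned at
≥ 95% identity; when both attempts succeed the duplication is kept (the
shorter explanatory distance) and the conflict recorded. Because ITDs
often carry a few inserted bases between the copies, a realignment's
*core* is obtained by trimming through any non-match column within six
columns of either alignment end; chance matching of one or two inserted
bases at the boundary otherwise dilutes identity and shifts the inferred
copy edge. The residue `gap length − core length` is reported as the
ITD's inserted bases.

## Stages 1.2–1.3: grouping and annotation

Meta-assemblies represent one event in several contigs. Candidates join
one group (single linkage) when they share the chromosome pair and
orientation signature and both breakpoints lie within 10 nt. The
signature orders the two sides canonically by genomic position and
complements both strands when the ordering swaps the sides, so a contig
and its reverse complement group together. Groups may mix gap- and
split-candidates.

Genes are assigned per side when any exon of any transcript intersects
any alignment block (contigs are transcript-derived, so intronic-only
overlap does not count). Each breakpoint either matches an annotated
exon boundary — the first or last base of any exon, exact by default —
or not; the tolerance is configurable and the both/one/neither summary
is monotone in it. For duplication-family candidates the breakpoints are
the first and last genomic positions of the duplicated segment (the
union span of the two genomic intervals, or the realigned copy's span
for gap candidates).

## Stage 2: read support

Sequence homology around a junction makes the exact breakpoint position
ambiguous, so support is computed over a search region $P$ on the
contig: the contig-coordinate overlap of the two alignments extended by
1 nt each side (two junction-flanking bases when they abut), or, for
gap duplications, the interval between the two copies. At each position
$p \in P$, $R(p)$ counts reads aligned to the contig with no mismatches
(NM = 0 and a single match-run CIGAR — junction evidence must be exact)
overlapping $p$ by at least `min_flank` = 5 nt on each side. The
reported support is $\min_p R(p)$: a floor on junction-spanning evidence
wherever the true breakpoint lies. Reads are counted per alignment
record; a pair may contribute two.

A read $r$ mapping to contig set $C(r)$ *strongly* supports an event
represented by contig group $E$ when
$|C(r) \cap E| / |C(r)| \ge 0.5$; otherwise weakly. Both totals are
reported, and the strong count feeds the read-support filter.

## Stage 3: the ten filters

All ten filters are always evaluated (no short-circuit) so review output
lists every violation: (1) contig in more than 3 candidate groups;
(2) multi-mapping; (3) homopolymer gap (every base of the realigned gap
portion identical — gap-candidates only); (4) breakpoints in annotated
repeats (off by default); (5) breakpoints in structural RNA regions;
(6) either alignment's identity below 99.0%; (7) union inclusion of the
pair below 0.9 (union coverage, so overlapped positions are not double
counted); (8) fewer than 5 strongly supporting reads; (9) more than
75 nt of contig-coordinate alignment overlap (a read length); (10) a
poly(A)-tail misalignment — one alignment covering only a terminal run,
T's at the contig start or A's at the end, at least 8 nt long and ≥ 90%
one base.

## Stage 4: event typing

Fusions come from split-candidates of any topology whose sides overlap
only distinct genes and are genomically disjoint; whether transcription
direction is maintained is reported, and no exon-boundary condition
applies. PTDs are split-candidates with duplication or eversion topology
(short junction contigs spanning the non-canonical exon junction between
the copies) in a single gene with *both* breakpoints on exon boundaries;
the same pattern with at least one off-boundary breakpoint is a long
ITD. Short ITDs come from gap-duplication candidates with an
off-boundary breakpoint; a gap-duplication whose breakpoints both sit on
boundaries is routed to PTD. Junctions from the end of the last exon
back to the start of the first are indistinguishable from circular
isoforms in poly(A)-selected data and are labeled PTD by convention.
Typing is deterministic and assigns at most one label.

As a post-filter, predictions whose contig (or its reverse complement)
aligns full-length and collinearly to any single wild-type transcript
are removed: coverage ≥ 95% of the contig at ≥ 98% identity in one
monotone alignment *containing no indel longer than 5 nt*. The indel cap
is essential — a short ITD differs from its wild-type transcript only by
one 15–50 nt insertion and would otherwise clear the coverage and
identity bars.

## Stage 5: relative coverage

Two genomic regions A and B are built from the alignment blocks on each
side of the breakpoint, cut from the far end or extended along the
annotated transcript structure until each holds $2\ell$ nt of transcript
($\ell$ = read length); a region hitting a transcript end is truncated
and flagged. Using read-to-genome alignments, the depth at each region
position $s$ (reads overlapping by ≥ q = 5 aligned bases each side)
partitions as $T = DW + T_1 + T_2$: reads spanning a wild-type junction
or adjacency that the chimera destroys ($DW$ — for fusions, reads whose
alignment continues across the breakpoint; duplications have no
operationally identifiable $DW$), reads at positions inside the
duplicated segment ($T_2$), and everything else ($T_1$). Assuming a
single extra copy per duplication, the wild-type depth estimate is

$$W(r,s) = DW + I_1 (T_1 - C) + I_2 (T_2 - 2C),$$

with $C$ the junction's read-to-contig support and $I_j$ indicating
$T_j > 0$; negative intermediates are clamped at zero and flagged.
$W(r) = \max_s W(r,s)$, $T(r)$ is the largest total among positions
attaining $W(r)$, and the starred values average A and B. Seven depths
and the six ratios $C/W(r)$, $C/T(r)$ are reported; a non-positive
denominator yields an infinite sentinel rather than an error. For
fusions the A and B ratios describe two different genes and are read
separately; for duplications the starred averages are the headline
values.

At desk-scale coverage (tens of reads) the max-based $W$ and $T$
statistics carry upward sampling bias while $C$ is a minimum, so a
single event's $C/T(*)$ is noisy (relative spread roughly a third at
60×). Mixture-recovery checks therefore average the estimate over 24
independent implanted fusions, which is unbiased in our simulations to
within ±0.05 across chimeric fractions 0.1–0.5.

## The synthetic-data module

`simulate_genome` builds random chromosomes with non-overlapping
multi-exon gene models (defaults: 3–6 exons of 150–400 nt, introns
200–600 nt, all plus-strand). `simulate_events` implants fusions (5′
exons of one gene joined to 3′ exons of another, on different
chromosomes when available), PTDs (whole exon runs duplicated; emitted
as 150 nt junction contigs, one read length each side of the junction),
and ITDs (15–45 nt sub-exonic segments duplicated in place with up to 3
inserted bases, kept below a tenth of the segment as in FLT3-style
events; emitted as full-length contigs). Products shorter than 200 nt
are discarded. `simulate_reads` draws per-transcript coverage from a
two-component log-normal mixture and places error-free 75 nt pairs with
fragment length 114 ± 10 nt, so mates overlap, as in short-fragment
libraries. The mixture defaults (log-means log 12 and log 65, log-SDs
0.7 and 1.0, weight 0.45) give a long-tailed distribution with median
near 30×, a figure chosen as a realistic bulk-expression reference
point; the exact parameters are exposed, not claimed to match any
particular dataset. `synthesize_alignments` then emits the alignments a
perfect aligner would produce — split PSL pairs for fusions and PTD
junction contigs, single gapped alignments for ITDs, perfect
read-to-contig records for reads wholly inside a contig, and spliced
read-to-genome records with junction-spanning reads soft-clipped to
their longer side.

What passing on these fixtures shows — and what it does not: the
pipeline's logic is exercised end to end without an assembler or
aligner, but real data adds sequencing error, misassembly, alignment
ambiguity in repeats, minus-strand genes, alternative isoforms and
coverage far below the filter thresholds; recovery rates on the
synthetic conditions are upper bounds, not forecasts.

## Numerical choices and degenerate inputs

Score comparisons in subset selection use a $10^{-12}$ tolerance with
total quality as tie-break; grouping is order-independent (union-find
over a symmetric predicate); empty breakpoint regions are an error
(malformed candidate) while empty transcript sets make the wild-type
filter vacuous; an empty prediction list writes a header-only report.
Report rows sort by (event type, chromosome, breakpoint) so reruns are
byte-identical. Test and acceptance problem sizes — 200 random contigs
for the metric oracle, 500 read layouts for the support oracle, 20
genes × 30 events for end-to-end recovery, 24 fusions per chimeric
fraction for mixture recovery — were chosen as the smallest sets whose
Monte-Carlo spread is well inside the asserted tolerances.

## Known limitations

Case IV contigs (three and more pieces, e.g. double fusions) are labeled
and dropped; the simulator does not model minus-strand genes, sequencing
error or quality scores; reading-frame annotation and repeat-expansion
subtyping are out of scope; the relative-coverage estimator assumes a
single extra copy per duplication and inherits the small-sample biases
described above; and mate-pair information is not used to deduplicate
read support (reads are counted per alignment record).
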