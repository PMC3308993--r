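---
title: "plastidcomp: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastidcomp: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidcomp)
```

## The scientific setting

Plastid chromosomes are small circular genomes, typically organized into
four parts: a large single-copy region (LSC), a small single-copy region
(SSC), and two near-identical inverted repeats (IRA/IRB) that usually
carry the rRNA operon. When a plastid is acquired secondarily — a
eukaryote engulfing an alga that already carried a plastid, as in
photosynthetic euglenids whose plastid derives from a *Pyramimonas*-like
green alga — the organellar genome is reshaped on two very different
clocks. Gene **content** is pruned early: genes are either lost outright
or relocated to the host nucleus (endosymbiotic gene transfer, EGT),
after which the surviving gene set freezes to an essential core. Gene
**order** and intron content, by contrast, keep diverging long after the
content has stabilized. `plastidcomp` implements the comparative
measurements behind that picture: per-genome feature summaries,
architecture detection, a gene-order conservation statistic, gene-content
set algebra, a gene-fate classifier, coverage-based organelle binning for
assemblies, and relative node ages on clock trees — plus a synthetic
genome generator so that all of it is testable with known ground truth
and no downloads.

## Data model and coordinates

All positional data live in 0-based half-open intervals; file readers and
writers convert to and from the 1-based inclusive convention of GenBank
and GFF3 exactly at the boundary (a lossless round-trip covered by
property tests). Intervals on circular sequences may wrap the origin
(`wraps = TRUE`) and their lengths are computed modulo the genome length;
wrapping features (e.g. a CDS spanning the origin, serialized as
`join(a..L, 1..b)`) are folded into a single wrapping segment on input.

A `gene_feature` is one annotated locus of type CDS, tRNA or rRNA with
one or more exon segments in transcription order; more than one segment
encodes introns, and `intron bases = span − exon bases` always holds.
"Conserved gene" is operationalized as: normalized name does not match
`orf<digits>`. Gene names are normalized (conventional casing such as
`psbA`/`rpoC1`, tRNA labels canonicalized to `trn<AA>-<anticodon>` when
parseable) through an extensible alias table packaged as a two-column
TSV; the packaged table maps `ycf13 → mat1` and `rpl3 → ycf65` (the same
putative ribosomal protein has been annotated under both labels; `ycf65`
was chosen as the canonical side). Normalization is idempotent, a tested
invariant, so labels can safely pass through the pipeline repeatedly.

Only the GenBank flat-file layout is parsed (not EMBL's ID/FT variant):
no GenBank reader exists in the supported dependency set, so a minimal
parser is implemented here, restricted to the constructs the pipeline
emits and consumes (LOCUS topology, join/complement locations, ORIGIN).
GFF3 is read as the 9-column TSV it is, with FASTA via Biostrings.

## Feature summaries

`summarize_genome()` computes the comparison-table row. Where published
tables leave conventions implicit, the following choices are made and
tested:

* **Gene-unique loci** collapse only IR-resident duplicates: two loci
  collapse when both lie within the IR intervals and share normalized
  name and feature type. Tandem paralogs elsewhere are not collapsed.
  With no partition supplied, the count is simply the number of
  features.
* **rRNA/tRNA totals** sum bases over *all* copies while the count is of
  distinct (name, type) species — deliberately different conventions in
  one row, documented because published tables use exactly that mix
  (e.g. 2 rRNA species but ~8.9 kb of rRNA when both IR copies are
  summed).
* **Intergenic bases** are bases covered by no feature span at all;
  **overlapping bases** are covered by ≥ 2 spans, counted once. This
  reproduces the published arithmetic: genome size − intergenic equals
  the span sum minus overlap.
* **Rounding** happens only at the reporting layer: GC to 2 decimals,
  density (CDS per kb) to 3, coding percentage to 1, all half-up;
  average CDS length is floor-rounded. Published values round these
  quantities inconsistently (e.g. an average length printed as 692 where
  the quotient is 692.95, and an intron total printed as 1630 where the
  stated intron lengths sum to 1632); the package reports computed
  values and does not force agreement.

## Inverted repeats

`detect_inverted_repeats()` is a seed-and-extend detector without
indels, which is the right model for plastid IR copies that differ by a
handful of substitutions:

1. **Seeding.** Anchor k-mers (k = 21) taken every ⌊k/3⌋ bases of the
   forward strand are matched exactly against the reverse complement
   (`Biostrings::matchPDict`, C-level). An indel-free inverted match
   stays on one anti-diagonal (i − j constant), so seeds are grouped by
   diagonal; hyper-repetitive seeds (> 10 matches) are skipped. A repeat
   is seeded whenever it contains a clean window of k + step − 1 ≈ 28
   bases, which sparse substitutions allow.
2. **Extension and trimming.** Each diagonal run is greedily extended
   outward to the next matching position while the cumulative mismatch
   rate stays within `max_mismatch_rate` (default 0.01), then trimmed to
   the maximal-scoring sub-window (match +1, mismatch −3; ties toward
   the longer window), and the two steps are iterated to a fixpoint.
   The score trim is essential: at a 1% rate a 6 kb hit carries a
   ~60-mismatch budget, so rate-bounded extension alone walks far into
   random flanking sequence, and trimming only *terminal* mismatches
   would keep chance flank matches (a flanking base pairs with
   probability 1/4). The −3 mismatch penalty makes random sequence
   score-negative in expectation (0.25·1 − 0.75·3 < 0), so the maximal
   window ends at the true repeat boundary with high probability. The
   fixpoint iteration matters too: a one-sided overshoot can exhaust the
   budget before the other side has passed a legitimate interior
   mismatch, and re-extending after the trim releases it.
3. **Reporting.** Overlapping hits collapse to the longest; output is
   sorted by length descending, ties by smaller start. Hits whose copies
   would cross the circular origin are not searched for — genome
   numbering conventions place the origin in single-copy sequence, and
   the simulator does the same.

The detector reports the *sequence-defined* repeat length, which may
legitimately differ from an annotation-derived figure (rRNA genes plus
spacer need not add up to the homologous repeat length); nothing is
tuned toward any particular published value.

## Quadripartite partition and insertions

Given the top repeat hit on a circular genome, the two arcs between the
copies are the single-copy regions; the shorter (after insertion
carving) is the SSC. Real plastid IRs can carry single-copy *insertions*
— blocks of genes present in only one copy. Because the detected repeat
is by construction the exactly-repeated sequence, such blocks manifest
as gene runs immediately adjacent to one IR boundary. The carving rule
is annotation-driven: a maximal run of features that starts within
`max_gap` (default 150 bp) of an IR edge, has internal gaps ≤ `max_gap`,
and is terminated by a spacer > `max_gap` before the rest of the arc is
reported as an insertion and excluded from LSC/SSC. A run that would
absorb an entire arc is not an insertion (so a gene-dense SSC is not
swallowed). The reported intervals — IRA, IRB, LSC, SSC, insertions —
tile the circle exactly, a tested invariant. Arcs of length zero
(adjacent repeat copies) set a `degenerate` flag.

## Strand switch

Plastid genes typically occupy two arcs of consistent coding strand.
`detect_strand_switch()` searches **all** ordered pairs of inter-gene
boundaries (exhaustive, O(n²) with prefix sums) for the two-arc
partition maximizing the number of genes on their arc's majority strand,
and reports the achieved consistency plus the genomic switch positions
(midpoints of the intergenic gaps). All genes on one strand returns no
switch points and consistency 1. Equivalence with a brute-force oracle
is tested for up to 40 genes; boundary pairs describing the same
bipartition are interchangeable, so the oracle compares consistency.

## Tandem repeats

`find_tandem_repeats()` scans each period p in [5, 100] for maximal runs
of `seq[i] == seq[i+p]`; a run of length r spans r + p bases and is
(r+p)/p copies, reported when ≥ `min_copies` (default 2.5) with a
majority-vote consensus unit. Copy numbers are fractional by design
(e.g. 3.4 × 33 bp) and rounded to 1 decimal only in reports. A locus is
reported at its primitive period only: a run whose consensus unit is
itself perfectly periodic with a shorter period is suppressed, which
both removes nested multiples (period 2p at the same locus) and keeps
homopolymers from reappearing at every scanned period.

## Shared adjacencies (synteny)

The gene-order conservation statistic is the number of neighboring gene
pairs common to two genomes: genes are ordered by start coordinate
around the circle, each genome with n retained genes contributes exactly
n unordered adjacent pairs (n − 1 if linear, wrap-around pair included
if circular), and the statistic is the multiset intersection of the two
pair sets. The published counts this reproduces state no convention, so
every switch is a policy field: feature types included (default
CDS+tRNA+rRNA), unnamed ORFs excluded (default), IR duplicates collapsed
to one copy (default, using the quadripartite partition), strand always
ignored. Nested genes are kept at the position of their start
coordinate. Tested invariants: symmetry; self-comparison equals n;
equivalence with a rotation-enumeration oracle (≤ 30 genes); and the
inversion bound — k random segment inversions break at most 2k
adjacencies, so `shared_adjacency(G, invert^k(G)) ≥ n − 2k`.

## Gene content and gene fate

`content_partition()` is exact set algebra over normalized gene names
(2–4 genomes, all 2^k − 1 membership regions; protein-coding only by
default). `classify_fates()` encodes the EGT inference as a decision
rule over two inputs — membership of each reference gene in the
descendant plastid sets, and a transcriptome presence/absence evidence
table:

| plastid sets | evidence | fate |
|---|---|---|
| all | — | `retained_plastid` |
| proper subset | — | `lost_post_split` |
| none | all sources | `transferred_ancestral_both` |
| none | proper subset | `transferred_ancestral_lost_in_one` |
| none | none | `lost_completely` |

Genes in a plastid set but not the reference are
`lineage_specific_gain`. The evidence is deliberately an *input table*
(optionally thresholded from a tabular homology-search export at
e ≤ 1e-10), not a computed search, so the classifier is exact,
order-invariant and testable offline; the cost is that `lost_completely`
means "no transcript observed" and inherits any incompleteness of the
transcriptomes — a caveat, not a category.

The packaged worked-example fixture ships the worked-example gene sets: a
24-gene missing set (10 NADH-dehydrogenase-complex genes; petA, petN,
chlL, chlN, chlB, ccsA, psaI, infA, clpP, ftsH; ycf3; and three
unknown-function placeholders named ycfx1–ycfx3), evidence positive in
both transcriptome sources for petA, petN, ycf3, clpP, ftsH and in one
source for ccsA, and lineage-specific sets of 5 and 8 genes. The shared
core behind them is a representative standard plastid gene list — a
documented synthetic stand-in, since no full list is printed — and the
source texts disagree internally on its size (57 stated in one place,
31+5+21+mat1 = 58 enumerated in another); the fixture ships the
enumeration. The classifier's headline counts (6 transferred, 18 lost)
depend only on the missing set and evidence, not on the core list.

## Coverage binning

Organellar contigs in a total-DNA assembly share a characteristic
fold-coverage. "Similar coverage" is operationalized as the symmetric
fractional window `[min(seed cov)·(1−t), max(seed cov)·(1+t)]`
(inclusive; default t = 0.25) around homology-identified seed contigs;
seeds are always selected, non-seeds additionally need length ≥ 500.
Selection is superset-monotone in t (tested). The number of extra
contigs this selected in the original assembly depends on the raw read
set and is not a target.

## Chronology

`node_age_ratio()` consumes ultrametric trees (all root-to-tip paths
equal within relative tolerance 1e-6 — a hard error otherwise, since
node heights are only ages on an ultrametric tree) and returns
height(MRCA(old)) / height(MRCA(young)). When per-node 95% intervals are
supplied — via a sidecar TSV keyed by the taxa whose MRCA is the node;
BEAST metacomment parsing is intentionally not implemented — the ratio
interval is `[low_old/high_young, high_old/low_young]`, which always
contains the point ratio. Reciprocal ratios multiply to 1 (tested). No
clock inference is performed; trees are consumed, not estimated.

## The simulator: a stated world

`simulate_genome()` generates the world the analyses are tested against,
with defaults fixed at the regime the package targets: a 60 kb circle at
GC 0.34; an IR of 6000 bp per copy carrying a 16S (1400 bp) and a 23S
(2900 bp) gene plus a non-coding spacer with two planted tandem repeats
(3 × 11 bp and 3.4 × 33 bp); 3 substitutions between the IR copies,
planted inside the mirrored 23S; an 8-gene single-copy block inserted
next to one IR copy and a single tRNA next to the other; an SSC of
~1.2 kb holding one unnamed ORF; 42 single-copy CDS (two of them
intron-containing) and 17 tRNAs in the LSC; and a coding-strand switch
planted at 2/3 of the gene order, with the second switch in the SSC so
each IR copy sits in a different strand arc (the only two-arc layout
consistent with the copies being reverse complements of each other).
Background sequence is i.i.d. at the target GC; CDS are random ORFs
(start/stop codons, no in-frame stops, no codon-usage realism); layout
gaps are fixed small constants except the LSC gaps, which absorb the
multinomially-distributed slack. Generation is deterministic per
(config, seed) down to the serialized bytes.

Two deliberate sharpenings make planted truths well-defined: two forced
mismatching base pairs flank each IR copy (real IR boundaries are sharp;
without this, the planted "repeat length" would be ill-defined up to
chance flank matches), and IR substitutions are planted ≥ 100 bases from
the copy ends. Tandem-repeat arrays likewise get periodicity-breaking
bases at both ends.

What a green round-trip test establishes: that the analysis operations
exactly invert the generator on noise-free structured input — every
summary field equals planted truth, IR coordinates/mismatches recover
exactly over 50 seeds, insertions and SSC are carved as planted, planted
fates classify back perfectly. What it does not establish: robustness to
real annotation noise (inconsistent naming beyond the synonym table,
overlapping or mis-bounded features), IRs interrupted internally by
large insertions (which surface as two hits, not one), repeats or
features crossing the chosen origin, sequencing error, or base
composition beyond i.i.d. The published-record reproduction criterion
exists precisely to cover the real-data path and is reported honestly as
unavailable offline.

`apply_inversions()` rearranges gene order by reverse-complementing the
spanned sequence block and remapping the features (strands flipped,
segment order reversed), recording every inverted run — the fixture
behind the inversion-bound property. `simulate_fate_scenario()` and
`simulate_contig_table()` plant fate and coverage truths; the contig
model is bimodal (plastid ~N(32, 2²)×, nuclear ~N(5, 1²)×, 20 of 200
contigs plastid — separations chosen to match the regime where
coverage binning is actually used).

## Command-line interface

All stages are exposed by one launcher (`inst/scripts/plastidcomp`):
`summarize`, `ir`, `vntr`, `synteny`, `content`, `fate`, `bin-contigs`,
`chrono`, `simulate`. Reports are TSV (primary) or JSON (`--json`);
rounding is applied only when reporting; exit status is 0 on success, 1
on data errors, 2 on usage errors. Config files are JSON (the supported
dependency set has no YAML parser); `simulate` writes `genome.gb`,
`genome.gff3`, `genome.fasta` and `truth.json`.

## Known limitations

* IR pairs crossing the circular origin are not detected; rotate the
  origin into single-copy sequence first.
* The IR model is substitution-only (no indels), appropriate for
  near-identical plastid IRs but not for diverged repeats.
* EMBL flat files are not parsed (GenBank layout only); GFF3 attribute
  handling covers ID/Name/gene.
* `lost_completely` is evidence-bounded: absence of a transcript is not
  proof of loss.
* The strand-switch search models exactly two arcs; genomes with more
  strand blocks get the best two-arc approximation, quantified by the
  consistency score.
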