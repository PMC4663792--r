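---
title: "Methods: map-based scaffold anchoring, comparative statistics and LD decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map-based scaffold anchoring, comparative statistics and LD decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomap)
```

This vignette documents the models and rules `pseudomap` implements, the
parameters that matter, the numerical and design choices made where the
problem was genuinely open, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## The anchoring problem

A draft assembly is a set of scaffolds with no chromosome assignment. Two
kinds of evidence can anchor them:

* **Genetic markers.** A marker with a known linkage group (LG) and
  centimorgan (cM) position that aligns inside a scaffold assigns that
  scaffold to the marker's LG, at roughly the marker's cM position. Because
  cM increases monotonically along a chromosome, several markers also order
  and orient scaffolds.
* **BAC-end sequences (BES).** Each BAC clone belongs to a physical-map
  (FPC) contig — a fingerprint-assembled group of clones covering a
  contiguous genomic region. When the ends of clones from one contig align
  to two scaffolds, those scaffolds are physical neighbours; a scaffold
  with no markers can therefore be placed next to a marker-placed scaffold
  from the same contig.

The pipeline consumes marker alignments (PSL or BLAST tabular), two
genetic-map tables, BES alignments with a BAC-to-contig membership table,
and the scaffold FASTA; it emits placements, split decisions, link calls,
and gap-padded pseudomolecules as FASTA + AGP v2.1.

## Marker stage

**Alignment filter.** A hit is retained iff identity > 0.9 **and** query
coverage > 0.9 — strict inequalities, so a hit at exactly 90% is dropped.
PSL identity is computed as `matches / (matches + misMatches)`, ignoring
`repMatches` and N counts: the simplest defensible reading, since BLAT's
own percent-identity formula involves gap corrections that cannot be
reconstructed from the retention rule alone. BLAST tabular lacks the query
length, so coverage uses an external length table. Readers never filter;
all thresholding is downstream and therefore testable in isolation.

**Dual-map merging** (`merge_map_positions()`). Markers may appear in a
previously published map, a newly built map, or both. When both position a
marker and the positions differ by more than 30 cM, the new value is
discarded in favour of the published one; otherwise the arithmetic mean is
used; a single source is used as is. The 30 cM comparison is made per
marker, before any per-scaffold voting — the alternative order (vote
first, merge later) would let a corrupted position influence the vote it
is later judged against. Markers whose two maps name different linkage
groups are removed outright (`discordant_unresolvable`): there is no
principled way to average linkage groups.

**Per-scaffold resolution** (`resolve_scaffold_lg()`). Multi-position
("ambiguous") markers are tagged and retained but never decide a linkage
group alone: voting uses single-position markers when any exist, and a
scaffold supported only by ambiguous markers needs at least two of them in
agreement. A single marker dissenting against two or more agreeing markers
is removed as a dissenter — implemented literally as count 1 versus
count ≥ 2; larger minorities are not removable and instead trigger the
split logic.

**Chimera splitting.** When two linkage groups each hold at least two
markers, the scaffold is a candidate chimera. The implementation searches
for the two-segment coordinate partition minimizing cross-assigned
markers; a split is accepted when each segment retains a majority of at
least two markers of its own linkage group and the cross-assigned markers
are a strict minority on their side. Those violators are removed as
dissenters — the single-dissenter principle applied per segment, which is
what makes splits robust to an isolated wrong-LG marker sitting inside one
half. Ties on the violation count go to the partition whose *weaker* side
has the most support; remaining ties resolve to the leftmost cut, making
the outcome order-invariant and deterministic. Truly interleaved groups
(e.g. alternating membership) admit no valid partition and the scaffold is
left unplaced with an `interleaved` flag. The split position is the
midpoint between the innermost majority markers of the two segments — the
marker evidence cannot localize the breakpoint more precisely than the
interval between its flanking markers, and the midpoint is the symmetric
choice. With three or more ≥2-marker groups (possible when corrupted
markers happen to agree), partitions are searched over every pair of such
groups. Split children are renamed `<id>_1`/`<id>_2`, their markers are
reassigned with shifted coordinates, and the children are re-resolved like
any other scaffold.

## Physical-link stage

**Sink filtering.** A repeat-derived "sink" contig aggregates clones from
all over the genome and would link everything to everything. Known sink
ids can be given explicitly; in addition, automatic detection flags any
contig whose scaffold degree (number of distinct scaffolds its clone ends
hit) exceeds the mean plus three standard deviations of the *other*
contigs' degrees. The leave-one-out form matters: an extreme sink inflates
the pooled standard deviation enough to mask itself (degrees
{2, 2, 3, 3, 40} have pooled mean + 3·SD ≈ 60, hiding the 40), while
against the remaining degrees {2, 2, 3, 3} the threshold is ≈ 4.2 and the
sink is caught. Auto-detection needs at least three contigs.

**Link classification** (`classify_links()`). Per scaffold, accepted BES
alignments are counted per contig and the top contig's link is classified
in order: *unique* — every alignment to one contig, with at least
`min_total_unique = 2` alignments; *dominant* — the top contig holds more
than 50% of at least `min_total_dominant = 4` alignments; *strong* — the
top count is at least `strong_ratio = 2` times the runner-up and at least
`strong_min = 3`; anything else, including a tie for the top contig, is
rejected. The dominant minimum and the strong ratio quantify the
qualitative notions of "a minimum number of total alignments" and
"significantly higher": with single-digit counts a formal test is
unstable, so explicit reproducible thresholds are used, and all four are
configuration parameters.

**Propagation** (`propagate_placement()`). An unplaced scaffold with an
accepted link to contig *C* is placed on the linkage group of a
marker-placed scaffold that also links *C*, inserted immediately **after**
that anchor (same cM key, increasing sub-rank) with orientation `?`:
the shared contig says "adjacent", not "before" or "after", so the
insertion side is a convention and the orientation is honestly unknown.
When several anchors share the contig, the one with the most supporting
alignments wins (ties by scaffold id); anchors disagreeing on the linkage
group abstain with a logged conflict. Placed scaffolds are never moved, no
scaffold is placed twice, and scaffolds that were split are excluded as
candidates (their halves already went through the marker stage).

## Pseudomolecule construction

Scaffolds are ordered within each linkage group by `cm_key` — the mean
resolved cM of the supporting markers — with lexicographic scaffold-id
tie-breaks; markers at a single cM cannot order scaffolds, so the
tie-break is purely for reproducibility. Orientation is the sign of the
Kendall-type concordant-minus-discordant pair count between scaffold
position and cM: `+` if cM increases along the scaffold, `-` if it
decreases, `?` when fewer than two distinct-cM markers are available or
the signal is balanced. Emission concatenates the (possibly
reverse-complemented) scaffolds with a fixed 10 kb `N` gap at every join —
a single configurable gap length, since no evidence class here justifies
evidence-specific gap sizes. `?` components are emitted forward but keep
`?` in the AGP, so downstream users can distinguish asserted from assumed
orientation. AGP rows are 1-based inclusive (the AGP v2.1 standard);
everything internal is 0-based half-open, and `agp_lift()`/`agp_unlift()`
map coordinates between scaffold and pseudomolecule exactly, including
through minus-strand components.

## Comparative computations

**Kimura two-parameter divergence.** For equal-length aligned sequences,
sites where either sequence is gapped or ambiguous are excluded; with
transition proportion *P* (A↔G, C↔T) and transversion proportion *Q* over
the remaining sites,

$$K = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

The estimator diverges as its arguments approach the model boundary;
`(1-2P-Q) ≤ 0` or `(1-2Q) ≤ 0` raises a saturation error rather than
returning a number without meaning. The unit test cross-checks against
`ape::dist.dna(model = "K80")` and the first-order expansion `K ≈ P + Q`
for small divergence.

**LTR insertion age.** The two long terminal repeats of a retrotransposon
are identical on insertion and diverge independently afterwards, so the
age is `T = K / (2r)` with `r` the substitution rate per site per year
(default 1.3 × 10⁻⁸, the standard plant LTR rate).

**Synteny blocks.** Anchors are orthologous gene pairs ranked along a
chromosome of each genome. "Consecutive" pairs are interpreted in rank
space with a tolerated gap (`max_rank_gap = 5` by default) — strict
rank-adjacency would shatter blocks at every unanchored gene, while the
gap tolerance matches how collinearity tools chain anchors. Within each
chromosome pair the longest strictly monotone chain (increasing/increasing
for forward blocks, increasing/decreasing for inverted) under the gap
constraint is extracted by an exact O(n²) dynamic program, its anchors are
removed, and extraction repeats while chains of at least `min_pairs = 30`
anchors remain — so overlaps resolve in favour of the longer chain, with
length ties going to the chain starting at the smaller rank. An exact DP
rather than a heuristic keeps the implementation equal to a brute-force
longest-chain oracle, which the test suite verifies on hundreds of random
instances.

**Divergence histograms** use half-open bins `[i·w, (i+1)·w)` with the
modal bin reported; ties go to the smaller bin.

## GBS genotype calling and LD

**Calling.** An individual-site needs ≥ 10 reads to be called at all, and
a heterozygote needs ≥ 2 reads of the minor allele. A site-individual with
enough total depth but exactly one minor-allele read is called homozygous
for the major allele by default — a single read is most plausibly a
sequencing error — with `single_minor = "missing"` exposing the
conservative alternative.

**Filtering.** A site is kept iff its missing fraction ≤ 0.20 and its
minor allele frequency ≥ 0.05, the MAF computed from called dosages after
excluding missing data; removal is strict (`>`/`<`), so sites exactly at
either boundary survive.

**r² and decay.** GBS genotypes are unphased, so r² is the composite
(dosage-correlation) estimator: the squared Pearson correlation of
alt-allele dosages over individuals called at both sites, undefined with
fewer than two informative individuals or zero variance. Decay bins all
intra-chromosomal pairs closer than `max_dist` into half-open bins of
`bin_width`; empty bins are reported with zero pairs and an undefined
mean rather than silently dropped.

## The synthetic-data generator

Every generator is a pure function of its parameters and seed, and writes
exactly the dialects the readers parse, so the pipeline can be exercised
end to end with full ground truth. The default desk-scale scenario — 3
chromosomes × 2 Mb, ~130 scaffolds (lognormal lengths, mean ≈ 40 kb),
400 markers per map, ~560 BAC clones in 80 physical contigs plus
singletons and one sink contig, 60 individuals × 500 GBS sites — keeps
every end-to-end test and the acceptance script within a couple of minutes
on one CPU; the vignette states these sizes as the package's chosen study
conditions.

Two scale choices deserve explanation. Physical length is compressed
roughly fifty-fold relative to a real plant genome, but *genetic* length
is kept chromosome-realistic: marker maps use 40 cM/Mb so each 2 Mb
chromosome spans ~80 cM, which is what makes >30 cM discordances
representable at all. The population simulator similarly uses 50 cM/Mb so
that recombination visibly erodes LD across ≤ 500 kb within a few
generations. BAC clones are scaled to 20 kb mean length for the same
reason: clones of realistic absolute size would tile a 2 Mb chromosome
into one merged physical contig, erasing the contig structure the link
classifier needs; instead clones are generated in overlapping groups (one
per contig) with gaps between groups, plus isolated singletons.

Corruptions are injected at exactly the rounded counts and recorded in the
truth table: `wrong_lg` markers get a wrong linkage group in *both* maps
(so they survive to the dissenter stage, which is the rule they exercise —
maps disagreeing on the LG is a different, earlier removal path);
`discordant_cm` markers get a > 30 cM shift in the new map; `multi_map`
markers gain a second alignment on a random other scaffold. Chimeric
scaffolds concatenate two large scaffold pieces from different chromosomes
with the breakpoint recorded. The population model draws founder alleles
independently per site (initial LD is founder-pool drift, ~1/(2·founders),
distance-independent) and decays it by per-generation recombination with
Poisson crossover counts per chromosome.

What the generator does **not** emulate: sequence-level realism (markers
and BES are placed by coordinate bookkeeping, not alignment of real
reads), repeat landscapes, assembly gaps inside scaffolds, fingerprinting
noise in contig assembly, genetic-map interference (the cM map is
piecewise-linear monotone with no interference model), or coalescent-exact
population genetics. Passing the end-to-end tests therefore demonstrates
that the *decision rules* behave correctly under the modelled noise modes,
not that the pipeline is robust to every artefact of real data.

## Evaluation conventions

`evaluate_anchoring()` scores chromosome accuracy over all placed
scaffolds (split children count against the true chromosome of their side;
an unsplit chimera counts against its longer piece), order correlation as
the per-chromosome Spearman correlation between recovered order index and
true chromosome start over correctly assigned *marker-placed* scaffolds
(BAC-link insertion next to the anchor is a heuristic with no exact order
claim), orientation accuracy over scaffolds whose recovered orientation is
not `?`, and split recall as the fraction of true chimeras split with the
correct linkage group on each side. The acceptance tests additionally
require each split position to fall between the innermost uncorrupted
markers flanking the true breakpoint — the tightest interval the marker
evidence can localize.

## Known limitations

* The dissenter and split rules reason over marker counts, not map
  distances; two corrupted markers that agree with each other on the same
  side of a scaffold can still force a wrong or missed split (seen
  occasionally in the corrupted scenario when both corruptions land on one
  chimera side, or when a chimera piece receives no markers at all).
* `cm_key` ordering cannot order scaffolds sharing a single marker cM;
  ties are broken lexicographically for determinism, not correctness.
* Propagated (BAC-link) placements have unknown orientation and
  side-of-anchor; they extend chromosome membership, not fine order.
* The composite r² estimator is biased upward at small sample sizes and
  is not the haplotype-based EM estimator; with 60 individuals the
  difference is small relative to binning noise.
* The synteny chainer is exact but O(n²) per chromosome pair; it is meant
  for anchor tables (thousands of pairs), not raw alignment chaining.
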