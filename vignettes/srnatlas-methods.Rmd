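---
title: "Building a small-RNA expression atlas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a small-RNA expression atlas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnatlas)
library(dplyr)
```

srnatlas turns raw plant small-RNA sequencing libraries into a normalized
miRNA expression atlas: per-library unique-tag tables, TP5M abundances,
hairpin-validated loci with miR/miR* duplex geometry, dual-replicate
expression calls with organ-specificity classes, sample clustering and PCA,
and target-site predictions filtered by expression anti-correlation. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, and what the synthetic data generator does and does not
emulate.

## The quantification model

Reads are trimmed at the leftmost occurrence of the 3' adapter; when the
full adapter is absent, a terminal adapter prefix of at least 7 nt still
counts as evidence and the longest such prefix is removed. This dialect is
stated explicitly so results are bit-reproducible; reads with no adapter
evidence are discarded rather than kept untrimmed, because an untrimmed
read cannot be assigned an insert boundary. Inserts outside 18-34 nt are
discarded: that range brackets the plant small-RNA populations of interest
(20-22 nt miRNAs, 24 nt heterochromatic siRNAs) while excluding degradation
products.

Distinct insert sequences become *tags* with counts. Tags are mapped to the
genome by exact, full-length matching on both strands - no mismatches, no
seed heuristics - and tags matching any structural-RNA reference sequence
(rRNA, tRNA, snRNA, snoRNA; substring match on either strand) are flagged.
Abundance is normalized to transcripts per five million:

$$\mathrm{TP5M}(t) = \frac{\text{count}(t)}{D} \times 5{,}000{,}000,$$

where the denominator $D$ is the total count of genome-matched tags minus
the structural-matched count (and minus organellar matches when organellar
sequences are supplied in the structural set; when they are not, the
denominator excludes only the structural classes and this is logged).
Per library, TP5M over counted tags sums to exactly 5,000,000, and the
normalization is invariant to rescaling all counts - these two properties
are asserted in the test-suite. Deliberately, no between-library
variance-stabilizing normalization (TMM, size factors) is applied: the
atlas is defined on linear count scaling only.

Library quality is summarized by the size-class profile of genome-matched,
non-structural abundance. Angiosperm libraries typically show local maxima
at 21 nt (miRNAs) and 24 nt (siRNAs); a library with neither peak, or with
fewer than `min_distinct` distinct genome-matched tags, is flagged. The
`min_distinct` default (1000) is a package choice scaled to the synthetic
libraries; the underlying criterion is qualitative and should be adjusted
to the sequencing depth at hand.

## Hairpin model and duplex geometry

Precursor structure is computed by weighted base-pair maximization
(a Nussinov-style dynamic program) with weights G:C = 3, A:U = 2,
G:U = 1, a minimum hairpin loop of 3 nt, and a deterministic traceback
(among co-optimal structures the pair with the smallest 5' index is taken
first). This is not a thermodynamic model: it has no stacking energies and
no ensemble, and it will happily pair isolated bases. The choice is
deliberate - the criterion is automated, exact and deterministic, and the
DP is verified against exhaustive enumeration on short sequences. A
thermodynamic folder could be substituted behind the same `hairpin_model`
contract (partner vector, arms, loop); the multi-window validation
described below compensates for the main weakness of pair maximization
(spurious recruitment of flanking sequence into the stem).

The main stem is the chain of nested pairs from the outermost pair inward,
taking the better-populated branch at multiloops; a structure whose main
stem has fewer than `min_stem = 15` pairs is not hairpin-like. Both the
pair weights and the stem threshold are stated defaults, configurable in
`fold_hairpin()` and `candidate_criteria()`.

miR* inference encodes the RNase III (Dicer-like) product geometry: the
star's 5' end faces `mature_end - 2` and its 3' end extends two bases past
the partner of `mature_start`, giving 2-nt 3' overhangs on both duplex
strands. On a perfect stem the operation is an involution (the star of the
star is the mature), which the tests assert. When an anchor base is
unpaired the nearest paired position inside the mature is used and the
result is flagged non-canonical rather than silently accepted.

A locus' *dominant isoform* is the tag with the highest TP5M summed over
usable libraries among tags mapping within the precursor; exact ties go to
the annotated sequence. The dominant is classified against the annotation
as identical, a length variant (same 5' end) or a shift variant (signed
start offset). Secondary duplexes - abundant tags away from the primary
mature/star (isomiR-like near-duplicates within 2 nt of both ends are
excluded) - are reported with their phasing: tandem (gap 0), phased
(gap a positive multiple of 21 nt, the register of sequential Dicer
processing), overlapping (negative gap), otherwise unphased. Antisense
locus pairs are linked when precursor spans overlap at least 50%
reciprocally on opposite strands.

Because "as abundant as" has no stated tolerance in the star-dominance
comparison, equality is evaluated on the TP5M value itself and flagged;
any other tolerance is a caller decision.

## Novel-candidate validation

Outside annotated loci, overlapping tag alignments (gap <= 30 nt, strands
pooled) form clusters; each cluster is anchored on its most abundant tag
and discarded outright when that tag is not 20-22 nt long - the guard
against heterogeneous 24-nt siRNA clusters. A 250-nt window around the
anchor is folded on the anchor's strand. Windows are folded at several
widths (full, 150, 100 nt, all containing the anchor) and the locus passes
if any width yields a clean duplex; this mirrors the practice of hairpin
annotation tools that scan multiple window sizes, and counters the
pair-maximization artifact noted above.

Acceptance requires: a hairpin-like stem; the mature within one arm (a
mature crossing the loop is rejected "in loop"); at most `max_mismatch = 4`
unpaired mature bases and no unpaired run longer than `max_bulge = 2` in
mature or star ("sub-optimal pairing" / "bulge too large" otherwise); and
duplex-associated reads (mature and star, ends within 2 nt) at least
`min_duplex_fraction = 0.75` of window reads ("read dispersion"
otherwise). These thresholds encode community plant-miRNA annotation
practice; every one is configurable through `candidate_criteria()` and
reported alongside results. Acceptance is monotone: relaxing any single
threshold never rejects a previously accepted locus.

The dual-replicate abundance gate (10 TP5M) is applied at the atlas stage
by default, not during discovery, matching a workflow in which
under-threshold candidates are eliminated when the expression atlas is
assembled; a flag moves the gate to discovery time.

Family assignment uses unit-cost global edit distance: identity
$(L - d)/L$ against a reference set of known mature miRNAs, assigning the
best family strictly above 90% identity (ties: smaller distance, then
lexicographic family name). Candidate summaries report the fraction of
matures starting with uridine - the 5'-U bias characteristic of
AGO1-loaded plant miRNAs - plus length and family histograms.

## Atlas calls and organ identity

A miRNA is *expressed* in a sample only when every biological replicate
reaches 10 TP5M; a missing replicate makes the sample unusable for that
miRNA rather than silently passing. *Common* miRNAs are expressed in every
usable sample; *organ-specific* miRNAs are expressed in at least one stage
of exactly one organ and nowhere else (specificity is decided on
sample-level calls, not averaged values, preserving the dual-replicate
rule); everything else is *neither*. With a single organ the common class
takes precedence, a tie-break that matters only in degenerate designs.
Stage-sharing tables count miRNAs by the number of stages expressed within
an organ. Stage-variable miRNAs are selected by pairwise fold change
between stage averages with the denominator floored at 1 TP5M - the floor
keeps fold changes finite when a miRNA is absent from a stage and is
reported with the outputs - requiring expression in at least one compared
stage and a maximum fold change of at least 5.

Sample relationships use log10(1 + TP5M) - the unit shift keeps zeros at
zero - with one-minus-Pearson distance over all miRNAs, average-linkage
agglomeration, and exact optimal leaf ordering: among the orders reachable
by subtree flips, dynamic programming finds the one minimizing the sum of
adjacent-leaf distances. The exact search runs up to 64 leaves (the DP is
quartic in the worst case and instantaneous at atlas scale); above that
the hclust order is kept. Both replicate-level and replicate-averaged
matrices can be clustered; the averaged matrix is the default
presentation. PCA z-scores each miRNA before decomposition, drops
zero-variance features with a record, fixes each component's sign by
making its largest-magnitude loading positive, and reports variance
fractions that sum to one.

## Target prediction and the anti-correlation filter

The scorer implements the classic plant penalty scheme, applied position
by position from the miRNA 5' end against antiparallel transcript windows
of miRNA length: Watson-Crick 0, G:U wobble 0.5, mismatch 1, all doubled
at positions 2-13. Only the ungapped mode is implemented; scores are
computed to a permissive internal cutoff of 4 and reported at the
confident cutoff of 3. A positional asymmetry is inherent to the scheme:
the doubled 2-13 region means the score is not invariant under swapping
the two strands, although the per-position penalty matrix itself is
symmetric (asserted in the tests).

Each reported pair is then tested for expression anti-correlation: Pearson
r over the samples shared by the miRNA and transcript matrices, both
log10(1 + x)-transformed (the transformed scale is used on both sides; the
alternative of raw transcript abundances is deliberately not offered, and
this choice is flagged here). The two-sided p-value uses the exact t
transform with n - 2 degrees of freedom. A pair is retained only when r is
negative and p < 0.05 - a sign rule, not a two-sided screen - and no
multiple-testing correction is applied by default, matching the declared
selection rule; pairs with fewer than 4 shared samples are untestable.

## What the synthetic generator emulates

`sim_config()` + `plant_genome()` + `simulate_libraries()` +
`generate_mrna_atlas()` produce a fully specified dataset with ground
truth: a random genome hosting hairpin loci built around their matures
(perfect stems with 2-nt 3' overhang duplex geometry, loop drawn from
{A, C} so it cannot pair), 200-nt siRNA cluster spans, and structural
decoys that appear both in the genome and in the structural reference.
Feature placement keeps at least 50 bp between features and every planted
sequence occurs exactly once.

Designed abundances are expressed in TP5M and drive expected per-library
read counts; counts are drawn from a negative binomial with variance
$\mu + \phi\mu^2$ (dispersion 0 giving the Poisson limit) - the standard
count-noise model in sequencing, since no noise model is prescribed by the
atlas definition itself. Default study conditions are a 100 kb genome, 30
miRNA loci, 10 siRNA clusters, 5 structural decoys, 6 organs x 2 stages x
2 replicates and 200,000 reads per library. Locus roles: 30%
organ-specific (home organs cycled through a shuffled organ order so every
organ receives specific loci, emulating per-organ specific miRNA sets),
40% common, and the remainder split evenly between stage-trajectory loci
(planted fold change 5 between first and last stage) and low-abundance
background loci that sit below the 10 TP5M call threshold. Designed
medians (about 2 x 10^4 TP5M for common loci, 5 x 10^3 for organ-specific)
put miRNAs at a realistic 10-20% share of each library, with the 24-nt
siRNA background absorbing the remaining genome-matched budget, so the
size profile reproduces the 21/24-nt bimodality. IsomiRs are emitted as
end shifts of 1-3 nt with geometric decay at spread 0.15 per arm - a
placeholder shape chosen once, not an estimate of any empirical isomiR
distribution. A single fixed 3' adapter is appended and no sequencing
errors are injected: trimming logic, not error correction, is what the
pipeline tests. A 0.5% adapter-free junk fraction exercises the trimming
statistics. All sequences are stored as DNA; comparisons are done in DNA
space throughout.

Planted mRNA targets embed a perfectly complementary site (score 0) and
receive expression constructed on the transformed scale as
$3 + 0.6\,(r z + \sqrt{1-r^2}\,\varepsilon)$ with $z$ the z-scored
transformed miRNA profile, so the transformed-scale Pearson correlation
has expectation $r$ exactly and the noiseless $r = -1$ case is exact.

What the generator does **not** emulate: sequencing errors and quality
variation, multi-adapter dialects and chimeras, multi-chromosome genomes,
repeat-driven multi-mapping, organellar genomes, imperfect hairpins
(planted stems are perfect; imperfect pairing enters only through genomic
context in discovery windows), and any empirical isomiR spectrum. Passing
tests on this data therefore demonstrate the correctness of the
bookkeeping, geometry, statistics and thresholds - not robustness to
error-rich or repeat-rich real libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, matching R string
  semantics and GFF3 output; there is no internal coordinate conversion.
* Tag-to-genome matching counts occurrences on both strands; a palindromic
  tag counts its site twice (once per strand), consistently with the naive
  both-strand oracle used in tests.
* Problem sizes in the test-suite were chosen to exercise every code path
  at desk scale: the end-to-end recovery test runs the full default
  conditions above (about 4.8 million reads across 24 libraries); the
  organ-identity check runs twenty 3-organ atlases at dispersion 0.3; the
  target-filter check runs 200 planted pairs over 24 samples.
* The fold-change floor (1 TP5M), the equality convention for star
  dominance, the discovery-time vs atlas-time abundance gate, and the
  transformed-scale correlation on both sides are all explicit choices
  documented above; each has a configurable surface.
* `nominate_loci()` pools strands when clustering alignments because the
  folding step re-orients the window to the dominant tag's strand; only
  that strand is folded, since a candidate whose mature is absent from the
  folded strand cannot be validated.

## Known limitations

Base-pair maximization over-estimates pairing relative to thermodynamic
folding; the multi-window validation mitigates but does not eliminate
this, and very long or highly structured loci may still present distorted
arms. Exact optimal leaf ordering is limited to 64 leaves. The target
scorer has no gapped (bulged) alignment mode and no accessibility/energy
term. The expression model plants organ and stage effects but no
library-preparation batch effects, so clustering recovery rates on
synthetic data are optimistic relative to real experiments.
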