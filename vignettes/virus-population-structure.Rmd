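---
title: "Methods: population structure, coinfection and reassortment for segmented viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, coinfection and reassortment for segmented viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viropop)
```

viropop analyses per-segment nucleotide alignments of a segmented RNA
virus sampled from individual hosts, together with sample metadata
(location, date, species) and optional qPCR/read-count tables. This
vignette records the models and procedures, the parameters that matter,
the numerical edge cases, and the design choices that were genuinely
open — in enough detail that a maintainer can judge every default.

## Distances and diversity

All pairwise comparisons use *comparable columns* only: alignment
columns where both sequences carry an unambiguous A/C/G/T. Columns with
a gap, `N`, or an IUPAC ambiguity in either sequence are dropped from
numerator and denominator alike. This is the common
"identical sites over aligned non-gap sites" convention; it makes
self-identity exactly 100 for any gap pattern with at least one
comparable column. Percent identities are conventionally reported to
0.1 point; computations keep full precision.

The evolutionary distance is Tamura–Nei (TN93), which separates the two
transition classes (A↔G, C↔T) from transversions and allows unequal
base composition. Base frequencies are estimated from the *pooled pair*
over its comparable columns, the standard choice for pairwise distances
when no alignment-wide model fit is available; identities and distances
are therefore functions of the two sequences alone, and a distance
matrix is exactly the matrix of independent per-pair calls (a property
the test suite asserts).

Two degenerate regimes are treated as errors, not values:

- *Saturation*: any logarithm argument ≤ 0. Capping at some large
  distance would silently distort nearest-neighbour sets downstream, so
  the pair is instead recorded as missing; `distance_matrix()` tolerates
  up to 10% missing pairs before declaring the matrix unusable.
- *Degenerate composition*: a pair with no purines or no pyrimidines
  among its comparable sites has no defined TN93 distance.

## Trees

Trees are `ape::phylo` objects throughout. The package builds
neighbour-joining trees from TN93 matrices (negative estimated branch
lengths clamped to zero) as its internal tree method; externally
inferred maximum-likelihood trees can be supplied as newick and are
used identically. Trees are midpoint rooted — the natural choice when
no outgroup exists for a virus whose entire known diversity is in the
sample — and, before any cophylogeny comparison, internal branches
shorter than 0.001 substitutions/site are collapsed into polytomies.
Only internal branches collapse: removing terminal branches would
delete tips. The threshold is interpreted in the branch-length units of
the input tree. Collapse is idempotent, and midpoint rooting preserves
the tip-to-tip path-length matrix (both asserted in tests).

## Genotype assignment

A genotype (major clade) is a group of sequences sharing at least 95%
pairwise identity under single-linkage clustering *and* forming a
monophyletic clade. Single linkage is the right linkage for this
definition: densely sampled virus populations connect divergent
subclades through chains of intermediate lineages, so a major clade may
legitimately contain pairs below the threshold as long as a chain of
above-threshold links connects them. Candidate clusters failing
monophyly are flagged, never silently merged or split — the two
criteria are independent evidence and their disagreement is a finding.
Clade labels (`G1`, `G2`, ...) are ordered by clade size with ties
broken by smallest member id, so labels are invariant to input order.

Subclades are a heuristic refinement: re-clustering within each major
clade at 97%. They are reported for orientation, and nothing downstream
depends on them.

Because labels are assigned per segment, cross-segment comparisons
(concordance, satellite association) first harmonize labels: each
segment's clades are renamed to the reference segment's label with
maximal shared-sample overlap, greedily. Unmatched clades keep a
segment-prefixed name and count as discordant only on the genome
segments (see below).

## Coinfection

Within each sample-and-segment group, coding-complete sequences
sharing ≥ 99% identity are one genotype; the genotype count is the
number of single-linkage groups at that threshold. The 99% figure
mirrors the redundancy threshold commonly used to collapse
near-identical assembled sequences; read-level evidence (distinct read
sets under competitive mapping) is not reproducible from assembled
sequences, so sequence identity stands in for it. A sample is
*coinfected* when any segment carries ≥ 2 genotypes and a *complete
coinfection* when all three genome segments do; the satellite counts
per segment but is not required for completeness.

## Geographic structure: Snn

For sequence *i*, the nearest-neighbour set contains **all** sequences
at minimal distance from *i*. Keeping the full tied set matters:
surveys of clonally spreading viruses contain many exact duplicates
(distance 0), and a tie-broken single neighbour would make the
statistic depend on input order. Zero-distance duplicates with
different labels dilute `x_i` rather than being excluded — they are
genuine nearest neighbours under the definition. Snn depends only on
within-row distance ranks, hence is invariant under monotone transforms
of the distances (tested).

The permutation test shuffles labels without replacement; the one-sided
p-value `(1 + #{Snn* ≥ obs})/(1 + B)` uses the add-one correction so
that perfect structure reports the smallest attainable p (`1/(B+1)`),
never zero. B defaults to 5000. Nearest-neighbour sets are computed
once and reused across permutations (they do not depend on labels).
Sequences with > 10% of their row missing (saturation) are dropped with
a warning; isolated missing pairs are ignored within the row.

## Reassortment detection

Visual tanglegram discordance is operationalised: a pair of singly
infected samples is flagged when identity ≥ `high` on one segment and
≤ `low` on another. `low = 95` sits at the genotype threshold — the
divergent segment must look like a different lineage. `high = 98.5`
captures near-clonal pairs; it is set just below 99 because genuinely
discordant pairs in published surveys include clonal-segment identities
of 98.7%, and the 3.5-point gap between the thresholds is roughly seven
times the sampling noise of an identity estimate on a full-length
segment (binomial s.e. ≈ 0.5 points at ~1500 nt), which is what keeps
the false-positive rate on clonal simulations at zero. When collapsed
trees are supplied, the divergent-segment sequences must additionally
not share a parent node — a pair sitting in the same polytomy of
near-identical sequences is not discordant. Both thresholds are
recorded in every report, since the criterion is this package's
operationalisation rather than a community standard.

One reassortment event makes the recipient discordant against the
donor *and* the donor's whole neighbourhood, so flagged pairs sharing a
sample are merged into events by connected components. Event counts are
therefore a lower bound; detector recall is defined per planted event
(does some flagged pair involve the recipient?), which is the quantity
the validation suite drives to 100%.

Between-clade reassortment is assessed independently of the pair
screen by the concordance table: each singly infected sample's
harmonized major-clade label per genome segment, with discordant
samples listed. The satellite column is displayed but not scored —
satellite sampling is inherently sparser (it is absent from a whole
clade and from many samples), so its clusters can fragment without
implying reassortment.

## The statistical layer

ΔCt quantification (`2^(ct_reference − ct_target)`), Clopper–Pearson
intervals, two-sided Fisher exact tests (sum of hypergeometric
probabilities ≤ the observed table's), Holm step-down adjustment,
Wilcoxon rank-sum (exact for combined n ≤ 20 without ties), RPM
normalisation (reads per million host-mapping reads), strand ratios and
log10–log10 OLS all delegate to the standard R implementations behind
thin validating wrappers; the tests cross-check them against
independent oracles (Beta quantiles, full hypergeometric enumeration,
rank-permutation Monte Carlo, hand-computed step-downs).

The bootstrap t test for comparing identity distributions is
implemented here: both groups are centred at their own means (imposing
the null), resampled with replacement, and the Welch t statistic
recomputed; `p = (1 + #{|t*| ≥ |t_obs|})/(1 + B)` with B = 10000.
Degenerate resamples where both groups are constant and equal
contribute t* = 0. Resampling is blocked (~2M values per block) so
memory stays bounded on large inputs. Undetected qPCR targets are
negatives, never imputed to a maximal Ct; prevalence uses
reference-positive samples as the denominator.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth, so every stage is testable without downloads.

**Clade geometry.** Three major clades (proportions 0.5/0.3/0.2, two
*melanogaster*-like and one *simulans*-like) sit on a star backbone at
~80% between-clade identity. Each clade is a *chain of subclades*:
tight coalescent subtrees (99% expected within-subclade identity) hung
on a linear backbone placing adjacent subclades at 96.5%. This chained
geometry is essential and deliberate: a single coalescent clade rescaled
to ~96% mean identity fragments under single-linkage clustering at 95%
(nothing bridges its basal split), whereas chained subclades cohere at
95% while still providing within-clade lineage pairs near 93% — exactly
the structure real surveys show (named subclades within major
genotypes), and the raw material for *resolvable* reassortment events.

**Calibration.** The substitution process is a two-rate
transition/transversion model (κ = 4, uniform base frequencies), so the
TN93 estimator's rate classes are exercised. Branch lengths are set by
inverting the closed-form expected mismatch at path length *d*,
`m(d) = 3/4 − ¼e^{−4βd} − ½e^{−2(α+β)d}` with α = κβ, α + 2β = 1;
each target identity therefore holds in expectation exactly, with
binomial sampling noise (s.e. ≈ 0.5 points at the default 1300–1600 nt
segment lengths). Alignments are gapless; gap and ambiguity handling is
exercised by hand-crafted fixtures instead, since indel simulation adds
machinery without touching any computation under test.

**Reassortment and coinfection.** Reassortment replaces a recipient's
segment with an exact copy of a donor's, donor and recipient drawn
jointly from the same clade with ≤ 95% identity on every unswapped
genome segment — guaranteeing each planted event is resolvable by the
identity-gap rule. Between-clade donors require an explicit override,
guarding the headline negative result in tests. Coinfected samples
(11% by default) gain an extra genotype from another clade on segments
drawn with RNA3-biased weights (RNA3 0.5, RNA2 0.2, chaq 0.2, RNA1
0.1), or a complete extra set with probability 0.15; an extra chaq
genotype is only planted in samples that themselves carry chaq. The
satellite is restricted to the two permitted clades with 60% carriage.

**Geography.** Location labels follow lineage: connected components of
the realised nearest-neighbour graph (union over segments) are
distributed over 5 labels, so at mixing 0 every nearest-neighbour set
is label-pure and Snn is exactly 1. Each sample is instead relabelled
uniformly at random with probability *f* (`geographic_mixing`). For
balanced labels the expectation is approximately
`E[Snn] ≈ (1−f)(1−f+f/L)`: an unmoved sequence's neighbours are unmoved
with probability ≈ 1−f, and moved sequences contribute ≈ 1/L. The
default f = 0.06 with L = 5 places Snn in the 0.85–0.91 band reported
for strongly but incompletely structured wild populations; a naive
f = 0.15 would land near 0.76, visibly below that band, which is why
the default is derived from the closed form rather than set by feel.

**Abundance.** Relative RNA levels are a two-mode log-normal mixture
(modes 4.1 and 1/3907 copies per reference mRNA, high-mode weight 0.7,
log10 s.d. 0.5); Ct values are back-computed from levels, read counts
scale with level and a per-clade factor (the melB-like clade at 1/4.9),
and strand counts follow per-segment plus/minus ratios with RNA1
lowest (5 vs 20).

**What it does not emulate.** Indels and alignment error; partial
(non-coding-complete) sequences; within-host quasispecies diversity;
read-level data; recombination within segments; temporal structure
beyond random collection dates. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted structure
under clean alignments — not robustness to alignment artefacts or
assembly error, which real pipelines must handle upstream.

## Problem sizes and determinism

Every generator operation takes a seed and is a deterministic function
of it; the pipeline derives sub-seeds from the configuration seed. The
validation suite uses 24–45 samples with full-length (1300–1600 nt)
segments where identity-noise margins matter (reassortment recall and
false-positive loops, 20 seeds each), 30–40 samples with 600–800 nt
segments elsewhere, a 118-sample default survey for rate recovery, 500
replicates for the Snn type-I-error calibration (B = 199 each) and 400
for the bootstrap-t size check, and full hypergeometric enumeration of
every 2×2 table up to total 30 for the Fisher cross-check. These sizes
hold all calibration checks comfortably inside binomial error while the
whole suite runs in a few minutes.

## Known limitations

- Genotype labels are dataset-relative (`G1`, `G2`, ...); mapping them
  to named clades from the literature requires reference sequences in
  the input.
- The identity-gap screen cannot see reassortment between nearly
  identical lineages (both segments ≥ 95%): such events are invisible
  to sequence-level analysis by construction.
- Snn treats locations as unordered labels; it measures structure, not
  distance or direction of spread.
- The NJ tree is a working phylogeny. For publication-grade trees,
  supply external ML trees via `read_newick()`; every downstream step
  accepts them.
- With very sparse per-clade sampling the single-linkage chain can
  break and a true clade may report as two; the assignment output
  exposes the realized within/between identity gap precisely so such
  threshold sensitivity is visible.
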