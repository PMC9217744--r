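---
title: "Models and methods: replication initiation zones at stratified domain boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`replitad` links DNA replication initiation zones (IZs) to structurally and
genetically stratified TAD/subTAD boundaries. This vignette is the
package's own account of the models it implements, the parameters that
matter, the synthetic data it validates against, and the design choices
made where the design was genuinely open. Coordinates are 0-based,
half-open everywhere; bins are indexed from 0; a boundary position is the
first bin of its right-hand domain.

## Domain detection: multi-scale insulation

For a bin `b` and window `w`, the insulation statistic is the mean contact
value over the inter-domain square `[b-w, b-1] x [b, b+w-1]` — the set of
contacts a boundary at `b` would have to insulate. The score is
`log2(mean / chromosome median of the statistic)`, so it is invariant to
global scaling of the matrix, and it is undefined within `w` bins of the
chromosome ends.

Boundaries are local minima of the score with prominence at least 0.1
(default), where prominence is measured against the maximum of the two
flanking wings of `2w` bins. Before minima detection each track is
smoothed with a Gaussian kernel of sd 1.5 bins: with Poisson counting
noise the un-smoothed score has a per-bin sd of roughly 0.03-0.07 at a
depth of 100 counts on the first diagonal, so spurious dips on
domain-interior plateaus would otherwise clear a 0.1 prominence threshold;
dips at true boundaries are an order of magnitude deeper (about -1 in
log2 units at a domain multiplier of 2) and survive smoothing essentially
unchanged. Smoothing at sd 2 begins to merge boundaries closer than ~10
bins, hence 1.5.

Windows default to 4, 8 and 16 bins (200/400/800 kb at 50-kb bins).
Candidates from all windows are merged: candidates within one bin collapse
to the deepest minimum (ties to the leftmost bin). Edges supported only by
the finest window mark subTAD-scale structure: spans between consecutive
coarse-supported edges that contain at least two leaf domains are emitted
as level-0 parents and their leaves become level-1 children. External
domain calls (BED) can be substituted at any point — the downstream
stratification needs only edges, extents and corner-dot flags.

## Dot (loop) detection: Poisson test against four local backgrounds

Every pixel at distance 2-60 bins is tested. The local expected value is

```
lambda(i, j) = expected(|i - j|) * max(ratio_donut, ratio_ll, ratio_h, ratio_v)
```

where each ratio is (sum of observed / sum of distance-expected) over one
of four neighborhoods: the donut ring (Chebyshev radius 5 minus radius 2,
minus the row/column arms), the lower-left quadrant of that ring, and the
horizontal and vertical arms beyond the inner radius. Taking the maximum —
i.e. requiring enrichment over the strictest background — matters: with a
donut alone, the corner pixels of *every* domain test as enriched because
the ring spans the domain edge, and the corner pixels of nested subTADs
test as enriched against their parent's background. Both failure modes
flag dotless domains as corner-dot domains. The P value is the Poisson
upper tail `P(X >= obs | lambda)`; BH correction runs over all tested
pixels, with defaults q <= 0.10 and observed/lambda >= 1.75. Significant
pixels are clustered by 8-connectivity; clusters of fewer than 2 pixels
are dropped (a dot is a punctate *group* of adjacent pixels, and isolated
single-pixel fluctuations at q near the threshold occasionally land at
domain corners); each cluster reports its maximum-observed pixel as the
centroid.

The expected profile is the per-distance arithmetic mean of all pixels of
the chromosome; distances with fewer than 100 pixels are pooled into
logarithmically spaced groups to control long-range variance.

## Boundary stratification

A domain is a corner-dot domain iff a dot centroid lies within `tol_bins`
(default 2) of both its first and its last bin. Boundary positions are the
interior domain-edge bins, merged within one bin; a boundary is
`double_dot` / `single_dot` / `dotless` according to whether corner-dot
domains flank it on both, one, or neither side. Double- and single-dot
boundaries pool into *dot* boundaries.

CTCF/cohesin sites are assigned to at most one boundary each: a site must
fall within `[bin - 1, bin + 2)` bins (one bin of positional uncertainty
on either side) and goes to the boundary with the nearest bin midpoint,
ties to the leftmost. Orientation uses only stranded CTCF+cohesin-bound
motifs, in genomic order: none (0 motifs), tandem/single (1 motif, or all
on one strand), complex (2 or more with both strands present). Convergent
(`+ ... -`) versus divergent (`- ... +`) versus mixed is recorded as
metadata only — the class index pools them. Cohesin-only sites are counted
descriptively and never affect the class. The six classes are the product
(dot, dotless) x (complex, tandem/single, none), classes 1-3 dot and 4-6
dotless.

## Repli-seq: normalization, timing, IZ calling

Sixteen fractions span S phase, fraction 1 earliest. Normalization:
(1) each fraction column is scaled to the mean column total — the step
assumes each S-phase gate contributes comparable true signal genome-wide,
and corrects library-size differences; (2) each covered bin's 16-vector is
scaled to unit sum; (3) optional (default on) Gaussian smoothing along the
genome, sd 1 bin, identical weights in every fraction, so unit sums are
preserved. All-zero bins are flagged uncovered and stay zero.

The per-bin timing value is the center of mass `T = sum(f * p_f)`,
in [1, 16]. IZs are local minima of T with prominence at least 0.5
fractions against the surrounding 10 bins per side; the extent is the
maximal run around the apex where T stays within 1.0 fraction of the apex
and is non-decreasing outward; apexes closer than 2 bins merge (keeping
the earlier apex) and overlapping extents are split at the intervening
timing maximum, so calls never overlap. Because T is computed from
unit-sum vectors, calls are invariant to uniform count rescaling. Timing
classes split at T = 5.5 and 10.5 into early / early-mid / late — three
near-equal waves of the 16 fractions. The two-fraction track is
`log2((E + 1) / (L + 1))` with E and L the sums of fractions 1-8 and 9-16.

## The randomization enrichment test

For each (boundary class, timing class) cell, the observed statistic is
the number of IZs whose interval overlaps a boundary window
`[bin - 1, bin + 2)` bins (a one-bin colocalization window, matching the
one-bin boundary uncertainty; exposed as a parameter). Null sets preserve,
for every real IZ, its exact bin width and its majority A/B compartment
label: a replicate draws, for each IZ, a uniform position among *all*
eligible starts on autosome-flagged chromosomes. Majority label means the
label covering more than half the IZ's bins; exact ties resolve to the
apex bin's label for real IZs and to the center bin for candidate
windows. The eligible-position set is enumerated exhaustively per
(width, label) — sampling from the enumerated set is exact and
reproducible, where rejection sampling would merely consume different
random draws on its way to the same distribution. The empirical P is the
add-one rule `P_right = (1 + #{X_r >= X_obs}) / (R + 1)` (never 0, never
below 1/(R+1)); the left tail is reported symmetrically for depletion
statements. R defaults to 1000. No multiple-testing correction is applied
across the 6 x 3 grid; cells are reported individually. Null intervals may
overlap each other and real IZs — exclusion rules would break
exchangeability without a principled replacement.

## The synthetic genome generator

The generator is first-class, tested code: it defines the study conditions
every property in the test suite is measured under.

**Architecture.** Leaf domains of 8-20 bins tile each chromosome; the
requested number of boundaries of each class is placed exactly. Dot-class
boundaries occupy the left block of each chromosome and dotless-class the
right, and each dot boundary's left flanking domain receives a corner-dot
loop at its (first bin, last bin) anchor pair: interior dot boundaries
become double-dot, the last one single-dot, and no dotted domain ever
flanks a dotless-class boundary. Class labels are shuffled within each
block. With probability 0.3 two adjacent leaves are covered by an undotted
parent TAD — true nesting without extra edges, so per-class counts stay
exact. Motif arrays follow the class grammar (complex: 2-4 co-bound sites
with both strands; tandem/single: one site or 2-3 same-strand sites;
none: no co-bound sites), plus Poisson(1) cohesin-only sites per boundary
and scattered decoy CTCF+cohesin sites (0.2/Mb, uniform strand — a neutral
null for the orientation classifier). Compartments alternate in A/B blocks
of 20-40 bins.

**Contact maps.** `lambda(i,j) = depth * (1 + |i-j|)^-alpha *
domain_mult^(shared nesting depth) * dot_mult^[near a loop anchor pair] *
compartment_mult^[same label, distance > cutoff]`, Poisson counts,
symmetric. Defaults: depth 100 at distance 0, alpha 1, domain 2, dot 4
(radius 1 bin), compartment 1.5 beyond 40 bins (2 Mb). The compartment
cutoff sits above the largest insulation window span deliberately:
checkerboard plaid is a Mb-scale feature of real maps, and letting it act
at sub-Mb distances creates insulation dips at A/B block edges that real
data do not show at that scale.

**Replication timing.** Each planted IZ contributes a profile that rises
linearly from the apex timing to +1 fraction at the IZ edge, climbs a
steep shoulder (1.5 fractions/bin for 2 bins) just outside, then follows
the fork slope (4 fractions/Mb), capped at fraction 16; the field is the
minimum over contributions. The shoulder makes the IZ extent sharply
delimited, so the caller's `T <= T(apex) + 1` width matches the planted
width to within ~1 bin even after smoothing. Apex timings are drawn from
2.5-4.3 (early), 6.5-8.3 (early-mid) and 11.5-13.3 (late): each range is
narrower than the shadowing reach at the minimum boundary spacing, so
same-class IZs never shadow each other, and each range keeps ~1-fraction
margin from the 5.5/10.5 class cut points. A planted IZ whose apex relief
against an earlier-firing neighbor's fork is under 2 fractions is marked
`expressed = FALSE` — passively replicated, like the excess licensed
origins that never fire; the truth table keeps all planted IZs, the
timing field and recovery metrics use the expressed subset. Signal:
`depth * Gaussian(f; tau, spread 1.5)` per fraction, Poisson-noised,
default 200 expected counts per bin.

**Planting probabilities** (per boundary, at most one IZ each; rows are
classes 1-6): early 0.70/0.30/0.10/0.05/0.05/0.05, early-mid
0.10/0.10/0.05/0.05/0.10/0.10, late 0.02/0.05/0.05/0.10/0.30/0.40, plus a
0.05/Mb background away from boundaries. The 0.7-vs-0.05 early contrast at
class 1 versus elsewhere is the headline association the statistical test
must detect; the late concentration at classes 5-6 mirrors the weak
dotless boundaries where low-efficiency zones live.

**Paired conditions.** Each chromosome's layout and its IZ/loop planting
are drawn from separate seeded substreams, so two configs differing only
in IZ or loop parameters share byte-identical architecture — the
synthetic analogue of assaying the same genome in two conditions. The
cohesin-depletion analogue reduces class-1 early planting (0.7 to 0.3)
and widens early IZs; the WAPL-depletion analogue narrows early IZs to
one bin and adds two gained long-range loops per class-1 boundary.

## Study conditions and problem sizes

The default genome is one 50-Mb chromosome at 50-kb bins with 16
boundaries per class. Sixteen is a sample-size choice made by power
analysis of the test's discrete floor: `P_right <= 0.001` at R = 999
requires the observed class-1-early count — roughly Binomial(16, 0.7) —
to strictly exceed all 999 matched-null counts (null max ~4-5), which 16
clears reliably and 8 does not. Calibration is checked on genomes with
200 class-1 boundaries on 150 Mb: empirical P values from count
statistics are only near-uniform when ties are rare, which needs per-cell
expected counts of order 10 or more; at smaller sizes the add-one P is
valid but conservative (sub-uniform), which would mask miscalibration in
the other direction. Condition contrasts use three 65-Mb chromosomes with
165 class-1 boundaries so each arm carries at least 100 class-1 early
IZs; their width comparison is run without genome smoothing in both arms,
because sd-1-bin smoothing imposes a ~3-bin floor on called widths that
masks bin-scale narrowing.

## What the simulation does and does not emulate

It emulates: distance decay, nested domain enrichment, focal corner-dot
enrichment, Mb-scale compartment plaid, motif orientation grammars with
decoys, V/U-shaped 16-fraction timing geometry with fork slopes and
passive replication, Poisson counting noise, and paired-condition designs.
It does not emulate: read-level artifacts (mappability, copy number),
trans contacts, matrix balancing (inputs are assumed balanced), stripes,
chromosome-scale timing gradients uncorrelated with IZs, library-specific
Repli-seq biases, or any coupling between compartments and timing beyond
what IZ placement induces. Passing tests therefore demonstrate
correctness of the algorithms under this generative model, not
performance on real sequencing data; parameter stringency on real maps
shifts absolute counts of domains, dots and boundary classes
substantially, and those counts are data- and stringency-dependent rather
than reproducible targets.

## Numerical and degenerate-input conventions

Contact matrices must be square, symmetric to 1e-9 relative tolerance and
non-negative. Insulation of an all-between-zero junction is undefined
(log of zero) rather than forced. A chromosome with no detected boundary
returns one whole-chromosome domain with a warning; a class with no
boundaries yields an empty profile or APA map with n = 0, not an error. A
Repli-seq fraction with zero total signal, a null request with no
eligible position, an empty Mann-Whitney sample and an infeasible
boundary count are all hard errors naming the offending object. The
Mann-Whitney P is exact by enumeration when the pooled sample is at most
16 without ties, otherwise a tie-corrected normal approximation with
continuity correction (delegated to `stats::wilcox.test`, with the branch
policy enforced by the wrapper). Empirical P values use the add-one rule
and are never zero. All generators and samplers are deterministic under a
fixed seed.
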