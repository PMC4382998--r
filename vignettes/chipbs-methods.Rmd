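---
title: "Methods: joint occupancy and methylation analysis of ChIP-BS-Seq"
author: "chipbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint occupancy and methylation analysis of ChIP-BS-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

ChIP-bisulphite sequencing couples chromatin immunoprecipitation with
bisulphite conversion, so a single library answers two questions about
the same DNA molecules: where was the protein bound, and which CpGs
were methylated. The motivating application is RNA polymerase III at
Alu SINEs — young Alu subfamilies are both CpG-dense and heavily
methylated, so if methylation excluded the polymerase, bound molecules
would be hypomethylated relative to input. Testing that requires every
awkward feature of repeat epigenomics at once: multi-mapping reads,
strand-asymmetric bisulphite chemistry, a conversion control, joint
FDR control for occupancy calling, and family-level statistics on
consensus coordinates.

`chipbs` implements that pipeline as composable stages
(alignment loading → cytosine calling → occupancy scanning →
differential methylation → consensus profiles → family statistics),
plus a synthetic-data generator that emulates the experiment's
statistical structure so every stage can be validated against known
truth.

# Models and procedures

## Bisulphite calling

A directional protocol is assumed: original-top (OT) molecules align
to the plus strand and original-bottom (OB) molecules to the minus
strand (an `XB` tag overrides the inference when present). For OT
records, each covered reference plus-strand C is classified from the
read base — C retained (methylated), T converted (unmethylated),
anything else ignored as a sequencing error; OB records are handled
symmetrically at reference Gs (read G retained, A converted). Context
(CpG/CHG/CHH) comes from the reference on the cytosine's own strand.
No base-quality filter is applied, deliberately: quality filters
preferentially remove repeat reads, which are the object of study.
Plus- and minus-strand calls of one CpG are kept separate by default
(profiles are per-cytosine); `poolCpG = TRUE` merges symmetric pairs.

**Multi-mapper weighting.** Reads with up to `maxAlignments` (default
7) reported placements contribute weight 1/k at each placement, which
conserves one unit of evidence per read; reads above the cap are
dropped and counted. The published repeat-rescue strategy fixes the
cap at 7 but not the weighting; 1/k was chosen because it conserves
totals, and a unit-weight mode is kept for sensitivity analysis.

**Conversion control.** Every cytosine observation on the spike-in
contig is truly unmethylated, so the conversion rate is the weighted
fraction converted, pooled over contexts. Zero spike-in coverage is a
hard error ("no conversion control"), not a silent skip.

## Occupancy scanning

Records collapse to points at `start + shift/2` (plus strand) or
`end − shift/2` (minus strand); the default 116 bp shift is the
published fragment-shift estimate and is a parameter, not something
re-estimated here. Windows of 300 bp, stepped by half a window, are
scored by:

* weighted ChIP and input sums;
* `log2` ratio of library-size-normalised sums with pseudocount 0.5;
* a one-sided binomial test of rounded ChIP counts among ChIP+input
  counts with success probability `chipLib / (chipLib + inputLib)`.

The binomial-vs-library-size statistic is this package's documented
choice for the window test (the original toolchain names its scanner
but not its statistic); it is swappable (`normalized = TRUE` tests
normalised counts against 0.5). Weighted counts are rounded half-up
so exact tests see integers and results do not depend on parity
round-to-even behaviour.

Two FDR scales are attached: a phred-scaled Benjamini–Hochberg
Q-value, and a phred-scaled empirical FDR from re-scanning with the
library labels swapped —
`max(1, #swapped with p' ≤ p) / (#real with p' ≤ p)`, with q-value
style monotone enforcement (cumulative minimum over thresholds).
Without that enforcement the floor of 1 in the numerator penalises
exactly the strongest windows, whose real-window rank is below ~20;
with it, an empirical FDR is always at least as good for a stronger
window. Phred thresholds of 20 (regions), 70 (per-element) and 13
(empirical FDR) with log2 ≥ 1 reproduce the published settings, so 20
means FDR 10⁻² and 70 means 10⁻⁷. Windows passing all thresholds
merge into regions when overlapping or book-ended; elements are
flagged enriched on ≥ 1 bp region overlap, and every element is also
scored directly over its own span with BH correction across covered
elements only.

## Differential methylation

Windows are defined in CpG-index space: 10 consecutive covered CpG
sites, sliding one site at a time, so sparse-CpG regions are testable
with fixed information per window (a bp-window mode exists, but the
CpG-count reading of the published window flag is the default; the
flag string `-w 10 -m 10 -f 13 -l 0` is interpreted as CpGs per
window, minimum observations, phred FDR threshold and minimum |log2
ratio|, each configurable). Each window's pooled
(methylated, unmethylated) × (ChIP, input) table is tested with a
two-sided Fisher exact test — hypergeometric tail summation including
ties up to a 1e-7 relative guard, the same tie rule as
`stats::fisher.test`, implemented vectorised over windows — then
BH-corrected. Element-level tests pool counts over each element span;
class-level summaries report the percentage of tested elements that
are significantly methylation-enriched in the ChIP.

## Consensus meta-profiles

Reads overlapping annotated SINEs by ≥ 1 bp are realigned to family
consensus sequences, concatenated with a 100 N spacer (an internal
layout only — output coordinates are per family). Matching is
ungapped in collapsed bisulphite space: read C→T against the C→T
index, and reverse-complemented read G→A against the G→A index, which
between them cover both bisulphite strands and both element
orientations. A placement is valid at ≤ 20% collapsed-space
mismatches; all placements within 1 mismatch of the best are reported
up to 14 (the published all-alignments consensus cap), weight 1/k.
Ungapped matching with a near-best window was chosen over full
aligner scoring because Alu-length consensi and short reads make
indels a negligible factor at this scale, while the near-best window
reproduces all-alignments reporting behaviour. Reads compete across
all family consensi simultaneously, so a read is never double-counted
between families. Profiles accumulate retained/converted calls per
consensus position exactly as the genomic caller does.

## Family statistics

Occupancy scores and percent methylation are compared across families
with the tie-corrected Kruskal–Wallis test (`stats::kruskal.test`
behind the package API, with pooled mean ranks exposed) followed by
Dunn's pairwise z tests,
`z = (R̄ᵢ − R̄ⱼ) / sqrt((N(N+1)/12 − ΣT/(12(N−1)))(1/nᵢ + 1/nⱼ))`,
Bonferroni-adjusted by default (Holm and none selectable) — the
published analysis names Dunn's test but not the adjustment, and no
installed package provides Dunn's test, so it is implemented from the
rank means directly. The joint occupancy–methylation curve sorts
elements by methylation and averages both axes in sliding blocks of
25 elements. Family comparisons can be run on all elements or only on
enriched ones; both modes are exposed because the published
genome-wide comparison does not disambiguate them.

# The synthetic-data generator

The generator emulates the statistical structure of a HeLa pol III
ChIP-BS-Seq experiment at toy scale, and its defaults are the study
conditions:

* three SINE families whose CpG density (8, 5, 2.5 per 100 bp) and
  methylation probability (0.60, 0.35, 0.13) fall from a young
  AluY-like family to an old AluJ-like one, mirroring the observed
  B-block methylation contrast between Alu age classes; a handful of
  CpG-poor, lowly methylated tRNA-gene-like loci; background CpGs at
  0.75 (genome-wide somatic levels);
* per-copy divergence 2% with at least one exact-duplicate pair per
  family, so multi-mapping reads necessarily arise;
* occupied loci sampled from the annotation with ChIP fragment mass
  multiplied by `occupancyFold` (default 6, the reported scale of
  pol III enrichment at Alu-class elements) and renormalised;
* bisulphite chemistry at the molecule level: each CpG's methylation
  state is drawn once per fragment, unmethylated Cs read T with
  probability 0.9976 (the mid-point of the two reported library
  conversion rates), methylated Cs read T at 0.003, non-CpG cytosines
  are always unmethylated (CpG-only methylation is simulated because
  the analysis is CpG-only);
* fragment lengths are truncated normal, mean 170 bp, sd 35, floored
  at the 101 bp read length — the libraries were small-insert and
  unsized, so the mean is a free parameter chosen once at a plausible
  small-insert value;
* a fully unmethylated spike-in contig contributes 2% of reads;
  uniform sequencing error 0.001/base is applied after conversion.

Truth alignments are emitted directly rather than simulating the
external aligner: a read contained in an element with k identical
copies gets k placements (primary plus secondaries, `NH:i:k`), and an
optional alignment-noise mode collapses such reads to one random
placement while keeping `NH`, so downstream multi-mapper handling can
be tested without implementing genomic alignment. Coordinates are
0-based half-open internally and converted to 1-based exactly once at
the SAM boundary.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: PCR duplicates and adapter
read-through, base-quality miscalibration, indels and soft-clipping,
CHG/CHH methylation, copy-number variation, and aligner-specific bias
beyond the k-placement model. Conclusions about those failure modes
need real libraries.

# Numerical and design choices

* Phred scales are capped at 100; p = 0 maps to the cap rather than
  infinity.
* Weighted counts are rounded half-up before exact tests; ratios use
  pseudocount 0.5 after library-size normalisation.
* The empirical FDR numerator is floored at 1 and the estimate made
  monotone (see above); empirical FDRs are capped at 1 before phred
  scaling.
* An all-zero Fisher table has p = 1 by convention; tie comparison
  uses a 1e-7 relative tolerance so enumeration and dhyper routes
  agree to 1e-12.
* The Kruskal–Wallis p-value uses the chi-square approximation; its
  deviation from a permutation reference at small group sizes
  (observed up to ~0.03 for 3 groups of 8–15) is a property of the
  approximation, not of the implementation, and the test suite checks
  the H statistic exactly while allowing that approximation error on
  the p-scale.
* Fisher's exact test is conservative on discrete tables, so null
  calibration is asserted as a one-sided bound on the type-I rate.
* Region-count monotonicity in thresholds does not hold in general
  (dropping a middle window can split a region); the monotone
  quantities — passing windows and covered bases — are the ones
  tested.
* Elements with zero coverage are flagged and excluded from
  multiple-testing families rather than scored at a pseudocount.
* No read deduplication is performed before methylation calling (the
  upstream protocol question is open; a flag could be added, but the
  default mirrors the no-filter philosophy of the repeat analysis).

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` run entirely on synthetic
data sized for laptop-scale validation: 50,000 reads for
conversion-rate recovery (±0.002); 3 families × 100 copies at ~30×
coverage for methylation recovery (±0.03, Kruskal–Wallis p < 0.01 and
Dunn separation of the extreme pair); 50 occupied loci at 8-fold among
300 elements spaced ~5 kb apart — spacing chosen large relative to the
300 bp window plus ~200 bp fragment flank, as for genomic Alu elements
relative to pol III peak widths, so windows resolve individual
elements — with ≥ 45/50 recovery, ≤ 2 false elements and a null run
calibrated at q ≥ 20; 1,000 random tables against full hypergeometric
enumeration; 20 tied datasets against 100,000-rep permutation
references; ~24,000-read libraries for consensus-profile fidelity
(truth correlation ≥ 0.95 at coverage ≥ 20, ChIP–input agreement
within binomial noise); and duplicate pipeline runs for byte-level
determinism.

# Known limitations

Single-end logic only (paired ends are treated as two records sharing
a molecule id upstream); ungapped consensus realignment; no
beta-binomial dispersion modelling in differential methylation (between
-replicate variability is out of scope when one ChIP and one input
library are compared); the window statistic tests enrichment against
the global library-size ratio and will mis-calibrate if large copy
-number aberrations dominate a contig; and the genome-scale published
numbers (enriched-gene counts, class percentages) depend on the real
deposited libraries and are not reproduced by the synthetic runs —
the synthetic acceptance quantities validate the procedures, not the
biology.
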