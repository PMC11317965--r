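---
title: "Calling DnaA-bound regions and testing the double DnaA box model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DnaA-bound regions and testing the double DnaA box model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublebox)
```

## The scientific question

DnaA is the bacterial replication initiator. It binds 9 bp "DnaA boxes"
(consensus `TTATCCACA`) at the origin of replication and at regulatory
sites across the chromosome. A striking observation from genome-wide
ChIP mapping of *E. coli* DnaA is that the perfect 9-mer alone is a poor
predictor of where DnaA actually binds: most consensus boxes in the
genome are unbound, while almost every bound region carries a *pair* of
boxes whose 9-mer cores sit 2 or 3 bp apart — a "double DnaA box",
consistent with a DnaA dimer contacting two adjacent sites. `doublebox`
implements the computational side of that analysis as a reusable,
testable pipeline:

1. **Region calling** — turn replicate signal/control coverage into a
   filtered set of bound regions;
2. **Motif modelling** — build a single-box position weight matrix (PWM)
   from windows around region centres, then compose double-box PWMs at
   2 bp and 3 bp core spacing;
3. **Scanning** — score the genome on both strands with log-odds and
   exact p-values;
4. **Recovery analysis** — rank hits and ask how quickly each motif
   model "recovers" the bound regions, the operational definition of
   predictive power.

A synthetic-data module generates genomes with planted sites and
matching coverage, so every stage (and the pipeline end to end) is
exercised against a known ground truth without any external download.

## Region calling

Point peaks are aggregated by single linkage: consecutive peaks less
than `max_gap = 100` bp apart join one region (a gap of exactly 100 bp
splits — the comparison is strict). The region centre is the midpoint of
the first and last member peak, rounded half up; rounding direction is
arbitrary for even spans and is fixed for determinism.

Each region is scored by *coverage relative to control*: the mean, over
a 201 bp window centred on the region centre, of the replicate-averaged
normalized signal coverage, divided by the same quantity for the
control. The window mean is used rather than the sum; for a fixed window
length the ratio is identical either way. A pseudocount (default 0.25
normalized units, i.e. a quarter of the genome-wide mean after
normalization to mean depth 1) is added to the control denominator so
zero-coverage control windows stay finite; it is configurable and only
matters for very sparse controls. Regions with a ratio strictly below
`min_ratio = 3` are discarded, as are regions whose centre falls in a
user-supplied exclusion interval (the escape hatch for repetitive
sequence where misalignment inflates coverage).

Peak *detection* is deliberately a simple stand-in, because region
definitions should not depend on any particular external caller: the
replicate-averaged tracks are smoothed with a 101 bp running mean,
divided (signal over control plus pseudocount), and strict local maxima
of the ratio above `min_fold = 3` are greedily thinned to at least
200 bp apart. The 101/200 bp choices follow from the simulated bump
geometry (sd 75 bp): one enrichment bump then yields exactly one point
peak. Users with a preferred caller can pass its peaks directly and skip
this step entirely.

## Motif model

The single-box PWM has `motif_width = 11` columns: one flanking column
on each side of the 9-mer core. This width is what makes the double-box
composition exact: concatenating a width-11 PWM with itself in tandem
places the two cores exactly `2f = 2` columns apart, and inserting one
background-distributed column between the copies gives 3 bp spacing.
Other odd widths are accepted, with the two supported spacings
reinterpreted as `2f` and `2f + 1`.

PWM columns use the pseudocount convention
`p[i,b] = (count(b) + a * bg[b]) / (n + a)` with `a = 0.1` distributed
by the background composition, so every probability is strictly
positive and log-odds scores stay finite.

Motif discovery is a seeded expectation-maximization finder, not a port
of any external program. Every window offset on both strands is a
candidate site in a two-component mixture (motif vs background) with no
limit on occurrences per window. Seeds are the most over-represented
9-mers (the box width) counted on both strands — counting at core width
concentrates signal that full-width counting would spread over flank
variants — embedded centrally in a width-11 initial PWM with background
flanks. Each seed is refined until the information content changes by
under `1e-6` bits (or 200 iterations), and the highest-information
converged motif wins; ties are broken toward the lexicographically
smallest seed so the result is deterministic. The discovered motif's
orientation is arbitrary (a motif and its reverse complement are the
same object for scanning); downstream stages never depend on it. A PWM
can also be loaded from a MEME-format file or built from a user-supplied
alignment, bypassing discovery.

## Scanning and exact p-values

A k-mer is scored as `sum_i log2(p[i, base_i] / bg[base_i])` (bits).
Per-column scores are discretized to 0.001-bit bins; the null
distribution of the discretized total under a 0-order background is
computed exactly by positionwise convolution (a dynamic program over
attainable integer scores), giving `p(s) = P(score >= s)` without
sampling error. Observed window scores are discretized with the same
per-column rounding, so scan p-values are exact for the discretized
score; the suite checks the dynamic program against exhaustive
enumeration of all k-mers for small widths. Hits are reported when
`p <= p_max = 1e-4` (inclusive). Windows containing `N` are never
scored. Scanning treats the genome as linear even when it is flagged
circular — the behaviour of standard scanners — while window extraction
may wrap on circular genomes when the caller opts in. The scan
background defaults to the 0-order base composition of the scanned
sequence with complementary bases averaged, and can be overridden.

## Ranking and recovery curves

Hit lists (for the combined double-box model, the 2 bp and 3 bp scans)
are concatenated, deduplicated (identical coordinates keep the
higher-scoring entry, so one locus is never counted twice), and sorted
by score with deterministic tie-breaks (p-value, then start, then
strand). A hit is associated with a bound region when its nearest base
lies within 100 bp of the region centre; each region keeps its
best-ranked eligible hit. "Nearest base" is the most permissive
defensible reference point and is configurable (`start` and `midpoint`
are also supported). The recovery curve then reports, for every rank
*r*, the fraction of regions whose best hit ranks at or better than
*r*; comparing the single-box and combined double-box curves — per-rank
difference, ranks at 50/80/100 % recovery, area between curves — is the
package's predictive-power comparison.

## What the synthetic data emulate — and what they do not

`fixture_profile()` defines two layouts. The `"small"` profile (50 kb, 8
plants) is for fast smoke tests. The `"paper-like"` profile (500 kb, 30
plants) is the study condition used by the end-to-end tests and the
acceptance script: consensus double boxes at 2 and 3 bp spacing on both
strands, a mismatch series (1 or 2 changes per box, and a fully mutated
pair), spacing-perturbed pairs at 4 bp, and single boxes. Plant
strengths encode the binding model the analysis is designed to detect:
matched-spacing doubles bind strongly (enrichment 8–20x), mismatches
degrade binding (6–12x), while spacing-4 pairs and single boxes —
including perfect consensus singles — are weak (0–3x, below the calling
threshold). That last choice mirrors the in vivo observation that most
perfect single boxes are unbound; it is what makes the single-vs-double
comparison scientifically meaningful rather than circular.

Coverage is simulated as negative-binomial noise (dispersion 0.2,
variance `mu + 0.2 mu^2`) around a background mean of 20, with each
plant adding a Gaussian bump (sd 75 bp, height `strength x background`)
to the signal tracks; two replicates each of signal and control use
distinct substreams of one master seed, and every track is normalized to
mean depth 1. The simulation deliberately omits read-level artefacts:
GC bias, mappability structure, fragment-length variation, replicate
batch effects, and repetitive sequence. Passing tests therefore
demonstrate the correctness of the algorithms under a clean
overdispersed-count model, not robustness to every artefact of real
libraries — which is exactly why the region caller accepts external
peak lists and exclusion intervals.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere internally; conversion to
  0-based half-open happens only at the BED/bedGraph boundary.
* Score discretization 0.001 bits/bin: fine enough that discretization
  error is below any threshold of interest, coarse enough that the
  convolution table stays small.
* EM convergence `1e-6` bits; all tie-breaks (seed choice, consensus
  string, hit ordering) are lexicographic/positional and deterministic.
* Zero retained regions (e.g. an extreme `min_ratio`) is a clean result:
  the pipeline returns empty downstream tables, not an error. Fewer than
  four usable motif windows likewise skips motif discovery.
* All-zero control with all-zero signal yields no peaks, not a division
  error.

## A boundary phenomenon worth knowing about

Exact p-values make one behaviour visible that a casual reading of
"double-box motif" might not predict: a *single* consensus box — or a
pair at the wrong spacing — embedded in random sequence can still fall
in the `1e-4` upper tail of a 22/23-column double PWM's null
distribution, because one perfectly matched core plus the partial
self-overlap of the consensus is already far better than almost all
random k-mers. In the bundled study conditions the acceptance script
measures this directly: spacing-4 pairs are usually *hit* by the double
PWMs at `p <= 1e-4`, but at scores and p-values orders of magnitude
worse than matched-spacing pairs (the unit suite asserts a >=100-fold
p-value separation). The spacing signal is therefore carried by score
and rank, not by bare presence in a thresholded hit list; conclusions
about spacing preference should always be drawn from the ranked
comparison.

## Problem sizes

The test suite runs the full pipeline on the 50 kb profile and the
properties above on 2 kb random genomes; the acceptance script runs ten
independent 500 kb end-to-end replicates, 50 random PWMs for the
p-value cross-check, and reports pooled percentages. These sizes give
stable statistics (pooled denominators of 90–170 events) while keeping
a complete run in the tens of seconds on one CPU.

## Known limitations

* The peak detector is intentionally minimal; it is a stand-in, not a
  statistical caller, and reports no significance for peaks.
* Single-replicon genomes only; no multi-chromosome support.
* 0-order background model for scanning; no higher-order Markov
  background, no FDR/q-values for hits.
* The EM finder implements only the any-number-of-repetitions site
  model; no palindrome mode, no motif-width optimization, no E-value
  objective.
* Recovery curves are the comparison device; no significance test is
  attached to the difference between two curves.
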