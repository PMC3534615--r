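---
title: "Processing and normalizing genomic 3C contact maps with scn3c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and normalizing genomic 3C contact maps with scn3c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scn3c)
```

## The problem

Chromosome conformation capture with deep sequencing (genomic 3C, the Hi-C
family of protocols) measures how often pairs of restriction fragments (RFs)
were crosslinked in a cell population. The raw read stream is dominated by
protocol byproducts and systematic biases, so the counts in a contact matrix
mix biology with chemistry. `scn3c` implements a complete processing chain
for such data at fragment resolution:

1. an in silico digest annotating every RF with its secondary-enzyme (RE2)
   sites, end GC content and end-flank mappability;
2. classification of each paired-end ligation product into self-loops,
   religations, adjacent loops and long-range intra/inter contacts, with the
   read-level filters of the protocol;
3. quantification of three experimental biases as binned
   reads-per-possible-interaction profiles;
4. contact-map normalization by Sequential Component Normalization (SCN)
   with norm-product and marginal-sum alternatives, genomic-distance
   detrending, correlation maps, binning and a display blur;
5. a modified ROC test for 3D colocalization of genomic feature sets;
6. a synthetic-data generator that emulates the protocol forward model with
   truth labels, so every estimator in the package is validated by
   parameter recovery.

## Event classification

Each RF has a low-coordinate `-` and a high-coordinate `+` extremity. A
sequenced mate engages the boundary in its 3' direction: forward-strand
mates engage `+` extremities, reverse-strand mates `-` extremities. This
single rule reproduces the three diagnostic orientation facts: a
self-circularized fragment joins its `-` to its `+` extremity; a religation
of two adjacent fragments joins upstream-`+` to downstream-`-` (restoring
the original sequence); a two-fragment loop joins upstream-`-` to
downstream-`+`. Everything else on the same chromosome is a long-range
intra contact, and cross-chromosome pairs are inter contacts.

Read-level filters are applied in a fixed order: mapping quality of at
least 30 on both mates (a phred score of 30 corresponds to a 1/1000 chance
of a misplaced alignment); a mate-to-RE1-cut distance in {20, 21, 22} bp
(condition A) or {21, 22, 23} bp (condition B), reflecting the type-III
enzyme geometry that releases tags about 20 bp from the junction; RE2
validity of both engaged extremities (the nearest RE2 site must lie at
least 20 bp from the RE1 cut, otherwise the tag cannot be distinguished
from the re-opened circle); and finally removal of the byproduct classes.
Event-class tallies are recorded after the read-level filters and before
the fragment-geometry filter, so the class mixture is comparable to the
generative mixture of the simulator. The accounting identity
`input = kept + sum(removed)` is asserted in the test suite.

## Bias models

**Fragment length.** The chance that a fragment of length $L$ is
crosslinked at least once is $f(L) = A\,(1 - (1 - p_c)^L)$, where $p_c$ is
the per-bp crosslink probability: reads per fragment rise roughly linearly
for short fragments and plateau near $A$. `fit_crosslink()` fits $(A, p_c)$
by Levenberg–Marquardt least squares on the 100-bp-binned profile
(unweighted, as bin occupancies are comparable in the informative range).
A flat profile is the saturation limit ($f(x) = A$ for every $x \ge 1$),
where the two parameters are not separable; the fit is then flagged
degenerate rather than reported.

**End GC content.** The profile covariate is the mean GC fraction of the
two engaged 20-bp end flanks, binned at 2.5%. The possible-interaction
universe $N_i$ enumerates all unordered pairs of RE2-valid fragment
extremities (exact outer enumeration, subsampled above 4000 ends).

**Circularization length.** Each tag derives from a circle of length
$d_A + d_B$, the summed distances from the two engaged RE1 cuts to their
nearest RE2 sites. The 1-bp profile of reads per possible pair shows the
classic circularization-efficiency curve — suppressed below ~200 bp by DNA
bending stiffness, decaying beyond ~1 kb entropically — with a ~10.5-bp
ripple from the helical twist: circles needing a fractional extra turn to
close ligate less efficiently. `estimate_period()` recovers that ripple by
subtracting a 21-bp moving-average envelope and locating the dominant DFT
peak (zero padding x8) in the 5-50 bp band; a peak is reported only when
its power exceeds 15x the median band power, otherwise the result is "no
significant periodicity". `profile_mode()` estimates the envelope optimum
by a 21-bp moving average followed by an N-weighted quadratic vertex fit of
log r against log length over a x1.6 window around the peak: efficiency
curves on a positive covariate are single-peaked and near-parabolic in log
space, so the vertex fit pools several hundred bins instead of trusting one
noisy argmax. Bias profiles are computed on the filtered long-range events,
matching the processing order in which byproduct removal precedes bias
quantification.

## Normalization

Low-signal fragments (Euclidean row norm below 30 in the raw counts) are
removed first: a normalization that gives each fragment equal weight would
amplify their noise. For intra maps the genomic-distance decay is divided
out next: reads per possible pair are averaged in log-spaced distance bins
and fitted with a degree-8 polynomial in log-log coordinates (heavy-tailed
monotone decay is poorly captured by low-degree polynomials in linear
space); the fitted expectation is evaluated with the distance clamped to
the observed range so it stays strictly positive.

SCN then alternately normalizes every column and every row to unit
Euclidean norm until all norms are within `tol` (default `1e-3`) of 1, and
symmetrizes the result as $(M + M^\top)/2$. On dense positive matrices two
or three sweeps suffice; sparse block-structured matrices can take many
more, and convergence is not guaranteed in general, so hitting `max_iter`
raises a typed condition instead of returning a half-normalized map. The
iteration count reported counts one column pass plus one row pass as one
sweep. Two one-shot alternatives are provided for comparison:
`norm_product()` divides by the product of row and column norms (its output
rows are not unit vectors, the motivation for SCN) and `marginal_sum()`
uses L1 marginals. SCN is exactly invariant under global rescaling of the
input; the two quotient maps scale by the inverse factor, i.e. are
invariant up to a global constant. On our synthetic maps the three methods
rank interactions almost identically; the contrast difference between SCN
and the marginal-sum map reported on real data is not reproduced by this
generator (the measured coefficients of variation differ by only a few
percent, in either direction depending on the map), so the package
documents the difference in weighting rather than asserting a direction.

## The colocalization test

For a feature set mapped to fragments (at least 1 bp interval overlap), the
test keeps every off-diagonal pair touching the set, ranks them by
normalized score (ties broken by index, so the ranking is stable), labels
pairs positive when both fragments carry the feature, and traverses the
ranking to build a curve of cumulative percent positives against percent
negatives; the trapezoid AUC summarizes enrichment. The essential control
reproduced in the test suite: a feature whose fragments merely interact
more with everything (coverage inflation, the classic artifact) shows
AUC well above 0.5 on the raw map but falls back to ~0.5 after SCN,
because equal-row-norm normalization removes exactly that kind of
separable coverage factor. A genuinely planted pairwise enrichment
($\gamma > 1$ between feature fragments) survives normalization.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the conditions
the package is validated under, not tuning knobs:

- three 200-kb chromosomes; RE1 motif `AAGCTT` (6-cutter-like) planted as
  a Poisson process with 2-kb mean spacing, RE2 motif `CCGG`
  (4-cutter-like) at 300-bp mean spacing — about 100 fragments per 200 kb,
  with arm lengths in the observable range;
- event mixture 0.40 self-loop, 0.35 religation, 0.05 adjacent loop,
  0.12 long-range intra, 0.08 inter, so loops plus religations are 80% of
  the stream, the hallmark composition of the protocol;
- intra distance decay $D_g^{-1.5}$ (equilibrium-globule-like scaling
  typical of yeast intra-arm contacts);
- crosslink length factor $f(L) = 1 - (1 - p_c)^L$ with $p_c = 0.004$;
- Gaussian GC acceptance centered at 0.45 with width 0.10;
- log-normal circularization envelope with optimum 500 bp and log-sd 0.35
  (a pronounced single peak spanning roughly 250-1000 bp at 2 sd, the
  shape of a typical circularization-efficiency curve), modulated by
  $1 + 0.3\cos(2\pi L / 10.5)$;
- mate offsets uniform over {20, 21, 22} bp (condition A geometry), 2% of
  mates with low mapping quality.

Biases act by rejection sampling, mimicking the physical losses of the
protocol rather than reweighting. Candidates whose mate offset reaches past
the engaged fragment, or (when the circularization bias is on) whose circle
length is undefined for lack of an RE2 site, are rejected: such molecules
are not observable under the protocol geometry. Long-range intra draws
exclude same-fragment and adjacent pairs — those belong to the other
mixture components — which is what makes the classifier provably exact on
truth labels. Everything is deterministic given the seed.

What the generator does *not* emulate: base-call sequences and sequencing
errors (coordinates only), chimeric reads, PCR duplicates, copy-number
variation, restriction-site polymorphism, and genuine higher-order 3D
structure beyond pairwise propensities. Passing recovery tests therefore
demonstrates the estimators are correct for the modeled data-generating
process, not that real libraries contain no further artifacts.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open (BED semantics) throughout; cut
  offsets within recognition motifs are configurable (default 1 for
  `A^AGCTT`-class enzymes), and all distances are measured to cut
  coordinates.
- RE2 validity is tracked per extremity with the nearest-site rule; the
  fragment-level flag is the OR of the extremities.
- Mappability proxies ambiguous alignment by exact duplication of the
  20-bp end flanks (either strand); a fragment is unmappable when both
  flanks are ambiguous. Without an aligner this is deliberately
  conservative.
- Empty profile bins carry `NA`, never silent zeros, and are flagged.
- Zero-variance rows in correlation maps yield flagged `NA`s; zero
  rows/columns make SCN fail fast with the offending index.
- The display blur applies the exact 3x3 kernel of 0.05 ten times with
  zero padding; its kernel sum is 0.45, so intensity is deliberately not
  preserved — it is for display only.
- Problem sizes in the validation suite: toy genomes of 0.4-2 Mb (about
  100-1000 fragments), event streams of 2x10^4 to 1.4x10^6 pairs. These
  sizes keep every recovery within a few percent while the whole suite
  runs in minutes on one core; the recovery tolerances quoted in the
  acceptance tests were chosen for these sizes.

## Known limitations

- SCN convergence is only typical, not guaranteed; highly sparse or
  near-reducible maps may need hundreds of sweeps or fail, which the
  package reports explicitly.
- Per-interaction bias *correction* (dividing each pair by an expected
  value under the fitted bias models) is intentionally absent: the
  circularization bias is strongly non-monotonic at 1-bp scale, which
  defeats smooth per-pair correction — the global normalization is the
  package's answer. Only the genomic-distance expectation is divided out.
- The ROC test reports enrichment, not calibrated significance;
  permutation p-values are out of scope.
- Fragment counts of a specific published digest are not reproduced; the
  package is validated against synthetic ground truth.
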