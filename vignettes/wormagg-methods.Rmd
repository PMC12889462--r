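---
title: "Methods: cluster-size estimation, aggregation metrics, and the evolutionary statistics layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-size estimation, aggregation metrics, and the evolutionary statistics layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which tunable parameters matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open.

## The measurement problem

Aggregating *C. elegans* lose individual identity the moment they touch:
a binarized video frame shows connected foreground components ("blobs")
that may be one worm or twenty. The quantity of interest per frame is the
multiset of cluster sizes — how many worms sit in each blob — from which
a scalar aggregation state follows. No per-worm tracking through clusters
is attempted anywhere in the package; all inference runs on blobs and on
the conservation of worm counts across frames.

## Segmentation

`estimate_background()` takes a per-pixel temporal median over a
stride-subsampled set of frames. The estimator is exact wherever a pixel
is foreground in under half of the sampled frames; a region occupied by a
near-stationary aggregate for most of a recording can bake into the
median. Two design choices limit the damage. First,
`adaptive_threshold(difference = "positive")` segments bright-foreground
video with the positive part of `image - background`, so a *vacated*
baked-in region (background bright, current frame dark) can never segment
as a ghost object; the default remains the absolute difference, which is
agnostic to contrast polarity. Second, the simulated clusters drift
slowly but persistently (see below), so in the synthetic study conditions
no pixel stays occupied long enough to contaminate the median.

Thresholding is local: a pixel is foreground iff its background
difference exceeds the mean difference within a `window × window` box by
more than `offset`. The window (default 65 px) must exceed the diameter
of the largest expected blob, otherwise cluster interiors sit at their
own local mean and drop out. Components are labelled 8-connected —
worms are thin, often diagonal shapes that 4-connectivity fragments —
and components below `min_area` (default a quarter of the nominal
single-worm area, removing detector noise) are discarded. None of the
window/offset/connectivity settings is prescribed by the assay itself;
they are declared defaults, isolated behind arguments.

## The temporal blob graph

`build_temporal_graph()` links blobs of consecutive frames whenever the
minimum distance between their pixel sets is at most
`max_link_distance`. Distances use boundary pixels only — identical
minima for filled components at a fraction of the cost — with a
bounding-box prefilter. The default radius, one body
length (15 px), was chosen from the event geometry: between consecutive
analysed frames a blob's own pixels move a small fraction of a body
length, while the blob of a worm that has just left or joined a cluster
lands up to a dozen pixels away once the cluster re-packs; one body
length covers those displacements with margin. A radius of one and a
half body lengths, plausible at first sight, measurably cross-links
distinct worms passing near each other under this motion scale.

Residual crossing edges are removed by *link dominance*: an edge is
dropped only when **both** endpoints have another link closer by more
than `prune_slack` (4 px). A genuine split or merge edge always
survives, because the departing or arriving blob has no closer
alternative on its side.

## Single-worm classification

Track segments — maximal chains of unambiguous links — are labelled
single iff

* a majority (> 0.5) of their frames have blob area below the dynamic
  area threshold,
* every internal node has in- and out-degree at most 1 (a track may
  *end* in a merge — that is how single tracks normally end — but may
  not contain a split/merge), and
* the trajectory shows single-like mobility.

The area threshold is `1.5 ×` the mode of the blob-area histogram
restricted to the lower half of the observed area range, where single
worms dominate: the pipeline self-calibrates without a worm-size input.
Classification iterates, recomputing the threshold from still-unlabelled
blobs, but never upward — once most singles are labelled the unlabelled
area mode drifts to the two-worm cluster area, which must not re-target
the threshold.

Mobility needs care. The trajectory convex-hull area separates roaming
singles from near-stationary clusters by one to two orders of magnitude
*per frame*, but two regimes defeat a fixed hull cutoff: short tracks
(hulls grow with track length; the requirement therefore ramps linearly
up to `hull_ref_frames = 150` frames and vanishes for tracks of five or
fewer frames, where area and degree decide alone) and near-straight runs
(the hull of a straight path is degenerate no matter how fast the worm
travels; short tracks may alternatively qualify through their
bounding-box diagonal, which grows with single-worm speed but stays near
zero for drifting clusters). The absolute hull default is `1.5 ×` the
modal single-worm area: measured against simulated ground truth, a
4-times-the-body-area requirement rejected about a third of genuine
single tracks while stationary-cluster hulls remained fifty-fold below
even the lower bar, so the conservative default was demonstrably
miscalibrated for its purpose.

## Size propagation and interval bounding

Worms move only along temporal edges, so within every connected
component of the edge graph between frames *t* and *t+1* worm counts are
conserved: the sizes on the left side sum to the sizes on the right.
Plain merges give the classic "whole equals sum of parts" equation;
crossing events — a worm transferring between clusters in one step —
still yield the valid component-sum constraint rather than being
discarded. Propagation seeds labelled singles at size 1, passes sizes
along unambiguous links, resolves any constraint with a single unknown,
and optionally applies the per-frame totals constraint (sizes sum to the
known worm count *n*; on by default, and doubled as quality control).
Sweeps run to a fixpoint with a 100-iteration cap.

A conservation contradiction — an implied size below one, or resolved
sizes violating an event equation — indicates a defective input. When
conservation implies a size other than one for a labelled single, the
label is the softer evidence and is revoked; otherwise the offending
event is rejected. Either way propagation restarts without the bad
input (rejections are logged in the result): letting one bad equation
flag otherwise-fine nodes as inconsistent proved far more damaging than
dropping it. Contradictions under the frame-totals constraint flag the
node itself.

Unresolved nodes then get interval bounds by propagating `[min, max]`
through the same constraints to a fixpoint, and are assigned the mean of
their endpoints — hence half-integer sizes are possible, with a known
upward-bias caveat for large, frequently splitting clusters. Unlabelled
unresolved nodes start at `[1, n-1]`: a lower bound of 2 (assuming the
classifier catches every true single) is available via `min_unresolved`,
but the default must admit size 1 because short single tracks are
genuinely unclassifiable. The pipeline driver additionally enables morphological interval
bounds (`area_floor`): an unresolved node whose blob areas sit above the
single-worm threshold in a majority of its frames starts at a lower
bound of 2, and one persistently below the stricter short-track bar at
an upper bound of 1. The op-level default keeps pure conservation
bounds. An exhaustive oracle
(`brute_force_size_oracle()`, a frame-by-frame dynamic program over all
feasible integer assignments) exists purely as an independent check; on
hundreds of random small instances the propagated values equal the
oracle's unique values and the intervals equal its feasible ranges.

Events are processed in (frame, blob id) order and all ties are broken
deterministically, so identical inputs give bit-identical outputs.

## Aggregation metrics

Cluster identities are discrete bins with probabilities
`P_i = size_i / n` (natural logarithm; normalisation by the nominal *n*
exactly as defined, even when a frame's sizes do not sum to *n* — a
`strict` mode renormalises instead). `A(t) = 1 / (-Σ P_i ln P_i)` is
dimensionless; the all-singleton state gives the floor `1 / ln n`.
Degenerate single-cluster frames (zero entropy) are capped at
`1 / H({n-1, 1})`, the largest finite index reachable with *n* worms,
rather than dropped or infinite: capping keeps the series finite for the
autocorrelation, and cap events are recorded per frame.

`μ_A` is the arithmetic time average. `C(τ)` uses the biased
(divide-by-total) estimator, so `C(0) = 1` exactly; the maximum lag
defaults to the full series. `τ_A` is the maximum of the running
left-rectangle integral of `C` including lag 0, so `τ_A ≥ δt` always; a
trapezoid variant exists behind a flag. For very long series the running
integral is best truncated (`max_lag_fraction`): beyond the decay of
`C`, lag estimates are noise whose cumulative sum random-walks, adding
variance without information — the AR(1) recovery checks use a 1%
window for exactly this reason. The bootstrap to a fixed number of
samples per strain resamples whole replicate rows (all traits jointly)
with replacement, also when a strain has more replicates than the
target.

## The synthetic-data generator

`simulate_worms()` emulates the assay conditions: 40 age-matched worms,
45-minute recordings analysed at 8.33 Hz, a circular arena with a
central food patch. Worms are persistent random walkers (1 px/frame,
heading noise 0.3 rad/frame, weak attraction to the patch); clusters are
slow rigid units (0.1 px/frame) whose members sit on a hexagonal-spiral
lattice with 4-px spacing and tangential body orientation. Three
properties are guaranteed by construction, because every downstream test
depends on them:

* *Truth–render consistency.* Worms join a cluster exactly when their
  capsule outlines come within `join_radius` (5 px) — the same geometry
  that would make their rendered blobs touch — so ground-truth
  partitions and rendered connected components agree frame by frame.
* *Cluster connectivity.* Worm centres lie on their own body axes, so
  the distance between two capsules is at most the distance between
  their centres: 4-px lattice spacing below the 5-px capsule half-length
  guarantees every member overlaps a neighbour, whatever its
  orientation, and each cluster renders as one component. Members keep
  their lattice slots by greedy nearest-position matching at every
  membership change, so nobody teleports across a cluster and
  consecutive-frame blob distances stay within the linking radius.
* *Clean events.* Splits are binary (one leaver per cluster per frame,
  unless `multiway_splits`); leavers are placed just outside contact
  range but inside the linking radius of their source cluster, and at
  least one body length clear of every other worm — a leaver surfacing
  near a second group either joins it in the same step (a crossing event
  with no usable conservation constraint) or draws a spurious proximity
  link to it, and both failure modes dominated the residual estimation
  error before this rule. When no clear exit exists the leave event is
  deferred.

What the generator does **not** emulate: worm posture and undulation,
area variability beyond rigid capsules, bacterial depletion, oxygen
dynamics, grayscale texture, illumination gradients, or imaging noise.
Passing tests therefore demonstrate the correctness of the graph
algorithms, the metrics, and the statistical layer under controlled
conditions with known truth — not robustness to real-video nuisances
such as posture-driven area fluctuations or segmentation noise, which
enter real deployments through the configurable segmentation and
classification parameters.

The trait/genotype generators are direct: strain effects with identity
or kinship covariance plus i.i.d. residuals (`simulate_traits`,
recording the generating heritability); selfing-homozygous 0/2 dosages
with uniform allele frequencies and, optionally, founder-family
structure (`simulate_genotypes(n_founders=)`) — without structure,
kinship matrices are near-identity and variance components on them are
unidentifiable; habitat environments with a 6.5 °C/km temperature lapse
and elevation-dependent temperature variability
(`simulate_strain_environment`), reproducing the predictor collinearity
pattern that matters for subset selection; and pair-indexed MLPE data
with known slope and variance components (`simulate_mlpe_pairs`).

## The evolutionary statistics layer

**PGLS.** `Ω` is the Brownian-motion covariance (shared root-to-MRCA
branch lengths, via the tree's variance–covariance matrix), used up to a
single scale absorbed into `σ²` — plain Brownian, no Pagel's λ. The GLS
closed form is evaluated by Cholesky whitening; `σ²` is the ML estimate,
standard errors use `σ̂²(XᵀΩ⁻¹X)⁻¹`, and t statistics are referred to
`n - k` degrees of freedom. Subset selection fits all `2⁷ - 1` nonempty
predictor subsets by ML (so AICs are comparable across fixed effects)
and returns the full ranking plus the best model's projected phenotype
`ŷ = Xβ̂`. Note that coefficients of the AIC-best model are selected for
apparent significance; the calibration property that holds (and is what
the package's checks assert) is the nominal type-I error of a
pre-specified predictor's PGLS test.

**Distances and MLPE.** Traits and elevation are z-scored, population
means taken, and pairwise Euclidean distances formed; geographic
distances are haversine kilometres on a 6371-km sphere (an ellipsoid
differs by under 0.6%), max-scaled to [0, 1]; genetic distances are
p-distances. The MLPE model `y_ij = Xβ + u_i + u_j + ε_ij` has
covariance `σ_u²` between pairs sharing exactly one population and zero
between disjoint pairs. It is fitted by REML profiled over
`λ = σ_u²/σ_ε²` (Woodbury identities keep every evaluation at
population-level cost), with a parallel ML fit supplying likelihoods
for AICc; `λ = 0` reduces the fit exactly to OLS. Whether the original
analyses used ML or REML likelihoods for selection is not knowable;
this package uses ML for model comparison and REML for the reported
variance components, the same convention as its PGLS layer.

**Heritability and QTL variance.** The one-component REML profile
rotates by the eigendecomposition of the strain covariance, making each
candidate ratio an O(n) evaluation; the two-component model (QTL
kinship + genome-background kinship) optimizes two log-ratios by
Nelder–Mead with a Cholesky per step, explicitly comparing the interior
optimum against each boundary (a component switched off). Variance
components are constrained non-negative by the log parameterization;
boundary convergence is flagged. Confidence intervals use a two-stage
percentile bootstrap — strains resampled with replacement, then
replicates within each drawn strain — because resampling replicates
alone deflates the within-strain variance and biases heritability
upward by roughly +0.1 at five replicates, producing intervals that can
exclude their own point estimate. Near-collinear QTL and background
kinships (off-diagonal correlation above 0.99) trigger a
non-identifiability warning.

## Problem sizes used in the checks

The packaged checks run at deliberately compact sizes: tracking recovery
uses twenty 4-minute recordings (2,000 analysed frames each) of 40 worms
in a 460-px arena; oracle comparisons use 200 instances of up to 8 worms
and 30 frames; timescale recovery uses AR(1) series of length 10⁵;
statistical recovery uses 50 strains × 5 replicates (heritability), 40
populations (MLPE), and 150 strains (QTL partitioning), with 100–200
Monte-Carlo replicates per property. These sizes are the package's
choices for routine verification; every routine scales to longer
recordings linearly in frames.

## Known limitations

* Interval bounding is box consistency, not exact feasibility: on
  pathological constraint networks the intervals can be wider than the
  true feasible range (they always contain it).
* The mean-of-extremes assignment biases sizes of large,
  frequently-splitting clusters upward, as flagged in the estimates'
  metadata.
* The per-frame totals constraint presumes all worms stay detectable;
  recordings violating it are flagged and excluded by QC rather than
  corrected.
* The temporal-median background fails for aggregates parked on one
  spot for most of a recording; positive-difference thresholding
  removes ghosts but cannot recover a blob standing on its own baked-in
  image.
* Heritability and QTL-variance estimates inherit REML's boundary
  behavior at small strain counts; boundary fits are flagged, not
  hidden.
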