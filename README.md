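# wormagg

Quantifying collective aggregation behavior in *Caenorhabditis elegans*
from multi-worm video, and relating the resulting traits to environment
and genotype.

*C. elegans* worms feeding together on a bacterial patch can aggregate
into multi-worm clusters. Measuring that collective behavior from video
is hard because clustered worms are indistinguishable inside a blob:
individual identity is lost at every merge. `wormagg` implements a
pipeline that sidesteps identity tracking entirely:

1. **Segmentation** — background subtraction (temporal median), adaptive
   local thresholding, and 8-connected component labelling turn each
   frame into a table of blobs (one worm or one multi-worm cluster each).
2. **Cluster-size estimation** — blobs become nodes of a *temporal blob
   graph*, linked across consecutive frames by minimal inter-component
   pixel distance. Single worms are identified iteratively from
   morphology (blob area below a dynamically computed threshold) and
   trajectory spatial extent (singles roam, clusters do not). Worm counts
   then propagate through the graph using conservation at split/merge
   events: when all but one participant of an event is known, the
   remaining count follows from the difference. Clusters still ambiguous
   at convergence get interval bounds and the mean of their minimum and
   maximum possible sizes.
3. **Aggregation metrics** — per frame, cluster sizes define a discrete
   probability distribution `P_i = size_i / n`. The aggregation
   magnitude is the inverse spatial entropy

   `A(t) = 1 / ( -Σ_i P_i ln P_i )`,

   high when worms concentrate in few clusters. A recording is summarised
   by its time average `μ_A` and by the temporal persistence

   `τ_A = max_t ∫_0^t C(τ) dτ`,

   the maximum of the running integral of the normalized autocorrelation
   `C(τ)` of `A(t)` — an integral timescale measuring how long the
   aggregation state persists.
4. **Evolutionary statistics** — phylogenetic generalized least squares
   (`β̂ = (XᵀΩ⁻¹X)⁻¹XᵀΩ⁻¹y` with Brownian-motion covariance `Ω`) with
   exhaustive AIC subset selection over environmental predictors;
   maximum-likelihood population effects (MLPE) models on pairwise
   distance matrices with AICc selection; VanRaden genomic relationship
   matrices `A = MMᵀ / Σ 2p_i q_i`; REML heritability
   `σ_u² / (σ_u² + σ_ε²)` (broad-sense with identity strain covariance,
   narrow-sense with the genomic relationship matrix); and
   two-random-effect QTL variance partitioning
   `σ_u² / (σ_u² + σ_v² + σ_ε²)`.

A first-class synthetic-data module simulates aggregating worms with
known ground-truth cluster partitions, renders binary frames, and
generates trait/genotype/pairwise-distance data with known parameters, so
every stage of the pipeline is testable end to end without external data.

## Worked example

Simulate a 4-minute recording of 40 worms, run the full pipeline, and
compute the two behavioral traits:

```r
library(wormagg)

cfg <- sim_config(n_worms = 40, arena_radius = 230, patch_radius = 115,
                  duration = 240, rng_seed = 1)
truth <- simulate_worms(cfg)              # ground-truth positions/partitions
blobs <- segment_recording(truth, cfg)    # render + segment, frame by frame
res <- estimate_cluster_sizes(blobs, cfg$n_worms)
res
#> <cluster_size_result> 42433 blobs: resolved=21094, single=21339
#> QC: pass (0.0% frames flagged)

traits <- aggregation_traits(res$frame_sizes, cfg$n_worms,
                             dt = 1 / cfg$frame_rate)
c(mu_A = traits$mu_A, tau_A = traits$tau_A)
#>       mu_A      tau_A
#>  0.3475431 13.5443370
```

`mu_A ≈ 0.35` sits between the all-singleton floor `1/ln 40 ≈ 0.27` and
strongly aggregated values above 1: over this 4-minute recording the
simulated worms form moderate clusters. `τ_A ≈ 13.5 s` says the
aggregation state decorrelates on a timescale of seconds at this early
stage of patch colonisation. (Exact counts vary with the seed.)

Downstream, trait tables feed the evolutionary layer:

```r
tab <- simulate_traits(50, 5, sigma_u2 = 1, sigma_e2 = 1, seed = 3)
reml_heritability(tab, n_boot = 200)
#> <heritability_fit> H2 (broad-sense) = 44.01%  CI[95%]: [42.90%, 66.60%]

mlpe_fit(simulate_mlpe_pairs(40, beta = 0.5, seed = 4))
#> <mlpe_fit> 780 pairs / 40 populations
#> sigma_u2 = 0.8335, sigma_e2 = 0.4814, AICc = 1818.133
#>               estimate        se          t            p
#> (Intercept) -0.1037265 0.2930787 -0.3539202 7.234946e-01
#> x            0.5380149 0.0450272 11.9486651 2.478769e-30
```

Fits carry broom-style `tidy()`/`glance()` methods; result objects have
`autoplot()` methods (aggregation series, autocorrelation with its
running integral, heritability bootstrap, per-frame QC).

A thin command-line wrapper is installed at `inst/cli/wormagg`
(subcommands `simulate`, `segment`, `track`, `metrics`, `pgls`, `mlpe`,
`heritability`, `qtlvar`, `all`); it drives the same exported functions
and writes a run manifest next to its outputs.

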