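# pcdyn

Statistics for long-lived plasma cell (LLPC) biology. Bone-marrow plasma
cells can be "timestamped" — irreversibly fluorescence-labeled at one
moment — so that cells still labeled months later are long-lived by
construction. Four kinds of quantitative analysis follow from that design,
and this package implements all of them, together with seeded
synthetic-data generators that provide known ground truth for every
statistic:

- **Track motility** (intravital time-lapse): track velocity (path length /
  duration) and displacement velocity (net displacement / duration) in
  μm/min; time-averaged ensemble mean-squared displacement
  (`MSD(τ) = v²τ²` for ballistic motion, `3σ²n` for an isotropic 3D
  Gaussian walk); fraction of fast movers (velocity > 1 μm/min); subset
  classification by the track-mean YFP/TdTomato intensity ratio
  (threshold 1.02, bright cells below).
- **Spatial clustering**: per-cell mean distance to the k = 20 nearest
  cells of the total population (self excluded), scored on a random
  subsample sized by Cochran's formula with finite-population correction
  (95% confidence, 5% margin; 278 of 1000) and iterated twice;
  grid-density cluster masking with connected components, plus occupancy
  and residence times of tracked cells inside masked clusters.
- **Decay kinetics**: one-phase decay
  `count(t) = (n0 − plateau)·e^(−kt) + plateau` fitted to labeled-cohort
  counts by nonlinear least squares; half-life `t½ = ln2/k`;
  case-resampling bootstrap comparison of half-lives between groups.
- **BCR repertoire**: clones keyed by heavy-chain V gene + exact CDR3
  amino-acid sequence with a size ≥ 10 filter; Chao1 richness
  (`S + f1²/2f2`); clonal overlap percentages; public clones (shared by
  ≥ 2 samples from ≥ 2 mice) and their abundance-ranked enrichment in a
  target subset; isotype composition; somatic hypermutation
  (mutations / V length) per IGHV allele with paired t tests and
  Benjamini-Hochberg correction.

## Worked example

```r
library(pcdyn)

# clustered vs uniform spatial organization of the llpc subset
clus <- genPointPattern(SpatialSimConfig(process = "clustered", seed = 1))
csr  <- genPointPattern(SpatialSimConfig(process = "csr", seed = 1))
subsampledNN(clus, "llpc", seed = 2)$pooledMean   # 27.12 um
subsampledNN(csr,  "llpc", seed = 2)$pooledMean   # 41.37 um

# cohort decay: 6 noisy replicates at days 5/30/90/150, true t1/2 = 58 d
ds <- genDecayCohort(DecaySimConfig(tHalf = 58, seed = 3))
fitOnePhaseDecay(ds)
#> DecayFit (plateau zero): n0 = 4.398e+04, k = 0.01052 /day, t1/2 = 65.9 days

# two motility phenotypes, classified by intensity ratio
st <- classifyByRatio(trackStatistics(genTracks(TrackSimConfig(seed = 5))))
tapply(st$track_velocity, st$subset_label, mean)
#>    bulk_dim llpc_bright
#>       1.075       0.055      # um/min

# spiked cross-mouse public clones are recovered exactly
sim <- genRepertoire(RepertoireSimConfig(seed = 4))
setequal(publicKeys(findPublicClones(sim$samples)), sim$publicClones)
#> TRUE
```

The clustered pattern's smaller pooled 20-NN distance (27 vs 41 μm) is the
clustering readout; the decay fit recovers the generating half-life within
the noise of six replicates; the sessile, bright subset moves ~20× slower
than the motile dim subset.

## Pipeline and CLI

`runPipeline(subcommand, config, out, seed)` binds the stages into
reproducible runs (`simulate`, `tracks`, `spatial`, `decay`,
`repertoire`), writing plain-text result tables plus a `manifest.json`
(config echo, seed, versions, checksums). Outputs are byte-identical for a
fixed config and seed. A thin wrapper lives at `inst/scripts/pcdyn.R`:

```sh
Rscript inst/scripts/pcdyn.R simulate --seed 3 --out results/
```

## Package layout

S4 classes (`PointPattern`, `TrackSet`, `ClusterMask`, `DecaySeries`,
`DecayFit`, `RepertoireSample`, `PublicCloneCatalog`, plus one config class
per generator) with validity checks, accessors and `show()` methods;
analysis functions are exported in camelCase. See the methods vignette
(`vignettes/plasma-cell-analytics.Rmd`) for the models, parameter
defaults, generator assumptions and design decisions.
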