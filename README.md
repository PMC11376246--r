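# ciliaflow

Quantification of cilia-driven bead transport from time-lapse
fluorescence movies, for labs running mucociliary-clearance assays on
airway epithelial cultures (air–liquid-interface inserts with
fluorescent tracer beads in viscous medium) or embryo surface-flow and
drift assays.

Undirected questions like "are the cilia working?" become three
concrete, complementary measurements:

* **Flow-field (PIV) pipeline** — `cambridgePipeline()`. A per-window
  flow velocity field is estimated by normalized cross-correlation of
  interrogation windows between frame pairs, with subpixel Gaussian
  peak refinement. The per-window velocity is the *vector mean* of
  per-pair displacements $\bar{\mathbf d}_w = \frac1n\sum_t \mathbf
  d_{w,t}$, so directed transport survives while jitter cancels; window
  speed is $|\bar{\mathbf d}_w|\cdot\mathrm{pixelSize}/\Delta t$ in
  µm/s. Reported: **percent of the circular field of view that is
  active** (speed above a self-calibrated noise floor) and **percent
  moving faster than the mean control speed** of the experiment's
  control cultures.
* **Moving/coordination pipeline** — `stevenagePipeline()`. Pixels
  whose intensity changes over the movie (temporal SD above a robust
  noise scale) form the *moving mask*; per-block flow directions are
  estimated inside it, and a block is *coordinated* when the circular
  mean resultant length $R$ of directions in its neighbourhood reaches
  $R_{\min}$ ($R = 1$: perfect alignment; $E[R]\approx 0.886/\sqrt n$
  under random directions). Reported: **percent of FOV moving**,
  **percent moving and coordinated**, **coordinated percent of the
  moving area**.
* **Tracking and drift** — `detectBeads()` / `linkTracks()` /
  `specimenSpeed()` and `embryoDrift()`. Laplacian-of-Gaussian spot
  detection, mutual-nearest-neighbour linking with gap closing,
  per-specimen mean track speed, and whole-specimen drift speed and
  straightness from segmented centroid series.

Because real assay movies are rarely shareable, the package includes a
simulator (`simulateBeadMovie()`, `simulateEmbryoDrift()`) that renders
bead movies from a piecewise-constant flow field with configurable
active-area fraction, speed, direction coherence, drift, and sensor
noise — and emits the exact ground truth (active mask, direction field,
per-bead tracks, drift vector) that every metric is validated against.

## Worked example

Simulate a culture where 60 % of the surface beats but directions are
only weakly coordinated, then quantify it with both pipelines:

```r
library(ciliaflow)

cfg <- simConfig(imageSize = 256, nFrames = 30, nBeads = 900,
                 patchGrid = 8, activeFraction = 0.6, coherence = 0.2,
                 meanSpeed = 5, noiseSD = 5, seed = 101)
sim <- simulateBeadMovie(cfg)

cambridgePipeline(sim$movie, windowSize = 32, overlap = 0, fov = 1.0,
                  thresholdSpeed = 5)
#> CambridgeResult
#>   percent active:          57.7 %
#>   percent above threshold: 34.6 % (threshold 5 um/s)
#>   noise floor:             0.349 um/s

stevenagePipeline(sim$movie, fov = matrix(TRUE, 256, 256))
#> RegionMasks (block size 32 px)
#>   moving area:            57.5 % of FOV
#>   coordinated area:       1.6 % of FOV
#>   coordinated of moving:  2.7 %
```

Reading the output: about 58 % of windows move above the noise floor —
matching the configured active area (60 % of patches, minus the ones
this seed's beads cover sparsely) — and roughly half of those exceed
the 5 µm/s control-level threshold (per-patch speeds are drawn around
5 µm/s, so about half lie above). The moving mask covers the same
~58 % of the culture, but under 3 % of that moving area is *locally
aligned*: activity without coordination, the signature this assay is
designed to detect. A control simulation with `coherence = 0.9` and the
same `activeFraction` leaves the moving area unchanged while the
coordinated share rises to ~60–70 %.

Movies round-trip through standard formats: `writeMovie()` /
`readMovie()` (16-bit multi-page TIFF), masks as TIFF, flow fields and
tracks as CSV, and every run can be wrapped in a JSON manifest
(`runManifest()`, `writeOutputs()`) recording parameters, seed and
output checksums. A command-line front end over these functions is in
`inst/scripts/ciliaflow.R` with subcommands `simulate`, `piv`, `coord`,
`track`, `drift`, `report`.

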