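---
title: "Quantifying mucociliary transport from bead movies"
author: "ciliaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mucociliary transport from bead movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaflow)
```

# The measurement problem

Multiciliated cells of the airway epithelium drive mucociliary
clearance: hundreds of motile cilia per cell beat in a coordinated,
polarized fashion and transport the overlying mucus layer. A standard
functional readout adds fluorescent tracer beads to the apical surface
of an air–liquid-interface culture in a viscous medium and records a
short time-lapse (typically 30 s at 10 frames/s). Healthy cultures move
beads fast and in locally consistent directions; cultures with impaired
ciliary coordination move beads slowly, over less of their area, or in
spatially incoherent directions even when the number of ciliated cells
is unchanged. A complementary whole-organism readout uses embryos whose
epidermal cilia propel both surface beads and the embryo itself: loss
of ciliary coordination shows up as slower surface bead transport and
as loss of the slow directional "drift" of the whole embryo.

`ciliaflow` turns such movies into numbers in three complementary ways,
and ships a simulator that generates movies with *known* flow structure
so that every number can be validated against ground truth.

# The flow-field (PIV) pipeline

`cambridgePipeline()` estimates a flow velocity vector field by
particle image velocimetry. The frame is tiled with interrogation
windows (default 32 px, 50 % overlap). For each window and each frame
pair $(t, t+\Delta)$ the displacement is the argmax of the normalized
cross-correlation of the two windows, computed on zero-padded arrays
with the triangular overlap taper divided out (so the peak location is
not biased toward zero shift) and refined to subpixel precision with a
three-point Gaussian fit along each axis. Correlation quality is the
first-to-second peak ratio; windows below 1.1 (or with zero intensity
variance) are treated as unscoreable and excluded from both numerator
and denominator of every percentage, so correlation artifacts are not
mistaken for static epithelium.

Two aggregation choices matter:

* **Vector-mean aggregation.** The per-window velocity is the vector
  mean of per-pair displacements, not the mean of magnitudes. Directed
  transport adds coherently; jitter cancels as $1/\sqrt{n}$. The window
  speed (µm/s) is the magnitude of this mean scaled by
  `pixelSize / (frameInterval * pairSpacing)`.
* **Self-calibrating noise floor.** A window counts as *active* when
  its speed exceeds a floor derived from the same movie: the
  alternating-sign (Nyquist) mean of the same per-pair displacements
  cancels any temporally coherent motion exactly (equal consecutive
  displacements annihilate pairwise) while preserving the white
  frame-to-frame jitter, so its magnitude samples the no-transport
  null. The floor is `k = 3` times the 95th percentile of that null
  speed over in-FOV windows. An earlier candidate — re-running PIV on a
  temporally shuffled copy of the movie — was rejected: shuffled frame
  pairs have random multi-frame lags, so moving content produces large
  spurious displacements and the floor scales with the *transport*
  speed rather than with the noise, collapsing the active percentage on
  short movies. The alternating-sign null has neither problem and needs
  no resampling, so it is exactly reproducible.

Percentages are reported over the circular field of view of the culture
insert (`fitCircularMask()`, fixed radius fraction or auto-fitted to
the bright culture disk of the temporal-mean image). The
*above-threshold* percentage counts active windows whose speed exceeds
an externally supplied threshold — by convention the mean speed over
active windows pooled across the control movies of the same batch
(`computeControlThreshold()`). Pooling over *active* windows only is
deliberate: including static windows would drag the control mean toward
zero and make the metric degenerate whenever controls have inactive
area. Above-threshold windows are a subset of active windows by
construction, so the two percentages always nest.

# The moving/coordination pipeline

`stevenagePipeline()` approaches the same movie without a vector field.

1. **Moving mask.** The per-pixel temporal standard deviation $s$
   captures how much each pixel's intensity changes over the movie. The
   sensor-noise scale $\sigma$ is estimated as the median absolute
   consecutive-frame difference over in-FOV pixels divided by
   $0.6745\sqrt 2$: even a pixel on a busy bead path is quiet in most
   frames, so this estimate is robust as long as the *instantaneous*
   bead coverage stays below about half the field of view — a far
   weaker condition than any quantile of $s$ itself, whose distribution
   is entirely contaminated once the *cumulative* path coverage
   approaches 100 %, as it does in a realistic 30 s movie. A pixel is
   moving when $s > 3\sigma$; the mask is cleaned by a 2 px opening and
   removal of components under 25 px.
2. **Block directions.** The frame is tiled with non-overlapping blocks
   (default 32 px). A block with at least half its pixels moving gets a
   direction: the angle of its time-averaged displacement, estimated
   with the same cross-correlation machinery as the PIV pipeline.
3. **Coordinated mask.** For each direction-bearing block, the
   alignment score is the circular mean resultant length $R$ of the
   unit direction vectors of all direction-bearing blocks within a
   2-block radius (self included; at least 3 required, otherwise the
   block is unscored and counted uncoordinated). $R = 1$ for identical
   directions; under independent uniform directions $E[R] \approx
   0.886/\sqrt n$ (Rayleigh), so with the default $R_{\min} = 0.8$
   random direction fields produce essentially no coordinated area.

Three areas are reported: percent of FOV moving, percent of FOV moving
*and* coordinated (moving pixels inside coordinated blocks, hence
always a subset), and coordinated percent of the moving area. The
decomposition separates "how much of the culture beats" from "how well
the beating aligns" — a culture can lose coordination without losing
moving area, which is exactly the phenotype signature the knockdown
emulation test reproduces.

# Tracking and drift

`detectBeads()` finds spots as strict local maxima of a
Laplacian-of-Gaussian response thresholded at `snrMin` (default 5)
robust SDs, refined to subpixel positions with a separable three-point
Gaussian fit on the background-subtracted intensity — exact for an
isolated Gaussian spot, which keeps path-length speeds unbiased at
steps well below one pixel. `linkTracks()` joins detections
frame-to-frame by greedy globally-nearest pairing (every accepted pair
is a mutual nearest neighbour) with a hard cutoff, bridging up to
`maxGap` missing frames with a proportionally scaled cutoff. A full
linear-assignment linker was deliberately not used: at assay bead
densities greedy mutual-nearest-neighbour linking is already exact
against simulator truth (the tests assert partition-level equality),
and it is far easier to verify.

Per-track speed is total path length over duration ("track mean speed"
semantics of common trackers); the net-displacement speed is emitted
alongside. The specimen speed is the unweighted mean over tracks.

`embryoDrift()` segments the single dark specimen per frame by Otsu's
threshold (taking the minority intensity class, then the largest
connected component) and reports the net centroid displacement per unit
time plus the net/total path ratio. Per-frame segmentation was chosen
over background-subtraction schemes because a stationary specimen has
no background-subtracted residual at all, yet must still yield a
well-defined drift of zero.

# The simulator and what it does (not) emulate

`simulateBeadMovie()` renders diffraction-limited Gaussian spots
advected by a piecewise-constant flow field over a patch grid. A
configured fraction of patches is active — the count is exactly
`round(activeFraction * nPatches)`, so ground truth is discrete and
unambiguous — and each active patch draws its direction from a mixture:
with probability `coherence` the shared global direction, otherwise an
independent uniform angle. Per-patch speeds are
`meanSpeed * (1 + speedCV * eps)` clamped at zero. Beads crossing an
active-patch boundary re-enter the same patch from the opposite side;
the wrap starts a new ground-truth track. This keeps density and
per-patch speed stationary over arbitrarily long movies at the price of
forbidding inter-patch transport — acceptable because every metric
under validation is local in space. `simulateEmbryoDrift()` renders a
dark textured ellipse translating at a configured drift velocity, with
the analytic texture evaluated in object-local coordinates so the
translation is rigid to subpixel accuracy; the drift path is centred in
the frame and configurations that would clip the specimen are rejected,
because a clipped centroid is silently biased.

Deliberate simplifications, and hence limits of what passing tests
prove about real data: flow is piecewise constant (no smooth spatial
interpolation, no swirl); beads neither diffuse (a `diffusionSD` knob
exists but defaults to 0 so kinematic oracles are exact) nor bleach,
and have constant amplitude; noise is additive Gaussian, not Poisson;
there is no mucus rheology, no out-of-focus blur, no illumination
drift. The simulator validates the *estimators*, not the optics.

Default study conditions: 300 frames at 0.1 s (the standard 30 s
acquisition), 0.5 µm pixels, 1.5 px spot width, 256 px frames, an 8×8
patch grid, mean speed 5 µm/s (≈ 1 px/frame — mid-range for bead
transport on healthy cultures in viscous media), speed CV 0.2, bead
amplitude 400 on background 100 with noise SD 5 (SNR ≈ 80), and a
circular FOV at 0.95 of the half-frame. Neither pixel size nor
field-of-view geometry is dictated by the assay itself; they are free
calibration parameters and the defaults are simply realistic choices.
Validation runs in the test-suite use shorter movies (16–40 frames) and
frame sizes of 128–352 px so the whole suite completes in minutes; the
recovery results are insensitive to this scaling because every metric
is an average over windows, blocks or tracks.

# Numerical choices and degenerate inputs

* Correlation peaks are searched within ±`windowSize/4`; the
  three-point Gaussian subpixel fit falls back to a parabolic fit when
  a neighbouring correlation value is non-positive, and to the integer
  peak at the search border.
* Zero-variance windows (blank or saturated) are invalid, contribute
  displacement 0 and are excluded from percentages.
* `percentActive` uses strict `speed > floor`, so an exactly static
  noise-free movie reports exactly 0.
* Active-fraction validation uses 64 px patches tiled exactly by
  aligned non-overlapping 32 px windows, so no window straddles a patch
  boundary and the expected percentage is exactly `100 * activeFraction`.
* The coherence-monotonicity sweep is scored at `rMin = 0.5` (not the
  0.8 used for the limit checks) because at 0.8 the coordinated
  fraction is pinned near zero for all low coherence levels and the
  sweep would compare ties; at 0.5 the Rayleigh null clears the
  threshold a few percent of the time and the statistic retains
  dynamic range across the whole sweep.
* `coordinatedOfMoving` is defined as 0 when nothing moves; the
  drift path ratio is defined as 0 for a perfectly stationary centroid
  series.
* All randomness is seeded: a `SimConfig` seed fixes the movie and its
  truth bit-for-bit; the permutation test takes an explicit seed; the
  noise floor involves no randomness at all. Re-running any pipeline
  with the same inputs produces byte-identical outputs, which the test
  suite asserts via file checksums.

# A worked validation

```{r phenotype, eval = FALSE}
batch <- function(coherence, seeds) t(sapply(seeds, function(s) {
    cfg <- simConfig(imageSize = 256, nFrames = 30, nBeads = 900,
                     patchGrid = 8, activeFraction = 0.6,
                     coherence = coherence, seed = s)
    sim <- simulateBeadMovie(cfg)
    res <- stevenagePipeline(sim$movie, fov = matrix(TRUE, 256, 256))
    c(moving = res@movingFraction, coordinated = res@coordinatedOfMoving)
}))
control   <- batch(0.9, 1:6)     # coordinated epithelium
knockdown <- batch(0.2, 101:106) # equal active area, scrambled directions

colMeans(control); colMeans(knockdown)
permutationGroupTest(values = c(control[, 2], knockdown[, 2]),
                     labels = rep(c("c", "k"), each = 6),
                     nPerm = 2000, seed = 5)$p.value
```

With these settings the two batches have indistinguishable moving area
(≈ 57 % each) while the coordinated share of it collapses from ≈ 64 %
to ≈ 5 % — the signature of impaired coordination without loss of
ciliary activity. `scripts/acceptance.R` re-derives this and every
other validation quantity from scratch; see the README for how to run
it.

# Known limitations

PIV windows mix flows at patch boundaries, so percentages carry a
discretization error of up to a few points when windows straddle
heterogeneous flow (the validation geometry avoids this by
construction, real data cannot). The moving-mask noise estimator
assumes under ~50 % instantaneous bead coverage. The greedy linker can
swap identities when beads pass within the linking cutoff of each
other. The drift segmentation assumes a single dominant specimen of
intensity distinct from the background. None of these limits is binding
for the assay geometries the package targets; all thresholds involved
are exposed as function arguments.
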