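---
title: "Quantifying subchondral bone change: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subchondral bone change: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histological grading of knee osteoarthritis has long been
cartilage-centred (Mankin, OARSI), yet the subchondral bone remodels from
the earliest stages: the cortical plate under the calcified cartilage
thickens dramatically, open fenestrae connecting marrow to cartilage close,
and the bone–cartilage interface (BCI) — the line where calcified cartilage
meets the subchondral plate — turns from a smooth, gently undulating
contour into a rugged, fibrillated one. This package quantifies those
changes from 2D sections: it measures layer thicknesses, reduces the BCI to
two texture descriptors via local binary patterns (LBP), and supplies the
statistics that relate a four-stage subchondral bone grade to the OARSI
cartilage grade.

## The analysis model

### From band to interface mask

The BCI is never segmented fully automatically. The input is a thick band
(nominally 7 px) drawn around the interface — by hand on real slides,
excluding cuts, blur, and other artefacts; synthetically by
`band_from_layermap()` on phantoms. Within the band, pixels are classified
cartilage vs bone by intensity threshold. `classify_band()` computes an
Otsu threshold *from band pixels only*, so tissue outside the band cannot
bias the split; a fixed threshold is available where stain contrast is
calibrated. The band is then thinned by `extract_interface()`: a pixel
survives iff its 8-neighbourhood (within the band) contains the opposite
class. On a smooth boundary this keeps the two one-pixel boundary layers
plus pixels touching both — about three pixels thick, which is the working
definition of the interface here. The choice of the *boundary pair* (one
pixel each side) rather than a one-sided layer is deliberate: the
interface belongs to neither tissue alone, and the pair construction is
idempotent and provably a subset of the band.

### Local angles by LBP

At each interface pixel (with a full neighbourhood; border pixels are
dropped and counted), the 8 radius-1 neighbours are compared to the
centre: a flag is set when the neighbour is *equal to or brighter than*
the centre. Ties count as set — this makes the pattern invariant to adding
a constant to the whole image, and on a level set the tie flags encode the
tangent direction. The set flags are then averaged *axially*: each flag at
compass direction θ contributes the doubled-angle unit vector
(cos 2θ, sin 2θ), and half the resultant's direction, mod 180°, is the
local orientation. Doubling is essential for axial data: an interface has
no sign, and without doubling the E and W flags of a horizontal structure
would cancel instead of reinforce.

The orientation is *undefined* when no or all flags are set, or when the
doubled resultant vanishes (ε = 1e-9). This is a real feature of the
estimator, not an error path: the set flags of a clean, monotone edge form
a contiguous half-plane arc of four neighbours, and the doubled vectors of
any 4-arc sum to exactly zero. Consequently the defined fraction is high
on flat interfaces (where ties produce 5-arcs) and drops substantially on
sloped smooth edges; `angle_field()` reports the undefined count, and the
histogram, entropy and ALCM are computed over defined pixels only. The
complete 256-pattern mapping is exported as `lbp_angle_table()` so the
convention is auditable at a glance.

### Descriptors

The angle distribution over `n_bins = 8` uniform bins of [0°, 180°)
(22.5° width; the bin count is configurable) is reduced to:

* **Entropy** `H = -sum(p_i log2 p_i)` in bits, 0 for a single occupied
  bin, `log2(B)` for uniform occupancy. High entropy = disordered,
  fibrillated interface.
* **ALCM homogeneity.** An angle-level co-occurrence matrix accumulates
  every unordered 8-adjacent pair of defined interface pixels in both
  directions, pooling all 8 adjacency directions into one matrix (the 2D
  realisation of rotation invariance), then normalises to total mass 1.
  Homogeneity is `sum(P(i,j) / (1 + |i - j|))`: 1 iff all co-occurring
  pairs share a bin, lower when consecutive pixels jump between
  orientation bins. Bin distance is linear by default; whether angle
  distance should wrap at 180° is genuinely undecidable from the method's
  verbal description, so a `circular` flag is provided (the elevation-angle
  reading of the construction, which we follow, does not wrap).

Entropy is invariant to permuting bins; homogeneity is not — the pair
(|i−j|) structure is exactly what distinguishes them, and both are
asserted against brute-force oracles in the tests.

### Morphometry and statistics

Layer thickness is the vertical chord of a layer at five columns, one
drawn uniformly inside each fifth of the image width ("randomly selected
but evenly distributed"), shared across the three layers as in one
microscope view. Columns crossing a fenestra yield 0 µm and are flagged
rather than resampled, so exclusion is the caller's explicit choice.
Thickness is not measured boundary-normal: the vertical chord matches
point-and-click practice on an upright view.

The statistical layer wraps the standard machinery (`stats::aov`,
`TukeyHSD`, `t.test`, `lm`) in tidy interfaces. The ICC is computed from
the classical two-way mean squares as ICC(3,1) — two-way mixed effects,
single rating, consistency — because the same fixed raters graded all
samples; a one-way form is available by flag. t-tests default to Welch:
the per-grade SDs of plate thickness differ several-fold, so pooling
variances is indefensible. `reproduce_study()` runs the whole layer on a
study table: per-grade OARSI and thickness summaries (mean ± SE), plate
fold changes against grade 0, descriptor group tests with grade 3
excluded (its plate surface is worn smooth, so the interface descriptors
no longer measure fibrillation there; group sizes are always reported),
descriptor-on-OARSI regressions, and the rater ICC. Samples with OARSI ≥ 5
carry no descriptors — with the cartilage essentially gone there is no
interface left to measure — and every such exclusion is counted.

## The synthetic phantoms

`generate_section()` renders what the analysis assumes: a layered
osteochondral section. Per-grade parameters live in
`default_grade_profiles()`:

| parameter | grades 0→3 | unit | rationale |
|---|---|---|---|
| plate thickness mean ± SD | 58±28, 176±87, 473±229, 1245±448 | µm | the per-grade study values |
| calcified cartilage | 84±69, 104±62, 128±50, 36±46 | µm | ditto |
| uncalcified cartilage | 2374±506, 1753±615, 1826±1268, 82±142 | µm | ditto |
| OARSI mean | 1.46, 3.45, 3.99, 5.19 | grade | ditto (SD 0.8/0.8/0.8/0.6, chosen) |
| roughness amplitude | 6, 14, 28, 4 | µm | fibrillation rises to grade 2; the grade-3 plate is worn smooth |
| fenestra rate | 1.5, 0.8, 0, 0 | gaps/mm | open marrow connections exist only at grades 0–1 |

Roughness is a random-phase sum of three sinusoids at wavelengths 200,
100, 50 µm (geometric spacing), each of amplitude A/√3, so the column-wise
displacement SD is A/√2 and the model is smooth and differentiable —
amplitude directly controls the interface angle spread without committing
to an unstated fractal texture. Thicknesses are drawn once per section
(per-sample, as one set of measurements per sample is reported), censored
to [max(0, µ−3σ), µ+3σ]; column-to-column variation comes only from the
roughness term, whose displacement field is shared by the
cartilage/calcified/plate boundary complex (the articular surface gets
independent phases). Amplitudes, wavelengths, fenestra rates, noise and
descriptor generator means are choices of this package — the study these
conditions emulate prints none of them — made once on plausibility grounds
(e.g. descriptor means 1.30/1.80/2.20/2.35 bits and 0.85/0.72/0.62/0.58
respect the observed orderings and the 8-bin dynamic range).

Two rendering details matter more than they look:

* **Partial-volume (anti-aliased) intensities.** Boundaries live at
  continuous sub-pixel positions; the pixel containing a boundary gets the
  coverage-weighted blend of the two layer intensities. Hard integer
  rasterisation would create exactly-flat treads whose LBP ties break
  randomly under any noise (the ≥ comparison is scale-free), erasing the
  orientation coherence real images carry through sub-pixel boundary
  encoding.
* **PSF blur.** Gaussian blur (σ = 1 px) after additive noise emulates
  band-limited microscope optics. Pixel-independent noise with no PSF is
  not a texture any real acquisition produces, and it saturates any
  neighbourhood-comparison estimator.

The intensity convention is bone brighter than cartilage in the analysed
channel (the red channel for Safranin-O by default), with an `invert`
flag, since stain polarity varies with acquisition.

What the phantoms do **not** emulate: stain heterogeneity within a layer,
vascular channels and osteophytes, tidemark duplication, cutting artefacts,
uneven illumination, and 3D out-of-plane structure. Passing tests on
phantoms therefore demonstrate that the pipeline recovers known geometry
and known statistical structure — not that it is robust to every artefact
of real slides, where the manual band remains the artefact filter.

`generate_study_table()` simulates the study design: patients × 3 site
categories (most intact → exposed bone), bone grade drawn per site from
mixing weights whose defaults were set so the expected site-level mean
OARSI approximates 2.1/4.4/5.3 (the site-3 target of 5.3 exceeds the
maximum attainable 5.19 — all-grade-3 — so it is approached, not met).
Replicate rater scores are true grade + rounded Gaussian noise clipped to
0–3; the default `rater_sd = 0.27` was derived in closed form (misrating
probability under rounding and clipping against the site-mixture grade
variance of ≈1.42) to emulate the near-perfect consistency (ICC ≈ 0.97) an
established grading panel reaches; `rater_sd = 0` gives ICC = 1 exactly.

## Numerical choices and degenerate inputs

* Otsu runs on a 256-bin histogram of band intensities; a constant band is
  an explicit error (no separable classes).
* The undefined-orientation ε is 1e-9 on the doubled resultant; the
  implementation uses exact integer doubled-angle components, so true
  zeros are exact.
* Angle bins are half-open [0, 180)/B with edges at 0; ALCM normalisation
  counts each unordered pair twice (both directions) and divides by total
  increments, so the matrix is symmetric with mass 1 by construction.
* Histogram and entropy require ≥ 1 defined angle; the ALCM requires ≥ 1
  adjacent defined pair; both fail loudly with counts otherwise.
* A raster too small for the drawn calcified cartilage + plate stack fails
  naming the layer that does not fit; the uncalcified cartilage may be
  truncated by the top border instead (the window is an interface-centred
  microscope view) and the truncation is recorded.
* ICC with zero between-sample variance is undefined and reported as `NA`
  with a warning, never silently 0.
* All generators are seeded (`withr::with_seed`); identical seeds give
  bit-identical rasters, tables and reports. Pipeline stage seeds derive
  from one root seed.

## Design choices where the method description is open

* **Band half-width 3** gives the nominal 7-px band; the synthetic band
  always includes the immediate cartilage-side pixel so both classes are
  represented even at half-width 0. Fenestra gap columns hold no BCI, and
  their flanking columns mostly cover the fenestra *wall* (a plate–marrow
  face), so the synthetic band skips the gap plus a half-width margin —
  the synthetic analogue of the manual operator selecting "only the data
  not affected by artefacts".
* **Pixel size** has no universal default at a given magnification (it is
  a camera property); it is a required calibration input. Synthetic
  studies in the tests and acceptance script run at 4 µm/px on
  256 × 448 px windows (20 sections per grade), sizes at which grade 0–2
  sections fit comfortably and a suite pass takes well under a minute per
  property.
* **Five measurement columns shared across layers** (not redrawn per
  layer): one view, one set of points.
* **"Subchondral bone thickness" is read as plate thickness** — the
  cortical lamella, the quantity whose per-grade means the fold changes
  refer to — not trabecular histomorphometry (BV/TV etc.), which is out of
  scope.

## Known limitations

* With the radius-1, 8-neighbour LBP the attainable angle alphabet is
  coarse, and on smooth sloped edges most patterns are half-plane 4-arcs
  with undefined orientation. Entropy therefore saturates near moderate
  roughness: in the phantom grade sweep the grade-1→2 entropy separation
  is small, while homogeneity — which uses spatial adjacency, not just the
  marginal distribution — keeps discriminating. Both directions of the
  grade response (entropy up, homogeneity down, grades 0→2) are asserted
  by the acceptance tests; the magnitudes are phantom-specific.
* The vertical-chord thickness overestimates oblique layers; a
  boundary-normal option would require an explicit boundary model and is
  deliberately left out.
* Grades are inputs. Nothing here classifies a section into a bone grade
  or an OARSI grade; the package quantifies what graded material looks
  like and how consistently humans grade it.
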