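# subchondral

Quantitative histomorphometry of subchondral bone in knee osteoarthritis
(OA), for researchers who grade osteochondral histology sections and want
the bone side of the joint measured, not just eyeballed. The package
implements a complete analysis pipeline around a four-stage subchondral
bone grade (0 = thin, porous plate with open fenestrae to the marrow;
3 = massive sclerosis with a flattened, worn plate) and its relation to
the OARSI cartilage grade (0–6):

- **Bone–cartilage interface (BCI) segmentation** — a thick (nominally
  7 px) hand-drawn or synthetic band around the interface is classified
  into cartilage vs bone (band-restricted Otsu) and thinned to the ≈3-px
  interface mask by an opposite-class 8-neighbour test.
- **Local binary pattern (LBP) orientation analysis** — each interface
  pixel's 8 neighbours are thresholded at the centre intensity (ties count
  as set); the set flags are averaged axially with the angle-doubling
  construction, giving a local orientation θ ∈ [0°, 180°). The full
  256-pattern → angle table ships as `lbp_angle_table()`.
- **Interface descriptors** — Shannon entropy of the binned angle
  distribution, H = −Σᵢ pᵢ log₂ pᵢ (disorder, "fibrillation"), and the
  homogeneity of an angle-level co-occurrence matrix (ALCM) over adjacent
  interface pixels, Σᵢⱼ P(i,j)/(1 + |i−j|) (continuity of consecutive
  orientations). Entropy rises and homogeneity falls as the interface
  degenerates.
- **Morphometry** — uncalcified cartilage, calcified cartilage and
  subchondral plate thickness measured at five randomly selected but
  evenly distributed columns, with per-grade mean ± SE summaries and fold
  changes (the subchondral plate thickens ~3-fold by grade 1 and >21-fold
  by grade 3 relative to grade 0).
- **Grading statistics** — ICC(3,1) two-way mixed consistency for rater
  agreement, one-way ANOVA with Tukey HSD, Welch t-tests, and linear
  regression of both descriptors on OARSI grade.
- **Synthetic phantoms** — `generate_section()` renders layered
  osteochondral sections (grade-dependent thicknesses, sinusoidal
  interface roughness, open fenestrae at low grades, anti-aliased
  partial-volume intensities, PSF blur, Gaussian noise) with pixel-level
  ground truth, and `generate_study_table()` simulates whole grading
  studies — so every stage is testable without any slide scanner.

## Worked example

```r
library(subchondral)

prof <- default_grade_profiles()           # grades 0-3 study parameters
sec  <- generate_section(prof[2, ],        # a grade-1 section
                         width_px = 256, height_px = 448,
                         pixel_size = 4, seed = 42)
band <- band_from_layermap(sec$layers)     # synthetic stand-in for the manual band
mask <- extract_interface(classify_band(sec$image, band), band)
describe_interface(sec$image, mask)
#>   entropy_bits homogeneity n_defined_pixels n_pairs n_bins
#> 1         1.95       0.810              216     225      8

tab    <- generate_study_table(n_patients = 20, seed = 1)
report <- reproduce_study(tab, cohort = cohort_patients())
report
#> Cohort: 20 patients, mean age 74.5 (range 57-88), mean OARSI 4.07
#> Samples: 60 (mean OARSI 4.00, mean bone grade 1.88)
#> ...
#> Subchondral plate fold change vs grade 0:
#>   bone_grade ratio  fold
#> 1          1  3.71     4
#> 2          2  8.31     8
#> 3          3 23.2     23
#> Rater consistency ICC = 0.971 (60 samples x 3 raters)
#> Regression entropy_bits ~ OARSI: slope 0.279, R^2 = 0.74 (n = 44)
#> Regression homogeneity ~ OARSI: slope -0.078, R^2 = 0.80 (n = 44)
```

The interface entropy of 1.95 bits (of at most 3 for 8 bins) and
homogeneity of 0.81 describe a moderately fibrillated grade-1 interface;
the study report shows mean OARSI rising with bone grade, the plate fold
changes, near-perfect rater consistency, and the opposite regression signs
of the two descriptors — entropy grows and homogeneity shrinks with
cartilage degeneration. Samples with OARSI ≥ 5 carry no descriptors (no
remaining cartilage) and every exclusion is counted, never silent.

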