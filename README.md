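# epistrat

Quantification of 3D cell-division orientation, daughter positional fate,
interphase cell geometry and junctional planar polarity in a stratifying
epithelium — with a fully seeded synthetic basal-layer generator so that
every measurement is testable by parameter recovery.

## The problem

In the basal layer of the embryonic epidermis, a progenitor's division
axis decides its daughters' fates.  Writing Δ for the vector between the
two daughter nuclear centroids at telophase, the division angle

    Θ = asin(|Δz| / ‖Δ‖) ∈ [0°, 90°]

is classified as planar (Θ ≤ 20°), oblique (20° < Θ ≤ 70°) or
perpendicular (70° < Θ ≤ 90°) relative to the basal plane.  Planar
divisions mostly yield two basal daughters (symmetric fate); perpendicular
divisions send one daughter suprabasal (asymmetric fate, scored over a
1.5-h tracking window).  The long-axis (Hertwig) rule ties this choice to
interphase shape: cells taller than wide tend to divide perpendicularly.
This package provides, for users analyzing tracked nuclei and segmented
basal-layer outlines:

* **division analysis** — telophase angles, categories, fate assignment
  with a jitter-robust persistence rule, angle-by-fate contingency tables,
  angular histograms;
* **cell geometry** — polygon area, apical–basal height, longest planar
  axis, height:width ratio, elongation nematic
  (100·(λ₁−λ₂)/(λ₁+λ₂) from the second-moment tensor), polygon classes,
  density, proliferation, tissue thickness, and long-axis-rule alignment
  statistics;
* **axial statistics** — a two-sample Kuiper test V = D⁺ + D⁻ computed on
  the bounded 0–90° range (no circular wrap), with exact permutation
  inference, a size-calibrated randomized variant and an asymptotic
  approximation;
* **polarity** — per-cell junctional nematics (Fourier-moment and
  harmonic-fit estimators), tissue-average magnitude/axis and rose
  histograms;
* **synthetic data** — a Lloyd-relaxed bounded-Voronoi basal layer with
  nuclear tracks, angle-coupled fates and polarized edge intensities,
  emitting complete ground truth.

## Worked example

Simulate a wildtype-like condition (51/29/20% planar/oblique/perpendicular,
310 divisions) against a crowded-mutant-like condition (27/39/34%, 271
divisions, weaker planar→symmetric coupling) and run the full pipeline:

```r
library(epistrat)

cfg_wt  <- sim_config(field_width = 150, field_height = 105, n_divisions = 310,
                      n_frames = 14, field_id = "wt", seed = 14)
cfg_mut <- sim_config(field_width = 150, field_height = 105, n_divisions = 271,
                      n_frames = 14, field_id = "mut",
                      angle_mixture = c(planar = 0.27, oblique = 0.39, perpendicular = 0.34),
                      fate_given_angle = c(planar = 0.78, oblique = 0.21, perpendicular = 0.06),
                      seed = 15)

rep <- run_pipeline(list(conditions = list(wildtype = cfg_wt, mutant = cfg_mut),
                         n_permutations = 9999, seed = 3))
rep
#> <epistrat_report>
#>   wildtype: 310 divisions; planar/oblique/perpendicular = 0.54/0.29/0.17
#>   mutant: 271 divisions; planar/oblique/perpendicular = 0.23/0.46/0.31
#>   wildtype vs mutant: Kuiper V = 0.316, p = 0.0001
```

The recovered proportions sit within sampling error of the configured
mixtures, and the permutation Kuiper test separates the two conditions at
its resolution floor (p = 1/(B+1) with B = 9999).  The orientation–fate
coupling is read off the contingency table:

```r
angle_fate_table(attr(rep, "events")$wildtype)$proportions
#>                fate
#> category        symmetric asymmetric
#>   planar             0.92       0.08
#>   oblique            0.47       0.53
#>   perpendicular      0.10       0.90
```

92% of planar divisions scored symmetric and 90% of perpendicular
divisions asymmetric — recovering the configured 94%/89% coupling from the
tracks alone.  `run_pipeline(..., out_dir = "out")` additionally writes
`report.json`, per-condition event CSVs and (with `plots = TRUE`) angular
histograms; identical configurations reproduce identical reports
byte-for-byte.

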