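---
title: "Methods: division orientation, cell geometry and planar polarity in a stratifying basal layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: division orientation, cell geometry and planar polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistrat)
```

# The measurement problem

Basal progenitor cells of the embryonic epidermis divide in three
dimensions.  A division whose axis lies in the epithelial plane renews the
progenitor pool with two basal daughters; a division oriented along the
apical–basal axis places one daughter above the basal layer, where it
differentiates.  Three linked quantities describe this system:

* the **division angle** Θ ∈ [0°, 90°], the elevation of the axis joining
  the two daughter nuclear centroids at telophase relative to the basal
  plane, classified as *planar* (Θ ≤ 20°), *oblique* (20° < Θ ≤ 70°) or
  *perpendicular* (70° < Θ ≤ 90°);
* the **positional fate**, scored 1.5 h after division: *symmetric* when
  both daughters stay basal, *asymmetric* when exactly one moves
  suprabasally;
* the **interphase geometry** of the mother — cross-sectional area,
  apical–basal height, longest planar axis — which the long-axis
  (Hertwig) rule links to the subsequent spindle orientation.

The package computes all three from tracked nuclear centroids and
segmented cell outlines, quantifies junctional planar-cell-polarity (PCP)
signal as a nematic, and compares angle distributions between conditions
with a Kuiper-type two-sample test restricted to the 0–90° range.  Because
raw microscopy is out of scope, a synthetic basal-layer generator with
full ground truth backs every stage with parameter-recovery tests.

# Division analysis

**Angle.** For daughter centroids $p_a, p_b$ (µm; z measured from the
basement membrane, apical positive), Θ = asin(|Δz| / ‖Δ‖)·180/π with
Δ = $p_b − p_a$.  The operation is symmetric in its arguments and
invariant to rigid in-plane motion; coincident centroids raise a
degenerate-geometry error.  Category boundaries are inclusive downward:
Θ = 20° is planar, Θ = 70° oblique.  Angles are kept at full floating
precision and categorized without rounding.

**Telophase proxy.** Spindles still rotate at metaphase, so the angle is
measured at the first frame at which both daughters exist as separate
tracked objects.  A mother track that persists past that frame indicates a
broken lineage and is rejected.

**Fate.** A daughter is suprabasal at a frame when its nuclear z exceeds a
threshold.  Over the post-division window (default 90 min; 9 frames at the
10-min default interval) a daughter is *labelled* suprabasal only if it
shows ≥ 2 consecutive suprabasal frames **and** is suprabasal at the
window's final frame.  This persistence rule absorbs single-frame z
excursions — including the genuine transient elevation of the upper
daughter of a steeply oriented but ultimately symmetric division — without
missing real stratification events.  Both-suprabasal outcomes are reported
separately and excluded from the symmetric/asymmetric dichotomy, as are
events whose window is incomplete (`indeterminate`, with a reason).

**Threshold.** No numeric suprabasal criterion is standard; the default is
the 75th percentile of the non-daughter population's nuclear z plus one
nuclear radius (2.5 µm), and any analysis can pass an explicit
`basal_threshold`.  The synthetic generator and the analyzer share one
threshold convention so that recovery tests are meaningful.

# Cell geometry

All lengths are µm, areas µm², angles degrees; axial orientations live in
[0°, 180°).  Cross-sectional area is the shoelace area of the segmented
outline (self-intersecting polygons are rejected).  The cell **width** is
the *longest planar axis*, implemented as the maximum vertex-pair chord —
the closest literal reading of a hand-drawn "longest axis", and one with
an exact brute-force oracle; ties take the first maximal pair in scan
order.  H:W is height over that chord.

**Elongation** comes from the area-normalized central second-moment tensor
of the polygon: magnitude $100·(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
and the principal-axis orientation.  A 2:1 ellipse scores 60.  The ×100
scale puts typical epithelial values in the tens, the range in which
tissue-segmentation tools report elongation; no cross-software numeric
identity is claimed, since those tools do not document their unit
convention.

Neighbor counts derive from shared polygon edges (two snapped vertices at
0.1 µm tolerance); density is centroid count normalized to a stated
reference area (1200 µm² by default); proliferation is the mitotic
percentage of cells in the field; tissue thickness is foreground area of a
cross-sectional mask divided by its lateral extent.  Cells touching the
field boundary are excluded from shape statistics (clipped polygons bias
area, chord and elongation) but counted for density.

# The restricted-range Kuiper test

Division angles occupy a bounded interval, not a circle, so the two-sample
statistic is Kuiper's $V = D^+ + D^-$ with
$D^+=\max(\hat F_a-\hat F_b)$, $D^-=\max(\hat F_b-\hat F_a)$ evaluated
over the pooled support of [0°, 90°] with right-continuous ECDFs and
pooled tie handling — no circular wrap-around.  Unlike a single KS
excursion, V weights both tails, which matters for distributions that
differ at both planar and perpendicular ends.

Since V depends only on ranks, it is invariant under any common strictly
monotone transform of both samples; in particular the quadrupled-angle
mapping θ→4θ sometimes used to spread 0–90° data around the circle leaves
V unchanged, and differs only in which null is attached to it.

**Inference.** The default is a pooled-relabeling permutation test, exact
by construction for any statistic: $p = (1+\#\{V_\pi \ge V\})/(1+B)$.
Because V lives on a discrete grid (multiples of $1/n$), permutation ties
make this p conservative — at $n_1=n_2=150$ the null atoms near the 95th
percentile are ~2% wide and the realized size at α = 0.05 is ≈ 0.03.
`kuiper_two_sample()` therefore also reports `p_randomized`, the classical
randomized tie-breaking p with exact size, which is the right quantity
when rejection *rates* are themselves under study (calibration
experiments).  For routine use the conservative exact p is the safer
default.  An asymptotic alternative uses the circular Kuiper tail
$2\sum_{j\ge1}(4j^2\lambda^2-1)e^{-2j^2\lambda^2}$ with
$\lambda = V(\sqrt{N_e}+0.155+0.24/\sqrt{N_e})$,
$N_e = n_1 n_2/(n_1+n_2)$; it falls back to permutation below 20
observations per sample.  Per-category comparisons across replicates
(per-embryo proportions) are plain Welch t-tests, provided as a
convenience wrapper.

# Junctional polarity nematics

PCP proteins enrich on opposite cell edges, a period-180° (nematic)
signal.  For boundary samples with outward-normal angles $\varphi_k$ and
intensities $I_k$, the default per-cell estimator is the
intensity-weighted second Fourier mode
$z = \sum_k I_k e^{2i\varphi_k} / \sum_k I_k$; magnitude $|z|$, axis
$\arg(z)/2 \bmod 180°$.  For a junctional profile
$I \propto 1 + m\cos 2(\varphi-\varphi_0)$ sampled uniformly this yields
magnitude $m/2$ at axis $\varphi_0$ — the factor 2 is inherent to the
moment estimator and all ground-truth bookkeeping uses the $m/2$ nematic
scale.

Real cell boundaries do not sample orientation uniformly: a polygon's
normals carry second and fourth shape modes, and the intensity-weighted
normalization couples to them, attenuating the moment estimate by up to
~15% on elongated or boundary-clipped cells.  For quantitative work the
package therefore also fits, per cell,
$I = c_0 + c_{2c}\cos 2\varphi + c_{2s}\sin 2\varphi$ by least squares
(`method = "harmonic"`), which accounts for the sampling design and is
unbiased whenever a boundary carries three distinct normal directions.
Rose plots use the simple moment estimator; recovery tests use the
harmonic fit with boundary cells excluded, mirroring the shape-statistics
exclusion.

Tissue polarity averages per-cell nematics as complex numbers
$|z|e^{2i\cdot\text{axis}}$ — each cell one vote by default ("average
magnitude and direction"), or weighted by total boundary intensity via a
flag, since published rose-plot conventions leave the weighting
unspecified.  The tissue magnitude is bounded by the mean per-cell
magnitude (triangle inequality), and orthogonal axes cancel exactly.

# The synthetic basal layer

The generator emulates the statistical structure the analysis assumes —
not the physics that produces it.

**Packing.** Cells are a bounded Voronoi tessellation of uniform points at
the target density, relaxed by 2 Lloyd iterations.  This yields the
hexagon-dominated polygon-class distribution of real epithelia without a
mechanics engine.  Tiles are assembled from the tessellation's segment
table and clipped to the field rectangle; realized cell count equals
`round(density × area / 100)` exactly.

**Defaults as study conditions.** The default field is 100 × 75 µm at
2.87 cells/100 µm² (≈ 215 cells), height 6.9 ± 1.5 µm (truncated normal).
Published density (215 cells per 1200 µm² field of view) and mean area
(≈ 116 µm²) figures for this tissue are mutually inconsistent, so the
defaults choose self-consistent geometry: mean area ≈ 35 µm² gives a
longest chord ≈ 7.5 µm and H:W ≈ 0.9, inside the reported 0.83–1.28 H:W
range; the 215-per-1200 µm² convention is reproduced exactly when that
density is requested.  The angle law is the wildtype-like mixture
(0.51/0.29/0.20 across planar/oblique/perpendicular), uniform within each
bin — the within-bin law is unreported, so uniform is the default and a
sine-weighted (3D-isotropic) option exists for null simulations.  Fate is
drawn conditionally on category (symmetric with probability
0.94/0.41/0.11).  In **hertwig mode** the angle instead follows the
cell's own 3D long axis — elevation 90° when height exceeds the longest
chord, 0° otherwise — plus wrapped Gaussian noise (default SD 10°)
applied to both elevation and the in-plane axis, reflected into [0°, 90°].

**Tracks.** Frames are 10 min apart, 48 per movie by default; division
frames are drawn so the full 1.5-h fate window fits.  Daughters appear one
frame after the mother ends, separated by 8 µm along the sampled 3D axis —
a plausible placeholder, flagged as such because daughter separations are
not reported quantitatively anywhere we know of.  The pair is shifted
upward as a unit if needed to keep both nuclei above the membrane, which
preserves the sampled angle exactly.  Basal daughters relax to the basal
nuclear plane (z = 3 µm) by the second post-division frame; a suprabasal
daughter ramps to its plateau (z = 10 µm) by the third frame and stays.
The shared suprabasal threshold sits at 5.5 µm.

**Noise.** z-jitter is AR(1) with per-frame correlation 0.7 and stationary
SD 0.3 µm: nuclear wobble is slow relative to a 10-min frame interval, and
0.3 µm is the centroid quantization implied by 1-µm z-steps (step/√12).
xy-jitter is white with SD 0.1 µm.  These defaults make synthetic
measurements realistically imperfect — at the category boundaries they
displace roughly 2% of planar calls — and recovery tests are run under
them; exactness tests (zero fate errors, angle reproduction to 1e-9°) set
the noise to zero explicitly.

**Edge intensities.** Boundary samples are placed along each polygon edge
at 0.75-µm spacing with outward-normal angles; intensity is
$100·(1+m\cos2(\varphi-\varphi_c))$ plus Gaussian noise (SD 5), where the
per-cell axis $\varphi_c$ jitters around the tissue axis (default 30°,
SD 10°).  Ground truth records each cell's $\varphi_c$ with nematic scale
$m/2$ and the realized tissue average of those per-cell nematics, so
recovery is judged against what the jittered tissue actually contains.

**What is not emulated.** No cell mechanics, neighbor exchange or
delamination; no suprabasal life beyond the fate threshold; no
fluorescence or photon noise; mother cells do not round up or displace
their neighbors.  Passing recovery tests therefore demonstrates
correctness of the measurement pipeline under the stated statistical
assumptions, not robustness to segmentation failure or imaging artifacts
in real microscopy.

# Numerical choices and degenerate inputs

* Angles are computed with `asin` of a ratio clamped to 1; orientation
  axes are reduced mod 180° with a 1e-9 snap at the wrap point.
* Longest-chord ties take the first maximal vertex pair in scan order;
  elongation of an exactly isotropic polygon returns magnitude 0 with an
  arbitrary axis.
* `polygon_area` validates simplicity in O(n²) (skippable for trusted
  tessellation output); zero-area and sub-3-vertex polygons are errors.
* Permutation p-values require an explicit seed; all generator randomness
  flows from the single config seed (sub-streams are derived as seed+1,
  seed+2 for tracks and edges), and identical configurations are
  byte-identical.
* The angular histogram closes its top bin so Θ = 90° is counted; rose
  bins treat 179.9° and 0.1° as adjacent, not equal.

# Test problem sizes

The packaged checks run at sizes chosen to make their statistical
assertions well powered while remaining quick: 200 replicate fields of 300
divisions for category recovery; pooled 4 × 200 divisions per noise level
for fate-error monotonicity; 2000 null and 500 alternative replicates
(B = 199/399 permutations) for Kuiper size and power; 1000 random
instances (n ≤ 30) against the brute-force statistic oracle; 20 seeded
fields for polarity recovery; 72 divisions (a realistic per-embryo pool)
for the long-axis-rule correlation.

# Known limitations

* The bounded-interval reading of the "0–90° modification" of Kuiper's
  test is one of several defensible variants (angle rescaling and data
  reflection are others); the permutation null makes inference correct for
  whichever statistic is used, but printed p-values from other software
  are not expected to match numerically.
* Elongation magnitudes are comparable within this package only.
* The fate rule scores nuclear z against a single threshold; membrane
  context, which some annotators use, is out of scope.
* Voronoi packing has no correlated cell-size gradients; regional
  comparisons (e.g. midline vs lateral geometry) are supported by running
  separate fields per region with different configurations.
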