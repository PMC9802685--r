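---
title: "Models and methods behind clemtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clemtarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clemtarget)
```

`clemtarget` implements the computational core of an automated correlative
light / FIB-SEM targeting workflow: cells are selected at the light
microscope (LM), and the instrument later has to find the very same cells —
now invisible inside a resin block — at the electron microscope (EM). The
bridge between the two coordinate frames is the alphanumeric grid imprinted
into the bottom of gridded culture dishes, whose bar crossings serve as
fiducial landmarks visible in both modalities. This vignette explains the
models, the tunable parameters with their defaults, the synthetic data used
for validation, and the numerical choices made where the design was open.

## The coordinate model

Stage coordinates are micrometres; image metadata refers stage coordinates
to the image center, so a point detected at pixel offset `(dx, dy)` from the
center sits at `stage + pixel_size * (dx, dy)`. Images are matrices indexed
`[y, x]` with the origin at the top-left and pixel centers on integer
coordinates. The substrate lattice (`grid_layout()`) defaults to 560 um
squares separated by 40 um bars — a 600 um pitch — with digit+letter square
identifiers such as `"8Q"`; both dimensions are parameters because etched
substrates vary (some carry 580 um squares with 20 um borders) and the
detector only relies on whatever layout it is given.

## Landmark detection by angular projection

`detect_lines()` follows a line-orientation detector design:

1. optional adaptive histogram equalization (unbalanced illumination) or a
   Laplacian prefilter (regular interference);
2. Canny-style edge detection — Sobel gradients with hysteresis thresholds
   expressed as fractions of the maximum gradient (defaults 0.06/0.075);
3. a stroke-support filter: an edge pixel is kept only when an oriented line
   kernel of length `stroke` (default 15 px at ~1.7 um/px) is substantially
   covered by (dilated) edge pixels at some orientation. This suppresses
   glyph strokes, speckle and dirt, which do not form long straight runs;
4. a weighted angle-offset accumulator (a Radon/Hough-style transform): each
   surviving edge pixel votes, with its gradient magnitude, for every line
   `(angle, offset)` passing through it, at 1 degree resolution over
   0-180 degrees and 1 px offset bins;
5. 2-D non-maxima suppression over the accumulator with a noise floor of
   `noise_floor_nsd` (default 5) standard deviations above the accumulator
   mean, followed by parabolic sub-pixel interpolation of each peak offset;
6. when a layout is supplied, a repetition/spacing test keeps only lines
   with a same-orientation partner at the bar width, square size or pitch
   (±15%).

`find_crossings()` pairs lines within an orientation family whose separation
matches the bar width (each bar contributes its two edge lines), intersects
the pairs of the two families, and emits the centroid of the four pairwise
intersections as the crossing center — the construction that makes the
center estimate robust to a biased localization of any single edge.

`refine_crossing()` re-runs the detector on a patch around each candidate
(about three bar widths across) and accepts it only if all of the following
hold:

* a crossing is re-found near the patch center;
* the two families' edge separations agree with each other within 10% and
  with the bar width within 15% of their mean (a pairing that mixes a defect
  edge with a bar edge fails this);
* each of the four expected bar-edge lines is individually supported by
  stroke-filtered edge pixels near the crossing (fraction >= 0.45, sampled
  outside the central area where edges genuinely vanish);
* the intensity model is consistent: the four background quadrants agree
  with one another, the four bar arms agree with one another, and both
  levels agree with the same measurement on a peripheral annulus. A defect
  overlapping the crossing core pulls at least one of these off.

The deviation thresholds (0.5 of the bar/background contrast for a single
sector, 0.25 for the center-vs-periphery comparison) were chosen to sit far
above the fluctuation of clean noisy scenes (<= 0.1 at 10% intensity noise)
and far below the deviations produced by cracks, scratches and dirt of at
least half a bar width (>= 0.7). Rejection reasons are reported
(`no_lines`, `spacing_mismatch`, `occluded`, `out_of_bounds`).

SEM surfaces show the grid as topographic ridges rather than dark bars.
`sem_edge_probability()` turns an SEM image into a per-pixel bar-edge
probability: the classical backend is the normalized oriented-edge response
(gradient magnitude modulated by stroke support at the stroke length and at
three times the stroke length — long scratches lose against full-length bar
edges under the longer kernel); the model backend is a logistic-regression
pixel classifier over the same filter bank, trained once per session on an
internally generated synthetic SEM grid with a known edge mask.

## Square identification

Square labels are digit+letter pairs. `classify_square_id()` binarizes and
despeckles the glyph patch, splits it at the widest column gap, normalizes
each character crop to 12 x 12, and scores the two crops with per-character
random forests trained by `train_glyph_classifier()` on the synthetic glyph
generator (rotation ±6 degrees, scale 0.85-1.15, translation ±5 px,
intensity and noise augmentation). A random forest on normalized crops
reaches the >= 99% held-out accuracy the workflow needs in well under a
minute of CPU training; the confidence of a prediction is the smaller of the
two class probabilities, and predictions under 0.5 are reported `unknown`.
`validate_neighbor_label()` additionally cross-checks a label against
already-accepted neighbours through the lattice geometry (`1A` may sit next
to `1B`, never next to `8B`).

## Registration

Three nested models translate LM stage coordinates into EM stage
coordinates:

* **Lattice model** (`fit_lattice()`): a least-squares affine map from
  integer label indices to stage positions. Four exact landmarks determine
  it completely, so every other crossing is predictable — the bootstrap for
  mapping a freshly loaded sample.
* **Global affine** (`fit_global_affine()`): least squares over all matched
  (LM, EM) landmark pairs. Reflections are permitted — the imprint is viewed
  from the opposite side after coverslip removal — and appear as a negative
  determinant; the handedness difference is handled entirely by the affine,
  with no explicit pre-flip. Plain least squares (not RANSAC) is used
  because landmarks arrive pre-validated by the crossing refinement;
  residual outliers beyond 3x the MAD are flagged but kept.
* **Local affine** (`fit_local_affine()`): the same fit restricted to the
  landmarks within 1200 um of the target, capped at the 8 nearest and
  requiring at least 3 usable ones, otherwise falling back (flagged) to the
  global transform. The cap reconciles the workflow's "eight landmarks"
  with its "usually four to eight": all in-radius neighbours, at most 8,
  minimum 3. Local refinement absorbs the smooth field distortions that a
  single global affine cannot.

`filter_targets()` enforces the 150 um minimum separation between kept
targets (a trench milled for one cell destroys its neighbourhood), removing
blocked/damaged targets first and then greedily the target with the most
conflicts — which keeps the maximal set on separation chains.

`build_landmark_map()` drives the mapping loop: it samples 30% of the grid
crossings uniformly at random (at least 20), predicts each position from the
current model (the supplied frame guess until four landmarks exist, the
refitted lattice model afterwards), detects and refines the central
crossing, retries once after a simulated refocus, flags persistent failures
`blocked`, and refits after every valid addition.

## Acquisition geometry

* **Coincidence point**: with the FIB and SEM axes crossing at
  `beam_angle_deg` (default 54 degrees), a surface sitting `dz` off the
  coincidence height displaces the sputtered fiducial mark by
  `dy = dz * tan(angle)` between the two views, so
  `coincidence_z_offset()` applies `dz = dy / tan(angle)`. The relation and
  its sign are configuration, and `simulate_coincidence()` — a genuine
  ray/plane projection of the two beams — is the source of truth the
  relation is tested against.
* **Beam-shift refinement** (`beamshift_refine()`): windowed normalized
  cross-correlation of the FIB and SEM mark images, run twice (integer
  alignment, then sub-pixel residual with log-parabola interpolation) to
  cancel the window-induced proportional bias; a normalized peak below 0.1
  means the mark was not found.
* **Trench detection** (`detect_trench()`): slight blur, two-threshold Otsu
  (three intensity classes), components of the darkest class tested for the
  FIB-perspective trapezoid signature: convex quadrilateral, near-horizontal
  top edge (±10 degrees), top/bottom edge ratio in [1.05, 4], and component
  area filling the quadrilateral. Largest wins; nearest-to-center wins when
  re-acquisitions left several trenches. Histogram-based thresholding makes
  the detector invariant to brightness/contrast changes.
* **AFAS site selection** (`select_afas_sites()`): Harris corners below the
  coating exclusion band, k-means clustering (k between 6 and 12, about one
  cluster per 50 corners), and ranking of cluster centroids by a weighted
  score of local variance (0.5), local entropy (0.3) and proximity to the
  image center (0.2) — weights are configuration since the prioritization
  order is a free choice. At most six sites are returned; a featureless
  cross-section falls back to the edge between cross-section and surface.

## Run monitoring

`monitor_stack()` supervises a slice-and-view acquisition. Drift between
consecutive slices is the RANSAC consensus of corner-feature patch matches
(normalized cross-correlation, sub-pixel by parabolic interpolation); when
fewer than 8 matches agree, alignment falls back to the bright gold coating
band, located as the bright low-entropy row band and compared between
slices (y only). Focus is scored by Vollath's F4 autocorrelation, with a
boundary correction so a constant image scores exactly zero, normalized by
pixel count to make thresholds resolution-independent; stigmatism by the
variance of the Laplacian-filtered image. A metric changing by more than 25%
between consecutive slices raises a warning (per metric independently — the
rule's scope is otherwise unspecified); warnings are structured report
fields rather than e-mails. Cumulative y-drift beyond one quarter of the
image height triggers a FOV shift opposing the drift, quantized upward to
0.5 um steps, after which the tracked reference is re-centered so the next
decision is quiet (hysteresis). The 45 min autotune interval is recorded
with the run; nothing sleeps on it. `place_autotune_box()` reuses the AFAS
scoring under the hard constraints that the box sit fully below the coating
and fully inside the upper half of the image.

## Phenotype features

Four intensity-independent Golgi-morphology scores are computed on the GFP
channel within each cell's cytoplasm (nuclei segmented from DAPI, cytoplasm
by radial dilation with nearest-nucleus partitioning):

* **diffuseness** — sum of the grayscale-opened signal over the raw sum; 1
  for homogeneously spread signal (the opening of a constant is the
  constant), small for signal concentrated in structures under the SE size.
  The opening runs on the full image; the measure assumes the signal decays
  to background at the cytoplasm boundary, which holds for these cells.
* **fragmentation** — count of 8-connected components after top-hat
  filtering and Otsu thresholding; no size floor by default (configurable).
* **tubularity** — per-pixel max-minus-min over grayscale openings with line
  SEs swept over 0-180 degrees, summed and normalized by total intensity;
  isotropic blobs score near zero, tubules high. The sweep step defaults to
  1 degree and is configurable (tests use 15 degrees; the statistic is
  stable well before that).
* **condensation** — shape factor `4*pi*A/P^2` of the binarized signal. The
  perimeter uses a four-direction Cauchy-Crofton estimator
  (`P = pi/8 * (C0 + C90 + (C45 + C135)/sqrt(2))` over boundary-crossing
  counts), chosen because naive pixel-edge counting would systematically
  prevent digital circles from reaching the analytic maximum of 1;
  rasterized circles converge to 1 within 2% from radius ~100 px. The
  estimator is exact in rotation average but carries a known direction
  bias of up to ~13% for axis-aligned rectangles. Components are
  aggregated by area-weighted mean (largest-component mode available).

Structuring element sizes (opening disc radius 10 px, top-hat radius 15 px,
line length 21 px) are calibrated to a 1.7 um/px prescan and scale with
pixel size. QC covariates mirror the screening workflow: integrated GFP
signal (dim cells), DAPI coefficient of variation inside the nucleus
(mitotic cells condense chromatin and raise it), and the log-log slope of
the radially averaged power spectrum (defocus pushes it more negative;
white noise sits near zero). `qc_filter()` applies the three rules
sequentially and records the first failing reason.

## Stereology

`cavalieri_volume()` implements the point-counting Cavalieri estimator
`V = t * a_p * sum(P)` on serial sections with spacing `t` (default 0.2 um)
and a point lattice with uniform random offset (`a_p` the area per point).
Unbiasedness over random offsets and random section starts is verified on
synthetic spheres. Cycloid probes (`cycloid_grid()`) address vertical
sections: arcs with the minor axis along the section's vertical axis, tiled
with a random phase and rasterized at <= 0.25 px steps for intersection
counting; an analytic arch/segment intersector serves as the test oracle.
The mean cisternae number per stack is the ratio of cisterna-midline
intersections to stack-face intersections; the stack face is counted per
boundary crossing (entering and exiting each count), a convention the
synthetic oracles are built for since the measure is only ever used as a
ratio. Profiles count as cisternae at a length-to-breadth ratio of at least
3:1, measured as extents along the principal axes (projection range + 1 px,
placing a 30 x 10 px rectangle exactly on the boundary).

## The synthetic fixtures — and what they do not show

Every input the pipeline consumes has a seeded generator with exact ground
truth: grid scenes (reflected-light and SEM styles, arbitrary affine frames
including reflections, polygonal crack/scratch/dirt defects with occlusion
truth defined as >= 15% defect coverage of the crossing core), glyph images,
trench images, drifting/defocusing slice stacks, archetype-controllable
cells (diffuse / fragmented / tubular / condensed against a juxtanuclear
ribbon control, with the archetype parameter stored in the truth), and
labelled Golgi volumes (spherical stack, plate cisternae). All randomness
flows through one per-call seed; equal parameters and seed give
bit-identical output, and no global RNG state is touched.

The generators emulate geometry, intensity statistics and the failure
taxonomy — not microscope physics. Bars render with ~1 px soft edges, SEM
topography as Gaussian ridges along bar edges, defects as textured
polygons; there is no electron-matter simulation, no real MatTek glyph
font, no shading or charging artifacts. Passing tests therefore demonstrate
correctness of the algorithms under controlled geometry and noise, not
performance on any particular instrument's images; the published
accuracies of the original microscope sessions (targeting errors of a few
micrometres on real resin blocks) are properties of real data that desk
validation cannot reproduce and are not claimed here.

Problem sizes used throughout validation — 384 px scenes at 1.7 um/px
(50-scene acceptance sweeps), 99-crossing simulated dishes sampled at 30%,
500-replicate registration Monte Carlo, 1000 held-out glyphs, 100 trench
and 1000 AFAS fixtures, 100-replicate Cavalieri sweeps — were chosen so the
full validation runs comfortably on a single CPU while keeping every
statistical bound far from its noise floor.

## Known limitations

* The line detector assumes two dominant orientation families roughly a
  right angle apart (after the affine); strongly sheared frames degrade the
  pairing tolerance before the detector fails outright.
* The occlusion checks are calibrated for defects of at least about half a
  bar width; a hairline scratch through a crossing that leaves the
  intensity model and edge support intact is accepted (and, empirically,
  leaves the center estimate unbiased).
* The glyph classifier is trained on the package's own raster font;
  applying it to real dish fonts requires retraining on annotated crops
  (the training entry point accepts any generator of labelled images).
* Drift estimation assumes pure translation between consecutive slices;
  rotation or scale drift is outside its model, as it is in the workflow it
  mirrors.
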