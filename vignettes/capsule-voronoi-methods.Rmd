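---
title: "Methods: Voronoi verification and nanoscale morphometry of honeycomb capsules"
author: "VoronoiCapsule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Voronoi verification and nanoscale morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VoronoiCapsule)
```

# The scientific problem

Electron micrographs of some *Micrococcus* isolates show a capsule surface
densely perforated with polygonal cavities — a honeycomb whose partition
walls look like the edges of a Voronoi diagram of the cavity centers — and,
at larger scale, sponge-like biofilms in which fibrous secretions hold
cells apart. Two quantitative questions follow:

1. **Is the wall network really Voronoi-like?** If cavity centers act as
   seed sites, every wall should lie on the perpendicular bisector of the
   segment joining the two adjacent centers, so each wall must cross the
   line joining those centers (its dual Delaunay edge) at 90°. Measuring
   the acute intersection angles of a traced wall network against the
   Delaunay edges, and comparing their mean with the theoretical 90°,
   turns the visual impression into a statistic.
2. **What are the structure's dimensions?** Cavity diameter and depth,
   dense-capsule-layer and cell-wall thickness, cell size, and the
   cell-to-cavity area ratio of biofilm sections are all measured from
   binarized micrographs with a nm-per-pixel calibration.

The package implements both analyses end to end, together with a
synthetic-micrograph generator that supplies ground-truth-annotated inputs,
so that every stage is testable without access to a microscope.

# The Voronoi model

For seed points $P_i$ in the plane, the region of $P_i$ is

$$V(P_i) = \{\,x : \lVert x - P_i\rVert \le \lVert x - P_j\rVert \ \forall j \ne i\,\},$$

the set of points at least as close to $P_i$ as to any other seed.
`buildVoronoi()` constructs each region literally by this definition:
starting from the bounding-box rectangle, the cell of $P_i$ is cut by the
half-plane of the perpendicular bisector against every other site. The
construction is quadratic in the number of sites, which is the right
trade-off here — capsule cross-sections carry tens to a few hundred pores,
and the half-plane form mirrors the defining mathematics exactly. A
nearest-first ordering with an exact termination bound (once half the
distance to the next site exceeds the cell's current vertex radius, no
later site can cut) keeps it fast in practice.

Three design choices are worth stating:

* **Clipping.** Published diagrams are finite figures, so unbounded outer
  regions are clipped to the bounding box (a tight box around the seeds
  padded by 10% per side by default). This makes cell areas and edge lists
  well defined; the partition invariant (cell areas sum to the box area)
  is tested to a relative $10^{-9}$.
* **Duality by construction.** Clipping tracks which bisector produced
  each polygon edge, so each finite Voronoi edge carries its dual site
  pair $(i, j)$; the edge lies on the bisector of $P_iP_j$ and is
  therefore perpendicular to its Delaunay edge to floating precision.
  `dualityAngles()` verifies this: the worked example on the bundled
  22-point coordinate fixture returns 90° on all 51 edges, relative error
  0.0% against the theoretical value.
* **Degeneracies.** Cocircular quadruples are resolved by the
  nearest-then-index clipping order; Voronoi edges shorter than
  $10^{-9}\times$ the bbox diagonal are dropped; coincident seeds (closer
  than the same epsilon, configurable) are rejected on construction.
  Coordinates are treated as plain Cartesian; image-derived coordinates
  map row $r$ to $y=-r$ so screen-style printed listings and image
  centroids share one convention, and the unit of printed seed listings is
  treated as dimensionless (it is never stated in practice).

An independent check accompanies the construction:
`nearestSiteRaster()` labels a pixel grid by literal argmin distance —
no geometry at all — and the test suite requires $\ge 99.9\%$ agreement
with polygon membership over 100 random seed sets.

## Wall networks against the ideal

Hand-traced walls deviate from the ideal tessellation.
`wallVsDelaunayAngles()` assigns each observed wall segment a candidate
Delaunay edge via the two sites nearest its midpoint — the wall separating
two pores is tested against the line joining those pores. This matching
rule is a package decision; the original measuring procedure (angles read
at wall/line crossings with an image-analysis angle tool) does not
prescribe one. Angles are always folded to the acute value in $[0°, 90°]$,
matching how intersection angles are read in practice (an observed mean
below 90°, e.g. 83.7°, implies folding). Segments whose candidate pair has
no finite Voronoi edge are skipped and counted.

Under Gaussian angular jitter with SD $\sigma$ the folded angle is
$90° - |\delta|$, $\delta \sim N(0, \sigma)$, so the expected mean is
$90° - \sigma\sqrt{2/\pi}$ — for $\sigma = 6°$ about $85.2°$. The test
suite checks the Monte-Carlo mean over $\ge 1000$ perturbed edges against
this closed form. The observed mean of a real hand-traced network (a
published 83.7° ± 5.99°, relative error 7.0%) is *not* reproducible
without the underlying micrograph; what the package reproduces is the
procedure and its behaviour under a known deviation model.

`tessellationCongruence()` quantifies the manual-versus-computed overlay:
points are sampled densely along both edge sets, and the report carries
the mean and maximum symmetric point-to-nearest-edge distance plus the
fraction of observed edge length within a tolerance of the computed
diagram. Self-comparison returns $(0, 0, 1)$ exactly, and mean distance is
monotone in applied jitter.

# Image morphometry

The measurement pipeline follows standard micrograph practice: optional
edge emphasis (3×3 Sobel gradient magnitude, rescaled to $[0,1]$), then
Gaussian smoothing (default $\sigma = 1.5$ px), then thresholding —
Otsu's between-class-variance criterion over a 256-bin histogram by
default, or a fixed level. The original description names the steps but
no parameters, so the defaults here are package decisions, exposed as
arguments; the acceptance surface is parameter recovery on synthetic
data, not bit-matching any particular GUI tool. One consequence of the
order of operations deserves emphasis: the gradient transform discards
region-fill information, so area-fraction analyses run with
`edgeEmphasis = FALSE` (smoothing + threshold only); edge emphasis is for
delineating boundaries in low-contrast images.

Operationalisations the source leaves unstated:

* **Pore diameter** (face-on sections): maximal inscribed-circle diameter
  per enclosed pore component, from the distance transform — robust to
  non-circular pores, equal to the chord definition on circular ones.
  Pores touching the image border are partial and excluded.
* **Pore depth** (profile sections): the dense layer surface is the first
  nearly-full image row; each wall protrusion above it is measured by its
  vertical (radial) extent, which equals the cavity depth.
* **Layer thickness**: $\ge 25$ radial rays from the layer's centroid;
  each ray reports the length of the first contiguous in-layer run. Rays
  crossing a gap in a broken layer are skipped with a warning and reduce
  $n$. A mask whose centroid is covered by foreground is rejected as
  non-annular.
* **Cell major axis**: per connected component, the longer of the
  bounding-box height and width (the longer of the vertical and
  horizontal dimensions), in µm. Touching cells merge and are measured as
  one cluster — deliberately, since clusters of 1–4 cells are the natural
  unit in these biofilms; no watershed splitting is applied by default.

Reports always carry mean, SD, SE and $n$ per structure kind, because
published morphometrics mix SD and SE conventions; comparisons must state
which is used. Calibration equivariance (scaling nm/px scales every
reported length exactly) and rotation invariance are tested properties.

# The synthetic-data generator

The generator emulates the study conditions so that recovery tests are
meaningful:

* **Pore centers** form a jittered hexagonal lattice — cavities are
  described as equally spaced, and a hexagonal packing is the natural
  model; spatial statistics beyond "equally spaced" are not available, so
  lattice regularity is an assumption, and a hardcore-Poisson alternative
  is provided for robustness studies. The per-axis jitter SD is
  $\text{poreDiameterSd}/\sqrt{2}$.
* **Printed SE → per-object SD.** Where a source prints mean ± SE with
  $n$ (pore diameter 95.0 ± 4.41, depth 166.3 ± 5.91, both $n=25$), the
  generator's per-object SD defaults to $SE\sqrt{n}$ — the SE describes
  the mean, but the generator must draw individual pores.
* **Calibration of the lattice scale.** Jitter changes the realised
  cavity sizes: the inscribed circle of a jittered Voronoi cell is not
  the nominal lattice constant minus the wall. The generator therefore
  root-finds the lattice scale, on the fixed jitter draw, until the mean
  realised pore diameter (inscribed-circle diameter of interior cells
  minus the wall) equals the requested mean. The generator's contract is
  the realised pore-size distribution, not the nominal spacing. A side
  effect is that the realised diameter SD is smaller than the nominal
  per-pore SD (the inscribed circle averages over neighbours); the mean,
  which is what recovery tests score, is matched.
* **Wall thickness 20 nm.** The partition-wall width between cavities is
  not reported anywhere; 20 nm is adopted as a realistic fibrous-wall
  width (comfortably below the 27.9 nm cell wall, and ≥ 10 px at the
  default calibration). It is a free parameter of `capsuleParams()`.
* **Default calibration 2 nm/px**, so a 95 nm pore spans ≈ 48 px; cell
  surface renders use 20 nm/px so micrometre-scale cells fit the frame.
* **Rendering.** Horizontal sections rasterise the true Voronoi edges of
  the true sites at the configured wall thickness (pixel-centre
  convention: a band of $n$ pixels spans $n-1$ centre-to-centre steps);
  vertical sections draw a comb of 25 protrusions with per-pore depths;
  biofilm sections place non-overlapping discs via the free-space
  distance transform until the ground-truth fraction is within 0.5
  points of target; cell surfaces draw non-touching shaded spheres with
  truncated-normal diameters and a bright-limb profile, as
  secondary-electron images of spheres show. Gaussian blur (σ = 1 px)
  and additive Gaussian noise (SD 0.05) apply to images only; truth
  masks are noise-free.
* **Spectra** are sums of exact-area Gaussian peaks on a flat baseline on
  a descending wavenumber grid; no scattering or reflection artifacts are
  simulated. Band-area ratios against the C–H reference window
  (2800–3000 cm⁻¹) are the evaluation indices, since absolute areas vary
  with sample placement and thickness; transmittance input is converted
  to absorbance before integration by default (the conventional basis for
  area comparison), with a flag to integrate raw. The default baseline is
  the linear join of window-edge values; flat-baseline synthetic tests
  use "none".

What the generator does **not** emulate: electron-optics physics
(charging, depth of field, detector noise correlations), curvature
distortion of near-spherical cells sectioned off-centre (noted but not
corrected in the source material), partial-volume effects, or 3-D sponge
connectivity. Passing recovery tests therefore demonstrates that the
measurement operations are unbiased under the stated geometric model with
blur and additive noise — not that they are robust to every real-world
imaging artifact.

# Statistics

`studentTTest()` is the two-tailed pooled-variance two-sample test with
p-values from the exact t distribution — with $n=3$ growth-assay groups,
normal approximations are not acceptable — and the conventional
significance labels (ns ≥ 0.05, \* < 0.05, \*\* < 0.01, \*\*\* < 0.001).
Zero pooled variance returns $t=0, p=1$ for equal means and is an error
otherwise. `relativeError()` implements the
$(\text{theory}-\text{observed})/\text{theory}\times 100$ convention
(83.7 vs 90 → 7.0%). `diffusionT90()` is the cited Fickian barrier time
$t_{90} = 1.03\,L^2/D_e$, quadratic in distance — the quantitative reason
sponge-like spacing and a thick porous capsule act as a diffusion barrier.
Whether published percent reductions were computed on raw band areas or
on reference ratios is ambiguous; both routes are available
(`percentReduction()` accepts either), and on ratio-preserving synthetic
spectra they agree.

# Problem sizes and reproducibility

Default test and demonstration sizes are chosen so a laptop-class single
core completes the whole suite in a few minutes: capsule sections of
1200 × 900 nm at 2 nm/px (≈ 80 sites, ≈ 50 measurable interior pores),
vertical profiles with 25 protrusions ($n$ matched to the study's
measurement count), 300 × 300 px biofilm sections, 40-cell surface
fields, and 100 random seed sets of 3–50 sites for the oracle-equivalence
property. Every generator is deterministic given its seed;
`runFullDemo()` derives stage seeds from one master seed and writes a
byte-identical JSON report when re-run with the same seed.

```{r demo, eval = FALSE}
rep <- runFullDemo(outDir = "demo_out", seed = 42)
rep$capsule_horizontal$seed_fixture_duality$mean   # 90
rep$biofilm_section$estimated_cell_fraction        # ~45
```

# Known limitations

* The half-plane construction is $O(n^2)$; beyond a few thousand sites a
  sweep-line algorithm would be preferable. The reference semantics are
  prioritised here.
* Pore-site inference uses pore centroids, which approximate Voronoi
  sites well only for near-centroidal (regular) tessellations; under
  heavy jitter the centroid–site offset is intrinsic. Border pores are
  clipped and their centroids biased inward; they are retained (a
  micrograph's periphery is equally clipped) and congruence scoring
  weights by edge length.
* Touching cells are measured as clusters, matching the biological unit
  but not single-cell size distributions.
* The vertical-profile depth measurement assumes an approximately flat,
  horizontal dense-layer surface; strongly curved profiles would need a
  local-normal formulation.
* Real micrograph numbers (e.g. an 83.7° traced-wall mean or a specific
  45.3:54.7 section ratio) depend on images that are not redistributable
  at analysis resolution; the package verifies the procedures on
  synthetic ground truth instead and treats such printed values as
  generator targets or worked-example inputs.
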