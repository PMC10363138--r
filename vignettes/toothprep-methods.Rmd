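---
title: "Automated geometric evaluation of tooth preparations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated geometric evaluation of tooth preparations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothprep)
```

## The measurement problem

When a tooth is prepared for a single-unit crown, its quality is judged on a
few geometric quantities: how much structure was removed at each cusp
(occlusal reduction), how strongly the opposing axial walls converge toward
the path of insertion (total occlusal convergence, TOC), and the geometry of
the finish line (here, the width of the chamfer margin band). Human raters
measure these on superimposed 3D scans by hand-picking reference points,
which is slow and inconsistent between raters and between repeat sessions.
`toothprep` computes all of them from the registered scan pair — the intact
anatomical tooth and the prepared abutment — with no human intervention, so
repeat evaluations of the same pair are bit-identical.

Inputs are two triangle meshes in millimetres (STL or PLY), a configuration
giving the path of insertion `p` (default +z) and the mesial direction
(default +x), and the seven standard occlusal landmarks of the reference
tooth (five cusp tips, two marginal ridge points). The pair is assumed
registered; `icpRegister()` (point-to-surface ICP, all vertices, no
sampling) is available when it is not, but nearest-neighbour ICP needs a
sane starting position, which scanner software normally provides.

## Margin detection

The preparation margin is the sharp crease where the prepared surface meets
untouched tooth. Two discrete sharpness measures drive its detection:

* **Vertex sharpness.** The cotangent-weighted Laplacian of the vertex
  coordinates,
  $(\Delta f)_i = \frac{1}{\Omega_i} \sum_{(i,j)}
  \frac{\cot\alpha_{ij} + \cot\beta_{ij}}{2} (v_i - v_j)$,
  whose magnitude approximates mean curvature: large exactly on creases.
  $\Omega_i$ is the barycentric cell area by default (one third of the
  incident triangle areas); the mixed Voronoi area is available as an
  option. Both behave identically on well-shaped scan meshes; barycentric is
  the default because it is robust to obtuse triangles. Cotangents are
  clamped to ±100 so sliver triangles in real scans cannot blow up the
  operator.
* **Edge sharpness.** Each interior edge gets an adjusted length
  $e'_{ij} = \frac{n_1 \cdot n_2 + 1}{2}\, e_{ij}$ from its two incident
  unit face normals: coplanar faces keep their length, a 90° dihedral halves
  it, a fold-back collapses it to zero. Sharp creases therefore become
  *short*, and shortest paths prefer them.

Detection proceeds in four steps. (1) Twelve seed vertices are placed around
the root at equal azimuth increments, at 25 % of the bounding-box height —
safely below any margin. (2) From each seed a walk ascends the anatomical
mesh (always to the neighbour with the greatest projection on `p`) while the
closest distance to the prepared mesh stays below the error bound ε; because
the two surfaces coincide below the margin and separate above it, the first
vertex beyond ε has just crossed the margin. (3) The candidate snaps to its
nearest prepared-mesh vertex and hill-climbs over 1-ring neighbours to a
local maximum of Laplacian sharpness — the crease. (4) The twelve anchors,
sorted by azimuth, are joined by Dijkstra shortest paths weighted by the
adjusted edge lengths; the concatenation is the closed margin loop.

ε defaults to 0.15 mm. It must sit between two scales: well above the scan
noise (the scanner the workflow targets reports 25 µm precision) and well
below the divergence of the two surfaces just above the margin, which is of
the order of the chamfer width. For phantoms with very narrow chamfers
`phantomConfig()` lowers ε to half the chamfer width; with real molar scans
the 0.15 mm default covers the usual 0.5–1 mm chamfers.

The walk runs on the anatomical mesh (whose geometry continues smoothly past
the margin), while the sharpness refinement runs on the prepared mesh — the
crease physically exists only there. Candidates are refined *before* path
connection, so all twelve anchors lie on the crease before any path is cut.

## Margin-band width and the axial window

The band between the margin and the start of the axial wall is measured by
projection along `p`: both boundary loops are projected onto the plane
perpendicular to `p`, and

$$\text{width} = \frac{|A_\text{outer}| - |A_\text{inner}|}
  {(P_\text{outer} + P_\text{inner})/2},$$

shoelace areas over mean perimeter. For concentric circles this is exactly
$r_2 - r_1$, which the tests exploit.

The inner boundary (axial lower boundary) is built by translating the margin
polyline by `offset` along `p` and casting each translated point
horizontally onto the prepared surface; `offset` (default 0.4 mm, the scale
of the reference preparation's chamfer) is the one place where the package
must decide where "the axial wall begins", and it is exposed as
configuration rather than guessed from curvature. The axial upper boundary
interior-divides each lower-boundary point toward its vertical projection on
the occlusal plane (the plane ⊥ `p` through the highest prepared vertex) in
ratio `t : (1 − t)`, `t = 0.5` by default, and maps the division points back
to the surface by closest-point queries — so walls that end low (under a
tilted occlusal table) get proportionally shorter bands.

## Taper and TOC

For each face with area $a_f$ and unit normal $n_f$ the taper is
$90° - \angle(p, n_f)$: zero for a wall parallel to the insertion path,
positive when the wall converges occlusally, negative for an undercut. The
per-quadrant taper is the area-weighted mean

$$T = 90° - \frac{1}{A}\sum_f a_f \cos^{-1}
 \frac{p \cdot n_f}{\lVert p\rVert\,\lVert n_f\rVert},
 \qquad A = \sum_f a_f,$$

with faces assigned to the buccal/lingual/mesial/distal quadrants by the
azimuth of their centroid (90° sectors about `p`, mesial at 0°, buccal 90°
counter-clockwise). The two plane values are the contralateral sums,
$\mathrm{TOC}_{BL} = T_B + T_L$ and $\mathrm{TOC}_{MD} = T_M + T_D$.

Two numerical properties of this estimator are worth knowing. First, faces
are never split at sector boundaries; assignment by centroid is
area-consistent at scan resolution. Second, under vertex noise the acos is
curved, which biases the estimated taper low by roughly
$\tfrac{\sigma_n^2}{2}\tan T$ with $\sigma_n$ the induced normal tilt; at
10 µm noise on 0.1 mm edges this is ≈ 0.25° for an 18° wall and negligible
for clinically typical tapers. The phantom tests quantify exactly this.

## Occlusal area and cusp reductions

Each standard point drops along the perpendicular to the prepared surface —
implemented as the closest-point foot, computed with a bounding volume
hierarchy (median split on the longest axis, leaf size 4) and a best-first
priority-queue traversal that prunes boxes whose lower bound exceeds the
current best, so the distance is globally minimal. The seven feet, joined in
cyclic azimuthal order by geodesic (Euclidean-weighted) shortest paths,
bound the occlusal reduction area; unweighted paths are used here because
the occlusal boundary is not a sharp feature. Cusp reduction is simply the
closest-point distance from the anatomical cusp tip to the prepared surface.
The marginal-ridge and distal-cusp distances are measured identically but
only logged — the grading rubric has no criterion for them. An experimental
minimum-reduction metric (smallest anatomical-to-prepared distance over the
occlusal area) is available behind a flag; it is reported but never graded.

## Grading

Each of the six criteria (four graded cusp reductions, two TOC planes) maps
to A (2 points, green), B (1 point, yellow) or C (0 points, red):

| criterion | acceptable (A) | marginal (B) | unacceptable (C) |
|---|---|---|---|
| MB, DB cusp | 1.5–2.0 mm | 1.0–1.5 or 2.0–2.5 mm | < 1.0 or > 2.5 mm |
| ML, DL cusp | 1.0–1.5 mm | 0.5–1.0 or 1.5–2.0 mm | < 0.5 or > 2.0 mm |
| TOC (each plane) | 6–20° | 0–6° or 20–30° | > 30° or < 0° (undercut) |

A value exactly on an acceptable/marginal boundary takes the better grade; a
value exactly on a marginal/unacceptable boundary stays marginal. This is
the only convention under which grading the printed reference table
reproduces its published score means (a 1.00 mm buccal reduction must earn 1
point, not 0). Grading operates on full-precision values; only reporting
rounds. The total is the unweighted 0–12 sum — how the six criteria should
be weighted into a single verdict is an open policy question, so the package
reports the per-criterion detail alongside. Margin width is reported
ungraded. `colorizeMesh()` paints the partition with the grade colors
(axial quadrants by their plane's TOC grade, occlusal faces by the nearest
graded cusp) into a per-vertex-RGB PLY.

## Agreement statistics

Repeat-rating reliability is Cronbach's α,
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i \sigma_i^2 / \sigma_T^2\bigr)$, with
bands excellent (> 0.9), good (0.75–0.90), moderate (0.50–0.75), poor
(< 0.5); identical columns give α = 1 by convention, and the two-way mixed
consistency ICC(3,k) — numerically equal to α on complete data — is
available behind a flag since the two names are often used interchangeably.
Between-rater agreement is weighted Cohen's κ with linear disagreement
weights $w_{ij} = |i-j|/(c-1)$ by default (quadratic optional; the weighting
scheme is a genuine free choice), bands almost perfect (0.81–1.00) down to
none (≤ 0).

## The phantom generator

Because no scan data ship with the package, every end-to-end claim is tested
on synthetic abutment pairs with analytic ground truth. The prepared phantom
is a surface of revolution: root cylinder up to the margin circle; a concave
quarter-circle chamfer fillet that leaves a ~90° crease exactly at the
margin and meets the wall tangentially (so the margin is the unique dominant
sharp feature, as on a real chamfer preparation); four wall sectors with
independent tapers, blended across a 6° half-width band at each boundary to
emulate rounded line angles; and a flat occlusal table. The anatomical twin
shares the root — the surfaces coincide below the margin, which is what the
ε-walk exploits — continues the crown as a cylinder, and raises
compact-support cosine bumps on the table so each cusp tip sits exactly its
nominal reduction above the prepared surface. Gaussian noise (default
σ = 10 µm, emulating the scanner's reported precision) is applied along
vertex normals under a fixed seed.

Ground truth: reductions and margin geometry are exact by construction
(margin width equals the chamfer width through the annulus identity). For
tapers, the area-weighted quadrant mean of any continuous surface with
per-sector tapers genuinely differs from the plateau values inside the
rounded line angles — so the generator's truth integrates the as-built
analytic surface per quadrant (`truthQuadrantTaper()`, a dense quadrature
independent of all mesh code), with the nominal plateaus kept alongside. On
symmetric phantoms the two coincide.

What the phantoms do *not* emulate: real occlusal anatomy (fissures,
functional cusp bevels), scan holes and topological defects, registration
error between the two scans, and spatially correlated scanner noise. Passing
the phantom suite therefore validates the geometry pipeline, not the
robustness of margin detection on pathological scans.

Default study conditions (chosen once): margin radius 4.5 mm and wall height
4 mm (a molar-sized abutment), chamfer 0.4 mm (the reference table's mean
margin width is 0.36 mm), 6° per-wall taper (12° TOC, mid-acceptable),
1.5 mm reductions, 0.12 mm mesh resolution (the crease must be resolved:
resolution < chamfer/2), noise 10 µm.

## Problem sizes and numerical choices

The shipped tests run phantoms between ~9 k faces (unit tests, resolution
0.2 mm) and ~29 k faces (end-to-end recoveries, resolution 0.12 mm); a full
evaluation of a 29 k-face pair takes about two seconds. Other fixed choices:
vertex merge tolerance 1e-6 mm at load (STL duplicates vertices per facet);
Dijkstra weights floored at 1e-12 so fold-back edges cannot create
zero-weight cycles; hill-climb bounded at 20 hops with lowest-index
tie-breaks; ICP stops at 1e-6 mm RMS improvement or 100 iterations and warns
(never silently) when the residual stays above 1 mm; BVH ray casts accept
t ≥ 0 so a boundary ray starting on the surface reports the surface point
itself. Everything downstream of the seeded generator is deterministic, so
repeat evaluations are bit-identical — the automated analogue of perfect
intra-rater agreement.

## Known limitations

Margin-quality attributes (chipping, smoothness, marginal integrity) are out
of scope — they are not measurable from these meshes at this resolution. The
azimuthal quadrant split assumes a roughly convex, single-axis crown; teeth
with extreme rotations would need a per-tooth mesial direction. The anchor
seeds fix the azimuth origin arbitrarily, so under a rigid transform of both
meshes the recovered margin loop is the same crease ring but may differ in a
few junction vertices near the anchors. Finally, ε must be chosen below the
local anatomical divergence scale; a preparation whose margin lies in an
area where the tooth was barely reduced (< ε) would not be detected there.
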