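---
title: "From stem micrograph to cell-wall beam model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stem micrograph to cell-wall beam model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellwallfem)
```

## The problem

Stalk lodging — the structural failure of crop stems under wind or load —
begins at the cellular scale: parenchyma tissue is a cellular solid whose
stiffness and failure are governed by the geometry and material of its cell
walls. `cellwallfem` digitizes stained brightfield cross-section micrographs
of plant stems into two-dimensional beam-network finite element models, so
that tissue stiffness, wall stress and microstructural phenotypes (cell
counts, sizes) can be computed from an ordinary microscope image.

The chain is: preprocess the micrograph, segment the dark cell walls from
the bright interiors, identify cell interiors and re-derive clean wall
center-lines by Voronoi tessellation, digitize the wall network into a
graph, mesh it with 2-node shear-flexible beams, and run a virtual tension
test plus a parametric sensitivity study.

## Preprocessing

Four deterministic raster operations mirror the usual interactive cleanup:

* `to_8bit()` — linear map of the observed range onto [0, 255] with
  rounding; constant images map to 0.
* `sharpen()` — the 3×3 kernel with center 12, neighbors −1, divisor 4.
* `rescale_contrast()` — windowing with defaults (−10, 127). Real
  micrographs need per-image windows (stain uptake varies); the defaults
  suit dark-wall/bright-interior Safranin-type staining and both endpoints
  are plain parameters.
* `despeckle()` — a 3×3 median filter, by default applied three times, to
  remove sectioning debris.

All 3×3 filters replicate edge pixels at the borders. This is the simplest
deterministic policy and differs from alternatives only in a 1-pixel rim.
RGB input is converted to grayscale by the unweighted channel mean.

## Segmentation

Two interchangeable routes produce a binary wall mask:

* **Band thresholding**: wall iff `lo <= I <= hi`, bounds inclusive
  (defaults 0 and 175 on the 8-bit scale). Cleanup is automated rather than
  manual: 8-connected wall specks below `min_speck_area` are deleted and
  enclosed 4-connected background holes below `max_hole_area` are filled.
  The 8/4 connectivity split is the standard digital-topology duality —
  using the same connectivity for both foreground and background creates
  paradoxes at diagonal crossings.
* **Trainable pixel classifier**: a random forest on a small, documented
  feature bank — raw intensity plus Gaussian-smoothed intensity and
  gradient magnitude at σ ∈ {1, 2, 4} px — trained from user scribbles
  (label 1 = wall, 2 = interior). Training is seeded and prediction ties
  break toward the wall class, so results are reproducible. The feature
  bank is intentionally small; parity with any particular interactive
  toolbox is a non-goal.

`edm()` computes the **exact** Euclidean distance of each wall pixel to the
nearest background pixel (two-pass exact algorithm on squared integer
distances, so there is no chamfer approximation error and distance ties are
decided exactly). The image border deliberately does *not* count as
background: otherwise walls running into the crop edge would be thinned
away artificially. `thin_walls()` then keeps wall pixels with distance at
least `thin_keep_min` — the "as thin as possible without merging cells"
binarization. The right value depends on the rendered wall width: for walls
of width w px, any value in (0, w/2] preserves separation; 1 px is a safe
default for clean, well-stained images and is what the package's own
end-to-end tests use on 3-px-wide rendered walls.

## Tessellation

* `interior_labels()` — 4-connected components of non-wall pixels, numbered
  in raster order; border-touching cells are flagged (partially imaged
  cells are kept, but their measurements are unreliable, so every
  downstream table carries the flag).
* `ueps()` — ultimate eroded points: regional maxima of each cell's
  interior distance map. Plateaus are iso-level components expanded across
  equal values; a plateau adjacent to any higher pixel is a ridge, not a
  maximum, which matters for dumbbell-shaped cells where a naive local test
  would place a spurious seed on the neck.
* `voronoi_partition()` — every pixel goes to the particle (cell interior)
  whose nearest *pixel* is closest, with ties to the smaller label. Growing
  whole particles rather than point seeds reproduces distance-map-based
  Voronoi of irregular cells; the UEPs are still computed for seed export
  and diagnostics.
* `boundary_skeleton()` — a pixel is a boundary candidate iff its
  8-neighborhood contains a larger label (so each boundary is carried by
  the smaller-label side, exactly once), thinned to unit width by
  Zhang–Suen thinning. Pixels on the image frame are protected during
  thinning: a 2-px-wide line end touching the frame would otherwise be
  retracted, opening a false passage between two border cells.
* `wall_graph()` — junction pixels are skeleton pixels with ≥ 3 skeleton
  neighbors *after* discarding redundant diagonal links (a diagonal link is
  a stair-step shortcut when its two pixels share an orthogonal skeleton
  neighbor — without this rule every staircase pixel looks like a
  junction). Junction clusters merge to one vertex at their centroid, path
  endpoints become vertices, maximal paths become walls, and polylines are
  simplified by Douglas–Peucker at 0.75 px — small enough to stay within
  the skeleton's own quantization, large enough to drop collinear chains.
* `prune_spurs()` — iteratively removes walls with a degree-1 endpoint
  shorter than `max_len` (default 5 μm) and dissolves the degree-2 joints
  that deletion leaves behind. This automates the manual deletion of small
  triangular artifacts that Voronoi extraction occasionally hangs off a
  wall.

On synthetic honeycombs the extracted center-lines track the true walls to
within about 1.5 px away from junctions; junction vertices themselves land
within about 2 px of the true vertices (the Voronoi junction of three
finite-width interiors is not exactly the geometric wall vertex). Voronoi
boundaries of border cells extend to the image frame; they are genuine
equidistance curves but have no counterpart wall in the tissue, which is
one more reason border cells are flagged.

## Morphometrics

`cell_areas()` reports pixel and physical areas (`area_um2 = area_px ·
scale²`), centroids and the border flag; `size_histogram()` uses
equal-width bins (default 10) normalized to the number of cells;
`color_by_size()` maps area **rank** (ties share a rank) onto a blue→red
ramp — rank rather than value, so one giant cell cannot compress all others
into a single color.

## The finite element model

Walls are meshed with 2-node Timoshenko (shear-flexible) beams — the 2D,
3-DOF-per-node element class that commercial codes call B21 — at a seed
size of 1 μm, subdividing each wall polyline into `ceil(length/seed)`
equal-length elements; junction vertices are shared nodes, so walls are
rigidly connected there. Halving the seed changes the honeycomb stiffness
by well under 0.5%, i.e. the discretization is converged at 1 μm.

Sections are rectangles of in-plane thickness t (default 4.3 μm, the
rounded mean of published maize wall measurements 3.7, 6.8, 2.0 and
4.6 μm) and out-of-plane depth 1 μm under the plane-stress idealization:
A = t·d, I = d·t³/12, shear area κA with κ = 5/6. All stiffnesses are per
unit depth. Units are consistent throughout: lengths in μm, E in force/μm²;
the default E = 1, ν = 0.3 is deliberate — normalized sensitivities are
scale-free, and no absolute wall modulus is assumed.

Two boundary-condition presets implement the virtual tension tests, with
nodes picked in coordinate bands of half a seed size at the mesh extremes:

* `right_stretch` (the sensitivity-study configuration, and the default):
  left edge fixed in x, its lowest node also fixed in y, right edge
  displaced +1 μm in x.
* `top_stretch`: bottom fixed in y, left and right edges fixed in x, top
  displaced +1 μm in y.

Rotations are never constrained. The solution is linear and
small-displacement: a 1 μm stretch on a several-hundred-μm specimen
produces strains of order 10⁻³, where geometric nonlinearity is a
second-order effect — consistent with the observed unit modulus
sensitivity of such models. The assembled system is solved by sparse
Cholesky with one step of iterative refinement; slender-wall networks are
ill-conditioned (bending terms scale as (t/l)³) and the refinement step
recovers reaction sums accurate to ~10⁻¹⁰ relative, which is what makes
the "modulus sensitivity = 1 within 10⁻⁹" check meaningful.

Structural stiffness is K = (Σ reactions on the driven nodes, along the
stretch direction)/stretch. Stress recovery per element takes the maximum
over both ends and both extreme fibers of
σ = |N|/A + |M|(t/2)/I, combined with transverse shear τ = |V|/(κA) as
σ_vm = √(σ² + 3τ²). `export_inp()` writes the complete model as a keyword
INP file (nodes, B21 elements, one rectangular beam section per distinct
thickness, elastic material, one static step with the boundary lines);
`read_inp()` parses it back, and the writer is byte-stable.

## Sensitivity study

`normalized_sensitivity()` multiplies the chosen parameter — wall modulus
or wall thickness, uniformly across all walls — by 1 + δ (default +5%),
re-solves, and reports S = ((K⁺ − K)/K)/δ, a one-sided forward difference
about the baseline. Forward rather than central differencing is the
procedure being modeled, and at δ = 0.05 it slightly exceeds the true
log-derivative for a super-linear response: a pure-cubic structure gives
((1.05³ − 1)/0.05) = 3.1525 rather than 3. Exact bounds:

* modulus: S ≡ 1 for every geometry (the solver is linear in E);
* thickness: S ∈ (1, 3.1525], from the axial limit (K ∝ A ∝ t) to the
  bending limit (K ∝ I ∝ t³).

Honeycomb tissue at realistic slenderness (t/l ≈ 0.07) is
bending-dominated with a small axial/shear share, landing near 3.07 — i.e.
a 5% thickness increase stiffens the tissue by ~15%, against ~5% for a 5%
modulus increase. The same ordering is what makes wall thickness the more
attractive breeding target for lodging resistance.

## Synthetic fixtures and what passing tests mean

`honeycomb_graph()` builds a rows×cols tiling of regular, pointy-top
hexagons (two vertical walls per cell) with edge length l (default 60 μm)
and optional seeded vertex jitter for irregular-tissue variants. The
default l puts t/l ≈ 0.07, the regime of maize parenchyma micrographs;
l itself is a fixture parameter, not a measured quantity.
`render_image()` rasterizes it as a brightfield-like image — dark walls
(intensity 40) of finite width on bright interiors (200), with optional
Gaussian noise and speckle, all bit-reproducible under a seed. The frame
outside the tiling is rendered at wall intensity so the ground-truth cells
are exactly the bright regions.

The renderer emulates contrast, wall width, sensor noise and debris
speckle. It does **not** emulate torn or overlapping cells, uneven stain
uptake, vignetting, wall-thickness variation along a wall, or strongly
rounded cell morphologies — passing the end-to-end tests therefore
demonstrates the machinery is correct on clean polygonal tissue, not that
segmentation parameters transfer to any particular real micrograph (they
are per-image parameters by design). Voronoi center-line extraction is
intrinsically limited to straight or mildly curved walls.

`gibson_ashby_modulus()` provides the independent closed form
E* = (4/√3)·E_s·(t/l)³ for the regular honeycomb. The beam solver's
homogenized modulus (K·W/(H·depth) from the right-stretch test) agrees
within 10% at t/l ≤ 0.05 on a 6×6 block and converges toward the closed
form as t/l decreases, as it must: the closed form keeps only the bending
compliance, the finite model also carries axial and shear terms plus free
edges.

## Problem sizes and numerical choices

The canonical analysis fixture is the 6×6 honeycomb with l = 60 μm and
t = 4.3 μm — 131 walls, ≈ 7 900 beam elements, ≈ 23 700 DOF — solved in a
few seconds. Pipeline-level tests run on 3×4 to 4×5 tilings with l = 20 μm
rendered at 2 px/μm. Distance transforms are exact in squared-integer
arithmetic (a finite sentinel replaces infinities, keeping every
comparison exact); Voronoi ties go to the smaller label by an ascending
strict-improvement sweep; degenerate color ranges (uniform stress, equal
areas) render as the blue endpoint; an all-wall mask, an empty scribble
class, a window with min ≥ max, and meshes with under 3 constrained DOFs
all raise immediate errors rather than propagating nonsense.

## Known limitations

Two-dimensional plane-stress idealization with hollow cells (no turgor,
no interior material); uniform thickness along each wall; linear elasticity
only; polyline (not spline) wall geometry; JPEG input is not supported
(use PNG or TIFF). Border cells are retained but flagged, and their
mechanics are least reliable, exactly as their measurements are.
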