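---
title: "Digitizing binary phase diagrams into probabilistic phase-state tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing binary phase diagrams into probabilistic phase-state tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedig)
```

## The problem

The equilibrium behavior of a binary surfactant-water mixture is summarized
by its phase diagram: a map from temperature (°C) and composition
(wt% surfactant; 0 is pure water, 100 pure surfactant) to a phase state.
States are either a single phase -- the micellar solution `L1`, mesophases
such as hexagonal `H1` or lamellar `La`, solid hydrates `X1`, `X2`, ... --
or a two-phase coexistence region written as the two states joined by
`"+"` in alphabetical order (the "cloud" region `L1+W`, narrow biphasic
gaps such as `H1+La`, and so on). Published diagrams exist almost entirely
as figures, so building a machine-readable corpus means digitizing raster
images.

`phasedig` implements that digitization workflow end to end: a raster
image of an enclosed diagram comes in; a gridded table of phase-state
*probabilities* comes out, serialized in the PhDat JSON record dialect.
The probabilistic representation is the scientific heart of the package:
instead of forcing each grid point into one state, each point receives a
normalized probability over all states, which absorbs drawing and scanning
imprecision near boundaries and represents narrow two-phase gaps honestly.

## The pipeline

1. **Binarize** (`binarize()`): a pixel is boundary ("black", 1) when its
   darkness `1 - intensity` reaches a threshold (default 0.5; scans vary,
   so it is configurable).
2. **Find and rectify the frame** (`find_plot_frame()`, `rectify()`): the
   diagram must be fully enclosed; the largest closed contour by filled
   area is the plot frame. Its four-corner hull is mapped to a rectangle
   by a projective transform, straightening sheared book scans. For
   binary images the warp uses supersampled nearest-neighbor resampling
   (max over four sub-pixel samples) so one-pixel boundary lines cannot
   drop pixels and leak a region; the frame border is redrawn after
   warping because the crop boundary *is* the frame.
3. **Repair** (`apply_edits()`): published diagrams often need manual
   edits expressed as data, not clicks: draw or erase a `segment`,
   insert a horizontal `isotherm` at a eutectic/peritectic temperature
   (in data coordinates, via the axis calibration), or `extend` an open
   boundary along its local slope (least-squares direction of the last
   five line pixels) until it meets another line or the frame. Dashed-line
   conversion is deliberately manual: dash detection is unreliable on
   old scans, so dashes are either erased as nuisance components or
   redrawn solid with a `segment` edit.
4. **Clean** (`keep_largest()`): text, arrows and tick labels are
   connected components detached from the frame-plus-boundaries
   structure; keeping only the `n` largest components (usually `n = 1`)
   removes them. Ranking is by pixel count with raster-order tie-breaks
   so results are reproducible.
5. **Thin** (`thin()`): boundary lines are reduced toward one-pixel
   width by removing pixels in order of their adjacency to white pixels.
   A pixel is removed only if (a) all its white 4-neighbors already
   belong to one region -- so the number of regions is exactly invariant,
   which is the property everything downstream depends on -- and (b) its
   black 8-neighbors form a single contiguous run, so thin lines are
   never broken locally (line interiors, corners and junctions survive;
   solid blobs still erode). The operation is idempotent. Ties in the
   removal order are broken in raster order, making thinning fully
   deterministic.
6. **Label** (`label_regions()`): white regions are 4-connected, lines
   8-connected. This asymmetric ("digital topology") choice prevents a
   region from tunneling diagonally through a line. Labels 1..n are
   assigned in raster order; the image edge counts as a closed wall.
7. **Sample** (`sample_grid()`): a regular lattice (default 1 °C by
   1 wt%, both endpoints inclusive -- a full 0-100 × 0-100 diagram gives
   101 × 101 = 10201 points) is laid over the calibrated ranges. Each
   lattice point maps to a test pixel (half-way values round toward the
   larger pixel index), the minimum distance `d_i` to each region's
   pixels is computed, and probabilities follow the exponential kernel

   `P_i = exp(-d_i / 2)`,

   with raw values below `1e-3` set to zero and the rest normalized to
   sum to one. A point inside region `i` has `d_i = 0` and keeps
   probability 1 unless another region is within the cutoff distance
   `-2 log(1e-3) ≈ 13.8` data units; a point on a boundary pixel is
   equidistant from the two adjacent regions and gets exactly 0.5 each.
8. **Record** (`phdat_record()`, `write_phdat()`): the curated
   region-to-state mapping (always a human decision -- region numbers
   carry no meaning) names the columns, probabilities are stored as
   percentages, and the record carries compound metadata (SMILES, name,
   source, figure, measurement-method letters A-F, ionic type, diagram
   completeness).

`run_pipeline()` chains all stages from a flat JSON config and is what
the `phasedig` command-line script wraps.

## Distances: units, exactness, log axes

Distances are measured in *data units*, treating a 1 °C step and a
1 wt% step as equal length: pixel offsets are converted through the axis
calibration before the Euclidean combination, so results are independent
of scan resolution. The kernel length scale (the `/2` in the exponent)
is likewise in data units. Alternative axis weightings are exposed via
the `weights` argument of the samplers but none are implemented beyond
the hook.

The distance transform is exact, not a chamfer approximation: per region
and column the nearest source row is found, then columns are scanned
outward with an early break. The returned minimum equals a brute-force
scan over all labeled pixels bit for bit (the test suite asserts exact
equality over randomized labelings and anisotropic scales), so there is
no hidden numerical fuzz under the kernel.

For logarithmic axes, pixel-to-data mapping goes through `log10`, but
the per-pixel distance scale is taken as the mean rate over the
calibrated span; distances on log axes are therefore approximate. The
published corpus is linear-axis, and the choice is isolated in one
internal function (`axis_scales()`) should a local-rate variant ever be
needed.

## Curve tracing

Where automatic cleaning is not enough, individual boundary curves are
reconstructed from ordered guide points (`trace_curve()`). Points snap
to the nearest black pixel (raster-order tie-break); near the image
border, a snapped pixel with an 8-connected neighbor on the frame snaps
onto the frame itself (margin: 2 px -- "near" is otherwise unquantified),
so curves that run into the frame seal against it. Consecutive points in
the same 8-connected line component are joined by a fewest-steps
4-connected path through that component only (white pixels are walls);
any fewest-steps path is acceptable, and the breadth-first expansion
order up, down, left, right makes the returned one deterministic. Points
in different components are joined by a straight 8-connected segment.
Because a same-component path can only traverse component pixels, every
traced piece is a subset of the original curve.

## The synthetic generator and what passing tests mean

Real source diagrams are copyrighted, so the package carries a generator
(`diagram_spec()`, `random_diagram_spec()`, `generate_diagram()`) whose
output is fully known: labeled convex polygonal regions tiling the axis
rectangle (a left-to-right sequence of 2-6 phase bands with slanted
straight boundaries, optionally one band split by a horizontal isotherm,
emulating eutectic/peritectic constructions), rasterized at a chosen
resolution with a rectangular frame. Boundaries are drawn as 4-connected
supercover strokes -- scanned pen strokes are contiguous, and the
4-connected maze tracer must be able to walk them -- and each shared edge
is drawn in a canonical endpoint order because integer line rasterization
is direction-asymmetric (drawing a shared edge from both polygons would
otherwise thicken it). Nuisance annotations (text-like blobs, detached
dashed segments, frame ticks) are placed only where they do not touch
the structural drawing, which is exactly the situation `keep_largest()`
is designed for. A seed fixes everything.

The companion oracle (`oracle_distances()`, `oracle_probabilities()`)
computes exact point-to-polygon distances in vector geometry -- fully
independent of the raster code paths -- and pushes them through the same
kernel. Agreement between pipeline and oracle is limited by
rasterization: along a boundary edge the raster distance overshoots the
vector distance by at most about 1.5 px (half a pixel of line placement
plus the one-pixel inset of region labels behind the line, which is
inherent to measuring distances to *labeled* pixels). Where two
one-pixel lines meet at a right angle -- isotherm junctions, frame
corners -- the region's corner pixel is crowded out by both lines, and
the overshoot viewed diagonally grows to about `1.5 * sqrt(2) ≈ 2.2` px
(measured maximum 2.41 px over twenty seeded diagrams at 201 px per 100
data units). The package's regression test therefore asserts probability
agreement within a 2.5 px distance perturbation; a tighter 1.5 px check
holds away from such corners but not uniformly, and no implementation
that measures distances to labeled pixels behind one-pixel lines can do
better at corners.

What the synthetic fixtures do *not* emulate: gray-scale scan artifacts
(fold shading, moiré), curved band boundaries, real text glyphs, or
dashed boundary lines that must become solid. Passing tests demonstrate
the geometry, topology, kernel and format machinery are correct; they do
not certify binarization thresholds or manual-edit choices on any
particular real scan.

## The vocabulary and its one flagged cell

The packaged controlled vocabulary (`phase_vocabulary()`) carries the
single-phase labels with descriptions and literature aliases (alias
resolution is case-, subscript- and punctuation-insensitive, and maps
the historical lamellar synonyms `D` and `G` to `La`), plus the
canonical ordered list of 118 observed phase states. The list was
recovered from a run-together rendering of the published state table by
longest-match tokenization; five trailing cells are exact duplicates of
earlier cells and were dropped, and one ambiguous run-together cell
(`"V2iV2p+X1"`) is retained as printed with its first token flagged as a
provisional label, reconciling the count to the published total. The
file records this in its `provenance` field; `--vocab`/`file =` lets a
future revision replace the packaged list wholesale. The reserved label
`U` (unknown region of an incomplete diagram) is valid in records but
excluded from the canonical list. `X1`-`X6`, `Xa`, `Xb` are opaque
distinct solid labels; no hydration-state semantics are modeled.

## Records, validation, querying

PhDat JSON is a top-level object keyed by record index; each record is a
dictionary of metadata plus columnar `keys`/`values` data, probabilities
as percentages, compositions in wt%. The reader also accepts a list form
with explicit `index` fields and collects malformed records into an
error report instead of aborting. Numbers are written at full precision
(Table-style `0.33` rounding is treated as presentation, not storage),
which makes write → read → write byte-identical -- asserted in the test
suite. `validate_phdat()` checks normalization (default tolerance 0.1
percentage points per row), composition ranges, vocabulary-valid state
columns, the rule that only incomplete diagrams may carry a `U` column,
and metadata fields. `query_phdat()` filters records by SMILES, ionic
type or completeness (SMILES are stored verbatim and are *not* unique
across records); `phdat_points()` filters points by temperature or
composition range and can drop points with non-zero unknown-state
probability. `state_frequencies()` tallies, per state, the number of
grid points with non-zero probability and the number of diagrams
containing the state, flagging (not deleting) states under a reporting
floor (default 1% of all points).

## Worked example

```{r example}
spec <- diagram_spec(
  list(list(state = "L1",
            polygon = rbind(c(0, 0), c(0, 50), c(100, 50), c(100, 0))),
       list(state = "L1+W",
            polygon = rbind(c(0, 50), c(0, 100), c(100, 100), c(100, 50)))),
  resolution = c(101, 101), seed = 1)
g <- generate_diagram(spec)
labeled <- label_regions(thin(g$mask))
attr(labeled, "n")

tab <- sample_grid(labeled, g$truth$cal, states = g$truth$states)
nrow(tab)
tab[tab$temperature == 50 & tab$composition %in% c(40, 50, 60), ]
```

The boundary row shows the 0.5/0.5 split; the rows either side show the
kernel decaying with distance from the boundary.

## Numerical choices, determinism, limitations

* All tie-breaks (component ranking, thinning order, snapping, BFS
  expansion, categorical argmin) are fixed to raster order or a stated
  neighbor order; identical inputs and seeds give identical outputs,
  including bytes of written JSON.
* Grid endpoints are inclusive on both axes.
* `assign_probabilities()` raises an error rather than emit an
  unnormalizable all-zero row; inside an enclosed diagram this cannot
  happen (some region is always within the cutoff).
* Categorical sampling (`categorical_grid()`), used only for
  cross-validation against manually digitized grids, breaks exact
  distance ties toward the lowest region label.
* Problem sizes in the test suite -- labelings up to 34 px, mazes 60 px,
  twenty 201-px diagrams for the oracle comparison -- were chosen as the
  smallest sizes that exercise every geometric regime (multi-band,
  isotherm junctions, nuisance, shear); the machinery is routinely used
  at scan resolutions of several hundred pixels.
* Out of scope by design: OCR of axis numerals or in-figure labels,
  automatic dash detection, automatic region-to-state assignment (the
  mapping is curated input), thermodynamic consistency checking beyond
  the two-label arity rule, and any interactive GUI -- guide points and
  edits are files, which is what makes runs reproducible.
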