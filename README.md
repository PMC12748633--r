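# phasedig

Semi-automatic digitization of binary surfactant–water phase diagrams:
from a raster image of a published temperature–composition diagram to a
gridded, *probabilistic* phase-state table in the PhDat JSON record
dialect.

## Who this is for

Anyone building machine-readable phase-behavior data from figures:
formulators and phase scientists curating literature diagrams, and
ML practitioners who need soft labels over `(T, wt%)` grids rather than
brittle categorical assignments. Published diagrams exist as figures —
often decades-old book scans — so the workflow has to cope with skewed
frames, annotation clutter, dashed lines and open regions, while staying
reproducible (every manual intervention is a file, not a mouse click).

## The method

A cleaned, rectified diagram is a binary image in which 1-pixel black
lines (the phase boundaries plus the enclosing frame) partition white
regions; connected-component labeling gives regions `1..n`, and a
curated mapping names each region with a controlled-vocabulary phase
state (single phases like `L1`, `H1`, `La`, `X1`, or two-phase states
written alphabetically, e.g. `L1+W`, `H1+La`). A regular lattice —
1 °C × 1 wt% by convention, endpoints inclusive — is laid over the
calibrated axes, and each lattice point gets, for every region *i*, its
minimum distance *d<sub>i</sub>* in data units (1 °C ≡ 1 wt%) to that
region's pixels. Probabilities follow the exponential distance kernel

> *P<sub>i</sub>* = exp(−*d<sub>i</sub>* / 2),

with raw values below 10⁻³ zeroed (phases farther than
−2 ln 10⁻³ ≈ 13.8 data units contribute exactly nothing) and the rest
normalized to sum to one. A point inside a region keeps probability 1
until another region comes within the cutoff; a point on a boundary
pixel is equidistant from both neighbors and gets exactly 0.5/0.5. The
soft assignment absorbs drawing and scanning imprecision near
boundaries and represents narrow biphasic gaps honestly.

Around that core the package provides the full pipeline — binarization,
largest-closed-contour frame detection, projective rectification of
sheared scans, edit primitives (segments, eutectic/peritectic isotherms,
slope-following boundary extension), n-largest-component annotation
removal, region-count-preserving thinning, guide-point curve tracing by
fewest-steps maze search — plus PhDat record I/O with validation and
querying, dataset-level state-frequency summaries, and a synthetic
diagram generator with an exact vector-geometry oracle that makes every
stage testable without any external data.

## Worked example

Rasterize a two-region diagram (micellar solution left, cloud region
right, boundary at 50 wt%), segment it, and sample the probability grid:

```r
library(phasedig)

spec <- diagram_spec(
  list(list(state = "L1",
            polygon = rbind(c(0, 0), c(0, 50), c(100, 50), c(100, 0))),
       list(state = "L1+W",
            polygon = rbind(c(0, 50), c(0, 100), c(100, 100), c(100, 50)))),
  resolution = c(101, 101), seed = 1)
g <- generate_diagram(spec)

labeled <- label_regions(thin(g$mask))
attr(labeled, "n")
#> [1] 2

tab <- sample_grid(labeled, g$truth$cal, states = g$truth$states)
nrow(tab)
#> [1] 10201
tab[tab$temperature == 50 & tab$composition %in% c(40, 46, 50, 54, 60), ]
#>      temperature composition      L1    L1+W
#> 5091          50          40 0.99593 0.00407
#> 5097          50          46 0.92414 0.07586
#> 5101          50          50 0.50000 0.50000
#> 5105          50          54 0.07586 0.92414
#> 5111          50          60 0.00407 0.99593
```

The full 0–100 × 0–100 grid at unit spacing has 101 × 101 = 10201
points. On the boundary the two phases split 50/50; moving away, the
kernel decays until the far phase is cut off entirely. Wrap the table
and metadata into a validated record:

```r
rec <- phdat_record(tab, smiles = "CCCCCCCCCCCCOCCOCCO", state = "complete",
  name = "triethylene glycol monododecyl ether (synthetic demo)",
  source = "synthetic demonstration diagram", figure = "1",
  method = "A", type = "nonionic",
  labels = list(c("L_1", "L1"), c("L_1 + W", "L1+W")))
validate_phdat(rec)
#> [1] record  check   message
#> <0 rows> (or 0-length row.names)
write_phdat(setNames(list(rec), "1"), "record.json")
```

For real images, replace the generator with `read_diagram()` +
`binarize()` + `find_plot_frame()` + `rectify()` (+ `apply_edits()` /
`keep_largest()` / `trace_curve()` as needed), or drive everything from
one JSON config with `run_pipeline()`.

## Vocabulary and data

The packaged controlled vocabulary (`inst/extdata/phase_vocab.json`)
carries the single-phase labels, their literature aliases (`D`, `G` and
`L_α` all resolve to `La`), and the canonical list of 118 observed phase
states; its `provenance` field documents how the list was reconstructed,
including one ambiguous table cell retained as printed and flagged.
`inst/extdata/phdat_example.json` is a small synthetic example record
illustrating the PhDat layout. Both are plain JSON and replaceable —
`phase_vocabulary(file = ...)` and the CLI `--vocab` flag accept a
custom vocabulary.
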