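---
title: "Models and conventions behind celltracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind celltracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltracks)
```

`celltracks` analyses and renders the output of automatic cell trackers:
per-frame bounding-box detections with identities and parent links. This
vignette is the package's own account of the conventions it commits to —
the coordinate frame, the division-counting model, histogram binning,
partition and viewport semantics, the synthetic generator — and of the
places where a design was genuinely open and we had to choose.

## Coordinate frame

Trajectory rows are `time step, ID, left, top, height, width, img_height,
img_width, parent`. We interpret coordinates in a **Cartesian, y-up**
frame with the origin at the field's bottom-left: `left` is the box's
minimum x and `top` its *maximum y*, taking the input format's own
wording literally. The maths downstream (centers, direction vectors,
drift) stays conventional; only the renderers flip y for screen output,
inside `field_to_screen()`. Pixel masks convert via
`x = col + 0.5`, `y = img_height − (row + 0.5)` for 0-based pixel
indices, which makes a label occupying pixel rows `r0..r1`, columns
`c0..c1` correspond to the box `left = c0`, `top = img_height − r0`,
`width = c1 − c0 + 1`, `height = r1 − r0 + 1`. The Cell Tracking
Challenge importer shifts that benchmark's 0-based frames to our 1-based
time steps (`t = t_ctc + 1`) and maps parent label 0 to "no parent".

Two validation regimes exist because real trackers overshoot the field
boundary by a pixel or two: strict (default, out-of-field boxes are
errors) and lenient (boxes are clamped with a warning). `img_height` and
`img_width` must be constant within one file — they define the field.
Time steps of one track need not be consecutive; a gap simply means the
cell was not detected, and no direction vector is emitted across it.

## Tracks, lineage, families

Observations group by id into tracks; a track's parent id must be
constant across its rows. The parent relation induces a forest; building
it checks acyclicity and that every referenced parent exists. A child
must be born strictly after its parent's birth (error otherwise), but a
child born while the parent is still observed is only a warning — the
format does not promise that a dividing parent vanishes, so we tolerate
tracker quirks while flagging them. `validate_dataset()` reports *all*
violations at once rather than stopping at the first, because a tracker
bug typically produces hundreds of identical problems.

A **clonal family** is the connected component of the forest: ascend
from the queried track to its root, then take the root and every
descendant. We deliberately return the whole tree rather than only the
sub-tree below the queried cell, since clonal-origin analysis (compare
migration or proliferation by founding cell) needs the complete clone;
`family_of()` is therefore an equivalence-class map, and the test suite
checks it against a brute-force transitive closure.

## Per-step statistics

The statistic table layout is `time step` plus named numeric columns.
When deriving statistics ourselves we count, per step t:

- `n_cells(t)`: tracks observed at t;
- `n_mitosis(t)`: *division events* — distinct parents with at least one
  daughter born at t. Counting events (not daughters) is the only
  convention consistent with the canonical worked example shipped in
  `inst/extdata/table1_stats.csv`, where 3 cells become 5 through 2
  mitoses and 0 appearances;
- `n_appearance(t)`: parentless tracks born at t. The initial population
  counts as appearing at t = 1 (again forced by the worked example:
  3 cells, 3 appearances in row 1);
- `n_disappearance(t)`: tracks ending at t−1 with no daughter at t, so a
  parent that divides is not also counted as disappearing.

Under two-daughter divisions these satisfy
`n_cells(t) − n_cells(t−1) = n_appearance(t) + n_mitosis(t) − n_disappearance(t)`,
asserted on synthetic data. Columns we did not derive (e.g. a tracker's
own error measure) are passed through verbatim and never recomputed —
their semantics belong to the tracker.

## Direction vectors and histograms

A direction vector is the displacement of a track's box center from step
t to t+1; tracks not observed at both steps contribute nothing, and
vectors are never formed across detection gaps ("next location" means
next frame). Histograms bin the *signed components* (Δx for the
horizontal histogram, Δy for the vertical one) rather than angles: the
directional readout of interest — e.g. "more vertical movement toward
positive values" in a stiffness gradient — lives on a signed axis. An
angle mode (`atan2`, 16 bins over [−π, π]) exists for heading analysis
but is not the default.

Default bin spec: 21 bins, symmetric about zero, spanning the largest
absolute component of the input vectors, recomputed per call; values
outside the edges clamp into the end bins so the counts always sum to
the number of vectors. Bins are `[e_i, e_{i+1})` with the last bin
closed. Regional histograms always reuse the global pair's edges so the
two read on the same axis.

## Space partitioning

Split mode is modelled as a **binary split tree**: each horizontal or
vertical line splits one current zone (a leaf) into two children that
tile it exactly, merging removes one line bottom-up, and at most one
leaf is selected. We chose tree semantics (a line spans only the chosen
zone, not the whole field) because merging "two sections" is only
well-defined with a tree; full-span lines would create a grid with no
canonical merge. Membership of a cell in a zone uses half-open intervals
`[x0, x1) × [y0, y1)` on box centers, with the field's own right/top
edge closed so a cell sitting exactly on the outer boundary still
belongs to a zone — ties are deterministic and zones partition the
cells. A vector belongs to the zone containing its *start* position
(motion leaving that region). Partitions persist across analyses and
serialize to a small JSON document.

## Viewport

The viewport keeps the visible sub-rectangle of the field plus the
output size; its aspect ratio always matches the output's. Zoom scales
the rectangle by 1/factor about an anchor and then *slides* the
rectangle back inside the field rather than reshaping it, matching
common map-widget behaviour; pan translates and clamps. One wheel notch
corresponds to ×1.25 in the interactive idiom. `field_to_screen()` is
the affine map of the visible rectangle onto the output with the y flip;
zoom/pan about interior anchors invert exactly and the suite checks the
round trip at 1e−9.

## Rendering

Rendering is **vector-first**: every view is emitted as a deterministic
SVG document (fixed number formatting, fixed element order), so
identical inputs yield byte-identical files, element counts are
testable contracts (solid circles = cells alive at the cursor, dotted
circles = disappeared cells, one polyline per visible statistic column),
and zooming never degrades quality. Rasterization is left to external
tools. Family colour is a pure function of the lineage root id (a fixed
20-colour qualitative palette, cycled), so colours are stable across
runs; highlighted families are drawn red on top. Cell labels read
`id(birth)`. Dash patterns for "disappeared" styling and the arrowhead
threshold (heads drawn only when a vector is longer than the point
radius) are configuration constants. The lineage layout gives leaves
consecutive integer rows in depth-first order (trees by root birth time
then id, children by birth time then id) and places each parent at the
mean of its children's rows. Animation export composes trajectory,
lineage and statistic panels side by side (2:1:1 area split) into one
SVG per time step, named `frame_0001.svg` onward.

## The synthetic generator

`simulate_cells()` emulates a time-lapse migration assay on a
1000 × 1000 px field: cells do Gaussian random walks (`step_sigma`, default
5 px/step) plus an optional position-dependent drift, **reflected** at
the field boundary; per cell-step they divide with `division_prob`
(default 0.01; the parent ends, two daughters start one box-size apart),
else disappear with `disappearance_prob` (default 0.005); and
Poisson(`appearance_rate`, default 0.2) new parentless cells enter per
step at uniform positions. Defaults (25 initial cells, 50 steps, 20 px
boxes) describe a moderately busy 2D assay. Everything is reproducible
from one seed, and the generator emits a ground-truth event log — the
oracle the statistics derivation is tested against — plus every input
format the package reads (trajectory CSV, statistic CSV, background PNG
frames, CTC track file + 16-bit TIFF masks).

Reflection (not absorption) at the walls keeps disappearance governed
solely by `disappearance_prob`, so population statistics stay
interpretable. Per-step events resolve in a fixed order — divisions,
disappearances, motion, appearances, over cells in ascending id — which
makes the event log unambiguous and the whole run a deterministic
function of the seed. Mask rasterization snaps box edges to the integer
pixel grid (warning when that moves an edge): masks cannot represent
fractional boxes, so the exact rasterize→import round trip is stated,
and tested, for pixel-aligned datasets.

What the generator does *not* emulate: cell morphology and texture,
detection noise and identity switches, photobleaching, crowding
interactions. Passing tests therefore demonstrate correctness of the
bookkeeping and statistics on clean tracks, not robustness to tracker
errors on real microscopy.

## The durotaxis scenario

`durotaxis_scenario()` models directed migration toward stiffer
substrate as a constant drift `bias` applied only inside a stiff region.
The study conditions used by the checks place the stiff region as a
**mid-field horizontal band (y ∈ [350, 650], full width)** with upward
bias `2·step_sigma` (10 px/step at the default σ = 5): cells drift up
through the band and leave it long before any of them can reach the
reflecting top wall, so in-region vectors are clean draws from
N(bias, σ) and the sample mean recovers the drift within the CLT bound
`4σ/√n`. A band flush against the wall would mix reflected steps into
the regional statistics and bias the mean low — a property of the
reflecting-walls model, not of the measurement. The scenario runs 500
cells for 21 steps (10 000 vectors, ≈ 2 200 of them in-region); the
zero-drift control (200 cells, 51 steps, 10 000 vectors) passes the
mean-zero check and recovers σ within 10%. The regional vertical
histogram's mode sits on the positive side while the global one stays
near-centred — the qualitative stiffness-gradient signature.

## Problem sizes and numerical choices

The oracle suites run 100 random pedigrees (20–200 tracks) against
brute-force family closure, 20 rasterized fixtures against brute-force
pixel bounding boxes, and 20 random edge specs against per-value linear
binning; conservation checks cover 50 random datasets × partitions.
These sizes give dense coverage while keeping the default check run
fast. Ties and tolerances: boundary cells go to the upper/right zone
(half-open intervals); histogram values on an interior edge go to the
upper bin; children order by (birth time, id); viewport round trips are
asserted at 1e−9; all other integer contracts are exact.

## Known limitations

- No gap-closing, re-linking or correction of tracker output — the
  package visualizes and summarises what the tracker produced.
- 2D only; a multi-page TIFF is treated as a per-slice 2D sequence.
- SVG is the only render target; rasterization (PNG/GIF) is delegated
  to external converters.
- Interactive behaviours (hover, drag-select) are exposed as library
  operations and CLI subcommands, not as a running GUI.
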