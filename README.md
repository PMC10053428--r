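# celltracks

Automatic cell trackers output large tables of per-frame detections with
identities and parent links, but interpreting them — who divided when,
which clone went where, whether motion is directionally biased — needs
dedicated tooling. `celltracks` is an R toolkit for exactly that: it
imports tracker output, assembles it into tracks and a cell lineage
forest, computes per-step motion and population statistics, partitions
the imaging field into zones for per-region analysis, and renders the
three classic coordinated views (trajectories, lineage trees, statistics)
as deterministic SVG documents and animation frame sequences. A seeded
synthetic-data generator with a ground-truth event log makes the whole
pipeline testable without microscopy data.

## Data model

The central input is a 9-column trajectory-with-lineage CSV in the
multiple-object-tracking box style:

```
time step, ID, left, top, height, width, img_height, img_width, parent
```

one row per cell per frame, `-1` in the last column meaning "no recorded
parent". Coordinates live in a Cartesian frame (x right, y up, origin at
the field's bottom-left; `top` is the box's maximum y). The Cell Tracking
Challenge result convention — a text file of `label begin end parent`
records plus per-frame 16-bit labelled masks — is imported through
`import_ctc()`. Optional inputs are a per-time-step statistic CSV
(`time step, stat 1, stat 2, ...`) and a background image sequence
(JPEG/PNG/BMP/GIF/TIFF).

Derived per step t from the assembled dataset:

- cell count n(t) — tracks observed at t;
- mitoses m(t) — distinct parents with a daughter born at t (a division
  is one event, two daughters, parent track ends);
- appearances a(t) — parentless tracks born at t (the initial population
  appears at t = 1);
- disappearances d(t) — tracks ending at t−1 without daughters at t;

which obey n(t) − n(t−1) = a(t) + m(t) − d(t). Direction vectors are
next-frame box-center displacements (Δx, Δy); their signed-component
histograms, global and per selected zone, are the durotaxis readout.

## Worked example

```r
library(celltracks)

sim <- simulate_cells(synth_config(seed = 3, n_steps = 20,
                                   n_initial_cells = 10))
sim$dataset
#> <tracking_dataset> 18 tracks, 249 observations, steps 1..20, field 1000 x 1000

derive_statistics(sim$dataset)[1:3, ]
#> # A tibble: 3 x 5
#>   time_step n_cells n_mitosis n_appearance n_disappearance
#>       <int>   <int>     <int>        <int>           <int>
#> 1         1      10         0           10               0
#> 2         2      10         0            0               0
#> 3         3      11         0            1               0
```

Ten cells seeded at step 1 (so 10 "appearances" in the first row), a new
cell entering the field at step 3; divisions and disappearances would
show up in the remaining columns. Zones and per-region motion:

```r
part <- split_region(new_partition(1000, 1000), 1L, "vertical", 500)
part <- select_region(part, 3L)          # right half
hs   <- regional_histograms(part, sim$dataset, t = 5)
sum(hs$global$horizontal$counts)         # all vectors at step 5
hs$regional                              # same bin edges, selected zone only
```

Rendering and animation (`frame_0001.svg`, one per time step, byte-stable
across re-runs):

```r
svg    <- render_trajectory_frame(sim$dataset,
            config = view_config(time_cursor = 5, cell_label = TRUE))
frames <- export_animation(sim$dataset, out_dir = "anim")
nrow(frames)
#> [1] 20
```

A shell entry point wrapping the same functions ships in `inst/cli/`:
`celltracks validate|convert-ctc|stats|render|animate|simulate|durotaxis-report`.

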