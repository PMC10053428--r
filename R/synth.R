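#' Configuration for the synthetic cell simulator
#'
#' The generator emulates a time-lapse of cells doing biased Gaussian
#' random walks on a rectangular field (default 1000 x 1000 px), with
#' divisions, disappearances and new cells entering the field, so that
#' every downstream operation can be exercised against a known
#' ground-truth event log. Defaults describe a moderately busy 2D
#' migration assay: tens of cells, displacement scale of a few px/frame,
#' and per-cell-step division/disappearance probabilities of order 1e-2.
#'
#' @param field_width,field_height field size in px.
#' @param n_steps number of time steps simulated.
#' @param n_initial_cells cells present at step 1.
#' @param step_sigma standard deviation of the per-step Gaussian
#'   displacement, px.
#' @param division_prob probability per cell-step that a cell divides
#'   (two daughters; the parent track ends).
#' @param disappearance_prob probability per cell-step that a
#'   non-dividing cell leaves the dataset.
#' @param appearance_rate Poisson mean of new parentless cells per step.
#' @param drift_field `NULL` for unbiased walks, or
#'   `function(x, y) c(dx_bias, dy_bias)` adding a position-dependent
#'   px/step drift.
#' @param cell_box_size side of the square bounding box around each
#'   center, px.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(field_width = 1000, field_height = 1000,
                         n_steps = 50L, n_initial_cells = 25L,
                         step_sigma = 5, division_prob = 0.01,
                         disappearance_prob = 0.005, appearance_rate = 0.2,
                         drift_field = NULL, cell_box_size = 20, seed = 1L) {
  stopifnot(
    field_width > 0, field_height > 0, n_steps >= 1, n_initial_cells >= 0,
    step_sigma >= 0, division_prob >= 0, division_prob <= 1,
    disappearance_prob >= 0, disappearance_prob <= 1,
    appearance_rate >= 0, cell_box_size > 0
  )
  structure(
    list(
      field_width = field_width, field_height = field_height,
      n_steps = as.integer(n_steps),
      n_initial_cells = as.integer(n_initial_cells),
      step_sigma = step_sigma, division_prob = division_prob,
      disappearance_prob = disappearance_prob,
      appearance_rate = appearance_rate, drift_field = drift_field,
      cell_box_size = cell_box_size, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

reflect_into <- function(x, lo, hi) {
  if (hi <= lo) {
    return(rep((lo + hi) / 2, length(x)))
  }
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate a synthetic cell-tracking dataset
#'
#' Runs the generative model of [synth_config()]. Per transition from
#' step t to t+1, in fixed order over cells (ascending id): a living cell
#' divides with `division_prob` (the parent ends at t; two daughters are
#' born at t+1, offset horizontally by one box size for separation), else
#' disappears with `disappearance_prob`, else moves by a Gaussian step
#' plus the local drift, reflected at the field boundary (so centers
#' never leave the field and disappearances are governed solely by the
#' configured probability). New parentless cells then appear at uniform
#' positions, `Poisson(appearance_rate)` of them per step. Boxes are
#' squares of `cell_box_size` centered on positions (clipped at the field
#' edge).
#'
#' @param config a `synth_config`.
#' @return list with `dataset` (a `tracking_dataset`), `events` (the
#'   ground-truth `event_log` tibble: `time_step`, `event` in
#'   birth/division/disappearance, `track_id`, `parent_id`), and `stats`
#'   (a `statistic_table` with `n_cells`, `n_mitosis`, `n_appearance`,
#'   `n_disappearance` computed from the event log).
#' @export
simulate_cells <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  half <- cfg$cell_box_size / 2
  xlo <- min(half, cfg$field_width / 2)
  xhi <- cfg$field_width - xlo
  ylo <- min(half, cfg$field_height / 2)
  yhi <- cfg$field_height - ylo
  next_id <- 1L
  new_cell <- function(x, y, parent, t) {
    id <- next_id
    next_id <<- next_id + 1L
    list(id = id, x = x, y = y, parent = parent, birth = t)
  }
  alive <- list()
  obs <- list()
  events <- list()
  log_event <- function(t, event, id, parent = NA_integer_) {
    events[[length(events) + 1L]] <<- tibble(
      time_step = as.integer(t), event = event, track_id = as.integer(id),
      parent_id = as.integer(parent)
    )
  }
  record <- function(cell, t) {
    obs[[length(obs) + 1L]] <<- tibble(
      time_step = as.integer(t), track_id = cell$id,
      x = cell$x, y = cell$y, parent = cell$parent
    )
  }
  for (i in seq_len(cfg$n_initial_cells)) {
    c0 <- new_cell(stats::runif(1, xlo, xhi), stats::runif(1, ylo, yhi),
                   NA_integer_, 1L)
    alive[[length(alive) + 1L]] <- c0
    log_event(1L, "birth", c0$id)
    record(c0, 1L)
  }
  if (cfg$n_steps > 1L) {
    for (t in seq_len(cfg$n_steps - 1L)) {
      # resolve in fixed order: divisions, disappearances, motion, appearances
      survivors <- list()
      for (cell in alive) {
        u <- stats::runif(1)
        if (u < cfg$division_prob) {
          dx <- min(cfg$cell_box_size, (xhi - xlo) / 2)
          d1 <- new_cell(reflect_into(cell$x - dx, xlo, xhi), cell$y,
                         cell$id, t + 1L)
          d2 <- new_cell(reflect_into(cell$x + dx, xlo, xhi), cell$y,
                         cell$id, t + 1L)
          log_event(t + 1L, "division", d1$id, cell$id)
          log_event(t + 1L, "division", d2$id, cell$id)
          record(d1, t + 1L)
          record(d2, t + 1L)
          survivors <- c(survivors, list(d1, d2))
        } else if (u < cfg$division_prob + cfg$disappearance_prob) {
          log_event(t + 1L, "disappearance", cell$id)
        } else {
          drift <- if (is.null(cfg$drift_field)) c(0, 0) else
            cfg$drift_field(cell$x, cell$y)
          cell$x <- reflect_into(
            cell$x + stats::rnorm(1, 0, cfg$step_sigma) + drift[1], xlo, xhi)
          cell$y <- reflect_into(
            cell$y + stats::rnorm(1, 0, cfg$step_sigma) + drift[2], ylo, yhi)
          record(cell, t + 1L)
          survivors <- c(survivors, list(cell))
        }
      }
      n_new <- stats::rpois(1, cfg$appearance_rate)
      for (k in seq_len(n_new)) {
        c0 <- new_cell(stats::runif(1, xlo, xhi), stats::runif(1, ylo, yhi),
                       NA_integer_, t + 1L)
        log_event(t + 1L, "birth", c0$id)
        record(c0, t + 1L)
        survivors <- c(survivors, list(c0))
      }
      alive <- survivors
    }
  }
  events <- if (length(events) > 0L) bind_rows(events) else
    tibble(time_step = integer(), event = character(),
           track_id = integer(), parent_id = integer())
  class(events) <- c("event_log", class(events))
  if (length(obs) == 0L) {
    dataset <- build_trackset(box_observations(
      integer(), integer(), double(), double(), double(), double(),
      double(), double()
    ))
    return(list(dataset = dataset, events = events,
                stats = event_log_statistics(events, cfg$n_steps)))
  }
  pos <- bind_rows(obs)
  box <- box_observations(
    time_step = pos$time_step,
    track_id = pos$track_id,
    left = pmax(0, pos$x - half),
    top = pmin(cfg$field_height, pos$y + half),
    height = pmin(pos$y + half, cfg$field_height) - pmax(pos$y - half, 0),
    width = pmin(pos$x + half, cfg$field_width) - pmax(pos$x - half, 0),
    img_height = cfg$field_height,
    img_width = cfg$field_width,
    parent_id = pos$parent
  )
  list(
    dataset = build_trackset(box),
    events = events,
    stats = event_log_statistics(events, cfg$n_steps)
  )
}

#' Per-step statistics from a ground-truth event log
#'
#' Reduces an `event_log` to the same table layout [derive_statistics()]
#' produces from the assembled dataset, giving the simulator's own view
#' of cells / mitoses / appearances / disappearances per step for
#' cross-checking.
#'
#' @param events an `event_log` tibble.
#' @param n_steps number of simulated steps.
#' @return a `statistic_table` tibble.
#' @export
event_log_statistics <- function(events, n_steps) {
  steps <- seq_len(n_steps)
  n_app <- vapply(steps, function(t)
    sum(events$event == "birth" & events$time_step == t), integer(1))
  n_mit <- vapply(steps, function(t)
    length(unique(events$parent_id[events$event == "division" &
                                     events$time_step == t])), integer(1))
  n_dis <- vapply(steps, function(t)
    sum(events$event == "disappearance" & events$time_step == t), integer(1))
  n_cells <- integer(length(steps))
  running <- 0L
  for (t in steps) {
    running <- running + n_app[t] + n_mit[t] - n_dis[t]
    n_cells[t] <- running
  }
  out <- tibble(
    time_step = steps, n_cells = n_cells, n_mitosis = n_mit,
    n_appearance = n_app, n_disappearance = n_dis
  )
  class(out) <- c("statistic_table", class(out))
  out
}

#' Durotaxis scenario
#'
#' A stiffness-gradient experiment in silico: inside `stiff_region` cells
#' feel a constant drift `bias` (px/step) on top of their random walk,
#' modelling migration toward stiffer substrate; outside it the walk is
#' unbiased. Everything else matches [simulate_cells()], so the regional
#' displacement histograms of the stiff zone shift toward the bias while
#' the global histograms stay near-centred.
#'
#' @param base a `synth_config` (its `drift_field` is replaced).
#' @param stiff_region list/row with `x0`, `y0`, `x1`, `y1` inside the
#'   field.
#' @param bias length-2 numeric `(dx, dy)` px/step drift inside the
#'   region.
#' @return same structure as [simulate_cells()].
#' @export
durotaxis_scenario <- function(base = synth_config(),
                               stiff_region, bias) {
  stopifnot(
    stiff_region$x0 >= 0, stiff_region$y0 >= 0,
    stiff_region$x1 <= base$field_width,
    stiff_region$y1 <= base$field_height,
    stiff_region$x0 < stiff_region$x1, stiff_region$y0 < stiff_region$y1,
    length(bias) == 2L
  )
  base$drift_field <- function(x, y) {
    if (x >= stiff_region$x0 && x < stiff_region$x1 &&
        y >= stiff_region$y0 && y < stiff_region$y1) {
      bias
    } else {
      c(0, 0)
    }
  }
  simulate_cells(base)
}

#' Rasterize a dataset into Cell Tracking Challenge masks
#'
#' Writes one 16-bit labelled TIFF mask per frame (each track's box filled
#' with its id; later ids overwrite earlier ones where boxes overlap) plus
#' the accompanying `man_track.txt` of `L B E P` records with 0-based
#' frames. Box edges are snapped to the integer pixel grid (with a warning
#' when snapping moves an edge), since masks cannot represent fractional
#' boxes; pixel-aligned datasets survive a rasterize-then-import round
#' trip exactly.
#'
#' @param dataset a `tracking_dataset`.
#' @param out_dir output directory (created if missing).
#' @return list with `track_file` and `mask_paths`.
#' @export
rasterize_masks <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  track_file <- file.path(out_dir, "man_track.txt")
  tr <- dataset$tracks
  if (nrow(tr) == 0L) {
    writeLines(character(), track_file)
    return(list(track_file = track_file, mask_paths = character()))
  }
  img_h <- as.integer(round(dataset$field_height))
  img_w <- as.integer(round(dataset$field_width))
  obs <- dataset$observations
  snapped <- c(obs$left, obs$top, obs$height, obs$width)
  if (max(abs(snapped - round(snapped))) > 1e-9) {
    warn("rasterize_masks: box edges snapped to the integer pixel grid")
  }
  steps <- dataset$t_min:dataset$t_max
  mask_paths <- character(length(steps))
  for (i in seq_along(steps)) {
    t <- steps[i]
    m <- matrix(0L, nrow = img_h, ncol = img_w)
    rows <- obs[obs$time_step == t, ]
    rows <- rows[order(rows$track_id), ]
    for (j in seq_len(nrow(rows))) {
      c0 <- as.integer(round(rows$left[j]))
      w <- as.integer(round(rows$width[j]))
      r0 <- img_h - as.integer(round(rows$top[j]))
      h <- as.integer(round(rows$height[j]))
      if (w < 1L) w <- 1L
      if (h < 1L) h <- 1L
      rr <- pmax(1L, pmin(img_h, (r0 + 1L):(r0 + h)))
      cc <- pmax(1L, pmin(img_w, (c0 + 1L):(c0 + w)))
      m[rr, cc] <- rows$track_id[j]
    }
    mask_paths[i] <- file.path(out_dir, sprintf("mask%03d.tif", i - 1L))
    tiff::writeTIFF(m / 65535, mask_paths[i], bits.per.sample = 16L)
  }
  recs <- sprintf(
    "%d %d %d %d",
    tr$track_id, tr$birth_time - 1L, tr$end_time - 1L,
    ifelse(is.na(tr$parent_id), 0L, tr$parent_id)
  )
  writeLines(recs, track_file)
  list(track_file = track_file, mask_paths = mask_paths)
}

#' Render plain background frames for a dataset
#'
#' Writes one grayscale PNG per time step: the field in mid-grey with
#' each cell's box darkened, a stand-in for microscopy frames when testing
#' image-sequence handling.
#'
#' @param dataset a `tracking_dataset`.
#' @param out_dir output directory (created if missing).
#' @param scale downsampling factor applied to the field (default 0.1
#'   keeps fixture frames small).
#' @return character vector of written paths.
#' @export
write_background_frames <- function(dataset, out_dir, scale = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_h <- max(1L, as.integer(round(dataset$field_height * scale)))
  img_w <- max(1L, as.integer(round(dataset$field_width * scale)))
  steps <- dataset$t_min:dataset$t_max
  obs <- box_center(dataset$observations)
  paths <- character(length(steps))
  for (i in seq_along(steps)) {
    m <- matrix(0.6, nrow = img_h, ncol = img_w)
    rows <- obs[obs$time_step == steps[i], ]
    for (j in seq_len(nrow(rows))) {
      r <- img_h - as.integer(round(rows$y[j] * scale))
      cc <- as.integer(round(rows$x[j] * scale))
      rr <- pmax(1L, pmin(img_h, (r - 1L):(r + 1L)))
      cc <- pmax(1L, pmin(img_w, (cc - 1L):(cc + 1L)))
      m[rr, cc] <- 0.2
    }
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", i))
    png::writePNG(m, paths[i])
  }
  paths
}

#' Write every input format for a simulated dataset
#'
#' Convenience bundle around the writers: the trajectory CSV, the
#' event-log statistic CSV, background PNG frames, and the CTC track file
#' plus labelled masks, all under `out_dir`.
#'
#' @param sim result of [simulate_cells()] or [durotaxis_scenario()].
#' @param out_dir output directory.
#' @param masks also rasterize CTC masks (default `FALSE`; mask stacks
#'   are large for big fields).
#' @return named list of written paths.
#' @export
write_synth_bundle <- function(sim, out_dir, masks = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tracks_csv <- file.path(out_dir, "tracks.csv")
  write_track_csv(sim$dataset$observations, tracks_csv)
  stats_csv <- file.path(out_dir, "stats.csv")
  write_statistic_csv(sim$stats, stats_csv)
  bg <- write_background_frames(sim$dataset, file.path(out_dir, "frames"))
  out <- list(tracks_csv = tracks_csv, stats_csv = stats_csv,
              background_frames = bg)
  if (masks) {
    out$ctc <- rasterize_masks(sim$dataset, file.path(out_dir, "ctc"))
  }
  out
}
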