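TOGGLES <- c(
  "cell_point", "all_points", "cell_label", "cell_vector",
  "cell_trajectory", "all_trajectories", "map_grid"
)

#' View configuration for the trajectory renderer
#'
#' Mirrors the interactive option controller: three continuous controls
#' (background transparency, circle radius, line thickness), seven
#' visibility toggles, the Normal/Split mode switch, the set of
#' highlighted (red) tracks, and the time cursor. The default shows the
#' positions and trajectories of cells currently living, everything else
#' off.
#'
#' @param image_alpha background image opacity in `[0, 1]`.
#' @param circle_radius cell point radius, px > 0.
#' @param line_thickness trajectory/vector stroke width, px > 0.
#' @param cell_point solid circles at the current positions of living
#'   cells.
#' @param all_points dotted circles at the last positions of disappeared
#'   cells too.
#' @param cell_label text labels `id(birth)` next to living cells.
#' @param cell_vector arrows to each cell's next position.
#' @param cell_trajectory solid polylines of living cells' histories.
#' @param all_trajectories dotted polylines of disappeared cells'
#'   histories.
#' @param map_grid grid lines over the field.
#' @param mode `"normal"` or `"split"` (draw the region partition).
#' @param highlight_ids track ids whose clonal families are drawn red.
#' @param time_cursor current time step.
#' @return a `view_config` list.
#' @export
view_config <- function(image_alpha = 1, circle_radius = 5,
                        line_thickness = 1,
                        cell_point = TRUE, all_points = FALSE,
                        cell_label = FALSE, cell_vector = FALSE,
                        cell_trajectory = TRUE, all_trajectories = FALSE,
                        map_grid = FALSE,
                        mode = c("normal", "split"),
                        highlight_ids = integer(), time_cursor = 1L) {
  mode <- match.arg(mode)
  if (image_alpha < 0 || image_alpha > 1) {
    abort("image_alpha must lie in [0, 1]")
  }
  if (circle_radius <= 0 || line_thickness <= 0) {
    abort("circle_radius and line_thickness must be positive")
  }
  structure(
    list(
      image_alpha = image_alpha, circle_radius = circle_radius,
      line_thickness = line_thickness,
      toggles = c(
        cell_point = cell_point, all_points = all_points,
        cell_label = cell_label, cell_vector = cell_vector,
        cell_trajectory = cell_trajectory,
        all_trajectories = all_trajectories, map_grid = map_grid
      ),
      mode = mode,
      highlight_ids = as.integer(highlight_ids),
      time_cursor = as.integer(time_cursor)
    ),
    class = "view_config"
  )
}

# 20-colour qualitative palette; family colour is a pure function of the
# lineage root id, so colours are stable across runs and zoom levels.
FAMILY_PALETTE <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
  "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
  "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
  "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5"
)

HIGHLIGHT_COLOR <- "#ff0000"

#' Deterministic family color
#'
#' @param root_id lineage root track id (vectorized).
#' @return hex color string(s), a pure function of the root id.
#' @export
family_color <- function(root_id) {
  FAMILY_PALETTE[(as.integer(root_id) - 1L) %% length(FAMILY_PALETTE) + 1L]
}

expand_highlight <- function(forest, ids) {
  if (length(ids) == 0L) {
    return(integer())
  }
  sort(unique(unlist(lapply(ids, function(i) family_of(forest, i)))))
}

#' Render one trajectory-view frame as SVG
#'
#' Draws the trajectory panel at the config's time cursor: per toggle,
#' solid circles for cells observed at the cursor (`cell_point`), dotted
#' circles at the last position of cells that disappeared before it
#' (`all_points`), `id(birth)` labels (`cell_label`), arrows to the next
#' position (`cell_vector`), solid history polylines for living cells
#' (`cell_trajectory`), dotted ones for disappeared cells
#' (`all_trajectories`) and a map grid. Tracks are colored by clonal
#' family (a pure function of the root id); the clonal families of
#' `highlight_ids` are drawn red on top. In split mode the partition's
#' zone boundaries are drawn and the selected zone shaded.
#'
#' @param dataset a `tracking_dataset`.
#' @param forest its `lineage_forest` (built if omitted).
#' @param config a [view_config()].
#' @param partition optional `region_partition` (drawn in split mode).
#' @param viewport optional `viewport`; defaults to the whole field.
#' @param background optional path to a background image for this frame.
#' @return single-element character vector holding the SVG document.
#' @export
render_trajectory_frame <- function(dataset, forest = NULL,
                                    config = view_config(),
                                    partition = NULL, viewport = NULL,
                                    background = NULL) {
  t <- config$time_cursor
  if (is.na(dataset$t_min) || t < dataset$t_min || t > dataset$t_max) {
    abort(sprintf("time cursor %s outside dataset range", t))
  }
  forest <- forest %||% build_lineage_forest(dataset)
  vp <- viewport %||% new_viewport(dataset$field_width, dataset$field_height)
  tg <- config$toggles
  red_ids <- expand_highlight(forest, config$highlight_ids)
  roots <- vapply(dataset$tracks$track_id, function(id) root_of(forest, id),
                  integer(1))
  names(roots) <- as.character(dataset$tracks$track_id)
  col_of <- function(id) {
    if (id %in% red_ids) HIGHLIGHT_COLOR else
      family_color(roots[[as.character(id)]])
  }
  ctr <- box_center(dataset$observations)
  tr <- dataset$tracks
  living <- tr$track_id[tr$birth_time <= t & tr$end_time >= t]
  gone <- tr$track_id[tr$end_time < t]
  els <- character()
  if (!is.null(background) && config$image_alpha > 0) {
    if (!file.exists(background)) {
      warn(sprintf("background frame missing: %s; rendering without it",
                   background))
    } else {
      orig <- field_to_screen(vp, 0, dataset$field_height)
      size <- field_to_screen(vp, dataset$field_width, 0)
      els <- c(els, svg_image(background, orig$sx, orig$sy,
                              size$sx - orig$sx, size$sy - orig$sy,
                              class = "background",
                              opacity = config$image_alpha))
    }
  }
  if (tg[["map_grid"]]) {
    for (gx in seq(0, dataset$field_width, length.out = 11L)) {
      p <- field_to_screen(vp, c(gx, gx), c(0, dataset$field_height))
      els <- c(els, svg_line(p$sx[1], p$sy[1], p$sx[2], p$sy[2],
                             class = "map-grid", stroke = "#cccccc",
                             width = 0.5))
    }
    for (gy in seq(0, dataset$field_height, length.out = 11L)) {
      p <- field_to_screen(vp, c(0, dataset$field_width), c(gy, gy))
      els <- c(els, svg_line(p$sx[1], p$sy[1], p$sx[2], p$sy[2],
                             class = "map-grid", stroke = "#cccccc",
                             width = 0.5))
    }
  }
  if (config$mode == "split" && !is.null(partition)) {
    lv <- partition_leaves(partition)
    for (i in seq_len(nrow(lv))) {
      a <- field_to_screen(vp, lv$x0[i], lv$y1[i])
      b <- field_to_screen(vp, lv$x1[i], lv$y0[i])
      if (lv$selected[i]) {
        els <- c(els, svg_rect(a$sx, a$sy, b$sx - a$sx, b$sy - a$sy,
                               class = "region-selected",
                               fill = HIGHLIGHT_COLOR, opacity = 0.15))
      }
      els <- c(els, svg_rect(a$sx, a$sy, b$sx - a$sx, b$sy - a$sy,
                             class = "split-line", stroke = "#333333",
                             width = 1))
    }
  }
  path_els <- function(ids, class, dash) {
    out <- character()
    for (id in ids) {
      h <- ctr[ctr$track_id == id & ctr$time_step <= t, ]
      if (nrow(h) < 2L) next
      p <- field_to_screen(vp, h$x, h$y)
      out <- c(out, svg_polyline(p$sx, p$sy,
        class = class, stroke = col_of(id),
        width = config$line_thickness, dash = dash,
        extra = list(`data-track` = id)
      ))
    }
    out
  }
  if (tg[["all_trajectories"]]) {
    els <- c(els, path_els(gone, "gone-trajectory", "4 3"))
  }
  if (tg[["cell_trajectory"]]) {
    els <- c(els, path_els(living, "cell-trajectory", NULL))
  }
  if (tg[["cell_vector"]]) {
    v <- direction_vectors(dataset, if (t < dataset$t_max) t else NULL)
    if (t == dataset$t_max) v <- v[0, ]
    for (i in seq_len(nrow(v))) {
      a <- field_to_screen(vp, v$x[i], v$y[i])
      b <- field_to_screen(vp, v$x[i] + v$dx[i], v$y[i] + v$dy[i])
      els <- c(els, svg_line(a$sx, a$sy, b$sx, b$sy,
        class = "cell-vector", stroke = col_of(v$track_id[i]),
        width = config$line_thickness
      ))
      # arrowhead only for vectors long enough to read at the point radius
      len <- sqrt(v$dx[i]^2 + v$dy[i]^2)
      if (len > config$circle_radius) {
        ang <- atan2(b$sy - a$sy, b$sx - a$sx)
        hl <- config$circle_radius * 0.8
        for (da in c(2.6, -2.6)) {
          els <- c(els, svg_line(
            b$sx, b$sy,
            b$sx + hl * cos(ang + da), b$sy + hl * sin(ang + da),
            class = "vector-head", stroke = col_of(v$track_id[i]),
            width = config$line_thickness
          ))
        }
      }
    }
  }
  if (tg[["all_points"]]) {
    for (id in gone) {
      h <- ctr[ctr$track_id == id, ]
      last <- h[nrow(h), ]
      p <- field_to_screen(vp, last$x, last$y)
      els <- c(els, svg_circle(p$sx, p$sy, config$circle_radius,
        class = "gone-point", stroke = col_of(id), dash = "2 2",
        width = config$line_thickness
      ))
    }
  }
  if (tg[["cell_point"]]) {
    cur <- ctr[ctr$time_step == t, ]
    for (i in seq_len(nrow(cur))) {
      p <- field_to_screen(vp, cur$x[i], cur$y[i])
      els <- c(els, svg_circle(p$sx, p$sy, config$circle_radius,
        class = "cell-point", fill = col_of(cur$track_id[i])
      ))
    }
  }
  if (tg[["cell_label"]]) {
    cur <- ctr[ctr$time_step == t, ]
    birth <- tr$birth_time[match(cur$track_id, tr$track_id)]
    for (i in seq_len(nrow(cur))) {
      p <- field_to_screen(vp, cur$x[i], cur$y[i])
      els <- c(els, svg_text(
        p$sx + config$circle_radius + 1, p$sy,
        sprintf("%d(%d)", cur$track_id[i], birth[i]),
        class = "cell-label"
      ))
    }
  }
  svg_document(vp$out_width, vp$out_height, els, class = "trajectory-view")
}

#' Lay out a lineage forest for drawing
#'
#' The classic pedigree layout: time runs along x; every track is a
#' horizontal segment from its birth to its end step; each division adds a
#' vertical connector at the children's birth step. Leaves get consecutive
#' integer rows in depth-first order (trees ordered by root birth time
#' then id; children by birth time then id); an internal track sits at the
#' mean of its children's rows, so trees stack without overlap.
#'
#' @param forest a `lineage_forest`.
#' @param dataset unused placeholder for datasets carrying extra per-track
#'   annotation; the forest's own track table supplies the spans.
#' @return a `lineage_layout`: list with `segments` (tibble `track_id`,
#'   `root_id`, `row`, `t0`, `t1`), `connectors` (tibble `parent_id`,
#'   `time`, `row0`, `row1`), `n_leaves`, `t_min`, `t_max`.
#' @export
layout_lineage_forest <- function(forest, dataset = NULL) {
  tr <- forest$tracks
  if (nrow(tr) == 0L) {
    return(structure(
      list(
        segments = tibble(track_id = integer(), root_id = integer(),
                          row = double(), t0 = integer(), t1 = integer()),
        connectors = tibble(parent_id = integer(), time = integer(),
                            row0 = double(), row1 = double()),
        n_leaves = 0L, t_min = NA_integer_, t_max = NA_integer_
      ),
      class = "lineage_layout"
    ))
  }
  rows <- new.env(parent = emptyenv())
  next_leaf <- 0L
  assign_rows <- function(id) {
    kids <- forest$children[[as.character(id)]]
    if (is.null(kids) || length(kids) == 0L) {
      r <- next_leaf
      next_leaf <<- next_leaf + 1L
      assign(as.character(id), as.double(r), envir = rows)
      return(as.double(r))
    }
    kid_rows <- vapply(kids, assign_rows, double(1))
    r <- mean(kid_rows)
    assign(as.character(id), r, envir = rows)
    r
  }
  root_order <- tr |>
    filter(is.na(.data$parent_id)) |>
    arrange(.data$birth_time, .data$track_id)
  for (r in root_order$track_id) assign_rows(r)
  seg_rows <- unname(vapply(as.character(tr$track_id), function(k)
    get(k, envir = rows), double(1)))
  root_ids <- vapply(tr$track_id, function(id) root_of(forest, id),
                     integer(1))
  segments <- tibble(
    track_id = tr$track_id,
    root_id = root_ids,
    row = seg_rows,
    t0 = tr$birth_time,
    t1 = tr$end_time
  ) |> arrange(.data$row, .data$t0)
  conn <- list()
  for (pid in names(forest$children)) {
    kids <- forest$children[[pid]]
    kr <- vapply(as.character(kids), function(k) get(k, envir = rows),
                 double(1))
    kb <- tr$birth_time[match(kids, tr$track_id)]
    for (b in unique(kb)) {
      sel <- kb == b
      conn[[length(conn) + 1L]] <- tibble(
        parent_id = as.integer(pid),
        time = as.integer(b),
        row0 = min(c(kr[sel], get(pid, envir = rows))),
        row1 = max(c(kr[sel], get(pid, envir = rows)))
      )
    }
  }
  structure(
    list(
      segments = segments,
      connectors = if (length(conn) > 0L) bind_rows(conn) else
        tibble(parent_id = integer(), time = integer(),
               row0 = double(), row1 = double()),
      n_leaves = next_leaf,
      t_min = min(tr$birth_time),
      t_max = max(tr$end_time)
    ),
    class = "lineage_layout"
  )
}

#' @method autoplot lineage_layout
#' @export
autoplot.lineage_layout <- function(object, time_cursor = NULL, ...) {
  s <- object$segments
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = s,
      ggplot2::aes(x = .data$t0, xend = .data$t1, y = .data$row,
                   yend = .data$row, colour = factor(.data$root_id))
    ) +
    ggplot2::geom_segment(
      data = object$connectors,
      ggplot2::aes(x = .data$time, xend = .data$time, y = .data$row0,
                   yend = .data$row1),
      colour = "grey40"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time step", y = NULL, colour = "family") +
    ggplot2::theme_minimal()
  if (!is.null(time_cursor)) {
    p <- p + ggplot2::geom_vline(xintercept = time_cursor,
                                 linetype = "dashed")
  }
  p
}

#' Render the lineage view as SVG
#'
#' Draws every track segment and division connector of the layout, a
#' full-height vertical cursor line at `time_cursor`, and the given
#' tracks' segments in red.
#'
#' @param layout a `lineage_layout`.
#' @param time_cursor time step for the moving cursor line.
#' @param highlight_ids track ids to draw red (pass a [family_of()] result
#'   to highlight a whole family).
#' @param width,height output size in px.
#' @return SVG document string.
#' @export
render_lineage_view <- function(layout, time_cursor,
                                highlight_ids = integer(),
                                width = 600, height = 400) {
  els <- character()
  if (layout$n_leaves > 0L) {
    if (time_cursor < layout$t_min || time_cursor > layout$t_max) {
      abort(sprintf("time cursor %s outside lineage span", time_cursor))
    }
    tspan <- max(1L, layout$t_max - layout$t_min)
    sx <- function(t) (t - layout$t_min) / tspan * (width - 40) + 20
    sy <- function(r) {
      if (layout$n_leaves == 1L) height / 2 else
        r / (layout$n_leaves - 1L) * (height - 40) + 20
    }
    s <- layout$segments
    for (i in seq_len(nrow(s))) {
      red <- s$track_id[i] %in% highlight_ids
      els <- c(els, svg_line(
        sx(s$t0[i]), sy(s$row[i]), sx(s$t1[i]), sy(s$row[i]),
        class = if (red) "lineage-segment highlight" else "lineage-segment",
        stroke = if (red) HIGHLIGHT_COLOR else family_color(s$root_id[i]),
        width = if (red) 2 else 1
      ))
    }
    cn <- layout$connectors
    for (i in seq_len(nrow(cn))) {
      red <- cn$parent_id[i] %in% highlight_ids
      els <- c(els, svg_line(
        sx(cn$time[i]), sy(cn$row0[i]), sx(cn$time[i]), sy(cn$row1[i]),
        class = "lineage-connector",
        stroke = if (red) HIGHLIGHT_COLOR else "#555555",
        width = 1
      ))
    }
    els <- c(els, svg_line(sx(time_cursor), 0, sx(time_cursor), height,
                           class = "time-cursor", stroke = "#000000",
                           width = 1, dash = "5 3"))
  } else {
    els <- c(els,
      svg_line(20, height - 20, width - 20, height - 20,
               class = "time-axis", stroke = "#000000", width = 1),
      svg_line(20, 0, 20, height, class = "time-cursor",
               stroke = "#000000", width = 1, dash = "5 3"))
  }
  svg_document(width, height, els, class = "lineage-view")
}

#' Render the statistic view as SVG
#'
#' The quantified-information panel: one polyline per visible statistic
#' column (shared time axis), a vertical cursor bar annotated with each
#' visible column's exact value at the cursor step, and up to four
#' displacement histograms (global horizontal/vertical and, when a zone is
#' selected, the regional pair below on the same per-axis scales).
#'
#' @param stats a `statistic_table` (from [read_statistic_csv()] or
#'   [derive_statistics()]), or `NULL` for histograms only.
#' @param histograms result of [regional_histograms()], or `NULL`.
#' @param time_cursor step for the cursor bar (`NULL` = no cursor).
#' @param visible_columns statistic columns to plot (default all);
#'   unknown names are an error.
#' @param width,height output size in px.
#' @return SVG document string.
#' @export
render_statistic_view <- function(stats = NULL, histograms = NULL,
                                  time_cursor = NULL,
                                  visible_columns = NULL,
                                  width = 600, height = 600) {
  els <- character()
  half <- if (!is.null(histograms)) height / 2 else height
  if (!is.null(stats)) {
    cols <- visible_columns %||% setdiff(names(stats), "time_step")
    bad <- setdiff(cols, names(stats))
    if (length(bad) > 0L) {
      abort(sprintf("unknown statistic column(s): %s",
                    paste(bad, collapse = ", ")))
    }
    ts <- stats$time_step
    if (length(cols) > 0L && length(ts) > 0L) {
      tspan <- max(1L, max(ts) - min(ts))
      vmax <- max(1e-9, max(vapply(cols, function(cn) max(stats[[cn]]),
                                   double(1))))
      vmin <- min(0, min(vapply(cols, function(cn) min(stats[[cn]]),
                                double(1))))
      sx <- function(t) (t - min(ts)) / tspan * (width - 60) + 40
      sy <- function(v) half - 20 - (v - vmin) / (vmax - vmin) * (half - 40)
      for (j in seq_along(cols)) {
        els <- c(els, svg_polyline(
          sx(ts), sy(stats[[cols[j]]]),
          class = "stat-line",
          stroke = FAMILY_PALETTE[(j - 1L) %% 20L + 1L],
          extra = list(`data-column` = cols[j])
        ))
      }
      if (!is.null(time_cursor)) {
        els <- c(els, svg_line(sx(time_cursor), 0, sx(time_cursor), half,
                               class = "stat-cursor", stroke = "#000000",
                               width = 1, dash = "5 3"))
        row <- stats[stats$time_step == time_cursor, , drop = FALSE]
        if (nrow(row) == 1L) {
          for (j in seq_along(cols)) {
            els <- c(els, svg_text(
              sx(time_cursor) + 4, 12 * j,
              sprintf("%s = %s", cols[j],
                      format(row[[cols[j]]], trim = TRUE)),
              class = "cursor-value"
            ))
          }
        }
      }
    }
  }
  if (!is.null(histograms)) {
    panel_w <- width / 2
    draw_hist <- function(hist, x_off, y_off, panel_h, cls) {
      n <- length(hist$counts)
      cmax <- max(1L, max(hist$counts))
      bw <- (panel_w - 30) / n
      out <- character()
      for (i in seq_len(n)) {
        bh <- hist$counts[i] / cmax * (panel_h - 30)
        out <- c(out, svg_rect(
          x_off + 15 + (i - 1) * bw, y_off + panel_h - 15 - bh, bw, bh,
          class = cls, fill = "#6699cc", stroke = "#334455", width = 0.5
        ))
      }
      out
    }
    panel_h <- if (!is.null(histograms$regional)) half / 2 else half
    els <- c(els,
      draw_hist(histograms$global$horizontal, 0, half, panel_h,
                "hist-bar global-h"),
      draw_hist(histograms$global$vertical, panel_w, half, panel_h,
                "hist-bar global-v"))
    if (!is.null(histograms$regional)) {
      els <- c(els,
        draw_hist(histograms$regional$horizontal, 0, half + panel_h,
                  panel_h, "hist-bar regional-h"),
        draw_hist(histograms$regional$vertical, panel_w, half + panel_h,
                  panel_h, "hist-bar regional-v"))
    }
  }
  svg_document(width, height, els, class = "statistic-view")
}

#' Export the coordinated views as an animation frame sequence
#'
#' Writes one composed SVG frame per time step from `t_min` to `t_max`:
#' trajectory view on the left, lineage view top-right, statistic view
#' bottom-right (2:1:1 area ratio). File names are zero-padded and
#' 1-based (`frame_0001.svg`, ...); output is deterministic, so
#' re-exporting identical inputs yields byte-identical files. Frame t's
#' trajectory panel embeds exactly [render_trajectory_frame()]'s document
#' for cursor t.
#'
#' @param dataset a `tracking_dataset`.
#' @param forest its `lineage_forest` (built if omitted).
#' @param config a [view_config()] (its `time_cursor` is overridden per
#'   frame).
#' @param out_dir output directory (created if missing).
#' @param partition optional `region_partition` for split mode.
#' @param stats optional `statistic_table` for the statistic panel
#'   (derived from the dataset if omitted).
#' @param backgrounds optional `image_sequence` for per-frame backgrounds.
#' @return tibble with `time_step` and `path` of the written frames.
#' @export
export_animation <- function(dataset, forest = NULL, config = view_config(),
                             out_dir, partition = NULL, stats = NULL,
                             backgrounds = NULL) {
  if (is.na(dataset$t_min)) {
    abort("cannot animate an empty dataset")
  }
  forest <- forest %||% build_lineage_forest(dataset)
  stats <- stats %||% derive_statistics(dataset, forest)
  layout <- layout_lineage_forest(forest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- dataset$t_min:dataset$t_max
  paths <- character(length(steps))
  side_w <- 400
  traj_size <- 800
  red_ids <- expand_highlight(forest, config$highlight_ids)
  for (i in seq_along(steps)) {
    t <- steps[i]
    cfg <- config
    cfg$time_cursor <- t
    bg <- NULL
    if (!is.null(backgrounds)) {
      hit <- backgrounds$path[backgrounds$time_step == t]
      if (length(hit) == 1L) bg <- hit
    }
    traj <- render_trajectory_frame(dataset, forest, cfg,
                                    partition = partition, background = bg)
    lin <- render_lineage_view(layout, t, highlight_ids = red_ids,
                               width = side_w, height = traj_size / 2)
    hists <- if (!is.null(partition)) {
      regional_histograms(partition, dataset,
                          t = if (t < dataset$t_max) t else NULL)
    } else {
      NULL
    }
    stat <- render_statistic_view(stats, hists, time_cursor = t,
                                  width = side_w, height = traj_size / 2)
    frame <- svg_document(
      traj_size + side_w, traj_size,
      c(
        svg_el("svg", x = 0, y = 0, width = traj_size, height = traj_size,
               content = traj),
        svg_el("svg", x = traj_size, y = 0, width = side_w,
               height = traj_size / 2, content = lin),
        svg_el("svg", x = traj_size, y = traj_size / 2, width = side_w,
               height = traj_size / 2, content = stat)
      ),
      class = "composed-frame"
    )
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.svg", i))
    writeLines(frame, paths[i], sep = "")
  }
  tibble(time_step = steps, path = paths)
}

#' Trajectory scatter/path plot of a dataset
#'
#' ggplot2 companion to the SVG renderer for quick interactive looks:
#' every track's center path colored by clonal family.
#'
#' @param dataset a `tracking_dataset`.
#' @param forest optional `lineage_forest` for family colors.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(dataset, forest = NULL) {
  forest <- forest %||% build_lineage_forest(dataset)
  ctr <- box_center(dataset$observations)
  ctr$root_id <- vapply(ctr$track_id, function(id) root_of(forest, id),
                        integer(1))
  ggplot2::ggplot(ctr, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$track_id,
                                    colour = factor(.data$root_id))) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_fixed(xlim = c(0, dataset$field_width),
                         ylim = c(0, dataset$field_height)) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "family") +
    ggplot2::theme_minimal()
}
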