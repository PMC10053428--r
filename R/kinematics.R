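#' Box centers of observations
#'
#' Reduces bounding boxes to point positions: `x = left + width/2`,
#' `y = top - height/2` in the Cartesian (y-up) field frame.
#'
#' @param observations observation tibble.
#' @return the tibble with `x` and `y` columns added.
#' @export
box_center <- function(observations) {
  mutate(observations,
    x = .data$left + .data$width / 2,
    y = .data$top - .data$height / 2
  )
}

#' Direction vectors between consecutive time steps
#'
#' One vector per track observed at both `t` and `t + 1`: the displacement
#' of the box center. Tracks ending at `t`, or with a gap at `t + 1`,
#' contribute nothing — the vector describes motion to the *next frame*,
#' never across a gap.
#'
#' @param dataset a `tracking_dataset`.
#' @param t time step at which vectors start; `NULL` (default) returns the
#'   vectors of every step from `t_min` to `t_max - 1` at once.
#' @return tibble with columns `track_id`, `time_step` (the start step),
#'   `x`, `y` (start position), `dx`, `dy`.
#' @export
direction_vectors <- function(dataset, t = NULL) {
  if (!is.null(t) && (t < dataset$t_min || t >= dataset$t_max)) {
    abort(sprintf("t = %s outside the dataset's step range %d..%d",
                  t, dataset$t_min, dataset$t_max - 1L))
  }
  ctr <- box_center(dataset$observations)
  v <- ctr |>
    arrange(.data$track_id, .data$time_step) |>
    group_by(.data$track_id) |>
    mutate(
      next_step = dplyr::lead(.data$time_step),
      dx = dplyr::lead(.data$x) - .data$x,
      dy = dplyr::lead(.data$y) - .data$y
    ) |>
    ungroup() |>
    filter(!is.na(.data$next_step), .data$next_step == .data$time_step + 1L) |>
    select("track_id", "time_step", "x", "y", "dx", "dy") |>
    arrange(.data$time_step, .data$track_id)
  if (!is.null(t)) {
    v <- filter(v, .data$time_step == t)
  }
  v
}

default_bin_edges <- function(values, n_bins = 21L) {
  m <- if (length(values) == 0L) 1 else max(abs(values))
  if (m == 0) m <- 1
  seq(-m, m, length.out = n_bins + 1L)
}

#' Histogram of displacement components
#'
#' Bins the horizontal (`dx`) or vertical (`dy`) components of a set of
#' direction vectors. Values outside the edge range are clamped into the
#' end bins, so the counts always sum to the number of vectors. The
#' default edge spec is 21 bins symmetric about zero spanning the largest
#' absolute component. An angle mode (`atan2(dy, dx)`, radians) is
#' available for heading analysis.
#'
#' @param vectors tibble from [direction_vectors()].
#' @param axis `"horizontal"` (bins `dx`) or `"vertical"` (bins `dy`).
#' @param bins strictly increasing numeric vector of bin edges, or `NULL`
#'   for the default spec.
#' @param mode `"displacement"` (signed px/step, default) or `"angle"`
#'   (heading angle, default edges = 16 bins over \eqn{[-\pi, \pi]}).
#' @return a `direction_histogram`: list with `bin_edges`, `counts`,
#'   `axis`, `mode`.
#' @export
displacement_histogram <- function(vectors, axis = c("horizontal", "vertical"),
                                   bins = NULL,
                                   mode = c("displacement", "angle")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  vals <- if (mode == "angle") {
    atan2(vectors$dy, vectors$dx)
  } else if (axis == "horizontal") {
    vectors$dx
  } else {
    vectors$dy
  }
  if (is.null(bins)) {
    bins <- if (mode == "angle") {
      seq(-pi, pi, length.out = 17L)
    } else {
      default_bin_edges(vals)
    }
  }
  if (length(bins) < 2L || any(diff(bins) <= 0)) {
    abort("bin edges must be a strictly increasing vector of length >= 2")
  }
  clamped <- pmin(pmax(vals, bins[1]), bins[length(bins)])
  counts <- as.integer(table(cut(clamped, breaks = bins, include.lowest = TRUE,
                                 right = FALSE)))
  # cut(right = FALSE) puts values equal to the top edge in their own NA;
  # include.lowest with right = FALSE includes the maximum in the last bin
  structure(
    list(bin_edges = bins, counts = counts, axis = axis, mode = mode),
    class = "direction_histogram"
  )
}

#' @export
print.direction_histogram <- function(x, ...) {
  cat(sprintf("<direction_histogram> %s %s, %d bins, %d vectors\n",
              x$axis, x$mode, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' @method tidy direction_histogram
#' @export
tidy.direction_histogram <- function(x, ...) {
  tibble(
    bin_low = x$bin_edges[-length(x$bin_edges)],
    bin_high = x$bin_edges[-1],
    count = x$counts
  )
}

#' @method autoplot direction_histogram
#' @export
autoplot.direction_histogram <- function(object, ...) {
  d <- tidy(object)
  d$mid <- (d$bin_low + d$bin_high) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges), fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("%s displacement (px/step)", object$axis),
      y = "cells"
    ) +
    ggplot2::theme_minimal()
}

#' Per-step population statistics derived from tracks and lineage
#'
#' Computes, for every step of the dataset's span: `n_cells` (tracks
#' observed at t), `n_mitosis` (division events: distinct parents with at
#' least one child born at t), `n_appearance` (parentless tracks born at
#' t — the initial population counts as appearing at the first step), and
#' `n_disappearance` (tracks that ended at t-1 without any child born at
#' t). Under two-daughter divisions that terminate the parent this obeys
#' `n_cells(t) - n_cells(t-1) = n_appearance(t) + n_mitosis(t) - n_disappearance(t)`.
#'
#' @param dataset a `tracking_dataset`.
#' @param forest its `lineage_forest` (built if omitted).
#' @return a `statistic_table` tibble with columns `time_step`, `n_cells`,
#'   `n_mitosis`, `n_appearance`, `n_disappearance`.
#' @export
derive_statistics <- function(dataset, forest = NULL) {
  if (nrow(dataset$tracks) == 0L) {
    out <- tibble(
      time_step = integer(), n_cells = integer(), n_mitosis = integer(),
      n_appearance = integer(), n_disappearance = integer()
    )
    class(out) <- c("statistic_table", class(out))
    return(out)
  }
  forest <- forest %||% build_lineage_forest(dataset)
  tr <- dataset$tracks
  steps <- dataset$t_min:dataset$t_max
  n_cells <- vapply(steps, function(t)
    sum(dataset$observations$time_step == t), integer(1))
  kids <- filter(tr, !is.na(.data$parent_id))
  n_mitosis <- vapply(steps, function(t) {
    length(unique(kids$parent_id[kids$birth_time == t]))
  }, integer(1))
  roots <- filter(tr, is.na(.data$parent_id))
  n_appearance <- vapply(steps, function(t)
    sum(roots$birth_time == t), integer(1))
  n_disappearance <- vapply(steps, function(t) {
    ended <- tr$track_id[tr$end_time == t - 1L]
    divided <- unique(kids$parent_id[kids$birth_time == t])
    sum(!(ended %in% divided))
  }, integer(1))
  out <- tibble(
    time_step = steps,
    n_cells = n_cells,
    n_mitosis = n_mitosis,
    n_appearance = n_appearance,
    n_disappearance = n_disappearance
  )
  class(out) <- c("statistic_table", class(out))
  out
}

#' @method autoplot statistic_table
#' @export
autoplot.statistic_table <- function(object, columns = NULL, ...) {
  cols <- columns %||% setdiff(names(object), "time_step")
  d <- tidyr::pivot_longer(as_tibble(object)[c("time_step", cols)],
    -"time_step",
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_step, y = .data$value,
                                  colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = NULL) +
    ggplot2::theme_minimal()
}
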