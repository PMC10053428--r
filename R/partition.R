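#' Create a fresh region partition
#'
#' Split mode models the imaging field as a binary split tree of
#' axis-aligned rectangles: each horizontal or vertical line divides one
#' current zone (a leaf) into two, merging removes a line, and at most one
#' leaf can be selected for per-region statistics. A new partition is a
#' single leaf covering the whole field with nothing selected.
#'
#' @param field_width,field_height positive field dimensions in px.
#' @return a `region_partition`.
#' @export
new_partition <- function(field_width, field_height) {
  if (field_width <= 0 || field_height <= 0) {
    abort("field dimensions must be positive")
  }
  structure(
    list(
      nodes = list(`1` = list(
        id = 1L, x0 = 0, y0 = 0, x1 = as.double(field_width),
        y1 = as.double(field_height),
        axis = NA_character_, coord = NA_real_,
        child_lo = NA_integer_, child_hi = NA_integer_,
        parent = NA_integer_
      )),
      next_id = 2L,
      selected = NA_integer_,
      field_width = as.double(field_width),
      field_height = as.double(field_height)
    ),
    class = "region_partition"
  )
}

is_leaf <- function(node) is.na(node$child_lo)

#' Current zones of a partition
#'
#' @param partition a `region_partition`.
#' @return tibble of leaves: `region_id`, `x0`, `y0`, `x1`, `y1`,
#'   `selected`.
#' @export
partition_leaves <- function(partition) {
  leaves <- purrr::keep(partition$nodes, is_leaf)
  ids <- unname(vapply(leaves, `[[`, integer(1), "id"))
  tibble(
    region_id = ids,
    x0 = unname(vapply(leaves, `[[`, double(1), "x0")),
    y0 = unname(vapply(leaves, `[[`, double(1), "y0")),
    x1 = unname(vapply(leaves, `[[`, double(1), "x1")),
    y1 = unname(vapply(leaves, `[[`, double(1), "y1")),
    selected = !is.na(partition$selected) & ids == partition$selected
  ) |> arrange(.data$region_id)
}

#' @export
print.region_partition <- function(x, ...) {
  lv <- partition_leaves(x)
  cat(sprintf("<region_partition> %d zone(s) over %g x %g field%s\n",
              nrow(lv), x$field_width, x$field_height,
              if (!is.na(x$selected))
                sprintf(", zone %d selected", x$selected) else ""))
  invisible(x)
}

get_node <- function(partition, region_id) {
  node <- partition$nodes[[as.character(region_id)]]
  if (is.null(node)) {
    abort(sprintf("unknown region id: %s", region_id))
  }
  node
}

#' Split a zone with a horizontal or vertical line
#'
#' The line must lie strictly inside the chosen leaf. A `"vertical"` line
#' at `coordinate = c` splits on x into `[x0, c)` and `[c, x1)`; a
#' `"horizontal"` line splits on y. The lower/left child keeps ids
#' deterministic: children are numbered in creation order. Any selection
#' on an untouched leaf survives; splitting the selected leaf clears the
#' selection.
#'
#' @param partition a `region_partition`.
#' @param region_id id of a current leaf.
#' @param axis `"horizontal"` or `"vertical"` (orientation of the added
#'   line).
#' @param coordinate position of the line in field px.
#' @return the updated partition.
#' @export
split_region <- function(partition, region_id,
                         axis = c("horizontal", "vertical"), coordinate) {
  axis <- match.arg(axis)
  node <- get_node(partition, region_id)
  if (!is_leaf(node)) {
    abort(sprintf("region %d is not a leaf", node$id))
  }
  lo_hi <- if (axis == "vertical") c(node$x0, node$x1) else c(node$y0, node$y1)
  if (coordinate <= lo_hi[1] || coordinate >= lo_hi[2]) {
    abort(sprintf(
      "split coordinate %g not strictly inside (%g, %g)",
      coordinate, lo_hi[1], lo_hi[2]
    ))
  }
  id_lo <- partition$next_id
  id_hi <- partition$next_id + 1L
  mk <- function(id, x0, y0, x1, y1) {
    list(
      id = id, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
      axis = NA_character_, coord = NA_real_,
      child_lo = NA_integer_, child_hi = NA_integer_, parent = node$id
    )
  }
  if (axis == "vertical") {
    lo <- mk(id_lo, node$x0, node$y0, coordinate, node$y1)
    hi <- mk(id_hi, coordinate, node$y0, node$x1, node$y1)
  } else {
    lo <- mk(id_lo, node$x0, node$y0, node$x1, coordinate)
    hi <- mk(id_hi, node$x0, coordinate, node$x1, node$y1)
  }
  node$axis <- axis
  node$coord <- as.double(coordinate)
  node$child_lo <- id_lo
  node$child_hi <- id_hi
  partition$nodes[[as.character(node$id)]] <- node
  partition$nodes[[as.character(id_lo)]] <- lo
  partition$nodes[[as.character(id_hi)]] <- hi
  partition$next_id <- id_hi + 1L
  if (!is.na(partition$selected) && partition$selected == node$id) {
    partition$selected <- NA_integer_
  }
  partition
}

#' Merge the two child zones of a split back into one
#'
#' Removes the split line of an internal node whose children are both
#' leaves (merges proceed bottom-up). A selection pointing into the merged
#' pair is cleared.
#'
#' @param partition a `region_partition`.
#' @param node_id id of the internal node to merge (or of either of its
#'   leaf children, as a convenience matching "remove this line").
#' @return the updated partition.
#' @export
merge_regions <- function(partition, node_id) {
  node <- get_node(partition, node_id)
  if (is_leaf(node)) {
    if (is.na(node$parent)) {
      abort("cannot merge: the whole field is a single zone")
    }
    node <- get_node(partition, node$parent)
  }
  lo <- get_node(partition, node$child_lo)
  hi <- get_node(partition, node$child_hi)
  if (!is_leaf(lo) || !is_leaf(hi)) {
    abort(sprintf(
      "region %d has subdivided children; merge those first", node$id
    ))
  }
  if (!is.na(partition$selected) &&
      partition$selected %in% c(lo$id, hi$id)) {
    partition$selected <- NA_integer_
  }
  partition$nodes[[as.character(lo$id)]] <- NULL
  partition$nodes[[as.character(hi$id)]] <- NULL
  node$axis <- NA_character_
  node$coord <- NA_real_
  node$child_lo <- NA_integer_
  node$child_hi <- NA_integer_
  partition$nodes[[as.character(node$id)]] <- node
  partition
}

#' Select a zone for per-region statistics
#'
#' @param partition a `region_partition`.
#' @param region_id id of a current leaf, or `NA` to clear the selection.
#' @return the updated partition.
#' @export
select_region <- function(partition, region_id) {
  if (is.na(region_id)) {
    partition$selected <- NA_integer_
    return(partition)
  }
  node <- get_node(partition, region_id)
  if (!is_leaf(node)) {
    abort(sprintf("region %d is not a current zone", node$id))
  }
  partition$selected <- node$id
  partition
}

#' Track ids inside a rectangular region at a time step
#'
#' Membership uses half-open intervals `[x0, x1) x [y0, y1)` on box
#' centers, with a cell sitting exactly on the field's right or top edge
#' assigned to the zone touching that edge, so zones partition the cells
#' with deterministic boundary ties.
#'
#' @param region one row of [partition_leaves()] (or any list with
#'   `x0`, `y0`, `x1`, `y1`), optionally with the field attached via
#'   `field_width`/`field_height` arguments.
#' @param dataset a `tracking_dataset`.
#' @param t time step.
#' @return integer vector of track ids.
#' @export
points_in_region <- function(region, dataset, t) {
  ctr <- box_center(filter(dataset$observations, .data$time_step == t))
  inside <- region_contains(region, ctr$x, ctr$y,
                            dataset$field_width, dataset$field_height)
  sort(ctr$track_id[inside])
}

region_contains <- function(region, x, y, field_w, field_h) {
  hi_x <- if (region$x1 >= field_w) x <= region$x1 else x < region$x1
  hi_y <- if (region$y1 >= field_h) y <= region$y1 else y < region$y1
  x >= region$x0 & hi_x & y >= region$y0 & hi_y
}

#' Global and selected-region displacement histograms
#'
#' The statistic view's histogram block: horizontal and vertical
#' displacement histograms over all direction vectors at step `t`, plus —
#' when a zone is selected — the same pair restricted to vectors whose
#' *start* position lies in the selected zone. Both pairs share bin edges
#' so the regional histogram reads directly against the global one.
#'
#' @param partition a `region_partition` (its selection drives the
#'   regional pair).
#' @param dataset a `tracking_dataset`.
#' @param t time step (vectors from `t` to `t + 1`); `NULL` pools every
#'   step.
#' @param bins bin edges shared by all histograms (`NULL` = default spec
#'   computed from the global vectors, per axis).
#' @return list with `global` (list of `horizontal`/`vertical`
#'   histograms), `regional` (same shape, or `NULL` when nothing is
#'   selected), and `n_vectors`.
#' @export
regional_histograms <- function(partition, dataset, t = NULL, bins = NULL) {
  v <- direction_vectors(dataset, t)
  global <- list(
    horizontal = displacement_histogram(v, "horizontal", bins),
    vertical = displacement_histogram(v, "vertical", bins)
  )
  regional <- NULL
  if (!is.na(partition$selected)) {
    leaf <- get_node(partition, partition$selected)
    inside <- region_contains(leaf, v$x, v$y,
                              partition$field_width, partition$field_height)
    vr <- v[inside, ]
    regional <- list(
      horizontal = displacement_histogram(
        vr, "horizontal", global$horizontal$bin_edges),
      vertical = displacement_histogram(
        vr, "vertical", global$vertical$bin_edges)
    )
  }
  list(global = global, regional = regional, n_vectors = nrow(v))
}

#' Serialize a partition to JSON
#'
#' Zones survive a session: the split tree and selection are stored as a
#' small JSON document restorable with [read_partition_json()].
#'
#' @param partition a `region_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  doc <- list(
    field_width = partition$field_width,
    field_height = partition$field_height,
    next_id = partition$next_id,
    selected = if (is.na(partition$selected)) NULL else partition$selected,
    nodes = unname(lapply(partition$nodes, function(n) {
      n[!vapply(n, function(v) is.na(v) && !is.character(v), logical(1))]
    }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a partition from JSON
#'
#' @param path path written by [write_partition_json()].
#' @return a `region_partition`.
#' @export
read_partition_json <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- list()
  for (n in doc$nodes) {
    node <- list(
      id = as.integer(n$id),
      x0 = as.double(n$x0), y0 = as.double(n$y0),
      x1 = as.double(n$x1), y1 = as.double(n$y1),
      axis = if (is.null(n$axis)) NA_character_ else n$axis,
      coord = if (is.null(n$coord)) NA_real_ else as.double(n$coord),
      child_lo = if (is.null(n$child_lo)) NA_integer_ else
        as.integer(n$child_lo),
      child_hi = if (is.null(n$child_hi)) NA_integer_ else
        as.integer(n$child_hi),
      parent = if (is.null(n$parent)) NA_integer_ else as.integer(n$parent)
    )
    nodes[[as.character(node$id)]] <- node
  }
  structure(
    list(
      nodes = nodes,
      next_id = as.integer(doc$next_id),
      selected = if (is.null(doc$selected)) NA_integer_ else
        as.integer(doc$selected),
      field_width = as.double(doc$field_width),
      field_height = as.double(doc$field_height)
    ),
    class = "region_partition"
  )
}
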