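# Fixture builders and independent oracles used across the suite.

# A 7-track handcrafted pedigree: 3 initial cells at t = 1, tracks 1 and 2
# each divide at t = 2 (parents end at t = 1), and 2 new unparented cells
# appear at t = 3. Gives n_cells (3, 5, 7), n_mitosis (0, 2, 0),
# n_appearance (3, 0, 2).
toy_division_dataset <- function() {
  rows <- list(
    c(1, 1, 100, 120, 20, 20, NA),
    c(1, 2, 300, 320, 20, 20, NA),
    c(1, 3, 500, 520, 20, 20, NA),
    c(2, 3, 505, 525, 20, 20, NA),
    c(3, 3, 510, 530, 20, 20, NA),
    c(2, 4, 80, 120, 20, 20, 1),
    c(2, 5, 120, 120, 20, 20, 1),
    c(3, 4, 85, 125, 20, 20, 1),
    c(3, 5, 125, 125, 20, 20, 1),
    c(2, 6, 280, 320, 20, 20, 2),
    c(2, 7, 320, 320, 20, 20, 2),
    c(3, 6, 285, 325, 20, 20, 2),
    c(3, 7, 325, 325, 20, 20, 2),
    c(3, 8, 700, 720, 20, 20, NA),
    c(3, 9, 800, 820, 20, 20, NA)
  )
  m <- do.call(rbind, rows)
  build_trackset(box_observations(
    time_step = m[, 1], track_id = m[, 2], left = m[, 3], top = m[, 4],
    height = m[, 5], width = m[, 6], img_height = 1000, img_width = 1000,
    parent_id = m[, 7]
  ))
}

# Random valid observation tibble (no lineage) with pixel-aligned boxes.
random_observations <- function(n_rows, field = 1000, n_tracks = 50) {
  ids <- sample.int(n_tracks, n_rows, replace = TRUE)
  steps <- sample.int(50, n_rows, replace = TRUE)
  keep <- !duplicated(cbind(steps, ids))
  ids <- ids[keep]
  steps <- steps[keep]
  n <- length(ids)
  w <- sample(5:30, n, replace = TRUE)
  h <- sample(5:30, n, replace = TRUE)
  left <- sample.int(field - 31, n, replace = TRUE)
  top <- h + sample.int(field - 31, n, replace = TRUE)
  box_observations(
    time_step = steps, track_id = ids, left = left, top = pmin(top, field),
    height = h, width = w, img_height = field, img_width = field
  )
}

# Random pedigree: each non-root is born after its parent track ends.
random_forest_dataset <- function(n_tracks, p_child = 0.6, field = 1000) {
  birth <- integer(n_tracks)
  parent <- rep(NA_integer_, n_tracks)
  end <- integer(n_tracks)
  birth[1] <- 1L
  end[1] <- birth[1] + sample.int(5, 1L) - 1L
  for (i in seq_len(n_tracks)[-1]) {
    assigned <- FALSE
    if (stats::runif(1) < p_child) {
      cand <- which(end[seq_len(i - 1L)] < 40L)
      if (length(cand) > 0L) {
        parent[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        birth[i] <- end[parent[i]] + sample.int(3, 1L)
        assigned <- TRUE
      }
    }
    if (!assigned) birth[i] <- sample.int(10, 1L)
    end[i] <- birth[i] + sample.int(5, 1L) - 1L
  }
  obs <- lapply(seq_len(n_tracks), function(i) {
    steps <- birth[i]:end[i]
    tibble::tibble(
      time_step = steps, track_id = i,
      left = stats::runif(1, 0, field - 20),
      top = stats::runif(1, 20, field),
      parent = parent[i]
    )
  })
  d <- dplyr::bind_rows(obs)
  build_trackset(box_observations(
    time_step = d$time_step, track_id = d$track_id, left = d$left,
    top = d$top, height = 10, width = 10, img_height = field,
    img_width = field, parent_id = d$parent
  ))
}

# Oracle: connected component of the undirected parent graph.
brute_force_family <- function(tracks, id) {
  edges <- tracks[!is.na(tracks$parent_id), c("track_id", "parent_id")]
  comp <- id
  repeat {
    grown <- union(
      comp,
      c(
        edges$track_id[edges$parent_id %in% comp],
        edges$parent_id[edges$track_id %in% comp]
      )
    )
    if (length(grown) == length(comp)) {
      return(sort(as.integer(comp)))
    }
    comp <- grown
  }
}

# Oracle: per-value linear search over bins [e_i, e_{i+1}), last bin
# closed, values clamped into the end bins.
brute_force_bin_counts <- function(values, edges) {
  n <- length(edges) - 1L
  counts <- integer(n)
  for (v in values) {
    v <- min(max(v, edges[1]), edges[length(edges)])
    placed <- FALSE
    for (i in seq_len(n)) {
      hi_ok <- if (i == n) v <= edges[i + 1L] else v < edges[i + 1L]
      if (v >= edges[i] && hi_ok) {
        counts[i] <- counts[i] + 1L
        placed <- TRUE
        break
      }
    }
    stopifnot(placed)
  }
  counts
}

# Oracle: tight bounding box of a label in a mask matrix (1-based rows from
# the image top), returned in the Cartesian observation convention.
brute_force_bbox <- function(mask, label) {
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(NULL)
  }
  img_h <- nrow(mask)
  r0 <- min(idx[, 1]) - 1L
  r1 <- max(idx[, 1]) - 1L
  c0 <- min(idx[, 2]) - 1L
  c1 <- max(idx[, 2]) - 1L
  list(
    left = c0, top = img_h - r0,
    height = r1 - r0 + 1L, width = c1 - c0 + 1L
  )
}

# Apply a random sequence of valid splits to a fresh partition.
random_partition <- function(field_w, field_h, n_splits) {
  part <- new_partition(field_w, field_h)
  for (k in seq_len(n_splits)) {
    lv <- partition_leaves(part)
    i <- sample.int(nrow(lv), 1L)
    axis <- sample(c("horizontal", "vertical"), 1L)
    rng <- if (axis == "vertical") c(lv$x0[i], lv$x1[i]) else
      c(lv$y0[i], lv$y1[i])
    if (diff(rng) < 2) next
    coord <- stats::runif(1, rng[1] + diff(rng) / 4, rng[2] - diff(rng) / 4)
    part <- split_region(part, lv$region_id[i], axis, coord)
  }
  part
}

# Count elements in an SVG document; use the "svg:" prefix in xpath.
count_svg_elements <- function(svg, xpath) {
  doc <- xml2::read_xml(svg)
  length(xml2::xml_find_all(
    doc, xpath, ns = c(svg = "http://www.w3.org/2000/svg")
  ))
}
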