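#' Assemble observations into a tracking dataset
#'
#' Groups box observations by track id into time-ordered tracks, records
#' each track's (constant) parent link, birth and end time, and captures
#' the field dimensions and overall time span. This is the central record
#' every downstream query (lineage, kinematics, partitioning, rendering)
#' operates on.
#'
#' @param observations observation tibble (see [box_observations()]).
#' @param lenient passed to observation validation: clamp out-of-field
#'   boxes instead of rejecting them.
#' @return a `tracking_dataset`: list with `observations` (sorted tibble),
#'   `tracks` (one row per id: `track_id`, `parent_id`, `birth_time`,
#'   `end_time`, `n_obs`), `t_min`, `t_max`, `field_width`, `field_height`.
#' @export
build_trackset <- function(observations, lenient = FALSE) {
  obs <- validate_observations(
    arrange(observations, .data$time_step, .data$track_id),
    lenient = lenient, source = "observations"
  )
  if (nrow(obs) == 0L) {
    ds <- structure(
      list(
        observations = obs,
        tracks = tibble(
          track_id = integer(), parent_id = integer(),
          birth_time = integer(), end_time = integer(), n_obs = integer()
        ),
        t_min = NA_integer_, t_max = NA_integer_,
        field_width = NA_real_, field_height = NA_real_
      ),
      class = "tracking_dataset"
    )
    return(ds)
  }
  par_chk <- obs |>
    group_by(.data$track_id) |>
    summarise(n_par = dplyr::n_distinct(.data$parent_id), .groups = "drop")
  if (any(par_chk$n_par > 1L)) {
    abort(sprintf(
      "track %d reports more than one parent id across its rows",
      par_chk$track_id[which(par_chk$n_par > 1L)[1]]
    ))
  }
  tracks <- obs |>
    group_by(.data$track_id) |>
    summarise(
      parent_id = .data$parent_id[1],
      birth_time = min(.data$time_step),
      end_time = max(.data$time_step),
      n_obs = n(),
      .groups = "drop"
    ) |>
    arrange(.data$track_id)
  structure(
    list(
      observations = obs,
      tracks = tracks,
      t_min = min(tracks$birth_time),
      t_max = max(tracks$end_time),
      field_width = obs$img_width[1],
      field_height = obs$img_height[1]
    ),
    class = "tracking_dataset"
  )
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat(sprintf(
    "<tracking_dataset> %d tracks, %d observations, steps %s..%s, field %g x %g\n",
    nrow(x$tracks), nrow(x$observations), x$t_min, x$t_max,
    x$field_width, x$field_height
  ))
  invisible(x)
}

#' @method glance tracking_dataset
#' @export
glance.tracking_dataset <- function(x, ...) {
  tibble(
    n_tracks = nrow(x$tracks),
    n_observations = nrow(x$observations),
    t_min = x$t_min,
    t_max = x$t_max,
    field_width = x$field_width,
    field_height = x$field_height,
    n_roots = sum(is.na(x$tracks$parent_id))
  )
}

#' Build the lineage forest of a dataset
#'
#' Derives the ancestry forest induced by the per-track parent links:
#' mirrored parent/children maps over track ids, plus the set of roots
#' (tracks with no recorded parent). Children of one parent are ordered by
#' (birth time, id). Referencing a parent id absent from the dataset, or
#' any cycle in the parent relation, is an error.
#'
#' @param dataset a `tracking_dataset`.
#' @return a `lineage_forest`: list with `parent` (named integer vector,
#'   child id -> parent id), `children` (named list, parent id -> ordered
#'   child ids), `roots` (integer vector), and `tracks` (the dataset's
#'   track summary, for layout and queries).
#' @export
build_lineage_forest <- function(dataset) {
  tr <- dataset$tracks
  ids <- tr$track_id
  orphan <- !is.na(tr$parent_id) & !(tr$parent_id %in% ids)
  if (any(orphan)) {
    abort(sprintf(
      "parent id(s) absent from dataset: %s",
      paste(unique(tr$parent_id[orphan]), collapse = ", ")
    ))
  }
  parent <- tr$parent_id
  names(parent) <- as.character(ids)
  kids <- tr |>
    filter(!is.na(.data$parent_id)) |>
    arrange(.data$parent_id, .data$birth_time, .data$track_id)
  children <- split(kids$track_id, as.character(kids$parent_id))
  # cycle check: follow parent links from every node
  idx <- match(tr$parent_id, ids)
  for (s in seq_along(ids)) {
    i <- s
    steps <- 0L
    while (!is.na(idx[i])) {
      i <- idx[i]
      steps <- steps + 1L
      if (steps > length(ids)) {
        abort(sprintf("cycle detected in lineage at track %d", ids[s]))
      }
    }
  }
  structure(
    list(
      parent = parent,
      children = children,
      roots = ids[is.na(tr$parent_id)],
      tracks = tr
    ),
    class = "lineage_forest"
  )
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf(
    "<lineage_forest> %d tracks in %d tree(s), %d division(s)\n",
    length(x$parent), length(x$roots), length(x$children)
  ))
  invisible(x)
}

#' Tidy a lineage forest into an edge table
#'
#' @param x a `lineage_forest`.
#' @param ... unused.
#' @return tibble with one row per track: `track_id`, `parent_id`,
#'   `root_id`, `birth_time`, `end_time`.
#' @method tidy lineage_forest
#' @export
tidy.lineage_forest <- function(x, ...) {
  tr <- x$tracks
  root <- vapply(tr$track_id, function(id) root_of(x, id), integer(1))
  tibble(
    track_id = tr$track_id,
    parent_id = tr$parent_id,
    root_id = root,
    birth_time = tr$birth_time,
    end_time = tr$end_time
  )
}

root_of <- function(forest, id) {
  i <- id
  repeat {
    p <- forest$parent[[as.character(i)]]
    if (is.na(p)) {
      return(as.integer(i))
    }
    i <- p
  }
}

descendants_of <- function(forest, id) {
  out <- integer()
  stack <- id
  while (length(stack) > 0L) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- forest$children[[as.character(cur)]]
    if (!is.null(kids)) {
      out <- c(out, kids)
      stack <- c(stack, kids)
    }
  }
  out
}

#' Clonal family of a track
#'
#' Returns the full clonal family of `id`: the root of the lineage tree
#' containing `id` together with every descendant of that root — i.e. the
#' connected component of the forest. Selecting any member of a family
#' therefore yields the same set, so families partition the track ids.
#'
#' @param forest a `lineage_forest`.
#' @param id a track id present in the forest.
#' @return sorted integer vector of track ids.
#' @export
family_of <- function(forest, id) {
  if (!(as.character(id) %in% names(forest$parent))) {
    abort(sprintf("unknown track id: %s", id))
  }
  r <- root_of(forest, id)
  sort(c(r, descendants_of(forest, r)))
}

#' Validate a tracking dataset's pedigree and geometry
#'
#' Runs every consistency check and reports all violations at once rather
#' than stopping at the first: unique ids, no self-parenting, parents
#' present, acyclic pedigree, children born strictly after their parent
#' (a child born while the parent is still observed is only a warning),
#' and boxes inside the field.
#'
#' @param dataset a `tracking_dataset`.
#' @return a `validation_report` tibble with columns `severity`
#'   (`"error"`/`"warning"`), `code`, `message`, `track_id`. Zero error
#'   rows means the dataset is accepted.
#' @export
validate_dataset <- function(dataset) {
  tr <- dataset$tracks
  obs <- dataset$observations
  rep <- list()
  add <- function(severity, code, message, id = NA_integer_) {
    rep[[length(rep) + 1L]] <<- tibble(
      severity = severity, code = code, message = message,
      track_id = as.integer(id)
    )
  }
  selfp <- tr$track_id[!is.na(tr$parent_id) & tr$parent_id == tr$track_id]
  for (id in selfp) {
    add("error", "PEDIGREE_SELF", sprintf("track %d is its own parent", id), id)
  }
  known <- tr$parent_id %in% tr$track_id
  orphan <- tr$track_id[!is.na(tr$parent_id) & !known &
                          !(tr$track_id %in% selfp)]
  for (id in orphan) {
    add("error", "PEDIGREE_ORPHAN",
        sprintf("track %d references a parent absent from the dataset", id), id)
  }
  # birth ordering (only where the parent exists and is not a self-link)
  j <- match(tr$parent_id, tr$track_id)
  ok <- !is.na(j) & tr$parent_id != tr$track_id
  for (i in which(ok)) {
    pb <- tr$birth_time[j[i]]
    pe <- tr$end_time[j[i]]
    if (tr$birth_time[i] <= pb) {
      add("error", "BIRTH_ORDER",
          sprintf("track %d born at step %d, not after its parent's birth %d",
                  tr$track_id[i], tr$birth_time[i], pb), tr$track_id[i])
    } else if (tr$birth_time[i] <= pe) {
      add("warning", "PARENT_COEXISTS",
          sprintf("track %d born at step %d while parent %d persists to %d",
                  tr$track_id[i], tr$birth_time[i], tr$parent_id[i], pe),
          tr$track_id[i])
    }
  }
  if (nrow(obs) > 0L) {
    w <- dataset$field_width
    h <- dataset$field_height
    oob <- obs$left < 0 | obs$left + obs$width > w |
      obs$top > h | obs$top - obs$height < 0
    for (i in which(oob)) {
      add("error", "BOX_BOUNDS",
          sprintf("track %d box at step %d exceeds the field",
                  obs$track_id[i], obs$time_step[i]), obs$track_id[i])
    }
  }
  # acyclicity (skip if self/orphan already reported)
  if (length(selfp) == 0L && length(orphan) == 0L && nrow(tr) > 0L) {
    idx <- match(tr$parent_id, tr$track_id)
    for (s in seq_len(nrow(tr))) {
      i <- s
      steps <- 0L
      while (!is.na(idx[i])) {
        i <- idx[i]
        steps <- steps + 1L
        if (steps > nrow(tr)) {
          add("error", "PEDIGREE_CYCLE",
              sprintf("cycle in lineage involving track %d", tr$track_id[s]),
              tr$track_id[s])
          break
        }
      }
    }
  }
  out <- if (length(rep) == 0L) {
    tibble(severity = character(), code = character(),
           message = character(), track_id = integer())
  } else {
    bind_rows(rep)
  }
  class(out) <- c("validation_report", class(out))
  out
}
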