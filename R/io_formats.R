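#' @importFrom rlang .data abort warn
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   bind_rows left_join n distinct
#' @importFrom tibble tibble as_tibble
NULL

TRACK_COLS <- c(
  "time_step", "track_id", "left", "top", "height", "width",
  "img_height", "img_width", "parent_id"
)

#' Construct a box-observation tibble
#'
#' One row per object per frame, in the 9-column multiple-object-tracking
#' style layout used throughout the package: frame index, track id, an
#' axis-aligned bounding box, the field (image) dimensions, and a parent
#' track id encoding the lineage link. Coordinates live in a Cartesian
#' frame with x rightward and y upward, origin at the bottom-left of the
#' field; `top` is the maximum y of the box, `left` the minimum x.
#'
#' @param time_step integer frame index, first frame = 1.
#' @param track_id positive integer cell id.
#' @param left,top,height,width bounding box in field pixels (`top` is the
#'   box's maximum y coordinate).
#' @param img_height,img_width field dimensions in pixels (constant across
#'   a dataset).
#' @param parent_id parent track id, or `NA` for cells with no recorded
#'   ancestor.
#' @return a tibble with the nine canonical columns, typed and ordered.
#' @export
box_observations <- function(time_step, track_id, left, top, height, width,
                             img_height, img_width, parent_id = NA_integer_) {
  obs <- tibble(
    time_step = as.integer(time_step),
    track_id = as.integer(track_id),
    left = as.double(left),
    top = as.double(top),
    height = as.double(height),
    width = as.double(width),
    img_height = as.double(img_height),
    img_width = as.double(img_width),
    parent_id = as.integer(parent_id)
  )
  arrange(obs, .data$time_step, .data$track_id)
}

validate_observations <- function(obs, lenient = FALSE, source = "input") {
  stopifnot(all(TRACK_COLS %in% names(obs)))
  if (nrow(obs) == 0L) {
    return(obs)
  }
  if (anyNA(obs$time_step) || anyNA(obs$track_id)) {
    abort(sprintf("%s: missing time step or track id", source))
  }
  if (any(obs$track_id < 1L)) {
    abort(sprintf("%s: track ids must be positive", source))
  }
  if (any(obs$height < 0 | obs$width < 0)) {
    abort(sprintf("%s: negative box dimensions", source))
  }
  dup <- duplicated(obs[c("time_step", "track_id")])
  if (any(dup)) {
    bad <- obs[dup, c("time_step", "track_id")]
    abort(sprintf(
      "%s: duplicate (time_step, track_id) pairs, e.g. (%d, %d)",
      source, bad$time_step[1], bad$track_id[1]
    ))
  }
  if (any(obs$parent_id == obs$track_id, na.rm = TRUE)) {
    abort(sprintf("%s: a track cannot be its own parent", source))
  }
  if (length(unique(obs$img_width)) != 1L ||
      length(unique(obs$img_height)) != 1L) {
    abort(sprintf("%s: img_height/img_width must be constant per file", source))
  }
  w <- obs$img_width[1]
  h <- obs$img_height[1]
  oob <- obs$left < 0 | obs$left + obs$width > w |
    obs$top > h | obs$top - obs$height < 0
  if (any(oob)) {
    if (!lenient) {
      abort(sprintf(
        "%s: %d box(es) exceed the %g x %g field (first offending track %d at step %d); use lenient = TRUE to clamp",
        source, sum(oob), w, h,
        obs$track_id[which(oob)[1]], obs$time_step[which(oob)[1]]
      ))
    }
    warn(sprintf("%s: clamped %d out-of-field box(es)", source, sum(oob)))
    obs <- mutate(obs,
      width = pmin(.data$width, w),
      height = pmin(.data$height, h),
      left = pmin(pmax(.data$left, 0), w - .data$width),
      top = pmax(pmin(.data$top, h), .data$height)
    )
  }
  obs
}

#' Read a trajectory-with-lineage CSV
#'
#' Parses the 9-column comma-separated layout
#' `time step, ID, left, top, height, width, img_height, img_width, parent`.
#' A first header row is auto-detected (a row whose second field is not
#' numeric) and skipped. The sentinel `-1` in the parent column denotes an
#' absent parent and is mapped to `NA`.
#'
#' @param path path to the CSV file.
#' @param lenient if `TRUE`, boxes that overshoot the field boundary are
#'   clamped with a warning instead of rejected.
#' @return observation tibble sorted by (`time_step`, `track_id`).
#' @export
read_track_csv <- function(path, lenient = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("track file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L) {
    first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2])))) {
      lines <- lines[-1]
    }
  }
  if (length(lines) == 0L) {
    return(box_observations(integer(), integer(), double(), double(),
                            double(), double(), double(), double()))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity != 9L)) {
    abort(sprintf(
      "malformed trajectory row %d: expected 9 fields, found %d",
      which(arity != 9L)[1], arity[which(arity != 9L)[1]]
    ))
  }
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(fields)))),
              ncol = 9L, byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf(
      "malformed trajectory row %d: non-numeric field",
      which(rowSums(is.na(m)) > 0)[1]
    ))
  }
  parent <- as.integer(m[, 9])
  parent[parent == -1L] <- NA_integer_
  obs <- box_observations(
    time_step = m[, 1], track_id = m[, 2], left = m[, 3], top = m[, 4],
    height = m[, 5], width = m[, 6], img_height = m[, 7], img_width = m[, 8],
    parent_id = parent
  )
  validate_observations(obs, lenient = lenient, source = path)
}

#' Write a trajectory-with-lineage CSV
#'
#' Inverse of [read_track_csv()]: emits rows in the canonical 9-column
#' order, writing absent parents as the sentinel `-1`, so that a
#' read-after-write round trip reproduces the observation tibble exactly.
#'
#' @param observations observation tibble (see [box_observations()]).
#' @param path output file path.
#' @param header write a header row naming the columns (default `TRUE`;
#'   the reader auto-detects either form).
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(observations, path, header = TRUE) {
  obs <- arrange(observations, .data$time_step, .data$track_id)
  parent <- ifelse(is.na(obs$parent_id), -1L, obs$parent_id)
  rows <- sprintf(
    "%d,%d,%s,%s,%s,%s,%s,%s,%d",
    obs$time_step, obs$track_id,
    format(obs$left, trim = TRUE, scientific = FALSE, digits = 15),
    format(obs$top, trim = TRUE, scientific = FALSE, digits = 15),
    format(obs$height, trim = TRUE, scientific = FALSE, digits = 15),
    format(obs$width, trim = TRUE, scientific = FALSE, digits = 15),
    format(obs$img_height, trim = TRUE, scientific = FALSE, digits = 15),
    format(obs$img_width, trim = TRUE, scientific = FALSE, digits = 15),
    parent
  )
  if (header) {
    rows <- c(paste(TRACK_COLS, collapse = ","), rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a per-time-step statistic CSV
#'
#' Layout: `time step, 1st stat., 2nd stat., ...` — the first field of each
#' row is the time step, the rest are numeric statistic columns. Column
#' names come from a header row when present, else from `column_names`,
#' else are auto-named `stat_1 .. stat_k`.
#'
#' @param path path to the CSV file.
#' @param column_names optional character vector naming the statistic
#'   columns (excluding the time-step column).
#' @return a `statistic_table` tibble: integer `time_step` plus one numeric
#'   column per statistic.
#' @export
read_statistic_csv <- function(path, column_names = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("statistic file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("%s: empty statistic file", path))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- NULL
  first <- fields[[1]]
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2])))) {
    header <- trimws(first[-1])
    fields <- fields[-1]
  }
  if (length(fields) == 0L) {
    abort(sprintf("%s: statistic file has a header but no data rows", path))
  }
  arity <- lengths(fields)
  if (length(unique(arity)) != 1L) {
    abort(sprintf("%s: ragged statistic rows (row %d)",
                  path, which(arity != arity[1])[1]))
  }
  if (arity[1] < 2L) {
    abort(sprintf("%s: statistic rows need a time step and at least one column",
                  path))
  }
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(fields)))),
              ncol = arity[1], byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf("%s: non-numeric statistic field (row %d)",
                  path, which(rowSums(is.na(m)) > 0)[1]))
  }
  k <- ncol(m) - 1L
  names_k <- header %||% column_names %||% paste0("stat_", seq_len(k))
  if (length(names_k) != k) {
    abort(sprintf("%s: %d column names supplied for %d statistic columns",
                  path, length(names_k), k))
  }
  ts <- as.integer(m[, 1])
  if (any(diff(ts) <= 0)) {
    abort(sprintf("%s: time steps must be strictly increasing", path))
  }
  out <- as_tibble(as.data.frame(m[, -1, drop = FALSE]))
  names(out) <- names_k
  out <- dplyr::bind_cols(tibble(time_step = ts), out)
  class(out) <- c("statistic_table", class(out))
  out
}

#' Write a statistic table as CSV
#'
#' Mirrors the layout read by [read_statistic_csv()]: the time step first,
#' then one numeric field per statistic column, with a header row.
#'
#' @param stats a `statistic_table` tibble (or any data frame whose first
#'   column is `time_step`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_statistic_csv <- function(stats, path) {
  stopifnot(names(stats)[1] == "time_step")
  vals <- lapply(stats[-1], function(x)
    format(x, trim = TRUE, scientific = FALSE, digits = 15))
  rows <- do.call(paste, c(list(stats$time_step), vals, sep = ","))
  writeLines(c(paste(names(stats), collapse = ","), rows), path)
  invisible(path)
}

#' Import Cell Tracking Challenge results
#'
#' Reads the CTC convention: a whitespace-separated track file of
#' `L B E P` records (label, begin frame, end frame, parent label; frames
#' 0-based; parent 0 = none) together with one integer-labelled mask image
#' per frame in `mask_dir` (lexicographic order). For each label and frame
#' in its span where the label occupies at least one pixel, the tight
#' pixel bounding box is emitted as a box observation in the canonical
#' Cartesian frame (y up, `top` = maximum y), with internal time steps
#' shifted to first-frame = 1.
#'
#' @param track_file path to the `L B E P` track text file.
#' @param mask_dir directory of labelled mask images (TIFF or PNG).
#' @return observation tibble sorted by (`time_step`, `track_id`).
#' @export
import_ctc <- function(track_file, mask_dir) {
  if (!file.exists(track_file)) {
    abort(sprintf("CTC track file not found: %s", track_file))
  }
  recs <- utils::read.table(track_file,
    col.names = c("label", "begin", "end", "parent")
  )
  if (nrow(recs) == 0L) {
    return(box_observations(integer(), integer(), double(), double(),
                            double(), double(), double(), double()))
  }
  mask_paths <- sort(list.files(mask_dir,
    pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE, full.names = TRUE
  ))
  n_needed <- max(recs$end) + 1L
  if (length(mask_paths) < n_needed) {
    abort(sprintf(
      "CTC mask directory %s holds %d mask(s) but tracks span %d frame(s)",
      mask_dir, length(mask_paths), n_needed
    ))
  }
  masks <- lapply(mask_paths[seq_len(n_needed)], read_label_mask)
  img_h <- nrow(masks[[1]])
  img_w <- ncol(masks[[1]])
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    lab <- recs$label[i]
    hits <- list()
    for (fr in recs$begin[i]:recs$end[i]) {
      m <- masks[[fr + 1L]]
      idx <- which(m == lab, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      r0 <- min(idx[, 1]) - 1L # 0-based pixel rows/cols
      r1 <- max(idx[, 1]) - 1L
      c0 <- min(idx[, 2]) - 1L
      c1 <- max(idx[, 2]) - 1L
      hits[[length(hits) + 1L]] <- tibble(
        time_step = fr + 1L,
        track_id = lab,
        left = as.double(c0),
        top = as.double(img_h - r0),
        height = as.double(r1 - r0 + 1L),
        width = as.double(c1 - c0 + 1L)
      )
    }
    if (length(hits) == 0L) {
      warn(sprintf("CTC label %d absent from all masks in its span; skipped",
                   lab))
      next
    }
    h <- bind_rows(hits)
    h$img_height <- as.double(img_h)
    h$img_width <- as.double(img_w)
    h$parent_id <- if (recs$parent[i] == 0L) NA_integer_ else
      as.integer(recs$parent[i])
    out[[i]] <- h
  }
  obs <- bind_rows(out)
  if (nrow(obs) == 0L) {
    return(box_observations(integer(), integer(), double(), double(),
                            double(), double(), double(), double()))
  }
  obs <- box_observations(
    obs$time_step, obs$track_id, obs$left, obs$top, obs$height, obs$width,
    obs$img_height, obs$img_width, obs$parent_id
  )
  validate_observations(obs, source = track_file)
}

read_label_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path)
    # png stores intensities in [0,1]; labels were written as v / 65535
    m <- round(m * 65535)
  } else {
    abort(sprintf("unsupported mask format: %s", path))
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

IMAGE_EXTS <- c("jpg", "jpeg", "png", "bmp", "gif", "tif", "tiff")

#' Enumerate a background image sequence
#'
#' Collects the frames backing the trajectory view: either a directory (or
#' explicit file list) of single-frame images in lexicographic order, or a
#' single multi-page TIFF stack whose slices are treated as consecutive
#' frames. Frame i serves time step i (1-based); all files must share one
#' of the supported formats (JPEG, PNG, BMP, GIF, TIFF).
#'
#' @param source a directory, a character vector of files, or one TIFF
#'   stack path.
#' @return an `image_sequence` tibble with columns `time_step`, `path`,
#'   `slice` (slice index within a stack, 1 for plain files) and `format`.
#' @export
load_image_sequence <- function(source) {
  if (length(source) == 1L && dir.exists(source)) {
    files <- sort(list.files(source, full.names = TRUE))
  } else {
    files <- sort(source)
  }
  if (length(files) == 0L) {
    abort("empty image sequence source")
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    abort(sprintf("image frame not found: %s", missing[1]))
  }
  exts <- tolower(tools::file_ext(files))
  bad <- setdiff(unique(exts), IMAGE_EXTS)
  if (length(bad) > 0L) {
    abort(sprintf("unsupported image format(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fmt <- ifelse(exts %in% c("tif", "tiff"), "tiff",
         ifelse(exts %in% c("jpg", "jpeg"), "jpeg", exts))
  if (length(unique(fmt)) > 1L) {
    abort(sprintf("mixed image formats in one sequence: %s",
                  paste(unique(fmt), collapse = ", ")))
  }
  if (length(files) == 1L && fmt[1] == "tiff") {
    slices <- tiff::readTIFF(files[1], all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    out <- tibble(
      time_step = seq_along(slices),
      path = files[1],
      slice = seq_along(slices),
      format = "tiff"
    )
  } else {
    out <- tibble(
      time_step = seq_along(files),
      path = files,
      slice = 1L,
      format = fmt
    )
  }
  class(out) <- c("image_sequence", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
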