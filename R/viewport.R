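#' Create a viewport over the field
#'
#' The viewport is the mini-map/zoom state: the visible sub-rectangle of
#' the field (in field px, Cartesian y-up) plus the output size in screen
#' px. The visible rectangle's aspect ratio always matches the output's;
#' the initial visible rectangle is the largest such rectangle anchored at
#' the field's lower-left that fits the field.
#'
#' @param field_width,field_height field size in px.
#' @param out_width,out_height output (screen) size in px; defaults to the
#'   field size.
#' @return a `field_viewport` object.
#' @export
new_viewport <- function(field_width, field_height,
                         out_width = field_width, out_height = field_height) {
  if (field_width <= 0 || field_height <= 0 ||
      out_width <= 0 || out_height <= 0) {
    abort("viewport dimensions must be positive")
  }
  aspect <- out_width / out_height
  if (field_width / field_height >= aspect) {
    vis_h <- field_height
    vis_w <- vis_h * aspect
  } else {
    vis_w <- field_width
    vis_h <- vis_w / aspect
  }
  structure(
    list(
      x0 = 0, y0 = 0, x1 = vis_w, y1 = vis_h,
      out_width = as.double(out_width), out_height = as.double(out_height),
      field_width = as.double(field_width),
      field_height = as.double(field_height)
    ),
    class = "field_viewport"
  )
}

clamp_viewport <- function(vp) {
  w <- vp$x1 - vp$x0
  h <- vp$y1 - vp$y0
  if (w > vp$field_width || h > vp$field_height) {
    s <- min(vp$field_width / w, vp$field_height / h)
    cx <- (vp$x0 + vp$x1) / 2
    cy <- (vp$y0 + vp$y1) / 2
    w <- w * s
    h <- h * s
    vp$x0 <- cx - w / 2
    vp$x1 <- cx + w / 2
    vp$y0 <- cy - h / 2
    vp$y1 <- cy + h / 2
  }
  dx <- max(0, -vp$x0) - max(0, vp$x1 - vp$field_width)
  dy <- max(0, -vp$y0) - max(0, vp$y1 - vp$field_height)
  vp$x0 <- vp$x0 + dx
  vp$x1 <- vp$x1 + dx
  vp$y0 <- vp$y0 + dy
  vp$y1 <- vp$y1 + dy
  vp
}

#' Zoom the viewport about an anchor point
#'
#' Scales the visible rectangle by `1/factor` about `anchor` (field
#' coordinates): `factor > 1` zooms in. The rectangle is then slid (not
#' reshaped) back inside the field if the anchor was near a boundary, so
#' the aspect ratio is always preserved. One mouse-wheel notch in the
#' interactive idiom corresponds to `factor = 1.25`.
#'
#' @param viewport a `viewport`.
#' @param factor positive zoom factor.
#' @param anchor length-2 numeric `(x, y)` in field px; defaults to the
#'   visible center.
#' @return the updated viewport.
#' @export
zoom <- function(viewport, factor, anchor = NULL) {
  if (factor <= 0) {
    abort("zoom factor must be positive")
  }
  anchor <- anchor %||% c((viewport$x0 + viewport$x1) / 2,
                          (viewport$y0 + viewport$y1) / 2)
  s <- 1 / factor
  viewport$x0 <- anchor[1] + (viewport$x0 - anchor[1]) * s
  viewport$x1 <- anchor[1] + (viewport$x1 - anchor[1]) * s
  viewport$y0 <- anchor[2] + (viewport$y0 - anchor[2]) * s
  viewport$y1 <- anchor[2] + (viewport$y1 - anchor[2]) * s
  clamp_viewport(viewport)
}

#' Pan the viewport
#'
#' Translates the visible rectangle by `delta` field px, clamping so it
#' stays inside the field.
#'
#' @param viewport a `viewport`.
#' @param delta length-2 numeric `(dx, dy)` in field px.
#' @return the updated viewport.
#' @export
pan <- function(viewport, delta) {
  viewport$x0 <- viewport$x0 + delta[1]
  viewport$x1 <- viewport$x1 + delta[1]
  viewport$y0 <- viewport$y0 + delta[2]
  viewport$y1 <- viewport$y1 + delta[2]
  clamp_viewport(viewport)
}

#' Map field coordinates to screen coordinates
#'
#' Affine map of the visible rectangle onto the output rectangle with the
#' y axis flipped (field y-up to screen y-down): the visible corner
#' `(x0, y1)` maps to screen `(0, 0)`. Points outside the visible
#' rectangle map outside the output bounds.
#'
#' @param viewport a `viewport`.
#' @param x,y field coordinates (vectors of equal length).
#' @return tibble with screen `sx`, `sy`.
#' @export
field_to_screen <- function(viewport, x, y) {
  w <- viewport$x1 - viewport$x0
  h <- viewport$y1 - viewport$y0
  if (w <= 0 || h <= 0) {
    abort("degenerate viewport")
  }
  tibble(
    sx = (x - viewport$x0) / w * viewport$out_width,
    sy = (viewport$y1 - y) / h * viewport$out_height
  )
}

#' Map screen coordinates back to field coordinates
#'
#' Inverse of [field_to_screen()].
#'
#' @param viewport a `viewport`.
#' @param sx,sy screen coordinates.
#' @return tibble with field `x`, `y`.
#' @export
screen_to_field <- function(viewport, sx, sy) {
  w <- viewport$x1 - viewport$x0
  h <- viewport$y1 - viewport$y0
  if (w <= 0 || h <= 0) {
    abort("degenerate viewport")
  }
  tibble(
    x = viewport$x0 + sx / viewport$out_width * w,
    y = viewport$y1 - sy / viewport$out_height * h
  )
}

#' @export
print.field_viewport <- function(x, ...) {
  cat(sprintf("<viewport> visible (%g, %g)-(%g, %g) of %g x %g field -> %g x %g px\n",
              x$x0, x$y0, x$x1, x$y1, x$field_width, x$field_height,
              x$out_width, x$out_height))
  invisible(x)
}
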