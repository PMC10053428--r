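# Minimal deterministic SVG emission. Numbers are formatted with a fixed
# %.3f so identical inputs always yield byte-identical documents.

fmt_num <- function(x) {
  s <- sprintf("%.3f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

svg_attrs <- function(...) {
  a <- list(...)
  a <- a[!vapply(a, is.null, logical(1))]
  if (length(a) == 0L) {
    return("")
  }
  vals <- vapply(a, function(v) {
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }, character(1))
  paste0(" ", paste(sprintf('%s="%s"', names(a), vals), collapse = " "))
}

svg_el <- function(tag, ..., content = NULL) {
  if (is.null(content)) {
    sprintf("<%s%s/>", tag, svg_attrs(...))
  } else {
    sprintf("<%s%s>%s</%s>", tag, svg_attrs(...),
            paste(content, collapse = ""), tag)
  }
}

svg_circle <- function(cx, cy, r, class, fill = "none", stroke = "none",
                       dash = NULL, width = 1) {
  svg_el("circle",
    cx = cx, cy = cy, r = r, class = class, fill = fill, stroke = stroke,
    `stroke-width` = width, `stroke-dasharray` = dash
  )
}

svg_line <- function(x1, y1, x2, y2, class, stroke = "#000000", width = 1,
                     dash = NULL) {
  svg_el("line",
    x1 = x1, y1 = y1, x2 = x2, y2 = y2, class = class, stroke = stroke,
    `stroke-width` = width, `stroke-dasharray` = dash
  )
}

svg_polyline <- function(x, y, class, stroke = "#000000", width = 1,
                         dash = NULL, extra = list()) {
  pts <- paste(paste0(vapply(x, fmt_num, character(1)), ",",
                      vapply(y, fmt_num, character(1))), collapse = " ")
  do.call(svg_el, c(
    list("polyline", points = pts, class = class, fill = "none",
         stroke = stroke, `stroke-width` = width, `stroke-dasharray` = dash),
    extra
  ))
}

svg_rect <- function(x, y, w, h, class, fill = "none", stroke = "none",
                     width = 1, opacity = NULL) {
  svg_el("rect",
    x = x, y = y, width = w, height = h, class = class, fill = fill,
    stroke = stroke, `stroke-width` = width, opacity = opacity
  )
}

svg_text <- function(x, y, label, class, size = 10, fill = "#000000") {
  svg_el("text",
    x = x, y = y, class = class, `font-size` = size, fill = fill,
    content = xml_escape(label)
  )
}

svg_image <- function(href, x, y, w, h, class, opacity = 1) {
  svg_el("image",
    href = href, x = x, y = y, width = w, height = h, class = class,
    opacity = opacity, preserveAspectRatio = "none"
  )
}

svg_group <- function(content, class = NULL, transform = NULL) {
  svg_el("g", class = class, transform = transform, content = content)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_document <- function(width, height, content, class = NULL) {
  paste0(
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s"%s>',
      fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height),
      if (is.null(class)) "" else sprintf(' class="%s"', class)
    ),
    paste(content, collapse = ""),
    "</svg>"
  )
}
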