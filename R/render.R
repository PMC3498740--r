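# Static deliverables: network renders with the painted images embedded in
# the nodes, visual-clustering grids, stacked comparisons, and a
# self-contained HTML gallery. Every export is deterministic: fixed inputs
# give byte-identical output (no timestamps, no unordered iteration, text
# drawn with the package's own bitmap font).

#' Rendering style for network figures
#'
#' @param node_padding Padding between node border and embedded image (px).
#' @param edge_color Integer RGB triple for edges.
#' @param edge_width Stroke width (px).
#' @param font_color Integer RGB triple for labels.
#' @param background Integer RGB triple for the canvas.
#' @param margin Canvas margin around the node extents (px).
#' @return A list of class `render_style`.
#' @export
render_style <- function(node_padding = 3, edge_color = c(80L, 80L, 80L),
                         edge_width = 1, font_color = c(0L, 0L, 0L),
                         background = c(255L, 255L, 255L), margin = 40) {
  stopifnot(node_padding >= 0, edge_width > 0, margin >= 0)
  structure(list(node_padding = node_padding, edge_color = edge_color,
                 edge_width = edge_width, font_color = font_color,
                 background = background, margin = margin),
            class = "render_style")
}

# Arrowhead family per interaction string: inhibition-like terms get a flat
# bar, everything else a solid arrow.
.edge_head <- function(interaction) {
  ifelse(grepl("inhibit|repress|suppress", tolower(interaction)),
         "bar", "arrow")
}

.resolve_image <- function(ref, images_dir) {
  if (!is.na(ref) && !file.exists(ref) && !is.null(images_dir)) {
    cand <- file.path(images_dir, ref)
    if (file.exists(cand)) return(cand)
  }
  ref
}

#' Render a network to SVG or PNG
#'
#' Nodes are drawn as rounded rectangles at their layout positions (a grid
#' fallback is applied first when positions are missing); a node with an
#' `image_ref` shows the painted image inside its boundary at preserved
#' aspect ratio with the label beneath. Edges get interaction-specific
#' heads (arrow; flat bar for inhibition). SVG embeds the rasters as base64
#' data URIs so the file is self-contained.
#'
#' @param net An [omics_network()].
#' @param path Output file; extension selects the format unless `format`
#'   is given.
#' @param style A [render_style()].
#' @param format `"svg"` or `"png"`.
#' @param images_dir Directory against which relative `image_ref` paths are
#'   resolved.
#' @return `path`, invisibly.
#' @export
render_network <- function(net, path, style = render_style(),
                           format = c("auto", "svg", "png"),
                           images_dir = NULL) {
  stopifnot(inherits(net, "omics_network"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "png") "png" else "svg"
  }
  net <- assign_grid_layout(net)
  n <- net$nodes
  refs <- vapply(n$image_ref, .resolve_image, "", images_dir = images_dir)
  for (i in seq_len(nrow(n))) {
    if (!is.na(refs[i]) && !file.exists(refs[i])) {
      stop("image for node '", n$id[i], "' not found: ", refs[i])
    }
  }
  if (format == "svg") {
    .render_svg(net, refs, path, style)
  } else {
    .render_png(net, refs, path, style)
  }
  invisible(path)
}

.canvas_box <- function(n, margin) {
  x0 <- min(n$x - n$w / 2) - margin
  y0 <- min(n$y - n$h / 2) - margin - 12  # room for labels
  x1 <- max(n$x + n$w / 2) + margin
  y1 <- max(n$y + n$h / 2) + margin + 12
  c(x0, y0, x1, y1)
}

# Clip the segment from (x1,y1) towards (x2,y2) at the border of the
# w-by-h rectangle centred on (x2,y2); keeps arrowheads outside the node.
.clip_at_node <- function(x1, y1, x2, y2, w, h) {
  dx <- x2 - x1; dy <- y2 - y1
  if (dx == 0 && dy == 0) return(c(x2, y2))
  tx <- if (dx != 0) (w / 2) / abs(dx) else Inf
  ty <- if (dy != 0) (h / 2) / abs(dy) else Inf
  t <- min(tx, ty)
  t <- max(0, 1 - t)
  c(x1 + t * dx, y1 + t * dy)
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

.fmt <- function(x) format(round(x, 3), scientific = FALSE, trim = TRUE)

.render_svg <- function(net, refs, path, style) {
  n <- net$nodes
  box <- .canvas_box(n, style$margin)
  W <- .fmt(box[3] - box[1]); H <- .fmt(box[4] - box[2])
  ec <- rgb_to_hex(style$edge_color)
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'xmlns:xlink="http://www.w3.org/1999/xlink" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            W, H, W, H),
    "<defs>",
    sprintf(paste0('<marker id="arrow" viewBox="0 0 10 10" refX="9" refY="5" ',
                   'markerWidth="7" markerHeight="7" orient="auto-start-reverse">',
                   '<path d="M 0 0 L 10 5 L 0 10 z" fill="%s"/></marker>'), ec),
    sprintf(paste0('<marker id="bar" viewBox="0 0 4 10" refX="3" refY="5" ',
                   'markerWidth="4" markerHeight="8" orient="auto-start-reverse">',
                   '<rect x="1" y="0" width="2" height="10" fill="%s"/></marker>'),
            ec),
    "</defs>",
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            W, H, rgb_to_hex(style$background))
  )
  xs <- n$x - box[1]; ys <- n$y - box[2]
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    s <- match(e$source[i], n$id); t <- match(e$target[i], n$id)
    head <- .edge_head(e$interaction[i])
    if (s == t) { # self-loop at the node's top-right corner
      cx <- xs[s] + n$w[s] / 2; cy <- ys[s] - n$h[s] / 2
      r <- 12
      out <- c(out, sprintf(
        paste0('<path class="edge" d="M %s %s C %s %s %s %s %s %s" ',
               'fill="none" stroke="%s" stroke-width="%s" ',
               'marker-end="url(#%s)"/>'),
        .fmt(cx - r), .fmt(cy), .fmt(cx - r), .fmt(cy - 2 * r),
        .fmt(cx + r), .fmt(cy - 2 * r), .fmt(cx), .fmt(cy + 2),
        ec, .fmt(style$edge_width), head))
    } else {
      p1 <- .clip_at_node(xs[t], ys[t], xs[s], ys[s], n$w[s], n$h[s])
      p2 <- .clip_at_node(xs[s], ys[s], xs[t], ys[t], n$w[t], n$h[t])
      out <- c(out, sprintf(
        paste0('<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" ',
               'stroke="%s" stroke-width="%s" marker-end="url(#%s)"/>'),
        .fmt(p1[1]), .fmt(p1[2]), .fmt(p2[1]), .fmt(p2[2]),
        ec, .fmt(style$edge_width), head))
    }
  }
  for (i in seq_len(nrow(n))) {
    x0 <- xs[i] - n$w[i] / 2; y0 <- ys[i] - n$h[i] / 2
    dashed <- if (nzchar(n$node_class[i]) &&
                  !n$node_class[i] %in% c("macromolecule", "species", ""))
      ' stroke-dasharray="4 2"' else ""
    out <- c(out, sprintf(
      paste0('<rect class="node" x="%s" y="%s" width="%s" height="%s" rx="4" ',
             'fill="#FFFFFF" stroke="#303030" stroke-width="1"%s/>'),
      .fmt(x0), .fmt(y0), .fmt(n$w[i]), .fmt(n$h[i]), dashed))
    if (!is.na(refs[i])) {
      pad <- style$node_padding
      b64 <- jsonlite::base64_enc(readBin(refs[i], "raw",
                                          file.info(refs[i])$size))
      b64 <- gsub("[\r\n]", "", b64)
      out <- c(out, sprintf(
        paste0('<image class="node-image" x="%s" y="%s" width="%s" ',
               'height="%s" preserveAspectRatio="xMidYMid meet" ',
               'xlink:href="data:image/png;base64,%s"/>'),
        .fmt(x0 + pad), .fmt(y0 + pad), .fmt(n$w[i] - 2 * pad),
        .fmt(n$h[i] - 2 * pad), b64))
    }
    out <- c(out, sprintf(
      paste0('<text class="node-label" x="%s" y="%s" text-anchor="middle" ',
             'font-family="monospace" font-size="10" fill="%s">%s</text>'),
      .fmt(xs[i]), .fmt(y0 + n$h[i] + 11), rgb_to_hex(style$font_color),
      .xml_escape(n$label[i])))
  }
  out <- c(out, "</svg>")
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(out, collapse = "\n"), "\n")), con)
  close(con)
}

# Bresenham line into a raster.
.draw_line <- function(raster, x1, y1, x2, y2, color) {
  npt <- max(abs(x2 - x1), abs(y2 - y1), 1) + 1
  xs <- round(seq(x1, x2, length.out = npt))
  ys <- round(seq(y1, y2, length.out = npt))
  h <- dim(raster)[1]; w <- dim(raster)[2]
  ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  for (k in which(ok)) raster[ys[k], xs[k], ] <- as.integer(color)
  raster
}

.fill_rect <- function(raster, x0, y0, x1, y1, color) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  xr <- max(1, round(x0)):min(w, round(x1))
  yr <- max(1, round(y0)):min(h, round(y1))
  for (ch in 1:3) raster[yr, xr, ch] <- as.integer(color[ch])
  raster
}

.render_png <- function(net, refs, path, style) {
  n <- net$nodes
  box <- .canvas_box(n, style$margin)
  W <- ceiling(box[3] - box[1]); H <- ceiling(box[4] - box[2])
  cv <- new_raster(W, H, style$background)
  xs <- n$x - box[1]; ys <- n$y - box[2]
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    s <- match(e$source[i], n$id); t <- match(e$target[i], n$id)
    if (s == t) next  # self-loops are drawn as a corner tick below
    p1 <- .clip_at_node(xs[t], ys[t], xs[s], ys[s], n$w[s], n$h[s])
    p2 <- .clip_at_node(xs[s], ys[s], xs[t], ys[t], n$w[t], n$h[t])
    cv <- .draw_line(cv, p1[1], p1[2], p2[1], p2[2], style$edge_color)
    if (.edge_head(e$interaction[i]) == "arrow") {
      cv <- .fill_rect(cv, p2[1] - 2, p2[2] - 2, p2[1] + 2, p2[2] + 2,
                       style$edge_color)
    } else {
      dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
      len <- sqrt(dx^2 + dy^2); if (len == 0) len <- 1
      cv <- .draw_line(cv, p2[1] - 3 * dy / len, p2[2] + 3 * dx / len,
                       p2[1] + 3 * dy / len, p2[2] - 3 * dx / len,
                       style$edge_color)
    }
  }
  for (i in seq_len(nrow(n))) {
    x0 <- xs[i] - n$w[i] / 2; y0 <- ys[i] - n$h[i] / 2
    x1 <- x0 + n$w[i]; y1 <- y0 + n$h[i]
    cv <- .fill_rect(cv, x0, y0, x1, y1, c(255L, 255L, 255L))
    border <- c(48L, 48L, 48L)
    cv <- .draw_line(cv, x0, y0, x1, y0, border)
    cv <- .draw_line(cv, x0, y1, x1, y1, border)
    cv <- .draw_line(cv, x0, y0, x0, y1, border)
    cv <- .draw_line(cv, x1, y0, x1, y1, border)
    has_self <- any(e$source == n$id[i] & e$target == n$id[i])
    if (has_self) {
      cv <- .fill_rect(cv, x1 - 3, y0 - 3, x1 + 3, y0 + 3, style$edge_color)
    }
    if (!is.na(refs[i])) {
      pad <- style$node_padding
      img <- read_raster(refs[i])
      iw <- max(1L, round(n$w[i] - 2 * pad))
      ih <- max(1L, round(iw * dim(img)[1] / dim(img)[2]))
      avail <- max(1L, round(n$h[i] - 2 * pad))
      if (ih > avail) { ih <- avail; iw <- max(1L, round(ih * dim(img)[2] / dim(img)[1])) }
      tile <- resize_raster(img, iw, ih)
      tx <- round(xs[i] - iw / 2); ty <- round(ys[i] - ih / 2)
      if (tx >= 1 && ty >= 1 && tx + iw - 1 <= W && ty + ih - 1 <= H) {
        cv <- blit(cv, tile, tx, ty)
      }
    }
    lab <- n$label[i]
    cv <- draw_text(cv, lab, round(xs[i] - text_width_px(lab) / 2),
                    round(y1 + 3), style$font_color)
  }
  write_raster(cv, path)
}

#' Compose a visual-clustering grid sheet
#'
#' Places painted images row-major into a grid of uniform cells (max image
#' size plus a caption strip). The caller supplies the order: visual
#' clustering is a manual rearrangement, an input to this function, not a
#' computation.
#'
#' @param images List of `painted_image` objects (or plain rasters), in
#'   display order.
#' @param columns Number of grid columns (>= 1).
#' @param captions Draw each image's gene id (and non-default condition)
#'   beneath it.
#' @param cell_padding Padding inside each cell (px).
#' @return The grid sheet as an RGB raster.
#' @export
compose_grid <- function(images, columns = 4L, captions = TRUE,
                         cell_padding = 4L) {
  stopifnot(length(images) >= 1, columns >= 1)
  columns <- min(columns, length(images))   # no empty trailing columns
  rasters <- lapply(images, function(p)
    if (inherits(p, "painted_image")) p$raster else p)
  caps <- vapply(images, function(p) {
    if (!inherits(p, "painted_image")) return("")
    if (p$condition %in% c("default", "")) p$gene_id
    else paste0(p$gene_id, " (", p$condition, ")")
  }, "")
  hs <- vapply(rasters, function(r) dim(r)[1], 0L)
  ws <- vapply(rasters, function(r) dim(r)[2], 0L)
  cap_h <- if (captions) 12L else 0L
  cw <- max(ws) + 2L * cell_padding
  chh <- max(hs) + 2L * cell_padding + cap_h
  ncells <- length(rasters)
  nrows <- ceiling(ncells / columns)
  sheet <- new_raster(cw * columns, chh * nrows)
  for (k in seq_len(ncells)) {
    row <- (k - 1L) %/% columns
    col <- (k - 1L) %% columns
    x0 <- col * cw + cell_padding + 1L
    y0 <- row * chh + cell_padding + 1L
    sheet <- blit(sheet, rasters[[k]], x0, y0)
    if (captions && nzchar(caps[k])) {
      sheet <- draw_text(sheet, caps[k], x0, row * chh + max(hs) +
                           cell_padding + 3L, c(0L, 0L, 0L))
    }
  }
  sheet
}

#' Compose a stacked comparison strip
#'
#' Vertical strip with one image per row and its caption: the static
#' replacement for interactive side-panel stacking of a node selection.
#'
#' @param images List of `painted_image` objects.
#' @param captions Draw captions.
#' @return The strip as an RGB raster.
#' @export
compose_stack <- function(images, captions = TRUE) {
  compose_grid(images, columns = 1L, captions = captions)
}

#' Gallery specification
#'
#' @param title Page title.
#' @param entries data.frame with columns `image` (file path), `caption`,
#'   and optionally `href` (hyperlink target for the entry).
#' @return A list of class `gallery_spec`.
#' @export
gallery_spec <- function(title, entries) {
  stopifnot(is.data.frame(entries) || is.null(entries))
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- data.frame(image = character(0), caption = character(0),
                          href = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(entries$href)) entries$href <- NA_character_
  if (is.null(entries$caption)) entries$caption <- basename(entries$image)
  structure(list(title = title,
                 entries = entries[, c("image", "caption", "href")]),
            class = "gallery_spec")
}

#' Export a static HTML gallery
#'
#' Writes a self-contained website directory: `index.html` plus an
#' `images/` folder with copies of every entry's image. Entries with an
#' `href` become hyperlinks (to other networks or external resources). No
#' network access is needed to view the result.
#'
#' @param spec A [gallery_spec()].
#' @param out_dir Output directory (created; must be writable).
#' @return `out_dir`, invisibly.
#' @export
export_gallery <- function(spec, out_dir) {
  stopifnot(inherits(spec, "gallery_spec"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create gallery directory: ", out_dir)
  e <- spec$entries
  missing <- e$image[!file.exists(e$image)]
  if (length(missing)) {
    stop("gallery entry image(s) not found: ", paste(missing, collapse = ", "))
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  rel <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    fn <- basename(e$image[i])
    file.copy(e$image[i], file.path(img_dir, fn), overwrite = TRUE)
    rel[i] <- paste0("images/", fn)
  }
  items <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    img_tag <- sprintf('<img src="%s" alt="%s"/>', rel[i],
                       .xml_escape(e$caption[i]))
    if (!is.na(e$href[i]) && nzchar(e$href[i])) {
      img_tag <- sprintf('<a href="%s">%s</a>', e$href[i], img_tag)
    }
    items[i] <- sprintf(
      '<figure class="entry">%s<figcaption>%s</figcaption></figure>',
      img_tag, .xml_escape(e$caption[i]))
  }
  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en"><head><meta charset="utf-8"/>',
    sprintf("<title>%s</title>", .xml_escape(spec$title)),
    "<style>",
    "body{font-family:sans-serif;margin:2em;background:#fafafa}",
    ".gallery{display:flex;flex-wrap:wrap;gap:1em}",
    ".entry{border:1px solid #ccc;padding:0.5em;background:#fff;margin:0}",
    ".entry img{max-width:320px;display:block}",
    "figcaption{font-size:0.85em;margin-top:0.3em}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", .xml_escape(spec$title)),
    '<div class="gallery">',
    items,
    "</div></body></html>"
  )
  con <- file(file.path(out_dir, "index.html"), "wb")
  writeBin(charToRaw(paste0(paste(html, collapse = "\n"), "\n")), con)
  close(con)
  invisible(out_dir)
}
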