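# Labelfield semantics: a source anatomical image is paired with a
# pixel-aligned "labelfield" raster in which every region of interest is
# flat-filled with one unique color. A legend (TSV side file) maps label
# colors to spatial identifiers and, for stage montages, to stages.
# Label matching is exact RGB equality; pixels whose color is neither a
# legend color nor a background color are classified "unknown" and are
# never painted.

#' Construct a segment legend
#'
#' @param entries A data.frame with columns `color_hex` (`"#RRGGBB"`),
#'   `spatial_id`, and optionally `stage` and `display_name`.
#' @param background_colors Character vector of hex colors treated as
#'   background (default pure white and pure black).
#' @return An object of class `segment_legend`: the entries data.frame with
#'   the background set attached. Each entry's key is `stage:spatial_id`
#'   when a stage is set, else `spatial_id`; keys are what template
#'   `spatial_id` values must match.
#' @export
segment_legend <- function(entries,
                           background_colors = c("#FFFFFF", "#000000")) {
  stopifnot(is.data.frame(entries),
            all(c("color_hex", "spatial_id") %in% names(entries)))
  e <- entries
  e$color_hex <- toupper(ifelse(grepl("^#", e$color_hex),
                                e$color_hex, paste0("#", e$color_hex)))
  e$spatial_id <- trimws(as.character(e$spatial_id))
  if (is.null(e$stage)) e$stage <- NA_character_
  e$stage <- as.character(e$stage)
  e$stage[!is.na(e$stage) & e$stage == ""] <- NA_character_
  if (is.null(e$display_name)) e$display_name <- e$spatial_id
  e$display_name <- ifelse(is.na(e$display_name) | e$display_name == "",
                           e$spatial_id, as.character(e$display_name))
  hex_to_rgb(e$color_hex)  # validates
  if (any(e$spatial_id == "")) stop("empty spatial_id in legend")
  e$key <- ifelse(is.na(e$stage), e$spatial_id,
                  paste0(e$stage, ":", e$spatial_id))
  if (anyDuplicated(e$color_hex)) {
    d <- e$color_hex[duplicated(e$color_hex)]
    stop("legend label color collision: ", paste(unique(d), collapse = ", "))
  }
  if (anyDuplicated(e$key)) {
    d <- e$key[duplicated(e$key)]
    stop("duplicate legend spatial id: ", paste(unique(d), collapse = ", "))
  }
  bg <- toupper(background_colors)
  hex_to_rgb(bg)
  clash <- intersect(e$color_hex, bg)
  if (length(clash)) {
    stop("label color equals a background color: ",
         paste(clash, collapse = ", "))
  }
  e <- e[, c("color_hex", "spatial_id", "stage", "display_name", "key")]
  rownames(e) <- NULL
  structure(e, background_colors = bg, class = c("segment_legend", "data.frame"))
}

#' Read a legend TSV
#'
#' Expected columns: `color_hex`, `spatial_id`, optional `stage`,
#' `display_name`. Lines starting `#background:` list extra background
#' colors (comma-separated hex).
#'
#' @param path Legend file.
#' @return A [segment_legend()].
#' @export
read_legend <- function(path) {
  if (!file.exists(path)) stop("legend file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bg <- c("#FFFFFF", "#000000")
  bgl <- grep("^#background:", lines, value = TRUE)
  if (length(bgl)) {
    extra <- trimws(strsplit(sub("^#background:", "", bgl[1]), ",")[[1]])
    bg <- unique(c(bg, toupper(extra[nzchar(extra)])))
  }
  # comment lines start with '#' but data rows also start with a hex color,
  # so only drop '#' lines that are not "#RRGGBB<TAB>..." records
  is_comment <- grepl("^#", lines) & !grepl("^#[0-9A-Fa-f]{6}\t", lines)
  body <- lines[!is_comment]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  names(tab) <- trimws(tolower(names(tab)))
  segment_legend(tab, background_colors = bg)
}

#' Write a legend TSV
#' @param legend A `segment_legend`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#background: ",
                    paste(attr(legend, "background_colors"), collapse = ",")),
             con)
  out <- as.data.frame(legend)[, c("color_hex", "spatial_id", "stage",
                                   "display_name")]
  out$stage[is.na(out$stage)] <- ""
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a segmented image
#'
#' @param source RGB raster of the anatomical source image.
#' @param labels RGB labelfield raster, same dimensions as `source`.
#' @param legend A [segment_legend()].
#' @return An object of class `segmented_image`.
#' @export
segmented_image <- function(source, labels, legend) {
  stopifnot(inherits(legend, "segment_legend"))
  ds <- dim(source); dl <- dim(labels)
  if (!identical(ds[1:2], dl[1:2])) {
    stop("source (", ds[2], "x", ds[1], ") and labelfield (", dl[2], "x",
         dl[1], ") dimensions differ")
  }
  structure(list(source = source, labels = labels, legend = legend),
            class = "segmented_image")
}

#' Load a source/labelfield/legend triple from disk
#'
#' Enforces the dimension check and flattens alpha channels against white.
#' A warning is raised when the labelfield comes from a lossy format.
#'
#' @param source_path,labels_path PNG image paths.
#' @param legend_path Legend TSV path.
#' @return A [segmented_image()].
#' @export
load_segmented_image <- function(source_path, labels_path, legend_path) {
  segmented_image(read_raster(source_path), read_raster(labels_path),
                  read_legend(legend_path))
}

#' @export
print.segmented_image <- function(x, ...) {
  d <- dim(x$labels)
  cat("Segmented image ", d[2], "x", d[1], " px, ",
      nrow(x$legend), " legend entries\n", sep = "")
  invisible(x)
}

#' Per-segment pixel statistics
#'
#' Classifies every labelfield pixel by exact color match against the
#' legend. Returns one row per legend entry with its pixel count and
#' half-open bounding box `[x0, x1) x [y0, y1)` (top-left origin); entries
#' with zero pixels get an NA box. Pixels matching no legend or background
#' color are tallied as "unknown" rather than raising an error, so lossy
#' labelfields surface in the report.
#'
#' @param si A [segmented_image()].
#' @return A data.frame (class `segment_stats`) with columns `key`,
#'   `spatial_id`, `stage`, `pixels`, `x0`, `y0`, `x1`, `y1`; attributes
#'   `background_pixels`, `unknown_pixels`, `total_pixels`.
#' @export
extract_segments <- function(si) {
  stopifnot(inherits(si, "segmented_image"))
  leg <- si$legend
  codes <- raster_codes(si$labels)
  leg_codes <- as.integer(hex_to_rgb(leg$color_hex) %*% c(65536L, 256L, 1L))
  bg_codes <- as.integer(hex_to_rgb(attr(leg, "background_colors")) %*%
                           c(65536L, 256L, 1L))
  idx <- match(codes, leg_codes)          # matrix-shaped via dim below
  dim(idx) <- dim(codes)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(leg))
  box <- matrix(NA_integer_, nrow(leg), 4,
                dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  for (i in which(counts > 0)) {
    w <- which(idx == i, arr.ind = TRUE)
    box[i, ] <- c(min(w[, 2]) - 1L, min(w[, 1]) - 1L, max(w[, 2]), max(w[, 1]))
  }
  n_bg <- sum(codes %in% bg_codes & is.na(idx))
  n_unknown <- length(codes) - sum(counts) - n_bg
  out <- data.frame(key = leg$key, spatial_id = leg$spatial_id,
                    stage = leg$stage, pixels = counts,
                    box, stringsAsFactors = FALSE)
  structure(out,
            background_pixels = n_bg,
            unknown_pixels = n_unknown,
            total_pixels = length(codes),
            class = c("segment_stats", "data.frame"))
}

#' Boolean mask of one segment
#'
#' @param si A [segmented_image()].
#' @param spatial_id A legend key (`spatial_id`, or `stage:spatial_id` for
#'   montage legends).
#' @return Logical matrix, TRUE exactly where the labelfield carries that
#'   entry's color.
#' @export
segment_mask <- function(si, spatial_id) {
  stopifnot(inherits(si, "segmented_image"))
  leg <- si$legend
  i <- match(spatial_id, leg$key)
  if (is.na(i)) {
    stop("unknown spatial id '", spatial_id, "'; legend ids: ",
         paste(leg$key, collapse = ", "))
  }
  m <- raster_codes(si$labels) == rgb_code(hex_to_rgb(leg$color_hex[i]))
  dim(m) <- dim(si$labels)[1:2]
  m
}

#' Concatenate stage images into a montage
#'
#' Joins several segmented images into one canvas so that a single
#' labelfield covers all stages; segment identity becomes
#' (stage, spatial id) and legend keys become `stage:spatial_id`. Smaller
#' parts are padded with the background color along the perpendicular
#' dimension. Label colors that collide across parts are remapped to fresh
#' unique colors; the remap table is returned.
#'
#' @param parts List of parts, each a list with elements `image` (a
#'   [segmented_image()]) and `stage` (string).
#' @param axis `"horizontal"` (stages side by side) or `"vertical"`.
#' @return A list with `image` (the montage [segmented_image()]) and
#'   `remap` (data.frame `stage`, `spatial_id`, `old_hex`, `new_hex`).
#' @export
compose_montage <- function(parts, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stopifnot(length(parts) >= 1)
  stages <- vapply(parts, function(p) p$stage, "")
  if (anyDuplicated(stages)) {
    stop("stages must be distinct across montage parts; got: ",
         paste(stages, collapse = ", "))
  }
  bg_all <- unique(unlist(lapply(parts, function(p)
    attr(p$image$legend, "background_colors"))))
  bg_rgb <- hex_to_rgb(bg_all[1])[1, ]
  hs <- vapply(parts, function(p) dim(p$image$labels)[1], 0L)
  ws <- vapply(parts, function(p) dim(p$image$labels)[2], 0L)
  H <- if (axis == "horizontal") max(hs) else sum(hs)
  W <- if (axis == "horizontal") sum(ws) else max(ws)
  src <- new_raster(W, H, bg_rgb)
  lab <- new_raster(W, H, bg_rgb)
  used <- character(0)
  entries <- list()
  remap <- list()
  xo <- 1L; yo <- 1L
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    leg <- p$image$legend
    lraster <- p$image$labels
    for (i in seq_len(nrow(leg))) {
      old <- leg$color_hex[i]
      new <- old
      if (new %in% used || new %in% bg_all) {
        new <- .fresh_color(c(used, bg_all))
        old_code <- rgb_code(hex_to_rgb(old))
        hit <- raster_codes(lraster) == old_code
        dim(hit) <- dim(lraster)[1:2]
        nrgb <- hex_to_rgb(new)[1, ]
        for (ch in 1:3) {
          plane <- lraster[, , ch]; plane[hit] <- nrgb[ch]
          lraster[, , ch] <- plane
        }
        remap[[length(remap) + 1L]] <- data.frame(
          stage = p$stage, spatial_id = leg$spatial_id[i],
          old_hex = old, new_hex = new, stringsAsFactors = FALSE)
      }
      used <- c(used, new)
      entries[[length(entries) + 1L]] <- data.frame(
        color_hex = new, spatial_id = leg$spatial_id[i], stage = p$stage,
        display_name = leg$display_name[i], stringsAsFactors = FALSE)
    }
    src <- blit(src, p$image$source, xo, yo)
    lab <- blit(lab, lraster, xo, yo)
    if (axis == "horizontal") xo <- xo + ws[k] else yo <- yo + hs[k]
  }
  legend <- segment_legend(do.call(rbind, entries), background_colors = bg_all)
  list(image = segmented_image(src, lab, legend),
       remap = if (length(remap)) do.call(rbind, remap) else
         data.frame(stage = character(0), spatial_id = character(0),
                    old_hex = character(0), new_hex = character(0)))
}

# Deterministic fresh color not in `taken`: walk a coarse RGB lattice.
.fresh_color <- function(taken) {
  taken <- toupper(taken)
  steps <- seq(15L, 240L, by = 45L)
  for (r in steps) for (g in steps) for (b in steps) {
    hex <- sprintf("#%02X%02X%02X", r, g, b)
    if (!hex %in% taken) return(hex)
  }
  stop("color space exhausted")
}

#' Labelfield validation report
#'
#' @param si A [segmented_image()].
#' @return A list with the `segment_stats`, the unknown-pixel fraction, and
#'   legend entries with zero pixels.
#' @export
validate_labelfield <- function(si) {
  st <- extract_segments(si)
  list(
    stats = st,
    unknown_fraction = attr(st, "unknown_pixels") / attr(st, "total_pixels"),
    empty_segments = st$key[st$pixels == 0]
  )
}
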