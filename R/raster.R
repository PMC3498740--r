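# Rasters are integer arrays dim c(height, width, 3), channels R,G,B in 0..255.
# Origin is the top-left corner; x runs rightward (columns), y downward (rows).

#' Create a flat-colored RGB raster
#'
#' @param width,height Raster dimensions in pixels.
#' @param color Integer RGB triple in 0..255.
#' @return An integer array of dimension `c(height, width, 3)`.
#' @keywords internal
new_raster <- function(width, height, color = c(255L, 255L, 255L)) {
  stopifnot(width >= 1, height >= 1, length(color) == 3)
  arr <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) arr[, , ch] <- as.integer(color[ch])
  arr
}

#' Read a PNG (or BMP-free path) image as an integer RGB raster
#'
#' Alpha channels are flattened against white; grayscale images are expanded
#' to three identical channels. Values are rescaled to integers in 0..255.
#'
#' @param path Path to a PNG file.
#' @return Integer array `c(height, width, 3)`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    warning("'", path, "' looks like a JPEG; lossy compression perturbs ",
            "label colors. Use a lossless format (PNG) for labelfields.")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  nc <- dim(img)[3]
  if (nc == 2L) { # gray + alpha
    a <- img[, , 2]
    g <- img[, , 1] * a + (1 - a)
    img <- array(rep(g, 3L), dim = c(dim(img)[1:2], 3L))
  } else if (nc == 4L) {
    a <- img[, , 4]
    out <- array(0, dim = c(dim(img)[1:2], 3L))
    for (ch in 1:3) out[, , ch] <- img[, , ch] * a + (1 - a)
    img <- out
  } else if (nc != 3L) {
    stop("unsupported channel count in ", path, ": ", nc)
  }
  arr <- array(as.integer(floor(img * 255 + 0.5)), dim = dim(img))
  storage.mode(arr) <- "integer"
  arr
}

#' Write an integer RGB raster as PNG
#'
#' @param raster Integer array `c(height, width, 3)`, values 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L)
  png::writePNG(raster / 255, target = path)
  invisible(path)
}

# Encode RGB channel planes into one integer per pixel (r*2^16 + g*2^8 + b).
raster_codes <- function(raster) {
  raster[, , 1] * 65536L + raster[, , 2] * 256L + raster[, , 3]
}

rgb_code <- function(rgb) {
  as.integer(rgb[1]) * 65536L + as.integer(rgb[2]) * 256L + as.integer(rgb[3])
}

#' Convert "#RRGGBB" hex to an integer RGB triple
#' @param hex Character vector of hex colors.
#' @return Integer matrix with one row per color, columns r,g,b.
#' @keywords internal
hex_to_rgb <- function(hex) {
  hex <- toupper(sub("^#", "", trimws(hex)))
  bad <- !grepl("^[0-9A-F]{6}$", hex)
  if (any(bad)) stop("invalid hex color(s): ", paste(hex[bad], collapse = ", "))
  m <- cbind(
    r = strtoi(substr(hex, 1, 2), 16L),
    g = strtoi(substr(hex, 3, 4), 16L),
    b = strtoi(substr(hex, 5, 6), 16L)
  )
  storage.mode(m) <- "integer"
  m
}

#' Convert integer RGB triples to "#RRGGBB"
#' @param rgb Integer vector of length 3, or matrix with columns r,g,b.
#' @return Character vector of hex colors.
#' @keywords internal
rgb_to_hex <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  sprintf("#%02X%02X%02X", rgb[, 1], rgb[, 2], rgb[, 3])
}

# Nearest-neighbour resize; used when fitting painted images into node boxes.
resize_raster <- function(raster, width, height) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  yi <- pmin(h, floor((seq_len(height) - 0.5) * h / height) + 1L)
  xi <- pmin(w, floor((seq_len(width) - 0.5) * w / width) + 1L)
  raster[yi, xi, , drop = FALSE]
}

# Blit `tile` onto `canvas` with its top-left corner at (x0, y0), 1-based.
blit <- function(canvas, tile, x0, y0) {
  th <- dim(tile)[1]; tw <- dim(tile)[2]
  canvas[y0:(y0 + th - 1L), x0:(x0 + tw - 1L), ] <- tile
  canvas
}
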