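# A tiny 5x7 bitmap font so captions and node labels can be drawn straight
# into rasters, keeping every render byte-deterministic (no graphics device,
# no platform font stack). Lowercase maps to uppercase; unknown characters
# render as blanks. Glyphs are stored as 7 rows of '.'/'#'.

.glyphs <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#..##", "#.#.#", "##..#", "#...#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", "....."),
  "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  "_" = c(".....", ".....", ".....", ".....", ".....", ".....", "#####"),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "," = c(".....", ".....", ".....", ".....", ".##..", "..#..", ".#..."),
  "(" = c("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#."),
  ")" = c(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#..."),
  "/" = c("....#", "....#", "...#.", "..#..", ".#...", "#....", "#...."),
  "+" = c(".....", "..#..", "..#..", "#####", "..#..", "..#..", "....."),
  "=" = c(".....", ".....", "#####", ".....", "#####", ".....", "....."),
  "%" = c("##..#", "##..#", "...#.", "..#..", ".#...", "#..##", "#..##")
)

.glyph_matrix <- function(ch) {
  rows <- .glyphs[[toupper(ch)]]
  if (is.null(rows)) rows <- .glyphs[[" "]]
  m <- do.call(rbind, lapply(rows, function(r)
    strsplit(r, "")[[1]] == "#"))
  m
}

#' Draw text into a raster with the built-in 5x7 bitmap font
#'
#' @param raster Integer RGB raster.
#' @param text Single string. Lowercase is drawn as uppercase.
#' @param x,y Top-left pixel of the first glyph (1-based).
#' @param color Integer RGB triple.
#' @return The modified raster.
#' @keywords internal
draw_text <- function(raster, text, x, y, color = c(0L, 0L, 0L)) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  chars <- strsplit(text, "")[[1]]
  cx <- as.integer(x)
  for (ch in chars) {
    g <- .glyph_matrix(ch)
    for (gy in 1:7) for (gx in 1:5) {
      if (g[gy, gx]) {
        py <- y + gy - 1L; px <- cx + gx - 1L
        if (py >= 1 && py <= h && px >= 1 && px <= w) {
          raster[py, px, ] <- as.integer(color)
        }
      }
    }
    cx <- cx + 6L
  }
  raster
}

text_width_px <- function(text) 6L * nchar(text)
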