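# Shared in-code fixtures: everything is generated at test time.

# A minimal 3-row TSV template written to a temp file.
write_tiny_template <- function(path = tempfile(fileext = ".tsv"),
                                value_cells = c("1.5", "2.5", "3.5")) {
  writeLines(c(
    "#project_name: tiny",
    "#subjects: test organ",
    "gene_id\tspatial_id\tcondition\ttime\treplicate\tvalue",
    paste("G1", "T1", "default", "", "1", value_cells[1], sep = "\t"),
    paste("G1", "T2", "default", "", "1", value_cells[2], sep = "\t"),
    paste("G2", "T1", "default", "", "1", value_cells[3], sep = "\t")
  ), path)
  path
}

# A 10x10 two-segment labelfield: left half color A -> T1, right half B -> T2.
tiny_segmented_image <- function() {
  leg <- segment_legend(data.frame(
    color_hex = c("#FF0000", "#00FF00"),
    spatial_id = c("T1", "T2"), stringsAsFactors = FALSE))
  lab <- atlaspaint:::new_raster(10L, 10L)
  lab[, 1:5, 1] <- 255L; lab[, 1:5, 2] <- 0L; lab[, 1:5, 3] <- 0L
  lab[, 6:10, 1] <- 0L; lab[, 6:10, 2] <- 255L; lab[, 6:10, 3] <- 0L
  src <- atlaspaint:::new_raster(10L, 10L, c(200L, 180L, 160L))
  segmented_image(src, lab, leg)
}

# Dataset over the tiny image's two segments for a set of genes/conditions.
tiny_dataset <- function(values) {
  # values: data.frame(gene_id, spatial_id, condition, value[, replicate])
  expression_dataset(values)
}
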