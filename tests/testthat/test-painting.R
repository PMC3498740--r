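# Color scales, value-to-color mapping, painting, inversion recovery.

test_that("scale domains follow the global / symmetric / per_gene policies", {
  rec <- data.frame(gene_id = c("G1", "G1", "G2", "G2"),
                    spatial_id = c("T1", "T2", "T1", "T2"),
                    value = c(1, 2, 9, 4))
  ds <- expression_dataset(rec)
  g <- build_color_scale(ds, "global")
  expect_equal(g$domain, c(1, 9))
  # symmetric over a difference-like dataset
  ds2 <- expression_dataset(data.frame(gene_id = "G1",
                                       spatial_id = c("T1", "T2"),
                                       value = c(-2, 3)))
  s <- build_color_scale(ds2, "symmetric")
  expect_equal(s$domain, c(-3, 3))
  expect_equal(s$midpoint, 0)
  # per_gene: groupwise min/max oracle
  pg <- build_color_scale(ds, "per_gene")
  expect_equal(pg$G1$domain, c(1, 2))
  expect_equal(pg$G2$domain, c(4, 9))
  # no present values -> error
  expect_error(build_color_scale(expression_dataset(
    data.frame(gene_id = "G1", spatial_id = "T1", value = NA))),
    "no present values")
})

test_that("endpoints map exactly to the low/high colors, midpoint pins", {
  sc <- color_scale(c(0, 10), mode = "diverging")
  expect_equal(as.vector(value_to_color(sc, 10)), c(255L, 0L, 0L))   # pure red
  expect_equal(as.vector(value_to_color(sc, 0)), c(0L, 0L, 255L))    # pure blue
  expect_equal(as.vector(value_to_color(sc, 5)), c(255L, 255L, 255L))
  # clamping, not error, outside the domain
  expect_equal(value_to_color(sc, 99), value_to_color(sc, 10))
  expect_equal(value_to_color(sc, -99), value_to_color(sc, 0))
  # missing stays missing
  expect_true(all(is.na(value_to_color(sc, NA_real_))))
})

test_that("sequential interpolation uses round-half-up per channel", {
  sc <- color_scale(c(0, 1), mode = "sequential",
                    low_color = c(0L, 0L, 255L), high_color = c(255L, 0L, 0L))
  expect_equal(as.vector(value_to_color(sc, 0.5)), c(128L, 0L, 128L))
  # monotonicity: red non-decreasing, blue non-increasing in the value
  v <- seq(0, 1, length.out = 101)
  cols <- value_to_color(sc, v)
  expect_true(all(diff(cols[, "r"]) >= 0))
  expect_true(all(diff(cols[, "b"]) <= 0))
})

test_that("degenerate domain maps everything to the midpoint color", {
  expect_warning(sc <- color_scale(c(3, 3)), "degenerate")
  expect_equal(as.vector(value_to_color(sc, 3)), c(255L, 255L, 255L))
  expect_equal(value_to_color(sc, 3), value_to_color(sc, 99))
})

test_that("painting sets segment pixels and conserves everything else", {
  si <- tiny_segmented_image()
  ds <- expression_dataset(data.frame(
    gene_id = c("G1", "G1", "G2"), spatial_id = c("T1", "T2", "T1"),
    value = c(0, 10, 5)))
  sc <- build_color_scale(ds, "global")
  p <- paint_gene(si, ds, "G1", scale = sc)
  m1 <- segment_mask(si, "T1"); m2 <- segment_mask(si, "T2")
  for (ch in 1:3) {
    expect_true(all(p$raster[, , ch][m1] == c(0L, 0L, 255L)[ch]))
    expect_true(all(p$raster[, , ch][m2] == c(255L, 0L, 0L)[ch]))
  }
  # G2: T2 unmeasured -> source kept there, reported unpainted
  p2 <- paint_gene(si, ds, "G2", scale = sc)
  expect_equal(p2$unpainted_ids, "T2")
  for (ch in 1:3) {
    expect_equal(p2$raster[, , ch][m2], si$source[, , ch][m2])
  }
  expect_error(paint_gene(si, ds, "NOPE", scale = sc), "unknown gene")
  expect_error(paint_gene(si, ds, "G1", condition = "heat", scale = sc),
               "unknown condition")
})

test_that("a gene measured in no segment reproduces the source raster", {
  si <- tiny_segmented_image()
  ds <- expression_dataset(data.frame(
    gene_id = c("G1", "G2"), spatial_id = c("other1", "other2"),
    value = c(1, 2)))
  sc <- build_color_scale(ds, "global")
  p <- paint_gene(si, ds, "G1", scale = sc)
  expect_identical(p$raster, si$source)
  expect_setequal(p$unpainted_ids, c("T1", "T2"))
})

test_that("all segments sharing one value paint one identical color", {
  si <- tiny_segmented_image()
  ds <- expression_dataset(data.frame(
    gene_id = "G1", spatial_id = c("T1", "T2"), value = c(4, 4)))
  sc <- color_scale(c(0, 10))
  p <- paint_gene(si, ds, "G1", scale = sc)
  body <- segment_mask(si, "T1") | segment_mask(si, "T2")
  px <- cbind(p$raster[, , 1][body], p$raster[, , 2][body],
              p$raster[, , 3][body])
  expect_equal(nrow(unique(px)), 1L)
})

test_that("segment mean colors equal value_to_color exactly (3-level fixture)", {
  spec <- fixture_spec(seed = 4, n_tissues = 3, n_stages = 1, n_genes = 1,
                       image_size = c(60L, 60L))
  seg <- make_segmented_image(spec)
  ds <- expression_dataset(data.frame(
    gene_id = "G1", spatial_id = spec$tissue_names, value = c(0, 5, 10)))
  sc <- color_scale(c(0, 10), mode = "sequential")
  p <- paint_gene(seg$image, ds, "G1", scale = sc)
  want <- value_to_color(sc, c(0, 5, 10))
  for (i in 1:3) {
    m <- segment_mask(seg$image, spec$tissue_names[i])
    got <- c(mean(p$raster[, , 1][m]), mean(p$raster[, , 2][m]),
             mean(p$raster[, , 3][m]))
    expect_equal(got, as.numeric(want[i, ]))
  }
})

test_that("alpha blending mixes expression color with the source", {
  si <- tiny_segmented_image()   # source is (200,180,160)
  ds <- expression_dataset(data.frame(gene_id = "G1",
                                      spatial_id = c("T1", "T2"),
                                      value = c(10, 10)))
  sc <- color_scale(c(0, 10))    # value 10 -> (255,0,0)
  p <- paint_gene(si, ds, "G1", scale = sc, blend_alpha = 0.5)
  m <- segment_mask(si, "T1")
  # floor(0.5*255 + 0.5*200 + 0.5) etc.
  expect_equal(p$raster[, , 1][m][1], 228L)
  expect_equal(p$raster[, , 2][m][1], 90L)
  expect_equal(p$raster[, , 3][m][1], 80L)
})

test_that("paint_all: one image per gene, lexicographic, shared global scale", {
  si <- tiny_segmented_image()
  ds <- expression_dataset(data.frame(
    gene_id = c("B", "B", "A", "A"), spatial_id = c("T1", "T2", "T1", "T2"),
    value = c(2, 8, 8, 0)))
  ps <- paint_all(si, ds)
  expect_equal(names(ps), c("A", "B"))
  # equal value (8) => bit-identical color across genes under global policy
  mA <- segment_mask(si, "T1"); mB <- segment_mask(si, "T2")
  expect_equal(ps$A$raster[, , 1][mA], ps$B$raster[, , 1][mB])
  expect_equal(ps$A$raster[, , 3][mA], ps$B$raster[, , 3][mB])
  # empty dataset of genes -> empty list
  expect_equal(paint_all(si, expression_dataset(
    data.frame(gene_id = character(0), spatial_id = character(0),
               value = numeric(0))), "global"), list())
})

test_that("color inversion recovers values within channel quantization", {
  sc <- color_scale(c(-1.5, 7), mode = "sequential")
  v <- seq(-1.5, 7, length.out = 57)
  rec <- color_to_value(sc, value_to_color(sc, v))
  expect_lt(max(abs(rec - v)), diff(sc$domain) / 255)
  # diverging scale inverts too
  scd <- color_scale(c(-4, 4), mode = "diverging")
  vd <- seq(-4, 4, length.out = 41)
  recd <- color_to_value(scd, value_to_color(scd, vd))
  expect_lt(max(abs(recd - vd)), diff(scd$domain) / 255)
})
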