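# Labelfield semantics: legend, pixel classification, masks, montages.

test_that("segmented image construction enforces matched dimensions", {
  si <- tiny_segmented_image()
  expect_s3_class(si, "segmented_image")
  lab12 <- atlaspaint:::new_raster(12L, 10L)
  expect_error(segmented_image(si$source, lab12, si$legend),
               "dimensions differ")
})

test_that("legend invariants: distinct colors/ids, no background overlap", {
  expect_error(segment_legend(data.frame(
    color_hex = c("#FF0000", "#FF0000"), spatial_id = c("T1", "T2"))),
    "color collision")
  expect_error(segment_legend(data.frame(
    color_hex = c("#FF0000", "#00FF00"), spatial_id = c("T1", "T1"))),
    "duplicate legend spatial id")
  expect_error(segment_legend(data.frame(
    color_hex = "#FFFFFF", spatial_id = "T1")),
    "background")
})

test_that("exact-color classification counts segments, background, unknown", {
  si <- tiny_segmented_image()
  st <- extract_segments(si)
  expect_equal(st$pixels[st$spatial_id == "T1"], 50L)
  expect_equal(st$pixels[st$spatial_id == "T2"], 50L)
  expect_equal(attr(st, "unknown_pixels"), 0L)
  # bounding boxes are half-open [x0,x1) x [y0,y1)
  expect_equal(unlist(st[st$spatial_id == "T1", c("x0", "y0", "x1", "y1")],
                      use.names = FALSE), c(0L, 0L, 5L, 10L))

  # all-background labelfield: every legend entry empty, 0 unknown
  blank <- segmented_image(si$source, atlaspaint:::new_raster(10L, 10L),
                           si$legend)
  stb <- extract_segments(blank)
  expect_true(all(stb$pixels == 0L))
  expect_equal(attr(stb, "unknown_pixels"), 0L)
  expect_equal(attr(stb, "background_pixels"), 100L)
  expect_setequal(validate_labelfield(blank)$empty_segments, c("T1", "T2"))

  # off-legend pixels are reported as unknown, not an error
  odd <- si$labels; odd[1, 1, ] <- c(7L, 7L, 7L)
  sto <- extract_segments(segmented_image(si$source, odd, si$legend))
  expect_equal(attr(sto, "unknown_pixels"), 1L)
})

test_that("pixel counts partition the raster (conservation)", {
  spec <- fixture_spec(seed = 1, n_tissues = 3, n_stages = 1, n_genes = 1,
                       image_size = c(40L, 40L))
  seg <- make_segmented_image(spec)
  st <- extract_segments(seg$image)
  expect_equal(sum(st$pixels) + attr(st, "background_pixels") +
                 attr(st, "unknown_pixels"), attr(st, "total_pixels"))
  # generator tally is the ground truth
  expect_equal(stats::setNames(st$pixels, st$key), seg$truth_counts)
})

test_that("segment masks partition non-background pixels and match counts", {
  si <- tiny_segmented_image()
  m1 <- segment_mask(si, "T1")
  m2 <- segment_mask(si, "T2")
  expect_false(any(m1 & m2))                  # unique colors => disjoint
  expect_true(all(m1 | m2))                   # legend covers whole raster here
  st <- extract_segments(si)
  expect_equal(sum(m1), st$pixels[st$key == "T1"])
  expect_error(segment_mask(si, "nope"), "unknown spatial id.*T1, T2")
})

test_that("montage geometry, stage annotation and color remapping", {
  a <- tiny_segmented_image()
  b <- tiny_segmented_image()   # same colors: must be remapped
  mt <- compose_montage(list(list(image = a, stage = "early"),
                             list(image = b, stage = "late")),
                        axis = "vertical")
  expect_equal(dim(mt$image$labels)[1:2], c(20L, 10L))
  leg <- mt$image$legend
  expect_equal(nrow(leg), 4L)
  expect_setequal(leg$key, c("early:T1", "early:T2", "late:T1", "late:T2"))
  expect_equal(nrow(mt$remap), 2L)            # late panel's two colors moved
  expect_false(anyDuplicated(leg$color_hex) > 0)
  # single-part montage is the part with its stage annotated
  one <- compose_montage(list(list(image = a, stage = "only")))
  expect_equal(one$image$labels, a$labels)
  expect_equal(one$image$legend$key, c("only:T1", "only:T2"))
  expect_equal(nrow(one$remap), 0L)
  # duplicate stages are rejected
  expect_error(compose_montage(list(list(image = a, stage = "s"),
                                    list(image = b, stage = "s"))),
               "distinct")
})

test_that("montage + extract equals concatenated per-part extraction", {
  spec <- fixture_spec(seed = 5, n_tissues = 4, n_stages = 3, n_genes = 1,
                       image_size = c(90L, 30L))
  seg <- make_segmented_image(spec)
  whole <- extract_segments(seg$image)
  per_part <- unlist(lapply(seq_along(seg$panels), function(s)
    stats::setNames(extract_segments(seg$panels[[s]])$pixels,
                    paste0(spec$stage_names[s], ":",
                           extract_segments(seg$panels[[s]])$spatial_id))))
  expect_equal(stats::setNames(whole$pixels, whole$key), per_part)
})

test_that("montage legend is the stage x tissue product for fixtures", {
  spec <- fixture_spec(seed = 2, n_tissues = 7, n_stages = 4, n_genes = 1,
                       image_size = c(120L, 30L))
  seg <- make_segmented_image(spec)
  leg <- seg$image$legend
  expect_equal(nrow(leg), 28L)
  expect_setequal(leg$key, as.vector(outer(spec$stage_names,
                                           spec$tissue_names, paste,
                                           sep = ":")))
})

test_that("loading from disk is deterministic and validates dimensions", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 3, n_tissues = 3, n_stages = 1, n_genes = 1,
                       image_size = c(30L, 30L))
  seg <- make_segmented_image(spec)
  write_raster(seg$image$source, file.path(d, "src.png"))
  write_raster(seg$image$labels, file.path(d, "lab.png"))
  write_legend(seg$image$legend, file.path(d, "leg.tsv"))
  si1 <- load_segmented_image(file.path(d, "src.png"), file.path(d, "lab.png"),
                              file.path(d, "leg.tsv"))
  si2 <- load_segmented_image(file.path(d, "src.png"), file.path(d, "lab.png"),
                              file.path(d, "leg.tsv"))
  expect_identical(extract_segments(si1), extract_segments(si2))
  expect_identical(si1$labels, seg$image$labels)
  # dimension mismatch reported with both sizes
  bad <- atlaspaint:::new_raster(12L, 10L)
  write_raster(bad, file.path(d, "bad.png"))
  expect_error(load_segmented_image(file.path(d, "src.png"),
                                    file.path(d, "bad.png"),
                                    file.path(d, "leg.tsv")),
               "30x30.*12x10")
})
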