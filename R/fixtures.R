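# Deterministic synthetic bundles emulating the two worked input kinds:
# a single-stage flower-like anatomy (four whorls, a handful of regulators)
# and a multi-stage seed-like montage (stages x tissues, ~100 regulators).
# Each stage panel is drawn as concentric square rings (innermost tissue
# first, emulating embryo-inside-endosperm-inside-seed-coat anatomy) on a
# white background; the generator records exact per-segment pixel tallies
# as ground truth while it paints.
#
# One integer seed drives every random draw (patterns, noise); label colors
# come from a maximally spaced hue wheel so they are pairwise distinct.

#' Specification for synthetic fixture bundles
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_tissues Tissues per stage (>= 1).
#' @param n_stages Developmental stages (>= 1); stages are concatenated
#'   horizontally into a montage when `n_stages > 1`.
#' @param n_genes Number of genes.
#' @param image_size `c(width, height)` of the full (montage) image in px.
#' @param pattern_mix Named proportions over the pattern classes
#'   `tissue_specific`, `stage_specific`, `ubiquitous`, `graded`; must sum
#'   to 1.
#' @param noise_sd Gaussian noise SD added to generated values (>= 0).
#' @param value_range `c(lo, hi)` range of generated normalized values.
#' @param tissue_names,stage_names Optional identifier vectors.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_tissues = 4L, n_stages = 1L,
                         n_genes = 10L, image_size = c(120L, 120L),
                         pattern_mix = c(tissue_specific = 0.4,
                                         stage_specific = 0.2,
                                         ubiquitous = 0.2,
                                         graded = 0.2),
                         noise_sd = 0, value_range = c(0, 10),
                         tissue_names = NULL, stage_names = NULL) {
  stopifnot(n_tissues >= 1, n_stages >= 1, n_genes >= 0,
            abs(sum(pattern_mix) - 1) < 1e-8, noise_sd >= 0,
            value_range[1] < value_range[2])
  if (is.null(tissue_names)) tissue_names <- sprintf("T%d", seq_len(n_tissues))
  if (is.null(stage_names)) stage_names <- sprintf("S%d", seq_len(n_stages))
  stopifnot(length(tissue_names) == n_tissues,
            length(stage_names) == n_stages)
  structure(list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
                 n_stages = as.integer(n_stages), n_genes = as.integer(n_genes),
                 image_size = as.integer(image_size),
                 pattern_mix = pattern_mix, noise_sd = noise_sd,
                 value_range = as.numeric(value_range),
                 tissue_names = tissue_names, stage_names = stage_names),
            class = "fixture_spec")
}

# Evenly spaced label colors avoiding white/black backgrounds.
.wheel_colors <- function(n) {
  hues <- (seq_len(n) - 1) / n
  m <- grDevices::col2rgb(grDevices::hsv(hues, s = 0.78, v = 0.88))
  hex <- sprintf("#%02X%02X%02X", m[1, ], m[2, ], m[3, ])
  stopifnot(!anyDuplicated(hex))
  hex
}

# One stage panel: concentric square rings, tissue 1 innermost.
.make_panel <- function(width, height, tissue_names, colors) {
  nt <- length(tissue_names)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  d <- pmax(abs(xs - cx), abs(ys - cy))
  margin <- 2
  E <- min(width, height) / 2 - margin
  t <- E / nt
  ring <- ceiling(d / t)
  ring[ring < 1] <- 1L
  ring[d > E] <- NA_integer_
  lab <- new_raster(width, height)
  rgbm <- hex_to_rgb(colors)
  for (k in seq_len(nt)) {
    hit <- !is.na(ring) & ring == k
    for (ch in 1:3) {
      plane <- lab[, , ch]; plane[hit] <- rgbm[k, ch]; lab[, , ch] <- plane
    }
  }
  # source: a gray radial gradient, a stand-in for anatomical texture
  g <- as.integer(floor(230 - 120 * pmin(d / max(E, 1), 1)))
  src <- array(rep(g, 3L), dim = c(height, width, 3L))
  storage.mode(src) <- "integer"
  counts <- vapply(seq_len(nt), function(k)
    sum(!is.na(ring) & ring == k), 0L)
  legend <- segment_legend(data.frame(
    color_hex = colors, spatial_id = tissue_names, stringsAsFactors = FALSE))
  list(image = segmented_image(src, lab, legend),
       counts = stats::setNames(counts, tissue_names))
}

#' Generate a synthetic segmented image with ground truth
#'
#' Builds one panel of concentric flat-colored tissue rings per stage and,
#' for multi-stage specs, concatenates the panels horizontally into a
#' montage whose legend keys are `stage:tissue`. The generator tallies
#' pixels as it paints; the tally is the ground truth that
#' [extract_segments()] must reproduce.
#'
#' @param spec A [fixture_spec()].
#' @return List with `image` (a [segmented_image()]), `truth_counts`
#'   (named integer vector keyed like the legend), and `panels` (the
#'   per-stage [segmented_image()]s).
#' @export
make_segmented_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  w_total <- spec$image_size[1]; h <- spec$image_size[2]
  wp <- w_total %/% spec$n_stages
  all_colors <- .wheel_colors(spec$n_stages * spec$n_tissues)
  panels <- list()
  truth <- integer(0)
  for (s in seq_len(spec$n_stages)) {
    cols <- all_colors[(s - 1) * spec$n_tissues + seq_len(spec$n_tissues)]
    p <- .make_panel(wp, h, spec$tissue_names, cols)
    panels[[s]] <- p$image
    key <- if (spec$n_stages == 1) names(p$counts) else
      paste0(spec$stage_names[s], ":", names(p$counts))
    truth <- c(truth, stats::setNames(p$counts, key))
  }
  if (spec$n_stages == 1) {
    image <- panels[[1]]
  } else {
    parts <- lapply(seq_len(spec$n_stages), function(s)
      list(image = panels[[s]], stage = spec$stage_names[s]))
    image <- compose_montage(parts, axis = "horizontal")$image
  }
  list(image = image, truth_counts = truth, panels = panels)
}

#' Generate a synthetic expression dataset with ground-truth patterns
#'
#' Each gene is assigned one spatial pattern class: `tissue_specific`
#' (high in 1-2 chosen tissues across all stages, low elsewhere),
#' `stage_specific` (high in every tissue of one chosen stage),
#' `ubiquitous` (high everywhere), or `graded` (values rise monotonically
#' across the stage order, constant within a stage). High/low levels sit at
#' 90%/10% of the value range; Gaussian noise of SD `noise_sd` is added and
#' clipped to the range. With a single stage the stage-dependent classes
#' fall back to `tissue_specific`/`ubiquitous`.
#'
#' @param spec A [fixture_spec()].
#' @param legend A [segment_legend()] whose keys name the segments to
#'   measure.
#' @param gene_ids Optional gene id vector (default `G001...`).
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (data.frame `gene_id`, `pattern`, `targets`).
#' @export
make_dataset <- function(spec, legend, gene_ids = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(legend, "segment_legend"))
  set.seed(spec$seed + 1L)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf(paste0("G%0", max(3, nchar(spec$n_genes)), "d"),
                        seq_len(spec$n_genes))
  }
  stopifnot(length(gene_ids) == spec$n_genes)
  lo <- spec$value_range[1]; hi <- spec$value_range[2]
  span <- hi - lo
  v_hi <- lo + 0.9 * span; v_lo <- lo + 0.1 * span
  keys <- legend$key
  stages <- legend$stage
  tissues <- legend$spatial_id
  single_stage <- all(is.na(stages))
  stage_levels <- if (single_stage) "" else unique(stages)
  mix <- spec$pattern_mix
  if (single_stage) {
    # stage-dependent classes are meaningless with one stage
    mix["tissue_specific"] <- mix["tissue_specific"] + mix["stage_specific"] +
      mix["graded"]
    mix["stage_specific"] <- 0; mix["graded"] <- 0
  }
  classes <- sample(names(mix), spec$n_genes, replace = TRUE, prob = mix)
  recs <- vector("list", spec$n_genes)
  truth <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    cls <- classes[g]
    if (cls == "tissue_specific") {
      k <- sample(1:min(2, length(unique(tissues))), 1)
      targets <- sample(unique(tissues), k)
      vals <- ifelse(tissues %in% targets, v_hi, v_lo)
      tgt <- paste(sort(targets), collapse = ",")
    } else if (cls == "stage_specific") {
      st <- sample(stage_levels, 1)
      vals <- ifelse(stages == st, v_hi, v_lo)
      tgt <- st
    } else if (cls == "graded") {
      pos <- match(stages, stage_levels)
      vals <- lo + 0.1 * span +
        0.8 * span * (pos - 1) / (length(stage_levels) - 1)
      tgt <- "stage-order"
    } else { # ubiquitous
      vals <- rep(v_hi, length(keys))
      tgt <- "all"
    }
    if (spec$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
      vals <- pmin(pmax(vals, lo), hi)
    }
    recs[[g]] <- data.frame(
      gene_id = gene_ids[g], spatial_id = keys, condition = "default",
      time = ifelse(is.na(stages), "", stages), replicate = 1L,
      value = vals, stringsAsFactors = FALSE)
    truth[[g]] <- data.frame(gene_id = gene_ids[g], pattern = cls,
                             targets = tgt, stringsAsFactors = FALSE)
  }
  ds <- expression_dataset(
    do.call(rbind, recs),
    list(project_name = "synthetic fixture bundle",
         subjects = "synthetic anatomy",
         source_note = paste0("generated, seed ", spec$seed)))
  list(dataset = ds, truth = do.call(rbind, truth))
}

#' Classify a gene's per-segment values into a pattern class
#'
#' The inverse of the generator's pattern assignment, used to check that
#' painted images remain readable: values are thresholded at the midpoint
#' of `value_range`; the high set decides the class. Graded genes are
#' recognised by stage-wise constant, strictly increasing values.
#'
#' @param values Numeric vector of per-segment values.
#' @param tissues,stages Character vectors aligned with `values` (stages
#'   may be all NA for single-stage data).
#' @param value_range The generator's `c(lo, hi)`.
#' @return One of `"tissue_specific"`, `"stage_specific"`, `"ubiquitous"`,
#'   `"graded"`, `"other"`.
#' @export
classify_pattern <- function(values, tissues, stages, value_range) {
  mid <- mean(value_range)
  high <- values > mid
  single_stage <- all(is.na(stages))
  if (!single_stage) {
    sl <- unique(stages)
    stage_means <- vapply(sl, function(s) mean(values[stages == s]), 0)
    stage_const <- all(vapply(sl, function(s) {
      v <- values[stages == s]; max(v) - min(v) < 1e-6 * diff(value_range)
    }, TRUE))
    if (stage_const && length(sl) > 1 && all(diff(stage_means) > 0)) {
      return("graded")
    }
  }
  if (all(high)) return("ubiquitous")
  if (!any(high)) return("other")
  if (!single_stage) {
    sl <- unique(stages)
    for (s in sl) {
      if (all(high[stages == s]) && !any(high[stages != s])) {
        return("stage_specific")
      }
    }
    ht <- unique(tissues[high])
    if (length(ht) < length(unique(tissues)) &&
        all(high == (tissues %in% ht))) {
      return("tissue_specific")
    }
    return("other")
  }
  "tissue_specific"
}

#' Generate a synthetic regulatory network over dataset genes
#'
#' Topology echoes curated regulator networks: one hub with out-edges to
#' every other member (activation), a three-node feedback cycle, one
#' positive autoregulatory self-loop on the hub, and one inhibition edge
#' back to the hub.
#'
#' @param spec A [fixture_spec()].
#' @param gene_ids Gene ids to draw nodes from; the first `n_nodes` become
#'   nodes.
#' @param n_nodes Node count (default: up to 8, the scale of curated
#'   regulator cascades).
#' @return An [omics_network()].
#' @export
make_network <- function(spec, gene_ids,
                         n_nodes = min(length(gene_ids), 8L)) {
  stopifnot(inherits(spec, "fixture_spec"), length(gene_ids) >= 2,
            n_nodes >= 2, n_nodes <= length(gene_ids))
  set.seed(spec$seed + 2L)
  ids <- gene_ids[seq_len(n_nodes)]
  hub <- ids[1]
  edges <- data.frame(source = hub, target = setdiff(ids, hub),
                      interaction = "activation", stringsAsFactors = FALSE)
  edges <- rbind(edges, data.frame(source = hub, target = hub,
                                   interaction = "activation"))
  if (length(ids) >= 4) {
    cyc <- ids[2:4]
    edges <- rbind(edges, data.frame(
      source = cyc, target = c(cyc[-1], cyc[1]), interaction = "activation"))
  }
  edges <- rbind(edges, data.frame(source = ids[length(ids)], target = hub,
                                   interaction = "inhibition"))
  net <- omics_network(
    data.frame(id = ids, label = ids, node_class = "macromolecule",
               stringsAsFactors = FALSE),
    edges, directed = TRUE, source_format = "generated")
  assign_grid_layout(net)
}

#' Write a complete synthetic use-case bundle to a directory
#'
#' `flower_like`: one stage with the four floral whorls (sepal, petal,
#' stamen, carpel) and ten named floral regulators. `seed_like`: a
#' four-stage seed-development montage (globular, heart, linear cotyledon,
#' green mature) with seven seed tissues per stage and 100 genes. All
#' structures are synthetic stand-ins generated in code.
#'
#' Writes `template.tsv`, `source.png`, `labels.png`, `legend.tsv`,
#' `network.gml`, and `truth.tsv`; identical seeds give byte-identical
#' files.
#'
#' @param which `"flower_like"` or `"seed_like"`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created).
#' @param n_genes Override the bundle's default gene count.
#' @return The [fixture_spec()] used, invisibly.
#' @export
make_usecase_bundle <- function(which = c("flower_like", "seed_like"),
                                seed = 1L, out_dir, n_genes = NULL) {
  which <- match.arg(which)
  if (which == "flower_like") {
    spec <- fixture_spec(
      seed = seed, n_tissues = 4L, n_stages = 1L,
      n_genes = n_genes %||% 10L, image_size = c(120L, 120L),
      pattern_mix = c(tissue_specific = 0.7, stage_specific = 0,
                      ubiquitous = 0.3, graded = 0),
      tissue_names = c("carpel", "stamen", "petal", "sepal"))  # innermost first
    gene_ids <- c("AP1", "AP2", "AP3", "PI", "AG", "AGL11", "SEP1", "SEP2",
                  "SEP3", "LFY")
    gene_ids <- gene_ids[seq_len(min(spec$n_genes, length(gene_ids)))]
    if (spec$n_genes > length(gene_ids)) {
      gene_ids <- c(gene_ids, sprintf("TF%03d",
                                      seq_len(spec$n_genes - length(gene_ids))))
    }
  } else {
    spec <- fixture_spec(
      seed = seed, n_tissues = 7L, n_stages = 4L,
      n_genes = n_genes %||% 100L, image_size = c(400L, 100L),
      tissue_names = c("embryo", "suspensor", "endosperm_micropylar",
                       "endosperm_peripheral", "endosperm_chalazal",
                       "seed_coat", "seed_coat_chalazal"),
      stage_names = c("globular", "heart", "linear_cotyledon",
                      "green_mature"))
    gene_ids <- c("LEC1", "LEC2", "FUS3", "ABI3",
                  sprintf("TF%03d", seq_len(spec$n_genes - 4L)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- make_segmented_image(spec)
  made <- make_dataset(spec, seg$image$legend, gene_ids)
  net <- make_network(spec, gene_ids)
  write_raster(seg$image$source, file.path(out_dir, "source.png"))
  write_raster(seg$image$labels, file.path(out_dir, "labels.png"))
  write_legend(seg$image$legend, file.path(out_dir, "legend.tsv"))
  write_template(made$dataset, file.path(out_dir, "template.tsv"))
  write_network(net, file.path(out_dir, "network.gml"), "gml")
  utils::write.table(made$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(spec)
}
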