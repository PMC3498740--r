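# Value-to-color mapping and segment painting.
#
# One shared ("global") color scale across all genes, segments and stages is
# the default, so equal expression means equal color everywhere. The default
# colors follow the red-high / blue-low convention of expression atlases;
# the diverging variant passes through white at the domain midpoint, which
# is what difference views use so that zero change stays neutral.

#' Construct a color scale
#'
#' @param domain Numeric length-2 vector `c(min, max)`.
#' @param mode `"diverging"` (blue-white-red through the midpoint, default)
#'   or `"sequential"` (straight blue-to-red interpolation).
#' @param low_color,mid_color,high_color Integer RGB triples (0..255).
#' @param missing_color Either the string `"keep-source"` (default: segments
#'   with a missing value keep their source-image pixels) or an RGB triple.
#' @param policy How the domain was chosen: `"global"`, `"per_gene"`, or
#'   `"symmetric"`; informational, recorded for provenance.
#' @return An object of class `color_scale`.
#' @export
color_scale <- function(domain, mode = c("diverging", "sequential"),
                        low_color = c(0L, 0L, 255L),
                        mid_color = c(255L, 255L, 255L),
                        high_color = c(255L, 0L, 0L),
                        missing_color = "keep-source",
                        policy = "global") {
  mode <- match.arg(mode)
  stopifnot(length(domain) == 2, is.finite(domain))
  degenerate <- domain[1] == domain[2]
  if (degenerate) {
    warning("degenerate color scale: all values equal ", domain[1],
            "; every painted pixel maps to the midpoint color")
  }
  if (domain[1] > domain[2]) stop("domain must be increasing")
  structure(list(domain = as.numeric(domain),
                 midpoint = mean(as.numeric(domain)),
                 mode = mode,
                 low_color = as.integer(low_color),
                 mid_color = as.integer(mid_color),
                 high_color = as.integer(high_color),
                 missing_color = missing_color,
                 policy = policy,
                 degenerate = degenerate),
            class = "color_scale")
}

#' @export
print.color_scale <- function(x, ...) {
  cat("Color scale (", x$mode, ", ", x$policy, "): [",
      format(x$domain[1]), ", ", format(x$domain[2]), "] ",
      rgb_to_hex(x$low_color), " -> ",
      if (x$mode == "diverging") paste0(rgb_to_hex(x$mid_color), " -> "),
      rgb_to_hex(x$high_color), "\n", sep = "")
  invisible(x)
}

#' Build a color scale from a dataset
#'
#' Domain policies: `"global"` spans the min and max over all genes,
#' segments and conditions of the dataset (the default, so one scale serves
#' every painted image); `"per_gene"` returns one scale per gene with that
#' gene's min/max; `"symmetric"` spans `[-m, +m]` with `m = max(|value|)`,
#' intended for difference datasets so that zero sits exactly at the
#' diverging midpoint.
#'
#' @param ds An `expression_dataset`.
#' @param policy `"global"`, `"per_gene"` or `"symmetric"`.
#' @param mode Passed to [color_scale()].
#' @param ... Further arguments passed to [color_scale()].
#' @return A `color_scale`, or for `"per_gene"` a named list of them.
#' @export
build_color_scale <- function(ds, policy = c("global", "symmetric", "per_gene"),
                              mode = c("diverging", "sequential"), ...) {
  stopifnot(inherits(ds, "expression_dataset"))
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  v <- ds$records$value
  if (all(is.na(v))) stop("cannot build a color scale: no present values")
  if (policy == "global") {
    color_scale(range(v, na.rm = TRUE), mode = mode, policy = "global", ...)
  } else if (policy == "symmetric") {
    m <- max(abs(v), na.rm = TRUE)
    color_scale(c(-m, m), mode = mode, policy = "symmetric", ...)
  } else {
    genes <- dataset_genes(ds)
    out <- lapply(genes, function(g) {
      vg <- v[ds$records$gene_id == g]
      if (all(is.na(vg))) return(NULL)
      color_scale(range(vg, na.rm = TRUE), mode = mode, policy = "per_gene", ...)
    })
    names(out) <- genes
    out[!vapply(out, is.null, TRUE)]
  }
}

#' Map values to colors
#'
#' Values are clamped to the scale domain. Sequential scales interpolate
#' each channel linearly from `low_color` to `high_color`; diverging scales
#' interpolate piecewise, low-to-mid below the midpoint and mid-to-high
#' above it, pinning the midpoint exactly to `mid_color`. Channel results
#' are rounded half-up to integers. Missing values yield NA rows (the
#' painter then applies the scale's missing-value policy).
#'
#' @param scale A [color_scale()].
#' @param v Numeric vector of values (NA allowed).
#' @return Integer matrix, one row per value, columns r,g,b.
#' @export
value_to_color <- function(scale, v) {
  stopifnot(inherits(scale, "color_scale"))
  n <- length(v)
  out <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("r", "g", "b")))
  ok <- !is.na(v)
  if (!any(ok)) return(out)
  x <- pmin(pmax(v[ok], scale$domain[1]), scale$domain[2])
  if (scale$degenerate) {
    col <- if (scale$mode == "diverging") scale$mid_color else scale$low_color
    out[ok, ] <- matrix(col, sum(ok), 3, byrow = TRUE)
    return(out)
  }
  lerp <- function(t, a, b) {
    sapply(1:3, function(ch) as.integer(floor(a[ch] + t * (b[ch] - a[ch]) + 0.5)))
  }
  if (scale$mode == "sequential") {
    t <- (x - scale$domain[1]) / diff(scale$domain)
    cols <- t(vapply(t, lerp, integer(3), a = scale$low_color,
                     b = scale$high_color))
  } else {
    mid <- scale$midpoint
    cols <- t(vapply(x, function(xi) {
      if (xi <= mid) {
        t <- (xi - scale$domain[1]) / (mid - scale$domain[1])
        lerp(t, scale$low_color, scale$mid_color)
      } else {
        t <- (xi - mid) / (scale$domain[2] - mid)
        lerp(t, scale$mid_color, scale$high_color)
      }
    }, integer(3)))
  }
  out[ok, ] <- cols
  out
}

#' Invert a painted color back to a value
#'
#' Recovers the expression value a color was painted from, up to the 1/255
#' channel quantization. For sequential scales the channel with the widest
#' low-to-high span is inverted; diverging scales try both halves and keep
#' the candidate whose forward mapping reproduces the color best.
#'
#' @param scale A [color_scale()].
#' @param rgb Integer RGB triple or matrix of triples.
#' @return Numeric vector of recovered values.
#' @export
color_to_value <- function(scale, rgb) {
  stopifnot(inherits(scale, "color_scale"))
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (scale$degenerate) return(rep(scale$midpoint, nrow(rgb)))
  inv_seg <- function(col, a, b, lo, hi) {
    span <- b - a
    ch <- which.max(abs(span))
    t <- (col[ch] - a[ch]) / span[ch]
    lo + pmin(pmax(t, 0), 1) * (hi - lo)
  }
  apply(rgb, 1, function(col) {
    if (scale$mode == "sequential") {
      inv_seg(col, scale$low_color, scale$high_color,
              scale$domain[1], scale$domain[2])
    } else {
      v1 <- inv_seg(col, scale$low_color, scale$mid_color,
                    scale$domain[1], scale$midpoint)
      v2 <- inv_seg(col, scale$mid_color, scale$high_color,
                    scale$midpoint, scale$domain[2])
      e1 <- sum(abs(value_to_color(scale, v1)[1, ] - col))
      e2 <- sum(abs(value_to_color(scale, v2)[1, ] - col))
      if (e1 <= e2) v1 else v2
    }
  })
}

#' Paint one gene's expression onto the anatomy
#'
#' Produces the color-coded image for one (gene, condition): every segment
#' with a present value has its pixels set to `value_to_color(scale, value)`
#' (or alpha-blended over the source when `blend_alpha < 1`); segments with
#' missing values follow the scale's missing-value policy (default: keep
#' the source pixels), and background/unknown pixels are always copied from
#' the source unchanged.
#'
#' Replicates are aggregated (mean) before painting so each segment gets
#' exactly one value. For montage legends, template spatial ids of the form
#' `"stage:tissue"` address the matching legend entry.
#'
#' @param si A [segmented_image()].
#' @param ds An `expression_dataset`.
#' @param gene_id Gene to paint.
#' @param condition Condition to paint (default `"default"`).
#' @param scale A [color_scale()]; build one with [build_color_scale()].
#' @param blend_alpha Opacity of the expression color over the source in
#'   `[0, 1]`; 1 (default) replaces segment pixels outright.
#' @return An object of class `painted_image`: list with `raster`,
#'   `gene_id`, `condition`, `time`, `scale`, `unpainted_ids` (legend keys
#'   left unpainted because their value is missing or unmeasured).
#' @export
paint_gene <- function(si, ds, gene_id, condition = "default", scale,
                       blend_alpha = 1) {
  stopifnot(inherits(si, "segmented_image"),
            inherits(ds, "expression_dataset"),
            inherits(scale, "color_scale"),
            blend_alpha >= 0, blend_alpha <= 1)
  r <- ds$records
  if (!gene_id %in% r$gene_id) stop("unknown gene '", gene_id, "'")
  if (!condition %in% r$condition) {
    stop("unknown condition '", condition, "'; available: ",
         paste(ds$metadata$conditions, collapse = ", "))
  }
  r <- r[r$gene_id == gene_id & r$condition == condition, ]
  agg <- aggregate_replicates(
    expression_dataset(r, ds$metadata))$records
  leg <- si$legend
  vals <- agg$value[match(leg$key, agg$spatial_id)]
  cols <- value_to_color(scale, vals)
  codes <- raster_codes(si$labels)
  idx <- match(codes, as.integer(hex_to_rgb(leg$color_hex) %*%
                                   c(65536L, 256L, 1L)))
  dim(idx) <- dim(codes)
  out <- si$source
  keep_source <- identical(scale$missing_color, "keep-source")
  for (i in seq_len(nrow(leg))) {
    if (is.na(vals[i])) {
      if (keep_source) next
      col <- as.integer(scale$missing_color)
    } else {
      col <- cols[i, ]
    }
    hit <- !is.na(idx) & idx == i
    if (!any(hit)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      if (blend_alpha >= 1) {
        plane[hit] <- col[ch]
      } else {
        plane[hit] <- as.integer(floor(
          blend_alpha * col[ch] + (1 - blend_alpha) * plane[hit] + 0.5))
      }
      out[, , ch] <- plane
    }
  }
  unpainted <- leg$key[is.na(vals)]
  structure(list(raster = out, gene_id = gene_id, condition = condition,
                 time = if (nrow(agg)) agg$time[1] else "",
                 scale = scale, unpainted_ids = unpainted),
            class = "painted_image")
}

#' @export
print.painted_image <- function(x, ...) {
  d <- dim(x$raster)
  cat("Painted image: gene ", x$gene_id, ", condition ", x$condition,
      ", ", d[2], "x", d[1], " px", sep = "")
  if (length(x$unpainted_ids))
    cat(" (", length(x$unpainted_ids), " segments unpainted)", sep = "")
  cat("\n")
  invisible(x)
}

#' Paint every gene of a dataset
#'
#' One painted image per distinct gene id, in lexicographic gene order.
#' With `scale_policy = "global"` (default) a single shared scale is built
#' over the whole dataset so equal values give equal colors across genes.
#'
#' @param si A [segmented_image()].
#' @param ds An `expression_dataset`.
#' @param scale_policy `"global"`, `"symmetric"`, or `"per_gene"`.
#' @param condition Condition to paint.
#' @param mode Scale mode, see [color_scale()].
#' @param blend_alpha See [paint_gene()].
#' @param ... Passed to [color_scale()] via [build_color_scale()].
#' @return Named list of `painted_image` objects, one per gene.
#' @export
paint_all <- function(si, ds, scale_policy = "global", condition = "default",
                      mode = "diverging", blend_alpha = 1, ...) {
  genes <- dataset_genes(ds)
  if (!length(genes)) return(list())
  scales <- if (scale_policy == "per_gene") {
    build_color_scale(ds, "per_gene", mode, ...)
  } else {
    sc <- build_color_scale(ds, scale_policy, mode, ...)
    stats::setNames(rep(list(sc), length(genes)), genes)
  }
  out <- lapply(genes, function(g)
    paint_gene(si, ds, g, condition, scales[[g]], blend_alpha))
  names(out) <- genes
  out
}

#' Write painted images and a manifest
#'
#' Writes one `<gene>__<condition>.png` per painted image plus a
#' `manifest.tsv` (columns `gene_id`, `condition`, `path`) and a horizontal
#' color-scale legend strip `scale_legend.png`.
#'
#' @param paintings Named list from [paint_all()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_paintings <- function(paintings, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(paintings, function(p) {
    fn <- paste0(p$gene_id, "__", p$condition, ".png")
    write_raster(p$raster, file.path(out_dir, fn))
    data.frame(gene_id = p$gene_id, condition = p$condition, path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(paintings)) {
    write_raster(scale_strip(paintings[[1]]$scale),
                 file.path(out_dir, "scale_legend.png"))
  }
  invisible(manifest)
}

#' Render a color-scale strip
#'
#' A horizontal strip sweeping the scale domain left (low) to right (high),
#' with min, midpoint and max tick labels.
#'
#' @param scale A [color_scale()].
#' @param width,height Strip size in pixels.
#' @return An RGB raster.
#' @export
scale_strip <- function(scale, width = 256L, height = 32L) {
  v <- seq(scale$domain[1], scale$domain[2], length.out = width)
  cols <- value_to_color(scale, v)
  bar_h <- height - 12L
  strip <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) {
    strip[seq_len(bar_h), , ch] <- matrix(cols[, ch], bar_h, width,
                                          byrow = TRUE)
    strip[(bar_h + 1):height, , ch] <- 255L
  }
  lab_lo <- formatC(scale$domain[1], format = "g", digits = 3)
  lab_hi <- formatC(scale$domain[2], format = "g", digits = 3)
  strip <- draw_text(strip, lab_lo, 1L, bar_h + 3L, c(0L, 0L, 0L))
  strip <- draw_text(strip, lab_hi,
                     max(1L, width - 6L * nchar(lab_hi)), bar_h + 3L,
                     c(0L, 0L, 0L))
  strip
}
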