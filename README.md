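# atlaspaint

Expression-atlas painting of anatomical images, and embedding of the
painted images into biological networks.

## The problem

Spatio-temporal transcriptome datasets — one normalized expression value
per gene, tissue, developmental stage and condition — are usually read off
heatmaps, which discard the anatomy the samples came from. `atlaspaint`
puts the values back onto the organ: it color-codes the segments of a 2D
anatomical image by expression level, one image per gene, so a gene's
spatial expression pattern can be recognised at a glance, and then embeds
those per-gene pictographs into the nodes of a gene-regulatory (or any
other) network so patterns can be compared in their regulatory context.
The intended users are biologists with their *own* images and *own*
datasets: any species, any resolution, any number of stages or conditions.

## How it works

**Labelfield segmentation.** The user supplies a source image and a paired
*labelfield*: a pixel-aligned copy in which every region of interest
(tissue, cell type, or a whole stage panel in a montage) is flat-filled
with a unique color. A legend TSV maps each label color to a *spatial
identifier* (and optionally a stage). Label matching is exact RGB
equality; off-legend pixels (e.g. anti-aliased boundaries) are reported as
"unknown" and never painted. Several stage images can be concatenated into
one montage, where segment identity becomes `stage:tissue`.

**Value-to-color mapping.** Expression values arrive in a long-format
template (`gene_id`, `spatial_id`, `condition`, `time`, `replicate`,
`value`); replicates are averaged so each segment gets one value. A single
**global color scale** spans the min and max over *all* genes, segments
and stages, so equal expression means equal color everywhere:

    sequential:  color(v) = lerp(low, high, (v - min) / (max - min))
    diverging:   low -> mid at the domain midpoint, mid -> high above it

with blue = low, red = high, white midpoint, channels rounded half-up. For
each gene, every segment with a present value has its pixels set to
`color(v)` (or alpha-blended over the source); everything else — missing
segments, background, unknown pixels — is copied from the source
unchanged. Condition comparisons use a derived dataset of per-segment
differences `v(A) − v(B)` painted on a symmetric diverging scale
(`domain = [−max|v|, +max|v|]`), so "no change" is exactly the neutral
midpoint color.

**Network embedding.** Networks are read from GML (layout and attributes
preserved), SIF, edge-list CSV or SBML (topology, with reaction-centric
hyperedge expansion). Mapping is identifier equality between manifest
keys and node labels (or ids): matched nodes get the painted image
embedded at preserved aspect ratio. Exports are deterministic SVG/PNG
renders, visual-clustering grid sheets, stacked comparison strips, and a
self-contained HTML gallery.

A deterministic synthetic generator (`make_usecase_bundle()`) builds
complete template/labelfield/legend/network bundles shaped like the two
classic use cases — a single-stage four-whorl flower and a four-stage,
seven-tissue seed-development montage — so the whole workflow can be run
and tested without any external data.

## Worked example

```r
library(atlaspaint)

d <- tempfile("demo"); b <- file.path(d, "bundle")
atlaspaint_cli(c("simulate", "--usecase", "seed_like", "--seed", "7", "-o", b))

ds <- read_template(file.path(b, "template.tsv"))
ds
#> Expression dataset: 100 genes x 28 spatial ids, 2800 records
#>   project:    synthetic fixture bundle
#>   conditions: default

si <- load_segmented_image(file.path(b, "source.png"),
                           file.path(b, "labels.png"),
                           file.path(b, "legend.tsv"))
si
#> Segmented image 400x100 px, 28 legend entries

build_color_scale(ds, "global")
#> Color scale (diverging, global): [1, 9] #0000FF -> #FFFFFF -> #FF0000

ps <- paint_all(si, ds)
ps[["LEC1"]]
#> Painted image: gene LEC1, condition default, 400x100 px

head(as.data.frame(extract_segments(si)), 3)
#>                             key           spatial_id    stage pixels x0 y0 x1 y1
#> 1               globular:embryo               embryo globular    196 43 43 57 57
#> 2            globular:suspensor            suspensor globular    588 36 36 64 64
#> 3 globular:endosperm_micropylar endosperm_micropylar globular    980 29 29 71 71

man <- write_paintings(ps, file.path(d, "painted"))
net <- read_network(file.path(b, "network.gml"))
res <- attach_images(net, man, base_dir = file.path(d, "painted"))
res$network
#> Omics network (gml): 8 nodes, 12 directed edges
#>   nodes with attached images: 8

render_network(res$network, file.path(d, "figure.svg"),
               images_dir = file.path(d, "painted"))
```

Reading the output: the dataset holds 100 regulators measured in 28
segments (4 stages x 7 seed tissues); the color scale `[1, 9]` is the
global value range, blue at 1, red at 9; the segment table gives each
stage:tissue segment's exact pixel count and bounding box; all 8 network
nodes (LEC1, LEC2, FUS3, ABI3 and four more regulators) matched a painted
image by label, so the rendered figure shows each gene's spatio-temporal
expression pattern inside its network node.

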