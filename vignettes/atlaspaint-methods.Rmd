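---
title: "Painting expression atlases onto anatomical images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting expression atlases onto anatomical images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaspaint)
```

# The method

`atlaspaint` implements a two-step integration. First, normalized
expression values are assigned to segments of a 2D anatomical image and
the segments are color-coded by value, producing one pictograph per gene
and condition. Second, the pictographs are embedded into the nodes of a
biological network by gene-identifier matching, so spatial expression
patterns can be compared along regulatory relationships.

## The labelfield model

The spatial substrate is a pair of pixel-aligned rasters: the *source*
(the anatomical image shown to the user) and the *labelfield*, in which
every region of interest is flat-filled with one unique RGB color. A
legend TSV declares the color-to-identifier assignment; pure white and
pure black are background by default, extensible via a `#background:`
line. This declarative legend replaces an interactive color-to-tissue
assignment step: it makes runs reproducible and lets validators check the
labelfield before any painting happens.

Label matching is **exact RGB equality with tolerance zero**. Labelfields
are flat-filled paint images, so any pixel that matches no legend or
background color is evidence of lossy processing (JPEG compression,
anti-aliasing). Such pixels are classified *unknown*: they are counted
and reported by `validate_labelfield()` but never painted, so a slightly
damaged labelfield degrades gracefully instead of mis-assigning tissue
identity. A labelfield arriving with a `.jpg` extension triggers a
warning for the same reason. This treatment of off-legend pixels is this
package's convention; the alternative (nearest-color snapping) was
rejected because it silently moves pixels between tissues.

Stage series use a **montage**: per-stage images concatenated onto one
canvas so a single labelfield covers all stages. Segment identity then
becomes the pair (stage, tissue), written `stage:tissue` both in legend
keys and in template spatial identifiers (split on the first colon).
`compose_montage()` remaps label colors that collide across stages to
fresh colors and returns the remap table, so independently segmented
stage images can be combined without coordination.

Coordinates are top-left origin, x rightward, y downward; bounding boxes
are half-open `[x0, x1) × [y0, y1)`.

## The expression template

The canonical template is plain TSV: `#key: value` metadata lines
(project name, subjects, free-text source note) followed by a header row
naming `gene_id`, `spatial_id`, `condition`, `time`, `replicate`,
`value` in any order. A spreadsheet reader (via readxl) translates to
the same record model; TSV remains canonical because it diffs, versions
and round-trips exactly. Two contracts matter:

* **Missing is a state, never 0.** Empty cells and `NA` parse to an
  explicit missing value; painted output leaves such segments showing the
  source anatomy (configurable to a flat missing color).
* **One value per segment.** Replicates are aggregated before painting —
  mean by default (median available), ignoring missing replicates; a
  group with only missing replicates stays missing. Mean was chosen
  because the painting model assigns a single representative level per
  segment; the aggregation is idempotent, so pre-aggregated data passes
  through unchanged.

Identifier matching (template to legend, manifest to network) is exact
and case-sensitive by default, with an opt-in case-folding flag. Strict
equality is the only rule that never surprises; case folding exists
because display labels like `Ap1`/`AP1` are inconsistently cased in
curated networks.

## Color scales

A scale has a domain `[min, max]`, low/mid/high colors, a mode and a
domain policy:

* `global` (default): domain is the min/max over *all* genes, segments,
  conditions. One shared scale is what makes per-gene images comparable —
  equal value, equal color, everywhere.
* `per_gene`: each gene gets its own min/max; useful for shape rather
  than level comparisons, at the cost of cross-gene comparability.
* `symmetric`: domain `[-m, +m]` with `m = max |value|`, for difference
  views, so a zero difference is exactly the midpoint color.

The default ramp is diverging blue → white → red (low → high), the
red-high/blue-low convention of expression atlases; white was chosen as
the midpoint for print legibility. The exact hues and interpolation are
this package's reconstruction — only the endpoints' semantics (blue low,
red high) are fixed by convention. A sequential mode interpolates
low → high directly.

Numerical choices, stated so results are exactly reproducible:

* Channel interpolation is linear, **rounded half-up** to integers
  (`floor(x + 0.5)`), making small worked examples exact.
* Out-of-domain values are **clamped**, not errors: they legitimately
  arise when a global scale is reused on a subset.
* A **degenerate domain** (all values equal) maps everything to the
  midpoint color and warns.
* `color_to_value()` inverts the mapping using the channel with the
  widest span; for diverging scales both halves are inverted and the
  candidate whose forward mapping best reproduces the color wins
  (ties break toward the low half). Recovery is exact to one part in 255
  of the domain — the channel quantization bound.

## Painting

For each (gene, condition), segments with present values have their
pixels replaced by the scale color (`blend_alpha = 1`, the default) or
alpha-blended over the source so anatomical texture shows through.
Background, unknown and missing-value pixels are copied from the source
bit-for-bit — the *pixel conservation* invariant asserted raster-wide in
the tests. `paint_all()` produces one image per gene in lexicographic
order under one shared scale.

Difference views are ordinary datasets produced by
`derive_difference(ds, A, B)` — per-(gene, segment, time) subtraction
with missing propagation, antisymmetric by construction — painted on a
symmetric diverging scale.

## Networks and rendering

GML is read and written by a parser built for this package because
layout survives only there: the nested `graphics [ x y w h ... ]` block
and all unknown keys are preserved verbatim through round-trips (the
igraph GML reader, used as an independent cross-check in the tests,
discards nested blocks). SIF and edge-list CSV carry topology only;
writing a laid-out network to SIF warns about the loss. SBML is consumed
as topology with one intermediate process node per reaction
(reactant → process → product, modifiers attached to the process node),
the usual process-description convention.

`attach_images()` matches manifest keys against node labels by default —
in practice network genes are display labels, not locus ids — with `id`
matching and case folding as options, and resizes matched nodes to the
image aspect ratio (width kept, height derived). Stored `image_ref`
paths stay manifest-relative so exported networks are relocatable. Nodes
of different aspect ratios are resized independently; re-tiling a montage
into, say, a 2 × 2 arrangement per node is a pre-step the user applies to
the images, not something the mapper automates.

Renders are deterministic by construction: SVG is generated as text with
base64-embedded PNGs (no timestamps, fixed iteration order), and PNG
output is rasterized by the package itself — lines, node boxes,
nearest-neighbour image scaling, and labels drawn with a built-in 5×7
bitmap font — rather than through a graphics device, whose output can
vary across platforms and sessions. Interaction strings containing
"inhibit"/"repress"/"suppress" get a flat-bar head, everything else an
arrow. Node glyph vocabulary from pathway notations is *not* redrawn;
the class string is kept verbatim and only selects a border style,
because the embedded expression image is the visual payload here.

Grids (`compose_grid()`) and stacks (`compose_stack()`) place images
row-major into uniform cells; the *order* of images is caller input —
visual clustering is a manual, knowledge-driven arrangement, not an
algorithm. The HTML gallery is a dependency-free static page with the
images copied next to it; entry hyperlinks (e.g. to other networks or
database entries) are carried through verbatim.

# The synthetic generator

`fixture_spec()` + `make_segmented_image()` / `make_dataset()` /
`make_network()` / `make_usecase_bundle()` generate complete input
bundles. Design:

* Stage panels are concentric square rings (innermost tissue first),
  echoing nested anatomy such as embryo–endosperm–seed coat; panels are
  concatenated horizontally into montages. The generator tallies pixels
  as it paints; that tally is ground truth for the segmenter.
* Label colors come from an evenly spaced hue wheel (s = 0.78,
  v = 0.88), guaranteeing pairwise-distinct non-background colors.
* Gene patterns: `tissue_specific` (high in 1–2 tissues in all stages),
  `stage_specific` (high in every tissue of one stage), `ubiquitous`
  (high everywhere), `graded` (monotone across the stage order). High
  and low sit at 90% and 10% of the value range `[0, 10]`; the default
  mix is 0.4/0.2/0.2/0.2 and Gaussian noise (default sd 0, i.e.
  noise-free) is clipped to the range. With one stage, the
  stage-dependent classes fall back to the stage-free ones.
* The two bundle presets mirror the worked use cases **as synthetic
  stand-ins**: `flower_like` — one stage, four whorls (carpel, stamen,
  petal, sepal, innermost first), ten named floral regulators, 120×120
  px; `seed_like` — four stages (globular, heart, linear cotyledon,
  green mature) × seven seed tissues, 100 genes, 400×100 px. One seed
  makes every generated file byte-identical across runs.
* The regulator network preset has one hub with out-edges to all
  members, a three-node feedback cycle, a positive autoregulatory
  self-loop and one inhibition edge — the motifs of curated regulator
  cascades.

What the generator does **not** emulate: realistic expression
distributions or platform noise models, irregular segment shapes,
anti-aliased boundaries, lossy labelfields, or identifier mismatches
between template and network. Tests passing on these fixtures therefore
certify the mechanics (classification, painting, inversion, round-trips,
determinism) — they do not certify robustness to messy real-world
labelfields beyond the explicit unknown-pixel reporting path, nor any
biological conclusion.

`classify_pattern()` closes the loop: thresholding recovered per-segment
values at the domain midpoint recovers every gene's generated pattern
class in the noise-free setting — the measurable counterpart of "patterns
are readable at a glance". Note its graded-vs-stage-specific distinction
needs at least three stages; with two, a single late stage is
indistinguishable from a monotone ramp.

# Problem sizes and tolerances

The test suite and `scripts/acceptance.R` run the seed-like setting at
100 genes, 4 stages × 7 tissues and 400×100 px (2 800 painted segment
values, 4 million painted pixels total), the flower-like setting at 10
genes and 120×120 px, and network checks at 20 nodes — sizes at which
every check completes in seconds while exercising montages, global
scales and mapping at use-case shape. Color-inversion recovery is
asserted at the quantization bound (domain/255); conservation,
difference, montage and determinism checks are exact (zero mismatching
pixels/bytes). The 400-gene template check exercises the template reader
at the scale of a genome-wide regulator set.

# Known limitations

* Exact-color matching means labelfields must be lossless; JPEG
  labelfields are detected and warned about, not repaired.
* GML support targets the classic key-value dialect with one level of
  `graphics` nesting; exotic nested structures are preserved only as
  opaque attributes of that block.
* SIF/CSV inputs have no layout; the grid fallback is a placement, not a
  layout algorithm.
* PNG network renders use a fixed-size bitmap font; long labels overrun
  small nodes (SVG renders scale text properly).
* Aggregation supports mean/median only; weighted schemes would need the
  template to carry weights.
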