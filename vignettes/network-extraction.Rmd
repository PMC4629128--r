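---
title: "Extracting spatial graphs from images of networks: methods and design"
author: "netextract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting spatial graphs from images of networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(netextract)
```

Many biological structures — the vein networks of *Physarum polycephalum*
plasmodia, insect wing venation, leaf vasculature, crack patterns — are
observed as 2D images but analysed as graphs. `netextract` turns such an
image into an edge-weighted undirected spatial graph: vertices carry pixel
coordinates, edges carry centreline lengths and stroke-width estimates.
This vignette explains the pipeline's methods, the parameters that matter,
the synthetic benchmark, and the design decisions that were genuinely open.

## The extraction pipeline

A pipeline is an ordered sequence of named steps from four stages:

1. **Preprocessing** (optional): Gaussian, median or bilateral smoothing,
   or non-local-means denoising. Slight blurring can suppress spurious
   foreground speckles; too much erodes the thin structures whose widths
   we want to measure. All convolution-like operators use reflect padding
   so that the image border does not acquire artificial dark halos that a
   threshold would pick up as structure.
2. **Segmentation**: one of seven interchangeable methods labels each
   pixel foreground ("white", the structure) or background. Foreground is
   the brighter phase by default; every method takes an `invert` flag for
   dark-on-light material such as wing venation.
3. **Graph detection**: Guo–Hall thinning reduces the foreground to a
   one-pixel skeleton; a local criterion marks endpoints and junctions as
   nodes; a simultaneous breadth-first search traces the edges between
   them; the Euclidean distance transform of the segmentation supplies a
   stroke-diameter sample at every path pixel.
4. **Graph filtering**: post-hoc cleanup on the graph itself — keep the
   largest connected component, smooth degree-2 vertices, keep only
   edges that lie on cycles. Filtering the *graph* rather than repairing
   the segmented image or skeleton keeps every repair step transparent
   and reversible.

```{r pipeline-demo}
g <- generate_truth_graph(12, seed = 7, dim = c(320, 320),
                          margin = 25, min_sep = 45)
img <- render_graph(g)
res <- run_pipeline(img, predefined_pipeline("otsu"))
res$final_graph
```

## Segmentation methods and their failure modes

* `seg_otsu()` maximizes between-class variance of the gray histogram —
  ideal when the histogram is bimodal, brittle when the background drifts.
* `seg_adaptive()` thresholds against the local `block`-window mean:
  foreground iff intensity exceeds the local mean by more than `offset`.
  This makes the output exactly invariant to any smooth background ramp
  (the ramp shifts pixel and window mean alike). The window must be
  larger than the widest stroke, otherwise stroke interiors see an
  all-foreground window and hollow out; the benchmark pipelines use
  `block = 51` for strokes up to 15 px, with `offset = 10` chosen above
  the within-window ramp variation and far below the stroke/background
  contrast. The step's own defaults (`block = 11`, `offset = 2`) mirror
  the common library defaults.
* `seg_watershed()` floods the morphological gradient of the blurred
  luma from marker seeds; `seg_grabcut()` alternates Gaussian-mixture
  appearance estimation with a minimum cut on the 8-neighbourhood grid.
  Both are *guided*: they need a `marker_image` with sure-foreground and
  sure-background seeds, and they are only as good as those markers.

Three marker strategies are provided. `marker_erosion()` erodes a rough
binary guess (3×3 square element, 2 iterations by default — enough to
survive on strokes ≥ 5 px while guaranteeing seeds stay inside the
structure). `marker_distance_transform()` keeps pixels whose distance
value reaches 70% of the image-wide maximum. That global cut is the
strategy's Achilles heel, on purpose: any blob of misclassified
background immediately owns the maximum and starves every thinner,
disconnected structure of seeds, which is exactly the failure mode the
benchmark exposes. `marker_adaptive()` feeds an adaptive-threshold guess
into the erosion construction.

## Graph detection

**Thinning.** The Guo–Hall two-subiteration operator is iterated to a
fixed point (a compiled kernel; a pure-R reference implementation lives in
the test suite and the two are asserted identical). It deletes only, never
adds; preserves 8-connectivity of foreground and 4-connectivity of
background; and leaves the skeleton of a straight stroke on the stroke's
centreline — the property that justifies reading widths off the distance
transform at skeleton pixels. Off-grid pixels count as background.

**Nodes.** A skeleton pixel becomes a node when removing it leaves
exactly one (endpoint) or at least three (junction) 4-connected white
components among its eight neighbours. Because those eight positions form
a cycle under 4-adjacency, the count is the number of circular runs of
white neighbours, which makes the classification a 256-entry table lookup.
Single-pixel node locations cap the detected degree at four; a junction of
higher degree appears as a cluster of nearby nodes, which
`merge_close_nodes()` collapses to its centroid (extending edge paths to
the moved pixel, and discarding self-loops at or below the merge radius as
below-resolution artifacts).

**Edges.** Every white pixel adjacent to a node seeds a uniquely numbered
FIFO queue; queues are served round-robin in ascending label order, one
pixel per pass (labels assigned in row-major scan order — the published
procedure leaves service order open, a fixed order makes paths
bit-reproducible). A dequeued pixel that already carries a different label
means two searches met: an edge between the two owning nodes. Lengths sum
1 per axial and √2 per diagonal step, with the meeting step and the
node-to-seed steps each counted once, so a straight n-pixel node-to-node
path measures exactly n − 1 units. Two reconstruction choices deserve
note: collisions between two mutually adjacent seeds of the *same* node
are skipped (in a thin skeleton these are staircase corner artifacts, not
loops), and an edge is recorded only if its interior pixels are not
already claimed, which enforces "every skeleton pixel belongs to at most
one edge path". Node-free cycle components — perfect rings, on which the
criterion fires nowhere — get an anchor node at their row-major-smallest
pixel so the cycle is representable rather than silently dropped.
Self-loops shorter than 3 units are discarded as thinning artifacts.

**Widths.** The local stroke diameter at a path pixel is `2d − 1` where
`d` is the Euclidean distance to the nearest background pixel: a stroke of
odd width w has centreline distance (w + 1)/2 measured centre-to-centre,
so this calibration returns w exactly, where doubling alone would
overestimate every width by one pixel. Per-edge width is summarised as the
median (robust to the inflated samples near junction blobs) and the
population variance of the per-pixel diameters.

## The synthetic benchmark

No public corpus accompanies the evaluation protocol, so the package
manufactures ground truth. `generate_truth_graph()` draws random points
with a minimum separation, connects them with the Gabriel graph (a
subgraph of the Delaunay triangulation, hence planar and crossing-free; a
supergraph of the minimum spanning tree, hence connected), thins edges at
random, caps degrees at four and removes degree-2 vertices by merging
their edges into polylines — endpoint-and-junction-only graphs are what a
skeleton detector can represent. Edge widths are odd integers (symmetric
rasterization) drawn uniformly from 3–11 px on a 1024×1024 canvas with
vertices at least 70 px apart; truth edge lengths are the axial/diagonal
chain lengths of the rasterized centrelines, i.e. the length the drawing
actually preserves.

`render_graph()` draws each edge as a stroke of its width along its pixel
path (a union of disks — round caps, no anti-aliasing) and each vertex as
a disk of its maximum incident width, at foreground 220 on background 30.

`build_test_set()` then follows the published protocol's two defining
moves. First, *distillation*: the rendered image is processed by the
reference otsu/thin/detect pipeline and the extracted graph — not the
geometric original — becomes the ground truth, which is re-rendered to
give the test image. The image therefore depicts exactly its annotation,
junction-cluster geometry included, and discrepancies measured afterwards
belong to the pipeline under test, not to the fixture. The extract-render
map needs a few iterations to reach its fixed point (junction
configurations can flip between a detected junction and a "braid" of two
paths crossing without a junction pixel); three rounds suffice at the
default conditions. Second, *distortion*: each edge of the distilled truth
is deleted with probability 0.1, disconnections allowed, which diversifies
the set with multi-component networks — the structural feature that
separates the marker strategies (a component whose widest stroke falls
below the distance-transform marker's global cut simply vanishes from that
method's output).

Three corrupted conditions emulate progressively harder inputs:
per-edge random brightness in [60, 255]; a horizontal background ramp
[0, 160] behind untouched foreground; global Gaussian blur with σ = 2
(which measurably widens every extracted stroke). The brightness, ramp
and blur magnitudes are this package's own calibration — chosen so that
local contrast varies widely, the ramp materially disturbs global
thresholds, and the blur stays below stroke-destroying levels — since no
reference values exist for them.

What the generator does *not* emulate: curvilinear vein paths (generated
edges are straight strokes; distilled paths inherit mild raster
curvature), photometric texture and sensor noise, and width variation
along an edge. Passing benchmarks here therefore demonstrate the
correctness and internal consistency of the pipeline machinery, not
performance on raw micrographs.

## Scoring extractions

`match_vertices()` computes the correspondence between truth A and
extraction B as the maximum-cardinality, minimum-total-distance injective
matching among vertex pairs within `radius` (10 px at the 1024 scale,
scaled with image size — comfortably above thinning jitter, below the
70 px vertex separation). Optimal assignment, not greedy matching, keeps
the result deterministic and order-free. Edges correspond when both
endpoints do, parallel edges pairing off in length order. The similarity
score is

$$ s(A,B) = \tfrac12 \frac{\sum_{(a,b)} \bigl(1 - d(a,b)/r\bigr)}{\max(|V_A|,|V_B|)}
        + \tfrac12 \frac{\sum_{(e_A,e_B)} \tfrac12\bigl[c(\ell_A,\ell_B) + c(w_A,w_B)\bigr]}{\max(|E_A|,|E_B|)},
\qquad c(x,y) = 1 - \frac{|x-y|}{\max(x,y)}, $$

with c(0,0) = 1 and s = 1 for two empty graphs. It is 1 exactly at
self-comparison, 0 when no correspondence exists, symmetric, and
monotone under feature loss and weight drift. The published measure's
exact form is not publicly specified, so this reconstruction is
version-stamped (`netextract-s1`); scores are comparable only within a
version. Pooled counts over vertices and edges give sensitivity
TP/(TP+FN) and precision TP/(TP+FP); true negatives are undefined for
this task.

```{r evaluate}
set <- build_test_set(2, "ideal", params = list(
  n_vertices = 12, dim = c(320, 320), margin = 25, min_sep = 45),
  seed = 1)
evaluate_pipelines(list(otsu = method_pipeline("otsu")), set)
```

## Numerical and design choices

* **Coordinates.** Pixels are 0-based (row, col); a vertex (x, y) is
  (col, row). One convention everywhere prevents transposition bugs
  between image and graph space.
* **Adaptive threshold polarity.** Foreground iff intensity > local mean
  + offset (offset ≥ 0). The equivalent formulation with a subtracted
  negative constant would classify *constant* regions as foreground; the
  chosen sign convention makes a constant image empty, as it should be.
* **Evaluation pipelines** (`method_pipeline()`) append
  `merge_close_nodes` (radius 12 px at the 1024 scale — above the
  junction-cluster diameter set by the widest strokes, far below vertex
  separation) and the degree-2 smoothing filter, so that junctions of
  degree > 4 compare as single vertices on both sides of the score. The
  *predefined* pipelines shipped as configuration files keep merging off;
  merging is presented as optional post-processing.
* **Degenerate inputs.** A constant image segments to empty; an empty
  segmentation yields the empty graph; empty-vs-empty similarity is 1 by
  convention; sensitivity and precision are reported `NA` when their
  denominators vanish.
* **Ties.** Largest-component ties break by vertex count, then edge
  count, then the component holding the lexicographically smallest
  (x, y); degree-2 smoothing processes vertices in ascending id and
  re-checks eligibility after every contraction; both choices exist only
  to make results bit-stable.
* **GrabCut** re-estimates k = 5 mixture components per side from a
  quantile-seeded k-means (deterministic), β from the mean squared
  neighbour contrast, γ = 50, and solves each round's labelling with an
  exact s-t minimum cut. The grid graph construction makes it suited to
  moderate image sizes; the benchmark exercises the thresholding and
  watershed methods at full scale and GrabCut on smaller renders.
* **Problem sizes.** The shipped acceptance script measures 50 images per
  condition at 1024×1024 — the package's scaled-down restatement of the
  published 250-image protocol; the test suite uses 12 at the same
  render scale, and smaller canvases (320²) for unit fixtures.

## Known limitations

* The single-pixel node criterion cannot represent junctions of degree
  > 4 except as node clusters, and certain X-crossings thin into two
  touching paths with no junction pixel at all; distillation puts such
  configurations into the truth rather than pretending they are errors.
* Widths are trustworthy only where the skeleton runs along the middle
  of the stroke; at junction blobs the distance transform inflates, which
  the per-edge median absorbs but short junction edges do not.
* Otsu segmentation under a full-frame linear ramp is bistable: it
  either ignores the ramp entirely or splits it down the middle; there is
  no moderate-failure regime, so gradient-condition scores for global
  thresholding sit lower here than a partial-gradient corpus would give.
* The GrabCut energy uses full covariance Gaussians with a fixed
  regularizer; exotic colour distributions may need more components.
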