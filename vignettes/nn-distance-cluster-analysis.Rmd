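---
title: "Cluster analysis of SMLM point data with nearest-neighbour distance classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster analysis of SMLM point data with nearest-neighbour distance classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The method in one paragraph

Single-molecule localization microscopy (SMLM) reduces an image to a
list of point coordinates in nanometres. `smlmclust` decides, for every
localization, whether it belongs to a cluster by looking at the sorted
sequence of its distances to its $k$ nearest neighbours: a clustered
point sees compressed early distances relative to a point in complete
spatial randomness (CSR) at the same overall density. A small neural
network is trained to make that per-point call on simulated fields with
known ground truth; clustered points are then chained into discrete
clusters, and each cluster is given an outline polygon (a morphologically
eroded union of discs) from which area and shape statistics follow.

The pipeline is organized as discrete stages — simulate, featurize,
train (or classify), segment, report — each of which reads and writes
plain files, so any stage can be re-run or replaced independently.

# The input representation

For a field of $n$ points, `knn_distances(table, k)` computes the exact
$n \times k$ matrix of sorted Euclidean distances (2D or 3D as the
table dictates). Three representations are available:

* `distance` — raw nm distances;
* `difference` — consecutive gaps $d_1, d_2-d_1, \dots$;
* `normalized-distance` (default) — each row divided by its own $k$-th
  entry, so every row ends at exactly 1.

The default was chosen because per-row normalization makes the model
invariant to the absolute density scale: multiplying all coordinates by
a constant leaves the features untouched, which lets one trained model
serve fields at densities it never saw. The trade-off is that the
absolute density information is discarded; the raw representation is one
flag away when that matters.

Points need $k$ genuine neighbours, so fields with $n \le k$ are
rejected rather than padded — padding semantics would silently
manufacture geometry that does not exist.

# Simulation model

Training data are entirely synthetic. A field is generated inside an
irregular "cell-like" polygon built by radially perturbing a circle
(default mean diameter 10 µm, perturbation ±25%, 64 vertices, 3-vertex
circular smoothing). The perturb-then-smooth construction is the
simplest generator with protrusion-like, uneven edges and exactly two
interpretable knobs (diameter, irregularity); because every vertex sits
on its own ray from the centre the polygon is star-shaped and therefore
always simple.

A **clustering scenario** is the tuple (overall density, % clustered,
points per cluster, cluster radius), plus a cluster model:

* `uniform-disc` — uniform over a disc of the given radius;
* `gaussian` — isotropic normal, $\sigma = r/2$ truncated at $2\sigma$,
  so the nominal radius carries ~95% of the untruncated mass and the
  hard-edge and soft-edge models are comparable at equal $r$;
* `ring` — uniform over the annulus $[r/2, r]$;
* `fiber` — uniform along a bounded-turning random-walk polyline
  (length 2 µm, step 100 nm, turns ±30°) with 20 nm lateral jitter;
  fibre points carry a third class label;
* `sphere-3d` — uniform in a ball, with all $z$ confined to
  $[0, 500]$ nm, emulating the axial capture range of astigmatic 3D
  SMLM.

Counts round half-up; the last cluster may be under-filled so the
clustered-point total is met exactly; the remaining points are CSR
inside the polygon; the output row order is shuffled so file order
carries no label information. One integer seed makes a field fully
reproducible.

**What the generator does not model:** fluorophore re-blinking and
multiple detections, localization uncertainty, drift, and boundary
effects of clusters straddling the cell edge (cluster members are
redrawn until they land inside). Data with strong residual blinking
artefacts will present over-compressed first distances and should be
pair-corrected before classification.

## Scenario viability

Not every parameter tuple is a sensible training condition. A scenario
is **viable** when it yields between 1 and 5 clusters per µm²
(inclusive) and an in-cluster/out-of-cluster density ratio between 1.5
and 100 (inclusive): below these bounds clusters are indistinguishable
from CSR fluctuations, above them the task is trivially easy and
dominates the loss. The derived quantities are analytic:
$c = \rho \cdot p / \mathrm{ppc}$ clusters per µm², inside density
$\mathrm{ppc}/(\pi r^2)$, outside density from the non-clustered points
over the cluster-free area. The default training grid (densities
50–500 µm⁻², 10–90% clustered, 5–100 points per cluster, radii
10–100 nm) is filtered by this rule, which keeps roughly a quarter of
the 2700 tuples. Every quantity in the rule is intensive (per µm²) —
the cell area cancels in the outside-density term — so the viable set
is a property of the grid alone, not of the particular cell; the
package still computes it from the rule rather than hard-coding a
count.

# Models and training

Five presets are provided, named by their historical identifiers:

| preset  | input | layers | task |
|---------|-------|--------|------|
| XPILJZ  | 100   | 4 (dense 128 → dense 64) | binary, 2D |
| 07VEJJ  | 100   | 12 (conv/pool/dropout ×2, LSTM 64+32, dense 32) | binary, 2D |
| 87B144  | 1000  | 12 (as 07VEJJ) | binary, 2D |
| GAXJPR  | 1000  | 4 (dense 128 → dense 64) | binary, 3D |
| 3TXKFS  | 1000  | 3 (dense 128) | 3-class (none/cluster/fibre) |

Hidden-layer widths, kernel sizes and dropout rates are this package's
own defaults — the preset names promise the topology class and input
window, not bit-fidelity to any previously trained weights. Everything
is configurable through `model_spec()`.

Training uses softmax cross-entropy, Adam (learning rate $10^{-3}$),
batch 256, at most 50 epochs with early stopping on validation accuracy
(patience 5, best-epoch weights kept). These are deliberately
conventional choices: the interesting signal is in the features, and
the dense model is within noise of its asymptote long before epoch 50.
Training pools are balanced (equal class counts, within one row) and
the train/validation/test splits are disjoint by construction.

The network engine itself is implemented in R matrix operations (GEMM
via the linked BLAS) with analytic backpropagation for dense, 1-D
convolution, max-pool, inverted dropout and LSTM layers. The test suite
validates every layer's gradient against central finite differences;
training is deterministic for a fixed seed under single-threaded
numerics.

A practical note on scale: the headline dense models train on ~50k-row
pools in well under a minute of CPU; the recurrent presets are an order
of magnitude slower per epoch and only approach their asymptotic
accuracy with pools in the 10⁵–10⁶ row range, which is an overnight CPU
job rather than a desk-scale one.

# Segmentation and cluster shapes

Classified points are partitioned by a walk-and-stop rule: each
clustered point visits its neighbours in increasing distance order,
adding every clustered neighbour to its group and stopping at the first
non-clustered one. Groups sharing members merge (union–find). The walk
reuses the k-NN index from featurization and is therefore capped at $k$
neighbours — the same "reach" as the classifier. Clusters below
`min_cluster_size` (default 3; pairs and singletons are geometrically
degenerate for outlines) are demoted back to the unclustered pool.

Each cluster's outline is the union of discs centred on its members,
eroded inward. Both the disc radius and the erosion depth are
proportional to the cluster's own mean nearest-neighbour distance
(defaults: factor 1.0 and 0.5), so dense, tight clusters get tight
outlines and sparse ones stay closed without bridging to neighbours.
Rather than polygonizing discs and buffering, the implementation uses
the exact characterization of the eroded union as the sublevel set
$\{\,p : \max_{|u| \le e} d(p+u,\,\mathrm{members}) \le r\,\}$: the
distance field is evaluated on a grid (default 24 nodes per disc
radius), its disc-maximum is taken by sampling the erosion circle with
bilinear interpolation (valid because the distance-to-point-set field
has no interior local maxima), and the zero contour of $r - \tilde D$
is extracted with sub-grid linear interpolation. Areas agree with
closed forms (single disc, two-disc unions) and with an independent
exact-distance oracle to well under 2%, and erosion is monotone by
construction. Translation leaves areas identical to ~10⁻⁶ relative;
rotation re-discretizes the grid and agrees at the contouring-error
level (~10⁻³ relative at the default grid), which is the honest
tolerance for any grid-based construction.

Erosion can split a shape into parts (all parts keep the one cluster
id, areas summed, `n_parts` flagged) or annihilate it entirely, in
which case the un-eroded union is reported with `eroded_away = TRUE`.
3D clusters are segmented on 3D distances but outlined in 2D
projection.

# File formats and provenance

Localization tables read and write the ThunderSTORM CSV convention
(`"x [nm]"`, `"y [nm]"`, optional `"z [nm]"`; an uncertainty column is
tolerated and ignored), with a generic `x,y[,z]` fallback and
configurable dialects including pixel units with an explicit pixel
pitch. Coordinates are nanometres everywhere downstream. Feature
matrices persist in a binary container (one JSON header line, then
little-endian doubles) because featurization is the most expensive
stage and is reusable across models. Every output file is accompanied
by a JSON sidecar naming the tool version, seed and upstream file
hashes, so a result can be traced to its inputs; the classify stage
checks model-vs-feature compatibility from these headers before loading
any weights.

# A worked example

```{r example}
library(smlmclust)

cell <- generate_cell_shape(seed = 42)
scenarios <- sample_scenarios(
  viable_scenarios(default_training_grid(), cell), 40, seed = 101)
pools <- simulate_training_pools(scenarios, cell, k = 100,
                                 n_train = 50000, n_val = 10000,
                                 n_test = 10000, seed = 1,
                                 max_rows_per_field = 4000)
model <- train_model(model_preset("XPILJZ"), pools$train, pools$val,
                     seed = 1)
evaluate_model(model, pools$test)

field <- simulate_field(cluster_scenario(100, 40, 10, 40), cell, seed = 7)
fm <- knn_distances(field$table, k = 100)
labels <- classify_points(model, fm)
seg <- segment_points(field$table, labels, knn = fm)
shapes <- cluster_shapes(field$table, seg)
summarize_clusters(seg, shapes, analysis_area_um2 = cell$area_um2)
```

# Limitations

* Accuracy figures obtained from reduced training pools (a few times
  10⁴ rows) sit a few percentage points below the asymptote reached
  with 10⁵–10⁶-row pools; they are statistical reproductions, not
  fixed constants.
* The classifier reads only inter-point geometry: two biological
  conditions with identical second-order structure are
  indistinguishable by design.
* The simulator's cluster models are idealized; transferring a model
  trained on them to experimental data assumes blinking- and
  drift-corrected input.
* Shape areas inherit a grid discretization error (kept below 2% at
  the default resolution) and 3D cluster outlines are 2D projections.
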