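---
title: "Constraint maps and the binding problem in two-pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint maps and the binding problem in two-pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package simulates

Biological vision splits visual processing across functionally specialised
cortical streams — classically a ventral ("what") and a dorsal ("where")
pathway. Feed-forward network models of this organisation train one
convolutional *pathway network* per attribute. With a single object that is
unproblematic; with several objects it creates a *binding problem*: if one
pathway reports the identities present in a scene and another reports the
occupied locations, nothing in either output says *which* identity sits at
*which* location.

A cheap, purely representational way to constrain the problem is to make
both pathways order their output slots by the same rule — a **constraint
map**. If each pathway's slot *k* refers to the *k*-th object under a shared
ordering, the read-out network that combines the two pathways can align
their slot structures and recover per-object conjunctions. Any attribute can
supply the ordering:

* **location map** — slot order is the raster order of object positions
  (top row first, then left to right). This is a *relative* code: jointly
  translating all objects leaves the ordering unchanged.
* **identity map** — objects ordered by a fixed class order (t-shirt, pant,
  shoe, bag by default).
* **luminance map** — dark objects first (low, medium-low, medium-high,
  high).
* **orientation map** — up, left, down, right.

The simulation question is comparative: *which map yields the most accurate
two-pathway read-out?* The package reproduces the design of the published
simulation study this question comes from: when attributes are statistically
independent, a relative location map is the best choice for every attribute
pair, consistent with the predominantly retinotopic organisation of visual
cortex.

## Stimuli

Scenes are square black canvases (140 px at full scale) carrying
`n_objects = 3` object patches centred on cells of a 3×3 grid, locations
numbered 1–9 in raster order. Patches never overlap (each sits strictly
inside its own grid cell). Each object carries four attributes:

* **identity** — one of four classes;
* **luminance** — the *mean over all pixels of the object patch, including
  its black background pixels*, binned at multiples of 255/8 into four
  levels (low < 31.875 ≤ medium-low < 63.75 ≤ medium-high < 95.625 ≤ high;
  boundaries closed below);
* **orientation** — up, left, down or right (successive 90° counter-
  clockwise rotations of the canonical patch);
* **location** — the grid cell, 1–9.

Luminance is *intrinsic*: it is measured from the rendered patch and never
equalised, so class-dependent luminance distributions survive into the
scenes exactly as configured.

Three structural variants control attribute statistics:

* `original` — 6000 scenes; identities, luminance levels and orientations
  free to repeat within a scene (locations always distinct).
* `equal_classes` — locations restricted to the four corners {1, 3, 7, 9},
  so all four attributes have exactly four classes.
* `unique_attributes` — the three objects are pairwise distinct in *all
  four* attributes.

Each variant also exists with a `_tops` suffix, meaning the bank holds four
visually similar "tops" classes (t-shirt, pullover, coat, shirt) with
matched luminance distributions — the configuration that removes the
dependencies between identity, luminance and orientation.

Datasets split 2/3 train, 1/6 validation, 1/6 test (6000 → 4000/1000/1000)
and are byte-reproducible from their seed.

### The procedural glyph bank

The original study drew objects from a photographic clothing-image set.
This package's default object source is a *procedural glyph bank*:
parameterised silhouettes (with per-exemplar shape jitter) for seven
classes — t-shirt, pant, shoe, bag, pullover, coat, shirt — designed to
preserve the statistical structure the simulation depends on:

* classes are pairwise distinguishable (a nearest-centroid read-out on raw
  pixels separates them well above chance);
* every silhouette is rotation-asymmetric, so orientation is decodable;
* per-class intrinsic luminance is controlled by
  `glyph_luminance_means`/`sds`. The defaults reproduce the class-dependent
  luminance of the photographic set (shoes ≈ 33.6 ± 14.9, pants ≈ 57.2 ±
  13.7, t-shirts ≈ 81.0 ± 28.6, bags ≈ 85.8 ± 26.2); equal means remove the
  dependency, as in the tops condition.

Two rendering choices deserve a note. First, like photographs of dark
clothing, a low-luminance glyph is not uniformly faint: the renderer keeps a
brighter outline and a few near-white highlight pixels and lets the interior
fill absorb the luminance target, so dark objects remain detectable against
the black background. Second, luminance targets are truncated to a range
shared by all classes (`glyph_luminance_range`, default [4, 105]); without
this, classes with smaller silhouettes would truncate more of the upper
tail, quietly re-introducing an identity–luminance dependency in banks
configured with equal means.

What the glyph bank does *not* emulate: the intra-class shape diversity and
pixel texture of photographs. Glyph identity is easier than photographic
identity at matched resolution, and absolute accuracies are therefore not
comparable to the published full-scale numbers; the package's claims are
about *orderings between maps* under controlled conditions, which the
comparative design measures. An adapter for the original photographic set
(IDX files) is included for full-scale reproduction; bags are filtered to
those with handles using a documented heuristic (foreground pixels reaching
the top rows of the patch), since orientation is otherwise ill-defined for
them.

## Target encodings, ties, and scoring

`order_objects()` sorts a scene's objects by the map key; `encode_targets()`
then writes one one-hot vector per slot per task attribute. Both attributes
of a two-attribute task share the single ordering — that is the whole point
of a constraint map.

Maps other than location can tie (two pants under the identity map). The
study design permits tied objects to be reported in any order, but
supervised targets need a concrete assignment, so training labels break
ties canonically by location. Scoring defaults to the same canonical
convention; `score_predictions(..., tie_policy = "free")` instead accepts
any permutation within a tie group, jointly across the task attributes.

Accuracy is **per-slot** by default: the fraction of output heads whose
argmax equals the target class (the natural multi-head classification
accuracy). A `per_image` mode (all heads correct) is provided because
"number of correct classifications" can be read at either granularity; all
comparisons in the package use one mode consistently (per-slot).

## Networks

All pathway networks share one trunk configuration and differ only in their
heads (`n_objects` softmax groups, one per slot). The full-scale default
mirrors the published hyperparameters: two 3×3 convolution blocks (32 and
64 filters, 2×2 max pooling), dense 512 and 256, ReLU throughout, softmax
heads, 30% dropout on dense layers only, batch size 256, Adam with initial
learning rate 0.001, per-head cross-entropy losses summed with equal
weight. "Trained until the highest possible validation accuracy" is
operationalised as early stopping on validation per-slot accuracy with
configurable patience and best-weight restoration.

The engine is written in base R against BLAS: convolution by im2col gather
plus one matrix product, pooling by vectorised gathers, exact analytic
gradients (verified against numeric differentiation in the tests). Because
all randomness flows through R's RNG, training is bit-reproducible from a
seed — there is no backend nondeterminism.

A **two-pathway network** takes two pathways pre-trained under the *same*
map (enforced as a precondition), drops their heads, freezes their weights,
concatenates their final trunk activations, and trains common dense layers
(default one layer at desk scale) plus `2 × n_objects` heads. Since the
trunks are frozen, their activations are computed once per split; this is
mathematically identical to backpropagating through frozen layers and keeps
the combination step cheap. The freeze contract — trunk weights
bit-identical to the pre-trained snapshot after training — is asserted after
every fit.

## Experiment harness and statistics

`run_grid()` runs variants × maps × repetitions; within one (variant, map,
repetition) cell the four pathway networks are trained once and reused by
every attribute pair of that cell, matching the study's reuse of
independently pre-trained pathways. Each cell gets its own seed via a
deterministic label hash (`seed_for()`), datasets are fixed per variant,
and repetitions vary only the training run. Records stream to a CSV ledger,
making long grids resumable; a failed cell is recorded and skipped.

`summarize_cells()` prints mean ± SD percentages over the (default three)
repetitions. Map conditions are compared with two-sided Welch two-sample
*t*-tests (implemented closed-form, cross-checked against `stats::t.test`),
significance at p < 0.05 and no multiple-testing correction, matching the
study's reporting. The location map's advantage is expressed as

$$\mathrm{Gain} = \frac{\mathrm{LocationMapAccuracy} -
\mathrm{OtherMapAccuracy}}{\mathrm{OtherMapAccuracy}} \times 100\%$$

computed on mean accuracies per task pair.

## Desk scale

The package's tested configuration is a reduced **desk preset** chosen once
for single-CPU runs: 56 px canvas, 16 px glyphs, 60 exemplars per class,
1500 scenes (1000/250/250), a dense trunk (256, 128) on a 2× average-pooled
input, learning rate 0.003, at most 120 epochs with patience 15, and a
64-unit common layer in two-pathway networks. At this scale the location
pathway under the location map reaches ≥ 99% test accuracy, and the full
grid — 4 maps × (4 pathway tasks + 6 pairs) × 3 repetitions — runs in tens
of minutes on one core.

```{r desk, eval = FALSE}
library(bindmap)
bank <- build_bank(desk_bank_config(tops = TRUE, seed = 1))
grid <- grid_spec(variants = "original_tops", reps = 3, base_seed = 1)
records <- run_grid(bank, grid, desk_net_config(),
                    n_images = 1500, canvas_size = 56,
                    ledger_path = "ledger.csv", verbose = TRUE)
summarize_cells(records)
compare_to_location_map(records)
render_report(records, "report")
```

The acceptance script (`scripts/acceptance.R`) runs exactly this grid from
a command-line seed and writes the headline quantities as JSON.

## Numerical and design notes

* **Grid geometry.** Cell centres are the continuous centres of an even
  3×3 partition; patches are placed at `floor(centre − size/2) + 1` and a
  cell must be at least as large as a patch, which guarantees pixel-level
  disjointness. Location numbering is row-major (1 = top-left); only the
  relative order matters to the encodings.
* **Sampling.** Exemplars are drawn without replacement within a scene
  (two pants in one scene are two different pant exemplars). In the
  unique-attributes variant the sampler draws distinct attribute values
  first and then matches exemplars, retrying the level assignment when a
  (class, level) combination is unpopulated and failing with the offending
  attribute named if it cannot be satisfied.
* **Degenerate statistics.** Welch's test with two zero-variance samples
  returns p = 1 when the means agree (no evidence of difference) and is
  flagged degenerate otherwise; the gain formula refuses a zero
  denominator.
* **Untrained networks** score at chance (≈ 1/classes per head), which the
  tests use as a baseline contract.

## Limitations

* Absolute desk-scale accuracies are not calibrated to the published
  full-scale numbers; only the comparative structure (which map wins, and
  the direction of the gains) is expected to transfer.
* The glyph bank's identity classes are cleaner than photographs; identity
  pathways saturate faster than they would on the original imagery.
* No occlusion, scaling, continuous rotation, colour, or noise; the
  orientation attribute is exactly four right angles.
* One-pathway baselines, Hungarian-style set-matching losses and attention
  mechanisms are out of scope by design.
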