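# bindmap

Simulations of the multi-object **binding problem** in two-pathway visual
network models, and of the **constraint maps** that solve it.

## The scientific problem

Models of biological vision often process different object attributes in
separate specialised pathways (the classic ventral "what" / dorsal "where"
division). With several objects per scene this segregation creates a binding
problem: a pathway that reports *which identities are present* and a pathway
that reports *which locations are occupied* do not, by themselves, say which
identity belongs at which location.

The networks studied here constrain the problem representationally: both
pathways order their output slots by a shared rule — a *constraint map* —
so slot *k* of every pathway refers to the same object. The map can be based
on any attribute:

| map | slot order |
|---|---|
| location | raster order of positions (top row first, left to right) — a *relative* code |
| identity | fixed class order (t-shirt, pant, shoe, bag) |
| luminance | dark to bright (low, medium-low, medium-high, high) |
| orientation | up, left, down, right |

Scenes are black 140 px canvases with three non-overlapping object patches
on a 3×3 location grid. Each object carries four attributes: identity (4
classes), luminance (mean over all patch pixels, background included,
binned at multiples of 255/8), orientation (four 90° rotations) and
location (grid cell 1–9). A pathway network (convolutional/dense trunk,
one softmax head per slot) is trained per attribute; a **two-pathway
network** freezes two pre-trained trunks, concatenates their final layers,
and trains common dense layers to report both attributes of every object.
Map conditions are compared by test accuracy over three seeded repetitions
(Welch two-sample *t*-tests), and the location map's advantage is
summarised as

```
Gain = (LocationMapAccuracy - OtherMapAccuracy) / OtherMapAccuracy * 100%
```

The headline phenomenon this package reproduces at desk scale: **when the
objects' attributes are statistically independent, the location map yields
the highest two-pathway accuracy for every attribute pair** — a
computational rationale for the predominantly retinotopic organisation of
visual cortex.

Objects come from a built-in procedural glyph bank (seven distinguishable,
rotation-asymmetric clothing silhouettes with controllable per-class
luminance distributions); an adapter for Fashion-MNIST IDX files supports
full-scale reproduction. See `vignettes/constraint-maps.Rmd` for the
methods.

## Worked example

Train an identity and a location pathway under the location map at desk
scale (56 px canvas, 16 px glyphs, 1500 scenes), then bind identity to
location with a two-pathway network:

```r
library(bindmap)

bank <- build_bank(desk_bank_config(tops = TRUE, seed = 1))
ds   <- generate_dataset(bank, desk_dataset_config("original_tops",
                                                   n_images = 1500, seed = 1))

idp  <- train_pathway(NULL, ds, "identity", "location", desk_net_config(), seed = 1)
locp <- train_pathway(NULL, ds, "location", "location", desk_net_config(), seed = 2)
tp   <- train_two_pathways(build_two_pathways(idp, locp, desk_net_config()),
                           ds, c("identity", "location"), seed = 3)
idp; locp; tp
```

```
<trained_pathway> task identity, location map: val 0.697, test 0.671 (69 epochs)
<trained_pathway> task location, location map: val 1.000, test 0.997 (43 epochs)
<two_pathway_net> pathways (identity, location), location map: tasks (identity, location), test 0.819
```

The identity pathway reads the three identities in raster order of position
(67% per slot; chance is 25%), the location pathway reports the three
occupied cells almost perfectly (99.7%; chance 11%), and the two-pathway
read-out binds identity to absolute location at 82% per head — possible
only because both frozen trunks index objects the same way. Re-running
`run_grid()` over all four maps and all six attribute pairs shows the
location map winning every pair (see the vignette and the acceptance
script).

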