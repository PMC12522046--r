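---
title: "Synthesizing annotated reaction-scheme images and scoring their parsers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing annotated reaction-scheme images and scoring their parsers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnsketch)
```

## The problem

Most published chemical reactions live in figures, not in machine-readable
databases. Training and evaluating models that parse reaction-scheme images
requires large volumes of images with exact ground truth: where each reaction
component is, whether it is a reactant, a condition region or a product,
what the condition text says and which role each text span plays (agent,
solvent, temperature, time, yield), and the reaction SMILES each drawn step
encodes. Hand-labelling at that scale is impractical; the practical route is
to *synthesize* the images from reaction SMILES, so that every annotation is
correct by construction.

`rxnsketch` implements that route end to end in R, plus the two companion
pieces a parser project needs: a lossless token-sequence serialization of the
annotations (the kind of linearized target sequence detection-as-language
models train on), and an evaluation suite that scores any parser's output
against ground truth at the reaction, condition and reaction-SMILES levels.

## The generation pipeline

For each image the pipeline:

1. draws a **style**: font size, line width and molecule depiction scale,
   each uniform over a configured range, and a **layout pattern** from
   configured weights (`draw_style()`);
2. samples **abstract steps** from a reaction source — reactant, agent and
   product SMILES per step (`sample_steps()`);
3. samples **condition text** per arrow (`sample_conditions()`): agent names,
   a solvent, temperature/time/yield realizations of format patterns, and
   occasionally an out-of-role text such as "pH 10–11";
4. **lays out** boxes, arrows and text (`layout_scheme()`);
5. **renders** a PNG and re-measures every box against the drawn pixels
   (`render_scheme()`);
6. writes the annotation JSON and a manifest with an 8:1:1
   train/validation/test split (`build_dataset()`).

All randomness flows from one root seed through named substreams
(`rng_stream()`/`rng_fork()`), so a dataset, an image, or a single condition
sample can be reproduced in isolation; rebuilding with the same seed
reproduces annotations byte for byte.

### Layout patterns

Four scheme topologies cover the layouts common in the literature:

* **single line** — reactants, arrow, products left to right, with `+`
  between co-reactants. Content wider than `canvas_max_width` (default
  1024 px) wraps onto a continuation line, as happens in journals when a
  product does not fit.
* **multiple line** — one step per row. When the source provides a chained
  sequence (the product of row *i* is the reactant of row *i + 1*), the
  intermediate molecule is drawn once and the next row starts with its
  arrow; the shared molecule belongs to both steps' id lists.
* **branch** — several reactions fanning out of one shared reactant.
* **cycle** — 3–4 chained steps on a circle with clockwise curved arrows,
  the catalytic-cycle style.

### Condition placement

Agent text sits above the arrow; solvent, temperature, time and yield sit
below it, stacked in that order. For non-horizontal arrows "above/below"
generalizes to *left/right of the travel direction*: for a horizontal
left-to-right arrow the left-hand side is exactly "above", and for the
clockwise arcs of a cycle it is the outside of the circle. The choice makes
the rule checkable from geometry alone (`arrow_side()`), and the generator
maintains it as an invariant: every generated agent item's box center lies on
the agent side of its arrow, every other role on the opposite side. Branch
arms share a start point, so their condition blocks are anchored 72% of the
way along each arrow with clearance computed from the chord slope; arm
spacing is derived from the block extents so text from different arms cannot
collide.

### What the renderer guarantees

Molecules are depicted from Open Babel 2D coordinates (bond segments with
order-dependent doubling, element labels on heteroatoms); arrows get filled
heads, bidirectional arrows two opposed half-arrows, crossed-out arrows an
"×" at the midpoint. After drawing, the raster is read back and every
component and item box is replaced by the tight box of the ink inside its
allocated region — ground-truth boxes are therefore pixel-accurate
regardless of font metrics. Rendering is deterministic for a fixed scheme
and device configuration (fixed point size, cairo PNG device); the package
relies on the device's default font rather than bundled font files, so
pixel-identity holds within an environment rather than across operating
systems. Annotations (boxes included) are identical across reruns on the
same machine.

### What the generator does *not* emulate

Synthetic schemes are cleaner than real figures: no scanning artifacts,
no hand-drawn wedges, no R-group tables, no footnote markers, no overlapping
text, one font family per device. Passing tests on synthetic data therefore
bound a parser's behaviour under ideal rendering, not under real-literature
noise. Optional rotated condition text (a `text_rotation_range` draw,
off by default, ground truth being the axis-aligned box of the rotated text)
narrows but does not close that gap.

## The reaction sources

The bundled source (`toy_reaction_source()`) combines a curated list of
classic reactions with a combinatorial generator: scaffolds (alkyl chains,
branched alkyls, cyclohexyl, benzyl) crossed with functional-group
transforms (alcohol → aldehyde → acid → ester, alcohol → bromide → amine /
nitrile, acetylation), each transform carrying literature-style reagent
names ("DMP", "PBr3", "NaBH4", ...). The transform graph is what makes the
patterns non-trivial: chains give multi-line schemes, the out-edges of the
alcohol node give branches, and closed walks of length 3 and 4 give cycles.
User reactions come in via `reaction_source_file()` (one reaction SMILES per
line); such a flat list supports every pattern except cycles, which need
chainable steps.

Two conventions keep the assembled annotation equal to its source reaction:

* In branch and cycle layouts each node draws one molecule; surplus reactant
  molecules are written above the arrow (as the literature does with
  acylating agents and the like) and move to the agent field of the step's
  recorded source reaction.
* Only condition texts that parse as SMILES enter the agent field of the
  assembled reaction SMILES. The default vocabularies are reagent *names*
  that do not parse as SMILES, so name agents never leak into the string.

Every annotation stores both `reaction_smiles` (assembled from the drawn
components) and `source_smiles` (the reaction it was generated from), and
the two are `reaction_equal()` under both agent-comparison settings — a
tested invariant.

## The token codec

`encode_scheme()` linearizes a scheme into one block per step delimited by
paired `RXN_START`/`RXN_END` tokens; inside, each component becomes its own
paired block (`RCT_*`, `CND_*`, `PRD_*`) carrying four quantized coordinate
tokens, and condition blocks carry `role-token text` per item with role
tokens `[Age] [Sol] [Tem] [Time] [Yld]` — items of role "other" carry text
but *no* role token, mirroring how out-of-scope text should be transcribed
without classification. Numeric coordinate tokens are used rather than a
vocabulary of location words: each coordinate maps to
`round(c / extent * (B - 1))` with `B = 1000` bins by default, which keeps
the worst-case round-trip error at half a bin (sub-pixel on canvases up to
2000 px). Texts travel as single tokens with spaces and bracket prefixes
escaped.

Step order in the sequence is reading order (top-to-bottom, left-to-right by
arrow midpoint) for line and branch patterns, and arrow-chain order starting
from the topmost component for cycles. `decode_tokens()` is total: malformed
streams produce a best-effort scheme plus diagnostics, never an error —
a property enforced by fuzzing in the test suite.

## The evaluator

A predicted step matches a ground-truth step iff their components admit a
bijection in which every pair has box IoU at least τ (default 0.5) and
agreeing roles. The **soft** criterion relaxes exactly one thing: a
ground-truth agent-bearing condition may be predicted as a reactant — the
chronic ambiguity of species drawn over the arrow. Because the relaxation
only ever adds admissible pairs, soft precision, recall and F1 are *provably*
at least their hard counterparts, and the test suite checks the ordering on
hundreds of corrupted prediction sets. Reaction-level scoring uses
maximum-cardinality bipartite matching (augmenting paths, deterministic in
input order) between predicted and ground-truth steps; on small instances it
is verified against brute-force enumeration over all injections.

Condition metrics pair items by box IoU (greedy, highest first): **CRI**
(condition role identification) tabulates a 6-role confusion matrix with a
dedicated *missed* column for unpaired ground truth, unpaired predictions
charging precision of their predicted role; **condition OCR** counts paired
items whose texts are identical after NFKC normalization, whitespace
stripping and degree-glyph unification ("35C" ≡ "35 °C" ≡ "35℃").
**Reaction SMILES exact match** scores whole images: the predicted reaction
set must equal the ground truth under canonical-form multiset equality,
order-insensitively across steps; bidirectional arrows first expand into
both directions and crossed-out steps are dropped. Whether the agent field
participates in reaction equality is a flag (`include_agents`); the default
compares reactants and products only, the conservative reading of
"exact match" when a parser may legitimately transcribe agents as text
rather than structures.

Precision with zero predictions is defined as 0 (matching the F1 = 0
convention), so empty outputs score 0 rather than raising.

## Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| font size | 10–16 pt | journal caption-to-body range at 72 ppi |
| line width | 1–3 px | print-quality bond strokes |
| molecule scale | 20–32 px/bond | typical depiction sizes at screen resolution |
| pattern weights | uniform over 4 | the real corpus mix is configurable, not fixed |
| canvas max width | 1024 px | common figure column width at 72 ppi |
| coordinate bins B | 1000 | half-bin error stays sub-pixel on these canvases |
| IoU threshold τ | 0.5 | the standard detection correspondence criterion; a flag, echoed in reports |
| split ratios | 8:1:1 | standard train/val/test proportions |

Split sizes follow `round(N·0.8)` / `round(N·0.1)` (round half up) with the
remainder to test, so `N = 1000` gives 800/100/100 and `N = 7` gives 6/1/0;
the rule is stated because any other rounding changes small-dataset splits.

Degenerate inputs are handled as data, not crashes: `validate_scheme()`
returns violations as a data frame; the decoder reports diagnostics; a
molecule wider than the wrap threshold at the drawn scale is a hard layout
error, and `build_dataset()` logs such failures and resamples the item
(at most 25 attempts before giving up).

## Scales used by the tests

The test suite exercises 1000 generated schemes for the validity sweep,
500 corrupted prediction sets for the soft/hard ordering, 300 schemes ×
three bin widths for codec round trips plus 1000 random token streams for
decoder totality, 200 small instances for the matching oracle, and a
rendered 12-image dataset for the self-evaluation identity; the acceptance
script rebuilds a 24-image dataset and a 200-scheme sweep from its seed.
These sizes were chosen so the full property sweep stays comfortable on a
single CPU while still crossing every pattern, role and augmentation
extreme many times over.

## A worked example

```{r example, eval = FALSE}
library(rxnsketch)

manifest <- build_dataset(24, "demo_dataset", seed = 7)
gts <- load_schemes(manifest)

# ground truth scores perfectly against itself
evaluate_dataset(gts, gts)

# a corrupted copy behaves like an imperfect parser: soft >= hard
preds <- lapply(seq_along(gts), function(i)
  perturb_scheme(gts[[i]], rng_fork(rng_stream(99), i)))
evaluate_dataset(preds, gts)

# token round trip
toks <- encode_scheme(gts[[1]], n_bins = 1000)
decode_tokens(toks)$scheme
```

## Known limitations

* Molecule depiction is schematic (no implicit-hydrogen counts on labels,
  no stereo wedges); recognition models trained only on these depictions
  will not see the full variety of published drawing styles.
* The generator emits straight and curved one-way arrows; bidirectional and
  crossed-out arrows are fully supported by the data model, the codec and
  the evaluator, but are not currently sampled by the layout engine.
* Name-to-structure resolution is out of scope: a name agent stays text and
  never becomes part of a reaction SMILES.
* Pixel-identical rendering across machines is not guaranteed (fonts and
  antialiasing are device properties); annotation determinism is.
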