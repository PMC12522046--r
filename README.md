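# rxnsketch

Synthesize annotated chemical reaction-scheme images from reaction SMILES,
serialize the annotations as token sequences, and score any reaction-image
parser against exact ground truth.

## Who this is for

Building a model that reads reaction schemes out of the chemical literature
requires two things that are hard to get: large training sets of images with
exact ground truth, and a scoring protocol that measures what chemists care
about. `rxnsketch` provides both without any hand labeling. Images are
*generated* — molecules depicted from 2D coordinates, placed on a canvas in
one of four layout patterns (single-line, multiple-line, branch, catalytic
cycle) with arrows and role-tagged condition text — so the positions, roles,
texts and per-step reaction SMILES in the annotation are correct by
construction.

## What it computes

**Generation.** For each image: a style draw (font size, line width,
molecule scale, pattern — the augmentation axes), reaction steps from a
reaction source (a bundled toy source or a file of reaction SMILES, one
`reactants>agents>products` line each), sampled condition text with roles
`agent | solvent | temperature | time | yield | other`, layout, PNG
rendering with pixel-tight re-measured boxes, annotation JSON, and a
manifest with an 8:1:1 train/val/test split. Agent text is placed above the
arrow, other roles below it — an invariant checkable from box geometry.

**Token codec.** Annotations linearize into paired start–end token blocks
(`RXN_*` per step; `RCT_* / CND_* / PRD_*` per component) with four numeric
coordinate tokens per box, quantized as `round(c / extent · (B−1))` with
B = 1000 bins by default; condition items carry role tokens
`[Age] [Sol] [Tem] [Time] [Yld]`, with role-`other` text transported without
a role token. Decoding is total and inverts coordinates within half a bin.

**Evaluation.** A predicted reaction matches ground truth iff its components
admit a bijection with box IoU ≥ τ (default 0.5) and matching roles — the
*hard* criterion; the *soft* criterion additionally accepts a ground-truth
agent predicted as a reactant. Reported metrics: precision, recall and
F1 = 2PR/(P+R) (hard and soft, overall and per pattern, via
maximum-cardinality bipartite matching of steps), a condition-role confusion
matrix with per-role P/R/F1, condition OCR accuracy under text normalization
("35C" ≡ "35 °C"), and reaction SMILES exact-match accuracy under
canonical-form multiset equality (bidirectional arrows expand to both
directions; crossed-out reactions are excluded).

## Worked example

```r
library(rxnsketch)

manifest <- build_dataset(8, "demo", seed = 7)
table(manifest$records$pattern)
#>        branch         cycle multiple_line   single_line
#>             2             1             1             4

gts <- load_schemes(manifest)
evaluate_dataset(gts, gts)
#> Reaction-image parsing metrics over 8 images
#> hard match (IoU >= 0.50): TP 16 FP 0 FN 0 | P 1.000 R 1.000 F1 1.000
#> soft match (IoU >= 0.50): TP 16 FP 0 FN 0 | P 1.000 R 1.000 F1 1.000
#> CRI accuracy: 1.000 | OCR accuracy: 1.000 | SMILES exact match: 1.000
```

Ground truth scored against itself is perfect on every level — the identity
that anchors the whole evaluation. A corrupted copy behaves like an
imperfect parser and shows the soft ≥ hard ordering:

```r
preds <- lapply(seq_along(gts), function(i)
  perturb_scheme(gts[[i]], rng_fork(rng_stream(21), i)))
r <- evaluate_dataset(preds, gts)
r$hard$overall$f1; r$soft$overall$f1
#> [1] 0.5806452
#> [1] 0.7741935
```

Token round trip:

```r
toks <- encode_scheme(gts[[1]], n_bins = 1000)
head(toks, 8)
#> [1] "RXN_START" "RCT_START" "76" "267" "204" "443" "RCT_END" "RCT_START"
decode_tokens(toks)$diagnostics   # empty: well-formed stream
```

A thin CLI wraps the same functions
(`inst/cli/rxnsketch.R generate|evaluate|codec|inspect`); `inspect` renders
an annotation overlay for eyeballing.

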