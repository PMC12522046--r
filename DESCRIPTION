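Package: rxnsketch
Title: Synthetic Reaction-Scheme Images, Token Annotations, and Parser Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates annotated chemical reaction-scheme images from reaction
    SMILES: molecules are depicted from 2D coordinates, placed on a canvas in
    one of four layout patterns (single-line, multiple-line, branch, cycle)
    with arrows and role-tagged condition text (agent, solvent, temperature,
    time, yield), and every image is written together with machine-readable
    ground truth (component boxes and roles, condition items, per-step
    reaction SMILES). Annotations can be linearized into a token sequence
    with paired start-end tokens and quantized numeric coordinates, and
    parsed back. A scoring module evaluates any reaction-image parser against
    such ground truth: hard/soft reaction-level precision, recall and F1,
    condition role identification (confusion matrix and per-role metrics),
    condition OCR accuracy, and reaction SMILES exact-match accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stringi,
    stats,
    grDevices,
    graphics,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
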