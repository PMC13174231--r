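Package: iraekit
Title: Multi-Label Identification of Immune-Related Adverse Events in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable pipeline for identifying immune-related adverse
    events (irAEs) attributable to immune checkpoint inhibitor (ICI) therapy in
    unstructured patient notes. Renders zero-shot, synset-augmented prompts from
    site-specific vocabularies, classifies notes through a pluggable backend
    (including a deterministic rule-based backend with negation, hypothetical and
    alternative-etiology cue handling), parses JSON model output robustly,
    aggregates note-level calls to patient-level outcomes via a positive-note-count
    decision threshold with micro-F1 threshold sweeps, and evaluates multi-label
    performance (precision, recall, specificity, F1; micro and macro averages) at
    note, patient and organ-category level. A synthetic clinical-corpus generator
    with known ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
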