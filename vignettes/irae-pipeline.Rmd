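---
title: "Identifying immune-related adverse events in clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying immune-related adverse events in clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraekit)
library(dplyr)
```

## The problem

Immune checkpoint inhibitors (ICIs) — PD-1/PD-L1 and CTLA-4 blockers such as
nivolumab, pembrolizumab, atezolizumab and ipilimumab — cause immune-related
adverse events (irAEs) in a large fraction of treated patients: colitis,
pneumonitis, hepatitis, endocrinopathies, rash and many rarer toxicities.
These events are poorly captured by structured data; the causal link between
drug and toxicity is usually documented only in free-text clinical notes.
Extracting irAEs from notes is harder than named-entity recognition for two
reasons:

1. **Assertion status.** A mention of "colitis" may be negated ("no evidence
   of colitis"), hypothetical ("discussed risk of colitis"), or about a
   possibility rather than an event.
2. **Causal attribution.** Even a positively asserted event may have a
   non-ICI etiology ("diarrhoea secondary to *C. difficile*"). Only events
   attributable to the ICI count.

`iraekit` implements a multi-label pipeline for this task: each patient (or
note) is assigned any subset of a site-specific irAE label list, including
the empty set ("None"). The pipeline has five stages — prompt rendering,
backend classification, output parsing, note-to-patient aggregation, and
evaluation — plus a synthetic-corpus generator that makes every stage
testable with no clinical data and no model API.

## Site profiles and synsets

Institutions annotate irAEs differently, so the vocabulary is configuration,
not code. A *site profile* (one YAML file) carries the label list, per-label
*synsets* (synonyms, acronyms and related concepts, e.g. neuropathy ~
{neurotox, neurotoxicity}), the ICI drug list, and a mapping from each label
to one of ten closed organ-level categories (Cardiovascular, Dermatologic,
Endocrine, Gastrointestinal, Haematological, Musculoskeletal and
Rheumatologic, Neurologic, Other, Pulmonary, Renal). The three shipped
example profiles illustrate real cross-site differences: one keeps colitis
and diarrhoea as separate labels, another merges them under a single colitis
label whose synset carries both surface forms, and the third uses
trial-report preferred terms (pyrexia rather than fever). Labels missing
from the category map are assigned to "Other" with a warning rather than
dropped, since silent drops would corrupt pooled (micro) counts.

```{r}
profile <- example_site_profile("ucsf")
profile
```

## The zero-shot prompt

For each note the pipeline renders one binary query per label:

```{r}
render_query("neuropathy", c("neurotox", "neurotoxicity"))
```

plus a preamble naming the patient-note context and the ICI list, a JSON
output directive (one `"Yes"`/`"No"` field per label), and the note body.
Queries follow profile order, so rendering is a pure function and a fixed
profile gives byte-reproducible prompts. Two choices the template records
explicitly: the note body is placed *after* the instructions, framed by
`<<<NOTE ... NOTE>>>` delimiters (so any backend, including the rule-based
one, can recover exactly what it was shown), and notes beyond a configurable
character budget (default 48,000) are truncated tail-first with a warning,
reflecting bounded model context windows. The template lives in
`inst/templates/prompt_template.txt` and can be overridden per run.

## Backends and the rule-based annotator

Backends plug in behind a single contract: a request (flattened prompt,
expected label keys, decoding temperature — fixed at 0 so compliant model
backends always emit their highest-probability token per label) goes in, a
raw text response with a transport-success flag comes out. Failures never
escape the boundary; they are encoded as `ok = FALSE` and become all-"No"
predictions flagged `failed` downstream.

The package's primary backend is deterministic and rule-based
(`mock_annotate()`), designed around the two failure modes above. For each
label it scans sentence by sentence for case-insensitive, word-boundary
matches of the display name or any synset term (multi-word terms match as
contiguous token runs). A match is a positive call unless:

* a **negation or hypothetical cue** ("no evidence of", "denies", "ruled
  out", "risk of", "monitor for", ...) ends within `window` tokens (default
  10) *before* the match in the same sentence; or
* the sentence's **nearest etiology marker** ("due to", "secondary to",
  "attributed to", "caused by", ...) is followed within the window by an
  identified non-ICI agent (infection, cytotoxic chemotherapy, radiation,
  ...) and not by an ICI drug.

Mentions with no etiology marker, and mentions whose marker's agent is
neither an ICI nor a known non-ICI agent, count as positive: suppression
requires an *identified* alternative cause. Immune-mediation markers
("immune-mediated") are causally compatible by construction. Sentence
segmentation is a simple split on terminal punctuation followed by
whitespace; clinical-abbreviation false splits are accepted — segmentation
fidelity is not this package's subject. The rule set is data
(`cue_rules()`), so sites can extend the lexicons without touching code.

This backend is an original, fully testable component — a deterministic
oracle aligned with the assertion/causation error taxonomy — not an
emulation of any language model. A remote adapter for OpenAI-compatible
endpoints honours the same contract (temperature passed through, two retries
with backoff, soft failure without credentials).

## Parsing

Model output drifts from the requested JSON in practice, so the parser
recovers rather than raises: prose-wrapped JSON is extracted between the
outermost braces; missing keys default to "No"; off-vocabulary values map to
"No"; unexpected keys are dropped with a warning. Each prediction carries a
`parse_status` (`clean` / `repaired` / `failed`) so repair frequency is
observable per run. The conservative "No" default is deliberate: generative
classifiers in this task lean toward over-predicting positives, so recovery
must never add positives.

## Note-to-patient aggregation and the decision threshold

A patient's notes are classified independently (one prompt per note — whole
records do not fit any bounded context window), then aggregated: a patient
is positive for a label when at least `k` notes carry a positive call.
`k = 1` is the logical OR over notes, appropriate when patients have few
notes; on note-rich corpora a larger `k` suppresses false positives at the
cost of recall. `sweep_threshold()` re-thresholds every patient at each
`k = 1, ..., k_max` (default: the corpus's maximum per-patient note count,
beyond which the curve is constant) and reports micro-averaged precision,
recall, specificity and F1 per `k`; `k_best` maximises micro-F1, with ties
broken toward the smallest `k` (favouring recall). Because positive sets are
nested in `k`, micro-recall is non-increasing and micro-specificity
non-decreasing — properties the test suite verifies by exhaustive
re-thresholding. Sweeping on the evaluation corpus itself is the package's
default because it mirrors common practice for this design; it is optimistic
about generalisation, and the stage functions accept any held-out split a
user prefers.

## Evaluation

Per label: precision (PPV), recall (sensitivity), specificity and F1 over
the 2x2 table of evaluation units (notes or patients). A ratio is `NA`
exactly when its denominator is zero; F1 is `NA` when TP = FP = FN = 0 and 0
when TP = 0 with errors present. The micro row pools counts over labels
before computing metrics; the macro row is an unweighted mean over labels,
excluding `NA` entries per metric — with `NA`-bearing labels present, this
exclusion is the only reading under which averages remain well defined, and
the output documents it. Category-level evaluation projects both prediction
and gold through the profile's category map (category positivity is the OR
over member irAEs) and scores identically; within-category confusions
therefore become category-level agreements. Note-level evaluation requires
explicit note-level gold; it is never inferred from patient-level
annotations.

## The synthetic corpus generator

The generator emulates the *structure* of an ICI cohort's notes, not
clinical language: per patient an exposure interval, dated notes, and a gold
label set drawn per-label Bernoulli(prevalence). Every gold label is
realised as at least one positive-causal mention sentence; non-gold labels
may receive confounder mentions — negated, hypothetical, or
alternative-etiology with a named non-ICI agent — with probability
`1 - mixture["positive_causal"]`, regime drawn from the renormalised
confounder weights. Confounders attach to non-gold labels only, keeping the
ground truth unambiguous (a deliberately excluded realism: true events
missed by annotators, which would poison the oracle). Sentence templates are
data (`inst/extdata/sentence_templates.yaml`); positive templates are
constructed to be positively asserted and ICI-attributed, confounder
templates to carry their governing cue or agent, so the generator and the
rule-based backend agree by construction on a confounder-free corpus — the
end-to-end perfect-recovery property (micro-F1 = 1.0) that anchors the test
suite. Passing it shows the pipeline's plumbing is exact; it does not show
performance on real clinical language, whose variability neither the
generator nor the rule backend models.

Default conditions: 50 patients, 3–8 notes each, per-label prevalence 0.25,
regime mixture (0.70 positive-causal, 0.12 negated, 0.10 hypothetical, 0.08
alt-cause), synonym use 0.3, two distractor sentences per note (Poisson) —
a small, hospitalisation-style cohort; note counts per patient are far below
EHR-scale corpora, and the test suite scales `n_patients` between 10 and
1000 by what each property needs. Timestamps are drawn inside the exposure
window plus six months, so default corpora pass the window filter unchanged.

The window filter itself retains notes from the first ICI exposure date to
six calendar months (configurable) after the last administration date, both
bounds inclusive, with end-of-month clamping (Aug 31 + 6 months = Feb 28).
The bound convention is the package's choice; only the six-month extent is
standard.

## Reproducibility

Everything downstream of the generator is deterministic: the corpus is a
pure function of its seed, the rule backend of its inputs, and aggregation
and evaluation are arithmetic. `run_pipeline()` persists every intermediate
(notes JSONL, predictions JSONL, threshold-curve and metrics CSVs) plus a
manifest (profile hash, backend id, seed, chosen `k`) sufficient to
re-execute bit-identically, and any stage can be re-run from the persisted
files.

```{r, message = FALSE}
run <- run_pipeline(
  example_site_profile("ucsf"),
  sim = sim_config(n_patients = 40, seed = 7),
  out_dir = file.path(tempdir(), "demo_run"), seed = 7
)
glance(run$patient_metrics)
glance(run$curve)
```

```{r, fig.width = 6, fig.height = 3.5}
autoplot(run$curve)
```

## Known limitations

* The rule-based backend shares its cue vocabulary with the generator's
  templates; results on synthetic corpora certify the pipeline, not
  clinical-text performance.
* Sentence segmentation and tokenisation are intentionally simple; clinical
  abbreviations can split sentences spuriously.
* Thresholds are global, not per-label, and aggregation is count-based, not
  probabilistic.
* The shipped profiles reconstruct only publicly summarised site
  vocabularies; real deployments must supply their own.
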