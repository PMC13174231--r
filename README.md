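# iraekit

Multi-label identification of immune-related adverse events (irAEs) in
unstructured patient notes.

Immune checkpoint inhibitors (ICIs — PD-1/PD-L1 and CTLA-4 blockers such as
nivolumab, pembrolizumab, atezolizumab, ipilimumab) cause immune-related
toxicities in most treated patients, and the causal link between drug and
event is usually documented only in free-text clinical notes. `iraekit` is
an R toolkit for pharmacovigilance and clinical-NLP researchers who need to
extract those events at scale and evaluate the extraction rigorously. Each
patient (or note) receives any subset of a site-specific irAE label list,
including the empty set ("None") — a multi-label problem scored per label
and in aggregate.

## What it does

The pipeline runs in five stages, each an exported verb over tibbles:

1. **Prompt rendering** — a zero-shot prompt per note built from a *site
   profile* (irAE labels, per-label synonym sets, ICI drug list,
   irAE-to-organ-category map in one YAML file). Each label becomes one
   binary query, e.g. *"Output 'Yes' if the patient has experienced
   neuropathy (neurotox, neurotoxicity) because of exposure to one or more
   immune checkpoint inhibitors. Otherwise, output 'No'."*
2. **Classification** — through a pluggable backend contract. The primary
   backend is a deterministic rule annotator that handles negation
   ("no evidence of colitis"), hypothetical mentions ("discussed risk of
   pneumonitis") and alternative etiologies ("diarrhoea secondary to
   *C. difficile*"); an adapter for OpenAI-compatible endpoints honours the
   same contract at decoding temperature 0.
3. **Parsing** — robust recovery of the JSON `{"label": "Yes"/"No", ...}`
   answer from raw model text; every failure mode becomes a `parse_status`
   flag, never an exception, and missing values default conservatively
   to "No".
4. **Aggregation** — note-level calls roll up to patient level: positive
   when at least `k` notes are positive. `k = 1` is the OR over notes;
   `sweep_threshold()` scans `k` and picks the micro-F1 optimum
   (`k_best`, smallest on ties).
5. **Evaluation** — precision, recall, specificity and F1 per label, with
   micro (pooled-count) and macro (per-label mean, NA-excluded) averages, at
   note, patient and organ-category level (a category is positive when any
   member irAE is).

A synthetic corpus generator with exact ground truth (`generate_corpus()`)
makes the whole pipeline testable without clinical data: gold labels appear
as positively asserted, ICI-attributed mentions; confounder mentions
(negated / hypothetical / alternative-cause) attach only to non-gold labels.
A six-month exposure-window note filter (`filter_notes_by_window()`)
reproduces the standard cohort-construction step.

## Worked example

```r
library(iraekit)

run <- run_pipeline(
  example_site_profile("ucsf"),            # merged colitis/diarrhoea vocabulary
  sim = sim_config(n_patients = 40, seed = 7),
  out_dir = "demo_run", seed = 7
)
#> [classify] 221 notes, 40 patients, backend=mock
#> [parse] status: clean=221
#> [aggregate] k_best = 1 (micro-F1 = 1.0000)

run
#> <irae_run> ucsf | 40 patients | backend: mock | k = 1
#>   patient-level micro-F1: 1

glance(run$curve)
#>   k_best micro_precision micro_recall micro_specificity micro_f1 k_max
#> 1      1               1            1                 1        1     8

head(run$patient_metrics[, c("label_id", "tp", "fp", "fn", "tn", "precision", "recall", "f1")], 4)
#>      label_id tp fp fn tn precision recall f1
#> 1     colitis 11  0  0 29         1      1  1
#> 2   hepatitis 10  0  0 30         1      1  1
#> 3 pneumonitis 17  0  0 23         1      1  1
#> 4        rash 12  0  0 28         1      1  1
```

Forty simulated patients (221 notes) are classified by the rule-based
backend, aggregated with the swept threshold (`k_best = 1` here), and scored
against the generator's gold labels. The perfect scores are the designed
closed-loop property: the rule backend resolves exactly the assertion and
causation regimes the generator plants, so any pipeline defect — a parsing
bug, an off-by-one in thresholding, a miscounted confusion cell — shows up
as micro-F1 < 1. On real notes and a real model backend the same code
produces imperfect tables, a non-trivial threshold curve (`autoplot(run$curve)`),
and per-category roll-ups (`run$category_metrics`).

Every intermediate is persisted in `out_dir` (notes and predictions as
JSONL, threshold curve and metrics as CSV, plus a run manifest), so
aggregation and evaluation re-run from disk without re-invoking any backend.
A thin command-line wrapper with `simulate` / `run` / `prompt` / `evaluate`
subcommands ships in `inst/cli/irae.R`.

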