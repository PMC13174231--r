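#' Count irAE-positive notes per patient and label
#'
#' `count_positive_notes()` implements the single-patient contract (all rows
#' must share one `patient_id`; mixed ids are an error).
#' `positive_note_counts()` is the corpus-wide verb, grouping by patient. Both
#' also record each patient's total note count, which bounds the counts and
#' defaults the sweep range.
#'
#' @param preds Long prediction tibble (see [predictions_tbl()]): columns
#'   `note_id`, `patient_id`, `label_id`, `call`.
#' @return Tibble with columns `patient_id`, `label_id`, `n_pos` (notes called
#'   "Yes" for the label) and `n_notes` (the patient's note count).
#' @export
count_positive_notes <- function(preds) {
  stopifnot(all(c("note_id", "patient_id", "label_id", "call") %in% names(preds)))
  ids <- unique(preds$patient_id)
  if (length(ids) > 1) {
    abort(paste0("predictions span multiple patients: ", paste(ids, collapse = ", ")))
  }
  positive_note_counts(preds)
}

#' @rdname count_positive_notes
#' @export
positive_note_counts <- function(preds) {
  stopifnot(all(c("note_id", "patient_id", "label_id", "call") %in% names(preds)))
  preds %>%
    group_by(patient_id, label_id) %>%
    summarise(
      n_pos = sum(call),
      n_notes = dplyr::n_distinct(note_id),
      .groups = "drop"
    )
}

#' Threshold note counts into patient-level calls
#'
#' A patient is called positive for a label when at least `k` of their notes
#' carry a positive call for it. With `k = 1` this is the logical OR over
#' notes — the aggregation rule appropriate for small per-patient note counts.
#' Larger `k` trades recall for precision, countering the positive-call bias
#' of generative backends on note-rich corpora.
#'
#' @param counts Count table from [positive_note_counts()].
#' @param k Decision threshold, integer >= 1.
#' @return Tibble with `patient_id`, `label_id`, `n_pos`, `call` (logical:
#'   `n_pos >= k`), carrying attribute `k`.
#' @examples
#' counts <- tibble::tibble(
#'   patient_id = "p1", label_id = "rash", n_pos = 3, n_notes = 5
#' )
#' apply_threshold(counts, k = 3)$call  # TRUE
#' apply_threshold(counts, k = 4)$call  # FALSE
#' @export
apply_threshold <- function(counts, k = 1) {
  stopifnot(all(c("patient_id", "label_id", "n_pos") %in% names(counts)))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    abort("decision threshold k must be a single integer >= 1")
  }
  out <- counts %>% mutate(call = n_pos >= k)
  attr(out, "k") <- as.integer(k)
  out
}

#' Sweep the decision threshold to maximise micro-averaged F1
#'
#' Re-thresholds every patient's counts at each `k = 1, ..., k_max`, scores
#' the resulting patient-level calls against gold, and reports the
#' micro-averaged precision, recall, specificity and F1 per `k`. The optimal
#' threshold `k_best` is the argmax of micro-F1; ties go to the smallest `k`
#' (favouring recall). Because the positive set at `k + 1` is nested in the
#' positive set at `k`, micro-recall is non-increasing and micro-specificity
#' non-decreasing in `k`.
#'
#' @param counts Count table from [positive_note_counts()] covering every
#'   patient to be scored.
#' @param gold Patient-level label-set table (see [label_sets()] /
#'   [read_gold_csv()]); must cover every patient in `counts`.
#' @param labels Character vector of label_ids to score.
#' @param k_max Largest threshold to evaluate. Defaults to the maximum
#'   per-patient note count in `counts` (beyond it the curve is constant).
#' @return A tibble of class `irae_threshold_curve`: columns `k`,
#'   `micro_precision`, `micro_recall`, `micro_specificity`, `micro_f1`;
#'   attributes `k_best` and `per_label` (per-k per-label confusion counts,
#'   for audit).
#' @export
sweep_threshold <- function(counts, gold, labels, k_max = NULL) {
  stopifnot(all(c("patient_id", "label_id", "n_pos") %in% names(counts)))
  gold <- as_label_set_tbl(gold)
  if (nrow(gold) == 0) abort("no patients to sweep")
  if (is.null(k_max)) {
    if (!"n_notes" %in% names(counts)) {
      abort("k_max not given and counts carry no n_notes column")
    }
    k_max <- max(counts$n_notes)
  }
  stopifnot(k_max >= 1)

  rows <- vector("list", k_max)
  audit <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    calls <- apply_threshold(counts, k)
    pred_sets <- label_sets(calls, unit = "patient_id")
    # patients with no rows in counts (e.g. zero notes) predict 'None'
    missing <- setdiff(gold$unit_id, pred_sets$unit_id)
    if (length(missing)) {
      pred_sets <- bind_rows(
        pred_sets,
        tibble(unit_id = missing, labels = rep(list(character()), length(missing)))
      )
    }
    cc <- confusion_counts(pred_sets, gold, labels)
    pooled <- summarise(cc, tp = sum(tp), fp = sum(fp), fn = sum(fn), tn = sum(tn))
    rows[[k]] <- tibble(
      k = k,
      micro_precision = safe_ratio(pooled$tp, pooled$tp + pooled$fp),
      micro_recall = safe_ratio(pooled$tp, pooled$tp + pooled$fn),
      micro_specificity = safe_ratio(pooled$tn, pooled$tn + pooled$fp),
      micro_f1 = f1_from_counts(pooled$tp, pooled$fp, pooled$fn)
    )
    audit[[k]] <- mutate(cc, k = k)
  }
  curve <- bind_rows(rows)
  f1s <- ifelse(is.na(curve$micro_f1), -Inf, curve$micro_f1)
  k_best <- curve$k[which.max(f1s)]  # which.max returns the first (smallest k) on ties
  structure(
    curve,
    k_best = as.integer(k_best),
    per_label = bind_rows(audit),
    class = c("irae_threshold_curve", class(tibble()))
  )
}

#' @export
print.irae_threshold_curve <- function(x, ...) {
  cat("<irae_threshold_curve> k = 1..", max(x$k), ", k_best = ",
      attr(x, "k_best"), " (micro-F1 = ",
      format(x$micro_f1[x$k == attr(x, "k_best")], digits = 4), ")\n", sep = "")
  NextMethod()
}

#' Write a threshold curve as CSV
#'
#' @param curve An `irae_threshold_curve`.
#' @param path Output CSV path.
#' @export
write_threshold_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, na = "NA")
  invisible(path)
}
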