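#' Label-set tables
#'
#' Multi-label gold annotations and predictions are represented as label-set
#' tables: one row per evaluation unit (note or patient) with a list-column
#' `labels` of label_ids; an empty vector is the 'None' annotation.
#' `label_sets()` builds one from a long binary call table (e.g. the output of
#' [apply_threshold()] or [predictions_tbl()]).
#'
#' @param calls Long tibble with a logical `call` column, a `label_id` column
#'   and the unit id column named by `unit`.
#' @param unit Name of the unit id column (`"patient_id"` or `"note_id"`).
#' @return Tibble with columns `unit_id` and `labels` (list of character).
#' @export
label_sets <- function(calls, unit = "patient_id") {
  stopifnot(unit %in% names(calls), all(c("label_id", "call") %in% names(calls)))
  calls %>%
    group_by(unit_id = .data[[unit]]) %>%
    summarise(labels = list(sort(label_id[call])), .groups = "drop")
}

as_label_set_tbl <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot(all(c("unit_id", "labels") %in% names(x)))
    return(as_tibble(x))
  }
  # named list: unit_id -> character vector of labels
  tibble(unit_id = names(x), labels = map(unname(x), as.character))
}

#' Per-label confusion counts over evaluation units
#'
#' Each unit (note or patient) contributes one cell to every label's 2x2
#' table: TP when the label is in both prediction and gold, FP when predicted
#' only, FN when gold only, TN otherwise. A unit with empty gold ('None')
#' therefore contributes a TN or FP for every label. Prediction and gold must
#' cover identical unit ids.
#'
#' @param pred,gold Label-set tables (see [label_sets()]) or named lists
#'   mapping unit id to a character vector of labels.
#' @param labels Character vector of label_ids to score (the profile's label
#'   list, or category names for category-level scoring).
#' @return Tibble of class `irae_confusion`: `label_id`, `tp`, `fp`, `fn`,
#'   `tn`. For every label `tp + fp + fn + tn` equals the number of units.
#' @export
confusion_counts <- function(pred, gold, labels) {
  pred <- as_label_set_tbl(pred)
  gold <- as_label_set_tbl(gold)
  labels <- as.character(labels)
  stopifnot(length(labels) > 0)
  if (!setequal(pred$unit_id, gold$unit_id) ||
      nrow(pred) != nrow(gold) ||
      anyDuplicated(pred$unit_id) || anyDuplicated(gold$unit_id)) {
    abort("pred and gold must cover identical unit ids (one row each)")
  }
  gold <- gold[match(pred$unit_id, gold$unit_id), ]

  # labels x units membership matrices
  pm <- vapply(pred$labels, function(s) labels %in% s, logical(length(labels)))
  gm <- vapply(gold$labels, function(s) labels %in% s, logical(length(labels)))
  pm <- matrix(pm, nrow = length(labels))
  gm <- matrix(gm, nrow = length(labels))
  counts <- tibble(
    label_id = labels,
    tp = as.integer(rowSums(pm & gm)),
    fp = as.integer(rowSums(pm & !gm)),
    fn = as.integer(rowSums(!pm & gm)),
    tn = as.integer(rowSums(!pm & !gm))
  )
  structure(counts, class = c("irae_confusion", class(tibble())))
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

f1_from_counts <- function(tp, fp, fn) {
  dplyr::case_when(
    tp == 0 & fp == 0 & fn == 0 ~ NA_real_,
    tp == 0 ~ 0,
    TRUE ~ 2 * tp / (2 * tp + fp + fn)
  )
}

#' Per-label and averaged multi-label metrics
#'
#' Computes precision (PPV), recall (sensitivity), specificity and F1 per
#' label, plus a micro-average row (metrics of the pooled 2x2 table summed
#' over labels) and a macro-average row (unweighted mean over labels,
#' excluding NA entries per metric).
#'
#' NA conventions: a ratio is NA exactly when its denominator is 0 (e.g.
#' precision with no predicted positives, recall with no gold positives).
#' F1 is NA when TP = FP = FN = 0 (the label never occurs on either side) and
#' 0 when TP = 0 but errors exist. Micro-F1 is the harmonic mean of micro-P
#' and micro-R.
#'
#' @param counts An `irae_confusion` table from [confusion_counts()].
#' @return Tibble of class `irae_metrics`: one row per label plus
#'   `"micro avg"` and `"macro avg"` rows, columns `label_id`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `specificity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("label_id", "tp", "fp", "fn", "tn") %in% names(counts)))
  per_label <- counts %>%
    mutate(
      precision = safe_ratio(tp, tp + fp),
      recall = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      f1 = f1_from_counts(tp, fp, fn)
    )
  pooled <- counts %>%
    summarise(tp = sum(tp), fp = sum(fp), fn = sum(fn), tn = sum(tn))
  micro <- pooled %>%
    mutate(
      label_id = "micro avg",
      precision = safe_ratio(tp, tp + fp),
      recall = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      f1 = f1_from_counts(tp, fp, fn)
    )
  macro <- tibble(
    label_id = "macro avg",
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_integer_,
    precision = mean(per_label$precision, na.rm = TRUE),
    recall = mean(per_label$recall, na.rm = TRUE),
    specificity = mean(per_label$specificity, na.rm = TRUE),
    f1 = mean(per_label$f1, na.rm = TRUE)
  ) %>%
    mutate(across(c(precision, recall, specificity, f1), ~ ifelse(is.nan(.x), NA_real_, .x)))
  out <- bind_rows(per_label, micro, macro)
  structure(out, class = c("irae_metrics", class(tibble())))
}

#' Score predictions against gold label sets
#'
#' Convenience wrapper: [confusion_counts()] then [compute_metrics()].
#'
#' @inheritParams confusion_counts
#' @return An `irae_metrics` table.
#' @export
evaluate_label_sets <- function(pred, gold, labels) {
  compute_metrics(confusion_counts(pred, gold, labels))
}

#' Organ-category-level evaluation
#'
#' Projects both predictions and gold through the profile's irAE-to-category
#' mapping ([map_to_categories()]), then scores the projected sets exactly as
#' at label level. Because a category is positive when any member irAE is,
#' within-category confusions (e.g. predicting colitis where gold says
#' hepatitis, both gastrointestinal) become category-level agreements.
#'
#' @inheritParams confusion_counts
#' @param profile A [site_profile()] supplying the category map.
#' @return An `irae_metrics` table whose `label_id` column holds category
#'   names (only categories used by the profile appear).
#' @export
evaluate_at_category_level <- function(pred, gold, profile) {
  stopifnot(inherits(profile, "irae_profile"))
  pred <- as_label_set_tbl(pred)
  gold <- as_label_set_tbl(gold)
  pred$labels <- map(pred$labels, map_to_categories, profile = profile)
  gold$labels <- map(gold$labels, map_to_categories, profile = profile)
  cats <- sort(unique(unname(profile$category_map)))
  evaluate_label_sets(pred, gold, cats)
}

#' Write a metrics table as CSV
#'
#' One row per label plus `"micro avg"` and `"macro avg"` rows; columns
#' label, P, R, S, F1 (and the underlying counts).
#'
#' @param metrics An `irae_metrics` table.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(as.data.frame(metrics), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write gold label-set CSVs
#'
#' Format: two columns, the unit id (`patient_id` or `note_id`) and `labels`,
#' the semicolon-joined label_ids (empty string for 'None').
#'
#' @param x Label-set table (`unit_id`, `labels` list-column).
#' @param path CSV path.
#' @param unit Column name to use for the unit id on disk.
#' @export
write_gold_csv <- function(x, path, unit = "patient_id") {
  x <- as_label_set_tbl(x)
  df <- data.frame(
    unit = x$unit_id,
    labels = map_chr(x$labels, paste, collapse = ";")
  )
  names(df)[1] <- unit
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold_csv
#' @export
read_gold_csv <- function(path, unit = "patient_id") {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(unit %in% names(df), "labels" %in% names(df))
  tibble(
    unit_id = df[[unit]],
    labels = map(df$labels, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  )
}
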