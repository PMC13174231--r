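make_preds <- function(patient_id, notes_yes) {
  # notes_yes: list note_id -> character vector of labels called Yes
  dplyr::bind_rows(lapply(names(notes_yes), function(nid) {
    tibble::tibble(
      note_id = nid, patient_id = patient_id,
      label_id = c("colitis", "rash"),
      call = c("colitis", "rash") %in% notes_yes[[nid]],
      parse_status = "clean"
    )
  }))
}

test_that("positive-note counts are exact and bounded by the note count", {
  preds <- make_preds("p1", list(n1 = "colitis", n2 = c("colitis", "rash"), n3 = character()))
  counts <- count_positive_notes(preds)
  expect_identical(counts$n_pos[counts$label_id == "colitis"], 2L)
  expect_identical(counts$n_pos[counts$label_id == "rash"], 1L)
  expect_true(all(counts$n_pos <= counts$n_notes))

  # mixed patient ids are rejected by the single-patient contract
  mixed <- dplyr::bind_rows(preds, make_preds("p2", list(n9 = "rash")))
  expect_error(count_positive_notes(mixed), "multiple patients")
  # but the corpus-wide verb groups them
  expect_identical(nrow(positive_note_counts(mixed)), 4L)

  # zero notes: empty counts
  empty <- preds[0, ]
  expect_identical(nrow(positive_note_counts(empty)), 0L)
})

test_that("thresholding implements n_pos >= k with OR semantics at k = 1", {
  counts <- tibble::tibble(
    patient_id = "p1", label_id = c("colitis", "rash"),
    n_pos = c(1L, 3L), n_notes = 3L
  )
  expect_true(apply_threshold(counts, 1)$call[1])  # single positive note suffices
  expect_true(apply_threshold(counts, 3)$call[2])  # boundary: k = n_pos
  expect_false(apply_threshold(counts, 4)$call[2]) # boundary: k = n_pos + 1
  # k beyond the patient's note count: nothing can be positive
  expect_true(all(!apply_threshold(counts, 10)$call))
  expect_error(apply_threshold(counts, 0), "k must be")
  expect_error(apply_threshold(counts, 1.5), "k must be")
})

test_that("k = 1 thresholding equals the per-label logical OR over notes", {
  set.seed(31)
  labels <- c("a", "b", "c")
  counts <- random_count_tbl(40, labels)
  or_calls <- counts$n_pos > 0
  expect_identical(apply_threshold(counts, 1)$call, or_calls)
})

test_that("sweep recovers the brute-force curve, its optimum, and the tie rule", {
  set.seed(52)
  labels <- c("colitis", "rash", "fever")
  counts <- random_count_tbl(30, labels, max_notes = 6)
  gold <- random_label_sets(30, labels, p = 0.3, prefix = "p")
  names(gold) <- sprintf("p%03d", 1:30)
  curve <- sweep_threshold(counts, as_set_tbl(gold), labels, k_max = 6)
  brute <- oracle_sweep(as.data.frame(counts), gold, labels, k_max = 6)
  expect_equal(curve$micro_f1, brute$curve$micro_f1, tolerance = 1e-12)
  expect_equal(curve$micro_precision, brute$curve$micro_p, tolerance = 1e-12)
  expect_equal(curve$micro_recall, brute$curve$micro_r, tolerance = 1e-12)
  expect_identical(attr(curve, "k_best"), as.integer(brute$k_best))

  # nesting: positive patient sets shrink as k grows; recall/specificity monotone
  for (k in 1:5) {
    pos_k <- apply_threshold(counts, k)$call
    pos_k1 <- apply_threshold(counts, k + 1)$call
    expect_true(all(pos_k[pos_k1]))  # positives at k+1 are positives at k
  }
  expect_true(all(diff(curve$micro_recall) <= 1e-12))
  expect_true(all(diff(curve$micro_specificity) >= -1e-12))

  # explicit tie: thresholds 1 and 2 give identical calls => smallest k wins
  tie_counts <- tibble::tibble(
    patient_id = c("p1", "p2"), label_id = "colitis",
    n_pos = c(2L, 0L), n_notes = 3L
  )
  tie_gold <- as_set_tbl(list(p1 = "colitis", p2 = character()))
  tie_curve <- sweep_threshold(tie_counts, tie_gold, "colitis", k_max = 2)
  expect_equal(tie_curve$micro_f1[1], tie_curve$micro_f1[2])
  expect_identical(attr(tie_curve, "k_best"), 1L)

  expect_error(
    sweep_threshold(counts, tibble::tibble(unit_id = character(), labels = list()), labels),
    "no patients"
  )
})

test_that("note-level oracle predictions give k_best = 1 with micro-F1 = 1", {
  # predictions identical to gold at note level; every gold label in >= 1 note
  labels <- c("colitis", "rash")
  counts <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2"),
    label_id = rep(labels, 2),
    n_pos = c(2L, 0L, 1L, 1L),
    n_notes = c(3L, 3L, 2L, 2L)
  )
  gold <- as_set_tbl(list(p1 = "colitis", p2 = c("colitis", "rash")))
  curve <- sweep_threshold(counts, gold, labels)
  expect_identical(attr(curve, "k_best"), 1L)
  expect_identical(curve$micro_f1[1], 1)
  # sweep followed by apply at k_best reproduces the curve's micro-F1 exactly
  calls <- apply_threshold(counts, attr(curve, "k_best"))
  m <- evaluate_label_sets(label_sets(calls, "patient_id"), gold, labels)
  expect_identical(m$f1[m$label_id == "micro avg"], curve$micro_f1[1])
})
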