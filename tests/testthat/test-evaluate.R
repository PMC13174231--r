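test_that("confusion counts match exhaustive enumeration and conserve totals", {
  labels <- c("colitis", "rash")
  pred <- list(u1 = "colitis", u2 = c("colitis", "rash"), u3 = character(), u4 = "rash")
  gold <- list(u1 = "colitis", u2 = "colitis", u3 = "rash", u4 = character())
  cc <- confusion_counts(pred, gold, labels)
  brute <- oracle_confusion(pred, gold, labels)
  expect_identical(as.data.frame(cc), brute)
  # every unit lands in exactly one cell per label
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 4L))
  # conservation: TP+FN = gold positives, TP+FP = predicted positives
  for (l in labels) {
    row <- cc[cc$label_id == l, ]
    expect_identical(row$tp + row$fn, sum(vapply(gold, function(s) l %in% s, TRUE)))
    expect_identical(row$tp + row$fp, sum(vapply(pred, function(s) l %in% s, TRUE)))
  }

  # a 'None' gold unit contributes FP for the predicted label, TN elsewhere
  cc2 <- confusion_counts(list(u1 = "colitis"), list(u1 = character()), labels)
  expect_identical(cc2$fp[cc2$label_id == "colitis"], 1L)
  expect_identical(cc2$tn[cc2$label_id == "rash"], 1L)

  # perfect agreement: no errors anywhere
  cc3 <- confusion_counts(pred, pred, labels)
  expect_true(all(cc3$fp == 0L) && all(cc3$fn == 0L))

  expect_error(
    confusion_counts(list(u1 = "colitis"), list(u2 = "colitis"), labels),
    "identical unit ids"
  )
})

test_that("metrics follow the stated formulas and NA conventions", {
  counts <- tibble::tibble(label_id = "x", tp = 1L, fp = 1L, fn = 1L, tn = 1L)
  m <- compute_metrics(counts)
  row <- m[m$label_id == "x", ]
  expect_equal(row$precision, 0.5)
  expect_equal(row$recall, 0.5)
  expect_equal(row$specificity, 0.5)
  expect_equal(row$f1, 0.5)

  # label never predicted nor gold: P, R, F1 undefined; S defined
  degen <- compute_metrics(tibble::tibble(label_id = "x", tp = 0L, fp = 0L, fn = 0L, tn = 5L))
  expect_true(is.na(degen$precision[1]) && is.na(degen$recall[1]) && is.na(degen$f1[1]))
  expect_identical(degen$specificity[1], 1)

  # TP = 0 with errors present: F1 = 0, not NA
  z <- compute_metrics(tibble::tibble(label_id = "x", tp = 0L, fp = 2L, fn = 1L, tn = 3L))
  expect_identical(z$f1[1], 0)
})

test_that("per-label, micro and macro rows agree with the brute-force oracle", {
  set.seed(91)
  for (rep in 1:30) {
    n_lab <- sample(2:6, 1)
    counts <- tibble::tibble(
      label_id = paste0("l", seq_len(n_lab)),
      tp = sample(0:10, n_lab, TRUE), fp = sample(0:10, n_lab, TRUE),
      fn = sample(0:10, n_lab, TRUE), tn = sample(0:10, n_lab, TRUE)
    )
    m <- compute_metrics(counts)
    o <- oracle_metrics(as.data.frame(counts))
    per <- m[!m$label_id %in% c("micro avg", "macro avg"), ]
    expect_equal(per$precision, unname(o$per_label[, "precision"]), tolerance = 1e-14)
    expect_equal(per$f1, unname(o$per_label[, "f1"]), tolerance = 1e-14)
    micro <- m[m$label_id == "micro avg", ]
    expect_equal(micro$f1, unname(o$micro[["f1"]]), tolerance = 1e-14)
    # micro-F1 is the harmonic mean of micro-P and micro-R when both defined
    if (!is.na(micro$precision) && !is.na(micro$recall) && micro$precision + micro$recall > 0) {
      expect_equal(
        micro$f1,
        2 * micro$precision * micro$recall / (micro$precision + micro$recall),
        tolerance = 1e-12
      )
    }
    macro <- m[m$label_id == "macro avg", ]
    expect_equal(macro$precision, unname(o$macro[["precision"]]), tolerance = 1e-14)
    expect_equal(macro$f1, unname(o$macro[["f1"]]), tolerance = 1e-14)
  }
})

test_that("category projection turns within-category confusions into agreements", {
  p <- tiny_profile()
  # pred colitis vs gold hepatitis: label-level FP+FN, category-level TP
  pred <- list(u1 = "colitis")
  gold <- list(u1 = "hepatitis")
  lab <- evaluate_label_sets(pred, gold, profile_labels(p))
  expect_identical(lab$fp[lab$label_id == "colitis"], 1L)
  expect_identical(lab$fn[lab$label_id == "hepatitis"], 1L)
  cat <- evaluate_at_category_level(pred, gold, p)
  expect_identical(cat$tp[cat$label_id == "Gastrointestinal"], 1L)
  expect_identical(cat$f1[cat$label_id == "micro avg"], 1)

  # identical pred/gold projects to F1 = 1 for every populated category
  sets <- list(u1 = c("colitis", "rash"), u2 = "pneumonitis", u3 = character())
  same <- evaluate_at_category_level(sets, sets, p)
  populated <- same[!is.na(same$f1) & !same$label_id %in% c("micro avg", "macro avg"), ]
  expect_true(all(populated$f1 == 1))

  # all-within-category errors: category micro-F1 1, label micro-F1 < 1
  pred2 <- list(u1 = "colitis", u2 = "hepatitis", u3 = "colitis")
  gold2 <- list(u1 = "hepatitis", u2 = "colitis", u3 = "colitis")
  lab2 <- evaluate_label_sets(pred2, gold2, profile_labels(p))
  cat2 <- evaluate_at_category_level(pred2, gold2, p)
  expect_lt(lab2$f1[lab2$label_id == "micro avg"], 1)
  expect_identical(cat2$f1[cat2$label_id == "micro avg"], 1)
})

test_that("metrics tables export tidy/glance views and CSV", {
  p <- tiny_profile()
  sets <- list(u1 = "colitis", u2 = character())
  m <- evaluate_label_sets(sets, sets, profile_labels(p))
  g <- glance(m)
  expect_identical(g$micro_f1, 1)
  td <- tidy(m)
  expect_identical(sort(unique(td$metric)), sort(c("precision", "recall", "specificity", "f1")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(m, path)
  back <- read.csv(path)
  expect_true(all(c("micro avg", "macro avg") %in% back$label_id))
})
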