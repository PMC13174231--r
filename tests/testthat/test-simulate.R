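test_that("generation is deterministic and validates its config", {
  p <- tiny_profile()
  cfg <- sim_config(n_patients = 10, seed = 9)
  a <- generate_corpus(cfg, p)
  b <- generate_corpus(cfg, p)
  expect_identical(a$notes$text, b$notes$text)
  expect_identical(a$gold_patient, b$gold_patient)
  expect_identical(a$exposures, b$exposures)

  expect_error(sim_config(mixture = c(positive_causal = 0.5, negated = 0.2,
                                      hypothetical = 0.2, alt_cause = 0.2)),
               "sum to 1")
  expect_error(sim_config(prevalence = 1.2))
  expect_error(
    generate_corpus(sim_config(notes_per_patient = c(0, 0), prevalence = 0.5), p),
    "zero notes"
  )
})

test_that("zero prevalence gives an all-'None' cohort with only confounders", {
  p <- tiny_profile()
  corpus <- generate_corpus(sim_config(n_patients = 15, prevalence = 0, seed = 3), p)
  expect_true(all(lengths(corpus$gold_patient$labels) == 0))
  expect_true(all(lengths(corpus$gold_notes$labels) == 0))
})

test_that("note-level ground truth is consistent with patient-level gold", {
  p <- tiny_profile()
  corpus <- generate_corpus(sim_config(n_patients = 40, seed = 21), p)
  note_union <- corpus$gold_notes %>%
    dplyr::left_join(corpus$notes[, c("note_id", "patient_id")],
                     by = c(unit_id = "note_id")) %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(labels = list(sort(unique(unlist(labels)))), .groups = "drop")
  for (i in seq_len(nrow(note_union))) {
    pid <- note_union$patient_id[i]
    expect_identical(
      note_union$labels[[i]],
      corpus$gold_patient$labels[[which(corpus$gold_patient$unit_id == pid)]]
    )
  }
})

test_that("empirical prevalence converges to the configured rate", {
  one <- site_profile(
    "mini",
    tibble::tibble(label_id = "colitis", display_name = "colitis", synset = list(character())),
    "nivolumab", c(colitis = "Gastrointestinal")
  )
  cfg <- sim_config(n_patients = 1000, notes_per_patient = c(1, 2),
                    prevalence = 0.3, distractor_rate = 0, seed = 8)
  corpus <- generate_corpus(cfg, one)
  phat <- mean(lengths(corpus$gold_patient$labels) > 0)
  # binomial 99.9% band around 0.3 at n = 1000
  expect_lt(abs(phat - 0.3), 3.3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("alternative-etiology confounders name a non-ICI agent and stay out of gold", {
  p <- tiny_profile()
  cfg <- sim_config(
    n_patients = 30, prevalence = 0.2, seed = 14,
    mixture = c(positive_causal = 0.2, negated = 0, hypothetical = 0, alt_cause = 0.8)
  )
  corpus <- generate_corpus(cfg, p)
  rules <- cue_rules()
  alt_markers <- paste(rules$alt_cause_markers, collapse = "|")
  gold_by_pid <- setNames(corpus$gold_patient$labels, corpus$gold_patient$unit_id)
  found_any <- FALSE
  for (i in seq_len(nrow(corpus$notes))) {
    sentences <- unlist(strsplit(corpus$notes$text[i], "(?<=[.!?])\\s+", perl = TRUE))
    alt <- grep(alt_markers, tolower(sentences), value = TRUE)
    for (s in alt) {
      found_any <- TRUE
      # names a non-ICI agent...
      expect_true(any(vapply(rules$non_ici_agents,
                             function(a) grepl(a, tolower(s), fixed = TRUE), TRUE)))
      # ...and its label is absent from that patient's gold
      pid <- corpus$notes$patient_id[i]
      mentioned <- profile_labels(p)[vapply(seq_len(nrow(p$labels)), function(j) {
        terms <- tolower(c(p$labels$display_name[j], p$labels$synset[[j]]))
        any(vapply(terms, function(t) grepl(paste0("\\b", t, "\\b"), tolower(s)), TRUE))
      }, TRUE)]
      expect_true(all(!mentioned %in% gold_by_pid[[pid]]))
    }
  }
  expect_true(found_any)
})

test_that("the exposure window filter applies inclusive calendar-month bounds", {
  exposures <- tibble::tibble(
    patient_id = "p1", drug = "nivolumab",
    first_date = as.Date("2018-03-10"), last_date = as.Date("2018-08-31")
  )
  notes <- tibble::tibble(
    note_id = c("on_first_day", "before_first", "exactly_6mo", "one_day_past", "seven_months"),
    patient_id = "p1",
    timestamp = as.Date(c("2018-03-10", "2018-03-09", "2019-02-28", "2019-03-01", "2019-04-01")),
    note_type = "progress",
    text = "x"
  )
  kept <- filter_notes_by_window(notes, exposures, months_after = 6)
  # 2018-08-31 + 6 calendar months clamps to 2019-02-28, inclusive
  expect_setequal(kept$note_id, c("on_first_day", "exactly_6mo"))

  expect_error(
    filter_notes_by_window(notes, exposures[0, ], months_after = 6),
    "no ICI exposure"
  )
  expect_identical(nrow(filter_notes_by_window(notes[0, ], exposures)), 0L)

  # default synthetic corpora are generated inside the window
  p <- tiny_profile()
  corpus <- generate_corpus(sim_config(n_patients = 10, seed = 2), p)
  expect_identical(
    nrow(filter_corpus_window(corpus, 6)$notes),
    nrow(corpus$notes)
  )
})

test_that("a corpus round-trips through its on-disk formats", {
  p <- tiny_profile()
  corpus <- generate_corpus(sim_config(n_patients = 6, seed = 4), p)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  notes <- read_corpus_notes(file.path(dir, "notes.jsonl"))
  expect_identical(as.data.frame(notes), as.data.frame(corpus$notes))
  gold <- read_gold_csv(file.path(dir, "gold_patients.csv"), "patient_id")
  expect_identical(gold$unit_id, corpus$gold_patient$unit_id)
  expect_identical(gold$labels, corpus$gold_patient$labels)
})
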