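#' Simulation configuration for the synthetic corpus generator
#'
#' Fixes the study conditions for a synthetic corpus: cohort size, per-patient
#' note counts, per-label prevalence, the mixture of assertion/causation
#' regimes used to realise mentions, synonym usage and distractor density.
#' Defaults describe a small EHR-style cohort with a handful of notes per
#' patient and moderately prevalent irAEs.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(min, max)`; each patient's note
#'   count is drawn uniformly from it.
#' @param prevalence Per-label probability that a patient truly experiences
#'   the irAE. A scalar applies to every label; a named vector sets individual
#'   labels.
#' @param mixture Named probabilities over the mention regimes
#'   `positive_causal`, `negated`, `hypothetical`, `alt_cause`; must sum to 1.
#'   Gold labels are always realised as positive-causal mentions; the
#'   complement `1 - mixture["positive_causal"]` sets the chance that a
#'   non-gold label receives a confounder mention (regime drawn from the
#'   renormalised confounder weights). Confounders never make a label gold.
#' @param synonym_prob Probability that a mention surfaces as a synset term
#'   rather than the display name (labels with empty synsets always use the
#'   display name).
#' @param extra_positive_rate Per-note probability that a gold label's
#'   positive-causal mention is repeated in additional notes (beyond the one
#'   guaranteed note), giving per-label positive-note counts > 1 so threshold
#'   sweeps have structure.
#' @param distractor_rate Mean number of distractor sentences per note
#'   (Poisson).
#' @param seed Integer RNG seed; fixed seed gives a byte-identical corpus.
#' @return A list of class `irae_sim_config`.
#' @export
sim_config <- function(n_patients = 50,
                       notes_per_patient = c(3, 8),
                       prevalence = 0.25,
                       mixture = c(positive_causal = 0.7, negated = 0.12,
                                   hypothetical = 0.1, alt_cause = 0.08),
                       synonym_prob = 0.3,
                       extra_positive_rate = 0.25,
                       distractor_rate = 2,
                       seed = 1L) {
  if (length(notes_per_patient) == 1) notes_per_patient <- rep(notes_per_patient, 2)
  regimes <- c("positive_causal", "negated", "hypothetical", "alt_cause")
  stopifnot(
    n_patients >= 1,
    length(notes_per_patient) == 2,
    notes_per_patient[1] >= 0, notes_per_patient[2] >= notes_per_patient[1],
    all(prevalence >= 0), all(prevalence <= 1),
    setequal(names(mixture), regimes),
    all(mixture >= 0),
    synonym_prob >= 0, synonym_prob <= 1,
    extra_positive_rate >= 0, extra_positive_rate <= 1,
    distractor_rate >= 0
  )
  if (abs(sum(mixture) - 1) > 1e-8) abort("mixture probabilities must sum to 1")
  structure(
    list(
      n_patients = as.integer(n_patients),
      notes_per_patient = as.integer(notes_per_patient),
      prevalence = prevalence,
      mixture = mixture[regimes],
      synonym_prob = synonym_prob,
      extra_positive_rate = extra_positive_rate,
      distractor_rate = distractor_rate,
      seed = as.integer(seed)
    ),
    class = "irae_sim_config"
  )
}

load_sentence_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sentence_templates.yaml", package = "iraekit")
  tpl <- yaml::read_yaml(path)
  needed <- c("positive_causal", "negated", "hypothetical", "alt_cause",
              "alt_cause_agents", "distractor")
  missing <- setdiff(needed, names(tpl))
  if (length(missing)) abort(paste0("template file missing sections: ", paste(missing, collapse = ", ")))
  tpl
}

fill_template <- function(template, term, ici = "", agent = "") {
  out <- gsub("{term}", term, template, fixed = TRUE)
  out <- gsub("{ici}", ici, out, fixed = TRUE)
  gsub("{agent}", agent, out, fixed = TRUE)
}

#' Generate a synthetic patient corpus with known ground truth
#'
#' Emulates the structure of an ICI-treated cohort's note corpus: each patient
#' gets an ICI exposure interval, a set of dated notes, and a gold irAE label
#' set drawn per-label Bernoulli(prevalence). Every gold label is realised as
#' at least one positive-causal mention sentence in at least one note (more
#' under `extra_positive_rate`); non-gold labels may receive confounder
#' mentions (negated, hypothetical, or alternative-etiology with a named
#' non-ICI agent) per the regime mixture — confounders never make a label
#' gold. Distractor sentences pad the notes. `gold_notes` records exactly the
#' notes carrying positive-causal mentions, so the union of a patient's note
#' labels equals the patient's gold set.
#'
#' Note timestamps are drawn inside the exposure window plus six months, so
#' the default corpus survives [filter_notes_by_window()] unchanged.
#' Generation is deterministic given `config$seed`.
#'
#' @param config An [sim_config()].
#' @param profile A [site_profile()].
#' @param templates Optional sentence-template list (see
#'   `inst/extdata/sentence_templates.yaml`).
#' @return A list of class `irae_corpus`: tibbles `notes` (`note_id`,
#'   `patient_id`, `timestamp`, `note_type`, `text`), `exposures`
#'   (`patient_id`, `drug`, `first_date`, `last_date`), `gold_patient` and
#'   `gold_notes` (label-set tables), plus `site_id` and the `config`.
#' @examples
#' p <- example_site_profile("ucsf")
#' corpus <- generate_corpus(sim_config(n_patients = 5, seed = 42), p)
#' corpus$notes$text[1]
#' @export
generate_corpus <- function(config, profile, templates = load_sentence_templates()) {
  stopifnot(inherits(config, "irae_sim_config"), inherits(profile, "irae_profile"))
  label_ids <- profile_labels(profile)
  prev <- config$prevalence
  if (is.null(names(prev))) {
    prev <- setNames(rep(prev[1], length(label_ids)), label_ids)
  } else {
    bad <- setdiff(names(prev), label_ids)
    if (length(bad)) abort(paste0("prevalence names not in profile: ", paste(bad, collapse = ", ")))
    full <- setNames(rep(0, length(label_ids)), label_ids)
    full[names(prev)] <- prev
    prev <- full
  }
  if (config$notes_per_patient[2] == 0 && any(prev > 0)) {
    abort("cannot realise nonzero prevalence with zero notes per patient")
  }
  p_conf <- 1 - config$mixture[["positive_causal"]]
  conf_weights <- config$mixture[c("negated", "hypothetical", "alt_cause")]
  if (sum(conf_weights) > 0) conf_weights <- conf_weights / sum(conf_weights)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  note_types <- c("progress", "consult", "discharge summary")
  notes_l <- list(); gold_p <- list(); gold_n <- list(); expo_l <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("p%04d", i)
    drug <- sample(profile$ici_drugs, 1)
    first_date <- as.Date("2018-01-01") + sample.int(365, 1) - 1
    last_date <- first_date + sample(30:180, 1)
    expo_l[[i]] <- tibble(patient_id = pid, drug = drug,
                          first_date = first_date, last_date = last_date)

    n_notes <- sample(config$notes_per_patient[1]:config$notes_per_patient[2], 1)
    gold <- label_ids[runif(length(label_ids)) < prev]
    gold_p[[i]] <- tibble(unit_id = pid, labels = list(gold))
    if (n_notes == 0) next

    window_end <- add_months_clamped(last_date, 6)
    ts <- sort(first_date + sample.int(as.integer(window_end - first_date) + 1, n_notes,
                                       replace = TRUE) - 1)
    note_ids <- sprintf("%s_n%03d", pid, seq_len(n_notes))
    sentences <- setNames(vector("list", n_notes), note_ids)
    note_gold <- setNames(vector("list", n_notes), note_ids)

    # gold labels: >=1 positive-causal mention, maybe repeated in other notes
    for (l in gold) {
      host <- sample.int(n_notes, 1)
      extra <- which(runif(n_notes) < config$extra_positive_rate)
      for (j in unique(c(host, extra))) {
        sentences[[j]] <- c(sentences[[j]], positive_sentence(l, profile, drug, config, templates))
        note_gold[[j]] <- union(note_gold[[j]], l)
      }
    }
    # confounders for non-gold labels only
    for (l in setdiff(label_ids, gold)) {
      if (p_conf > 0 && runif(1) < p_conf) {
        regime <- sample(names(conf_weights), 1, prob = conf_weights)
        j <- sample.int(n_notes, 1)
        sentences[[j]] <- c(sentences[[j]],
                            confounder_sentence(l, profile, regime, config, templates))
      }
    }
    # distractors
    for (j in seq_len(n_notes)) {
      n_d <- stats::rpois(1, config$distractor_rate)
      if (n_d > 0) {
        sentences[[j]] <- c(sentences[[j]],
                            sample(unlist(templates$distractor), n_d, replace = TRUE))
      }
      if (length(sentences[[j]]) > 1) sentences[[j]] <- sample(sentences[[j]])
    }

    notes_l[[i]] <- tibble(
      note_id = note_ids,
      patient_id = pid,
      timestamp = ts,
      note_type = sample(note_types, n_notes, replace = TRUE),
      text = map_chr(sentences, paste, collapse = " ")
    )
    gold_n[[i]] <- tibble(
      unit_id = note_ids,
      labels = map(note_gold, function(x) sort(x %||% character()))
    )
  }

  structure(
    list(
      notes = bind_rows(notes_l),
      exposures = bind_rows(expo_l),
      gold_patient = bind_rows(gold_p) %>% mutate(labels = map(labels, sort)),
      gold_notes = bind_rows(gold_n),
      site_id = profile$site_id,
      config = config
    ),
    class = "irae_corpus"
  )
}

mention_term <- function(label_id, profile, config) {
  row <- which(profile$labels$label_id == label_id)
  syn <- profile$labels$synset[[row]]
  if (length(syn) && runif(1) < config$synonym_prob) sample(syn, 1)
  else profile$labels$display_name[[row]]
}

positive_sentence <- function(label_id, profile, drug, config, templates) {
  fill_template(
    sample(unlist(templates$positive_causal), 1),
    term = mention_term(label_id, profile, config), ici = drug
  )
}

confounder_sentence <- function(label_id, profile, regime, config, templates) {
  agent <- if (regime == "alt_cause") sample(unlist(templates$alt_cause_agents), 1) else ""
  fill_template(
    sample(unlist(templates[[regime]]), 1),
    term = mention_term(label_id, profile, config), agent = agent
  )
}

#' @export
print.irae_corpus <- function(x, ...) {
  cat("<irae_corpus> site:", x$site_id, "|", nrow(x$gold_patient), "patients |",
      nrow(x$notes), "notes\n")
  invisible(x)
}

# Calendar-month arithmetic with end-of-month clamping: 2018-08-31 + 6 months
# is 2019-02-28, not an overflow into March.
add_months_clamped <- function(date, months) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12 + lt$mon + months
  y <- m0 %/% 12 + 1900; m <- m0 %% 12 + 1
  nxt <- m0 + 1
  first_of_next <- as.Date(sprintf("%04d-%02d-01", nxt %/% 12 + 1900, nxt %% 12 + 1))
  last_dom <- as.integer(format(first_of_next - 1, "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y, m, min(lt$mday, last_dom)))
}

#' Select notes inside the ICI exposure window
#'
#' Keeps notes timestamped between the patient's first date of ICI exposure
#' and `months_after` calendar months after the last date of ICI
#' administration, both bounds inclusive. Month arithmetic clamps to the end
#' of short months. Patients without any exposure record are an error.
#'
#' @param notes Notes tibble (`note_id`, `patient_id`, `timestamp`, ...).
#' @param exposures Exposure tibble (`patient_id`, `drug`, `first_date`,
#'   `last_date`); multiple rows per patient are combined (earliest first
#'   date, latest last date).
#' @param months_after Window extent after the last administration, in
#'   calendar months (default 6).
#' @return The filtered notes tibble.
#' @export
filter_notes_by_window <- function(notes, exposures, months_after = 6) {
  stopifnot(all(c("patient_id", "timestamp") %in% names(notes)),
            all(c("patient_id", "first_date", "last_date") %in% names(exposures)))
  no_expo <- setdiff(unique(notes$patient_id), unique(exposures$patient_id))
  if (length(no_expo)) {
    abort(paste0("no ICI exposure recorded for patient(s): ", paste(no_expo, collapse = ", ")))
  }
  bounds <- exposures %>%
    group_by(patient_id) %>%
    summarise(first_date = min(first_date), last_date = max(last_date), .groups = "drop") %>%
    mutate(window_end = add_months_clamped_vec(last_date, months_after))
  notes %>%
    left_join(bounds, by = "patient_id") %>%
    filter(timestamp >= first_date, timestamp <= window_end) %>%
    select(-first_date, -last_date, -dplyr::any_of("window_end"))
}

add_months_clamped_vec <- function(dates, months) {
  as.Date(map_chr(as.list(dates), function(d) as.character(add_months_clamped(d, months))))
}

#' @rdname filter_notes_by_window
#' @param corpus An `irae_corpus`; its notes (and note-level gold) are
#'   filtered in place. Note-level gold rows for excluded notes are dropped,
#'   so after filtering the union of note labels may be a subset of
#'   `gold_patient`.
#' @export
filter_corpus_window <- function(corpus, months_after = 6) {
  stopifnot(inherits(corpus, "irae_corpus"))
  corpus$notes <- filter_notes_by_window(corpus$notes, corpus$exposures, months_after)
  corpus$gold_notes <- filter(corpus$gold_notes, unit_id %in% corpus$notes$note_id)
  corpus
}

#' Write / read a corpus in its on-disk formats
#'
#' Notes go to JSONL (one note object per line: `patient_id`, `note_id`,
#' `timestamp`, `note_type`, `text`); patient-level gold to
#' `gold_patients.csv` (`patient_id`, semicolon-joined labels, empty for
#' 'None'); note-level gold to `gold_notes.csv`; exposures to
#' `exposures.csv`.
#'
#' @param corpus An `irae_corpus`.
#' @param dir Output directory (created if needed).
#' @return `write_corpus()`: `dir` invisibly. `read_corpus_notes()`: the
#'   notes tibble from a JSONL file.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "irae_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- pmap(
    corpus$notes[, c("patient_id", "note_id", "timestamp", "note_type", "text")],
    function(patient_id, note_id, timestamp, note_type, text) {
      jsonlite::toJSON(list(
        patient_id = patient_id, note_id = note_id,
        timestamp = as.character(timestamp), note_type = note_type, text = text
      ), auto_unbox = TRUE)
    }
  )
  writeLines(unlist(lines), file.path(dir, "notes.jsonl"))
  write_gold_csv(corpus$gold_patient, file.path(dir, "gold_patients.csv"), unit = "patient_id")
  write_gold_csv(corpus$gold_notes, file.path(dir, "gold_notes.csv"), unit = "note_id")
  write.csv(as.data.frame(corpus$exposures %>%
                            mutate(first_date = as.character(first_date),
                                   last_date = as.character(last_date))),
            file.path(dir, "exposures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_corpus
#' @param path Path to a notes JSONL file.
#' @export
read_corpus_notes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- map(lines[nzchar(lines)], function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble(
      note_id = o$note_id, patient_id = o$patient_id,
      timestamp = as.Date(o$timestamp), note_type = o$note_type %||% NA_character_,
      text = o$text %||% ""
    )
  })
  bind_rows(rows)
}
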