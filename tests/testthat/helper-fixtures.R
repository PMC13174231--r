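# In-code fixtures shared across test files.

tiny_profile <- function() {
  site_profile(
    site_id = "test",
    labels = tibble::tibble(
      label_id = c("colitis", "hepatitis", "pneumonitis", "rash", "neuropathy"),
      display_name = c("colitis", "hepatitis", "pneumonitis", "rash", "neuropathy"),
      synset = list(
        c("colitis", "diarrhoea"), character(), character(), c("dermatitis"),
        c("neurotox", "neurotoxicity")
      )
    ),
    ici_drugs = c("nivolumab", "pembrolizumab", "ipilimumab"),
    category_map = c(
      colitis = "Gastrointestinal", hepatitis = "Gastrointestinal",
      pneumonitis = "Pulmonary", rash = "Dermatologic",
      neuropathy = "Neurologic"
    )
  )
}

# Random label sets over `labels` for `n` units (possibly empty = 'None').
random_label_sets <- function(n, labels, p = 0.35, prefix = "u") {
  sets <- lapply(seq_len(n), function(i) labels[stats::runif(length(labels)) < p])
  names(sets) <- paste0(prefix, seq_len(n))
  sets
}

as_set_tbl <- function(sets) {
  tibble::tibble(unit_id = names(sets), labels = unname(sets))
}

# Random per-patient positive-note count table.
random_count_tbl <- function(n_patients, labels, max_notes = 8) {
  rows <- lapply(seq_len(n_patients), function(i) {
    nn <- sample.int(max_notes, 1)
    tibble::tibble(
      patient_id = sprintf("p%03d", i),
      label_id = labels,
      n_pos = sample(0:nn, length(labels), replace = TRUE),
      n_notes = nn
    )
  })
  dplyr::bind_rows(rows)
}
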