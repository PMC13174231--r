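#' Render the per-label binary query sentence
#'
#' Each irAE label becomes one binary query. Synset terms are injected in a
#' parenthetical so the model is explicitly told which alternative surface
#' forms count as the label; the parenthetical is omitted when the synset is
#' empty.
#'
#' @param display_name Human-readable label name.
#' @param synset Character vector of synonym/acronym surface forms (may be
#'   empty).
#' @return The query sentence, e.g. for neuropathy with synset
#'   `c("neurotox", "neurotoxicity")`:
#'   `"Output 'Yes' if the patient has experienced neuropathy (neurotox,
#'   neurotoxicity) because of exposure to one or more immune checkpoint
#'   inhibitors. Otherwise, output 'No'."`
#' @export
render_query <- function(display_name, synset = character()) {
  stopifnot(is.character(display_name), length(display_name) == 1, nzchar(display_name))
  synset <- as.character(synset)
  parenthetical <- if (length(synset)) paste0(" (", paste(synset, collapse = ", "), ")") else ""
  paste0(
    "Output 'Yes' if the patient has experienced ", display_name, parenthetical,
    " because of exposure to one or more immune checkpoint inhibitors.",
    " Otherwise, output 'No'."
  )
}

default_prompt_template <- function() {
  path <- system.file("templates", "prompt_template.txt", package = "iraekit")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

json_output_instruction <- function(label_ids) {
  paste0(
    "Return your answers as a single JSON object with exactly one field per ",
    "question, keyed by the identifiers ",
    paste0('"', label_ids, '"', collapse = ", "),
    ", in that order. Each field's value must be \"Yes\" or \"No\". ",
    "Output only the JSON object."
  )
}

#' Render the zero-shot prompt for one note
#'
#' Assembles the full prompt: a preamble naming the patient-note context and
#' the site's ICI drug list, one synset-augmented binary query per irAE label
#' (in profile order), the JSON output directive, and the note body. Rendering
#' is a pure function: identical `(note_text, profile, template)` give a
#' byte-identical prompt.
#'
#' The note body is framed by explicit `<<<NOTE` / `NOTE>>>` delimiters in the
#' default template; the rule-based backend relies on these to recover the note
#' from the flattened prompt. The queries precede the note so instructions are
#' read before the evidence; the template file is the audit record of this
#' layout and can be overridden.
#'
#' @param note_text The clinical note body (non-empty).
#' @param profile A [site_profile()] with at least one label.
#' @param template Prompt template string with placeholders `{{ici_drugs}}`,
#'   `{{queries}}`, `{{output_instruction}}` and `{{note_text}}`. Defaults to
#'   the versioned template shipped in
#'   `system.file("templates/prompt_template.txt", package = "iraekit")`.
#' @param max_chars Character budget for the note body. Longer notes are
#'   truncated tail-first with a warning (mirrors bounded model context
#'   windows). Default 48000 characters.
#' @return An object of class `irae_prompt`: list with `text` (the flattened
#'   prompt), `label_ids`, `queries`, and `site_id`.
#' @examples
#' p <- example_site_profile("ucsf")
#' pr <- render_prompt("Colitis attributed to nivolumab.", p)
#' cat(substr(pr$text, 1, 200))
#' @export
render_prompt <- function(note_text, profile, template = default_prompt_template(),
                          max_chars = 48000) {
  stopifnot(inherits(profile, "irae_profile"))
  note_text <- as.character(note_text)
  if (length(note_text) != 1 || is.na(note_text) || !nzchar(note_text)) {
    abort("note text must be a non-empty string")
  }
  if (nchar(note_text) > max_chars) {
    warn(paste0("note truncated from ", nchar(note_text), " to ", max_chars, " characters"))
    note_text <- substr(note_text, 1, max_chars)
  }
  labels <- profile$labels
  queries <- map2(labels$display_name, labels$synset, render_query)
  queries <- unlist(queries)
  out_instr <- json_output_instruction(labels$label_id)
  text <- template
  text <- gsub("{{ici_drugs}}", paste(profile$ici_drugs, collapse = ", "), text, fixed = TRUE)
  text <- gsub("{{queries}}", paste(queries, collapse = "\n"), text, fixed = TRUE)
  text <- gsub("{{output_instruction}}", out_instr, text, fixed = TRUE)
  text <- gsub("{{note_text}}", note_text, text, fixed = TRUE)
  structure(
    list(
      text = text,
      label_ids = labels$label_id,
      queries = queries,
      site_id = profile$site_id
    ),
    class = "irae_prompt"
  )
}

#' @export
print.irae_prompt <- function(x, ...) {
  cat("<irae_prompt> site:", x$site_id, "|", length(x$label_ids), "queries |",
      nchar(x$text), "chars\n")
  invisible(x)
}

# Recover the note body from a flattened prompt via the template delimiters.
extract_note_from_prompt <- function(prompt_text) {
  m <- regmatches(
    prompt_text,
    regexpr("<<<NOTE\\n(.*?)\\nNOTE>>>", prompt_text, perl = TRUE)
  )
  if (length(m) == 0 || !nzchar(m)) return(NA_character_)
  sub("^<<<NOTE\\n", "", sub("\\nNOTE>>>$", "", m))
}
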