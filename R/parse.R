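#' Parse a backend's raw output into a note-level prediction
#'
#' Model output is requested as a single JSON object with one "Yes"/"No" field
#' per irAE label, but real output drifts: prose-wrapped JSON, missing or extra
#' keys, wrong-case or off-vocabulary values, outright refusals. This parser
#' never raises — every failure mode is encoded in `parse_status` so batch
#' runs never abort mid-corpus:
#'
#' * `clean` — the text is a single JSON object with exactly the expected keys
#'   and "Yes"/"No" values (case-insensitive).
#' * `repaired` — a JSON object was extracted from surrounding prose, missing
#'   keys were defaulted to "No", off-vocabulary values mapped to "No", or
#'   unexpected keys dropped.
#' * `failed` — no JSON object could be recovered (or transport failed);
#'   all calls default to "No" and a diagnostic is recorded.
#'
#' Missing keys default to "No" deliberately: generative models lean toward
#' over-predicting positives in this task, so defaults must not add positives.
#'
#' @param raw An `irae_raw_response` from [classify()], or a plain string.
#' @param expected_labels Character vector of label_ids the profile defines;
#'   the output call set always has exactly these keys, in this order.
#' @param note_id,patient_id Identifiers carried through to the prediction.
#' @return An object of class `irae_note_prediction`: list with `note_id`,
#'   `patient_id`, `calls` (named "Yes"/"No" vector over `expected_labels`),
#'   `parse_status`, `diagnostic`.
#' @examples
#' parse_response('{"colitis":"Yes","rash":"No"}', c("colitis", "rash"))$parse_status
#' parse_response("I cannot help with that.", c("colitis", "rash"))$parse_status
#' @export
parse_response <- function(raw, expected_labels, note_id = NA_character_,
                           patient_id = NA_character_) {
  expected_labels <- as.character(expected_labels)
  stopifnot(length(expected_labels) > 0)
  if (is.character(raw)) raw <- raw_response(raw, backend_id = "unknown")

  all_no <- setNames(rep("No", length(expected_labels)), expected_labels)
  failed <- function(why) {
    new_note_prediction(note_id, patient_id, all_no, "failed", why)
  }
  if (!isTRUE(raw$ok)) return(failed(raw$diagnostic %||% "transport failure"))
  text <- raw$text
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(failed("empty response text"))
  }

  parsed <- try_parse_json_object(text)
  repaired <- FALSE
  if (is.null(parsed)) {
    inner <- extract_json_object(text)
    if (!is.na(inner)) {
      parsed <- try_parse_json_object(inner)
      repaired <- TRUE
    }
  }
  if (is.null(parsed)) return(failed("no JSON object found in response"))

  keys <- names(parsed)
  extra <- setdiff(keys, expected_labels)
  missing <- setdiff(expected_labels, keys)
  if (length(extra)) {
    warn(paste0("dropping unexpected key(s) in response: ", paste(extra, collapse = ", ")))
    repaired <- TRUE
  }
  if (length(missing)) repaired <- TRUE

  calls <- all_no
  for (k in intersect(keys, expected_labels)) {
    v <- tolower(trimws(as.character(parsed[[k]] %||% "")))
    if (identical(v, "yes")) {
      calls[[k]] <- "Yes"
    } else if (!identical(v, "no")) {
      repaired <- TRUE  # off-vocabulary value (e.g. "unknown") maps to No
    }
  }
  new_note_prediction(
    note_id, patient_id, calls,
    if (repaired) "repaired" else "clean", NA_character_
  )
}

new_note_prediction <- function(note_id, patient_id, calls, parse_status, diagnostic) {
  structure(
    list(
      note_id = note_id, patient_id = patient_id, calls = calls,
      parse_status = parse_status, diagnostic = diagnostic
    ),
    class = "irae_note_prediction"
  )
}

try_parse_json_object <- function(text) {
  out <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.list(out) && !is.null(names(out)) && all(nzchar(names(out)))) out else NULL
}

# Substring between the outermost braces; NA when none present.
extract_json_object <- function(text) {
  first <- regexpr("{", text, fixed = TRUE)
  last <- max(gregexpr("}", text, fixed = TRUE)[[1]])
  if (first < 0 || last < 0 || last <= first) return(NA_character_)
  substr(text, first, last)
}

#' @export
print.irae_note_prediction <- function(x, ...) {
  cat("<irae_note_prediction>", x$note_id %||% "?", "|", x$parse_status, "|",
      sum(x$calls == "Yes"), "positive call(s)\n")
  invisible(x)
}

#' Convert note predictions to a long tibble
#'
#' The long (note x label) prediction table is the package's working currency:
#' one row per note per label with a logical `call`, chaining directly into
#' [count_positive_notes()] and the evaluation verbs.
#'
#' @param preds A single `irae_note_prediction` or a list of them.
#' @return Tibble with columns `note_id`, `patient_id`, `label_id`,
#'   `call` (logical), `parse_status`.
#' @export
predictions_tbl <- function(preds) {
  if (inherits(preds, "irae_note_prediction")) preds <- list(preds)
  bind_rows(map(preds, function(p) {
    tibble(
      note_id = as.character(p$note_id),
      patient_id = as.character(p$patient_id),
      label_id = names(p$calls),
      call = unname(p$calls == "Yes"),
      parse_status = p$parse_status
    )
  }))
}

#' Persist / reload note-level predictions as JSONL
#'
#' One JSON object per line (`note_id`, `patient_id`, `parse_status`, `calls`),
#' so aggregation and evaluation can re-run from disk without re-invoking any
#' backend.
#'
#' @param preds Long prediction tibble from [predictions_tbl()].
#' @param path Output file path.
#' @return `write_predictions()`: `path`, invisibly. `read_predictions()`: the
#'   long prediction tibble.
#' @export
write_predictions <- function(preds, path) {
  stopifnot(all(c("note_id", "patient_id", "label_id", "call", "parse_status") %in% names(preds)))
  by_note <- split(preds, preds$note_id)
  lines <- map_chr(by_note[unique(preds$note_id)], function(d) {
    jsonlite::toJSON(list(
      note_id = d$note_id[1],
      patient_id = d$patient_id[1],
      parse_status = d$parse_status[1],
      calls = as.list(setNames(ifelse(d$call, "Yes", "No"), d$label_id))
    ), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  preds <- map(lines[nzchar(lines)], function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    new_note_prediction(
      o$note_id, o$patient_id,
      setNames(as.character(unlist(o$calls)), names(o$calls)),
      o$parse_status, NA_character_
    )
  })
  predictions_tbl(preds)
}
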