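#' Assertion and causation cue rules
#'
#' The rule set driving the deterministic rule-based backend. A candidate irAE
#' mention only yields a positive call when it is positively asserted (no
#' negation or hypothetical cue shortly before it in the same sentence) and
#' causally compatible with ICI exposure (the nearest etiology marker in the
#' sentence, if any, does not point to a non-ICI agent). This mirrors the
#' assertion/causation failure modes that dominate errors in clinical-text
#' adverse-event extraction: negated mentions, hypothetical risk discussions,
#' and positively asserted events with an unrelated etiology.
#'
#' @param negation_cues Phrases marking a negated mention (must occur within
#'   `window` tokens before the mention).
#' @param hypothetical_cues Phrases marking hypothetical/uncertain mentions.
#' @param alt_cause_markers Etiology markers that typically introduce an
#'   alternative (non-ICI) cause; interpreted together with `non_ici_agents`.
#' @param causal_markers Etiology markers compatible with ICI causation;
#'   interpreted together with the profile's ICI drug list.
#' @param non_ici_agents Lexicon of non-ICI etiological agents (infections,
#'   cytotoxic chemotherapy, radiation, ...).
#' @param window Maximum token distance for a cue to govern a mention, and for
#'   an agent to be attributed to a marker. Default 10; must be >= 1.
#' @return An object of class `irae_cue_rules`.
#' @export
cue_rules <- function(
    negation_cues = c(
      "no evidence of", "no signs of", "no", "not", "without", "denies",
      "denied", "ruled out", "negative for", "resolved without", "free of"
    ),
    hypothetical_cues = c(
      "risk of", "risks of", "monitor for", "watch for", "concern for",
      "possible", "possibly", "may develop", "could develop", "potential for",
      "counselled about", "counseled about"
    ),
    alt_cause_markers = c("secondary to", "due to", "in the setting of"),
    causal_markers = c(
      "attributed to", "caused by", "related to", "immune-mediated",
      "immune mediated", "immune-related"
    ),
    non_ici_agents = c(
      "infection", "infectious", "sepsis", "chemotherapy", "carboplatin",
      "radiation", "radiotherapy", "clostridium difficile", "c diff", "cdiff",
      "viral", "virus", "bacterial", "alcohol", "nsaid", "nsaids",
      "antibiotic", "antibiotics", "statin", "opioid", "dehydration",
      "anesthesia"
    ),
    window = 10) {
  stopifnot(
    length(negation_cues) > 0, length(hypothetical_cues) > 0,
    length(alt_cause_markers) > 0, length(causal_markers) > 0,
    length(non_ici_agents) > 0,
    is.numeric(window), length(window) == 1, window >= 1
  )
  structure(
    list(
      negation_cues = as.character(negation_cues),
      hypothetical_cues = as.character(hypothetical_cues),
      alt_cause_markers = as.character(alt_cause_markers),
      causal_markers = as.character(causal_markers),
      non_ici_agents = as.character(non_ici_agents),
      window = as.integer(window)
    ),
    class = "irae_cue_rules"
  )
}

# --- tokenization ---------------------------------------------------------

# Sentence split: period/question/exclamation followed by whitespace. Clinical
# abbreviation false splits are accepted; segmentation fidelity is not this
# tool's subject.
split_sentences <- function(text) {
  s <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  s[nzchar(trimws(s))]
}

# Lowercase word tokens; multi-word phrases match as contiguous token runs.
tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9']+"))
  toks[nzchar(toks)]
}

# Start positions (1-based token index) where phrase tokens occur contiguously.
phrase_positions <- function(tokens, phrase_tokens) {
  np <- length(phrase_tokens)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(integer())
  starts <- which(tokens == phrase_tokens[1])
  if (np == 1) return(starts)
  keep(starts, function(i) {
    i + np - 1 <= nt && all(tokens[i:(i + np - 1)] == phrase_tokens)
  }) |> as.integer()
}

# --- the rule-based annotator ---------------------------------------------

#' Deterministic rule-based note annotation
#'
#' For each irAE label in the profile, scans the note sentence by sentence for
#' case-insensitive word-boundary matches of the label's display name or any
#' synset term. A match yields a positive call unless (a) a negation or
#' hypothetical cue occurs within `rules$window` tokens before it in the same
#' sentence, or (b) the nearest etiology marker in the sentence points to an
#' identified non-ICI agent rather than an ICI drug or an immune-mediation
#' marker. A label is "Yes" when at least one match in the note survives;
#' otherwise "No". An empty note yields all "No".
#'
#' The function is pure: identical `(note_text, profile, rules)` always give
#' identical output, and adding a synset term can only add matches (it never
#' flips a Yes to No).
#'
#' @param note_text Clinical note body (may be empty).
#' @param profile A [site_profile()].
#' @param rules A [cue_rules()] object.
#' @return Named character vector (`"Yes"`/`"No"`), one element per profile
#'   label, in profile order.
#' @examples
#' p <- example_site_profile("ucsf")
#' mock_annotate("Colitis attributed to nivolumab; steroids started.", p)[["colitis"]]
#' mock_annotate("No evidence of colitis.", p)[["colitis"]]
#' @export
mock_annotate <- function(note_text, profile, rules = cue_rules()) {
  stopifnot(inherits(profile, "irae_profile"), inherits(rules, "irae_cue_rules"))
  label_ids <- profile_labels(profile)
  calls <- setNames(rep("No", length(label_ids)), label_ids)
  note_text <- as.character(note_text %||% "")
  if (length(note_text) != 1 || is.na(note_text) || !nzchar(trimws(note_text))) {
    return(calls)
  }

  terms_by_label <- map2(
    profile$labels$display_name, profile$labels$synset,
    function(name, syn) unique(map(c(name, syn), tokenize))
  )
  neg_cues <- map(c(rules$negation_cues, rules$hypothetical_cues), tokenize)
  alt_markers <- map(rules$alt_cause_markers, tokenize)
  causal_markers <- map(rules$causal_markers, tokenize)
  agents <- map(rules$non_ici_agents, tokenize)
  ici <- map(profile$ici_drugs, tokenize)
  w <- rules$window

  for (sentence in split_sentences(note_text)) {
    toks <- tokenize(sentence)
    if (length(toks) == 0) next
    cue_ends <- unlist(map(neg_cues, function(ct) phrase_positions(toks, ct) + length(ct) - 1L))
    marker_pos <- bind_rows(
      marker_positions(toks, alt_markers, "alt"),
      marker_positions(toks, causal_markers, "causal")
    )

    for (li in seq_along(label_ids)) {
      if (calls[[li]] == "Yes") next
      for (term_toks in terms_by_label[[li]]) {
        if (length(term_toks) == 0) next
        for (pos in phrase_positions(toks, term_toks)) {
          if (mention_is_positive(pos, toks, cue_ends, marker_pos, agents, ici, w)) {
            calls[[li]] <- "Yes"
            break
          }
        }
        if (calls[[li]] == "Yes") break
      }
    }
  }
  calls
}

marker_positions <- function(toks, marker_token_lists, kind) {
  starts <- map(marker_token_lists, function(mt) phrase_positions(toks, mt))
  lens <- map2(starts, marker_token_lists, function(s, mt) rep(length(mt), length(s)))
  tibble(
    start = as.integer(unlist(starts) %||% integer()),
    len = as.integer(unlist(lens) %||% integer()),
    kind = kind
  )
}

# Assertion + causation resolution for one mention at token index `pos`.
mention_is_positive <- function(pos, toks, cue_ends, marker_pos, agents, ici, w) {
  # (a) negation/hypothetical cue within `w` tokens before the mention
  if (length(cue_ends) && any(cue_ends >= pos - w & cue_ends < pos)) {
    return(FALSE)
  }
  # (b) nearest etiology marker in the sentence, if any
  if (nrow(marker_pos) == 0) return(TRUE)
  d <- abs(marker_pos$start - pos)
  nearest <- marker_pos[which.min(d), ]
  after_start <- nearest$start + nearest$len
  after <- toks[seq.int(after_start, min(length(toks), after_start + w - 1))]
  after <- after[!is.na(after)]
  ici_hit <- any(map_lgl(ici, function(dt) length(phrase_positions(after, dt)) > 0))
  if (ici_hit) return(TRUE)
  agent_hit <- any(map_lgl(agents, function(at) length(phrase_positions(after, at)) > 0))
  if (agent_hit) return(FALSE)
  # Unspecified agent: suppression fires only on an identified non-ICI agent.
  TRUE
}

# --- backend contract -----------------------------------------------------

#' Build a backend request
#'
#' The request fixes the decoding temperature at 0 by default so repeated runs
#' of any compliant backend are deterministic (the model always emits its
#' highest-probability token, "Yes" or "No", per label).
#'
#' @param prompt An `irae_prompt` from [render_prompt()], or a list with
#'   elements `text` and `label_ids`.
#' @param decoding_temperature Non-negative number; 0 for replication runs.
#' @return An object of class `irae_backend_request`.
#' @export
backend_request <- function(prompt, decoding_temperature = 0) {
  stopifnot(
    !is.null(prompt$text), !is.null(prompt$label_ids),
    is.numeric(decoding_temperature), decoding_temperature >= 0
  )
  structure(
    list(
      prompt_text = prompt$text,
      label_ids = prompt$label_ids,
      decoding_temperature = decoding_temperature
    ),
    class = "irae_backend_request"
  )
}

#' Classification backends
#'
#' `backend_mock()` wraps the deterministic rule-based annotator
#' ([mock_annotate()]) behind the backend contract; it recovers the note body
#' from the flattened prompt (via the template's note delimiters) and emits a
#' JSON object with one "Yes"/"No" field per requested label. It exists as a
#' fully testable, reproducible stand-in for a remote model — it does not
#' emulate any particular LLM.
#'
#' `backend_remote()` is an adapter for an OpenAI-compatible chat-completions
#' endpoint. Endpoint, deployment and credentials come from arguments or
#' environment variables (`IRAE_REMOTE_ENDPOINT`, `IRAE_REMOTE_DEPLOYMENT`,
#' `IRAE_REMOTE_API_KEY`), never hard-coded. Transient transport failures are
#' retried twice with backoff; persistent failure yields `ok = FALSE` rather
#' than an error, so batch runs never abort mid-corpus.
#'
#' @param profile A [site_profile()] (mock backend).
#' @param rules A [cue_rules()] object (mock backend).
#' @param endpoint,deployment,api_key Remote service coordinates.
#' @param retries Number of retries on transport failure (remote backend).
#' @return A backend handle for [classify()].
#' @export
backend_mock <- function(profile, rules = cue_rules()) {
  stopifnot(inherits(profile, "irae_profile"))
  structure(
    list(backend_id = "mock", profile = profile, rules = rules),
    class = c("irae_backend_mock", "irae_backend")
  )
}

#' @rdname backend_mock
#' @export
backend_remote <- function(endpoint = Sys.getenv("IRAE_REMOTE_ENDPOINT"),
                           deployment = Sys.getenv("IRAE_REMOTE_DEPLOYMENT"),
                           api_key = Sys.getenv("IRAE_REMOTE_API_KEY"),
                           retries = 2) {
  structure(
    list(
      backend_id = "openai-compatible", endpoint = endpoint,
      deployment = deployment, api_key = api_key, retries = retries
    ),
    class = c("irae_backend_remote", "irae_backend")
  )
}

#' Select a backend by name
#'
#' @param name `"mock"` or `"openai-compatible"`.
#' @param profile Site profile (required for the mock backend).
#' @param ... Passed to the backend constructor.
#' @export
backend_by_name <- function(name, profile = NULL, ...) {
  switch(name,
    "mock" = backend_mock(profile, ...),
    "openai-compatible" = backend_remote(...),
    abort(paste0("unknown backend: ", name))
  )
}

#' Classify one rendered prompt
#'
#' The contract boundary between the pipeline and any classification backend:
#' takes a [backend_request()], returns a raw-response record with `ok`
#' signalling transport success. Errors never propagate past this boundary —
#' failures are encoded as `ok = FALSE` with a diagnostic.
#'
#' @param request A [backend_request()].
#' @param backend A backend handle ([backend_mock()] or [backend_remote()]).
#' @return A list of class `irae_raw_response` with fields `text`,
#'   `backend_id`, `ok` and `diagnostic`.
#' @export
classify <- function(request, backend) {
  stopifnot(inherits(request, "irae_backend_request"))
  UseMethod("classify", backend)
}

raw_response <- function(text, backend_id, ok = TRUE, diagnostic = NA_character_) {
  structure(
    list(text = text, backend_id = backend_id, ok = ok, diagnostic = diagnostic),
    class = "irae_raw_response"
  )
}

#' @export
classify.irae_backend_mock <- function(request, backend) {
  note <- extract_note_from_prompt(request$prompt_text)
  if (is.na(note)) note <- ""
  calls <- mock_annotate(note, backend$profile, backend$rules)
  calls <- calls[request$label_ids]
  calls[is.na(calls)] <- "No"
  names(calls) <- request$label_ids
  raw_response(
    text = jsonlite::toJSON(as.list(calls), auto_unbox = TRUE),
    backend_id = backend$backend_id
  )
}

#' @export
classify.irae_backend_remote <- function(request, backend) {
  if (!nzchar(backend$endpoint) || !nzchar(backend$api_key)) {
    return(raw_response(
      text = NA_character_, backend_id = backend$backend_id, ok = FALSE,
      diagnostic = "remote backend credentials/endpoint not configured"
    ))
  }
  body <- jsonlite::toJSON(list(
    model = backend$deployment,
    temperature = request$decoding_temperature,
    messages = list(list(role = "user", content = request$prompt_text))
  ), auto_unbox = TRUE)
  last_err <- "unknown transport failure"
  for (attempt in seq_len(backend$retries + 1)) {
    out <- tryCatch({
      tmp <- tempfile(fileext = ".json")
      writeLines(body, tmp)
      res <- suppressWarnings(system2(
        "curl",
        c("-sS", "--fail", "-X", "POST", shQuote(backend$endpoint),
          "-H", shQuote("Content-Type: application/json"),
          "-H", shQuote(paste0("Authorization: Bearer ", backend$api_key)),
          "--data-binary", paste0("@", tmp)),
        stdout = TRUE, stderr = TRUE
      ))
      status <- attr(res, "status") %||% 0
      if (status != 0) stop(paste(res, collapse = " "))
      parsed <- jsonlite::fromJSON(paste(res, collapse = "\n"), simplifyVector = FALSE)
      parsed$choices[[1]]$message$content %||% stop("no message content in response")
    }, error = function(e) structure(conditionMessage(e), class = "transport_error"))
    if (!inherits(out, "transport_error")) {
      return(raw_response(text = out, backend_id = backend$backend_id))
    }
    last_err <- unclass(out)
    if (attempt <= backend$retries) Sys.sleep(2^(attempt - 1))
  }
  raw_response(
    text = NA_character_, backend_id = backend$backend_id, ok = FALSE,
    diagnostic = last_err
  )
}
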