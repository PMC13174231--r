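#' Organ-level irAE categories
#'
#' The closed set of organ-level category names that a site profile's
#' `category_map` may use. Labels missing from the map are assigned to
#' `"Other"` with a warning.
#'
#' @export
IRAE_CATEGORIES <- c(
  "Cardiovascular", "Dermatologic", "Endocrine", "Gastrointestinal",
  "Haematological", "Musculoskeletal and Rheumatologic", "Neurologic",
  "Other", "Pulmonary", "Renal"
)

#' Construct a site profile
#'
#' A site profile carries everything site-specific that drives a run: the irAE
#' label list with per-label synonym sets ("synsets" — surface expressions,
#' acronyms and related concepts injected into the prompt), the ICI drug list,
#' and the mapping from irAE labels to organ-level categories. Sites differ in
#' how they annotated irAEs (e.g. one site may keep colitis and diarrhoea as
#' separate labels while another merges them under one label whose synset
#' carries both terms), so each site gets its own profile.
#'
#' @param site_id Character scalar naming the site (e.g. `"vumc"`).
#' @param labels A data frame with columns `label_id`, `display_name` and a
#'   list-column `synset` (character vectors, possibly empty). `label_id`s are
#'   normalized to lowercase with underscores.
#' @param ici_drugs Non-empty character vector of immune checkpoint inhibitor
#'   drug names.
#' @param category_map Named character vector or named list mapping `label_id`
#'   to one of [IRAE_CATEGORIES]. Labels absent from the map are assigned to
#'   `"Other"` with a warning.
#'
#' @return An object of class `irae_profile`: a list with elements `site_id`,
#'   `labels` (tibble), `ici_drugs` and `category_map` (named character).
#' @seealso [read_site_profile()], [map_to_categories()]
#' @examples
#' p <- site_profile(
#'   site_id = "demo",
#'   labels = tibble::tibble(
#'     label_id = c("colitis", "rash"),
#'     display_name = c("colitis", "rash"),
#'     synset = list(c("colitis", "diarrhoea"), character())
#'   ),
#'   ici_drugs = c("nivolumab", "pembrolizumab"),
#'   category_map = c(colitis = "Gastrointestinal", rash = "Dermatologic")
#' )
#' profile_labels(p)
#' @export
site_profile <- function(site_id, labels, ici_drugs, category_map = NULL) {
  labels <- as_tibble(labels)
  stopifnot(all(c("label_id", "display_name") %in% names(labels)))
  if (!"synset" %in% names(labels)) {
    labels$synset <- rep(list(character()), nrow(labels))
  }
  labels$label_id <- normalize_label_id(labels$label_id)
  labels$synset <- map(labels$synset, function(s) {
    s <- as.character(s %||% character())
    s[nzchar(s)]
  })
  category_map <- unlist(category_map %||% character())
  if (length(category_map)) names(category_map) <- normalize_label_id(names(category_map))

  prof <- structure(
    list(
      site_id = as.character(site_id),
      labels = labels,
      ici_drugs = as.character(ici_drugs),
      category_map = category_map
    ),
    class = "irae_profile"
  )
  validate_site_profile(prof)
}

normalize_label_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[^a-z0-9]+", "_", x)
}

validate_site_profile <- function(profile) {
  labels <- profile$labels
  if (nrow(labels) == 0) {
    abort("site profile must define at least one irAE label")
  }
  if (anyDuplicated(labels$label_id)) {
    abort(paste0(
      "duplicate label_id in profile: ",
      paste(unique(labels$label_id[duplicated(labels$label_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(labels$display_name)) {
    abort("display_name appears twice under different label_ids")
  }
  bad_syn <- map_lgl(labels$synset, function(s) any(!nzchar(s)))
  if (any(bad_syn)) abort("synset entries must be non-empty strings")
  if (length(profile$ici_drugs) == 0 || all(!nzchar(profile$ici_drugs))) {
    abort("ici_drugs must be non-empty")
  }
  cm <- profile$category_map
  unknown <- setdiff(names(cm), labels$label_id)
  if (length(unknown)) {
    abort(paste0("category_map references unknown label(s): ", paste(unknown, collapse = ", ")))
  }
  bad_cat <- setdiff(unname(cm), IRAE_CATEGORIES)
  if (length(bad_cat)) {
    abort(paste0(
      "category name(s) outside the closed set: ", paste(bad_cat, collapse = ", "),
      "\nallowed: ", paste(IRAE_CATEGORIES, collapse = ", ")
    ))
  }
  unmapped <- setdiff(labels$label_id, names(cm))
  if (length(unmapped)) {
    warn(paste0(
      "label(s) missing from category_map assigned to 'Other': ",
      paste(unmapped, collapse = ", ")
    ))
    cm <- c(cm, setNames(rep("Other", length(unmapped)), unmapped))
    profile$category_map <- cm
  }
  profile
}

#' @export
print.irae_profile <- function(x, ...) {
  cat("<irae_profile> site:", x$site_id, "\n")
  cat("  labels:    ", nrow(x$labels), " (",
      paste(head(x$labels$label_id, 6), collapse = ", "),
      if (nrow(x$labels) > 6) ", ..." else "", ")\n", sep = "")
  cat("  ici_drugs: ", paste(x$ici_drugs, collapse = ", "), "\n", sep = "")
  cat("  categories:", length(unique(x$category_map)), "distinct\n")
  invisible(x)
}

#' @rdname site_profile
#' @param profile An `irae_profile`.
#' @export
profile_labels <- function(profile) {
  stopifnot(inherits(profile, "irae_profile"))
  profile$labels$label_id
}

#' Read / write a site profile config file
#'
#' One structured YAML file per site holds labels, synsets, ICI drugs and the
#' category map together, so a run is reproducible from a single artifact.
#' Three example profiles ship with the package under
#' `system.file("extdata/profiles", package = "iraekit")`.
#'
#' The expected YAML layout:
#' ```yaml
#' site_id: vumc
#' ici_drugs: [ipilimumab, nivolumab]
#' labels:
#'   - label_id: colitis
#'     display_name: colitis
#'     synset: [colitis]
#'     category: Gastrointestinal
#' ```
#'
#' @param path Path to the YAML config file.
#' @return `read_site_profile()` returns a validated [site_profile()];
#'   validation failures raise before any pipeline stage runs.
#' @export
read_site_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("site profile file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$labels) || length(cfg$labels) == 0) {
    abort("site profile must define at least one irAE label")
  }
  labels <- tibble(
    label_id = map_chr(cfg$labels, function(l) l$label_id %||% abort("label missing label_id")),
    display_name = map_chr(cfg$labels, function(l) l$display_name %||% l$label_id),
    synset = map(cfg$labels, function(l) as.character(unlist(l$synset %||% character())))
  )
  cats <- map(cfg$labels, function(l) l$category)
  has_cat <- !map_lgl(cats, is.null)
  category_map <- setNames(unlist(cats[has_cat]), labels$label_id[has_cat])
  site_profile(
    site_id = cfg$site_id %||% tools::file_path_sans_ext(basename(path)),
    labels = labels,
    ici_drugs = as.character(unlist(cfg$ici_drugs)),
    category_map = category_map
  )
}

#' @rdname read_site_profile
#' @param profile An `irae_profile` to serialize.
#' @return `write_site_profile()` returns `path` invisibly; reading the file
#'   back yields a field-by-field identical profile.
#' @export
write_site_profile <- function(profile, path) {
  stopifnot(inherits(profile, "irae_profile"))
  cfg <- list(
    site_id = profile$site_id,
    ici_drugs = as.list(profile$ici_drugs),
    labels = pmap(
      list(profile$labels$label_id, profile$labels$display_name, profile$labels$synset),
      function(id, name, syn) {
        list(
          label_id = id, display_name = name, synset = as.list(syn),
          category = unname(profile$category_map[[id]])
        )
      }
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Project irAE labels onto organ-level categories
#'
#' Category-level positivity is the logical OR over member irAEs: a category is
#' positive when any of its member labels is. The projection of a label set is
#' therefore the union of its members' categories, and never larger than the
#' label set itself.
#'
#' @param labels Character vector of label_ids (an empty vector denotes the
#'   'None' annotation).
#' @param profile An [site_profile()].
#' @return Character vector of distinct category names (sorted).
#' @examples
#' p <- example_site_profile("vumc")
#' map_to_categories(c("colitis", "hepatitis"), p)
#' map_to_categories(character(), p)
#' @export
map_to_categories <- function(labels, profile) {
  stopifnot(inherits(profile, "irae_profile"))
  labels <- as.character(labels)
  if (length(labels) == 0) return(character())
  bad <- setdiff(labels, profile_labels(profile))
  if (length(bad)) abort(paste0("label(s) not in profile: ", paste(bad, collapse = ", ")))
  sort(unique(unname(profile$category_map[labels])))
}

#' Load one of the shipped example site profiles
#'
#' Three example profiles mirror cross-site vocabulary differences: `"vumc"`
#' keeps colitis and diarrhoea as separate labels, `"ucsf"` merges them under a
#' single colitis label whose synset contains both terms, and `"roche"` uses a
#' trial-report vocabulary (e.g. pyrexia). The shipped lists cover only labels
#' named in published site summaries; real deployments supply their own config.
#'
#' @param site One of `"vumc"`, `"ucsf"`, `"roche"`.
#' @return An [site_profile()].
#' @export
example_site_profile <- function(site = c("vumc", "ucsf", "roche")) {
  site <- arg_match(site)
  path <- system.file("extdata", "profiles", paste0(site, ".yaml"), package = "iraekit")
  if (!nzchar(path)) abort("example profile not found; is the package installed?")
  read_site_profile(path)
}
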