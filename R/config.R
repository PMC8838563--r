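#' Load a surgery concept lexicon
#'
#' Reads a YAML lexicon mapping surgery concepts to token-level surface
#' patterns, plus exclusion tokens that veto a match when they occur within a
#' small token window around it (the classic confusables: hysteroscopy,
#' biopsy, oophoropexy, cystectomy). With `path = NULL` the default lexicon
#' shipped with the package is used.
#'
#' @param path Path to a lexicon YAML file, or `NULL` for the default.
#' @return An object of class `surg_lexicon`: a compiled pattern index ready
#'   for [match_concepts()].
#' @examples
#' lex <- load_lexicon()
#' length(lex$entries)
#' @export
load_lexicon <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gsn$lexicon)) return(.gsn$lexicon)
  if (default) path <- .gsn_extdata("lexicon.yaml")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$concepts) || !length(raw$concepts)) {
    abort("lexicon file defines no concepts", class = "gsn_config_error")
  }
  bad <- setdiff(names(raw$concepts), concept_levels())
  if (length(bad)) {
    abort(paste0("unknown lexicon concept(s): ", paste(bad, collapse = ", ")),
          class = "gsn_config_error")
  }
  entries <- list()
  for (concept in names(raw$concepts)) {
    for (pat in raw$concepts[[concept]]$patterns) {
      toks <- .tok(tolower(pat))$token
      toks <- toks[!toks %in% c(";", ":", ",", ".", "!", "?")]
      if (!length(toks)) next
      entries[[length(entries) + 1L]] <-
        list(concept = concept, tokens = toks, n = length(toks))
    }
  }
  lex <- .compile_lexicon(entries,
                          excl_tokens = as.character(raw$exclusions$tokens %||% character()),
                          excl_window = as.integer(raw$exclusions$window %||% 3L))
  if (default) .gsn$lexicon <- lex
  lex
}

# build a first-token index with entries sorted longest-first, plus a cheap
# sentence-level screening regex
.compile_lexicon <- function(entries, excl_tokens, excl_window) {
  if (!length(entries)) abort("empty lexicon", class = "gsn_config_error")
  idx <- new.env(parent = emptyenv())
  for (e in entries) {
    key <- e$tokens[[1L]]
    idx[[key]] <- c(idx[[key]] %||% list(), list(e))
  }
  for (key in ls(idx)) {
    ents <- idx[[key]]
    idx[[key]] <- ents[order(vapply(ents, `[[`, 1L, "n"), decreasing = TRUE)]
  }
  first <- unique(vapply(entries, function(e) e$tokens[[1L]], character(1)))
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", first)
  screen <- paste0("(?:^|[^a-z0-9])(?:", paste(esc, collapse = "|"),
                   ")(?:$|[^a-z0-9-])")
  structure(
    list(entries = entries, index = idx, first_tokens = first,
         screen_regex = screen, excl_tokens = excl_tokens,
         excl_window = excl_window),
    class = "surg_lexicon"
  )
}

#' Load assertion cue configuration
#'
#' Reads the NegEx/ConText-style cue lists used by [assert_context()]:
#' negation, family, hypothetical and planned cues, each split into
#' pre-mention and post-mention lists, plus the scan window size (tokens) and
#' the scope-breaker tokens that terminate a scan.
#'
#' @param path Path to a cue YAML file, or `NULL` for the default.
#' @return A list of class `surg_cues`.
#' @export
load_cue_config <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gsn$cues)) return(.gsn$cues)
  if (default) path <- .gsn_extdata("cues.yaml")
  raw <- yaml::read_yaml(path)
  split_cues <- function(x) {
    lapply(x, function(v) lapply(as.character(v), function(s) .split_cue(s)))
  }
  cues <- structure(list(
    window = as.integer(raw$window %||% 6L),
    scope_breakers = as.character(raw$scope_breakers %||% c("but", "however", ";", ".")),
    negated = split_cues(raw$negation),
    family = split_cues(raw$family),
    hypothetical = split_cues(raw$hypothetical),
    planned = split_cues(raw$planned)
  ), class = "surg_cues")
  if (default) .gsn$cues <- cues
  cues
}

.split_cue <- function(s) strsplit(tolower(s), " ", fixed = TRUE)[[1L]]

#' Load section segmentation configuration
#'
#' Reads the line-anchored header patterns used by [segment_sections()] and
#' the whitelist of normalized headers considered relevant to the patient's
#' own history (family history, social history, allergies and medication
#' lists are excluded by default).
#'
#' @param path Path to a section YAML file, or `NULL` for the default.
#' @return A list of class `surg_sections` with elements `header_patterns`,
#'   `whitelist`, `exclude` and `include_unknown`.
#' @export
load_section_config <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gsn$sections)) return(.gsn$sections)
  if (default) path <- .gsn_extdata("sections.yaml")
  raw <- yaml::read_yaml(path)
  cfg <- structure(list(
    header_patterns = as.character(raw$header_patterns),
    whitelist = normalize_header(as.character(raw$whitelist)),
    exclude = normalize_header(as.character(raw$exclude %||% character())),
    include_unknown = isTRUE(raw$include_unknown %||% TRUE)
  ), class = "surg_sections")
  if (!length(cfg$header_patterns)) {
    abort("section config must provide at least one header pattern",
          class = "gsn_config_error")
  }
  if (default) .gsn$sections <- cfg
  cfg
}

#' Assemble a pipeline configuration
#'
#' Bundles the lexicon, assertion cues, section rules and the remaining
#' tunables of the extraction pipeline into one object passed to
#' [extract_note()] and friends.
#'
#' @param lexicon A `surg_lexicon` (see [load_lexicon()]); default lexicon if
#'   `NULL`.
#' @param cues A `surg_cues` (see [load_cue_config()]).
#' @param sections A `surg_sections` (see [load_section_config()]).
#' @param date_dialect `"mdy"` (default, US month-first) or `"dmy"` for the
#'   interpretation of slash dates.
#' @param include_unknown_sections Process text outside any recognized section
#'   header? Defaults to `TRUE` (many notes are unsectioned).
#' @param mode `"faithful"` reproduces the documented matcher behaviour,
#'   including matching specimen-template lines such as
#'   `"Uterus, endometrium, hysterectomy: Inactive"`; `"strict"` suppresses
#'   matches on such colon-terminated template lines.
#' @return A list of class `nlp_config`.
#' @examples
#' cfg <- nlp_config()
#' cfg$date_dialect
#' @export
nlp_config <- function(lexicon = NULL, cues = NULL, sections = NULL,
                       date_dialect = c("mdy", "dmy"),
                       include_unknown_sections = NULL,
                       mode = c("faithful", "strict")) {
  date_dialect <- match.arg(date_dialect)
  mode <- match.arg(mode)
  lexicon <- lexicon %||% load_lexicon()
  cues <- cues %||% load_cue_config()
  sections <- sections %||% load_section_config()
  if (!is.null(include_unknown_sections)) {
    sections$include_unknown <- isTRUE(include_unknown_sections)
  }
  structure(list(lexicon = lexicon, cues = cues, sections = sections,
                 date_dialect = date_dialect, mode = mode),
            class = "nlp_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
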