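#' Normalize a section header
#'
#' Lowercases, collapses internal whitespace and strips trailing colons. The
#' transformation is idempotent, so already-normalized headers pass through
#' unchanged.
#'
#' @param x Character vector of raw header strings.
#' @return Character vector of normalized headers.
#' @examples
#' normalize_header("PAST SURGICAL HISTORY:")
#' @export
normalize_header <- function(x) {
  out <- stringr::str_squish(stringr::str_to_lower(x))
  stringr::str_squish(stringr::str_remove(out, ":+\\s*$"))
}

#' Segment a note into sections
#'
#' Splits free note text into contiguous section spans using line-anchored
#' header patterns. Every character of the input belongs to exactly one
#' section; text before the first recognized header (or all text, when no
#' header matches) forms a synthetic `"UNKNOWN"` section. Offsets are 0-based,
#' half-open, character-based.
#'
#' @param note_text A single character string.
#' @param header_patterns Character vector of regexes anchored at line starts
#'   (`^...`); multiline mode is applied internally. `NULL` uses the default
#'   section configuration.
#' @return A tibble with columns `header` (normalized), `start`, `end`
#'   (0-based half-open character offsets) and `relevant` (logical, `NA` until
#'   [filter_relevant_sections()] is applied).
#' @examples
#' segment_sections("PAST SURGICAL HISTORY:\ns/p TAH-BSO 1995.\nPLAN:\nfollow up.")
#' @export
segment_sections <- function(note_text, header_patterns = NULL) {
  stopifnot(is.character(note_text), length(note_text) == 1L)
  if (is.na(note_text)) note_text <- ""
  header_patterns <- header_patterns %||% load_section_config()$header_patterns
  if (!length(header_patterns)) {
    abort("header_patterns must be non-empty", class = "gsn_config_error")
  }
  n <- nchar(note_text)
  starts <- integer(0)
  lens <- integer(0)
  for (pat in header_patterns) {
    m <- gregexpr(paste0("(?m)", pat), note_text, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      starts <- c(starts, as.integer(m))
      lens <- c(lens, attr(m, "match.length"))
    }
  }
  if (length(starts)) {
    keep <- !duplicated(starts)
    ord <- order(starts[keep])
    starts <- starts[keep][ord]
    lens <- lens[keep][ord]
  }
  if (!length(starts)) {
    return(tibble(header = "UNKNOWN", start = 0L, end = n, relevant = NA))
  }
  headers <- normalize_header(substring(note_text, starts, starts + lens - 1L))
  sec_start <- starts - 1L                       # to 0-based
  sec_end <- c(sec_start[-1L], n)
  out <- tibble(header = headers, start = sec_start, end = sec_end,
                relevant = NA)
  if (sec_start[1L] > 0L) {
    out <- dplyr::bind_rows(
      tibble(header = "UNKNOWN", start = 0L, end = sec_start[1L], relevant = NA),
      out
    )
  }
  out
}

#' Keep the sections relevant to the patient's own history
#'
#' Marks each section as relevant when its normalized header is in the
#' whitelist (or is `"UNKNOWN"` and `include_unknown` is set) and returns the
#' relevant subset. Content of excluded sections -- family history above all
#' -- never reaches concept matching, so it cannot yield valid patient
#' events.
#'
#' @param sections A tibble from [segment_sections()].
#' @param whitelist Character vector of normalized headers to keep; `NULL`
#'   uses the default section configuration.
#' @param include_unknown Keep `"UNKNOWN"` (unsectioned) spans? Defaults to
#'   the section configuration value.
#' @return The subset of `sections` that is relevant, with the `relevant`
#'   column filled in.
#' @export
filter_relevant_sections <- function(sections, whitelist = NULL,
                                     include_unknown = NULL) {
  cfg <- load_section_config()
  whitelist <- whitelist %||% cfg$whitelist
  include_unknown <- include_unknown %||% cfg$include_unknown
  sections <- dplyr::mutate(
    sections,
    relevant = .data$header %in% whitelist |
      (include_unknown & .data$header == "UNKNOWN")
  )
  dplyr::filter(sections, .data$relevant)
}

# abbreviations whose trailing period never ends a sentence
.sentence_abbrevs <- c("dr", "mr", "mrs", "ms", "st", "vs", "etc", "eg", "ie",
                       "approx", "e.g", "i.e", "ft", "cm", "mm", "wk", "mo")

#' Split text into sentences
#'
#' Deterministic rule-based sentence detection: terminal punctuation followed
#' by whitespace ends a sentence unless the preceding word is a known
#' abbreviation; newlines always end a sentence (clinical notes are strongly
#' line-oriented). Decimal points and slash dates never split because their
#' periods/slashes are not followed by whitespace. The returned spans are
#' trimmed to non-whitespace, so their concatenation covers all
#' non-whitespace text.
#'
#' @param section_text A single character string (typically one section).
#' @return A tibble with columns `text`, `start`, `end` (0-based half-open
#'   offsets into `section_text`).
#' @examples
#' split_sentences("She had a TAH in 1990. She denies pain.")
#' @export
split_sentences <- function(section_text) {
  stopifnot(is.character(section_text), length(section_text) == 1L)
  if (is.na(section_text) || !nzchar(section_text)) {
    return(tibble(text = character(), start = integer(), end = integer()))
  }
  txt <- section_text
  n <- nchar(txt)
  m <- gregexpr("[.!?]+(?=\\s|$)|\\n", txt, perl = TRUE)[[1L]]
  bounds <- integer(0)
  if (m[1L] != -1L) {
    pos <- as.integer(m)
    len <- attr(m, "match.length")
    for (i in seq_along(pos)) {
      p <- pos[i]
      ch <- substring(txt, p, p)
      if (ch == "\n") {
        bounds <- c(bounds, p)          # boundary *before* the newline char
        next
      }
      prev <- substring(txt, max(1L, p - 12L), p - 1L)
      word <- tolower(sub(".*?([A-Za-z.]+)$", "\\1", prev))
      word <- sub("\\.$", "", word)
      if (word %in% .sentence_abbrevs) next
      bounds <- c(bounds, p + len[i] - 1L)  # include the punctuation run
    }
  }
  bounds <- sort(unique(c(bounds, n)))
  out_text <- character(0); out_start <- integer(0); out_end <- integer(0)
  seg_start <- 1L
  for (b in bounds) {
    if (b < seg_start) next
    seg <- substring(txt, seg_start, b)
    first_ns <- regexpr("\\S", seg, perl = TRUE)
    if (first_ns != -1L) {
      last_ns <- nchar(sub("\\s+$", "", seg))
      s0 <- seg_start + as.integer(first_ns) - 1L     # 1-based
      e0 <- seg_start + last_ns - 1L
      out_text <- c(out_text, substring(txt, s0, e0))
      out_start <- c(out_start, s0 - 1L)              # 0-based
      out_end <- c(out_end, e0)
    }
    seg_start <- b + 1L
  }
  tibble(text = out_text, start = out_start, end = out_end)
}

# fast internal tokenizer: lowercased word tokens (hyphen/slash compounds such
# as "tah-bso" and "s/p" kept whole) plus punctuation tokens used as assertion
# scope breakers; offsets are 0-based into the source text
.tok <- function(text) {
  low <- tolower(text)
  m <- gregexpr("[a-z0-9]+(?:[-/][a-z0-9]+)*|[;:,.!?]", low, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  list(token = substring(low, start, start + len - 1L),
       start = start - 1L, end = start + len - 1L)
}

#' Tokenize a sentence
#'
#' Lowercases and splits a sentence into word tokens, preserving hyphen- and
#' slash-joined surgical compounds (`"tah-bso"`, `"s/p"`,
#' `"salpingo-oophorectomy"`) as single tokens. Sentence-internal punctuation
#' (`; : , . ! ?`) is emitted as its own token so assertion scope breakers
#' remain visible. Offsets map back into the source text (0-based,
#' half-open).
#'
#' @param sentence_text A single character string.
#' @param keep_list Optional character vector of additional multi-word units
#'   (space-separated, lowercase) to merge into single tokens.
#' @return A tibble with columns `token`, `start`, `end`.
#' @examples
#' tokenize("TAH-BSO in 1995")
#' @export
tokenize <- function(sentence_text, keep_list = NULL) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1L)
  if (is.na(sentence_text)) sentence_text <- ""
  tk <- .tok(sentence_text)
  out <- tibble(token = tk$token, start = tk$start, end = tk$end)
  if (!is.null(keep_list) && nrow(out) > 1L) {
    units <- lapply(tolower(keep_list), function(s) strsplit(s, " ")[[1L]])
    units <- units[lengths(units) > 1L]
    for (u in units) {
      k <- length(u)
      i <- 1L
      while (i <= nrow(out) - k + 1L) {
        if (all(out$token[i:(i + k - 1L)] == u)) {
          out$token[i] <- paste(u, collapse = " ")
          out$end[i] <- out$end[i + k - 1L]
          out <- out[-((i + 1L):(i + k - 1L)), ]
        }
        i <- i + 1L
      }
    }
  }
  out
}
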