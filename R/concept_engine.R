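#' Match surgery concepts in a tokenized sentence
#'
#' Dictionary lookup over token sequences: scanning left to right, the
#' longest pattern starting at each token wins, and matches never overlap. A
#' match is vetoed when an exclusion token (e.g. `"hysteroscopy"`,
#' `"biopsy"`) occurs within the lexicon's exclusion window around it, which
#' keeps diagnostic confusables from being read as surgeries.
#'
#' @param tokens A tibble from [tokenize()] (columns `token`, `start`,
#'   `end`), or a plain character vector of lowercase tokens.
#' @param lexicon A `surg_lexicon`; default lexicon if `NULL`.
#' @param sentence_text Optional source sentence used to fill `matched_text`
#'   with the original character slice.
#' @return A tibble with one row per mention: `concept`, `matched_text`,
#'   `tok_start`, `tok_end` (1-based token indices) and `char_start`,
#'   `char_end` (0-based half-open offsets; `NA` for bare token input).
#' @examples
#' s <- "A total abdominal hysterectomy with bilateral salpingo-oophorectomy
#'       was performed the usual fashion."
#' match_concepts(tokenize(s))
#' @export
match_concepts <- function(tokens, lexicon = NULL, sentence_text = NULL) {
  lexicon <- lexicon %||% load_lexicon()
  if (!inherits(lexicon, "surg_lexicon") || !length(lexicon$entries)) {
    abort("empty or invalid lexicon", class = "gsn_config_error")
  }
  if (is.character(tokens)) {
    tokens <- tibble(token = tokens,
                     start = rep(NA_integer_, length(tokens)),
                     end = rep(NA_integer_, length(tokens)))
  }
  toks <- tokens$token
  m <- .match_raw(toks, lexicon)
  concept <- m$concept; ts <- m$ts; te <- m$te
  char_start <- tokens$start[ts]
  char_end <- tokens$end[te]
  matched_text <- if (!is.null(sentence_text) && length(ts)) {
    substring(sentence_text, char_start + 1L, char_end)
  } else if (length(ts)) {
    vapply(seq_along(ts), function(k) paste(toks[ts[k]:te[k]], collapse = " "),
           character(1))
  } else character(0)
  tibble(concept = concept, matched_text = matched_text,
         tok_start = ts, tok_end = te,
         char_start = char_start %||% integer(0),
         char_end = char_end %||% integer(0))
}

# core left-to-right longest-match scan over a lowercase token vector
.match_raw <- function(toks, lexicon) {
  nt <- length(toks)
  concept <- character(0); ts <- integer(0); te <- integer(0)
  i <- 1L
  idx <- lexicon$index
  excl <- lexicon$excl_tokens
  w <- lexicon$excl_window
  while (i <= nt) {
    ents <- idx[[toks[i]]]
    advanced <- FALSE
    if (!is.null(ents)) {
      for (e in ents) {
        j <- i + e$n - 1L
        if (j <= nt && all(toks[i:j] == e$tokens)) {
          lo <- max(1L, i - w); hi <- min(nt, j + w)
          if (!any(toks[lo:hi] %in% excl)) {
            concept <- c(concept, e$concept)
            ts <- c(ts, i); te <- c(te, j)
          }
          i <- j + 1L
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) i <- i + 1L
  }
  list(concept = concept, ts = ts, te = te)
}

# does `window` (a token vector in reading order) contain the cue sequence?
.contains_seq <- function(window, cue) {
  k <- length(cue)
  if (k == 0L || length(window) < k) return(FALSE)
  if (k == 1L) return(cue %in% window)
  for (i in seq_len(length(window) - k + 1L)) {
    if (all(window[i:(i + k - 1L)] == cue)) return(TRUE)
  }
  FALSE
}

# collect up to `window` tokens on one side of a mention, stopping at scope
# breakers; direction -1 = before the mention, +1 = after
.cue_window <- function(toks, from, dir, window, breakers) {
  out <- character(0)
  i <- from
  n <- length(toks)
  while (i >= 1L && i <= n && length(out) < window) {
    if (toks[i] %in% breakers) break
    out <- c(out, toks[i])
    i <- i + dir
  }
  if (dir < 0) rev(out) else out
}

#' Classify the assertion context of a concept mention
#'
#' Scoped cue search in the NegEx/ConText tradition: cue lists are scanned in
#' windows before and after the mention (default 6 tokens each way,
#' terminated by scope breakers such as `"but"`, `"however"`, `";"`, `"."`).
#' A mention inside a family-history section is forced to `"family"`
#' regardless of cues. Precedence when several classes fire:
#' negated > family > hypothetical > planned; with no cue the mention is
#' `"positive"`. Only positive mentions become valid surgery events.
#'
#' @param tokens A tibble from [tokenize()] or a character vector of tokens.
#' @param mention A one-row mention from [match_concepts()] (or any list with
#'   `tok_start`/`tok_end`).
#' @param cues A `surg_cues` object; default cues if `NULL`.
#' @param section_header Normalized header of the enclosing section
#'   (`"UNKNOWN"` when unsectioned).
#' @return A single assertion label (see [assertion_levels()]).
#' @examples
#' tk <- tokenize("no history of hysterectomy")
#' m <- match_concepts(tk)
#' assert_context(tk, m[1, ])
#' @export
assert_context <- function(tokens, mention, cues = NULL,
                           section_header = "UNKNOWN") {
  cues <- cues %||% load_cue_config()
  if (normalize_header(section_header) == "family history") return("family")
  toks <- if (is.character(tokens)) tokens else tokens$token
  pre <- .cue_window(toks, mention$tok_start - 1L, -1L, cues$window,
                     cues$scope_breakers)
  post <- .cue_window(toks, mention$tok_end + 1L, +1L, cues$window,
                      cues$scope_breakers)
  fires <- function(class_cues) {
    any(vapply(class_cues$pre %||% list(), .contains_seq, logical(1),
               window = pre)) ||
      any(vapply(class_cues$post %||% list(), .contains_seq, logical(1),
                 window = post))
  }
  if (fires(cues$negated)) return("negated")
  if (fires(cues$family)) return("family")
  if (fires(cues$hypothetical)) return("hypothetical")
  if (fires(cues$planned)) return("planned")
  "positive"
}

#' Resolve the laterality of an oophorectomy mention
#'
#' Sentence-scoped laterality cues: explicitly bilateral surface forms and
#' cues (`"bilateral"`, `"b/l"`, `"both"`) give `"bilateral"`; otherwise
#' `"left"`/`"right"` tokens anywhere in the sentence decide the side, with
#' both sides present resolving to `"bilateral"` and no cue giving
#' `"unspecified"` (the left-side default is applied later, at patient-level
#' aggregation). Laterality applies only to oophorectomy-family concepts;
#' calling this on a hysterectomy-only mention is an error.
#'
#' @inheritParams assert_context
#' @return One of [laterality_levels()].
#' @examples
#' tk <- tokenize("left salpingo-oophorectomy")
#' resolve_laterality(tk, match_concepts(tk)[1, ])
#' @export
resolve_laterality <- function(tokens, mention) {
  concept <- mention$concept
  if (!concept %in% .ooph_family()) {
    abort(paste0("laterality applies only to oophorectomy-family concepts, not ",
                 concept), class = "gsn_misuse_error")
  }
  if (concept %in% .bilateral_concepts()) return("bilateral")
  toks <- if (is.character(tokens)) tokens else tokens$token
  has_bi <- any(c("bilateral", "b/l", "both", "bilaterally") %in% toks)
  has_l <- "left" %in% toks
  has_r <- "right" %in% toks
  if (has_bi || (has_l && has_r)) return("bilateral")
  if (has_l) return("left")
  if (has_r) return("right")
  "unspecified"
}

#' Extract dates from a sentence
#'
#' Recognizes the three date pattern families used in surgical narratives:
#' full slash dates, slash dates with 2-digit years, and bare 4-digit years.
#' Two-digit years pivot into the century window ending at the note date
#' (`(note year - 100, note year]`); bare years are accepted in
#' `[1900, note year]`. Slash dates are read month-first under the default
#' `"mdy"` dialect. Every returned full date is a real calendar date.
#'
#' @param sentence_text A single character string.
#' @param note_date The note's date (`Date` or ISO string); anchors the
#'   2-digit-year pivot and bounds bare years.
#' @param dialect `"mdy"` (default) or `"dmy"`.
#' @return A tibble with columns `text`, `char_start`, `char_end` (0-based,
#'   half-open), `year`, `month`, `day` (`NA` for bare years) and `date`
#'   (`Date`, `NA` for bare years).
#' @examples
#' extract_dates("TAH on 11/22/1994", as.Date("2001-06-01"))
#' @export
extract_dates <- function(sentence_text, note_date, dialect = c("mdy", "dmy")) {
  dialect <- match.arg(dialect)
  note_date <- as.Date(note_date)
  note_year <- as.integer(format(note_date, "%Y"))
  txt <- sentence_text
  res_text <- character(0); res_s <- integer(0); res_e <- integer(0)
  res_y <- integer(0); res_m <- integer(0); res_d <- integer(0)

  m <- gregexpr("(?<![0-9/])\\d{1,2}/\\d{1,2}/\\d{2,4}(?![0-9/])", txt,
                perl = TRUE)[[1L]]
  masked <- txt
  if (m[1L] != -1L) {
    pos <- as.integer(m); len <- attr(m, "match.length")
    for (i in seq_along(pos)) {
      s <- pos[i]; e <- pos[i] + len[i] - 1L
      piece <- substring(txt, s, e)
      parts <- as.integer(strsplit(piece, "/", fixed = TRUE)[[1L]])
      ystr <- strsplit(piece, "/", fixed = TRUE)[[1L]][3L]
      if (nchar(ystr) == 3L) next
      yy <- parts[3L]
      year <- if (nchar(ystr) == 2L) {
        if (2000L + yy > note_year) 1900L + yy else 2000L + yy
      } else yy
      mo <- if (dialect == "mdy") parts[1L] else parts[2L]
      dy <- if (dialect == "mdy") parts[2L] else parts[1L]
      d <- if (mo >= 1 && mo <= 12 && dy >= 1 && dy <= 31) {
        suppressWarnings(tryCatch(
          as.Date(sprintf("%04d-%02d-%02d", year, mo, dy)),
          error = function(e) as.Date(NA)
        ))
      } else as.Date(NA)
      masked <- paste0(substring(masked, 1L, s - 1L),
                       strrep("x", e - s + 1L),
                       substring(masked, e + 1L))
      if (is.na(d)) next
      res_text <- c(res_text, piece); res_s <- c(res_s, s - 1L)
      res_e <- c(res_e, e); res_y <- c(res_y, year)
      res_m <- c(res_m, mo); res_d <- c(res_d, dy)
    }
  }
  ym <- gregexpr("(?<![0-9])(19|20)\\d{2}(?![0-9])", masked, perl = TRUE)[[1L]]
  if (ym[1L] != -1L) {
    pos <- as.integer(ym); len <- attr(ym, "match.length")
    for (i in seq_along(pos)) {
      s <- pos[i]; e <- pos[i] + len[i] - 1L
      year <- as.integer(substring(masked, s, e))
      if (year < 1900L || year > note_year) next
      res_text <- c(res_text, substring(txt, s, e))
      res_s <- c(res_s, s - 1L); res_e <- c(res_e, e)
      res_y <- c(res_y, year); res_m <- c(res_m, NA_integer_)
      res_d <- c(res_d, NA_integer_)
    }
  }
  date <- rep(as.Date(NA), length(res_y))
  full <- !is.na(res_m)
  if (any(full)) {
    date[full] <- as.Date(sprintf("%04d-%02d-%02d", res_y[full],
                                  res_m[full], res_d[full]))
  }
  ord <- order(res_s)
  tibble(text = res_text[ord], char_start = res_s[ord], char_end = res_e[ord],
         year = res_y[ord], month = res_m[ord], day = res_d[ord],
         date = date[ord])
}

# zero-row events tibble with the canonical schema (cached: it is returned
# for every note without a mention)
.events_schema <- function() {
  if (!is.null(.gsn$events_schema)) return(.gsn$events_schema)
  .gsn$events_schema <- tibble(patient_id = character(), note_id = character(),
         note_date = as.Date(character()), note_type = character(),
         section = character(), concept = character(),
         assertion = character(), laterality = character(),
         valid = logical(), event_date = as.Date(character()),
         event_year = integer(), matched_text = character(),
         char_start = integer(), char_end = integer())
}

# colon-terminated specimen-template line, e.g.
# "uterus, endometrium, hysterectomy: inactive" -- suppressed in strict mode
.is_template_line <- function(sentence_text) {
  grepl("^[^:]{1,80}:\\s*\\S*\\s*\\.?$", sentence_text) &&
    grepl(":", sentence_text, fixed = TRUE)
}

#' Extract surgery events from one clinical note
#'
#' Runs the full per-note pipeline: section segmentation, relevance
#' filtering, sentence detection, tokenization, concept matching, assertion
#' classification, laterality resolution and in-sentence date extraction.
#' The nearest date within the same sentence is attached to each mention
#' (absent otherwise). All mentions from relevant sections are returned for
#' audit; only mentions with a positive assertion are flagged `valid`, and
#' only valid events feed patient-level aggregation. The function is a pure
#' function of `(note, config)`.
#'
#' @param note A one-row data frame or list with `patient_id`, `note_id`,
#'   `note_date`, `note_type` and `text`.
#' @param config An [nlp_config()].
#' @return A tibble of events (possibly zero rows); offsets are 0-based into
#'   the full note text.
#' @export
extract_note <- function(note, config = nlp_config()) {
  note <- as.list(note)
  text <- note$text %||% ""
  if (is.na(text) || !nzchar(text)) return(.events_schema())
  note_date <- as.Date(note$note_date)
  lexicon <- config$lexicon
  cues <- config$cues

  if (!grepl(lexicon$screen_regex, tolower(text), perl = TRUE)) {
    return(.events_schema())
  }
  secs <- segment_sections(text, config$sections$header_patterns)
  keep_mask <- secs$header %in% config$sections$whitelist |
    (config$sections$include_unknown & secs$header == "UNKNOWN")
  if (!any(keep_mask)) return(.events_schema())
  keep_idx <- which(keep_mask)

  r_section <- character(0); r_concept <- character(0)
  r_assert <- character(0); r_lat <- character(0)
  r_date <- numeric(0); r_year <- integer(0)
  r_text <- character(0); r_cs <- integer(0); r_ce <- integer(0)

  for (si in keep_idx) {
    sec_start <- secs$start[si]
    stext <- substring(text, sec_start + 1L, secs$end[si])
    if (!grepl(lexicon$screen_regex, tolower(stext), perl = TRUE)) next
    sents <- split_sentences(stext)
    for (qi in seq_len(nrow(sents))) {
      sent <- sents$text[qi]
      if (!grepl(lexicon$screen_regex, tolower(sent), perl = TRUE)) next
      if (config$mode == "strict" && .is_template_line(sent)) next
      tk <- .tok(sent)
      m <- .match_raw(tk$token, lexicon)
      if (!length(m$ts)) next
      dates <- extract_dates(sent, note_date, config$date_dialect)
      off <- sec_start + sents$start[qi]
      for (mi in seq_along(m$ts)) {
        men <- list(concept = m$concept[mi], tok_start = m$ts[mi],
                    tok_end = m$te[mi])
        mcs <- tk$start[men$tok_start]
        mce <- tk$end[men$tok_end]
        assertion <- assert_context(tk$token, men, cues,
                                    section_header = secs$header[si])
        lat <- if (men$concept %in% .ooph_family()) {
          resolve_laterality(tk$token, men)
        } else NA_character_
        ev_date <- NA_real_; ev_year <- NA_integer_
        if (nrow(dates)) {
          dist <- pmin(abs(dates$char_start - mcs), abs(dates$char_start - mce))
          di <- which.min(dist)
          ev_date <- as.numeric(dates$date[di])
          ev_year <- dates$year[di]
          if (!is.na(ev_date) && dates$date[di] > note_date) {
            inform(paste0("event date ", format(dates$date[di]),
                          " after note date ", format(note_date), " in note ",
                          note$note_id, "; event kept"),
                   class = "gsn_future_date")
          }
        }
        r_section <- c(r_section, secs$header[si])
        r_concept <- c(r_concept, men$concept)
        r_assert <- c(r_assert, assertion)
        r_lat <- c(r_lat, lat)
        r_date <- c(r_date, ev_date)
        r_year <- c(r_year, ev_year)
        r_text <- c(r_text, substring(sent, mcs + 1L, mce))
        r_cs <- c(r_cs, off + mcs)
        r_ce <- c(r_ce, off + mce)
      }
    }
  }
  if (!length(r_concept)) return(.events_schema())
  n_ev <- length(r_concept)
  tibble(
    patient_id = rep(as.character(note$patient_id), n_ev),
    note_id = rep(as.character(note$note_id), n_ev),
    note_date = rep(note_date, n_ev),
    note_type = rep(as.character(note$note_type %||% "clinical_note"), n_ev),
    section = r_section,
    concept = r_concept,
    assertion = r_assert,
    laterality = r_lat,
    valid = r_assert == "positive",
    event_date = as.Date(r_date, origin = "1970-01-01"),
    event_year = r_year,
    matched_text = r_text,
    char_start = r_cs,
    char_end = r_ce
  )
}

#' Extract surgery events from a corpus of notes
#'
#' Applies [extract_note()] to every row of a notes tibble and binds the
#' results.
#'
#' @param notes A tibble of notes (`patient_id`, `note_id`, `note_date`,
#'   `note_type`, `text`), e.g. from [read_notes_jsonl()] or
#'   [generate_corpus()].
#' @param config An [nlp_config()].
#' @return A tibble of events across all notes.
#' @export
extract_corpus <- function(notes, config = nlp_config()) {
  n <- nrow(notes)
  if (!n) return(.events_schema())
  pid <- as.character(notes$patient_id)
  nid <- as.character(notes$note_id)
  nd <- as.Date(notes$note_date)
  nt <- as.character(notes$note_type)
  tx <- as.character(notes$text)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- extract_note(
      list(patient_id = pid[i], note_id = nid[i], note_date = nd[i],
           note_type = nt[i], text = tx[i]),
      config
    )
  }
  dplyr::bind_rows(out)
}
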