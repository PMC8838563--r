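#' Read clinical notes from JSON lines
#'
#' One JSON object per line with fields `patient_id`, `note_id`, `note_date`
#' (ISO-8601), `note_type` and `text`. A malformed line is reported to the
#' condition system and skipped; it never aborts the run.
#'
#' @param path Path to a `.jsonl` file.
#' @return A notes tibble. The number of skipped lines is attached as the
#'   `n_skipped` attribute.
#' @export
read_notes_jsonl <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("notes file not found: ", path), class = "gsn_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    ok <- !is.null(rec) &&
      all(c("patient_id", "note_id", "note_date", "text") %in% names(rec)) &&
      !is.na(suppressWarnings(as.Date(rec$note_date)))
    if (!ok) {
      skipped <- skipped + 1L
      inform(paste0("skipping malformed note record at line ", i, " of ", path),
             class = "gsn_skipped_note")
      next
    }
    rows[[i]] <- tibble(
      patient_id = as.character(rec$patient_id),
      note_id = as.character(rec$note_id),
      note_date = as.Date(rec$note_date),
      note_type = as.character(rec$note_type %||% "clinical_note"),
      text = as.character(rec$text)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(patient_id = character(), note_id = character(),
                  note_date = as.Date(character()), note_type = character(),
                  text = character())
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write clinical notes as JSON lines
#'
#' @param notes A notes tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(
                    paste0("cannot open ", path, ": ", conditionMessage(e)),
                    class = "gsn_config_error"))
  on.exit(close(con))
  if (nrow(notes)) {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(list(
        patient_id = notes$patient_id[i],
        note_id = notes$note_id[i],
        note_date = format(as.Date(notes$note_date[i])),
        note_type = notes$note_type[i],
        text = notes$text[i]
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
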