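# ---- template bank -------------------------------------------------------

#' Load the sentence template bank
#'
#' The generator's hand-authored sentence templates, stored as data so tests
#' can enumerate coverage: positive surgery phrasings in varied surface forms
#' (including abbreviations such as TAH-BSO), and the distractor families
#' that stress extraction (negation, family history, hysteroscopy/biopsy
#' confusables, discussed and planned surgery), plus neutral filler.
#'
#' @param path Path to a template YAML file, or `NULL` for the default bank.
#' @return A named list of character vectors, one per template kind.
#' @export
load_templates <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gsn$templates)) return(.gsn$templates)
  if (default) path <- .gsn_extdata("templates.yaml")
  tpl <- yaml::read_yaml(path)
  tpl <- lapply(tpl, as.character)
  if (default) .gsn$templates <- tpl
  tpl
}

.fill_template <- function(tpl, date_phrase = "", side = "", concept = "") {
  out <- gsub("{date_phrase}", date_phrase, tpl, fixed = TRUE)
  out <- gsub("{side}", side, out, fixed = TRUE)
  out <- gsub("{concept}", concept, out, fixed = TRUE)
  out <- gsub("\\s+([.,])", "\\1", out)
  stringr::str_squish(out)
}

.render_date_phrase <- function(date, config) {
  if (runif(1) >= config$p_date_attach) {
    # the common real-world alternative: age at surgery, which the date
    # extractor deliberately does not convert
    if (runif(1) < 0.5) {
      return(sprintf("at age %d", sample(25:49, 1L)))
    }
    return("")
  }
  fmt <- sample(c("full", "short", "year"), 1L, prob = config$date_format_probs)
  if (fmt == "year") return(format(date, "in %Y"))
  ord <- if (config$date_dialect == "mdy") c("%m", "%d") else c("%d", "%m")
  if (fmt == "full") {
    format(date, paste0("on ", ord[1], "/", ord[2], "/%Y"))
  } else {
    format(date, paste0("on ", ord[1], "/", ord[2], "/%y"))
  }
}

.typo_map <- c("salpingo-oophorectomy" = "salpingo-oophrectomy",
               "oophorectomy" = "oophrectomy",
               "hysterectomy" = "hysterectmy",
               "ovariectomy" = "ovariectmy",
               "tah-bso" = "tahbso",
               "bso" = "bs0",
               "tah" = "tha")

.apply_typo <- function(sentence) {
  for (key in names(.typo_map)) {
    if (grepl(key, sentence, ignore.case = TRUE)) {
      return(sub(paste0("(?i)", key), .typo_map[[key]], sentence, perl = TRUE))
    }
  }
  sentence
}

.flip_sides <- function(text) {
  out <- gsub("(?i)\\bleft\\b", "@SIDE@", text, perl = TRUE)
  out <- gsub("(?i)\\bright\\b", "left", out, perl = TRUE)
  gsub("@SIDE@", "right", out, fixed = TRUE)
}

# sentence record as a plain list; tibbles are built once per patient
.rec <- function(text, kind, procedure_id = NA_integer_,
                 fact_type = NA_character_, fact_lat = NA_character_,
                 corrupted = FALSE, subcategory = NA_character_,
                 fam_section = FALSE) {
  list(text = text, kind = kind, procedure_id = procedure_id,
       fact_type = fact_type, fact_lat = fact_lat, corrupted = corrupted,
       subcategory = subcategory, fam_section = fam_section)
}

.recs_to_tibble <- function(recs, note_ids) {
  tibble(
    text = vapply(recs, `[[`, character(1), "text"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    procedure_id = vapply(recs, function(r) as.integer(r$procedure_id),
                          integer(1)),
    fact_type = vapply(recs, `[[`, character(1), "fact_type"),
    fact_lat = vapply(recs, `[[`, character(1), "fact_lat"),
    corrupted = vapply(recs, `[[`, logical(1), "corrupted"),
    subcategory = vapply(recs, `[[`, character(1), "subcategory"),
    fam_section = vapply(recs, `[[`, logical(1), "fam_section"),
    note_id = note_ids
  )
}

.empty_sentences <- function() {
  tibble(text = character(), kind = character(), procedure_id = integer(),
         fact_type = character(), fact_lat = character(),
         corrupted = logical(), subcategory = character(),
         fam_section = logical(), note_id = character())
}

# render the sentences documenting one procedure (a same-day operation),
# applying the sentence-level internal-gap noise (typo, laterality flip);
# `ooph_phrasing` fixes, per procedure, whether its oophorectomy is phrased
# with an explicit side or unsided, so restatements never contradict the
# anchor under the left-side default
.render_procedure <- function(proc_rows, ooph_phrasing, config, tpl) {
  date <- proc_rows$date[1L]
  pid <- proc_rows$procedure_id[1L]
  types <- proc_rows$type
  out <- list()
  emit <- function(text, fact_type, fact_lat, flippable = FALSE) {
    corrupted <- FALSE
    sub <- NA_character_
    if (runif(1) < config$p_typo) {
      text2 <- .apply_typo(text)
      if (!identical(text2, text)) {
        text <- text2; corrupted <- TRUE; sub <- "typo"
      }
    }
    if (!corrupted && flippable && runif(1) < config$p_laterality_flip &&
        grepl("(?i)\\b(left|right)\\b", text, perl = TRUE)) {
      text <- .flip_sides(text)
      corrupted <- TRUE; sub <- "incorrect_laterality"
    }
    out[[length(out) + 1L]] <<-
      .rec(text, "surgery", pid, fact_type, fact_lat, corrupted, sub)
  }
  dp <- .render_date_phrase(date, config)
  if (all(c("hysterectomy", "bilateral_oophorectomy") %in% types)) {
    if (runif(1) < 0.6) {
      txt <- .fill_template(sample(tpl$tahbso_pos, 1L), date_phrase = dp)
      corrupted <- FALSE; sub <- NA_character_
      if (runif(1) < config$p_typo) {
        txt2 <- .apply_typo(txt)
        if (!identical(txt2, txt)) { txt <- txt2; corrupted <- TRUE; sub <- "typo" }
      }
      # one combined sentence documents both facts
      out[[length(out) + 1L]] <-
        .rec(txt, "surgery", pid, "hysterectomy", NA_character_, corrupted, sub)
      out[[length(out) + 1L]] <-
        .rec(txt, "surgery", pid, "bilateral_oophorectomy", "bilateral",
             corrupted, NA_character_)
      return(out)
    }
    emit(.fill_template(sample(tpl$hyst_pos, 1L), date_phrase = dp),
         "hysterectomy", NA_character_)
    emit(.fill_template(sample(tpl$bso_pos, 1L), date_phrase = dp),
         "bilateral_oophorectomy", "bilateral")
    return(out)
  }
  for (k in seq_len(nrow(proc_rows))) {
    type <- proc_rows$type[k]
    if (type == "hysterectomy") {
      emit(.fill_template(sample(tpl$hyst_pos, 1L), date_phrase = dp),
           "hysterectomy", NA_character_)
    } else if (type == "bilateral_oophorectomy") {
      emit(.fill_template(sample(tpl$bso_pos, 1L), date_phrase = dp),
           "bilateral_oophorectomy", "bilateral")
    } else {
      phr <- ooph_phrasing[[as.character(pid)]]
      if (identical(phr, "unspecified")) {
        emit(.fill_template(sample(tpl$ooph_unspec_pos, 1L), date_phrase = dp),
             "oophorectomy", "unspecified")
      } else {
        emit(.fill_template(sample(tpl$ooph_side_pos, 1L), date_phrase = dp,
                            side = phr), "oophorectomy", phr, flippable = TRUE)
      }
    }
  }
  out
}

.distractor_concepts <- c("hysterectomy", "oophorectomy",
                          "bilateral oophorectomy",
                          "bilateral salpingo-oophorectomy")

# distractor sentence records for one note, drawn per the configured rates
.render_distractors <- function(config, tpl, allow_family_section) {
  out <- list()
  if (runif(1) < config$p_negation_sentence) {
    out[[length(out) + 1L]] <- .rec(
      .fill_template(sample(tpl$negation, 1L),
                     concept = sample(.distractor_concepts, 1L)),
      "distractor", subcategory = "negated_as_positive")
  }
  if (runif(1) < config$p_family_mention) {
    as_section <- allow_family_section && runif(1) < 0.5
    out[[length(out) + 1L]] <- .rec(
      .fill_template(sample(tpl$family, 1L),
                     concept = sample(.distractor_concepts, 1L)),
      "distractor", subcategory = "family_vs_patient",
      fam_section = as_section)
  }
  if (runif(1) < config$p_confusable) {
    txt <- .fill_template(sample(tpl$confusable, 1L), date_phrase = "in 2003")
    sub <- if (grepl("hysteroscop", txt, ignore.case = TRUE)) {
      "hysterectomy_vs_hysteroscopy"
    } else "biopsy_vs_complete"
    out[[length(out) + 1L]] <- .rec(txt, "distractor", subcategory = sub)
  }
  if (runif(1) < config$p_discussion) {
    out[[length(out) + 1L]] <- .rec(
      .fill_template(sample(tpl$discussion, 1L),
                     concept = sample(.distractor_concepts, 1L)),
      "distractor", subcategory = "discussion_vs_real")
  }
  if (runif(1) < config$p_planned) {
    out[[length(out) + 1L]] <- .rec(
      .fill_template(sample(tpl$planned, 1L),
                     concept = sample(.distractor_concepts, 1L)),
      "distractor", subcategory = "planned_vs_real")
  }
  out
}

# ---- note rendering ------------------------------------------------------

#' Render the clinical notes of one synthetic patient
#'
#' Emits a dated dossier from the template bank: every procedure gets an
#' anchor note shortly after it, later notes restate earlier surgeries with
#' probability `p_mention`, and distractor sentences, copy-paste-propagated
#' false claims, typos and laterality flips are injected at the configured
#' rates. Each unilateral oophorectomy is phrased consistently across its
#' mentions (either always with its side or always unsided), as one
#' documentation trail would be. Every injected distortion is appended to
#' the noise ledger with its discrepancy-taxonomy subcategory.
#'
#' @param truth A `patient_truth` from [sample_patient_truth()].
#' @param config A [sim_config()].
#' @param seed Optional explicit seed (defaults to the patient's derived
#'   stream).
#' @return A list with `notes` (notes tibble), `sentences` (per-sentence
#'   bookkeeping: which note documents which procedure, with corruption
#'   flags) and `ledger` (tibble of `patient_id`, `subcategory`, `note_id`).
#' @export
render_notes <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "patient_truth"), inherits(config, "sim_config"))
  seed <- seed %||% .patient_seed(config$seed, truth$index, 1L)
  set.seed(seed)
  tpl <- load_templates()
  fu <- truth$followup_date
  win_start <- fu - round(config$note_window_years * 365.25)
  tl <- truth$timeline
  proc_ids <- unique(tl$procedure_id)
  side_required <- sum(tl$type == "oophorectomy") >= 2L

  # sticky phrasing per unilateral oophorectomy procedure
  ooph_phrasing <- list()
  for (id in proc_ids) {
    rows <- tl[tl$procedure_id == id, ]
    if (any(rows$type == "oophorectomy")) {
      side <- rows$laterality[rows$type == "oophorectomy"][1L]
      ooph_phrasing[[as.character(id)]] <-
        if (side_required || runif(1) < 0.75) side else "unspecified"
    }
  }

  n_bg <- rpois(1L, config$notes_per_patient_mean)
  if (!length(proc_ids) && n_bg == 0L) n_bg <- 1L

  n_anchor <- length(proc_ids)
  note_dates <- as.Date(numeric(0), origin = "1970-01-01")
  note_anchor <- integer(0)
  for (id in proc_ids) {
    pd <- tl$date[tl$procedure_id == id][1L]
    ad <- min(max(pd + round(runif(1, 0, 180)), pd, win_start), fu)
    note_dates <- c(note_dates, ad)
    note_anchor <- c(note_anchor, id)
  }
  if (n_bg > 0L) {
    bg <- win_start + round(runif(n_bg, 0, as.numeric(fu - win_start)))
    note_dates <- c(note_dates, as.Date(bg, origin = "1970-01-01"))
    note_anchor <- c(note_anchor, rep(NA_integer_, n_bg))
  }
  ord <- order(note_dates)
  note_dates <- note_dates[ord]
  note_anchor <- note_anchor[ord]
  n_notes <- length(note_dates)

  false_claim <- NULL
  if (runif(1) < config$p_copy_paste_error) {
    ev <- tibble(concept = tl$type, laterality = tl$laterality, valid = TRUE)
    extent <- resolve_oophorectomy_extent(apply_default_laterality(ev))
    has_hyst <- any(tl$type == "hysterectomy")
    claim <- if (extent != "bilateral") {
      .fill_template(sample(tpl$bso_pos, 1L), date_phrase = "")
    } else if (!has_hyst) {
      .fill_template(sample(tpl$hyst_pos, 1L), date_phrase = "")
    } else NULL
    if (!is.null(claim)) false_claim <- claim
  }
  claim_notes <- if (!is.null(false_claim) && n_notes) {
    sample(seq_len(n_notes), min(2L, n_notes))
  } else integer(0)

  all_recs <- list(); all_rec_notes <- character(0)
  note_ids <- character(n_notes); note_types <- character(n_notes)
  note_texts <- character(n_notes)

  for (ni in seq_len(n_notes)) {
    note_id <- sprintf("%s-N%02d", truth$patient_id, ni)
    anchor <- note_anchor[ni]
    note_types[ni] <- if (!is.na(anchor)) {
      sample(c("clinical_note", "operative_report"), 1L, prob = c(0.7, 0.3))
    } else "clinical_note"
    unsectioned <- runif(1) < config$p_unsectioned_note

    recs <- list()
    if (!is.na(anchor)) {
      recs <- c(recs, .render_procedure(
        tl[tl$procedure_id == anchor, , drop = FALSE],
        ooph_phrasing, config, tpl))
    }
    for (id in proc_ids) {
      if (!is.na(anchor) && id == anchor) next
      if (tl$date[tl$procedure_id == id][1L] < note_dates[ni] &&
          runif(1) < config$p_mention) {
        recs <- c(recs, .render_procedure(
          tl[tl$procedure_id == id, , drop = FALSE],
          ooph_phrasing, config, tpl))
      }
    }
    if (ni %in% claim_notes) {
      recs <- c(recs, list(.rec(
        false_claim, "false_claim",
        subcategory = if (ni == claim_notes[1L]) "correction_over_time"
        else NA_character_)))
    }
    recs <- c(recs, .render_distractors(config, tpl,
                                        allow_family_section = !unsectioned))
    n_fill <- 1L + rpois(1L, 2)
    fillers <- sample(tpl$filler, min(n_fill, length(tpl$filler)))
    recs <- c(recs, lapply(fillers, function(s) .rec(s, "filler")))

    texts <- vapply(recs, `[[`, character(1), "text")
    kinds <- vapply(recs, `[[`, character(1), "kind")
    fams <- vapply(recs, `[[`, logical(1), "fam_section")
    surg_txt <- unique(texts[kinds %in% c("surgery", "false_claim")])
    fam_txt <- unique(texts[fams])
    other_txt <- unique(texts[!fams & !kinds %in% c("surgery", "false_claim")])
    if (unsectioned) {
      body <- paste(c(other_txt, surg_txt), collapse = "\n")
    } else {
      parts <- character(0)
      if (length(other_txt)) {
        parts <- c(parts, paste0("HISTORY OF PRESENT ILLNESS:\n",
                                 paste(other_txt, collapse = "\n")))
      }
      if (length(surg_txt)) {
        parts <- c(parts, paste0("PAST SURGICAL HISTORY:\n",
                                 paste(surg_txt, collapse = "\n")))
      }
      if (length(fam_txt)) {
        parts <- c(parts, paste0("FAMILY HISTORY:\n",
                                 paste(fam_txt, collapse = "\n")))
      }
      body <- paste(parts, collapse = "\n")
    }
    note_ids[ni] <- note_id
    note_texts[ni] <- body
    all_recs <- c(all_recs, recs)
    all_rec_notes <- c(all_rec_notes, rep(note_id, length(recs)))
  }

  notes <- tibble(patient_id = rep(truth$patient_id, n_notes),
                  note_id = note_ids, note_date = note_dates,
                  note_type = note_types, text = note_texts)
  sentences <- if (length(all_recs)) {
    .recs_to_tibble(all_recs, all_rec_notes)
  } else .empty_sentences()
  led_idx <- which(!is.na(sentences$subcategory))
  ledger <- if (length(led_idx)) {
    tibble(patient_id = truth$patient_id,
           subcategory = sentences$subcategory[led_idx],
           note_id = sentences$note_id[led_idx])
  } else .empty_ledger()
  list(notes = notes, sentences = sentences, ledger = ledger)
}

.empty_ledger <- function() {
  tibble(patient_id = character(), subcategory = character(),
         note_id = character())
}

# recoverable status given the surviving, uncorrupted genuine surgery
# sentences (false claims and corrupted sentences excluded)
.recoverable_status <- function(sentences, surviving_note_ids, followup_date) {
  facts <- sentences[sentences$kind == "surgery" & !sentences$corrupted &
                       sentences$note_id %in% surviving_note_ids, ,
                     drop = FALSE]
  if (!nrow(facts)) return("no_surgery")
  ev <- tibble(concept = facts$fact_type, laterality = facts$fact_lat,
               note_date = rep(followup_date, nrow(facts)),
               event_date = as.Date(NA), valid = TRUE)
  aggregate_patient(ev, followup_date)
}

#' Inject external information gaps
#'
#' Emulates care received outside the institution and care predating the
#' EHR: with probability `p_drop_surgery_note` per surgery, every note
#' documenting that surgery is removed; with probability
#' `p_pre_ehr_truncation` per patient, all notes before `ehr_start_year` are
#' removed. Patients never end up with zero notes (a filler-only visit note
#' at follow-up replaces a fully emptied dossier). Returns the expected
#' discrepancy labels (`mayo_missing` when the recoverable status collapses
#' to no surgery, `mayo_partial` when it changes otherwise) for patients
#' whose recoverable status changed.
#'
#' @param rendered The list returned by [render_notes()].
#' @param truth The matching `patient_truth`.
#' @param config A [sim_config()].
#' @param seed Optional explicit seed.
#' @return A list with `notes` (surviving notes), `gap_labels` (ledger rows)
#'   and `dropped_note_ids`.
#' @export
inject_external_gaps <- function(rendered, truth, config, seed = NULL) {
  seed <- seed %||% .patient_seed(config$seed, truth$index, 2L)
  set.seed(seed)
  notes <- rendered$notes
  sentences <- rendered$sentences
  tl <- truth$timeline
  proc_ids <- unique(tl$procedure_id)
  drop_notes <- character(0)
  if (length(proc_ids) && config$p_drop_surgery_note > 0) {
    dropped <- proc_ids[runif(length(proc_ids)) < config$p_drop_surgery_note]
    if (length(dropped)) {
      drop_notes <- unique(sentences$note_id[
        sentences$kind == "surgery" & sentences$procedure_id %in% dropped
      ])
    }
  }
  if (config$p_pre_ehr_truncation > 0 && runif(1) < config$p_pre_ehr_truncation) {
    old <- notes$note_id[as.integer(format(notes$note_date, "%Y")) <
                           config$ehr_start_year]
    drop_notes <- unique(c(drop_notes, old))
  }
  r0 <- .recoverable_status(sentences, notes$note_id, truth$followup_date)
  surviving <- setdiff(notes$note_id, drop_notes)
  r1 <- .recoverable_status(sentences, surviving, truth$followup_date)
  out_notes <- notes[notes$note_id %in% surviving, , drop = FALSE]
  if (!nrow(out_notes)) {
    out_notes <- tibble(patient_id = truth$patient_id,
                        note_id = sprintf("%s-NF", truth$patient_id),
                        note_date = truth$followup_date,
                        note_type = "clinical_note",
                        text = "Annual examination unremarkable.")
  }
  gap_labels <- if (!identical(r1, r0)) {
    tibble(patient_id = truth$patient_id,
           subcategory = if (r1 == "no_surgery") "mayo_missing" else "mayo_partial",
           note_id = NA_character_)
  } else .empty_ledger()
  list(notes = out_notes, gap_labels = gap_labels,
       dropped_note_ids = drop_notes)
}

#' Generate a synthetic EHR corpus
#'
#' Draws `n_patients` ground-truth surgical histories, renders their note
#' dossiers with the configured noise, and injects external information
#' gaps. Fully seeded and reproducible: the same configuration (including
#' `seed`) yields byte-identical output, and per-patient substreams keep
#' early patients stable when `n_patients` changes.
#'
#' @param config A [sim_config()].
#' @return A `surg_corpus` list: `notes` (all notes), `gold` (`patient_id`,
#'   `true_status`, `followup_date`), `ledger` (`patient_id`, `subcategory`,
#'   `note_id`) and the `config`.
#' @examples
#' corpus <- generate_corpus(sim_config(n_patients = 5, seed = 42))
#' corpus$gold
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  notes <- vector("list", n); gold <- vector("list", n)
  ledger <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- sample_patient_truth(config, i)
    rend <- render_notes(truth, config)
    gap <- inject_external_gaps(rend, truth, config)
    notes[[i]] <- gap$notes
    ledger[[i]] <- dplyr::bind_rows(rend$ledger, gap$gap_labels)
    gold[[i]] <- list(patient_id = truth$patient_id,
                      true_status = truth$status,
                      followup_date = truth$followup_date)
  }
  empty_notes <- tibble(patient_id = character(), note_id = character(),
                        note_date = as.Date(character()),
                        note_type = character(), text = character())
  gold_tbl <- if (n) {
    tibble(
      patient_id = vapply(gold, `[[`, character(1), "patient_id"),
      true_status = vapply(gold, `[[`, character(1), "true_status"),
      followup_date = as.Date(vapply(gold, function(g)
        as.numeric(g$followup_date), numeric(1)), origin = "1970-01-01")
    )
  } else {
    tibble(patient_id = character(), true_status = character(),
           followup_date = as.Date(character()))
  }
  structure(list(
    notes = if (n) dplyr::bind_rows(notes) else empty_notes,
    gold = gold_tbl,
    ledger = if (n) dplyr::bind_rows(ledger) else .empty_ledger(),
    config = config
  ), class = "surg_corpus")
}

#' Write a corpus to disk
#'
#' Writes `notes.jsonl` (JSON lines, one note per line), `gold.csv` and
#' `ledger.csv` into `dir`. Identical corpora write byte-identical files.
#'
#' @param corpus A `surg_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "surg_corpus"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir),
                   class = "gsn_config_error")
  }
  paths <- c(notes = file.path(dir, "notes.jsonl"),
             gold = file.path(dir, "gold.csv"),
             ledger = file.path(dir, "ledger.csv"))
  write_notes_jsonl(corpus$notes, paths[["notes"]])
  readr::write_csv(corpus$gold, paths[["gold"]])
  readr::write_csv(corpus$ledger, paths[["ledger"]])
  invisible(paths)
}

#' Run the extraction and aggregation pipeline over a notes table
#'
#' Convenience wrapper: extract events from all notes, then aggregate one
#' status per patient in the follow-up table.
#'
#' @param notes A notes tibble.
#' @param followup A tibble with `patient_id`, `followup_date`.
#' @param config An [nlp_config()].
#' @param mode Aggregation mode (see [aggregate_patient()]).
#' @return The status tibble from [aggregate_statuses()].
#' @export
run_pipeline <- function(notes, followup, config = nlp_config(),
                         mode = c("faithful", "evidence")) {
  mode <- match.arg(mode)
  events <- extract_corpus(notes, config)
  aggregate_statuses(events, followup, mode = mode)
}

#' Evaluate the pipeline on a synthetic corpus
#'
#' Runs [run_pipeline()] on a generated corpus and scores the predictions
#' against the corpus gold labels.
#'
#' @param corpus A `surg_corpus`.
#' @param config An [nlp_config()].
#' @param mode Aggregation mode.
#' @return A list with `statuses` (per-patient predictions joined to gold)
#'   and `eval` (a `surg_eval`).
#' @export
evaluate_corpus <- function(corpus, config = nlp_config(),
                            mode = c("faithful", "evidence")) {
  mode <- match.arg(mode)
  st <- run_pipeline(corpus$notes,
                     corpus$gold[, c("patient_id", "followup_date")],
                     config, mode)
  joined <- dplyr::inner_join(corpus$gold[, c("patient_id", "true_status")],
                              st, by = "patient_id")
  list(statuses = joined,
       eval = evaluate_statuses(joined, gold = "true_status",
                                pred = "predicted_status"))
}
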