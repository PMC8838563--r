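# ---- fixtures -------------------------------------------------------------

worked_sentence <- paste(
  "A total abdominal hysterectomy with bilateral salpingo-oophorectomy",
  "was performed the usual fashion."
)

make_note <- function(text, patient_id = "p1", note_id = "n1",
                      note_date = "2010-06-01", note_type = "clinical_note") {
  tibble::tibble(patient_id = patient_id, note_id = note_id,
                 note_date = as.Date(note_date), note_type = note_type,
                 text = text)
}

# events row builder for resolver tests
make_event <- function(concept, laterality = NA_character_,
                       note_date = "2005-01-01", event_date = NA,
                       note_type = "clinical_note", valid = TRUE) {
  tibble::tibble(concept = concept, laterality = laterality,
                 note_date = as.Date(note_date),
                 event_date = as.Date(event_date),
                 note_type = note_type, valid = valid)
}

# simulation config with all noise processes switched off; named arguments
# in ... override the zeros
noise_free_config <- function(n_patients, seed, ...) {
  args <- list(n_patients = n_patients, seed = seed,
               p_drop_surgery_note = 0, p_pre_ehr_truncation = 0,
               p_negation_sentence = 0, p_family_mention = 0, p_confusable = 0,
               p_discussion = 0, p_planned = 0, p_copy_paste_error = 0,
               p_typo = 0, p_laterality_flip = 0)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# ---- independent metric oracles (brute-force, used only as references) ----

oracle_prf <- function(m) {
  k <- nrow(m)
  res <- matrix(0, k, 3, dimnames = list(rownames(m),
                                         c("precision", "recall", "f1")))
  for (c in seq_len(k)) {
    tp <- 0; fp <- 0; fn <- 0
    for (g in seq_len(k)) {
      for (p in seq_len(k)) {
        if (g == c && p == c) tp <- tp + m[g, p]
        if (g != c && p == c) fp <- fp + m[g, p]
        if (g == c && p != c) fn <- fn + m[g, p]
      }
    }
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    res[c, ] <- c(pr, rc, f1)
  }
  res
}

oracle_kappa <- function(m) {
  n <- sum(m)
  po <- 0
  for (i in seq_len(nrow(m))) po <- po + m[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(m))) {
    ri <- 0; ci <- 0
    for (j in seq_len(ncol(m))) {
      ri <- ri + m[i, j]
      ci <- ci + m[j, i]
    }
    pe <- pe + ri * ci
  }
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

random_cm <- function() {
  m <- matrix(rpois(36, 4), 6, 6)
  dimnames(m) <- list(surgery_status_levels(), surgery_status_levels())
  # avoid degenerate all-zero matrices
  if (sum(m) == 0) m[1, 1] <- 1L
  storage.mode(m) <- "integer"
  structure(m, class = c("surg_confusion", "matrix"))
}

# ovary-set oracle for the aggregation truth table: tracks which ovaries a
# subset of events removes, independently of the extent-rule implementation
oracle_status <- function(events) {
  removed <- character(0)
  has_hyst <- FALSE
  for (i in seq_len(nrow(events))) {
    concept <- events$concept[i]
    lat <- events$laterality[i]
    if (concept %in% c("hysterectomy", "hysterectomy_bso_combined")) {
      has_hyst <- TRUE
    }
    if (concept %in% c("bilateral_oophorectomy", "hysterectomy_bso_combined")) {
      removed <- c("left", "right")
    } else if (concept == "oophorectomy") {
      side <- if (is.na(lat) || lat == "unspecified") "left" else lat
      if (side == "bilateral") removed <- c("left", "right")
      else removed <- union(removed, side)
    }
  }
  extent <- if (setequal(removed, c("left", "right"))) "bilateral"
  else if (length(removed)) "unilateral" else "none"
  if (extent == "bilateral" && has_hyst) "hyst_and_bilateral_ooph"
  else if (extent == "bilateral") "bilateral_ooph_only"
  else if (extent == "unilateral" && has_hyst) "hyst_and_unilateral_ooph"
  else if (extent == "unilateral") "unilateral_ooph_only"
  else if (has_hyst) "hyst_only"
  else "no_surgery"
}

# all lexicon surface patterns as plain strings (the synthetic sentence bank)
lexicon_surfaces <- function() {
  raw <- yaml::read_yaml(system.file("extdata", "lexicon.yaml",
                                     package = "gynsurgnlp"))
  unlist(lapply(raw$concepts, function(x) x$patterns), use.names = FALSE)
}
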