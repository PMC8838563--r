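test_that("invalid probabilities are rejected before generation", {
  expect_error(sim_config(p_typo = 1.2), class = "gsn_config_error")
  expect_error(sim_config(p_drop_surgery_note = -0.1),
               class = "gsn_config_error")
  expect_error(sim_config(class_probs = c(no_surgery = 1)),
               class = "gsn_config_error")
})

test_that("sampled truths realize their target status", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  for (i in 1:300) {
    truth <- sample_patient_truth(cfg, i)
    expect_equal(status_from_timeline(truth), truth$status,
                 info = paste("patient", i))
    tl <- truth$timeline
    if (nrow(tl)) {
      expect_true(all(tl$date < truth$followup_date))
      # no second removal of an already-removed ovary
      sides <- tl$laterality[tl$type == "oophorectomy"]
      expect_equal(anyDuplicated(sides), 0L)
      if (any(tl$type == "bilateral_oophorectomy")) {
        expect_equal(sum(tl$type == "oophorectomy"), 0L)
      }
    } else {
      expect_equal(truth$status, "no_surgery")
    }
  }
})

test_that("status frequencies follow the configured class distribution", {
  cfg <- sim_config(n_patients = 1, seed = 12)
  n <- 10000
  draws <- vapply(seq_len(n), function(i) sample_patient_truth(cfg, i)$status,
                  character(1))
  tab <- table(factor(draws, surgery_status_levels()))
  for (cls in surgery_status_levels()) {
    p <- cfg$class_probs[[cls]]
    expect_lt(abs(tab[[cls]] - n * p), 3 * sqrt(n * p * (1 - p)) + 1,
              label = paste("count deviation for", cls))
  }
})

test_that("noiseless rendering recovers the truth exactly", {
  cfg <- noise_free_config(1, seed = 8)
  for (i in c(2, 5, 9, 14)) {
    truth <- sample_patient_truth(cfg, i)
    rend <- render_notes(truth, cfg)
    ev <- extract_corpus(rend$notes)
    st <- aggregate_patient(ev[ev$valid & ev$note_date <= truth$followup_date, ],
                            truth$followup_date)
    expect_equal(st, truth$status, info = paste("patient", i))
    expect_equal(nrow(rend$ledger), 0L)
  }
})

test_that("forced laterality flips are rendered and ledgered", {
  cfg <- sim_config(n_patients = 1, seed = 21, p_laterality_flip = 1,
                    p_drop_surgery_note = 0, p_pre_ehr_truncation = 0,
                    p_negation_sentence = 0, p_family_mention = 0,
                    p_confusable = 0, p_discussion = 0, p_planned = 0,
                    p_copy_paste_error = 0, p_typo = 0)
  found <- FALSE
  for (i in 1:40) {
    truth <- sample_patient_truth(cfg, i)
    if (!any(truth$timeline$type == "oophorectomy")) next
    rend <- render_notes(truth, cfg)
    sided <- rend$sentences[rend$sentences$kind == "surgery" &
                              !is.na(rend$sentences$fact_lat) &
                              rend$sentences$fact_lat %in% c("left", "right"), ]
    if (!nrow(sided)) next  # unsided phrasing drawn for this patient
    found <- TRUE
    expect_true(all(sided$corrupted))
    expect_true("incorrect_laterality" %in% rend$ledger$subcategory)
    # rendered side contradicts the documented fact
    for (k in seq_len(nrow(sided))) {
      opposite <- setdiff(c("left", "right"), sided$fact_lat[k])
      expect_match(tolower(sided$text[k]), opposite)
    }
  }
  expect_true(found)
})

test_that("a saturated negation corpus still classifies no-surgery patients", {
  cfg <- sim_config(n_patients = 30, seed = 31,
                    class_probs = c(no_surgery = 1, bilateral_ooph_only = 0,
                                    hyst_and_bilateral_ooph = 0,
                                    unilateral_ooph_only = 0,
                                    hyst_and_unilateral_ooph = 0,
                                    hyst_only = 0),
                    p_negation_sentence = 1, p_drop_surgery_note = 0,
                    p_pre_ehr_truncation = 0, p_family_mention = 0,
                    p_confusable = 0, p_discussion = 0, p_planned = 0,
                    p_copy_paste_error = 0, p_typo = 0, p_laterality_flip = 0)
  corp <- generate_corpus(cfg)
  # negated mentions are present in the text but never become valid events
  expect_true(any(grepl("(?i)no history|denies|never had|no prior",
                        corp$notes$text, perl = TRUE)))
  res <- evaluate_corpus(corp)
  expect_true(all(res$statuses$predicted_status == "no_surgery"))
})

test_that("external gaps drop whole surgeries and label the ledger", {
  cfg <- sim_config(n_patients = 1, seed = 41, p_drop_surgery_note = 1,
                    p_pre_ehr_truncation = 0, p_negation_sentence = 0,
                    p_family_mention = 0, p_confusable = 0, p_discussion = 0,
                    p_planned = 0, p_copy_paste_error = 0, p_typo = 0,
                    p_laterality_flip = 0)
  found_missing <- FALSE
  for (i in 1:30) {
    truth <- sample_patient_truth(cfg, i)
    if (truth$status == "no_surgery") next
    rend <- render_notes(truth, cfg)
    gap <- inject_external_gaps(rend, truth, cfg)
    # all surgery documentation removed -> recoverable status collapses
    expect_equal(gap$gap_labels$subcategory, "mayo_missing")
    surviving_ev <- extract_corpus(gap$notes)
    st <- aggregate_patient(
      surviving_ev[surviving_ev$valid &
                     surviving_ev$note_date <= truth$followup_date, ],
      truth$followup_date
    )
    expect_equal(st, "no_surgery")
    found_missing <- TRUE
  }
  expect_true(found_missing)

  # with both rates zero the notes pass through untouched
  cfg0 <- noise_free_config(1, seed = 42)
  truth <- sample_patient_truth(cfg0, 3)
  rend <- render_notes(truth, cfg0)
  gap <- inject_external_gaps(rend, truth, cfg0)
  expect_identical(gap$notes, rend$notes)
  expect_equal(nrow(gap$gap_labels), 0L)
})

test_that("dropping only one staged unilateral yields a partial gap", {
  cfg <- noise_free_config(
    1, seed = 55,
    class_probs = c(no_surgery = 0, bilateral_ooph_only = 1,
                    hyst_and_bilateral_ooph = 0, unilateral_ooph_only = 0,
                    hyst_and_unilateral_ooph = 0, hyst_only = 0)
  )
  # find a staged (two-date) bilateral-only truth whose second surgery keeps
  # documentation of its own once notes about the first surgery are removed
  truth <- NULL; rend <- NULL; drop_ids <- NULL
  for (i in 1:100) {
    t <- sample_patient_truth(cfg, i)
    if (sum(t$timeline$type == "oophorectomy") != 2) next
    r <- render_notes(t, cfg)
    s <- r$sentences[r$sentences$kind == "surgery", ]
    p1 <- t$timeline$procedure_id[1]
    p2 <- t$timeline$procedure_id[2]
    notes_p1 <- unique(s$note_id[s$procedure_id == p1])
    notes_p2 <- unique(s$note_id[s$procedure_id == p2])
    if (!length(setdiff(notes_p2, notes_p1))) next
    truth <- t; rend <- r
    drop_ids <- setdiff(notes_p1, notes_p2)
    break
  }
  expect_false(is.null(truth))
  surviving <- setdiff(rend$notes$note_id, drop_ids)
  notes_left <- rend$notes[rend$notes$note_id %in% surviving, ]
  ev <- extract_corpus(notes_left)
  st <- aggregate_patient(ev[ev$valid & ev$note_date <= truth$followup_date, ],
                          truth$followup_date)
  expect_equal(st, "unilateral_ooph_only")
})

test_that("corpus generation is deterministic and writes identical files", {
  cfg <- sim_config(n_patients = 12, seed = 77)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$gold, c2$gold)
  expect_identical(c1$ledger, c2$ledger)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(c1, d1)
  write_corpus(c2, d2)
  for (f in c("notes.jsonl", "gold.csv", "ledger.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("an empty corpus round-trips through files", {
  cfg <- sim_config(n_patients = 0, seed = 1)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$notes), 0L)
  expect_equal(nrow(corp$gold), 0L)
  d <- withr::local_tempdir()
  write_corpus(corp, d)
  notes <- read_notes_jsonl(file.path(d, "notes.jsonl"))
  expect_equal(nrow(notes), 0L)
})

test_that("every truth-prediction mismatch is explained by the ledger", {
  cfg <- sim_config(n_patients = 120, seed = 88)  # default noise rates
  corp <- generate_corpus(cfg)
  res <- evaluate_corpus(corp)
  bad <- res$statuses$patient_id[res$statuses$true_status !=
                                   res$statuses$predicted_status]
  for (pid in bad) {
    expect_true(pid %in% corp$ledger$patient_id,
                label = paste("ledger entry for mismatched patient", pid))
  }
})

test_that("notes JSONL round-trips and skips malformed lines", {
  corp <- generate_corpus(sim_config(n_patients = 4, seed = 9))
  d <- withr::local_tempdir()
  p <- file.path(d, "notes.jsonl")
  write_notes_jsonl(corp$notes, p)
  lines <- readLines(p)
  lines <- append(lines, "this is { not json", after = 2)
  writeLines(lines, p)
  back <- suppressMessages(read_notes_jsonl(p))
  expect_equal(nrow(back), nrow(corp$notes))
  expect_equal(attr(back, "n_skipped"), 1L)
  expect_equal(back$text, corp$notes$text)
})
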