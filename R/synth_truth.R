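#' Simulation configuration for the synthetic EHR generator
#'
#' Defines the study conditions the generator emulates: the marginal
#' distribution of the six surgery statuses (defaulting to the proportions of
#' the full reference cohort), the 1997--2019 follow-up window, the mixture
#' of distinct surgery-date counts per surgical patient (86.3% one date,
#' 12.7% two, 1% three), and the rates of the documented information-gap
#' noise processes: external gaps (care documented elsewhere or predating the
#' EHR), internal gaps (copy-paste propagation, typos, flipped laterality)
#' and the distractor contexts that stress the extraction rules (negation,
#' family history, hysteroscopy/biopsy confusables, discussed or planned
#' surgery).
#'
#' All probabilities must lie in `[0, 1]`; the class distribution is
#' normalized to sum to 1.
#'
#' @param n_patients Number of synthetic patients.
#' @param class_probs Named probabilities over [surgery_status_levels()].
#' @param followup_start,followup_end Bounds of the follow-up date window.
#' @param surgery_lookback_years Surgeries occur up to this many years before
#'   follow-up (and at least one year before).
#' @param note_window_years Notes span this many years before follow-up.
#' @param notes_per_patient_mean Poisson mean for background (non-anchor)
#'   notes per patient.
#' @param n_surgery_dates_probs Mixture over 1, 2 or 3 distinct surgery
#'   dates for surgical patients (restricted to what the drawn status
#'   permits).
#' @param p_mention Probability that a later note restates an earlier
#'   surgery.
#' @param p_date_attach Probability that a surgery sentence carries a date.
#' @param date_format_probs Mixture over the three date renderings: full
#'   slash date, 2-digit-year slash date, bare year.
#' @param date_dialect `"mdy"` or `"dmy"` for rendering slash dates.
#' @param p_drop_surgery_note Per-surgery probability that every note
#'   documenting it is removed (external-institution care).
#' @param p_pre_ehr_truncation Per-patient probability that notes before
#'   `ehr_start_year` are removed.
#' @param ehr_start_year First year of the emulated EHR.
#' @param p_negation_sentence,p_family_mention,p_confusable,p_discussion,p_planned
#'   Per-note distractor sentence rates.
#' @param p_copy_paste_error Per-patient probability of a false surgery claim
#'   propagated across notes.
#' @param p_typo Per-surgery-sentence probability of a concept-word typo.
#' @param p_laterality_flip Per-side-bearing-sentence probability that the
#'   side word is flipped.
#' @param p_unsectioned_note Probability that a note has no section headers.
#' @param seed Master seed; per-patient streams are derived from it so
#'   corpora are stable under changes of `n_patients`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L,
                       class_probs = c(no_surgery = 1473,
                                       bilateral_ooph_only = 35,
                                       hyst_and_bilateral_ooph = 1685,
                                       unilateral_ooph_only = 214,
                                       hyst_and_unilateral_ooph = 247,
                                       hyst_only = 216) / 3870,
                       followup_start = "1997-01-01",
                       followup_end = "2019-08-31",
                       surgery_lookback_years = 30,
                       note_window_years = 25,
                       notes_per_patient_mean = 6,
                       n_surgery_dates_probs = c(0.863, 0.127, 0.010),
                       p_mention = 0.25,
                       p_date_attach = 0.62,
                       date_format_probs = c(full = 0.4, short = 0.2, year = 0.4),
                       date_dialect = c("mdy", "dmy"),
                       p_drop_surgery_note = 0.05,
                       p_pre_ehr_truncation = 0.02,
                       ehr_start_year = 1997L,
                       p_negation_sentence = 0.10,
                       p_family_mention = 0.05,
                       p_confusable = 0.05,
                       p_discussion = 0.05,
                       p_planned = 0.02,
                       p_copy_paste_error = 0.01,
                       p_typo = 0.01,
                       p_laterality_flip = 0.01,
                       p_unsectioned_note = 0.2,
                       seed = 1L) {
  date_dialect <- match.arg(date_dialect)
  probs <- c(p_mention = p_mention, p_date_attach = p_date_attach,
             p_drop_surgery_note = p_drop_surgery_note,
             p_pre_ehr_truncation = p_pre_ehr_truncation,
             p_negation_sentence = p_negation_sentence,
             p_family_mention = p_family_mention,
             p_confusable = p_confusable, p_discussion = p_discussion,
             p_planned = p_planned, p_copy_paste_error = p_copy_paste_error,
             p_typo = p_typo, p_laterality_flip = p_laterality_flip,
             p_unsectioned_note = p_unsectioned_note)
  bad <- probs[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad)) {
    abort(paste0("probabilities outside [0, 1]: ",
                 paste(names(bad), collapse = ", ")),
          class = "gsn_config_error")
  }
  if (!setequal(names(class_probs), surgery_status_levels())) {
    abort("class_probs must be named with the six surgery statuses",
          class = "gsn_config_error")
  }
  if (any(class_probs < 0) || sum(class_probs) <= 0) {
    abort("class_probs must be non-negative with a positive sum",
          class = "gsn_config_error")
  }
  class_probs <- class_probs[surgery_status_levels()] / sum(class_probs)
  if (any(n_surgery_dates_probs < 0) || sum(n_surgery_dates_probs) <= 0 ||
      length(n_surgery_dates_probs) != 3L) {
    abort("n_surgery_dates_probs must be 3 non-negative values",
          class = "gsn_config_error")
  }
  n_surgery_dates_probs <- n_surgery_dates_probs / sum(n_surgery_dates_probs)
  if (length(date_format_probs) != 3L || any(date_format_probs < 0)) {
    abort("date_format_probs must be 3 non-negative values",
          class = "gsn_config_error")
  }
  date_format_probs <- date_format_probs / sum(date_format_probs)
  structure(list(
    n_patients = as.integer(n_patients),
    class_probs = class_probs,
    followup_start = as.Date(followup_start),
    followup_end = as.Date(followup_end),
    surgery_lookback_years = surgery_lookback_years,
    note_window_years = note_window_years,
    notes_per_patient_mean = notes_per_patient_mean,
    n_surgery_dates_probs = n_surgery_dates_probs,
    p_mention = p_mention, p_date_attach = p_date_attach,
    date_format_probs = date_format_probs, date_dialect = date_dialect,
    p_drop_surgery_note = p_drop_surgery_note,
    p_pre_ehr_truncation = p_pre_ehr_truncation,
    ehr_start_year = as.integer(ehr_start_year),
    p_negation_sentence = p_negation_sentence,
    p_family_mention = p_family_mention,
    p_confusable = p_confusable, p_discussion = p_discussion,
    p_planned = p_planned, p_copy_paste_error = p_copy_paste_error,
    p_typo = p_typo, p_laterality_flip = p_laterality_flip,
    p_unsectioned_note = p_unsectioned_note,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic per-patient, per-stage substream seed below 2^31
.patient_seed <- function(master, index, stage = 0L) {
  as.integer((as.numeric(master) %% 2147483647 + 1000003 * index +
                7907 * stage) %% 2147483646) + 1L
}

.multiplicity_feasible <- list(
  no_surgery = integer(0),
  hyst_only = 1L,
  unilateral_ooph_only = 1L,
  bilateral_ooph_only = c(1L, 2L),
  hyst_and_unilateral_ooph = c(1L, 2L),
  hyst_and_bilateral_ooph = c(1L, 2L, 3L)
)

#' Sample a ground-truth surgical history
#'
#' Draws a target status from the configured class distribution, then a
#' surgical timeline realizing it: the number of distinct surgery dates
#' follows the configured mixture restricted to what the status permits
#' (e.g. a staged bilateral oophorectomy needs two dates), dates precede the
#' follow-up date, and the timeline is internally consistent (an ovary is
#' never removed twice; a bilateral removal terminates the oophorectomy
#' sequence).
#'
#' @param config A [sim_config()].
#' @param index Patient index (drives the per-patient random stream).
#' @param seed Optional explicit seed overriding the derived stream.
#' @return A `patient_truth` list: `patient_id`, `index`, `status`,
#'   `followup_date` and a `timeline` tibble (`procedure_id`, `type`,
#'   `laterality`, `date`). Procedures sharing a date share a
#'   `procedure_id`, mirroring a single operation documented together.
#' @export
sample_patient_truth <- function(config, index = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% .patient_seed(config$seed, index, 0L)
  set.seed(seed)
  status <- sample(names(config$class_probs), 1L, prob = config$class_probs)
  span <- as.numeric(config$followup_end - config$followup_start)
  followup <- config$followup_start + round(runif(1, 0, span))
  feas <- .multiplicity_feasible[[status]]
  timeline <- tibble(procedure_id = integer(), type = character(),
                     laterality = character(), date = as.Date(character()))
  if (length(feas)) {
    p <- config$n_surgery_dates_probs[seq_along(feas)]
    m <- if (length(feas) == 1L) feas else sample(feas, 1L, prob = p / sum(p))
    dates <- sort(followup -
                    round(runif(m, 365, config$surgery_lookback_years * 365.25)))
    row <- function(id, type, lat) tibble(procedure_id = id, type = type,
                                          laterality = lat, date = dates[id])
    first_side <- sample(c("left", "right"), 1L)
    other_side <- setdiff(c("left", "right"), first_side)
    timeline <- switch(
      status,
      hyst_only = row(1L, "hysterectomy", NA_character_),
      unilateral_ooph_only = row(1L, "oophorectomy", first_side),
      bilateral_ooph_only = if (m == 1L) {
        row(1L, "bilateral_oophorectomy", "bilateral")
      } else {
        dplyr::bind_rows(row(1L, "oophorectomy", first_side),
                         row(2L, "oophorectomy", other_side))
      },
      hyst_and_unilateral_ooph = if (m == 1L) {
        dplyr::bind_rows(row(1L, "hysterectomy", NA_character_),
                         row(1L, "oophorectomy", first_side))
      } else {
        ord <- sample(1:2)
        dplyr::bind_rows(row(ord[1L], "hysterectomy", NA_character_),
                         row(ord[2L], "oophorectomy", first_side))
      },
      hyst_and_bilateral_ooph = if (m == 1L) {
        dplyr::bind_rows(row(1L, "hysterectomy", NA_character_),
                         row(1L, "bilateral_oophorectomy", "bilateral"))
      } else if (m == 2L) {
        ord <- sample(1:2)
        dplyr::bind_rows(row(ord[1L], "hysterectomy", NA_character_),
                         row(ord[2L], "bilateral_oophorectomy", "bilateral"))
      } else {
        hy <- sample(1:3, 1L)
        oo <- setdiff(1:3, hy)
        dplyr::bind_rows(row(hy, "hysterectomy", NA_character_),
                         row(oo[1L], "oophorectomy", first_side),
                         row(oo[2L], "oophorectomy", other_side))
      }
    )
    timeline <- dplyr::arrange(timeline, .data$procedure_id)
  }
  structure(list(patient_id = sprintf("P%05d", index), index = as.integer(index),
                 status = status, followup_date = followup,
                 timeline = timeline),
            class = "patient_truth")
}

#' Derive the status implied by a ground-truth timeline
#'
#' Feeds the timeline through the patient-level aggregation rules, providing
#' the consistency bridge between generator truths and the status resolver.
#'
#' @param truth A `patient_truth` from [sample_patient_truth()].
#' @return A status label.
#' @export
status_from_timeline <- function(truth) {
  tl <- truth$timeline
  if (!nrow(tl)) return("no_surgery")
  ev <- tibble(concept = tl$type, laterality = tl$laterality,
               note_date = rep(truth$followup_date, nrow(tl)),
               event_date = as.Date(NA), valid = TRUE)
  aggregate_patient(ev, truth$followup_date)
}
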