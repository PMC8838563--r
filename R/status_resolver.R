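#' Apply the default left-side laterality
#'
#' Oophorectomy events whose sentence carried no laterality cue are rewritten
#' to `"left"` during patient-level aggregation, so an undated, unsided
#' oophorectomy mention counts as a unilateral (left-side) oophorectomy.
#' All other events pass through unchanged.
#'
#' @param events A tibble of valid surgery events (see [extract_note()]).
#' @return The events tibble with `"unspecified"` oophorectomy laterality
#'   replaced by `"left"`.
#' @export
apply_default_laterality <- function(events) {
  if (!nrow(events)) return(events)
  # an all-NA laterality column read back from CSV arrives as logical
  events$laterality <- as.character(events$laterality)
  dplyr::mutate(
    events,
    laterality = dplyr::if_else(
      .data$concept == "oophorectomy" & !is.na(.data$laterality) &
        .data$laterality == "unspecified",
      "left", .data$laterality
    )
  )
}

#' Resolve a patient's oophorectomy extent
#'
#' Bilateral oophorectomy is the removal of both ovaries in one surgery or
#' the staged removal of the remaining ovary after a prior unilateral
#' oophorectomy. Accordingly: any explicitly bilateral event forces
#' `"bilateral"`; otherwise a side set of both `"left"` and `"right"` (two
#' staged unilaterals) is `"bilateral"`; a single documented side is
#' `"unilateral"`; no oophorectomy event is `"none"`. Duplicate events
#' collapse under set semantics, so copy-paste repetition has no effect.
#' Default laterality ([apply_default_laterality()]) is assumed to have been
#' applied.
#'
#' @param events A tibble of valid surgery events for one patient.
#' @return `"none"`, `"unilateral"` or `"bilateral"`.
#' @export
resolve_oophorectomy_extent <- function(events) {
  if (!nrow(events)) return("none")
  ooph <- events[!is.na(events$concept) & events$concept %in% .ooph_family(), ]
  if (!nrow(ooph)) return("none")
  if (any(ooph$concept %in% .bilateral_concepts()) ||
      any(!is.na(ooph$laterality) & ooph$laterality == "bilateral")) {
    return("bilateral")
  }
  sides <- intersect(unique(ooph$laterality), c("left", "right"))
  if (length(sides) == 2L) return("bilateral")
  if (length(sides) == 1L) return("unilateral")
  "none"
}

.status_from <- function(has_hyst, extent) {
  switch(extent,
         bilateral = if (has_hyst) "hyst_and_bilateral_ooph" else "bilateral_ooph_only",
         unilateral = if (has_hyst) "hyst_and_unilateral_ooph" else "unilateral_ooph_only",
         none = if (has_hyst) "hyst_only" else "no_surgery",
         abort(paste0("unknown extent: ", extent), class = "gsn_data_error"))
}

#' Aggregate one patient's events into a surgery status
#'
#' Crosses hysterectomy presence (any hysterectomy-family valid event,
#' including the combined TAH-BSO concept) with the oophorectomy extent to
#' yield one of the six mutually exclusive statuses. The result is invariant
#' under event reordering and duplication. Events dated after the follow-up
#' date signal unfiltered input and raise an error.
#'
#' @param events A tibble of valid surgery events for one patient (zero rows
#'   means no surgery). If a `valid` column is present, only valid rows are
#'   used.
#' @param followup_date The patient's follow-up date; the status is assigned
#'   as of this date.
#' @param mode `"faithful"` (default) unions all valid events, reproducing
#'   the documented behaviour in which a single bilateral mention forces
#'   bilateral status. `"evidence"` restricts conflicting oophorectomy
#'   evidence to the most authoritative source type present
#'   (operative > pathology > radiology > clinical note).
#' @return A single status label (see [surgery_status_levels()]).
#' @examples
#' aggregate_patient(tibble::tibble(
#'   concept = c("hysterectomy", "bilateral_oophorectomy"),
#'   laterality = c(NA, "bilateral"),
#'   note_date = as.Date(c("2001-01-01", "2001-01-01"))
#' ), followup_date = as.Date("2010-01-01"))
#' @export
aggregate_patient <- function(events, followup_date,
                              mode = c("faithful", "evidence")) {
  mode <- match.arg(mode)
  followup_date <- as.Date(followup_date)
  if (nrow(events)) {
    if ("valid" %in% names(events)) events <- events[events$valid, ]
  }
  if (nrow(events) && "note_date" %in% names(events)) {
    if (any(as.Date(events$note_date) > followup_date)) {
      abort("events with note_date after followup_date: filter the dossier first",
            class = "gsn_data_error")
    }
  }
  has_hyst <- nrow(events) > 0L && any(events$concept %in% .hyst_family())
  ev <- apply_default_laterality(events)
  if (mode == "evidence" && nrow(ev)) {
    rank <- c(operative_report = 1L, pathology_report = 2L,
              radiology_report = 3L, clinical_note = 4L)
    ooph_idx <- ev$concept %in% .ooph_family()
    if (any(ooph_idx) && "note_type" %in% names(ev)) {
      r <- rank[ev$note_type]
      r[is.na(r)] <- 4L
      best <- min(r[ooph_idx])
      ev <- ev[!ooph_idx | r == best, ]
    }
  }
  extent <- resolve_oophorectomy_extent(ev)
  .status_from(has_hyst, extent)
}

#' Aggregate statuses for a whole cohort
#'
#' Filters events to each patient's follow-up window (valid events with
#' `note_date <= followup_date`), aggregates per patient, and returns one row
#' per patient in the follow-up table. Patients with no valid events are
#' `"no_surgery"`.
#'
#' @param events A tibble of events from [extract_corpus()].
#' @param followup A tibble with `patient_id` and `followup_date` (one row
#'   per patient; duplicates are an error).
#' @inheritParams aggregate_patient
#' @return A tibble with `patient_id`, `followup_date`, `predicted_status`,
#'   `n_valid_events`, `earliest_event_date`, `latest_event_date`.
#' @export
aggregate_statuses <- function(events, followup,
                               mode = c("faithful", "evidence")) {
  mode <- match.arg(mode)
  if (anyDuplicated(followup$patient_id)) {
    abort("duplicate patient_id in followup table", class = "gsn_data_error")
  }
  followup <- dplyr::mutate(followup,
                            followup_date = as.Date(.data$followup_date))
  ev <- events
  if (nrow(ev)) {
    if ("valid" %in% names(ev)) ev <- ev[ev$valid, ]
    ev <- dplyr::inner_join(ev, followup[, c("patient_id", "followup_date")],
                            by = "patient_id")
    ev <- ev[as.Date(ev$note_date) <= ev$followup_date, ]
  }
  if (nrow(ev) && !"event_date" %in% names(ev)) {
    ev$event_date <- as.Date(NA)
  }
  if (nrow(ev)) {
    ev <- apply_default_laterality(ev)
    if (mode == "evidence") {
      per <- ev |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::group_modify(function(d, key) {
          st <- aggregate_patient(d, d$followup_date[1L], mode = "evidence")
          tibble(predicted_status = st,
                 n_valid_events = nrow(d),
                 earliest_event_date = .safe_min_date(d$event_date),
                 latest_event_date = .safe_max_date(d$event_date))
        }) |>
        dplyr::ungroup()
    } else {
      per <- ev |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(
          has_hyst = any(.data$concept %in% .hyst_family()),
          bilat = any(.data$concept %in% .bilateral_concepts()) |
            any(!is.na(.data$laterality) & .data$laterality == "bilateral"),
          has_l = any(!is.na(.data$laterality) & .data$laterality == "left" &
                        .data$concept %in% .ooph_family()),
          has_r = any(!is.na(.data$laterality) & .data$laterality == "right" &
                        .data$concept %in% .ooph_family()),
          n_valid_events = dplyr::n(),
          earliest_event_date = .safe_min_date(.data$event_date),
          latest_event_date = .safe_max_date(.data$event_date),
          .groups = "drop"
        ) |>
        dplyr::mutate(
          extent = dplyr::case_when(
            .data$bilat | (.data$has_l & .data$has_r) ~ "bilateral",
            .data$has_l | .data$has_r ~ "unilateral",
            TRUE ~ "none"
          ),
          predicted_status = dplyr::case_when(
            .data$extent == "bilateral" & .data$has_hyst ~ "hyst_and_bilateral_ooph",
            .data$extent == "bilateral" ~ "bilateral_ooph_only",
            .data$extent == "unilateral" & .data$has_hyst ~ "hyst_and_unilateral_ooph",
            .data$extent == "unilateral" ~ "unilateral_ooph_only",
            .data$has_hyst ~ "hyst_only",
            TRUE ~ "no_surgery"
          )
        ) |>
        dplyr::select("patient_id", "predicted_status", "n_valid_events",
                      "earliest_event_date", "latest_event_date")
    }
  } else {
    per <- tibble(patient_id = character(), predicted_status = character(),
                  n_valid_events = integer(),
                  earliest_event_date = as.Date(character()),
                  latest_event_date = as.Date(character()))
  }
  followup |>
    dplyr::left_join(per, by = "patient_id") |>
    dplyr::mutate(
      predicted_status = dplyr::coalesce(.data$predicted_status, "no_surgery"),
      n_valid_events = dplyr::coalesce(.data$n_valid_events, 0L)
    ) |>
    dplyr::select("patient_id", "followup_date", "predicted_status",
                  "n_valid_events", "earliest_event_date", "latest_event_date")
}

.safe_min_date <- function(x) {
  if (is.null(x)) return(as.Date(NA))
  x <- x[!is.na(x)]
  if (!length(x)) as.Date(NA) else min(x)
}
.safe_max_date <- function(x) {
  if (is.null(x)) return(as.Date(NA))
  x <- x[!is.na(x)]
  if (!length(x)) as.Date(NA) else max(x)
}
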