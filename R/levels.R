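#' Controlled vocabularies
#'
#' The closed vocabularies used throughout the pipeline: the six mutually
#' exclusive patient-level surgery statuses, the surgery concepts recognized
#' by the lexicon, the assertion (contextual certainty) labels, and the
#' laterality values. Statuses are exhaustive and mutually exclusive: every
#' patient receives exactly one as of her follow-up date.
#'
#' @return A character vector of level names, in canonical order.
#' @examples
#' surgery_status_levels()
#' @export
surgery_status_levels <- function() {
  c("no_surgery", "bilateral_ooph_only", "hyst_and_bilateral_ooph",
    "unilateral_ooph_only", "hyst_and_unilateral_ooph", "hyst_only")
}

#' @rdname surgery_status_levels
#' @export
concept_levels <- function() {
  c("hysterectomy", "oophorectomy", "bilateral_oophorectomy",
    "hysterectomy_bso_combined")
}

#' @rdname surgery_status_levels
#' @export
assertion_levels <- function() {
  c("positive", "negated", "hypothetical", "family", "planned")
}

#' @rdname surgery_status_levels
#' @export
laterality_levels <- function() {
  c("left", "right", "bilateral", "unspecified")
}

# concept families used by laterality and aggregation rules
.ooph_family <- function() {
  c("oophorectomy", "bilateral_oophorectomy", "hysterectomy_bso_combined")
}
.hyst_family <- function() {
  c("hysterectomy", "hysterectomy_bso_combined")
}
.bilateral_concepts <- function() {
  c("bilateral_oophorectomy", "hysterectomy_bso_combined")
}

.note_types <- function() {
  c("clinical_note", "pathology_report", "radiology_report", "operative_report")
}
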