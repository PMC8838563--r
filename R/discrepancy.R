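#' The discrepancy taxonomy
#'
#' The three-way taxonomy of reasons why an extracted surgery status can
#' disagree with a multi-institution gold standard: external information gaps
#' (the record simply lacks the history), internal information gaps
#' (inconsistent or inaccurate statements within the record) and technical
#' errors of the extraction algorithm itself.
#'
#' @return A tibble with columns `subcategory` and `category`
#'   (`"external"`, `"internal"`, `"technical"`).
#' @export
discrepancy_taxonomy <- function() {
  tibble(
    subcategory = c(
      "mayo_missing", "mayo_partial", "gold_missing", "gold_partial",
      "both_partial",
      "correction_over_time", "partial_vs_complete", "biopsy_vs_complete",
      "planned_vs_real", "hysterectomy_vs_hysteroscopy",
      "incorrect_laterality", "typo",
      "discussion_vs_real", "family_vs_patient", "complex_partial_expression",
      "complex_laterality_expression", "negated_as_positive",
      "positive_as_negated", "positive_as_hypothetical",
      "irrelevant_section_header", "unknown_keywords"
    ),
    category = c(rep("external", 5), rep("internal", 7), rep("technical", 9))
  )
}

#' Tabulate discrepancy records
#'
#' Counts analyst-supplied discrepancy labels by subcategory and category and
#' reports category shares of the total. Records may be one row per
#' discrepancy or pre-aggregated with an `n` column. A `category` column, if
#' present, is validated against the taxonomy and any inconsistent record is
#' an error naming the offender.
#'
#' @param records A data frame with a `subcategory` column (optionally `n`,
#'   `category`, `patient_id`).
#' @return A `discrepancy_summary` object with elements `by_subcategory`,
#'   `by_category` (shares in percent, 1 decimal place) and `total`.
#' @examples
#' counts <- readr::read_csv(
#'   system.file("extdata", "discrepancy_counts.csv", package = "gynsurgnlp"),
#'   show_col_types = FALSE
#' )
#' summarize_discrepancies(counts)
#' @export
summarize_discrepancies <- function(records) {
  tax <- discrepancy_taxonomy()
  if (nrow(records)) {
    bad <- which(!records$subcategory %in% tax$subcategory)
    if (length(bad)) {
      abort(paste0("unknown discrepancy subcategory in record ", bad[1L], ": ",
                   records$subcategory[bad[1L]]), class = "gsn_data_error")
    }
    if ("category" %in% names(records)) {
      expected <- tax$category[match(records$subcategory, tax$subcategory)]
      mism <- which(records$category != expected)
      if (length(mism)) {
        abort(paste0("record ", mism[1L], " (", records$subcategory[mism[1L]],
                     ") labelled ", records$category[mism[1L]],
                     " but taxonomy says ", expected[mism[1L]]),
              class = "gsn_data_error")
      }
    }
  }
  if (!"n" %in% names(records)) records$n <- rep(1L, nrow(records))
  counts <- records |>
    dplyr::group_by(.data$subcategory) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  by_sub <- tax |>
    dplyr::left_join(counts, by = "subcategory") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  total <- sum(by_sub$n)
  by_cat <- by_sub |>
    dplyr::group_by(category = factor(.data$category,
                                      c("external", "internal", "technical"))) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(category = as.character(.data$category),
                  share_pct = if (total > 0) round(100 * .data$n / total, 1)
                  else 0)
  structure(list(by_subcategory = by_sub, by_category = by_cat, total = total),
            class = "discrepancy_summary")
}

#' @export
print.discrepancy_summary <- function(x, ...) {
  cat("Discrepancy summary (", x$total, " discrepancies)\n\n", sep = "")
  print(as.data.frame(x$by_subcategory), row.names = FALSE)
  cat("\n")
  print(as.data.frame(x$by_category), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.discrepancy_summary <- function(x, ...) x$by_subcategory

#' @export
glance.discrepancy_summary <- function(x, ...) {
  bc <- setNames(x$by_category$n, x$by_category$category)
  sh <- setNames(x$by_category$share_pct, x$by_category$category)
  tibble(total = x$total,
         external = bc[["external"]], internal = bc[["internal"]],
         technical = bc[["technical"]],
         external_share_pct = sh[["external"]],
         internal_share_pct = sh[["internal"]],
         technical_share_pct = sh[["technical"]])
}
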