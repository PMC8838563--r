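#' Recovery ratio of a truncated record window
#'
#' The fraction of full-record extraction performance retained by a limited
#' record window: the weighted F1 obtained from the truncated records divided
#' by the weighted F1 obtained from all records.
#'
#' @param weighted_f1_k Weighted F1 using only the truncated window.
#' @param weighted_f1_all Weighted F1 using all records (must be > 0).
#' @return The ratio (a proportion; multiply by 100 for percent).
#' @examples
#' round(100 * recovery_ratio(0.13, 0.76), 1)
#' @export
recovery_ratio <- function(weighted_f1_k, weighted_f1_all) {
  if (any(weighted_f1_all == 0)) {
    abort("weighted F1 on the full record is 0; recovery ratio undefined",
          class = "gsn_data_error")
  }
  weighted_f1_k / weighted_f1_all
}

#' Recovery-ratio curve over reverse-chronological record windows
#'
#' For each window length `k` (years), keeps only the notes dated within
#' `(followup_date - k years, followup_date]` for each patient, re-runs
#' extraction and patient-level aggregation on the truncated dossiers,
#' computes the weighted F1 against the gold statuses, and reports the
#' recovery ratio `R(k) = F1w(k) / F1w(all)`. `k = Inf` denotes the full
#' record and has `R = 1` by construction. Extraction is per-note and
#' deterministic, so events are extracted once and filtered per window.
#'
#' @param notes A notes tibble (see [extract_corpus()]).
#' @param gold A tibble with `patient_id`, `followup_date` and a gold status
#'   column named `true_status` (or `gold_status`).
#' @param k_values Numeric vector of window lengths in years; `Inf` (all
#'   records) is added if absent.
#' @param config An [nlp_config()].
#' @param mode Aggregation mode passed to [aggregate_statuses()].
#' @return A `surg_recovery` tibble with columns `k`, `weighted_f1`, `ratio`.
#' @export
recovery_curve <- function(notes, gold, k_values = c(1, 2, 5, 10, 15, Inf),
                           config = nlp_config(),
                           mode = c("faithful", "evidence")) {
  mode <- match.arg(mode)
  gold_col <- if ("true_status" %in% names(gold)) "true_status" else "gold_status"
  if (!gold_col %in% names(gold)) {
    abort("gold table needs a true_status (or gold_status) column",
          class = "gsn_data_error")
  }
  gold <- dplyr::mutate(gold, followup_date = as.Date(.data$followup_date))
  k_values <- sort(unique(c(k_values, Inf)))
  events <- extract_corpus(notes, config)
  fu <- gold[, c("patient_id", "followup_date")]

  f1_for <- function(ev) {
    st <- aggregate_statuses(ev, fu, mode = mode)
    d <- dplyr::inner_join(
      gold[, c("patient_id", gold_col)], st[, c("patient_id", "predicted_status")],
      by = "patient_id"
    )
    ev_res <- evaluate_statuses(d, gold = gold_col, pred = "predicted_status")
    ev_res$weighted$f1
  }

  ev_all <- events
  if (nrow(ev_all)) {
    ev_all <- dplyr::inner_join(ev_all, fu, by = "patient_id")
    ev_all <- ev_all[as.Date(ev_all$note_date) <= ev_all$followup_date, ]
    ev_all$followup_date <- NULL
  }
  f1_all <- f1_for(ev_all)
  if (f1_all == 0) {
    abort("weighted F1 on the full record is 0; recovery ratio undefined",
          class = "gsn_data_error")
  }
  res <- purrr::map_dfr(k_values, function(k) {
    if (is.infinite(k)) {
      return(tibble(k = k, weighted_f1 = f1_all, ratio = 1))
    }
    ev_k <- events
    if (nrow(ev_k)) {
      ev_k <- dplyr::inner_join(ev_k, fu, by = "patient_id")
      nd <- as.Date(ev_k$note_date)
      keep <- nd <= ev_k$followup_date &
        nd > (ev_k$followup_date - round(k * 365.25))
      ev_k <- ev_k[keep, ]
      ev_k$followup_date <- NULL
    }
    f1k <- f1_for(ev_k)
    tibble(k = k, weighted_f1 = f1k, ratio = recovery_ratio(f1k, f1_all))
  })
  if (any(res$ratio > 1)) {
    inform("recovery ratio above 1 observed: truncation removed misleading text",
           class = "gsn_recovery_gain")
  }
  class(res) <- c("surg_recovery", class(res))
  attr(res, "weighted_f1_all") <- f1_all
  res
}

#' Plot a recovery-ratio curve
#'
#' @param object A `surg_recovery` tibble from [recovery_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surg_recovery <- function(object, ...) {
  d <- object[is.finite(object$k), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = "years of records before follow-up",
                  y = "recovery ratio of weighted F1") +
    ggplot2::theme_minimal()
}
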