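#' Build a multiclass confusion matrix
#'
#' Rows are gold labels, columns are predicted labels, in the canonical
#' status order.
#'
#' @param gold,pred Character vectors of equal length with labels drawn from
#'   `labels`.
#' @param labels Ordered label set; defaults to the six surgery statuses.
#' @return A `surg_confusion` object (an integer matrix with `gold` rows and
#'   `pred` columns).
#' @examples
#' build_confusion(c("no_surgery", "hyst_only"), c("no_surgery", "no_surgery"))
#' @export
build_confusion <- function(gold, pred, labels = surgery_status_levels()) {
  if (length(gold) != length(pred)) {
    abort("gold and pred must have equal length", class = "gsn_data_error")
  }
  unknown <- setdiff(unique(c(gold, pred)), labels)
  if (length(unknown)) {
    abort(paste0("unknown label(s): ", paste(unknown, collapse = ", ")),
          class = "gsn_data_error")
  }
  m <- table(gold = factor(gold, levels = labels),
             pred = factor(pred, levels = labels))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  structure(m, class = c("surg_confusion", "matrix"))
}

.cm_matrix <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("not a square confusion matrix", class = "gsn_data_error")
  }
  m
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest metrics per class: precision is the proportion of patients the
#' algorithm assigned to a class who truly belong to it; recall is the
#' proportion of patients truly in the class that the algorithm found; F1 is
#' their harmonic mean (0 when precision + recall = 0). Zero-denominator
#' precision or recall is reported as 0 with a warning.
#'
#' @param cm A `surg_confusion` from [build_confusion()].
#' @return A tibble with columns `class`, `support`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
per_class_prf <- function(cm) {
  m <- .cm_matrix(cm)
  n <- sum(m)
  if (n == 0) abort("empty confusion matrix", class = "gsn_data_error")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  zero_p <- (tp + fp) == 0
  zero_r <- (tp + fn) == 0
  if (any(zero_p) || any(zero_r)) {
    warn(paste0("zero-denominator precision/recall set to 0 for class(es): ",
                paste(rownames(m)[zero_p | zero_r], collapse = ", ")))
  }
  precision <- ifelse(zero_p, 0, tp / (tp + fp))
  recall <- ifelse(zero_r, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  tibble(class = rownames(m), support = as.integer(rowSums(m)),
         tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = unname(precision), recall = unname(recall),
         f1 = unname(f1))
}

#' Macro-averaged metrics
#'
#' Unweighted arithmetic mean of the per-class metrics over all classes,
#' i.e. every surgery status counts equally regardless of its sample size.
#'
#' @param per_class A tibble with `precision`, `recall`, `f1` columns (one
#'   row per class), e.g. from [per_class_prf()].
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
macro_average <- function(per_class) {
  tibble(precision = mean(per_class$precision),
         recall = mean(per_class$recall),
         f1 = mean(per_class$f1))
}

#' Support-weighted metrics
#'
#' Mean of the per-class metrics weighted by class sample size (gold label
#' counts by default), so prevalent statuses dominate.
#'
#' @inheritParams macro_average
#' @param supports Non-negative class weights; defaults to the `support`
#'   column of `per_class`.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
weighted_average <- function(per_class, supports = per_class$support) {
  if (is.null(supports) || sum(supports) == 0) {
    abort("supports must have a positive sum", class = "gsn_data_error")
  }
  w <- supports / sum(supports)
  tibble(precision = sum(w * per_class$precision),
         recall = sum(w * per_class$recall),
         f1 = sum(w * per_class$f1))
}

#' Accuracy and percent agreement
#'
#' Accuracy is the proportion of correctly classified statuses
#' (trace / total); percent agreement is the same quantity expressed as a
#' percentage (conventionally reported to 1 decimal place).
#'
#' @inheritParams per_class_prf
#' @return A single numeric value.
#' @export
accuracy <- function(cm) {
  m <- .cm_matrix(cm)
  n <- sum(m)
  if (n == 0) abort("empty confusion matrix", class = "gsn_data_error")
  sum(diag(m)) / n
}

#' @rdname accuracy
#' @export
percent_agreement <- function(cm) 100 * accuracy(cm)

#' Cohen's kappa
#'
#' Chance-corrected agreement for a square confusion matrix:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / N` and chance agreement
#' `p_e = sum_c rowsum_c * colsum_c / N^2`. When `p_e = 1` the statistic is
#' defined as 1 if `p_o = 1` and is an error otherwise.
#'
#' @inheritParams per_class_prf
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  m <- .cm_matrix(cm)
  n <- sum(m)
  if (n == 0) abort("empty confusion matrix", class = "gsn_data_error")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    abort("chance agreement is 1 but observed agreement is not; kappa undefined",
          class = "gsn_data_error")
  }
  (po - pe) / (1 - pe)
}

#' Evaluate predicted statuses against gold labels
#'
#' Builds the confusion matrix and computes the full metric set: per-class
#' precision/recall/F1, macro and support-weighted averages, accuracy,
#' percent agreement and Cohen's kappa.
#'
#' @param data A data frame holding both label columns.
#' @param gold,pred Column names (strings) of the gold and predicted labels.
#' @param labels Ordered label set.
#' @return A `surg_eval` object; see [tidy()] for the per-class table and
#'   [glance()] for the one-row summary.
#' @examples
#' d <- tibble::tibble(gold = c("no_surgery", "hyst_only"),
#'                     pred = c("no_surgery", "hyst_only"))
#' glance(evaluate_statuses(d, "gold", "pred"))
#' @export
evaluate_statuses <- function(data, gold = "true_status",
                              pred = "predicted_status",
                              labels = surgery_status_levels()) {
  cm <- build_confusion(data[[gold]], data[[pred]], labels)
  per_class <- suppressWarnings(per_class_prf(cm))
  structure(list(
    confusion = cm,
    per_class = per_class,
    macro = macro_average(per_class),
    weighted = weighted_average(per_class),
    accuracy = accuracy(cm),
    percent_agreement = percent_agreement(cm),
    kappa = cohen_kappa(cm),
    n = sum(.cm_matrix(cm))
  ), class = "surg_eval")
}

#' @export
print.surg_eval <- function(x, ...) {
  cat("Surgery status evaluation (n = ", x$n, ")\n\n", sep = "")
  pc <- dplyr::mutate(x$per_class,
                      dplyr::across(c("precision", "recall", "f1"),
                                    ~ round(.x, 2)))
  print(as.data.frame(pc), row.names = FALSE)
  cat(sprintf("\nmacro    P %.2f  R %.2f  F1 %.2f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("weighted P %.2f  R %.2f  F1 %.2f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  cat(sprintf("accuracy %.3f  agreement %.1f%%  kappa %.3f\n",
              x$accuracy, x$percent_agreement, x$kappa))
  invisible(x)
}

#' @export
tidy.surg_eval <- function(x, ...) x$per_class

#' @export
glance.surg_eval <- function(x, ...) {
  tibble(n = x$n,
         accuracy = x$accuracy,
         percent_agreement = x$percent_agreement,
         kappa = x$kappa,
         macro_precision = x$macro$precision,
         macro_recall = x$macro$recall,
         macro_f1 = x$macro$f1,
         weighted_precision = x$weighted$precision,
         weighted_recall = x$weighted$recall,
         weighted_f1 = x$weighted$f1)
}

#' @export
tidy.surg_confusion <- function(x, ...) {
  m <- .cm_matrix(x)
  as_tibble(as.data.frame.table(m, responseName = "n")) |>
    dplyr::mutate(gold = as.character(.data$gold),
                  pred = as.character(.data$pred),
                  n = as.integer(.data$n))
}

#' Plot a confusion matrix
#'
#' Heat-tile display of the gold-by-predicted counts.
#'
#' @param object A `surg_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surg_confusion <- function(object, ...) {
  d <- tidy(object)
  lv <- rownames(.cm_matrix(object))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$pred, levels = lv),
    y = factor(.data$gold, levels = rev(lv)),
    fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted status", y = "gold status", fill = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Fraction of patients with at least one dated surgery event
#'
#' For each surgery type (unilateral oophorectomy, bilateral oophorectomy,
#' hysterectomy), the fraction of patients having that surgery whose events
#' include at least one dated mention of the matching concept family.
#'
#' @param events A tibble of valid events with `patient_id`, `concept`,
#'   `laterality`, `event_date`, `event_year`.
#' @param truth_types A tibble with `patient_id` and `surgery_type`
#'   (`"unilateral_oophorectomy"`, `"bilateral_oophorectomy"`,
#'   `"hysterectomy"`), one row per patient-type; see
#'   [surgery_types_from_status()].
#' @return A tibble with `surgery_type`, `n_patients`, `n_with_date`,
#'   `fraction`.
#' @export
date_presence_report <- function(events, truth_types) {
  dated <- events[(!is.na(events$event_date)) | (!is.na(events$event_year)), ]
  has_type <- function(pid, type) {
    d <- dated[dated$patient_id == pid, ]
    if (!nrow(d)) return(FALSE)
    switch(type,
           hysterectomy = any(d$concept %in% .hyst_family()),
           bilateral_oophorectomy =
             any(d$concept %in% .bilateral_concepts() |
                   (d$concept == "oophorectomy" & !is.na(d$laterality) &
                      d$laterality == "bilateral")),
           unilateral_oophorectomy =
             any(d$concept == "oophorectomy"),
           FALSE)
  }
  truth_types |>
    dplyr::group_by(.data$surgery_type) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      n_with_date = sum(vapply(.data$patient_id, has_type, logical(1),
                               type = .data$surgery_type[1L])),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$n_with_date / .data$n_patients)
}

#' Map a status to the surgery types it implies
#'
#' @param status Character vector of surgery statuses.
#' @return A tibble with `status` and `surgery_type`, one row per implied
#'   type.
#' @export
surgery_types_from_status <- function(status) {
  map <- list(
    no_surgery = character(0),
    bilateral_ooph_only = "bilateral_oophorectomy",
    hyst_and_bilateral_ooph = c("hysterectomy", "bilateral_oophorectomy"),
    unilateral_ooph_only = "unilateral_oophorectomy",
    hyst_and_unilateral_ooph = c("hysterectomy", "unilateral_oophorectomy"),
    hyst_only = "hysterectomy"
  )
  purrr::map_dfr(seq_along(status), function(i) {
    types <- map[[status[i]]]
    tibble(status = rep(status[i], length(types)), surgery_type = types)
  })
}
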