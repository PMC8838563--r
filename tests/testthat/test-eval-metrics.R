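test_that("confusion matrix counts gold by predicted", {
  lv <- surgery_status_levels()
  cm <- build_confusion(c(lv[1], lv[1], lv[2]), c(lv[1], lv[2], lv[2]))
  m <- unclass(cm)
  expect_equal(m[lv[1], lv[1]], 1L)
  expect_equal(m[lv[1], lv[2]], 1L)
  expect_equal(m[lv[2], lv[2]], 1L)
  expect_equal(sum(m), 3L)

  same <- build_confusion(lv, lv)
  expect_equal(sum(diag(unclass(same))), 6L)

  empty <- build_confusion(character(0), character(0))
  expect_equal(sum(unclass(empty)), 0L)
  expect_error(per_class_prf(empty), class = "gsn_data_error")
  expect_error(build_confusion("a", c("a", "b")), class = "gsn_data_error")
  expect_error(build_confusion("bogus", "bogus"), class = "gsn_data_error")
})

test_that("per-class metrics handle perfect and degenerate classes", {
  lv <- surgery_status_levels()
  diag_cm <- build_confusion(rep(lv, 2), rep(lv, 2))
  pc <- per_class_prf(diag_cm)
  expect_true(all(pc$precision == 1) && all(pc$recall == 1) && all(pc$f1 == 1))

  # a class predicted but never correct has precision 0
  cm <- build_confusion(c(lv[1], lv[1]), c(lv[2], lv[2]))
  expect_warning(pc <- per_class_prf(cm))
  expect_equal(pc$precision[pc$class == lv[2]], 0)
  expect_equal(pc$recall[pc$class == lv[1]], 0)
})

test_that("metric implementations agree with brute-force oracles", {
  set.seed(202)
  for (i in 1:200) {
    cm <- random_cm()
    m <- unclass(cm)
    pc <- suppressWarnings(per_class_prf(cm))
    or <- oracle_prf(m)
    expect_lt(max(abs(pc$precision - or[, "precision"])), 1e-12)
    expect_lt(max(abs(pc$recall - or[, "recall"])), 1e-12)
    expect_lt(max(abs(pc$f1 - or[, "f1"])), 1e-12)

    mac <- macro_average(pc)
    expect_lt(abs(mac$precision - mean(or[, "precision"])), 1e-12)
    expect_lt(abs(mac$f1 - mean(or[, "f1"])), 1e-12)

    w <- rowSums(m)
    if (sum(w) > 0) {
      wa <- weighted_average(pc, w)
      expect_lt(abs(wa$f1 - sum(w * or[, "f1"]) / sum(w)), 1e-12)
    }
    expect_lt(abs(cohen_kappa(cm) - oracle_kappa(m)), 1e-12)
    expect_lt(abs(accuracy(cm) - sum(diag(m)) / sum(m)), 1e-12)
  }
})

test_that("weighted average equals macro under equal supports", {
  set.seed(203)
  cm <- random_cm()
  pc <- suppressWarnings(per_class_prf(cm))
  expect_equal(weighted_average(pc, rep(3, 6)), macro_average(pc))
  expect_error(weighted_average(pc, rep(0, 6)), class = "gsn_data_error")
  single <- weighted_average(pc, c(5, 0, 0, 0, 0, 0))
  expect_equal(single$precision, pc$precision[1])
})

test_that("percent agreement reproduces the 49-of-54 arithmetic", {
  lv <- surgery_status_levels()
  gold <- c(rep(lv, length.out = 49), rep(lv[1], 5))
  pred <- c(gold[1:49], rep(lv[2], 5))
  cm <- build_confusion(gold, pred)
  expect_equal(round(percent_agreement(cm), 1), 90.7)
  expect_equal(percent_agreement(build_confusion(lv, lv)), 100)
  zero <- build_confusion(rep(lv[1], 3), rep(lv[2], 3))
  expect_equal(percent_agreement(zero), 0)
})

test_that("kappa is 1 at perfect agreement and 0 at chance level", {
  lv <- surgery_status_levels()
  expect_equal(cohen_kappa(build_confusion(lv, lv)), 1)
  uniform <- structure(matrix(1L, 6, 6, dimnames = list(lv, lv)),
                       class = c("surg_confusion", "matrix"))
  expect_equal(cohen_kappa(uniform), 0)
})

test_that("evaluate_statuses exposes tidy and glance views", {
  lv <- surgery_status_levels()
  d <- tibble::tibble(true_status = rep(lv, 3), predicted_status = rep(lv, 3))
  res <- evaluate_statuses(d)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$accuracy, 1)
  expect_equal(g$macro_f1, 1)
  expect_equal(g$kappa, 1)
  expect_equal(g$n, 18L)
  p <- autoplot(res$confusion)
  expect_s3_class(p, "ggplot")
})

test_that("discrepancy taxonomy totals and shares follow the fixture", {
  counts <- readr::read_csv(
    system.file("extdata", "discrepancy_counts.csv", package = "gynsurgnlp"),
    show_col_types = FALSE
  )
  ds <- summarize_discrepancies(counts)
  g <- glance(ds)
  expect_equal(g$total, 464L)
  expect_equal(c(g$external, g$internal, g$technical), c(199L, 144L, 121L))
  expect_equal(c(g$external_share_pct, g$internal_share_pct,
                 g$technical_share_pct), c(42.9, 31.0, 26.1))

  empty <- summarize_discrepancies(tibble::tibble(subcategory = character()))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$by_subcategory$n == 0))

  one <- summarize_discrepancies(tibble::tibble(subcategory = "mayo_missing"))
  expect_equal(one$by_category$share_pct, c(100, 0, 0))
})

test_that("inconsistent discrepancy records are rejected by name", {
  expect_error(
    summarize_discrepancies(tibble::tibble(subcategory = "not_a_category")),
    class = "gsn_data_error"
  )
  expect_error(
    summarize_discrepancies(tibble::tibble(subcategory = "typo",
                                           category = "external")),
    "typo", class = "gsn_data_error"
  )
})

test_that("recovery ratio arithmetic and degenerate input behave", {
  expect_equal(round(100 * recovery_ratio(0.13, 0.76), 1), 17.1)
  expect_error(recovery_ratio(0.5, 0), class = "gsn_data_error")
})

test_that("date presence report covers the all-dated and none-dated poles", {
  ev <- tibble::tibble(
    patient_id = c("a", "a", "b"),
    concept = c("hysterectomy", "bilateral_oophorectomy", "oophorectomy"),
    laterality = c(NA, "bilateral", "left"),
    event_date = as.Date(c("1990-01-01", "1990-01-01", NA)),
    event_year = c(1990L, 1990L, 1992L)
  )
  types <- tibble::tibble(
    patient_id = c("a", "a", "b"),
    surgery_type = c("hysterectomy", "bilateral_oophorectomy",
                     "unilateral_oophorectomy")
  )
  rep1 <- date_presence_report(ev, types)
  expect_true(all(rep1$fraction == 1))

  ev$event_date <- as.Date(NA)
  ev$event_year <- NA_integer_
  rep0 <- date_presence_report(ev, types)
  expect_true(all(rep0$fraction == 0))
})

test_that("surgery types implied by a status are correct", {
  tt <- surgery_types_from_status(c("hyst_and_bilateral_ooph", "no_surgery"))
  expect_setequal(tt$surgery_type, c("hysterectomy", "bilateral_oophorectomy"))
})
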