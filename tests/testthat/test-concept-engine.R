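test_that("concept matching finds both concepts in the combined sentence", {
  m <- match_concepts(tokenize(worked_sentence))
  expect_equal(nrow(m), 2L)
  expect_equal(m$concept, c("hysterectomy", "bilateral_oophorectomy"))
})

test_that("confusable surface forms never match", {
  expect_equal(nrow(match_concepts(tokenize("She underwent hysteroscopy in 2005"))), 0L)
  expect_equal(nrow(match_concepts(tokenize("ovarian biopsy was performed"))), 0L)
  # exclusion window vetoes a true surface form near a confusable token
  expect_equal(nrow(match_concepts(tokenize("oophorectomy biopsy site noted"))), 0L)
})

test_that("abbreviated combined form maps to the combined concept", {
  m <- match_concepts(tokenize("s/p TAH-BSO 1995"))
  expect_equal(m$concept, "hysterectomy_bso_combined")
})

test_that("longest match wins and matches never overlap", {
  m <- match_concepts(tokenize("bilateral salpingo-oophorectomy"))
  expect_equal(m$concept, "bilateral_oophorectomy")
  expect_equal(nrow(m), 1L)
})

test_that("empty lexicon signals misconfiguration", {
  expect_error(match_concepts(tokenize("hysterectomy"), lexicon = list()),
               class = "gsn_config_error")
})

test_that("assertion classification follows cue precedence", {
  classify <- function(s) {
    tk <- tokenize(s)
    assert_context(tk, match_concepts(tk)[1, ])
  }
  expect_equal(classify("no history of hysterectomy"), "negated")
  expect_equal(classify("her mother had a hysterectomy"), "family")
  expect_equal(classify("we discussed the possibility of hysterectomy"),
               "hypothetical")
  expect_equal(classify("she is scheduled for hysterectomy next month"),
               "planned")
  expect_equal(classify("status post hysterectomy"), "positive")
  # negation outranks the other classes
  expect_equal(classify("never discussed hysterectomy"), "negated")
  # scope breakers cut the cue window
  expect_equal(classify("she denies pain but had a hysterectomy"), "positive")
})

test_that("family-history section forces the family label", {
  tk <- tokenize("status post hysterectomy")
  m <- match_concepts(tk)[1, ]
  expect_equal(assert_context(tk, m, section_header = "family history"),
               "family")
  expect_equal(assert_context(tk, m, section_header = "FAMILY HISTORY:"),
               "family")
})

test_that("laterality resolution reads sentence-level cues", {
  lat_of <- function(s) {
    tk <- tokenize(s)
    resolve_laterality(tk, match_concepts(tk)[1, ])
  }
  expect_equal(lat_of("left salpingo-oophorectomy"), "left")
  expect_equal(lat_of("right oophorectomy in 1992"), "right")
  expect_equal(lat_of("oophorectomy performed without complication"),
               "unspecified")
  expect_equal(lat_of("bilateral salpingo-oophorectomy"), "bilateral")
  expect_equal(lat_of("oophorectomy of the left and right ovaries"),
               "bilateral")
  expect_equal(lat_of("s/p TAH-BSO"), "bilateral")
})

test_that("laterality on a hysterectomy-only mention is a misuse error", {
  tk <- tokenize("status post hysterectomy")
  expect_error(resolve_laterality(tk, match_concepts(tk)[1, ]),
               class = "gsn_misuse_error")
})

test_that("date extraction covers the three pattern families", {
  d <- extract_dates("TAH on 11/22/1994", as.Date("2001-06-01"))
  expect_equal(d$date, as.Date("1994-11-22"))

  y <- extract_dates("hysterectomy in 1998", as.Date("2001-06-01"))
  expect_equal(y$year, 1998L)
  expect_true(is.na(y$date))

  p <- extract_dates("seen on 03/05/99", as.Date("2001-06-01"))
  expect_equal(p$date, as.Date("1999-03-05"))

  # day-first dialect swaps month and day
  dmy <- extract_dates("TAH on 22/11/1994", as.Date("2001-06-01"),
                       dialect = "dmy")
  expect_equal(dmy$date, as.Date("1994-11-22"))
})

test_that("extracted full dates are always real calendar dates", {
  d <- extract_dates("impossible 02/30/1994 and real 02/28/1994",
                     as.Date("2001-06-01"))
  expect_equal(d$date[!is.na(d$date)], as.Date("1994-02-28"))
  set.seed(77)
  for (i in 1:50) {
    s <- sprintf("seen on %d/%d/%d and in %d", sample(1:19, 1),
                 sample(1:39, 1), sample(c(80, 99, 1985, 2001), 1),
                 sample(1850:2050, 1))
    d <- extract_dates(s, as.Date("2010-01-01"))
    full <- d[!is.na(d$month), ]
    if (nrow(full)) expect_false(any(is.na(full$date)))
    expect_true(all(d$year >= 1900 & d$year <= 2010))
  }
})

test_that("bare years outside [1900, note year] are rejected", {
  expect_equal(nrow(extract_dates("in 2015", as.Date("2010-01-01"))), 0L)
  expect_equal(nrow(extract_dates("in 1850", as.Date("2010-01-01"))), 0L)
})

test_that("extract_note composes the pipeline on the worked sentence", {
  ev <- extract_note(make_note(worked_sentence))
  expect_equal(sum(ev$valid), 2L)
  expect_setequal(ev$concept, c("hysterectomy", "bilateral_oophorectomy"))
  expect_equal(ev$laterality[ev$concept == "bilateral_oophorectomy"],
               "bilateral")
})

test_that("family-history sections yield no valid events", {
  ev <- extract_note(make_note("FAMILY HISTORY:\nMother: hysterectomy."))
  expect_equal(sum(ev$valid), 0L)
})

test_that("empty notes yield no events", {
  expect_equal(nrow(extract_note(make_note(""))), 0L)
})

test_that("nearest in-sentence date is attached to each mention", {
  ev <- extract_note(make_note(
    "PAST SURGICAL HISTORY:\ns/p TAH in 1990. Left oophorectomy on 11/22/1994."
  ))
  ev <- ev[ev$valid, ]
  expect_equal(ev$event_year[ev$concept == "hysterectomy"], 1990L)
  expect_equal(ev$event_date[ev$concept == "oophorectomy"],
               as.Date("1994-11-22"))
  # no date in sentence -> event date absent
  ev2 <- extract_note(make_note("Status post hysterectomy."))
  expect_true(is.na(ev2$event_date) && is.na(ev2$event_year))
})

test_that("strict mode suppresses specimen-template lines", {
  line <- "Uterus, endometrium, hysterectomy: Inactive"
  faithful <- extract_note(make_note(line))
  expect_equal(sum(faithful$valid), 1L)  # documented faithful behaviour
  strict <- extract_note(make_note(line), nlp_config(mode = "strict"))
  expect_equal(nrow(strict), 0L)
})

test_that("negation closure holds over the full lexicon sentence bank", {
  for (surface in lexicon_surfaces()) {
    pos <- extract_note(make_note(paste0("She underwent ", surface, ".")))
    expect_gt(sum(pos$valid), 0)
    neg <- extract_note(make_note(paste0("No history of ", surface, ".")))
    expect_equal(sum(neg$valid), 0L)
  }
})

test_that("swapping left and right tokens swaps laterality counts exactly", {
  corp <- generate_corpus(noise_free_config(40, seed = 91))
  swap <- corp$notes
  swap$text <- gsub("(?i)\\bleft\\b", "@L@", swap$text, perl = TRUE)
  swap$text <- gsub("(?i)\\bright\\b", "left", swap$text, perl = TRUE)
  swap$text <- gsub("@L@", "right", swap$text, fixed = TRUE)

  ev1 <- extract_corpus(corp$notes)
  ev2 <- extract_corpus(swap)
  n1 <- table(factor(ev1$laterality[ev1$valid], laterality_levels()))
  n2 <- table(factor(ev2$laterality[ev2$valid], laterality_levels()))
  expect_equal(n1[["left"]], n2[["right"]])
  expect_equal(n1[["right"]], n2[["left"]])
  expect_equal(n1[["bilateral"]], n2[["bilateral"]])
  expect_equal(n1[["unspecified"]], n2[["unspecified"]])
})

test_that("extraction is a pure function of note and config", {
  note <- make_note(paste0(
    "PAST SURGICAL HISTORY:\ns/p TAH-BSO on 03/05/99.\n",
    "FAMILY HISTORY:\nMother: hysterectomy."
  ))
  expect_identical(extract_note(note), extract_note(note))
})
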