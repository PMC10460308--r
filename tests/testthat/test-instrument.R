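test_that("involvement scores sum the configured item weights", {
  w <- assist_weights()
  # all-never responses score zero
  zero <- score_substance_involvement(
    list(q2 = "never", q3 = "never", q4 = "never", q5 = "never",
         q6 = "never", q7 = "never"), "cannabis", w)
  expect_identical(zero$raw, 0)
  expect_identical(zero$log_value, 0)
  # maximal cannabis response reaches the weight-table ceiling
  mx <- score_substance_involvement(max_answers(), "cannabis", w)
  expect_equal(mx$raw, 39)
  expect_equal(mx$raw, assist_max_score("cannabis", w))
  expect_equal(mx$log_value, log(40))
  # tobacco never gets the failed-expectations item
  mt <- score_substance_involvement(max_answers(), "tobacco", w)
  expect_equal(mt$raw, 31)
  expect_equal(mt$raw, assist_max_score("tobacco", w))
})

test_that("a missing item makes the substance score missing", {
  resp <- max_answers()
  resp$q4 <- NA
  sc <- score_substance_involvement(resp, "cannabis")
  expect_true(is.na(sc$raw))
  expect_true(is.na(sc$log_value))
})

test_that("unknown response levels raise a named validation error", {
  coh <- make_cohort_row(cannabis = list(q2 = "sometimes"))
  expect_error(involvement_scores(coh),
               "sometimes.*participant 1.*cannabis.*q2")
})

test_that("cohort scoring matches single-response scoring and is monotone", {
  set.seed(42)
  freq <- assist_levels("q2")
  yn <- assist_levels("q6")
  for (rep in 1:20) {
    resp <- list(q2 = sample(freq, 1), q3 = sample(freq, 1),
                 q4 = sample(freq, 1), q5 = sample(freq, 1),
                 q6 = sample(yn, 1), q7 = sample(yn, 1))
    coh <- make_cohort_row(alcohol = resp)
    sc <- involvement_scores(coh)
    one <- score_substance_involvement(resp, "alcohol")
    expect_equal(sc$alcohol_score, one$raw)
    # bumping one item to a higher level never lowers the score
    it <- sample(paste0("q", 2:7), 1)
    lv <- assist_levels(it)
    pos <- match(resp[[it]], lv)
    if (pos < length(lv)) {
      resp2 <- resp
      resp2[[it]] <- lv[pos + 1]
      bumped <- score_substance_involvement(resp2, "alcohol")
      expect_gte(bumped$raw, one$raw)
    }
  }
})

test_that("dichotomisation follows the 3-month rule", {
  coh <- make_cohort_row(
    cannabis = list(q2 = "once_or_twice", q6 = "yes_not_past_3mo"),
    alcohol = list(q3 = "weekly"))
  ind <- dichotomize_items(coh)
  expect_true(ind$cannabis_used)
  expect_false(ind$alcohol_used)
  # prior-to-3-months concern does not count as a current harm
  expect_false(ind$cannabis_concerns)
  expect_true(ind$alcohol_urge)
  expect_true(ind$any_urge)
  # harm without use is legal but surfaced in QC
  qc <- attr(ind, "qc_harm_without_use")
  expect_equal(unname(qc["alcohol_urge"]), 1L)
})

test_that("missing answers propagate through dichotomisation", {
  coh <- make_cohort_row()
  for (cl in grep("_q[2-7]$", names(coh), value = TRUE)) coh[[cl]] <- NA
  ind <- dichotomize_items(coh)
  expect_true(all(is.na(unlist(ind[1, ]))))
})

test_that("tobacco has no failed-expectations flag", {
  ind <- dichotomize_items(make_cohort_row())
  expect_false("tobacco_failed_expect" %in% names(ind))
  expect_true("cannabis_failed_expect" %in% names(ind))
})

test_that("polysubstance classification honours the tobacco/alcohol variants", {
  coh <- rbind(
    make_cohort_row(tobacco = list(q2 = "monthly"),
                    alcohol = list(q2 = "weekly")),
    make_cohort_row(cannabis = list(q2 = "once_or_twice")),
    make_cohort_row())
  ind <- dichotomize_items(coh)
  incl <- classify_polysubstance(ind, TRUE)
  excl <- classify_polysubstance(ind, FALSE)
  # tobacco + alcohol only: polydrug when counted, none when excluded
  expect_equal(as.character(incl[1]), "polydrug")
  expect_equal(as.character(excl[1]), "none")
  expect_equal(as.character(excl[2]), "one_only")
  expect_equal(as.character(incl[3]), "none")
  expect_equal(as.character(excl[3]), "none")
})

test_that("including tobacco/alcohol never lowers the polysubstance count", {
  coh <- generate_cohort(paper_like_config(n = 300, seed = 5,
                                           missing_rate = 0.05))
  ind <- dichotomize_items(coh)
  incl <- classify_polysubstance(ind, TRUE)
  excl <- classify_polysubstance(ind, FALSE)
  ord <- c(none = 0, one_only = 1, polydrug = 2)
  both <- !is.na(incl) & !is.na(excl)
  expect_true(all(ord[as.character(incl[both])] >=
                    ord[as.character(excl[both])]))
})

test_that("group assignment follows the ATS > cannabis > other hierarchy", {
  coh <- rbind(
    make_cohort_row(ats = list(q2 = "monthly"),
                    cannabis = list(q2 = "weekly"),
                    tobacco = list(q2 = "daily_or_almost_daily")),
    make_cohort_row(cannabis = list(q2 = "weekly"),
                    tobacco = list(q2 = "monthly")),
    make_cohort_row(sedatives = list(q2 = "once_or_twice")),
    make_cohort_row())
  grp <- assign_group(dichotomize_items(coh))
  expect_equal(as.character(grp),
               c("ats", "cannabis_no_ats", "alcohol_tobacco_other", "none"))
})

test_that("an unresolvable ATS or cannabis flag makes the group missing", {
  coh <- rbind(
    make_cohort_row(cannabis = list(q2 = "weekly")),
    make_cohort_row(tobacco = list(q2 = "weekly")))
  coh$ats_q2[1] <- NA       # could be ats or cannabis_no_ats
  coh$cannabis_q2[2] <- NA  # could be cannabis_no_ats or alcohol_tobacco_other
  grp <- assign_group(dichotomize_items(coh))
  expect_true(all(is.na(grp)))
})

test_that("groups partition participants with complete data", {
  coh <- generate_cohort(paper_like_config(n = 500, seed = 9,
                                           missing_rate = 0.05))
  ind <- dichotomize_items(coh)
  grp <- assign_group(ind)
  expect_equal(sum(table(grp)), sum(!is.na(grp)))
  # cannabis use is universal in the cannabis group, ATS use only in ats
  can <- ind$cannabis_used[!is.na(grp) & grp == "cannabis_no_ats"]
  expect_true(all(can))
  ats_out <- ind$ats_used[!is.na(grp) & grp != "ats"]
  expect_true(all(!ats_out, na.rm = TRUE))
})
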