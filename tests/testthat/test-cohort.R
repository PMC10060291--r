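# Cohort construction: diagnosis confirmation, index date, eligibility
# rules and ordering, follow-up, SCT detection, Charlson scoring.

test_that("diagnosis confirmation implements the two-record rule", {
  cfg <- test_config()
  # two hospital stays -> confirmed
  d1 <- make_diag("P1", c("C900", "C901"), c(10, 40),
                  c("hospital_primary", "hospital_related"))
  r1 <- confirm_mm_diagnosis(d1, cfg)
  expect_true(r1$confirmed)
  expect_equal(r1$index_candidate, ORIGIN + 10L)

  # a single long-term-disease record fails both disjuncts
  d2 <- make_diag("P2", "C900", 10, "long_term_disease")
  expect_false(confirm_mm_diagnosis(d2, cfg)$confirmed)

  # associated hospital diagnosis + long-term disease -> confirmed
  d3 <- make_diag("P3", c("C90", "C90"), c(10, 40),
                  c("hospital_associated", "long_term_disease"))
  expect_true(confirm_mm_diagnosis(d3, cfg)$confirmed)

  # two hospital records on the same date count as one stay
  d4 <- make_diag("P4", c("C900", "C901"), c(10, 10),
                  c("hospital_primary", "hospital_associated"))
  expect_false(confirm_mm_diagnosis(d4, cfg)$confirmed)

  # non-MM codes never confirm
  d5 <- make_diag("P5", c("C34", "C34"), c(10, 40),
                  c("hospital_primary", "hospital_related"))
  expect_equal(nrow(confirm_mm_diagnosis(d5, cfg)), 0L)
})

test_that("index date is the earliest in-window MM diagnosis", {
  cfg <- test_config()
  # pre-window record exists: index moves to the first in-window record
  d <- make_diag("P1", c("C900", "C900"),
                 c(as.integer(as.Date("2012-06-01") - ORIGIN),
                   as.integer(as.Date("2014-02-01") - ORIGIN)),
                 c("hospital_primary", "hospital_primary"))
  r <- confirm_mm_diagnosis(d, cfg)
  expect_equal(r$index_candidate, as.Date("2014-02-01"))
  expect_equal(r$first_mm_date, as.Date("2012-06-01"))

  # record on the last day of the window is still inside
  d2 <- make_diag("P2", c("C900", "C900"),
                  rep(as.integer(as.Date("2018-12-31") - ORIGIN), 2),
                  c("hospital_primary", "long_term_disease"))
  expect_equal(confirm_mm_diagnosis(d2, cfg)$index_candidate,
               as.Date("2018-12-31"))

  # all records outside the window: no candidate
  d3 <- make_diag("P3", c("C900", "C900"),
                  rep(as.integer(as.Date("2012-01-05") - ORIGIN), 2),
                  c("hospital_primary", "long_term_disease"))
  expect_true(is.na(confirm_mm_diagnosis(d3, cfg)$index_candidate))
})

eligibility_fixture <- function(birth_year = 1950L, scheme = TRUE,
                                diag_extra = NULL, disp_days = 5) {
  pts <- data.table::data.table(patient_id = "P1",
                                birth_year = birth_year, sex = "M",
                                general_scheme = scheme,
                                death_date = as.Date(NA),
                                coverage_end_date = as.Date(NA))
  dg <- data.table::rbindlist(list(
    make_diag("P1", c("C900", "C900"), c(0, 14),
              c("hospital_primary", "long_term_disease")),
    diag_extra), use.names = TRUE)
  dp <- if (length(disp_days)) make_disp("A", disp_days) else
    make_disp("A", 5)[0]
  idx <- data.table::data.table(patient_id = "P1", index_date = ORIGIN)
  apply_eligibility(pts, dg, dp, idx, test_config())
}

test_that("eligibility rules fire in order with correct boundaries", {
  # exactly 18 at index fails the strict 'older than 18' reading
  v <- eligibility_fixture(birth_year = 1996L)
  expect_false(v$eligible)
  expect_equal(v$first_failed_rule, "age")
  # the configurable >=18 switch admits the same patient
  pts <- data.table::data.table(patient_id = "P1", birth_year = 1996L,
                                sex = "M", general_scheme = TRUE,
                                death_date = as.Date(NA),
                                coverage_end_date = as.Date(NA))
  dg <- make_diag("P1", c("C900", "C900"), c(0, 14),
                  c("hospital_primary", "long_term_disease"))
  idx <- data.table::data.table(patient_id = "P1", index_date = ORIGIN)
  v18 <- apply_eligibility(pts, dg, make_disp("A", 5), idx,
                           test_config(age_rule = "ge18"))
  expect_true(v18$eligible)

  expect_equal(eligibility_fixture(scheme = FALSE)$first_failed_rule,
               "scheme")

  # dispensing exactly on day 30 is inside the closed window
  expect_true(eligibility_fixture(disp_days = 30)$eligible)
  v31 <- eligibility_fixture(disp_days = 31)
  expect_equal(v31$first_failed_rule, "late_treatment")
  v0 <- eligibility_fixture(disp_days = numeric(0))
  expect_equal(v0$first_failed_rule, "untreated")

  # MM record in the washout year before index
  vmm <- eligibility_fixture(
    diag_extra = make_diag("P1", "C901", -100, "hospital_primary"))
  expect_equal(vmm$first_failed_rule, "prior_mm")

  # other malignancy within five years excludes ...
  vc <- eligibility_fixture(
    diag_extra = make_diag("P1", "C341", -700, "hospital_associated"))
  expect_equal(vc$first_failed_rule, "other_malignancy")
  # ... but non-melanoma skin cancer (C44) does not
  vskin <- eligibility_fixture(
    diag_extra = make_diag("P1", "C441", -700, "hospital_associated"))
  expect_true(vskin$eligible)
  # ... and neither does a malignancy older than five years
  vold <- eligibility_fixture(
    diag_extra = make_diag("P1", "C341", -2000, "hospital_associated"))
  expect_true(vold$eligible)
})

test_that("missing demographics yield a missing_data verdict", {
  dg <- make_diag("PX", c("C900", "C900"), c(0, 14),
                  c("hospital_primary", "long_term_disease"))
  idx <- data.table::data.table(patient_id = "PX", index_date = ORIGIN)
  pts <- data.table::data.table(patient_id = "other", birth_year = 1950L,
                                sex = "M", general_scheme = TRUE,
                                death_date = as.Date(NA),
                                coverage_end_date = as.Date(NA))
  v <- apply_eligibility(pts, dg, make_disp("PX", 5), idx, test_config())
  expect_false(v$eligible)
  expect_equal(v$first_failed_rule, "missing_data")
})

test_that("follow-up ends at death, gap, or end of observation", {
  cfg <- test_config()
  idx <- data.table::data.table(patient_id = "P1", index_date = ORIGIN)
  mk_claims <- function(visit_days, death = NA, cov_end = NA) {
    list(patients = data.table::data.table(
      patient_id = "P1", birth_year = 1950L, sex = "M",
      general_scheme = TRUE, death_date = as.Date(death),
      coverage_end_date = as.Date(cov_end)),
      dispensings = make_disp("A", 5),
      stays = tiny_claims()$stays[0],
      procedures = tiny_claims()$procedures,
      cost_items = data.table::data.table(
        patient_id = "P1", date = ORIGIN + as.integer(visit_days),
        category = "physician_visit", cost_eur = 25, days = 0L))
  }
  # death 400 days after index with continuous claims
  fu <- determine_follow_up(mk_claims(seq(0, 395, by = 30),
                                      death = ORIGIN + 400L), idx, cfg)
  expect_equal(fu$end_reason, "death")
  expect_equal(fu$end_date, ORIGIN + 400L)
  expect_equal(round(fu$months, 1), 13.1)

  # last claim at day 100, nothing after: lost to follow-up at day 100
  fu2 <- determine_follow_up(mk_claims(c(0, 50, 100)), idx, cfg)
  expect_equal(fu2$end_reason, "lost_to_follow_up")
  expect_equal(fu2$end_date, ORIGIN + 100L)

  # same gap with a coverage-termination record: disenrollment
  fu3 <- determine_follow_up(mk_claims(c(0, 50, 100),
                                       cov_end = ORIGIN + 130L), idx, cfg)
  expect_equal(fu3$end_reason, "disenrollment")

  # claims continuing to study end
  all_days <- seq(0, as.integer(cfg$study_end - ORIGIN), by = 30)
  fu4 <- determine_follow_up(mk_claims(all_days), idx, cfg)
  expect_equal(fu4$end_reason, "end_of_observation")
  expect_equal(fu4$end_date, cfg$study_end)
  expect_true(fu4$months >= 0)
})

test_that("SCT detection uses DRG or CCAM within follow-up", {
  cfg <- test_config()
  fu <- make_fu(end = 400L)
  empty_stays <- tiny_claims()$stays[0]
  proc <- data.table::data.table(patient_id = "P1", date = ORIGIN + 90L,
                                 ccam_code = "CCAMSCTAUTO",
                                 cost_eur = 500)
  r <- detect_sct(empty_stays, proc, fu, cfg)
  expect_true(r$sct)
  expect_equal(r$sct_date, ORIGIN + 90L)
  expect_equal(r$graft_type, "autologous")

  # DRG alone is sufficient
  st <- data.table::data.table(
    patient_id = "P1", admit_date = ORIGIN + 120L,
    discharge_date = ORIGIN + 140L, stay_type = "mco_complete",
    drg_code = "DRGSCTALLO", primary_dx = "C900", related_dx = "",
    associated_dx = "", cost_eur = 20000)
  r2 <- detect_sct(st, proc[0], fu, cfg)
  expect_true(r2$sct)
  expect_equal(r2$graft_type, "allogeneic")

  # one day after follow-up end: out of window
  r3 <- detect_sct(empty_stays,
                   data.table::copy(proc)[, date := ORIGIN + 401L],
                   fu, cfg)
  expect_false(r3$sct)

  # empty code lists are a configuration error
  cl <- cfg$code_lists
  cl$sct_drg_codes <- character(0); cl$sct_ccam_codes <- character(0)
  expect_error(detect_sct(st, proc, fu,
                          test_config(code_lists = cl)), "empty")
})

test_that("Charlson scoring floors at 2 for MM and sums distinct weights", {
  idx <- data.table::data.table(patient_id = "P1", index_date = ORIGIN)
  mm_only <- make_diag("P1", "C900", -10, "hospital_primary")
  r <- charlson_score(mm_only, idx)
  expect_equal(r$score, 2L)
  expect_equal(r$conditions, "malignancy")

  # MM + diabetes (1) + renal (2) = 5
  dg <- make_diag("P1", c("C900", "E119", "N183"), c(-10, -100, -200),
                  rep("hospital_associated", 3))
  expect_equal(charlson_score(dg, idx)$score, 5L)

  # duplicates of one condition count once
  dg2 <- make_diag("P1", c("C900", "E119", "E119", "E110"),
                   c(-10, -100, -150, -300),
                   rep("hospital_associated", 4))
  expect_equal(charlson_score(dg2, idx)$score, 3L)

  # records outside the one-year window are ignored
  dg3 <- make_diag("P1", c("C900", "N183"), c(-10, -400),
                   rep("hospital_associated", 2))
  expect_equal(charlson_score(dg3, idx)$score, 2L)
})

test_that("verdicts are complete, exclusive, and order-insensitive", {
  sc <- sim_config(n_patients = 60, seed = 11)
  pop <- generate_population(sc)
  pop <- inject_protocol_violations(
    pop, rates = list(untreated = 0.1, late_treatment = 0.1,
                      prior_malignancy = 0.1), seed = 11)
  b <- build_cohort(pop, mmlot_config())
  n <- nrow(pop$patients)
  # every patient is either in the cohort or logged exactly once
  expect_equal(nrow(b$cohort) +
                 data.table::uniqueN(b$exclusion_log$patient_id), n)
  expect_equal(anyDuplicated(b$exclusion_log$patient_id), 0L)

  # shuffling input row order changes nothing
  shuf <- lapply(pop, function(t) {
    if (nrow(t)) t[sample.int(nrow(t))] else t
  })
  b2 <- build_cohort(shuf, mmlot_config())
  expect_equal(b$cohort, b2$cohort)
  expect_equal(data.table::setorder(b$exclusion_log, patient_id),
               data.table::setorder(b2$exclusion_log, patient_id))
  expect_equal(b$followup[order(patient_id)],
               b2$followup[order(patient_id)])
})

test_that("verdicts equal ground truth on noise-free synthetic data", {
  sc <- sim_config(n_patients = 120, seed = 3)
  pop <- generate_population(sc)
  pop <- inject_protocol_violations(
    pop, rates = list(untreated = 0.08, late_treatment = 0.08,
                      prior_malignancy = 0.08), seed = 3)
  b <- build_cohort(pop, mmlot_config())
  gt <- pop$ground_truth
  verdict <- data.table::data.table(
    patient_id = gt$patient_id,
    eligible = gt$patient_id %in% b$cohort$patient_id)
  expect_equal(verdict$eligible, gt$true_eligible)
  # per-reason exclusion counts match the injected labels exactly
  injected <- gt[true_eligible == FALSE,
                 .N, by = .(rule = true_reason)]
  logged <- b$exclusion_log[, .N, by = rule]
  m <- merge(injected, logged, by = "rule", all = TRUE)
  expect_equal(m$N.x, m$N.y)
})
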