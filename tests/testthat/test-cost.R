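# Cost engine: annualisation, rates, attribution flags, event-of-interest
# accounting, table conservation.

test_that("annualisation multiplies by the claim-year index", {
  idx <- c(`2015` = 1.0, `2016` = 1.05)
  expect_equal(annualise(100, as.Date("2015-06-01"), idx), 100)
  expect_equal(annualise(100, as.Date("2016-06-01"), idx), 105)
  expect_error(annualise(100, as.Date("2017-06-01"), idx), "2017")
  expect_error(annualise(-1, as.Date("2015-06-01"), idx), "negative")
})

test_that("PPPY divides by stratum person-years including non-users", {
  expect_equal(pppy(1000, 2), 500)
  expect_true(is.na(pppy(1000, 0)))
  fu <- data.table::data.table(
    patient_id = c("a", "b"), index_date = ORIGIN,
    end_date = ORIGIN + c(730L, 365L))
  expect_equal(person_years(fu), (730 + 365) / 365.25)
  # single patient, one 365.25-day year, 58300 euros -> 58300 PPPY
  fu1 <- data.table::data.table(patient_id = "a", index_date = ORIGIN,
                                end_date = ORIGIN + 365L)
  expect_equal(pppy(58300, person_years(fu1)) * (365 / 365.25), 58300,
               tolerance = 1e-12)
})

test_that("PPPM sums costs over summed observation months", {
  fu <- data.table::data.table(
    patient_id = c("a", "b"), index_date = ORIGIN,
    end_date = ORIGIN + round(12 * 30.4375))
  led <- data.table::data.table(
    patient_id = c("a", "b"), date = ORIGIN + 10L,
    cost_eur_2019 = c(12000, 12000))
  expect_equal(pppm(led, fu), 24000 / (2 * round(12 * 30.4375) / 30.4375))
  expect_equal(pppm(led[0], fu), 0)
  expect_true(is.na(pppm(led, fu[0])))
})

test_that("first-year PPPM truncates numerator and denominator", {
  # three patients: 2 years, 1 year, 6 months of follow-up
  fu <- data.table::data.table(
    patient_id = c("a", "b", "c"), index_date = ORIGIN,
    end_date = ORIGIN + c(730L, 365L, 183L))
  led <- data.table::data.table(
    patient_id = c("a", "a", "b", "c"),
    date = ORIGIN + c(100L, 500L, 200L, 100L),
    cost_eur_2019 = c(1000, 9999, 2000, 3000))
  # first-year numerator drops the day-500 item; denominator:
  # (365 + 365 + 183) days in months
  pm <- (365 + 365 + 183) / 30.4375
  expect_equal(pppm(led, fu, first_year = TRUE), 6000 / pm)
  # PPPM * 12 == PPPY exactly (30.4375 * 12 = 365.25 by construction)
  pppy_rate <- pppy(sum(led$cost_eur_2019), person_years(fu))
  expect_equal(pppm(led, fu) * 12, pppy_rate)
})

cost_fixture <- function() {
  cfg <- test_config()
  fu <- make_fu(end = 600L)
  stays <- data.table::data.table(
    patient_id = "P1",
    admit_date = ORIGIN + c(10L, 100L, 103L, 200L, 300L),
    discharge_date = ORIGIN + c(10L, 102L, 110L, 201L, 302L),
    stay_type = c("chemo_session", "mco_complete", "rehab",
                  "chemo_session", "mco_complete"),
    drg_code = "DRG",
    primary_dx = c("Z511", "C900", "Z501", "Z511", "J181"),
    related_dx = c("C900", "", "", "", ""),
    associated_dx = "",
    cost_eur = c(500, 3000, 2000, 450, 1500))
  cost_items <- data.table::data.table(
    patient_id = "P1",
    date = ORIGIN + c(10L, 11L, 15L, 39L, 205L, 210L, 400L),
    category = c("transport", "sick_leave_invalidity", "lab_test",
                 "transport", "transport", "sick_leave_invalidity",
                 "transport"),
    cost_eur = c(60, 900, 40, 55, 70, 800, 80),
    days = c(0L, 14L, 0L, 0L, 0L, 10L, 0L))
  claims <- list(patients = tiny_claims()$patients[1],
                 diagnoses = tiny_claims()$diagnoses[0],
                 dispensings = make_disp("B", c(10, 38)),
                 stays = stays,
                 procedures = tiny_claims()$procedures,
                 cost_items = cost_items)
  led <- build_cost_ledger(claims, fu, cfg)
  led <- tag_mm_treatment_admin(led, cfg)
  led <- tag_mm_related(led, cfg)
  led <- tag_aoe(led, cfg)
  list(cfg = cfg, fu = fu, led = led, claims = claims)
}

test_that("MM treatment-administration flags follow the quoted rules", {
  f <- cost_fixture()
  led <- f$led
  # chemo-session stay with MM related diagnosis: full stay cost flagged
  expect_true(led[source == "stay" & date == ORIGIN + 10L,
                  mm_treatment_admin])
  # chemo-session stay without any MM diagnosis: not flagged
  expect_false(led[source == "stay" & date == ORIGIN + 200L,
                   mm_treatment_admin])
  # MM drug dispensings flagged in any setting class
  expect_true(all(led[source == "dispensing", mm_treatment_admin]))
  # transport on/next-day of an MM treatment is flagged; distant is not
  expect_true(led[category == "transport" & date == ORIGIN + 10L,
                  mm_treatment_admin])
  # next-day transport after the day-38 dispensing
  expect_true(led[category == "transport" & date == ORIGIN + 39L,
                  mm_treatment_admin])
  expect_false(led[category == "transport" & date == ORIGIN + 205L,
                   mm_treatment_admin])
  expect_false(led[category == "transport" & date == ORIGIN + 400L,
                   mm_treatment_admin])
  # sick leave within 7 days of MM treatment yes, 8+ days or distant no
  expect_true(led[category == "sick_leave_invalidity" &
                    date == ORIGIN + 11L, mm_treatment_admin])
  expect_false(led[category == "sick_leave_invalidity" &
                     date == ORIGIN + 210L, mm_treatment_admin])
})

test_that("MM-related flags add MM stays and linked rehab, never labs", {
  f <- cost_fixture()
  led <- f$led
  # stay with primary MM diagnosis
  expect_true(led[source == "stay" & date == ORIGIN + 100L, mm_related])
  # rehab admitted one day after the MM stay discharge
  expect_true(led[source == "stay" & date == ORIGIN + 103L, mm_related])
  # pneumonia stay is neither treatment nor MM-related
  expect_false(led[source == "stay" & date == ORIGIN + 300L, mm_related])
  # outpatient lab tests are excluded by definition
  expect_false(led[category == "lab_test", mm_related])
  # monotonicity on the whole ledger
  expect_true(all(!led$mm_treatment_admin | led$mm_related))
})

test_that("event-of-interest stays count per primary diagnosis", {
  f <- cost_fixture()
  a <- aoe_hospitalisations(f$led, f$fu, f$cfg)
  # only the pneumonia (J181) stay qualifies; Z-codes and C90 do not
  expect_equal(a$n_events, 1L)
  expect_equal(a$n_patients, 1L)
  expect_equal(a$pct_patients, 100)
  # two qualifying stays still count one patient once
  led2 <- data.table::copy(f$led)
  extra <- led2[source == "stay" & date == ORIGIN + 300L]
  extra[, date := ORIGIN + 310L]
  a2 <- aoe_hospitalisations(rbind(led2, extra), f$fu, f$cfg)
  expect_equal(a2$n_events, 2L)
  expect_equal(a2$n_patients, 1L)
  # AE code only in associated position does not count
  led3 <- data.table::copy(f$led)
  led3[source == "stay" & date == ORIGIN + 300L,
       `:=`(primary_dx = "C900", associated_dx = "J181")]
  expect_equal(aoe_hospitalisations(led3, f$fu, f$cfg)$n_events, 0L)
})

test_that("all-cause table conserves sums, shares, and strata", {
  sc <- sim_config(n_patients = 80, seed = 23)
  pop <- generate_population(sc)
  cfg <- mmlot_config()
  b <- build_cohort(pop, cfg)
  led <- build_cost_ledger(pop, b$followup, cfg)
  led <- tag_mm_related(tag_mm_treatment_admin(led, cfg), cfg)
  tab <- build_allcause_table(led, b$followup)

  cats <- tab[level == "category"]
  expect_equal(sum(cats$sum_eur), tab[category == "total", sum_eur])
  expect_equal(sum(cats$fy_sum_eur), tab[category == "total", fy_sum_eur])
  expect_equal(tab[category == "all_hospitalisation", sum_eur] +
                 tab[category == "all_treatment", sum_eur] +
                 tab[category == "all_other", sum_eur],
               tab[category == "total", sum_eur])
  expect_equal(sum(cats$share_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cats$fy_share_pct), 100, tolerance = 1e-9)
  # first-year totals never exceed overall totals
  expect_true(all(cats$fy_sum_eur <= cats$sum_eur + 1e-9))
  # ledger total equals the table total
  expect_equal(tab[category == "total", sum_eur], sum(led$cost_eur_2019))

  # SCT / non-SCT partition the overall ledger
  sct <- detect_sct(pop$stays, pop$procedures, b$followup, cfg)
  sct_ids <- sct[sct == TRUE, patient_id]
  t_sct <- build_allcause_table(led[patient_id %in% sct_ids],
                                b$followup[patient_id %in% sct_ids])
  t_non <- build_allcause_table(led[!patient_id %in% sct_ids],
                                b$followup[!patient_id %in% sct_ids])
  expect_equal(t_sct[category == "total", sum_eur] +
                 t_non[category == "total", sum_eur],
               tab[category == "total", sum_eur])
})

test_that("lot attribution assigns in-line dates and between-line policy", {
  lots <- data.table::data.table(
    patient_id = "P1", lot_number = c(1L, 2L),
    regimen = c("A", "B"), start = ORIGIN + c(0L, 300L),
    end = ORIGIN + c(100L, 400L), end_reason = "discontinuation",
    duration_days = c(100L, 100L))
  led <- data.table::data.table(
    patient_id = "P1", date = ORIGIN + c(-5L, 50L, 200L, 350L, 450L),
    category = "lab_test", cost_eur_2019 = 10, source = "cost_item")
  cfg <- test_config()
  a <- attribute_lot(data.table::copy(led), lots, cfg)
  expect_equal(a$lot_number, c(NA, 1L, 1L, 2L, 2L))
  cfg2 <- test_config(attach_between_lots = "drop")
  a2 <- attribute_lot(data.table::copy(led), lots, cfg2)
  expect_equal(a2$lot_number, c(NA, 1L, NA, 2L, NA))
})

test_that("MM-admin by-LOT table components add up to their totals", {
  sc <- sim_config(n_patients = 60, seed = 12)
  pop <- generate_population(sc)
  cfg <- mmlot_config()
  b <- build_cohort(pop, cfg)
  lots <- derive_lots(pop$dispensings, b$followup, cfg$lot, cfg$catalogue)
  led <- build_cost_ledger(pop, b$followup, cfg)
  led <- tag_mm_related(tag_mm_treatment_admin(led, cfg), cfg)
  led <- attribute_lot(led, lots, cfg)
  sct <- detect_sct(pop$stays, pop$procedures, b$followup, cfg)
  tab <- build_mm_admin_table(led, b$followup, lots, sct)
  for (s in unique(tab$stratum)) {
    t <- tab[stratum == s]
    drugs <- t[component %in% c("high_cost_drug",
                                "temporary_authorised_drug",
                                "retrocession_drug", "community_drug"),
               sum(sum_eur)]
    expect_equal(t[component == "mm_treatment", sum_eur],
                 drugs + t[component == "chemo_session_mm", sum_eur])
    expect_equal(t[component == "total_mm_treatment_admin", sum_eur],
                 t[component == "mm_treatment", sum_eur] +
                   t[component == "transport_linked", sum_eur] +
                   t[component == "sick_leave_linked", sum_eur])
  }
  # the total stratum covers the whole flagged ledger
  expect_equal(tab[stratum == "total" &
                     component == "total_mm_treatment_admin", sum_eur],
               sum(led[mm_treatment_admin == TRUE, cost_eur_2019]))
})
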