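# Shared fixtures: a tiny three-drug catalogue with pinned grace periods,
# dispensing-stream builders on a day grid, and claim-table scaffolds.

ORIGIN <- as.Date("2014-01-01")

# test drugs A/B/C with explicit grace values (42/49/30 days)
abc_catalogue <- function() {
  data.table::data.table(
    atc_code = c("TSTA", "TSTB", "TSTC", "TSTX"),
    drug_name = c("A", "B", "C", "steroid"),
    mm_indicated = c(TRUE, TRUE, TRUE, TRUE),
    observability = c("full", "full", "full", "partial"),
    setting_class = c("community", "high_cost", "retrocession",
                      "community"),
    grace_days = c(42L, 49L, 30L, 42L),
    lot_exempt = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# dispensings of drugs named by letter at integer day offsets from ORIGIN
make_disp <- function(drugs, days, patient = "P1", cost = 100) {
  ct <- abc_catalogue()
  data.table::data.table(
    patient_id = patient,
    atc_code = ct$atc_code[match(drugs, ct$drug_name)],
    drug_label = drugs,
    dispense_date = ORIGIN + as.integer(days),
    setting_class = ct$setting_class[match(drugs, ct$drug_name)],
    packs = 1L, cost_eur = cost)
}

make_fu <- function(patient = "P1", index = 0L, end = 1000L) {
  data.table::data.table(patient_id = patient,
                         index_date = ORIGIN + as.integer(index),
                         end_date = ORIGIN + as.integer(end),
                         end_reason = "end_of_observation",
                         months = (as.integer(end) - as.integer(index)) /
                           30.4375)
}

# minimal diagnosis records
make_diag <- function(patient, codes, days, sources) {
  data.table::data.table(patient_id = patient, icd10_code = codes,
                         date = ORIGIN + as.integer(days),
                         source = sources)
}

# one fully specified small population for cohort tests
tiny_claims <- function() {
  pts <- data.table::data.table(
    patient_id = c("P1", "P2"),
    birth_year = c(1950L, 1944L), sex = c("M", "F"),
    general_scheme = c(TRUE, TRUE),
    death_date = as.Date(c(NA, NA)),
    coverage_end_date = as.Date(c(NA, NA)))
  stays <- data.table::data.table(
    patient_id = c("P1", "P1"),
    admit_date = ORIGIN + c(0L, 30L),
    discharge_date = ORIGIN + c(3L, 31L),
    stay_type = "mco_complete", drg_code = "DRGMED",
    primary_dx = c("C900", "C901"), related_dx = "", associated_dx = "",
    cost_eur = 1000)
  list(patients = pts,
       diagnoses = make_diag("P2", c("C900", "C900"), c(10L, 40L),
                             c("hospital_associated", "long_term_disease")),
       dispensings = data.table::rbindlist(list(
         make_disp("A", c(5, 33, 61), patient = "P1"),
         make_disp("A", c(15, 43), patient = "P2"))),
       stays = stays,
       procedures = data.table::data.table(
         patient_id = character(0), date = as.Date(character(0)),
         ccam_code = character(0), cost_eur = numeric(0)),
       cost_items = data.table::data.table(
         patient_id = c("P1", "P2"), date = ORIGIN + c(100L, 200L),
         category = "physician_visit", cost_eur = 25, days = 0L))
}

# configuration matched to the fixtures: index window covering ORIGIN
test_config <- function(...) {
  mmlot_config(inclusion_start = as.Date("2013-01-01"),
               inclusion_end = as.Date("2018-12-31"),
               catalogue = data.table::rbindlist(
                 list(default_drug_catalogue(), abc_catalogue())), ...)
}
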