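HCRU_CATEGORIES <- c(
  "hospitalisation_excl_chemo", "chemo_session", "home_hospitalisation",
  "rehab", "emergency",
  "high_cost_drug", "temporary_authorised_drug", "retrocession_drug",
  "community_drug",
  "lab_test", "medical_procedure", "physician_visit",
  "other_professional_visit", "transport", "medical_device",
  "sick_leave_invalidity")

HOSPITAL_CATEGORIES <- c("hospitalisation_excl_chemo", "chemo_session",
                         "home_hospitalisation", "rehab", "emergency")
DRUG_CATEGORIES <- c("high_cost_drug", "temporary_authorised_drug",
                     "retrocession_drug", "community_drug")
OTHER_CATEGORIES <- setdiff(HCRU_CATEGORIES,
                            c(HOSPITAL_CATEGORIES, DRUG_CATEGORIES))
# outpatient categories never attributable to MM under the MM-related rule
MM_EXCLUDED_CATEGORIES <- c("lab_test", "medical_procedure",
                            "physician_visit", "other_professional_visit",
                            "medical_device")

STAY_TYPE_CATEGORY <- c(mco_complete = "hospitalisation_excl_chemo",
                        chemo_session = "chemo_session",
                        home = "home_hospitalisation",
                        rehab = "rehab",
                        emergency = "emergency")
SETTING_CATEGORY <- c(high_cost = "high_cost_drug",
                      temporary_authorised = "temporary_authorised_drug",
                      retrocession = "retrocession_drug",
                      community = "community_drug")

#' Annualise costs to reference-year prices
#'
#' Multiplies each cost by the price-index factor of its claim year. The
#' default configuration maps every year to 1 (identity), because the
#' actual deflators are jurisdiction data supplied at run time.
#'
#' @param cost numeric vector of non-negative raw costs (euros).
#' @param dates claim dates (used only for the year).
#' @param price_index named numeric vector, year -> multiplier.
#' @return numeric vector of reference-year costs.
#' @export
annualise <- function(cost, dates, price_index) {
  if (any(cost < 0, na.rm = TRUE)) stop("annualise: negative cost input")
  yrs <- format(as.Date(dates), "%Y")
  missing_years <- setdiff(unique(yrs), names(price_index))
  if (length(missing_years)) {
    stop("annualise: price index has no entry for year(s) ",
         paste(missing_years, collapse = ", "))
  }
  cost * unname(price_index[yrs])
}

#' Build the per-patient cost ledger
#'
#' Flattens every claim of cohort patients into one dated, categorised
#' cost row, restricted to the follow-up interval and annualised to
#' reference-year prices. Stay rows keep their diagnoses and dates so the
#' MM attribution rules can be evaluated on the ledger alone.
#'
#' @param claims list of claims tables.
#' @param follow_up data.table `patient_id`, `index_date`, `end_date`.
#' @param config an [mmlot_config()].
#' @return data.table with columns `patient_id`, `date`, `category`,
#'   `cost_eur_2019`, `source`, plus carriers (`drug_label`,
#'   `setting_class`, `atc_code`, `stay_type`, `primary_dx`, `related_dx`,
#'   `associated_dx`, `discharge_date`, `days`) and flag columns
#'   `mm_treatment_admin`, `mm_related`, `aoe_event` initialised FALSE.
#' @export
build_cost_ledger <- function(claims, follow_up, config = mmlot_config()) {
  fu <- data.table::as.data.table(follow_up)[, .(patient_id, index_date,
                                                 end_date)]
  rows <- list()
  dp <- data.table::as.data.table(claims$dispensings)
  if (nrow(dp)) {
    rows$disp <- dp[, .(patient_id, date = dispense_date,
                        category = unname(SETTING_CATEGORY[setting_class]),
                        cost_eur = cost_eur, source = "dispensing",
                        drug_label, setting_class, atc_code)]
  }
  st <- data.table::as.data.table(claims$stays)
  if (nrow(st)) {
    rows$stay <- st[, .(patient_id, date = admit_date,
                        category = unname(STAY_TYPE_CATEGORY[stay_type]),
                        cost_eur = cost_eur, source = "stay",
                        stay_type, primary_dx, related_dx, associated_dx,
                        discharge_date)]
  }
  pr <- data.table::as.data.table(claims$procedures)
  if (!is.null(pr) && nrow(pr)) {
    rows$proc <- pr[, .(patient_id, date, category = "medical_procedure",
                        cost_eur = cost_eur, source = "procedure")]
  }
  ci <- data.table::as.data.table(claims$cost_items)
  if (nrow(ci)) {
    bad <- setdiff(unique(ci$category), HCRU_CATEGORIES)
    if (length(bad)) {
      stop("build_cost_ledger: unknown cost_items category: ",
           paste(bad, collapse = ", "))
    }
    rows$item <- ci[, .(patient_id, date, category, cost_eur = cost_eur,
                        source = "cost_item", days)]
  }
  led <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  if (is.null(led) || !nrow(led)) {
    led <- data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0)),
                                  category = character(0),
                                  cost_eur = numeric(0),
                                  source = character(0))
  }
  led <- merge(led, fu, by = "patient_id")
  led <- led[date >= index_date & date <= end_date]
  led[, cost_eur_2019 := annualise(cost_eur, date, config$price_index)]
  led[, `:=`(mm_treatment_admin = FALSE, mm_related = FALSE,
             aoe_event = FALSE)]
  led[order(patient_id, date, category)]
}

# anchor intervals [start, end] after which linked items may follow
link_within <- function(items_dates, items_pid, anchors, link_days) {
  if (!nrow(anchors) || !length(items_dates)) {
    return(rep(FALSE, length(items_dates)))
  }
  flag <- rep(FALSE, length(items_dates))
  idx <- split(seq_along(items_dates), items_pid)
  anc <- split(anchors, by = "patient_id")
  for (pid in intersect(names(idx), names(anc))) {
    a <- anc[[pid]]
    for (k in idx[[pid]]) {
      d <- items_dates[k]
      if (any(d >= a$from & d <= a$to + link_days)) flag[k] <- TRUE
    }
  }
  flag
}

#' Flag costs of MM treatment administration
#'
#' Sets `mm_treatment_admin` on: dispensings of MM-indicated drugs (any
#' setting, hospital high-cost and outpatient alike); chemotherapy-session
#' stays whose main diagnosis is a chemotherapy-session code and whose
#' related diagnosis is MM (the entire stay cost counts); transport dated
#' on, or within `transport_link_days` after, such a stay or an MM drug
#' dispensing; and sick leave starting within `sickleave_link_days` after
#' an MM treatment or such a stay.
#'
#' @param ledger output of [build_cost_ledger()].
#' @param config an [mmlot_config()].
#' @return the ledger with `mm_treatment_admin` (and the implied
#'   `mm_related`) updated, invisibly by reference semantics of
#'   data.table; also returned.
#' @export
tag_mm_treatment_admin <- function(ledger, config = mmlot_config()) {
  led <- data.table::as.data.table(ledger)
  cl <- config$code_lists
  mm_atc <- config$catalogue[mm_indicated == TRUE, atc_code]

  drug_rows <- led$source == "dispensing" & led$atc_code %in% mm_atc
  chemo_rows <- led$source == "stay" & led$category == "chemo_session" &
    icd10_match_prefix(icd10_norm(led$primary_dx), cl$chemo_session_codes) &
    is_mm_code(led$related_dx, cl)
  led[drug_rows | chemo_rows, mm_treatment_admin := TRUE]

  anchors <- data.table::rbindlist(list(
    led[drug_rows, .(patient_id, from = date, to = date)],
    led[chemo_rows, .(patient_id, from = date,
                      to = data.table::fifelse(is.na(discharge_date), date,
                                               discharge_date))]
  ), use.names = TRUE)
  tr <- which(led$category == "transport")
  if (length(tr)) {
    hit <- link_within(led$date[tr], led$patient_id[tr], anchors,
                       config$transport_link_days)
    led[tr[hit], mm_treatment_admin := TRUE]
  }
  sl <- which(led$category == "sick_leave_invalidity")
  if (length(sl)) {
    hit <- link_within(led$date[sl], led$patient_id[sl], anchors,
                       config$sickleave_link_days)
    led[sl[hit], mm_treatment_admin := TRUE]
  }
  led[mm_treatment_admin == TRUE, mm_related := TRUE]
  led[]
}

#' Flag costs related to MM
#'
#' `mm_related` is the superset of `mm_treatment_admin` plus: all stays
#' with a primary or associated MM diagnosis, all home hospitalisations
#' with any MM diagnosis, and rehabilitation stays admitted within
#' `rehab_link_days` of the discharge of an MM-related stay. Outpatient
#' laboratory tests, imaging/procedures, physician and paramedic visits
#' and medical devices are never MM-related.
#'
#' @param ledger ledger with `mm_treatment_admin` already computed.
#' @param config an [mmlot_config()].
#' @return the ledger with `mm_related` updated.
#' @export
tag_mm_related <- function(ledger, config = mmlot_config()) {
  led <- data.table::as.data.table(ledger)
  cl <- config$code_lists
  stay <- led$source == "stay"
  mm_stay <- stay & (is_mm_code(led$primary_dx, cl) |
                       is_mm_code(led$associated_dx, cl))
  home_mm <- stay & led$category == "home_hospitalisation" &
    (is_mm_code(led$primary_dx, cl) | is_mm_code(led$related_dx, cl) |
       is_mm_code(led$associated_dx, cl))
  led[(mm_stay | home_mm), mm_related := TRUE]

  # rehab directly following an MM-related stay
  anchors <- led[source == "stay" & mm_related == TRUE,
                 .(patient_id, from = date,
                   to = data.table::fifelse(is.na(discharge_date), date,
                                            discharge_date))]
  rb <- which(led$category == "rehab" & led$source == "stay")
  if (length(rb) && nrow(anchors)) {
    hit <- link_within(led$date[rb], led$patient_id[rb],
                       anchors[, .(patient_id, from = to, to = to)],
                       config$rehab_link_days)
    led[rb[hit], mm_related := TRUE]
  }
  led[category %in% MM_EXCLUDED_CATEGORIES, mm_related := FALSE]
  # flags must stay monotone after the exclusion
  led[category %in% MM_EXCLUDED_CATEGORIES, mm_treatment_admin := FALSE]
  led[]
}

#' Person-years and person-months of follow-up
#'
#' @param follow_up data.table with `index_date` and `end_date`.
#' @param first_year truncate each patient's interval to the first 365
#'   days after index.
#' @return numeric scalar (sum over patients).
#' @export
person_years <- function(follow_up, first_year = FALSE) {
  d <- followup_days(follow_up, first_year)
  sum(days_to_years(d))
}

#' @rdname person_years
#' @export
person_months <- function(follow_up, first_year = FALSE) {
  d <- followup_days(follow_up, first_year)
  sum(days_to_months(d))
}

followup_days <- function(follow_up, first_year = FALSE) {
  fu <- data.table::as.data.table(follow_up)
  d <- as.integer(fu$end_date - fu$index_date)
  if (first_year) d <- pmin(d, 365L)
  pmax(d, 0L)
}

#' Per-patient-per-year rate
#'
#' Total quantity divided by the person-years of the whole stratum,
#' regardless of individual exposure (non-users contribute denominator).
#'
#' @param total summed quantity (cost or count).
#' @param py person-years, see [person_years()].
#' @return rate, or `NA` when `py` is zero.
#' @export
pppy <- function(total, py) if (py > 0) total / py else NA_real_

#' Per-patient-per-month cost
#'
#' Sum of all selected costs divided by the summed observation months.
#' With `first_year = TRUE` both numerator and denominator truncate to
#' each patient's first 365 days after index.
#'
#' @param ledger cost ledger (rows already restricted to the follow-up
#'   window); any subset may be passed.
#' @param follow_up follow-up table for the same stratum.
#' @param first_year logical.
#' @return K-euro-free rate in euros per month; `NA` when no person-time.
#' @export
pppm <- function(ledger, follow_up, first_year = FALSE) {
  led <- data.table::as.data.table(ledger)
  if (first_year && nrow(led)) {
    fu <- data.table::as.data.table(follow_up)
    led <- merge(led[, .(patient_id, date, cost_eur_2019)],
                 fu[, .(patient_id, index_date)], by = "patient_id")
    led <- led[date <= index_date + 365L]
  }
  pm <- person_months(follow_up, first_year)
  if (pm <= 0) return(NA_real_)
  sum(led$cost_eur_2019) / pm
}

#' Event-of-interest hospitalisation accounting
#'
#' A stay is an event of interest when its primary diagnosis matches the
#' configured AE code list; each qualifying stay counts as one event.
#' Reports, per stratum: number of events, number and share of patients
#' with at least one event, events per patient-year, AE-stay cost, and
#' the AE share of all hospitalisation cost.
#'
#' @param ledger tagged cost ledger.
#' @param follow_up follow-up table for the stratum (defines N and
#'   person-time).
#' @param config an [mmlot_config()].
#' @param first_year restrict to the first 365 days after index.
#' @return one-row data.table of the measures above (also sets
#'   `aoe_event` on the ledger rows of qualifying stays when called on the
#'   full ledger).
#' @export
aoe_hospitalisations <- function(ledger, follow_up,
                                 config = mmlot_config(),
                                 first_year = FALSE) {
  led <- data.table::as.data.table(ledger)
  fu <- data.table::as.data.table(follow_up)
  led <- led[patient_id %in% fu$patient_id]
  if (first_year) {
    led <- merge(led, fu[, .(patient_id, fy_end = index_date + 365L)],
                 by = "patient_id")
    led <- led[date <= fy_end]
  }
  stays <- led[source == "stay"]
  qual <- stays[icd10_match_prefix(icd10_norm(primary_dx),
                                   config$code_lists$aoe_codes)]
  n_pat <- data.table::uniqueN(fu$patient_id)
  py <- person_years(fu, first_year)
  hosp_cost <- sum(stays$cost_eur_2019)
  data.table::data.table(
    n_events = nrow(qual),
    n_patients = data.table::uniqueN(qual$patient_id),
    pct_patients = if (n_pat > 0)
      100 * data.table::uniqueN(qual$patient_id) / n_pat else NA_real_,
    events_pppy = pppy(nrow(qual), py),
    cost_eur = sum(qual$cost_eur_2019),
    pct_of_hospitalisation_cost = if (hosp_cost > 0)
      100 * sum(qual$cost_eur_2019) / hosp_cost else NA_real_)
}

#' Mark event-of-interest stays on the ledger
#'
#' @param ledger cost ledger.
#' @param config an [mmlot_config()].
#' @return ledger with `aoe_event` set on qualifying stay rows.
#' @export
tag_aoe <- function(ledger, config = mmlot_config()) {
  led <- data.table::as.data.table(ledger)
  led[, aoe_event := source == "stay" &
        icd10_match_prefix(icd10_norm(primary_dx),
                           config$code_lists$aoe_codes)]
  led[]
}

#' Attribute ledger rows to lines of therapy
#'
#' Each row is assigned the line whose `[start, end]` interval contains
#' its date; rows dated between two lines attach to the most recent prior
#' line (or are dropped when `attach_between_lots = "drop"`); rows before
#' the first line get `NA`.
#'
#' @param ledger cost ledger.
#' @param lots output of [derive_lots()].
#' @param config an [mmlot_config()].
#' @return ledger with an integer `lot_number` column.
#' @export
attribute_lot <- function(ledger, lots, config = mmlot_config()) {
  led <- data.table::as.data.table(ledger)
  lt <- data.table::as.data.table(lots)
  led[, lot_number := NA_integer_]
  if (!nrow(lt) || !nrow(led)) return(led[])
  lt_by <- split(lt, by = "patient_id")
  led_idx <- split(seq_len(nrow(led)), led$patient_id)
  for (pid in intersect(names(led_idx), names(lt_by))) {
    l <- lt_by[[pid]][order(start)]
    rows <- led_idx[[pid]]
    dts <- led$date[rows]
    pos <- findInterval(as.integer(dts), as.integer(l$start))
    assigned <- ifelse(pos >= 1L, l$lot_number[pmax(pos, 1L)], NA_integer_)
    if (config$attach_between_lots == "drop") {
      inside <- pos >= 1L & dts <= l$end[pmax(pos, 1L)]
      assigned[!inside] <- NA_integer_
    }
    data.table::set(led, i = rows, j = "lot_number",
                    value = as.integer(assigned))
  }
  led[]
}

#' All-cause cost table (overall-population shape)
#'
#' One row per HCRU category plus the three group rows (all
#' hospitalisation, all treatment, all other costs) and the grand total.
#' Columns: total cost (sum, mean per person, share, PPPY) and first-year
#' cost (sum, mean, share, PPPM). Values are full precision, in euros
#' except where the name says `meur`/`keur`; rendering rounds.
#'
#' @param ledger tagged cost ledger for the stratum.
#' @param follow_up follow-up table for the same stratum (defines N and
#'   person-time).
#' @return data.table, one row per category/group, with a `level` column
#'   (`category`, `group`, `total`).
#' @export
build_allcause_table <- function(ledger, follow_up) {
  led <- data.table::as.data.table(ledger)
  fu <- data.table::as.data.table(follow_up)
  n <- nrow(fu)
  py <- person_years(fu)
  pm_fy <- person_months(fu, first_year = TRUE)
  fy <- merge(led[, .(patient_id, date, cost_eur_2019, category)],
              fu[, .(patient_id, index_date)], by = "patient_id")
  fy <- fy[date <= index_date + 365L]
  sum_by <- function(dt) {
    s <- dt[, .(s = sum(cost_eur_2019)), by = "category"]
    v <- s$s[match(HCRU_CATEGORIES, s$category)]
    ifelse(is.na(v), 0, v)
  }
  tot <- sum_by(led)
  fys <- sum_by(fy)
  base <- data.table::data.table(category = HCRU_CATEGORIES,
                                 level = "category",
                                 sum_eur = tot, fy_sum_eur = fys)
  grp <- function(name, cats) {
    data.table::data.table(category = name, level = "group",
                           sum_eur = sum(base[category %in% cats, sum_eur]),
                           fy_sum_eur = sum(base[category %in% cats,
                                                 fy_sum_eur]))
  }
  tab <- data.table::rbindlist(list(
    base,
    grp("all_hospitalisation", HOSPITAL_CATEGORIES),
    grp("all_treatment", DRUG_CATEGORIES),
    grp("all_other", OTHER_CATEGORIES),
    data.table::data.table(category = "total", level = "total",
                           sum_eur = sum(base$sum_eur),
                           fy_sum_eur = sum(base$fy_sum_eur))
  ), use.names = TRUE)
  total_sum <- sum(base$sum_eur)
  total_fy <- sum(base$fy_sum_eur)
  tab[, `:=`(
    mean_pp_eur = if (n > 0) sum_eur / n else NA_real_,
    share_pct = if (total_sum > 0) 100 * sum_eur / total_sum else NA_real_,
    pppy_eur = pppy(1, py) * sum_eur,
    fy_mean_pp_eur = if (n > 0) fy_sum_eur / n else NA_real_,
    fy_share_pct = if (total_fy > 0) 100 * fy_sum_eur / total_fy
                   else NA_real_,
    fy_pppm_eur = if (!is.na(pm_fy) && pm_fy > 0) fy_sum_eur / pm_fy
                  else NA_real_
  )]
  tab[]
}

#' MM-treatment-administration cost table by stratum
#'
#' Reproduces the by-line treatment-administration breakdown: for each
#' stratum, the mean cost per stratum patient, the summed cost, and the
#' first-year monthly cost of each MM-attributed component (chemotherapy
#' sessions, the four drug classes, their treatment total, linked
#' transport and sick leave, and the overall MM-treatment total), plus
#' the MM-treatment share of the stratum's total all-cause cost.
#'
#' @param ledger tagged ledger with `lot_number` attributed (see
#'   [attribute_lot()]).
#' @param follow_up cohort follow-up table.
#' @param lots derived lines (defines the by-line strata membership).
#' @param sct SCT status table (`patient_id`, `sct`).
#' @param max_line lines above this aggregate into `LOT<max_line>+`
#'   (default 5).
#' @return data.table with columns `stratum`, `component`, `mean_pp_eur`,
#'   `sum_eur`, `fy_pppm_eur`, plus per-stratum `share_of_total_pct` on
#'   the `total_mm_treatment_admin` component.
#' @export
build_mm_admin_table <- function(ledger, follow_up, lots, sct,
                                 max_line = 5L) {
  led <- data.table::as.data.table(ledger)
  fu <- data.table::as.data.table(follow_up)
  lt <- data.table::as.data.table(lots)
  sct <- data.table::as.data.table(sct)
  led[, lot_cap := pmin(lot_number, max_line)]
  lt[, lot_cap := pmin(lot_number, max_line)]

  comp <- function(dt) {
    list(
      chemo_session_mm = sum(dt[category == "chemo_session" &
                                  mm_treatment_admin == TRUE,
                                cost_eur_2019]),
      high_cost_drug = sum(dt[category == "high_cost_drug" &
                                mm_treatment_admin == TRUE, cost_eur_2019]),
      temporary_authorised_drug = sum(dt[category ==
                                           "temporary_authorised_drug" &
                                           mm_treatment_admin == TRUE,
                                         cost_eur_2019]),
      retrocession_drug = sum(dt[category == "retrocession_drug" &
                                   mm_treatment_admin == TRUE,
                                 cost_eur_2019]),
      community_drug = sum(dt[category == "community_drug" &
                                mm_treatment_admin == TRUE, cost_eur_2019]),
      transport_linked = sum(dt[category == "transport" &
                                  mm_treatment_admin == TRUE,
                                cost_eur_2019]),
      sick_leave_linked = sum(dt[category == "sick_leave_invalidity" &
                                   mm_treatment_admin == TRUE,
                                 cost_eur_2019]),
      all_cause_total = sum(dt$cost_eur_2019))
  }
  one_stratum <- function(name, led_s, fu_s, led_fy, pm_fy) {
    s <- comp(led_s)
    drug_total <- s$high_cost_drug + s$temporary_authorised_drug +
      s$retrocession_drug + s$community_drug
    mm_total <- s$chemo_session_mm + drug_total + s$transport_linked +
      s$sick_leave_linked
    f <- comp(led_fy)
    f_drug <- f$high_cost_drug + f$temporary_authorised_drug +
      f$retrocession_drug + f$community_drug
    f_mm <- f$chemo_session_mm + f_drug + f$transport_linked +
      f$sick_leave_linked
    n <- nrow(fu_s)
    components <- c("chemo_session_mm", "high_cost_drug",
                    "temporary_authorised_drug", "retrocession_drug",
                    "community_drug", "mm_treatment",
                    "transport_linked", "sick_leave_linked",
                    "total_mm_treatment_admin")
    sums <- c(s$chemo_session_mm, s$high_cost_drug,
              s$temporary_authorised_drug, s$retrocession_drug,
              s$community_drug, drug_total + s$chemo_session_mm,
              s$transport_linked, s$sick_leave_linked, mm_total)
    fy_sums <- c(f$chemo_session_mm, f$high_cost_drug,
                 f$temporary_authorised_drug, f$retrocession_drug,
                 f$community_drug, f_drug + f$chemo_session_mm,
                 f$transport_linked, f$sick_leave_linked, f_mm)
    data.table::data.table(
      stratum = name, n = n, component = components, sum_eur = sums,
      mean_pp_eur = if (n > 0) sums / n else NA_real_,
      fy_pppm_eur = if (!is.na(pm_fy) && pm_fy > 0) fy_sums / pm_fy
                    else NA_real_,
      share_of_total_pct = data.table::fifelse(
        components == "total_mm_treatment_admin" & s$all_cause_total > 0,
        100 * mm_total / s$all_cause_total, NA_real_))
  }
  first_year_rows <- function(led_s, fu_s) {
    x <- merge(led_s, fu_s[, .(patient_id, index_date)],
               by = "patient_id", suffixes = c("", ".fu"))
    x[date <= index_date + 365L]
  }
  out <- list()
  for (k in seq_len(max_line)) {
    ids <- unique(lt[lot_cap == k, patient_id])
    fu_s <- fu[patient_id %in% ids]
    led_s <- led[lot_cap == k & patient_id %in% ids]
    # first-year monthly rate over person-months spent in the line within
    # the first year after index
    lt_s <- merge(lt[lot_cap == k],
                  fu_s[, .(patient_id, index_date)], by = "patient_id")
    lt_s[, fy_end := index_date + 365L]
    lt_s[, overlap := pmax(0L, as.integer(pmin(end, fy_end) -
                                            pmax(start, index_date)))]
    pm_fy <- sum(days_to_months(lt_s$overlap))
    led_fy <- first_year_rows(led_s, fu_s)
    nm <- if (k == max_line) paste0("LOT", k, "+") else paste0("LOT", k)
    out[[nm]] <- one_stratum(nm, led_s, fu_s, led_fy, pm_fy)
  }
  sct_ids <- sct[sct == TRUE, patient_id]
  groups <- list(SCT = sct_ids, total = fu$patient_id)
  for (nm in names(groups)) {
    fu_s <- fu[patient_id %in% groups[[nm]]]
    led_s <- led[patient_id %in% groups[[nm]]]
    pm_fy <- person_months(fu_s, first_year = TRUE)
    led_fy <- first_year_rows(led_s, fu_s)
    out[[nm]] <- one_stratum(nm, led_s, fu_s, led_fy, pm_fy)
  }
  data.table::rbindlist(out, use.names = TRUE)
}

#' HCRU use by line of therapy
#'
#' Per stratum (each line, the SCT subgroup, and the total cohort):
#' number and share of patients using each HCRU category and the use rate
#' per patient-year (counts of stays/visits/claims; days for sick leave).
#'
#' @param ledger ledger with `lot_number` attributed.
#' @param follow_up cohort follow-up.
#' @param lots derived lines.
#' @param sct SCT status table.
#' @param max_line aggregate lines above this (default 5).
#' @return data.table `stratum`, `category`, `n_users`, `pct_users`,
#'   `rate_pppy`.
#' @export
build_hcru_by_lot <- function(ledger, follow_up, lots, sct, max_line = 5L) {
  led <- data.table::as.data.table(ledger)
  fu <- data.table::as.data.table(follow_up)
  lt <- data.table::as.data.table(lots)
  sct <- data.table::as.data.table(sct)
  led[, lot_cap := pmin(lot_number, max_line)]
  lt[, lot_cap := pmin(lot_number, max_line)]
  one <- function(name, led_s, fu_s, py) {
    n <- data.table::uniqueN(fu_s$patient_id)
    g <- led_s[, .(
      n_users = data.table::uniqueN(patient_id),
      volume = if (.BY$category == "sick_leave_invalidity")
        sum(pmax(days, 1L, na.rm = TRUE)) else .N
    ), by = "category"]
    g[, `:=`(stratum = name,
             pct_users = if (n > 0) 100 * n_users / n else NA_real_,
             rate_pppy = if (py > 0) volume / py else NA_real_)]
    g[, .(stratum, category, n_users, pct_users, rate_pppy)]
  }
  out <- list()
  for (k in seq_len(max_line)) {
    ids <- unique(lt[lot_cap == k, patient_id])
    fu_s <- fu[patient_id %in% ids]
    lt_s <- lt[lot_cap == k]
    py <- sum(days_to_years(pmax(0L, as.integer(lt_s$end - lt_s$start))))
    nm <- if (k == max_line) paste0("LOT", k, "+") else paste0("LOT", k)
    out[[nm]] <- one(nm, led[lot_cap == k & patient_id %in% ids], fu_s, py)
  }
  for (nm in c("SCT", "total")) {
    ids <- if (nm == "SCT") sct[sct == TRUE, patient_id] else
      fu$patient_id
    fu_s <- fu[patient_id %in% ids]
    out[[nm]] <- one(nm, led[patient_id %in% ids], fu_s,
                     person_years(fu_s))
  }
  data.table::rbindlist(out, use.names = TRUE)
}
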