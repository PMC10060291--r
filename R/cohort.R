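#' Confirm multiple-myeloma diagnosis from claims records
#'
#' A patient's MM diagnosis is confirmed when the claims carry at least 2
#' hospital-stay MM diagnosis records (primary, related or associated
#' C90/C90.x, from distinct stays) or at least 1 hospital-stay record plus
#' at least 1 long-term-disease MM registration. The earliest MM diagnosis
#' date inside the inclusion window is returned as the candidate index
#' date.
#'
#' @param diagnoses data.table of diagnosis records with columns
#'   `patient_id`, `icd10_code`, `date`, `source` (one of
#'   `hospital_primary`, `hospital_related`, `hospital_associated`,
#'   `long_term_disease`). Use [extract_diagnoses()] to unroll hospital
#'   stays into this shape.
#' @param config an [mmlot_config()].
#' @return data.table with one row per patient appearing in `diagnoses`:
#'   `patient_id`, `confirmed`, `first_mm_date` (earliest MM record
#'   anywhere), `index_candidate` (earliest MM record inside the inclusion
#'   window, NA if none).
#' @export
confirm_mm_diagnosis <- function(diagnoses, config = mmlot_config()) {
  dg <- data.table::as.data.table(diagnoses)
  dg <- dg[is_mm_code(dg$icd10_code, config$code_lists)]
  if (!nrow(dg)) {
    return(data.table::data.table(patient_id = character(0),
                                  confirmed = logical(0),
                                  first_mm_date = as.Date(character(0)),
                                  index_candidate = as.Date(character(0))))
  }
  hosp_src <- c("hospital_primary", "hospital_related",
                "hospital_associated")
  incl_lo <- config$inclusion_start
  incl_hi <- config$inclusion_end
  dg[, {
    hosp <- source %in% hosp_src
    # hospital records on distinct dates count as distinct stays
    n_hosp <- data.table::uniqueN(date[hosp])
    n_ltd <- sum(source == "long_term_disease")
    confirmed <- n_hosp >= 2L || (n_hosp >= 1L && n_ltd >= 1L)
    inwin <- date >= incl_lo & date <= incl_hi
    list(confirmed = confirmed,
         first_mm_date = min(date),
         index_candidate = if (any(inwin)) min(date[inwin])
                           else as.Date(NA))
  }, by = "patient_id"]
}

#' Unroll hospital-stay diagnoses into diagnosis records
#'
#' Converts the typed diagnosis columns of the stays table
#' (primary/related/associated) into the long `DiagnosisRecord` shape and
#' appends any standalone diagnosis records (e.g. long-term-disease
#' registrations).
#'
#' @param stays data.table of hospital stays.
#' @param diagnoses optional standalone diagnosis records (same shape as
#'   the output) to append.
#' @return data.table with columns `patient_id`, `icd10_code`, `date`,
#'   `source`.
#' @export
extract_diagnoses <- function(stays, diagnoses = NULL) {
  st <- data.table::as.data.table(stays)
  pick <- function(col, src) {
    x <- st[nzchar(trimws(ifelse(is.na(st[[col]]), "", st[[col]])))]
    if (!nrow(x)) return(NULL)
    data.table::data.table(patient_id = x$patient_id,
                           icd10_code = x[[col]], date = x$admit_date,
                           source = src)
  }
  out <- data.table::rbindlist(list(
    pick("primary_dx", "hospital_primary"),
    pick("related_dx", "hospital_related"),
    pick("associated_dx", "hospital_associated"),
    if (!is.null(diagnoses)) data.table::as.data.table(diagnoses)
  ), use.names = TRUE)
  if (is.null(out) || !nrow(out)) {
    out <- data.table::data.table(patient_id = character(0),
                                  icd10_code = character(0),
                                  date = as.Date(character(0)),
                                  source = character(0))
  }
  out[order(patient_id, date)]
}

#' Apply the eligibility algorithm
#'
#' Rules are evaluated in fixed order; the first failure is recorded:
#' 1. `age` — older than 18 years at index (default: at least 19 completed
#'    years, configurable to `>= 18`);
#' 2. `scheme` — affiliation with the general reimbursement scheme;
#' 3. `history` — at least `history_days` of observable history before
#'    index;
#' 4. `prior_mm` — no MM diagnosis record in the `prior_mm_days` before
#'    index (exclusive of the index date itself);
#' 5. `other_malignancy` — no other-malignancy record (C00–C97 excluding
#'    C90 and non-melanoma skin C44) in the `malignancy_years` before
#'    index;
#' 6. `untreated` / `late_treatment` — at least one MM-indicated drug
#'    dispensing in `[index, index + treatment_window_days]` (day 30
#'    inclusive); `untreated` when no MM drug is ever dispensed on/after
#'    index, `late_treatment` when the first one falls after the window.
#'
#' Missing demographics give verdict `missing_data`.
#'
#' @param patients patients table (`patient_id`, `birth_year`, `sex`,
#'   `general_scheme`, ...).
#' @param diagnoses long diagnosis records (see [extract_diagnoses()]).
#' @param dispensings dispensings table.
#' @param index data.table `patient_id`, `index_date` for confirmed
#'   patients.
#' @param config an [mmlot_config()].
#' @return data.table `patient_id`, `eligible`, `first_failed_rule`
#'   (`NA` when eligible), `evidence` (short human-readable note).
#' @export
apply_eligibility <- function(patients, diagnoses, dispensings, index,
                              config = mmlot_config()) {
  pts <- data.table::as.data.table(patients)
  dg <- data.table::as.data.table(diagnoses)
  dp <- data.table::as.data.table(dispensings)
  idx <- data.table::as.data.table(index)
  mm_drugs <- config$catalogue[mm_indicated == TRUE, atc_code]
  dp <- dp[atc_code %in% mm_drugs]
  if (!nrow(idx)) {
    return(data.table::data.table(patient_id = character(0),
                                  eligible = logical(0),
                                  first_failed_rule = character(0),
                                  evidence = character(0)))
  }
  res <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    pid <- idx$patient_id[i]
    t0 <- idx$index_date[i]
    p <- pts[patient_id == pid]
    fail <- NULL; note <- ""
    if (nrow(p) != 1L || is.na(p$birth_year)) {
      fail <- "missing_data"; note <- "no demographics record"
    }
    if (is.null(fail)) {
      # completed years approximated from birth year
      age <- as.integer(format(t0, "%Y")) - p$birth_year
      min_age <- if (config$age_rule == "gt18") 19L else 18L
      if (age < min_age) { fail <- "age"; note <- paste("age", age) }
    }
    if (is.null(fail) && !isTRUE(p$general_scheme)) {
      fail <- "scheme"; note <- "not in general scheme"
    }
    if (is.null(fail) &&
        as.integer(t0 - config$history_start) < config$history_days) {
      fail <- "history"
      note <- paste("history", as.integer(t0 - config$history_start), "d")
    }
    if (is.null(fail)) {
      d <- dg[patient_id == pid]
      mm <- d[is_mm_code(icd10_code, config$code_lists)]
      prior <- mm[date < t0 & date > t0 - config$prior_mm_days]
      if (nrow(prior)) {
        fail <- "prior_mm"
        note <- paste("MM record", format(max(prior$date)))
      } else {
        mal <- d[is_other_malignancy(icd10_code, config$code_lists)]
        mal <- mal[date < t0 &
                     date >= t0 - round(config$malignancy_years * DAYS_PER_YEAR)]
        if (nrow(mal)) {
          fail <- "other_malignancy"
          note <- paste(mal$icd10_code[1], format(mal$date[1]))
        }
      }
    }
    if (is.null(fail)) {
      dd <- dp[patient_id == pid & dispense_date >= t0, dispense_date]
      if (!length(dd)) {
        fail <- "untreated"; note <- "no MM drug dispensing after index"
      } else if (min(dd) > t0 + config$treatment_window_days) {
        fail <- "late_treatment"
        note <- paste("first dispensing", format(min(dd)))
      }
    }
    res[[i]] <- data.table::data.table(
      patient_id = pid, eligible = is.null(fail),
      first_failed_rule = if (is.null(fail)) NA_character_ else fail,
      evidence = note)
  }
  data.table::rbindlist(res)
}

#' Determine per-patient follow-up
#'
#' Follow-up runs from the index date to the earliest of: death, the start
#' of the first claim-free gap of at least `followup_gap_days` (the end is
#' then the last claim date before the gap; reason `disenrollment` when an
#' explicit coverage-termination date exists, otherwise
#' `lost_to_follow_up`), or the administrative study end
#' (`end_of_observation`). A trailing claim-free period reaching the study
#' end also counts as a gap. Months use the calendar-mean month
#' (days / 30.4375).
#'
#' @param claims list of claims tables (any of `dispensings`, `stays`,
#'   `procedures`, `cost_items` contribute claim dates; `patients`
#'   supplies death and coverage-termination dates).
#' @param index data.table `patient_id`, `index_date`.
#' @param config an [mmlot_config()].
#' @return data.table `patient_id`, `index_date`, `end_date`,
#'   `end_reason`, `months`.
#' @export
determine_follow_up <- function(claims, index, config = mmlot_config()) {
  idx <- data.table::as.data.table(index)
  if (!nrow(idx)) {
    return(data.table::data.table(patient_id = character(0),
                                  index_date = as.Date(character(0)),
                                  end_date = as.Date(character(0)),
                                  end_reason = character(0),
                                  months = numeric(0)))
  }
  pts <- data.table::as.data.table(claims$patients)
  ev <- claim_dates(claims)
  gap <- config$followup_gap_days
  send <- config$study_end

  out <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    pid <- idx$patient_id[i]
    t0 <- idx$index_date[i]
    p <- pts[patient_id == pid]
    death <- if (nrow(p)) p$death_date[1] else as.Date(NA)
    cov_end <- if (nrow(p) && "coverage_end_date" %in% names(p)) {
      p$coverage_end_date[1]
    } else as.Date(NA)
    dts <- sort(unique(c(t0, ev[patient_id == pid & date >= t0 &
                                  date <= send, date])))
    hard_end <- min(c(send, death), na.rm = TRUE)
    # first >= gap-day claim-free interval (incl. the tail to study end)
    bounds <- c(dts, hard_end)
    gaps <- diff(as.integer(bounds))
    g <- which(gaps >= gap)
    gap_end <- if (length(g)) dts[g[1]] else as.Date(NA)
    cand <- c(death = death, gap = gap_end,
              end_of_observation = send)
    end <- min(cand, na.rm = TRUE)
    reason <- names(cand)[which(cand == end)][1]
    if (reason == "gap") {
      reason <- if (!is.na(cov_end)) "disenrollment" else "lost_to_follow_up"
    }
    out[[i]] <- data.table::data.table(
      patient_id = pid, index_date = t0, end_date = end,
      end_reason = reason,
      months = days_to_months(as.integer(end - t0)))
  }
  data.table::rbindlist(out)
}

# all reimbursed-care event dates per patient, one long table
claim_dates <- function(claims) {
  grab <- function(dt, col) {
    if (is.null(dt) || !nrow(dt)) return(NULL)
    data.table::data.table(patient_id = dt$patient_id, date = dt[[col]])
  }
  out <- data.table::rbindlist(list(
    grab(claims$dispensings, "dispense_date"),
    grab(claims$stays, "admit_date"),
    grab(claims$procedures, "date"),
    grab(claims$cost_items, "date")
  ), use.names = TRUE)
  if (is.null(out) || !nrow(out)) {
    out <- data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0)))
  }
  out
}

#' Detect stem cell transplantation
#'
#' SCT status is positive when any hospital stay carries a configured SCT
#' DRG code or any procedure claim carries a configured SCT CCAM code
#' within the patient's follow-up interval. Graft type
#' (autologous/allogeneic) is read from the configured code-to-graft map.
#'
#' @param stays stays table; @param procedures procedures table.
#' @param follow_up output of [determine_follow_up()].
#' @param config an [mmlot_config()]; its `code_lists` must carry
#'   non-empty `sct_drg_codes`/`sct_ccam_codes`.
#' @return data.table `patient_id`, `sct`, `sct_date`, `graft_type`.
#' @export
detect_sct <- function(stays, procedures, follow_up,
                       config = mmlot_config()) {
  cl <- config$code_lists
  if (!length(cl$sct_drg_codes) && !length(cl$sct_ccam_codes)) {
    stop("detect_sct: SCT code lists are empty")
  }
  st <- data.table::as.data.table(stays)
  pr <- data.table::as.data.table(procedures)
  fu <- data.table::as.data.table(follow_up)
  hits <- data.table::rbindlist(list(
    if (nrow(st)) st[drg_code %in% cl$sct_drg_codes,
                     .(patient_id, date = admit_date, code = drg_code)],
    if (nrow(pr)) pr[ccam_code %in% cl$sct_ccam_codes,
                     .(patient_id, date, code = ccam_code)]
  ), use.names = TRUE)
  res <- fu[, .(patient_id, index_date, end_date)]
  if (!is.null(hits) && nrow(hits)) {
    hits <- merge(hits, res, by = "patient_id")
    hits <- hits[date >= index_date & date <= end_date]
    first <- hits[order(date), .SD[1], by = "patient_id"]
    first[, graft_type := unname(cl$sct_graft_types[code])]
    res <- merge(res, first[, .(patient_id, sct_date = date, graft_type)],
                 by = "patient_id", all.x = TRUE)
  } else {
    res[, `:=`(sct_date = as.Date(NA), graft_type = NA_character_)]
  }
  res[, sct := !is.na(sct_date)]
  res[, .(patient_id, sct, sct_date, graft_type)]
}

#' Charlson comorbidity score from ICD-10 claims
#'
#' Sums the weights of distinct Charlson conditions recorded at the index
#' date or during the year preceding it (window `[index - 365, index]`,
#' both ends inclusive). MM itself maps to the malignancy condition
#' (weight 2), so the minimum score in an MM cohort is 2.
#'
#' @param diagnoses long diagnosis records (see [extract_diagnoses()]).
#' @param index data.table `patient_id`, `index_date`.
#' @param weight_map prefix weight map, see [default_charlson_map()].
#' @return data.table `patient_id`, `score`, `conditions`
#'   (comma-joined condition names).
#' @export
charlson_score <- function(diagnoses, index,
                           weight_map = default_charlson_map()) {
  dg <- data.table::as.data.table(diagnoses)
  idx <- data.table::as.data.table(index)
  wm <- data.table::as.data.table(weight_map)
  wm[, icd10_prefix := icd10_norm(icd10_prefix)]
  if (!nrow(idx)) {
    return(data.table::data.table(patient_id = character(0),
                                  score = integer(0),
                                  conditions = character(0)))
  }
  out <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    pid <- idx$patient_id[i]
    t0 <- idx$index_date[i]
    codes <- icd10_norm(dg[patient_id == pid & date <= t0 &
                             date >= t0 - 365L, icd10_code])
    conds <- character(0); wts <- integer(0)
    if (length(codes)) {
      for (j in seq_len(nrow(wm))) {
        if (wm$condition[j] %in% conds) next
        if (any(startsWith(codes, wm$icd10_prefix[j]))) {
          conds <- c(conds, wm$condition[j])
          wts <- c(wts, wm$weight[j])
        }
      }
    }
    # a condition may appear under several prefixes; weights counted once
    keep <- !duplicated(conds)
    out[[i]] <- data.table::data.table(
      patient_id = pid, score = sum(wts[keep]),
      conditions = paste(sort(conds[keep]), collapse = ","))
  }
  data.table::rbindlist(out)
}

#' Build the study cohort from claims tables
#'
#' End-to-end cohort construction: diagnosis confirmation, index date,
#' eligibility, follow-up, SCT detection and Charlson scoring. Patients
#' whose diagnosis is not confirmed, or confirmed only outside the
#' inclusion window, are logged with reasons `diagnosis_unconfirmed` /
#' `no_inwindow_diagnosis`.
#'
#' @param claims named list of claims tables (`patients`, `diagnoses`,
#'   `dispensings`, `stays`, `procedures`, `cost_items`).
#' @param config an [mmlot_config()].
#' @return list with `cohort` (eligible patients: index, follow-up, SCT,
#'   Charlson), `followup`, `exclusion_log` (`patient_id`, `rule`,
#'   `evidence`), and `attrition` (stage, n remaining).
#' @export
build_cohort <- function(claims, config = mmlot_config()) {
  dg_long <- extract_diagnoses(claims$stays, claims$diagnoses)
  conf <- confirm_mm_diagnosis(dg_long, config)
  n0 <- data.table::uniqueN(claims$patients$patient_id)

  excl <- list()
  unconf <- conf[confirmed == FALSE, patient_id]
  no_mm <- setdiff(claims$patients$patient_id, conf$patient_id)
  if (length(c(unconf, no_mm))) {
    excl[[length(excl) + 1L]] <- data.table::data.table(
      patient_id = c(unconf, no_mm), rule = "diagnosis_unconfirmed",
      evidence = "fewer than 2 qualifying MM records")
  }
  conf <- conf[confirmed == TRUE]
  noidx <- conf[is.na(index_candidate), patient_id]
  if (length(noidx)) {
    excl[[length(excl) + 1L]] <- data.table::data.table(
      patient_id = noidx, rule = "no_inwindow_diagnosis",
      evidence = "no MM record inside the inclusion window")
  }
  idx <- conf[!is.na(index_candidate),
              .(patient_id, index_date = index_candidate)]
  n_confirmed <- nrow(idx)

  verdict <- apply_eligibility(claims$patients, dg_long,
                               claims$dispensings, idx, config)
  bad <- verdict[eligible == FALSE]
  if (nrow(bad)) {
    excl[[length(excl) + 1L]] <- bad[, .(patient_id,
                                         rule = first_failed_rule,
                                         evidence)]
  }
  keep <- verdict[eligible == TRUE, patient_id]
  idx <- idx[patient_id %in% keep]

  fu <- determine_follow_up(claims, idx, config)
  sct <- detect_sct(claims$stays, claims$procedures, fu, config)
  cci <- charlson_score(dg_long, idx, config$charlson_map)

  cohort <- merge(idx, claims$patients[, .(patient_id, birth_year, sex)],
                  by = "patient_id", all.x = TRUE)
  cohort[, age_at_index := as.integer(format(index_date, "%Y")) - birth_year]
  cohort <- Reduce(function(a, b) merge(a, b, by = "patient_id"),
                   list(cohort, fu[, .(patient_id, end_date, end_reason,
                                       months)],
                        sct, cci[, .(patient_id, charlson = score)]))

  exclusion_log <- if (length(excl)) {
    data.table::rbindlist(excl, use.names = TRUE)
  } else {
    data.table::data.table(patient_id = character(0), rule = character(0),
                           evidence = character(0))
  }
  attrition <- data.table::data.table(
    stage = c("all_patients", "mm_confirmed_inwindow", "eligible"),
    n = c(n0, n_confirmed, nrow(cohort)))
  list(cohort = cohort[order(patient_id)], followup = fu,
       exclusion_log = exclusion_log, attrition = attrition)
}
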