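#' Default per-line regimen menus for the synthetic generator
#'
#' Line 1 is dominated by bortezomib-based combinations (as observed in
#' French first-line MM practice in 2013-2018); later lines draw from a
#' wider menu of immunomodulatory-, proteasome-inhibitor- and
#' antibody-based regimens. Probabilities are illustrative, not estimates.
#'
#' @return list with elements `line1` and `line2plus`, each a list of
#'   `list(drugs = <character>, p = <numeric>)`, probabilities summing to 1.
#' @export
default_regimen_menu <- function() {
  list(
    line1 = list(
      list(drugs = c("bortezomib", "dexamethasone"), p = 0.62),
      list(drugs = c("bortezomib", "lenalidomide", "dexamethasone"),
           p = 0.23),
      list(drugs = c("bortezomib", "melphalan", "prednisone"), p = 0.12),
      list(drugs = c("lenalidomide", "dexamethasone"), p = 0.03)
    ),
    line2plus = list(
      list(drugs = c("lenalidomide", "dexamethasone"), p = 0.35),
      list(drugs = c("pomalidomide", "dexamethasone"), p = 0.15),
      list(drugs = c("daratumumab"), p = 0.12),
      list(drugs = c("carfilzomib", "dexamethasone"), p = 0.10),
      list(drugs = c("ixazomib", "lenalidomide", "dexamethasone"), p = 0.10),
      list(drugs = c("bortezomib", "dexamethasone"), p = 0.10),
      list(drugs = c("bendamustine", "prednisone"), p = 0.05),
      list(drugs = c("doxorubicine", "cyclophosphamide", "dexamethasone"),
           p = 0.03)
    )
  )
}

#' Synthetic claims simulation configuration
#'
#' Describes the world the generator emits: cohort size, study calendar,
#' age and transplant mix, the number of lines per patient, per-line
#' regimen menus and duration distributions, inter-line gaps, death
#' hazards, cost distributions and noise. Defaults emulate the qualitative
#' features of a French incident-MM claims cohort (2013-2018) and are
#' documented as illustrative; none are calibrated estimates.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer master seed; every stream the generator uses is
#'   derived from it, so identical `(config, seed)` gives identical output.
#' @param inclusion_start,inclusion_end,history_start,study_end study
#'   calendar (defaults 2013-01-01..2018-12-31, history from 2008-01-01).
#' @param sct_probability probability a patient belongs to the stem cell
#'   transplantation stratum (0.30).
#' @param age_mean,age_sd named numeric `c(sct=, nonsct=)`: age at index
#'   by stratum (58/8.1 and 73.5/9.7 years).
#' @param male_probability probability of male sex (0.52).
#' @param treatment_delay_max maximum days from diagnosis to first
#'   dispensing, drawn uniformly on 0..max (21; must stay inside the
#'   30-day active-treatment rule for eligible patients).
#' @param n_lot_probs named probabilities over the number of lines
#'   `0,1,2,3,4,5` where `0` means treated with non-identifiable drugs
#'   only (undetermined LOT) and `5` means five or more.
#' @param regimen_menu see [default_regimen_menu()].
#' @param lot_duration_median per-line median duration in days (declining
#'   with line, defaults 200, 150, 120, 90, 60); durations are lognormal
#'   around the median with `lot_duration_sdlog`.
#' @param lot_duration_sdlog lognormal shape for durations (0.55).
#' @param gap_between_lots `c(min=, max=)` uniform inter-line claim-free
#'   gap in days. The default 140..260 always exceeds grace + 90-day
#'   discontinuation gap, so every true boundary is recoverable.
#' @param death_hazard_month named per-month death hazard by stratum
#'   (`sct` 0.005, `nonsct` 0.024).
#' @param dropout_probability probability that a patient silently stops
#'   making any claim >= 12 months before study end (lost to follow-up /
#'   disenrollment; 0.005).
#' @param cycle_days dispensing cadence: one claim per drug per cycle (28).
#' @param cost_meanlog,cost_sdlog named lognormal parameters (euro scale)
#'   per generated cost component.
#' @param noise list with `p_missing_dispensing` (each dispensing dropped
#'   independently with this probability) and `p_benign_skin_history`
#'   (probability of a pre-index non-melanoma skin cancer record, which
#'   must *not* exclude).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       inclusion_start = as.Date("2013-01-01"),
                       inclusion_end = as.Date("2018-12-31"),
                       history_start = as.Date("2008-01-01"),
                       study_end = as.Date("2018-12-31"),
                       sct_probability = 0.30,
                       age_mean = c(sct = 58, nonsct = 73.5),
                       age_sd = c(sct = 8.1, nonsct = 9.7),
                       male_probability = 0.52,
                       treatment_delay_max = 21L,
                       n_lot_probs = c(`0` = 0.029, `1` = 0.398,
                                       `2` = 0.277, `3` = 0.142,
                                       `4` = 0.063, `5` = 0.091),
                       regimen_menu = default_regimen_menu(),
                       lot_duration_median = c(200, 150, 120, 90, 60),
                       lot_duration_sdlog = 0.55,
                       gap_between_lots = c(min = 140, max = 260),
                       death_hazard_month = c(sct = 0.005, nonsct = 0.024),
                       dropout_probability = 0.005,
                       cycle_days = 28L,
                       cost_meanlog = c(mco_stay = 8.0, chemo_session = 6.2,
                                        sct_stay = 10.1, drug = 7.2,
                                        physician_visit = 3.2,
                                        lab_test = 3.4, transport = 4.2,
                                        sick_leave = 5.6, device = 5.0,
                                        other_visit = 3.0, emergency = 5.8,
                                        rehab_stay = 8.3, home_stay = 7.6),
                       cost_sdlog = 0.5,
                       noise = list(p_missing_dispensing = 0,
                                    p_benign_skin_history = 0)) {
  cfg <- as.list(environment())
  cfg$inclusion_start <- as.Date(inclusion_start)
  cfg$inclusion_end <- as.Date(inclusion_end)
  cfg$history_start <- as.Date(history_start)
  cfg$study_end <- as.Date(study_end)
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients)) {
    stop("sim_config: n_patients must be a non-negative integer")
  }
  probs <- c(sct_probability, male_probability, dropout_probability,
             noise$p_missing_dispensing, noise$p_benign_skin_history)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]")
  }
  if (abs(sum(n_lot_probs) - 1) > 1e-8) {
    stop("sim_config: n_lot_probs must sum to 1")
  }
  for (side in names(regimen_menu)) {
    ps <- vapply(regimen_menu[[side]], `[[`, numeric(1), "p")
    if (abs(sum(ps) - 1) > 1e-8) {
      stop("sim_config: regimen_menu$", side, " probabilities must sum to 1")
    }
  }
  if (cfg$inclusion_start < cfg$history_start ||
      cfg$inclusion_end > cfg$study_end) {
    stop("sim_config: inclusion_window must lie within history_start..study_end")
  }
  if (any(lot_duration_median <= 0) || lot_duration_sdlog <= 0 ||
      gap_between_lots["min"] <= 0 ||
      gap_between_lots["max"] < gap_between_lots["min"]) {
    stop("sim_config: duration/gap parameters must be positive and ordered")
  }
  if (any(death_hazard_month < 0)) {
    stop("sim_config: death_hazard_month must be non-negative")
  }
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed per named stream, kept inside 32-bit range
sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(k)
}

set_stream <- function(seed, k) {
  set.seed(sub_seed(seed, k), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
}

rlnorm_cost <- function(n, meanlog, sdlog) {
  round(stats::rlnorm(n, meanlog, sdlog), 2)
}

# empty, correctly typed claim table templates (also the written schemas)
claims_templates <- function() {
  d <- as.Date(character(0))
  list(
    patients = data.table::data.table(
      patient_id = character(0), birth_year = integer(0),
      sex = character(0), general_scheme = logical(0),
      death_date = d, coverage_end_date = d),
    diagnoses = data.table::data.table(
      patient_id = character(0), icd10_code = character(0), date = d,
      source = character(0)),
    dispensings = data.table::data.table(
      patient_id = character(0), atc_code = character(0),
      drug_label = character(0), dispense_date = d,
      setting_class = character(0), packs = integer(0),
      cost_eur = numeric(0)),
    stays = data.table::data.table(
      patient_id = character(0), admit_date = d, discharge_date = d,
      stay_type = character(0), drg_code = character(0),
      primary_dx = character(0), related_dx = character(0),
      associated_dx = character(0), cost_eur = numeric(0)),
    procedures = data.table::data.table(
      patient_id = character(0), date = d, ccam_code = character(0),
      cost_eur = numeric(0)),
    cost_items = data.table::data.table(
      patient_id = character(0), date = d, category = character(0),
      cost_eur = numeric(0), days = integer(0)),
    ground_truth = data.table::data.table(
      patient_id = character(0), true_sct = logical(0), true_sct_date = d,
      true_death_date = d, true_obs_end = d, true_end_reason = character(0),
      true_eligible = logical(0), true_reason = character(0),
      true_n_lot = integer(0), true_lot_seq = character(0))
  )
}

serialise_lots <- function(lots) {
  if (!length(lots)) return("")
  paste(vapply(lots, function(l) {
    paste(paste(sort(l$drugs), collapse = "+"),
          format(l$start), format(l$end), sep = ":")
  }, character(1)), collapse = ";")
}

#' Parse a serialised ground-truth LOT sequence
#'
#' Inverse of the `true_lot_seq` encoding in `ground_truth.csv`
#' (`drugA+drugB:start:end;...`).
#'
#' @param x character vector of serialised sequences.
#' @return list (one element per input) of data.tables with columns
#'   `drugs` (plus-joined string), `start`, `end`.
#' @export
parse_lot_seq <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.table::data.table(drugs = character(0),
                                    start = as.Date(character(0)),
                                    end = as.Date(character(0))))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.table::data.table(
      drugs = vapply(parts, `[[`, character(1), 1),
      start = as.Date(vapply(parts, `[[`, character(1), 2)),
      end = as.Date(vapply(parts, `[[`, character(1), 3)))
  })
}

#' Generate a synthetic claims population
#'
#' Simulates per-patient event streams shaped like national claims
#' extracts: drug dispensings along a ground-truth line-of-therapy
#' trajectory (one claim per drug per 28-day cycle), MM diagnosis records
#' (hospital stays and long-term-disease registrations), chemotherapy
#' session stays for injectable drugs, SCT stays/procedures, background
#' outpatient care (visits, tests, transport, sick leave), and vital
#' status. Ground-truth labels (true LOT intervals, SCT status and date,
#' eligibility verdict, death/censoring) are retained so downstream stages
#' can be scored exactly.
#'
#' Death truncates all subsequent events. A small fraction of patients
#' stop claiming entirely >= 12 months before study end, emulating loss to
#' follow-up; half of these carry an explicit coverage-termination date
#' (disenrollment).
#'
#' @param config a [sim_config()].
#' @return named list of data.tables: `patients`, `diagnoses`,
#'   `dispensings`, `stays`, `procedures`, `cost_items`, `ground_truth`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("generate_population: config must be built by sim_config()")
  }
  tmpl <- claims_templates()
  n <- as.integer(config$n_patients)
  if (n == 0L) return(tmpl)

  catalogue <- default_drug_catalogue()
  drug_row <- split(catalogue, by = "drug_name")
  study_end <- config$study_end
  cyc <- as.integer(config$cycle_days)

  # ---- stream 1: trajectories, demographics, vital status ----------------
  set_stream(config$seed, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%06d", i)
    sct <- stats::runif(1) < config$sct_probability
    stratum <- if (sct) "sct" else "nonsct"
    diag_date <- config$inclusion_start +
      floor(stats::runif(1) *
              (as.integer(config$inclusion_end - config$inclusion_start) + 1L))
    age <- round(stats::rnorm(1, config$age_mean[[stratum]],
                              config$age_sd[[stratum]]))
    age <- max(19, min(99, age))
    birth_year <- as.integer(format(diag_date, "%Y")) - as.integer(age)
    sex <- if (stats::runif(1) < config$male_probability) "M" else "F"
    delay <- sample.int(config$treatment_delay_max + 1L, 1L) - 1L

    # vital status / censoring
    haz_day <- config$death_hazard_month[[stratum]] / DAYS_PER_MONTH
    death_offset <- if (haz_day > 0) {
      round(stats::rexp(1, haz_day))
    } else Inf
    death_date <- if (is.finite(death_offset) &&
                      diag_date + death_offset <= study_end) {
      diag_date + death_offset
    } else as.Date(NA)
    dropout <- stats::runif(1) < config$dropout_probability
    dropout_date <- as.Date(NA)
    if (dropout) {
      # must leave a >= 12-month claim-free window before study end
      latest <- as.integer((study_end - 380) - diag_date)
      if (latest > 90) {
        dropout_date <- diag_date + (90L + sample.int(latest - 90L, 1L))
      }
    }
    ends <- c(death = death_date, dropout = dropout_date,
              end_of_observation = study_end)
    obs_end <- min(ends, na.rm = TRUE)
    end_reason <- names(ends)[which(ends == obs_end)][1]
    if (end_reason == "dropout") {
      # half of the silent dropouts carry a coverage-termination record
      end_reason <- if (stats::runif(1) < 0.5) "disenrollment"
                    else "lost_to_follow_up"
    }
    if (!is.na(death_date) && death_date > obs_end) death_date <- as.Date(NA)

    # number of lines and regimen trajectory
    k_lot <- sample(names(config$n_lot_probs), 1L,
                    prob = config$n_lot_probs)
    k_lot <- if (k_lot == "5") 5L + stats::rbinom(1, 1L, 0.3) else
      as.integer(k_lot)
    lots <- list()
    if (k_lot >= 1L) {
      t0 <- diag_date + delay
      start <- t0
      for (k in seq_len(k_lot)) {
        if (start > obs_end) break
        menu <- if (k == 1L) config$regimen_menu$line1 else
          config$regimen_menu$line2plus
        pick <- sample.int(length(menu), 1L,
                           prob = vapply(menu, `[[`, numeric(1), "p"))
        drugs <- menu[[pick]]$drugs
        med <- config$lot_duration_median[min(k,
                   length(config$lot_duration_median))]
        dur <- round(stats::rlnorm(1, log(med), config$lot_duration_sdlog))
        dur <- max(cyc, min(900L, dur))
        end <- min(start + dur, obs_end)
        lots[[length(lots) + 1L]] <-
          list(lot = k, drugs = drugs, start = start, end = end)
        if (end >= obs_end) break
        gap <- round(stats::runif(1, config$gap_between_lots[["min"]],
                                  config$gap_between_lots[["max"]]))
        start <- end + gap
      }
    }
    sct_date <- as.Date(NA)
    graft <- NA_character_
    if (sct && length(lots)) {
      cand <- lots[[1]]$start + 80L + sample.int(80L, 1L)
      if (cand <= obs_end) {
        sct_date <- cand
        graft <- if (stats::runif(1) < 0.977) "autologous" else "allogeneic"
      }
    }
    benign_skin <- stats::runif(1) < config$noise$p_benign_skin_history
    ltd_second <- stats::runif(1) < 0.7 # second MM record source
    out[[i]] <- list(
      pid = pid, sct = sct, stratum = stratum, diag_date = diag_date,
      birth_year = birth_year, sex = sex, delay = delay,
      death_date = death_date, obs_end = obs_end, end_reason = end_reason,
      lots = lots, sct_date = sct_date, graft = graft,
      benign_skin = benign_skin, ltd_second = ltd_second)
  }

  # ---- stream 2: dispensings + treatment stays ---------------------------
  set_stream(config$seed, 2L)
  inject_classes <- c("high_cost", "temporary_authorised")
  disp_l <- list(); stay_l <- list(); proc_l <- list(); diag_l <- list()
  for (i in seq_len(n)) {
    p <- out[[i]]
    # MM diagnosis confirmation records: a diagnostic complete stay at
    # diagnosis plus either a long-term-disease registration or a second
    # stay with MM as related diagnosis
    stay_l[[length(stay_l) + 1L]] <- data.table::data.table(
      patient_id = p$pid, admit_date = p$diag_date,
      discharge_date = min(p$diag_date + 5L, p$obs_end),
      stay_type = "mco_complete", drg_code = "DRGMED",
      primary_dx = "C900", related_dx = "", associated_dx = "",
      cost_eur = rlnorm_cost(1, config$cost_meanlog[["mco_stay"]],
                             config$cost_sdlog))
    second_date <- min(p$diag_date + 14L, p$obs_end)
    if (p$ltd_second) {
      diag_l[[length(diag_l) + 1L]] <- data.table::data.table(
        patient_id = p$pid, icd10_code = "C900", date = second_date,
        source = "long_term_disease")
    } else {
      stay_l[[length(stay_l) + 1L]] <- data.table::data.table(
        patient_id = p$pid, admit_date = second_date,
        discharge_date = min(second_date + 2L, p$obs_end),
        stay_type = "mco_complete", drg_code = "DRGMED",
        primary_dx = "R778", related_dx = "C900", associated_dx = "",
        cost_eur = rlnorm_cost(1, config$cost_meanlog[["mco_stay"]],
                               config$cost_sdlog))
    }
    if (p$benign_skin) {
      diag_l[[length(diag_l) + 1L]] <- data.table::data.table(
        patient_id = p$pid, icd10_code = "C441",
        date = p$diag_date - 400L, source = "hospital_associated")
    }
    # SCT stay + procedure
    if (!is.na(p$sct_date)) {
      code_sfx <- if (p$graft == "autologous") "AUTO" else "ALLO"
      stay_l[[length(stay_l) + 1L]] <- data.table::data.table(
        patient_id = p$pid, admit_date = p$sct_date,
        discharge_date = min(p$sct_date + 18L, p$obs_end),
        stay_type = "mco_complete",
        drg_code = paste0("DRGSCT", code_sfx),
        primary_dx = "C900", related_dx = "", associated_dx = "",
        cost_eur = rlnorm_cost(1, config$cost_meanlog[["sct_stay"]],
                               config$cost_sdlog))
      proc_l[[length(proc_l) + 1L]] <- data.table::data.table(
        patient_id = p$pid, date = p$sct_date,
        ccam_code = paste0("CCAMSCT", code_sfx),
        cost_eur = rlnorm_cost(1, 7.0, config$cost_sdlog))
    }
    # dispensings: one claim per drug per cycle inside each true LOT;
    # patients with zero identifiable lines get corticosteroid courses only
    emit_disp <- function(drugs, start, end) {
      res <- list()
      for (dg in drugs) {
        info <- drug_row[[dg]]
        dates <- seq(0L, max(0L, as.integer(end - start)), by = cyc)
        dates <- start + dates
        dates <- dates[dates <= p$obs_end]
        if (!length(dates)) next
        res[[dg]] <- data.table::data.table(
          patient_id = p$pid, atc_code = info$atc_code, drug_label = dg,
          dispense_date = dates, setting_class = info$setting_class,
          packs = 1L,
          cost_eur = rlnorm_cost(length(dates),
                                 config$cost_meanlog[["drug"]],
                                 config$cost_sdlog))
      }
      data.table::rbindlist(res)
    }
    if (length(p$lots)) {
      for (l in p$lots) {
        dd <- emit_disp(l$drugs, l$start, l$end)
        if (nrow(dd)) disp_l[[length(disp_l) + 1L]] <- dd
        # injectable hospital drugs come with a chemotherapy-session stay
        inj <- dd[dd$setting_class %in% inject_classes, ]
        if (nrow(inj)) {
          stay_l[[length(stay_l) + 1L]] <- data.table::data.table(
            patient_id = p$pid, admit_date = inj$dispense_date,
            discharge_date = inj$dispense_date,
            stay_type = "chemo_session", drg_code = "DRGCHEMO",
            primary_dx = "Z511", related_dx = "C900", associated_dx = "",
            cost_eur = rlnorm_cost(nrow(inj),
                                   config$cost_meanlog[["chemo_session"]],
                                   config$cost_sdlog))
        }
      }
    } else if (p$obs_end >= p$diag_date + p$delay) {
      dd <- emit_disp("dexamethasone", p$diag_date + p$delay,
                      min(p$diag_date + p$delay + 180L, p$obs_end))
      if (nrow(dd)) disp_l[[length(disp_l) + 1L]] <- dd
    }
  }

  # ---- stream 3: background care (visits, tests, transport, leave) -------
  set_stream(config$seed, 3L)
  cost_l <- list()
  for (i in seq_len(n)) {
    p <- out[[i]]
    span <- as.integer(p$obs_end - p$diag_date)
    if (span < 0) span <- 0L
    mk <- function(offsets, category, meanlog, days = 0L) {
      offsets <- offsets[offsets <= span]
      if (!length(offsets)) return(NULL)
      data.table::data.table(
        patient_id = p$pid, date = p$diag_date + offsets,
        category = category,
        cost_eur = rlnorm_cost(length(offsets), meanlog, config$cost_sdlog),
        days = as.integer(days))
    }
    jitter <- function(step) {
      if (span < 1) return(integer(0))
      base <- seq(0L, span, by = step)
      pmax(0L, base + sample.int(7L, length(base), replace = TRUE) - 4L)
    }
    cost_l[[length(cost_l) + 1L]] <- data.table::rbindlist(list(
      mk(jitter(30L), "physician_visit",
         config$cost_meanlog[["physician_visit"]]),
      mk(jitter(45L), "lab_test", config$cost_meanlog[["lab_test"]]),
      mk(jitter(90L), "other_professional_visit",
         config$cost_meanlog[["other_visit"]]),
      if (stats::runif(1) < 0.15)
        mk(sample.int(max(span, 1L), 1L), "medical_device",
           config$cost_meanlog[["device"]])
    ))
    # sick leave around line starts (working-age patients only)
    if (length(p$lots) && p$birth_year > 1958) {
      for (l in p$lots) {
        if (stats::runif(1) < 0.4) {
          off <- as.integer(l$start - p$diag_date) +
            sample.int(5L, 1L) - 1L
          row <- mk(off, "sick_leave_invalidity",
                    config$cost_meanlog[["sick_leave"]], days = 14L)
          if (!is.null(row)) cost_l[[length(cost_l) + 1L]] <- row
        }
      }
    }
  }
  stays <- data.table::rbindlist(c(list(tmpl$stays), stay_l),
                                 use.names = TRUE, fill = TRUE)
  # transport on the day of most chemotherapy sessions
  chemo <- stays[stays$stay_type == "chemo_session", ]
  if (nrow(chemo)) {
    keep <- stats::runif(nrow(chemo)) < 0.8
    if (any(keep)) {
      cost_l[[length(cost_l) + 1L]] <- data.table::data.table(
        patient_id = chemo$patient_id[keep],
        date = chemo$admit_date[keep], category = "transport",
        cost_eur = rlnorm_cost(sum(keep), config$cost_meanlog[["transport"]],
                               config$cost_sdlog),
        days = 0L)
    }
  }

  # ---- stream 4: dispensing noise ---------------------------------------
  dispensings <- data.table::rbindlist(disp_l, use.names = TRUE)
  if (!nrow(dispensings)) dispensings <- tmpl$dispensings
  set_stream(config$seed, 4L)
  if (config$noise$p_missing_dispensing > 0 && nrow(dispensings)) {
    drop <- stats::runif(nrow(dispensings)) <
      config$noise$p_missing_dispensing
    dispensings <- dispensings[!drop, ]
  }

  # ---- assemble ---------------------------------------------------------
  patients <- data.table::rbindlist(lapply(out, function(p) {
    data.table::data.table(
      patient_id = p$pid, birth_year = p$birth_year, sex = p$sex,
      general_scheme = TRUE, death_date = p$death_date,
      coverage_end_date = if (p$end_reason == "disenrollment") p$obs_end
                          else as.Date(NA))
  }))
  diagnoses <- data.table::rbindlist(c(list(tmpl$diagnoses), diag_l),
                                     use.names = TRUE)
  procedures <- data.table::rbindlist(c(list(tmpl$procedures), proc_l),
                                      use.names = TRUE)
  cost_items <- data.table::rbindlist(
    c(list(tmpl$cost_items), cost_l), use.names = TRUE)

  ground_truth <- data.table::rbindlist(lapply(out, function(p) {
    # eligibility truth: active treatment (any MM drug, identifiable or
    # not) must start within the 30-day window and before observation end
    tstart <- p$diag_date + p$delay
    eligible <- tstart <= p$obs_end && p$delay <= 30L
    reason <- if (eligible) "" else "untreated"
    data.table::data.table(
      patient_id = p$pid, true_sct = !is.na(p$sct_date),
      true_sct_date = p$sct_date, true_death_date = p$death_date,
      true_obs_end = p$obs_end,
      true_end_reason = if (p$end_reason == "death" &&
                            !is.na(p$death_date)) "death" else p$end_reason,
      true_eligible = eligible, true_reason = reason,
      true_n_lot = length(p$lots), true_lot_seq = serialise_lots(p$lots))
  }))

  list(patients = patients[order(patient_id)],
       diagnoses = diagnoses[order(patient_id, date)],
       dispensings = dispensings[order(patient_id, dispense_date,
                                       atc_code)],
       stays = stays[order(patient_id, admit_date)],
       procedures = procedures[order(patient_id, date)],
       cost_items = cost_items[order(patient_id, date, category)],
       ground_truth = ground_truth[order(patient_id)])
}

#' Inject eligibility-rule violations into a synthetic population
#'
#' Creates the ineligible strata of a realistic attrition waterfall by
#' editing claims of randomly chosen patients and updating the ground
#' truth so cohort verdicts can be scored exactly:
#'
#' * `untreated` — all MM drug dispensings (and their chemotherapy-session
#'   stays) are removed; the patient receives no active treatment.
#' * `late_treatment` — all dispensings and chemotherapy stays are shifted
#'   45 days later, so the first treatment falls outside the 30-day
#'   active-treatment window.
#' * `prior_malignancy` — a non-MM malignancy diagnosis (lung, C34) is
#'   added two years before the index date.
#'
#' Rates are applied to disjoint patient subsets, sampled without
#' replacement under the derived seed stream.
#'
#' @param population list of claims tables from [generate_population()].
#' @param rates named list/vector of probabilities for `untreated`,
#'   `late_treatment`, `prior_malignancy` (default all 0).
#' @param seed integer seed for the violation stream.
#' @return the edited population (same shape), ground truth updated.
#' @export
inject_protocol_violations <- function(population,
                                       rates = list(untreated = 0,
                                                    late_treatment = 0,
                                                    prior_malignancy = 0),
                                       seed = 1L) {
  rates <- utils::modifyList(
    list(untreated = 0, late_treatment = 0, prior_malignancy = 0),
    as.list(rates))
  stopifnot(all(unlist(rates) >= 0), sum(unlist(rates)) <= 1)
  if (sum(unlist(rates)) == 0) return(population)
  pop <- lapply(population, data.table::copy)
  gt <- pop$ground_truth
  ids <- gt$patient_id[gt$true_eligible]
  set_stream(seed, 9L)
  n_u <- round(rates$untreated * length(ids))
  n_l <- round(rates$late_treatment * length(ids))
  n_m <- round(rates$prior_malignancy * length(ids))
  picked <- sample(ids, min(length(ids), n_u + n_l + n_m))
  grp <- rep(c("untreated", "late_treatment", "prior_malignancy"),
             c(n_u, n_l, n_m))[seq_along(picked)]

  u_ids <- picked[grp == "untreated"]
  if (length(u_ids)) {
    pop$dispensings <- pop$dispensings[!patient_id %in% u_ids]
    pop$stays <- pop$stays[!(patient_id %in% u_ids &
                               stay_type == "chemo_session")]
    gt[patient_id %in% u_ids,
       `:=`(true_eligible = FALSE, true_reason = "untreated",
            true_n_lot = 0L, true_lot_seq = "")]
  }
  l_ids <- picked[grp == "late_treatment"]
  if (length(l_ids)) {
    sel <- pop$dispensings$patient_id %in% l_ids
    pop$dispensings[sel, dispense_date := dispense_date + 45L]
    sel2 <- pop$stays$patient_id %in% l_ids &
      pop$stays$stay_type == "chemo_session"
    pop$stays[sel2, `:=`(admit_date = admit_date + 45L,
                         discharge_date = discharge_date + 45L)]
    obs <- gt[match(pop$dispensings$patient_id, patient_id), true_obs_end]
    keep <- !sel | pop$dispensings$dispense_date <= obs
    pop$dispensings <- pop$dispensings[keep]
    obs2 <- gt[match(pop$stays$patient_id, patient_id), true_obs_end]
    pop$stays <- pop$stays[!sel2 | admit_date <= obs2]
    gt[patient_id %in% l_ids,
       `:=`(true_eligible = FALSE, true_reason = "late_treatment")]
    # shift the truth intervals too so labels stay consistent with claims
    shifted <- vapply(gt[patient_id %in% l_ids, true_lot_seq],
                      shift_lot_seq, character(1), delta = 45L)
    gt[patient_id %in% l_ids, true_lot_seq := shifted]
    # a shift past the observation end leaves no treatment at all
    still <- unique(pop$dispensings[patient_id %in% l_ids, patient_id])
    gone <- setdiff(l_ids, still)
    if (length(gone)) {
      gt[patient_id %in% gone,
         `:=`(true_reason = "untreated", true_n_lot = 0L,
              true_lot_seq = "")]
    }
  }
  m_ids <- picked[grp == "prior_malignancy"]
  if (length(m_ids)) {
    idx <- gt[match(m_ids, patient_id)]
    first_start <- vapply(parse_lot_seq(idx$true_lot_seq), function(d) {
      if (nrow(d)) as.integer(d$start[1]) else NA_integer_
    }, integer(1))
    base <- data.table::fifelse(is.na(first_start),
                                as.integer(idx$true_obs_end), first_start)
    pop$diagnoses <- data.table::rbindlist(list(
      pop$diagnoses,
      data.table::data.table(
        patient_id = m_ids, icd10_code = "C341",
        date = as.Date(base, origin = "1970-01-01") - 730L,
        source = "hospital_associated")), use.names = TRUE)
    gt[patient_id %in% m_ids,
       `:=`(true_eligible = FALSE, true_reason = "other_malignancy")]
  }
  pop$ground_truth <- gt
  pop$diagnoses <- pop$diagnoses[order(patient_id, date)]
  pop
}

shift_lot_seq <- function(s, delta) {
  d <- parse_lot_seq(s)[[1]]
  if (!nrow(d)) return(s)
  paste(paste(d$drugs, format(d$start + delta), format(d$end + delta),
              sep = ":"), collapse = ";")
}

#' Write claims tables as CSV
#'
#' Writes each table of a population to `<dir>/<name>.csv` with ISO-8601
#' dates.
#'
#' @param population list of claims tables.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_claims <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(population)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(population[[nm]], path, dateTimeAs = "ISO")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read claims tables from CSV
#'
#' @param dir directory containing the CSV tables written by
#'   [write_claims()] (at minimum `patients`, `diagnoses`, `dispensings`,
#'   `stays`, `cost_items`; `procedures` and `ground_truth` when present).
#' @return named list of data.tables with parsed `Date` columns.
#' @export
read_claims <- function(dir) {
  tmpl <- claims_templates()
  date_cols <- lapply(tmpl, function(t) {
    names(t)[vapply(t, inherits, logical(1), "Date")]
  })
  need <- c("patients", "diagnoses", "dispensings", "stays", "cost_items")
  pop <- list()
  for (nm in names(tmpl)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm %in% need) stop("read_claims: missing input file ", path)
      next
    }
    dt <- data.table::fread(path, na.strings = "NA")
    for (cn in intersect(names(tmpl[[nm]]), names(dt))) {
      if (cn %in% date_cols[[nm]]) {
        data.table::set(dt, j = cn, value = as.Date(as.character(dt[[cn]])))
      } else if (is.character(tmpl[[nm]][[cn]]) &&
                 !is.character(dt[[cn]])) {
        v <- as.character(dt[[cn]])
        v[is.na(v)] <- ""
        data.table::set(dt, j = cn, value = v)
      }
    }
    pop[[nm]] <- dt
  }
  pop
}
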