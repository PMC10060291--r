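#' Build per-drug treatment episodes from dispensings
#'
#' Consecutive dispensings of one drug merge into an episode while the
#' inter-dispense gap does not exceed the drug's grace period; the
#' episode's exposure extends `grace_days` past its last dispensing.
#'
#' @param dispensings dispensings table (`patient_id`, `atc_code`,
#'   `dispense_date`, ...).
#' @param catalogue drug catalogue, see [default_drug_catalogue()].
#' @param grace_override optional named vector (drug name -> days)
#'   overriding catalogue grace periods.
#' @return data.table `patient_id`, `drug`, `first_dispense`,
#'   `last_dispense`, `exposure_end`, `n_dispense`.
#' @export
build_episodes <- function(dispensings, catalogue = default_drug_catalogue(),
                           grace_override = NULL) {
  catalogue <- validate_catalogue(catalogue)
  dp <- data.table::as.data.table(dispensings)
  unknown <- setdiff(unique(dp$atc_code), catalogue$atc_code)
  if (length(unknown)) {
    stop("build_episodes: unknown ATC code(s) not in catalogue: ",
         paste(unknown, collapse = ", "))
  }
  dp <- merge(dp, catalogue[, .(atc_code, drug = drug_name, grace_days,
                                mm_indicated)],
              by = "atc_code")
  dp <- dp[mm_indicated == TRUE]
  if (!is.null(grace_override)) {
    ov <- grace_override[dp$drug]
    dp[!is.na(ov), grace_days := as.integer(ov[!is.na(ov)])]
  }
  if (!nrow(dp)) {
    return(data.table::data.table(patient_id = character(0),
                                  drug = character(0),
                                  first_dispense = as.Date(character(0)),
                                  last_dispense = as.Date(character(0)),
                                  exposure_end = as.Date(character(0)),
                                  n_dispense = integer(0)))
  }
  dp <- dp[order(patient_id, drug, dispense_date)]
  dp[, gap_prev := c(Inf, diff(as.integer(dispense_date))),
     by = .(patient_id, drug)]
  dp[, episode := cumsum(gap_prev > grace_days), by = .(patient_id, drug)]
  dp[, .(first_dispense = min(dispense_date),
         last_dispense = max(dispense_date),
         exposure_end = max(dispense_date) + grace_days[1],
         n_dispense = .N),
     by = .(patient_id, drug, episode)][, episode := NULL][]
}

# resolve per-dispensing attributes needed by the segmentation scan
lot_input <- function(dispensings, catalogue, params) {
  catalogue <- validate_catalogue(catalogue)
  dp <- data.table::as.data.table(dispensings)
  unknown <- setdiff(unique(dp$atc_code), catalogue$atc_code)
  if (length(unknown)) {
    stop("derive_lots: unknown ATC code(s) not in catalogue: ",
         paste(unknown, collapse = ", "))
  }
  dp <- merge(dp,
              catalogue[, .(atc_code, drug = drug_name, grace_days,
                            mm_indicated, lot_exempt, observability)],
              by = "atc_code")
  dp <- dp[mm_indicated == TRUE & lot_exempt == FALSE &
             observability != "none"]
  if (!params$include_partially_observable) {
    dp <- dp[observability != "partial"]
  }
  if (!is.null(params$grace_override)) {
    ov <- params$grace_override[dp$drug]
    dp[!is.na(ov), grace_days := as.integer(ov[!is.na(ov)])]
  }
  dp[order(patient_id, dispense_date, drug)]
}

# segmentation scan for one patient; disp has columns day (integer),
# drug, grace; fu_end integer day of follow-up end
segment_one <- function(day, drug, grace, fu_end, params) {
  W <- params$regimen_window_days
  G <- params$gap_days
  OV <- params$overlap_days
  n <- length(day)
  lots <- list()
  exp_end <- numeric(0) # named per drug, current exposure end
  carry <- character(0)
  j <- 1L
  start <- day[1L]
  repeat {
    window_end <- start + W
    regimen <- carry
    max_exp <- if (length(carry)) max(exp_end[carry]) else -Inf
    end <- NA_integer_
    reason <- NA_character_
    next_start <- NA_integer_
    while (j <= n) {
      d <- day[j]; g <- drug[j]
      if (d <= window_end) {
        if (!(g %in% regimen)) regimen <- c(regimen, g)
        e <- d + grace[j]
        exp_end[g] <- max(e, if (is.null(exp_end[g]) || is.na(exp_end[g]))
          -Inf else exp_end[g])
        if (e > max_exp) max_exp <- e
        j <- j + 1L
        next
      }
      if (d - max_exp >= G) { # discontinuation of all regimen drugs
        end <- as.integer(max_exp)
        reason <- "discontinuation"
        next_start <- d
        carry <- character(0)
        break
      }
      if (g %in% regimen) {
        e <- d + grace[j]
        if (e > exp_end[g]) exp_end[g] <- e
        if (e > max_exp) max_exp <- e
        j <- j + 1L
        next
      }
      # new non-exempt drug during the line: line switch at its start;
      # previous-regimen drugs carry over when their exposure overlaps
      # the new line by at least overlap_days (or they are re-dispensed
      # inside the new regimen window, handled by the window scan)
      end <- as.integer(d - 1L)
      reason <- "new_drug"
      next_start <- d
      carry <- regimen[exp_end[regimen] >= d + OV]
      break
    }
    if (is.na(end)) { # stream exhausted
      if (fu_end >= max_exp + G) {
        end <- as.integer(max_exp)
        reason <- "discontinuation"
      } else {
        end <- as.integer(min(max_exp, fu_end))
        reason <- "censored"
      }
    }
    lots[[length(lots) + 1L]] <- list(start = start, end = end,
                                      regimen = sort(regimen),
                                      reason = reason)
    if (is.na(next_start)) break
    start <- next_start
  }
  lots
}

#' Derive lines of therapy from a dispensing stream
#'
#' Segments each patient's MM-drug dispensings into numbered lines of
#' therapy:
#'
#' * the first line starts at the first dispensing of a non-exempt,
#'   MM-indicated drug; all such drugs first dispensed within the
#'   `regimen_window_days` (28-day) window belong to its regimen;
#' * a non-exempt drug first appearing after the window ends the current
#'   line the day before and starts the next one at its dispensing date
#'   (new-drug rule); previous-regimen drugs whose exposure extends at
#'   least `overlap_days` past the new start carry into the new regimen
#'   (add-on combination), otherwise the event is a switch;
#' * when no regimen drug is dispensed for at least `gap_days` after all
#'   grace periods end, the line ends at the date the grace period ended
#'   (discontinuation) and the next dispensing starts a new line;
#' * lines truncated by the end of follow-up are `censored`.
#'
#' Corticosteroids and other `lot_exempt` drugs never open, join or end a
#' line. Patients whose dispensings contain only exempt or unobservable
#' drugs receive zero lines (undetermined LOT).
#'
#' @param dispensings dispensings table.
#' @param follow_up data.table `patient_id`, `index_date`, `end_date`;
#'   dispensings outside `[index_date, end_date]` are ignored and line
#'   ends are capped at `end_date`.
#' @param params a [lot_params()].
#' @param catalogue drug catalogue.
#' @return data.table `patient_id`, `lot_number`, `regimen` (plus-joined
#'   sorted drug names), `start`, `end`, `end_reason`, `duration_days`.
#' @export
derive_lots <- function(dispensings, follow_up, params = lot_params(),
                        catalogue = default_drug_catalogue()) {
  fu <- data.table::as.data.table(follow_up)
  dp <- lot_input(dispensings, catalogue, params)
  dp <- merge(dp, fu[, .(patient_id, index_date, end_date)],
              by = "patient_id")
  dp <- dp[dispense_date >= index_date & dispense_date <= end_date]
  if (!nrow(dp)) {
    return(data.table::data.table(patient_id = character(0),
                                  lot_number = integer(0),
                                  regimen = character(0),
                                  start = as.Date(character(0)),
                                  end = as.Date(character(0)),
                                  end_reason = character(0),
                                  duration_days = integer(0)))
  }
  dp <- dp[order(patient_id, dispense_date, drug)]
  res <- dp[, {
    lots <- segment_one(as.integer(dispense_date), drug, grace_days,
                        as.integer(end_date[1]), params)
    data.table::data.table(
      lot_number = seq_along(lots),
      regimen = vapply(lots, function(l) paste(l$regimen, collapse = "+"),
                       character(1)),
      start = as.Date(vapply(lots, `[[`, numeric(1), "start"),
                      origin = "1970-01-01"),
      end = as.Date(vapply(lots, `[[`, numeric(1), "end"),
                    origin = "1970-01-01"),
      end_reason = vapply(lots, `[[`, character(1), "reason"))
  }, by = "patient_id"]
  # cap line ends at follow-up end (grace may extend past it)
  res <- merge(res, fu[, .(patient_id, end_date)], by = "patient_id")
  res[end > end_date, `:=`(end = end_date, end_reason = "censored")]
  res[, end_date := NULL]
  res[, duration_days := as.integer(end - start)]
  res[order(patient_id, lot_number)]
}

#' Label a regimen by its backbone drug
#'
#' The first drug of the precedence list present in the regimen names it
#' (`"<drug>-based"`); regimens containing none of the listed drugs are
#' labelled `"other"`.
#'
#' @param regimen character vector of plus-joined regimen strings (as in
#'   the `regimen` column of [derive_lots()] output).
#' @param precedence character vector of drug names, highest first.
#' @return character vector of labels.
#' @export
classify_regimen <- function(regimen,
                             precedence = default_regimen_precedence()) {
  vapply(strsplit(regimen, "+", fixed = TRUE), function(drugs) {
    hit <- precedence[precedence %in% drugs]
    if (length(hit)) paste0(hit[1], "-based") else "other"
  }, character(1))
}

#' Kaplan-Meier duration of a line of therapy
#'
#' Product-limit estimate of the duration distribution of one line.
#' Lines with `end_reason = "censored"` enter as censored observations;
#' all others as events. The KM median is the first time the survival
#' curve drops to 0.5 or below; when the curve never does, the median is
#' not reached (`NA`). The descriptive median is computed over completed
#' (uncensored) lines only.
#'
#' @param lots output of [derive_lots()] (optionally pre-filtered).
#' @param line line number to analyse, or `NULL` for all rows of `lots`.
#' @return list with `curve` (data.table `time`, `n_risk`, `n_event`,
#'   `survival`), `median_km`, `median_descriptive`, `n`, `n_censored`.
#' @export
lot_duration_km <- function(lots, line = NULL) {
  lt <- data.table::as.data.table(lots)
  if (!is.null(line)) lt <- lt[lot_number == line]
  if (!nrow(lt)) stop("lot_duration_km: no lines at the requested line")
  time <- lt$duration_days
  event <- as.integer(lt$end_reason != "censored")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.table::data.table(time = fit$time, n_risk = fit$n.risk,
                                  n_event = fit$n.event,
                                  survival = fit$surv)
  below <- curve[n_event > 0 & survival <= 0.5 + 1e-12]
  median_km <- if (nrow(below)) min(below$time) else NA_real_
  median_desc <- if (any(event == 1)) {
    stats::median(time[event == 1])
  } else NA_real_
  list(curve = curve, median_km = median_km,
       median_descriptive = median_desc,
       n = nrow(lt), n_censored = sum(event == 0))
}
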