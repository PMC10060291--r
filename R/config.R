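# Calendar conventions used throughout: a month is the calendar-mean month
# (30.4375 days), a year is 365.25 days. Both are fixed here so that every
# rate (PPPY, PPPM, follow-up months) uses the same denominators.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Line-of-therapy algorithm parameters
#'
#' @param regimen_window_days length of the combination window after each
#'   line start; all non-exempt drugs first dispensed inside it belong to
#'   the line's regimen (default 28 days).
#' @param gap_days discontinuation gap: a line ends when no regimen drug is
#'   dispensed for at least this many days after the end of the grace
#'   period (default 90 days).
#' @param overlap_days overlap criterion deciding whether, at a new-drug
#'   line switch, drugs of the previous regimen carry into the new regimen:
#'   a previous drug carries over when its exposure extends at least
#'   `overlap_days` past the new line start, or when it is re-dispensed
#'   inside the new line's regimen window (default 40 days).
#' @param include_partially_observable whether partially observable drugs
#'   (oral melphalan, cyclophosphamide) participate in LOT derivation
#'   (default TRUE; their hospital IV forms are invisible in claims so
#'   including the oral forms may oversegment).
#' @param grace_override optional named integer vector (drug name ->
#'   grace days) overriding the catalogue's per-drug grace periods.
#' @return a validated list of class `lot_params`.
#' @export
lot_params <- function(regimen_window_days = 28L,
                       gap_days = 90L,
                       overlap_days = 40L,
                       include_partially_observable = TRUE,
                       grace_override = NULL) {
  p <- list(
    regimen_window_days = as.integer(regimen_window_days),
    gap_days = as.integer(gap_days),
    overlap_days = as.integer(overlap_days),
    include_partially_observable = isTRUE(include_partially_observable),
    grace_override = grace_override
  )
  for (f in c("regimen_window_days", "gap_days", "overlap_days")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) {
      stop("lot_params: ", f, " must be a non-negative integer")
    }
  }
  structure(p, class = "lot_params")
}

#' Analysis configuration
#'
#' Bundles every configurable rule of the cohort, LOT and cost stages:
#' study windows, code lists, the drug catalogue, eligibility boundary
#' conventions, attribution linkage windows and the price index used for
#' annualisation.
#'
#' @param inclusion_start,inclusion_end inclusion window for the index
#'   date (first MM diagnosis); defaults 2013-01-01 to 2018-12-31.
#' @param history_start earliest date claims history is observable
#'   (default 2008-01-01).
#' @param study_end administrative end of observation (default
#'   2018-12-31).
#' @param age_rule `"gt18"` (strictly older than 18, i.e. at least 19
#'   completed years at index — the default, literal reading) or `"ge18"`.
#' @param history_days minimum observable history before index (365).
#' @param prior_mm_days washout for MM diagnoses before index (365).
#' @param malignancy_years washout for other malignancies (5).
#' @param treatment_window_days days after index within which active MM
#'   treatment must start, inclusive of the last day (30).
#' @param followup_gap_days claim-free gap that ends follow-up (365).
#' @param price_index named numeric vector year -> multiplier used to
#'   annualise costs to 2019 prices; the default maps every study year to
#'   1 (identity — real deflators are jurisdiction data).
#' @param transport_link_days transport is MM-treatment linked when dated
#'   within this many days after an MM stay/dispensing (1).
#' @param rehab_link_days a rehabilitation stay "directly follows" an
#'   MM-related stay when admitted within this many days of its
#'   discharge (1).
#' @param sickleave_link_days sick leave is MM-treatment linked when
#'   starting within this many days after MM treatment or stay (7).
#' @param attach_between_lots `"previous"` (cost items dated between two
#'   lines attach to the earlier line — default) or `"drop"`.
#' @param lot lot algorithm parameters, see [lot_params()].
#' @param catalogue drug catalogue, see [default_drug_catalogue()].
#' @param code_lists clinical code lists, see [default_code_lists()].
#' @param charlson_map Charlson weights, see [default_charlson_map()].
#' @param regimen_precedence see [default_regimen_precedence()].
#' @return a validated list of class `mmlot_config`.
#' @export
mmlot_config <- function(inclusion_start = as.Date("2013-01-01"),
                         inclusion_end = as.Date("2018-12-31"),
                         history_start = as.Date("2008-01-01"),
                         study_end = as.Date("2018-12-31"),
                         age_rule = c("gt18", "ge18"),
                         history_days = 365L,
                         prior_mm_days = 365L,
                         malignancy_years = 5L,
                         treatment_window_days = 30L,
                         followup_gap_days = 365L,
                         price_index = NULL,
                         transport_link_days = 1L,
                         rehab_link_days = 1L,
                         sickleave_link_days = 7L,
                         attach_between_lots = c("previous", "drop"),
                         lot = lot_params(),
                         catalogue = default_drug_catalogue(),
                         code_lists = default_code_lists(),
                         charlson_map = default_charlson_map(),
                         regimen_precedence = default_regimen_precedence()) {
  age_rule <- match.arg(age_rule)
  attach_between_lots <- match.arg(attach_between_lots)
  inclusion_start <- as.Date(inclusion_start)
  inclusion_end <- as.Date(inclusion_end)
  history_start <- as.Date(history_start)
  study_end <- as.Date(study_end)
  if (inclusion_start > inclusion_end) {
    stop("mmlot_config: inclusion_start is after inclusion_end")
  }
  if (history_start > inclusion_start) {
    stop("mmlot_config: history_start must precede the inclusion window")
  }
  if (is.null(price_index)) {
    yrs <- seq(as.integer(format(history_start, "%Y")),
               as.integer(format(study_end, "%Y")) + 1L)
    price_index <- stats::setNames(rep(1, length(yrs)), yrs)
  }
  cfg <- list(
    inclusion_start = inclusion_start, inclusion_end = inclusion_end,
    history_start = history_start, study_end = study_end,
    age_rule = age_rule,
    history_days = as.integer(history_days),
    prior_mm_days = as.integer(prior_mm_days),
    malignancy_years = as.integer(malignancy_years),
    treatment_window_days = as.integer(treatment_window_days),
    followup_gap_days = as.integer(followup_gap_days),
    price_index = price_index,
    transport_link_days = as.integer(transport_link_days),
    rehab_link_days = as.integer(rehab_link_days),
    sickleave_link_days = as.integer(sickleave_link_days),
    attach_between_lots = attach_between_lots,
    lot = lot,
    catalogue = validate_catalogue(catalogue),
    code_lists = code_lists,
    charlson_map = data.table::as.data.table(charlson_map),
    regimen_precedence = regimen_precedence
  )
  if (!length(cfg$code_lists$sct_drg_codes) &&
      !length(cfg$code_lists$sct_ccam_codes)) {
    stop("mmlot_config: SCT code lists are empty")
  }
  structure(cfg, class = "mmlot_config")
}

#' @export
print.mmlot_config <- function(x, ...) {
  cat("<mmlot_config>\n")
  cat("  inclusion:", format(x$inclusion_start), "..",
      format(x$inclusion_end), "\n")
  cat("  history from:", format(x$history_start),
      " study end:", format(x$study_end), "\n")
  cat("  age rule:", x$age_rule,
      " treatment window:", x$treatment_window_days, "d",
      " follow-up gap:", x$followup_gap_days, "d\n")
  cat("  lot: window", x$lot$regimen_window_days, "d, gap",
      x$lot$gap_days, "d, overlap", x$lot$overlap_days, "d\n")
  cat("  catalogue:", nrow(x$catalogue), "drugs\n")
  invisible(x)
}

# internal: months from a day count under the calendar-mean convention
days_to_months <- function(days) as.numeric(days) / DAYS_PER_MONTH

# internal: person-years from a day count
days_to_years <- function(days) as.numeric(days) / DAYS_PER_YEAR
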