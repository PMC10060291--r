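#' Default multiple-myeloma drug catalogue
#'
#' The catalogue maps ATC codes of drugs used in MM to the attributes the
#' LOT engine and the cost engine need:
#'
#' * `setting_class` — one of the four observability/dispensing classes of
#'   drugs in French claims: `"high_cost"` (costly hospital drugs billed on
#'   top of the DRG tariff), `"temporary_authorised"` (exceptional hospital
#'   use before marketing authorisation), `"retrocession"` (hospital-pharmacy
#'   drugs dispensed to ambulatory patients) and `"community"` (community
#'   pharmacies only).
#' * `observability` — `"full"`, `"partial"` (drugs such as melphalan and
#'   cyclophosphamide whose oral community form is observable but whose
#'   hospital IV form is not) or `"none"`.
#' * `grace_days` — per-drug grace period: the number of days after a
#'   dispensing during which the drug is still considered on treatment,
#'   proxying the usual duration of a full prescription. Defaults are 42
#'   days for oral community/retrocession drugs and 49 days for injectable
#'   hospital drugs; both are overridable.
#' * `lot_exempt` — widely used supportive therapies (corticosteroids) that
#'   never open or extend a line of therapy.
#' * `mm_indicated` — whether the drug counts as active MM treatment for
#'   eligibility and cost attribution.
#'
#' @return A `data.table` with one row per ATC code and columns
#'   `atc_code`, `drug_name`, `mm_indicated`, `observability`,
#'   `setting_class`, `grace_days`, `lot_exempt`.
#' @export
default_drug_catalogue <- function() {
  ct <- data.table::data.table(
    atc_code = c(
      "L01XX32", "L01XX45", "L01AA09", "L01DB01",
      "L01XC24",
      "L04AX04", "L04AX06", "L04AX02",
      "L01XX50", "L01AA03", "L01AA01",
      "H02AB02", "H02AB07"
    ),
    drug_name = c(
      "bortezomib", "carfilzomib", "bendamustine", "doxorubicine",
      "daratumumab",
      "lenalidomide", "pomalidomide", "thalidomide",
      "ixazomib", "melphalan", "cyclophosphamide",
      "dexamethasone", "prednisone"
    ),
    mm_indicated = c(
      TRUE, TRUE, TRUE, TRUE,
      TRUE,
      TRUE, TRUE, TRUE,
      TRUE, TRUE, TRUE,
      TRUE, TRUE
    ),
    observability = c(
      "full", "full", "full", "full",
      "full",
      "full", "full", "full",
      "full", "partial", "partial",
      "partial", "partial"
    ),
    setting_class = c(
      "high_cost", "high_cost", "high_cost", "high_cost",
      "temporary_authorised",
      "retrocession", "retrocession", "retrocession",
      "community", "community", "community",
      "retrocession", "community"
    ),
    grace_days = c(
      49L, 49L, 49L, 49L,
      49L,
      42L, 42L, 42L,
      42L, 42L, 42L,
      42L, 42L
    ),
    lot_exempt = c(
      FALSE, FALSE, FALSE, FALSE,
      FALSE,
      FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE,
      TRUE, TRUE
    )
  )
  ct[]
}

#' Validate a drug catalogue
#'
#' @param catalogue a data.frame with the columns of
#'   [default_drug_catalogue()].
#' @return the catalogue as a `data.table`, invisibly validated.
#' @keywords internal
validate_catalogue <- function(catalogue) {
  catalogue <- data.table::as.data.table(catalogue)
  need <- c("atc_code", "drug_name", "mm_indicated", "observability",
            "setting_class", "grace_days", "lot_exempt")
  miss <- setdiff(need, names(catalogue))
  if (length(miss)) {
    stop("drug catalogue is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(catalogue$atc_code)) {
    stop("drug catalogue has duplicated atc_code entries")
  }
  if (any(!is.finite(catalogue$grace_days)) || any(catalogue$grace_days <= 0)) {
    stop("grace_days must be positive for every catalogue row")
  }
  bad <- setdiff(catalogue$setting_class,
                 c("high_cost", "temporary_authorised", "retrocession",
                   "community"))
  if (length(bad)) stop("unknown setting_class: ", paste(bad, collapse = ", "))
  catalogue
}

#' Default regimen-naming precedence
#'
#' Regimens are labelled by backbone drug: the first drug of the precedence
#' list present in the regimen gives the label `"<drug>-based"`. Novel
#' agents rank before the older backbones so that, e.g., a
#' daratumumab + bortezomib combination is "daratumumab-based".
#'
#' @return character vector of drug names, highest precedence first.
#' @export
default_regimen_precedence <- function() {
  c("daratumumab", "carfilzomib", "pomalidomide", "ixazomib",
    "bortezomib", "lenalidomide", "thalidomide", "bendamustine",
    "melphalan", "cyclophosphamide", "doxorubicine")
}

#' Default clinical code lists
#'
#' Configurable stand-ins for the code lists a production deployment would
#' take from a national terminology service:
#'
#' * `mm_codes`: ICD-10 prefixes identifying multiple myeloma (C90 and all
#'   C90.x subcodes).
#' * `malignancy_exclusion`: prefix range of other-malignancy codes
#'   (C00-C97) with exceptions for MM itself (C90) and non-melanoma skin
#'   cancer (C44).
#' * `sct_drg_codes` / `sct_ccam_codes`: synthetic stand-in DRG and CCAM
#'   procedure codes flagging stem cell transplantation, with graft type
#'   encoded in the code suffix. The real lists are jurisdiction specific
#'   and must be supplied via configuration for real data.
#' * `chemo_session_codes`: ICD-10 main-diagnosis codes marking a
#'   chemotherapy-session stay (Z51.1 encounter for chemotherapy).
#' * `aoe_codes`: ICD-10 prefixes of events of interest (infection,
#'   cytopenias, thromboembolism, neuropathy, renal failure, bone events,
#'   ...) counted when they are the primary diagnosis of a stay.
#'
#' @return named list of character vectors (plus the named
#'   `sct_graft_types` map from code to graft type).
#' @export
default_code_lists <- function() {
  list(
    mm_codes = c("C90"),
    malignancy_range = c("C00", "C97"),
    malignancy_exempt = c("C90", "C44"),
    sct_drg_codes = c("DRGSCTAUTO", "DRGSCTALLO"),
    sct_ccam_codes = c("CCAMSCTAUTO", "CCAMSCTALLO"),
    sct_graft_types = c(
      DRGSCTAUTO = "autologous", DRGSCTALLO = "allogeneic",
      CCAMSCTAUTO = "autologous", CCAMSCTALLO = "allogeneic"
    ),
    chemo_session_codes = c("Z511"),
    aoe_codes = c(
      "A41",            # sepsis
      "J12", "J15", "J18", # pneumonia
      "B02",            # shingles
      "D61", "D64", "D69", "D70", # anaemia / cytopenias
      "I26", "I80", "I82",        # venous thromboembolism
      "G62",            # peripheral neuropathy
      "N17",            # acute renal failure
      "M80", "M84",     # skeletal-related events
      "A09", "K52",     # diarrhoea
      "H16", "H26", "H40" # ocular events
    )
  )
}

#' Default Charlson comorbidity weight map (ICD-10, claims adapted)
#'
#' ICD-10 prefix to (condition, weight) mapping in the classical Charlson
#' weighting adapted for claims coding. Matching is by prefix: a diagnosis
#' code maps to a condition when it starts with one of the condition's
#' prefixes. Each distinct condition contributes its weight once. Multiple
#' myeloma itself (C90) maps to the malignancy condition (weight 2), so any
#' MM cohort has a floor score of 2.
#'
#' @return `data.table` with columns `icd10_prefix`, `condition`, `weight`.
#' @export
default_charlson_map <- function() {
  rows <- list(
    list(c("I21", "I22", "I252"), "myocardial_infarction", 1L),
    list(c("I50", "I110", "I130", "I132"), "congestive_heart_failure", 1L),
    list(c("I70", "I71", "I731", "I738", "I739"), "peripheral_vascular", 1L),
    list(c("I60", "I61", "I62", "I63", "I64", "G45", "G46"),
         "cerebrovascular", 1L),
    list(c("F00", "F01", "F02", "F03", "G30"), "dementia", 1L),
    list(c("J40", "J41", "J42", "J43", "J44", "J45", "J46", "J47", "J60",
           "J61", "J62", "J63", "J64", "J65", "J66", "J67"),
         "chronic_pulmonary", 1L),
    list(c("M05", "M06", "M32", "M33", "M34", "M315", "M351", "M353",
           "M360"), "rheumatologic", 1L),
    list(c("K25", "K26", "K27", "K28"), "peptic_ulcer", 1L),
    list(c("B18", "K700", "K701", "K702", "K703", "K709", "K713", "K714",
           "K715", "K73", "K74", "K760"), "mild_liver", 1L),
    list(c("E100", "E101", "E106", "E108", "E109", "E110", "E111", "E116",
           "E118", "E119", "E130", "E131", "E136", "E138", "E139"),
         "diabetes", 1L),
    list(c("E102", "E103", "E104", "E105", "E107", "E112", "E113", "E114",
           "E115", "E117", "E132", "E133", "E134", "E135", "E137"),
         "diabetes_complicated", 2L),
    list(c("G81", "G82", "G041", "G114", "G801", "G802", "G830", "G831",
           "G832", "G833", "G834", "G839"), "hemiplegia", 2L),
    list(c("N18", "N19", "N052", "N053", "N054", "N055", "N056", "N057",
           "N250", "I120", "I131", "Z490", "Z491", "Z492", "Z940", "Z992"),
         "renal", 2L),
    # Any malignancy including lymphoma and leukaemia (C00-C26, C30-C34,
    # C37-C41, C43, C45-C58, C60-C76, C81-C85, C88, C90-C97)
    list(c(sprintf("C%02d", c(0:26, 30:34, 37:41, 43, 45:58, 60:76,
                              81:85, 88, 90:97))),
         "malignancy", 2L),
    list(c("K704", "K711", "K721", "K729", "K765", "K766", "K767", "I85"),
         "moderate_severe_liver", 3L),
    list(c("C77", "C78", "C79", "C80"), "metastatic_solid", 6L),
    list(c("B20", "B21", "B22", "B24"), "aids", 6L)
  )
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(icd10_prefix = r[[1]], condition = r[[2]],
                           weight = r[[3]])
  }))
}

# normalise an ICD-10 code for prefix matching: uppercase, drop dots
icd10_norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

# TRUE where code starts with any of the given prefixes (codes already
# normalised)
icd10_match_prefix <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  pat <- paste0("^(", paste(icd10_norm(prefixes), collapse = "|"), ")")
  grepl(pat, codes)
}

# TRUE where code is an other-malignancy code: inside [lo, hi] 3-character
# prefix range, minus exempt prefixes
is_other_malignancy <- function(codes, lists = default_code_lists()) {
  codes <- icd10_norm(codes)
  pre <- substr(codes, 1, 3)
  lo <- lists$malignancy_range[1]
  hi <- lists$malignancy_range[2]
  inside <- pre >= lo & pre <= hi
  inside & !icd10_match_prefix(codes, lists$malignancy_exempt)
}

# TRUE where code is an MM code (C90 or C90.x)
is_mm_code <- function(codes, lists = default_code_lists()) {
  icd10_match_prefix(icd10_norm(codes), lists$mm_codes)
}
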