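# Rendering precision conventions: monetary K-euro / M-euro cells round to
# two decimals, percentages to one decimal. Full-precision tables are
# always emitted alongside; rounding happens only here.

#' Report-arithmetic primitives
#'
#' The formulas every rendered cell is built from: a percentage of a
#' count, a per-person mean in thousand euros from a summed cost in
#' million euros, and a share of a total. Kept as tiny exported functions
#' so report arithmetic is checkable in isolation against published
#' tables.
#'
#' @param numerator,denominator counts (or sums in identical units).
#' @param digits rounding digits for rendering (1 for percentages).
#' @return rendered numeric value.
#' @export
render_pct <- function(numerator, denominator, digits = 1) {
  if (any(denominator == 0)) stop("render_pct: zero denominator")
  round(100 * numerator / denominator, digits)
}

#' @rdname render_pct
#' @param sum_meur summed cost in million euros.
#' @param n cohort size.
#' @export
render_mean_pp_keur <- function(sum_meur, n, digits = 2) {
  if (any(n == 0)) stop("render_mean_pp_keur: zero cohort")
  round(sum_meur * 1000 / n, digits)
}

#' @rdname render_pct
#' @param part,whole sums in identical units.
#' @export
render_share_pct <- function(part, whole, digits = 1) {
  if (any(whole == 0)) stop("render_share_pct: zero total")
  round(100 * part / whole, digits)
}

#' Render an all-cause cost table from published category sums
#'
#' Applies the report formulas to a table of per-category summed costs
#' (overall and first-year, in million euros): group and total rows by
#' addition, per-person means (K-euro) by division by the cohort size,
#' and shares as percentages of the total. This is the arithmetic surface
#' of the all-cause cost table; it runs equally on sums computed by
#' [build_allcause_table()] or on published sums used as validation
#' input.
#'
#' @param category_sums data.table/data.frame with columns `category`,
#'   `sum_meur`, `fy_sum_meur` (one row per leaf HCRU category).
#' @param n cohort size.
#' @return data.table with rendered `mean_pp_keur`, `share_pct`,
#'   `fy_mean_pp_keur`, `fy_share_pct` per category plus group rows
#'   (`all_hospitalisation`, `all_treatment`, `all_other`, `total`).
#' @export
render_allcause_from_sums <- function(category_sums, n) {
  cs <- data.table::as.data.table(category_sums)
  need <- c("category", "sum_meur", "fy_sum_meur")
  if (!all(need %in% names(cs))) {
    stop("render_allcause_from_sums: need columns ",
         paste(need, collapse = ", "))
  }
  grp <- function(name, cats) data.table::data.table(
    category = name,
    sum_meur = sum(cs[category %in% cats, sum_meur]),
    fy_sum_meur = sum(cs[category %in% cats, fy_sum_meur]))
  tab <- data.table::rbindlist(list(
    cs[, .(category, sum_meur, fy_sum_meur)],
    grp("all_hospitalisation", HOSPITAL_CATEGORIES),
    grp("all_treatment", DRUG_CATEGORIES),
    grp("all_other", OTHER_CATEGORIES),
    grp("total", HCRU_CATEGORIES)))
  total <- tab[category == "total", sum_meur]
  fy_total <- tab[category == "total", fy_sum_meur]
  tab[, `:=`(
    mean_pp_keur = render_mean_pp_keur(sum_meur, n),
    share_pct = render_share_pct(sum_meur, total),
    fy_mean_pp_keur = render_mean_pp_keur(fy_sum_meur, n),
    fy_share_pct = render_share_pct(fy_sum_meur, fy_total))]
  tab[]
}

#' Published summary inputs bundled for validation
#'
#' Reads the published all-cause cost sums (per-category overall and
#' first-year totals, million euros, 2019 prices, N = 6413) and the
#' published cohort disposition counts for the French incident-MM claims
#' cohort 2013-2018. These are printed aggregate inputs — no patient-level
#' data — used to validate that the report renderer's arithmetic
#' reproduces the published cells.
#'
#' @return list with `allcause` (data.table `category`, `sum_meur`,
#'   `fy_sum_meur`), `n_cohort`, and `counts` (data.table `measure`,
#'   `numerator`, `denominator`).
#' @export
published_summary_inputs <- function() {
  dir <- system.file("extdata", package = "mmlot")
  allcause <- data.table::fread(file.path(dir, "published_allcause_sums.csv"))
  counts <- data.table::fread(file.path(dir, "published_cohort_counts.csv"))
  list(allcause = allcause, n_cohort = 6413L, counts = counts)
}

#' Baseline characteristics table
#'
#' Age (mean/SD/median/range/IQR and bands), sex, Charlson score classes,
#' the per-patient LOT-count distribution (including undetermined),
#' follow-up months and end-of-follow-up reasons — stratified by SCT
#' status and for the total cohort. Percentages use the stratum N as
#' denominator.
#'
#' @param cohort cohort table from [build_cohort()] (needs
#'   `age_at_index`, `sex`, `charlson`, `months`, `end_reason`, `sct`).
#' @param lots derived lines (for the per-patient LOT count).
#' @return data.table `stratum`, `measure`, `value` (numeric), `pct`
#'   (where applicable).
#' @export
render_table1 <- function(cohort, lots) {
  co <- data.table::as.data.table(cohort)
  lt <- data.table::as.data.table(lots)
  nlot <- if (nrow(lt)) {
    lt[, .(n_lot = max(lot_number)), by = "patient_id"]
  } else {
    data.table::data.table(patient_id = character(0), n_lot = integer(0))
  }
  co <- merge(co, nlot, by = "patient_id", all.x = TRUE)
  co[is.na(n_lot), n_lot := 0L]
  strata <- list(SCT = co[sct == TRUE], no_SCT = co[sct == FALSE],
                 total = co)
  rows <- list()
  add <- function(stratum, measure, value, pct = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      stratum = stratum, measure = measure, value = value, pct = pct)
  }
  for (nm in names(strata)) {
    s <- strata[[nm]]
    n <- nrow(s)
    add(nm, "n", n)
    if (n == 0) next
    add(nm, "age_mean", mean(s$age_at_index))
    add(nm, "age_sd", stats::sd(s$age_at_index))
    add(nm, "age_median", stats::median(s$age_at_index))
    add(nm, "age_min", min(s$age_at_index))
    add(nm, "age_max", max(s$age_at_index))
    add(nm, "age_iqr", stats::IQR(s$age_at_index, type = 2))
    bands <- cut(s$age_at_index, c(-Inf, 30, 50, 70, Inf),
                 labels = c("18-30", "31-50", "51-70", ">70"))
    for (b in levels(bands)) {
      add(nm, paste0("age_band_", b), sum(bands == b),
          render_pct(sum(bands == b), n))
    }
    add(nm, "sex_male", sum(s$sex == "M"),
        render_pct(sum(s$sex == "M"), n))
    add(nm, "sex_female", sum(s$sex == "F"),
        render_pct(sum(s$sex == "F"), n))
    add(nm, "charlson_mean", mean(s$charlson))
    add(nm, "charlson_median", stats::median(s$charlson))
    cls <- cut(s$charlson, c(-Inf, 2, 4, Inf),
               labels = c("1-2", "3-4", ">=5"))
    for (b in levels(cls)) {
      add(nm, paste0("charlson_class_", b), sum(cls == b),
          render_pct(sum(cls == b), n))
    }
    lotg <- cut(s$n_lot, c(-Inf, 0, 1, 2, 3, 4, Inf),
                labels = c("undetermined", "1", "2", "3", "4", "5+"))
    for (b in levels(lotg)) {
      add(nm, paste0("n_lot_", b), sum(lotg == b),
          render_pct(sum(lotg == b), n))
    }
    add(nm, "followup_months_mean", mean(s$months))
    add(nm, "followup_months_median", stats::median(s$months))
    add(nm, "followup_months_iqr", stats::IQR(s$months, type = 2))
    for (r in c("death", "disenrollment", "lost_to_follow_up",
                "end_of_observation")) {
      add(nm, paste0("end_", r), sum(s$end_reason == r),
          render_pct(sum(s$end_reason == r), n))
    }
  }
  data.table::rbindlist(rows)
}

#' Regimen frequencies per line and SCT stratum
#'
#' @param lots derived lines with a `label` column (see
#'   [classify_regimen()]); when absent, labels are computed with the
#'   default precedence.
#' @param sct SCT status table (`patient_id`, `sct`).
#' @param max_line aggregate lines above this (default 5).
#' @return data.table `stratum`, `line`, `label`, `n`, `pct` (share of
#'   the line's patients in the stratum), plus per-line
#'   `distinct_regimens` (cardinality of the observed regimen set).
#' @export
render_regimen_figure <- function(lots, sct, max_line = 5L) {
  lt <- data.table::as.data.table(lots)
  sct <- data.table::as.data.table(sct)
  if (!"label" %in% names(lt)) lt[, label := classify_regimen(regimen)]
  lt <- merge(lt, sct[, .(patient_id, sct)], by = "patient_id")
  lt[, line := pmin(lot_number, max_line)]
  strata <- list(SCT = lt[sct == TRUE], no_SCT = lt[sct == FALSE],
                 total = lt)
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (!nrow(s)) next
    g <- s[, .(n = .N,
               distinct_regimens = data.table::uniqueN(regimen)),
           by = .(line, label)]
    g[, line_n := sum(n), by = "line"]
    g[, `:=`(stratum = nm, pct = render_pct(n, line_n))]
    g[, distinct_regimens := sum(distinct_regimens), by = "line"]
    out[[nm]] <- g[, .(stratum, line, label, n, pct, distinct_regimens)]
  }
  data.table::rbindlist(out)[order(stratum, line, -n)]
}
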