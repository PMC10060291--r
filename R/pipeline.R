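#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> cohort -> lines of therapy ->
#' cost ledger and attribution -> report tables, writing every output as
#' CSV plus a JSON run manifest with row counts, digests and the
#' attrition waterfall.
#'
#' @param out_dir output directory (created if needed).
#' @param in_dir directory with input claims CSVs (ignored when
#'   `simulate` is given).
#' @param simulate optional [sim_config()]; when supplied the claims are
#'   generated (and also written to `out_dir/claims/`).
#' @param config an [mmlot_config()].
#' @param violations optional `rates` list passed to
#'   [inject_protocol_violations()] after simulation.
#' @param verbose print one line per stage.
#' @return invisibly, a list with all in-memory results (`claims`,
#'   `cohort`, `lots`, `ledger`, tables, `manifest`).
#' @export
run_pipeline <- function(out_dir, in_dir = NULL, simulate = NULL,
                         config = mmlot_config(), violations = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[mmlot] ", ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(simulate)) {
    say("simulate: n=", simulate$n_patients, " seed=", simulate$seed)
    claims <- generate_population(simulate)
    if (!is.null(violations)) {
      claims <- inject_protocol_violations(claims, violations,
                                           seed = simulate$seed)
    }
    write_claims(claims, file.path(out_dir, "claims"))
  } else {
    if (is.null(in_dir)) stop("run_pipeline: need in_dir or simulate")
    say("read claims from ", in_dir)
    claims <- read_claims(in_dir)
  }
  counts <- vapply(claims, nrow, integer(1))
  say("claims rows: ", paste(names(counts), counts, sep = "=",
                             collapse = " "))

  say("cohort")
  built <- build_cohort(claims, config)
  cohort <- built$cohort
  fu <- built$followup

  say("lots")
  lots <- derive_lots(claims$dispensings, fu, config$lot, config$catalogue)
  if (nrow(lots)) {
    lots[, label := classify_regimen(regimen, config$regimen_precedence)]
  } else {
    lots[, label := character(0)]
  }

  say("costs")
  ledger <- build_cost_ledger(claims, fu, config)
  ledger <- tag_mm_treatment_admin(ledger, config)
  ledger <- tag_mm_related(ledger, config)
  ledger <- tag_aoe(ledger, config)
  ledger <- attribute_lot(ledger, lots, config)

  say("tables")
  sct <- cohort[, .(patient_id, sct)]
  table_allcause <- build_allcause_table(ledger, fu)
  table_mm_admin <- build_mm_admin_table(ledger, fu, lots, sct)
  table_hcru <- build_hcru_by_lot(ledger, fu, lots, sct)
  aoe <- data.table::rbindlist(list(
    overall = aoe_hospitalisations(ledger, fu, config),
    first_year = aoe_hospitalisations(ledger, fu, config,
                                      first_year = TRUE),
    SCT = aoe_hospitalisations(ledger[patient_id %in%
                                        sct[sct == TRUE, patient_id]],
                               fu[patient_id %in%
                                    sct[sct == TRUE, patient_id]], config)
  ), idcol = "stratum")
  table1 <- render_table1(cohort, lots)
  regimens <- render_regimen_figure(lots, sct)

  outputs <- list(cohort = cohort, followup = fu,
                  exclusion_log = built$exclusion_log,
                  attrition = built$attrition, lots = lots,
                  ledger = ledger, table_allcause = table_allcause,
                  table_mm_admin_by_lot = table_mm_admin,
                  table_hcru_by_lot = table_hcru, aoe_summary = aoe,
                  table1 = table1, regimen_frequencies = regimens)
  paths <- character(0)
  for (nm in names(outputs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    data.table::fwrite(outputs[[nm]], p, dateTimeAs = "ISO")
    paths[nm] <- p
  }
  manifest <- list(
    seed = if (!is.null(simulate)) simulate$seed else NA,
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = list(claims = as.list(counts),
                  cohort = nrow(cohort), lots = nrow(lots),
                  ledger = nrow(ledger)),
    attrition = as.list(stats::setNames(built$attrition$n,
                                        built$attrition$stage)),
    digests = lapply(stats::setNames(nm = names(paths)), function(nm) {
      unname(tools::md5sum(paths[[nm]]))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", nrow(cohort), " eligible patients, ", nrow(lots),
      " lines")
  invisible(c(list(claims = claims, manifest = manifest), outputs))
}
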