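# End-to-end orchestration: ingest -> deletions -> dedup -> cohort ->
# signals -> subgroup -> SOC summary, with per-stage TSV outputs and a
# record-count log.

#' Run the full screening pipeline
#'
#' Executes every stage in order on either files on disk or a synthetic
#' configuration, writing each stage's TSV plus a stage log and a
#' machine-readable run manifest to `out_dir`. Identical configuration
#' (including any generator seed) reproduces identical outputs.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{input}{Either `list(synth = synth_config(...))` or
#'       `list(demo =, drug =, reac =, deleted =, soc_map =)` file paths
#'       (each of `demo`/`drug`/`reac` may be a vector, one per quarter).}
#'     \item{cohort}{A [cohort_spec()].}
#'     \item{criteria}{A [signal_criteria()] (optional, defaults used).}
#'     \item{ic_shrinkage, zero_correction}{Optional screening switches.}
#'   }
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results
#'   (`snapshot`, `cohort`, `signals`, `subgroup`, `soc`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), inherits(config$cohort, "cohort_spec"))
  criteria <- config$criteria %||% signal_criteria()
  ic_shrinkage <- isTRUE(config$ic_shrinkage)
  zero_correction <- config$zero_correction %||% "none"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ingest
  if (!is.null(config$input$synth)) {
    gen <- stage("ingest", synth_generate(config$input$synth))
    snapshot <- stage("ingest", synth_as_snapshot(gen))
    soc_map <- gen$soc_map
  } else {
    inp <- config$input
    snapshot <- stage("ingest", faers_assemble(
      demo = lapply(inp$demo, faers_read_table, kind = "demo"),
      drug = lapply(inp$drug, faers_read_table, kind = "drug"),
      reac = lapply(inp$reac, faers_read_table, kind = "reac"),
      deleted_caseids = faers_read_deleted(inp$deleted %||% character()),
      provenance = inp$demo
    ))
    soc_map <- if (!is.null(inp$soc_map)) {
      stage("ingest", load_pt_soc_map(inp$soc_map))
    } else NULL
  }

  ## deletions, dedup
  snapshot <- stage("deletions", apply_deletions(snapshot))
  snapshot <- stage("dedup", dedup_reports(snapshot))

  ## cohort
  cohort <- stage("cohort", select_cohort(snapshot, config$cohort))
  descr <- stage("cohort", descriptive_summary(cohort))
  conc <- stage("cohort", concomitant_summary(cohort))

  ## signals
  signals <- stage("signals", screen_signals(
    cohort$pair_table, criteria = criteria, soc_map = soc_map,
    ic_shrinkage = ic_shrinkage, zero_correction = zero_correction
  ))

  ## subgroup
  sub <- stage("subgroup", subgroup_signals(
    cohort, criteria = criteria, soc_map = soc_map,
    ic_shrinkage = ic_shrinkage, zero_correction = zero_correction
  ))

  ## SOC summary
  soc <- if (!is.null(soc_map)) {
    stage("soc", soc_summary(signals, soc_map))
  } else {
    tibble::tibble(soc = character(), n_pairs = integer(),
                   share = double(), n_signals = integer())
  }

  log <- dplyr::bind_rows(
    snapshot$log,
    tibble::tibble(
      stage = c("cohort", "signals", "subgroup", "soc"),
      rows_in = c(nrow(snapshot$reports), nrow(cohort$pair_table),
                  nrow(cohort$pair_table), nrow(signals)),
      rows_out = c(length(cohort$member_primaryids), nrow(signals),
                   nrow(sub$signals), nrow(soc)),
      note = c(
        paste0("background_pairs=", nrow(cohort$pair_table)),
        paste0("combined_signals=", sum(signals$signal)),
        paste0("discordant_pts=", nrow(sub$discordance)),
        ""
      )
    )
  )

  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  w(descr$tallies, "cohort_demographics.tsv")
  w(conc, "cohort_concomitants.tsv")
  w(signals, "signal_table.tsv")
  w(sub$signals, "subgroup_signal_table.tsv")
  w(sub$discordance, "subgroup_discordance.tsv")
  w(soc, "soc_summary.tsv")
  w(render_forest_data(signals), "forest_data.tsv")
  w(log, "stage_log.tsv")
  jsonlite::write_json(
    list(
      n_reports_post_dedup = nrow(snapshot$reports),
      n_members = length(cohort$member_primaryids),
      n_background_pairs = nrow(cohort$pair_table),
      n_signals = sum(signals$signal),
      age_mean = descr$age_mean, age_sd = descr$age_sd,
      outputs = list.files(out_dir, pattern = "\\.tsv$")
    ),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA
  )

  invisible(list(snapshot = snapshot, cohort = cohort, descriptives = descr,
                 concomitants = conc, signals = signals, subgroup = sub,
                 soc = soc, log = log))
}

#' Forest-plot-ready data from a signal table
#'
#' Extracts the columns a ROR forest plot displays — preferred term, SOC,
#' co-occurrence count and the ROR with its interval — sorted by SOC then
#' descending count.
#'
#' @param signal_table A [screen_signals()] result.
#' @return Tibble with columns `pt`, `soc`, `a`, `ror`, `ror_l95`,
#'   `ror_u95`.
#' @export
render_forest_data <- function(signal_table) {
  x <- signal_table
  if (!"soc" %in% names(x)) x$soc <- NA_character_
  x <- x[, c("pt", "soc", "a", "ror", "ror_l95", "ror_u95")]
  dplyr::arrange(x, .data$soc, dplyr::desc(.data$a), .data$pt)
}
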