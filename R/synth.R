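# Synthetic spontaneous-report generator: FAERS-shaped snapshots with known
# ground truth (planted drug-event associations, duplicate versions,
# deletion lists), fully reproducible from a single seed.

#' Default synthetic drug vocabulary
#'
#' Two antiviral target drugs, each under a generic and a trade name that
#' share one active ingredient, a handful of decoy names sharing 3-letter
#' prefixes with the targets (to exercise substring matching), and common
#' background/concomitant medications. `prob` is the marginal probability
#' of being the primary suspect of a report.
#'
#' @return Tibble with columns `name`, `prod_ai`, `prob`.
#' @export
synth_drug_vocabulary <- function() {
  v <- tibble::tribble(
    ~name,                 ~prod_ai,                ~prob,
    "TAMIFLU",             "OSELTAMIVIR PHOSPHATE", 0.08,
    "OSELTAMIVIR",         "OSELTAMIVIR PHOSPHATE", 0.06,
    "XOFLUZA",             "BALOXAVIR MARBOXIL",    0.05,
    "BALOXAVIR MARBOXIL",  "BALOXAVIR MARBOXIL",    0.04,
    "TAMSULOSIN",          "TAMSULOSIN",            0.02,
    "OSERADINE",           "OSERADINE",             0.02,
    "BALSALAZIDE",         "BALSALAZIDE",           0.01,
    "ACETAMINOPHEN",       "ACETAMINOPHEN",         0.18,
    "IBUPROFEN",           "IBUPROFEN",             0.12,
    "AMOXICILLIN",         "AMOXICILLIN",           0.09,
    "AZITHROMYCIN",        "AZITHROMYCIN",          0.07,
    "CEFTRIAXONE",         "CEFTRIAXONE",           0.05,
    "METHOTREXATE",        "METHOTREXATE",          0.06,
    "ADALIMUMAB",          "ADALIMUMAB",            0.06,
    "SERTRALINE",          "SERTRALINE",            0.05,
    "METFORMIN",           "METFORMIN",             0.04
  )
  v$prob <- v$prob / sum(v$prob)
  v
}

#' Default synthetic event vocabulary
#'
#' Preferred terms with a primary system organ class and a marginal
#' probability of appearing in a report. Terms intended as planting targets
#' are kept rare (marginal probability at or below 0.01) so that a planted
#' reporting-rate ratio carries over to the reporting odds ratio with
#' little renormalization distortion.
#'
#' @return Tibble with columns `pt`, `soc`, `prob` (normalized).
#' @export
synth_event_vocabulary <- function() {
  v <- tibble::tribble(
    ~pt,                              ~soc,                                        ~prob,
    "VOMITING",                       "Gastrointestinal disorders",                0.100,
    "NAUSEA",                         "Gastrointestinal disorders",                0.080,
    "DIARRHOEA",                      "Gastrointestinal disorders",                0.070,
    "ABDOMINAL PAIN",                 "Gastrointestinal disorders",                0.050,
    "PYREXIA",                        "General disorders",                         0.090,
    "FATIGUE",                        "General disorders",                         0.060,
    "DRUG INEFFECTIVE",               "General disorders",                         0.080,
    "NO ADVERSE EVENT",               "General disorders",                         0.020,
    "INSOMNIA",                       "Psychiatric disorders",                     0.030,
    "HALLUCINATION",                  "Psychiatric disorders",                     0.010,
    "ABNORMAL BEHAVIOUR",             "Psychiatric disorders",                     0.008,
    "DELIRIUM",                       "Psychiatric disorders",                     0.005,
    "HEADACHE",                       "Nervous system disorders",                  0.070,
    "DIZZINESS",                      "Nervous system disorders",                  0.050,
    "SEIZURE",                        "Nervous system disorders",                  0.010,
    "TREMOR",                         "Nervous system disorders",                  0.008,
    "RASH",                           "Skin and subcutaneous tissue disorders",    0.060,
    "PRURITUS",                       "Skin and subcutaneous tissue disorders",    0.040,
    "URTICARIA",                      "Skin and subcutaneous tissue disorders",    0.020,
    "STEVENS-JOHNSON SYNDROME",       "Skin and subcutaneous tissue disorders",    0.002,
    "OFF LABEL USE",                  "Injury, poisoning and procedural complications", 0.030,
    "MEDICATION ERROR",               "Injury, poisoning and procedural complications", 0.010,
    "INTENTIONAL PRODUCT USE ISSUE",  "Injury, poisoning and procedural complications", 0.005,
    "ANAPHYLACTIC SHOCK",             "Immune system disorders",                   0.003,
    "HYPERSENSITIVITY",               "Immune system disorders",                   0.010,
    "COUGH",                          "Respiratory disorders",                     0.050,
    "DYSPNOEA",                       "Respiratory disorders",                     0.040,
    "PNEUMONIA",                      "Infections and infestations",               0.020
  )
  v$prob <- v$prob / sum(v$prob)
  v
}

#' Default synthetic demographics
#'
#' Mixture emulating a spontaneous-reporting population: a pediatric slice
#' (ages 0-18, with months/weeks/days unit codes under age 2), adults with
#' occasional decade coding, a small missing-age rate, sexes with a
#' missing category, consumer-dominated reporter occupations, and
#' US-dominated reporting countries over the 2019-2023 receipt years.
#'
#' @return A list of sampling parameters used by [synth_generate()].
#' @export
synth_demographics <- function() {
  list(
    pediatric_fraction = 0.30,
    pediatric_range = c(0, 18),
    adult_range = c(19, 90),
    missing_age_rate = 0.05,
    sex_probs = c("F" = 0.45, "M" = 0.45, "U" = 0.10),
    reporter_probs = c(CN = 0.55, MD = 0.20, PH = 0.12, OT = 0.06,
                       LW = 0.01, U = 0.06),
    country_probs = c(US = 0.65, JP = 0.12, CN = 0.05, DE = 0.03,
                      FR = 0.03, OTHER = 0.12),
    year_probs = c("2019" = 0.25, "2020" = 0.30, "2021" = 0.10,
                   "2022" = 0.15, "2023" = 0.20)
  )
}

#' Configuration for the synthetic-report generator
#'
#' @param n_cases Number of distinct cases to generate.
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param drug_vocabulary Tibble `(name, prod_ai, prob)`; probabilities are
#'   renormalized.
#' @param event_vocabulary Tibble `(pt, soc, prob)`; renormalized.
#' @param planted_signals `NULL` or a data frame with columns `drug`
#'   (matched as a normalized substring against the PS drug's name or
#'   active ingredient), `pt`, `rate_ratio` (> 0), and optionally `sex`
#'   (`"F"`/`"M"`/`NA` for both) restricting the association to one
#'   stratum. In matching reports the planted PT's sampling probability is
#'   multiplied by `rate_ratio` and the event distribution renormalized.
#' @param events_lambda Events per report are `1 + Poisson(events_lambda)`.
#' @param concomitant_mean Concomitant mentions per report are
#'   `min(Poisson(concomitant_mean), 5)`.
#' @param demographics See [synth_demographics()].
#' @param duplicate_rate Fraction of cases carrying 1-2 extra follow-up
#'   versions with later receipt dates and higher primaryids.
#' @param deletion_rate Fraction of cases placed on the deleted-case list.
#' @param orphan_events Number of event rows planted with a primaryid
#'   absent from DEMO (referential-violation exercise).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases, seed,
                         drug_vocabulary = synth_drug_vocabulary(),
                         event_vocabulary = synth_event_vocabulary(),
                         planted_signals = NULL,
                         events_lambda = 2,
                         concomitant_mean = 1,
                         demographics = synth_demographics(),
                         duplicate_rate = 0.10,
                         deletion_rate = 0.02,
                         orphan_events = 0) {
  stopifnot(n_cases >= 0, length(seed) == 1, is.finite(seed))
  drug_vocabulary$prob <- drug_vocabulary$prob / sum(drug_vocabulary$prob)
  event_vocabulary$prob <- event_vocabulary$prob / sum(event_vocabulary$prob)
  if (is.null(planted_signals)) {
    planted_signals <- tibble::tibble(drug = character(), pt = character(),
                                      rate_ratio = double(), sex = character())
  } else {
    planted_signals <- tibble::as_tibble(planted_signals)
    if (!"sex" %in% names(planted_signals)) planted_signals$sex <- NA_character_
    stopifnot(all(c("drug", "pt", "rate_ratio") %in% names(planted_signals)),
              all(planted_signals$rate_ratio > 0),
              all(planted_signals$pt %in% event_vocabulary$pt))
    base <- event_vocabulary$prob[match(planted_signals$pt, event_vocabulary$pt)]
    if (any(base * planted_signals$rate_ratio >= 1)) {
      stop("Infeasible planted signal: rate_ratio drives an event ",
           "probability to 1 or above before renormalization", call. = FALSE)
    }
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         drug_vocabulary = drug_vocabulary,
         event_vocabulary = event_vocabulary,
         planted_signals = planted_signals,
         events_lambda = events_lambda,
         concomitant_mean = concomitant_mean,
         demographics = demographics,
         duplicate_rate = duplicate_rate,
         deletion_rate = deletion_rate,
         orphan_events = as.integer(orphan_events)),
    class = "synth_config"
  )
}

#' Generate a synthetic FAERS snapshot with ground truth
#'
#' Produces canonical-column DEMO/DRUG/REAC tibbles (one row set per case
#' version), a deleted-case list, the PT-to-SOC map of the event
#' vocabulary, and a truth table recording, per case, the surviving
#' version, demographics after unit encoding, the primary-suspect drug and
#' deletion status — everything the pipeline's output can be checked
#' against. Identical configurations (including the seed) give identical
#' output.
#'
#' @param config A [synth_config()].
#' @return A `synth_snapshot` list with elements `demo`, `drug`, `reac`
#'   (tibbles), `deleted_caseids`, `soc_map` ([pt_soc_map()]), `truth`
#'   (list with `cases` and `planted`), and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cases
  dg <- config$demographics
  dv <- config$drug_vocabulary
  ev <- config$event_vocabulary

  if (n == 0) {
    empty <- function(cols) {
      tibble::as_tibble(stats::setNames(rep(list(character()), length(cols)), cols))
    }
    demo <- empty(c("primaryid", "caseid", "fda_dt", "age_value", "age_code",
                    "sex", "reporter", "country", "event_year"))
    demo$age_value <- double(); demo$event_year <- integer()
    return(structure(list(
      demo = demo,
      drug = empty(c("primaryid", "drug_seq", "role_code", "drugname", "prod_ai")),
      reac = empty(c("primaryid", "pt")),
      deleted_caseids = character(),
      soc_map = pt_soc_map(ev[, c("pt", "soc")]),
      truth = list(cases = empty("caseid"), planted = config$planted_signals),
      config = config
    ), class = "synth_snapshot"))
  }

  caseid <- as.character(10000000L + seq_len(n))

  ## demographics -----------------------------------------------------------
  pediatric <- stats::runif(n) < dg$pediatric_fraction
  age_raw <- ifelse(pediatric,
                    stats::runif(n, dg$pediatric_range[1], dg$pediatric_range[2]),
                    stats::runif(n, dg$adult_range[1], dg$adult_range[2]))
  infant <- age_raw < 2
  code <- character(n)
  code[infant] <- sample(c("MON", "WK", "DY"), sum(infant), TRUE,
                         prob = c(0.6, 0.2, 0.2))
  adult_dec <- !infant & !pediatric & stats::runif(n) < 0.05
  code[!infant] <- "YR"
  code[adult_dec] <- "DEC"
  value <- round(age_raw / .age_factor[code])
  missing_age <- stats::runif(n) < dg$missing_age_rate
  value[missing_age] <- NA_real_
  code[missing_age] <- NA_character_
  age_years <- parse_age_years(value, code)

  sex <- sample(names(dg$sex_probs), n, TRUE, prob = dg$sex_probs)
  sex[sex == "U"] <- NA_character_
  reporter <- sample(names(dg$reporter_probs), n, TRUE, prob = dg$reporter_probs)
  reporter[reporter == "U"] <- NA_character_
  country <- sample(names(dg$country_probs), n, TRUE, prob = dg$country_probs)
  year <- as.integer(sample(names(dg$year_probs), n, TRUE, prob = dg$year_probs))
  date0 <- as.Date(sprintf("%04d-%02d-%02d", year,
                           sample(1:12, n, TRUE), sample(1:28, n, TRUE)))

  ## versions ---------------------------------------------------------------
  extra <- ifelse(stats::runif(n) < config$duplicate_rate,
                  sample(1:2, n, TRUE), 0L)
  n_versions <- 1L + extra

  ## primary suspect drug and concomitants ----------------------------------
  ps_idx <- sample.int(nrow(dv), n, TRUE, prob = dv$prob)
  n_conc <- pmin(stats::rpois(n, config$concomitant_mean), 5L)

  ## events with planted associations ---------------------------------------
  n_events <- 1L + stats::rpois(n, config$events_lambda)
  planted <- config$planted_signals
  # which planted rows apply to each case: PS drug (substring on normalized
  # name or ingredient) and, when restricted, sex
  ps_name_norm <- .normalize_name(dv$name[ps_idx])
  ps_ai_norm <- .normalize_name(dv$prod_ai[ps_idx])
  applies <- matrix(FALSE, nrow = n, ncol = nrow(planted))
  if (nrow(planted)) {
    for (j in seq_len(nrow(planted))) {
      pat <- .normalize_name(planted$drug[j])
      drug_ok <- grepl(pat, ps_name_norm, fixed = TRUE) |
        grepl(pat, ps_ai_norm, fixed = TRUE)
      sex_ok <- if (is.na(planted$sex[j])) TRUE else !is.na(sex) & sex == planted$sex[j]
      applies[, j] <- drug_ok & sex_ok
    }
  }
  dist_key <- if (nrow(planted)) {
    apply(applies, 1, function(z) paste(which(z), collapse = ","))
  } else {
    rep("", n)
  }
  event_pt <- vector("list", n)
  for (key in unique(dist_key)) {
    rows <- which(dist_key == key)
    q <- ev$prob
    if (nzchar(key)) {
      for (j in as.integer(strsplit(key, ",")[[1]])) {
        q[ev$pt == planted$pt[j]] <- q[ev$pt == planted$pt[j]] * planted$rate_ratio[j]
      }
    }
    q <- q / sum(q)
    total <- sum(n_events[rows])
    draws <- sample.int(nrow(ev), total, TRUE, prob = q)
    event_pt[rows] <- split(ev$pt[draws], rep(seq_along(rows), n_events[rows]))
  }

  ## expand to report versions ----------------------------------------------
  vcase <- rep(seq_len(n), n_versions)
  vnum <- sequence(n_versions)
  # per-case follow-up spacing so receipt dates strictly increase with version
  follow_gap <- sample(10:120, n, TRUE)
  vdate <- date0[vcase] + (vnum - 1L) * follow_gap[vcase]
  primaryid <- paste0(caseid[vcase], vnum)
  fda_dt <- format(vdate, "%Y%m%d")

  demo <- tibble::tibble(
    primaryid = primaryid,
    caseid = caseid[vcase],
    fda_dt = fda_dt,
    age_value = value[vcase],
    age_code = code[vcase],
    sex = sex[vcase],
    reporter = reporter[vcase],
    country = country[vcase],
    event_year = as.integer(substr(fda_dt, 1, 4))
  )

  conc_idx <- sample.int(nrow(dv), sum(n_conc), TRUE, prob = dv$prob)
  conc_case <- rep(seq_len(n), n_conc)
  drug_case <- tibble::tibble(
    case = c(seq_len(n), conc_case),
    drug_seq = c(rep(1L, n), unlist(lapply(n_conc, function(k) seq_len(k) + 1L),
                                    use.names = FALSE)),
    role_code = c(rep("PS", n), rep("C", length(conc_case))),
    vocab_idx = c(ps_idx, conc_idx)
  )
  drug_rows <- drug_case[order(drug_case$case, drug_case$drug_seq), ]
  reps <- n_versions[drug_rows$case]
  expanded <- drug_rows[rep(seq_len(nrow(drug_rows)), reps), ]
  ver_of <- unlist(lapply(reps, seq_len), use.names = FALSE)
  expanded$primaryid <- paste0(caseid[expanded$case], ver_of)
  drug <- tibble::tibble(
    primaryid = expanded$primaryid,
    drug_seq = as.character(expanded$drug_seq),
    role_code = expanded$role_code,
    drugname = dv$name[expanded$vocab_idx],
    prod_ai = dv$prod_ai[expanded$vocab_idx]
  )

  ev_case <- rep(seq_len(n), lengths(event_pt))
  ev_rows <- tibble::tibble(case = ev_case, pt = unlist(event_pt, use.names = FALSE))
  reps_e <- n_versions[ev_rows$case]
  expanded_e <- ev_rows[rep(seq_len(nrow(ev_rows)), reps_e), ]
  ver_e <- unlist(lapply(reps_e, seq_len), use.names = FALSE)
  reac <- tibble::tibble(
    primaryid = paste0(caseid[expanded_e$case], ver_e),
    pt = expanded_e$pt
  )
  if (config$orphan_events > 0) {
    reac <- dplyr::bind_rows(reac, tibble::tibble(
      primaryid = paste0("99999", seq_len(config$orphan_events)),
      pt = ev$pt[sample.int(nrow(ev), config$orphan_events, TRUE)]
    ))
  }

  deleted <- caseid[stats::runif(n) < config$deletion_rate]

  truth_cases <- tibble::tibble(
    caseid = caseid,
    n_versions = n_versions,
    survivor_primaryid = paste0(caseid, n_versions),
    deleted = caseid %in% deleted,
    age_years = age_years,
    sex = sex,
    reporter = reporter,
    country = country,
    ps_drugname = dv$name[ps_idx],
    ps_prod_ai = dv$prod_ai[ps_idx],
    n_concomitant = n_conc,
    n_event_draws = n_events
  )

  structure(
    list(demo = demo, drug = drug, reac = reac,
         deleted_caseids = deleted,
         soc_map = pt_soc_map(ev[, c("pt", "soc")]),
         truth = list(cases = truth_cases, planted = planted),
         config = config),
    class = "synth_snapshot"
  )
}

#' @export
print.synth_snapshot <- function(x, ...) {
  cat("<synth_snapshot>", nrow(x$truth$cases), "cases,",
      nrow(x$demo), "report versions,", nrow(x$reac), "event rows,",
      length(x$deleted_caseids), "deleted,",
      nrow(x$truth$planted), "planted signal(s)\n")
  invisible(x)
}

#' Assemble a generated snapshot for the pipeline
#'
#' Wraps the generated tibbles in a `faers_snapshot` (via
#' [faers_assemble()]) so they can flow through deduplication, cohorting
#' and screening exactly like data read from disk.
#'
#' @param gen A `synth_snapshot` from [synth_generate()].
#' @return A `faers_snapshot`.
#' @export
synth_as_snapshot <- function(gen) {
  stopifnot(inherits(gen, "synth_snapshot"))
  faers_assemble(gen$demo, gen$drug, gen$reac,
                 deleted_caseids = gen$deleted_caseids,
                 provenance = sprintf("synth_seed_%d", gen$config$seed))
}

#' Write a generated snapshot as FAERS-dialect ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt` in the `$`-delimited dialect
#' [faers_read_table()] reads (with the FAERS header spellings `age`,
#' `age_cod`, `role_cod`, `occp_cod`, `occr_country`), a `DELETED.txt`
#' caseid list, the vocabulary's `pt_soc_map.tsv`, and `truth_cases.tsv` /
#' `truth_planted.tsv`.
#'
#' @param gen A `synth_snapshot`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(gen, dir) {
  stopifnot(inherits(gen, "synth_snapshot"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- gen$demo
  demo <- demo[, setdiff(names(demo), "event_year")]
  names(demo)[match(c("age_value", "age_code", "reporter", "country"),
                    names(demo))] <- c("age", "age_cod", "occp_cod", "occr_country")
  drug <- gen$drug
  names(drug)[names(drug) == "role_code"] <- "role_cod"
  faers_write_table(demo, file.path(dir, "DEMO.txt"))
  faers_write_table(drug, file.path(dir, "DRUG.txt"))
  faers_write_table(gen$reac, file.path(dir, "REAC.txt"))
  writeLines(c("caseid", gen$deleted_caseids), file.path(dir, "DELETED.txt"))
  readr::write_tsv(gen$soc_map, file.path(dir, "pt_soc_map.tsv"), progress = FALSE)
  readr::write_tsv(gen$truth$cases, file.path(dir, "truth_cases.tsv"), progress = FALSE)
  readr::write_tsv(gen$truth$planted, file.path(dir, "truth_planted.tsv"), progress = FALSE)
  invisible(dir)
}

#' Recovery report for a screen run on generated data
#'
#' Compares a [screen_signals()] table with the generator's truth:
#' sensitivity (share of planted PTs with at least `a_min` observed
#' co-occurrences that carry the combined signal flag), the false-flag rate
#' among non-planted PTs with `a >= 3`, and the bias of `log(ROR)` against
#' the planted `log(rate_ratio)`.
#'
#' @param truth The `truth` element of a `synth_snapshot`.
#' @param signal_table A [screen_signals()] result.
#' @param a_min Minimum observed `a` for a planted PT to enter the
#'   sensitivity denominator (default 10).
#' @return A list with `sensitivity`, `false_flag_rate`, `log_ror_bias`,
#'   and the joined `planted` tibble.
#' @export
estimate_recovery <- function(truth, signal_table, a_min = 10) {
  planted <- dplyr::left_join(truth$planted, signal_table, by = "pt")
  eligible <- !is.na(planted$a) & planted$a >= a_min
  sensitivity <- if (any(eligible)) mean(planted$signal[eligible]) else NA_real_
  null_rows <- !(signal_table$pt %in% truth$planted$pt) & signal_table$a >= 3
  false_flag_rate <- if (any(null_rows)) mean(signal_table$signal[null_rows]) else NA_real_
  bias <- if (any(eligible)) {
    mean(log(planted$ror[eligible]) - log(planted$rate_ratio[eligible]))
  } else NA_real_
  list(sensitivity = sensitivity, false_flag_rate = false_flag_rate,
       log_ror_bias = bias, planted = planted)
}
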