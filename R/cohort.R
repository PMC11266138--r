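# Target-drug primary-suspect cohort selection in the pediatric stratum,
# plus the descriptive summaries reported alongside a screen.

.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                 DY = 1 / 365, HR = 1 / 8760)

#' Convert FAERS age fields to years
#'
#' FAERS stores patient age as a value plus a unit code: decades (`DEC`),
#' years (`YR`), months (`MON`), weeks (`WK`), days (`DY`) or hours (`HR`).
#' Missing values propagate; an unknown unit code yields a missing age with
#' a warning.
#'
#' @param age_value Numeric vector of age values (may contain `NA`).
#' @param age_code Character vector of unit codes, recycled against
#'   `age_value`.
#' @return Numeric vector of ages in years.
#' @examples
#' parse_age_years(c(18, 6, 2), c("YR", "MON", "DEC"))
#' @export
parse_age_years <- function(age_value, age_code) {
  n <- max(length(age_value), length(age_code))
  age_value <- rep_len(as.numeric(age_value), n)
  age_code <- rep_len(toupper(as.character(age_code)), n)
  fac <- .age_factor[age_code]
  unknown <- !is.na(age_value) & !is.na(age_code) & is.na(fac)
  if (any(unknown)) {
    warning("Unknown age unit code(s): ",
            paste(unique(age_code[unknown]), collapse = ", "),
            "; treated as missing", call. = FALSE)
  }
  unname(age_value * fac)
}

# Uppercase, strip punctuation to spaces, collapse whitespace.
.normalize_name <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Flag drug mentions that match a target-drug name list
#'
#' A mention matches when any pattern (an uppercase generic or trade-name
#' substring, e.g. `"OSELTAMIVIR"`, `"TAMIFLU"`) occurs as a substring of
#' the normalized `drugname` or `prod_ai`. Normalization uppercases, strips
#' punctuation and collapses whitespace, which is how FAERS free-text drug
#' names are conventionally matched.
#'
#' @param drugs Tibble of drug mentions with columns `drugname`, `prod_ai`.
#' @param patterns Character vector of uppercase name substrings.
#' @return Logical vector, one element per row of `drugs`.
#' @export
match_target_drug <- function(drugs, patterns) {
  stopifnot(length(patterns) >= 1)
  patterns <- .normalize_name(patterns)
  nm <- .normalize_name(ifelse(is.na(drugs$drugname), "", drugs$drugname))
  ai <- .normalize_name(ifelse(is.na(drugs$prod_ai), "", drugs$prod_ai))
  hit <- rep(FALSE, nrow(drugs))
  for (p in patterns) {
    hit <- hit | grepl(p, nm, fixed = TRUE) | grepl(p, ai, fixed = TRUE)
  }
  hit
}

#' Specify a primary-suspect cohort
#'
#' @param drug_patterns Uppercase name substrings identifying the target
#'   drug (generic and trade names).
#' @param age_min_years,age_max_years Inclusive age window in years after
#'   unit conversion; the default `[0, 18]` is the pediatric stratum.
#'   Reports with missing age are excluded from the stratum.
#' @param ps_exclusive If `TRUE` (default), a member report must have the
#'   target as its only distinct primary-suspect active ingredient.
#' @param background_scope Comparator for the screen: `"stratum"` (default)
#'   uses the age stratum, `"full"` the whole deduplicated database.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(drug_patterns, age_min_years = 0, age_max_years = 18,
                        ps_exclusive = TRUE,
                        background_scope = c("stratum", "full")) {
  stopifnot(length(drug_patterns) >= 1, age_min_years <= age_max_years)
  structure(
    list(
      drug_patterns = toupper(drug_patterns),
      age_min_years = age_min_years,
      age_max_years = age_max_years,
      ps_exclusive = isTRUE(ps_exclusive),
      background_scope = match.arg(background_scope)
    ),
    class = "cohort_spec"
  )
}

#' Select the target-drug cohort and build the pair table
#'
#' Restricts the deduplicated snapshot to the age stratum, flags reports in
#' which the target drug is a primary suspect (PS), and builds the unit of
#' all downstream counting: the table of unique (report, preferred term)
#' pairs over the chosen background scope, with a membership flag.
#'
#' With `ps_exclusive = TRUE` a report whose PS mentions include any other
#' distinct active ingredient besides the target is not a member.
#'
#' @param snapshot A deduplicated `faers_snapshot`.
#' @param spec A [cohort_spec()].
#' @return A `faers_cohort` object: list with `member_primaryids`,
#'   `pair_table` (columns `primaryid`, `pt`, `is_member`, `sex`),
#'   `stratum_reports`, `member_reports`, `spec`.
#' @export
select_cohort <- function(snapshot, spec) {
  stopifnot(inherits(snapshot, "faers_snapshot"), inherits(spec, "cohort_spec"))
  rep <- snapshot$reports
  rep$age_years <- parse_age_years(rep$age_value, rep$age_code)
  in_stratum <- !is.na(rep$age_years) &
    rep$age_years >= spec$age_min_years & rep$age_years <= spec$age_max_years
  stratum <- rep[in_stratum, , drop = FALSE]

  drugs <- snapshot$drugs
  is_target <- match_target_drug(drugs, spec$drug_patterns)
  is_ps <- !is.na(drugs$role_code) & drugs$role_code == "PS"
  target_ps_pids <- unique(drugs$primaryid[is_target & is_ps])
  if (spec$ps_exclusive) {
    # PS mentions of a non-target ingredient disqualify the report
    other_ps <- is_ps & !is_target
    target_ps_pids <- setdiff(target_ps_pids, unique(drugs$primaryid[other_ps]))
  }
  member_pids <- intersect(stratum$primaryid, target_ps_pids)
  if (!length(member_pids)) {
    warning("Cohort is empty for pattern(s): ",
            paste(spec$drug_patterns, collapse = ", "), call. = FALSE)
  }

  background <- if (spec$background_scope == "stratum") stratum else rep
  ev <- snapshot$events[snapshot$events$primaryid %in% background$primaryid, ,
                        drop = FALSE]
  pair_table <- ev |>
    dplyr::distinct(.data$primaryid, .data$pt) |>
    dplyr::left_join(
      dplyr::select(background, "primaryid", "sex"), by = "primaryid"
    ) |>
    dplyr::mutate(is_member = .data$primaryid %in% member_pids)

  structure(
    list(
      member_primaryids = member_pids,
      pair_table = pair_table,
      stratum_reports = stratum,
      member_reports = stratum[stratum$primaryid %in% member_pids, , drop = FALSE],
      snapshot_drugs = drugs,
      target_mention = is_target,
      spec = spec
    ),
    class = "faers_cohort"
  )
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort>", length(x$member_primaryids), "member reports;",
      sum(x$pair_table$is_member), "member (report, PT) pairs;",
      nrow(x$pair_table), "background pairs\n")
  invisible(x)
}

#' Pediatric age groups
#'
#' Bins an age in years into the standard pediatric reporting groups
#' 0-1, 2-5, 6-12 and 13-18 years (bins `[0,2)`, `[2,6)`, `[6,13)`,
#' `[13,18]`).
#'
#' @param years Numeric vector, each in `[0, 18]`; `NA` propagates.
#' @return Factor with levels `"0-1"`, `"2-5"`, `"6-12"`, `"13-18"`.
#' @export
assign_age_group <- function(years) {
  ok <- is.na(years) | (years >= 0 & years <= 18)
  if (!all(ok)) {
    stop("Age out of range [0, 18]: ", paste(years[!ok], collapse = ", "),
         call. = FALSE)
  }
  cut(years, breaks = c(0, 2, 6, 13, 18.000001), right = FALSE,
      labels = c("0-1", "2-5", "6-12", "13-18"))
}

#' Descriptive summary of a cohort
#'
#' Tallies the member reports by sex, age group, reporter occupation,
#' country and receipt year, with shares of the cohort, plus the mean and
#' SD of age over non-missing values — the demographics table customarily
#' reported next to a disproportionality screen.
#'
#' @param cohort A `faers_cohort`.
#' @return A list with `n` (cohort size), `age_mean`, `age_sd`, and a
#'   tibble `tallies` with columns `characteristic`, `level`, `n`, `share`.
#' @export
descriptive_summary <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  m <- cohort$member_reports
  n <- nrow(m)
  n_total <- max(n, 1L)
  tally_one <- function(values, characteristic) {
    values <- ifelse(is.na(values) | values == "", "unknown", as.character(values))
    tibble::tibble(characteristic = characteristic, level = values) |>
      dplyr::count(.data$characteristic, .data$level, name = "n") |>
      dplyr::mutate(share = .data$n / n_total) |>
      dplyr::arrange(.data$characteristic, dplyr::desc(.data$n), .data$level)
  }
  age_grp <- if (n) assign_age_group(pmin(pmax(m$age_years, 0), 18)) else factor()
  tallies <- dplyr::bind_rows(
    tally_one(if (n) m$sex else character(), "sex"),
    tally_one(age_grp, "age_group"),
    tally_one(if (n) m$reporter else character(), "reporter"),
    tally_one(if (n) m$country else character(), "country"),
    tally_one(if (n) as.character(m$event_year) else character(), "year")
  )
  list(
    n = n,
    age_mean = if (n && any(!is.na(m$age_years))) mean(m$age_years, na.rm = TRUE) else NA_real_,
    age_sd = if (n && sum(!is.na(m$age_years)) > 1) stats::sd(m$age_years, na.rm = TRUE) else NA_real_,
    tallies = tallies
  )
}

#' Ranked concomitant medications within a cohort
#'
#' Counts non-target drug mentions that are not primary suspects within the
#' member reports, in mention units (a report naming a drug twice counts
#' twice), with shares of all concomitant mentions. Ties rank
#' alphabetically.
#'
#' @param cohort A `faers_cohort`.
#' @param top_n Keep the first `top_n` rows (default all).
#' @return Tibble with columns `drug`, `n`, `share`.
#' @export
concomitant_summary <- function(cohort, top_n = Inf) {
  stopifnot(inherits(cohort, "faers_cohort"))
  d <- cohort$snapshot_drugs
  keep <- d$primaryid %in% cohort$member_primaryids &
    !cohort$target_mention &
    (is.na(d$role_code) | d$role_code != "PS")
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) {
    return(tibble::tibble(drug = character(), n = integer(), share = double()))
  }
  out <- tibble::tibble(drug = .normalize_name(d$drugname)) |>
    dplyr::count(.data$drug, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$drug)
  utils::head(out, top_n)
}
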