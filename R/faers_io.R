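# Reading and assembling FAERS-dialect quarterly ASCII extracts.

# Canonical output columns per table kind; everything else in the source file
# is carried along untouched so schema drift across quarters is not fatal.
.faers_kinds <- list(
  demo = c("primaryid", "caseid", "fda_dt", "age_value", "age_code", "sex",
           "reporter", "country", "event_year"),
  drug = c("primaryid", "drug_seq", "role_code", "drugname", "prod_ai"),
  reac = c("primaryid", "pt")
)

# Header aliases seen across FAERS quarters, lowercased.
.faers_aliases <- list(
  age_value = c("age"),
  age_code  = c("age_cod"),
  role_code = c("role_cod"),
  reporter  = c("occp_cod"),
  country   = c("occr_country", "reporter_country")
)

.valid_age_codes <- c("DEC", "YR", "MON", "WK", "DY", "HR")

#' Read one FAERS quarterly ASCII table
#'
#' Parses a `$`-delimited FAERS extract (DEMO, DRUG or REAC) into a tibble
#' with canonical column names. FAERS files have a header line, no quoting,
#' and free text that is best treated as Latin-1; all fields are read as
#' character and only the fields the pipeline needs are typed. Unknown
#' columns are preserved as-is, so OUTC/INDI/THER-style extras pass through.
#'
#' Rows with an unparseable receipt date or age keep the row but get a
#' missing value in that field, with a warning; a header that lacks the
#' columns the table kind requires is a hard error naming the file.
#'
#' @param path Path to the ASCII file.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`.
#' @return A tibble with the canonical columns for `kind` first
#'   (see Details), one row per data line.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$fda_dt$age$age_cod$sex$occp_cod$occr_country",
#'              "1001$100$20200115$8$YR$F$MD$US"), f)
#' faers_read_table(f, "demo")
#' @export
faers_read_table <- function(path, kind = c("demo", "drug", "reac")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("FAERS table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(
    path, delim = "$", quote = "", col_types = readr::cols(.default = "c"),
    locale = readr::locale(encoding = "latin1"), na = c("", "NA"),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  # resolve aliases onto canonical names
  for (canon in names(.faers_aliases)) {
    if (!canon %in% names(raw)) {
      hit <- intersect(.faers_aliases[[canon]], names(raw))
      if (length(hit)) names(raw)[match(hit[1], names(raw))] <- canon
    }
  }
  required <- switch(kind,
    demo = c("primaryid", "caseid"),
    drug = c("primaryid", "drugname"),
    reac = c("primaryid", "pt")
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("Malformed ", toupper(kind), " header in ", path,
         ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- switch(kind,
    demo = .type_demo(raw, path),
    drug = .type_drug(raw),
    reac = .type_reac(raw)
  )
  canon <- intersect(.faers_kinds[[kind]], names(out))
  dplyr::relocate(out, dplyr::all_of(canon))
}

.type_demo <- function(raw, path) {
  out <- raw
  if (!"fda_dt" %in% names(out)) out$fda_dt <- NA_character_
  bad_dt <- !is.na(out$fda_dt) & !grepl("^[0-9]{8}$", out$fda_dt)
  if (any(bad_dt)) {
    warning(sum(bad_dt), " DEMO row(s) with unparseable fda_dt in ",
            basename(path), "; kept with missing date", call. = FALSE)
    out$fda_dt[bad_dt] <- NA_character_
  }
  age_chr <- if ("age_value" %in% names(out)) out$age_value else NA_character_
  age_num <- suppressWarnings(as.numeric(age_chr))
  bad_age <- !is.na(age_chr) & is.na(age_num)
  if (any(bad_age)) {
    warning(sum(bad_age), " DEMO row(s) with non-numeric age in ",
            basename(path), "; kept with missing age", call. = FALSE)
  }
  out$age_value <- age_num
  out$age_code <- if ("age_code" %in% names(out)) toupper(out$age_code) else NA_character_
  out$age_code[!out$age_code %in% .valid_age_codes] <- NA_character_
  out$sex <- if ("sex" %in% names(out)) toupper(out$sex) else NA_character_
  out$sex[!out$sex %in% c("F", "M")] <- NA_character_
  if (!"reporter" %in% names(out)) out$reporter <- NA_character_
  if (!"country" %in% names(out)) out$country <- NA_character_
  out$event_year <- suppressWarnings(as.integer(substr(out$fda_dt, 1, 4)))
  out
}

.type_drug <- function(raw) {
  out <- raw
  if (!"drug_seq" %in% names(out)) out$drug_seq <- as.character(seq_len(nrow(out)))
  if (!"role_code" %in% names(out)) out$role_code <- NA_character_
  out$role_code <- toupper(out$role_code)
  out$role_code[!out$role_code %in% c("PS", "SS", "C", "I")] <- NA_character_
  if (!"prod_ai" %in% names(out)) out$prod_ai <- NA_character_
  out
}

.type_reac <- function(raw) {
  out <- raw[!is.na(raw$pt) & nzchar(raw$pt), , drop = FALSE]
  dropped <- nrow(raw) - nrow(out)
  if (dropped > 0) {
    warning(dropped, " REAC row(s) with empty preferred term dropped",
            call. = FALSE)
  }
  out
}

#' Write a table in the FAERS ASCII dialect
#'
#' Inverse of [faers_read_table()] for generator output and round-trip
#' checks: `$`-delimited, header line, no quoting, missing values as empty
#' fields.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
faers_write_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (is.double(v)) v <- ifelse(is.na(v), NA_character_, format(v, trim = TRUE, scientific = FALSE))
    x[[j]] <- as.character(v)
  }
  lines <- c(
    paste(names(x), collapse = "$"),
    if (nrow(x)) do.call(paste, c(lapply(x, function(v) ifelse(is.na(v), "", v)),
                                  sep = "$"))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read FAERS deleted-case lists
#'
#' Each list file holds one case identifier per line (a header line named
#' `caseid` is tolerated). The union across files is returned; with no files
#' the deleted set is empty.
#'
#' @param paths Character vector of file paths (may be empty).
#' @return Character vector of unique case identifiers.
#' @export
faers_read_deleted <- function(paths = character()) {
  if (!length(paths)) return(character())
  ids <- unlist(lapply(paths, function(p) {
    if (!file.exists(p)) stop("Deleted-case list not found: ", p, call. = FALSE)
    x <- readLines(p, warn = FALSE, encoding = "latin1")
    x <- trimws(x)
    x[nzchar(x) & tolower(x) != "caseid"]
  }))
  unique(ids)
}

#' Assemble a raw FAERS snapshot from one or more quarters
#'
#' Concatenates per-quarter DEMO/DRUG/REAC tables into a single snapshot,
#' records provenance, and counts referential violations (drug or event rows
#' whose `primaryid` has no DEMO row). Violations are logged as a warning,
#' not an error — real FAERS quarters contain orphans.
#'
#' @param demo,drug,reac A tibble or a list of per-quarter tibbles as
#'   returned by [faers_read_table()].
#' @param deleted_caseids Character vector of deleted case identifiers.
#' @param provenance Character vector naming the source quarters/files.
#' @return A `faers_snapshot` object: a list with elements `reports`,
#'   `drugs`, `events`, `deleted_caseids`, `provenance`, `log`.
#' @export
faers_assemble <- function(demo, drug, reac, deleted_caseids = character(),
                           provenance = NULL) {
  as_quarters <- function(x) if (is.data.frame(x)) list(x) else x
  demo <- as_quarters(demo); drug <- as_quarters(drug); reac <- as_quarters(reac)
  if (!length(demo)) stop("No quarters supplied", call. = FALSE)
  if (is.null(provenance)) provenance <- paste0("quarter_", seq_along(demo))
  reports <- dplyr::bind_rows(demo)
  drugs   <- dplyr::bind_rows(drug)
  events  <- dplyr::bind_rows(reac)
  if (anyDuplicated(reports$primaryid)) {
    warning("Duplicated primaryid within assembled snapshot; keeping all rows",
            call. = FALSE)
  }
  orphan_drugs  <- sum(!drugs$primaryid %in% reports$primaryid)
  orphan_events <- sum(!events$primaryid %in% reports$primaryid)
  if (orphan_drugs + orphan_events > 0) {
    warning(orphan_drugs, " drug and ", orphan_events,
            " event row(s) reference a primaryid absent from DEMO",
            call. = FALSE)
  }
  structure(
    list(
      reports = tibble::as_tibble(reports),
      drugs = tibble::as_tibble(drugs),
      events = tibble::as_tibble(events),
      deleted_caseids = unique(as.character(deleted_caseids)),
      provenance = provenance,
      log = tibble::tibble(
        stage = "assemble",
        rows_in = nrow(reports),
        rows_out = nrow(reports),
        note = paste0("quarters=", length(demo),
                      "; orphan_drug_rows=", orphan_drugs,
                      "; orphan_event_rows=", orphan_events)
      )
    ),
    class = "faers_snapshot"
  )
}

#' @export
print.faers_snapshot <- function(x, ...) {
  cat("<faers_snapshot>\n")
  cat("  reports:", nrow(x$reports), " drugs:", nrow(x$drugs),
      " events:", nrow(x$events), "\n")
  cat("  deleted caseids:", length(x$deleted_caseids),
      " quarters:", length(x$provenance), "\n")
  if (nrow(x$log)) {
    cat("  stages:", paste(x$log$stage, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Append one row to a snapshot's stage log.
.log_stage <- function(snapshot, stage, rows_in, rows_out, note = "") {
  snapshot$log <- dplyr::bind_rows(
    snapshot$log,
    tibble::tibble(stage = stage, rows_in = rows_in, rows_out = rows_out,
                   note = note)
  )
  snapshot
}

# Numeric interpretation of primaryid for "higher primaryid" tie-breaks;
# non-numeric identifiers sort below all numeric ones, lexicographically.
.pid_rank <- function(primaryid) {
  num <- suppressWarnings(as.numeric(primaryid))
  num[is.na(num)] <- -Inf
  ord <- order(num, primaryid)
  r <- integer(length(primaryid))
  r[ord] <- seq_along(primaryid)
  r
}
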