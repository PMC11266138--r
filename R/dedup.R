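# Two-step deduplication of a raw snapshot: FDA deleted-case lists first,
# then one surviving version per case.

#' Remove deleted cases from a snapshot
#'
#' Drops every report whose `caseid` appears in the snapshot's deleted-case
#' set, together with its drug and event rows. Deletion is applied before
#' version selection so that a deleted case cannot resurrect an older
#' version of itself.
#'
#' @param snapshot A `faers_snapshot` from [faers_assemble()].
#' @return The snapshot with deleted cases removed and the stage logged.
#' @export
apply_deletions <- function(snapshot) {
  stopifnot(inherits(snapshot, "faers_snapshot"))
  n_in <- nrow(snapshot$reports)
  keep <- !snapshot$reports$caseid %in% snapshot$deleted_caseids
  snapshot$reports <- snapshot$reports[keep, , drop = FALSE]
  kept_pids <- snapshot$reports$primaryid
  snapshot$drugs <- snapshot$drugs[snapshot$drugs$primaryid %in% kept_pids, , drop = FALSE]
  snapshot$events <- snapshot$events[snapshot$events$primaryid %in% kept_pids, , drop = FALSE]
  .log_stage(snapshot, "apply_deletions", n_in, nrow(snapshot$reports),
             paste0("deleted_cases_removed=", sum(!keep)))
}

#' Keep one report version per case
#'
#' Implements the FDA-recommended duplicate rule for spontaneous reports:
#' when several versions share a `caseid`, keep the version with the most
#' recent FDA receipt date (`fda_dt`); when receipt dates tie, keep the
#' higher `primaryid` (numeric interpretation, lexicographic fallback).
#' Versions with a missing `fda_dt` lose to any dated version; if every
#' version of a case lacks a date the largest `primaryid` survives and a
#' warning is emitted. Drug and event rows are restricted to survivors.
#'
#' The operation is idempotent and insensitive to input row order.
#'
#' @param snapshot A `faers_snapshot`, normally after [apply_deletions()].
#' @return The snapshot reduced to one `primaryid` per `caseid`.
#' @export
dedup_reports <- function(snapshot) {
  stopifnot(inherits(snapshot, "faers_snapshot"))
  rep <- snapshot$reports
  n_in <- nrow(rep)
  if (n_in == 0) {
    return(.log_stage(snapshot, "dedup_reports", 0L, 0L, "empty"))
  }
  undated_cases <- unique(rep$caseid[is.na(rep$fda_dt)])
  dated_cases <- unique(rep$caseid[!is.na(rep$fda_dt)])
  all_undated <- setdiff(undated_cases, dated_cases)
  if (length(all_undated)) {
    warning(length(all_undated),
            " case(s) with no dated version; keeping largest primaryid",
            call. = FALSE)
  }
  # sort each case by (receipt date, primaryid rank) ascending and keep the
  # last row; missing dates sort below any real date
  dt_key <- ifelse(is.na(rep$fda_dt), "00000000", rep$fda_dt)
  ord <- order(rep$caseid, dt_key, .pid_rank(rep$primaryid))
  sorted <- rep[ord, , drop = FALSE]
  survivors <- sorted[!duplicated(sorted$caseid, fromLast = TRUE), , drop = FALSE]
  snapshot$reports <- survivors
  kept <- survivors$primaryid
  snapshot$drugs <- snapshot$drugs[snapshot$drugs$primaryid %in% kept, , drop = FALSE]
  snapshot$events <- snapshot$events[snapshot$events$primaryid %in% kept, , drop = FALSE]
  .log_stage(snapshot, "dedup_reports", n_in, nrow(survivors),
             paste0("versions_dropped=", n_in - nrow(survivors)))
}

#' Run the full two-step deduplication
#'
#' Convenience wrapper: [apply_deletions()] then [dedup_reports()].
#'
#' @inheritParams apply_deletions
#' @return The deduplicated snapshot.
#' @export
deduplicate_snapshot <- function(snapshot) {
  dedup_reports(apply_deletions(snapshot))
}

#' Dedup audit log
#'
#' @param snapshot A `faers_snapshot`.
#' @return The per-stage record-count log as a tibble.
#' @export
snapshot_log <- function(snapshot) {
  stopifnot(inherits(snapshot, "faers_snapshot"))
  snapshot$log
}
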