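# Gender-stratified re-screening: the full screen repeated within the
# female and male strata, plus the list of discordant signals.

#' Split a cohort into female and male strata
#'
#' Members with missing sex are excluded from both strata. By default each
#' stratum's background is the same-sex slice of the cohort's background
#' (contrasts are made within gender); `pooled_background = TRUE` keeps the
#' full background for both strata instead.
#'
#' @param cohort A `faers_cohort` from [select_cohort()].
#' @param pooled_background Use the unstratified background (default
#'   `FALSE`).
#' @return Named list of two `faers_cohort` objects, `"F"` and `"M"`.
#' @export
stratify_cohort <- function(cohort, pooled_background = FALSE) {
  stopifnot(inherits(cohort, "faers_cohort"))
  one <- function(sx) {
    sub <- cohort
    member_sex <- cohort$member_reports$sex
    sub$member_primaryids <-
      cohort$member_reports$primaryid[!is.na(member_sex) & member_sex == sx]
    sub$member_reports <-
      cohort$member_reports[!is.na(member_sex) & member_sex == sx, , drop = FALSE]
    pt <- cohort$pair_table
    if (!pooled_background) {
      pt <- pt[!is.na(pt$sex) & pt$sex == sx, , drop = FALSE]
    }
    pt$is_member <- pt$primaryid %in% sub$member_primaryids
    sub$pair_table <- pt
    sub$stratum <- sx
    sub
  }
  list("F" = one("F"), "M" = one("M"))
}

#' Gender-subgroup signal screen
#'
#' Runs [screen_signals()] within each gender stratum and reports the
#' discordance list: preferred terms flagged as a combined signal in
#' exactly one stratum.
#'
#' @param cohort A `faers_cohort`.
#' @param criteria A [signal_criteria()].
#' @param soc_map Optional [pt_soc_map()].
#' @param pooled_background Passed to [stratify_cohort()].
#' @param ... Further arguments passed to [screen_signals()].
#' @return List with `signals` (one tibble, `stratum` column first) and
#'   `discordance` (tibble of PT, the stratum it signals in).
#' @export
subgroup_signals <- function(cohort, criteria = signal_criteria(),
                             soc_map = NULL, pooled_background = FALSE, ...) {
  strata <- stratify_cohort(cohort, pooled_background = pooled_background)
  tabs <- lapply(names(strata), function(sx) {
    tab <- screen_signals(strata[[sx]]$pair_table, criteria = criteria,
                          soc_map = soc_map, ...)
    dplyr::mutate(tab, stratum = sx, .before = 1)
  })
  signals <- dplyr::bind_rows(tabs)
  flagged <- signals[signals$signal, c("stratum", "pt")]
  counts <- table(flagged$pt)
  discordant_pts <- names(counts)[counts == 1]
  discordance <- flagged[flagged$pt %in% discordant_pts, c("pt", "stratum")]
  discordance <- dplyr::arrange(tibble::as_tibble(discordance), .data$pt)
  list(signals = signals, discordance = discordance)
}
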