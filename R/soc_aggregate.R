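# Preferred-term to system-organ-class mapping and SOC-level aggregation.
# MedDRA is licensed content, so the map is always supplied by the user
# (or by the synthetic generator for its own vocabulary).

#' Construct and validate a PT-to-SOC map
#'
#' @param x Data frame with columns `pt` and `soc` (extra columns are
#'   dropped). Each PT must map to exactly one primary SOC; duplicate
#'   identical rows are collapsed, conflicting ones are an error.
#' @return A `pt_soc_map` tibble with columns `pt`, `soc`.
#' @export
pt_soc_map <- function(x) {
  stopifnot(is.data.frame(x), all(c("pt", "soc") %in% names(x)))
  map <- dplyr::distinct(tibble::as_tibble(x)[, c("pt", "soc")])
  dup <- unique(map$pt[duplicated(map$pt)])
  if (length(dup)) {
    stop("PT(s) mapped to more than one primary SOC: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  structure(map, class = c("pt_soc_map", class(map)))
}

#' Load a PT-to-SOC map from a delimited file
#'
#' Reads a two-column (`pt`, `soc`) tab- or `$`-delimited file with header.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return A [pt_soc_map()].
#' @export
load_pt_soc_map <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, quote = "",
                         col_types = readr::cols(.default = "c"),
                         locale = readr::locale(encoding = "latin1"),
                         progress = FALSE, show_col_types = FALSE)
  names(x) <- tolower(names(x))
  if (!all(c("pt", "soc") %in% names(x))) {
    stop("PT->SOC map must have columns 'pt' and 'soc': ", path,
         call. = FALSE)
  }
  pt_soc_map(x)
}

#' Annotate a table of PTs with their SOC
#'
#' PTs absent from the map receive the SOC `"UNMAPPED"`.
#'
#' @param x Data frame with a `pt` column.
#' @param map A [pt_soc_map()].
#' @return `x` with a `soc` column added (after `pt`).
#' @export
annotate_soc <- function(x, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  x$soc <- map$soc[match(x$pt, map$pt)]
  x$soc[is.na(x$soc)] <- "UNMAPPED"
  dplyr::relocate(x, "soc", .after = "pt")
}

#' SOC-level summary of a screen
#'
#' Aggregates member (report, PT) pair counts by system organ class —
#' shares are of all member pairs, so they sum to 1 when every PT is
#' mapped — and counts combined signals per SOC when a screened signal
#' table is supplied.
#'
#' @param signal_table A [screen_signals()] result (uses `a` and `signal`),
#'   or any pair-count table with columns `pt` and `a`.
#' @param map A [pt_soc_map()].
#' @return Tibble with columns `soc`, `n_pairs`, `share`, `n_signals`,
#'   sorted by descending `n_pairs`.
#' @export
soc_summary <- function(signal_table, map) {
  x <- annotate_soc(signal_table[, setdiff(names(signal_table), "soc")], map)
  if (!"signal" %in% names(x)) x$signal <- FALSE
  out <- x |>
    dplyr::group_by(.data$soc) |>
    dplyr::summarise(
      n_pairs = sum(.data$a),
      n_signals = sum(.data$signal),
      .groups = "drop"
    ) |>
    dplyr::mutate(share = .data$n_pairs / sum(.data$n_pairs)) |>
    dplyr::select("soc", "n_pairs", "share", "n_signals") |>
    dplyr::arrange(dplyr::desc(.data$n_pairs), .data$soc)
  out
}
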