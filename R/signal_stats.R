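# Four-algorithm disproportionality statistics on 2x2 contingency tables
# of unique (report, preferred term) pairs, and the signal criteria.
#
# Cell layout for one (drug, event) pair:
#   a = pairs with target drug and target event
#   b = pairs with target drug and other events
#   c = pairs with other drugs and target event
#   d = pairs with neither
#   N = a + b + c + d  (all pairs in the background scope)
#
# ROR, chi-squared, IC and EBGM are invariant to swapping b and c; PRR is
# not, so the layout above is load-bearing for PRR only.

#' Build the 2x2 contingency table for one preferred term
#'
#' Counts unique (report, PT) pairs in the background: `a` member pairs with
#' the term, `b` member pairs with other terms, `c` non-member pairs with
#' the term, `d` the remainder. A term absent from the background yields a
#' valid table with `a = c = 0`.
#'
#' @param pair_table Tibble with columns `primaryid`, `pt`, `is_member`
#'   (unique rows), e.g. `select_cohort(...)$pair_table`.
#' @param pt Preferred term (exact string).
#' @return Named list with elements `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(pair_table, pt) {
  pair_table <- dplyr::distinct(pair_table, .data$primaryid, .data$pt,
                                .keep_all = TRUE)
  n <- nrow(pair_table)
  m <- sum(pair_table$is_member)
  is_pt <- pair_table$pt == pt
  a <- sum(is_pt & pair_table$is_member)
  c <- sum(is_pt) - a
  list(a = a, b = m - a, c = c, d = n - m - c, n = n)
}

#' Reporting odds ratio with 95\% confidence interval
#'
#' `ROR = ad/(bc)`; the interval is log-normal,
#' `exp(ln ROR +/- 1.96 sigma)` with `sigma = sqrt(1/a + 1/b + 1/c + 1/d)`.
#' Any zero cell leaves the statistic undefined (`NA`); no continuity
#' correction is applied by default.
#'
#' @param a,b,c,d Contingency cells (vectorized).
#' @param zero_correction `"none"` (default) or `"haldane"` to add 0.5 to
#'   every cell of tables containing a zero.
#' @return Tibble with columns `ror`, `ror_l95`, `ror_u95`.
#' @export
ror_stats <- function(a, b, c, d, zero_correction = c("none", "haldane")) {
  zc <- match.arg(zero_correction)
  cells <- .prep_cells(a, b, c, d, zc)
  with(cells, {
    ok <- defined & a > 0 & b > 0 & c > 0 & d > 0
    ror <- ifelse(ok, a * d / (b * c), NA_real_)
    sigma <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
    tibble::tibble(
      ror = ror,
      ror_l95 = ror * exp(-1.96 * sigma),
      ror_u95 = ror * exp(1.96 * sigma)
    )
  })
}

#' Proportional reporting ratio and chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` and the Pearson statistic without
#' continuity correction,
#' `chi2 = N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`.
#' Zero denominators leave both undefined.
#'
#' @inheritParams ror_stats
#' @return Tibble with columns `prr`, `chi2`.
#' @export
prr_stats <- function(a, b, c, d, zero_correction = c("none", "haldane")) {
  zc <- match.arg(zero_correction)
  cells <- .prep_cells(a, b, c, d, zc)
  with(cells, {
    n <- a + b + c + d
    ok_prr <- defined & (a + b) > 0 & (c + d) > 0 & c > 0
    prr <- ifelse(ok_prr, (a / (a + b)) / (c / (c + d)), NA_real_)
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    ok_chi <- defined & den > 0
    chi2 <- ifelse(ok_chi, n * (a * d - b * c)^2 / den, NA_real_)
    tibble::tibble(prr = prr, chi2 = chi2)
  })
}

#' BCPNN information component
#'
#' Default mode is the observed-over-expected log2 ratio on the raw cells,
#' `IC = log2[a N / ((a+b)(a+c))]`, which is also `log2(EBGM)` under this
#' package's (non-shrunk) EBGM. `shrinkage = TRUE` instead applies the
#' classic BCPNN closed form with Beta(1,1)/Dirichlet priors, which pulls
#' small-count estimates toward 0. The lower credibility bound is
#' `IC025 = IC - 2 sqrt(V(IC))` with the standard BCPNN variance.
#'
#' @inheritParams ror_stats
#' @param shrinkage Apply the Bayesian prior-shrinkage closed form
#'   (default `FALSE`, matching the raw observed/expected mode).
#' @return Tibble with columns `ic`, `ic025`.
#' @export
ic_stats <- function(a, b, c, d, shrinkage = FALSE,
                     zero_correction = c("none", "haldane")) {
  zc <- match.arg(zero_correction)
  cells <- .prep_cells(a, b, c, d, zc)
  with(cells, {
    n <- a + b + c + d
    ok <- defined & a > 0 & (a + b) > 0 & (a + c) > 0 & n > 0
    # Beta/Dirichlet prior constants of the two-layer BCPNN model
    gamma11 <- 1; alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2
    gamma <- gamma11 * (n + alpha) * (n + beta) /
      ((a + b + alpha1) * (a + c + beta1))
    if (isTRUE(shrinkage)) {
      e_ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                     ((n + gamma) * (a + b + alpha1) * (a + c + beta1)))
    } else {
      e_ic <- log2(a * n / ((a + b) * (a + c)))
    }
    v_ic <- (1 / log(2)^2) * (
      (n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
        (n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
        (n - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + n + beta))
    )
    tibble::tibble(
      ic = ifelse(ok, e_ic, NA_real_),
      ic025 = ifelse(ok, e_ic - 2 * sqrt(v_ic), NA_real_)
    )
  })
}

#' Empirical Bayes geometric mean (non-shrunk form) with lower bound
#'
#' The relative reporting ratio `EBGM = a N / ((a+b)(a+c))` and its lower
#' one-sided 95\% bound `EBGM05 = exp(ln EBGM - 1.96 sigma)`, where `sigma`
#' is the same log-scale standard error as in [ror_stats()] — the two
#' intervals share their variance term, so
#' `EBGM05/EBGM = ROR_l95/ROR` exactly. No gamma-Poisson hyperparameter
#' fitting is performed (see the methods vignette).
#'
#' @inheritParams ror_stats
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, b, c, d, zero_correction = c("none", "haldane")) {
  zc <- match.arg(zero_correction)
  cells <- .prep_cells(a, b, c, d, zc)
  with(cells, {
    n <- a + b + c + d
    ok <- defined & a > 0 & b > 0 & c > 0 & d > 0
    ebgm <- ifelse(defined & a > 0 & (a + b) > 0 & (a + c) > 0,
                   a * n / ((a + b) * (a + c)), NA_real_)
    sigma <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
    tibble::tibble(ebgm = ebgm, ebgm05 = ebgm * exp(-1.96 * sigma))
  })
}

.prep_cells <- function(a, b, c, d, zero_correction) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("Contingency cells must be non-negative", call. = FALSE)
  }
  defined <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d)
  if (zero_correction == "haldane") {
    has_zero <- defined & (a == 0 | b == 0 | c == 0 | d == 0)
    a <- a + 0.5 * has_zero; b <- b + 0.5 * has_zero
    c <- c + 0.5 * has_zero; d <- d + 0.5 * has_zero
  }
  list(a = a, b = b, c = c, d = d, defined = defined)
}

#' Signal criteria for the four algorithms
#'
#' Default thresholds: ROR lower 95\% bound > 1; PRR >= 2 with
#' chi-squared >= 4; IC025 > 0; EBGM05 >= 2; each additionally requires at
#' least `min_a` co-occurring reports (default 3). A pair is a combined
#' signal only when all four rules fire simultaneously. Undefined
#' statistics never flag.
#'
#' @param ror_l95_gt,prr_ge,chi2_ge,ic025_gt,ebgm05_ge Thresholds.
#' @param min_a Minimum co-occurrence count `a`.
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(ror_l95_gt = 1, prr_ge = 2, chi2_ge = 4,
                            ic025_gt = 0, ebgm05_ge = 2, min_a = 3) {
  structure(
    list(ror_l95_gt = ror_l95_gt, prr_ge = prr_ge, chi2_ge = chi2_ge,
         ic025_gt = ic025_gt, ebgm05_ge = ebgm05_ge, min_a = min_a),
    class = "signal_criteria"
  )
}

#' Apply signal criteria to computed statistics
#'
#' @param stats Data frame with columns `a`, `ror_l95`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (as produced by [screen_signals()] before flagging).
#' @param criteria A [signal_criteria()].
#' @return `stats` with logical columns `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm`, `signal` appended.
#' @export
evaluate_criteria <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  enough <- stats$a >= criteria$min_a
  flag <- function(x) !is.na(x) & enough & x
  stats$flag_ror <- flag(stats$ror_l95 > criteria$ror_l95_gt)
  stats$flag_prr <- flag(stats$prr >= criteria$prr_ge & stats$chi2 >= criteria$chi2_ge)
  stats$flag_ic <- flag(stats$ic025 > criteria$ic025_gt)
  stats$flag_ebgm <- flag(stats$ebgm05 >= criteria$ebgm05_ge)
  stats$signal <- stats$flag_ror & stats$flag_prr & stats$flag_ic & stats$flag_ebgm
  stats
}

#' Screen every preferred term against the background
#'
#' Builds the 2x2 table for every PT with at least `min_a_report` member
#' co-occurrences, computes all four statistics with their interval bounds,
#' and applies the signal criteria. Rows are ordered by descending `a`,
#' ties alphabetically by PT.
#'
#' @param pair_table Tibble of unique (report, PT) pairs with `is_member`.
#' @param criteria A [signal_criteria()].
#' @param soc_map Optional [pt_soc_map()] to annotate each PT's system
#'   organ class.
#' @param min_a_report Minimum `a` for a PT to appear in the output
#'   (default 1; the criteria's `min_a` still governs flagging).
#' @param ic_shrinkage Passed to [ic_stats()].
#' @param zero_correction Passed to the four statistic functions.
#' @return Tibble with one row per PT: cells, statistics, flags, `signal`.
#' @export
screen_signals <- function(pair_table, criteria = signal_criteria(),
                           soc_map = NULL, min_a_report = 1,
                           ic_shrinkage = FALSE,
                           zero_correction = c("none", "haldane")) {
  zc <- match.arg(zero_correction)
  pair_table <- dplyr::distinct(pair_table, .data$primaryid, .data$pt,
                                .keep_all = TRUE)
  n_total <- nrow(pair_table)
  m_total <- sum(pair_table$is_member)
  counts <- pair_table |>
    dplyr::group_by(.data$pt) |>
    dplyr::summarise(
      a = sum(.data$is_member),
      pt_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$a >= min_a_report)
  out <- counts |>
    dplyr::mutate(
      b = m_total - .data$a,
      c = .data$pt_total - .data$a,
      d = n_total - m_total - .data$c
    ) |>
    dplyr::select("pt", "a", "b", "c", "d")
  out <- dplyr::bind_cols(
    out,
    ror_stats(out$a, out$b, out$c, out$d, zero_correction = zc),
    prr_stats(out$a, out$b, out$c, out$d, zero_correction = zc),
    ic_stats(out$a, out$b, out$c, out$d, shrinkage = ic_shrinkage,
             zero_correction = zc),
    ebgm_stats(out$a, out$b, out$c, out$d, zero_correction = zc)
  )
  out <- evaluate_criteria(out, criteria)
  if (!is.null(soc_map)) {
    out <- annotate_soc(out, soc_map)
  }
  dplyr::arrange(out, dplyr::desc(.data$a), .data$pt)
}
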