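# Inversion oracle: recover the unknown cells of a 2x2 contingency table
# from a published statistic set (a, ROR, ROR lower bound, EBGM).
#
# ROR, chi-squared, IC and EBGM are symmetric in b and c, so only
# s = b + c and p = b * c are identifiable; with d they satisfy
#   ROR    = a d / p
#   sigma^2 = (ln(ROR / ROR_l95) / 1.96)^2 = 1/a + 1/d + s/p
#   EBGM   = a N / ((a+b)(a+c)) = a (a + s + d) / (a^2 + a s + p)
# Eliminating p = a d / ROR and s = p (sigma^2 - 1/a - 1/d) leaves one
# equation in d, solved by bounded root-finding on log(d).

#' Recover contingency cells from printed statistics
#'
#' Solves for the unobserved cells of the 2x2 table behind a published
#' statistic quadruple. Because the statistics used are symmetric in `b`
#' and `c`, the solution is returned as `s = b + c`, `p = b * c` and `d`,
#' together with the two `(b, c)` assignments (roots of
#' `x^2 - s x + p = 0`). The solution is verified by recomputing the three
#' inputs; residuals above `check_tol` (relative) are an error naming the
#' inconsistent input.
#'
#' @param a Co-occurrence count (reports with drug and event).
#' @param ror,ror_l95 Reporting odds ratio and its lower 95\% bound.
#' @param ebgm Empirical Bayes geometric mean (non-shrunk form).
#' @param d_range Search interval for `d` (default `10^2` to `10^8`).
#' @param tol Root-finder tolerance on the equation residual.
#' @param check_tol Maximum relative error allowed when the inputs are
#'   recomputed from the solution (default 0.005).
#' @return A `recovered_cells` list: `a`, `s`, `p`, `d`, `n`, `b1`, `c1`
#'   (first assignment, `b1 <= c1`), `b2`, `c2`, `sigma`, `residuals`.
#' @examples
#' cells <- recover_cells(a = 10, ror = 4,
#'                        ror_l95 = 4 * exp(-1.96 * sqrt(1/10 + 1/20 + 1/30 + 1/240)),
#'                        ebgm = 2.5)
#' round(c(cells$s, cells$p, cells$d))  # 50 600 240
#' @export
recover_cells <- function(a, ror, ror_l95, ebgm,
                          d_range = c(1e2, 1e8), tol = 1e-10,
                          check_tol = 0.005) {
  stopifnot(a > 0, ror > 0, ror_l95 > 0, ebgm > 0, ror_l95 < ror)
  sigma <- log(ror / ror_l95) / 1.96
  sig2 <- sigma^2
  sp_of_d <- function(d) {
    p <- a * d / ror
    s <- p * (sig2 - 1 / a - 1 / d)
    list(p = p, s = s)
  }
  f <- function(log_d) {
    d <- exp(log_d)
    sp <- sp_of_d(d)
    if (!is.finite(sp$s) || sp$s <= 0) return(NA_real_)
    a * (a + sp$s + d) / (a^2 + a * sp$s + sp$p) - ebgm
  }
  grid <- seq(log(d_range[1]), log(d_range[2]), length.out = 600)
  vals <- vapply(grid, f, numeric(1))
  ok <- which(!is.na(vals))
  if (length(ok) < 2) {
    stop("Inconsistent inputs: sigma^2 from (ror, ror_l95) leaves no ",
         "feasible b + c in the search range", call. = FALSE)
  }
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    stop("No solution for d in [", d_range[1], ", ", d_range[2],
         "]: EBGM inconsistent with (a, ROR, ROR_l95)", call. = FALSE)
  }
  root <- stats::uniroot(f, c(grid[ok[flip[1]]], grid[ok[flip[1] + 1]]),
                         tol = tol)
  d <- exp(root$root)
  sp <- sp_of_d(d)
  s <- sp$s; p <- sp$p
  if (s^2 < 4 * p * (1 - 1e-9)) {
    stop("Recovered (s, p) admit no real (b, c) split: s^2 < 4p",
         call. = FALSE)
  }
  disc <- sqrt(max(s^2 - 4 * p, 0))
  b1 <- (s - disc) / 2; c1 <- (s + disc) / 2
  # verification by forward recomputation
  ror_hat <- a * d / p
  sig_hat <- sqrt(1 / a + 1 / d + s / p)
  l95_hat <- ror_hat * exp(-1.96 * sig_hat)
  n <- a + s + d
  ebgm_hat <- a * n / (a^2 + a * s + p)
  residuals <- c(ror = abs(ror_hat / ror - 1),
                 ror_l95 = abs(l95_hat / ror_l95 - 1),
                 ebgm = abs(ebgm_hat / ebgm - 1))
  if (any(residuals > check_tol)) {
    bad <- names(residuals)[which.max(residuals)]
    stop("Recovered cells fail to reproduce input '", bad,
         "' within ", check_tol * 100, "% (relative error ",
         signif(max(residuals), 3), ")", call. = FALSE)
  }
  structure(
    list(a = a, s = s, p = p, d = d, n = n,
         b1 = b1, c1 = c1, b2 = c1, c2 = b1,
         sigma = sigma, residuals = residuals),
    class = "recovered_cells"
  )
}

#' @export
print.recovered_cells <- function(x, ...) {
  cat("<recovered_cells> a =", x$a, " b+c =", signif(x$s, 6),
      " b*c =", signif(x$p, 6), " d =", signif(x$d, 6), "\n")
  cat("  (b, c) assignments: (", signif(x$b1, 6), ",", signif(x$c1, 6),
      ") or swapped; max residual", signif(max(x$residuals), 3), "\n")
  invisible(x)
}

#' Evaluate a disproportionality statistic on recovered cells
#'
#' Applies the screening formulas to a [recover_cells()] solution. The
#' symmetric statistics (`"ror"`, `"chi2"`, `"ic"`, `"ebgm"`, `"ebgm05"`)
#' are single-valued; `"prr"` depends on which root is `b`, so both
#' assignment values are returned.
#'
#' @param cells A `recovered_cells` object.
#' @param which One of `"ror"`, `"chi2"`, `"ic"`, `"ebgm"`, `"ebgm05"`,
#'   `"prr"`.
#' @return A single number, or for `"prr"` a named length-2 vector
#'   (`prr_b_small`, `prr_b_large`).
#' @export
predict_statistic <- function(cells,
                              which = c("ror", "chi2", "ic", "ebgm",
                                        "ebgm05", "prr")) {
  stopifnot(inherits(cells, "recovered_cells"))
  which <- match.arg(which)
  a <- cells$a; s <- cells$s; p <- cells$p; d <- cells$d; n <- cells$n
  switch(which,
    ror = a * d / p,
    # (a+b)(a+c) = a^2 + a s + p and (c+d)(b+d) = d^2 + d s + p are both
    # symmetric in b, c
    chi2 = n * (a * d - p)^2 / ((a^2 + a * s + p) * (d^2 + d * s + p)),
    ic = log2(a * n / (a^2 + a * s + p)),
    ebgm = a * n / (a^2 + a * s + p),
    ebgm05 = {
      sg <- sqrt(1 / a + 1 / d + s / p)
      (a * n / (a^2 + a * s + p)) * exp(-1.96 * sg)
    },
    prr = {
      v1 <- (a / (a + cells$b1)) / (cells$c1 / (cells$c1 + d))
      v2 <- (a / (a + cells$b2)) / (cells$c2 / (cells$c2 + d))
      c(prr_b_small = v1, prr_b_large = v2)
    }
  )
}

#' Lower EBGM bound via the shared variance term
#'
#' The ROR and EBGM intervals both use
#' `sigma = sqrt(1/a + 1/b + 1/c + 1/d)`, so the lower EBGM bound follows
#' from printed point estimates alone:
#' `EBGM05 = EBGM * (ROR_l95 / ROR) = exp(ln EBGM - 1.96 sigma)`.
#'
#' @param ebgm Printed EBGM point estimate.
#' @param ror,ror_l95 Printed ROR and its lower 95\% bound.
#' @return The implied EBGM05.
#' @export
shared_variance_ebgm05 <- function(ebgm, ror, ror_l95) {
  stopifnot(ebgm > 0, ror > 0, ror_l95 > 0)
  ebgm * ror_l95 / ror
}

#' Transcribed printed signal rows
#'
#' The package ships a small fixture of published signal-table rows
#' (drug, preferred term, co-occurrence count, the four statistics and
#' their bounds) used by the consistency checks. Values are as printed,
#' i.e. rounded to two decimals.
#'
#' @return Tibble of printed rows.
#' @export
printed_signal_rows <- function() {
  path <- system.file("extdata", "printed_signal_rows.tsv",
                      package = "faerscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
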