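# The four disproportionality estimators and the signal criteria.

test_that("uniform table gives all ratios 1, chi2 = 0, IC = 0", {
  expect_equal(ror_stats(5, 5, 5, 5)$ror, 1)
  p <- prr_stats(5, 5, 5, 5)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(ic_stats(5, 5, 5, 5)$ic, 0)
  expect_equal(ebgm_stats(5, 5, 5, 5)$ebgm, 1)
})

test_that("hand-computed table (10, 20, 30, 240) reproduces every formula", {
  a <- 10; b <- 20; c <- 30; d <- 240
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  r <- ror_stats(a, b, c, d)
  expect_equal(r$ror, 4)
  expect_equal(r$ror_l95, 4 * exp(-1.96 * se), tolerance = 1e-12)
  expect_equal(r$ror_l95, 1.7118, tolerance = 1e-4)
  expect_equal(r$ror_u95, 9.3468, tolerance = 1e-4)
  p <- prr_stats(a, b, c, d)
  expect_equal(p$prr, 3)
  expect_equal(p$chi2, 300 * (10 * 240 - 20 * 30)^2 / (30 * 270 * 40 * 260))
  expect_equal(p$chi2, 11.538, tolerance = 1e-3)
  expect_equal(ic_stats(a, b, c, d)$ic, log2(2.5))
  e <- ebgm_stats(a, b, c, d)
  expect_equal(e$ebgm, 2.5)
  expect_equal(e$ebgm05, 2.5 * exp(-1.96 * se), tolerance = 1e-12)
  expect_equal(e$ebgm05, 1.0700, tolerance = 1e-4)
})

test_that("b-c swap leaves ror/chi2/ic/ebgm invariant but not prr", {
  set.seed(8)
  for (i in 1:20) {
    cl <- sample(1:400, 4)
    a <- cl[1]; b <- cl[2]; c <- cl[3]; d <- cl[4]
    expect_equal(ror_stats(a, b, c, d)$ror, ror_stats(a, c, b, d)$ror)
    expect_equal(prr_stats(a, b, c, d)$chi2, prr_stats(a, c, b, d)$chi2)
    expect_equal(ic_stats(a, b, c, d)$ic, ic_stats(a, c, b, d)$ic)
    expect_equal(ebgm_stats(a, b, c, d)$ebgm, ebgm_stats(a, c, b, d)$ebgm)
    if (b != c) {
      expect_false(isTRUE(all.equal(prr_stats(a, b, c, d)$prr,
                                    prr_stats(a, c, b, d)$prr)))
    }
  }
})

test_that("EBGM and ROR intervals share their variance term exactly", {
  set.seed(9)
  for (i in 1:20) {
    cl <- sample(1:1000, 4)
    r <- ror_stats(cl[1], cl[2], cl[3], cl[4])
    e <- ebgm_stats(cl[1], cl[2], cl[3], cl[4])
    expect_equal(e$ebgm05 / e$ebgm, r$ror_l95 / r$ror, tolerance = 1e-12)
    # default-mode IC is log2(EBGM) by construction
    expect_equal(ic_stats(cl[1], cl[2], cl[3], cl[4])$ic, log2(e$ebgm),
                 tolerance = 1e-12)
  }
})

test_that("all four point estimates increase strictly in a", {
  a <- c(5, 10, 20, 40); b <- 100; c <- 50; d <- 5000
  expect_true(all(diff(ror_stats(a, b, c, d)$ror) > 0))
  expect_true(all(diff(prr_stats(a, b, c, d)$prr) > 0))
  expect_true(all(diff(ic_stats(a, b, c, d)$ic) > 0))
  expect_true(all(diff(ebgm_stats(a, b, c, d)$ebgm) > 0))
})

test_that("zero cells leave statistics undefined unless corrected", {
  expect_true(is.na(ror_stats(3, 0, 10, 100)$ror))
  expect_true(is.na(ic_stats(0, 5, 5, 5)$ic))
  corrected <- ror_stats(3, 0, 10, 100, zero_correction = "haldane")
  expect_false(is.na(corrected$ror))
  expect_error(ror_stats(-1, 1, 1, 1), "non-negative")
})

test_that("criteria require a >= 3 and all four rules for a combined signal", {
  # enormous disproportion but a = 2: everything stays FALSE
  tab <- tibble::tibble(a = 2, b = 1, c = 1, d = 10000)
  st <- dplyr::bind_cols(tab, ror_stats(2, 1, 1, 10000),
                         prr_stats(2, 1, 1, 10000),
                         ic_stats(2, 1, 1, 10000),
                         ebgm_stats(2, 1, 1, 10000))
  fl <- evaluate_criteria(st)
  expect_false(any(fl$flag_ror, fl$flag_prr, fl$flag_ic, fl$flag_ebgm,
                   fl$signal))
  # uniform table at a >= 3: no rule fires
  st2 <- dplyr::bind_cols(tibble::tibble(a = 5), ror_stats(5, 5, 5, 5),
                          prr_stats(5, 5, 5, 5), ic_stats(5, 5, 5, 5),
                          ebgm_stats(5, 5, 5, 5))
  fl2 <- evaluate_criteria(st2)
  expect_false(any(fl2$flag_ror, fl2$flag_prr, fl2$flag_ic, fl2$flag_ebgm))
  # strong planted pair: combined signal is the conjunction
  st3 <- dplyr::bind_cols(tibble::tibble(a = 40),
                          ror_stats(40, 400, 800, 200000),
                          prr_stats(40, 400, 800, 200000),
                          ic_stats(40, 400, 800, 200000),
                          ebgm_stats(40, 400, 800, 200000))
  fl3 <- evaluate_criteria(st3)
  expect_true(fl3$signal)
  expect_true(all(fl3$flag_ror, fl3$flag_prr, fl3$flag_ic, fl3$flag_ebgm))
})

test_that("build_contingency counts unique pairs with fixed margins", {
  # single member report with one PT
  pt <- tibble::tibble(primaryid = "1", pt = "RASH", is_member = TRUE)
  tab <- build_contingency(pt, "RASH")
  expect_equal(unlist(tab), c(a = 1, b = 0, c = 0, d = 0, n = 1))
  # a PT absent from the background is a valid a = c = 0 table
  tab0 <- build_contingency(pt, "PYREXIA")
  expect_equal(tab0$a + tab0$c, 0)
  # duplicated (report, PT) rows collapse
  dup <- dplyr::bind_rows(pt, pt)
  expect_equal(build_contingency(dup, "RASH")$a, 1)
  # marginals a + b and a + c partition the pair table
  res <- synth_pair_table(seed = 61, n_cases = 400)
  ptab <- res$cohort$pair_table
  for (p in utils::head(sort(unique(ptab$pt)), 5)) {
    tb <- build_contingency(ptab, p)
    expect_equal(tb$a + tb$b, sum(ptab$is_member))
    expect_equal(tb$a + tb$b + tb$c + tb$d, nrow(ptab))
  }
})

test_that("screen_signals agrees with the naive per-report oracle", {
  for (seed in c(2, 12, 22)) {
    res <- synth_pair_table(seed = seed, n_cases = 250)
    fast <- screen_signals(res$cohort$pair_table)
    slow <- naive_screen(res$cohort$pair_table)
    slow <- slow[slow$a >= 1, ]
    merged <- merge(as.data.frame(fast), slow, by = "pt",
                    suffixes = c("", ".naive"))
    expect_equal(nrow(merged), nrow(fast))
    expect_equal(merged$a, merged$a.naive)
    expect_equal(merged$b, merged$b.naive)
    expect_equal(merged$c, merged$c.naive)
    expect_equal(merged$d, merged$d.naive)
    for (col in c("ror", "ror_l95", "prr", "chi2", "ic", "ebgm", "ebgm05")) {
      expect_rel_equal(merged[[col]], merged[[paste0(col, ".naive")]], 1e-12)
    }
  }
})

test_that("screen output is sorted by descending a and flags are populated", {
  res <- synth_pair_table(seed = 71, n_cases = 500)
  out <- screen_signals(res$cohort$pair_table)
  expect_true(all(diff(out$a) <= 0))
  expect_true(all(!is.na(out$signal)))
  expect_true(all(out$signal == (out$flag_ror & out$flag_prr &
                                   out$flag_ic & out$flag_ebgm)))
})
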