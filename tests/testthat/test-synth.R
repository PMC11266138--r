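# The synthetic-report generator: determinism, truth bookkeeping,
# marginal recovery, planted-signal calibration.

test_that("n_cases = 0 gives empty tables; same seed gives identical output", {
  gen0 <- synth_generate(synth_config(n_cases = 0, seed = 1))
  expect_equal(nrow(gen0$demo), 0)
  expect_equal(nrow(gen0$drug), 0)
  expect_equal(nrow(gen0$reac), 0)
  dir <- withr::local_tempdir()
  synth_write(gen0, dir)
  expect_equal(length(readLines(file.path(dir, "DEMO.txt"))), 1)

  g1 <- synth_generate(synth_config(n_cases = 200, seed = 99))
  g2 <- synth_generate(synth_config(n_cases = 200, seed = 99))
  expect_identical(g1$demo, g2$demo)
  expect_identical(g1$drug, g2$drug)
  expect_identical(g1$reac, g2$reac)
  expect_identical(g1$deleted_caseids, g2$deleted_caseids)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_write(g1, d1); synth_write(g2, d2)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "DELETED.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  g3 <- synth_generate(synth_config(n_cases = 200, seed = 100))
  expect_false(identical(g1$demo, g3$demo))
})

test_that("infeasible planted probabilities are rejected at config time", {
  expect_error(
    synth_config(n_cases = 10, seed = 1,
                 planted_signals = data.frame(drug = "OSELTAMIVIR",
                                              pt = "VOMITING",
                                              rate_ratio = 50)),
    "Infeasible"
  )
  expect_error(
    synth_config(n_cases = 10, seed = 1,
                 planted_signals = data.frame(drug = "OSELTAMIVIR",
                                              pt = "NOT A REAL PT",
                                              rate_ratio = 2))
  )
})

test_that("deletion and duplication rates land on the truth bookkeeping", {
  gen <- synth_generate(synth_config(n_cases = 1000, seed = 17,
                                     deletion_rate = 0.1,
                                     duplicate_rate = 0.2))
  truth <- gen$truth$cases
  expect_setequal(gen$deleted_caseids, truth$caseid[truth$deleted])
  expect_equal(length(gen$deleted_caseids), sum(truth$deleted))
  expect_equal(nrow(gen$demo), sum(truth$n_versions))
  # every extra version has a later receipt date and higher primaryid
  multi <- truth$caseid[truth$n_versions > 1]
  demo_multi <- gen$demo[gen$demo$caseid %in% multi, ]
  by_case <- split(demo_multi, demo_multi$caseid)
  for (d in by_case[1:min(20, length(by_case))]) {
    ord <- order(as.numeric(d$primaryid))
    expect_true(all(diff(as.Date(d$fda_dt[ord], "%Y%m%d")) > 0))
  }
})

test_that("demographic marginals are recovered within binomial 99% bounds", {
  n <- 10000
  gen <- synth_generate(synth_config(n_cases = n, seed = 23))
  truth <- gen$truth$cases
  dg <- synth_demographics()
  ci99 <- function(p) 2.576 * sqrt(p * (1 - p) / n)
  p_f <- mean(!is.na(truth$sex) & truth$sex == "F")
  expect_lt(abs(p_f - dg$sex_probs[["F"]]), ci99(dg$sex_probs[["F"]]))
  p_ped <- mean(!is.na(truth$age_years) & truth$age_years <= 18)
  expect_lt(abs(p_ped - dg$pediatric_fraction * (1 - dg$missing_age_rate)),
            ci99(dg$pediatric_fraction))
  p_us <- mean(truth$country == "US")
  expect_lt(abs(p_us - dg$country_probs[["US"]]),
            ci99(dg$country_probs[["US"]]))
})

test_that("planted empirical rate ratio converges to the configured one", {
  rr <- 6
  res <- synth_pair_table(
    seed = 33, n_cases = 40000,
    planted_signals = data.frame(drug = "OSELTAMIVIR", pt = "DELIRIUM",
                                 rate_ratio = rr)
  )
  pt <- res$cohort$pair_table
  members <- unique(pt$primaryid[pt$is_member])
  others <- setdiff(unique(pt$primaryid), members)
  has_pt <- tapply(pt$pt == "DELIRIUM", pt$primaryid, any)
  p1 <- mean(has_pt[members]); p0 <- mean(has_pt[others])
  a_obs <- sum(pt$is_member & pt$pt == "DELIRIUM")
  expect_gte(a_obs, 100)
  expect_lt(abs((p1 / p0) / rr - 1), 0.25)
})

test_that("ROR interval covers a rate ratio of 1 at nominal frequency", {
  hits <- 0; n_rep <- 30
  for (s in 1:n_rep) {
    res <- synth_pair_table(
      seed = 4000 + s, n_cases = 3000,
      planted_signals = data.frame(drug = "OSELTAMIVIR", pt = "VOMITING",
                                   rate_ratio = 1)
    )
    row <- screen_signals(res$cohort$pair_table)
    row <- row[row$pt == "VOMITING", ]
    if (nrow(row) == 1 && !is.na(row$ror_l95) &&
        row$ror_l95 <= 1 && row$ror_u95 >= 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("recovery report summarises sensitivity, false flags and bias", {
  res <- synth_pair_table(
    seed = 43, n_cases = 15000,
    planted_signals = data.frame(drug = "OSELTAMIVIR", pt = "DELIRIUM",
                                 rate_ratio = 10)
  )
  sig <- screen_signals(res$cohort$pair_table)
  rec <- estimate_recovery(res$gen$truth, sig)
  expect_equal(rec$sensitivity, 1)
  expect_true(is.finite(rec$log_ror_bias))
  expect_lt(rec$false_flag_rate, 0.2)

  # all-null config: sensitivity undefined, false-flag rate still reported
  null_res <- synth_pair_table(seed = 53, n_cases = 2000)
  null_sig <- screen_signals(null_res$cohort$pair_table)
  null_rec <- estimate_recovery(null_res$gen$truth, null_sig)
  expect_true(is.na(null_rec$sensitivity))
  expect_true(is.finite(null_rec$false_flag_rate))
})
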