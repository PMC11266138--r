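# Age parsing, drug-name matching, cohort selection and descriptives.

test_that("age unit conversion follows the FAERS code table", {
  expect_equal(parse_age_years(18, "YR"), 18)
  expect_equal(parse_age_years(6, "MON"), 0.5)
  expect_equal(parse_age_years(2, "DEC"), 20)
  expect_equal(parse_age_years(26, "WK"), 0.5)
  expect_equal(parse_age_years(73, "DY"), 0.2)
  expect_equal(parse_age_years(8760, "HR"), 1)
  expect_true(is.na(parse_age_years(NA, "YR")))
  expect_warning(res <- parse_age_years(5, "XX"), "Unknown age unit")
  expect_true(is.na(res))
})

test_that("target-drug matching is normalized substring matching", {
  drugs <- make_drug("1", "TAMIFLU 75MG")
  expect_true(match_target_drug(drugs, c("OSELTAMIVIR", "TAMIFLU")))
  bal <- make_drug("1", "BALOXAVIR MARBOXIL")
  expect_false(match_target_drug(bal, "XOFLUZA"))
  expect_true(match_target_drug(bal, c("XOFLUZA", "BALOXAVIR")))
  # matches through prod_ai and through punctuation noise
  mixed <- make_drug("1", "UNKNOWN BRAND", prod_ai = "oseltamivir-phosphate")
  expect_true(match_target_drug(mixed, "OSELTAMIVIR"))
})

test_that("decoy names sharing short prefixes never false-match long patterns", {
  voc <- synth_drug_vocabulary()
  decoys <- voc[voc$name %in% c("TAMSULOSIN", "OSERADINE", "BALSALAZIDE"), ]
  mentions <- make_drug(as.character(seq_len(nrow(decoys))), decoys$name,
                        prod_ai = decoys$prod_ai)
  hits <- match_target_drug(mentions,
                            c("OSELTAMIVIR", "TAMIFLU", "BALOXAVIR", "XOFLUZA"))
  expect_false(any(hits))
})

test_that("pediatric age groups bin correctly at the boundaries", {
  expect_equal(as.character(assign_age_group(c(1.9, 2, 12.99, 13, 18, 0))),
               c("0-1", "2-5", "6-12", "13-18", "13-18", "0-1"))
  expect_error(assign_age_group(19), "out of range")
})

test_that("cohort selection matches generator truth and handles empties", {
  res <- synth_pair_table(seed = 31, n_cases = 1200)
  truth <- res$gen$truth$cases
  expected <- truth$caseid[
    !truth$deleted &
      !is.na(truth$age_years) & truth$age_years <= 18 &
      grepl("OSELTAMIVIR", truth$ps_prod_ai)
  ]
  members <- res$snapshot$reports$caseid[
    res$snapshot$reports$primaryid %in% res$cohort$member_primaryids
  ]
  expect_setequal(members, expected)

  # no PS mention of the target -> empty cohort, with a warning not an error
  snap <- make_snapshot(make_demo("1"), make_drug("1", "IBUPROFEN"),
                        make_reac("1", "RASH"))
  expect_warning(coh <- select_cohort(snap, cohort_spec("OSELTAMIVIR")),
                 "empty")
  expect_length(coh$member_primaryids, 0)
  expect_equal(sum(coh$pair_table$is_member), 0)
})

test_that("ps_exclusive drops reports with a second distinct PS ingredient", {
  demo <- make_demo(c("1", "2"))
  drug <- dplyr::bind_rows(
    make_drug("1", "TAMIFLU", prod_ai = "OSELTAMIVIR PHOSPHATE"),
    make_drug("1", "IBUPROFEN"),
    make_drug("2", "TAMIFLU", prod_ai = "OSELTAMIVIR PHOSPHATE")
  )
  reac <- make_reac(c("1", "2"), "PYREXIA")
  snap <- make_snapshot(demo, drug, reac)
  excl <- select_cohort(snap, cohort_spec("OSELTAMIVIR", ps_exclusive = TRUE))
  expect_setequal(excl$member_primaryids, "2")
  incl <- select_cohort(snap, cohort_spec("OSELTAMIVIR", ps_exclusive = FALSE))
  expect_setequal(incl$member_primaryids, c("1", "2"))
})

test_that("pair table is unique and cohort is monotone in the age window", {
  res <- synth_pair_table(seed = 41, n_cases = 800)
  pt <- res$cohort$pair_table
  expect_equal(nrow(pt), nrow(dplyr::distinct(pt, primaryid, pt)))
  wide <- select_cohort(res$snapshot,
                        cohort_spec(c("OSELTAMIVIR", "TAMIFLU"),
                                    age_max_years = 25))
  expect_true(all(res$cohort$member_primaryids %in% wide$member_primaryids))
})

test_that("descriptive tallies equal the generator marginals exactly", {
  res <- synth_pair_table(seed = 51, n_cases = 1500)
  truth <- res$gen$truth$cases
  surv <- truth[!truth$deleted & !is.na(truth$age_years) &
                  truth$age_years <= 18 &
                  grepl("OSELTAMIVIR", truth$ps_prod_ai), ]
  d <- descriptive_summary(res$cohort)
  expect_equal(d$n, nrow(surv))
  sex_tab <- d$tallies[d$tallies$characteristic == "sex", ]
  expect_equal(sum(sex_tab$n), nrow(surv))
  expect_equal(sex_tab$n[match("F", sex_tab$level)],
               sum(surv$sex == "F", na.rm = TRUE))
  expect_equal(d$age_mean, mean(surv$age_years))
  expect_equal(d$age_sd, sd(surv$age_years))
  # age-group counts + missing = cohort size (no missing inside stratum)
  age_tab <- d$tallies[d$tallies$characteristic == "age_group", ]
  expect_equal(sum(age_tab$n), d$n)

  empty <- suppressWarnings(
    select_cohort(res$snapshot, cohort_spec("NOSUCHDRUGNAME"))
  )
  d0 <- descriptive_summary(empty)
  expect_equal(d0$n, 0)
  expect_true(is.na(d0$age_mean))
})

test_that("concomitant ranking counts non-PS, non-target mentions", {
  demo <- make_demo(c("1", "2"))
  drug <- dplyr::bind_rows(
    make_drug(c("1", "2"), "TAMIFLU", prod_ai = "OSELTAMIVIR PHOSPHATE"),
    make_drug("1", "ACETAMINOPHEN", role_code = "C"),
    make_drug("1", "IBUPROFEN", role_code = "C"),
    make_drug("2", "ACETAMINOPHEN", role_code = "C")
  )
  snap <- make_snapshot(demo, drug, make_reac(c("1", "2"), "PYREXIA"))
  coh <- select_cohort(snap, cohort_spec("OSELTAMIVIR"))
  conc <- concomitant_summary(coh)
  expect_equal(conc$drug, c("ACETAMINOPHEN", "IBUPROFEN"))
  expect_equal(conc$n, c(2L, 1L))
  expect_equal(conc$share, c(2 / 3, 1 / 3))

  none <- select_cohort(
    make_snapshot(make_demo("1"),
                  make_drug("1", "TAMIFLU", prod_ai = "OSELTAMIVIR"),
                  make_reac("1", "RASH")),
    cohort_spec("OSELTAMIVIR")
  )
  expect_equal(nrow(concomitant_summary(none)), 0)
})
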