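# Crafted-snapshot builders and an independent naive screening oracle.

# Build a faers_snapshot from minimal row specs; unspecified DEMO fields get
# benign defaults.
make_demo <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                      age_value = 10, age_code = "YR", sex = "F",
                      reporter = "MD", country = "US") {
  n <- length(primaryid)
  tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = rep_len(as.character(caseid), n),
    fda_dt = rep_len(fda_dt, n),
    age_value = rep_len(age_value, n),
    age_code = rep_len(age_code, n),
    sex = rep_len(sex, n),
    reporter = rep_len(reporter, n),
    country = rep_len(country, n),
    event_year = as.integer(substr(rep_len(fda_dt, n), 1, 4))
  )
}

make_drug <- function(primaryid, drugname, role_code = "PS",
                      prod_ai = drugname) {
  n <- length(primaryid)
  tibble::tibble(
    primaryid = as.character(primaryid),
    drug_seq = as.character(seq_len(n)),
    role_code = rep_len(role_code, n),
    drugname = rep_len(drugname, n),
    prod_ai = rep_len(prod_ai, n)
  )
}

make_reac <- function(primaryid, pt) {
  tibble::tibble(primaryid = as.character(primaryid), pt = pt)
}

make_snapshot <- function(demo, drug, reac, deleted = character()) {
  suppressWarnings(
    faers_assemble(demo, drug, reac, deleted_caseids = deleted,
                   provenance = "test")
  )
}

# Generate a small synthetic snapshot and return its pediatric
# oseltamivir-pattern pair table (the common test substrate).
synth_pair_table <- function(seed, n_cases = 300, ...) {
  cfg <- synth_config(n_cases = n_cases, seed = seed, ...)
  gen <- synth_generate(cfg)
  snap <- suppressWarnings(deduplicate_snapshot(synth_as_snapshot(gen)))
  coh <- suppressWarnings(
    select_cohort(snap, cohort_spec(c("OSELTAMIVIR", "TAMIFLU")))
  )
  list(gen = gen, snapshot = snap, cohort = coh)
}

# Independent oracle: per-report iteration over the pair table and direct
# transcription of the 2x2 formulas, no shared code with the package path.
naive_screen <- function(pair_table) {
  pt_tab <- unique(as.data.frame(pair_table)[, c("primaryid", "pt", "is_member")])
  by_report <- split(pt_tab$pt, pt_tab$primaryid)
  member <- vapply(split(pt_tab$is_member, pt_tab$primaryid), any, logical(1))
  pts <- sort(unique(pt_tab$pt))
  out <- lapply(pts, function(p) {
    a <- 0; b <- 0; cc <- 0; d <- 0
    for (rid in names(by_report)) {
      terms <- by_report[[rid]]
      has <- as.integer(p %in% terms)
      rest <- length(terms) - has
      if (member[[rid]]) { a <- a + has; b <- b + rest }
      else { cc <- cc + has; d <- d + rest }
    }
    n <- a + b + cc + d
    if (a > 0 && b > 0 && cc > 0 && d > 0) {
      ror <- (a * d) / (b * cc)
      se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
      ror_l95 <- exp(log(ror) - 1.96 * se)
      ebgm05 <- exp(log(a * n / ((a + b) * (a + cc))) - 1.96 * se)
    } else {
      ror <- ror_l95 <- ebgm05 <- NA_real_
    }
    # observed/expected forms only need a and its margins positive
    if (a > 0 && (a + b) > 0 && (a + cc) > 0) {
      ebgm <- a * n / ((a + b) * (a + cc))
      ic <- log(a * n / ((a + b) * (a + cc))) / log(2)
    } else {
      ebgm <- ic <- NA_real_
    }
    prr <- if (cc > 0 && (a + b) > 0 && (cc + d) > 0) {
      (a / (a + b)) / (cc / (cc + d))
    } else NA_real_
    chi2 <- {
      den <- (a + b) * (cc + d) * (a + cc) * (b + d)
      if (den > 0) n * (a * d - b * cc)^2 / den else NA_real_
    }
    data.frame(pt = p, a = a, b = b, c = cc, d = d, ror = ror,
               ror_l95 = ror_l95, prr = prr, chi2 = chi2, ic = ic,
               ebgm = ebgm, ebgm05 = ebgm05)
  })
  do.call(rbind, out)
}

expect_rel_equal <- function(x, y, tol) {
  ok <- ifelse(is.na(x) | is.na(y),
               is.na(x) & is.na(y),
               abs(x - y) <= tol * pmax(abs(x), abs(y), 1e-12))
  expect_true(all(ok))
}
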