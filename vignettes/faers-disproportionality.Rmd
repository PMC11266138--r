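---
title: "Methods: disproportionality screening of FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerscreen)
```

## Scope and model

faerscreen implements the standard single-drug pharmacovigilance screen
over spontaneous reports: after deduplication and cohort selection, every
adverse-event preferred term (PT) reported for the target drug is
contrasted against a background of reports via a 2×2 contingency table of
unique (report, PT) pairs, and four disproportionality estimators are
computed with their interval bounds. The screen is descriptive: a flagged
pair is a reporting-disproportion *signal*, not a causal or incidence
claim. Spontaneous-report data carry notification biases (stimulated
reporting, indication confounding, duplicate residue) that no
disproportionality statistic removes; the package's job is to make the
computation itself exact, configurable and verifiable.

### Counting unit

The unit of counting is the unique (report, PT) pair: a report listing
the same PT twice counts once, and the margins `a + b` (target-drug
pairs) and `a + c` (PT pairs) are consistent across all PTs for a given
background. The background defaults to the selected age stratum
(`background_scope = "stratum"`), so pediatric cohorts are contrasted
against pediatric reporting patterns; `"full"` switches to the entire
deduplicated database. Both conventions appear in published FAERS work,
and the choice materially shifts c and d for age-patterned events, which
is why it is a visible configuration rather than a constant.

### The four estimators

With cells a, b, c, d and N their total:

* `ROR = ad/(bc)`, CI `exp(ln ROR ± 1.96σ)`, `σ = √(1/a+1/b+1/c+1/d)`;
* `PRR = [a/(a+b)]/[c/(c+d)]`, `χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`
  without Yates correction;
* `IC = log₂[aN/((a+b)(a+c))]` (default mode), `IC025 = IC − 2√V(IC)`
  with the standard two-layer BCPNN variance (prior constants
  γ₁₁ = α₁ = β₁ = 1, α = β = 2);
* `EBGM = aN/((a+b)(a+c))`, `EBGM05 = exp(ln EBGM − 1.96σ)` with the same
  σ as the ROR interval.

Two deliberate identities follow and are enforced by tests: the default
IC equals `log₂(EBGM)`, and `EBGM05/EBGM = ROR_l95/ROR` exactly.

**Why EBGM is not gamma-Poisson shrunk here.** The multi-item gamma
Poisson shrinker proper fits hyperparameters of a gamma mixture over the
whole drug–event matrix and shrinks each observed/expected ratio toward
the prior. The published tables this package is validated against print
EBGM values that coincide with the raw relative reporting ratio
(`IC = log₂ EBGM` holds on every printed row to rounding), i.e. no
shrinkage was applied there, so the non-shrunk form is the default and
the only implemented form; a hyperparameter-fitting mode is out of scope.
For small a this overstates EBGM relative to a genuinely shrunk
estimator — users comparing against openFDA or Empirica outputs should
expect differences precisely at rare PTs.

**IC modes.** The default observed/expected mode matches those same
printed outputs. `ic_stats(..., shrinkage = TRUE)` applies the classic
closed-form Bayesian shrinkage (pulling small-count ICs toward 0), which
is the better-behaved estimator for new analyses. Published IC025 values
in this literature are frequently not reproducible from any single
documented formula (rounded inputs, garbled typography); the package
promises only its own `IC − 2√V(IC)` convention and does not treat
printed IC025 values as checkable.

**Cell labeling.** Table footnotes in this literature often swap the
verbal definitions of b and c relative to the algebra. faerscreen fixes
b = target drug ∧ other events, c = other drugs ∧ target event; ROR, χ²,
IC and EBGM are invariant under the swap, so only PRR depends on it. The
inversion oracle resolves the question empirically on published rows: of
the two (b, c) assignments consistent with a printed quadruple, the one
reproducing the printed PRR always places b at the stable drug-margin
scale while c tracks the event's background frequency across orders of
magnitude (see `test-consistency.R`), confirming this labeling.

### Signal criteria

Defaults follow the convention used across FAERS screens: ROR lower 95%
bound > 1; PRR ≥ 2 and χ² ≥ 4; IC025 > 0; EBGM05 ≥ 2; each requires
a ≥ 3; the combined signal is the conjunction of all four. Every
threshold is a field of `signal_criteria()`. Undefined statistics (zero
cells) never flag: by default no Haldane 0.5 correction is applied, since
the printed formulas carry none; `zero_correction = "haldane"` enables it
for users who want estimates at zero cells. No multiple-testing
adjustment is applied anywhere — that matches field practice for these
screens, and is a known cost in false-discovery terms.

## Deduplication

FAERS distributes case follow-ups as separate report versions. The
two-step rule implemented: first drop every case on the deleted-case
lists (applied cumulatively as a union across quarters), then keep one
version per case — the latest FDA receipt date, ties broken by the
numerically higher primaryid (non-numeric identifiers fall back to
lexicographic order, below all numeric ones). Deletion precedes version
selection so a deleted case cannot resurrect an older version. Versions
with missing dates lose to any dated version; a case with no dated
version keeps its largest primaryid and is logged. The operation is
idempotent and order-insensitive, both property-tested. Fuzzy duplicate
detection across *different* caseids (same patient reported twice) is
out of scope; residual duplicates therefore inflate counts exactly as
they do in the published analyses.

## Cohort selection

Age is converted to years from the FAERS unit codes
(DEC×10, YR×1, MON/12, WK/52, DY/365, HR/8760). The pediatric stratum is
0–18 years inclusive *after* conversion; reports with missing age are
excluded from the stratum (and hence from both cohort and background)
rather than imputed. Drug identification is case-insensitive substring
matching of user-supplied generic and trade names against `drugname` and
`prod_ai`, after uppercasing, stripping punctuation and collapsing
whitespace — the pragmatic reading of "fuzzy matching" in this
literature; no RxNorm-style ingredient normalization is attempted.
`ps_exclusive = TRUE` (default) additionally requires that no other
distinct active ingredient share the primary-suspect role in the report.
Concomitant medications are counted in *mention* units (not collapsed
per report), since published concomitant tables total mentions.

## The synthetic generator

`synth_generate()` exists so every pipeline stage has a ground truth:
multi-version cases with strictly increasing receipt dates and
primaryids, deletion lists, demographics (age with unit-code mixture and
a missing category, sex including unknown, reporter occupation, country,
receipt year 2019–2023), one primary-suspect drug per report with 0–5
concomitant mentions, and per-report PT lists drawn from a vocabulary
with marginal probabilities. A planted association multiplies the PT's
probability by `rate_ratio` in reports whose primary suspect (and
optionally sex) matches, then renormalizes the event distribution.

Design points worth knowing:

* **Renormalization bias.** After multiplying a planted PT's probability
  by RR, renormalization divides all probabilities by
  `1 + q₀(RR − 1)`; the realized reporting-rate ratio is therefore
  slightly below RR, and within-report PT deduplication adds a second
  small attenuation. Both shrink with the planted PT's base probability,
  which is why planting targets in the default vocabulary sit at
  marginal probabilities ≤ 0.01. At those defaults the validation runs
  measure a mean log-ROR recovery error below 0.07 for RR ∈ {2, 5, 10}.
* **Compressed background.** The default vocabulary gives the two target
  drugs a combined primary-suspect share of ~23%, orders of magnitude
  above any real drug's share of FAERS. This is a deliberate desk-scale
  compression: with realistic shares, cohorts at 10³–10⁵ generated cases
  would be empty. Consequences: EBGM and PRR are diluted toward 1
  relative to the planted rate ratio (the member margin is a visible
  fraction of the background), while the ROR is unaffected — the
  recovery tests therefore calibrate against the ROR.
* **Determinism.** One `set.seed(seed)` at entry; all draws descend from
  it in fixed order, so identical configs give byte-identical files
  (tested).
* **What it does not emulate.** Free-text drug-name noise beyond
  prefix-sharing decoy names, reporting-trend drift over time,
  correlated event co-occurrence (syndromes), and realistic PT
  vocabularies (28 PTs vs MedDRA's ~24,000). Passing recovery tests
  shows the *computation* is right at realistic orders of magnitude of
  a, not that real-FAERS idiosyncrasies are handled.

## The inversion oracle

Published signal tables print (a, ROR with CI, PRR with χ², IC with
IC025, EBGM with EBGM05) but not b, c, d. Because ROR, χ², IC and EBGM
are b↔c symmetric, the quadruple (a, ROR, ROR_l95, EBGM) determines
s = b + c, p = b·c and d through three equations (ROR, the shared σ²,
and EBGM). `recover_cells()` eliminates p and s analytically and solves
the remaining equation in d by sign-change bracketing on a 600-point
log grid over d ∈ [10², 10⁸] followed by `uniroot` at tolerance 1e-10 —
well-conditioned because every quantity is positive and smooth in
log d. The solution is verified by recomputing the three inputs
(default tolerance 0.5% relative, loosened to 2% for two-decimal printed
inputs); failure names the inconsistent input. The two (b, c)
assignments are the roots of x² − sx + p = 0; `predict_statistic()`
evaluates any screening formula on the recovered table, returning both
PRR values since PRR alone is labeling-dependent.

This is what makes published rows desk-scale test vectors: recomputing
χ² for the highest-count published row lands within 0.2% of the printed
value, and recovered-cell ICs match printed ICs to two decimals (see
`scripts/acceptance.R` output and `test-acceptance.R`).

## Numerical and degenerate-input conventions

* All identifiers are strings; primaryid comparisons use numeric
  interpretation with lexicographic fallback.
* Input text is read as Latin-1; encoding never aborts a read.
* Malformed headers are hard errors naming the file; unparseable dates
  or ages degrade to missing values with warnings, keeping the row.
* Zero cells: statistics undefined (`NA`), never flagged, unless the
  Haldane correction is explicitly enabled.
* A PT absent from the background yields a valid a = c = 0 table.
* Empty cohorts warn and propagate as schema-valid empty outputs through
  the whole pipeline.
* Ties in rankings (concomitants, screen output) break alphabetically;
  the screen sorts by descending a.
* PT→SOC maps must be single-primary (duplicate PT with conflicting SOC
  is an error); unmapped PTs aggregate under `"UNMAPPED"`.

## Subgroups

`subgroup_signals()` re-runs the identical screen within the female and
male strata; members with missing sex are excluded from both. Each
stratum's background is the same-sex slice of the cohort background
(within-gender contrast), with `pooled_background = TRUE` available
since the literature is not explicit about this choice. The discordance
list — PTs flagged in exactly one stratum — is descriptive; no formal
interaction test is computed, matching the practice this package
mirrors.

## Validation problem sizes

The shipped suite validates at sizes chosen to keep a full run around a
minute on one CPU: oracle-equivalence on 50 generated snapshots of 250
cases; dedup properties on snapshots up to 1,000 cases with 30–40%
duplication; demographic-marginal recovery at 10⁴ cases; rate-ratio
recovery over 20 seeds × 15,000 cases for RR ∈ {2, 5, 10}; interval
coverage over 30 replicates of 3,000 cases; null calibration on a single
140,000-case snapshot (≥10⁵ background pairs). Scaling any of these up
is a matter of editing the constants; the properties asserted do not
depend on the sizes.

## Known limitations

* The non-shrunk EBGM (and the resulting IC = log₂ EBGM identity) tracks
  the published convention it validates against, not MGPS proper.
* Printed IC025 values are not reproducible in general and are not
  targets.
* Real-FAERS scale replication (millions of reports) is supported by the
  same code paths but is not exercised by the shipped tests, which are
  generator-based by design.
* Drug-name matching is substring-based; misspelled or coded names in
  real free text will be missed unless added to the pattern list.
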