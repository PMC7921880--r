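---
title: "Methods: seasonal symptom profiles from pollen and diary data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal symptom profiles from pollen and diary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollendiary)
```

## The problem

Airborne grass pollen is a single aerobiological signal — Poaceae pollen
grains cannot be told apart by species under the microscope — but the season
it drives is composite: early-flowering meadow grasses, a dense main
pollination period, and late-flowering species produce staggered peaks.
Hay-fever sufferers differ in which part of this composite season hits them
hardest. `pollendiary` quantifies that heterogeneity from two inputs: daily
mean pollen concentrations (grains/m³, Hirst-type volumetric trap) and an
electronic symptom diary in which each user records eye, nose and lung
severity plus medication use per day.

## Season definition and the APIn

The season of a calendar year is delimited by cumulative percentage
thresholds on the daily series $c(d)$ of the target taxon: the start is the
first day on which $\sum_{d' \le d} c(d') \ge 0.01 \cdot C$ and the end the
first day on which the sum reaches $0.95 \cdot C$, where $C$ is the annual
total. Three numerical conventions matter and are fixed package-wide:

* **Crossing uses $\ge$** (the day the percentage *is reached*); with `>`
  the endpoints would differ whenever a threshold is hit exactly.
* **Whole days, no interpolation** — monitoring networks report whole start
  and end dates.
* **Closed intervals everywhere**: duration is `end − start + 1`, so a
  season from 30 April to 19 July lasts 81 days.

The Annual Pollen Integral, $\mathrm{APIn} = \sum_{d \in \text{season}}
c(d)$ (pollen·day/m³), is the season's total exposure and the basis of the
first partition method.

## The three partitions

All partitions split the season into three consecutive closed date
intervals; the two cut dates always belong to the section they end, and a
partition whose sections would be empty (`cut1 == cut2`, or a cut at the
season edge) is rejected as degenerate rather than silently clamped.

1. **APIn tertiles** (`apin_tertile_partition()`): cuts on the first days
   the within-season cumulative pollen sum reaches APIn/3 and 2·APIn/3.
   Scaling the whole series by a positive constant changes nothing.
2. **Phenology** (`phenology_partition()`): section 2 opens with the
   earliest flowering onset among the main-season grasses and section 3
   with the earliest onset among the late group; section 1 and 3 are
   clamped to the season's own start and end. The group membership is
   configuration (`run_config()$phenology_groups`) with the common
   central-European default (early: *Poa pratensis*, *Dactylis glomerata*;
   main: *Arrhenatherum elatius*, *Festuca* sp., *Lolium perenne*; late:
   *Phleum pratense*, *Cynodon dactylon*). Flowering onset — not full
   flowering — defines the boundary, because the sections are meant to
   *start with the beginning* of the defining grasses. Phenology sources
   that report ISO calendar weeks are converted via the Monday of the week
   (`iso_week_monday()`), a documented convention.
3. **Per-user symptom-load tertiles** (`sli_tertile_sections()`): for each
   user separately, cuts on the first days the user's cumulative daily
   score reaches one and two thirds of their season total. This requires a
   complete series, hence the imputation step below.

## Scoring, filtering and imputation

The daily total score is a weighted sum of the four sub-scores; the default
weights are all 1 and the default maxima (3, 3, 3, 1) give a 0–10 total.
The weights are configurable because diary platforms differ in how they
combine sub-scores; every downstream step consumes only the total.

The filter retains a user iff (i) the correlation between their daily score
and same-day pollen is positive, (ii) its one-sided p-value is below
`alpha = 0.05`, and (iii) they have at least `min_entries = 15` observed
in-season days. Spearman rank correlation is the default: the dose–response
saturates (see below), which attenuates Pearson but leaves a monotone
association intact. Ties are handled by midranks; users with a constant
score (or constant pollen exposure on their observed days) have no defined
correlation and fail the filter. Same-day pairing is the default; a `lag`
parameter exists purely for sensitivity analysis.

Missing days are filled by k-nearest-neighbour imputation
(`knn_impute()`, `k = 3`): the distance between a missing day and an
observed day is the Manhattan sum of two range-normalised variables, the
day of season and the pollen concentration — a Gower-style distance on two
numeric variables. The imputed value is the median of the k nearest
observed scores (middle order statistic for odd k, mean of the two middle
values for even k). Determinism is guaranteed by explicit tie-breaks:
equidistant neighbours are taken in order of earlier calendar day, then
lower score. Range normalisation uses the season-wide range per variable; a
constant variable contributes zero distance. Imputed values are medians of
observed values, so they can never leave the observed score range.

## Assignment and its one deliberate interpretation

For the APIn and phenology partitions a user's per-section severity is the
**mean** daily score in each section (argmax wins, ties to the earliest
section). Mean, not sum, because sections have unequal lengths and users
unequal coverage — a sum would systematically favour long sections. `sum`
and `peak` (highest single day) remain available via
`run_config(statistic = ...)`. If a user has no observed day in some
section, the mean is undefined and the error message points to imputation.

For the per-user tertile partition the same argmax-of-mean rule is applied
to the user's own three segments. Because the segments carry equal score
mass by construction, the argmax is the segment over which the symptom load
accumulates *fastest* (equivalently, the shortest segment). This is an
explicit design interpretation, and it has a consequence worth stating
plainly: for any unimodal symptom profile the middle tertile segment covers
the mode, so this method concentrates labels on section 2 far more than the
calendar-based methods do. It measures the *shape* of symptom accumulation
rather than the calendar position of the peak. The package therefore treats
true-section recovery (next section) as a property of the calendar-based
methods, and tests the tertile method against its own definition (the
fastest-accumulating segment is never the longest one).

A one-way fixed-effects ANOVA (`anova_sections()`, F with 2 and $n-3$
degrees of freedom) is available as the confirmatory check that section
membership explains daily scores; all-constant input yields an undefined F
and is flagged degenerate rather than reported as significant.

## The synthetic cohort generator

No individual diary data can be shipped, so the generator defines the study
conditions under which the pipeline is validated.

* **Pollen**: each taxon contributes a Gaussian-shaped curve
  $a \exp(-(d-p)^2 / 2\sigma^2)$; the seven-taxon default
  (`default_taxon_specs()`) staggers early/main/late peaks (doy 138–196,
  plus a small rebloom of *Phleum* around doy 235) with amplitudes chosen
  so the aggregate season integral is a few thousand pollen·day/m³ and the
  season spans roughly doy 125–200 — the magnitude of observed urban
  Poaceae seasons. Multiplicative lognormal day-to-day noise
  (`noise_sdlog = 0.3`, meanlog offset $-\sigma^2/2$ so the expectation
  stays on the curve) emulates weather-driven variation.
* **Users**: the latent daily score is
  $\min(\text{plateau},\; w_{s(d)} \cdot c(d)) + \varepsilon_d$ — a linear
  dose–response that saturates, as symptom data do once exposure is high —
  discretised to the 0–10 score range and split deterministically
  (round-robin nose → eye → lung → medication) into sub-scores. $w$ is
  the per-section sensitivity, strictly maximal in the user's true section;
  `gen_user_specs()` anchors it so the plateau (default 8) is reached at
  the true section's upper-quartile concentration, with off-section
  sensitivity 0.15 of that (cross-reactivity among grass allergens is
  extensive, but the dominant sensitisation wins). True sections are drawn
  20% / 70% / 10%, the early/main/late split typical of urban cohorts.
  Defaults `adherence = 0.7` (Bernoulli per day; an optional contiguous
  vacation block exists but is off by default) and
  `noise_sd = 0.5 · plateau` make the default cohort deliberately noisy
  and gappy.

What the generator does **not** emulate: polysensitisation (weed or fungal
co-triggers late in the season), medication feedback (treated users
reporting less), weather-driven reporting, or spatial mismatch between user
and station. Passing tests therefore show that the pipeline recovers the
structure *it defines*; they cannot show that real cohorts contain such
structure.

Under noise-free, full-adherence conditions with the classification
partition matching the generating one, the calendar-based methods recover
100% of true sections; at the default noisy conditions (100 users,
`noise_sd = 4`, `adherence = 0.7`) recovery stays above 90%, and the filter
passes null (pollen-independent) users at its nominal 5% rate — both are
recomputed by `scripts/acceptance.R` at every run.

## Reporting conventions

Percentages are rounded half-up (away from zero): one decimal in section
tables, whole percent in the stability summary. Stability considers only
users classified in every year on record: same section every year (robust
profile), same in all but one year, or different every year; the summary
also reports whether any such user ever occupied both section 1 and
section 3, i.e. whether a profile change ever skipped the middle section.
Profile curves plot the fraction of a user's season symptom load against
the fraction of APIn accumulated by the same day; both coordinates are
non-decreasing and end at (1, 1). The fast/slow reactor flag compares a
user's curve with the cohort mean at mid-APIn ($x = 0.5$) — the curves
define "above the average" but not where to evaluate it, so mid-exposure is
adopted as the convention.

## Problem sizes and test design

The test-suite simulations are sized to validate behaviour, not to survey
it: 50 random series for the season/tertile brute-force oracles, 5 × ~30%
missingness series for the imputation oracle, 10,000 permutations for the
correlation p-value oracle, 1,000 null users for the type-I-error check,
and 100-user cohorts for recovery — each against an independently coded
oracle (explicit cumulative scans, exhaustive neighbour search, enumeration
of all 27 three-year label triples, textbook ANOVA mean squares). The full
suite runs in well under a minute.

## Known limitations

* Only the 1%/95% cumulative season definition is implemented; other
  threshold conventions exist in aerobiology.
* One pollen station, one taxon per analysis; no zip-code-to-station
  assignment.
* The filter implements exactly `p < alpha`; platforms that pre-filter
  users server-side may apply additional floors.
* kNN is the only imputation; model-based alternatives (regression, EM)
  are out of scope.
* The per-user tertile labels are not commensurable with the calendar
  methods for users with strongly skewed profiles, as discussed above.
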