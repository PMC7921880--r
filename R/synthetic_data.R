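#' Specification of one taxon's pollen release curve
#'
#' A Gaussian-shaped daily concentration curve
#' `amplitude * exp(-(d - peak_day)^2 / (2 * spread_days^2))` over day of
#' year `d`, optionally with a second, smaller late-summer peak (a rebloom,
#' which some grass species show at the end of the season).
#'
#' @param taxon Taxon name.
#' @param peak_day Day of year of the peak.
#' @param spread_days Gaussian standard deviation in days (> 0).
#' @param amplitude Peak daily concentration in grains/m3 (> 0).
#' @param rebloom Optional list with `peak_day`, `spread_days`, `amplitude`
#'   for a second flowering period.
#' @return A `taxon_curve_spec` (named list).
#' @export
taxon_curve_spec <- function(taxon, peak_day, spread_days, amplitude,
                             rebloom = NULL) {
  if (!(amplitude > 0)) stop("amplitude must be > 0")
  if (!(spread_days > 0)) stop("spread_days must be > 0")
  if (!is.null(rebloom))
    stopifnot(rebloom$amplitude > 0, rebloom$spread_days > 0)
  structure(list(taxon = taxon, peak_day = peak_day, spread_days = spread_days,
                 amplitude = amplitude, rebloom = rebloom),
            class = "taxon_curve_spec")
}

#' Default grass taxon curves and flowering periods
#'
#' A seven-taxon template of a central-European grass pollen season with
#' three staggered groups: early (Poa pratensis, Dactylis glomerata), main
#' (Arrhenatherum elatius, Festuca sp., Lolium perenne) and late (Phleum
#' pratense with a small rebloom, Cynodon dactylon). Amplitudes are scaled so
#' that the aggregate season integral is a few thousand pollen day/m3, the
#' order of magnitude of observed Poaceae seasons at urban European stations.
#'
#' @return `default_taxon_specs()`: a list of [taxon_curve_spec()] objects.
#' @export
default_taxon_specs <- function() {
  list(
    taxon_curve_spec("Poa pratensis",         138,  9, 12),
    taxon_curve_spec("Dactylis glomerata",    142,  9, 16),
    taxon_curve_spec("Arrhenatherum elatius", 160, 10, 24),
    taxon_curve_spec("Festuca sp.",           163, 11, 20),
    taxon_curve_spec("Lolium perenne",        167, 12, 22),
    taxon_curve_spec("Phleum pratense",       190,  9,  9,
                     rebloom = list(peak_day = 235, spread_days = 8,
                                    amplitude = 3)),
    taxon_curve_spec("Cynodon dactylon",      196, 10,  7)
  )
}

#' @rdname default_taxon_specs
#' @param year Calendar year for which to date the flowering periods.
#' @param specs Taxon curve specifications.
#' @return `default_phenology()`: a `phenology_periods` tibble with the
#'   flowering period of each taxon spanning two standard deviations around
#'   its peak and full flowering spanning one.
#' @export
default_phenology <- function(year, specs = default_taxon_specs()) {
  origin <- as.Date(sprintf("%d-01-01", year)) - 1L
  d <- function(off) origin + as.integer(round(off))
  phenology_periods(
    taxon = vapply(specs, `[[`, "", "taxon"),
    flowering_start = d(vapply(specs, function(s) s$peak_day - 2 * s$spread_days, 0)),
    full_start = d(vapply(specs, function(s) s$peak_day - s$spread_days, 0)),
    full_end = d(vapply(specs, function(s) s$peak_day + s$spread_days, 0)),
    flowering_end = d(vapply(specs, function(s) s$peak_day + 2 * s$spread_days, 0))
  )
}

#' Generate one year of daily aggregate grass pollen
#'
#' Sums the taxon curves day by day over the calendar year into one
#' aggregate series for the reported taxon (airborne grass pollen cannot be
#' told apart by species, so monitoring stations report the family level).
#' Optional multiplicative lognormal noise emulates day-to-day variation;
#' its meanlog is offset by `-noise_sdlog^2/2` so the expected daily value
#' stays on the curve.
#'
#' @param specs Non-empty list of [taxon_curve_spec()].
#' @param year Calendar year.
#' @param seed Integer seed (only used when `noise_sdlog > 0`).
#' @param noise_sdlog Standard deviation of the log noise; 0 disables noise.
#'   Default 0.3.
#' @param taxon Name under which the aggregate is reported.
#' @param station_id Station identifier.
#' @return A [pollen_series()] covering every day of the year.
#' @export
#' @examples
#' ps <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
#' define_season(ps, 2015)
gen_pollen_year <- function(specs, year, seed = 1L, noise_sdlog = 0.3,
                            taxon = "Poaceae", station_id = "synthetic") {
  if (length(specs) == 0) stop("gen_pollen_year: need at least one taxon spec")
  stopifnot(all(vapply(specs, inherits, TRUE, "taxon_curve_spec")))
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  d <- seq_along(days)
  gauss <- function(peak, spread, amp) amp * exp(-(d - peak)^2 / (2 * spread^2))
  conc <- Reduce(`+`, lapply(specs, function(s) {
    g <- gauss(s$peak_day, s$spread_days, s$amplitude)
    if (!is.null(s$rebloom))
      g <- g + gauss(s$rebloom$peak_day, s$rebloom$spread_days,
                     s$rebloom$amplitude)
    g
  }))
  if (noise_sdlog > 0)
    conc <- conc * with_seed(seed, rlnorm(length(d), -noise_sdlog^2 / 2,
                                          noise_sdlog))
  pollen_series(days, conc, taxon = taxon, station_id = station_id)
}

#' Specification of one synthetic diary user
#'
#' A user is defined by the season section in which their symptoms truly
#' peak, a per-section sensitivity (score per grain/m3, strictly maximal in
#' the true section), a saturation plateau above which more pollen no longer
#' raises the daily score, a reporting adherence, and a daily noise level.
#'
#' @param user_id Identifier.
#' @param true_section Integer 1, 2 or 3.
#' @param sensitivity_weights Numeric length 3, non-negative, strict maximum
#'   at `true_section`.
#' @param plateau Score saturation level (> 0).
#' @param adherence Probability of entering data on a given season day.
#' @param noise_sd Standard deviation of the additive Gaussian day noise.
#' @return A `user_spec` (named list).
#' @export
user_spec <- function(user_id, true_section, sensitivity_weights, plateau,
                      adherence, noise_sd) {
  stopifnot(true_section %in% 1:3, length(sensitivity_weights) == 3,
            all(sensitivity_weights >= 0), plateau > 0,
            adherence >= 0, adherence <= 1, noise_sd >= 0)
  if (any(sensitivity_weights[-true_section] >= sensitivity_weights[true_section]))
    stop("sensitivity_weights must be strictly maximal at true_section")
  structure(list(user_id = as.character(user_id),
                 true_section = as.integer(true_section),
                 sensitivity_weights = as.numeric(sensitivity_weights),
                 plateau = plateau, adherence = adherence, noise_sd = noise_sd),
            class = "user_spec")
}

#' Draw a cohort of synthetic user specifications
#'
#' True sections are drawn with probabilities `section_probs` (default
#' 20% / 70% / 10%, the early / main / late split reported for urban
#' central-European cohorts). Each user's sensitivity in their true section
#' is calibrated against the pollen curve so that the plateau is reached on
#' the stronger days of that section (the dose-response saturates within the
#' season); sensitivity to the other sections is `cross_reactivity` times
#' that (cross-reactivity among grass allergens is extensive but the
#' dominant sensitisation wins).
#'
#' @param n Number of users.
#' @param pollen A [pollen_series()] for the year.
#' @param partition The ground-truth `section_partition` of the season.
#' @param seed Integer seed.
#' @param section_probs Probabilities of true sections 1..3.
#' @param plateau Score plateau (default 8 on the 0-10 total score).
#' @param adherence Daily reporting probability (default 0.7).
#' @param noise_sd Daily score noise SD (default `0.5 * plateau`).
#' @param cross_reactivity Off-section sensitivity ratio in (0, 1),
#'   default 0.15.
#' @return List of [user_spec()] objects.
#' @export
gen_user_specs <- function(n, pollen, partition, seed = 1L,
                           section_probs = c(0.2, 0.7, 0.1),
                           plateau = 8, adherence = 0.7,
                           noise_sd = 0.5 * plateau,
                           cross_reactivity = 0.15) {
  stopifnot(inherits(partition, "section_partition"), n >= 1,
            length(section_probs) == 3, all(section_probs >= 0),
            cross_reactivity > 0, cross_reactivity < 1)
  season <- partition$season
  px <- pollen[pollen$taxon == season$taxon &
                 pollen$date >= season$start_date &
                 pollen$date <= season$end_date, ]
  sec <- section_of(partition, px$date)
  # sensitivity scale per section: plateau reached at that section's upper
  # quartile concentration
  q75 <- vapply(1:3, function(s) stats::quantile(px$concentration[sec == s],
                                                 0.75, names = FALSE),
                numeric(1))
  if (any(q75 <= 0)) stop("gen_user_specs: a section has no pollen")
  truth <- with_seed(seed, sample(1:3, n, replace = TRUE,
                                  prob = section_probs / sum(section_probs)))
  lapply(seq_len(n), function(i) {
    ts <- truth[i]
    w <- rep(cross_reactivity * plateau / q75[ts], 3)
    w[ts] <- plateau / q75[ts]
    user_spec(sprintf("u%03d", i), ts, w, plateau, adherence, noise_sd)
  })
}

#' Generate a diary cohort with known ground truth
#'
#' For every user and season day, the latent daily score is
#' `min(plateau, w[section(d)] * c(d)) + N(0, noise_sd)` - the linear
#' dose-response with a hard saturation plateau - discretised to the
#' configured total score range and split across the four diary sub-scores.
#' The day is recorded with probability `adherence` (independently per day);
#' optionally one contiguous block of `vacation_days` days per user is
#' additionally dropped, emulating holiday absence.
#'
#' @param users List of [user_spec()] objects.
#' @param pollen A [pollen_series()].
#' @param partition The ground-truth `section_partition`; must cover the
#'   season being generated.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param cfg A [run_config()] (sub-score maxima and their round-robin
#'   split).
#' @param vacation_days Length of the per-user missing block (0 = off).
#' @return A list with `entries` (a `diary_entries` tibble of the observed
#'   user-days) and `truth` (a `synthetic_truth`: `users` tibble with
#'   `user_id`, `true_section`, ...; `days` tibble with every generated
#'   user-day, its latent and recorded score and whether it was observed;
#'   and the generator parameters).
#' @export
gen_cohort <- function(users, pollen, partition, seed = 1L, cfg = run_config(),
                       vacation_days = 0L) {
  stopifnot(length(users) >= 1,
            all(vapply(users, inherits, TRUE, "user_spec")),
            inherits(partition, "section_partition"))
  season <- partition$season
  days <- seq(season$start_date, season$end_date, by = "day")
  px <- pollen[pollen$taxon == season$taxon, ]
  conc <- px$concentration[match(days, px$date)]
  if (anyNA(conc)) stop("gen_cohort: pollen series does not cover the season")
  sec <- section_of(partition, days)
  score_max <- sum(cfg$score_maxima)

  day_rows <- with_seed(seed, lapply(users, function(u) {
    if (all(u$sensitivity_weights == 0)) stop("user ", u$user_id,
                                              ": all-zero weights")
    latent <- pmin(u$plateau, u$sensitivity_weights[sec] * conc) +
      rnorm(length(days), 0, u$noise_sd)
    score <- pmin(score_max, pmax(0, round(latent)))
    observed <- runif(length(days)) < u$adherence
    if (vacation_days > 0) {
      at <- sample(length(days) - vacation_days + 1L, 1L)
      observed[at:(at + vacation_days - 1L)] <- FALSE
    }
    tibble::tibble(user_id = u$user_id, date = days, latent = latent,
                   score = as.integer(score), observed = observed)
  }))
  days_tbl <- dplyr::bind_rows(day_rows)

  obs <- days_tbl[days_tbl$observed, ]
  sub <- split_subscores(obs$score, cfg$score_maxima)
  entries <- diary_entries(obs$user_id, obs$date, sub$eye, sub$nose, sub$lung,
                           sub$medication, cfg = cfg)
  truth <- structure(
    list(users = tibble::tibble(
           user_id = vapply(users, `[[`, "", "user_id"),
           true_section = vapply(users, `[[`, 1L, "true_section"),
           plateau = vapply(users, `[[`, 1, "plateau"),
           adherence = vapply(users, `[[`, 1, "adherence"),
           noise_sd = vapply(users, `[[`, 1, "noise_sd")),
         days = days_tbl, seed = seed, vacation_days = vacation_days,
         partition = partition),
    class = "synthetic_truth"
  )
  list(entries = entries, truth = truth)
}

# deterministic round-robin split of a total score over the four sub-scores,
# one point at a time in the order nose, eye, lung, medication; downstream
# analysis only ever uses the total, so only determinism matters here
split_subscores <- function(total, maxima) {
  order <- c("nose", "eye", "lung", "medication")
  caps <- unname(maxima[order])
  out <- matrix(0L, nrow = length(total), ncol = 4,
                dimnames = list(NULL, order))
  remaining <- as.integer(total)
  repeat {
    active <- remaining > 0L
    if (!any(active)) break
    for (j in 1:4) {
      give <- active & out[, j] < caps[j] & remaining > 0L
      out[give, j] <- out[give, j] + 1L
      remaining[give] <- remaining[give] - 1L
    }
  }
  list(eye = out[, "eye"], nose = out[, "nose"], lung = out[, "lung"],
       medication = out[, "medication"])
}

#' Simulate a complete multi-year study
#'
#' Convenience wrapper: generates a pollen year, delimits its season, builds
#' the APIn-tertile ground-truth partition and a user cohort for each year,
#' reusing the same users (with the same true section) across years so that
#' cross-year stability can be analysed.
#'
#' @param years Integer vector of calendar years.
#' @param n_users Cohort size.
#' @param seed Integer master seed.
#' @param specs Taxon curve specifications.
#' @param cfg A [run_config()].
#' @param ... Passed to [gen_user_specs()] (plateau, adherence, noise_sd,
#'   section_probs, cross_reactivity).
#' @return A list with `pollen` (multi-year [pollen_series()]), `seasons`,
#'   `partitions`, `phenology`, `entries` (all years) and `truth_users`.
#' @export
simulate_study <- function(years, n_users = 100, seed = 1L,
                           specs = default_taxon_specs(), cfg = run_config(),
                           ...) {
  pollen_all <- list(); seasons <- list(); partitions <- list()
  entries_all <- list(); truth_users <- NULL
  user_specs <- NULL
  for (i in seq_along(years)) {
    y <- years[i]
    ps <- gen_pollen_year(specs, y, seed = seed + i)
    season <- define_season(ps, y)
    part <- apin_tertile_partition(ps, season)
    # same user seed every year: identical user ids and true sections,
    # sensitivities re-anchored to this year's pollen curve
    user_specs <- gen_user_specs(n_users, ps, part, seed = seed, ...)
    coh <- gen_cohort(user_specs, ps, part, seed = seed + 100L + i, cfg = cfg)
    pollen_all[[i]] <- ps; seasons[[as.character(y)]] <- season
    partitions[[as.character(y)]] <- part
    entries_all[[i]] <- coh$entries
    if (is.null(truth_users)) truth_users <- coh$truth$users
  }
  pollen <- dplyr::bind_rows(pollen_all)
  class(pollen) <- c("pollen_series", class(tibble::tibble()))
  attr(pollen, "station_id") <- "synthetic"
  entries <- dplyr::bind_rows(entries_all)
  class(entries) <- c("diary_entries", class(tibble::tibble()))
  list(pollen = pollen, seasons = seasons, partitions = partitions,
       phenology = lapply(stats::setNames(years, years), default_phenology),
       entries = entries, truth_users = truth_users)
}

# run code with a private RNG state, leaving the caller's stream untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
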