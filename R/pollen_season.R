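#' Delimit the grass pollen season of one year
#'
#' Applies the cumulative-percentage season definition used by the European
#' aerobiological networks: the season starts on the day the running sum of
#' daily concentrations first reaches 1% of the annual total for the taxon,
#' and ends on the day it first reaches 95%. Both endpoints are whole days
#' and the season interval is closed.
#'
#' @param pollen A [pollen_series()].
#' @param year Calendar year to delimit.
#' @param taxon Taxon to use (default `"Poaceae"`).
#' @param start_frac,end_frac Cumulative fractions defining start and end
#'   (defaults 0.01 and 0.95).
#' @return A `season_definition`: list with `year`, `start_date`, `end_date`,
#'   `duration_days` (inclusive day count), `apin` (Annual Pollen Integral,
#'   pollen day/m3 summed over the season) and `annual_total`.
#' @export
#' @examples
#' ps <- pollen_series(as.Date("2015-01-01") + 0:364,
#'                     ifelse(seq_len(365) %in% 121:220, 10, 0))
#' define_season(ps, 2015)
define_season <- function(pollen, year, taxon = "Poaceae",
                          start_frac = 0.01, end_frac = 0.95) {
  stopifnot(inherits(pollen, "pollen_series"), start_frac < end_frac)
  x <- pollen[pollen$taxon == taxon &
                as.integer(format(pollen$date, "%Y")) == year, ]
  if (nrow(x) == 0) stop("no pollen records for taxon ", taxon, " in ", year)
  x <- x[order(x$date), ]
  total <- sum(x$concentration)
  if (total <= 0) stop("no pollen season: annual total for ", taxon,
                       " in ", year, " is zero")
  cum <- cumsum(x$concentration)
  start <- x$date[which(cum >= start_frac * total)[1]]
  end <- x$date[which(cum >= end_frac * total)[1]]
  season_definition(year, start, end,
                    apin = sum(x$concentration[x$date >= start & x$date <= end]),
                    annual_total = total, taxon = taxon)
}

season_definition <- function(year, start_date, end_date, apin, annual_total = NA_real_,
                              taxon = "Poaceae") {
  stopifnot(start_date <= end_date, apin >= 0)
  structure(
    list(year = as.integer(year), start_date = start_date, end_date = end_date,
         duration_days = season_duration(start_date, end_date),
         apin = apin, annual_total = annual_total, taxon = taxon),
    class = "season_definition"
  )
}

#' @export
print.season_definition <- function(x, ...) {
  cat(sprintf("<season %d (%s)> %s (doy %d) to %s (doy %d), %d days, APIn %.0f\n",
              x$year, x$taxon,
              format(x$start_date, "%d.%m.%Y"), doy(x$start_date),
              format(x$end_date, "%d.%m.%Y"), doy(x$end_date),
              x$duration_days, x$apin))
  invisible(x)
}

#' Inclusive duration of a date interval
#'
#' All season intervals are closed, so the duration counts both endpoints:
#' a season from 30 April to 19 July lasts 81 days.
#'
#' @param start,end Dates with `start <= end`.
#' @return Integer number of days.
#' @export
#' @examples
#' season_duration(as.Date("2014-04-30"), as.Date("2014-07-19"))  # 81
season_duration <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (any(start > end)) stop("season_duration: start after end")
  as.integer(end - start) + 1L
}

#' Annual Pollen Integral over a season
#'
#' Sum of the daily mean concentrations (grains/m3) within the closed season
#' interval, in pollen day/m3.
#'
#' @param pollen A [pollen_series()].
#' @param season A `season_definition`.
#' @return A single non-negative number.
#' @export
apin <- function(pollen, season) {
  stopifnot(inherits(pollen, "pollen_series"),
            inherits(season, "season_definition"))
  x <- pollen[pollen$taxon == season$taxon, ]
  sum(x$concentration[x$date >= season$start_date & x$date <= season$end_date])
}

# ---- season partitions -----------------------------------------------------

#' Three-way season partition
#'
#' A `section_partition` splits a season into three consecutive closed date
#' intervals by two cut dates, each cut date closing the section it ends:
#' section 1 is `[start, cut1]`, section 2 `[cut1 + 1, cut2]`, section 3
#' `[cut2 + 1, end]`. Degenerate partitions (empty sections) are rejected.
#'
#' @param season A `season_definition`.
#' @param cut1,cut2 Cut dates with `start <= cut1 < cut2 < end`.
#' @param method One of `"apin"`, `"phenology"`, `"sli"`.
#' @param user_id For per-user (`"sli"`) partitions, the owning user.
#' @return A `section_partition` object.
#' @export
section_partition <- function(season, cut1, cut2, method = c("apin", "phenology", "sli"),
                              user_id = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(season, "season_definition"))
  cut1 <- as.Date(cut1); cut2 <- as.Date(cut2)
  if (!(season$start_date <= cut1 && cut1 < cut2 && cut2 < season$end_date))
    stop("degenerate partition: need start <= cut1 < cut2 < end, got ",
         "start ", season$start_date, ", cut1 ", cut1, ", cut2 ", cut2,
         ", end ", season$end_date)
  structure(
    list(method = method, season = season, cut1 = cut1, cut2 = cut2,
         user_id = user_id),
    class = "section_partition"
  )
}

#' @export
print.section_partition <- function(x, ...) {
  s <- sections(x)
  cat(sprintf("<section_partition method=%s%s>\n", x$method,
              if (is.null(x$user_id)) "" else paste0(" user=", x$user_id)))
  for (i in 1:3)
    cat(sprintf("  section %d: %s .. %s (%d days)\n", i, s$start[i], s$end[i],
                season_duration(s$start[i], s$end[i])))
  invisible(x)
}

#' @rdname section_partition
#' @param x A `section_partition`.
#' @return `sections()` returns a 3-row tibble with `section`, `start`, `end`.
#' @export
sections <- function(x) {
  stopifnot(inherits(x, "section_partition"))
  tibble::tibble(
    section = 1:3,
    start = c(x$season$start_date, x$cut1 + 1L, x$cut2 + 1L),
    end = c(x$cut1, x$cut2, x$season$end_date)
  )
}

#' @rdname section_partition
#' @param dates Dates to place.
#' @return `section_of()` returns an integer vector in `{1, 2, 3}` (`NA` for
#'   dates outside the season).
#' @export
section_of <- function(x, dates) {
  stopifnot(inherits(x, "section_partition"))
  dates <- as.Date(dates)
  out <- rep(NA_integer_, length(dates))
  out[dates >= x$season$start_date & dates <= x$cut1] <- 1L
  out[dates > x$cut1 & dates <= x$cut2] <- 2L
  out[dates > x$cut2 & dates <= x$season$end_date] <- 3L
  out
}

#' Partition the season into pollen-integral tertiles
#'
#' First of the three partition methods: the cut dates are the first days on
#' which the within-season running pollen sum reaches one third and two
#' thirds of the season APIn; each cut date closes its section.
#'
#' @param pollen A [pollen_series()].
#' @param season A `season_definition` for the same taxon/year.
#' @return A `section_partition` with method `"apin"`.
#' @export
apin_tertile_partition <- function(pollen, season) {
  stopifnot(inherits(pollen, "pollen_series"),
            inherits(season, "season_definition"))
  x <- pollen[pollen$taxon == season$taxon &
                pollen$date >= season$start_date &
                pollen$date <= season$end_date, ]
  x <- x[order(x$date), ]
  total <- sum(x$concentration)
  if (total <= 0) stop("apin_tertile_partition: zero pollen mass in season")
  cum <- cumsum(x$concentration)
  cut1 <- x$date[which(cum >= total / 3)[1]]
  cut2 <- x$date[which(cum >= 2 * total / 3)[1]]
  section_partition(season, cut1, cut2, method = "apin")
}
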