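# shared fixture builders; everything is generated in code, no data files

# full-year pollen series with `value` on the given days-of-year, 0 elsewhere
uniform_pollen <- function(year = 2015, days = 1:100, value = 1) {
  all_days <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  conc <- ifelse(seq_along(all_days) %in% days, value, 0)
  pollen_series(all_days, conc)
}

# random non-negative pollen year: a lumpy season plus sparse background
random_pollen <- function(year = 2015) {
  all_days <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(all_days)
  d <- seq_len(n)
  peak <- sample(120:220, 1)
  conc <- sample(c(0, 1), n, replace = TRUE, prob = c(0.8, 0.2)) *
    stats::runif(n, 0, 3) +
    stats::runif(1, 20, 80) * exp(-(d - peak)^2 / (2 * sample(8:25, 1)^2))
  pollen_series(all_days, conc)
}

# a bare season over arbitrary dates (for interval-level tests)
make_season <- function(start, end, year = as.integer(format(as.Date(start), "%Y")),
                        apin = 100) {
  pollendiary:::season_definition(year, as.Date(start), as.Date(end),
                                  apin = apin)
}

# wrap a complete per-user daily score table as an imputed_series
as_imputed <- function(df, season) {
  df <- dplyr::arrange(tibble::as_tibble(df), user_id, date)
  if (!"imputed" %in% names(df)) df$imputed <- FALSE
  attr(df, "season") <- season
  class(df) <- c("imputed_series", class(tibble::tibble()))
  df
}

# wrap observed per-user scores as a user_series
as_series <- function(df, season) {
  df <- dplyr::arrange(tibble::as_tibble(df), user_id, date)
  attr(df, "season") <- season
  class(df) <- c("user_series", class(tibble::tibble()))
  df
}

# assignments tibble with given per-section counts (for table arithmetic)
assignments_from_counts <- function(counts, method = "apin", year = 2015) {
  tibble::tibble(
    user_id = sprintf("u%03d", seq_len(sum(counts))),
    year = year, method = method,
    section = rep(1:3, times = counts)
  )
}
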