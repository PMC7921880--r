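#' Daily total symptom and medication score
#'
#' Weighted sum of the four diary sub-scores. With the default unit weights
#' this is the plain sum of eye, nose and lung severity plus medication use,
#' the daily symptom load used everywhere downstream.
#'
#' @param entries A `diary_entries` tibble (or any data frame with `eye`,
#'   `nose`, `lung`, `medication` columns).
#' @param cfg A [run_config()] supplying the weights.
#' @return Numeric vector, one non-negative score per row.
#' @export
#' @examples
#' d <- diary_entries("u1", "2015-06-01", 3, 3, 3, 1)
#' total_score(d)  # 10
total_score <- function(entries, cfg = run_config()) {
  for (s in c("eye", "nose", "lung", "medication"))
    if (any(entries[[s]] < 0)) stop("negative ", s, " sub-score")
  w <- cfg$score_weights
  as.numeric(w[["eye"]] * entries$eye + w[["nose"]] * entries$nose +
               w[["lung"]] * entries$lung + w[["medication"]] * entries$medication)
}

#' Per-user daily score series within a season
#'
#' Drops diary entries outside the closed season interval, computes the daily
#' total score, and returns one row per user-day. Users without any in-season
#' entry do not appear.
#'
#' @param entries A `diary_entries` tibble.
#' @param season A `season_definition`.
#' @param cfg A [run_config()].
#' @return A `user_series` tibble with columns `user_id`, `date`, `score`;
#'   the season is attached as attribute `"season"`.
#' @export
build_user_series <- function(entries, season, cfg = run_config()) {
  stopifnot(inherits(season, "season_definition"))
  x <- entries[entries$date >= season$start_date &
                 entries$date <= season$end_date, , drop = FALSE]
  out <- tibble::tibble(user_id = x$user_id, date = x$date,
                        score = total_score(x, cfg))
  out <- dplyr::arrange(out, .data$user_id, .data$date)
  attr(out, "season") <- season
  class(out) <- c("user_series", class(out))
  out
}

#' Number of observed days per user
#'
#' @param series A `user_series` tibble.
#' @return Tibble with `user_id` and `n_entries`.
#' @export
n_entries <- function(series) {
  dplyr::count(tibble::as_tibble(series), .data$user_id, name = "n_entries")
}

#' Symptom-pollen correlation for the users of a season
#'
#' For each user, correlates the daily total score with the same-day pollen
#' concentration over that user's observed days (rank correlation by
#' default), with a one-sided p-value for positive association. Users whose
#' score or pollen exposure is constant over their observed days get an
#' undefined correlation (`NA`) and can never pass the filter.
#'
#' @param series A `user_series` tibble from [build_user_series()].
#' @param pollen A [pollen_series()].
#' @param cfg A [run_config()]; `cor_method`, `lag` and `alpha` are used.
#' @return A tibble with one row per user: `user_id`, `coefficient`,
#'   `p_value`, `n`, `method`.
#' @export
correlate_users <- function(series, pollen, cfg = run_config()) {
  season <- attr(series, "season")
  stopifnot(!is.null(season), inherits(pollen, "pollen_series"))
  px <- pollen[pollen$taxon == season$taxon, ]
  conc <- px$concentration[match(series$date - cfg$lag, px$date)]
  df <- data.frame(user_id = series$user_id, score = series$score,
                   conc = conc)
  rows <- lapply(split(df, df$user_id), function(g) {
    r <- correlate_one(g$score, g$conc, cfg)
    tibble::tibble(user_id = g$user_id[1], coefficient = r$estimate,
                   p_value = r$p_value, n = r$n, method = cfg$cor_method)
  })
  dplyr::bind_rows(rows)
}

# one user's test; NA result for constant vectors or n < 3
correlate_one <- function(score, conc, cfg = run_config()) {
  keep <- !is.na(conc)
  score <- score[keep]; conc <- conc[keep]
  n <- length(score)
  if (n < 3 || length(unique(score)) < 2 || length(unique(conc)) < 2)
    return(list(estimate = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(
    cor.test(conc, score, method = cfg$cor_method, alternative = "greater")
  )
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Filter users to grass pollen allergy sufferer profiles
#'
#' Retains a user if and only if the symptom-pollen correlation coefficient
#' is positive, its one-sided p-value is below `cfg$alpha`, and the user has
#' at least `cfg$min_entries` observed days in the season.
#'
#' @inheritParams correlate_users
#' @return The retained rows of `series` (same class and `season` attribute),
#'   with the full per-user correlation table attached as attribute
#'   `"correlations"` (columns as in [correlate_users()] plus logical
#'   `pass`).
#' @export
filter_users <- function(series, pollen, cfg = run_config()) {
  res <- correlate_users(series, pollen, cfg)
  ne <- n_entries(series)
  res <- dplyr::left_join(res, ne, by = "user_id")
  res$pass <- !is.na(res$coefficient) & res$coefficient > 0 &
    !is.na(res$p_value) & res$p_value < cfg$alpha &
    res$n_entries >= cfg$min_entries
  keep <- series$user_id %in% res$user_id[res$pass]
  out <- series[keep, , drop = FALSE]
  attr(out, "season") <- attr(series, "season")
  class(out) <- class(series)
  attr(out, "correlations") <- res
  out
}
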