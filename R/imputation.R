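#' k-nearest-neighbour imputation of missing daily scores
#'
#' Completes each user's daily score series over every day of the season.
#' For a missing day the distance to each observed day is the Gower-style
#' range-normalised Manhattan distance over two variables, the day of the
#' season and the same-day pollen concentration:
#' `|norm(day) - norm(day')| + |norm(c) - norm(c')|`, each variable scaled by
#' its range over the season (a constant variable contributes 0). The imputed
#' score is the median of the `k` nearest observed scores; for even `k` the
#' mean of the two middle order statistics is used. Distance ties are broken
#' by earlier calendar day, then by lower score, so the result is
#' deterministic and independent of input row order.
#'
#' @param series A `user_series` tibble from [build_user_series()] (one or
#'   several users).
#' @param pollen A [pollen_series()] covering the season.
#' @param k Number of neighbours (default 3). Every user must have at least
#'   `k` observed days.
#' @return An `imputed_series` tibble with columns `user_id`, `date`, `score`
#'   and logical `imputed`, covering every season day for every user;
#'   observed days keep their original scores. The `season` attribute is
#'   carried over.
#' @export
knn_impute <- function(series, pollen, k = 3L) {
  season <- attr(series, "season")
  stopifnot(!is.null(season), inherits(pollen, "pollen_series"), k >= 1)
  days <- seq(season$start_date, season$end_date, by = "day")
  px <- pollen[pollen$taxon == season$taxon, ]
  conc <- px$concentration[match(days, px$date)]
  if (anyNA(conc)) stop("pollen series does not cover the season")

  # season-wide range normalisation, shared by all users of this season
  norm_range <- function(v) {
    r <- diff(range(v))
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  day_n <- norm_range(as.numeric(days))
  conc_n <- norm_range(conc)

  impute_user <- function(d, uid) {
    obs_idx <- match(d$date, days)
    if (anyNA(obs_idx)) stop("user ", uid, ": entry outside the season")
    if (length(obs_idx) < k)
      stop("user ", uid, ": only ", length(obs_idx),
           " observed days, need at least k = ", k, " for imputation")
    score <- rep(NA_real_, length(days))
    score[obs_idx] <- d$score
    miss_idx <- which(is.na(score))
    # order observed days once by (date, score) so that after a stable sort
    # on distance, ties fall to the earlier day, then the lower score
    ord <- obs_idx[order(days[obs_idx], score[obs_idx])]
    for (m in miss_idx) {
      dist <- abs(day_n[m] - day_n[ord]) + abs(conc_n[m] - conc_n[ord])
      nn <- ord[sort.list(dist, method = "radix")[seq_len(k)]]
      score[m] <- median_mid(score[nn])
    }
    tibble::tibble(date = days, score = score,
                   imputed = seq_along(days) %in% miss_idx)
  }

  out <- dplyr::group_modify(dplyr::group_by(tibble::as_tibble(series),
                                             .data$user_id),
                             ~ impute_user(.x, .y$user_id))
  out <- dplyr::ungroup(out)
  attr(out, "season") <- season
  class(out) <- c("imputed_series", class(out))
  out
}

# median as middle order statistic(s): exact middle for odd n, mean of the
# two middle values for even n (same as stats::median, kept explicit)
median_mid <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else mean(x[n / 2 + 0:1])
}
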