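#' Partition the season by phenological flowering dates
#'
#' Second partition method: section 2 begins with the earliest flowering
#' onset among the main-season grasses and section 3 with the earliest onset
#' among the late-flowering grasses; each cut date is the day before the next
#' section starts. Section 1 opens at the season start and section 3 closes
#' at the season end, i.e. the partition is clamped to the season interval.
#' The defining taxa of each group come from `cfg$phenology_groups`.
#'
#' @param periods A `phenology_periods` tibble.
#' @param season A `season_definition`.
#' @param cfg A [run_config()].
#' @return A `section_partition` with method `"phenology"`.
#' @export
phenology_partition <- function(periods, season, cfg = run_config()) {
  stopifnot(inherits(periods, "phenology_periods"),
            inherits(season, "season_definition"))
  groups <- cfg$phenology_groups
  onset <- function(group) {
    rows <- periods[periods$taxon %in% groups[[group]], ]
    if (nrow(rows) == 0)
      stop("phenology_partition: no taxa matching the ", group,
           " group (", paste(groups[[group]], collapse = ", "), ")")
    min(rows$flowering_start)
  }
  cut1 <- onset("main") - 1L
  cut2 <- onset("late") - 1L
  tryCatch(
    section_partition(season, cut1, cut2, method = "phenology"),
    error = function(e)
      stop("degenerate phenology partition: main-group onset ", cut1 + 1L,
           ", late-group onset ", cut2 + 1L, " do not fall strictly inside ",
           "the season ", season$start_date, " .. ", season$end_date,
           " in increasing order")
  )
}

#' Per-user symptom-load tertile partition
#'
#' Third partition method, defined separately for every user from the
#' completed (imputed) daily score series: the first cut is the first season
#' day on which the user's cumulative score reaches one third of their total
#' season score, the second cut the first day it reaches two thirds. Each
#' user therefore owns a different partition; users with an all-zero series
#' are rejected.
#'
#' @param imputed An `imputed_series` tibble from [knn_impute()].
#' @return A named list of `section_partition` objects (method `"sli"`),
#'   one per user.
#' @export
sli_tertile_sections <- function(imputed) {
  season <- attr(imputed, "season")
  stopifnot(inherits(imputed, "imputed_series"), !is.null(season))
  one <- function(d, uid) {
    if (any(is.na(d$score))) stop("user ", uid, ": incomplete series")
    total <- sum(d$score)
    if (total <= 0) stop("user ", uid, ": all-zero score series, ",
                         "symptom-load tertiles undefined")
    cum <- cumsum(d$score[order(d$date)])
    cut1 <- sort(d$date)[which(cum >= total / 3)[1]]
    cut2 <- sort(d$date)[which(cum >= 2 * total / 3)[1]]
    tryCatch(
      section_partition(season, cut1, cut2, method = "sli", user_id = uid),
      error = function(e)
        stop("user ", uid, ": degenerate symptom-load partition (cuts ",
             cut1, ", ", cut2, ")")
    )
  }
  ids <- unique(imputed$user_id)
  stats::setNames(
    lapply(ids, function(u) one(imputed[imputed$user_id == u, ], u)),
    ids
  )
}

#' Assign one user-year to the section of peak symptom severity
#'
#' Summarises the user's daily scores within each of the three sections of a
#' partition by the configured severity statistic (mean daily score by
#' default) and returns the argmax section; ties go to the earliest section.
#' For the APIn and phenology partitions the series may be the observed one
#' as long as every section contains at least one observed day (otherwise
#' impute first); for the per-user symptom-load partition the user's own
#' tertile partition and completed series must be supplied, in which case the
#' argmax-of-mean rule picks the segment over which symptom load accumulates
#' fastest (with equal score mass per segment, the shortest one).
#'
#' @param scores Tibble with `date` and `score` for one user-year.
#' @param partition A `section_partition`.
#' @param statistic `"mean"`, `"sum"` or `"peak"` (maximum daily score).
#' @return A list with `section` (1, 2 or 3), `per_section_summary` (numeric
#'   length 3) and `tie` (logical).
#' @export
assign_section <- function(scores, partition, statistic = c("mean", "sum", "peak")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(partition, "section_partition"))
  sec <- section_of(partition, scores$date)
  if (anyNA(sec)) stop("assign_section: scores outside the season")
  f <- switch(statistic, mean = mean, sum = sum, peak = max)
  summ <- vapply(1:3, function(s) {
    v <- scores$score[sec == s]
    if (length(v) == 0) {
      if (statistic == "sum") return(0)
      stop("assign_section: section ", s, " has no observed days; ",
           "impute the series first (knn_impute) or use statistic = \"sum\"")
    }
    f(v)
  }, numeric(1))
  best <- which(summ == max(summ))
  list(section = best[1], per_section_summary = summ, tie = length(best) > 1)
}

#' Classify every user of a cohort under one or all partition methods
#'
#' High-level wrapper running [assign_section()] per user-year. For the
#' `"apin"` and `"phenology"` methods one shared partition is used (built
#' here if not supplied); for `"sli"` each user's own tertile partition is
#' derived from the imputed series.
#'
#' @param series A `user_series` tibble (observed days). Used for the APIn
#'   and phenology methods unless `cfg$impute_all_methods` is set.
#' @param pollen A [pollen_series()].
#' @param methods Character subset of `c("apin", "phenology", "sli")`.
#' @param periods A `phenology_periods` tibble (required for `"phenology"`).
#' @param imputed Optional precomputed `imputed_series`; computed on demand
#'   when the `"sli"` method (or `cfg$impute_all_methods`) needs it.
#' @param cfg A [run_config()].
#' @return A `section_assignments` tibble: `user_id`, `year`, `method`,
#'   `section`, `summary1..3`, `tie`.
#' @export
classify_cohort <- function(series, pollen, methods = c("apin", "phenology", "sli"),
                            periods = NULL, imputed = NULL, cfg = run_config()) {
  season <- attr(series, "season")
  stopifnot(!is.null(season))
  methods <- match.arg(methods, several.ok = TRUE)
  need_imp <- "sli" %in% methods || cfg$impute_all_methods
  if (need_imp && is.null(imputed)) imputed <- knn_impute(series, pollen, cfg$k)

  rows <- list()
  add <- function(uid, method, a) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      user_id = uid, year = season$year, method = method,
      section = a$section, summary1 = a$per_section_summary[1],
      summary2 = a$per_section_summary[2], summary3 = a$per_section_summary[3],
      tie = a$tie)
  }

  base <- if (cfg$impute_all_methods) imputed else series
  for (method in intersect(methods, c("apin", "phenology"))) {
    part <- if (method == "apin") apin_tertile_partition(pollen, season)
            else {
              if (is.null(periods)) stop("phenology method needs `periods`")
              phenology_partition(periods, season, cfg)
            }
    for (uid in unique(base$user_id))
      add(uid, method,
          assign_section(base[base$user_id == uid, ], part, cfg$statistic))
  }
  if ("sli" %in% methods) {
    parts <- sli_tertile_sections(imputed)
    for (uid in names(parts))
      add(uid, "sli",
          assign_section(imputed[imputed$user_id == uid, ], parts[[uid]], "mean"))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("section_assignments", class(out))
  out
}

#' One-way ANOVA of daily scores across season sections
#'
#' Confirmatory fixed-effects analysis of variance of daily scores grouped by
#' the section of their date, with 2 and n - 3 degrees of freedom. Supply the
#' pooled day-rows of one user or of a whole cohort. If all scores are
#' identical the F statistic is undefined and the result is flagged
#' degenerate.
#'
#' @param scores Tibble with `date` and `score` (one or more users' rows).
#' @param partition A `section_partition`.
#' @return A list: `f_statistic`, `p_value`, `df_between` (2), `df_within`,
#'   `degenerate`.
#' @export
anova_sections <- function(scores, partition) {
  stopifnot(inherits(partition, "section_partition"))
  sec <- factor(section_of(partition, scores$date), levels = 1:3)
  if (anyNA(sec)) stop("anova_sections: scores outside the season")
  n_per <- table(sec)
  if (any(n_per < 2))
    stop("anova_sections: need at least 2 days per section, got ",
         paste(n_per, collapse = "/"))
  res <- tryCatch(
    oneway.test(scores$score ~ sec, var.equal = TRUE),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$statistic))
    return(list(f_statistic = NA_real_, p_value = NA_real_,
                df_between = 2L, df_within = nrow(scores) - 3L,
                degenerate = TRUE))
  list(f_statistic = unname(res$statistic), p_value = res$p.value,
       df_between = 2L, df_within = as.integer(unname(res$parameter[2])),
       degenerate = FALSE)
}
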