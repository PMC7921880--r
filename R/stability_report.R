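#' Count-and-percentage table of section assignments
#'
#' Tallies how many classified user-years fall into each of the three season
#' sections under one method, pooled over all years in the assignments or
#' restricted to a single year, with percentages rounded half-up to one
#' decimal.
#'
#' @param assignments A `section_assignments` tibble from
#'   [classify_cohort()] (or any tibble with `user_id`, `year`, `method`,
#'   `section`).
#' @param method One of `"apin"`, `"phenology"`, `"sli"`.
#' @param scope `"pooled"` (default) or a single year.
#' @return A `section_table`: tibble with `section`, `count`, `percentage`;
#'   total classified user-years as attribute `"total"`.
#' @export
section_table <- function(assignments, method = c("apin", "phenology", "sli"),
                          scope = "pooled") {
  method <- match.arg(method)
  x <- assignments[assignments$method == method, ]
  if (!identical(scope, "pooled")) x <- x[x$year == scope, ]
  if (nrow(x) == 0) stop("section_table: no assignments for method ", method,
                         " in scope ", scope)
  counts <- vapply(1:3, function(s) sum(x$section == s), integer(1))
  out <- tibble::tibble(
    section = 1:3, count = counts,
    percentage = round_half_up(100 * counts / sum(counts), 1)
  )
  attr(out, "total") <- sum(counts)
  attr(out, "method") <- method
  attr(out, "scope") <- scope
  class(out) <- c("section_table", class(out))
  out
}

#' Cross-year stability of user profiles
#'
#' Considers only users classified in every year present in `assignments`
#' (under the given method) and sorts them into three stability classes:
#' the same section in all years (a robust profile), the same section in all
#' but one year, or a different section every year. Also reports whether any
#' such user was ever assigned to both the first and the third section -
#' i.e. whether a section change ever skipped the middle section.
#'
#' @inheritParams section_table
#' @return A `stability_summary` list: `n_users_all_years`, `same_all_years`,
#'   `same_two_of_three`, `variable_all_years`, `nonadjacent_pairs_present`,
#'   `percentages` (integer, round-half-up, named same/two/variable), and
#'   `per_user` (tibble of the yearly labels and class per user).
#' @export
stability <- function(assignments, method = c("apin", "phenology", "sli")) {
  method <- match.arg(method)
  x <- assignments[assignments$method == method, ]
  years <- sort(unique(assignments$year))
  if (length(years) < 2) stop("stability: need assignments from >= 2 years")
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$user_id),
    n_years = dplyr::n_distinct(.data$year),
    n_sections = dplyr::n_distinct(.data$section),
    has1 = any(.data$section == 1), has3 = any(.data$section == 3),
    labels = paste(.data$section[order(.data$year)], collapse = ""),
    .groups = "drop"
  )
  tab <- tab[tab$n_years == length(years), ]
  if (nrow(tab) == 0) stop("stability: no user classified in all years")
  tab$class <- ifelse(tab$n_sections == 1, "same_all",
                      ifelse(tab$n_sections == length(years), "variable",
                             "same_two"))
  n <- nrow(tab)
  counts <- c(same = sum(tab$class == "same_all"),
              two = sum(tab$class == "same_two"),
              variable = sum(tab$class == "variable"))
  structure(
    list(n_users_all_years = n,
         same_all_years = unname(counts["same"]),
         same_two_of_three = unname(counts["two"]),
         variable_all_years = unname(counts["variable"]),
         nonadjacent_pairs_present = any(tab$has1 & tab$has3),
         percentages = round_half_up(100 * counts / n, 0),
         per_user = tab[c("user_id", "labels", "class")]),
    class = "stability_summary"
  )
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("<stability over %d users present in all years>\n",
              x$n_users_all_years))
  cat(sprintf("  same section every year: %d (%d%%)\n", x$same_all_years,
              x$percentages[["same"]]))
  cat(sprintf("  same in all but one year: %d (%d%%)\n", x$same_two_of_three,
              x$percentages[["two"]]))
  cat(sprintf("  different every year: %d (%d%%)\n", x$variable_all_years,
              x$percentages[["variable"]]))
  cat("  section changes skipping the middle section:",
      if (x$nonadjacent_pairs_present) "present" else "none", "\n")
  invisible(x)
}

#' Cumulative symptom-load versus cumulative pollen profile curves
#'
#' For every user-year, plots (as data) the fraction of the user's total
#' season symptom load accumulated by each day against the fraction of the
#' season APIn accumulated by the same day. Both coordinates rise from near
#' (0, 0) to exactly (1, 1) at the season end. The pointwise mean curve over
#' all users is returned alongside; a user whose curve lies above the mean
#' at mid-APIn (x = 0.5) is flagged a fast reactor, below it a slow reactor.
#'
#' @param imputed An `imputed_series` tibble (complete daily scores).
#' @param pollen A [pollen_series()].
#' @param assignments Optional `section_assignments` used to attach each
#'   user's assigned section to their curve (method `"sli"` rows preferred,
#'   else the first method present).
#' @return A `profile_curves` list: `curves` (tibble `user_id`, `date`,
#'   `cum_apin_fraction`, `cum_sli_fraction`, `section`), `mean_curve`, and
#'   `reactors` (tibble `user_id`, `reactor` in fast/slow).
#' @export
profile_curves <- function(imputed, pollen, assignments = NULL) {
  season <- attr(imputed, "season")
  stopifnot(inherits(imputed, "imputed_series"), !is.null(season))
  days <- seq(season$start_date, season$end_date, by = "day")
  px <- pollen[pollen$taxon == season$taxon, ]
  conc <- px$concentration[match(days, px$date)]
  if (anyNA(conc)) stop("pollen series does not cover the season")
  x_frac <- cumsum(conc) / sum(conc)

  one <- function(d, uid) {
    d <- d[order(d$date), ]
    total <- sum(d$score)
    if (total <= 0) return(NULL)
    tibble::tibble(date = days, cum_apin_fraction = x_frac,
                   cum_sli_fraction = cumsum(d$score) / total)
  }
  ids <- unique(imputed$user_id)
  curves <- list()
  for (u in ids) {
    cu <- one(imputed[imputed$user_id == u, ], u)
    if (is.null(cu)) {
      warning("profile_curves: user ", u, " has zero total score, excluded")
      next
    }
    cu$user_id <- u
    curves[[u]] <- cu
  }
  if (length(curves) == 0) stop("profile_curves: no user with positive total")
  curves <- dplyr::bind_rows(curves)

  mean_curve <- dplyr::summarise(
    dplyr::group_by(curves, .data$date),
    cum_apin_fraction = .data$cum_apin_fraction[1],
    cum_sli_fraction = mean(.data$cum_sli_fraction),
    .groups = "drop"
  )
  # fast/slow reactors judged at the first day reaching mid-APIn
  i_half <- which(x_frac >= 0.5)[1]
  mid <- curves[curves$date == days[i_half], ]
  reactors <- tibble::tibble(
    user_id = mid$user_id,
    reactor = ifelse(mid$cum_sli_fraction >
                       mean_curve$cum_sli_fraction[i_half], "fast", "slow")
  )
  if (!is.null(assignments)) {
    a <- assignments[assignments$year == season$year, ]
    m <- if ("sli" %in% a$method) "sli" else a$method[1]
    a <- a[a$method == m, c("user_id", "section")]
    curves <- dplyr::left_join(curves, a, by = "user_id")
  }
  structure(list(curves = curves, mean_curve = mean_curve,
                 reactors = reactors, season = season),
            class = "profile_curves")
}

#' Plot profile curves
#'
#' Draws every user's cumulative symptom-load-versus-cumulative-pollen curve
#' coloured by assigned section (when available), with the cohort mean curve
#' in black.
#'
#' @param x A `profile_curves` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_profile_curves <- function(x, ...) {
  stopifnot(inherits(x, "profile_curves"))
  cu <- x$curves
  aes_line <- if ("section" %in% names(cu))
    ggplot2::aes(.data$cum_apin_fraction, .data$cum_sli_fraction,
                 group = .data$user_id, colour = factor(.data$section))
  else
    ggplot2::aes(.data$cum_apin_fraction, .data$cum_sli_fraction,
                 group = .data$user_id)
  ggplot2::ggplot(cu, aes_line) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_line(
      data = x$mean_curve,
      ggplot2::aes(.data$cum_apin_fraction, .data$cum_sli_fraction),
      inherit.aes = FALSE, linewidth = 1, colour = "black") +
    ggplot2::labs(x = "cumulative APIn fraction",
                  y = "cumulative symptom load fraction",
                  colour = "section",
                  title = sprintf("Symptom accumulation profiles, %d",
                                  x$season$year)) +
    ggplot2::theme_minimal()
}
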