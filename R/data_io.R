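#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline: the sub-score weights and
#' maxima that define the daily total symptom + medication score, the
#' correlation filter settings, the imputation neighbourhood size, the
#' severity statistic used for section assignment, and the phenology taxon
#' groups defining the early / main / late flowering grasses.
#'
#' @param score_weights Named numeric weights for the four diary sub-scores,
#'   in the order `eye`, `nose`, `lung`, `medication`. Default all 1 (the
#'   total score is the plain sum).
#' @param score_maxima Named integer maxima for the four sub-scores. Default
#'   `c(eye = 3, nose = 3, lung = 3, medication = 1)`, a 0-10 total score.
#' @param cor_method Correlation used by the user filter, `"spearman"`
#'   (default; rank correlation is robust to the saturation plateau of the
#'   dose-response) or `"pearson"`.
#' @param alpha One-sided significance level of the filter, in (0, 1).
#'   Default 0.05.
#' @param lag Days by which pollen is shifted before correlating (0 = same-day
#'   pairing, the default; positive values pair today's symptoms with pollen
#'   `lag` days earlier). Exposed for sensitivity analysis only.
#' @param min_entries Minimum number of in-season diary days a user must have
#'   to be retained. Default 15.
#' @param k Number of neighbours for k-nearest-neighbour imputation.
#'   Default 3.
#' @param statistic Per-section severity summary used for section assignment:
#'   `"mean"` (default), `"sum"` or `"peak"` (maximum daily score).
#' @param phenology_groups Named list with character vectors `early`, `main`
#'   and `late` giving the grass taxa whose flowering onsets delimit the
#'   phenological sections. Defaults to the common central-European grouping
#'   (early: Poa pratensis, Dactylis glomerata; main: Arrhenatherum elatius,
#'   Festuca sp., Lolium perenne; late: Phleum pratense, Cynodon dactylon).
#' @param impute_all_methods If `TRUE`, classification under the APIn and
#'   phenology partitions also uses the imputed series; by default only the
#'   per-user symptom-load tertile method requires (and uses) imputation.
#' @param seed Optional integer seed recorded in the configuration.
#'
#' @return An object of class `run_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config(alpha = 0.01, min_entries = 20)
#' cfg$alpha
run_config <- function(score_weights = c(eye = 1, nose = 1, lung = 1, medication = 1),
                       score_maxima = c(eye = 3, nose = 3, lung = 3, medication = 1),
                       cor_method = c("spearman", "pearson"),
                       alpha = 0.05,
                       lag = 0L,
                       min_entries = 15L,
                       k = 3L,
                       statistic = c("mean", "sum", "peak"),
                       phenology_groups = list(
                         early = c("Poa pratensis", "Dactylis glomerata"),
                         main  = c("Arrhenatherum elatius", "Festuca sp.", "Lolium perenne"),
                         late  = c("Phleum pratense", "Cynodon dactylon")
                       ),
                       impute_all_methods = FALSE,
                       seed = NULL) {
  cor_method <- match.arg(cor_method)
  statistic <- match.arg(statistic)
  sub <- c("eye", "nose", "lung", "medication")
  stopifnot(
    length(score_weights) == 4, length(score_maxima) == 4,
    all(score_weights >= 0), all(score_maxima >= 1)
  )
  names(score_weights) <- names(score_weights) %||% sub
  names(score_maxima) <- names(score_maxima) %||% sub
  if (!all(sub %in% names(score_weights)) || !all(sub %in% names(score_maxima)))
    stop("score_weights and score_maxima must be named eye, nose, lung, medication")
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be a single number in (0, 1)")
  if (!(length(k) == 1 && k >= 1)) stop("k must be >= 1")
  if (!(length(min_entries) == 1 && min_entries >= 1)) stop("min_entries must be >= 1")
  if (!all(c("early", "main", "late") %in% names(phenology_groups)))
    stop("phenology_groups must name early, main and late taxa")
  structure(
    list(
      score_weights = score_weights[sub], score_maxima = score_maxima[sub],
      cor_method = cor_method, alpha = alpha, lag = as.integer(lag),
      min_entries = as.integer(min_entries), k = as.integer(k),
      statistic = statistic, phenology_groups = phenology_groups,
      impute_all_methods = isTRUE(impute_all_methods),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Any field of [run_config()] may appear in the file; missing fields take
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  for (f in c("score_weights", "score_maxima"))
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  score weights:", paste(names(x$score_weights), x$score_weights,
                                sep = "=", collapse = " "), "\n")
  cat("  filter:", x$cor_method, "one-sided, alpha =", x$alpha,
      ", min entries =", x$min_entries, "\n")
  cat("  imputation k =", x$k, "; assignment statistic =", x$statistic, "\n")
  invisible(x)
}

# ---- pollen series ---------------------------------------------------------

#' Construct a daily pollen series
#'
#' A `pollen_series` is a tibble with columns `date` (class `Date`), `taxon`
#' and `concentration` (daily mean grains/m3, non-negative), sorted by date,
#' with no duplicate taxon-day and a `station_id` attribute.
#'
#' @param date Vector of dates (`Date` or ISO-8601 strings).
#' @param concentration Non-negative numeric, daily mean grains/m3.
#' @param taxon Taxon name, recycled if scalar. Default `"Poaceae"`.
#' @param station_id Identifier of the pollen monitoring station.
#' @return A `pollen_series` tibble.
#' @export
#' @examples
#' ps <- pollen_series(as.Date("2015-05-01") + 0:4, c(3, 10, 25, 12, 4))
#' ps
pollen_series <- function(date, concentration, taxon = "Poaceae",
                          station_id = "station") {
  date <- as.Date(date)
  x <- tibble::tibble(date = date, taxon = as.character(taxon),
                      concentration = as.numeric(concentration))
  x <- dplyr::arrange(x, .data$taxon, .data$date)
  validate_pollen_series(x)
  attr(x, "station_id") <- station_id
  class(x) <- c("pollen_series", class(x))
  x
}

validate_pollen_series <- function(x) {
  if (anyNA(x$date)) stop("pollen series: unparseable date at row ",
                          which(is.na(x$date))[1])
  if (anyNA(x$concentration)) stop("pollen series: missing concentration at row ",
                                   which(is.na(x$concentration))[1])
  neg <- which(x$concentration < 0)
  if (length(neg)) stop("pollen series: negative concentration at row ", neg[1],
                        " (", x$concentration[neg[1]], ")")
  dup <- which(duplicated(x[c("taxon", "date")]))
  if (length(dup)) stop("pollen series: duplicate date ", x$date[dup[1]],
                        " for taxon ", x$taxon[dup[1]])
  invisible(x)
}

#' Read / write a daily pollen CSV
#'
#' The file must have a header with columns `date` (ISO-8601), `taxon` and
#' `concentration`; an optional `station_id` column is honoured. Rows are
#' validated (parseable dates, non-negative concentrations, no duplicate
#' taxon-days) and returned sorted by taxon and date, so
#' `write_pollen_csv(read_pollen_csv(f))` is the canonical form of `f`.
#'
#' @param path File path.
#' @return `read_pollen_csv()` returns a [pollen_series()];
#'   `write_pollen_csv()` returns `path` invisibly.
#' @export
read_pollen_csv <- function(path) {
  raw <- read_checked_csv(path, c("date", "taxon", "concentration"))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("pollen CSV ", path, ": malformed date '", raw$date[which(is.na(dates))[1]],
         "' at line ", which(is.na(dates))[1] + 1L)
  conc <- suppressWarnings(as.numeric(raw$concentration))
  if (anyNA(conc))
    stop("pollen CSV ", path, ": non-numeric concentration at line ",
         which(is.na(conc))[1] + 1L)
  pollen_series(dates, conc, taxon = raw$taxon,
                station_id = if ("station_id" %in% names(raw))
                  raw$station_id[1] else "station")
}

#' @param x A `pollen_series`.
#' @rdname read_pollen_csv
#' @export
write_pollen_csv <- function(x, path) {
  stopifnot(inherits(x, "pollen_series"))
  out <- data.frame(date = format(x$date, "%Y-%m-%d"), taxon = x$taxon,
                    concentration = x$concentration)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- diary entries ---------------------------------------------------------

#' Construct and validate diary entries
#'
#' One row per user-day with the four sub-scores of the hay-fever diary
#' (eyes, nose, lungs, medication use). `(user_id, date)` pairs must be
#' unique and every sub-score must lie in `[0, maximum]` for the configured
#' maxima.
#'
#' @param user_id Character vector of opaque user identifiers.
#' @param date Dates (`Date` or ISO strings).
#' @param eye,nose,lung,medication Integer sub-scores.
#' @param zip_code Optional character vector.
#' @param cfg A [run_config()]; supplies the sub-score maxima.
#' @return A `diary_entries` tibble.
#' @export
diary_entries <- function(user_id, date, eye, nose, lung, medication,
                          zip_code = NULL, cfg = run_config()) {
  x <- tibble::tibble(
    user_id = as.character(user_id), date = as.Date(date),
    eye = as.integer(eye), nose = as.integer(nose),
    lung = as.integer(lung), medication = as.integer(medication)
  )
  if (!is.null(zip_code)) x$zip_code <- as.character(zip_code)
  validate_diary(x, cfg)
  x <- dplyr::arrange(x, .data$user_id, .data$date)
  class(x) <- c("diary_entries", class(x))
  x
}

validate_diary <- function(x, cfg) {
  if (anyNA(x$date)) stop("diary: unparseable date at row ", which(is.na(x$date))[1])
  dup <- which(duplicated(x[c("user_id", "date")]))
  if (length(dup)) stop("diary: duplicate entry for user ", x$user_id[dup[1]],
                        " on ", x$date[dup[1]])
  for (s in c("eye", "nose", "lung", "medication")) {
    v <- x[[s]]
    if (anyNA(v)) stop("diary: missing ", s, " score at row ", which(is.na(v))[1])
    bad <- which(v < 0 | v > cfg$score_maxima[[s]])
    if (length(bad))
      stop("diary: ", s, " score ", v[bad[1]], " out of range [0, ",
           cfg$score_maxima[[s]], "] at row ", bad[1],
           " (user ", x$user_id[bad[1]], ", ", x$date[bad[1]], ")")
  }
  invisible(x)
}

#' Read / write a diary CSV
#'
#' Expected columns: `user_id`, `date`, `eye`, `nose`, `lung`, `medication`
#' and optionally `zip_code`. Duplicate user-days and out-of-range sub-scores
#' are rejected with the offending line reported.
#'
#' @param path File path.
#' @param cfg A [run_config()] supplying the sub-score maxima.
#' @return `read_diary_csv()` returns a `diary_entries` tibble.
#' @export
read_diary_csv <- function(path, cfg = run_config()) {
  raw <- read_checked_csv(path, c("user_id", "date", "eye", "nose", "lung",
                                  "medication"))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("diary CSV ", path, ": malformed date '", raw$date[which(is.na(dates))[1]],
         "' at line ", which(is.na(dates))[1] + 1L)
  diary_entries(raw$user_id, dates, raw$eye, raw$nose, raw$lung, raw$medication,
                zip_code = raw[["zip_code"]], cfg = cfg)
}

#' @param x A `diary_entries` tibble.
#' @rdname read_diary_csv
#' @export
write_diary_csv <- function(x, path) {
  stopifnot(inherits(x, "diary_entries"))
  out <- as.data.frame(x)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- phenology -------------------------------------------------------------

#' Construct flowering periods
#'
#' One row per grass taxon with the four dates delimiting its pollination
#' period: flowering start, start and end of full flowering, and flowering
#' end. The dates must be non-decreasing in that order.
#'
#' @param taxon Character vector of taxon names.
#' @param flowering_start,full_start,full_end,flowering_end Dates.
#' @return A `phenology_periods` tibble.
#' @export
phenology_periods <- function(taxon, flowering_start, full_start, full_end,
                              flowering_end) {
  x <- tibble::tibble(
    taxon = as.character(taxon),
    flowering_start = as.Date(flowering_start),
    full_start = as.Date(full_start),
    full_end = as.Date(full_end),
    flowering_end = as.Date(flowering_end)
  )
  validate_phenology(x)
  class(x) <- c("phenology_periods", class(x))
  x
}

validate_phenology <- function(x) {
  for (col in c("flowering_start", "full_start", "full_end", "flowering_end"))
    if (anyNA(x[[col]])) stop("phenology: unparseable ", col, " at row ",
                              which(is.na(x[[col]]))[1])
  ok <- x$flowering_start <= x$full_start & x$full_start <= x$full_end &
    x$full_end <= x$flowering_end
  if (any(!ok))
    stop("phenology: dates out of order for taxon ", x$taxon[which(!ok)[1]],
         " at row ", which(!ok)[1])
  invisible(x)
}

#' Read / write a phenology CSV
#'
#' Expected columns: `taxon`, `flowering_start`, `full_start`, `full_end`,
#' `flowering_end` (ISO-8601 dates). If a source reports calendar weeks
#' rather than dates, convert using the Monday of the ISO week before
#' writing the file (see [iso_week_monday()]).
#'
#' @param path File path.
#' @return `read_phenology_csv()` returns a `phenology_periods` tibble.
#' @export
read_phenology_csv <- function(path) {
  raw <- read_checked_csv(path, c("taxon", "flowering_start", "full_start",
                                  "full_end", "flowering_end"))
  cols <- lapply(raw[-1], function(v) {
    d <- as.Date(v, format = "%Y-%m-%d")
    if (anyNA(d)) stop("phenology CSV ", path, ": malformed date '",
                       v[which(is.na(d))[1]], "' at line ", which(is.na(d))[1] + 1L)
    d
  })
  phenology_periods(raw$taxon, cols$flowering_start, cols$full_start,
                    cols$full_end, cols$flowering_end)
}

#' @param x A `phenology_periods` tibble.
#' @rdname read_phenology_csv
#' @export
write_phenology_csv <- function(x, path) {
  stopifnot(inherits(x, "phenology_periods"))
  out <- as.data.frame(x)
  for (col in c("flowering_start", "full_start", "full_end", "flowering_end"))
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monday of an ISO calendar week
#'
#' Helper for phenology sources that report flowering periods as ISO calendar
#' weeks: returns the date of the Monday opening ISO week `week` of `year`.
#'
#' @param year Integer year.
#' @param week Integer ISO week number (1-53).
#' @return A `Date` vector.
#' @export
#' @examples
#' iso_week_monday(2015, 22)
iso_week_monday <- function(year, week) {
  stopifnot(all(week >= 1), all(week <= 53))
  # ISO 8601: week 1 contains Jan 4; weeks start on Monday
  jan4 <- as.Date(sprintf("%d-01-04", year))
  wd <- as.integer(strftime(jan4, "%u"))  # 1 = Monday
  jan4 - (wd - 1L) + (as.integer(week) - 1L) * 7L
}

# shared CSV reader: header check + line-aware errors
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("CSV ", path, ": missing column(s) ", paste(missing, collapse = ", "))
  raw
}
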