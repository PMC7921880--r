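test_that("phenology cuts sit the day before each group's earliest onset", {
  s <- make_season("2015-05-01", "2015-07-31")
  phen <- phenology_periods(
    taxon = c("Poa pratensis", "Dactylis glomerata", "Arrhenatherum elatius",
              "Festuca sp.", "Lolium perenne", "Phleum pratense",
              "Cynodon dactylon"),
    flowering_start = as.Date(c("2015-04-25", "2015-05-02", "2015-06-01",
                                "2015-06-05", "2015-06-10", "2015-07-01",
                                "2015-07-05")),
    full_start = as.Date(c("2015-05-05", "2015-05-10", "2015-06-10",
                           "2015-06-12", "2015-06-18", "2015-07-08",
                           "2015-07-12")),
    full_end = as.Date(c("2015-05-20", "2015-05-25", "2015-06-20",
                         "2015-06-22", "2015-06-28", "2015-07-18",
                         "2015-07-20")),
    flowering_end = as.Date(c("2015-06-01", "2015-06-05", "2015-06-30",
                              "2015-07-02", "2015-07-08", "2015-07-28",
                              "2015-07-30")))
  p <- phenology_partition(phen, s)
  sec <- sections(p)
  expect_equal(sec$start, as.Date(c("2015-05-01", "2015-06-01", "2015-07-01")))
  expect_equal(sec$end, as.Date(c("2015-05-31", "2015-06-30", "2015-07-31")))

  # sections tile the season in order
  all_days <- seq(s$start_date, s$end_date, by = "day")
  lab <- section_of(p, all_days)
  expect_false(anyNA(lab))
  expect_true(all(diff(lab) >= 0))

  # a late group flowering before the main group is rejected
  cfg_swapped <- run_config(phenology_groups = list(
    early = "Poa pratensis", main = "Phleum pratense",
    late = "Arrhenatherum elatius"))
  expect_error(phenology_partition(phen, s, cfg_swapped), "degenerate")
  # an unmatched group is a configuration error
  cfg_missing <- run_config(phenology_groups = list(
    early = "Poa pratensis", main = "No such grass", late = "Phleum pratense"))
  expect_error(phenology_partition(phen, s, cfg_missing), "no taxa matching")
})

test_that("symptom-load tertile cuts land at thirds of the cumulative score", {
  s <- make_season("2015-06-01", "2015-06-30")
  days <- seq(s$start_date, s$end_date, by = "day")
  imp <- as_imputed(data.frame(user_id = "u1", date = days, score = 1), s)
  parts <- sli_tertile_sections(imp)
  p <- parts[["u1"]]
  expect_equal(p$cut1, s$start_date + 9)   # day 10
  expect_equal(p$cut2, s$start_date + 19)  # day 20

  # all score mass on the final day: no valid tertile split
  late <- as_imputed(data.frame(user_id = "u1", date = days,
                                score = c(rep(0, 29), 9)), s)
  expect_error(sli_tertile_sections(late), "degenerate")
  zero <- as_imputed(data.frame(user_id = "u1", date = days, score = 0), s)
  expect_error(sli_tertile_sections(zero), "all-zero")
})

test_that("random tertile cuts match a brute-force cumulative scan", {
  s <- make_season("2015-05-01", "2015-07-19")
  days <- seq(s$start_date, s$end_date, by = "day")
  set.seed(41)
  for (i in 1:50) {
    score <- sample(0:8, length(days), TRUE)
    imp <- as_imputed(data.frame(user_id = "u1", date = days, score = score), s)
    p <- tryCatch(sli_tertile_sections(imp)[["u1"]],
                  error = function(e) NULL)
    cum <- cumsum(score); total <- sum(score)
    i1 <- which(cum >= total / 3)[1]; i2 <- which(cum >= 2 * total / 3)[1]
    if (is.null(p)) {
      # only degenerate when the scanned cuts collide with each other/the end
      expect_true(i1 == i2 || i2 == length(days))
      next
    }
    expect_equal(p$cut1, days[i1])
    expect_equal(p$cut2, days[i2])
    expect_true(cum[i1] >= total / 3 && (i1 == 1 || cum[i1 - 1] < total / 3))
    expect_true(cum[i2] >= 2 * total / 3 && cum[i2 - 1] < 2 * total / 3)
    # discreteness bound: each segment carries a third of the mass up to
    # one day's score
    seg_mass <- c(cum[i1], cum[i2] - cum[i1], total - cum[i2])
    expect_true(all(abs(seg_mass - total / 3) <= max(score)))
  }
})

test_that("users are assigned to the argmax section with earliest-tie-break", {
  s <- make_season("2015-05-01", "2015-07-29")  # 90 days
  p <- section_partition(s, s$start_date + 29, s$start_date + 59)
  days <- seq(s$start_date, s$end_date, by = "day")

  # support only in section 2
  sc <- ifelse(section_of(p, days) == 2, 5, 0)
  a <- assign_section(data.frame(date = days, score = sc), p, "mean")
  expect_equal(a$section, 2)
  expect_equal(a$per_section_summary, c(0, 5, 0))

  # constant scores over equal-length sections: tie broken to section 1
  a2 <- assign_section(data.frame(date = days, score = 3), p, "mean")
  expect_equal(a2$section, 1)
  expect_true(a2$tie)

  # positive rescaling never changes the assignment
  set.seed(42)
  sc3 <- runif(length(days), 0, 8)
  a3 <- assign_section(data.frame(date = days, score = sc3), p)
  a3x <- assign_section(data.frame(date = days, score = sc3 * 17), p)
  expect_equal(a3$section, a3x$section)

  # an empty section under the mean statistic asks for imputation
  few <- data.frame(date = days[1:10], score = 1:10)
  expect_error(assign_section(few, p, "mean"), "impute")
  expect_equal(assign_section(few, p, "sum")$section, 1)
})

test_that("noise-free full-adherence cohorts are recovered perfectly", {
  ps <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
  s <- define_season(ps, 2015)
  part <- apin_tertile_partition(ps, s)
  users <- gen_user_specs(30, ps, part, seed = 2, noise_sd = 0, adherence = 1)
  coh <- gen_cohort(users, ps, part, seed = 3)
  ser <- build_user_series(coh$entries, s)
  truth <- coh$truth$users

  # phenology table whose section boundaries coincide with the generating
  # partition (well separated sections)
  onset <- c(s$start_date, part$cut1 + 1, part$cut2 + 1)
  phen <- phenology_periods(
    c("Poa pratensis", "Arrhenatherum elatius", "Phleum pratense"),
    onset, onset + 5, onset + 15, onset + 25)

  asn <- classify_cohort(ser, ps, methods = c("apin", "phenology"),
                         periods = phen)
  m <- merge(asn, truth, by = "user_id")
  for (meth in c("apin", "phenology")) {
    rec <- with(m[m$method == meth, ], mean(section == true_section))
    expect_equal(rec, 1, label = paste(meth, "recovery"))
  }
})

test_that("the per-user tertile assignment picks the fastest-accumulating segment", {
  ps <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
  s <- define_season(ps, 2015)
  part <- apin_tertile_partition(ps, s)
  users <- gen_user_specs(30, ps, part, seed = 2, noise_sd = 0, adherence = 1)
  coh <- gen_cohort(users, ps, part, seed = 3)
  ser <- build_user_series(coh$entries, s)
  imp <- knn_impute(ser, ps)
  parts <- sli_tertile_sections(imp)
  asn <- classify_cohort(ser, ps, methods = "sli", imputed = imp)
  for (i in seq_len(nrow(asn))) {
    u <- asn$user_id[i]
    seg <- sections(parts[[u]])
    len <- season_duration(seg$start, seg$end)
    summ <- unlist(asn[i, c("summary1", "summary2", "summary3")])
    # argmax of the mean daily score, ties to the earliest segment
    expect_equal(asn$section[i], unname(which.max(summ)))
    # segments carry near-equal mass, so the densest is never the longest
    expect_true(len[asn$section[i]] <= max(len))
  }
})

test_that("one-way ANOVA of section scores matches the textbook formula", {
  s <- make_season("2015-05-01", "2015-07-29")
  p <- section_partition(s, s$start_date + 29, s$start_date + 59)
  days <- seq(s$start_date, s$end_date, by = "day")

  # equal group means give F = 0
  eq <- data.frame(date = days, score = rep(c(1, 2, 3), 30))
  r0 <- anova_sections(eq, p)
  expect_equal(r0$f_statistic, 0, tolerance = 1e-12)
  expect_equal(r0$df_between, 2L)
  expect_equal(r0$df_within, 87L)

  # identical values everywhere: no variance to analyse
  rdeg <- anova_sections(data.frame(date = days, score = 4), p)
  expect_true(rdeg$degenerate)

  # random data against the between/within mean-square arithmetic
  set.seed(43)
  for (i in 1:10) {
    score <- rnorm(length(days), mean = section_of(p, days))
    r <- anova_sections(data.frame(date = days, score = score), p)
    g <- split(score, section_of(p, days))
    nj <- lengths(g); mj <- vapply(g, mean, 0); gm <- mean(score)
    ssb <- sum(nj * (mj - gm)^2); ssw <- sum(unlist(lapply(g, function(v)
      sum((v - mean(v))^2))))
    f_manual <- (ssb / 2) / (ssw / (length(days) - 3))
    expect_equal(r$f_statistic, f_manual, tolerance = 1e-10)
    expect_equal(r$p_value, stats::pf(f_manual, 2, length(days) - 3,
                                      lower.tail = FALSE), tolerance = 1e-10)
  }

  # fewer than two days in a section is an error
  expect_error(anova_sections(data.frame(date = days[c(1, 2, 31, 32, 61)],
                                         score = 1:5), p),
               "at least 2 days per section")
})
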