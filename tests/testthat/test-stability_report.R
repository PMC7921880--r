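test_that("section tables reproduce count-to-percentage arithmetic", {
  t1 <- section_table(assignments_from_counts(c(58, 161, 48)), "apin")
  expect_equal(t1$count, c(58, 161, 48))
  expect_equal(t1$percentage, c(21.7, 60.3, 18.0))
  expect_equal(attr(t1, "total"), 267L)

  t2 <- section_table(assignments_from_counts(c(16, 52, 6), method = "phenology",
                                              year = 2016),
                      "phenology", scope = 2016)
  expect_equal(t2$percentage, c(21.6, 70.3, 8.1))

  t3 <- section_table(assignments_from_counts(c(1, 0, 0)), "apin")
  expect_equal(t3$percentage, c(100.0, 0.0, 0.0))

  expect_error(section_table(assignments_from_counts(c(1, 0, 0)), "sli"),
               "no assignments")
})

test_that("section-table percentages always sum to about 100", {
  set.seed(51)
  for (i in 1:25) {
    counts <- c(sample(0:200, 2), sample(1:200, 1))
    tt <- section_table(assignments_from_counts(counts), "apin")
    expect_lt(abs(sum(tt$percentage) - 100), 0.2)
  }
})

test_that("cross-year stability reproduces the 23-user worked example", {
  # 8 users same section in all years, 11 same in two of three, 4 variable
  labels <- c(rep(list(c(2, 2, 2)), 8),
              rep(list(c(1, 2, 2)), 6), rep(list(c(2, 2, 3)), 5),
              rep(list(c(1, 2, 3)), 4))
  asn <- dplyr::bind_rows(lapply(seq_along(labels), function(i)
    tibble::tibble(user_id = sprintf("u%02d", i), year = 2014:2016,
                   method = "apin", section = labels[[i]])))
  st <- stability(asn, "apin")
  expect_equal(st$n_users_all_years, 23L)
  expect_equal(st$same_all_years, 8L)
  expect_equal(st$same_two_of_three, 11L)
  expect_equal(st$variable_all_years, 4L)
  expect_equal(unname(st$percentages), c(35, 48, 17))
  expect_true(st$nonadjacent_pairs_present)  # the (1,2,3) users span 1 and 3

  # a user not present in every year is excluded from the denominator
  asn2 <- dplyr::bind_rows(asn, tibble::tibble(
    user_id = "partial", year = 2015:2016, method = "apin", section = c(1, 1)))
  expect_equal(stability(asn2, "apin")$n_users_all_years, 23L)
})

test_that("all 27 three-year label triples classify as hand-enumerated", {
  triples <- expand.grid(y1 = 1:3, y2 = 1:3, y3 = 1:3)
  asn <- dplyr::bind_rows(lapply(seq_len(nrow(triples)), function(i)
    tibble::tibble(user_id = sprintf("t%02d", i), year = 2014:2016,
                   method = "apin",
                   section = as.integer(triples[i, ]))))
  st <- stability(asn, "apin")
  # oracle: classify each triple by its number of distinct labels
  n_distinct <- apply(triples, 1, function(v) length(unique(v)))
  expect_equal(st$n_users_all_years, 27L)
  expect_equal(st$same_all_years, sum(n_distinct == 1))      # 3
  expect_equal(st$same_two_of_three, sum(n_distinct == 2))   # 18
  expect_equal(st$variable_all_years, sum(n_distinct == 3))  # 6
  per <- merge(st$per_user,
               data.frame(user_id = sprintf("t%02d", seq_len(27)),
                          expected = c("same_all", "same_two",
                                       "variable")[n_distinct]))
  expect_equal(per$class, per$expected)

  # year order never changes the same_all / variable classes
  asn_rev <- asn
  asn_rev$year <- 2016 - (asn_rev$year - 2014)
  st_rev <- stability(asn_rev, "apin")
  expect_equal(st_rev$same_all_years, st$same_all_years)
  expect_equal(st_rev$variable_all_years, st$variable_all_years)
})

test_that("profile curves are monotone, end at (1,1) and honour proportionality", {
  ps <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
  s <- define_season(ps, 2015)
  days <- seq(s$start_date, s$end_date, by = "day")
  px <- ps[ps$taxon == "Poaceae", ]
  conc <- px$concentration[match(days, px$date)]

  # scores proportional to pollen: the curve is the identity diagonal
  prop <- as_imputed(data.frame(user_id = "prop", date = days,
                                score = 2 * conc), s)
  pc <- profile_curves(prop, ps)
  expect_equal(pc$curves$cum_sli_fraction, pc$curves$cum_apin_fraction,
               tolerance = 1e-12)

  # all score mass on the first season day: y jumps to 1 immediately
  first <- as_imputed(data.frame(user_id = "first", date = days,
                                 score = c(7, rep(0, length(days) - 1))), s)
  pc1 <- profile_curves(first, ps)
  expect_true(all(pc1$curves$cum_sli_fraction == 1))

  # random cohort: monotone coordinates terminating at (1, 1)
  set.seed(61)
  coh <- as_imputed(dplyr::bind_rows(lapply(1:5, function(i)
    data.frame(user_id = paste0("u", i), date = days,
               score = sample(0:9, length(days), TRUE)))), s)
  pcr <- profile_curves(coh, ps)
  for (u in unique(pcr$curves$user_id)) {
    cu <- pcr$curves[pcr$curves$user_id == u, ]
    expect_true(all(diff(cu$cum_sli_fraction) >= 0))
    expect_true(all(diff(cu$cum_apin_fraction) >= 0))
    expect_lt(abs(cu$cum_sli_fraction[nrow(cu)] - 1), 1e-9)
    expect_lt(abs(cu$cum_apin_fraction[nrow(cu)] - 1), 1e-9)
  }

  # the pointwise mean of identical curves is that curve
  twin <- as_imputed(dplyr::bind_rows(lapply(1:4, function(i)
    data.frame(user_id = paste0("w", i), date = days,
               score = rep(c(0, 3), length.out = length(days))))), s)
  pct <- profile_curves(twin, ps)
  one_curve <- pct$curves[pct$curves$user_id == "w1", ]
  expect_equal(pct$mean_curve$cum_sli_fraction, one_curve$cum_sli_fraction)

  # zero-total users are dropped with a warning
  zero <- as_imputed(dplyr::bind_rows(
    data.frame(user_id = "ok", date = days, score = 1),
    data.frame(user_id = "null", date = days, score = 0)), s)
  expect_warning(pcz <- profile_curves(zero, ps), "zero total score")
  expect_false("null" %in% pcz$curves$user_id)
})

test_that("fast and slow reactors split around the mean curve at mid-APIn", {
  ps <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
  s <- define_season(ps, 2015)
  days <- seq(s$start_date, s$end_date, by = "day")
  n <- length(days)
  early <- data.frame(user_id = "early", date = days,
                      score = c(rep(5, 20), rep(0, n - 20)))
  late <- data.frame(user_id = "late", date = days,
                     score = c(rep(0, n - 20), rep(5, 20)))
  pc <- profile_curves(as_imputed(dplyr::bind_rows(early, late), s), ps)
  r <- pc$reactors
  expect_equal(r$reactor[r$user_id == "early"], "fast")
  expect_equal(r$reactor[r$user_id == "late"], "slow")
})
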