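test_that("mean_profile averages segment-wise", {
  p <- width_profile("a", 1:9, 9:1)
  same <- cohort_from_profiles(list(p, width_profile("b", 1:9, 9:1)))
  mp <- mean_profile(same)
  expect_equal(unname(mp$mean_L), as.numeric(1:9))
  expect_equal(unname(mp$mean_R), as.numeric(9:1))

  two <- cohort_from_profiles(list(width_profile("a", rep(1, 9), rep(2, 9)),
                                   width_profile("b", rep(3, 9), rep(4, 9))))
  mp2 <- mean_profile(two)
  expect_equal(unname(mp2$mean_L), rep(2, 9))
  expect_equal(unname(mp2$mean_R), rep(3, 9))
  expect_error(mean_profile(two[0, ]), "empty")
})

test_that("ratio-of-means and mean-of-ratios coincide for one subject and differ in general", {
  set.seed(21)
  p <- random_profile("solo")
  one <- cohort_from_profiles(list(p))
  rt <- cohort_ratio_tables(one)
  expect_equal(rt$ratio_of_means_L, rt$mean_of_ratios_L)
  expect_equal(rt$ratio_of_means_R, rt$mean_of_ratios_R)

  # heterogeneous cohort: Jensen's gap makes the two tables differ
  many <- cohort_from_profiles(lapply(1:20, function(i)
    random_profile(paste0("s", i))))
  rtm <- cohort_ratio_tables(many)
  expect_gt(max(abs(rtm$ratio_of_means_L - rtm$mean_of_ratios_L)), 1e-3)

  # mean-of-ratios equals the brute-force average of per-subject ratios
  brute <- rowMeans(vapply(1:20, function(i) {
    adjacent_ratios(row_profile(many[i, ]))$L_ratios
  }, numeric(8)))
  expect_equal(unname(rtm$mean_of_ratios_L), unname(brute))
})

test_that("mean-of-ratios skips undefined entries and reports the skip count", {
  pz <- width_profile("z", c(1, 0, 2, 1, 1, 1, 1, 1, 1), rep(1, 9))
  pa <- width_profile("a", rep(2, 9), rep(1, 9))
  co <- cohort_from_profiles(list(pz, pa))
  rt <- cohort_ratio_tables(co)
  expect_equal(unname(rt$n_undefined_L), c(1, rep(0, 7)))
  expect_equal(rt$mean_of_ratios_L[["L1/L2"]], 1)  # only pa contributes
})

test_that("prominence distribution tallies zones with percentages summing to 100", {
  base <- rep(1, 9)
  all5 <- cohort_from_profiles(lapply(1:7, function(i)
    width_profile(paste0("m", i), replace(base, 5, 4), base)))
  pd <- prominence_distribution(all5)
  expect_equal(unname(pd$counts), c(0L, 7L, 0L))
  expect_equal(unname(pd$percent), c(0, 100, 0))

  set.seed(31)
  rnd <- cohort_from_profiles(lapply(1:60, function(i)
    random_profile(paste0("r", i))))
  pdr <- prominence_distribution(rnd)
  tally <- table(factor(vapply(1:60, function(i)
    prominence_class(row_profile(rnd[i, ]))$zone, character(1)),
    levels = c("anterior", "middle", "posterior")))
  expect_equal(unname(pdr$counts), as.integer(tally))
  # three roundings to 2 decimals can each contribute up to 0.005
  expect_lte(abs(sum(pdr$percent) - 100), 0.015)
  expect_equal(pdr$n, 60L)
})

test_that("reconstructed average shape is a closed polygon with the right area", {
  z <- reconstruct_average_shape(rep(0, 9), rep(0, 9))
  expect_equal(shape_area(z), 0)
  expect_equal(nrow(z$polygon), 21)
  expect_equal(z$polygon[1, ], z$polygon[21, ])  # closed

  cshape <- reconstruct_average_shape(rep(2, 9), rep(2, 9))
  # trapezoid sum per side: triangular end caps + 8 full rectangles = 9c
  expect_equal(shape_area(cshape), 2 * 2 * 9)
  expect_error(reconstruct_average_shape(c(-1, rep(1, 8)), rep(1, 9)),
               "non-negative")
})

test_that("re-measuring the average shape reproduces the input means", {
  set.seed(41)
  mL <- stats::runif(9, 0.5, 4); mR <- stats::runif(9, 0.5, 4)
  shape <- reconstruct_average_shape(mL, mR)
  ax <- build_axis(c(0, 0), c(0, 10))
  expect_equal(as.numeric(plumb_widths(shape$left, ax)), mL, tolerance = 1e-9)
  expect_equal(as.numeric(plumb_widths(shape$right, ax)), mR, tolerance = 1e-9)
})

test_that("stratification follows the protocol's bin edges and partitions the cohort", {
  co <- cohort_from_profiles(
    lapply(1:8, function(i) width_profile(paste0("s", i), 1:9, 1:9)),
    age = c(18, 30, 31, 40, 41, 50, 51, 70),
    births = c(0, 0, 1, 1, 2, 7, 0, 1),
    labiaplasty = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  g <- stratify(co, "age4")
  expect_equal(as.character(g), c("A", "A", "B", "B", "C", "C", "D", "D"))
  gp <- stratify(co, "parity3")
  expect_equal(as.character(gp), c("1", "1", "2", "2", "3", "3", "1", "2"))
  gl <- stratify(co, "labiaplasty2")
  expect_equal(as.character(gl), rep(c("I", "II"), 4))
  # disjoint and exhaustive over in-protocol subjects
  expect_equal(sum(table(g)), nrow(co))

  minor <- co; minor$age[1] <- 17
  expect_warning(gm <- stratify(minor, "age4"), "younger than 18")
  expect_true(is.na(gm[1]))
  expect_equal(sum(table(gm)), nrow(co) - 1L)
})

test_that("Levene test matches the formula oracle and behaves at the extremes", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.0)
  y <- c(2.1, 2.3, 2.0, 2.4, 2.2)
  got <- levene_test(x, y)
  want <- levene_oracle(x, y)
  expect_equal(got$W, want$W, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df, c(1L, 9L))

  same <- levene_test(x, x)
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)

  set.seed(51)
  big <- levene_test(stats::rnorm(50, sd = 1), stats::rnorm(50, sd = 10))
  expect_lt(big$p, 0.05)
  expect_error(levene_test(1, c(1, 2)), "at least 2")
})

test_that("median-centered Levene reproduces the Brown-Forsythe variant", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.0)
  y <- c(2.1, 2.3, 2.0, 2.4, 2.2)
  got <- levene_test(x, y, center = "median")
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(1:2, c(6, 5)))
  want <- stats::anova(stats::lm(z ~ g))
  expect_equal(got$W, want[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p, want[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("compare_groups gates on Levene and matches textbook t-tests", {
  set.seed(61)
  # equal-variance fixture: expect the pooled route on most segments
  a <- cohort_from_profiles(lapply(1:12, function(i)
    width_profile(paste0("a", i), stats::rnorm(9, 3, 0.3),
                  stats::rnorm(9, 3, 0.3))))
  b <- cohort_from_profiles(lapply(1:15, function(i)
    width_profile(paste0("b", i), stats::rnorm(9, 3.4, 0.3),
                  stats::rnorm(9, 3.4, 0.3))))
  cmp <- compare_groups(a, b, labels = c("a", "b"))
  expect_equal(nrow(cmp), 18L)
  for (i in seq_len(18)) {
    s <- cmp$segment[i]
    x <- a[[s]]; y <- b[[s]]
    want <- if (cmp$variance_equal[i]) pooled_t_oracle(x, y)
            else welch_t_oracle(x, y)
    expect_equal(cmp$t_statistic[i], want$t, tolerance = 1e-10)
    expect_equal(cmp$t_p[i], want$p, tolerance = 1e-10)
  }
  expect_equal(cmp$significant, cmp$t_p < 0.05)
  expect_equal(cmp$test_variant == "welch", !cmp$variance_equal)
})

test_that("comparing a group with itself gives t = 0, p = 1, nothing significant", {
  set.seed(71)
  a <- cohort_from_profiles(lapply(1:10, function(i)
    random_profile(paste0("a", i))))
  cmp <- compare_groups(a, a)
  expect_equal(cmp$t_statistic, rep(0, 18))
  expect_equal(cmp$t_p, rep(1, 18))
  expect_false(any(cmp$significant))
})

test_that("compare_groups is symmetric up to the sign of t", {
  set.seed(81)
  a <- cohort_from_profiles(lapply(1:9, function(i)
    random_profile(paste0("a", i))))
  b <- cohort_from_profiles(lapply(1:11, function(i)
    random_profile(paste0("b", i))))
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$t_p, ba$t_p)
  expect_equal(ab$levene_p, ba$levene_p)
  expect_error(compare_groups(a[1, ], b, labels = c("tiny", "b")), "tiny")
})

test_that("compare_strata covers every populated pair and skips degenerate ones", {
  set.seed(91)
  co <- cohort_from_profiles(
    lapply(1:30, function(i) random_profile(paste0("s", i))),
    age = rep(c(25, 35, 45), each = 10),
    births = rep(c(0, 1, 2), 10))
  cmp <- compare_strata(co, "age4")
  expect_setequal(names(cmp), c("A_vs_B", "A_vs_C", "B_vs_C"))
  expect_s3_class(cmp$A_vs_B, "group_comparison")

  solo <- cohort_from_profiles(
    lapply(1:6, function(i) random_profile(paste0("s", i))), age = 25)
  expect_message(none <- compare_strata(solo, "age4"), "skipped")
  expect_length(none, 0)
})

test_that("cohort_summary ties the aggregates together consistently", {
  set.seed(101)
  co <- cohort_from_profiles(lapply(1:25, function(i)
    random_profile(paste0("s", i))))
  s <- cohort_summary(co, golden = reference_labial_distances())
  expect_equal(s$n, 25L)
  expect_equal(unname(s$ratio_of_means_L),
               unname(s$mean_L[1:8] / s$mean_L[2:9]))
  expect_equal(sum(s$prominence_counts), 25L)
  expect_equal(round(s$golden_ratio$left, 3), 1.498)
  # the stored mean shape re-measures to the stored means
  ax <- build_axis(c(0, 0), c(0, 10))
  expect_equal(as.numeric(plumb_widths(s$mean_shape$left, ax)),
               unname(s$mean_L), tolerance = 1e-9)
})
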