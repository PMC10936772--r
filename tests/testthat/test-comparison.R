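test_that("decide_test follows the assumption-driven decision rules", {
  # normal, homoscedastic
  expect_equal(decide_test(c(0.4, 0.6, 0.2), 0.20, 3), "anova")
  expect_equal(decide_test(c(0.4, 0.6), 0.20, 2), "t_test")
  # heteroscedastic -> Welch variants
  expect_equal(decide_test(c(0.4, 0.6, 0.2), 0.01, 3), "welch_anova")
  expect_equal(decide_test(c(0.4, 0.6), 0.01, 2), "welch_t")
  # non-normal with two groups -> nonparametric fallback
  expect_equal(decide_test(c(0.003, 0.6), 0.20, 2), "mann_whitney_u")
  expect_equal(decide_test(c(0.003, 0.6), 0.01, 2), "mann_whitney_u")
  # k = 3 non-normality has no fallback: the Levene branch decides
  expect_equal(decide_test(c(0.003, 0.6, 0.5), 0.20, 3), "anova")
  expect_equal(decide_test(c(0.003, 0.6, 0.5), 0.01, 3), "welch_anova")
  # untestable normality (NA) falls through to the Levene branch
  expect_equal(decide_test(c(NA, NA), 0.20, 2), "t_test")
  expect_error(decide_test(numeric(0), 0.2, 3), "needs")
})

test_that("identical groups give a location p-value of 1", {
  tab <- make_table(list(P1 = c(1, 2, 3), P2 = c(1, 2, 3), P3 = c(1, 2, 3)))
  rep <- compare_populations(tab, "adult", "SLA")
  expect_equal(rep$p_value, 1, tolerance = 1e-12)
  tab2 <- make_table2(list(P1 = list(adult = c(1, 2, 3, 4),
                                     juvenile = c(1, 2, 3, 4))))
  rep2 <- compare_stages(tab2, "P1", "SLA")
  expect_equal(rep2$p_value, 1, tolerance = 1e-12)
  expect_equal(abs(rep2$statistic), 0, tolerance = 1e-12)
})

test_that("pooled and Welch variants agree when group variances are exactly equal", {
  g1 <- c(1, 2, 3, 4, 5, 8)
  groups <- list(a = g1, b = g1 + 2.5)  # identical variance, equal n
  pooled <- run_selected_test("t_test", groups)
  welch <- run_selected_test("welch_t", groups)
  expect_equal(welch$p_value, pooled$p_value, tolerance = 1e-9)
  expect_equal(welch$statistic, pooled$statistic, tolerance = 1e-9)
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  withr::with_seed(42, {
    a <- rlnorm(15, 3, 0.4)
    b <- rlnorm(15, 3.5, 0.4)
  })
  p_raw <- wilcox.test(a, b, exact = FALSE)$p.value
  p_log <- wilcox.test(log(a), log(b), exact = FALSE)$p.value
  p_cube <- wilcox.test(a^3, b^3, exact = FALSE)$p.value
  expect_equal(p_log, p_raw, tolerance = 1e-12)
  expect_equal(p_cube, p_raw, tolerance = 1e-12)
})

test_that("between-population test has calibrated type-I error and real power", {
  n_reps <- 300
  rej_null <- 0L
  for (i in seq_len(n_reps)) {
    tab <- generate_null_traits(one_trait_config(i))
    rej_null <- rej_null + (compare_populations(tab, "adult", "SLA")$p_value < 0.05)
  }
  expect_lt(abs(rej_null / n_reps - 0.05), 0.035)

  rej_alt <- 0L
  n_pow <- 150
  for (i in seq_len(n_pow)) {
    withr::with_seed(i, {
      tab <- make_table(list(P1 = exp(rnorm(20, 0, 1)),
                             P2 = exp(rnorm(20, 0, 1)),
                             P3 = exp(rnorm(20, 2, 1))))
    })
    rej_alt <- rej_alt + (compare_populations(tab, "adult", "SLA")$p_value < 0.05)
  }
  expect_gt(rej_alt / n_pow, 0.9)
})

test_that("test selection frequencies match the data-generating assumptions", {
  n_reps <- 200
  picks_eq <- character(n_reps)
  picks_het <- character(n_reps)
  for (i in seq_len(n_reps)) {
    withr::with_seed(i, {
      ad <- exp(rnorm(20, 1, 0.5))
      ju_eq <- exp(rnorm(20, 1.3, 0.5))
      ju_het <- exp(rnorm(20, 1, 0.5 / 3))
    })
    tab_eq <- make_table2(list(P1 = list(adult = ad, juvenile = ju_eq)))
    tab_het <- make_table2(list(P1 = list(adult = ad, juvenile = ju_het)))
    picks_eq[i] <- compare_stages(tab_eq, "P1", "SLA")$test_name
    picks_het[i] <- compare_stages(tab_het, "P1", "SLA")$test_name
  }
  # equal-variance lognormal: classical t picked about (1-alpha)^2 of the time
  expect_gt(mean(picks_eq == "t_test"), 0.80)
  # 9x variance ratio: Welch t must dominate
  expect_gt(mean(picks_het == "welch_t"),
            mean(picks_het %in% c("t_test", "mann_whitney_u")))
  expect_gt(mean(picks_het == "welch_t"), 0.5)
})

test_that("the battery covers every trait contrast and skips missing traits", {
  tab <- generate_traits(oak_study_config())
  battery <- run_comparison_battery(tab)
  # 6 traits x (2 between-population + 3 between-stage contrasts)
  expect_equal(nrow(battery), 30)
  expect_true(all(battery$p_value >= 0 & battery$p_value <= 1))
  expect_true(all(c("stars", "test_name") %in% names(battery)))

  tab$WD <- NA_real_
  battery2 <- run_comparison_battery(trait_table(tibble::as_tibble(tab)))
  expect_equal(nrow(battery2), 25)
  expect_length(attr(battery2, "skipped"), 5)
  expect_true(all(grepl("^WD", attr(battery2, "skipped"))))
})

test_that("optional BH adjustment adds a monotone p_adjusted column", {
  tab <- generate_traits(oak_study_config())
  battery <- run_comparison_battery(tab, adjust = TRUE)
  expect_true(all(battery$p_adjusted >= battery$p_value))
  expect_equal(battery$p_adjusted,
               p.adjust(battery$p_value, method = "BH"))
})
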