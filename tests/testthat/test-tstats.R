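test_that("observed variance ratio matches the brute-force oracle", {
  # forced small case: var{1,2,3} = 1, var{1,2,3,10} = 50/3
  tab1 <- make_table(list(P1 = c(1, 2, 3), P2 = 10))
  expect_error(t_ip_ir(tab1, "adult", "SLA", "P2"), "fewer than 2")
  expect_equal(t_ip_ir(tab1, "adult", "SLA", "P1"),
               brute_t_ratio(c(1, 2, 3), c(1, 2, 3, 10)), tolerance = 1e-12)
  expect_equal(t_ip_ir(tab1, "adult", "SLA", "P1"), 3 / 50, tolerance = 1e-12)
  # an all-identical cell against a heterogeneous pool
  tab <- make_table(list(P1 = c(1, 2, 3), P2 = c(10, 10)))
  expect_equal(t_ip_ir(tab, "adult", "SLA", "P2"), 0)
  # single population: cell is the pool
  solo <- make_table(list(P1 = c(4, 7, 9)))
  expect_equal(t_ip_ir(solo, "adult", "SLA", "P1"), 1, tolerance = 1e-15)
  # random tables against an independent two-pass variance computation
  for (i in 1:30) {
    withr::with_seed(i, {
      sizes <- sample(2:12, 3)
      vals <- lapply(sizes, function(n) rlnorm(n, 2, 0.6))
    })
    names(vals) <- c("P1", "P2", "P3")
    tab <- make_table(vals)
    pool <- unlist(vals)
    for (p in names(vals)) {
      expect_equal(t_ip_ir(tab, "adult", "SLA", p),
                   brute_t_ratio(vals[[p]], pool), tolerance = 1e-12)
    }
  }
})

test_that("degenerate pools and cells are rejected", {
  tab <- make_table(list(P1 = c(2, 2), P2 = c(2, 2)))
  expect_error(t_ip_ir(tab, "adult", "SLA", "P1"), "degenerate pool")
  expect_error(null_distribution(tab, "adult", "SLA",
                                 null_model_config(19)), "degenerate pool")
  expect_error(null_model_config(10), ">= 19")
})

test_that("permutation null is deterministic and holds the pool fixed", {
  tab <- generate_traits(one_trait_config(5))
  cfg <- null_model_config(99, seed = 3)
  s1 <- null_distribution(tab, "adult", "SLA", cfg)
  s2 <- null_distribution(tab, "adult", "SLA", cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(99, 3))
  s3 <- null_distribution(tab, "adult", "SLA", null_model_config(99, seed = 4))
  expect_false(identical(s1, s3))
})

test_that("permutation null matches exhaustive enumeration on a 2/2 split", {
  pool <- c(1, 2, 3, 4)
  tab <- make_table(list(A = pool[1:2], B = pool[3:4]))
  splits <- utils::combn(4, 2)
  exhaustive <- apply(splits, 2, function(ix) brute_t_ratio(pool[ix], pool))
  sims <- null_distribution(tab, "adult", "SLA",
                            null_model_config(6000, seed = 1))
  # empirical cdf of simulated T for population A vs the 6-point support
  support <- sort(unique(exhaustive))
  F_exh <- ecdf(exhaustive)(support)
  F_sim <- ecdf(sims[, "A"])(support)
  expect_lt(max(abs(F_sim - F_exh)), 0.03)
  # every simulated value lies on the exhaustive support
  expect_true(all(vapply(sims[, "A"], function(v) {
    any(abs(v - support) < 1e-12)
  }, logical(1))))
})

test_that("(n-1)-weighted mean of simulated variance ratios is near one", {
  tab <- generate_traits(one_trait_config(9, n_per_cell = 15))
  sims <- null_distribution(tab, "adult", "SLA", null_model_config(1000, seed = 2))
  # equal population sizes: the (n_pop - 1) weights are equal, so the
  # weighted mean reduces to the plain mean over populations and draws;
  # sample variances are unbiased under label permutation, so it is near 1
  expect_lt(abs(mean(sims) - 1), 0.02)
})

test_that("SES and one-sided p-values follow their closed forms", {
  expect_equal(ses(1, c(0.5, 1.0, 1.5)), 0)
  sims <- c(0.5, 1.5)  # mean 1, sd sqrt(0.5)
  expect_equal(ses(2, sims), 1 / sd(sims))
  expect_equal(ses(0, c(0, 2)), -1 / sqrt(2), tolerance = 1e-12)
  expect_error(ses(1, c(1, 1)), "degenerate null")
  expect_error(ses(1, 1), ">= 2")

  expect_equal(one_sided_pvalues(0.005, 1:999 / 100),
               c(p_low = 1 / 1000, p_high = 1))
  expect_equal(one_sided_pvalues(2, rep(2, 7)), c(p_low = 1, p_high = 1))
  expect_equal(one_sided_pvalues(2.5, c(1, 2, 3, 4)),
               c(p_low = 3 / 5, p_high = 3 / 5))
})

test_that("SES and p-values are invariant to shifting and rescaling traits", {
  tab <- generate_traits(one_trait_config(13))
  cfg <- null_model_config(199, seed = 5)
  base <- run_tstats(tab, cfg)
  scaled <- tibble::as_tibble(tab)
  scaled$SLA <- scaled$SLA * 37.5
  res_scaled <- run_tstats(trait_table(scaled), cfg)
  expect_equal(res_scaled$tstats$t_obs, base$tstats$t_obs, tolerance = 1e-12)
  expect_equal(res_scaled$tstats$ses, base$tstats$ses, tolerance = 1e-9)
  expect_equal(res_scaled$tstats$p_low, base$tstats$p_low)
  expect_equal(res_scaled$tstats$p_high, base$tstats$p_high)
  # shifting changes raw variances but not the ratio-based results
  shifted <- tibble::as_tibble(tab)
  shifted$SLA <- shifted$SLA + 500
  res_shift <- run_tstats(trait_table(shifted), cfg)
  expect_equal(res_shift$tstats$ses, base$tstats$ses, tolerance = 1e-9)
})

test_that("full analysis has the expected cardinality and degenerate behaviour", {
  tab <- generate_traits(oak_study_config())
  res <- run_tstats(tab, null_model_config(99, seed = 1))
  expect_equal(nrow(res$tstats), 6 * 2 * 3)
  expect_equal(nrow(res$mean_ses), 6 * 2)
  expect_equal(res$tstats$ses,
               (res$tstats$t_obs - res$tstats$null_mean) / res$tstats$null_sd)
  expect_true(all(res$tstats$p_low >= 1 / 100 & res$tstats$p_high >= 1 / 100))
  expect_equal(res$mean_ses$mean_ses,
               tapply(res$tstats$ses,
                      paste(res$tstats$acronym, res$tstats$stage),
                      mean)[paste(res$mean_ses$acronym, res$mean_ses$stage)],
               ignore_attr = TRUE)

  # a zero-variance population is a forced extreme
  flat <- tibble::as_tibble(tab)
  flat$SLA[flat$population == "Arcabuco"] <-
    rep(mean(flat$SLA[flat$population == "Arcabuco"]),
        sum(flat$population == "Arcabuco"))
  res2 <- run_tstats(trait_table(flat), null_model_config(199, seed = 2))
  row <- res2$tstats[res2$tstats$acronym == "SLA" &
                       res2$tstats$population == "Arcabuco", ]
  expect_equal(row$t_obs, c(0, 0))
  expect_true(all(row$ses < 0))
  expect_equal(row$p_low, c(1 / 200, 1 / 200))
})

test_that("lower-tail power increases as filtering strengthens", {
  strengths <- c(0.25, 1.0)
  rates <- vapply(strengths, function(s) {
    rej <- 0L
    n_reps <- 120
    for (i in seq_len(n_reps)) {
      tab <- generate_traits(one_trait_config(i, filtering_strength = c(P1 = s)))
      res <- run_tstats(tab, null_model_config(99, seed = i))
      rej <- rej + res$tstats$significant_low[res$tstats$population == "P1"]
    }
    rej / n_reps
  }, numeric(1))
  expect_gt(rates[1], rates[2])
  expect_gt(rates[1], 0.5)
})
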