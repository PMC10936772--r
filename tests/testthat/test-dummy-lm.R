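sim_cell_table <- function(cell_means, n = 20, sd = 0, seed = 1) {
  # cell_means: tibble(population, stage, mu) on the log scale
  withr::with_seed(seed, {
    rows <- purrr::pmap(cell_means, function(population, stage, mu) {
      tibble::tibble(
        individual_id = paste0(population, "_", stage, "_", seq_len(n)),
        population = population, stage = stage,
        SLA = exp(mu + rnorm(n, 0, sd))
      )
    })
  })
  trait_table(dplyr::bind_rows(rows))
}

full_grid <- function(mus) {
  grid <- tidyr::expand_grid(population = c("Arcabuco", "Chicaque", "Encino"),
                             stage = c("adult", "juvenile"))
  grid$mu <- mus
  grid
}

test_that("dummy design encodes the reference cell and interactions exactly", {
  tab <- sim_cell_table(full_grid(1:6), n = 2)
  d <- build_design(tab, reference_cell = list(population = "Arcabuco",
                                               stage = "adult"))
  m <- d$matrix
  expect_equal(colnames(m),
               c("(Intercept)", "stage_juvenile", "pop_Chicaque",
                 "pop_Encino", "stage_juvenile_x_pop_Chicaque",
                 "stage_juvenile_x_pop_Encino"))
  ref_row <- m[tab$population == "Arcabuco" & tab$stage == "adult", ][1, ]
  expect_equal(unname(ref_row), c(1, 0, 0, 0, 0, 0))
  # juvenile of the second non-reference population (Encino)
  enc_juv <- m[tab$population == "Encino" & tab$stage == "juvenile", ][1, ]
  expect_equal(unname(enc_juv), c(1, 1, 0, 1, 0, 1))
  # interaction columns are exact products
  expect_equal(m[, 5], m[, 2] * m[, 3])
  expect_equal(m[, 6], m[, 2] * m[, 4])
  expect_false(any(m[, 3] == 1 & m[, 4] == 1))
})

test_that("design is full rank with all cells populated, errors otherwise", {
  tab <- sim_cell_table(full_grid(rep(1, 6)), n = 20, sd = 0.1)
  d <- build_design(tab)
  expect_equal(qr(d$matrix)$rank, 6)
  expect_equal(nrow(d$matrix), 120)
  expect_error(build_design(tab, list(population = "Nowhere", stage = "adult")),
               "reference cell")
  # empty cell -> rank deficiency reported with the cell named
  sub <- tab[!(tab$population == "Encino" & tab$stage == "adult"), ]
  d2 <- build_design(trait_table(tibble::as_tibble(sub)))
  expect_error(fit_trait_lm(d2, log(sub$SLA)), "rank-deficient.*Encino")
})

test_that("noiseless saturated fit recovers cell means exactly", {
  mus <- c(1.0, 1.4, 0.7, 1.9, 2.2, 0.3)
  tab <- sim_cell_table(full_grid(mus), n = 5, sd = 0)
  d <- build_design(tab, list(population = "Arcabuco", stage = "adult"))
  fit <- suppressWarnings(fit_trait_lm(d, log(tab$SLA), acronym = "SLA"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  est <- fit$coefficients$estimate
  expect_equal(est[1], mus[1], tolerance = 1e-10)          # beta0 = ref mean
  expect_equal(est[2], mus[2] - mus[1], tolerance = 1e-10) # juvenile effect
  expect_equal(est[3], mus[3] - mus[1], tolerance = 1e-10) # Chicaque (adult)
  expect_equal(est[4], mus[5] - mus[1], tolerance = 1e-10) # Encino (adult)
  # interactions: juvenile shift in pop minus juvenile shift in reference
  expect_equal(est[5], (mus[4] - mus[3]) - (mus[2] - mus[1]), tolerance = 1e-10)
  expect_equal(est[6], (mus[6] - mus[5]) - (mus[2] - mus[1]), tolerance = 1e-10)
})

test_that("every cell's fitted value equals its sample mean (saturated identity)", {
  tab <- sim_cell_table(full_grid(c(1, 2, 1.5, 0.5, 2.5, 1)), n = 20,
                        sd = 0.3, seed = 7)
  d <- build_design(tab)
  fit <- fit_trait_lm(d, log(tab$SLA))
  cell <- paste(tab$population, tab$stage)
  cell_means <- tapply(log(tab$SLA), cell, mean)
  expect_equal(unname(fit$fitted), as.vector(cell_means[cell]),
               tolerance = 1e-10)
  # residuals orthogonal to every design column
  dots <- abs(crossprod(fit$model_matrix, fit$residuals))
  expect_lt(max(dots), 1e-8)
})

test_that("constant response yields a flagged null model", {
  tab <- sim_cell_table(full_grid(rep(2, 6)), n = 4, sd = 0)
  fit <- suppressWarnings(fit_trait_lm(build_design(tab), log(tab$SLA)))
  expect_equal(fit$coefficients$estimate[1], 2, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[-1], rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
  expect_true(is.na(fit$f_statistic))
})

test_that("fitted values, R2 and F are invariant to the reference cell", {
  tab <- sim_cell_table(full_grid(c(1, 2, 1.5, 0.5, 2.5, 1)), n = 20,
                        sd = 0.3, seed = 11)
  y <- log(tab$SLA)
  f1 <- fit_trait_lm(build_design(tab, list(population = "Arcabuco",
                                            stage = "juvenile")), y)
  f2 <- fit_trait_lm(build_design(tab, list(population = "Arcabuco",
                                            stage = "adult")), y)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$f_statistic, f1$f_statistic, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f2$coefficients$estimate[1],
                                f1$coefficients$estimate[1])))
})

test_that("95% confidence intervals cover the true coefficients", {
  mus <- c(1.0, 1.4, 0.7, 1.9, 2.2, 0.3)
  ref <- list(population = "Arcabuco", stage = "adult")
  true_beta <- c(mus[1], mus[2] - mus[1], mus[3] - mus[1], mus[5] - mus[1],
                 (mus[4] - mus[3]) - (mus[2] - mus[1]),
                 (mus[6] - mus[5]) - (mus[2] - mus[1]))
  n_reps <- 200
  covered <- matrix(FALSE, n_reps, 6)
  for (i in seq_len(n_reps)) {
    tab <- sim_cell_table(full_grid(mus), n = 20, sd = 0.1, seed = i)
    fit <- fit_trait_lm(build_design(tab, ref), log(tab$SLA))
    half <- qt(0.975, fit$n - 6) * fit$coefficients$std_error
    covered[i, ] <- abs(fit$coefficients$estimate - true_beta) <= half
  }
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("the battery fits every trait with tidy and glance accessors", {
  tab <- generate_traits(oak_study_config())
  fits <- run_lm_battery(tab)
  expect_length(fits, 6)
  td <- tidy(fits)
  expect_equal(nrow(td), 36)
  gl <- glance(fits)
  expect_equal(gl$acronym, trait_acronyms(tab))
  expect_true(all(gl$r_squared >= 0 & gl$r_squared <= 1))
  expect_true(all(gl$n == 120))
  ft <- fits$SLA$factor_tests
  expect_equal(ft$factor, c("ontogeny", "population", "interaction"))
  expect_true(all(ft$p_value >= 0 & ft$p_value <= 1))
})
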