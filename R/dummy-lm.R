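#' Build the dummy-coded two-factor design
#'
#' Encodes ontogenetic stage and population as 0/1 indicator variables
#' relative to a reference cell, with stage-by-population interaction
#' columns. For k populations and 2 stages the design has an intercept,
#' one stage dummy, k-1 population dummies (alphabetical among
#' non-reference populations) and k-1 interaction columns, so rows of the
#' reference cell are all-zero except the intercept. With all cells
#' populated the design is saturated: the fit reproduces every cell mean.
#'
#' @param table A trait table.
#' @param reference_cell Named list or vector with `population` and
#'   `stage`; defaults to juveniles of the first population.
#' @return A `trait_design` list: `matrix` (n x 2k columns), `stage` and
#'   `population` factors (reference level first), `reference_cell`,
#'   `individual_id`.
#' @export
#' @examples
#' d <- build_design(generate_traits(oak_study_config()))
#' colnames(d$matrix)
build_design <- function(table, reference_cell = NULL) {
  table <- as_trait_tbl(table)
  pops <- attr(table, "populations")
  if (is.null(reference_cell)) {
    reference_cell <- list(population = pops[1], stage = "juvenile")
  }
  reference_cell <- as.list(reference_cell)
  ref_pop <- reference_cell$population
  ref_stage <- reference_cell$stage
  if (!ref_pop %in% table$population || !ref_stage %in% table$stage ||
      !any(table$population == ref_pop & table$stage == ref_stage)) {
    stop("reference cell (", ref_pop, ", ", ref_stage,
         ") has no records", call. = FALSE)
  }
  other_stage <- setdiff(stage_levels(), ref_stage)
  other_pops <- sort(setdiff(unique(table$population), ref_pop))
  n <- nrow(table)
  stage_dummy <- as.numeric(table$stage == other_stage)
  pop_dummies <- vapply(other_pops,
                        function(p) as.numeric(table$population == p),
                        numeric(n))
  if (length(other_pops) == 1) pop_dummies <- matrix(pop_dummies, ncol = 1)
  inter <- pop_dummies * stage_dummy
  m <- cbind(1, stage_dummy, pop_dummies, inter)
  colnames(m) <- c("(Intercept)",
                   paste0("stage_", other_stage),
                   paste0("pop_", other_pops),
                   paste0("stage_", other_stage, "_x_pop_", other_pops))
  structure(
    list(matrix = m,
         stage = factor(table$stage, levels = c(ref_stage, other_stage)),
         population = factor(table$population,
                             levels = c(ref_pop, other_pops)),
         reference_cell = list(population = ref_pop, stage = ref_stage),
         individual_id = table$individual_id),
    class = "trait_design"
  )
}

#' Fit the two-factor dummy-coded linear model to one response
#'
#' Ordinary least squares of a (log-scale) trait on the dummy design:
#' `E(y) = b0 + b1*stage + b2..b_k*pop + interactions`. The intercept is
#' the reference-cell mean and, because the design is saturated, each
#' cell's fitted value equals that cell's sample mean. The overall F
#' tests all non-intercept coefficients jointly; factor-level
#' significance (ontogeny, population, interaction) is assessed by
#' Type-II nested-model F tests, which are order-invariant.
#'
#' @param design A `trait_design` from [build_design()].
#' @param response Numeric response vector aligned with the design rows
#'   (missing values dropped pairwise).
#' @param acronym Optional trait label carried into the result.
#' @return A `trait_lm` object; see [tidy.trait_lm()] and
#'   [glance.trait_lm()].
#' @export
fit_trait_lm <- function(design, response, acronym = NA_character_) {
  stopifnot(inherits(design, "trait_design"))
  m <- design$matrix
  if (length(response) != nrow(m)) {
    stop("response length does not match design rows", call. = FALSE)
  }
  keep <- !is.na(response)
  m <- m[keep, , drop = FALSE]
  y <- response[keep]
  stg <- droplevels(design$stage[keep])
  pop <- droplevels(design$population[keep])
  if (qr(m)$rank < ncol(m)) {
    cells <- table(pop, stg)
    empty <- which(cells == 0, arr.ind = TRUE)
    msg <- if (nrow(empty) > 0) {
      paste0(" (empty cell: ", rownames(cells)[empty[1, 1]], " ",
             colnames(cells)[empty[1, 2]], ")")
    } else ""
    stop("rank-deficient design", msg, call. = FALSE)
  }
  df <- data.frame(y = y, m[, -1, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  coef_tbl <- tibble::tibble(
    term = rownames(coefs),
    beta = paste0("beta", seq_len(nrow(coefs)) - 1),
    estimate = unname(coefs[, "Estimate"]),
    std_error = unname(coefs[, "Std. Error"]),
    statistic = unname(coefs[, "t value"]),
    p_value = unname(coefs[, "Pr(>|t|)"])
  )
  r_squared <- sm$r.squared
  if (stats::var(y) == 0) r_squared <- 0  # constant response: nothing to explain
  fstat <- sm$fstatistic
  if (stats::var(y) == 0) fstat <- NULL
  if (is.null(fstat) || !is.finite(fstat[1])) {
    f_statistic <- NA_real_; f_p <- NA_real_
  } else {
    f_statistic <- unname(fstat[1])
    f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  # Type II: each factor adjusted for the other, interaction last.
  factor_tests <- NULL
  if (nlevels(stg) == 2 && nlevels(pop) >= 2) {
    dat <- data.frame(y = y, stage = stg, population = pop)
    f_add <- stats::lm(y ~ stage + population, data = dat)
    f_full <- stats::lm(y ~ stage * population, data = dat)
    rows <- list(
      ontogeny = stats::anova(stats::lm(y ~ population, data = dat), f_add),
      population = stats::anova(stats::lm(y ~ stage, data = dat), f_add),
      interaction = stats::anova(f_add, f_full)
    )
    factor_tests <- dplyr::bind_rows(lapply(names(rows), function(nm) {
      a <- rows[[nm]]
      tibble::tibble(factor = nm, df = a$Df[2],
                     f_statistic = a$F[2], p_value = a$`Pr(>F)`[2])
    }))
  }
  structure(
    list(acronym = acronym,
         coefficients = coef_tbl,
         r_squared = r_squared,
         f_statistic = f_statistic,
         f_p = f_p,
         n = length(y),
         reference_cell = design$reference_cell,
         factor_tests = factor_tests,
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         model_matrix = m),
    class = "trait_lm"
  )
}

#' @export
print.trait_lm <- function(x, ...) {
  cat("Two-factor dummy-coded linear model",
      if (!is.na(x$acronym)) paste0(" for ", x$acronym), "\n", sep = "")
  cat("Reference cell: ", x$reference_cell$population, " ",
      x$reference_cell$stage, "; n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  cat(sprintf("R-squared %.4f; F %.3f (p %.3g)\n",
              x$r_squared, x$f_statistic, x$f_p))
  invisible(x)
}

#' Tidy a fitted two-factor trait model
#'
#' @param x A `trait_lm` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `beta`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `stars` (plus `acronym`).
#' @export
tidy.trait_lm <- function(x, ...) {
  out <- x$coefficients
  out$stars <- significance_stars(out$p_value)
  tibble::add_column(out, acronym = x$acronym, .before = 1)
}

#' Model-level summary of a fitted trait model
#'
#' @param x A `trait_lm` object.
#' @param ... Unused.
#' @return A one-row tibble: `acronym`, `r_squared`, `f_statistic`,
#'   `f_p`, `n`, `reference_population`, `reference_stage`.
#' @export
glance.trait_lm <- function(x, ...) {
  tibble::tibble(
    acronym = x$acronym,
    r_squared = x$r_squared,
    f_statistic = x$f_statistic,
    f_p = x$f_p,
    n = x$n,
    reference_population = x$reference_cell$population,
    reference_stage = x$reference_cell$stage
  )
}

#' Fit the dummy-coded model for every registered trait
#'
#' Each trait is log-transformed (unless the table already is), the design
#' is rebuilt on the trait's non-missing rows, and the model is fitted.
#'
#' @inheritParams build_design
#' @return A named list of `trait_lm` objects, classed
#'   `trait_lm_battery`; `tidy()` stacks the coefficient tables and
#'   `glance()` the model-level summaries.
#' @export
#' @examples
#' fits <- run_lm_battery(generate_traits(oak_study_config()))
#' generics::glance(fits)
run_lm_battery <- function(table, reference_cell = NULL) {
  table <- as_trait_tbl(table)
  reg <- get_registry(table)
  design <- build_design(table, reference_cell)
  fits <- lapply(reg$acronym, function(ac) {
    v <- table[[ac]]
    if (sum(!is.na(v)) < ncol(design$matrix) + 1) return(NULL)
    y <- if (reg$transform[reg$acronym == ac] == "log") v else log(v)
    fit_trait_lm(design, y, acronym = ac)
  })
  names(fits) <- reg$acronym
  structure(fits[!vapply(fits, is.null, logical(1))],
            class = "trait_lm_battery")
}

#' @export
tidy.trait_lm_battery <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @export
glance.trait_lm_battery <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' @export
print.trait_lm_battery <- function(x, ...) {
  cat("Dummy-coded linear models for", length(x), "traits\n")
  print(glance(x))
  invisible(x)
}
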