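#' Assumption-driven choice of a location test
#'
#' Deterministic decision rule used throughout the comparison battery:
#' \enumerate{
#'   \item if any per-group Shapiro-Wilk p-value (computed on
#'     log-transformed values) is below `alpha` and there are two groups,
#'     fall back to the Mann-Whitney U test;
#'   \item otherwise, if Levene's test rejects homoscedasticity
#'     (p < `alpha`), use the Welch variant (Welch ANOVA for three or more
#'     groups, Welch t-test for two);
#'   \item otherwise use the classical test (ANOVA or pooled t-test).
#' }
#' With three or more non-normal groups there is no nonparametric fallback:
#' the Welch/classical ANOVA on log values is retained and the normality
#' violation is recorded on the report.
#'
#' @param shapiro_ps Named numeric vector of per-group Shapiro-Wilk
#'   p-values (`NA` where a group is too small to test).
#' @param levene_p Levene's test p-value across groups.
#' @param k_groups Number of groups (2 or more).
#' @param alpha Decision level for the assumption checks (default 0.05).
#' @return One of `"anova"`, `"welch_anova"`, `"t_test"`, `"welch_t"`,
#'   `"mann_whitney_u"`.
#' @export
#' @examples
#' decide_test(c(a = 0.4, b = 0.6, c = 0.2), levene_p = 0.01, k_groups = 3)
decide_test <- function(shapiro_ps, levene_p, k_groups, alpha = 0.05) {
  if (length(shapiro_ps) == 0 || length(levene_p) != 1 || is.na(levene_p)) {
    stop("decide_test needs per-group shapiro p-values and one levene p-value",
         call. = FALSE)
  }
  if (k_groups < 2) stop("k_groups must be >= 2", call. = FALSE)
  nonnormal <- any(shapiro_ps < alpha, na.rm = TRUE)
  if (nonnormal && k_groups == 2) return("mann_whitney_u")
  if (levene_p < alpha) {
    if (k_groups >= 3) "welch_anova" else "welch_t"
  } else {
    if (k_groups >= 3) "anova" else "t_test"
  }
}

# Values of one trait, log-scale, split by a grouping column. Returns a named
# list of numeric vectors without missings.
trait_groups <- function(table, acronym, by, subset_col = NULL,
                         subset_val = NULL) {
  table <- as_trait_tbl(table)
  reg <- get_registry(table)
  if (!acronym %in% reg$acronym) {
    stop("unknown trait: ", acronym, call. = FALSE)
  }
  df <- tibble::as_tibble(table)
  if (!is.null(subset_col)) df <- df[df[[subset_col]] == subset_val, ]
  v <- df[[acronym]]
  already_logged <- reg$transform[reg$acronym == acronym] == "log"
  if (!already_logged) v <- log(v)
  keep <- !is.na(v)
  split(v[keep], df[[by]][keep])
}

run_selected_test <- function(test_name, groups) {
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  y <- unlist(groups, use.names = FALSE)
  switch(
    test_name,
    anova = {
      ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
      list(statistic = unname(ft$statistic), df = unname(ft$parameter),
           p_value = ft$p.value)
    },
    welch_anova = {
      ft <- stats::oneway.test(y ~ g, var.equal = FALSE)
      list(statistic = unname(ft$statistic), df = unname(ft$parameter),
           p_value = ft$p.value)
    },
    t_test = {
      ft <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      list(statistic = unname(ft$statistic), df = unname(ft$parameter),
           p_value = ft$p.value)
    },
    welch_t = {
      ft <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      list(statistic = unname(ft$statistic), df = unname(ft$parameter),
           p_value = ft$p.value)
    },
    mann_whitney_u = {
      ft <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE,
                               correct = TRUE)
      list(statistic = unname(ft$statistic), df = c(NA_real_),
           p_value = ft$p.value)
    },
    stop("unknown test: ", test_name, call. = FALSE)
  )
}

# Degenerate case: every observation identical across groups. Location tests
# return NaN there; report "no evidence against equality" as p = 1.
compare_groups <- function(groups, acronym, contrast, alpha = 0.05,
                           levene_center = stats::median) {
  small <- lengths(groups) < 2
  if (length(groups) < 2 || any(small)) {
    stop("need >= 2 groups with >= 2 non-missing values each for ", acronym,
         call. = FALSE)
  }
  shapiro_ps <- vapply(groups, function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) NA_real_
    else stats::shapiro.test(v)$p.value
  }, numeric(1))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  levene_p <- if (stats::var(y) == 0) {
    1
  } else {
    car::leveneTest(y, g, center = levene_center)[["Pr(>F)"]][1]
  }
  test_name <- decide_test(shapiro_ps, levene_p, k_groups = length(groups),
                           alpha = alpha)
  res <- run_selected_test(test_name, groups)
  if (is.na(res$p_value) && stats::var(y) == 0) {
    res$statistic <- 0
    res$p_value <- 1
  }
  tibble::tibble(
    acronym = acronym,
    contrast = contrast,
    transform_applied = "log",
    shapiro_p = list(shapiro_ps),
    levene_p = levene_p,
    test_name = test_name,
    statistic = res$statistic,
    df = list(res$df),
    p_value = res$p_value,
    group_ns = list(lengths(groups)),
    normality_violation = any(shapiro_ps < alpha, na.rm = TRUE) &&
      length(groups) >= 3
  )
}

#' Compare one trait between populations within a stage
#'
#' Log-transforms the trait (unless the table is already on the log scale),
#' checks normality per population (Shapiro-Wilk) and homoscedasticity
#' across populations (Levene, median-centred by default), then dispatches
#' via [decide_test()].
#'
#' @param table A trait table.
#' @param stage `"adult"` or `"juvenile"`.
#' @param acronym Trait code.
#' @param alpha Assumption-check level (default 0.05).
#' @param levene_center Centering function for Levene's test;
#'   `median` (Brown-Forsythe, default) or `mean`.
#' @return A one-row report tibble: trait, contrast, assumption p-values,
#'   selected test, statistic, df, p-value, group sizes.
#' @export
#' @examples
#' tab <- generate_traits(oak_study_config())
#' compare_populations(tab, "adult", "SLA")
compare_populations <- function(table, stage, acronym, alpha = 0.05,
                                levene_center = stats::median) {
  groups <- trait_groups(table, acronym, by = "population",
                         subset_col = "stage", subset_val = stage)
  compare_groups(groups, acronym,
                 contrast = paste0("between_populations(", stage, ")"),
                 alpha = alpha, levene_center = levene_center)
}

#' Compare one trait between stages within a population
#'
#' Two-group version of [compare_populations()]: adult versus juvenile
#' values of one population, with the Mann-Whitney U test as the
#' nonparametric fallback when log-transformation does not restore
#' normality.
#'
#' @inheritParams compare_populations
#' @param population Population label.
#' @return A one-row report tibble.
#' @export
compare_stages <- function(table, population, acronym, alpha = 0.05,
                           levene_center = stats::median) {
  groups <- trait_groups(table, acronym, by = "stage",
                         subset_col = "population", subset_val = population)
  if (length(groups) < 2) {
    stop("population '", population, "' lacks one of the two stages",
         call. = FALSE)
  }
  groups <- groups[intersect(stage_levels(), names(groups))]
  compare_groups(groups, acronym,
                 contrast = paste0("between_stages(", population, ")"),
                 alpha = alpha, levene_center = levene_center)
}

#' Significance stars
#'
#' Conventional coding: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Run the full comparison battery
#'
#' For every registered trait: one between-population comparison per stage
#' and one between-stage comparison per population — 18 reports for the
#' default 3-population, 2-stage, 6-trait design. Traits (or cells) with
#' insufficient data are skipped with a notice row in the `skipped`
#' attribute. Optionally applies a Benjamini-Hochberg correction across
#' the battery (off by default).
#'
#' @inheritParams compare_populations
#' @param adjust Apply Benjamini-Hochberg adjustment across all reports
#'   (`p_adjusted` column); default `FALSE`.
#' @return A tibble of reports with a `stars` column; skipped contrasts in
#'   `attr(, "skipped")`.
#' @export
#' @examples
#' battery <- run_comparison_battery(generate_traits(oak_study_config()))
#' dplyr::count(battery, test_name)
run_comparison_battery <- function(table, alpha = 0.05,
                                   levene_center = stats::median,
                                   adjust = FALSE) {
  table <- as_trait_tbl(table)
  acrs <- trait_acronyms(table)
  pops <- attr(table, "populations")
  stages <- intersect(stage_levels(), unique(table$stage))
  reports <- list()
  skipped <- character()
  for (ac in acrs) {
    for (st in stages) {
      r <- tryCatch(
        compare_populations(table, st, ac, alpha, levene_center),
        error = function(e) conditionMessage(e))
      if (is.character(r)) {
        skipped <- c(skipped, paste0(ac, " between_populations(", st, "): ", r))
      } else reports <- c(reports, list(r))
    }
    if (length(stages) == 2) {
      for (pop in pops) {
        r <- tryCatch(
          compare_stages(table, pop, ac, alpha, levene_center),
          error = function(e) conditionMessage(e))
        if (is.character(r)) {
          skipped <- c(skipped, paste0(ac, " between_stages(", pop, "): ", r))
        } else reports <- c(reports, list(r))
      }
    }
  }
  out <- dplyr::bind_rows(reports)
  if (nrow(out) > 0) {
    out$stars <- significance_stars(out$p_value)
    if (adjust) {
      out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    }
  }
  attr(out, "skipped") <- skipped
  out
}
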