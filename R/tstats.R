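#' Configure the randomization null model
#'
#' The null model asks whether populations behave as random subsets of the
#' regional pool: individual-to-population labels are permuted uniformly
#' at random within a stage, preserving each population's sample size,
#' and the variance-ratio statistic is recomputed for every permutation.
#' The pool (the denominator) is unchanged by permutation.
#'
#' @param n_randomizations Number of label permutations (default 1000).
#'   At least 19 are required for a 5\% one-sided empirical test.
#' @param seed Integer seed; per-(stage, trait) substreams are derived
#'   deterministically from it.
#' @param strategy Null-model strategy; only `"permute_labels"` is
#'   currently implemented (the registry is extensible).
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_randomizations = 1000, seed = 1L,
                              strategy = "permute_labels") {
  n_randomizations <- as.integer(n_randomizations)
  if (is.na(n_randomizations) || n_randomizations < 19) {
    stop("n_randomizations must be >= 19", call. = FALSE)
  }
  strategy <- match.arg(strategy, "permute_labels")
  structure(list(n_randomizations = n_randomizations,
                 seed = as.integer(seed),
                 strategy = strategy),
            class = "null_model_config")
}

stage_trait_values <- function(table, stage, acronym, scale = "raw") {
  table <- as_trait_tbl(table)
  if (!acronym %in% trait_acronyms(table)) {
    stop("unknown trait: ", acronym, call. = FALSE)
  }
  if (!stage %in% stage_levels()) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  df <- tibble::as_tibble(table)[table$stage == stage,
                                 c("population", acronym)]
  names(df) <- c("population", "value")
  df <- df[!is.na(df$value), , drop = FALSE]
  if (scale == "log") df$value <- log(df$value)
  df
}

#' Observed variance-ratio T-statistic T_IP.IR
#'
#' The ratio of one population's trait variance to the regional pool's
#' variance at the individual level, where the pool is the aggregate of
#' all individuals of that ontogenetic stage across populations. Values
#' well below the null expectation indicate external filtering
#' (a constricted local trait distribution). Sample variances use the
#' n-1 denominator in both numerator and denominator; the ratio is
#' invariant to shifting or rescaling the trait.
#'
#' @param table A trait table.
#' @param stage Ontogenetic stage defining the pool.
#' @param acronym Trait code.
#' @param population Population whose variance forms the numerator.
#' @return A single nonnegative number.
#' @export
#' @examples
#' tab <- generate_traits(oak_study_config())
#' t_ip_ir(tab, "adult", "SLA", "Arcabuco")
t_ip_ir <- function(table, stage, acronym, population) {
  df <- stage_trait_values(table, stage, acronym)
  cell <- df$value[df$population == population]
  if (length(cell) < 2) {
    stop("population '", population, "' has fewer than 2 non-missing '",
         acronym, "' values at stage '", stage, "'", call. = FALSE)
  }
  if (nrow(df) < 2) stop("pool has fewer than 2 values", call. = FALSE)
  pool_var <- stats::var(df$value)
  if (pool_var == 0) stop("degenerate pool: zero variance", call. = FALSE)
  stats::var(cell) / pool_var
}

# Grouped variance ratios for one permutation order via cumulative sums:
# after permuting, groups occupy contiguous blocks of sizes `sizes`.
perm_t_matrix <- function(values, sizes, n_sim, seed) {
  n_total <- length(values)
  k <- length(sizes)
  pool_var <- stats::var(values)
  b <- cumsum(sizes)
  out <- matrix(NA_real_, n_sim, k)
  withr::with_seed(seed, {
    for (s in seq_len(n_sim)) {
      xp <- values[sample.int(n_total)]
      cs <- cumsum(xp)
      cs2 <- cumsum(xp * xp)
      s1 <- cs[b] - c(0, cs[b[-k]])
      s2 <- cs2[b] - c(0, cs2[b[-k]])
      out[s, ] <- (s2 - s1 * s1 / sizes) / (sizes - 1) / pool_var
    }
  })
  out
}

#' Null distribution of T_IP.IR under label permutation
#'
#' @inheritParams t_ip_ir
#' @param config A [null_model_config()].
#' @param scale `"raw"` (default) to permute raw trait values, `"log"`
#'   to work on the log scale.
#' @return A matrix with one column per population (those with at least 2
#'   non-missing values) and one row per randomization.
#' @export
null_distribution <- function(table, stage, acronym,
                              config = null_model_config(),
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(config, "null_model_config"))
  df <- stage_trait_values(table, stage, acronym, scale)
  sizes <- table(df$population)
  sizes <- sizes[sizes >= 2]
  if (length(sizes) < 2) {
    stop("need >= 2 populations with >= 2 values at stage '", stage, "'",
         call. = FALSE)
  }
  pops <- names(sizes)
  df <- df[df$population %in% pops, , drop = FALSE]
  if (stats::var(df$value) == 0) {
    stop("degenerate pool: zero variance", call. = FALSE)
  }
  sims <- perm_t_matrix(df$value, as.integer(sizes),
                        config$n_randomizations,
                        cell_seed(config$seed, "tnull", stage, acronym))
  colnames(sims) <- pops
  sims
}

#' Standardized effect size
#'
#' `(observed - mean(null)) / sd(null)` with the n-1 standard deviation.
#' Negative values mean the observed variance ratio is smaller than
#' expected for a random subset of the pool.
#'
#' @param t_obs Observed statistic.
#' @param sims Numeric vector of null-model simulated statistics.
#' @return A single number.
#' @export
#' @examples
#' ses(2, c(0.5, 1.0, 1.5))
ses <- function(t_obs, sims) {
  if (length(sims) < 2) stop("need >= 2 simulated values", call. = FALSE)
  s <- stats::sd(sims)
  if (s == 0) stop("degenerate null: zero simulation sd", call. = FALSE)
  (t_obs - mean(sims)) / s
}

#' Two one-sided empirical p-values
#'
#' Add-one rank estimators against the null simulations:
#' `p_low = (#\{sims <= t_obs\} + 1) / (n_sim + 1)` and
#' `p_high = (#\{sims >= t_obs\} + 1) / (n_sim + 1)`, so neither tail can
#' return zero at finite randomizations. Significance at level `alpha`
#' per tail is `p < alpha`.
#'
#' @inheritParams ses
#' @return Named numeric vector `c(p_low, p_high)`.
#' @export
#' @examples
#' one_sided_pvalues(2.5, c(1, 2, 3, 4))
one_sided_pvalues <- function(t_obs, sims) {
  n <- length(sims)
  if (n == 0) stop("empty simulation set", call. = FALSE)
  c(p_low = (sum(sims <= t_obs) + 1) / (n + 1),
    p_high = (sum(sims >= t_obs) + 1) / (n + 1))
}

#' Run the full external-filtering analysis
#'
#' For every (trait, stage): computes the observed T_IP.IR of each
#' population against the stage-restricted pool, builds the
#' label-permutation null, and reports the standardized effect size with
#' lower and upper one-sided empirical p-values. A population-mean
#' summary per (trait, stage) gives the arithmetic mean and sd of the
#' per-population SES values; its significance compares the observed
#' across-population mean T to the null distribution of the mean over
#' the same randomization draws.
#'
#' @inheritParams null_distribution
#' @param alpha Per-tail significance level (default 0.05, the
#'   conventional two-one-sided-tests level).
#' @return A `tstat_results` list with tibbles `tstats` (one row per
#'   trait x stage x population) and `mean_ses` (one row per
#'   trait x stage); skipped combinations in `attr(, "skipped")` of
#'   `tstats`.
#' @export
#' @examples
#' res <- run_tstats(generate_traits(oak_study_config()),
#'                   null_model_config(n_randomizations = 99))
#' res$tstats
run_tstats <- function(table, config = null_model_config(), alpha = 0.05,
                       scale = c("raw", "log")) {
  scale <- match.arg(scale)
  table <- as_trait_tbl(table)
  acrs <- trait_acronyms(table)
  stages <- intersect(stage_levels(), unique(table$stage))
  rows <- list()
  mean_rows <- list()
  skipped <- character()
  for (ac in acrs) {
    for (st in stages) {
      sims <- tryCatch(
        null_distribution(table, st, ac, config, scale),
        error = function(e) conditionMessage(e))
      if (is.character(sims)) {
        skipped <- c(skipped, paste0(ac, " @ ", st, ": ", sims))
        next
      }
      df <- stage_trait_values(table, st, ac, scale)
      pops <- colnames(sims)
      sizes <- vapply(pops, function(p) sum(df$population == p), integer(1))
      pool_var <- stats::var(df$value[df$population %in% pops])
      t_obs <- vapply(pops, function(p) {
        stats::var(df$value[df$population == p]) / pool_var
      }, numeric(1))
      per_pop <- purrr::map_dfr(seq_along(pops), function(i) {
        t_i <- unname(t_obs[i])
        sims_i <- sims[, i]
        p2 <- one_sided_pvalues(t_i, sims_i)
        tibble::tibble(
          acronym = ac, stage = st, population = pops[i],
          t_obs = t_i,
          null_mean = mean(sims_i),
          null_sd = stats::sd(sims_i),
          ses = ses(t_i, sims_i),
          p_low = p2[["p_low"]],
          p_high = p2[["p_high"]],
          null_q_low = unname(stats::quantile(sims_i, alpha)),
          null_q_high = unname(stats::quantile(sims_i, 1 - alpha)),
          n_sim = nrow(sims),
          n_individuals = unname(sizes[i])
        )
      })
      rows <- c(rows, list(per_pop))
      mean_null <- rowMeans(sims)
      pm <- one_sided_pvalues(mean(t_obs), mean_null)
      mean_rows <- c(mean_rows, list(tibble::tibble(
        acronym = ac, stage = st,
        mean_t_obs = mean(t_obs),
        mean_ses = mean(per_pop$ses),
        sd_ses = stats::sd(per_pop$ses),
        p_low = pm[["p_low"]],
        p_high = pm[["p_high"]]
      )))
    }
  }
  tstats <- dplyr::bind_rows(rows)
  if (nrow(tstats) > 0) {
    tstats$significant_low <- tstats$p_low < alpha
    tstats$significant_high <- tstats$p_high < alpha
  }
  attr(tstats, "skipped") <- skipped
  structure(
    list(tstats = tstats,
         mean_ses = dplyr::bind_rows(mean_rows),
         alpha = alpha,
         config = config,
         scale = scale),
    class = "tstat_results"
  )
}

#' @export
print.tstat_results <- function(x, ...) {
  cat("External-filtering T_IP.IR analysis (", x$config$n_randomizations,
      " randomizations, alpha = ", x$alpha, ", ", x$scale, " scale)\n",
      sep = "")
  print(x$tstats)
  invisible(x)
}

#' @export
tidy.tstat_results <- function(x, ...) x$tstats

#' @export
glance.tstat_results <- function(x, ...) x$mean_ses
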