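#' Cell-parameter grid for the synthetic generator
#'
#' One row per (population, stage, trait) cell giving the log-scale
#' location and spread of that cell's lognormal distribution. Traits are
#' modelled as normal on the log scale — the minimal faithful assumption
#' for right-skewed positive traits that are analysed after
#' log-transformation.
#'
#' @param populations Character vector of population labels.
#' @param stages Character vector of stages (subset of adult/juvenile).
#' @param acronyms Trait codes.
#' @param meanlog,sdlog Baseline log-scale mean and sd, recycled across
#'   cells (per-cell values can be edited on the returned tibble).
#' @return A tibble with columns `population`, `stage`, `acronym`,
#'   `meanlog`, `sdlog`.
#' @export
cell_params_grid <- function(populations, stages = stage_levels(),
                             acronyms, meanlog = 0, sdlog = 0.25) {
  grid <- tidyr::expand_grid(population = populations, stage = stages,
                             acronym = acronyms)
  grid$meanlog <- rep_len(meanlog, nrow(grid))
  grid$sdlog <- rep_len(sdlog, nrow(grid))
  grid
}

#' Describe a synthetic trait study
#'
#' Bundles everything needed to simulate an individual-level trait table:
#' population labels, the per-cell sample size, per-cell lognormal
#' parameters, a per-population variance-filtering multiplier, a missing
#' rate, and a seed. `filtering_strength` multiplies the log-scale sd of
#' every cell of that population: values below 1 constrict the population's
#' trait variance relative to the pool, emulating an external
#' environmental filter; unlisted populations default to 1 (no filtering).
#'
#' @param populations Ordered population labels (default the three Andean
#'   oak study sites).
#' @param n_per_cell Individuals per (population, stage) cell (default 20).
#' @param cell_params Tibble as from [cell_params_grid()]; stages and
#'   traits are inferred from it.
#' @param filtering_strength Named numeric vector, population -> multiplier
#'   in (0, Inf) applied to `sdlog`.
#' @param missing_rate Probability in [0, 1) that any single trait value is
#'   missing.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(
#'   populations = c("A", "B"),
#'   cell_params = cell_params_grid(c("A", "B"), "adult", "SLA",
#'                                  meanlog = 4.3, sdlog = 0.25)
#' )
#' generate_traits(cfg)
synthetic_config <- function(populations = c("Arcabuco", "Chicaque", "Encino"),
                             n_per_cell = 20,
                             cell_params = cell_params_grid(populations,
                                                            acronyms = default_trait_registry()$acronym),
                             filtering_strength = numeric(),
                             missing_rate = 0,
                             seed = 1L) {
  cfg <- structure(
    list(populations = as.character(populations),
         n_per_cell = as.integer(n_per_cell),
         cell_params = tibble::as_tibble(cell_params),
         filtering_strength = filtering_strength,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  problems <- character()
  if (cfg$n_per_cell < 2) problems <- c(problems, "n_per_cell must be >= 2")
  cp <- cfg$cell_params
  needed <- c("population", "stage", "acronym", "meanlog", "sdlog")
  if (!all(needed %in% names(cp))) {
    problems <- c(problems, paste("cell_params needs columns:",
                                  paste(needed, collapse = ", ")))
  } else {
    if (any(cp$sdlog <= 0)) problems <- c(problems, "all sdlog must be > 0")
    if (!all(cp$population %in% cfg$populations)) {
      problems <- c(problems, "cell_params population not in label set")
    }
    if (!all(cp$stage %in% stage_levels())) {
      problems <- c(problems, "cell_params stage outside adult/juvenile")
    }
    grid <- tidyr::expand_grid(population = cfg$populations,
                               stage = unique(cp$stage),
                               acronym = unique(cp$acronym))
    key <- function(d) paste(d$population, d$stage, d$acronym)
    if (anyDuplicated(key(cp)) || !setequal(key(cp), key(grid))) {
      problems <- c(problems,
                    "cell_params must contain exactly one row per (population, stage, trait)")
    }
  }
  if (length(cfg$filtering_strength) > 0) {
    if (is.null(names(cfg$filtering_strength)) ||
        any(names(cfg$filtering_strength) == "")) {
      problems <- c(problems, "filtering_strength must be a named vector")
    }
    if (any(cfg$filtering_strength <= 0)) {
      problems <- c(problems, "filtering_strength values must be > 0")
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    problems <- c(problems, "missing_rate must be in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid synthetic config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic 31-bit sub-seed from the global seed plus cell identity, so
# adding a trait or population never perturbs other cells' draws.
cell_seed <- function(seed, ...) {
  s <- paste(seed, ..., sep = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

strength_of <- function(cfg, population) {
  s <- cfg$filtering_strength
  if (population %in% names(s)) unname(s[[population]]) else 1
}

generate_from_params <- function(cfg, params, tag) {
  stages <- unique(params$stage)
  cells <- tidyr::expand_grid(population = cfg$populations, stage = stages)
  acrs <- unique(params$acronym)
  rows <- purrr::pmap(cells, function(population, stage) {
    ids <- sprintf("%s_%s_%02d", population, substr(stage, 1, 3),
                   seq_len(cfg$n_per_cell))
    out <- tibble::tibble(individual_id = ids, population = population,
                          stage = stage)
    for (ac in acrs) {
      p <- params[params$population == population & params$stage == stage &
                    params$acronym == ac, ]
      sdl <- p$sdlog * strength_of(cfg, population)
      withr::with_seed(cell_seed(cfg$seed, tag, population, stage, ac), {
        v <- stats::rlnorm(cfg$n_per_cell, p$meanlog, sdl)
        if (cfg$missing_rate > 0) {
          v[stats::runif(cfg$n_per_cell) < cfg$missing_rate] <- NA_real_
        }
      })
      out[[ac]] <- v
    }
    out
  })
  reg <- dplyr::bind_rows(
    dplyr::filter(default_trait_registry(), .data$acronym %in% acrs),
    trait_registry(setdiff(acrs, default_trait_registry()$acronym))
  )
  reg <- reg[match(acrs, reg$acronym), , drop = FALSE]
  trait_table(dplyr::bind_rows(rows), registry = reg,
              populations = cfg$populations)
}

#' Simulate a trait table
#'
#' Draws each (population, stage, trait) cell from
#' lognormal(meanlog, sdlog x filtering_strength\[population\]), with
#' independent deterministic substreams per cell. The same config and seed
#' always yield a byte-identical table.
#'
#' @param config A [synthetic_config()].
#' @return A validated `trait_tbl` with
#'   `length(populations) * n_stages * n_per_cell` rows.
#' @export
#' @examples
#' tab <- generate_traits(oak_study_config())
#' nrow(tab)  # 3 populations x 2 stages x 20 individuals = 120
generate_traits <- function(config) {
  validate_synthetic_config(config)
  generate_from_params(config, config$cell_params, tag = "alt")
}

#' Simulate a null-world trait table
#'
#' The null world in which populations are random subsets of one regional
#' pool: within each (stage, trait), every population shares a single
#' lognormal distribution, obtained by averaging `meanlog` and `sdlog`
#' across the config's populations; per-population parameter differences
#' and `filtering_strength` are ignored. Population labels are then pure
#' partitions of one pool, which is the reference world for calibrating
#' the T_IP.IR permutation test.
#'
#' @inheritParams generate_traits
#' @return A validated `trait_tbl`.
#' @export
#' @examples
#' null_tab <- generate_null_traits(oak_study_config())
generate_null_traits <- function(config) {
  validate_synthetic_config(config)
  pooled <- dplyr::summarise(
    dplyr::group_by(config$cell_params, .data$stage, .data$acronym),
    meanlog = mean(.data$meanlog), sdlog = mean(.data$sdlog),
    .groups = "drop"
  )
  params <- tidyr::expand_grid(population = config$populations,
                               pooled)
  cfg <- config
  cfg$filtering_strength <- numeric()
  generate_from_params(cfg, params, tag = "null")
}

#' Canonical Andean-oak study configuration
#'
#' A ready-made config emulating a 3-population, 2-stage, 20-individual
#' per cell study of the six default traits, with biologically plausible
#' magnitudes, stage effects, population shifts, stage-by-population
#' interactions, and variance constriction (external filtering) in two
#' populations. Effect directions, not magnitudes, are the documented
#' content: juveniles of the first population (Arcabuco) have lower LA,
#' SLA and SRL and higher LDMC than the other populations, and Arcabuco
#' has the strongest variance filtering. Values are illustrative by
#' design, not estimates of any field population.
#'
#' @param seed Integer seed stored in the config.
#' @return A `synthetic_config`.
#' @export
#' @examples
#' cfg <- oak_study_config()
#' cfg$n_per_cell
oak_study_config <- function(seed = 20211L) {
  pops <- c("Arcabuco", "Chicaque", "Encino")
  base <- tibble::tribble(
    ~acronym, ~stage,     ~meanlog,   ~sdlog,
    "LT",     "adult",    log(0.30),  0.18,
    "LT",     "juvenile", log(0.22),  0.18,
    "LA",     "adult",    log(45),    0.35,
    "LA",     "juvenile", log(28),    0.35,
    "SLA",    "adult",    log(75),    0.25,
    "SLA",    "juvenile", log(110),   0.25,
    "LDMC",   "adult",    log(0.48),  0.10,
    "LDMC",   "juvenile", log(0.42),  0.10,
    "WD",     "adult",    log(0.65),  0.08,
    "WD",     "juvenile", log(0.55),  0.08,
    "SRL",    "adult",    log(900),   0.40,
    "SRL",    "juvenile", log(1400),  0.40
  )
  params <- tidyr::expand_grid(population = pops, base)
  shift <- function(params, pop, stg, ac, delta) {
    i <- params$population == pop & params$stage == stg & params$acronym == ac
    params$meanlog[i] <- params$meanlog[i] + delta
    params
  }
  # Arcabuco juveniles: conservative leaf economics, shorter cheaper roots.
  params <- shift(params, "Arcabuco", "juvenile", "LA", -0.30)
  params <- shift(params, "Arcabuco", "juvenile", "SLA", -0.20)
  params <- shift(params, "Arcabuco", "juvenile", "SRL", -0.25)
  params <- shift(params, "Arcabuco", "juvenile", "LDMC", +0.15)
  # Encino adults: denser tissues, longer specific root length.
  params <- shift(params, "Encino", "adult", "LDMC", +0.10)
  params <- shift(params, "Encino", "adult", "WD", +0.08)
  params <- shift(params, "Encino", "adult", "SRL", +0.20)
  # Chicaque juveniles: acquisitive leaves.
  params <- shift(params, "Chicaque", "juvenile", "SLA", +0.10)
  params <- shift(params, "Chicaque", "juvenile", "LDMC", -0.10)
  params <- shift(params, "Chicaque", "juvenile", "LT", +0.10)
  synthetic_config(
    populations = pops,
    n_per_cell = 20,
    cell_params = params,
    filtering_strength = c(Arcabuco = 0.6, Encino = 0.8),
    missing_rate = 0,
    seed = seed
  )
}
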