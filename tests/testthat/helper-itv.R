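# Build a single-stage, single-trait table from named per-population values.
make_table <- function(values_by_pop, stage = "adult", acronym = "SLA") {
  rows <- purrr::imap(values_by_pop, function(v, pop) {
    tibble::tibble(
      individual_id = paste0(pop, "_", stage, "_", seq_along(v)),
      population = pop, stage = stage, value = v
    )
  })
  df <- dplyr::bind_rows(rows)
  names(df)[names(df) == "value"] <- acronym
  trait_table(df)
}

# Two-stage variant: values_by_pop is pop -> list(adult = ..., juvenile = ...).
make_table2 <- function(values_by_pop, acronym = "SLA") {
  rows <- purrr::imap(values_by_pop, function(stages, pop) {
    purrr::imap(stages, function(v, st) {
      tibble::tibble(
        individual_id = paste0(pop, "_", st, "_", seq_along(v)),
        population = pop, stage = st, value = v
      )
    })
  })
  df <- dplyr::bind_rows(purrr::flatten(rows))
  names(df)[names(df) == "value"] <- acronym
  trait_table(df)
}

# Independent two-pass sample-variance oracle (never calls stats::var).
brute_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}
brute_t_ratio <- function(cell, pool) brute_var(cell) / brute_var(pool)

# Single-trait, single-stage synthetic config for fast simulations.
one_trait_config <- function(seed, populations = c("P1", "P2", "P3"),
                             n_per_cell = 20, stage = "adult",
                             meanlog = 4.3, sdlog = 0.25,
                             filtering_strength = numeric()) {
  synthetic_config(
    populations = populations, n_per_cell = n_per_cell,
    cell_params = cell_params_grid(populations, stage, "SLA",
                                   meanlog = meanlog, sdlog = sdlog),
    filtering_strength = filtering_strength, seed = seed
  )
}
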