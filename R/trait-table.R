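#' Default functional-trait registry
#'
#' The six leaf, wood and root traits routinely measured in individual-level
#' trait studies of woody plants, with their units and transform state.
#' Traits are stored on the raw measurement scale until [log_transform()] is
#' applied; the `transform` column records what has been applied so far.
#'
#' @details LDMC is stored as a dimensionless dry/fresh mass ratio
#'   (g g^-1); some labs report it in mg g^-1, so the unit label is
#'   configurable via [trait_registry()].
#'
#' @return A tibble with columns `acronym`, `trait`, `units`, `transform`.
#' @export
#' @examples
#' default_trait_registry()
default_trait_registry <- function() {
  tibble::tibble(
    acronym   = c("LT", "LA", "SLA", "LDMC", "WD", "SRL"),
    trait     = c("leaf thickness", "leaf area", "specific leaf area",
                  "leaf dry matter content", "wood density",
                  "specific root length"),
    units     = c("mm", "cm2", "cm2 g-1", "g g-1", "g cm-3", "cm g-1"),
    transform = "none"
  )
}

#' Build a custom trait registry
#'
#' @param acronym Character vector of unique short trait codes.
#' @param trait Full trait names (defaults to the acronyms).
#' @param units Unit labels (free text).
#' @param transform Transform already applied to stored values, `"none"` or
#'   `"log"` (recycled).
#' @return A registry tibble as in [default_trait_registry()].
#' @export
trait_registry <- function(acronym, trait = acronym, units = "",
                           transform = "none") {
  if (anyDuplicated(acronym)) {
    stop("trait acronyms must be unique within a registry", call. = FALSE)
  }
  if (!all(transform %in% c("none", "log"))) {
    stop("transform must be 'none' or 'log'", call. = FALSE)
  }
  tibble::tibble(acronym = as.character(acronym),
                 trait = as.character(trait),
                 units = as.character(units),
                 transform = as.character(transform))
}

stage_levels <- function() c("adult", "juvenile")

#' Construct and validate a trait table
#'
#' A trait table is a tibble with one row per sampled individual: an
#' `individual_id`, a `population` label, an ontogenetic `stage`
#' (`"adult"` or `"juvenile"`), and one numeric column per registered trait.
#' All downstream analyses — group summaries, population/stage comparisons,
#' the dummy-coded linear model, and the T_IP.IR external-filtering test —
#' consume this one format.
#'
#' @param x A data frame with columns `individual_id`, `population`,
#'   `stage`, and the trait columns named by registry acronyms.
#' @param registry Trait registry tibble; defaults to the trait columns
#'   found in `x` matched against [default_trait_registry()], falling back
#'   to an ad-hoc registry for unrecognized columns.
#' @param populations Optional ordered character vector of population
#'   labels; defaults to order of first appearance.
#' @return A validated `trait_tbl` (a tibble subclass carrying the registry
#'   and population order as attributes).
#' @export
#' @examples
#' tab <- generate_traits(oak_study_config())
#' trait_table(as.data.frame(tab))
trait_table <- function(x, registry = NULL, populations = NULL) {
  x <- tibble::as_tibble(x)
  mandatory <- c("individual_id", "population", "stage")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(registry)) {
    candidates <- setdiff(names(x), mandatory)
    known <- default_trait_registry()
    registry <- dplyr::bind_rows(
      dplyr::filter(known, .data$acronym %in% candidates),
      trait_registry(setdiff(candidates, known$acronym))
    )
    registry <- registry[match(candidates, registry$acronym), , drop = FALSE]
  }
  x$individual_id <- as.character(x$individual_id)
  x$population <- as.character(x$population)
  x$stage <- as.character(x$stage)

  if (anyDuplicated(x$individual_id)) {
    dups <- unique(x$individual_id[duplicated(x$individual_id)])
    stop("duplicate individual_id: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(x$stage), stage_levels())
  if (length(bad_stage) > 0) {
    stop("invalid stage value(s): ", paste(bad_stage, collapse = ", "),
         "; allowed levels are: ", paste(stage_levels(), collapse = ", "),
         call. = FALSE)
  }
  for (ac in registry$acronym) {
    if (!ac %in% names(x)) {
      x[[ac]] <- NA_real_
      next
    }
    v <- x[[ac]]
    if (!is.numeric(v)) {
      stop("trait column '", ac, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("nonpositive value for trait '", ac, "' in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (individual ", x$individual_id[bad[1]], ")", call. = FALSE)
    }
    x[[ac]] <- as.double(v)
  }
  if (is.null(populations)) {
    populations <- unique(x$population)
  } else if (!all(unique(x$population) %in% populations)) {
    stop("population label(s) in data absent from the supplied label set",
         call. = FALSE)
  }
  x <- x[, c(mandatory, registry$acronym), drop = FALSE]
  new_trait_tbl(x, registry, populations)
}

new_trait_tbl <- function(x, registry, populations) {
  structure(
    x,
    registry = registry,
    populations = as.character(populations),
    class = c("trait_tbl", class(tibble::tibble()))
  )
}

#' @export
print.trait_tbl <- function(x, ...) {
  reg <- trait_acronyms(x)
  cat("# Trait table: ", nrow(x), " individuals, ",
      length(attr(x, "populations")), " populations, ",
      length(reg), " traits (", paste(reg, collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Registry and trait accessors
#'
#' @param table A trait table (or plain data frame, in which case the
#'   registry is inferred).
#' @return `get_registry()` the registry tibble; `trait_acronyms()` the
#'   character vector of registered trait codes.
#' @export
get_registry <- function(table) {
  reg <- attr(table, "registry")
  if (is.null(reg)) reg <- attr(trait_table(table), "registry")
  reg
}

#' @rdname get_registry
#' @export
trait_acronyms <- function(table) get_registry(table)$acronym

as_trait_tbl <- function(table) {
  if (inherits(table, "trait_tbl")) table else trait_table(table)
}

#' Read a trait table from CSV
#'
#' Reads a comma-separated, header-row, decimal-point CSV. Unparseable
#' trait cells become missing values with a single summary warning; empty
#' fields are missing values.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   `c(individual_id = "tree", population = "site")`. Unmapped columns are
#'   used as-is.
#' @param registry Optional trait registry; by default inferred from the
#'   remaining columns.
#' @return A validated `trait_tbl`.
#' @export
read_trait_table <- function(path, col_map = NULL, registry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' (for '", canon, "') not in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("individual_id", "population", "stage")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trait_cols <- setdiff(names(raw), mandatory)
  n_bad <- 0L
  for (tc in trait_cols) {
    v <- raw[[tc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & v != "" & is.na(num)
    n_bad <- n_bad + sum(bad)
    raw[[tc]] <- num
  }
  if (n_bad > 0) {
    warning(n_bad, " unparseable trait cell(s) set to missing", call. = FALSE)
  }
  trait_table(raw, registry = registry)
}

#' Write a trait table to CSV
#'
#' Missing values are written as empty fields, never as sentinel numbers;
#' [read_trait_table()] reproduces the table up to floating-point text
#' round-trip.
#'
#' @param table A trait table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  table <- as_trait_tbl(table)
  readr::write_csv(tibble::as_tibble(table), path, na = "", progress = FALSE)
  invisible(path)
}

#' Natural-log transform of trait columns
#'
#' Replaces the selected trait values by their natural logarithm and flips
#' the registry's transform flag, guarding against double application.
#' Missing values stay missing. All six default traits are strictly
#' positive physical quantities, so the log is always defined on valid
#' tables.
#'
#' @param table A trait table.
#' @param acronyms Traits to transform; default all not-yet-transformed.
#' @return The transformed `trait_tbl`.
#' @export
#' @examples
#' tab <- generate_traits(oak_study_config())
#' logged <- log_transform(tab)
#' get_registry(logged)$transform
log_transform <- function(table, acronyms = NULL) {
  table <- as_trait_tbl(table)
  reg <- get_registry(table)
  if (is.null(acronyms)) acronyms <- reg$acronym[reg$transform == "none"]
  unknown <- setdiff(acronyms, reg$acronym)
  if (length(unknown) > 0) {
    stop("unregistered trait(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  already <- acronyms[reg$transform[match(acronyms, reg$acronym)] == "log"]
  if (length(already) > 0) {
    stop("trait(s) already log-transformed: ", paste(already, collapse = ", "),
         call. = FALSE)
  }
  for (ac in acronyms) {
    v <- table[[ac]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("cannot log-transform nonpositive value of '", ac,
           "' for individual ", table$individual_id[bad[1]], call. = FALSE)
    }
    table[[ac]] <- log(v)
  }
  reg$transform[reg$acronym %in% acronyms] <- "log"
  attr(table, "registry") <- reg
  table
}

#' Per-cell group summaries
#'
#' Mean and standard deviation (n-1 denominator) of every
#' (population, stage, trait) cell, counting non-missing values only.
#' Cells with no observed values are absent from the output; singleton
#' cells report `sd = NA`.
#'
#' @param table A trait table.
#' @return A tibble with columns `population`, `stage`, `acronym`, `n`,
#'   `mean`, `sd`.
#' @export
#' @examples
#' summarize_groups(generate_traits(oak_study_config()))
summarize_groups <- function(table) {
  table <- as_trait_tbl(table)
  acrs <- trait_acronyms(table)
  long <- tidyr::pivot_longer(tibble::as_tibble(table),
                              cols = dplyr::all_of(acrs),
                              names_to = "acronym", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$population, .data$stage, .data$acronym),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$population, .data$stage,
                 match(.data$acronym, acrs))
}
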