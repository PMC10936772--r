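pipeline_stage_names <- function() {
  c("summaries", "comparisons", "lm", "tstats", "pca")
}

#' Configure a full analysis run
#'
#' @param input Either a path to a trait CSV or a [synthetic_config()]
#'   (default: [oak_study_config()], so a run works out of the box).
#' @param output_dir Directory for the report files (created if needed).
#' @param alpha Significance level used throughout (default 0.05).
#' @param null_config [null_model_config()] for the T-statistics stage;
#'   its seed is overridden by a stream derived from `seed`.
#' @param reference_cell Reference cell for the linear models (default
#'   juveniles of the first population).
#' @param stages Pipeline stages to run, a subset of
#'   `r paste(pipeline_stage_names(), collapse = ", ")`.
#' @param seed Global seed; per-stage seeds are derived from it so
#'   disabling one stage never changes another stage's results.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = oak_study_config(),
                            output_dir = tempfile("itv_run_"),
                            alpha = 0.05,
                            null_config = null_model_config(),
                            reference_cell = NULL,
                            stages = pipeline_stage_names(),
                            seed = 1L) {
  if (length(stages) == 0) stop("at least one stage required", call. = FALSE)
  stages <- match.arg(stages, pipeline_stage_names(), several.ok = TRUE)
  if (!(is.character(input) || inherits(input, "synthetic_config"))) {
    stop("input must be a CSV path or a synthetic_config", call. = FALSE)
  }
  structure(
    list(input = input, output_dir = output_dir, alpha = alpha,
         null_config = null_config, reference_cell = reference_cell,
         stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

flatten_for_csv <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        paste(signif(unname(v), 6), collapse = ";")
      }, character(1))
    }
  }
  df
}

#' Run the full intraspecific trait-variation pipeline
#'
#' Ingests (or synthesizes) a trait table and runs the enabled stages:
#' group summaries, the assumption-driven comparison battery, the
#' dummy-coded linear models, the T_IP.IR external-filtering analysis,
#' and the per-stage trait PCAs. Every output is a tidy CSV in
#' `output_dir`; a JSON manifest records the config, seed, versions,
#' per-stage row counts, warnings and timings, and is written even when
#' a stage fails (failures are recorded, independent stages still run).
#' Given the same config and seed, outputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(output_dir = tempfile(),
#'                        null_config = null_model_config(99))
#' manifest <- run_pipeline(cfg)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(
    seed = config$seed,
    alpha = config$alpha,
    stages = config$stages,
    versions = list(itvtools = as.character(utils::packageVersion("itvtools")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    rows = list(), warnings = list(), errors = list(), seconds = list()
  )

  if (is.character(config$input)) {
    note("reading trait table from ", config$input)
    table <- read_trait_table(config$input)
    manifest$input <- config$input
  } else {
    gen_cfg <- config$input
    gen_cfg$seed <- cell_seed(config$seed, "generate")
    note("generating synthetic trait table (seed ", gen_cfg$seed, ")")
    table <- generate_traits(gen_cfg)
    write_trait_table(table, out("trait_table.csv"))
    manifest$input <- list(synthetic = TRUE,
                           n_per_cell = gen_cfg$n_per_cell,
                           populations = gen_cfg$populations,
                           generator_seed = gen_cfg$seed)
  }
  manifest$rows$trait_table <- nrow(table)

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      note("stage '", name, "' skipped (disabled)")
      manifest$warnings[[name]] <<- "skipped: disabled in config"
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    manifest$seconds[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      note("stage '", name, "' FAILED: ", conditionMessage(res))
      manifest$errors[[name]] <<- conditionMessage(res)
    } else {
      note("stage '", name, "' done")
    }
  }

  run_stage("summaries", function() {
    gs <- summarize_groups(table)
    readr::write_csv(gs, out("group_summaries.csv"), progress = FALSE)
    manifest$rows$group_summaries <<- nrow(gs)
  })
  run_stage("comparisons", function() {
    battery <- run_comparison_battery(table, alpha = config$alpha)
    readr::write_csv(flatten_for_csv(battery), out("test_battery.csv"),
                     progress = FALSE)
    sk <- attr(battery, "skipped")
    if (length(sk) > 0) manifest$warnings$comparisons <<- sk
    manifest$rows$test_battery <<- nrow(battery)
  })
  run_stage("lm", function() {
    fits <- run_lm_battery(table, reference_cell = config$reference_cell)
    readr::write_csv(tidy(fits), out("lm_results.csv"), progress = FALSE)
    readr::write_csv(glance(fits), out("lm_models.csv"), progress = FALSE)
    manifest$rows$lm_results <<- nrow(tidy(fits))
  })
  run_stage("tstats", function() {
    nm <- config$null_config
    nm$seed <- cell_seed(config$seed, "tstats")
    res <- run_tstats(table, nm, alpha = config$alpha)
    readr::write_csv(res$tstats, out("tstat_results.csv"), progress = FALSE)
    readr::write_csv(res$mean_ses, out("mean_ses.csv"), progress = FALSE)
    sk <- attr(res$tstats, "skipped")
    if (length(sk) > 0) manifest$warnings$tstats <<- sk
    manifest$rows$tstat_results <<- nrow(res$tstats)
    manifest$rows$mean_ses <<- nrow(res$mean_ses)
  })
  run_stage("pca", function() {
    for (st in intersect(stage_levels(), unique(table$stage))) {
      m <- stage_trait_matrix(table, st)
      p <- run_pca(standardize_matrix(m))
      readr::write_csv(glance(p), out(paste0("pca_explained_", st, ".csv")),
                       progress = FALSE)
      readr::write_csv(tidy(p), out(paste0("pca_loadings_", st, ".csv")),
                       progress = FALSE)
      scores <- tibble::as_tibble(p$scores, rownames = "individual_id")
      readr::write_csv(scores, out(paste0("pca_scores_", st, ".csv")),
                       progress = FALSE)
      manifest$rows[[paste0("pca_scores_", st)]] <- nrow(scores)
    }
  })

  writeLines(log_lines, out("run.log"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

report_section <- function(dir, file, label, describe) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    return(c(paste0("## ", label), "", paste0("`", file, "` absent."), ""))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  c(paste0("## ", label), "", describe(df), "")
}

#' Render a human-readable summary of a pipeline run
#'
#' Tabulates the run directory's CSVs as markdown, starring significant
#' results (* p < 0.05, ** p < 0.01, *** p < 0.001). Missing files are
#' listed as absent, never fatal.
#'
#' @param dir A directory produced by [run_pipeline()].
#' @param file Optional path to also write the markdown to.
#' @return The markdown text as a character vector, invisibly printed.
#' @export
render_report <- function(dir, file = NULL) {
  lines <- c("# Intraspecific trait variation run report", "",
             paste0("Directory: `", dir, "`"), "")
  lines <- c(lines, report_section(dir, "group_summaries.csv",
                                   "Group summaries", function(df) {
    sprintf("%d (population, stage, trait) cells summarised.", nrow(df))
  }))
  lines <- c(lines, report_section(dir, "test_battery.csv",
                                   "Population and stage comparisons",
                                   function(df) {
    sig <- df[df$p_value < 0.05, , drop = FALSE]
    c(sprintf("%d comparisons; %d significant at 0.05:",
              nrow(df), nrow(sig)),
      "",
      if (nrow(sig) > 0) {
        sprintf("- %s %s: %s, p = %.3g %s", sig$acronym, sig$contrast,
                sig$test_name, sig$p_value, significance_stars(sig$p_value))
      })
  }))
  lines <- c(lines, report_section(dir, "lm_models.csv",
                                   "Dummy-coded linear models",
                                   function(df) {
    sprintf("- %s: R2 = %.2f, F = %.2f, p = %.3g %s", df$acronym,
            df$r_squared, df$f_statistic, df$f_p,
            significance_stars(df$f_p))
  }))
  lines <- c(lines, report_section(dir, "tstat_results.csv",
                                   "External filtering (T_IP.IR)",
                                   function(df) {
    sig <- df[df$p_low < 0.05 | df$p_high < 0.05, , drop = FALSE]
    c(sprintf("%d population-level tests; %d significant at 0.05:",
              nrow(df), nrow(sig)),
      "",
      if (nrow(sig) > 0) {
        sprintf("- %s %s %s: SES = %.2f (p_low = %.3g, p_high = %.3g)",
                sig$acronym, sig$stage, sig$population, sig$ses,
                sig$p_low, sig$p_high)
      })
  }))
  for (st in stage_levels()) {
    f <- paste0("pca_explained_", st, ".csv")
    lines <- c(lines, report_section(dir, f, paste0("Trait PCA (", st, ")"),
                                     function(df) {
      paste0(df$component, ": ", sprintf("%.1f%%", 100 * df$explained),
             collapse = "; ")
    }))
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
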