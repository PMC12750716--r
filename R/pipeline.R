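# End-to-end orchestration: read config and data, derive variables,
# select adjustment sets from the DAG, estimate, bootstrap, and write a
# reproducible result bundle. Configuration lives in a YAML file; CLI
# flags (see inst/cli/gcompmed) override config keys. Output files
# carry no timestamps, so two runs with the same seed produce
# byte-identical bundles; wall-clock information goes only to run.log.

run_config_defaults <- function() {
  list(
    paths = list(data = NULL, dag = NULL, out = "gcompmed-results"),
    column_map = list(),
    confounders = NULL,
    adjustment = NULL,
    mediator_scale = "binary",
    m_binary_family = "linear_probability",
    bses_threshold = 56L,
    hlq_cut = 2.5,
    mc_draws = 100L,
    bootstrap_B = 1000L,
    seed = 1L,
    ci_level = 0.95,
    subsample = "first_visit",
    interaction = FALSE,
    draw_y = FALSE,
    write_replicates = FALSE)
}

#' Read a pipeline run configuration
#'
#' YAML file with keys `paths` (`data`, `dag`, `out`), `column_map`
#' (standard name -> CSV column name), `confounders`, `adjustment`
#' (optional explicit `mediator`/`outcome` sets overriding the DAG),
#' `mediator_scale`, `m_binary_family`, `bses_threshold`, `hlq_cut`,
#' `mc_draws`, `bootstrap_B`, `seed`, `ci_level`, `subsample`
#' (`first_visit`/`repeat_visit`), `interaction`, `draw_y`,
#' `write_replicates`. Missing keys take defaults.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  gc_assert(cfg$bootstrap_B >= 2, "bootstrap_B must be >= 2")
  gc_assert(cfg$ci_level > 0 && cfg$ci_level < 1,
            "ci_level must lie in (0, 1)")
  gc_assert(cfg$subsample %in% c("first_visit", "repeat_visit"),
            "subsample must be 'first_visit' or 'repeat_visit'")
  gc_assert(cfg$mediator_scale %in% c("raw", "binary"),
            "mediator_scale must be 'raw' or 'binary'")
  cfg
}

apply_column_map <- function(df, map) {
  for (std in names(map)) {
    src <- map[[std]]
    gc_assert(src %in% names(df),
              sprintf("mapped column '%s' (for '%s') absent from data",
                      src, std))
    names(df)[names(df) == src] <- std
  }
  df
}

#' Table-1-style descriptive summary
#'
#' Continuous variables as mean (SD), categorical as n (%), plus
#' median (IQR) for infant age and the BSES total.
#'
#' @param table derived analysis table.
#' @return List with `continuous`, `categorical` and `median_iqr`
#'   blocks; prints compactly.
#' @export
summarize_descriptives <- function(table) {
  cont <- intersect(c("maternal_age", "infant_age", "parity", "assets",
                      "bses_total"), names(table))
  cat_cols <- intersect(c("x_helpful", "m_bses_high", "y_exclusive",
                          "delivery_mode", "education", "employment",
                          "hiv", "hps_high", "hsi_high", "relationship",
                          "nurse_helpful"), names(table))
  continuous <- lapply(stats::setNames(cont, cont), function(col) {
    v <- table[[col]]
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  categorical <- lapply(stats::setNames(cat_cols, cat_cols), function(col) {
    tab <- table(table[[col]], useNA = "no")
    lapply(stats::setNames(as.list(as.integer(tab)), names(tab)),
           function(n) list(n = n, pct = 100 * n / sum(tab)))
  })
  med <- intersect(c("infant_age", "bses_total"), names(table))
  median_iqr <- lapply(stats::setNames(med, med), function(col) {
    v <- table[[col]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3])
  })
  structure(list(n = nrow(table), continuous = continuous,
                 categorical = categorical, median_iqr = median_iqr),
            class = "gcompmed_descriptives")
}

#' @export
print.gcompmed_descriptives <- function(x, ...) {
  cat(sprintf("Descriptives (n = %d)\n", x$n))
  for (nm in names(x$continuous)) {
    s <- x$continuous[[nm]]
    cat(sprintf("  %-14s %.1f (%.1f)\n", nm, s$mean, s$sd))
  }
  for (nm in names(x$median_iqr)) {
    s <- x$median_iqr[[nm]]
    cat(sprintf("  %-14s median %.0f (IQR %.0f-%.0f)\n",
                nm, s$median, s$q1, s$q3))
  }
  for (nm in names(x$categorical)) {
    lv <- x$categorical[[nm]]
    parts <- vapply(names(lv), function(l)
      sprintf("%s %d (%.0f%%)", l, lv[[l]]$n, lv[[l]]$pct), character(1L))
    cat(sprintf("  %-14s %s\n", nm, paste(parts, collapse = ", ")))
  }
  invisible(x)
}

#' Run the full estimation pipeline
#'
#' Reads the data CSV and DAG named in the config, derives analysis
#' variables, selects minimal sufficient adjustment sets, estimates the
#' mediation effects by G-computation, bootstraps them, and writes the
#' result bundle to the output directory: `derived_data.csv`,
#' `exclusion_log.json`, `adjustment_sets.json`, `inference.json`,
#' `inference.txt`, `descriptives.json`, `manifest.json`, `run.log`
#' (and `replicates.csv` when requested). On any failure the partially
#' written bundle is removed.
#'
#' @param config a `run_config` list (from [read_run_config()]) or a
#'   path to a YAML config file.
#' @param data optional data frame, bypassing `paths$data`.
#' @param dag optional [causal_dag()], bypassing `paths$dag`.
#' @return Invisibly, a list with the derived table, adjustment report,
#'   point estimates, inference table and output paths.
#' @export
run_pipeline <- function(config, data = NULL, dag = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  tryCatch({
    say("stage: input")
    if (is.null(data)) {
      gc_assert(!is.null(config$paths$data), "config paths$data is required")
      data <- utils::read.csv(config$paths$data, stringsAsFactors = FALSE)
    }
    data <- apply_column_map(as.data.frame(data), config$column_map)

    say("stage: derive")
    derived <- derive_variables(data, confounders = config$confounders,
                                bses_threshold = config$bses_threshold,
                                hlq_cut = config$hlq_cut)
    exclusions <- attr(derived, "exclusion_log")
    if (config$subsample == "repeat_visit") {
      derived <- select_repeat_visit(derived,
                                     bses_threshold = config$bses_threshold)
      exclusions <- c(exclusions,
                      repeat_visit = attr(derived, "exclusion_log"))
      say("subsample: repeat visit, n = %d", nrow(derived))
    }
    emit("derived_data.csv", function(p)
      utils::write.csv(derived, p, row.names = FALSE))
    emit("exclusion_log.json", function(p) write_json_file(exclusions, p))
    emit("descriptives.json", function(p)
      write_json_file(unclass(summarize_descriptives(derived)), p))

    say("stage: adjust")
    adj_report <- NULL
    adjustment <- config$adjustment
    if (is.null(adjustment)) {
      if (is.null(dag)) {
        gc_assert(!is.null(config$paths$dag),
                  "config paths$dag or explicit adjustment sets required")
        dag <- read_dag(config$paths$dag)
      }
      sets <- mediation_adjustment_sets(dag)
      adj_report <- list(
        for_mediator_equation = sets$for_mediator_equation,
        for_outcome_equation = sets$for_outcome_equation,
        chosen = sets$chosen,
        tie_break = "smallest set, ties broken lexicographically")
      mediator_col <- if (config$mediator_scale == "raw") "bses_total"
        else "m_bses_high"
      remap <- function(z) {
        z[z == dag$mediator] <- mediator_col
        z
      }
      adjustment <- list(mediator = remap(sets$chosen$mediator),
                         outcome = remap(sets$chosen$outcome))
      say("adjustment (mediator eq): {%s}",
          paste(adjustment$mediator, collapse = ", "))
      say("adjustment (outcome eq): {%s}",
          paste(adjustment$outcome, collapse = ", "))
    }
    emit("adjustment_sets.json", function(p)
      write_json_file(if (is.null(adj_report))
        list(explicit = adjustment) else adj_report, p))

    say("stage: estimate + bootstrap (seed %d, B = %d, draws = %d)",
        config$seed, config$bootstrap_B, config$mc_draws)
    inference <- gcomp_bootstrap(
      derived, adjustment = adjustment,
      mediator_scale = config$mediator_scale,
      m_binary_family = config$m_binary_family,
      B = config$bootstrap_B, mc_draws = config$mc_draws,
      rng_seed = config$seed, level = config$ci_level,
      interaction = config$interaction, draw_y = config$draw_y)

    emit("inference.json", function(p)
      write_json_file(inference_as_list(inference), p))
    emit("inference.txt", function(p)
      writeLines(format_inference_table(inference), p))
    if (isTRUE(config$write_replicates)) {
      emit("replicates.csv", function(p)
        utils::write.csv(as.data.frame(inference$replicates), p,
                         row.names = FALSE))
    }

    manifest <- list(
      package = "gcompmed",
      package_version = as.character(utils::packageVersion("gcompmed")),
      seed = config$seed,
      n_analysis = nrow(derived),
      config = config[setdiff(names(config), "paths")],
      outputs = basename(written))
    emit("manifest.json", function(p) write_json_file(manifest, p))
    writeLines(c(log_lines, sprintf("completed: %s", Sys.time())),
               file.path(out_dir, "run.log"))
    invisible(list(derived = derived, adjustment = adjustment,
                   adjustment_report = adj_report, inference = inference,
                   paths = c(written, file.path(out_dir, "run.log"))))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
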