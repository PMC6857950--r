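#' Configure a full pipeline run
#'
#' @param input Path to a sample CSV, or `NULL` to simulate.
#' @param sim_config A [simulation_config()] used when `input` is `NULL`;
#'   defaults to [default_study_config()] under `seed`.
#' @param panel Analyte panel.
#' @param outlier_method,alpha Screening settings.
#' @param index_variant,index_threshold Reference-interval typing settings.
#' @param nonnormal_method RI method for non-normal population analytes.
#' @param bootstrap_B,bootstrap_level Bootstrap settings.
#' @param factors Partition factors to summarize/compare.
#' @param dedup De-duplication for linear modeling (`"first"`/`"all"`).
#' @param seed Integer master seed for simulation and bootstrap.
#' @param outdir Output directory (created if absent).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, sim_config = NULL,
                       panel = default_analyte_panel(),
                       outlier_method = "horn", alpha = 0.05,
                       index_variant = "without_cva", index_threshold = 0.6,
                       nonnormal_method = "parametric_boxcox",
                       bootstrap_B = 1000, bootstrap_level = 0.90,
                       factors = partition_factors(), dedup = "first",
                       seed = 1L, outdir = tempfile("chelonRI_run_")) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  if (is.null(input) && is.null(sim_config)) {
    sim_config <- default_study_config(seed)
  }
  structure(list(input = input, sim_config = sim_config, panel = panel,
                 outlier_method = outlier_method, alpha = alpha,
                 index_variant = index_variant,
                 index_threshold = index_threshold,
                 nonnormal_method = nonnormal_method,
                 bootstrap_B = bootstrap_B,
                 bootstrap_level = bootstrap_level,
                 factors = factors, dedup = dedup,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the whole reference-interval pipeline
#'
#' Screening, variance components, reference intervals, partition summaries
#' and comparisons, AICc model selection, and a JSON provenance record, all
#' written as TSV/JSON files under `config$outdir`. Identical config and seed
#' give byte-identical outputs. Any stage error removes the partial outputs
#' of this run before propagating.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and `files`, the named
#'   vector of paths written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(screening = "screening.tsv",
             components = "variance_components.tsv",
             intervals = "reference_intervals.tsv",
             summaries = "group_summaries.tsv",
             comparisons = "comparisons.tsv",
             models = "model_selection.tsv",
             provenance = "provenance.json")
  files <- stats::setNames(file.path(config$outdir, files), names(files))
  written <- character(0)
  collected_warnings <- character(0)
  on.exit(NULL)

  run <- function() {
    data <- if (is.null(config$input)) {
      simulate_dataset(config$sim_config)
    } else {
      read_samples(config$input, config$panel)
    }

    screening <- screen_dataset(data, method = config$outlier_method,
                                alpha = config$alpha)
    write_table(screening$report, files["screening"])
    written <<- c(written, files["screening"])

    included <- apply_inclusion(data)
    comps <- variance_components(included,
                                 index_variant = config$index_variant,
                                 threshold = config$index_threshold)
    write_table(comps, files["components"])
    written <<- c(written, files["components"])

    intervals <- build_intervals(data, components = comps,
                                 screening = screening,
                                 nonnormal_method = config$nonnormal_method,
                                 level = config$bootstrap_level,
                                 B = config$bootstrap_B, seed = config$seed)
    write_table(intervals, files["intervals"])
    written <<- c(written, files["intervals"])

    summaries <- list(); comparisons <- list()
    for (a in data$analytes$analyte) {
      if (all(is.na(included$samples[[a]]))) next
      for (f in config$factors) {
        s <- tryCatch(summarize_groups(included, a, f, config$alpha),
                      error = function(e) NULL)
        if (!is.null(s)) summaries[[paste(a, f)]] <- s
        cmp <- tryCatch(compare_groups(included, a, f, config$alpha),
                        error = function(e) NULL)
        if (!is.null(cmp)) {
          pw <- cmp$pairwise
          comparisons[[paste(a, f)]] <- data.frame(
            analyte = a, factor = f, test = cmp$test,
            statistic = cmp$statistic, p = cmp$p,
            parametric = cmp$parametric,
            pairwise = if (is.null(pw)) "" else {
              paste(sprintf("%s~%s:%.4g", pw$level_a, pw$level_b, pw$p),
                    collapse = ";")
            },
            stringsAsFactors = FALSE)
        }
      }
    }
    write_table(do.call(rbind, c(summaries, list(make.row.names = FALSE))),
                files["summaries"])
    write_table(do.call(rbind, c(comparisons, list(make.row.names = FALSE))),
                files["comparisons"])
    written <<- c(written, files["summaries"], files["comparisons"])

    models <- list()
    for (a in data$analytes$analyte) {
      if (all(is.na(included$samples[[a]]))) next
      m <- tryCatch(select_model(included, a, dedup = config$dedup),
                    error = function(e) NULL)
      if (!is.null(m)) models[[a]] <- m
    }
    write_table(do.call(rbind, c(models, list(make.row.names = FALSE))),
                files["models"])
    written <<- c(written, files["models"])

    prov <- list(
      package = "chelonRI",
      version = as.character(utils::packageVersion("chelonRI")),
      seed = config$seed,
      settings = config[c("outlier_method", "alpha", "index_variant",
                          "index_threshold", "nonnormal_method",
                          "bootstrap_B", "bootstrap_level", "dedup",
                          "factors")],
      input = if (is.null(config$input)) "simulated" else config$input,
      n_samples = nrow(data$samples),
      n_animals = length(unique(data$samples$animal_id)),
      warnings = collected_warnings
    )
    jsonlite::write_json(prov, files["provenance"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <<- c(written, files["provenance"])

    list(data = data, screening = screening, components = comps,
         intervals = intervals,
         summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
         comparisons = do.call(rbind,
                               c(comparisons, list(make.row.names = FALSE))),
         models = models, files = files)
  }

  result <- withCallingHandlers(
    tryCatch(run(), error = function(e) {
      unlink(written)
      stop("pipeline failed (partial outputs removed): ",
           conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      collected_warnings <<- c(collected_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  invisible(result)
}
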