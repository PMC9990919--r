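#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order — data generation (or loading),
#' confidence-accuracy analysis, the accordance simulation, the group
#' train/test simulation, and power planning — writing one CSV per stage
#' into `out_dir`. Every CSV is accompanied by a `.provenance.json`
#' sidecar echoing the configuration, the seed and the package version.
#' On a stage failure a `FAILED` marker naming the stage is left in
#' `out_dir` and the error is rethrown; outputs of completed stages are
#' retained.
#'
#' @param config a named list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{global integer seed for all stochastic stages.}
#'     \item{data}{path of an input dataset CSV; not needed when a
#'       `generate` block is present.}
#'     \item{generate}{fields of [generator_config()]; writes `dataset.csv`.}
#'     \item{analyze}{`mode`: `"within"`, `"between"` or both; writes
#'       `coefficients_<mode>.csv` and `coefficient_summary.csv`.}
#'     \item{accordance}{`n_iterations`, `n_sample_questions`,
#'       `panel_size`; writes `accordance.csv`.}
#'     \item{groups}{`conditions` (list of `n_train`/`group_size`/
#'       `category` triples), `n_test`, `n_iterations`; writes
#'       `groups.csv` and `group_iterations.csv`.}
#'     \item{power}{`effect_size_f` (scalar or vector), `k_groups`,
#'       `alpha`, `power`; writes `power.csv`.}
#'   }
#' @param quiet suppress stage-boundary messages.
#' @return invisibly, a character vector of the written CSV paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("`config` must be a list or a YAML file path.")
  if (is.null(config$out_dir)) stopf("config must name an `out_dir`.")
  stages <- intersect(c("generate", "analyze", "accordance", "groups", "power"),
                      names(config))
  stochastic <- intersect(stages, c("generate", "accordance", "groups"))
  if (length(stochastic) > 0 && is.null(config$seed)) {
    stopf("config must carry a `seed` when stage(s) %s are enabled.",
          paste(stochastic, collapse = ", "))
  }
  if (!is.null(config$data) && !file.exists(config$data)) {
    stopf("input data file not found: %s", config$data)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  written <- character()
  emit <- function(table, name, stage) {
    path <- file.path(config$out_dir, name)
    write_summary(table, path)
    jsonlite::write_json(
      list(stage = stage, seed = config$seed,
           package_version = as.character(utils::packageVersion("crowdwise")),
           config = config[[stage]]),
      paste0(path, ".provenance.json"), auto_unbox = TRUE, null = "null")
    written <<- c(written, path)
    path
  }

  data <- NULL
  current_stage <- NULL
  withCallingHandlers(
    {
      if ("generate" %in% stages) {
        current_stage <- "generate"
        say("[generate] drawing synthetic dataset")
        gcfg <- config$generate
        if (is.null(gcfg$seed)) gcfg$seed <- config$seed
        data <- generate_dataset(do.call(generator_config, gcfg))
        path <- file.path(config$out_dir, "dataset.csv")
        write_dataset(data, path)
        jsonlite::write_json(
          list(stage = "generate", seed = gcfg$seed,
               package_version = as.character(utils::packageVersion("crowdwise")),
               config = config$generate),
          paste0(path, ".provenance.json"), auto_unbox = TRUE, null = "null")
        written <- c(written, path)
      } else if (!is.null(config$data)) {
        data <- read_dataset(config$data)
      }
      needs_data <- intersect(stages, c("analyze", "accordance", "groups"))
      if (length(needs_data) > 0 && is.null(data)) {
        stopf("stage(s) %s need a dataset: provide `data` or a `generate` block.",
              paste(needs_data, collapse = ", "))
      }

      if ("analyze" %in% stages) {
        current_stage <- "analyze"
        modes <- config$analyze$mode
        if (is.null(modes)) modes <- c("within", "between")
        summaries <- list()
        for (mode in modes) {
          say("[analyze] %s-question logistic fits", mode)
          est <- if (mode == "within") within_question_analysis(data)
                 else between_question_analysis(data)
          emit(est, sprintf("coefficients_%s.csv", mode), "analyze")
          s <- summarize_coefficients(est)
          s <- cbind(mode = mode, s)
          summaries[[mode]] <- s
        }
        emit(do.call(rbind, summaries), "coefficient_summary.csv", "analyze")
      }

      if ("accordance" %in% stages) {
        current_stage <- "accordance"
        acfg <- config$accordance
        say("[accordance] %s iterations",
            if (is.null(acfg$n_iterations)) 5000 else acfg$n_iterations)
        res <- run_accordance_simulation(
          data,
          n_iterations = acfg$n_iterations %||% 5000,
          n_sample_questions = acfg$n_sample_questions %||% 10,
          panel_size = acfg$panel_size %||% 15,
          seed = config$seed)
        emit(as.data.frame(res), "accordance.csv", "accordance")
      }

      if ("groups" %in% stages) {
        current_stage <- "groups"
        gcfg <- config$groups
        if (is.null(gcfg$conditions) || is.null(gcfg$n_test)) {
          stopf("groups stage needs `conditions` and `n_test`.")
        }
        summaries <- list()
        dumps <- list()
        for (ci in seq_along(gcfg$conditions)) {
          cond <- gcfg$conditions[[ci]]
          say("[groups] n_train=%s group_size=%s category=%s",
              cond$n_train, cond$group_size, cond$category)
          res <- run_group_simulation(
            data, n_train = cond$n_train, group_size = cond$group_size,
            category = cond$category, n_test = gcfg$n_test,
            n_iterations = gcfg$n_iterations %||% 5000,
            seed = substream_seed(config$seed, ci))
          tw <- summarize_test_worse(res)
          tw$mean_train_accuracy <- mean(res$train_accuracies)
          tw$mean_test_accuracy <- mean(res$test_accuracies)
          summaries[[ci]] <- tw
          dumps[[ci]] <- tibble::tibble(
            n_train = cond$n_train, group_size = cond$group_size,
            category = cond$category,
            iteration = seq_along(res$train_accuracies),
            train_accuracy = res$train_accuracies,
            test_accuracy = res$test_accuracies)
        }
        emit(do.call(rbind, summaries), "groups.csv", "groups")
        emit(do.call(rbind, dumps), "group_iterations.csv", "groups")
      }

      if ("power" %in% stages) {
        current_stage <- "power"
        pcfg <- config$power
        say("[power] sample-size planning")
        fs <- pcfg$effect_size_f %||% 0.25
        tab <- do.call(rbind, lapply(fs, function(f) {
          tibble::tibble(
            effect_size_f = f,
            k_groups = pcfg$k_groups %||% 3,
            alpha = pcfg$alpha %||% 0.05,
            power = pcfg$power %||% 0.80,
            required_n = anova_required_sample_size(
              f, k_groups = pcfg$k_groups %||% 3,
              alpha = pcfg$alpha %||% 0.05,
              power = pcfg$power %||% 0.80))
        }))
        emit(tab, "power.csv", "power")
      }
    },
    error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s",
                         current_stage %||% "setup", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
    })
  invisible(written)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
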