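#' Extract all feature blocks from a bundle
#'
#' Convenience wrapper running [sensor_features()], [phone_features()],
#' [sleep_features()], [diary_features()] and [big5_gender_features()].
#'
#' @param bundle A `cohort_bundle`.
#' @param ... Passed to [sensor_features()].
#' @return Named list of feature blocks for [assemble_modality()].
#' @export
extract_features <- function(bundle, ...) {
  list(
    sensors = sensor_features(bundle, ...),
    phone = phone_features(bundle),
    sleep = sleep_features(bundle),
    diary = diary_features(bundle),
    big5_gender = big5_gender_features(bundle)
  )
}

#' Restrict a bundle to the final week of observation
#'
#' A pure input filter: keeps only the last `n_days` days of streams, events,
#' locations, diaries and sleep episodes (re-zeroing clocks to the start of
#' the kept span) so that features can be computed from the week preceding the
#' post-study questionnaires; the rest of the pipeline runs unchanged.
#'
#' @param bundle A `cohort_bundle`.
#' @param n_days Number of trailing days to keep (default 7).
#' @return A `cohort_bundle` covering `n_days` days.
#' @export
filter_last_week <- function(bundle, n_days = 7L) {
  check_number(n_days, "n_days", min = 2, integer = TRUE)
  d0 <- bundle$config$days - n_days
  if (d0 <= 0) return(bundle)
  t0 <- d0 * SEC_PER_DAY
  clip_events <- function(tbl) {
    tbl <- tbl[tbl$ts >= t0, , drop = FALSE]
    tbl$ts <- tbl$ts - t0
    tbl
  }
  out <- bundle
  out$streams <- lapply(bundle$streams, function(s) {
    s <- s[s$ts >= t0, , drop = FALSE]
    s$ts <- s$ts - t0
    s
  })
  out$calls <- clip_events(bundle$calls)
  out$sms <- clip_events(bundle$sms)
  out$screen <- clip_events(bundle$screen)
  out$locations <- clip_events(bundle$locations)
  out$diary <- dplyr::mutate(bundle$diary[bundle$diary$day > d0, , drop = FALSE],
                             day = .data$day - d0)
  out$sleep <- bundle$sleep[bundle$sleep$day > d0, , drop = FALSE] |>
    dplyr::mutate(day = .data$day - d0,
                  bed_min = .data$bed_min - d0 * MIN_PER_DAY,
                  wake_min = .data$wake_min - d0 * MIN_PER_DAY)
  out$config$days <- as.integer(n_days)
  out
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_ws(sprintf("pipeline stage `%s` failed: %s", name,
                     conditionMessage(e)), "stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (or load), extract,
#' label, evaluate, group statistics, report -- and writes every output file
#' plus a manifest to `out_dir`. Rerunning with the same configuration
#' reproduces all numeric outputs.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   `generator` (arguments to [cohort_config()]) or `dataset` (directory for
#'   [read_dataset()]); `modalities`, `outcomes` (subset of `pss`, `mcs`),
#'   `models` (subset of `svm_rbf`, `svm_linear`, `lasso`); optional
#'   `pss_cutoff`, `mcs_mode`, `model_args` (passed to [model_spec()]),
#'   `last_week` flag and `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the feature blocks, label sets, evaluation
#'   objects and the report tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  modalities <- config$modalities %||% c("big5_gender", "sensors", "phone",
                                         "objective", "modifiable", "diary",
                                         "sleep", "all")
  outcomes <- config$outcomes %||% c("pss", "mcs")
  models <- config$models %||% c("svm_rbf", "svm_linear", "lasso")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(tbl, name) {
    readr::write_csv(tbl, file.path(out_dir, name), progress = FALSE)
    files <<- c(files, name)
  }

  bundle <- run_stage("simulate", {
    if (!is.null(config$dataset)) {
      read_dataset(config$dataset)
    } else {
      gen <- config$generator %||% list()
      if (is.null(gen$seed)) gen$seed <- derive_seed(seed, 1L)
      if (!is.null(gen$latent_effect_sizes)) {
        gen$latent_effect_sizes <- unlist(gen$latent_effect_sizes)
      }
      generate_cohort(do.call(cohort_config, gen))
    }
  })
  if (isTRUE(config$last_week)) bundle <- filter_last_week(bundle)

  blocks <- run_stage("extract", extract_features(bundle))
  for (b in names(blocks)) emit_csv(blocks[[b]], paste0("features_", b, ".csv"))

  labels <- run_stage("label", {
    out <- list()
    if ("pss" %in% outcomes) {
      out$pss <- label_pss(bundle$participants,
                           cutoff = config$pss_cutoff %||% 16,
                           seed = derive_seed(seed, 2L))
    }
    if ("mcs" %in% outcomes) {
      out$mcs <- label_mcs(bundle$participants,
                           mode = config$mcs_mode %||% "extremes")
    }
    out
  })
  for (oc in names(labels)) {
    lb <- labels[[oc]]
    jsonlite::write_json(
      list(outcome = oc, cutoff = as.list(attr(lb, "cutoff")),
           seed = attr(lb, "seed"), dropped_ids = attr(lb, "dropped_ids"),
           members = split(lb$participant_id, lb$class)),
      file.path(out_dir, paste0("labels_", oc, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, paste0("labels_", oc, ".json"))
  }

  evals <- list()
  report_rows <- list()
  sel_rows <- list()
  k <- 0L
  for (oc in names(labels)) {
    for (mo in modalities) {
      fm <- run_stage("assemble", assemble_modality(blocks, mo))
      for (fam in models) {
        k <- k + 1L
        spec_args <- c(list(family = fam, seed = derive_seed(seed, 10L + k)),
                       config$model_args)
        ev <- run_stage("evaluate",
                        loco_cv(fm, labels[[oc]], bundle$participants,
                                do.call(model_spec, spec_args)))
        key <- paste(oc, mo, fam, sep = ".")
        evals[[key]] <- ev
        report_rows[[key]] <- dplyr::bind_cols(
          tibble::tibble(outcome = oc, modality = mo, model = fam), glance(ev)[-1]
        )
        sel_rows[[key]] <- dplyr::mutate(ev$selection, outcome = oc,
                                         modality = mo, model = fam, .before = 1)
      }
    }
  }
  report <- dplyr::bind_rows(report_rows)
  emit_csv(report, "report.csv")
  emit_csv(dplyr::bind_rows(sel_rows), "selection_frequencies.csv")

  stats_out <- run_stage("stats", {
    out <- list()
    for (oc in names(labels)) {
      fm <- assemble_modality(blocks, "all")
      out[[oc]] <- group_feature_tests(fm, labels[[oc]])
      emit_csv(out[[oc]], paste0("group_tests_", oc, ".csv"))
    }
    out
  })

  run_stage("report", {
    cohort_anova <- lapply(outcomes, function(oc) {
      sc <- bundle$participants[[paste0(oc, "_post")]]
      av <- oneway.test(sc ~ factor(bundle$participants$cohort))
      list(outcome = oc, F = unname(av$statistic), p = av$p.value)
    })
    jsonlite::write_json(
      list(
        metrics = lapply(evals, function(ev) as.list(glance(ev))),
        cohort_anova = cohort_anova
      ),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
    files <- c(files, "evaluation.json")
    manifest <- list(
      package = "wearstress",
      version = as.character(utils::packageVersion("wearstress")),
      seed = seed,
      config_hash = rlang::hash(config),
      config = config,
      files = sort(files)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(bundle = bundle, blocks = blocks, labels = labels,
                 evaluations = evals, report = report, stats = stats_out))
}

#' Accuracy report plot across modalities and models
#'
#' Bar chart of concatenated out-of-fold accuracy per modality, faceted by
#' outcome, with adjusted-Wald 95% CI error bars and one fill per model
#' family.
#'
#' @param report The `report` tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_report <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$modality, y = .data$accuracy,
                               fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~ .data$outcome) +
    ggplot2::labs(x = NULL, y = "accuracy (adjusted-Wald 95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
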