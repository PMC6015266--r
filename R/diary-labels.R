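diary_items <- function() {
  c("all_nighter", "presleep_media", "presleep_interaction", "n_naps",
    "nap_duration_min", "n_academic", "academic_duration_min",
    "study_duration_min", "n_extracurricular", "extracurricular_duration_min",
    "n_exercise", "exercise_duration_min", "n_caffeine", "pos_interaction",
    "somewhat_neg_interaction", "very_neg_interaction", "last_caffeine_min")
}

#' Diary feature block (17 items x 3 = 51 features)
#'
#' Mean, median and SD across days of the 17 twice-daily diary items
#' (all-nighter, pre-sleep electronic media and personal interaction, naps and
#' nap duration, academic / study / extracurricular / exercise activity counts
#' and durations, caffeinated drinks, interaction valence flags, and last
#' caffeine intake time). Binary items aggregate as proportions; days with no
#' caffeine are excluded from the last-caffeine-time aggregates. Participants
#' with fewer than 2 diary days are dropped with a warning.
#'
#' @param x A `cohort_bundle` or a diary tibble (`participant_id`, `day`, and
#'   the 17 item columns).
#' @return Feature block tibble (51 columns) with [feature_meta()].
#' @export
diary_features <- function(x) {
  diary <- if (inherits(x, "cohort_bundle")) x$diary else x
  items <- diary_items()
  missing_items <- setdiff(items, names(diary))
  if (length(missing_items)) {
    abort_ws(paste0("diary table is missing items: ",
                    paste(missing_items, collapse = ", ")), "param_error")
  }
  aggs <- c("mean", "median", "sd")
  nm <- as.vector(vapply(items, function(it) paste("diary", it, aggs, sep = "_"),
                         character(3)))
  rows <- list()
  dropped <- character()
  for (pid in unique(diary$participant_id)) {
    p <- diary[diary$participant_id == pid, , drop = FALSE]
    if (nrow(p) < 2) {
      dropped <- c(dropped, pid)
      next
    }
    vals <- as.vector(vapply(items, function(it) agg3(as.numeric(p[[it]])),
                             numeric(3)))
    rows[[pid]] <- setNames(vals, nm)
  }
  if (length(dropped)) {
    rlang::warn(paste0("excluded participants with < 2 diary days: ",
                       paste(dropped, collapse = ", ")))
  }
  if (!length(rows)) abort_ws("no participant with >= 2 diary days", "param_error")
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(tibble::tibble(participant_id = names(rows)), out)
  meta <- tibble::tibble(
    column = nm, signal = "diary", statistic = rep(items, each = 3),
    window = "fullday", aggregate = rep(aggs, length(items)), block = "diary"
  )
  new_feature_block(out, meta)
}

#' Big Five + gender feature block (6 features)
#'
#' @param x A `cohort_bundle` or a participants tibble.
#' @return Feature block tibble (6 columns) with [feature_meta()].
#' @export
big5_gender_features <- function(x) {
  p <- if (inherits(x, "cohort_bundle")) x$participants else x
  out <- tibble::tibble(
    participant_id = p$participant_id,
    openness = p$openness,
    conscientiousness = p$conscientiousness,
    extraversion = p$extraversion,
    agreeableness = p$agreeableness,
    neuroticism = p$neuroticism,
    gender_male = as.numeric(p$gender == "M")
  )
  cols <- setdiff(names(out), "participant_id")
  meta <- tibble::tibble(
    column = cols, signal = "trait", statistic = cols, window = "all",
    aggregate = "none", block = "big5_gender"
  )
  new_feature_block(out, meta)
}

#' Assemble a feature modality from extracted blocks
#'
#' Combines the per-block feature tables into the evaluation modalities:
#' `sensors` (204), `phone` (237), `sleep` (25), `diary` (51), `big5_gender`
#' (6), `objective` = sensors + phone (441), `modifiable` = SRI + bedtime and
#' sleep-duration aggregates + diary + full-day accelerometer zero-crossing
#' summary + phone (296), and `all` = big5_gender + diary + sensors + phone
#' (498). Participants are joined by id (inner join across the needed blocks).
#'
#' @param blocks Named list of feature blocks, with names among `sensors`,
#'   `phone`, `sleep`, `diary`, `big5_gender`.
#' @param modality One of the modality names above.
#' @return Feature block tibble with [feature_meta()].
#' @export
assemble_modality <- function(blocks,
                              modality = c("all", "big5_gender", "sensors",
                                           "phone", "objective", "modifiable",
                                           "diary", "sleep")) {
  modality <- match.arg(modality)
  need <- switch(modality,
    all = c("big5_gender", "diary", "sensors", "phone"),
    big5_gender = "big5_gender",
    sensors = "sensors",
    phone = "phone",
    objective = c("sensors", "phone"),
    modifiable = c("sleep", "diary", "sensors", "phone"),
    diary = "diary",
    sleep = "sleep"
  )
  for (b in need) {
    if (is.null(blocks[[b]])) {
      abort_ws(sprintf("configuration error: missing feature block `%s`", b),
               "config_error")
    }
  }
  take <- function(block, cols = NULL) {
    m <- feature_meta(blocks[[block]])
    if (block == "sensors") m <- m[m$block == "sensor", , drop = FALSE]
    if (!is.null(cols)) m <- m[m$column %in% cols, , drop = FALSE]
    list(data = dplyr::select(blocks[[block]], "participant_id",
                              dplyr::all_of(m$column)),
         meta = m)
  }
  parts <- switch(modality,
    sensors = list(take("sensors")),
    phone = list(take("phone")),
    diary = list(take("diary")),
    sleep = list(take("sleep")),
    big5_gender = list(take("big5_gender")),
    objective = list(take("sensors"), take("phone")),
    all = list(take("big5_gender"), take("diary"), take("sensors"),
               take("phone")),
    modifiable = {
      sl <- c("sri", paste("sleep", rep(c("bedtime", "duration"), each = 3),
                           c("mean", "median", "sd"), sep = "_"))
      acc <- feature_meta(blocks$sensors)
      acc <- acc$column[acc$block == "sensor_extra"]
      list(take("sleep", sl), take("diary"),
           list(data = dplyr::select(blocks$sensors, "participant_id",
                                     dplyr::all_of(acc)),
                meta = feature_meta(blocks$sensors) |>
                  dplyr::filter(.data$block == "sensor_extra")),
           take("phone"))
    }
  )
  out <- purrr::reduce(purrr::map(parts, "data"),
                       ~ dplyr::inner_join(.x, .y, by = "participant_id"))
  new_feature_block(out, dplyr::bind_rows(purrr::map(parts, "meta")))
}

new_label_set <- function(tbl, outcome, cutoff, seed, dropped) {
  structure(tbl, class = c("label_set", class(tbl)),
            outcome = outcome, cutoff = cutoff, seed = seed,
            dropped_ids = dropped)
}

#' High/low perceived-stress groups with class balancing
#'
#' Splits participants at `pss_post >= cutoff` (default 16, the conventional
#' high-concern threshold; 14, the 18-29 population mean, is the supported
#' alternate) and randomly downsamples the larger class without replacement to
#' the smaller class's size so both class priors are 0.5.
#'
#' @param data Tibble with `participant_id` and the score column.
#' @param cutoff High-stress threshold (score >= cutoff is "high").
#' @param seed Seed for the balancing draw.
#' @param score_col Name of the score column (default `pss_post`).
#' @return A `label_set`: tibble (`participant_id`, `class` factor low/high)
#'   with balancing metadata in attributes.
#' @export
label_pss <- function(data, cutoff = 16, seed = 1L, score_col = "pss_post") {
  s <- data[[score_col]]
  if (is.null(s)) abort_ws(sprintf("missing score column `%s`", score_col), "param_error")
  keep <- !is.na(s)
  ids <- data$participant_id[keep]
  s <- s[keep]
  if (any(s < 0 | s > 40)) abort_ws("PSS scores must lie in [0, 40]", "param_error")
  high <- ids[s >= cutoff]
  low <- ids[s < cutoff]
  if (!length(high) || !length(low)) {
    abort_ws("labeling error: a class is empty at this cutoff", "labeling_error")
  }
  withr::local_seed(seed)
  n <- min(length(high), length(low))
  dropped <- character(0)
  if (length(high) > n) {
    drop_h <- sample(high, length(high) - n)
    dropped <- drop_h
    high <- setdiff(high, drop_h)
  } else if (length(low) > n) {
    drop_l <- sample(low, length(low) - n)
    dropped <- drop_l
    low <- setdiff(low, drop_l)
  }
  tbl <- tibble::tibble(
    participant_id = c(low, high),
    class = factor(rep(c("low", "high"), c(length(low), length(high))),
                   levels = c("low", "high"))
  )
  new_label_set(tbl, "pss", cutoff, seed, dropped)
}

#' High/low mental-health groups from SF-12 MCS scores
#'
#' `extremes` mode takes the good-mental-health tail (`score >= high_cutoff`,
#' default 50) and the low tail (`score <= low_cutoff`, default 29.4), the
#' middle being excluded; when `quantile` is given the cutoffs are derived so
#' each class has `round(quantile * n)` members (ties kept, then trimmed by
#' score order). `median` mode splits at the sample median
#' (`score >= median` is "high"). No balancing is applied: the extreme tails
#' are near-balanced by construction.
#'
#' @param data Tibble with `participant_id` and the score column.
#' @param mode `"extremes"` or `"median"`.
#' @param high_cutoff,low_cutoff Fixed cutoffs for `extremes` mode.
#' @param quantile Optional tail fraction (e.g. 0.12) overriding the fixed
#'   cutoffs.
#' @param score_col Name of the score column (default `mcs_post`).
#' @return A `label_set` tibble.
#' @export
label_mcs <- function(data, mode = c("extremes", "median"), high_cutoff = 50,
                      low_cutoff = 29.4, quantile = NULL,
                      score_col = "mcs_post") {
  mode <- match.arg(mode)
  s <- data[[score_col]]
  if (is.null(s)) abort_ws(sprintf("missing score column `%s`", score_col), "param_error")
  keep <- !is.na(s)
  ids <- data$participant_id[keep]
  s <- s[keep]
  if (!length(s)) abort_ws("no scores available", "param_error")

  if (mode == "median") {
    med <- median(s)
    high <- ids[s >= med]
    low <- ids[s < med]
    cutoff <- c(median = med)
  } else if (is.null(quantile)) {
    high <- ids[s >= high_cutoff]
    low <- ids[s <= low_cutoff]
    cutoff <- c(high = high_cutoff, low = low_cutoff)
  } else {
    target <- max(1L, round(quantile * length(s)))
    o_desc <- order(s, decreasing = TRUE)
    o_asc <- order(s)
    high <- ids[o_desc[seq_len(target)]]
    low <- ids[o_asc[seq_len(target)]]
    cutoff <- c(high = min(s[ids %in% high]), low = max(s[ids %in% low]))
  }
  if (!length(high) || !length(low)) {
    abort_ws("labeling error: a class is empty under the chosen cutoffs",
             "labeling_error")
  }
  if (length(intersect(high, low))) {
    abort_ws("labeling error: cutoffs produce overlapping classes", "labeling_error")
  }
  tbl <- tibble::tibble(
    participant_id = c(low, high),
    class = factor(rep(c("low", "high"), c(length(low), length(high))),
                   levels = c("low", "high"))
  )
  new_label_set(tbl, "mcs", cutoff, NA_integer_, character(0))
}
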