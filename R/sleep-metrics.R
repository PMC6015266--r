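#' Sleep Regularity Index
#'
#' Probability-scaled agreement of sleep/wake state at a 24-hour lag: with
#' minute-resolution states `s(t) = +1` (wake) / `-1` (sleep),
#' `SRI = -100 + 200 * P(s(t) = s(t + 1440 min))`, averaged over all valid
#' pairs. 100 means perfectly periodic sleep timing, 0 is the expectation for
#' independent random states, and negative values (down to -100 for alternating
#' 24 h of sleep and 24 h of wake) are possible. Pairs in which either state is
#' missing are excluded.
#'
#' @param states Numeric vector of minute states: `+1` wake, `-1` sleep, `NA`
#'   missing.
#' @param lag_min Lag in minutes (fixed at one day by default).
#' @return SRI scalar in `[-100, 100]`.
#' @export
sleep_regularity_index <- function(states, lag_min = 1440L) {
  check_number(lag_min, "lag_min", min = 1, integer = TRUE)
  T_ <- length(states)
  if (T_ <= lag_min) {
    abort_ws("undefined result: need more than one day of states", "undefined_result")
  }
  a <- states[seq_len(T_ - lag_min)]
  b <- states[(lag_min + 1):T_]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    abort_ws("undefined result: no valid 24-h state pair", "undefined_result")
  }
  -100 + 200 * mean(a[ok] == b[ok])
}

#' Minute-resolution sleep/wake vector from sleep episodes
#'
#' Minutes inside an episode are scored sleep (`-1`) except for within-episode
#' wake implied by `efficiency < 1`, which is placed uniformly at random under
#' a fixed seed; minutes outside episodes on covered days are wake (`+1`);
#' minutes of uncovered days are missing.
#'
#' @param episodes Tibble with `bed_min`, `wake_min` (minutes from study
#'   start; rows with missing `bed_min` are skipped) and optionally
#'   `efficiency` (default 1). Episodes must not overlap.
#' @param span_days Length of the output vector in days.
#' @param covered_days Integer days with observations (default: all).
#' @param seed Seed for within-episode wake placement.
#' @return Numeric vector of length `span_days * 1440` with values in
#'   `{-1, +1, NA}`.
#' @export
vector_from_episodes <- function(episodes, span_days, covered_days = NULL, seed = 1L) {
  check_number(span_days, "span_days", min = 1, integer = TRUE)
  ep <- episodes[!is.na(episodes$bed_min), , drop = FALSE]
  eff <- if ("efficiency" %in% names(ep)) ep$efficiency else rep(1, nrow(ep))
  eff[is.na(eff)] <- 1
  if (nrow(ep) > 1) {
    o <- order(ep$bed_min)
    if (any(ep$bed_min[o][-1] < ep$wake_min[o][-nrow(ep)])) {
      abort_ws("validation error: overlapping sleep episodes", "validation_error")
    }
  }
  n_min <- span_days * MIN_PER_DAY
  s <- rep(1, n_min)
  if (!is.null(covered_days)) {
    uncovered <- setdiff(seq_len(span_days), covered_days)
    for (d in uncovered) s[((d - 1) * MIN_PER_DAY + 1):(d * MIN_PER_DAY)] <- NA_real_
  }
  withr::local_seed(seed)
  for (r in seq_len(nrow(ep))) {
    i0 <- max(1, floor(ep$bed_min[r]) + 1)
    i1 <- min(n_min, ceiling(ep$wake_min[r]))
    if (i1 < i0) next
    idx <- i0:i1
    s[idx] <- -1
    n_wake <- round((1 - eff[r]) * length(idx))
    if (n_wake > 0) s[sample(idx, n_wake)] <- 1
  }
  s
}

# bedtime on a circular axis referenced to 18:00 so the midnight wrap does not
# split the distribution; 360 on this axis is midnight
bedtime_ref_axis <- function(bed_min_abs) {
  ((bed_min_abs %% MIN_PER_DAY) - 1080) %% MIN_PER_DAY
}

#' Sleep feature block (SRI + 3 x 8 = 25 features)
#'
#' Per participant: the Sleep Regularity Index plus mean/median/SD across days
#' of bedtime (minutes after 18:00 on a circular reference axis), sleep
#' duration (min), sleep efficiency, the all-nighter flag, the pre-sleep
#' electronic media and personal interaction flags, number of naps, and total
#' nap duration (min). Binary items aggregate as proportions. Participants with
#' fewer than 2 recorded days are dropped with a warning.
#'
#' @param x A `cohort_bundle`, or a per participant-day tibble with columns
#'   `participant_id`, `day`, `bed_min`, `wake_min`, `efficiency`,
#'   `all_nighter`, `presleep_media`, `presleep_interaction`, `n_naps`,
#'   `nap_duration_min`.
#' @param seed Seed for within-episode wake placement in the SRI state vector.
#' @return Feature block tibble (25 columns) with [feature_meta()].
#' @export
sleep_features <- function(x, seed = 1L) {
  days_tbl <- if (inherits(x, "cohort_bundle")) {
    dplyr::left_join(
      x$sleep,
      dplyr::select(x$diary, "participant_id", "day", "presleep_media",
                    "presleep_interaction", "n_naps", "nap_duration_min"),
      by = c("participant_id", "day")
    )
  } else {
    x
  }

  items <- c("bedtime", "duration", "efficiency", "all_nighter",
             "presleep_media", "presleep_interaction", "n_naps", "nap_duration")
  aggs <- c("mean", "median", "sd")
  nm <- as.vector(vapply(items, function(it) paste("sleep", it, aggs, sep = "_"),
                         character(3)))

  rows <- list()
  dropped <- character()
  for (pid in unique(days_tbl$participant_id)) {
    p <- days_tbl[days_tbl$participant_id == pid, , drop = FALSE]
    if (nrow(p) < 2) {
      dropped <- c(dropped, pid)
      next
    }
    span <- max(p$day) + 1
    states <- vector_from_episodes(p, span_days = span,
                                   covered_days = seq_len(span), seed = seed)
    # score regularity over the sleep-bracketed span only: minutes before the
    # first recorded bedtime and after the last wake are unobserved, and
    # counting them as wake would penalise even a perfectly periodic sleeper
    beds <- p$bed_min[!is.na(p$bed_min)]
    wakes <- p$wake_min[!is.na(p$wake_min)]
    if (length(beds)) {
      states <- states[(floor(min(beds)) + 1):min(ceiling(max(wakes)), length(states))]
    }
    sri <- sleep_regularity_index(states)
    per_day <- cbind(
      bedtime = bedtime_ref_axis(p$bed_min),
      duration = p$wake_min - p$bed_min,
      efficiency = p$efficiency,
      all_nighter = as.numeric(p$all_nighter),
      presleep_media = as.numeric(p$presleep_media),
      presleep_interaction = as.numeric(p$presleep_interaction),
      n_naps = p$n_naps,
      nap_duration = p$nap_duration_min
    )
    vals <- as.vector(apply(per_day, 2, agg3))
    rows[[pid]] <- c(sri = sri, stats::setNames(vals, nm))
  }
  if (length(dropped)) {
    rlang::warn(paste0("excluded participants with < 2 sleep days: ",
                       paste(dropped, collapse = ", ")))
  }
  if (!length(rows)) abort_ws("no participant with >= 2 sleep days", "param_error")

  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(tibble::tibble(participant_id = names(rows)), out)
  meta <- tibble::tibble(
    column = c("sri", nm),
    signal = "sleep",
    statistic = c("sri", rep(items, each = 3)),
    window = "fullday",
    aggregate = c("all", rep(aggs, length(items))),
    block = "sleep"
  )
  new_feature_block(out, meta)
}
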