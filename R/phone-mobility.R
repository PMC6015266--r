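phone_windows <- function() {
  tibble::tibble(
    window  = c("fullday", "latenight", "night"),
    start_s = c(0, 0, 18 * 3600),
    end_s   = c(24, 3, 24) * 3600
  )
}

# SMS sessionization: consecutive messages with the same contact separated by
# less than `gap_s` form one session; its duration is the span, its timestamp
# the first message
sms_sessions <- function(sms, gap_s = 300) {
  if (nrow(sms) == 0) {
    return(tibble::tibble(participant_id = character(), ts = numeric(),
                          duration_s = numeric()))
  }
  sms |>
    dplyr::arrange(.data$participant_id, .data$contact_hash, .data$ts) |>
    dplyr::group_by(.data$participant_id, .data$contact_hash) |>
    dplyr::mutate(new_sess = c(TRUE, diff(.data$ts) >= gap_s)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(sess = cumsum(.data$new_sess)) |>
    dplyr::group_by(.data$participant_id, .data$sess) |>
    dplyr::summarise(duration_s = max(.data$ts) - min(.data$ts),
                     ts = min(.data$ts), .groups = "drop") |>
    dplyr::select("participant_id", "ts", "duration_s")
}

# screen on/off events -> bouts; an unpaired trailing "on" is closed at the
# next local midnight
screen_bouts <- function(screen) {
  out <- list(tibble::tibble(participant_id = character(), ts = numeric(),
                             duration_s = numeric()))
  for (pid in unique(screen$participant_id)) {
    ev <- screen[screen$participant_id == pid, , drop = FALSE]
    ev <- ev[order(ev$ts), , drop = FALSE]
    open_ts <- NA_real_
    starts <- ends <- numeric(0)
    for (j in seq_len(nrow(ev))) {
      if (ev$state[j] == "on") {
        if (!is.na(open_ts)) {
          starts <- c(starts, open_ts)
          ends <- c(ends, (floor(open_ts / SEC_PER_DAY) + 1) * SEC_PER_DAY)
        }
        open_ts <- ev$ts[j]
      } else if (!is.na(open_ts)) {
        starts <- c(starts, open_ts)
        ends <- c(ends, ev$ts[j])
        open_ts <- NA_real_
      }
    }
    if (!is.na(open_ts)) {
      starts <- c(starts, open_ts)
      ends <- c(ends, (floor(open_ts / SEC_PER_DAY) + 1) * SEC_PER_DAY)
    }
    out[[pid]] <- tibble::tibble(participant_id = pid, ts = starts,
                                 duration_s = ends - starts)
  }
  dplyr::bind_rows(out)
}

# per participant-day stats of durations and window-referenced timestamps
event_day_stats <- function(ev, w_start, w_end, with_contacts = TRUE) {
  clock <- ev$ts %% SEC_PER_DAY
  ev <- ev[clock >= w_start & clock < w_end, , drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  ev$day <- floor(ev$ts / SEC_PER_DAY) + 1
  ev$tmin <- (ev$ts %% SEC_PER_DAY - w_start) / 60
  ev |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(
      dur_mean = mean(.data$duration_s), dur_median = median(.data$duration_s),
      dur_sd = if (dplyr::n() > 1) sd(.data$duration_s) else 0,
      time_mean = mean(.data$tmin), time_median = median(.data$tmin),
      time_sd = if (dplyr::n() > 1) sd(.data$tmin) else 0,
      total_dur = sum(.data$duration_s),
      n = as.numeric(dplyr::n()),
      n_contacts = if (with_contacts) as.numeric(dplyr::n_distinct(.data$contact_hash)) else NA_real_,
      .groups = "drop"
    )
}

#' Per-window phone event features
#'
#' Computes, for each of the three clock windows (full day 0-24, late night
#' 0-3, night 18-24, local time), per-day call / SMS / screen usage features
#' and aggregates each across days by mean, median and SD: calls contribute 9
#' per-day features (duration and timestamp-of-day mean/median/SD, total
#' duration, count, unique contacts), SMS 8 (sessionized durations; raw counts)
#' and screen 8 (on-bout durations and start times, total on time, on/off
#' cycle count) -- 25 x 3 windows x 3 aggregates = 225 columns. Days with no
#' events in a window are missing and excluded from aggregation. Timestamps
#' are encoded as minutes since the window start.
#'
#' @param calls,sms,screen Event tables with `participant_id`, `ts` (seconds
#'   from study start), plus `duration_s`/`contact_hash` (calls),
#'   `contact_hash` (SMS), `state` in on/off (screen).
#' @param session_gap_min Gap in minutes closing an SMS session (default 5).
#' @return Feature block tibble (225 columns) with [feature_meta()].
#' @export
phone_event_features <- function(calls, sms, screen, session_gap_min = 5) {
  wins <- phone_windows()
  sess <- sms_sessions(sms, gap_s = session_gap_min * 60)
  bouts <- screen_bouts(screen)

  ids <- sort(unique(c(calls$participant_id, sms$participant_id,
                       screen$participant_id)))
  feats <- list(
    call = c("dur_mean", "dur_median", "dur_sd", "time_mean", "time_median",
             "time_sd", "total_dur", "n", "n_contacts"),
    sms = c("dur_mean", "dur_median", "dur_sd", "time_mean", "time_median",
            "time_sd", "n", "n_contacts"),
    screen = c("dur_mean", "dur_median", "dur_sd", "time_mean", "time_median",
               "time_sd", "total_dur", "n")
  )
  aggs <- c("mean", "median", "sd")

  blocks <- list()
  meta_rows <- list()
  for (type in names(feats)) {
    for (wi in seq_len(nrow(wins))) {
      w <- wins$window[wi]
      ds <- switch(type,
        call = event_day_stats(calls, wins$start_s[wi], wins$end_s[wi]),
        sms = {
          d <- event_day_stats(sess, wins$start_s[wi], wins$end_s[wi],
                               with_contacts = FALSE)
          # counts and contacts from raw messages, not sessions
          clock <- sms$ts %% SEC_PER_DAY
          raw <- sms[clock >= wins$start_s[wi] & clock < wins$end_s[wi], , drop = FALSE]
          if (nrow(raw)) {
            raw$day <- floor(raw$ts / SEC_PER_DAY) + 1
            cnt <- raw |>
              dplyr::group_by(.data$participant_id, .data$day) |>
              dplyr::summarise(n = as.numeric(dplyr::n()),
                               n_contacts = as.numeric(dplyr::n_distinct(.data$contact_hash)),
                               .groups = "drop")
            if (is.null(d)) cnt else
              dplyr::full_join(dplyr::select(d, -"n", -"n_contacts"), cnt,
                               by = c("participant_id", "day"))
          } else d
        },
        screen = event_day_stats(bouts, wins$start_s[wi], wins$end_s[wi],
                                 with_contacts = FALSE)
      )
      for (f in feats[[type]]) {
        col <- paste(type, f, w, sep = "_")
        per_pid <- if (is.null(ds) || !f %in% names(ds)) NULL else
          tapply(ds[[f]], ds$participant_id, agg3, simplify = FALSE)
        m <- t(vapply(ids, function(pid) {
          v <- per_pid[[pid]]
          if (is.null(v)) c(NA_real_, NA_real_, NA_real_) else v
        }, numeric(3)))
        colnames(m) <- paste(col, aggs, sep = "_")
        blocks[[col]] <- m
        meta_rows[[col]] <- tibble::tibble(
          column = colnames(m), signal = type, statistic = f, window = w,
          aggregate = aggs, block = "phone"
        )
      }
    }
  }
  out <- tibble::as_tibble(do.call(cbind, blocks))
  out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  new_feature_block(out, dplyr::bind_rows(meta_rows))
}

#' Per-day mobility summaries
#'
#' For each day: total distance (sum of consecutive-fix displacements), 5-min
#' distance (mean displacement between successive non-empty 5-minute bin
#' centroids), and radius (maximum distance of any fix from the day centroid).
#' Days with fewer than 2 fixes yield missing values. Distances are Euclidean
#' on the planar meter grid.
#'
#' @param trace Tibble for one participant: `ts`, `x_m`, `y_m`.
#' @param bin_s Bin width for the 5-min distance, seconds.
#' @return Tibble with `day`, `total_dist_m`, `dist_5min_m`, `radius_m`.
#' @export
daily_mobility <- function(trace, bin_s = 300) {
  trace <- trace[order(trace$ts), , drop = FALSE]
  trace$day <- floor(trace$ts / SEC_PER_DAY) + 1
  purrr::map_dfr(split(trace, trace$day), function(d) {
    if (nrow(d) < 2) {
      return(tibble::tibble(day = d$day[1], total_dist_m = NA_real_,
                            dist_5min_m = NA_real_, radius_m = NA_real_))
    }
    dx <- diff(d$x_m); dy <- diff(d$y_m)
    total <- sum(sqrt(dx^2 + dy^2))
    bin <- floor((d$ts %% SEC_PER_DAY) / bin_s)
    bx <- tapply(d$x_m, bin, mean); by <- tapply(d$y_m, bin, mean)
    d5 <- if (length(bx) > 1) mean(sqrt(diff(bx)^2 + diff(by)^2)) else 0
    cx <- mean(d$x_m); cy <- mean(d$y_m)
    radius <- max(sqrt((d$x_m - cx)^2 + (d$y_m - cy)^2))
    tibble::tibble(day = d$day[1], total_dist_m = total, dist_5min_m = d5,
                   radius_m = radius)
  })
}

#' Fit a participant's routine-mobility Gaussian mixture model
#'
#' Fits a full-covariance Gaussian mixture to all of a participant's location
#' fixes, selecting the number of components by BIC over `1..max_k`
#' (`mclust`). With fewer than 10 fixes per candidate component the range is
#' reduced, falling back to a single multivariate normal.
#'
#' @param trace Tibble for one participant: `ts`, `x_m`, `y_m`.
#' @param max_k Maximum number of mixture components (default 8).
#' @return A `mobility_gmm` object.
#' @export
fit_mobility_gmm <- function(trace, max_k = 8L) {
  X <- cbind(trace$x_m, trace$y_m)
  n <- nrow(X)
  if (n < 3) abort_ws("need at least 3 fixes to fit a mobility model", "param_error")
  kmax <- max(1L, min(as.integer(max_k), n %/% 10L))
  fit <- tryCatch(
    mclust::Mclust(X, G = seq_len(kmax), modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(mclust::Mclust(X, G = 1, verbose = FALSE),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    # closed-form single-Gaussian fallback (MLE covariance)
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / n
    return(structure(list(fit = NULL, K = 1L, mean = mu, cov = S),
                     class = "mobility_gmm"))
  }
  structure(list(fit = fit, K = fit$G), class = "mobility_gmm")
}

#' Mean per-fix log likelihood of a day under a mobility model
#'
#' Higher values mean the day's locations match the participant's routine.
#'
#' @param model A [fit_mobility_gmm()] result.
#' @param trace Day trace: `x_m`, `y_m`.
#' @return Scalar mean log density.
#' @export
daily_loglik <- function(model, trace) {
  if (!inherits(model, "mobility_gmm")) abort_ws("not a mobility_gmm", "param_error")
  X <- cbind(trace$x_m, trace$y_m)
  if (nrow(X) == 0) return(NA_real_)
  if (is.null(model$fit)) {
    S <- model$cov
    Sinv <- solve(S)
    d <- sweep(X, 2, model$mean)
    q <- rowSums((d %*% Sinv) * d)
    return(mean(-log(2 * pi) - 0.5 * log(det(S)) - 0.5 * q))
  }
  mean(mclust::dens(model$fit$modelName, data = X,
                    parameters = model$fit$parameters, logarithm = TRUE))
}

mobility_block <- function(locations, max_k = 8L) {
  ids <- sort(unique(locations$participant_id))
  aggs <- c("mean", "median", "sd")
  feats <- c("mob_total_dist", "mob_dist_5min", "mob_radius", "mob_loglik")
  rows <- lapply(ids, function(pid) {
    tr <- locations[locations$participant_id == pid, , drop = FALSE]
    dm <- daily_mobility(tr)
    model <- fit_mobility_gmm(tr, max_k = max_k)
    ll <- vapply(split(tr, floor(tr$ts / SEC_PER_DAY)), function(d) {
      daily_loglik(model, d)
    }, 0)
    c(agg3(dm$total_dist_m), agg3(dm$dist_5min_m), agg3(dm$radius_m), agg3(ll))
  })
  mat <- do.call(rbind, rows)
  nm <- as.vector(vapply(feats, function(f) paste(f, aggs, sep = "_"), character(3)))
  colnames(mat) <- nm
  out <- dplyr::bind_cols(tibble::tibble(participant_id = ids),
                          tibble::as_tibble(mat))
  meta <- tibble::tibble(
    column = nm, signal = "mobility", statistic = rep(feats, each = 3),
    window = "fullday", aggregate = rep(aggs, length(feats)), block = "phone"
  )
  new_feature_block(out, meta)
}

#' Phone feature block (25 x 3 x 3 + 4 x 3 = 237 features)
#'
#' Combines [phone_event_features()] with the four across-day mobility
#' aggregates (total distance, 5-min distance, radius, routine log likelihood
#' under the participant's Gaussian mixture model), giving exactly 237 columns.
#'
#' @param x A `cohort_bundle`, or `NULL` if the event tables are given.
#' @param calls,sms,screen,locations Event tables (ignored when `x` is a
#'   bundle).
#' @param session_gap_min SMS session gap, minutes.
#' @param max_k Maximum mixture components for the mobility model.
#' @return Feature block tibble (237 columns) with [feature_meta()].
#' @export
phone_features <- function(x = NULL, calls = NULL, sms = NULL, screen = NULL,
                           locations = NULL, session_gap_min = 5, max_k = 8L) {
  if (inherits(x, "cohort_bundle")) {
    calls <- x$calls; sms <- x$sms; screen <- x$screen; locations <- x$locations
  }
  ev <- phone_event_features(calls, sms, screen, session_gap_min)
  mob <- mobility_block(locations, max_k = max_k)
  out <- dplyr::full_join(ev, mob, by = "participant_id")
  meta <- dplyr::bind_rows(feature_meta(ev), feature_meta(mob))
  new_feature_block(out, meta)
}
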