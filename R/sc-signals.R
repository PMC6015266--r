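#' Zero-phase FIR low-pass filter
#'
#' Designs a Hamming-windowed FIR low-pass filter (`signal::fir1`) and applies
#' it forward and backward (zero phase). The input is padded by odd reflection
#' at both ends before filtering so that edges are not distorted and the DC
#' gain is exactly preserved.
#'
#' @param x Numeric series.
#' @param sample_rate Sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff Cutoff frequency in Hz (default 0.4).
#' @param order Filter order (default 32).
#' @return Filtered series, same length as `x`.
#' @export
fir_lowpass <- function(x, sample_rate, cutoff = 0.4, order = 32L) {
  check_number(sample_rate, "sample_rate", min = 1e-9)
  check_number(cutoff, "cutoff", min = 1e-9)
  check_number(order, "order", min = 2, integer = TRUE)
  if (sample_rate <= 2 * cutoff) {
    abort_ws("invalid value for `sample_rate`: must exceed 2 * cutoff", "param_error")
  }
  n <- length(x)
  if (n < 2) return(as.numeric(x))
  b <- signal::fir1(order, cutoff / (sample_rate / 2))
  b <- signal::Ma(b / sum(b))         # unit DC gain
  L <- min(3L * order, n - 1L)
  pad_head <- 2 * x[1] - x[(L + 1):2]
  pad_tail <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(b, c(pad_head, x, pad_tail))
  y[(L + 1):(L + n)]
}

#' Physiological range masks for skin conductance and temperature
#'
#' Flags samples inside the published plausible ranges: 0.01-30 uS for skin
#' conductance and 20-42 degC for skin temperature (bounds inclusive). An
#' existing `valid` column (worn / device-ok mask) is combined by logical AND.
#'
#' @param stream Data frame with columns `sc_uS`, `st_C` and optionally `valid`.
#' @param sc_range,st_range Inclusive limits.
#' @return Tibble with logical columns `sc_valid`, `st_valid`.
#' @export
range_mask <- function(stream, sc_range = c(0.01, 30), st_range = c(20, 42)) {
  v <- if ("valid" %in% names(stream)) stream$valid else TRUE
  tibble::tibble(
    sc_valid = !is.na(stream$sc_uS) &
      stream$sc_uS >= sc_range[1] & stream$sc_uS <= sc_range[2] & v,
    st_valid = !is.na(stream$st_C) &
      stream$st_C >= st_range[1] & stream$st_C <= st_range[2] & v
  )
}

#' Detect skin conductance response peaks by slope threshold
#'
#' Computes the discrete first derivative of the (already low-pass-filtered,
#' non-normalized) SC series and emits one peak event per maximal contiguous
#' run of slope strictly above `slope_threshold`, timestamped at the run onset.
#'
#' @param x Filtered SC series (uS).
#' @param sample_rate Sampling rate in Hz.
#' @param slope_threshold Slope threshold in uS per second (default 0.02).
#' @return Tibble with columns `onset` (sample index) and `time` (seconds from
#'   series start). Series shorter than 2 samples give zero rows.
#' @export
detect_sc_peaks <- function(x, sample_rate, slope_threshold = 0.02) {
  check_number(sample_rate, "sample_rate", min = 1e-9)
  if (length(x) < 2) {
    return(tibble::tibble(onset = integer(), time = numeric()))
  }
  slope <- diff(x) * sample_rate
  above <- !is.na(slope) & slope > slope_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset <- starts[r$values]
  tibble::tibble(onset = as.integer(onset), time = (onset - 1) / sample_rate)
}

#' Per-epoch skin conductance and movement features
#'
#' Splits the series into 30-second epochs aligned to the series start (local
#' midnight for study streams) and computes per epoch: SC area under the curve
#' (uS*s; trapezoidal with right-endpoint continuation when the epoch is fully
#' valid, `mean(valid) * 30` otherwise), SC peak count (events whose onset
#' falls in the epoch), and total accelerometer zero crossings (sign changes of
#' each epoch-mean-removed axis, summed over axes). Epochs with less than
#' `min_valid_frac` valid SC samples have their SC features set to missing.
#'
#' @param sc Filtered, range-masked SC series (invalid samples `NA`).
#' @param peaks Peak events: tibble from [detect_sc_peaks()] or numeric onset
#'   times in seconds.
#' @param acc Matrix or data frame with 3 acceleration columns.
#' @param sample_rate Sampling rate in Hz (`30 * rate` must be an integer).
#' @param min_valid_frac Minimum valid fraction per epoch (default 0.5).
#' @return Tibble with one row per complete epoch.
#' @export
epoch_features <- function(sc, peaks, acc, sample_rate, min_valid_frac = 0.5) {
  spe <- 30 * sample_rate
  if (abs(spe - round(spe)) > 1e-9) {
    abort_ws("invalid value for `sample_rate`: 30 * rate must be an integer", "param_error")
  }
  spe <- as.integer(round(spe))
  ne <- length(sc) %/% spe
  if (ne < 1) abort_ws("series shorter than one epoch", "param_error")

  M <- matrix(sc[seq_len(ne * spe)], nrow = spe)
  vf <- colMeans(!is.na(M))
  nf <- c(M[1, -1], M[spe, ne])                    # right endpoint continuation
  auc_mean <- 30 * colMeans(M, na.rm = TRUE)
  auc_mean[is.nan(auc_mean)] <- NA_real_
  full <- vf == 1 & !is.na(nf)
  auc <- auc_mean
  if (spe > 1) {
    auc_trap <- (colSums(M) - M[1, ] / 2 + nf / 2) / sample_rate
    auc[full] <- auc_trap[full]
  }

  pk_times <- if (is.data.frame(peaks)) peaks$time else as.numeric(peaks)
  e_idx <- floor(pk_times / 30) + 1
  counts <- tabulate(e_idx[e_idx >= 1 & e_idx <= ne], nbins = ne)

  acc <- as.matrix(acc)
  zc <- numeric(ne)
  for (a in seq_len(ncol(acc))) {
    A <- matrix(acc[seq_len(ne * spe), a], nrow = spe)
    A <- A - rep(colMeans(A, na.rm = TRUE), each = spe)
    if (spe > 1) {
      zc <- zc + colSums(A[-1, , drop = FALSE] * A[-spe, , drop = FALSE] < 0,
                         na.rm = TRUE)
    }
  }

  bad <- vf < min_valid_frac
  auc[bad] <- NA_real_
  counts <- as.numeric(counts)
  counts[bad] <- NA_real_
  tibble::tibble(
    epoch = seq_len(ne),
    start_s = (seq_len(ne) - 1) * 30,
    sc_auc = auc,
    sc_peaks = counts,
    acc_zc = as.numeric(zc),
    sc_valid_frac = vf
  )
}

#' Per-day min-max normalization of skin conductance
#'
#' Rescales each local calendar day to `[0, 1]` using that day's own minimum
#' and maximum (individual daily normalization). Degenerate days (constant or
#' single-valued) map to 0; missing samples stay missing.
#'
#' @param x SC series (may contain `NA` for masked samples).
#' @param sample_rate Sampling rate in Hz (used to locate midnights).
#' @param day_index Optional explicit day index per sample.
#' @return Normalized series in `[0, 1]`.
#' @export
normalize_sc_daily <- function(x, sample_rate, day_index = NULL) {
  if (is.null(day_index)) {
    day_index <- floor((seq_along(x) - 1) / (sample_rate * SEC_PER_DAY)) + 1
  }
  out <- rep(NA_real_, length(x))
  for (d in unique(day_index)) {
    i <- which(day_index == d)
    xi <- x[i]
    ok <- !is.na(xi)
    if (!any(ok)) next
    lo <- min(xi[ok]); hi <- max(xi[ok])
    out[i][ok] <- if (hi > lo) (xi[ok] - lo) / (hi - lo) else 0
  }
  out
}

sensor_base_features <- function() {
  tibble::tibble(
    id = c("sc_auc", "sc_max", "sc_mean", "sc_median", "sc_sd",
           "sc_peaks_mean", "sc_peaks_median", "sc_peaks_sd",
           "sc_norm_mean", "sc_norm_median", "sc_norm_sd",
           "acc_zc",
           "st_max", "st_min", "st_mean", "st_median", "st_sd"),
    signal = c(rep("sc", 11), "acc", rep("st", 5))
  )
}

sensor_windows <- function() c("latenight", "sleep", "day", "night")

#' Sensor feature block (17 base features x 4 windows x 3 aggregates)
#'
#' For every participant, day and time window (late night 0-3, sleep episode,
#' day 9-18, night 18-24, local time) computes 17 base features from the
#' filtered and range-masked wearable streams -- SC epoch AUC (summed over the
#' window), SC amplitude max/mean/median/SD, per-epoch SC peak count
#' mean/median/SD, daily-normalized SC amplitude mean/median/SD, total
#' accelerometer zero crossings, and skin temperature max/min/mean/median/SD --
#' then aggregates each across days by mean, median and SD, yielding exactly
#' 204 named columns (plus one extra column, the across-day mean of full-day
#' accelerometer zero crossings, used by the modifiable-behaviour modality).
#'
#' A participant-day-window contributes only if at least `min_valid_frac` of
#' its expected samples are valid; across-day aggregates need at least 2
#' contributing days. Participants with fewer than 2 days of data are dropped
#' with a warning.
#'
#' @param x A `cohort_bundle`, or a named list of per-participant stream
#'   tibbles.
#' @param sleep Ground-truth sleep episode table (ignored when `x` is a
#'   bundle): `participant_id`, `day`, `bed_min`, `wake_min` in minutes from
#'   study start.
#' @param sample_rate Sampling rate in Hz (ignored when `x` is a bundle).
#' @param min_valid_frac Minimum valid-sample fraction per window and epoch.
#' @param cutoff,order Low-pass design passed to [fir_lowpass()].
#' @param slope_threshold Peak slope threshold in uS/s.
#' @return Feature block tibble (`participant_id` + 205 columns) with
#'   [feature_meta()] attached.
#' @export
sensor_features <- function(x, sleep = NULL, sample_rate = NULL,
                            min_valid_frac = 0.5, cutoff = 0.4, order = 32L,
                            slope_threshold = 0.02) {
  if (inherits(x, "cohort_bundle")) {
    streams <- x$streams
    sleep <- x$sleep
    sample_rate <- x$config$sc_sample_rate
  } else {
    streams <- x
  }
  if (is.null(sample_rate)) abort_ws("`sample_rate` is required", "param_error")

  base <- sensor_base_features()
  wins <- sensor_windows()
  aggs <- c("mean", "median", "sd")
  cw <- clock_windows()

  rows <- list()
  dropped <- character()
  for (pid in names(streams)) {
    s <- streams[[pid]]
    n <- nrow(s)
    days <- floor(n / (sample_rate * SEC_PER_DAY))
    if (days < 2) {
      dropped <- c(dropped, pid)
      next
    }
    msk <- range_mask(s)
    filt <- fir_lowpass(s$sc_uS, sample_rate, cutoff, order)
    sc_m <- filt
    sc_m[!msk$sc_valid] <- NA_real_
    pk <- detect_sc_peaks(filt, sample_rate, slope_threshold)
    pk <- pk[msk$sc_valid[pk$onset], , drop = FALSE]
    norm <- normalize_sc_daily(sc_m, sample_rate)
    st_m <- s$st_C
    st_m[!msk$st_valid] <- NA_real_
    ep <- epoch_features(sc_m, pk, s[c("acc_x", "acc_y", "acc_z")],
                         sample_rate, min_valid_frac)

    psleep <- sleep[sleep$participant_id == pid, , drop = FALSE]
    arr <- array(NA_real_, c(days, nrow(base), length(wins)))
    acc_full <- rep(NA_real_, days)

    for (d in seq_len(days)) {
      day0 <- (d - 1) * SEC_PER_DAY
      acc_full[d] <- sum(ep$acc_zc[ep$start_s >= day0 & ep$start_s < day0 + SEC_PER_DAY])
      for (wi in seq_along(wins)) {
        w <- wins[wi]
        if (w == "sleep") {
          r <- psleep[psleep$day == d & !is.na(psleep$bed_min), , drop = FALSE]
          if (nrow(r) == 0) next
          t0 <- r$bed_min[1] * 60
          t1 <- min(r$wake_min[1] * 60, n / sample_rate)
        } else {
          b <- cw[cw$window == w, ]
          t0 <- day0 + b$start_s
          t1 <- day0 + b$end_s
        }
        if (t1 <= t0) next
        i0 <- floor(t0 * sample_rate) + 1
        i1 <- min(floor(t1 * sample_rate), n)
        if (i1 < i0) next
        idx <- i0:i1
        e_in <- ep$start_s >= t0 & ep$start_s < t1

        v <- sc_m[idx]
        if (mean(!is.na(v)) >= min_valid_frac) {
          auc_e <- ep$sc_auc[e_in]
          arr[d, 1, wi] <- if (any(!is.na(auc_e))) sum(auc_e, na.rm = TRUE) else NA_real_
          vv <- v[!is.na(v)]
          arr[d, 2, wi] <- max(vv)
          arr[d, 3:5, wi] <- day_stats(vv)[c("mean", "median", "sd")]
          pe <- ep$sc_peaks[e_in]
          arr[d, 6:8, wi] <- day_stats(pe)
          arr[d, 9:11, wi] <- day_stats(norm[idx])
        }
        arr[d, 12, wi] <- sum(ep$acc_zc[e_in])
        stv <- st_m[idx]
        if (mean(!is.na(stv)) >= min_valid_frac) {
          sv <- stv[!is.na(stv)]
          arr[d, 13, wi] <- max(sv)
          arr[d, 14, wi] <- min(sv)
          arr[d, 15:17, wi] <- day_stats(sv)
        }
      }
    }

    vals <- numeric(nrow(base) * length(wins) * 3)
    k <- 1
    for (f in seq_len(nrow(base))) {
      for (wi in seq_along(wins)) {
        vals[k:(k + 2)] <- agg3(arr[, f, wi])
        k <- k + 3
      }
    }
    rows[[pid]] <- c(vals, acc_zc_fullday_mean = agg3(acc_full)[["mean"]])
  }

  if (length(dropped)) {
    rlang::warn(paste0("excluded participants with < 2 days of data: ",
                       paste(dropped, collapse = ", ")))
  }
  if (!length(rows)) abort_ws("no participant with >= 2 usable days", "param_error")

  nm <- as.vector(vapply(seq_len(nrow(base)), function(f) {
    vapply(wins, function(w) paste(base$id[f], w, aggs, sep = "_"), character(3))
  }, matrix("", 3, length(wins))))
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(nm, "acc_zc_fullday_mean")
  out <- dplyr::bind_cols(tibble::tibble(participant_id = names(rows)),
                          tibble::as_tibble(mat))

  meta <- tibble::tibble(
    column = c(nm, "acc_zc_fullday_mean"),
    signal = c(rep(base$signal, each = length(wins) * 3), "acc"),
    statistic = c(rep(base$id, each = length(wins) * 3), "acc_zc"),
    window = c(rep(rep(wins, each = 3), nrow(base)), "fullday"),
    aggregate = c(rep(aggs, length(wins) * nrow(base)), "mean"),
    block = c(rep("sensor", length(nm)), "sensor_extra")
  )
  new_feature_block(out, meta)
}
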