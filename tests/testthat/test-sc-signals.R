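test_that("low-pass filter preserves DC, kills the stopband, and validates inputs", {
  expect_lt(max(abs(fir_lowpass(rep(5, 400), 8) - 5)), 1e-6)
  expect_lt(max(abs(fir_lowpass(rep(5, 400), 1) - 5)), 1e-6)

  # 2 Hz tone sampled at 8 Hz must be attenuated by at least 20 dB
  t <- seq(0, 60, by = 1 / 8)
  s <- sin(2 * pi * 2 * t)
  atten_db <- 20 * log10(sqrt(mean(fir_lowpass(s, 8)^2)) / sqrt(mean(s^2)))
  expect_lt(atten_db, -20)

  # published design parameters are the defaults
  expect_equal(eval(formals(fir_lowpass)$cutoff), 0.4)
  expect_equal(eval(formals(fir_lowpass)$order), 32L)

  expect_error(fir_lowpass(rnorm(10), sample_rate = 0.5),
               class = "wearstress_param_error")
})

test_that("range masks apply the published inclusive bounds", {
  st_dummy <- c(25, 25, 25)
  m <- range_mask(tibble::tibble(sc_uS = c(0.005, 1.0, 31.0), st_C = st_dummy))
  expect_identical(m$sc_valid, c(FALSE, TRUE, FALSE))
  m2 <- range_mask(tibble::tibble(sc_uS = c(1, 1, 1), st_C = c(19.9, 36.5, 42.0)))
  expect_identical(m2$st_valid, c(FALSE, TRUE, TRUE))
  # boundary values are retained
  m3 <- range_mask(tibble::tibble(sc_uS = c(0.01, 30), st_C = c(20, 42)))
  expect_true(all(m3$sc_valid) && all(m3$st_valid))
  # device validity mask is ANDed in
  m4 <- range_mask(tibble::tibble(sc_uS = c(1, 1), st_C = c(30, 30),
                                  valid = c(TRUE, FALSE)))
  expect_identical(m4$sc_valid, c(TRUE, FALSE))
})

test_that("slope-threshold peak detection matches hand-built cases", {
  # global rise below threshold: no events
  expect_identical(nrow(detect_sc_peaks(seq(0, 10, by = 0.01 / 8), 8)), 0L)
  # flat signal with a single 2-s suprathreshold rise: one event at its onset
  x <- c(rep(1, 10), 1 + cumsum(rep(0.05, 2)), rep(1.1, 10))
  pk <- detect_sc_peaks(x, 1)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$onset, 10L)
  expect_identical(pk$time, 9)
  # amplitude offsets do not change derivative events
  x2 <- cumsum(rnorm(300, 0, 0.05)) + 5
  expect_identical(detect_sc_peaks(x2, 4), detect_sc_peaks(x2 + 3, 4))
  # degenerate input
  expect_identical(nrow(detect_sc_peaks(numeric(0), 8)), 0L)
  expect_identical(nrow(detect_sc_peaks(5, 8)), 0L)
})

test_that("peak detector equals the brute-force scan oracle on random signals", {
  withr::local_seed(42)
  for (i in 1:100) {
    rate <- sample(c(1, 2, 4, 8), 1)
    x <- cumsum(rnorm(200, 0, 0.03)) + 3
    expect_identical(detect_sc_peaks(x, rate)$onset,
                     as.integer(peak_scan_oracle(x, rate)))
  }
})

test_that("epoch features reproduce closed-form examples", {
  acc0 <- matrix(0, 30, 3)
  ep <- epoch_features(rep(2, 30), numeric(0), acc0, 1)
  expect_equal(ep$sc_auc, 60)                       # 2 uS x 30 s
  expect_equal(ep$sc_peaks, 0)

  ep8 <- epoch_features(rep(2, 240), numeric(0), matrix(0, 240, 3), 8)
  expect_equal(ep8$sc_auc, 60)

  acc <- cbind(rep(c(1, -1), 15), rep(0.5, 30), rep(-2, 30))
  ep2 <- epoch_features(rep(1, 30), numeric(0), acc, 1)
  expect_equal(ep2$acc_zc, 29)                      # 29 sign changes, one axis

  ep3 <- epoch_features(rep(0, 30), numeric(0), acc0, 1)
  expect_equal(unlist(ep3[c("sc_auc", "sc_peaks", "acc_zc")]),
               c(sc_auc = 0, sc_peaks = 0, acc_zc = 0))

  # epochs with under half their samples valid are missing
  sc <- rep(1, 60)
  sc[1:20] <- NA
  ep4 <- epoch_features(sc, numeric(0), matrix(0, 60, 3), 1)
  expect_true(is.na(ep4$sc_auc[1]) && !is.na(ep4$sc_auc[2]))
})

test_that("daily normalization is a per-day min-max map to [0, 1]", {
  x <- c(2, 4, 6)
  expect_equal(normalize_sc_daily(x, 1, day_index = c(1, 1, 1)), c(0, 0.5, 1))
  expect_equal(normalize_sc_daily(rep(3, 5), 1, day_index = rep(1, 5)), rep(0, 5))
  withr::local_seed(1)
  y <- normalize_sc_daily(rnorm(4000, 5), sample_rate = 1 / 60)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("the sensor block has 204 tagged columns plus the full-day ACC summary", {
  b <- small_sensor_bundle()
  sf <- sensor_features(b)
  meta <- feature_meta(sf)
  expect_identical(sum(meta$block == "sensor"), 204L)
  expect_identical(sum(meta$block == "sensor_extra"), 1L)
  expect_false(anyDuplicated(names(sf)) > 0)
  expect_setequal(unique(meta$window[meta$block == "sensor"]),
                  c("latenight", "sleep", "day", "night"))
  expect_setequal(unique(meta$aggregate[meta$block == "sensor"]),
                  c("mean", "median", "sd"))
  # stable names across runs
  expect_identical(names(sensor_features(b)), names(sf))
})

test_that("identical days give zero across-day dispersion and offsets only shift amplitudes", {
  b <- small_sensor_bundle()
  one_day <- b$streams[[1]][1:86400, ]
  rep_stream <- dplyr::bind_rows(one_day, dplyr::mutate(one_day, ts = ts + 86400))
  sleep <- tibble::tibble(participant_id = "px", day = c(1, 2),
                          bed_min = c(0, 1440) + 1410,
                          wake_min = c(0, 1440) + 1410 + 420,
                          efficiency = c(1, 1), all_nighter = c(FALSE, FALSE))
  sf <- suppressWarnings(sensor_features(list(px = rep_stream), sleep,
                                         sample_rate = 1))
  meta <- feature_meta(sf)
  sd_cols <- meta$column[meta$aggregate == "sd" & meta$window != "sleep"]
  # unfiltered signals repeat exactly, so their across-day SDs are zero;
  # filtered SC carries zero-phase end transients on the first/last day, so
  # its SDs are only bounded relative to the feature's own scale
  exact <- sd_cols[!startsWith(sd_cols, "sc_")]
  vals <- unlist(sf[exact])
  expect_true(all(abs(vals[!is.na(vals)]) < 1e-9))
  for (sc_col in sd_cols[startsWith(sd_cols, "sc_")]) {
    s <- sf[[sc_col]]
    if (is.na(s)) next
    m <- sf[[sub("_sd$", "_mean", sc_col)]]
    expect_lt(s, 0.01 * (abs(m) + 1), label = sc_col)
  }

  # constant amplitude shift: SC peak features unchanged
  shifted <- dplyr::mutate(b$streams[[1]], sc_uS = sc_uS + 3)
  sf1 <- sensor_features(b$streams[1], b$sleep, sample_rate = 1)
  sf2 <- sensor_features(setNames(list(shifted), names(b$streams)[1]), b$sleep,
                         sample_rate = 1)
  pk_cols <- grep("^sc_peaks_", names(sf1), value = TRUE)
  expect_equal(sf1[pk_cols], sf2[pk_cols], tolerance = 1e-12)
  # normalized-amplitude features invariant under per-day affine rescaling
  rescaled <- dplyr::mutate(b$streams[[1]], sc_uS = 2 * sc_uS + 1)
  sf3 <- sensor_features(setNames(list(rescaled), names(b$streams)[1]), b$sleep,
                         sample_rate = 1)
  nm_cols <- grep("^sc_norm_", names(sf1), value = TRUE)
  expect_equal(sf1[nm_cols], sf3[nm_cols], tolerance = 1e-6)
})

test_that("participants with fewer than two days are excluded with a warning", {
  b <- small_sensor_bundle()
  streams <- b$streams
  streams[[2]] <- streams[[2]][1:86400, ]
  expect_warning(sf <- sensor_features(streams, b$sleep, sample_rate = 1),
                 "excluded")
  expect_false(names(streams)[2] %in% sf$participant_id)
})
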