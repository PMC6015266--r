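#' Configuration for a synthetic cohort
#'
#' Describes a study cohort of the kind the pipeline analyses: participants
#' enrolled in semester cohorts, each contributing about a month of wrist
#' sensor streams (skin conductance in uS, skin temperature in degC, 3-axis
#' acceleration), phone event logs (calls, SMS, screen on/off), location fixes
#' on a planar meter grid, twice-daily diary records, ground-truth sleep
#' episodes, and pre/post Perceived Stress Scale (PSS, 0-40) and SF-12 Mental
#' Component Summary (MCS) scores.
#'
#' A single latent stress trait `z ~ N(0,1)` per participant drives the
#' outcomes and, through `latent_effect_sizes`, the behavioural/physiological
#' signal families. The PSS is modelled as a tight readout of the trait
#' (residual SD `2 * outcome_noise_sd` score points) and the MCS loading is
#' solved in closed form so that `cor(pss_post, mcs_post)` matches
#' `target_pss_mcs_corr` (see the package vignette for the algebra).
#'
#' @param n_participants Number of participants (>= 4).
#' @param n_cohorts Number of enrollment cohorts (>= 2); participants are
#'   assigned round-robin so cohorts are exchangeable.
#' @param days Days of data per participant (>= 2).
#' @param sc_sample_rate Wearable sampling rate in Hz. `30 * rate` must be a
#'   whole number so 30-second epochs tile exactly.
#' @param latent_effect_sizes Named numeric vector of standardized effect sizes
#'   linking the latent trait to the signal families
#'   `sc_peak`, `nap`, `mobility`, `screen`, `bedtime`. Missing names default
#'   to 0 (no effect).
#' @param outcome_noise_sd Multiplier on the idiosyncratic noise of the
#'   questionnaire scores (1 = calibrated defaults).
#' @param target_pss_mcs_corr Target Pearson correlation between post-study PSS
#'   and MCS, in `[-1, 0]`.
#' @param seed Integer seed; fully determines the generated bundle.
#' @return A `cohort_config` object (list).
#' @export
cohort_config <- function(n_participants,
                          n_cohorts = 5L,
                          days = 30L,
                          sc_sample_rate = 8,
                          latent_effect_sizes = c(sc_peak = 0, nap = 0, mobility = 0,
                                                  screen = 0, bedtime = 0),
                          outcome_noise_sd = 1,
                          target_pss_mcs_corr = -0.71,
                          seed = 1L) {
  check_number(n_participants, "n_participants", min = 4, integer = TRUE)
  check_number(n_cohorts, "n_cohorts", min = 2, integer = TRUE)
  check_number(days, "days", min = 2, integer = TRUE)
  check_number(sc_sample_rate, "sc_sample_rate", min = 1e-6)
  if (abs(30 * sc_sample_rate - round(30 * sc_sample_rate)) > 1e-9) {
    abort_ws("invalid value for `sc_sample_rate`: 30 * rate must be an integer",
             "param_error")
  }
  check_number(outcome_noise_sd, "outcome_noise_sd", min = 1e-6)
  check_number(target_pss_mcs_corr, "target_pss_mcs_corr", min = -1, max = 0)
  check_number(seed, "seed", min = 0, max = 2^31 - 1, integer = TRUE)

  fam <- c("sc_peak", "nap", "mobility", "screen", "bedtime")
  if (is.null(names(latent_effect_sizes)) ||
      !all(names(latent_effect_sizes) %in% fam)) {
    abort_ws("invalid value for `latent_effect_sizes`: names must be among sc_peak, nap, mobility, screen, bedtime",
             "param_error")
  }
  es <- stats::setNames(rep(0, length(fam)), fam)
  es[names(latent_effect_sizes)] <- as.numeric(latent_effect_sizes)
  if (any(is.na(es))) abort_ws("invalid value for `latent_effect_sizes`", "param_error")

  structure(
    list(
      n_participants = as.integer(n_participants),
      n_cohorts = as.integer(n_cohorts),
      days = as.integer(days),
      sc_sample_rate = as.numeric(sc_sample_rate),
      latent_effect_sizes = es,
      outcome_noise_sd = as.numeric(outcome_noise_sd),
      target_pss_mcs_corr = as.numeric(target_pss_mcs_corr),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Closed-form questionnaire loadings: pss = 17.1 + b1 z + s1 e, mcs = 40.4 - b2 z + s2 e'
# with total SDs 6.5 (PSS) and 10 (MCS), so cor = -b1 b2 / 65 = target.
outcome_loadings <- function(target_corr, noise_sd) {
  sd_pss <- 6.5; sd_mcs <- 10
  s1 <- min(2 * noise_sd, 0.92 * sd_pss)
  b1 <- sqrt(sd_pss^2 - s1^2)
  b2 <- abs(target_corr) * sd_pss * sd_mcs / b1
  if (b2 > 0.99 * sd_mcs) {
    b2 <- 0.99 * sd_mcs
    b1 <- min(abs(target_corr) * sd_pss * sd_mcs / b2, 0.99 * sd_pss)
    s1 <- sqrt(sd_pss^2 - b1^2)
  }
  s2 <- sqrt(sd_mcs^2 - b2^2)
  list(b1 = b1, s1 = s1, b2 = b2, s2 = s2, sd_pss = sd_pss, sd_mcs = sd_mcs)
}

#' Generate a synthetic study cohort
#'
#' Draws a full multimodal dataset bundle: participants (traits, cohort,
#' questionnaire scores), per-participant sensor streams, phone logs, location
#' traces, diaries and ground-truth sleep episodes. Equal configs and seeds
#' give identical bundles.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle`: list with elements `config`, `participants`,
#'   `streams` (named list of per-participant tibbles), `calls`, `sms`,
#'   `screen`, `locations`, `diary`, `sleep`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_ws("`config` must be a cohort_config object", "param_error")
  }
  withr::local_seed(config$seed)

  n <- config$n_participants
  days <- config$days
  es <- config$latent_effect_sizes
  ld <- outcome_loadings(config$target_pss_mcs_corr, config$outcome_noise_sd)

  z <- rnorm(n)
  pss_post <- pmin(40, pmax(0, round(17.1 + ld$b1 * z + ld$s1 * rnorm(n))))
  b1p <- min(0.6 * ld$sd_pss^2 / max(ld$b1, 0.5), 0.95 * ld$sd_pss)
  pss_pre <- pmin(40, pmax(0, round(15.0 + b1p * z +
                                      sqrt(ld$sd_pss^2 - b1p^2) * rnorm(n))))
  mcs_post <- pmax(5, pmin(75, round(40.4 - ld$b2 * z + ld$s2 * rnorm(n), 1)))
  b2p <- min(0.6 * ld$sd_mcs^2 / max(ld$b2, 0.5), 0.95 * ld$sd_mcs)
  mcs_pre <- pmax(5, pmin(75, round(44.4 - b2p * z +
                                      sqrt(ld$sd_mcs^2 - b2p^2) * rnorm(n), 1)))

  clip01 <- function(x) pmin(5, pmax(1, x))
  participants <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    cohort = rep_len(paste0("c", seq_len(config$n_cohorts)), n),
    gender = ifelse(runif(n) < 0.64, "M", "F"),
    openness = clip01(rnorm(n, 3.4, 0.7)),
    conscientiousness = clip01(rnorm(n, 3.5, 0.6) - 0.3 * z),
    extraversion = clip01(rnorm(n, 3.2, 0.7)),
    agreeableness = clip01(rnorm(n, 3.6, 0.6)),
    neuroticism = clip01(rnorm(n, 3.0, 0.5) + 0.5 * z),
    pss_pre = as.numeric(pss_pre),
    pss_post = as.numeric(pss_post),
    mcs_pre = as.numeric(mcs_pre),
    mcs_post = as.numeric(mcs_post),
    latent_trait = z
  )

  # participant-level signal-family parameters (latent effects + idiosyncrasy)
  m_sc     <- exp(0.33 * (es[["sc_peak"]] * z + 0.2 * rnorm(n)))
  lam_nap  <- pmin(3, pmax(0.02, 0.45 * exp(0.35 * (es[["nap"]] * z + 0.3 * rnorm(n)))))
  radius   <- pmin(5000, pmax(80, 700 * exp(0.30 * (-es[["mobility"]] * z + 0.3 * rnorm(n)))))
  m_screen <- exp(0.30 * (es[["screen"]] * z + 0.3 * rnorm(n)))
  sd_bed   <- pmax(4, 22 * exp(0.30 * (es[["bedtime"]] * z + 0.3 * rnorm(n))))

  streams <- stats::setNames(vector("list", n), participants$participant_id)
  sleep_l <- diary_l <- calls_l <- sms_l <- screen_l <- loc_l <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- participants$participant_id[i]
    sl <- gen_sleep(days, sd_bed[i])
    dy <- gen_diary(pid, days, sl, lam_nap[i])
    sleep_l[[i]] <- dplyr::mutate(sl, participant_id = pid, .before = 1)
    diary_l[[i]] <- dy
    streams[[i]] <- gen_stream(days, config$sc_sample_rate, m_sc[i], sl)
    ph <- gen_phone(pid, days, m_screen[i])
    calls_l[[i]] <- ph$calls; sms_l[[i]] <- ph$sms; screen_l[[i]] <- ph$screen
    loc_l[[i]] <- gen_locations(pid, days, radius[i])
  }

  structure(
    list(
      config = config,
      participants = participants,
      streams = streams,
      calls = dplyr::bind_rows(calls_l),
      sms = dplyr::bind_rows(sms_l),
      screen = dplyr::bind_rows(screen_l),
      locations = dplyr::bind_rows(loc_l),
      diary = dplyr::bind_rows(diary_l),
      sleep = dplyr::bind_rows(sleep_l)
    ),
    class = "cohort_bundle"
  )
}

# ground-truth sleep episodes; night of day d starts near 23:10 +/- jitter
gen_sleep <- function(days, sd_bed) {
  base_bed <- 1390 + rnorm(1, 0, 35)                      # minutes into day
  all_nighter <- runif(days) < 0.02
  bed_clock <- base_bed + rnorm(days, 0, sd_bed)
  dur <- pmax(120, rnorm(days, 450, 45))
  bed <- (seq_len(days) - 1) * MIN_PER_DAY + bed_clock
  wake <- bed + dur
  eff <- pmin(1, pmax(0.7, rnorm(days, 0.93, 0.03)))
  tibble::tibble(
    day = as.numeric(seq_len(days)),
    bed_min = ifelse(all_nighter, NA_real_, round(bed)),
    wake_min = ifelse(all_nighter, NA_real_, round(wake)),
    efficiency = ifelse(all_nighter, NA_real_, round(eff, 3)),
    all_nighter = all_nighter
  )
}

gen_diary <- function(pid, days, sl, lam_nap) {
  n_naps <- rpois(days, lam_nap)
  nap_dur <- vapply(n_naps, function(k) if (k == 0) 0 else sum(pmax(10, rnorm(k, 45, 15))), 0)
  n_caff <- rpois(days, 1.4)
  tibble::tibble(
    participant_id = pid,
    day = as.numeric(seq_len(days)),
    all_nighter = sl$all_nighter,
    presleep_media = runif(days) < 0.6,
    presleep_interaction = runif(days) < 0.45,
    n_naps = as.numeric(n_naps),
    nap_duration_min = round(nap_dur, 1),
    n_academic = as.numeric(rpois(days, 2.5)),
    academic_duration_min = round(pmax(0, rnorm(days, 240, 80)), 1),
    study_duration_min = round(pmax(0, rnorm(days, 170, 70)), 1),
    n_extracurricular = as.numeric(rpois(days, 1)),
    extracurricular_duration_min = round(pmax(0, rnorm(days, 60, 45)), 1),
    n_exercise = as.numeric(rpois(days, 0.5)),
    exercise_duration_min = round(pmax(0, rnorm(days, 25, 25)), 1),
    n_caffeine = as.numeric(n_caff),
    pos_interaction = runif(days) < 0.7,
    somewhat_neg_interaction = runif(days) < 0.25,
    very_neg_interaction = runif(days) < 0.07,
    last_caffeine_min = ifelse(n_caff > 0, round(runif(days, 8 * 60, 22 * 60)), NA_real_),
    reported_bed_min = sl$bed_min %% MIN_PER_DAY,
    reported_wake_min = sl$wake_min %% MIN_PER_DAY
  )
}

# skin conductance = bounded tonic walk + Poisson phasic responses + noise;
# phasic event rate per clock window scales with the participant multiplier
gen_stream <- function(days, rate, m_sc, sl) {
  n_s <- as.integer(round(days * SEC_PER_DAY * rate))
  ts <- (seq_len(n_s) - 1) / rate
  clock <- ts %% SEC_PER_DAY

  base_rate <- rep(0.12, n_s)                              # peaks per minute
  base_rate[clock < 3 * 3600] <- 0.10
  base_rate[clock >= 9 * 3600 & clock < 18 * 3600] <- 0.30
  base_rate[clock >= 18 * 3600] <- 0.18
  p_event <- base_rate * m_sc / (60 * rate)
  events <- which(runif(n_s) < p_event)

  tt <- seq(0, 40, by = 1 / rate)
  kern <- (tt / 4) * exp(1 - tt / 4)                       # rise ~4 s, slow decay
  phasic <- numeric(n_s)
  if (length(events)) {
    amps <- runif(length(events), 0.25, 0.8)
    lk <- length(kern)
    for (j in seq_along(events)) {
      e <- events[j]
      idx <- e:min(n_s, e + lk - 1)
      phasic[idx] <- phasic[idx] + amps[j] * kern[seq_along(idx)]
    }
  }
  rw <- cumsum(rnorm(n_s, 0, 0.005 / sqrt(rate)))
  tonic <- runif(1, 2.5, 6) + 3 * (stats::plogis(rw) - 0.5)
  # measurement noise at the device quantization scale: keeps the first
  # difference of the filtered trace well below the 0.02 uS/s peak threshold
  sc <- pmax(0.02, tonic + phasic + rnorm(n_s, 0, 0.003))

  st <- 33.5 + rnorm(1, 0, 0.8) + 1.2 * sinpi(2 * (clock / SEC_PER_DAY - 0.3)) +
    rnorm(n_s, 0, 0.15)

  asleep <- rep(FALSE, n_s)
  for (r in which(!is.na(sl$bed_min))) {
    i0 <- max(1L, as.integer(floor(sl$bed_min[r] * 60 * rate)) + 1L)
    i1 <- min(n_s, as.integer(floor(sl$wake_min[r] * 60 * rate)))
    if (i1 >= i0) asleep[i0:i1] <- TRUE
  }
  sig <- ifelse(asleep, 0.02, ifelse(clock >= 8 * 3600 & clock < 23 * 3600, 0.3, 0.1))
  tibble::tibble(
    ts = ts,
    sc_uS = sc,
    st_C = st,
    acc_x = rnorm(n_s, 0, sig),
    acc_y = rnorm(n_s, 0, sig),
    acc_z = 1 + rnorm(n_s, 0, sig),
    valid = TRUE
  )
}

gen_phone <- function(pid, days, m_screen) {
  contacts <- sprintf("%s_ct%02d", pid, seq_len(sample(6:18, 1)))
  mk_day_ts <- function(k, d) sort(runif(k, 8 * 3600, 24 * 3600)) + (d - 1) * SEC_PER_DAY

  calls <- lapply(seq_len(days), function(d) {
    k <- rpois(1, 3)
    if (k == 0) return(NULL)
    tibble::tibble(
      participant_id = pid,
      ts = round(mk_day_ts(k, d), 1),
      duration_s = round(rlnorm(k, log(120), 0.9), 1),
      contact_hash = sample(contacts, k, replace = TRUE),
      direction = sample(c("in", "out"), k, replace = TRUE)
    )
  })

  sms <- lapply(seq_len(days), function(d) {
    n_sess <- rpois(1, 3)
    if (n_sess == 0) return(NULL)
    purrr::map_dfr(seq_len(n_sess), function(s) {
      k <- sample(1:5, 1)
      t0 <- runif(1, 8 * 3600, 23.5 * 3600) + (d - 1) * SEC_PER_DAY
      tibble::tibble(
        participant_id = pid,
        ts = round(t0 + cumsum(c(0, runif(max(k - 1, 0), 20, 90))), 1),
        contact_hash = sample(contacts, 1),
        direction = sample(c("in", "out"), k, replace = TRUE)
      )
    })
  })

  screen <- lapply(seq_len(days), function(d) {
    k <- rpois(1, 25)
    if (k == 0) return(NULL)
    starts <- mk_day_ts(k, d)
    durs <- pmin(3600, rlnorm(k, log(120 * m_screen), 0.9))
    keep <- rep(TRUE, k)
    last_end <- -Inf
    for (j in seq_len(k)) {
      if (starts[j] < last_end) keep[j] <- FALSE else last_end <- starts[j] + durs[j]
    }
    starts <- starts[keep]; durs <- durs[keep]
    ends <- pmin(starts + durs, d * SEC_PER_DAY - 1)       # close at midnight
    tibble::tibble(
      participant_id = pid,
      ts = round(as.vector(rbind(starts, ends)), 1),
      state = rep(c("on", "off"), length(starts))
    )
  })

  list(calls = dplyr::bind_rows(calls), sms = dplyr::bind_rows(sms),
       screen = dplyr::bind_rows(screen))
}

# anchor-based mobility on a planar meter grid: home + 2-3 campus anchors at
# the participant's routine radius; fixes every ~10 min, 30 m GPS noise
gen_locations <- function(pid, days, radius) {
  home <- runif(2, -2000, 2000)
  n_anchor <- sample(2:3, 1)
  ang <- runif(n_anchor, 0, 2 * pi)
  anchors <- cbind(home[1] + radius * cos(ang), home[2] + radius * sin(ang))
  purrr::map_dfr(seq_len(days), function(d) {
    t_day <- seq(7 * 3600, 23.8 * 3600, by = 600) + runif(1, 0, 300)
    t_day <- t_day + runif(length(t_day), -120, 120)
    a_day <- sample(n_anchor, 1)
    at_home <- (t_day < 8.5 * 3600) | (t_day > 22 * 3600) | (runif(length(t_day)) < 0.3)
    px <- ifelse(at_home, home[1], anchors[a_day, 1]) + rnorm(length(t_day), 0, 30)
    py <- ifelse(at_home, home[2], anchors[a_day, 2]) + rnorm(length(t_day), 0, 30)
    tibble::tibble(
      participant_id = pid,
      ts = round(t_day + (d - 1) * SEC_PER_DAY, 1),
      x_m = round(px, 2),
      y_m = round(py, 2)
    )
  })
}

#' Inject out-of-range skin conductance artifacts
#'
#' Replaces approximately `fraction` of the SC samples with out-of-range values
#' (< 0.01 or > 30 uS) in contiguous bouts, emulating electrode lift-off and
#' saturation. The input stream is not modified.
#'
#' @param stream A per-participant stream tibble (from a bundle's `streams`).
#' @param fraction Proportion of samples to corrupt, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A modified copy of `stream`.
#' @export
inject_artifacts <- function(stream, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction >= 1) {
    abort_ws("invalid value for `fraction`: must be in [0, 1)", "param_error")
  }
  if (fraction == 0) return(stream)
  n <- nrow(stream)
  withr::local_seed(seed)
  marked <- logical(n)
  target <- round(fraction * n)
  while (sum(marked) < target) {
    len <- 10 + stats::rgeom(1, 1 / 110)
    start <- sample.int(n, 1)
    marked[start:min(n, start + len - 1)] <- TRUE
  }
  idx <- which(marked)
  low <- runif(length(idx)) < 0.5
  stream$sc_uS[idx] <- ifelse(low, runif(length(idx), 1e-4, 9e-3),
                              runif(length(idx), 31, 45))
  stream
}

dataset_files <- function() {
  c("participants.csv", "streams.csv", "calls.csv", "sms.csv", "screen.csv",
    "locations.csv", "diary.csv", "sleep.csv")
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Serializes every table to CSV (one `streams.csv` with a `participant_id`
#' column) plus a JSON manifest recording the schema version, the generating
#' configuration and seed, and the file list. `read_dataset()` restores an
#' identical bundle.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!inherits(bundle, "cohort_bundle")) abort_ws("not a cohort_bundle", "param_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  streams <- dplyr::bind_rows(bundle$streams, .id = "participant_id")
  tables <- list(
    participants.csv = bundle$participants, streams.csv = streams,
    calls.csv = bundle$calls, sms.csv = bundle$sms, screen.csv = bundle$screen,
    locations.csv = bundle$locations, diary.csv = bundle$diary,
    sleep.csv = bundle$sleep
  )
  for (f in names(tables)) readr::write_csv(tables[[f]], file.path(dir, f), progress = FALSE)
  cfg <- unclass(bundle$config)
  cfg$latent_effect_sizes <- as.list(cfg$latent_effect_sizes)
  # doubles as %.17g strings: JSON number printing is not guaranteed to be
  # shortest-round-trip, strtod parsing of 17 significant digits is exact
  cfg <- lapply(cfg, function(v) {
    if (is.list(v)) lapply(v, function(x) sprintf("%.17g", x))
    else if (is.double(v)) sprintf("%.17g", v)
    else v
  })
  manifest <- list(
    schema_version = "1",
    package = "wearstress",
    seed = bundle$config$seed,
    config = cfg,
    files = dataset_files()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort bundle from a directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `cohort_bundle`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    abort_ws(sprintf("format error: missing manifest.json in %s", dir), "format_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, "1")) {
    abort_ws(sprintf("format error in %s: unsupported schema version", mf), "format_error")
  }
  for (f in dataset_files()) {
    if (!file.exists(file.path(dir, f))) {
      abort_ws(sprintf("format error: missing file %s (line 1)", file.path(dir, f)),
               "format_error")
    }
  }
  # base read.csv: strtod parsing is exact, so doubles written by write_csv
  # (shortest round-trip representation) are restored bit for bit
  rd <- function(f, types) {
    classes <- c(c = "character", d = "numeric", l = "logical")[strsplit(types, "")[[1]]]
    tibble::as_tibble(utils::read.csv(file.path(dir, f), colClasses = unname(classes)))
  }
  participants <- rd("participants.csv", "cccdddddddddd")
  streams_all <- rd("streams.csv", "cddddddl")
  streams <- split(streams_all[-1], streams_all$participant_id)
  streams <- lapply(streams, tibble::as_tibble)
  streams <- streams[unique(streams_all$participant_id)]
  cfg <- manifest$config
  num <- function(v) if (is.character(v)) as.numeric(v) else v
  es <- vapply(cfg$latent_effect_sizes, num, 0)
  config <- cohort_config(
    n_participants = cfg$n_participants, n_cohorts = cfg$n_cohorts,
    days = cfg$days, sc_sample_rate = num(cfg$sc_sample_rate),
    latent_effect_sizes = es,
    outcome_noise_sd = num(cfg$outcome_noise_sd),
    target_pss_mcs_corr = num(cfg$target_pss_mcs_corr), seed = cfg$seed
  )
  structure(
    list(
      config = config,
      participants = participants,
      streams = streams,
      calls = rd("calls.csv", "cddcc"),
      sms = rd("sms.csv", "cdcc"),
      screen = rd("screen.csv", "cdc"),
      locations = rd("locations.csv", "cddd"),
      diary = rd("diary.csv", "cdlllddddddddddlllddd"),
      sleep = rd("sleep.csv", "cddddl")
    ),
    class = "cohort_bundle"
  )
}
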