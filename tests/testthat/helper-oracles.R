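# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately re-derive each quantity with the most literal possible
# algorithm (explicit loops, closed forms) and stay independent of the
# package's implementation paths.

# Sleep Regularity Index by explicit double loop over (t, t + 1440) pairs
sri_oracle <- function(s, lag = 1440L) {
  agree <- 0L
  total <- 0L
  for (t in seq_len(length(s) - lag)) {
    a <- s[t]
    b <- s[t + lag]
    if (!is.na(a) && !is.na(b)) {
      total <- total + 1L
      if (a == b) agree <- agree + 1L
    }
  }
  -100 + 200 * agree / total
}

# peak events by explicit scan over first differences
peak_scan_oracle <- function(x, rate, thr = 0.02) {
  onsets <- integer(0)
  in_run <- FALSE
  for (i in seq_len(length(x) - 1)) {
    up <- (x[i + 1] - x[i]) * rate > thr
    if (up && !in_run) onsets <- c(onsets, i)
    in_run <- up
  }
  onsets
}

# Benjamini-Hochberg step-up q-values by sort and cumulative minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Agresti-Coull interval evaluated directly from its closed form
wald_oracle <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  centre <- (x + z^2 / 2) / (n + z^2)
  hw <- z * sqrt(centre * (1 - centre) / (n + z^2))
  c(max(0, centre - hw), min(1, centre + hw))
}

# naive per-day loop oracle for call features in one clock window
call_day_oracle <- function(calls, w_start, w_end) {
  out <- list()
  for (pid in unique(calls$participant_id)) {
    pc <- calls[calls$participant_id == pid, ]
    for (d in unique(floor(pc$ts / 86400) + 1)) {
      rows <- pc[floor(pc$ts / 86400) + 1 == d, ]
      clock <- rows$ts %% 86400
      rows <- rows[clock >= w_start & clock < w_end, ]
      if (nrow(rows) == 0) next
      tmin <- (rows$ts %% 86400 - w_start) / 60
      out[[paste(pid, d)]] <- data.frame(
        participant_id = pid, day = d,
        dur_mean = mean(rows$duration_s),
        dur_median = median(rows$duration_s),
        dur_sd = if (nrow(rows) > 1) sd(rows$duration_s) else 0,
        time_mean = mean(tmin), time_median = median(tmin),
        time_sd = if (nrow(rows) > 1) sd(tmin) else 0,
        total_dur = sum(rows$duration_s), n = nrow(rows),
        n_contacts = length(unique(rows$contact_hash))
      )
    }
  }
  do.call(rbind, out)
}

# small cached fixtures shared across test files (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# a small cohort with full-rate streams usable by the sensor pipeline
small_sensor_bundle <- function() {
  cached_fixture("small_sensor", {
    generate_cohort(cohort_config(6, 2, days = 2, sc_sample_rate = 1, seed = 101))
  })
}

# a cheap cohort (sparse SC sampling) for tests that only need outcomes,
# events, diaries and sleep
cheap_bundle <- function(n = 60, seed = 5, ...) {
  generate_cohort(cohort_config(n, n_cohorts = 3, days = 2,
                                sc_sample_rate = 1 / 30, seed = seed, ...))
}

# three-cohort classification problem with one globally informative feature
# and one feature that is informative only inside cohort c1 (leakage probe)
leakage_fixture <- function() {
  cached_fixture("leakage", {
    withr::local_seed(13)
    n_per <- 20
    cohorts <- rep(c("c1", "c2", "c3"), each = n_per)
    y <- factor(rep(rep(c("low", "high"), each = n_per / 2), 3),
                levels = c("low", "high"))
    x <- matrix(rnorm(3 * n_per * 4), 3 * n_per, 4,
                dimnames = list(NULL, c("signal", "plant_c1", "noise1", "noise2")))
    x[, "signal"] <- ifelse(y == "high", 2, -2) + rnorm(3 * n_per, 0, 0.5)
    x[, "plant_c1"] <- 0
    x[cohorts == "c1", "plant_c1"] <- ifelse(y[cohorts == "c1"] == "high", 5, -5)
    ids <- sprintf("p%02d", seq_len(3 * n_per))
    list(
      features = tibble::tibble(participant_id = ids, tibble::as_tibble(x)),
      labels = structure(tibble::tibble(participant_id = ids, class = y),
                         class = c("label_set", "tbl_df", "tbl", "data.frame")),
      cohorts = tibble::tibble(participant_id = ids, cohort = cohorts),
      spec = model_spec("svm_rbf", cost = 1, gamma = c(0.1, 1), seed = 3)
    )
  })
}

# random minute-state vector with optional missingness
random_states <- function(n_days, p_missing = 0) {
  s <- sample(c(-1, 1), n_days * 1440, replace = TRUE)
  if (p_missing > 0) s[runif(length(s)) < p_missing] <- NA
  s
}
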