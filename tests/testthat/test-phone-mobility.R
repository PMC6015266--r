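empty_sms <- function() {
  tibble::tibble(participant_id = character(), ts = numeric(),
                 contact_hash = character(), direction = character())
}
empty_screen <- function() {
  tibble::tibble(participant_id = character(), ts = numeric(),
                 state = character())
}

test_that("call day features match closed-form arithmetic", {
  calls <- tibble::tibble(
    participant_id = "p1",
    ts = c(10 * 3600, 14 * 3600,                 # day 1: 10:00 and 14:00
           86400 + 11 * 3600),                   # day 2: one call
    duration_s = c(60, 180, 100),
    contact_hash = c("a", "b", "a"),
    direction = "out"
  )
  pf <- phone_event_features(calls, empty_sms(), empty_screen())
  # day 1 has total 240 s over 2 calls at mean clock 12:00 = 720 min
  expect_equal(pf$call_total_dur_fullday_mean, (240 + 100) / 2)
  expect_equal(pf$call_n_fullday_mean, 1.5)
  expect_equal(pf$call_time_mean_fullday_median, (720 + 660) / 2)
  # late-night window has no events at all: missing, not zero
  expect_true(is.na(pf$call_n_latenight_mean))
})

test_that("event features equal a naive per-day loop oracle on random logs", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    calls <- tibble::tibble(
      participant_id = sample(c("a", "b"), n, replace = TRUE),
      ts = runif(n, 0, 3 * 86400),
      duration_s = round(rexp(n, 1 / 120), 1),
      contact_hash = sample(c("x", "y", "z"), n, replace = TRUE),
      direction = "in"
    )
    pf <- phone_event_features(calls, empty_sms(), empty_screen())
    for (w in list(c("fullday", 0, 86400), c("night", 64800, 86400))) {
      oracle <- call_day_oracle(calls, as.numeric(w[2]), as.numeric(w[3]))
      for (pid in unique(calls$participant_id)) {
        po <- oracle[oracle$participant_id == pid, ]
        for (f in c("total_dur", "n", "n_contacts", "time_mean", "dur_sd")) {
          expected <- if (is.null(po) || nrow(po) < 2) NA_real_ else mean(po[[f]])
          got <- pf[[paste0("call_", f, "_", w[1], "_mean")]][pf$participant_id == pid]
          expect_equal(got, expected, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("SMS sessions and screen bouts follow the documented conventions", {
  sms <- tibble::tibble(
    participant_id = "p1",
    ts = c(100, 200, 300, 5000, 5100, 40000),
    contact_hash = c("a", "a", "a", "a", "b", "b"),
    direction = "in"
  )
  sess <- wearstress:::sms_sessions(sms)
  expect_identical(nrow(sess), 4L)      # gap and contact change both split
  expect_equal(sort(sess$duration_s), c(0, 0, 0, 200))

  screen <- tibble::tibble(
    participant_id = "p1",
    ts = c(1000, 1300, 85000),          # trailing "on" never turned off
    state = c("on", "off", "on")
  )
  bouts <- wearstress:::screen_bouts(screen)
  expect_equal(bouts$duration_s, c(300, 86400 - 85000))

  empty_calls <- tibble::tibble(participant_id = character(), ts = numeric(),
                                duration_s = numeric(), contact_hash = character(),
                                direction = character())
  # two identical days: across-day aggregates need at least 2 contributing days
  next_day <- function(tbl) dplyr::bind_rows(tbl, dplyr::mutate(tbl, ts = ts + 86400))
  pf <- phone_event_features(empty_calls, next_day(sms), next_day(screen))
  expect_equal(pf$sms_n_fullday_mean, 6)
  expect_equal(pf$sms_n_fullday_sd, 0)
  expect_equal(pf$screen_n_fullday_mean, 2)
})

test_that("the phone block has exactly 237 stably named columns", {
  b <- cached_fixture("phone_small", cheap_bundle(n = 6, seed = 17))
  pf <- phone_features(b)
  expect_identical(ncol(pf) - 1L, 237L)
  expect_identical(nrow(feature_meta(pf)), 237L)
  expect_false(anyDuplicated(names(pf)) > 0)
  expect_identical(names(phone_features(b)), names(pf))
})

test_that("daily mobility summaries match plane geometry", {
  still <- tibble::tibble(ts = seq(0, 3600, by = 600), x_m = 10, y_m = -5)
  dm <- daily_mobility(still)
  expect_equal(unlist(dm[c("total_dist_m", "dist_5min_m", "radius_m")]),
               c(total_dist_m = 0, dist_5min_m = 0, radius_m = 0))

  two <- tibble::tibble(ts = c(0, 1800), x_m = c(0, 300), y_m = c(0, 0))
  dm2 <- daily_mobility(two)
  expect_equal(dm2$total_dist_m, 300)
  expect_equal(dm2$radius_m, 150)

  sq <- tibble::tibble(ts = seq(0, 2400, by = 600),
                       x_m = c(0, 100, 100, 0, 0),
                       y_m = c(0, 0, 100, 100, 0))
  expect_equal(daily_mobility(sq)$total_dist_m, 400)

  one <- tibble::tibble(ts = 100, x_m = 0, y_m = 0)
  expect_true(all(is.na(daily_mobility(one)[-1])))
})

test_that("the mobility mixture model is deterministic and routine-sensitive", {
  withr::local_seed(3)
  anchors <- matrix(c(0, 0, 800, 0), 2, byrow = TRUE)
  pick <- sample(1:2, 300, replace = TRUE)
  tr <- tibble::tibble(ts = seq_len(300) * 600,
                       x_m = anchors[pick, 1] + rnorm(300, 0, 30),
                       y_m = anchors[pick, 2] + rnorm(300, 0, 30))
  m1 <- fit_mobility_gmm(tr)
  m2 <- fit_mobility_gmm(tr)
  expect_identical(m1$K, m2$K)
  expect_equal(daily_loglik(m1, tr), daily_loglik(m2, tr))

  day_same <- tr[1:50, ]
  day_far <- dplyr::mutate(day_same, x_m = x_m + 10000)
  expect_gt(daily_loglik(m1, day_same), daily_loglik(m1, day_far))

  # K = 1 equals the closed-form multivariate normal mean log density
  m3 <- fit_mobility_gmm(tr[1:25, ], max_k = 1)
  X <- cbind(tr$x_m[1:25], tr$y_m[1:25])
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)
  q <- rowSums((sweep(X, 2, mu) %*% solve(S)) * sweep(X, 2, mu))
  closed <- mean(-log(2 * pi) - 0.5 * log(det(S)) - 0.5 * q)
  expect_equal(daily_loglik(m3, tr[1:25, ]), closed, tolerance = 1e-6)

  # translation: distances invariant, log likelihood equivariant with the model
  sh <- dplyr::mutate(tr, x_m = x_m + 5000, y_m = y_m - 2000)
  expect_equal(daily_mobility(sh)[-1], daily_mobility(tr)[-1], tolerance = 1e-9)
  m_sh <- fit_mobility_gmm(sh)
  expect_equal(daily_loglik(m_sh, sh[1:50, ]), daily_loglik(m1, tr[1:50, ]),
               tolerance = 1e-6)
})
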