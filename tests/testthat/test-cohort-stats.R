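mk_labels <- function(ids_low, ids_high) {
  structure(
    tibble::tibble(
      participant_id = c(ids_low, ids_high),
      class = factor(rep(c("low", "high"), c(length(ids_low), length(ids_high))),
                     levels = c("low", "high"))
    ),
    class = c("label_set", "tbl_df", "tbl", "data.frame")
  )
}

test_that("identical group distributions give t = 0, p = 1; constants are skipped", {
  ids <- sprintf("p%02d", 1:10)
  f <- tibble::tibble(participant_id = ids,
                      same = rep(c(1, 2, 3, 4, 5), 2),
                      const = 7)
  gt <- group_feature_tests(f, mk_labels(ids[1:5], ids[6:10]))
  same <- gt[gt$feature == "same", ]
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_true(gt$skipped[gt$feature == "const"])
  expect_true(is.na(gt$q[gt$feature == "const"]))
})

test_that("q-values equal the Benjamini-Hochberg step-up oracle and are monotone", {
  withr::local_seed(21)
  ids <- sprintf("p%02d", 1:30)
  for (rep in 1:10) {
    f <- tibble::tibble(participant_id = ids)
    for (j in 1:12) f[[paste0("f", j)]] <- rnorm(30) + (j <= 2) * (j) *
        rep(c(0, 1), each = 15)
    gt <- group_feature_tests(f, mk_labels(ids[1:15], ids[16:30]))
    expect_equal(gt$q, bh_oracle(gt$p), tolerance = 1e-12)
    o <- order(gt$p)
    expect_true(all(diff(gt$q[o]) > -1e-12))
  }
  # degenerate spectrum: equal p-values map to the common value
  expect_equal(p.adjust(rep(0.2, 7), "BH"), rep(0.2, 7))
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("normality screening routes features to t or Mann-Whitney", {
  withr::local_seed(33)
  ids <- sprintf("p%02d", 1:40)
  f <- tibble::tibble(
    participant_id = ids,
    gauss = rnorm(40),
    heavy = rexp(40)^3
  )
  gt <- group_feature_tests(f, mk_labels(ids[1:20], ids[21:40]))
  expect_identical(gt$test[gt$feature == "gauss"], "t")
  expect_identical(gt$test[gt$feature == "heavy"], "mann_whitney")
})

test_that("paired pre/post comparisons behave at their boundary cases", {
  x <- c(10, 12, 14, 9, 11, 13, 15, 8, 10, 12)
  same <- paired_prepost(x, x, "paired_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  withr::local_seed(2)
  shifted <- paired_prepost(x, x + 1 + rnorm(10, 0, 1e-3), "paired_t")
  expect_lt(shifted$p, 0.001)

  w <- paired_prepost(x, x, "wilcoxon")
  expect_true(w$degenerate)
  expect_true(is.na(w$p))
  expect_false(paired_prepost(x, x + c(rep(0, 9), 2), "wilcoxon")$degenerate)

  expect_error(paired_prepost(1:3, 1:4), class = "wearstress_param_error")
})

test_that("pearson_corr is the plain product-moment correlation", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_equal(pearson_corr(c(x, NA), c(-x, 2)), -1)   # complete cases only
  expect_error(pearson_corr(c(1, 2), c(2, 1)), class = "wearstress_param_error")
})

test_that("null generator cohorts produce no false family discoveries", {
  # zero latent effects: the five family summaries must not separate the
  # eventual high/low stress groups beyond the nominal FDR level
  n_seeds <- 20
  n_disc <- 0
  n_feat <- 0
  fam_reject <- integer(0)
  for (seed in seq_len(n_seeds)) {
    b <- generate_cohort(cohort_config(40, 3, days = 2, sc_sample_rate = 1,
                                       seed = 400 + seed))
    peak_rate <- vapply(b$streams, function(s) {
      pk <- detect_sc_peaks(fir_lowpass(s$sc_uS, 1), 1)
      clock <- pk$time %% 86400
      sum(clock >= 9 * 3600 & clock < 18 * 3600) / (2 * 540)
    }, 0)
    fam <- b$diary |>
      dplyr::group_by(participant_id) |>
      dplyr::summarise(nap_rate = mean(n_naps), .groups = "drop") |>
      dplyr::left_join(
        b$screen |>
          dplyr::filter(state == "on") |>
          dplyr::count(participant_id, name = "screen_on"),
        by = "participant_id") |>
      dplyr::left_join(
        b$locations |>
          dplyr::group_by(participant_id) |>
          dplyr::summarise(radius = max(sqrt((x_m - mean(x_m))^2 +
                                               (y_m - mean(y_m))^2)),
                           .groups = "drop"),
        by = "participant_id") |>
      dplyr::left_join(
        b$sleep |>
          dplyr::group_by(participant_id) |>
          dplyr::summarise(bed_sd = sd(bed_min %% 1440, na.rm = TRUE),
                           .groups = "drop"),
        by = "participant_id")
    fam$sc_peak_rate <- peak_rate[fam$participant_id]
    gt <- group_feature_tests(fam, label_pss(b$participants, seed = seed))
    tested <- gt[!gt$skipped, ]
    n_disc <- n_disc + sum(tested$q < 0.05, na.rm = TRUE)
    n_feat <- n_feat + sum(!is.na(tested$q))
    hits <- tested$feature[!is.na(tested$q) & tested$q < 0.05]
    for (h in hits) {
      fam_reject[h] <- (if (h %in% names(fam_reject)) fam_reject[[h]] else 0L) + 1L
    }
  }
  # type-I control: pooled discovery fraction within 3 SE of the nominal level
  expect_lte(n_disc / n_feat, 0.05 + 3 * sqrt(0.05 * 0.95 / n_feat))
  # and no single family rejects more often than binomial noise allows
  if (length(fam_reject)) {
    expect_lte(max(fam_reject), qbinom(0.999, n_seeds, 0.05) + 1L)
  }
})
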