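mk_xy <- function(n = 40, p = 6, shift_col = NULL, shift = 0, seed = 1) {
  withr::local_seed(seed)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  if (!is.null(shift_col)) x[y == "high", shift_col] <- x[y == "high", shift_col] + shift
  list(x = x, y = y)
}

test_that("the t-test prefilter ranks by p and keeps min(k, p) features", {
  d <- mk_xy(p = 6, shift_col = 3, shift = 3, seed = 2)
  pf <- ttest_prefilter(d$x, d$y)
  expect_identical(nrow(pf), 6L)             # k defaults to 100 > p
  expect_identical(pf$feature[1], "f3")      # 3-SD shift ranks first
  expect_identical(eval(formals(ttest_prefilter)$k), 100L)

  # agrees with stats::t.test feature by feature
  for (j in 1:6) {
    tt <- t.test(d$x[d$y == "high", j], d$x[d$y == "low", j])
    row <- pf[pf$feature == paste0("f", j), ]
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
    expect_equal(abs(row$statistic), abs(unname(tt$statistic)), tolerance = 1e-12)
  }
  pf2 <- ttest_prefilter(d$x, d$y, k = 2)
  expect_identical(pf2$feature[1:2], pf$feature[1:2])
  expect_error(ttest_prefilter(d$x, factor(rep("a", 40))),
               class = "wearstress_protocol_error")
})

test_that("forward selection finds a single separating feature and obeys the budget", {
  d <- mk_xy(n = 40, p = 5, shift_col = 2, shift = 8, seed = 3)
  spec <- model_spec("svm_rbf", cost = c(1, 10), gamma = c(0.01, 0.1, 1), seed = 9)
  sel <- sfs_select(d$x, d$y, spec)
  expect_identical(sel$features, "f2")       # perfect separator, ties prefer fewer

  d2 <- mk_xy(n = 30, p = 8, seed = 4)       # pure noise
  sel2 <- sfs_select(d2$x, d2$y, spec)
  expect_lte(length(sel2$features), 5L)
  expect_true(all(sel2$features %in% colnames(d2$x)))
})

test_that("F1 follows its closed form with the degenerate-zero rule", {
  y <- factor(c("high", "high", "low", "low"), levels = c("low", "high"))
  expect_equal(f1_score(y, y), 1)
  # precision 0.5, recall 1 -> 2/3
  pred <- factor(c("high", "high", "high", "high"), levels = c("low", "high"))
  truth <- factor(c("high", "high", "low", "low"), levels = c("low", "high"))
  expect_equal(f1_score(pred, truth), 2 / 3)
  all_neg <- factor(rep("low", 4), levels = c("low", "high"))
  expect_equal(f1_score(all_neg, truth), 0)
  expect_error(f1_score(all_neg, all_neg), class = "wearstress_param_error")
})

test_that("the adjusted-Wald interval matches its closed form and the printed estimate", {
  ci <- adjusted_wald_ci(148, 189)
  expect_equal(round(100 * ci$estimate, 1), 78.3)
  oracle <- wald_oracle(148, 189)
  expect_equal(c(ci$lower, ci$upper), oracle, tolerance = 1e-12)

  expect_equal(adjusted_wald_ci(10, 10)$upper, 1)
  expect_equal(adjusted_wald_ci(0, 10)$lower, 0)
  withr::local_seed(5)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    ci <- adjusted_wald_ci(x, n)
    expect_equal(c(ci$lower, ci$upper), wald_oracle(x, n), tolerance = 1e-12)
  }
  expect_error(adjusted_wald_ci(11, 10), class = "wearstress_param_error")
})

test_that("selection frequencies are per-model percentages", {
  sel <- c(rep(list(c("a", "b")), 9), list("b"))
  sf <- selection_frequency(sel)
  expect_equal(sf$pct[sf$feature == "a"], 90)
  expect_equal(sf$pct[sf$feature == "b"], 100)
  expect_false("c" %in% sf$feature)
  expect_true(all(sf$pct <= 100) && all(sf$n_models == 10))
})

test_that("held-out cohorts cannot leak into prefilter or selection", {
  fx <- leakage_fixture()
  ev <- loco_cv(fx$features, fx$labels, fx$cohorts, fx$spec)
  f_c1 <- ev$folds[["c1"]]
  # the planted feature is constant on c1's training cohorts: untestable there
  expect_false("plant_c1" %in% f_c1$prefilter)
  expect_false("plant_c1" %in% f_c1$selected)
  for (f in ev$folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), fx$features$participant_id)
  }
})

test_that("concatenated accuracy equals the fold-size weighted mean", {
  fx <- leakage_fixture()
  ev <- loco_cv(fx$features, fx$labels, fx$cohorts, fx$spec)
  td <- tidy(ev)
  expect_identical(nrow(td), 3L)
  expect_equal(ev$accuracy, sum(td$accuracy * td$n_test) / sum(td$n_test))
  expect_identical(ev$n, nrow(fx$features))  # every participant predicted once
  expect_identical(anyDuplicated(ev$predictions$participant_id), 0L)
  gl <- glance(ev)
  expect_true(gl$accuracy >= 0 && gl$accuracy <= 1 && gl$f1 >= 0 && gl$f1 <= 1)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, type = "accuracy"), "ggplot")
})

test_that("every model family runs the protocol end to end", {
  fx <- leakage_fixture()
  for (fam in c("svm_linear", "lasso")) {
    spec <- model_spec(fam, cost = c(0.1, 1), gamma = 0.1, seed = 4)
    ev <- loco_cv(fx$features, fx$labels, fx$cohorts, spec)
    expect_identical(ev$n, 60L)
    expect_gt(ev$accuracy, 0.8)              # the "signal" column is easy
  }
  expect_error(
    loco_cv(fx$features, fx$labels,
            dplyr::mutate(fx$cohorts, cohort = dplyr::if_else(
              participant_id == "p01", NA_character_, cohort)),
            fx$spec),
    class = "wearstress_validation_error"
  )
})
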