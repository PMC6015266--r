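#' Group-difference tests per feature with FDR correction
#'
#' For each feature, screens each group for normality (Shapiro-Wilk at
#' `normality_alpha`); if both groups pass, a Welch two-sample t-test is used,
#' otherwise a Mann-Whitney U test. P-values are adjusted across all tested
#' features with the Benjamini-Hochberg false discovery rate (q-values).
#' Features with zero variance in both groups are skipped and flagged.
#'
#' @param features Feature block tibble (`participant_id` + numeric columns).
#' @param labels A `label_set` (or tibble with `participant_id`, `class`).
#' @param normality_alpha Significance level of the normality screen.
#' @return Tibble with one row per feature: `feature`, `test`, `statistic`,
#'   `p`, `q`, group means/medians, `direction` and `skipped`.
#' @export
group_feature_tests <- function(features, labels, normality_alpha = 0.05) {
  lab <- tibble::as_tibble(labels)[c("participant_id", "class")]
  d <- dplyr::inner_join(lab, features, by = "participant_id")
  if (!all(c("low", "high") %in% d$class)) {
    abort_ws("both groups must be nonempty", "param_error")
  }
  cols <- setdiff(names(d), c("participant_id", "class"))
  is_normalish <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    shapiro.test(v)$p.value > normality_alpha
  }
  rows <- purrr::map_dfr(cols, function(cn) {
    hi <- d[[cn]][d$class == "high"]
    lo <- d[[cn]][d$class == "low"]
    hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
    base <- tibble::tibble(
      feature = cn, test = NA_character_, statistic = NA_real_, p = NA_real_,
      mean_high = mean(hi), mean_low = mean(lo),
      median_high = median(hi), median_low = median(lo),
      direction = sign(mean(hi) - mean(lo)), skipped = TRUE
    )
    if (length(hi) < 2 || length(lo) < 2) return(base)
    if (sd(hi) == 0 && sd(lo) == 0) return(base)
    if (is_normalish(hi) && is_normalish(lo)) {
      tt <- t.test(hi, lo)
      base$test <- "t"; base$statistic <- unname(tt$statistic); base$p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(hi, lo, exact = FALSE))
      base$test <- "mann_whitney"; base$statistic <- unname(wt$statistic)
      base$p <- wt$p.value
    }
    base$skipped <- FALSE
    base
  })
  rows$q <- NA_real_
  tested <- !rows$skipped
  rows$q[tested] <- p.adjust(rows$p[tested], method = "BH")
  dplyr::relocate(rows, "q", .after = "p")
}

#' Paired pre/post comparison
#'
#' Paired t-test or Wilcoxon signed-rank test of post- versus pre-study
#' scores; pairs with a missing value are dropped. When all differences are
#' zero the Wilcoxon statistic is degenerate and flagged rather than computed.
#'
#' @param pre,post Equal-length paired score vectors.
#' @param test `"paired_t"` or `"wilcoxon"`.
#' @return Tibble with `test`, `statistic`, `p`, `n`, `degenerate`.
#' @export
paired_prepost <- function(pre, post, test = c("paired_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(pre) != length(post)) {
    abort_ws("`pre` and `post` must have equal length", "param_error")
  }
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 2) abort_ws("need at least 2 complete pairs", "param_error")
  diffs <- post - pre
  if (all(diffs == 0)) {
    # no change in any pair: the paired t statistic is 0 by convention, the
    # signed-rank statistic is undefined and flagged
    if (test == "paired_t") {
      return(tibble::tibble(test = test, statistic = 0, p = 1,
                            n = length(pre), degenerate = FALSE))
    }
    return(tibble::tibble(test = test, statistic = NA_real_, p = NA_real_,
                          n = length(pre), degenerate = TRUE))
  }
  res <- if (test == "paired_t") {
    t.test(post, pre, paired = TRUE)
  } else {
    suppressWarnings(wilcox.test(post, pre, paired = TRUE, exact = FALSE))
  }
  tibble::tibble(test = test, statistic = unname(res$statistic),
                 p = res$p.value, n = length(pre), degenerate = FALSE)
}

#' Pearson correlation on complete pairs
#'
#' @param x,y Numeric vectors; at least 3 complete pairs required.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) abort_ws("need at least 3 complete pairs", "param_error")
  cor(x[ok], y[ok])
}
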