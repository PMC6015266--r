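#' Classification protocol specification
#'
#' Bundles the knobs of the nested evaluation protocol: model family,
#' hyperparameter grids, t-test prefilter size, sequential-forward-selection
#' budget, inner CV folds and the run seed.
#'
#' @param family `"svm_rbf"`, `"svm_linear"` or `"lasso"`.
#' @param cost SVM cost grid.
#' @param gamma SVM RBF kernel width grid.
#' @param nlambda Number of log-spaced LASSO penalties.
#' @param prefilter_k Number of lowest-p features kept by the t-test prefilter.
#' @param max_features Sequential forward selection budget (best up to this
#'   many features).
#' @param inner_folds Inner stratified CV folds.
#' @param seed Run seed; all fold assignments derive from it.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("svm_rbf", "svm_linear", "lasso"),
                       cost = c(0.1, 1, 10, 100),
                       gamma = c(0.001, 0.01, 0.1, 1, 10),
                       nlambda = 50L,
                       prefilter_k = 100L,
                       max_features = 5L,
                       inner_folds = 10L,
                       seed = 1L) {
  family <- match.arg(family)
  if (!length(cost) || !length(gamma)) abort_ws("empty hyperparameter grid", "param_error")
  check_number(prefilter_k, "prefilter_k", min = 1, integer = TRUE)
  check_number(max_features, "max_features", min = 1, integer = TRUE)
  check_number(inner_folds, "inner_folds", min = 2, integer = TRUE)
  structure(list(family = family, cost = cost, gamma = gamma,
                 nlambda = as.integer(nlambda),
                 prefilter_k = as.integer(prefilter_k),
                 max_features = as.integer(max_features),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Two-sample t-test feature prefilter
#'
#' Computes a Welch two-sample t-test per feature on the training data
#' (missing values dropped pairwise) and returns the `min(k, p)` features with
#' the smallest p-values, in ascending-p order. Features that cannot be tested
#' (fewer than 2 observations in a class, or zero variance in both classes
#' with equal means) are ranked last and only returned if fewer than `k`
#' testable features exist.
#'
#' @param x Numeric matrix or data frame of training features.
#' @param y Two-level factor of training labels.
#' @param k Number of features to keep (default 100).
#' @return Tibble with `feature`, `statistic`, `p`, `rank`.
#' @export
ttest_prefilter <- function(x, y, k = 100L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) abort_ws("protocol error: need exactly 2 classes", "protocol_error")
  if (min(table(y)) < 2) {
    abort_ws("protocol error: need >= 2 training samples per class", "protocol_error")
  }
  stats_for <- function(g) {
    xg <- x[y == g, , drop = FALSE]
    n <- colSums(!is.na(xg))
    m <- colMeans(xg, na.rm = TRUE)
    v <- colSums(sweep(xg, 2, m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, m = m, v = v)
  }
  g1 <- stats_for(levels(y)[1])
  g2 <- stats_for(levels(y)[2])
  se2 <- g1$v / g1$n + g2$v / g2$n
  tstat <- (g2$m - g1$m) / sqrt(se2)
  df <- se2^2 / (g1$v^2 / (g1$n^2 * pmax(g1$n - 1, 1)) +
                   g2$v^2 / (g2$n^2 * pmax(g2$n - 1, 1)))
  p <- 2 * pt(-abs(tstat), df)
  p[g1$n < 2 | g2$n < 2 | !is.finite(tstat)] <- NA_real_
  ord <- order(p, na.last = NA)              # untestable features are dropped
  if (!length(ord)) abort_ws("protocol error: no testable feature", "protocol_error")
  keep <- ord[seq_len(min(k, length(ord)))]
  tibble::tibble(feature = colnames(x)[keep], statistic = unname(tstat[keep]),
                 p = unname(p[keep]), rank = seq_along(keep))
}

stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  if (min(counts) < 2) {
    abort_ws("stratification error: a class has fewer than 2 samples", "protocol_error")
  }
  k <- min(k, min(counts))
  withr::local_seed(seed)
  fold <- integer(length(y))
  for (g in levels(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

svm_cv_accuracy <- function(x, y, folds, kernel, cost, gamma = 0.1) {
  correct <- 0
  total <- 0
  for (te in folds) {
    fit <- e1071::svm(x = x[-te, , drop = FALSE], y = y[-te], kernel = kernel,
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- predict(fit, x[te, , drop = FALSE])
    correct <- correct + sum(pred == y[te])
    total <- total + length(te)
  }
  correct / total
}

#' Sequential forward feature selection under inner SVM-RBF cross-validation
#'
#' Greedy forward selection: at each step the candidate feature maximizing the
#' inner stratified k-fold CV accuracy of an SVM with RBF kernel, jointly
#' grid-searched over (cost, gamma), is added, up to `max_features`. The
#' returned set is the prefix with the best inner-CV accuracy; ties prefer
#' fewer features, then the lower prefilter rank (column order of `x`).
#'
#' @param x Numeric matrix of training features (no missing values), columns
#'   in prefilter-rank order.
#' @param y Two-level factor of training labels.
#' @param spec A [model_spec()].
#' @return List with `features`, `cost`, `gamma`, `inner_accuracy` and the
#'   step `path` tibble.
#' @export
sfs_select <- function(x, y, spec = model_spec()) {
  x <- as.matrix(x)
  y <- factor(y)
  folds <- stratified_folds(y, spec$inner_folds, spec$seed)
  grid <- expand.grid(cost = spec$cost, gamma = spec$gamma)
  p <- ncol(x)
  selected <- integer(0)
  remaining <- seq_len(p)
  step_acc <- numeric(0)
  step_cost <- numeric(0)
  step_gamma <- numeric(0)

  for (step in seq_len(min(spec$max_features, p))) {
    best_acc <- -Inf
    best_j <- NA_integer_
    best_cg <- c(NA_real_, NA_real_)
    for (j in remaining) {
      xs <- x[, c(selected, j), drop = FALSE]
      acc_j <- -Inf
      cg_j <- c(NA_real_, NA_real_)
      for (g in seq_len(nrow(grid))) {
        acc <- svm_cv_accuracy(xs, y, folds, "radial", grid$cost[g], grid$gamma[g])
        if (acc > acc_j + 1e-12) {
          acc_j <- acc
          cg_j <- c(grid$cost[g], grid$gamma[g])
        }
      }
      if (acc_j > best_acc + 1e-12) {
        best_acc <- acc_j
        best_j <- j
        best_cg <- cg_j
      }
    }
    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
    step_acc <- c(step_acc, best_acc)
    step_cost <- c(step_cost, best_cg[1])
    step_gamma <- c(step_gamma, best_cg[2])
  }
  m <- which.max(step_acc)           # first max: ties prefer fewer features
  list(
    features = colnames(x)[selected[seq_len(m)]],
    cost = step_cost[m],
    gamma = step_gamma[m],
    inner_accuracy = step_acc[m],
    path = tibble::tibble(step = seq_along(step_acc),
                          feature = colnames(x)[selected],
                          inner_accuracy = step_acc,
                          cost = step_cost, gamma = step_gamma)
  )
}

fit_transform <- function(xtr) {
  med <- apply(xtr, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(xtr))) xtr[is.na(xtr[, j]), j] <- med[j]
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, sd)
  sdev[!is.finite(sdev) | sdev <= 0] <- 1
  list(
    apply = function(x) {
      for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
      sweep(sweep(x, 2, mu), 2, sdev, "/")
    },
    train = sweep(sweep(xtr, 2, mu), 2, sdev, "/")
  )
}

#' Nested leave-one-cohort-out evaluation
#'
#' For each enrollment cohort: hold it out, and on the remaining cohorts only,
#' impute (training-fold medians) and standardize (training-fold mean/SD), run
#' the t-test prefilter and -- for SVM families -- sequential forward
#' selection with inner stratified 10-fold CV (the selection model is always
#' SVM-RBF; the final model's own hyperparameters are tuned on the same inner
#' folds), or -- for LASSO -- 10-fold CV choice of the penalty on the full
#' feature set; then fit on all training cohorts and predict the held-out
#' cohort. Out-of-fold predictions are concatenated before computing accuracy
#' (with adjusted-Wald 95% CI), F1 (positive class = "high"), and the
#' selection-frequency table.
#'
#' @param features A feature block tibble (`participant_id` + feature
#'   columns).
#' @param labels A `label_set` from [label_pss()] / [label_mcs()].
#' @param cohorts Tibble with `participant_id` and `cohort` (a participants
#'   table works).
#' @param spec A [model_spec()].
#' @return A `loco_eval` object; see [tidy()], [glance()], [autoplot()].
#' @export
loco_cv <- function(features, labels, cohorts, spec = model_spec()) {
  lab <- tibble::as_tibble(labels)[c("participant_id", "class")]
  co <- tibble::as_tibble(cohorts)[c("participant_id", "cohort")]
  d <- dplyr::left_join(lab, co, by = "participant_id")
  if (anyNA(d$cohort)) {
    abort_ws("validation error: cohort label missing for labeled participants",
             "validation_error")
  }
  d <- dplyr::inner_join(d, features, by = "participant_id")
  if (nrow(d) < nrow(lab)) {
    rlang::warn(sprintf("%d labeled participants missing from the feature matrix",
                        nrow(lab) - nrow(d)))
  }
  if (length(unique(d$cohort)) < 2) {
    abort_ws("need at least 2 cohorts", "param_error")
  }
  feat_cols <- setdiff(names(d), c("participant_id", "class", "cohort"))
  X <- as.matrix(d[feat_cols])
  y <- factor(d$class, levels = c("low", "high"))

  fold_list <- list()
  preds <- list()
  cohort_ids <- sort(unique(d$cohort))
  for (fi in seq_along(cohort_ids)) {
    ch <- cohort_ids[fi]
    te <- which(d$cohort == ch)
    tr <- which(d$cohort != ch)
    if (length(te) == 0 || nlevels(droplevels(y[tr])) < 2) {
      rlang::warn(sprintf("skipping fold %s: missing class in training data", ch))
      next
    }
    fold_seed <- derive_seed(spec$seed, fi)
    tf <- fit_transform(X[tr, , drop = FALSE])
    xtr <- tf$train
    xte <- tf$apply(X[te, , drop = FALSE])
    pf <- ttest_prefilter(X[tr, , drop = FALSE], y[tr], spec$prefilter_k)

    if (spec$family %in% c("svm_rbf", "svm_linear")) {
      fspec <- spec
      fspec$seed <- fold_seed
      sel <- sfs_select(xtr[, pf$feature, drop = FALSE], y[tr], fspec)
      xs <- xtr[, sel$features, drop = FALSE]
      if (spec$family == "svm_rbf") {
        fit <- e1071::svm(x = xs, y = y[tr], kernel = "radial",
                          cost = sel$cost, gamma = sel$gamma, scale = FALSE)
        hyper <- c(cost = sel$cost, gamma = sel$gamma)
      } else {
        folds <- stratified_folds(y[tr], spec$inner_folds, fold_seed)
        accs <- vapply(spec$cost, function(cc) {
          svm_cv_accuracy(xs, y[tr], folds, "linear", cc)
        }, 0)
        cc <- spec$cost[which.max(accs)]
        fit <- e1071::svm(x = xs, y = y[tr], kernel = "linear", cost = cc,
                          scale = FALSE)
        hyper <- c(cost = cc)
      }
      pred <- predict(fit, xte[, sel$features, drop = FALSE])
      selected <- sel$features
    } else {
      withr::local_seed(fold_seed)
      foldid <- integer(length(tr))
      for (g in levels(y)) {
        idx <- sample(which(y[tr] == g))
        foldid[idx] <- rep_len(seq_len(min(spec$inner_folds, length(idx))),
                               length(idx))
      }
      cvfit <- glmnet::cv.glmnet(xtr, y[tr], family = "binomial",
                                 foldid = foldid, nlambda = spec$nlambda)
      pred <- factor(drop(predict(cvfit, xte, s = "lambda.min", type = "class")),
                     levels = levels(y))
      cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
      selected <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
      hyper <- c(lambda = cvfit$lambda.min)
    }

    preds[[ch]] <- tibble::tibble(
      participant_id = d$participant_id[te], cohort = ch,
      truth = y[te], pred = factor(as.character(pred), levels = levels(y))
    )
    fold_list[[ch]] <- list(cohort = ch, train_ids = d$participant_id[tr],
                            test_ids = d$participant_id[te],
                            selected = selected, hyper = hyper,
                            prefilter = pf$feature)
  }
  if (!length(preds)) abort_ws("no evaluable fold", "protocol_error")
  pr <- dplyr::bind_rows(preds)
  acc <- mean(pr$pred == pr$truth)
  ci <- adjusted_wald_ci(sum(pr$pred == pr$truth), nrow(pr))
  structure(
    list(
      predictions = pr,
      folds = fold_list,
      accuracy = acc,
      ci = ci,
      f1 = f1_score(pr$pred, pr$truth),
      selection = selection_frequency(lapply(fold_list, `[[`, "selected")),
      spec = spec,
      n = nrow(pr)
    ),
    class = "loco_eval"
  )
}

#' F1 score for the high-class detection problem
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, with the "high" group
#' as the positive class; defined as 0 when precision + recall is 0.
#'
#' @param pred,truth Factors or vectors of class labels.
#' @param positive Positive class label (default `"high"`).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(pred, truth, positive = "high") {
  pred_pos <- pred == positive
  true_pos <- truth == positive
  if (!any(true_pos) && !any(pred_pos)) {
    abort_ws("need at least one positive truth or prediction", "param_error")
  }
  tp <- sum(pred_pos & true_pos)
  if (tp == 0) return(0)
  precision <- tp / sum(pred_pos)
  recall <- tp / sum(true_pos)
  2 * precision * recall / (precision + recall)
}

#' Adjusted-Wald (Agresti-Coull) binomial confidence interval
#'
#' `p~ = (x + z^2/2) / (n + z^2)`, half-width `z * sqrt(p~ (1 - p~) / (n +
#' z^2))`, clipped to `[0, 1]`.
#'
#' @param successes Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lower`, `upper`.
#' @export
adjusted_wald_ci <- function(successes, n, level = 0.95) {
  check_number(n, "n", min = 1, integer = TRUE)
  check_number(successes, "successes", min = 0, max = n)
  check_number(level, "level", min = 1e-6, max = 1 - 1e-6)
  z <- qnorm(1 - (1 - level) / 2)
  pt_ <- (successes + z^2 / 2) / (n + z^2)
  hw <- z * sqrt(pt_ * (1 - pt_) / (n + z^2))
  tibble::tibble(estimate = successes / n,
                 lower = max(0, pt_ - hw),
                 upper = min(1, pt_ + hw))
}

#' Feature selection frequency across fitted models
#'
#' @param selected List of character vectors, one per fitted model, of the
#'   features it selected.
#' @return Tibble with `feature`, `n_selected`, `n_models`, `pct`, sorted by
#'   descending percentage.
#' @export
selection_frequency <- function(selected) {
  n_models <- length(selected)
  if (n_models < 1) abort_ws("need at least one completed model", "param_error")
  tab <- table(unlist(selected))
  tibble::tibble(
    feature = names(tab),
    n_selected = as.integer(tab),
    n_models = n_models,
    pct = 100 * as.integer(tab) / n_models
  ) |>
    dplyr::arrange(dplyr::desc(.data$pct), .data$feature)
}

#' @export
print.loco_eval <- function(x, ...) {
  cat(sprintf("Leave-one-cohort-out evaluation (%s): %d predictions over %d folds\n",
              x$spec$family, x$n, length(x$folds)))
  cat(sprintf("  accuracy %.3f [%.3f, %.3f], F1 %.3f\n",
              x$accuracy, x$ci$lower, x$ci$upper, x$f1))
  invisible(x)
}

#' @rdname loco_cv
#' @param x A `loco_eval` object.
#' @param ... Unused.
#' @method tidy loco_eval
#' @export
tidy.loco_eval <- function(x, ...) {
  purrr::map_dfr(x$folds, function(f) {
    pr <- x$predictions[x$predictions$cohort == f$cohort, ]
    tibble::tibble(
      cohort = f$cohort,
      n_test = nrow(pr),
      accuracy = mean(pr$pred == pr$truth),
      n_selected = length(f$selected),
      selected = paste(f$selected, collapse = ";")
    )
  })
}

#' @rdname loco_cv
#' @method glance loco_eval
#' @export
glance.loco_eval <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    n = x$n,
    n_folds = length(x$folds),
    accuracy = x$accuracy,
    ci_lower = x$ci$lower,
    ci_upper = x$ci$upper,
    f1 = x$f1
  )
}

#' @rdname loco_cv
#' @param object A `loco_eval` object.
#' @param type `"selection"` (feature selection frequencies) or `"accuracy"`
#'   (per-fold and overall accuracy with the adjusted-Wald CI).
#' @param top_n Number of features shown in the selection plot.
#' @method autoplot loco_eval
#' @export
autoplot.loco_eval <- function(object, type = c("selection", "accuracy"),
                               top_n = 20, ...) {
  type <- match.arg(type)
  if (type == "selection") {
    d <- utils::head(object$selection, top_n)
    ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$pct),
                                    y = .data$pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "% of models selecting the feature") +
      ggplot2::theme_minimal()
  } else {
    d <- tidy(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$cohort, y = .data$accuracy)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
      ggplot2::geom_hline(yintercept = c(object$ci$lower, object$ci$upper),
                          linetype = 3) +
      ggplot2::labs(y = "held-out cohort accuracy", x = "held-out cohort") +
      ggplot2::theme_minimal()
  }
}
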