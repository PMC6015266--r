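#' @keywords internal
#' @importFrom rlang abort warn .data := %||%
#' @importFrom stats median sd qnorm pt p.adjust rnorm runif rpois rlnorm rbinom
#'   t.test wilcox.test shapiro.test cor predict complete.cases plogis rgeom
#'   setNames quantile oneway.test
#' @importFrom utils head
"_PACKAGE"

SEC_PER_DAY <- 86400
MIN_PER_DAY <- 1440

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

abort_ws <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("wearstress_", class), "wearstress_error"))
}

#' Derive a stage seed from a run seed
#'
#' All randomness in the package flows from a single integer seed; stage- or
#' fold-specific seeds are derived with this function so that reruns with the
#' same run seed are byte-identical while stages stay decorrelated.
#'
#' @param seed Integer run seed.
#' @param offset Integer stage offset.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + 104729 * (offset + 1)) %% 2147483647)
}

# Clock windows used throughout: half-open [start, end) seconds since local
# midnight. "sleep" is per-day and resolved from ground-truth episodes.
clock_windows <- function() {
  tibble::tibble(
    window  = c("latenight", "day", "night", "fullday"),
    start_s = c(0, 9, 18, 0) * 3600,
    end_s   = c(3, 18, 24, 24) * 3600
  )
}

# mean/median/sd across days, requiring >= min_n non-missing contributions
agg3 <- function(x, min_n = 2L) {
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_))
  }
  c(mean = mean(x), median = stats::median(x), sd = stats::sd(x))
}

# stats of a per-day sample vector (may be empty -> NAs)
day_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_))
  }
  c(mean = mean(x), median = stats::median(x),
    sd = if (length(x) > 1) stats::sd(x) else 0)
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max ||
      (integer && x != round(x))) {
    abort_ws(sprintf("invalid value for `%s`", name), "param_error")
  }
  invisible(x)
}

new_feature_block <- function(data, meta) {
  stopifnot(identical(names(data)[1], "participant_id"))
  stopifnot(setequal(meta$column, setdiff(names(data), "participant_id")))
  attr(data, "feature_meta") <- meta
  data
}

#' Feature metadata of a feature block
#'
#' Every feature block produced by the extraction functions carries a metadata
#' table tagging each column with its signal, statistic, window, across-day
#' aggregate and modality block.
#'
#' @param block A feature block tibble.
#' @return A tibble with one row per feature column.
#' @export
feature_meta <- function(block) {
  m <- attr(block, "feature_meta")
  if (is.null(m)) abort_ws("not a feature block: missing metadata", "param_error")
  m
}
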