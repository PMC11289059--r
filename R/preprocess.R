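#' Exclude participants who did not perform the task
#'
#' A participant is removed entirely when their overall accuracy over the
#' main-task trials is below 50%, or when a single response button
#' accounts for more than 75% of their trials (both inequalities strict:
#' exactly 50% accuracy or exactly 75% one-button use is kept). Training
#' trials never count.
#'
#' @param trials long-format trial table with columns `participant_id`,
#'   `correct`, `response` (and optionally `phase`).
#' @return list with `trials` (surviving rows, unchanged) and `report`, a
#'   data.frame of class `exclusion_report` with one row per participant:
#'   `accuracy`, `max_button_prop`, `excluded`, `reason`.
#' @export
exclude_participants <- function(trials) {
  need <- c("participant_id", "correct", "response")
  if (!all(need %in% names(trials)))
    stop(errorCondition(paste("missing columns:",
                              paste(setdiff(need, names(trials)), collapse = ", ")),
                        class = c("prtddm_schema_error", "error", "condition")))
  main <- if ("phase" %in% names(trials)) trials[trials$phase == "main", ] else trials
  ids <- unique(main$participant_id)
  rep_rows <- lapply(ids, function(id) {
    d <- main[main$participant_id == id, ]
    acc <- mean(d$correct)
    btn <- max(table(d$response)) / nrow(d)
    reason <- if (acc < 0.5 && btn > 0.75) "accuracy;single-button"
      else if (acc < 0.5) "accuracy"
      else if (btn > 0.75) "single-button"
      else ""
    data.frame(participant_id = id, accuracy = acc, max_button_prop = btn,
               excluded = acc < 0.5 || btn > 0.75, reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  class(report) <- c("exclusion_report", class(report))
  keep <- report$participant_id[!report$excluded]
  list(trials = trials[trials$participant_id %in% keep, ],
       report = report)
}

#' Filter trials by response-time window
#'
#' Drops main-task trials with RT below `lo` or above `hi` seconds (both
#' bounds kept: the exclusion rule is strictly outside the window, so an
#' RT of exactly 0.250 s or 2.500 s survives). Training trials are also
#' dropped here, as they precede all analyses.
#'
#' @param trials trial table with an `rt` column in seconds.
#' @param lo,hi window bounds in seconds.
#' @return list with `trials` (kept rows) and `report`, a `filter_report`
#'   list: `n_before`, `n_after`, `fraction_removed`, `bounds`.
#' @export
filter_rts <- function(trials, lo = 0.250, hi = 2.500) {
  if (!"rt" %in% names(trials))
    stop(errorCondition("missing rt column",
                        class = c("prtddm_schema_error", "error", "condition")))
  if (any(trials$rt < 0, na.rm = TRUE))
    stop(errorCondition("negative response times: corrupt input",
                        class = c("prtddm_rt_error", "error", "condition")))
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "main", ]
  n0 <- nrow(trials)
  kept <- trials[trials$rt >= lo & trials$rt <= hi, ]
  report <- structure(list(n_before = n0, n_after = nrow(kept),
                           fraction_removed = if (n0 > 0) 1 - nrow(kept) / n0 else 0,
                           bounds = c(lo = lo, hi = hi)),
                      class = "filter_report")
  list(trials = kept, report = report)
}

#' Variance-stabilising transforms
#'
#' `transform_rt()` applies the decimal logarithm to response times to
#' approximate a Gaussian distribution; `transform_accuracy()` applies
#' the arcsine-square-root transform `asin(sqrt(p))` to accuracy
#' proportions.
#'
#' @param rt positive response times (seconds).
#' @return `log10(rt)`.
#' @export
transform_rt <- function(rt) {
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("response times must be positive and finite")
  log10(rt)
}

#' @rdname transform_rt
#' @param p proportions in \[0, 1\].
#' @return `asin(sqrt(p))`, in radians.
#' @export
transform_accuracy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Winsorize outliers within groups
#'
#' Within each group, values outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are replaced by the nearer fence
#' (`method = "tukey"`, the default); `method = "percentile"` clamps at
#' the 5th/95th percentiles instead. Idempotent: a second pass changes
#' nothing, because the quartiles are unaffected by moving points that
#' already lie beyond the fences onto them.
#'
#' @param values numeric vector.
#' @param grouping factor-like vector, same length (a single group if
#'   omitted).
#' @param method "tukey" or "percentile".
#' @return numeric vector with attribute `n_replaced`, the count of
#'   replaced values.
#' @examples
#' winsorize(c(0, 0, 0, 0, 100))
#' @export
winsorize <- function(values, grouping = NULL, method = c("tukey", "percentile")) {
  method <- match.arg(method)
  if (is.null(grouping)) grouping <- rep(1L, length(values))
  stopifnot(length(grouping) == length(values))
  out <- values
  n_replaced <- 0L
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    x <- values[idx]
    if (length(x) < 4)
      stop(errorCondition(sprintf("group '%s' has fewer than 4 values", g),
                          class = c("prtddm_group_size_error", "error",
                                    "condition")))
    if (method == "tukey") {
      q <- quantile(x, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      fence <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    } else {
      fence <- quantile(x, c(0.05, 0.95), names = FALSE)
    }
    y <- pmin(pmax(x, fence[1]), fence[2])
    n_replaced <- n_replaced + sum(y != x)
    out[idx] <- y
  }
  attr(out, "n_replaced") <- n_replaced
  out
}
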