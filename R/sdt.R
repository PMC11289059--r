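#' Rich/lean-by-correctness contingency table for one participant-block
#'
#' Counts the filtered trials of one participant in one block into the
#' four cells used by the signal-detection indices: rich-correct (RC),
#' rich-incorrect (RI), lean-correct (LC) and lean-incorrect (LI).
#'
#' @param trials filtered trial table (`stimulus`, `correct` columns).
#' @param participant participant id to tabulate.
#' @param block block index.
#' @return an object of class `contingency_table`: named integer vector
#'   `rich_correct`, `rich_incorrect`, `lean_correct`, `lean_incorrect`.
#' @export
sdt_tabulate <- function(trials, participant, block) {
  d <- trials[trials$participant_id == participant & trials$block == block, ]
  if ("phase" %in% names(d)) d <- d[d$phase == "main", ]
  if (nrow(d) == 0)
    stop(errorCondition(
      sprintf("no valid trials for participant %s block %s", participant, block),
      class = c("prtddm_empty_block_error", "error", "condition")))
  tab <- c(rich_correct = sum(d$stimulus == "rich" & d$correct),
           rich_incorrect = sum(d$stimulus == "rich" & !d$correct),
           lean_correct = sum(d$stimulus == "lean" & d$correct),
           lean_incorrect = sum(d$stimulus == "lean" & !d$correct))
  structure(as.integer(tab), names = names(tab), class = "contingency_table")
}

#' Response bias index log b
#'
#' `log b = 0.5 * log10( (RC + 0.5)(LI + 0.5) / ((RI + 0.5)(LC + 0.5)) )`.
#' 0.5 is added to every cell to avoid division by zero. Positive values
#' indicate a bias toward the rich response; the index is antisymmetric
#' under relabelling rich and lean.
#'
#' @param table a [sdt_tabulate()] result (or any vector/list with the
#'   four named cells).
#' @return response bias, dimensionless.
#' @export
log_b <- function(table) {
  ct <- as_ct(table)
  0.5 * log10(((ct["rich_correct"] + 0.5) * (ct["lean_incorrect"] + 0.5)) /
              ((ct["rich_incorrect"] + 0.5) * (ct["lean_correct"] + 0.5)))[[1]]
}

#' Discriminability index log d
#'
#' `log d = 0.5 * log10( (RC + 0.5)(LC + 0.5) / ((RI + 0.5)(LI + 0.5)) )`:
#' perceptual sensitivity independent of bias, symmetric under rich/lean
#' relabelling and increasing in the correct-cell counts.
#'
#' @inheritParams log_b
#' @return discriminability, dimensionless.
#' @export
log_d <- function(table) {
  ct <- as_ct(table)
  0.5 * log10(((ct["rich_correct"] + 0.5) * (ct["lean_correct"] + 0.5)) /
              ((ct["rich_incorrect"] + 0.5) * (ct["lean_incorrect"] + 0.5)))[[1]]
}

as_ct <- function(table) {
  need <- c("rich_correct", "rich_incorrect", "lean_correct", "lean_incorrect")
  v <- unlist(table)[need]
  if (any(is.na(v)) || any(v < 0)) stop("invalid contingency table")
  v
}

#' Per-participant, per-block signal-detection indices
#'
#' @param trials filtered trial table.
#' @return data.frame with one row per (participant, block):
#'   `participant_id`, `group` (if present), `block`, `log_b`, `log_d`.
#' @export
sdt_indices <- function(trials) {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "main", ]
  cells <- unique(trials[, c("participant_id", "block")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tab <- sdt_tabulate(trials, cells$participant_id[i], cells$block[i])
    g <- if ("group" %in% names(trials))
      trials$group[trials$participant_id == cells$participant_id[i]][1]
    else NA_character_
    data.frame(participant_id = cells$participant_id[i], group = g,
               block = cells$block[i], log_b = log_b(tab), log_d = log_d(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$participant_id, out$block), ]
}

#' Reward-learning score: change in response bias across the session
#'
#' The difference between the block-3 and block-1 response bias per
#' participant captures how strongly reward contingencies shifted
#' responding over the session.
#'
#' @param logb_by_block data.frame with columns `participant_id`, `block`,
#'   `log_b` (as from [sdt_indices()]), or a numeric vector indexed by
#'   block for a single participant.
#' @param first,last blocks to difference (defaults 1 and 3).
#' @return for a data.frame input, a data.frame `participant_id`,
#'   `delta_log_b`; for a vector, a single number.
#' @export
reward_learning <- function(logb_by_block, first = 1, last = 3) {
  if (is.numeric(logb_by_block)) {
    if (length(logb_by_block) < last)
      stop(errorCondition("missing block for reward-learning score",
                          class = c("prtddm_missing_block_error", "error",
                                    "condition")))
    return(logb_by_block[last] - logb_by_block[first])
  }
  stopifnot(all(c("participant_id", "block", "log_b") %in% names(logb_by_block)))
  ids <- unique(logb_by_block$participant_id)
  rows <- lapply(ids, function(id) {
    d <- logb_by_block[logb_by_block$participant_id == id, ]
    b1 <- d$log_b[d$block == first]; b3 <- d$log_b[d$block == last]
    if (length(b1) != 1 || length(b3) != 1)
      stop(errorCondition(sprintf("participant %s lacks block %d or %d", id,
                                  first, last),
                          class = c("prtddm_missing_block_error", "error",
                                    "condition")))
    data.frame(participant_id = id, delta_log_b = b3 - b1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
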