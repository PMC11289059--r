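#' Probabilistic reward task configuration
#'
#' Describes one PRT session: three blocks of 96 main trials preceded by a
#' short training run; on each trial a schematic face is shown, then a
#' short or long mouth, and the participant judges the mouth length. One
#' mouth (the "rich" stimulus) has 75% of its correct responses rewarded,
#' the other ("lean") only 25%. Event durations are carried as schedule
#' metadata only; no real-time presentation is simulated.
#'
#' @param n_blocks number of main-task blocks.
#' @param trials_per_block trials per block; must be even so rich and lean
#'   stimuli appear equally often.
#' @param n_training_trials training trials emitted before block 1
#'   (flagged `phase = "training"`; never used in analyses).
#' @param p_reward_rich probability a correct rich response is rewarded.
#' @param p_reward_lean probability a correct lean response is rewarded.
#' @param timing named event durations in milliseconds.
#' @param reward_mode "bernoulli" draws each reward independently
#'   (default, matching a stated per-response probability); "quota" fills
#'   an exactly proportioned reward pool per block and stimulus, as in
#'   classic laboratory PRT variants with controlled reward counts.
#' @return a list of class `prt_config`.
#' @examples
#' cfg <- prt_config()
#' cfg$timing[["feedback"]]  # 1750 ms
#' @export
prt_config <- function(n_blocks = 3, trials_per_block = 96,
                       n_training_trials = 10,
                       p_reward_rich = 0.75, p_reward_lean = 0.25,
                       timing = c(face = 500, mouth = 100,
                                  feedback = 1750, iti = 500),
                       reward_mode = c("bernoulli", "quota")) {
  reward_mode <- match.arg(reward_mode)
  if (trials_per_block %% 2 != 0)
    stop(errorCondition(
      "trials_per_block must be even: unbalanced rich/lean design",
      class = c("prtddm_design_error", "error", "condition")))
  if (!(p_reward_lean >= 0 && p_reward_lean < p_reward_rich &&
        p_reward_rich <= 1))
    stop("need 0 <= p_reward_lean < p_reward_rich <= 1")
  if (any(timing <= 0)) stop("all event durations must be positive")
  stopifnot(n_blocks >= 1, n_training_trials >= 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 n_training_trials = as.integer(n_training_trials),
                 p_reward_rich = p_reward_rich,
                 p_reward_lean = p_reward_lean,
                 timing = timing,
                 reward_mode = reward_mode),
            class = "prt_config")
}

# parity of a participant identifier: numeric ids use their value,
# other strings the sum of their character codes
participant_parity <- function(participant_id) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", as.character(participant_id))))
  if (is.finite(num)) return(num %% 2)
  sum(utf8ToInt(as.character(participant_id))) %% 2
}

# run code under a temporary RNG state derived from (seed, participant_id)
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable small-integer stream offset per participant
participant_stream <- function(seed, participant_id) {
  h <- sum(utf8ToInt(as.character(participant_id))) %% 100003L
  (as.integer(seed) %% 1000003L) * 1009L + h * 7L
}

#' Build the trial schedule for one participant
#'
#' Each block holds exactly `trials_per_block / 2` rich and lean slots in
#' seeded-random order. Which mouth length (short/long) plays the rich
#' role alternates with participant parity, emulating counterbalancing
#' across participants. Deterministic given `(seed, participant_id)`.
#'
#' @param config a [prt_config()].
#' @param participant_id participant identifier (numeric or string).
#' @param seed integer seed.
#' @return data.frame with columns `block`, `trial_index`, `stimulus`
#'   ("rich"/"lean") and `mouth` ("short"/"long").
#' @export
build_schedule <- function(config, participant_id, seed) {
  stopifnot(inherits(config, "prt_config"))
  half <- config$trials_per_block %/% 2L
  rich_mouth <- if (participant_parity(participant_id) == 0) "short" else "long"
  lean_mouth <- if (rich_mouth == "short") "long" else "short"
  with_local_seed(participant_stream(seed, participant_id), {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      stim <- sample(rep(c("rich", "lean"), each = half))
      data.frame(block = b, trial_index = seq_len(config$trials_per_block),
                 stimulus = stim,
                 mouth = ifelse(stim == "rich", rich_mouth, lean_mouth),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
}

#' Assign reward feedback to responses
#'
#' Only correct responses can be rewarded: correct rich responses with
#' probability `p_reward_rich`, correct lean responses with
#' `p_reward_lean`, independently per trial (Bernoulli mode). Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param stimulus character vector of "rich"/"lean".
#' @param correct logical vector.
#' @param config a [prt_config()].
#' @return logical vector `rewarded`.
#' @export
assign_feedback <- function(stimulus, correct, config) {
  stopifnot(inherits(config, "prt_config"), length(stimulus) == length(correct))
  p <- ifelse(stimulus == "rich", config$p_reward_rich, config$p_reward_lean)
  as.logical(correct) & (runif(length(stimulus)) < p)
}

# quota-mode reward assignment for one block: among the correct responses
# of each stimulus, an exactly proportioned shuffled pool of rewards is
# dealt out in trial order (classic controlled-reward PRT variants)
assign_feedback_quota <- function(stimulus, correct, config) {
  rewarded <- logical(length(stimulus))
  for (stim in c("rich", "lean")) {
    p <- if (stim == "rich") config$p_reward_rich else config$p_reward_lean
    idx <- which(stimulus == stim & correct)
    n <- length(idx)
    if (n == 0) next
    pool <- sample(c(rep(TRUE, round(p * n)), rep(FALSE, n - round(p * n))))
    rewarded[idx] <- pool
  }
  rewarded
}

#' Specification of a synthetic DDM agent
#'
#' An agent stands in for one participant: a full set of DDM parameters
#' per block, with drift, boundary and non-decision time specific to rich
#' and lean trials and a single raw starting bias per block (the mapped
#' lean-trial bias is the complement of the rich-trial bias).
#'
#' @param participant_id identifier.
#' @param group feedback-type group label ("star", "verbal", "face",
#'   "thumbs").
#' @param block_params data.frame with one row per block and columns
#'   `v_rich`, `v_lean`, `a_rich`, `a_lean`, `t_rich`, `t_lean`, `z_raw`.
#' @param seed integer seed fixed for this agent.
#' @return a list of class `agent_spec`.
#' @export
agent_spec <- function(participant_id, group, block_params, seed) {
  need <- c("v_rich", "v_lean", "a_rich", "a_lean", "t_rich", "t_lean", "z_raw")
  if (!all(need %in% names(block_params)))
    stop("block_params must contain: ", paste(need, collapse = ", "))
  for (b in seq_len(nrow(block_params))) {
    r <- block_params[b, ]
    validate_ddm_params(list(v = r$v_rich, a = r$a_rich, t0 = r$t_rich,
                             z_raw = r$z_raw, s = 1))
    validate_ddm_params(list(v = r$v_lean, a = r$a_lean, t0 = r$t_lean,
                             z_raw = r$z_raw, s = 1))
  }
  structure(list(participant_id = as.character(participant_id),
                 group = group, block_params = block_params,
                 seed = as.integer(seed)),
            class = "agent_spec")
}

#' Simulate one agent performing a full PRT session
#'
#' Composes [build_schedule()], the DDM forward sampler and
#' [assign_feedback()]. Accuracy coding is used throughout: the upper
#' boundary is the correct response, and the accumulator starts at
#' `Phi(z_raw)` on rich trials and `1 - Phi(z_raw)` on lean trials, so a
#' positive `z_raw` biases responses toward "rich" regardless of the
#' stimulus shown. Training trials are emitted with `phase = "training"`,
#' `block = 0` and no reward feedback.
#'
#' @param spec an [agent_spec()].
#' @param config a [prt_config()].
#' @param dt Euler step for the DDM sampler (seconds).
#' @return data.frame of trial records: `participant_id`, `group`,
#'   `phase`, `block`, `trial_index`, `stimulus`, `mouth`, `response`,
#'   `correct`, `rewarded`, `rt`.
#' @export
simulate_agent <- function(spec, config = prt_config(), dt = 1e-3) {
  stopifnot(inherits(spec, "agent_spec"), inherits(config, "prt_config"))
  if (nrow(spec$block_params) < config$n_blocks)
    stop("agent_spec must provide parameters for every block")
  sched <- build_schedule(config, spec$participant_id, spec$seed)
  with_local_seed(participant_stream(spec$seed, spec$participant_id) + 1L, {
    rows <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      pars <- spec$block_params[b, ]
      sb <- sched[sched$block == b, ]
      out <- sb
      out$response <- NA_character_
      out$correct <- NA
      out$rt <- NA_real_
      for (stim in c("rich", "lean")) {
        idx <- which(sb$stimulus == stim)
        w_raw <- if (stim == "rich") pars$z_raw else -pars$z_raw
        p <- ddm_params(v = if (stim == "rich") pars$v_rich else pars$v_lean,
                        a = if (stim == "rich") pars$a_rich else pars$a_lean,
                        t0 = if (stim == "rich") pars$t_rich else pars$t_lean,
                        z_raw = w_raw)
        d <- sample_ddm(p, n = length(idx), dt = dt)
        out$correct[idx] <- d$boundary == "upper"
        out$rt[idx] <- d$rt
      }
      other <- c(rich = "lean", lean = "rich")
      out$response <- ifelse(out$correct, out$stimulus, other[out$stimulus])
      out$rewarded <-
        if (config$reward_mode == "bernoulli")
          assign_feedback(out$stimulus, out$correct, config)
        else
          assign_feedback_quota(out$stimulus, out$correct, config)
      rows[[b]] <- out
    }
    main <- do.call(rbind, rows)
    main$phase <- "main"
    if (config$n_training_trials > 0) {
      tr <- simulate_training(spec, config, dt)
      main <- rbind(tr, main)
    }
    main$participant_id <- spec$participant_id
    main$group <- spec$group
    rownames(main) <- NULL
    main[, c("participant_id", "group", "phase", "block", "trial_index",
             "stimulus", "mouth", "response", "correct", "rewarded", "rt")]
  })
}

# training run before block 1: balanced stimuli, block-1 parameters,
# correctness feedback only (rewarded is NA and never analysed)
simulate_training <- function(spec, config, dt) {
  n <- config$n_training_trials
  pars <- spec$block_params[1, ]
  half <- n %/% 2
  stim <- sample(c(rep("rich", half), rep("lean", n - half)))
  rich_mouth <- if (participant_parity(spec$participant_id) == 0) "short" else "long"
  other <- c(rich = "lean", lean = "rich")
  correct <- logical(n); rt <- numeric(n)
  for (stim_i in c("rich", "lean")) {
    idx <- which(stim == stim_i)
    if (!length(idx)) next
    p <- ddm_params(v = if (stim_i == "rich") pars$v_rich else pars$v_lean,
                    a = if (stim_i == "rich") pars$a_rich else pars$a_lean,
                    t0 = if (stim_i == "rich") pars$t_rich else pars$t_lean,
                    z_raw = if (stim_i == "rich") pars$z_raw else -pars$z_raw)
    d <- sample_ddm(p, n = length(idx), dt = dt)
    correct[idx] <- d$boundary == "upper"
    rt[idx] <- d$rt
  }
  lean_mouth <- if (rich_mouth == "short") "long" else "short"
  data.frame(block = 0L, trial_index = seq_len(n), stimulus = stim,
             mouth = ifelse(stim == "rich", rich_mouth, lean_mouth),
             response = ifelse(correct, stim, other[stim]),
             correct = correct, rewarded = NA, rt = rt, phase = "training",
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of DDM agents
#'
#' Draws each agent's per-block DDM parameters from group-level normal
#' distributions truncated to the valid supports, simulates every agent's
#' session, and returns the long-format trial table together with the true
#' parameters (for parameter recovery).
#'
#' @param group_specs named list mapping group label to a list with
#'   elements `mean` and `sd`: either length-7 vectors (shared across
#'   blocks) or `n_blocks` x 7 matrices, columns ordered `v_rich, v_lean,
#'   a_rich, a_lean, t_rich, t_lean, z_raw`. `sd = 0` gives identical
#'   agents.
#' @param n_per_group agents per group.
#' @param config a [prt_config()].
#' @param seed integer master seed.
#' @param dt Euler step for the DDM sampler.
#' @return list of class `prt_cohort` with elements `trials` (long-format
#'   data.frame), `truth` (one row per participant x block with the true
#'   parameters), `config` and `seed`.
#' @export
simulate_cohort <- function(group_specs, n_per_group, config = prt_config(),
                            seed = 1, dt = 1e-3) {
  stopifnot(n_per_group >= 1, length(group_specs) >= 1,
            !is.null(names(group_specs)))
  param_names <- c("v_rich", "v_lean", "a_rich", "a_lean",
                   "t_rich", "t_lean", "z_raw")
  lo <- c(-Inf, -Inf, 1e-6, 1e-6, 0, 0, -4)
  hi <- c(Inf, Inf, Inf, Inf, 1, 1, 4)
  all_trials <- list(); all_truth <- list(); k <- 0L
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    m <- gs$mean; sdv <- gs$sd
    if (is.null(dim(m))) m <- matrix(m, config$n_blocks, 7, byrow = TRUE)
    if (is.null(dim(sdv))) sdv <- matrix(sdv, config$n_blocks, 7, byrow = TRUE)
    colnames(m) <- colnames(sdv) <- param_names
    if (any(m[, "a_rich"] <= 0) || any(m[, "a_lean"] <= 0) ||
        any(m[, "t_rich"] < 0 | m[, "t_rich"] > 1) ||
        any(m[, "t_lean"] < 0 | m[, "t_lean"] > 1) ||
        any(abs(m[, "z_raw"]) > 4) || any(sdv < 0))
      stop("group_specs means outside valid parameter supports")
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      pid <- sprintf("%s_%03d", g, i)
      aseed <- (participant_stream(seed, pid) + 13L * k) %% .Machine$integer.max
      bp <- with_local_seed(aseed, {
        draw <- matrix(NA_real_, config$n_blocks, 7,
                       dimnames = list(NULL, param_names))
        for (b in seq_len(config$n_blocks))
          for (j in 1:7)
            draw[b, j] <- rnorm_trunc(m[b, j], sdv[b, j], lo[j], hi[j])
        draw
      })
      spec <- agent_spec(pid, g, as.data.frame(bp), seed = aseed + 1L)
      all_trials[[k]] <- simulate_agent(spec, config, dt)
      tr <- as.data.frame(bp)
      tr$participant_id <- pid; tr$group <- g
      tr$block <- seq_len(config$n_blocks)
      all_truth[[k]] <- tr
    }
  }
  structure(list(trials = do.call(rbind, all_trials),
                 truth = do.call(rbind, all_truth),
                 config = config, seed = seed),
            class = "prt_cohort")
}

# one draw from a truncated normal by rejection (degenerate sd allowed)
rnorm_trunc <- function(mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("degenerate draw outside support")
    return(mean)
  }
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection sampling failed: support too far from mean")
}

#' Write a simulated cohort to disk
#'
#' The trial table goes to CSV (RTs with 6 decimal places) and the true
#' agent parameters plus the configuration to a JSON sidecar.
#'
#' @param cohort a `prt_cohort` from [simulate_cohort()].
#' @param csv_path output CSV path.
#' @param sidecar_path output JSON path (default: csv path with
#'   `.truth.json`).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, csv_path,
                         sidecar_path = sub("\\.csv$", ".truth.json", csv_path)) {
  stopifnot(inherits(cohort, "prt_cohort"))
  tr <- cohort$trials
  tr$rt <- round(tr$rt, 6)
  write.csv(tr, csv_path, row.names = FALSE)
  side <- list(seed = cohort$seed,
               config = unclass(cohort$config),
               truth = cohort$truth)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv_path, sidecar = sidecar_path))
}
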