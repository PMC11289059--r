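#' Reference accuracy rates for the online PRT
#'
#' Descriptive accuracy norms (percent correct by feedback-type group,
#' stimulus and block) from a large online administration of the task,
#' used as default per-trial correctness probabilities for
#' schedule-level simulations such as [simulate_reward_counts()].
#' Accuracy is higher for the rich than the lean stimulus and sits in the
#' low-to-high 70s throughout, as is typical for the PRT.
#'
#' @return data.frame with columns `group`, `stimulus`, `block`,
#'   `accuracy` (proportion in 0-1).
#' @export
reference_accuracy <- function() {
  acc <- c(  # rich blocks 1-3, then lean blocks 1-3, per group
    star = c(74.13, 75.42, 78.22, 68.94, 67.20, 66.63),
    verbal = c(75.99, 76.94, 77.69, 69.33, 69.34, 69.73),
    face = c(76.44, 78.63, 79.46, 71.08, 70.85, 71.07),
    thumbs = c(76.22, 78.94, 77.87, 69.17, 70.02, 69.42))
  data.frame(group = rep(c("star", "verbal", "face", "thumbs"), each = 6),
             stimulus = rep(rep(c("rich", "lean"), each = 3), times = 4),
             block = rep(1:3, times = 8),
             accuracy = as.numeric(acc) / 100,
             stringsAsFactors = FALSE)
}

#' Simulate total reward counts for schedule-level sessions
#'
#' Simulates full sessions in which each trial is correct with a fixed
#' probability (by stimulus and block) and correct responses are rewarded
#' under the skewed 75%/25% schedule, and returns the total number of
#' reward feedbacks per session. With the default accuracy table
#' (across-group means of [reference_accuracy()]) this reproduces the
#' final reward count participants are shown at the end of the task.
#'
#' @param n_sessions number of sessions.
#' @param config a [prt_config()].
#' @param acc data.frame `stimulus`, `block`, `accuracy`; defaults to the
#'   across-group mean of [reference_accuracy()].
#' @param seed integer seed.
#' @return integer vector of per-session reward totals.
#' @examples
#' mean(simulate_reward_counts(200, seed = 1))
#' @export
simulate_reward_counts <- function(n_sessions = 1000, config = prt_config(),
                                   acc = NULL, seed = 1) {
  if (is.null(acc)) {
    ra <- reference_accuracy()
    acc <- aggregate(accuracy ~ stimulus + block, data = ra, FUN = mean)
  }
  half <- config$trials_per_block %/% 2L
  totals <- integer(n_sessions)
  with_local_seed(as.integer(seed), {
    for (b in seq_len(config$n_blocks)) {
      for (stim in c("rich", "lean")) {
        p_acc <- acc$accuracy[acc$stimulus == stim & acc$block == b]
        stopifnot(length(p_acc) == 1)
        p_rew <- if (stim == "rich") config$p_reward_rich else config$p_reward_lean
        correct <- matrix(runif(n_sessions * half) < p_acc, n_sessions, half)
        rewarded <- correct & matrix(runif(n_sessions * half) < p_rew,
                                     n_sessions, half)
        totals <- totals + rowSums(rewarded)
      }
    }
    totals
  })
}

#' Default group-level parameter distributions for cohort simulation
#'
#' Means and SDs (per block, columns `v_rich, v_lean, a_rich, a_lean,
#' t_rich, t_lean, z_raw`) chosen to produce the behavioural signature of
#' the task: drift higher for rich than lean trials and rising over
#' blocks, boundary near 1.3, non-decision time near 0.28 s (consistent
#' with mean RTs around 0.55-0.62 s), and a mapped starting bias slightly
#' above 0.5 toward the rich response.
#'
#' @param groups character vector of group labels.
#' @param z_mean mean raw starting bias (default `qnorm(0.53)`).
#' @return named list usable as `group_specs` in [simulate_cohort()].
#' @export
default_group_specs <- function(groups = c("star", "verbal", "face", "thumbs"),
                                z_mean = qnorm(0.53)) {
  mean_mat <- cbind(v_rich = c(1.05, 1.15, 1.25),
                    v_lean = c(0.90, 0.98, 1.05),
                    a_rich = c(1.30, 1.27, 1.27),
                    a_lean = c(1.29, 1.25, 1.26),
                    t_rich = c(0.28, 0.28, 0.28),
                    t_lean = c(0.28, 0.28, 0.28),
                    z_raw = rep(z_mean, 3))
  sd_mat <- cbind(v_rich = rep(0.25, 3), v_lean = rep(0.25, 3),
                  a_rich = rep(0.15, 3), a_lean = rep(0.15, 3),
                  t_rich = rep(0.04, 3), t_lean = rep(0.04, 3),
                  z_raw = rep(0.10, 3))
  setNames(lapply(groups, function(g) list(mean = mean_mat, sd = sd_mat)),
           groups)
}

#' Draw true agent parameters spanning the plausible recovery region
#'
#' One parameter set per agent — DDM parameters behave as stable traits
#' over a single session, so the truth is held constant across blocks
#' (between-participant differences dwarf block effects in this task).
#' Drifts are drawn uniformly over \[0.6, 1.6\] and boundaries over
#' \[1.0, 1.6\] (independently for rich and lean trials), non-decision
#' times uniformly over \[0.2, 0.35\] s, and the raw starting bias from a
#' normal around `z_mean` (sd `z_sd`) truncated so the mapped bias stays
#' in \[0.45, 0.60\]. Uniform draws maximise the spread of true values,
#' which is what a recovery correlation is measured against.
#'
#' @param n_agents number of agents.
#' @param n_blocks blocks per agent.
#' @param z_mean,z_sd raw-bias distribution (default centred on a mapped
#'   bias of 0.53).
#' @param z_bounds raw-scale truncation bounds for the bias draw; default
#'   keeps the mapped bias in \[0.45, 0.60\]. Pass bounds symmetric
#'   around `z_mean` when simulating an unbiased cohort.
#' @param seed integer seed.
#' @param group label assigned to all agents.
#' @return truth data.frame (one row per agent x block; rows of one agent
#'   repeat the agent's trait values).
#' @export
recovery_truth <- function(n_agents = 12, n_blocks = 3,
                           z_mean = qnorm(0.53), z_sd = 0.1, seed = 1,
                           group = "sim",
                           z_bounds = qnorm(c(0.45, 0.60))) {
  with_local_seed(as.integer(seed), {
    agents <- data.frame(
      participant_id = sprintf("%s_%03d", group, seq_len(n_agents)),
      group = group,
      v_rich = runif(n_agents, 0.6, 1.6), v_lean = runif(n_agents, 0.6, 1.6),
      a_rich = runif(n_agents, 1.0, 1.6), a_lean = runif(n_agents, 1.0, 1.6),
      t_rich = runif(n_agents, 0.2, 0.35), t_lean = runif(n_agents, 0.2, 0.35),
      z_raw = vapply(seq_len(n_agents), function(i)
        rnorm_trunc(z_mean, z_sd, z_bounds[1], z_bounds[2]), numeric(1)),
      stringsAsFactors = FALSE)
    truth <- agents[rep(seq_len(n_agents), each = n_blocks), ]
    truth$block <- rep(seq_len(n_blocks), times = n_agents)
    rownames(truth) <- NULL
    truth[, c("participant_id", "group", "block", "v_rich", "v_lean",
              "a_rich", "a_lean", "t_rich", "t_lean", "z_raw")]
  })
}

#' Simulate a cohort from an explicit truth table
#'
#' @param truth data.frame as returned by [recovery_truth()].
#' @param config a [prt_config()].
#' @param seed integer seed for the trial-level simulation.
#' @param dt Euler step.
#' @return a `prt_cohort` (see [simulate_cohort()]).
#' @export
simulate_from_truth <- function(truth, config = prt_config(), seed = 1,
                                dt = 1e-3) {
  ids <- unique(truth$participant_id)
  all_trials <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- truth[truth$participant_id == ids[i], ]
    d <- d[order(d$block), ]
    spec <- agent_spec(ids[i], d$group[1],
                       d[, c("v_rich", "v_lean", "a_rich", "a_lean",
                             "t_rich", "t_lean", "z_raw")],
                       seed = (participant_stream(seed, ids[i]) + i) %%
                         .Machine$integer.max)
    all_trials[[i]] <- simulate_agent(spec, config, dt)
  }
  structure(list(trials = do.call(rbind, all_trials), truth = truth,
                 config = config, seed = seed),
            class = "prt_cohort")
}

#' Parameter-recovery harness
#'
#' Simulates a cohort with known parameters, runs the full preprocessing
#' and hierarchical fit, and scores recovery: Pearson correlation, mean
#' signed bias and RMSE between true and estimated individual parameters
#' (drift and boundary pooled over rich/lean and blocks; bias on the
#' mapped scale), plus coverage of the true cell means by the group-level
#' 95% posterior intervals and the posterior interval for the
#' cohort-mean mapped bias.
#'
#' @param n_agents agents in the simulated cohort.
#' @param config a [prt_config()].
#' @param seed integer seed governing truth draw, simulation and fit.
#' @param z_mean,z_sd true raw-bias distribution.
#' @param z_bounds raw-bias truncation bounds (see [recovery_truth()]).
#' @param spec a [model_spec()] (default reduced settings).
#' @param dt Euler step for simulation.
#' @return object of class `recovery_report`.
#' @export
run_recovery <- function(n_agents = 12, config = prt_config(), seed = 1,
                         z_mean = qnorm(0.53), z_sd = 0.1,
                         z_bounds = qnorm(c(0.45, 0.60)),
                         spec = model_spec("reduced"), dt = 2.5e-4) {
  truth <- recovery_truth(n_agents, config$n_blocks, z_mean, z_sd,
                          seed = seed, z_bounds = z_bounds)
  cohort <- simulate_from_truth(truth, config, seed = seed + 1L, dt = dt)
  ex <- exclude_participants(cohort$trials)
  fl <- filter_rts(ex$trials)
  model <- build_model(fl$trials, prior_spec(), spec)
  fit <- fit_hddm(model, seed = seed + 2L)
  est <- extract_subject_params(fit)
  # score at the level the truth varies: agent x condition, pooling the
  # per-block posterior means of each agent
  agg <- function(df, cols) {
    out <- aggregate(df[cols], by = list(participant_id = df$participant_id),
                     FUN = mean)
    out[order(out$participant_id), ]
  }
  cols_t <- c("v_rich", "v_lean", "a_rich", "a_lean", "t_rich", "t_lean")
  tr_a <- agg(truth, c(cols_t, "z_raw"))
  es_a <- agg(est, c(cols_t, "z_rich"))
  stopifnot(identical(tr_a$participant_id, es_a$participant_id))
  score <- function(true, est) {
    c(r = cor(true, est), bias = mean(est - true),
      rmse = sqrt(mean((est - true)^2)))
  }
  scores <- rbind(
    v = score(c(tr_a$v_rich, tr_a$v_lean), c(es_a$v_rich, es_a$v_lean)),
    a = score(c(tr_a$a_rich, tr_a$a_lean), c(es_a$a_rich, es_a$a_lean)),
    t = score(c(tr_a$t_rich, tr_a$t_lean), c(es_a$t_rich, es_a$t_lean)),
    z = score(pnorm(tr_a$z_raw), es_a$z_rich))
  # group-level coverage for drift and boundary cell means
  cells <- fit$model$cells
  cover <- list()
  for (p in c("v_rich", "v_lean", "a_rich", "a_lean")) {
    for (ci in seq_len(nrow(cells))) {
      nm <- sprintf("mu[%s,%s,%s]", cells$group[ci], cells$block[ci], p)
      d <- fit$draws[, , nm]
      ci95 <- quantile(d, c(0.025, 0.975), names = FALSE)
      tv <- mean(truth[[p]][truth$block == cells$block[ci]])
      cover[[nm]] <- data.frame(parameter = p, block = cells$block[ci],
                                true_mean = tv, lo = ci95[1], hi = ci95[2],
                                covered = tv >= ci95[1] & tv <= ci95[2])
    }
  }
  coverage <- do.call(rbind, cover)
  rownames(coverage) <- NULL
  bias_int <- cohort_bias_interval(fit)
  structure(list(scores = scores, coverage = coverage,
                 bias_interval = bias_int,
                 truth = truth, estimates = est, fit = fit,
                 meta = list(n_agents = n_agents,
                             trials_per_agent = config$n_blocks *
                               config$trials_per_block,
                             chains = fit$spec$chains,
                             warmup = fit$spec$warmup,
                             draws = fit$spec$draws, seed = seed,
                             max_rhat = fit$diagnostics$max_rhat)),
            class = "recovery_report")
}

#' Posterior interval for the cohort-mean mapped starting bias
#'
#' For each posterior draw, the group-level raw-bias means of all cells
#' are mapped through Phi and averaged; the returned quantiles summarise
#' that cohort-level bias.
#'
#' @param fit an [fit_hddm()] result.
#' @param probs interval probabilities.
#' @return named vector: interval quantiles and posterior mean.
#' @export
cohort_bias_interval <- function(fit, probs = c(0.025, 0.975)) {
  cells <- fit$model$cells
  nms <- sprintf("mu[%s,%s,z_raw]", cells$group, cells$block)
  zdraws <- sapply(nms, function(nm) as.vector(pnorm(fit$draws[, , nm])))
  cohort_mean <- rowMeans(zdraws)
  c(quantile(cohort_mean, probs), mean = mean(cohort_mean))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery on", x$meta$n_agents, "agents x",
      x$meta$trials_per_agent, "trials\n")
  cat(sprintf("MCMC: %d chains, %d warmup + %d draws, max R-hat %.3f\n",
              x$meta$chains, x$meta$warmup, x$meta$draws, x$meta$max_rhat))
  print(round(x$scores, 3))
  cat(sprintf("Group-mean coverage (95%% CI): %d/%d cells\n",
              sum(x$coverage$covered), nrow(x$coverage)))
  cat(sprintf("Cohort-mean mapped bias: %.3f [%.3f, %.3f]\n",
              x$bias_interval[["mean"]], x$bias_interval[[1]],
              x$bias_interval[[2]]))
  invisible(x)
}

#' Descriptive group summaries
#'
#' Group x block (x stimulus / condition) means and SDs for reaction
#' times, accuracy, the signal-detection indices and, when provided, the
#' DDM point estimates. With a single participant in a group the SD is
#' reported as 0 and flagged.
#'
#' @param trials filtered trial table.
#' @param indices output of [sdt_indices()] (computed from `trials` when
#'   omitted).
#' @param estimates optional output of [extract_subject_params()].
#' @return list of data.frames: `behavior` (RT and accuracy by group,
#'   block, stimulus), `indices` (log b / log d by group, block),
#'   `params` (DDM parameters by group, block, condition; `NULL` when no
#'   estimates given).
#' @export
summarize_groups <- function(trials, indices = NULL, estimates = NULL) {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "main", ]
  if (nrow(trials) == 0) stop("empty trial table")
  if (is.null(indices)) indices <- sdt_indices(trials)
  msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                       n = length(x))
  # per-participant cell means first, then group summaries over participants
  beh_cells <- unique(trials[, c("group", "block", "stimulus")])
  beh <- do.call(rbind, lapply(seq_len(nrow(beh_cells)), function(i) {
    cell <- beh_cells[i, ]
    d <- trials[trials$group == cell$group & trials$block == cell$block &
                  trials$stimulus == cell$stimulus, ]
    per <- split(d, d$participant_id)
    rts <- vapply(per, function(p) mean(p$rt), numeric(1))
    accs <- vapply(per, function(p) mean(p$correct), numeric(1))
    data.frame(group = cell$group, block = cell$block,
               stimulus = cell$stimulus,
               mean_rt = mean(rts), sd_rt = if (length(rts) > 1) sd(rts) else 0,
               mean_acc = mean(accs),
               sd_acc = if (length(accs) > 1) sd(accs) else 0,
               n = length(rts), single_n = length(rts) == 1)
  }))
  idx_cells <- unique(indices[, c("group", "block")])
  idx <- do.call(rbind, lapply(seq_len(nrow(idx_cells)), function(i) {
    cell <- idx_cells[i, ]
    d <- indices[indices$group == cell$group & indices$block == cell$block, ]
    data.frame(group = cell$group, block = cell$block,
               mean_log_b = mean(d$log_b),
               sd_log_b = if (nrow(d) > 1) sd(d$log_b) else 0,
               mean_log_d = mean(d$log_d),
               sd_log_d = if (nrow(d) > 1) sd(d$log_d) else 0,
               n = nrow(d), single_n = nrow(d) == 1)
  }))
  params <- NULL
  if (!is.null(estimates)) {
    long <- do.call(rbind, lapply(c("v", "a", "t", "z"), function(p) {
      do.call(rbind, lapply(c("rich", "lean"), function(cond) {
        col <- paste0(p, "_", cond)
        data.frame(group = estimates$group, block = estimates$block,
                   condition = cond, parameter = p,
                   value = estimates[[col]], stringsAsFactors = FALSE)
      }))
    }))
    pc <- unique(long[, c("group", "block", "condition", "parameter")])
    params <- do.call(rbind, lapply(seq_len(nrow(pc)), function(i) {
      cell <- pc[i, ]
      d <- long[long$group == cell$group & long$block == cell$block &
                  long$condition == cell$condition &
                  long$parameter == cell$parameter, ]
      data.frame(cell, mean = mean(d$value),
                 sd = if (nrow(d) > 1) sd(d$value) else 0, n = nrow(d))
    }))
    rownames(params) <- NULL
  }
  rownames(beh) <- rownames(idx) <- NULL
  list(behavior = beh, indices = idx, params = params)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulation, preprocessing (participant exclusion, then RT filtering),
#' signal-detection indices and descriptive summaries; optionally the
#' hierarchical DDM fit. All outputs are written as CSV/JSON into
#' `out_dir`; reruns with the same configuration are byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_group agents per group.
#' @param groups group labels.
#' @param config a [prt_config()].
#' @param seed master seed.
#' @param fit_model also fit the hierarchical DDM (slow).
#' @param spec [model_spec()] used when `fit_model = TRUE`.
#' @return invisibly, a list with all in-memory artifacts.
#' @export
run_pipeline <- function(out_dir, n_per_group = 4,
                         groups = c("star", "verbal", "face", "thumbs"),
                         config = prt_config(), seed = 1,
                         fit_model = FALSE, spec = model_spec("reduced")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- simulate_cohort(default_group_specs(groups), n_per_group,
                              config, seed)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    stage <- "preprocess"
    ex <- exclude_participants(cohort$trials)
    fl <- filter_rts(ex$trials)
    write.csv(fl$trials, file.path(out_dir, "cohort.filtered.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(exclusion = ex$report,
                              filter = unclass(fl$report)),
                         file.path(out_dir, "preprocess_report.json"),
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
    stage <- "metrics"
    indices <- sdt_indices(fl$trials)
    write.csv(indices, file.path(out_dir, "indices.csv"), row.names = FALSE)
    rl <- reward_learning(indices)
    write.csv(rl, file.path(out_dir, "reward_learning.csv"), row.names = FALSE)
    est <- NULL; fit <- NULL
    if (fit_model) {
      stage <- "fit"
      model <- build_model(fl$trials, prior_spec(), spec)
      fit <- fit_hddm(model, seed = seed + 2L)
      est <- extract_subject_params(fit)
      write.csv(est, file.path(out_dir, "estimates.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(rhat = as.list(fit$diagnostics$rhat),
             max_rhat = fit$diagnostics$max_rhat,
             converged = fit$diagnostics$converged),
        file.path(out_dir, "fit_diagnostics.json"), auto_unbox = TRUE,
        digits = NA)
      write_draws_csv(fit, file.path(out_dir, "draws.csv"))
    }
    stage <- "report"
    summ <- summarize_groups(fl$trials, indices, est)
    write.csv(summ$behavior, file.path(out_dir, "summary_behavior.csv"),
              row.names = FALSE)
    write.csv(summ$indices, file.path(out_dir, "summary_indices.csv"),
              row.names = FALSE)
    if (!is.null(summ$params))
      write.csv(summ$params, file.path(out_dir, "summary_params.csv"),
                row.names = FALSE)
    list(cohort = cohort, exclusion = ex$report, filter = fl$report,
         indices = indices, reward_learning = rl, fit = fit,
         estimates = est, summaries = summ, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

# tidy posterior draws: chain, draw, parameter, value
write_draws_csv <- function(fit, path) {
  d <- fit$draws
  dn <- dimnames(d)[[3]]
  long <- data.frame(
    chain = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
    draw = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    parameter = rep(dn, each = dim(d)[1] * dim(d)[2]),
    value = as.vector(d))
  write.csv(long, path, row.names = FALSE)
}
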