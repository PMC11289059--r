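# task schedule, reward assignment, agents, cohorts

test_that("schedules are balanced, counterbalanced and deterministic", {
  cfg <- prt_config()
  s <- build_schedule(cfg, participant_id = 1, seed = 7)
  expect_equal(nrow(s), 3 * 96)
  for (b in 1:3) {
    sb <- s[s$block == b, ]
    expect_equal(sum(sb$stimulus == "rich"), 48)
    expect_equal(sum(sb$stimulus == "lean"), 48)
  }
  # smallest balanced block
  s2 <- build_schedule(prt_config(n_blocks = 1, trials_per_block = 2), 1, 7)
  expect_setequal(s2$stimulus, c("rich", "lean"))
  # determinism and seed sensitivity
  expect_identical(s, build_schedule(cfg, 1, 7))
  expect_false(identical(s$stimulus, build_schedule(cfg, 1, 8)$stimulus))
  # mouth-role counterbalancing by participant parity
  m1 <- unique(s$mouth[s$stimulus == "rich"])
  m2 <- unique(build_schedule(cfg, 2, 7)$mouth[
    build_schedule(cfg, 2, 7)$stimulus == "rich"])
  expect_length(m1, 1)
  expect_false(m1 == m2)
  expect_error(prt_config(trials_per_block = 95),
               class = "prtddm_design_error")
})

test_that("rewards hit only correct responses at the scheduled rates", {
  cfg <- prt_config()
  set.seed(21)
  expect_false(any(assign_feedback(rep("rich", 1000), rep(FALSE, 1000), cfg)))
  n <- 20000
  r <- assign_feedback(rep("rich", n), rep(TRUE, n), cfg)
  l <- assign_feedback(rep("lean", n), rep(TRUE, n), cfg)
  ci_r <- qbinom(c(0.005, 0.995), n, 0.75) / n
  ci_l <- qbinom(c(0.005, 0.995), n, 0.25) / n
  expect_gte(mean(r), ci_r[1]); expect_lte(mean(r), ci_r[2])
  expect_gte(mean(l), ci_l[1]); expect_lte(mean(l), ci_l[2])
})

test_that("quota mode deals out exactly proportioned rewards", {
  cfg <- prt_config(reward_mode = "quota")
  set.seed(22)
  stim <- rep(c("rich", "lean"), each = 40)
  correct <- rep(TRUE, 80)
  rew <- prtddm:::assign_feedback_quota(stim, correct, cfg)
  expect_equal(sum(rew[stim == "rich"]), 30)  # 75% of 40
  expect_equal(sum(rew[stim == "lean"]), 10)  # 25% of 40
})

test_that("agents saturate, symmetrise and land in the plausible band", {
  cfg <- prt_config(n_training_trials = 0)
  bp <- data.frame(v_rich = 0, v_lean = 0, a_rich = 1.3, a_lean = 1.3,
                   t_rich = 0.28, t_lean = 0.28, z_raw = qnorm(0.99))
  heavy <- agent_spec("p1", "star", bp[rep(1, 3), ], seed = 31)
  tr <- simulate_agent(heavy, cfg)
  expect_gt(mean(tr$response == "rich"), 0.95)  # bias saturation
  # symmetric agent: equal accuracy by stimulus, up to binomial error
  bp2 <- transform(bp, v_rich = 1, v_lean = 1, z_raw = 0)
  sym <- agent_spec("p2", "star", bp2[rep(1, 3), ], seed = 32)
  tr2 <- do.call(rbind, lapply(1:8, function(i)
    simulate_agent(agent_spec(paste0("p", i), "star", bp2[rep(1, 3), ],
                              seed = 32 + i), cfg)))
  acc_rich <- mean(tr2$correct[tr2$stimulus == "rich"])
  acc_lean <- mean(tr2$correct[tr2$stimulus == "lean"])
  expect_lt(abs(acc_rich - acc_lean), 0.04)
  # drifts/boundaries of published magnitude give accuracy in the
  # 65-80% band (Monte-Carlo, ~1e4 trials)
  p <- ddm_params(v = 1.0, a = 1.3, t0 = 0.28, z_raw = 0)
  set.seed(33)
  d <- sample_ddm(p, 10000, dt = 5e-4)
  acc <- mean(d$boundary == "upper")
  expect_gt(acc, 0.65); expect_lt(acc, 0.80)
})

test_that("trial records satisfy their invariants", {
  cfg <- prt_config()
  bp <- data.frame(v_rich = 1.1, v_lean = 0.95, a_rich = 1.3, a_lean = 1.28,
                   t_rich = 0.28, t_lean = 0.28, z_raw = qnorm(0.53))
  tr <- simulate_agent(agent_spec("p9", "face", bp[rep(1, 3), ], seed = 41),
                       cfg)
  main <- tr[tr$phase == "main", ]
  expect_equal(nrow(main), 288)
  expect_equal(nrow(tr[tr$phase == "training", ]), 10)
  expect_true(all(main$rewarded[main$rewarded] &
                    main$correct[main$rewarded]))  # rewarded => correct
  expect_true(all(tr$rt > 0.28))                   # rt > non-decision time
  expect_true(all((main$response == main$stimulus) == main$correct))
  expect_gt(mean(main$rt), median(main$rt))        # right-skewed RTs
})

test_that("cohorts carry truth, balance groups, and reproduce exactly", {
  specs <- default_group_specs(c("star", "verbal"))
  co <- simulate_cohort(specs, n_per_group = 1, seed = 5)
  expect_s3_class(co, "prt_cohort")
  one <- co$trials[co$trials$participant_id == "star_001" &
                     co$trials$phase == "main", ]
  expect_equal(nrow(one), 288)
  expect_equal(nrow(co$truth), 2 * 3)
  co2 <- simulate_cohort(specs, n_per_group = 1, seed = 5)
  expect_identical(co$trials, co2$trials)  # byte-identical given seed
  expect_identical(co$truth, co2$truth)
  # invalid support rejected
  bad <- list(g = list(mean = c(1, 1, -1, 1.3, 0.3, 0.3, 0), sd = rep(0, 7)))
  expect_error(simulate_cohort(bad, 1, seed = 1), "support")
  # degenerate (zero-variance) distributions are allowed
  degen <- list(g = list(mean = c(1, 1, 1.3, 1.3, 0.3, 0.3, 0),
                         sd = rep(0, 7)))
  co3 <- simulate_cohort(degen, 1, prt_config(n_blocks = 1), seed = 2)
  expect_true(all(co3$truth$v_rich == 1))
})

test_that("groups with identical distributions are exchangeable", {
  specs <- default_group_specs(c("a", "b"))
  co <- simulate_cohort(specs, n_per_group = 6,
                        prt_config(n_training_trials = 0), seed = 6)
  m <- with(co$trials, tapply(correct, group, mean))
  expect_lt(abs(m[["a"]] - m[["b"]]), 0.02)  # < 2 percentage points
})

test_that("written cohorts round-trip through CSV with sidecar", {
  co <- simulate_cohort(default_group_specs("star"), 1,
                        prt_config(n_blocks = 1, n_training_trials = 0),
                        seed = 9)
  tmp <- file.path(tempdir(), "cohort.csv")
  paths <- write_cohort(co, tmp)
  expect_true(file.exists(paths["csv"]))
  expect_true(file.exists(paths["sidecar"]))
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(co$trials))
  expect_equal(back$rt, co$trials$rt, tolerance = 1e-6)
  side <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  expect_equal(side$seed, 9)
  expect_equal(nrow(side$truth), nrow(co$truth))
  unlink(paths)
})
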