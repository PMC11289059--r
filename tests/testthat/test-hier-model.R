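# model assembly, log-posterior, sampler, diagnostics

test_that("build_model validates its inputs and maps cells", {
  tr <- make_trials("p1", correct = rep(c(TRUE, FALSE), 24),
                    rt = runif(48, 0.4, 0.9))
  m <- build_model(tr, prior_spec(), model_spec("reduced"))
  expect_s3_class(m, "hddm_model")
  expect_equal(length(m$units), 1)
  expect_equal(nrow(m$cells), 1)
  # participant with an empty block is named in the error
  tr2 <- rbind(tr, make_trials("p2", correct = rep(TRUE, 10),
                               block = rep(2L, 10), rt = runif(10, 0.4, 0.9)))
  expect_error(build_model(tr2, prior_spec(), model_spec("reduced")),
               class = "prtddm_empty_block_error")
  expect_error(build_model(data.frame(rt = 1), prior_spec(),
                           model_spec("reduced")),
               class = "prtddm_schema_error")
})

test_that("log-posterior matches an independently assembled sum", {
  set.seed(81)
  tr <- make_trials("p1", correct = runif(40) < 0.75,
                    rt = runif(40, 0.4, 1.2))
  pr <- prior_spec()
  m <- build_model(tr, pr, model_spec("reduced"))
  th <- matrix(c(1.1, 0.9, 1.3, 1.25, 0.25, 0.27, 0.1), 1)
  mu <- matrix(c(1.0, 1.0, 1.3, 1.3, 0.3, 0.3, 0.0), 1)
  sg <- matrix(rep(0.3, 7), 1)
  lp <- log_posterior(m, list(theta = th, mu = mu, sigma = sg))
  expect_true(is.finite(lp))

  # oracle: per-trial wfpt_logpdf + explicit prior terms
  ll <- 0
  for (i in seq_len(nrow(tr))) {
    rich <- tr$stimulus[i] == "rich"
    p <- ddm_params(v = if (rich) th[1] else th[2],
                    a = if (rich) th[3] else th[4],
                    t0 = if (rich) th[5] else th[6],
                    z_raw = if (rich) th[7] else -th[7])
    ll <- ll + wfpt_logpdf(tr$rt[i], if (tr$correct[i]) "upper" else "lower", p)
  }
  lo <- c(-Inf, -Inf, 0, 0, 0, 0, -4); hi <- c(Inf, Inf, Inf, Inf, 1, 1, 4)
  for (j in 1:7) {
    zc <- pnorm(hi[j], mu[j], sg[j]) - pnorm(lo[j], mu[j], sg[j])
    ll <- ll + dnorm(th[j], mu[j], sg[j], log = TRUE) - log(zc)
    ll <- ll + log(2) - log(pi * pr$sd_scale * (1 + (sg[j] / pr$sd_scale)^2))
  }
  ll <- ll + dnorm(mu[1], 0, 10, log = TRUE) + dnorm(mu[2], 0, 10, log = TRUE)
  ll <- ll - log(diff(pr$a_bounds)) * 2 - log(diff(pr$t_bounds)) * 2 -
    log(diff(pr$zraw_bounds))
  expect_equal(lp, ll, tolerance = 1e-10)
})

test_that("duplicating a participant's trials adds exactly the likelihood", {
  set.seed(82)
  tr <- make_trials("p1", correct = runif(30) < 0.7, rt = runif(30, 0.4, 1))
  m1 <- build_model(tr, prior_spec(), model_spec("reduced"))
  m2 <- build_model(rbind(tr, tr), prior_spec(), model_spec("reduced"))
  st <- list(theta = matrix(c(1, 1, 1.3, 1.3, 0.25, 0.25, 0), 1),
             mu = matrix(c(1, 1, 1.3, 1.3, 0.3, 0.3, 0), 1),
             sigma = matrix(rep(0.3, 7), 1))
  lp1 <- log_posterior(m1, st)
  lp2 <- log_posterior(m2, st)
  # likelihood-only value via a zero-trial comparison
  m0 <- build_model(NULL, prior_spec(), model_spec("reduced"),
                    prior_only = TRUE)
  lik <- lp1 - log_posterior(m0, st)
  expect_equal(lp2 - lp1, lik, tolerance = 1e-9)
})

test_that("fits are deterministic given the seed", {
  f1 <- tiny_fit()
  truth <- recovery_truth(n_agents = 3, n_blocks = 1, seed = 11)
  cfg <- prt_config(n_blocks = 1, trials_per_block = 48,
                    n_training_trials = 0)
  co <- simulate_from_truth(truth, cfg, seed = 12)
  fl <- filter_rts(co$trials)
  m <- build_model(fl$trials, prior_spec(),
                   model_spec("reduced", warmup = 150, draws = 150, thin = 4))
  f2 <- suppressWarnings(fit_hddm(m, seed = 13))
  expect_identical(f1$draws, f2$draws)
})

test_that("draws respect every truncation bound", {
  fit <- tiny_fit()
  d <- fit$draws
  nm <- dimnames(d)[[3]]
  expect_true(all(d[, , grepl("a_rich|a_lean", nm) & grepl("theta", nm)] > 0))
  tt <- d[, , grepl("theta.*t_", nm)]
  expect_true(all(tt >= 0 & tt <= 1))
  zz <- d[, , grepl("z_raw", nm) & grepl("theta", nm)]
  expect_true(all(zz >= -4 & zz <= 4))
  expect_true(all(d[, , grepl("sigma", nm)] > 0))
})

test_that("a prior-only fit centres the group drift on zero", {
  m <- build_model(NULL, prior_spec(), model_spec("reduced"),
                   prior_only = TRUE)
  fit <- suppressWarnings(
    fit_hddm(m, seed = 5, spec = model_spec("reduced", warmup = 400,
                                            draws = 800, thin = 8)))
  mu_v <- fit$draws[, , "mu[prior,1,v_rich]"]
  expect_lt(abs(mean(mu_v)), 2.5)  # prior sd is 10; MC error band
  expect_gt(sd(mu_v), 5)           # spread reflects the wide prior
})

test_that("point estimates map the bias and mirror constant draws", {
  fit <- tiny_fit()
  est <- suppressWarnings(extract_subject_params(fit))
  expect_true(all(est$z_rich > 0 & est$z_rich < 1))
  expect_identical(est$z_lean, 1 - est$z_rich)
  expect_setequal(names(est),
                  c("participant_id", "group", "block", "v_rich", "v_lean",
                    "a_rich", "a_lean", "t_rich", "t_lean", "z_rich",
                    "z_lean"))
  # constant draws give back the constant
  fake <- fit
  fake$draws[, , "theta[sim_001,1,v_rich]"] <- 0.77
  fake$diagnostics$converged <- TRUE
  est2 <- extract_subject_params(fake)
  expect_equal(est2$v_rich[est2$participant_id == "sim_001"], 0.77)
})

test_that("R-hat detects mixing and matches the reference implementation", {
  set.seed(91)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_equal(rhat(iid), 1, tolerance = 0.02)
  expect_equal(rhat(iid, method = "classic"), 1, tolerance = 0.02)
  consts <- cbind(rep(0, 100), rep(5, 100))
  expect_gt(rhat(consts, method = "classic"), 1.1)
  expect_gt(rhat(consts), 1.1)
  expect_error(rhat(matrix(rnorm(100), 100, 1)),
               class = "prtddm_chains_error")
  # frozen cross-library oracle (arviz 0.23.4) on a fixed seeded matrix
  set.seed(42)
  m <- matrix(rnorm(400), 100, 4)
  m[, 2] <- m[, 2] + 0.3
  expect_equal(rhat(m, method = "rank"), 1.0013137958937328,
               tolerance = 1e-9)
  expect_equal(rhat(m, method = "classic"), 0.9972840789758092,
               tolerance = 1e-9)
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(92)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_gt(ess_basic(iid), 2000)
  ar <- matrix(0, 1000, 4)  # strongly autocorrelated chains
  for (j in 1:4) {
    x <- numeric(1000); for (i in 2:1000) x[i] <- 0.95 * x[i - 1] + rnorm(1)
    ar[, j] <- x
  }
  expect_lt(ess_basic(ar), 500)
})

test_that("few-trial individuals are shrunk toward the group mean", {
  set.seed(93)
  cfg <- prt_config(n_blocks = 1, trials_per_block = 48,
                    n_training_trials = 0)
  base <- data.frame(v_rich = 1.0, v_lean = 1.0, a_rich = 1.3, a_lean = 1.3,
                     t_rich = 0.28, t_lean = 0.28, z_raw = 0)
  trials <- do.call(rbind, lapply(1:5, function(i)
    simulate_agent(agent_spec(sprintf("g%02d", i), "g", base, seed = 200 + i),
                   cfg)))
  # one agent with an extreme drift but only 24 trials
  few_cfg <- prt_config(n_blocks = 1, trials_per_block = 24,
                        n_training_trials = 0)
  few <- simulate_agent(agent_spec("few", "g",
                                   transform(base, v_rich = 3.0, v_lean = 3.0),
                                   seed = 299), few_cfg)
  all_tr <- filter_rts(rbind(trials, few))$trials
  m <- build_model(all_tr, prior_spec(),
                   model_spec("reduced", warmup = 300, draws = 300, thin = 8))
  fit <- suppressWarnings(fit_hddm(m, seed = 94))
  est <- suppressWarnings(extract_subject_params(fit))
  post_few <- est$v_rich[est$participant_id == "few"]
  group_mean <- mean(fit$draws[, , "mu[g,1,v_rich]"])
  # trial-only ML estimate with the same free parameters as the model
  d <- all_tr[all_tr$participant_id == "few", ]
  nll <- function(th) {
    if (any(th[3:4] <= 0) || any(th[5:6] < 0) || abs(th[7]) > 4)
      return(1e10)
    tot <- 0
    for (i in seq_len(nrow(d))) {
      rich <- d$stimulus[i] == "rich"
      l <- tryCatch(wfpt_logpdf(
        d$rt[i], if (d$correct[i]) "upper" else "lower",
        ddm_params(v = th[if (rich) 1 else 2], a = th[if (rich) 3 else 4],
                   t0 = th[if (rich) 5 else 6],
                   z_raw = if (rich) th[7] else -th[7])),
        error = function(e) -Inf)
      if (!is.finite(l)) return(1e10)
      tot <- tot - l
    }
    tot
  }
  mle <- optim(c(1, 1, 1.3, 1.3, 0.25, 0.25, 0), nll,
               control = list(maxit = 3000))$par[1]
  expect_lt(abs(post_few - group_mean), abs(mle - group_mean))
})
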