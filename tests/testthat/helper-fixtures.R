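# shared fixtures built in code

# a typical mid-range parameter set
fix_params <- function(v = 1, a = 1.3, t0 = 0.3, z_raw = 0)
  ddm_params(v = v, a = a, t0 = t0, z_raw = z_raw)

# numerical integral of the full WFPT density (upper + lower)
wfpt_total_mass <- function(params, upper_only = FALSE) {
  iu <- integrate(function(t) wfpt_pdf(t, "upper", params),
                  params$t0, Inf, rel.tol = 1e-8)$value
  if (upper_only) return(iu)
  il <- integrate(function(t) wfpt_pdf(t, "lower", params),
                  params$t0, Inf, rel.tol = 1e-8)$value
  iu + il
}

# small trial table for preprocessing tests: one participant with given
# per-trial correctness/response/rt vectors
make_trials <- function(id, correct, response = NULL, rt = NULL,
                        stimulus = NULL, block = NULL, group = "star") {
  n <- length(correct)
  if (is.null(stimulus)) stimulus <- rep(c("rich", "lean"), length.out = n)
  if (is.null(response))
    response <- ifelse(correct, stimulus,
                       ifelse(stimulus == "rich", "lean", "rich"))
  if (is.null(rt)) rt <- rep(0.5, n)
  if (is.null(block)) block <- rep(1L, n)
  data.frame(participant_id = id, group = group, phase = "main",
             block = block, trial_index = seq_len(n), stimulus = stimulus,
             mouth = "short", response = response, correct = correct,
             rewarded = FALSE, rt = rt, stringsAsFactors = FALSE)
}

# contingency table literal
ct <- function(rc, ri, lc, li)
  structure(c(rich_correct = rc, rich_incorrect = ri,
              lean_correct = lc, lean_incorrect = li),
            class = "contingency_table")

# a tiny fitted model for structural tests (cached per session)
tiny_fit_cache <- new.env()
tiny_fit <- function() {
  if (!is.null(tiny_fit_cache$fit)) return(tiny_fit_cache$fit)
  truth <- recovery_truth(n_agents = 3, n_blocks = 1, seed = 11)
  cfg <- prt_config(n_blocks = 1, trials_per_block = 48,
                    n_training_trials = 0)
  co <- simulate_from_truth(truth, cfg, seed = 12)
  fl <- filter_rts(co$trials)
  m <- build_model(fl$trials, prior_spec(),
                   model_spec("reduced", warmup = 150, draws = 150, thin = 4))
  fit <- suppressWarnings(fit_hddm(m, seed = 13))
  tiny_fit_cache$fit <- fit
  fit
}
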