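#' Prior hyperparameters of the hierarchical DDM
#'
#' Group-level means for boundary separation, non-decision time and raw
#' starting bias carry uniform priors on the stated intervals (these
#' intervals double as hard initialisation ranges); group-level drift
#' means are normal with location 0 and scale 10; all group-level
#' standard deviations are half-Cauchy with scale 2.5. Individual
#' parameters are normal around their group mean, truncated to the
#' supports `a > 0`, `t0` in \[0, 1\], `z_raw` in \[-4, 4\] (drift is
#' unbounded).
#'
#' @param a_bounds,t_bounds,zraw_bounds group-level uniform prior bounds.
#' @param v_prior_mean,v_prior_sd normal prior on group drift means.
#' @param sd_scale half-Cauchy scale of the group SD priors.
#' @return a list of class `prior_spec`.
#' @export
prior_spec <- function(a_bounds = c(0.1, 10), t_bounds = c(0.1, 1),
                       zraw_bounds = c(-4, 4),
                       v_prior_mean = 0, v_prior_sd = 10,
                       sd_scale = 2.5) {
  stopifnot(a_bounds[1] < a_bounds[2], t_bounds[1] < t_bounds[2],
            zraw_bounds[1] < zraw_bounds[2], v_prior_sd > 0, sd_scale > 0)
  structure(list(a_bounds = a_bounds, t_bounds = t_bounds,
                 zraw_bounds = zraw_bounds, v_prior_mean = v_prior_mean,
                 v_prior_sd = v_prior_sd, sd_scale = sd_scale),
            class = "prior_spec")
}

#' MCMC and structural settings of the hierarchical DDM
#'
#' Parameters are estimated for each participant and block separately;
#' group-level distributions are specific to each feedback-type-by-block
#' cell. Drift, boundary and non-decision time are split by rich/lean
#' trials; the starting bias for lean trials is the complement of the
#' rich-trial bias, z(lean) = 1 - z(rich), so a single raw bias per block
#' is estimated.
#'
#' @param preset "paper" (4 chains, 2000 warmup, 2000 draws) or "reduced"
#'   (2 chains, 500/500) for tests and recovery runs.
#' @param chains,warmup,draws override the preset.
#' @param thin full Gibbs sweeps per stored draw. Random-walk
#'   Metropolis-within-Gibbs moves more slowly per sweep than the
#'   gradient-based samplers usually used for this model, so each kept
#'   draw summarises several sweeps; `warmup` and `draws` count kept
#'   draws.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(preset = c("paper", "reduced"),
                       chains = NULL, warmup = NULL, draws = NULL,
                       thin = 8) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") c(4L, 2000L, 2000L) else c(2L, 500L, 500L)
  chains <- if (is.null(chains)) def[1] else as.integer(chains)
  warmup <- if (is.null(warmup)) def[2] else as.integer(warmup)
  draws <- if (is.null(draws)) def[3] else as.integer(draws)
  if (chains < 2) stop("at least 2 chains are required for diagnostics")
  stopifnot(warmup >= 0, draws >= 1, thin >= 1)
  structure(list(preset = preset, chains = chains, warmup = warmup,
                 draws = draws, thin = as.integer(thin)),
            class = "model_spec")
}

PARAM_NAMES <- c("v_rich", "v_lean", "a_rich", "a_lean",
                 "t_rich", "t_lean", "z_raw")
IND_LO <- c(-Inf, -Inf, 0, 0, 0, 0, -4)
IND_HI <- c(Inf, Inf, Inf, Inf, 1, 1, 4)

#' Build the hierarchical DDM from a preprocessed trial table
#'
#' Assembles the per-(participant, block) trial data in accuracy coding
#' (the upper boundary is the correct response; the accumulator starts at
#' `Phi(z_raw)` on rich trials, `1 - Phi(z_raw)` on lean trials), the
#' participant-to-cell mapping (cell = feedback type x block), and the
#' prior structure. The trial table must already be RT-filtered.
#'
#' @param trials preprocessed trial table (columns `participant_id`,
#'   `group`, `block`, `stimulus`, `correct`, `rt`), or `NULL` with
#'   `prior_only = TRUE` for a data-free model.
#' @param prior a [prior_spec()].
#' @param spec a [model_spec()].
#' @param prior_only build a skeleton model with no likelihood
#'   contribution (one participant, one block).
#' @return object of class `hddm_model`.
#' @export
build_model <- function(trials, prior = prior_spec(), spec = model_spec(),
                        prior_only = FALSE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(spec, "model_spec"))
  if (prior_only || is.null(trials)) {
    unit_meta <- data.frame(participant_id = "prior", group = "prior",
                            block = 1L, stringsAsFactors = FALSE)
    units <- list(list(rt = numeric(0), upper = integer(0),
                       rich = integer(0)))
  } else {
    need <- c("participant_id", "group", "block", "stimulus", "correct", "rt")
    if (!all(need %in% names(trials)))
      stop(errorCondition(paste("missing columns:",
                                paste(setdiff(need, names(trials)), collapse = ", ")),
                          class = c("prtddm_schema_error", "error", "condition")))
    if ("phase" %in% names(trials)) trials <- trials[trials$phase == "main", ]
    blocks <- sort(unique(trials$block))
    ids <- unique(trials$participant_id)
    grid <- expand.grid(block = blocks, participant_id = ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    empty <- character(0)
    units <- vector("list", nrow(grid))
    grp <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      d <- trials[trials$participant_id == grid$participant_id[i] &
                    trials$block == grid$block[i], ]
      if (nrow(d) == 0) {
        empty <- c(empty, sprintf("%s/block %s", grid$participant_id[i],
                                  grid$block[i]))
        next
      }
      units[[i]] <- list(rt = as.numeric(d$rt),
                         upper = as.integer(d$correct),
                         rich = as.integer(d$stimulus == "rich"))
      grp[i] <- d$group[1]
    }
    if (length(empty))
      stop(errorCondition(
        paste("participants with empty blocks:", paste(empty, collapse = ", ")),
        class = c("prtddm_empty_block_error", "error", "condition")))
    unit_meta <- data.frame(participant_id = grid$participant_id,
                            group = grp, block = grid$block,
                            stringsAsFactors = FALSE)
  }
  cells <- unique(unit_meta[, c("group", "block")])
  rownames(cells) <- NULL
  cell_of <- match(paste(unit_meta$group, unit_meta$block),
                   paste(cells$group, cells$block))
  structure(list(units = units, unit_meta = unit_meta, cells = cells,
                 cell_of = as.integer(cell_of), prior = prior, spec = spec,
                 prior_only = prior_only || is.null(trials)),
            class = "hddm_model")
}

# flat parameter names in the order the C++ sampler stores them
hddm_param_names <- function(model) {
  um <- model$unit_meta
  ind <- as.vector(t(outer(seq_len(nrow(um)), PARAM_NAMES, function(i, p)
    sprintf("theta[%s,%s,%s]", um$participant_id[i], um$block[i], p))))
  cells <- model$cells
  mu <- as.vector(t(outer(seq_len(nrow(cells)), PARAM_NAMES, function(i, p)
    sprintf("mu[%s,%s,%s]", cells$group[i], cells$block[i], p))))
  sg <- as.vector(t(outer(seq_len(nrow(cells)), PARAM_NAMES, function(i, p)
    sprintf("sigma[%s,%s,%s]", cells$group[i], cells$block[i], p))))
  c(ind, mu, sg)
}

#' Log-posterior of the hierarchical DDM at a parameter point
#'
#' Sum of the per-trial WFPT log-likelihoods, the individual-level
#' truncated-normal log-priors, and the group-level log-priors. Useful
#' for validating the model assembly independently of the sampler.
#'
#' @param model an [build_model()] object.
#' @param state list with matrices `theta` (units x 7), `mu` and `sigma`
#'   (cells x 7); columns ordered `v_rich, v_lean, a_rich, a_lean,
#'   t_rich, t_lean, z_raw`.
#' @return a single log-posterior value (may be `-Inf`).
#' @export
log_posterior <- function(model, state) {
  stopifnot(inherits(model, "hddm_model"))
  th <- state$theta; mu <- state$mu; sg <- state$sigma
  U <- length(model$units); C <- nrow(model$cells)
  stopifnot(nrow(th) == U, nrow(mu) == C, nrow(sg) == C, ncol(th) == 7)
  pr <- model$prior
  lp <- 0
  mu_lo <- c(-Inf, -Inf, pr$a_bounds[1], pr$a_bounds[1],
             pr$t_bounds[1], pr$t_bounds[1], pr$zraw_bounds[1])
  mu_hi <- c(Inf, Inf, pr$a_bounds[2], pr$a_bounds[2],
             pr$t_bounds[2], pr$t_bounds[2], pr$zraw_bounds[2])
  for (c_i in seq_len(C)) {
    for (j in 1:7) {
      m <- mu[c_i, j]; s <- sg[c_i, j]
      if (s <= 0) return(-Inf)
      if (j <= 2) {
        lp <- lp + dnorm(m, pr$v_prior_mean, pr$v_prior_sd, log = TRUE)
      } else {
        if (m < mu_lo[j] || m > mu_hi[j]) return(-Inf)
        lp <- lp - log(mu_hi[j] - mu_lo[j])
      }
      lp <- lp + log(2) - log(pi * pr$sd_scale * (1 + (s / pr$sd_scale)^2))
    }
  }
  for (u in seq_len(U)) {
    c_i <- model$cell_of[u]
    for (j in 1:7) {
      x <- th[u, j]
      if (x < IND_LO[j] || x > IND_HI[j]) return(-Inf)
      z <- pnorm(IND_HI[j], mu[c_i, j], sg[c_i, j]) -
        pnorm(IND_LO[j], mu[c_i, j], sg[c_i, j])
      lp <- lp + dnorm(x, mu[c_i, j], sg[c_i, j], log = TRUE) - log(z)
    }
    dat <- model$units[[u]]
    if (length(dat$rt) == 0) next
    zmap <- pnorm(th[u, 7])
    for (cond in c(1, 0)) {
      idx <- dat$rich == cond
      if (!any(idx)) next
      v <- th[u, if (cond) 1 else 2]; a <- th[u, if (cond) 3 else 4]
      t0 <- th[u, if (cond) 5 else 6]
      w <- if (cond) zmap else 1 - zmap
      ll <- .wfpt_loglik_sum_cpp(dat$rt[idx], dat$upper[idx], v, a, t0, w,
                                 1.0, 1e-7)
      if (!is.finite(ll)) return(-Inf)
      lp <- lp + ll
    }
  }
  lp
}

# initial values for one chain; drawn from the current RNG state
hddm_init <- function(model) {
  U <- length(model$units); C <- nrow(model$cells)
  th <- matrix(NA_real_, U, 7)
  for (u in seq_len(U)) {
    dat <- model$units[[u]]
    min_rich <- if (any(dat$rich == 1)) min(dat$rt[dat$rich == 1]) else 1
    min_lean <- if (any(dat$rich == 0)) min(dat$rt[dat$rich == 0]) else 1
    th[u, ] <- c(runif(2, 0.3, 1.5),
                 runif(2, 0.9, 1.7),
                 min(0.9, 0.5 * min_rich) * runif(1, 0.6, 1.0),
                 min(0.9, 0.5 * min_lean) * runif(1, 0.6, 1.0),
                 runif(1, -0.3, 0.3))
  }
  mu <- matrix(NA_real_, C, 7); sg <- matrix(NA_real_, C, 7)
  for (c_i in seq_len(C)) {
    in_cell <- model$cell_of == c_i
    mu[c_i, ] <- colMeans(th[in_cell, , drop = FALSE])
    mu[c_i, 3:4] <- pmax(mu[c_i, 3:4], model$prior$a_bounds[1] + 0.01)
    mu[c_i, 5:6] <- pmin(pmax(mu[c_i, 5:6], model$prior$t_bounds[1] + 0.01),
                         model$prior$t_bounds[2] - 0.01)
    sg[c_i, ] <- runif(7, 0.15, 0.5)
  }
  list(theta = th, mu = mu, sigma = sg)
}

#' Fit the hierarchical DDM by MCMC
#'
#' Runs `spec$chains` independent chains of an adaptive
#' Metropolis-within-Gibbs sampler (random-walk proposals per parameter,
#' step sizes tuned to ~44% acceptance during warmup and frozen after).
#' Draws respect all truncation bounds by construction. Deterministic
#' given `seed`.
#'
#' @param model an [build_model()] object.
#' @param seed integer seed.
#' @param spec optional [model_spec()] overriding the one in `model`.
#' @return object of class `hddm_fit`: `draws` (array iterations x
#'   chains x parameters, with parameter dimnames), `diagnostics` (R-hat
#'   and effective sample size per parameter, `max_rhat`, `converged`),
#'   `model`, `seed`.
#' @export
fit_hddm <- function(model, seed = 1, spec = NULL) {
  stopifnot(inherits(model, "hddm_model"))
  if (is.null(spec)) spec <- model$spec
  pr <- model$prior
  prior_list <- list(v_prior_sd = pr$v_prior_sd, sd_scale = pr$sd_scale,
                     mu_lo = c(-Inf, -Inf, pr$a_bounds[1], pr$a_bounds[1],
                               pr$t_bounds[1], pr$t_bounds[1],
                               pr$zraw_bounds[1]),
                     mu_hi = c(Inf, Inf, pr$a_bounds[2], pr$a_bounds[2],
                               pr$t_bounds[2], pr$t_bounds[2],
                               pr$zraw_bounds[2]))
  pnames <- hddm_param_names(model)
  draws <- array(NA_real_, c(spec$draws, spec$chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  base <- (abs(as.integer(seed)) %% 2000000L) * 1000L
  for (ch in seq_len(spec$chains)) {
    set.seed(base + ch)
    init <- hddm_init(model)
    res <- .hddm_chain_cpp(model$units, model$cell_of - 1L,
                           nrow(model$cells), init$theta, init$mu,
                           init$sigma, prior_list, spec$warmup, spec$draws,
                           if (is.null(spec$thin)) 1L else spec$thin,
                           1.0, 1e-7)
    draws[, ch, ] <- res$draws
  }
  if (any(!is.finite(draws)))
    stop("sampler produced non-finite draws")
  # stuck chains are a sampler failure, never silent
  if (spec$draws >= 100) {
    stuck <- apply(draws, 3, function(m) any(apply(m, 2, function(x)
      max(x) == min(x))))
    if (any(stuck))
      stop(errorCondition(
        paste("sampler failure: no accepted proposals for",
              paste(utils::head(pnames[stuck], 5), collapse = ", ")),
        class = c("prtddm_sampler_error", "error", "condition")))
  }
  check_truncation(draws, pnames)
  rh <- apply(draws, 3, function(m) rhat(m))
  es <- apply(draws, 3, function(m) ess_basic(m))
  diagnostics <- list(rhat = setNames(rh, pnames), ess = setNames(es, pnames),
                      max_rhat = max(rh), converged = max(rh) <= 1.01)
  structure(list(draws = draws, diagnostics = diagnostics, model = model,
                 seed = seed, spec = spec),
            class = "hddm_fit")
}

check_truncation <- function(draws, pnames) {
  kind <- sub("^(theta|mu|sigma)\\[.*,(\\w+)\\]$", "\\1.\\2", pnames)
  for (i in seq_along(pnames)) {
    x <- draws[, , i]
    p <- kind[i]
    bad <- switch(sub("\\..*$", "", p),
                  theta = switch(sub("^.*\\.", "", p),
                                 a_rich = , a_lean = any(x <= 0),
                                 t_rich = , t_lean = any(x < 0 | x > 1),
                                 z_raw = any(x < -4 | x > 4),
                                 FALSE),
                  sigma = any(x <= 0),
                  FALSE)
    if (isTRUE(bad))
      stop("draws violate truncation bounds for ", pnames[i])
  }
  invisible(TRUE)
}

#' Posterior point estimates per participant, block and condition
#'
#' Posterior means of the individual-level parameters, with the starting
#' bias reported on the mapped (0, 1) scale: `z_rich` is the posterior
#' mean of `Phi(z_raw)` and `z_lean = 1 - z_rich` exactly.
#'
#' @param fit an [fit_hddm()] result.
#' @return data.frame with one row per (participant, block):
#'   `participant_id`, `group`, `block`, `v_rich`, `v_lean`, `a_rich`,
#'   `a_lean`, `t_rich`, `t_lean`, `z_rich`, `z_lean`.
#' @export
extract_subject_params <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!fit$diagnostics$converged)
    warning("fit has max R-hat ", round(fit$diagnostics$max_rhat, 3),
            " > 1.01: estimates may be unreliable")
  um <- fit$model$unit_meta
  out <- um
  for (p in PARAM_NAMES) {
    vals <- vapply(seq_len(nrow(um)), function(i) {
      nm <- sprintf("theta[%s,%s,%s]", um$participant_id[i], um$block[i], p)
      d <- fit$draws[, , nm]
      if (p == "z_raw") mean(pnorm(d)) else mean(d)
    }, numeric(1))
    out[[if (p == "z_raw") "z_rich" else p]] <- vals
  }
  out$z_lean <- 1 - out$z_rich
  out
}

#' Potential scale reduction factor (R-hat)
#'
#' Split-chain R-hat: each chain is halved, and the Gelman-Rubin
#' between/within-variance ratio computed over the resulting half-chains.
#' The default rank-normalises the draws first (and takes the maximum
#' with the folded version, which is sensitive to scale differences);
#' `method = "classic"` gives the original statistic on the raw draws.
#'
#' @param draws matrix (iterations x chains) or 3-d array (iterations x
#'   chains x parameters).
#' @param method "rank" or "classic".
#' @return a single R-hat, or a named vector for an array input.
#' @export
rhat <- function(draws, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (length(dim(draws)) == 3)
    return(apply(draws, 3, rhat, method = method))
  m <- as.matrix(draws)
  if (ncol(m) < 2)
    stop(errorCondition("R-hat requires at least 2 chains",
                        class = c("prtddm_chains_error", "error", "condition")))
  n2 <- floor(nrow(m) / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[1:n2, j], m[(nrow(m) - n2 + 1):nrow(m), j])))
  if (method == "classic") return(rhat_basic(split))
  bulk <- rhat_basic(zscale(split))
  folded <- rhat_basic(zscale(abs(split - stats::median(split))))
  max(bulk, folded)
}

# classic split-Rhat on a (n x chains) matrix
rhat_basic <- function(m) {
  n <- nrow(m)
  if (stats::var(as.vector(m)) == 0) return(1)
  means <- colMeans(m)
  B <- n * stats::var(means)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# rank-normalisation (fractional offset 3/8)
zscale <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

#' Effective sample size (basic)
#'
#' Autocorrelation-based ESS pooled over split chains, using Geyer's
#' initial positive sequence to truncate the autocorrelation sum.
#'
#' @inheritParams rhat
#' @return estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  if (length(dim(draws)) == 3) return(apply(draws, 3, ess_basic))
  m <- as.matrix(draws)
  n <- nrow(m); nch <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(n * nch)
  W <- mean(apply(m, 2, stats::var))
  B <- if (nch > 1) n * stats::var(colMeans(m)) else 0
  varplus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariance
  max_lag <- min(n - 1, 1000)
  acov <- sapply(seq_len(nch), function(j) {
    x <- m[, j] - mean(m[, j])
    stats::acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1, 1]
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov) / varplus
  # Geyer initial positive sequence over lag pairs
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(1, n * nch / tau)
}
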