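#' DDM parameter set for one condition
#'
#' Bundles the four drift-diffusion parameters governing evidence
#' accumulation in one condition: drift rate `v` (evidence units per
#' second, signed), boundary separation `a` (> 0), non-decision time `t0`
#' (seconds, in \[0, 1\]), and the starting bias `z_raw` on the
#' unconstrained \[-4, 4\] scale, mapped to a relative start point in
#' (0, 1) by the standard-normal CDF (see [map_bias()]). The diffusion
#' scale `s` is a fixed convention (1.0 here; 0.1 in some older DDM
#' literature) and must be held constant within an analysis.
#'
#' @param v drift rate.
#' @param a boundary separation, must be positive.
#' @param t0 non-decision time in seconds, in \[0, 1\].
#' @param z_raw starting bias on the unconstrained scale, in \[-4, 4\].
#' @param s diffusion scale constant.
#' @return an object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1, a = 1.3, t0 = 0.3, z_raw = 0)
#' map_bias(p$z_raw)  # 0.5: unbiased start
#' @export
ddm_params <- function(v, a, t0, z_raw = 0, s = 1.0) {
  p <- structure(list(v = v, a = a, t0 = t0, z_raw = z_raw, s = s),
                 class = "ddm_params")
  validate_ddm_params(p)
}

#' Validate DDM parameters
#'
#' Enforces the truncation bounds of the model: `a > 0`, `t0` in \[0, 1\]
#' (closed), `z_raw` in \[-4, 4\] (closed), `s > 0`. Each violated bound
#' raises its own error condition class so callers can distinguish them.
#'
#' @param p a `ddm_params` object or a list with fields v, a, t0, z_raw, s.
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_ddm_params <- function(p) {
  stopifnot(is.list(p))
  for (f in c("v", "a", "t0", "z_raw", "s")) {
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || length(p[[f]]) != 1 ||
        is.na(p[[f]]))
      stop(errorCondition(sprintf("DDM parameter '%s' missing or not a number", f),
                          class = c("prtddm_param_error", "error", "condition")))
  }
  if (p$a <= 0)
    stop(errorCondition("boundary separation 'a' must be positive",
                        class = c("prtddm_boundary_error", "prtddm_param_error",
                                  "error", "condition")))
  if (p$t0 < 0 || p$t0 > 1)
    stop(errorCondition("non-decision time 't0' must lie in [0, 1] seconds",
                        class = c("prtddm_ndt_error", "prtddm_param_error",
                                  "error", "condition")))
  if (p$z_raw < -4 || p$z_raw > 4)
    stop(errorCondition("starting bias 'z_raw' must lie in [-4, 4]",
                        class = c("prtddm_bias_error", "prtddm_param_error",
                                  "error", "condition")))
  if (p$s <= 0)
    stop(errorCondition("diffusion scale 's' must be positive",
                        class = c("prtddm_scale_error", "prtddm_param_error",
                                  "error", "condition")))
  invisible(p)
}

#' Map the raw starting bias to a probability
#'
#' The starting bias is estimated on an unconstrained \[-4, 4\] scale and
#' mapped to the (0, 1) relative start point of the diffusion process by
#' the cumulative distribution function of the standard normal (Phi).
#' `map_bias(0)` is 0.5 (no bias); values above 0.5 start the accumulator
#' closer to the rich-response boundary.
#'
#' @param z_raw numeric vector in \[-4, 4\].
#' @return Phi(z_raw), a vector of probabilities in (0, 1).
#' @examples
#' map_bias(0)            # 0.5
#' map_bias(c(-1, 1))     # sums to 1 by symmetry
#' @export
map_bias <- function(z_raw) {
  if (any(!is.finite(z_raw)) || any(z_raw < -4) || any(z_raw > 4))
    stop(errorCondition("z_raw out of range [-4, 4]",
                        class = c("prtddm_bias_error", "error", "condition")))
  pnorm(z_raw)
}

#' Options for the WFPT density evaluation
#'
#' @param tolerance absolute error bound on the density used to choose the
#'   truncation depth of the small-time/large-time series expansions.
#' @param min_rt_gap smallest admissible `rt - t0` gap treated as a valid
#'   decision time; smaller gaps have zero likelihood.
#' @return a list of class `wfpt_options`.
#' @export
wfpt_options <- function(tolerance = 1e-7, min_rt_gap = 1e-6) {
  stopifnot(tolerance > 0, min_rt_gap >= 0)
  structure(list(tolerance = tolerance, min_rt_gap = min_rt_gap),
            class = "wfpt_options")
}

#' Wiener first-passage-time log-density
#'
#' Joint log-density of hitting the given boundary at time `rt` under the
#' drift-diffusion model. The evaluation switches between the small-time
#' and large-time series expansions of the density so that the absolute
#' density error stays below `opts$tolerance`; the upper-boundary density
#' is obtained from the lower-boundary form through the reflection
#' identity (v -> -v, z -> 1 - z).
#'
#' @param rt response time(s) in seconds; must exceed `params$t0`.
#' @param boundary "upper" or "lower" (recycled along `rt`). Under
#'   accuracy coding the upper boundary is the correct response.
#' @param params a [ddm_params()] object.
#' @param opts a [wfpt_options()] object.
#' @return vector of log-densities.
#' @examples
#' p <- ddm_params(v = 1, a = 1.3, t0 = 0.3, z_raw = 0)
#' wfpt_logpdf(0.6, "upper", p)
#' @export
wfpt_logpdf <- function(rt, boundary, params, opts = wfpt_options()) {
  validate_ddm_params(params)
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = FALSE)
  if (any(rt <= params$t0 + opts$min_rt_gap))
    stop(errorCondition(
      "rt at or below the non-decision time: the likelihood is zero there",
      class = c("prtddm_rt_error", "error", "condition")))
  # reflection on the raw-bias scale keeps the lower/upper identity exact
  v <- if (boundary == "upper") -params$v else params$v
  w <- if (boundary == "upper") map_bias(-params$z_raw)
       else map_bias(params$z_raw)
  .wfpt_logpdf_cpp(as.numeric(rt), rep.int(0L, length(rt)),
                   v, params$a, params$t0, w, params$s, opts$tolerance)
}

#' WFPT density (natural scale)
#'
#' Convenience wrapper around [wfpt_logpdf()] that returns 0 (instead of
#' raising) for `rt <= t0`, which makes it directly integrable.
#'
#' @inheritParams wfpt_logpdf
#' @return vector of densities.
#' @export
wfpt_pdf <- function(rt, boundary, params, opts = wfpt_options()) {
  validate_ddm_params(params)
  boundary <- match.arg(boundary, c("upper", "lower"))
  v <- if (boundary == "upper") -params$v else params$v
  w <- if (boundary == "upper") map_bias(-params$z_raw)
       else map_bias(params$z_raw)
  out <- numeric(length(rt))
  ok <- rt > params$t0 + opts$min_rt_gap
  if (any(ok)) {
    lg <- .wfpt_logpdf_cpp(as.numeric(rt[ok]), rep.int(0L, sum(ok)),
                           v, params$a, params$t0, w, params$s,
                           opts$tolerance)
    out[ok] <- exp(lg)
  }
  out
}

#' Sample choices and response times from the DDM
#'
#' Forward Euler-Maruyama simulation of the diffusion process: starting
#' from `a * z`, increments `v * dt + s * sqrt(dt) * N(0, 1)` accumulate
#' until a boundary is crossed; the response time is the crossing time
#' plus the non-decision time `t0`. Walks not absorbed within `tmax`
#' simulated seconds are flagged `censored` and should be excluded from
#' fits. Driven by R's RNG, so `set.seed()` makes draws reproducible.
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials to simulate.
#' @param dt Euler step in seconds (must be <= 1e-3).
#' @param tmax non-termination guard in simulated seconds.
#' @return data.frame with columns `rt` (seconds), `boundary`
#'   ("upper"/"lower") and `censored` (logical).
#' @examples
#' set.seed(1)
#' d <- sample_ddm(ddm_params(v = 2, a = 1, t0 = 0.2), n = 100)
#' mean(d$boundary == "upper")
#' @export
sample_ddm <- function(params, n, dt = 1e-4, tmax = 20) {
  validate_ddm_params(params)
  stopifnot(n >= 1, dt > 0, tmax > 0)
  if (dt > 1e-3)
    stop("Euler step dt must be at most 1e-3 s for acceptable discretisation error")
  w <- map_bias(params$z_raw)
  res <- .ddm_sample_cpp(as.integer(n), params$v, params$a, params$t0, w,
                         params$s, dt, tmax)
  data.frame(rt = res$rt,
             boundary = ifelse(res$upper == 1L, "upper", "lower"),
             censored = res$censored,
             stringsAsFactors = FALSE)
}

#' Probability of absorption at the upper boundary (closed form)
#'
#' @param params a [ddm_params()] object.
#' @return P(upper boundary hit), a single probability.
#' @export
ddm_p_upper <- function(params) {
  validate_ddm_params(params)
  .ddm_p_upper_cpp(params$v, params$a, map_bias(params$z_raw), params$s)
}
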