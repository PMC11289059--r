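# likelihood core: bias mapping, density, sampler, validation

test_that("map_bias is the standard-normal CDF with range checks", {
  expect_identical(map_bias(0), 0.5)
  # high-precision external evaluation of Phi(1) (erf-based)
  expect_equal(map_bias(1.0), 0.8413447460685429, tolerance = 1e-12)
  for (z in c(0.3, 1.7, 3.9)) # CDF symmetry
    expect_equal(map_bias(z) + map_bias(-z), 1, tolerance = 1e-12)
  expect_true(all(diff(map_bias(seq(-4, 4, by = 0.5))) > 0))
  expect_error(map_bias(4.1), class = "prtddm_bias_error")
  expect_error(map_bias(-4.0001), class = "prtddm_bias_error")
})

test_that("parameter validation enforces each truncation bound by name", {
  expect_error(ddm_params(v = 1, a = -1, t0 = 0.3),
               class = "prtddm_boundary_error")
  expect_error(ddm_params(v = 1, a = 1, t0 = 1.2),
               class = "prtddm_ndt_error")
  expect_error(ddm_params(v = 1, a = 1, t0 = 0.3, z_raw = 4.1),
               class = "prtddm_bias_error")
  expect_error(ddm_params(v = 1, a = 1, t0 = 0.3, s = 0),
               class = "prtddm_scale_error")
  # closed bounds are accepted
  expect_s3_class(ddm_params(v = 0, a = 0.5, t0 = 1.0, z_raw = 4), "ddm_params")
  expect_s3_class(ddm_params(v = 0, a = 0.5, t0 = 0, z_raw = -4), "ddm_params")
})

test_that("density normalises to 1 across a parameter grid", {
  grid <- expand.grid(v = c(-1.5, 0, 1, 2.5), a = c(0.8, 1.3, 2),
                      z_raw = c(-1, 0, 0.6))
  for (i in seq_len(nrow(grid))) {
    p <- ddm_params(grid$v[i], grid$a[i], 0.25, grid$z_raw[i])
    expect_equal(wfpt_total_mass(p), 1, tolerance = 1e-4)
  }
})

test_that("symmetric configuration splits mass 50/50", {
  p <- fix_params(v = 0, z_raw = 0)
  expect_equal(wfpt_total_mass(p, upper_only = TRUE), 0.5, tolerance = 1e-4)
})

test_that("reflection identity holds exactly", {
  rts <- c(0.35, 0.5, 0.9, 1.8)
  for (v in c(-0.8, 0.6, 2)) for (z in c(-1.2, 0.4)) {
    lo <- wfpt_logpdf(rts, "lower", fix_params(v = v, z_raw = z))
    up <- wfpt_logpdf(rts, "upper", fix_params(v = -v, z_raw = -z))
    expect_identical(lo, up)
  }
})

test_that("rt at or below non-decision time is rejected", {
  p <- fix_params(t0 = 0.3)
  expect_error(wfpt_logpdf(0.3, "upper", p), class = "prtddm_rt_error")
  expect_error(wfpt_logpdf(c(0.5, 0.2), "upper", p),
               class = "prtddm_rt_error")
  expect_identical(wfpt_pdf(0.2, "upper", p), 0)  # integrable form
})

test_that("sampler matches the density: choice probabilities and RT law", {
  p <- fix_params(v = 1, a = 1.3, t0 = 0.3, z_raw = 0.3)
  set.seed(101)
  d <- sample_ddm(p, 5000, dt = 1e-4)
  expect_true(all(d$rt > p$t0))
  expect_false(any(d$censored))
  # choice probability vs closed form and vs numerical integration
  p_up <- ddm_p_upper(p)
  expect_equal(wfpt_total_mass(p, upper_only = TRUE), p_up, tolerance = 1e-4)
  ci <- qbinom(c(0.005, 0.995), 5000, p_up) / 5000
  expect_gte(mean(d$boundary == "upper"), ci[1])
  expect_lte(mean(d$boundary == "upper"), ci[2])
  # two-sample KS against inverse-CDF draws from the density
  grid <- seq(p$t0 + 5e-4, 8, length.out = 4000)
  pdf_up <- wfpt_pdf(grid, "upper", p)
  cdf <- cumsum(pdf_up) * (grid[2] - grid[1])
  cdf <- cdf / max(cdf)
  set.seed(102)
  inv <- approx(cdf, grid, runif(5000), ties = "ordered")$y
  ks <- suppressWarnings(ks.test(d$rt[d$boundary == "upper"], inv))
  expect_gt(ks$p.value, 0.01)
})

test_that("drift dominance and monotonicity of P(upper)", {
  set.seed(103)
  d <- sample_ddm(fix_params(v = 6, a = 1), 500)
  expect_gt(mean(d$boundary == "upper"), 0.99)
  d0 <- sample_ddm(fix_params(v = 0), 2000)
  expect_equal(mean(d0$boundary == "upper"), 0.5, tolerance = 0.04)
  # strict monotonicity in v and z (closed form, cross-checked above)
  pv <- sapply(seq(-2, 2, by = 0.5), function(v)
    ddm_p_upper(fix_params(v = v)))
  pz <- sapply(seq(-2, 2, by = 0.5), function(z)
    ddm_p_upper(fix_params(v = 0.5, z_raw = z)))
  expect_true(all(diff(pv) > 0))
  expect_true(all(diff(pz) > 0))
})

test_that("density matches an Euler-simulated histogram", {
  # simulation oracle for the series expansions
  p <- fix_params(v = 1, a = 1.3, t0 = 0.3, z_raw = 0)
  set.seed(104)
  d <- sample_ddm(p, 20000, dt = 1e-4)
  up <- d$rt[d$boundary == "upper"]
  br <- seq(p$t0, 3, by = 0.1)
  h <- hist(up[up < 3], breaks = br, plot = FALSE)
  dens_pred <- sapply(seq_len(length(br) - 1), function(i)
    integrate(function(t) wfpt_pdf(t, "upper", p), br[i], br[i + 1])$value)
  # bin-wise agreement within Monte-Carlo error (3.5 sigma + small abs floor)
  n_up <- length(up)
  obs <- h$counts / n_up
  pred <- dens_pred / ddm_p_upper(p)
  se <- sqrt(pred * (1 - pred) / n_up)
  expect_true(all(abs(obs - pred) < 3.5 * se + 0.002))
})

test_that("sampler guards against invalid settings and non-termination", {
  expect_error(sample_ddm(fix_params(), 10, dt = 0.01), "dt")
  set.seed(105)  # drift toward neither boundary, tiny tmax: censoring
  d <- sample_ddm(ddm_params(v = 0, a = 30, t0 = 0), n = 5, dt = 1e-3,
                  tmax = 0.05)
  expect_true(all(d$censored))
})
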