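test_that("split R-hat behaves on reference cases", {
  set.seed(1)
  x <- rnorm(1e4)
  # two identical stationary chains
  expect_lt(abs(rhat(cbind(x, x)) - 1), 0.01)
  # degenerate separated chains: zero within-chain variance
  expect_identical(rhat(cbind(rep(0, 4), rep(1, 4))), Inf)
  expect_true(is.nan(rhat(cbind(rep(2, 4), rep(2, 4)))))
  # independent chains from the same distribution
  ch <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(rhat(ch), 1.01)
  expect_gte(rhat(ch), 1 - 1e-8)
  # clearly non-overlapping chains are flagged large
  expect_gt(rhat(cbind(rnorm(100), rnorm(100, 10))), 2)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), class = "mjmcrt_argument")
})

test_that("autocorrelation estimates match reference behaviour", {
  expect_warning(out <- acf_draws(rep(1, 50), 5), "constant")
  expect_true(all(is.nan(out)))
  alt <- rep(c(1, -1), 50)
  r <- acf_draws(alt, 2)
  expect_equal(r[1], 1)
  expect_lt(r[2], -0.9)
  set.seed(42)
  ar <- as.numeric(arima.sim(list(ar = 0.8), n = 5000))
  expect_lt(abs(acf_draws(ar, 1)[2] - 0.8), 0.05)
  expect_error(acf_draws(1:5, 10), class = "mjmcrt_argument")
})

test_that("summarize_draws applies the documented summaries and quantile rule", {
  s <- summarize_draws(matrix(1:4, ncol = 1))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(1:4))  # sample SD ~ 1.291
  s2 <- summarize_draws(matrix(1:100, ncol = 1))
  expect_equal(s2$q2.5, 3.475)   # linear-interpolation quantiles
  expect_equal(s2$q97.5, 97.525)
  s3 <- summarize_draws(matrix(rep(7, 20), ncol = 2))
  expect_equal(s3$sd, 0)
  expect_equal(s3$q2.5, 7)
  expect_equal(s3$q97.5, 7)
})

test_that("fits are bit-reproducible and carry the convergence verdict", {
  sim <- small_sim(seed = 5, L = 6, group_size = 6)
  grid <- equal_length_grid(9, 2)
  cfg <- mcmc_config(chains = 2, adapt = 100, burn_in = 100, thin = 1,
                     draws_per_chain = 50, seed = 7)
  f1 <- fit_mjm(sim$data, mjm_spec(), grid, config = cfg,
                monitor_random_effects = FALSE, compute_dic = FALSE)
  f2 <- fit_mjm(sim$data, mjm_spec(), grid, config = cfg,
                monitor_random_effects = FALSE, compute_dic = FALSE)
  expect_identical(f1$draws$draws, f2$draws$draws)
  expect_type(f1$convergence$converged, "logical")
  expect_true(all(c("alpha", "time:treatment", "sigma_v", "sigma_g", "sigma_eps")
                  %in% names(f1$convergence$rhat)))
  f3 <- fit_mjm(sim$data, mjm_spec(), grid,
                config = mcmc_config(chains = 2, adapt = 100, burn_in = 100,
                                     thin = 1, draws_per_chain = 50, seed = 8),
                monitor_random_effects = FALSE, compute_dic = FALSE)
  expect_false(identical(f1$draws$draws, f3$draws$draws))
})

test_that("DIC matches a two-pass oracle over the draws", {
  sim <- small_sim(seed = 5, L = 6, group_size = 6)
  grid <- equal_length_grid(9, 2)
  fit <- fit_mjm(sim$data, mjm_spec(), grid,
                 config = mcmc_config(chains = 2, adapt = 200, burn_in = 300,
                                      thin = 1, draws_per_chain = 150, seed = 3),
                 monitor_random_effects = TRUE, compute_dic = TRUE)
  arr <- fit$draws$draws
  flat <- matrix(arr, nrow = dim(arr)[1] * dim(arr)[2], ncol = dim(arr)[3])
  colnames(flat) <- dimnames(arr)[[3]]
  ps <- split_dataset(sim$data, grid)
  pf <- mjmcrt:::pseudo_frame(ps, sim$data)
  spec <- fit$spec
  dev_oracle <- function(vals) {
    st <- mjmcrt:::state_from_draw(vals, fit)
    st$Sigma_u <- diag(2)  # not part of the conditional deviance
    m <- longitudinal_mean(st, spec, pf)
    -2 * (log_density_longitudinal(st, spec, sim$data) +
            log_density_survival(st, spec, pf, m))
  }
  devs <- apply(flat, 1, dev_oracle)
  dbar <- mean(devs)
  dhat <- dev_oracle(colMeans(flat))
  expect_equal(unname(fit$dic["Dbar"]), dbar, tolerance = 1e-8)
  expect_equal(unname(fit$dic["Dhat"]), dhat, tolerance = 1e-8)
  expect_equal(unname(fit$dic["DIC"]), 2 * dbar - dhat, tolerance = 1e-8)
  expect_gt(fit$dic["pD"], 0)
})

test_that("summaries are insensitive to thinning on the same model and data", {
  sim <- small_sim(seed = 5, L = 6, group_size = 6)
  grid <- equal_length_grid(9, 2)
  base <- list(chains = 2, adapt = 200, burn_in = 400, seed = 21)
  f_thin1 <- fit_mjm(sim$data, mjm_spec(), grid,
                     config = mcmc_config(chains = 2, adapt = 200, burn_in = 400,
                                          thin = 1, draws_per_chain = 600, seed = 21),
                     monitor_random_effects = FALSE, compute_dic = FALSE)
  f_thin <- fit_mjm(sim$data, mjm_spec(), grid,
                    config = mcmc_config(chains = 2, adapt = 200, burn_in = 400,
                                         thin = 25, draws_per_chain = 120, seed = 21),
                    monitor_random_effects = FALSE, compute_dic = FALSE)
  for (par in c("(Intercept)", "time", "treatment", "time:treatment", "alpha")) {
    m1 <- f_thin1$summary[par, ]
    m2 <- f_thin$summary[par, ]
    mcse <- sqrt(m1$sd^2 / max(m1$ess, 4) + m2$sd^2 / max(m2$ess, 4))
    expect_lt(abs(m1$mean - m2$mean), 3 * mcse)
  }
})

test_that("fit reports serialize to JSON", {
  sim <- small_sim(seed = 5, L = 4, group_size = 4)
  fit <- fit_mjm(sim$data, mjm_spec(), equal_length_grid(9, 2),
                 config = mcmc_config(chains = 2, adapt = 100, burn_in = 50,
                                      thin = 1, draws_per_chain = 20, seed = 2),
                 monitor_random_effects = FALSE, compute_dic = FALSE)
  path <- tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(is.logical(rep$convergence$converged))
  expect_true("alpha" %in% rep$summary$parameter)
  expect_equal(rep$config$seed, 2)
})

test_that("draw archives round-trip and re-summarize identically", {
  sim <- small_sim(seed = 5, L = 4, group_size = 4)
  fit <- fit_mjm(sim$data, mjm_spec(), equal_length_grid(9, 2),
                 config = mcmc_config(chains = 2, adapt = 100, burn_in = 50,
                                      thin = 2, draws_per_chain = 30, seed = 6),
                 monitor_random_effects = FALSE, compute_dic = FALSE)
  dir <- tempfile(); write_draws(fit$draws, dir)
  back <- read_draws(dir)
  expect_equal(back$draws, fit$draws$draws, tolerance = 1e-15)
  s1 <- summarize_draws(fit$draws); s2 <- summarize_draws(back)
  expect_equal(s2$mean, s1$mean, tolerance = 1e-15)
  expect_equal(s2$rhat, s1$rhat, tolerance = 1e-12)
})

test_that("quadratic trajectory variants build, fit and rank by DIC", {
  sim <- small_sim(seed = 29, L = 6, group_size = 8)
  grid <- equal_length_grid(9, 2)
  cfg <- mcmc_config(chains = 2, adapt = 150, burn_in = 300, thin = 1,
                     draws_per_chain = 150, seed = 17)
  specs <- list(
    linear = mjm_spec("linear"),
    quad_shared = mjm_spec("quadratic_shared_curvature",
                           subject_random = "intercept_only"),
    quad_full = mjm_spec("quadratic_full", subject_random = "intercept_only"))
  dics <- vapply(specs, function(sp) {
    fit <- fit_mjm(sim$data, sp, grid, config = cfg)
    expect_s3_class(fit$summary, "posterior_summary")
    if (sp$trajectory != "linear")
      expect_true("I(time^2)" %in% rownames(fit$summary))
    if (sp$trajectory == "quadratic_full")
      expect_true("treatment:I(time^2)" %in% rownames(fit$summary))
    unname(fit$dic["DIC"])
  }, 0)
  expect_true(all(is.finite(dics)))
  # data generated from a linear trajectory: the linear spec should not
  # lose by a wide margin to the quadratic elaborations
  expect_lt(dics[["linear"]], max(dics) + 50)
})
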