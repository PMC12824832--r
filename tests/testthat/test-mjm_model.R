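make_frame <- function(time, treatment, subject_index = 1L, group_index = 1L)
  data.frame(time = time, treatment = treatment,
             subject_index = subject_index, group_index = group_index)

zero_state <- function(beta = c(16, -0.8, 1.6, -2), n = 1, L = 1, Q = 1,
                       alpha = -0.2, lam = 0.1) {
  mjm_state(beta = beta, sigma_eps = 1, Sigma_u = diag(2), alpha = alpha,
            lam = lam, u = matrix(0, n, 2), sigma_v = 1, sigma_g = 1,
            v = rep(0, L), g = rep(0, L))
}

test_that("longitudinal_mean reproduces the linear-trajectory arithmetic", {
  spec <- mjm_spec()
  st <- zero_state()
  # treated subject at t = 1: 16 + 1.6 + (-0.8 - 2) * 1
  expect_equal(longitudinal_mean(st, spec, make_frame(1, 1)), 14.8)
  # control at t = 0 returns the intercept
  expect_equal(longitudinal_mean(st, spec, make_frame(0, 0)), 16)
  # random effects enter linearly
  st2 <- zero_state()
  st2$u[1, ] <- c(1, 0.5); st2$v[1] <- -0.25
  expect_equal(longitudinal_mean(st2, spec, make_frame(2, 0)),
               16 + 1 - 0.8 * 2 + 0.5 * 2 - 0.25)
  # unknown covariate name in the spec is a spec error
  bad <- mjm_spec(fixed_covariates_long = "nonexistent")
  expect_error(longitudinal_mean(zero_state(), bad, make_frame(1, 1)),
               class = "mjmcrt_spec")
})

test_that("longitudinal log-density matches closed forms and a per-point oracle", {
  spec <- mjm_spec()
  ds <- fixture_dataset()
  st <- fixture_state()

  # a single measurement at its mean with unit SD
  tabs <- fixture_tables()
  one_ds <- trial_dataset(tabs$longitudinal[1, ], tabs$survival[1, ],
                          tabs$groups[1, ])
  stm <- st; stm$sigma_eps <- 1
  fr <- mjmcrt:::with_group_columns(one_ds$longitudinal, one_ds)
  stm2 <- stm
  stm2$beta[1] <- stm$beta[1] + (fr$y - longitudinal_mean(stm, spec, fr))
  expect_equal(log_density_longitudinal(stm2, spec, one_ds), -0.5 * log(2 * pi))
  # doubling sigma at y = m costs log 2 per observation
  stm3 <- stm2; stm3$sigma_eps <- 2
  expect_equal(log_density_longitudinal(stm2, spec, one_ds) -
                 log_density_longitudinal(stm3, spec, one_ds), log(2))

  # 7-point fixture equals the brute-force per-point sum
  fr_all <- mjmcrt:::with_group_columns(ds$longitudinal, ds)
  m <- longitudinal_mean(st, spec, fr_all)
  oracle <- sum(vapply(seq_along(m), function(i)
    dnorm(fr_all$y[i], m[i], st$sigma_eps, log = TRUE), 0))
  expect_equal(log_density_longitudinal(st, spec, ds), oracle)
})

test_that("log_mu follows the offset + piecewise-hazard + association structure", {
  spec <- mjm_spec()
  ps <- data.frame(q = 1L, exposure = 0.5, d = 0L, eval_time = 1,
                   subject_index = 1L, group_index = 1L, time = 1, treatment = 1)
  st <- zero_state()
  expect_equal(log_mu(st, spec, ps, 14.8), log(0.5) + log(0.1) - 0.2 * 14.8)
  # null-association limit
  st0 <- zero_state(alpha = 0)
  expect_equal(log_mu(st0, spec, ps, 123), log(0.5 * 0.1))
  # additivity of the frailty
  stg <- zero_state(); stg$g[1] <- 0.3
  expect_equal(log_mu(stg, spec, ps, 14.8) - log_mu(st, spec, ps, 14.8), 0.3)
  ps$exposure <- 0
  expect_error(log_mu(st, spec, ps, 14.8), class = "mjmcrt_domain")
})

test_that("survival log-density matches the Poisson form on single records", {
  spec <- mjm_spec()
  st <- zero_state(alpha = 0, lam = 0.5)
  ps <- data.frame(q = 1L, exposure = 1, d = 0L, eval_time = 0,
                   subject_index = 1L, group_index = 1L, time = 0, treatment = 0)
  expect_equal(log_density_survival(st, spec, ps, 0), -0.5)
  ps$d <- 1L
  expect_equal(log_density_survival(st, spec, ps, 0), log(0.5) - 0.5)
})

test_that("log-prior is symmetric in beta and matches component oracles", {
  spec <- mjm_spec(); priors <- mjm_priors()
  st <- fixture_state()
  st_neg <- st; st_neg$beta <- -st$beta
  expect_equal(log_prior(st, spec, priors), log_prior(st_neg, spec, priors))

  # Gamma(0.01, 0.01) term for one lambda piece
  st1 <- st; st1$lam[1] <- 1
  st2 <- st; st2$lam[1] <- 2
  expect_equal(log_prior(st1, spec, priors) - log_prior(st2, spec, priors),
               dgamma(1, 0.01, rate = 0.01, log = TRUE) -
                 dgamma(2, 0.01, rate = 0.01, log = TRUE))

  # inverse-Wishart density against an independent Wishart-route oracle:
  # p_IW(X; I, nu) = p_W(X^-1; I, nu) * |X|^-(p+1)
  dwish_log <- function(W, V, nu) {
    p <- nrow(W)
    lmvg <- p * (p - 1) / 4 * log(pi) + sum(lgamma(nu / 2 + (1 - seq_len(p)) / 2))
    (nu - p - 1) / 2 * determinant(W)$modulus - sum(diag(solve(V, W))) / 2 -
      nu * p / 2 * log(2) - nu / 2 * determinant(V)$modulus - lmvg
  }
  for (X in list(diag(2), matrix(c(10, 1, 1, 10), 2), matrix(c(2, -0.7, -0.7, 1), 2))) {
    expect_equal(mjmcrt:::dinvwishart_log(X, diag(2), 2),
                 as.numeric(dwish_log(solve(X), diag(2), 2) -
                              (2 + 1) * determinant(X)$modulus),
                 tolerance = 1e-10)
  }
  # outside the support
  st_bad <- st; st_bad$sigma_eps <- -1
  expect_identical(log_prior(st_bad, spec, priors), -Inf)
})

test_that("log-posterior is the sum of its components and nests the two-level model", {
  ds <- fixture_dataset()
  ps <- split_dataset(ds, fixture_grid())
  spec <- mjm_spec(); priors <- mjm_priors()
  st <- fixture_state()

  pf <- mjmcrt:::pseudo_frame(ps, ds)
  m <- longitudinal_mean(st, spec, pf)
  expect_equal(log_posterior(st, spec, priors, ds, ps),
               log_prior(st, spec, priors) +
                 mjmcrt:::random_effect_log_density(st, spec) +
                 log_density_longitudinal(st, spec, ds) +
                 log_density_survival(st, spec, pf, m))

  # with v = g = 0 and their density/prior terms removed, the MJM
  # log-posterior equals the standard two-level JM log-posterior
  st0 <- st; st0$v[] <- 0; st0$g[] <- 0
  spec2 <- mjm_spec(multilevel = FALSE)
  st2 <- st0; st2$v <- NULL; st2$g <- NULL; st2$sigma_v <- NULL; st2$sigma_g <- NULL
  extra <- sum(dnorm(0, 0, st0$sigma_v, log = TRUE)) * length(st0$v) +
    sum(dnorm(0, 0, st0$sigma_g, log = TRUE)) * length(st0$g) +
    mjmcrt:::dinvgamma_log(st0$sigma_v^2, 1 / 2, 1 / 2) +
    mjmcrt:::dinvgamma_log(st0$sigma_g^2, 1 / 2, 1 / 2)
  expect_equal(log_posterior(st0, spec, priors, ds, ps) - extra,
               log_posterior(st2, spec2, priors, ds, ps), tolerance = 1e-10)
})

test_that("log-posterior is invariant under subject relabeling", {
  sim <- small_sim(seed = 23, L = 4, group_size = 5)
  ds <- sim$data
  ps <- split_dataset(ds, equal_length_grid(9, 2))
  spec <- mjm_spec(); priors <- mjm_priors()
  set.seed(9)
  n <- nrow(ds$survival)
  st <- mjm_state(beta = c(16, -0.8, 1.6, -2), sigma_eps = 5,
                  Sigma_u = matrix(c(8, 1, 1, 9), 2), alpha = -0.2,
                  lam = c(0.1, 0.2), u = matrix(rnorm(2 * n), n, 2),
                  sigma_v = 2, sigma_g = 0.6,
                  v = rnorm(4), g = rnorm(4))
  lp1 <- log_posterior(st, spec, priors, ds, ps)

  # permute subject ids (relabel) and permute u rows accordingly
  perm <- sample(n)
  relab <- setNames(sprintf("r%03d", perm), ds$survival$subject_id)
  tabs <- list(longitudinal = ds$longitudinal, survival = ds$survival, groups = ds$groups)
  tabs$longitudinal$subject_id <- relab[tabs$longitudinal$subject_id]
  tabs$survival$subject_id <- relab[tabs$survival$subject_id]
  ord <- order(tabs$survival$subject_id)
  tabs$survival <- tabs$survival[ord, ]
  ds2 <- do.call(trial_dataset, lapply(tabs, function(x)
    x[, setdiff(names(x), c("subject_index", "group_index"))]))
  ps2 <- split_dataset(ds2, equal_length_grid(9, 2))
  st2 <- st
  old_pos <- match(ds2$survival$subject_id, relab[ds$survival$subject_id])
  st2$u <- st$u[old_pos, ]
  expect_equal(log_posterior(st2, spec, priors, ds2, ps2), lp1, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  sim <- small_sim(seed = 41, L = 4, group_size = 5)
  ds <- sim$data
  ps <- split_dataset(ds, equal_length_grid(9, 2))
  spec <- mjm_spec(); priors <- mjm_priors()
  f <- function(s) log_posterior(s, spec, priors, ds, ps)
  set.seed(11)
  n <- nrow(ds$survival)
  st <- mjm_state(beta = c(16, -0.8, 1.6, -2) + rnorm(4, 0, 0.5),
                  sigma_eps = 5.5, Sigma_u = matrix(c(9, 2, 2, 8), 2),
                  alpha = -0.25, lam = c(0.08, 0.2),
                  u = matrix(rnorm(2 * n, 0, 1), n, 2),
                  sigma_v = 2.1, sigma_g = 0.7, v = rnorm(4), g = rnorm(4, 0, 0.5))
  gr <- log_posterior_grad(st, spec, priors, ds, ps)

  coords <- list(
    beta1 = list(function(s, x) { s$beta[1] <- x; s }, function(s) s$beta[1]),
    beta4 = list(function(s, x) { s$beta[4] <- x; s }, function(s) s$beta[4]),
    alpha = list(function(s, x) { s$alpha <- x; s }, function(s) s$alpha),
    u1_3 = list(function(s, x) { s$u[3, 1] <- x; s }, function(s) s$u[3, 1]),
    u2_9 = list(function(s, x) { s$u[9, 2] <- x; s }, function(s) s$u[9, 2]),
    v2 = list(function(s, x) { s$v[2] <- x; s }, function(s) s$v[2]),
    g3 = list(function(s, x) { s$g[3] <- x; s }, function(s) s$g[3]),
    lam1 = list(function(s, x) { s$lam[1] <- x; s }, function(s) s$lam[1]),
    lam2 = list(function(s, x) { s$lam[2] <- x; s }, function(s) s$lam[2]),
    var_eps = list(function(s, x) { s$sigma_eps <- sqrt(x); s }, function(s) s$sigma_eps^2),
    var_v = list(function(s, x) { s$sigma_v <- sqrt(x); s }, function(s) s$sigma_v^2),
    var_g = list(function(s, x) { s$sigma_g <- sqrt(x); s }, function(s) s$sigma_g^2),
    Sigma_u_1_1 = list(function(s, x) { s$Sigma_u[1, 1] <- x; s }, function(s) s$Sigma_u[1, 1]),
    Sigma_u_2_2 = list(function(s, x) { s$Sigma_u[2, 2] <- x; s }, function(s) s$Sigma_u[2, 2]),
    Sigma_u_2_1 = list(function(s, x) { s$Sigma_u[2, 1] <- x; s$Sigma_u[1, 2] <- x; s },
                       function(s) s$Sigma_u[2, 1]))
  for (nm in names(coords)) {
    num <- central_diff(f, st, coords[[nm]][[1]], coords[[nm]][[2]])
    expect_lt(abs(num - gr[[nm]]) / (abs(gr[[nm]]) + 1), 1e-5)
  }
})

test_that("model and prior configuration round-trips through YAML", {
  spec <- mjm_spec(trajectory = "quadratic_full", subject_random = "intercept_only",
                   multilevel = FALSE, fixed_covariates_surv = "treatment")
  priors <- mjm_priors(beta_variance = 500, lambda_gamma = c(0.1, 0.1))
  path <- tempfile(fileext = ".yaml")
  write_model_config(spec, priors, path)
  back <- read_model_config(path)
  expect_equal(back$spec, spec)
  expect_equal(back$priors, priors)
})
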