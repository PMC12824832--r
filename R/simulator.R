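#' True generative parameter values
#'
#' Parameter values of the generative model for nested trial data: a
#' linear subject trajectory \eqn{m_{jl}(t) = \beta_{000} + u_{0jl} +
#' v_{00l} + (\beta_{100} + u_{1jl}) t + \beta_{001}\mathrm{TRT}_l +
#' \beta_{101}\mathrm{TRT}_l\, t}, measurement noise with variance
#' `var_eps`, and a hazard \eqn{\lambda_{jl}(t) = \lambda_0(t)
#' \exp(\alpha\, m_{jl}(t) + g_l)} with Weibull baseline
#' \eqn{\lambda_0(t) = \mathrm{scale} \cdot \mathrm{shape} \cdot
#' t^{\mathrm{shape}-1}}.
#'
#' Defaults are the simulation-study values used throughout the
#' package's tests; `scale` defaults to `NULL`, meaning it is calibrated
#' to the scenario's censoring target by [calibrate_scale()]. `shape`
#' defaults to 1.5 (increasing hazard); it is configuration, echoed in
#' all outputs.
#'
#' @param beta000 mean outcome at baseline in the control arm.
#' @param beta001 baseline difference, treated vs control.
#' @param beta100 yearly change in the control arm.
#' @param beta101 treatment-by-time interaction (the treatment effect).
#' @param var_u0,var_u1,rho_u subject random intercept/slope variances
#'   and their correlation.
#' @param var_eps residual (measurement-error) variance.
#' @param alpha current-value association on the log-hazard.
#' @param var_v group-level variance, longitudinal submodel.
#' @param var_g group-level frailty variance, survival submodel.
#' @param shape,scale Weibull baseline hazard parameters.
#' @return An object of class `true_params`.
#' @export
true_params <- function(beta000 = 16, beta001 = 1.6, beta100 = -0.8, beta101 = -2,
                        var_u0 = 10, var_u1 = 10, rho_u = 0, var_eps = 33,
                        alpha = -0.2, var_v = 5, var_g = 0.4,
                        shape = 1.5, scale = NULL) {
  if (any(c(var_u0, var_u1, var_eps, var_v, var_g) < 0))
    stop_mjm("domain", "variances must be >= 0")
  if (abs(rho_u) > 1) stop_mjm("domain", "|rho_u| must be <= 1")
  if (shape <= 0 || (!is.null(scale) && scale <= 0))
    stop_mjm("domain", "shape and scale must be > 0")
  structure(list(beta000 = beta000, beta001 = beta001, beta100 = beta100,
                 beta101 = beta101, var_u0 = var_u0, var_u1 = var_u1,
                 rho_u = rho_u, var_eps = var_eps, alpha = alpha,
                 var_v = var_v, var_g = var_g, shape = shape, scale = scale),
            class = "true_params")
}

#' One cell of the simulation design
#'
#' Describes one scenario: censoring target, number of groups L, group
#' size, group-level variances, interval count Q, the generative truths,
#' and the follow-up design (5 years of 6-monthly measurements, 9 years
#' of survival follow-up with administrative censoring, treatment
#' assigned to half the groups).
#'
#' @param censoring_target targeted administrative censoring proportion.
#' @param L number of groups.
#' @param group_size subjects per group.
#' @param var_v,var_g group-level variances (copied into `truths`).
#' @param Q number of hazard intervals used when fitting.
#' @param truths a [true_params()].
#' @param longitudinal_follow_up,measurement_gap,survival_follow_up
#'   measurement window, spacing, and administrative censoring time
#'   (years).
#' @param treated_fraction fraction of groups assigned to treatment.
#' @param seed master seed of the scenario; replicate and purpose
#'   substreams are derived from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(censoring_target = 0.2, L = 50, group_size = 30,
                            var_v = 5, var_g = 0.4, Q = 11,
                            truths = true_params(),
                            longitudinal_follow_up = 5, survival_follow_up = 9,
                            measurement_gap = 0.5, treated_fraction = 0.5,
                            seed = 1L) {
  if (censoring_target <= 0 || censoring_target >= 1)
    stop_mjm("domain", "censoring_target must be in (0, 1)")
  truths$var_v <- var_v
  truths$var_g <- var_g
  structure(list(censoring_target = censoring_target, L = as.integer(L),
                 group_size = as.integer(group_size), var_v = var_v, var_g = var_g,
                 Q = as.integer(Q), truths = truths,
                 longitudinal_follow_up = longitudinal_follow_up,
                 survival_follow_up = survival_follow_up,
                 measurement_gap = measurement_gap,
                 treated_fraction = treated_fraction, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Intraclass correlations of the longitudinal submodel
#'
#' Based on the intercept-only decomposition: subject-level ICC
#' \eqn{\sigma_{u0}^2 / (\sigma_{u0}^2 + \sigma_\varepsilon^2 +
#' \sigma_v^2)} and group-level ICC \eqn{\sigma_v^2 / (\sigma_{u0}^2 +
#' \sigma_\varepsilon^2 + \sigma_v^2)}.
#'
#' @param var_u0 subject random-intercept variance.
#' @param var_eps residual variance.
#' @param var_v group-level variance.
#' @return List with `icc_subject` and `icc_group`.
#' @export
icc_longitudinal <- function(var_u0, var_eps, var_v) {
  if (any(c(var_u0, var_eps, var_v) < 0)) stop_mjm("domain", "variances must be >= 0")
  tot <- var_u0 + var_eps + var_v
  if (tot == 0) stop_mjm("domain", "all variance components are zero")
  list(icc_subject = var_u0 / tot, icc_group = var_v / tot)
}

#' Weibull cumulative baseline hazard
#'
#' \eqn{\Lambda_0(t) = \mathrm{scale}\cdot t^{\mathrm{shape}}}, the
#' exact integral of \eqn{\lambda_0(t) = \mathrm{scale}\cdot
#' \mathrm{shape}\cdot t^{\mathrm{shape}-1}}.
#'
#' @param scale,shape Weibull parameters (> 0).
#' @param t time (>= 0), vectorized.
#' @return \eqn{\Lambda_0(t)}.
#' @export
weibull_cum_hazard <- function(scale, shape, t) {
  if (any(t < 0)) stop_mjm("domain", "t must be >= 0")
  scale * t^shape
}

# Cumulative hazard under the current-value model for one subject:
# Lambda(t) = int_0^t scale*shape*s^(shape-1) * exp(alpha*(a + b s) + g) ds,
# by adaptive quadrature (absolute tolerance 1e-10 by default).
cum_hazard_cv <- function(t, a, b, alpha, g, scale, shape, abs.tol = 1e-10) {
  if (t < 0) stop_mjm("domain", "t must be >= 0")
  if (t == 0) return(0)
  scale * stats::integrate(
    function(s) shape * s^(shape - 1) * exp(alpha * (a + b * s) + g),
    0, t, rel.tol = 1e-10, abs.tol = abs.tol)$value
}

# Vectorized scale-free cumulative hazard at `tmax` for many subjects:
# K_i = Lambda_i(tmax) / scale, via Gauss-Legendre quadrature after the
# substitution s = w^2 (removes the s^(shape-1) kink at 0 for the
# default shape 1.5).
cum_hazard_cv_batch <- function(tmax, a, b, alpha, g, shape, nodes = 96) {
  gl <- pracma::gaussLegendre(nodes, 0, sqrt(tmax))
  w <- gl$x
  wt <- gl$w * 2 * shape * w^(2 * shape - 1)
  E <- exp(outer(alpha * b, w^2) + alpha * a + g)
  drop(E %*% wt)
}

#' Simulate one event time by cumulative-hazard inversion
#'
#' Solves \eqn{\Lambda(T) = -\log u} for a subject with linear latent
#' trajectory \eqn{m(t) = a + b t}, current-value association `alpha`,
#' frailty `g` and Weibull baseline, using adaptive quadrature for
#' \eqn{\Lambda} and bracketed (Brent) root finding. Returns `Inf` when
#' no root exists below `horizon`.
#'
#' @param a,b intercept and slope of the latent trajectory.
#' @param alpha association coefficient.
#' @param g group frailty on the log-hazard.
#' @param scale,shape Weibull baseline parameters.
#' @param u uniform draw in (0, 1).
#' @param horizon upper bracket for the root (years).
#' @param tol absolute tolerance of the root, in years.
#' @return Event time in years, or `Inf`.
#' @export
simulate_event_time <- function(a, b, alpha, g, scale, shape, u,
                                horizon = 9, tol = 1e-8) {
  if (u <= 0 || u >= 1) stop_mjm("domain", "u must be in (0, 1)")
  if (tol <= 0) stop_mjm("domain", "tol must be > 0")
  target <- -log(u)
  f <- function(t) cum_hazard_cv(t, a, b, alpha, g, scale, shape) - target
  if (f(horizon) < 0) return(Inf)
  stats::uniroot(f, c(0, horizon), tol = tol)$root
}

# Draw the group/subject structure and random effects of a scenario:
# treatment assignment, v, g per group, (u0, u1) per subject, and the
# implied per-subject trajectory coefficients a (intercept) and b (slope).
draw_structure <- function(L, group_size, truths, treated_fraction) {
  n <- L * group_size
  gid <- rep(seq_len(L), each = group_size)
  n_trt <- floor(L * treated_fraction)
  trt_g <- integer(L)
  trt_g[sample.int(L, n_trt)] <- 1L
  v <- stats::rnorm(L, 0, sqrt(truths$var_v))
  g <- stats::rnorm(L, 0, sqrt(truths$var_g))
  sd0 <- sqrt(truths$var_u0); sd1 <- sqrt(truths$var_u1)
  u0 <- stats::rnorm(n, 0, sd0)
  # conditional draw preserves the (u0, u1) correlation rho_u
  u1 <- if (sd0 > 0)
    stats::rnorm(n, truths$rho_u * sd1 / sd0 * u0,
                 sd1 * sqrt(max(0, 1 - truths$rho_u^2)))
  else stats::rnorm(n, 0, sd1)
  trt <- trt_g[gid]
  list(gid = gid, trt_g = trt_g, trt = trt, v = v, g = g, u0 = u0, u1 = u1,
       a = truths$beta000 + truths$beta001 * trt + u0 + v[gid],
       b = truths$beta100 + truths$beta101 * trt + u1)
}

#' Calibrate the Weibull scale to a censoring target
#'
#' Finds the baseline scale at which the probability that the event time
#' exceeds the survival follow-up (administrative censoring) equals the
#' target, under the full generative model with random effects
#' integrated by Monte Carlo. Because the scale multiplies the whole
#' hazard, a subject with scale-free cumulative hazard \eqn{K_i} at the
#' follow-up end is censored iff \eqn{\mathrm{scale} \cdot K_i < E_i}
#' with \eqn{E_i \sim \mathrm{Exp}(1)}; the calibrated scale is the
#' \eqn{(1-\mathrm{target})} quantile of \eqn{E_i / K_i}, the exact
#' fixed point that common-random-number bisection would converge to.
#'
#' @param target_censoring censoring proportion in (0, 1).
#' @param shape Weibull shape.
#' @param scenario a [scenario_config()] supplying the generative model
#'   and follow-up length.
#' @param mc_size Monte-Carlo sample size (>= 1e4).
#' @param seed seed for the Monte-Carlo draw.
#' @return Calibrated scale (scalar).
#' @export
calibrate_scale <- function(target_censoring, shape, scenario,
                            mc_size = 1e5, seed = 1L) {
  if (target_censoring <= 0 || target_censoring >= 1)
    stop_mjm("domain", "target_censoring must be in (0, 1)")
  if (mc_size < 1e4) stop_mjm("argument", "mc_size must be >= 1e4")
  tr <- scenario$truths
  with_seed(seed, {
    Lg <- ceiling(mc_size / scenario$group_size)
    st <- draw_structure(Lg, scenario$group_size, tr, scenario$treated_fraction)
    keep <- seq_len(mc_size)
    K <- cum_hazard_cv_batch(scenario$survival_follow_up, st$a[keep], st$b[keep],
                             tr$alpha, st$g[st$gid[keep]], tr$shape)
    E <- stats::rexp(mc_size)
    sc <- unname(stats::quantile(E / K, 1 - target_censoring, type = 7))
    if (sc < 1e-8 || sc > 1e3)
      stop_mjm("calibration", sprintf("calibrated scale %g outside [1e-8, 1e3]", sc))
    sc
  })
}

#' Achieved censoring fraction on an independent validation draw
#'
#' Simulates `n` fresh subjects under the scenario's generative model at
#' the given scale and returns the fraction whose event time exceeds the
#' survival follow-up.
#'
#' @inheritParams calibrate_scale
#' @param scale Weibull scale to validate.
#' @param n validation sample size.
#' @return Achieved censoring proportion.
#' @export
censoring_fraction <- function(scenario, scale, n = 1e5, seed = 2L) {
  tr <- scenario$truths
  with_seed(seed, {
    Lg <- ceiling(n / scenario$group_size)
    st <- draw_structure(Lg, scenario$group_size, tr, scenario$treated_fraction)
    keep <- seq_len(n)
    K <- cum_hazard_cv_batch(scenario$survival_follow_up, st$a[keep], st$b[keep],
                             tr$alpha, st$g[st$gid[keep]], tr$shape)
    mean(stats::rexp(n) > scale * K)
  })
}

#' Generate one synthetic nested trial dataset
#'
#' Full generative pipeline: draw group-level treatment assignment and
#' random effects, subject random effects, event times by inverting the
#' cumulative hazard of the current-value model (the hazard depends on
#' the noise-free trajectory \eqn{m_{jl}(t)}, so event times are
#' invariant to measurement noise), apply administrative censoring at
#' the survival follow-up, and record measurements on the 6-monthly
#' schedule strictly before the true event time.
#'
#' If the scenario's truths carry no `scale`, it is first calibrated to
#' the censoring target on a 1e5-subject Monte-Carlo draw from a
#' dedicated substream of the scenario seed.
#'
#' @param scenario a [scenario_config()].
#' @param replicate_index replicate number; each replicate uses an
#'   independent substream of the scenario seed.
#' @return List with elements `data` (a [trial_dataset()]) and `truth`
#'   (true parameters including the calibrated scale, and the true
#'   random effects `u0`, `u1`, `v`, `g`, the true event times `Tstar`,
#'   and the seed used).
#' @export
generate_dataset <- function(scenario, replicate_index = 1L) {
  tr <- scenario$truths
  if (is.null(tr$scale))
    tr$scale <- calibrate_scale(scenario$censoring_target, tr$shape, scenario,
                                seed = derive_seed(scenario$seed, "calibration"))
  seed_re <- derive_seed(scenario$seed, "replicate", replicate_index, "effects")
  seed_ev <- derive_seed(scenario$seed, "replicate", replicate_index, "events")
  seed_ns <- derive_seed(scenario$seed, "replicate", replicate_index, "noise")

  st <- with_seed(seed_re,
                  draw_structure(scenario$L, scenario$group_size, tr,
                                 scenario$treated_fraction))
  n <- scenario$L * scenario$group_size
  tmax <- scenario$survival_follow_up
  uu <- with_seed(seed_ev, stats::runif(n))
  Tstar <- vapply(seq_len(n), function(i)
    simulate_event_time(st$a[i], st$b[i], tr$alpha, st$g[st$gid[i]],
                        tr$scale, tr$shape, uu[i], horizon = tmax), 0)
  observed <- pmin(Tstar, tmax)
  event <- as.integer(Tstar <= tmax)

  sched <- seq(0, scenario$longitudinal_follow_up, by = scenario$measurement_gap)
  ids <- sprintf("s%04d", seq_len(n))
  gids <- sprintf("g%03d", st$gid)
  times <- lapply(seq_len(n), function(i) sched[sched < Tstar[i]])
  nrep <- lengths(times)
  tt <- unlist(times)
  irow <- rep(seq_len(n), nrep)
  m <- st$a[irow] + st$b[irow] * tt
  y <- m + with_seed(seed_ns, stats::rnorm(length(tt), 0, sqrt(tr$var_eps)))

  longitudinal <- data.frame(subject_id = ids[irow], group_id = gids[irow],
                             time = tt, y = y, stringsAsFactors = FALSE)
  survival <- data.frame(subject_id = ids, group_id = gids,
                         observed_time = observed, event = event,
                         stringsAsFactors = FALSE)
  groups <- data.frame(group_id = sprintf("g%03d", seq_len(scenario$L)),
                       treatment = st$trt_g, stringsAsFactors = FALSE)
  list(
    data = trial_dataset(longitudinal, survival, groups),
    truth = list(params = tr, u0 = st$u0, u1 = st$u1, v = st$v, g = st$g,
                 Tstar = Tstar, treatment = st$trt_g,
                 scenario_seed = scenario$seed, replicate_index = replicate_index)
  )
}

#' Write a generated dataset and its generative truth to disk
#'
#' Writes `longitudinal.csv`, `survival.csv`, `groups.csv` and
#' `truth.json` (true parameters, calibrated scale, seeds, and true
#' random effects, for oracle recovery checks).
#'
#' @param sim output of [generate_dataset()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  write_trial(sim$data, dir)
  truth <- sim$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a scenario configuration from YAML
#'
#' Accepts the fields of [scenario_config()] plus an optional `truths`
#' block with the fields of [true_params()]; omitted fields fall back
#' to the defaults.
#'
#' @param path YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tr <- do.call(true_params, cfg$truths %||% list())
  args <- cfg[setdiff(names(cfg), "truths")]
  args$truths <- tr
  do.call(scenario_config, args)
}
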