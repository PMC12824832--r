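#' MCMC configuration
#'
#' Defaults mirror a conservative Gibbs workflow: three chains (to check
#' initialization influence), a short adaptation phase, a long burn-in,
#' and heavy thinning chosen from autocorrelation inspection. For
#' desk-scale work pass smaller values; the contract is the posterior,
#' not the iteration counts.
#'
#' @param chains number of chains (>= 1; >= 2 needed for R-hat).
#' @param adapt adaptation iterations.
#' @param burn_in burn-in iterations discarded before sampling.
#' @param thin thinning stride (>= 1).
#' @param draws_per_chain retained draws per chain after thinning.
#' @param seed integer seed; chain-level RNG streams and initial-value
#'   jitter are derived from it, so a fit is bit-reproducible given
#'   (seed, config, platform).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, adapt = 100, burn_in = 4000, thin = 150,
                        draws_per_chain = 200, seed = 1L) {
  if (chains < 1 || thin < 1 || adapt < 0 || burn_in < 0 || draws_per_chain < 1)
    stop_mjm("argument", "invalid MCMC configuration")
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 draws_per_chain = as.integer(draws_per_chain),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Generate the JAGS model string for a given spec. `constraints` may fix
# alpha or sigma_eps at known values, or clamp the subject random
# effects to zero (u_zero); these restricted sub-models are used for
# null-association fits and analytic sampler checks.
jags_model_code <- function(spec, priors, p_beta, p_gamma, constraints = list()) {
  xl <- paste0("X[k,", seq_len(p_beta), "]*beta[", seq_len(p_beta), "]", collapse = " + ")
  xs <- paste0("Xs[k,", seq_len(p_beta), "]*beta[", seq_len(p_beta), "]", collapse = " + ")
  u_l <- if (spec$p_u == 2) "u[subl[k],1] + u[subl[k],2]*tl[k]" else "u[subl[k],1]"
  u_s <- if (spec$p_u == 2) "u[subp[k],1] + u[subp[k],2]*ts[k]" else "u[subp[k],1]"
  v_l <- if (spec$multilevel) " + v[grpl[k]]" else ""
  v_s <- if (spec$multilevel) " + v[grpp[k]]" else ""
  g_s <- if (spec$multilevel) " + gg[grpp[k]]" else ""
  w_s <- if (p_gamma > 0)
    paste0(" + ", paste0("W[k,", seq_len(p_gamma), "]*gamma[", seq_len(p_gamma), "]",
                         collapse = " + "))
  else ""
  u_zero <- isTRUE(constraints$u_zero)

  lines <- c(
    "model {",
    "  for (k in 1:Nl) {",
    sprintf("    muy[k] <- %s + %s%s", xl, u_l, v_l),
    "    y[k] ~ dnorm(muy[k], tau_eps)",
    "  }",
    "  for (k in 1:Np) {",
    sprintf("    mval[k] <- %s + %s%s", xs, u_s, v_s),
    sprintf("    log(mu[k]) <- logexpo[k] + loglam[qi[k]]%s + alpha*mval[k]%s", w_s, g_s),
    "    d[k] ~ dpois(mu[k])",
    "  }")

  if (u_zero) {
    lines <- c(lines,
      sprintf("  for (j in 1:N) { %s }",
              paste0("u[j,", seq_len(spec$p_u), "] <- 0", collapse = "; ")))
  } else if (spec$p_u == 2) {
    lines <- c(lines,
      "  for (j in 1:N) { u[j,1:2] ~ dmnorm(zero_u, Omega_u) }",
      "  Omega_u ~ dwish(R_u, 2)",
      "  Sigma_u <- inverse(Omega_u)")
  } else {
    lines <- c(lines,
      "  for (j in 1:N) { u[j,1] ~ dnorm(0, tau_u) }",
      sprintf("  tau_u ~ dgamma(0.5, %.17g)", 0.5 * priors$wishart_scale),
      "  Sigma_u <- 1/tau_u")
  }
  if (spec$multilevel) {
    lines <- c(lines,
      "  for (l in 1:L) {",
      "    v[l] ~ dnorm(0, tau_v)",
      "    gg[l] ~ dnorm(0, tau_g)",
      "  }",
      sprintf("  tau_v ~ dgamma(0.5, %.17g)", 0.5 * priors$wishart_scale),
      sprintf("  tau_g ~ dgamma(0.5, %.17g)", 0.5 * priors$wishart_scale),
      "  sigma_v <- 1/sqrt(tau_v)",
      "  sigma_g <- 1/sqrt(tau_g)")
  }
  lines <- c(lines,
    sprintf("  for (s in 1:%d) { beta[s] ~ dnorm(0, %.17g) }", p_beta, 1 / priors$beta_variance))
  if (p_gamma > 0)
    lines <- c(lines,
      sprintf("  for (s in 1:%d) { gamma[s] ~ dnorm(0, %.17g) }", p_gamma, 1 / priors$gamma_variance))
  lines <- c(lines,
    if (!is.null(constraints$alpha))
      sprintf("  alpha <- %.17g", constraints$alpha)
    else
      sprintf("  alpha ~ dnorm(0, %.17g)", 1 / priors$alpha_variance),
    sprintf("  for (q in 1:Q) { lam[q] ~ dgamma(%.17g, %.17g); loglam[q] <- log(lam[q]) }",
            priors$lambda_gamma[1], priors$lambda_gamma[2]),
    if (!is.null(constraints$sigma_eps))
      sprintf("  tau_eps <- %.17g", 1 / constraints$sigma_eps^2)
    else
      sprintf("  tau_eps ~ dgamma(%.17g, %.17g)", priors$sigma_eps_ig[1], priors$sigma_eps_ig[2]),
    "  sigma_eps <- 1/sqrt(tau_eps)",
    "}")
  paste(lines, collapse = "\n")
}

# Assemble the data objects shared by the JAGS run and the in-R
# likelihood evaluations.
assemble_model_data <- function(data, spec, grid, eval_rule) {
  pseudo <- split_dataset(data, grid, eval_rule)
  lframe <- with_group_columns(data$longitudinal, data)
  lframe <- with_survival_columns(lframe, data)
  sframe <- pseudo_frame(pseudo, data)
  X <- long_design(spec, lframe)
  Xs <- long_design(spec, sframe)
  W <- surv_design(spec, sframe)
  list(pseudo = pseudo, lframe = lframe, sframe = sframe,
       X = X, Xs = Xs, W = W,
       n = nrow(data$survival), L = nrow(data$groups), Q = grid$Q)
}

# Two-stage warm start: longitudinal-only least squares for beta and the
# residual variance; interval event rates for lambda; association at 0;
# random effects at 0 with moderate prior variances. Per-chain jitter.
warm_start <- function(md, spec, constraints, chain_seed) {
  with_seed(chain_seed, {
    fit <- stats::lm.fit(md$X, md$lframe$y)
    beta0 <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    s2 <- max(stats::var(fit$residuals), 1e-3)
    agg_d <- tapply(md$pseudo$d, factor(md$pseudo$q, levels = seq_len(md$Q)), sum)
    agg_e <- tapply(md$pseudo$exposure, factor(md$pseudo$q, levels = seq_len(md$Q)), sum)
    lam0 <- (ifelse(is.na(agg_d), 0, agg_d) + 0.5) / (ifelse(is.na(agg_e), 0, agg_e) + 1)
    ini <- list(
      beta = beta0 + stats::rnorm(length(beta0), 0, 0.1 * (abs(beta0) + 0.5)),
      lam = as.numeric(lam0 * exp(stats::rnorm(md$Q, 0, 0.2))))
    if (is.null(constraints$alpha)) ini$alpha <- stats::rnorm(1, 0, 0.05)
    if (is.null(constraints$sigma_eps)) ini$tau_eps <- 1 / (s2 * exp(stats::rnorm(1, 0, 0.2)))
    if (ncol(md$W) > 0) ini$gamma <- stats::rnorm(ncol(md$W), 0, 0.1)
    if (!isTRUE(constraints$u_zero)) {
      if (spec$p_u == 2) {
        ini$u <- matrix(0, md$n, 2)
        ini$Omega_u <- diag(2) * stats::runif(1, 0.05, 0.5)
      } else {
        ini$u <- matrix(0, md$n, 1)
        ini$tau_u <- stats::runif(1, 0.05, 0.5)
      }
    }
    if (spec$multilevel) {
      ini$v <- rep(0, md$L); ini$gg <- rep(0, md$L)
      ini$tau_v <- stats::runif(1, 0.2, 2); ini$tau_g <- stats::runif(1, 0.2, 2)
    }
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- derive_seed(chain_seed, "jags-rng")
    ini
  })
}

# Map JAGS monitor names to canonical parameter names.
canonical_names <- function(jnames, md) {
  out <- jnames
  bi <- grepl("^beta\\[", jnames)
  out[bi] <- colnames(md$X)[as.integer(sub("beta\\[(\\d+)\\]", "\\1", jnames[bi]))]
  if (ncol(md$W) > 0) {
    gi <- grepl("^gamma\\[", jnames)
    out[gi] <- paste0("surv:", colnames(md$W)[as.integer(sub("gamma\\[(\\d+)\\]", "\\1", jnames[gi]))])
  }
  out <- sub("^gg\\[", "g[", out)
  out[out == "Sigma_u"] <- "Sigma_u[1,1]"
  ui <- grepl("^u\\[\\d+\\]$", out)
  out[ui] <- sub("\\]$", ",1]", out[ui])
  out
}

#' Fit a (multilevel) joint model by MCMC
#'
#' Fits the joint model described by `spec` to a [trial_dataset()] with
#' JAGS (Gibbs sampling), using the auxiliary Poisson representation of
#' the survival submodel on the pseudo-records implied by `grid`.
#' Initial values come from a two-stage warm start (longitudinal least
#' squares; interval event rates), jittered per chain; chain RNG streams
#' are derived from `config$seed`, so the fit is reproducible.
#'
#' The fit report applies the convergence gate: the fit "converges" iff
#' split R-hat < 1.1 for all gated parameters (fixed effects, the
#' association, and all variance components).
#'
#' @param data a [trial_dataset()].
#' @param spec an [mjm_spec()].
#' @param grid an [interval_grid()] for the piecewise hazard.
#' @param priors an [mjm_priors()].
#' @param config an [mcmc_config()].
#' @param eval_rule within-interval evaluation time of the current
#'   value; see [split_subject()].
#' @param monitor_random_effects monitor `u`, `v`, `g` (required for
#'   DIC).
#' @param compute_dic compute the conditional-deviance DIC.
#' @param constraints optional restricted sub-model: list with any of
#'   `alpha` (fix the association), `sigma_eps` (fix the residual SD),
#'   `u_zero = TRUE` (clamp subject random effects to zero). Used for
#'   null-association fits and analytic sampler checks.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `mjm_fit`: list with `draws` (a
#'   `posterior_draws`), `summary` (a `posterior_summary` data frame),
#'   `convergence` (gate verdict + gated R-hats), `dic`, and the
#'   configuration echo (`spec`, `priors`, `config`, `grid`,
#'   `eval_rule`, `data_fingerprint`).
#' @export
fit_mjm <- function(data, spec = mjm_spec(), grid, priors = mjm_priors(),
                    config = mcmc_config(), eval_rule = "interval_start",
                    monitor_random_effects = TRUE, compute_dic = monitor_random_effects,
                    constraints = list(), quiet = TRUE) {
  stopifnot(inherits(data, "trial_dataset"), inherits(grid, "interval_grid"))
  md <- assemble_model_data(data, spec, grid, eval_rule)
  code <- jags_model_code(spec, priors, ncol(md$X), ncol(md$W), constraints)

  jd <- list(Nl = nrow(md$lframe), y = md$lframe$y,
             subl = md$lframe$subject_index, X = md$X,
             Np = nrow(md$pseudo), d = md$pseudo$d,
             logexpo = log(md$pseudo$exposure), qi = md$pseudo$q,
             subp = md$pseudo$subject_index, Xs = md$Xs,
             N = md$n, Q = md$Q)
  if (spec$p_u == 2) {
    # measurement / evaluation times enter only through the random slope
    jd$tl <- md$lframe$time
    jd$ts <- md$pseudo$eval_time
  }
  if (spec$multilevel) {
    jd$grpl <- md$lframe$group_index
    jd$grpp <- md$pseudo$group_index
    jd$L <- md$L
  }
  if (ncol(md$W) > 0) jd$W <- md$W
  if (spec$p_u == 2 && !isTRUE(constraints$u_zero)) {
    jd$zero_u <- c(0, 0)
    jd$R_u <- priors$wishart_scale * diag(2)
  }

  inits <- lapply(seq_len(config$chains), function(ch)
    warm_start(md, spec, constraints, derive_seed(config$seed, "chain", ch)))

  monitors <- c("beta", "lam")
  if (is.null(constraints$alpha)) monitors <- c(monitors, "alpha")
  if (is.null(constraints$sigma_eps)) monitors <- c(monitors, "sigma_eps")
  if (!isTRUE(constraints$u_zero)) monitors <- c(monitors, "Sigma_u")
  if (ncol(md$W) > 0) monitors <- c(monitors, "gamma")
  if (spec$multilevel) monitors <- c(monitors, "sigma_v", "sigma_g")
  if (monitor_random_effects) {
    if (!isTRUE(constraints$u_zero)) monitors <- c(monitors, "u")
    if (spec$multilevel) monitors <- c(monitors, "v", "gg")
  }

  run <- function() {
    # the glm module's block samplers cut autocorrelation of the GLMM
    # blocks by an order of magnitude on these models
    rjags::load.module("glm", quiet = TRUE)
    jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                            n.chains = config$chains,
                            n.adapt = config$adapt, quiet = quiet)
    if (config$burn_in > 0) stats::update(jm, config$burn_in,
                                          progress.bar = if (quiet) "none" else "text")
    rjags::coda.samples(jm, variable.names = monitors,
                        n.iter = config$draws_per_chain * config$thin,
                        thin = config$thin,
                        progress.bar = if (quiet) "none" else "text")
  }
  sm <- withCallingHandlers(
    tryCatch(run(), error = function(e)
      stop_mjm("initialization", paste0("sampler failed: ", conditionMessage(e)))),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  mats <- lapply(sm, as.matrix)
  jnames <- colnames(mats[[1]])
  arr <- array(unlist(mats),
               dim = c(nrow(mats[[1]]), length(jnames), length(mats)),
               dimnames = list(NULL, canonical_names(jnames, md), NULL))
  arr <- aperm(arr, c(1, 3, 2))  # draw x chain x parameter
  draws <- structure(list(draws = arr, params = dimnames(arr)[[3]],
                          config = config), class = "posterior_draws")

  summ <- summarize_draws(draws)
  gated <- gated_parameters(spec, md, constraints)
  gate_rh <- summ[rownames(summ) %in% gated, "rhat"]
  convergence <- list(
    converged = length(gate_rh) > 0 && all(is.finite(gate_rh)) && all(gate_rh < 1.1),
    threshold = 1.1,
    rhat = stats::setNames(summ$rhat[rownames(summ) %in% gated],
                           rownames(summ)[rownames(summ) %in% gated]))

  fit <- structure(list(
    draws = draws, summary = summ, convergence = convergence, dic = NULL,
    spec = spec, priors = priors, config = config, grid = grid,
    eval_rule = eval_rule, constraints = constraints,
    data_fingerprint = data_fingerprint(data),
    model_code = code), class = "mjm_fit")
  fit$.md <- md
  if (compute_dic && monitor_random_effects) fit$dic <- dic(fit)
  fit
}

# Parameters whose R-hat is gated: fixed effects, association, variance
# components (the reported quantities); baseline pieces and random
# effects are reported but not gated.
gated_parameters <- function(spec, md, constraints = list()) {
  out <- colnames(md$X)
  if (ncol(md$W) > 0) out <- c(out, paste0("surv:", colnames(md$W)))
  if (is.null(constraints$alpha)) out <- c(out, "alpha")
  if (is.null(constraints$sigma_eps)) out <- c(out, "sigma_eps")
  if (!isTRUE(constraints$u_zero)) {
    p <- spec$p_u
    out <- c(out, sprintf("Sigma_u[%d,%d]", rep(seq_len(p), p), rep(seq_len(p), each = p)))
  }
  if (spec$multilevel) out <- c(out, "sigma_v", "sigma_g")
  out
}

# Cheap order-independent fingerprint used to assert that paired model
# fits saw identical data.
data_fingerprint <- function(data) {
  c(n_long = nrow(data$longitudinal), n_subj = nrow(data$survival),
    sum_y = sum(data$longitudinal$y), sum_t = sum(data$longitudinal$time),
    sum_T = sum(data$survival$observed_time), events = sum(data$survival$event))
}

#' @export
print.mjm_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("%d chains x %d draws (thin %d, burn-in %d); convergence gate (R-hat < %.1f): %s\n",
              x$config$chains, x$config$draws_per_chain, x$config$thin,
              x$config$burn_in, x$convergence$threshold,
              if (x$convergence$converged) "PASSED" else "NOT PASSED"))
  if (!is.null(x$dic)) cat(sprintf("DIC: %.2f (pD = %.1f)\n", x$dic["DIC"], x$dic["pD"]))
  keep <- !grepl("^(u|v|g)\\[", rownames(x$summary))
  print(round(x$summary[keep, c("mean", "sd", "q2.5", "q97.5", "rhat", "ess")], 4))
  invisible(x)
}

#' Split-chain Gelman-Rubin-Brooks diagnostic (R-hat)
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half, so within-chain trends inflate the statistic. Values below
#' 1.1 on all reported parameters are taken as convergence.
#'
#' @param chains matrix of draws (iterations x chains) or list of
#'   equal-length numeric vectors; at least 2 chains of at least 4
#'   draws.
#' @return Scalar R-hat; `Inf` when between-chain variance is positive
#'   but within-chain variance is zero; `NaN` for fully degenerate
#'   input.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop_mjm("argument", "R-hat requires at least 2 chains")
  if (nrow(chains) < 4L) stop_mjm("argument", "R-hat requires at least 4 draws per chain")
  n2 <- floor(nrow(chains) / 2)
  split <- cbind(chains[seq_len(n2), , drop = FALSE],
                 chains[seq(nrow(chains) - n2 + 1, nrow(chains)), , drop = FALSE])
  W <- mean(apply(split, 2, stats::var))
  B <- n2 * stats::var(colMeans(split))
  if (W == 0) return(if (B > 0) Inf else NaN)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Autocorrelation function of a chain of draws
#'
#' Standard (biased, variance-normalized) autocorrelation estimator;
#' lag 0 is 1 by construction. A constant chain has no defined
#' autocorrelation and yields `NaN` with a warning.
#'
#' @param draws numeric vector of draws from one chain.
#' @param max_lag largest lag (must be < length of the chain).
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
acf_draws <- function(draws, max_lag) {
  draws <- as.numeric(draws)
  if (max_lag >= length(draws)) stop_mjm("argument", "max_lag must be < number of draws")
  if (stats::var(draws) == 0) {
    warning("constant chain: autocorrelation undefined")
    return(rep(NaN, max_lag + 1))
  }
  drop(stats::acf(draws, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

# Effective sample size by the initial-positive-sequence
# autocorrelation-sum estimator, on chain-mean-centered draws pooled
# across chains.
ess_draws <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (n < 4) return(NA_real_)
  v <- apply(chains, 2, stats::var)
  if (all(v == 0)) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    if (v[j] == 0) rep(0, max_lag + 1)
    else drop(stats::acf(chains[, j], lag.max = max_lag, plot = FALSE)$acf)
  }, numeric(max_lag + 1)))
  tau <- 1
  k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho[k + 1] + rho[k + 2]
    if (is.na(pair) || pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  # block samplers can produce slightly antithetic draws (tau < 1);
  # cap the ESS at the draw count so MCSEs are never understated
  n * m / max(tau, 1)
}

#' Summarize posterior draws
#'
#' Pooled-chain posterior mean, SD, 2.5% and 97.5% quantiles (linear
#' interpolation), split-chain R-hat and effective sample size per
#' parameter.
#'
#' @param draws a `posterior_draws` object from [fit_mjm()], or a
#'   (draws x chains) matrix for a single parameter.
#' @return Data frame of class `posterior_summary`, one row per
#'   parameter, columns `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, `ess`.
#' @export
summarize_draws <- function(draws) {
  if (is.matrix(draws) || is.numeric(draws)) {
    arr <- array(as.matrix(draws),
                 dim = c(NROW(as.matrix(draws)), NCOL(as.matrix(draws)), 1),
                 dimnames = list(NULL, NULL, "param"))
  } else arr <- draws$draws
  params <- dimnames(arr)[[3]]
  multi <- dim(arr)[2] >= 2 && dim(arr)[1] >= 4
  rows <- lapply(seq_along(params), function(p) {
    x <- arr[, , p, drop = FALSE]
    pooled <- as.numeric(x)
    qs <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = qs[1], q97.5 = qs[2],
               rhat = if (multi) rhat(matrix(x, dim(arr)[1], dim(arr)[2])) else NA_real_,
               ess = ess_draws(matrix(x, dim(arr)[1], dim(arr)[2])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- params
  class(out) <- c("posterior_summary", "data.frame")
  out
}

# Reconstruct an mjm_state from one draw (a named vector of canonical
# parameters), filling constrained components from `constraints`.
state_from_draw <- function(vals, fit) {
  md <- fit$.md
  spec <- fit$spec
  p <- spec$p_u
  n <- md$n
  cn <- names(vals)
  pick <- function(nms) unname(vals[nms])
  beta <- pick(colnames(md$X))
  lam <- pick(paste0("lam[", seq_len(md$Q), "]"))
  alpha <- if (!is.null(fit$constraints$alpha)) fit$constraints$alpha else unname(vals["alpha"])
  sigma_eps <- if (!is.null(fit$constraints$sigma_eps)) fit$constraints$sigma_eps
               else unname(vals["sigma_eps"])
  gamma <- if (ncol(md$W) > 0) pick(paste0("surv:", colnames(md$W))) else numeric(0)
  if (isTRUE(fit$constraints$u_zero)) {
    u <- matrix(0, n, p); Sigma_u <- diag(p)
  } else {
    u <- matrix(pick(sprintf("u[%d,%d]", rep(seq_len(n), p), rep(seq_len(p), each = n))), n, p)
    Sigma_u <- matrix(pick(sprintf("Sigma_u[%d,%d]", rep(seq_len(p), p),
                                   rep(seq_len(p), each = p))), p, p)
    Sigma_u <- (Sigma_u + t(Sigma_u)) / 2
  }
  v <- g <- NULL; sigma_v <- sigma_g <- NULL
  if (spec$multilevel) {
    v <- pick(paste0("v[", seq_len(md$L), "]"))
    g <- pick(paste0("g[", seq_len(md$L), "]"))
    sigma_v <- unname(vals["sigma_v"]); sigma_g <- unname(vals["sigma_g"])
  }
  list(beta = beta, sigma_eps = sigma_eps, Sigma_u = Sigma_u, sigma_v = sigma_v,
       gamma = gamma, alpha = alpha, sigma_g = sigma_g, lam = lam,
       u = u, v = v, g = g)
}

# Conditional deviance of one state: -2 * (longitudinal + survival
# log-likelihood), conditional on the random effects.
conditional_deviance <- function(state, fit) {
  md <- fit$.md
  spec <- fit$spec
  m_long <- drop(md$X %*% state$beta) +
    rowSums(z_columns(spec, md$lframe$time) * state$u[md$lframe$subject_index, , drop = FALSE])
  if (spec$multilevel) m_long <- m_long + state$v[md$lframe$group_index]
  ll_y <- sum(stats::dnorm(md$lframe$y, m_long, state$sigma_eps, log = TRUE))
  m_s <- drop(md$Xs %*% state$beta) +
    rowSums(z_columns(spec, md$sframe$time) * state$u[md$sframe$subject_index, , drop = FALSE])
  if (spec$multilevel) m_s <- m_s + state$v[md$sframe$group_index]
  eta <- log(md$pseudo$exposure) + log(state$lam[md$pseudo$q]) + state$alpha * m_s
  if (length(state$gamma)) eta <- eta + drop(md$W %*% state$gamma)
  if (spec$multilevel) eta <- eta + state$g[md$pseudo$group_index]
  ll_s <- sum(md$pseudo$d * eta - exp(eta))
  -2 * (ll_y + ll_s)
}

#' Deviance information criterion (conditional on random effects)
#'
#' \eqn{\mathrm{DIC} = \bar{D} + p_D} with \eqn{p_D = \bar{D} -
#' D(\bar\theta)}, where the deviance is minus twice the sum of the
#' longitudinal and survival log-likelihoods conditional on the random
#' effects (the convention of hierarchical Gibbs samplers; DIC variants
#' differ, and this is the one that reproduces trajectory selection
#' among nested joint models). \eqn{\bar\theta} plugs in the posterior
#' means of every quantity entering the deviance, including the random
#' effects.
#'
#' @param fit an [fit_mjm()] result with random effects monitored.
#' @return Named vector with `DIC`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "mjm_fit"))
  arr <- fit$draws$draws
  flat <- matrix(aperm(arr, c(1, 2, 3)),
                 nrow = dim(arr)[1] * dim(arr)[2], ncol = dim(arr)[3])
  colnames(flat) <- dimnames(arr)[[3]]
  if (!isTRUE(fit$constraints$u_zero) && !any(grepl("^u\\[", colnames(flat))))
    stop_mjm("argument", "DIC needs monitored random effects (monitor_random_effects = TRUE)")
  devs <- vapply(seq_len(nrow(flat)), function(i)
    conditional_deviance(state_from_draw(flat[i, ], fit), fit), 0)
  dbar <- mean(devs)
  dhat <- conditional_deviance(state_from_draw(colMeans(flat), fit), fit)
  pd <- dbar - dhat
  c(DIC = dbar + pd, pD = pd, Dbar = dbar, Dhat = dhat)
}

#' Serialize a fit report to JSON
#'
#' Writes the posterior summary table, gated R-hats, convergence
#' verdict, DIC and the configuration echo.
#'
#' @param fit an [fit_mjm()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  summ <- fit$summary
  rep <- list(
    summary = cbind(parameter = rownames(summ), as.data.frame(summ)),
    convergence = list(converged = fit$convergence$converged,
                       threshold = fit$convergence$threshold,
                       rhat = as.list(fit$convergence$rhat)),
    dic = if (!is.null(fit$dic)) as.list(fit$dic),
    config = unclass(fit$config),
    eval_rule = fit$eval_rule,
    data_fingerprint = as.list(fit$data_fingerprint))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an MCMC configuration from YAML
#'
#' @param path YAML file with any of the fields of [mcmc_config()].
#' @return An [mcmc_config()].
#' @export
read_mcmc_config <- function(path) {
  do.call(mcmc_config, yaml::read_yaml(path) %||% list())
}

#' Write posterior draws to a columnar archive
#'
#' Long-format CSV (`chain,draw,parameter,value`) plus a JSON manifest
#' (parameter registry, chain count, thinning, seed), loadable with
#' [read_draws()] for re-summarization.
#'
#' @param draws a `posterior_draws` object (e.g. `fit$draws`).
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arr <- draws$draws
  nd <- dim(arr)[1]; nc <- dim(arr)[2]
  long <- data.frame(
    chain = rep(seq_len(nc), each = nd, times = dim(arr)[3]),
    draw = rep(seq_len(nd), times = nc * dim(arr)[3]),
    parameter = rep(draws$params, each = nd * nc),
    value = formatC(as.vector(arr), digits = 17, format = "g"))
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(parameters = draws$params, chains = nc, draws_per_chain = nd,
         thin = draws$config$thin, burn_in = draws$config$burn_in,
         seed = draws$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a posterior draw archive
#'
#' @param dir directory written by [write_draws()].
#' @return A `posterior_draws` object.
#' @export
read_draws <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "draws.csv"))
  arr <- array(long$value[order(match(long$parameter, man$parameters),
                                long$chain, long$draw)],
               dim = c(man$draws_per_chain, man$chains, length(man$parameters)),
               dimnames = list(NULL, NULL, man$parameters))
  structure(list(draws = arr, params = man$parameters,
                 config = mcmc_config(chains = man$chains, adapt = 0,
                                      burn_in = man$burn_in, thin = man$thin,
                                      draws_per_chain = man$draws_per_chain,
                                      seed = man$seed)),
            class = "posterior_draws")
}
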