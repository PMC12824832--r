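#' Model specification for the multilevel joint model
#'
#' Describes one member of the model family: the shape of the
#' longitudinal trajectory, the subject-level random effects, whether
#' group-level random effects are present in each submodel (the
#' three-level multilevel joint model, MJM) or absent (the two-level
#' standard joint model, JM), and the fixed-effect covariate sets. The
#' two submodels are linked by the current-value association: the
#' log-hazard at time t contains \eqn{\alpha \, m(t)}, the model-implied
#' (noise-free) longitudinal mean.
#'
#' Trajectories:
#' \describe{
#'   \item{linear}{\code{1 + time + treatment + time:treatment}; random
#'     intercepts and slopes at the subject level by default.}
#'   \item{quadratic_shared_curvature}{adds \code{time^2} with a common
#'     curvature in both arms.}
#'   \item{quadratic_full}{also lets the curvature differ by treatment.}
#' }
#'
#' @param trajectory trajectory shape (see Details).
#' @param subject_random subject-level random-effect structure.
#' @param multilevel if `TRUE` (the MJM), group-level random intercepts
#'   enter both submodels; if `FALSE` (the standard JM) neither does.
#' @param fixed_covariates_long extra fixed-effect terms for the
#'   longitudinal submodel (column names, optionally `name:time`
#'   interactions).
#' @param fixed_covariates_surv fixed-effect covariates \eqn{\omega} for
#'   the survival submodel (may duplicate longitudinal covariates; the
#'   sets are configured independently). Empty by default: treatment
#'   then affects the hazard only through the current value.
#' @param association only `"current_value"` is supported.
#' @return An object of class `mjm_spec`.
#' @export
mjm_spec <- function(trajectory = c("linear", "quadratic_shared_curvature", "quadratic_full"),
                     subject_random = c("intercept_slope", "intercept_only"),
                     multilevel = TRUE,
                     fixed_covariates_long = character(),
                     fixed_covariates_surv = character(),
                     association = "current_value") {
  trajectory <- match.arg(trajectory)
  subject_random <- match.arg(subject_random)
  if (!identical(association, "current_value"))
    stop_mjm("spec", "only the current-value association is supported")
  structure(list(
    trajectory = trajectory,
    subject_random = subject_random,
    multilevel = isTRUE(multilevel),
    group_random_longitudinal = if (isTRUE(multilevel)) "intercept" else "none",
    group_random_survival = if (isTRUE(multilevel)) "intercept" else "none",
    fixed_covariates_long = as.character(fixed_covariates_long),
    fixed_covariates_surv = as.character(fixed_covariates_surv),
    association = "current_value",
    p_u = if (subject_random == "intercept_slope") 2L else 1L
  ), class = "mjm_spec")
}

#' @export
print.mjm_spec <- function(x, ...) {
  cat(sprintf("%s joint model: %s trajectory, subject random effects: %s\n",
              if (x$multilevel) "Multilevel (three-level)" else "Standard (two-level)",
              gsub("_", " ", x$trajectory), gsub("_", " + ", x$subject_random)))
  invisible(x)
}

long_formula <- function(spec) {
  terms <- c("time", "treatment", "time:treatment")
  if (spec$trajectory != "linear") terms <- c(terms, "I(time^2)")
  if (spec$trajectory == "quadratic_full") terms <- c(terms, "I(time^2):treatment")
  terms <- c(terms, spec$fixed_covariates_long)
  stats::reformulate(terms, intercept = TRUE)
}

# Fixed-effect design for the longitudinal mean, given a frame with
# columns time, treatment and any extra covariates.
long_design <- function(spec, frame) {
  mm <- tryCatch(stats::model.matrix(long_formula(spec), frame),
                 error = function(e) stop_mjm("spec", conditionMessage(e)))
  mm
}

# Survival fixed-effect design (no intercept: absorbed by log lambda_q).
surv_design <- function(spec, frame) {
  if (!length(spec$fixed_covariates_surv))
    return(matrix(0, nrow(frame), 0))
  tryCatch(stats::model.matrix(
    stats::reformulate(spec$fixed_covariates_surv, intercept = FALSE), frame),
    error = function(e) stop_mjm("spec", conditionMessage(e)))
}

# Join group-level columns (treatment + group covariates) onto a table
# carrying group_id.
with_group_columns <- function(df, data) {
  grp <- data$groups
  add <- setdiff(names(grp), c("group_id", "group_index", names(df)))
  idx <- match(df$group_id, grp$group_id)
  for (nm in c("treatment", setdiff(add, "treatment")))
    if (!nm %in% names(df)) df[[nm]] <- grp[[nm]][idx]
  df
}

# Join subject-level survival covariates onto a table carrying subject_id.
with_survival_columns <- function(df, data) {
  sv <- data$survival
  add <- setdiff(names(sv),
                 c("subject_id", "group_id", "subject_index", "group_index",
                   "observed_time", "event", names(df)))
  idx <- match(df$subject_id, sv$subject_id)
  for (nm in add) df[[nm]] <- sv[[nm]][idx]
  df
}

#' Priors for the multilevel joint model
#'
#' Weakly informative defaults: normal priors with variance 1000
#' (precision 0.001) on all regression coefficients and the association;
#' Inverse-Gamma(0.01, 0.01) on the residual variance
#' \eqn{\sigma_\varepsilon^2}; Gamma(0.01, 0.01) on each baseline-hazard
#' piece \eqn{\lambda_q}; Inverse-Wishart with identity scale and
#' degrees of freedom equal to the dimension on each random-effect
#' covariance. For scalar group-level variances the 1x1
#' Inverse-Wishart(I, 1) is applied through its exact reduction,
#' Inverse-Gamma(1/2, 1/2) on the variance.
#'
#' @param beta_variance,gamma_variance,alpha_variance prior variances of
#'   the fixed-effect, survival-covariate and association coefficients.
#' @param sigma_eps_ig shape and rate of the Inverse-Gamma prior on the
#'   residual variance.
#' @param lambda_gamma shape and rate of the Gamma prior on each
#'   \eqn{\lambda_q}.
#' @param wishart_scale scalar multiplier of the identity scale matrix
#'   of the Inverse-Wishart priors.
#' @return An object of class `mjm_priors`.
#' @export
mjm_priors <- function(beta_variance = 1000, sigma_eps_ig = c(0.01, 0.01),
                       lambda_gamma = c(0.01, 0.01),
                       gamma_variance = 1000, alpha_variance = 1000,
                       wishart_scale = 1) {
  pr <- list(beta_variance = beta_variance, sigma_eps_ig = sigma_eps_ig,
             lambda_gamma = lambda_gamma, gamma_variance = gamma_variance,
             alpha_variance = alpha_variance, wishart_scale = wishart_scale)
  if (any(unlist(pr) <= 0)) stop_mjm("argument", "all prior hyperparameters must be > 0")
  structure(pr, class = "mjm_priors")
}

#' Parameter state of the joint model
#'
#' Houses the full parameter vector
#' \eqn{\Theta = (\beta, \sigma_\varepsilon, \Sigma_u, \sigma_v, \gamma,
#' \alpha, \sigma_g, \lambda)} together with the random effects
#' (subject-level `u`, group-level longitudinal `v`, group-level
#' frailty `g`).
#'
#' @param beta fixed-effect coefficients, in the column order of the
#'   longitudinal design matrix.
#' @param sigma_eps residual SD (> 0).
#' @param Sigma_u subject random-effect covariance (p_u x p_u, SPD).
#' @param sigma_v group-level SD in the longitudinal submodel (MJM only).
#' @param gamma survival fixed-effect coefficients (may be empty).
#' @param alpha current-value association coefficient.
#' @param sigma_g group-level frailty SD in the survival submodel (MJM only).
#' @param lam baseline hazard pieces \eqn{\lambda_1, \dots, \lambda_Q} (> 0).
#' @param u subject random effects (n x p_u matrix).
#' @param v group random intercepts, longitudinal (length L; MJM only).
#' @param g group frailties (length L; MJM only).
#' @return An object of class `mjm_state`.
#' @export
mjm_state <- function(beta, sigma_eps, Sigma_u, alpha, lam, u,
                      sigma_v = NULL, sigma_g = NULL, gamma = numeric(0),
                      v = NULL, g = NULL) {
  Sigma_u <- as.matrix(Sigma_u)
  u <- as.matrix(u)
  if (sigma_eps <= 0) stop_mjm("domain", "sigma_eps must be > 0")
  if (any(lam <= 0)) stop_mjm("domain", "all lambda_q must be > 0")
  if (!isSymmetric(unname(Sigma_u)) || any(eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop_mjm("domain", "Sigma_u must be symmetric positive definite")
  if (ncol(u) != ncol(Sigma_u)) stop_mjm("spec", "u and Sigma_u dimensions disagree")
  if (!is.null(sigma_v) && sigma_v <= 0) stop_mjm("domain", "sigma_v must be > 0")
  if (!is.null(sigma_g) && sigma_g <= 0) stop_mjm("domain", "sigma_g must be > 0")
  structure(list(beta = beta, sigma_eps = sigma_eps, Sigma_u = Sigma_u,
                 sigma_v = sigma_v, gamma = gamma, alpha = alpha,
                 sigma_g = sigma_g, lam = lam, u = u, v = v, g = g),
            class = "mjm_state")
}

# Random-effect design values per subject_random structure.
z_columns <- function(spec, time) {
  if (spec$subject_random == "intercept_slope") cbind(1, time) else cbind(rep(1, length(time)))
}

#' Model-implied longitudinal mean
#'
#' Evaluates \eqn{m_{jl}(t) = X^T\beta + Z^T u_{jl} + v_l} for each row
#' of `frame`.
#'
#' @param state an [mjm_state()].
#' @param spec an [mjm_spec()].
#' @param frame data frame with columns `time`, `treatment`,
#'   `subject_index`, `group_index` and any covariates named in the spec.
#' @return Numeric vector of means, one per row.
#' @export
longitudinal_mean <- function(state, spec, frame) {
  X <- long_design(spec, frame)
  if (length(state$beta) != ncol(X))
    stop_mjm("spec", sprintf("beta has length %d but design has %d columns",
                             length(state$beta), ncol(X)))
  m <- as.numeric(X %*% state$beta)
  Z <- z_columns(spec, frame$time)
  m <- m + rowSums(Z * state$u[frame$subject_index, , drop = FALSE])
  if (spec$multilevel) m <- m + state$v[frame$group_index]
  m
}

#' Log-likelihood of the longitudinal submodel
#'
#' Sum over measurements of the normal log-density with mean
#' \eqn{m_{jl}(t_{ijl})} and SD \eqn{\sigma_\varepsilon}, conditional on
#' the random effects.
#'
#' @inheritParams longitudinal_mean
#' @param data a [trial_dataset()].
#' @return Scalar log-likelihood.
#' @export
log_density_longitudinal <- function(state, spec, data) {
  if (state$sigma_eps <= 0) stop_mjm("domain", "sigma_eps must be > 0")
  frame <- with_group_columns(data$longitudinal, data)
  m <- longitudinal_mean(state, spec, frame)
  sum(stats::dnorm(frame$y, m, state$sigma_eps, log = TRUE))
}

# Frame for evaluating the current value at each pseudo-record's
# evaluation time.
pseudo_frame <- function(pseudo, data) {
  frame <- pseudo
  frame$time <- pseudo$eval_time
  frame <- with_group_columns(frame, data)
  with_survival_columns(frame, data)
}

#' Log-mean of the pseudo-Poisson outcome
#'
#' \eqn{\log\mu_{jlq} = \log t_{jlq} + \log\lambda_q + \omega^T\gamma +
#' \alpha\, m_{jlq}(t) + g_l}: the auxiliary Poisson representation of
#' the piecewise-constant proportional-hazards submodel, with the
#' exposure time as offset.
#'
#' @inheritParams longitudinal_mean
#' @param pseudo pseudo-record table from [split_dataset()] (optionally
#'   augmented with survival covariate columns).
#' @param m_value current value \eqn{m(t)} per record, evaluated at the
#'   record's `eval_time`.
#' @return Numeric vector of log-means.
#' @export
log_mu <- function(state, spec, pseudo, m_value) {
  if (any(pseudo$exposure <= 0)) stop_mjm("domain", "exposure must be > 0")
  eta <- log(pseudo$exposure) + log(state$lam[pseudo$q]) + state$alpha * m_value
  if (length(state$gamma)) {
    W <- surv_design(spec, pseudo)
    eta <- eta + drop(W %*% state$gamma)
  }
  if (spec$multilevel) eta <- eta + state$g[pseudo$group_index]
  eta
}

#' Log-likelihood of the survival submodel (auxiliary Poisson form)
#'
#' \eqn{\sum_k [d_k \log\mu_k - \mu_k]}, conditional on the random
#' effects (the \eqn{\log d_k!} term vanishes for \eqn{d \in \{0,1\}}).
#'
#' @inheritParams log_mu
#' @return Scalar log-likelihood.
#' @export
log_density_survival <- function(state, spec, pseudo, m_value) {
  lmu <- log_mu(state, spec, pseudo, m_value)
  sum(pseudo$d * lmu - exp(lmu))
}

#' Log-likelihood of the piecewise-exponential survival model
#'
#' The direct piecewise-exponential form
#' \eqn{\sum_{jl} [\delta_{jl}\log\lambda_{jl}(T_{jl}) - \sum_q t_{jlq}
#' \lambda_{jlq}]}, computed from the same per-record hazard values as
#' the auxiliary Poisson form. The two differ by the parameter-free
#' constant \eqn{\sum_{d=1}\log t_{jlq}} (the likelihoods are
#' proportional, so posteriors over shared parameters coincide).
#'
#' @inheritParams log_mu
#' @return Scalar log-likelihood.
#' @export
log_lik_piecewise_exp <- function(state, spec, pseudo, m_value) {
  log_h <- log_mu(state, spec, pseudo, m_value) - log(pseudo$exposure)
  sum(pseudo$d * log_h - pseudo$exposure * exp(log_h))
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Inverse-Wishart log-density with scale Psi and df nu.
dinvwishart_log <- function(X, Psi, df) {
  p <- nrow(X)
  cx <- tryCatch(chol(X), error = function(e) NULL)
  if (is.null(cx)) return(-Inf)
  ldX <- 2 * sum(log(diag(cx)))
  ldPsi <- 2 * sum(log(diag(chol(Psi))))
  df / 2 * ldPsi - df * p / 2 * log(2) - lmvgamma(df / 2, p) -
    (df + p + 1) / 2 * ldX - 0.5 * sum(diag(Psi %*% chol2inv(cx)))
}

# Inverse-Gamma log-density (shape a, rate b) on x.
dinvgamma_log <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

#' Joint log-prior of the parameter state
#'
#' Sum of the component log-priors described in [mjm_priors()]; returns
#' `-Inf` outside the support rather than erroring.
#'
#' @inheritParams longitudinal_mean
#' @param priors an [mjm_priors()].
#' @return Scalar log-prior density.
#' @export
log_prior <- function(state, spec, priors) {
  if (state$sigma_eps <= 0 || any(state$lam <= 0)) return(-Inf)
  if (spec$multilevel && (state$sigma_v <= 0 || state$sigma_g <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(state$beta, 0, sqrt(priors$beta_variance), log = TRUE)) +
    stats::dnorm(state$alpha, 0, sqrt(priors$alpha_variance), log = TRUE) +
    dinvgamma_log(state$sigma_eps^2, priors$sigma_eps_ig[1], priors$sigma_eps_ig[2]) +
    sum(stats::dgamma(state$lam, shape = priors$lambda_gamma[1],
                      rate = priors$lambda_gamma[2], log = TRUE)) +
    dinvwishart_log(state$Sigma_u, priors$wishart_scale * diag(nrow(state$Sigma_u)),
                    nrow(state$Sigma_u))
  if (length(state$gamma))
    lp <- lp + sum(stats::dnorm(state$gamma, 0, sqrt(priors$gamma_variance), log = TRUE))
  if (spec$multilevel)
    lp <- lp +
      dinvgamma_log(state$sigma_v^2, 1 / 2, priors$wishart_scale / 2) +
      dinvgamma_log(state$sigma_g^2, 1 / 2, priors$wishart_scale / 2)
  lp
}

# Log-density of the random effects given their (co)variances.
random_effect_log_density <- function(state, spec) {
  p <- ncol(state$Sigma_u)
  cS <- tryCatch(chol(state$Sigma_u), error = function(e) NULL)
  if (is.null(cS)) return(-Inf)
  Sinv <- chol2inv(cS)
  quad <- rowSums((state$u %*% Sinv) * state$u)
  ld <- -nrow(state$u) * (p / 2 * log(2 * pi) + sum(log(diag(cS)))) - 0.5 * sum(quad)
  if (spec$multilevel)
    ld <- ld + sum(stats::dnorm(state$v, 0, state$sigma_v, log = TRUE)) +
      sum(stats::dnorm(state$g, 0, state$sigma_g, log = TRUE))
  ld
}

#' Joint log-posterior (up to the normalizing constant)
#'
#' Longitudinal log-likelihood + survival (auxiliary Poisson)
#' log-likelihood + random-effect log-densities + log-prior, over the
#' original (constrained) parameters. Setting up a two-level spec
#' (`multilevel = FALSE`) with `v`, `g` absent yields exactly the
#' standard joint model's log-posterior.
#'
#' @inheritParams log_prior
#' @param data a [trial_dataset()].
#' @param pseudo pseudo-record table from [split_dataset()].
#' @return Scalar log-posterior density (finite on the interior of the
#'   support; `-Inf` outside).
#' @export
log_posterior <- function(state, spec, priors, data, pseudo) {
  lp <- log_prior(state, spec, priors)
  if (!is.finite(lp)) return(lp)
  re <- random_effect_log_density(state, spec)
  if (!is.finite(re)) return(re)
  frame <- pseudo_frame(pseudo, data)
  m_value <- longitudinal_mean(state, spec, frame)
  lp + re + log_density_longitudinal(state, spec, data) +
    log_density_survival(state, spec, frame, m_value)
}

#' Analytic gradient of the joint log-posterior
#'
#' Gradient with respect to the flattened parameter vector in the order:
#' `beta`, `gamma`, `alpha`, `u` (column-major), `v`, `g`, `lam`,
#' `var_eps` (\eqn{\sigma_\varepsilon^2}), `var_v`, `var_g`, and the
#' lower triangle of `Sigma_u` (diagonal first-order, off-diagonals as
#' symmetric pairs). Variance components are differentiated on the
#' variance scale.
#'
#' @inheritParams log_posterior
#' @return Named numeric vector.
#' @export
log_posterior_grad <- function(state, spec, priors, data, pseudo) {
  lframe <- with_group_columns(data$longitudinal, data)
  X <- long_design(spec, lframe)
  Zl <- z_columns(spec, lframe$time)
  m_long <- longitudinal_mean(state, spec, lframe)
  r <- lframe$y - m_long
  ve <- state$sigma_eps^2
  p_u <- ncol(state$Sigma_u)
  n <- nrow(state$u)

  sframe <- pseudo_frame(pseudo, data)
  Xs <- long_design(spec, sframe)
  Zs <- z_columns(spec, sframe$time)
  m_surv <- longitudinal_mean(state, spec, sframe)
  s <- sframe$d - exp(log_mu(state, spec, sframe, m_surv))

  g_beta <- drop(crossprod(X, r)) / ve + state$alpha * drop(crossprod(Xs, s)) -
    state$beta / priors$beta_variance
  g_alpha <- sum(s * m_surv) - state$alpha / priors$alpha_variance
  g_gamma <- if (length(state$gamma)) {
    W <- surv_design(spec, sframe)
    drop(crossprod(W, s)) - state$gamma / priors$gamma_variance
  } else numeric(0)

  Sinv <- chol2inv(chol(state$Sigma_u))
  g_u <- matrix(0, n, p_u)
  for (k in seq_len(p_u)) {
    g_u[, k] <- g_u[, k] +
      unname(tapply(Zl[, k] * r, lframe$subject_index, sum)[as.character(seq_len(n))]) / ve
    g_u[, k] <- ifelse(is.na(g_u[, k]), 0, g_u[, k])
    add <- tapply(state$alpha * Zs[, k] * s, sframe$subject_index, sum)[as.character(seq_len(n))]
    g_u[, k] <- g_u[, k] + ifelse(is.na(add), 0, add)
  }
  g_u <- g_u - state$u %*% Sinv

  nm <- c(paste0("beta", seq_along(state$beta)),
          if (length(state$gamma)) paste0("gamma", seq_along(state$gamma)), "alpha",
          paste0("u", rep(seq_len(p_u), each = n), "_", rep(seq_len(n), p_u)))
  out <- c(g_beta, g_gamma, g_alpha, as.vector(g_u))

  if (spec$multilevel) {
    L <- length(state$v)
    gl_long <- tapply(r, lframe$group_index, sum)[as.character(seq_len(L))] / ve
    gl_surv <- tapply(state$alpha * s, sframe$group_index, sum)[as.character(seq_len(L))]
    g_v <- ifelse(is.na(gl_long), 0, gl_long) + ifelse(is.na(gl_surv), 0, gl_surv) -
      state$v / state$sigma_v^2
    gg <- tapply(s, sframe$group_index, sum)[as.character(seq_len(L))]
    g_g <- ifelse(is.na(gg), 0, gg) - state$g / state$sigma_g^2
    out <- c(out, g_v, g_g)
    nm <- c(nm, paste0("v", seq_len(L)), paste0("g", seq_len(L)))
  }

  g_lam <- (unname(tapply(s, factor(sframe$q, levels = seq_along(state$lam)), sum))) / state$lam
  g_lam[is.na(g_lam)] <- 0
  g_lam <- g_lam + (priors$lambda_gamma[1] - 1) / state$lam - priors$lambda_gamma[2]
  out <- c(out, g_lam)
  nm <- c(nm, paste0("lam", seq_along(state$lam)))

  a_e <- priors$sigma_eps_ig[1]; b_e <- priors$sigma_eps_ig[2]
  g_ve <- -length(r) / (2 * ve) + sum(r^2) / (2 * ve^2) - (a_e + 1) / ve + b_e / ve^2
  out <- c(out, g_ve); nm <- c(nm, "var_eps")

  if (spec$multilevel) {
    vv <- state$sigma_v^2; vg <- state$sigma_g^2; L <- length(state$v)
    g_vv <- -L / (2 * vv) + sum(state$v^2) / (2 * vv^2) - (1 / 2 + 1) / vv +
      priors$wishart_scale / 2 / vv^2
    g_vg <- -L / (2 * vg) + sum(state$g^2) / (2 * vg^2) - (1 / 2 + 1) / vg +
      priors$wishart_scale / 2 / vg^2
    out <- c(out, g_vv, g_vg); nm <- c(nm, "var_v", "var_g")
  }

  S <- crossprod(state$u)
  G <- -n / 2 * Sinv + Sinv %*% S %*% Sinv / 2
  nu <- p_u
  G <- G - (nu + p_u + 1) / 2 * Sinv + priors$wishart_scale / 2 * Sinv %*% Sinv
  for (i in seq_len(p_u)) for (j in seq_len(i)) {
    out <- c(out, if (i == j) G[i, i] else 2 * G[i, j])
    nm <- c(nm, sprintf("Sigma_u_%d_%d", i, j))
  }
  stats::setNames(out, nm)
}

#' Serialize a model and prior specification to YAML
#'
#' @inheritParams log_prior
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_model_config <- function(spec, priors, path) {
  yaml::write_yaml(list(model = unclass(spec), priors = unclass(priors)), path)
  invisible(path)
}

#' Read a model and prior specification from YAML
#'
#' @param path YAML file produced by [write_model_config()] (or written
#'   by hand against the same schema; omitted prior fields fall back to
#'   the defaults of [mjm_priors()]).
#' @return List with elements `spec` and `priors`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$model %||% list()
  spec <- mjm_spec(
    trajectory = m$trajectory %||% "linear",
    subject_random = m$subject_random %||% "intercept_slope",
    multilevel = m$multilevel %||% TRUE,
    fixed_covariates_long = m$fixed_covariates_long %||% character(),
    fixed_covariates_surv = m$fixed_covariates_surv %||% character())
  p <- cfg$priors %||% list()
  priors <- mjm_priors(
    beta_variance = p$beta_variance %||% 1000,
    sigma_eps_ig = unlist(p$sigma_eps_ig %||% c(0.01, 0.01)),
    lambda_gamma = unlist(p$lambda_gamma %||% c(0.01, 0.01)),
    gamma_variance = p$gamma_variance %||% 1000,
    alpha_variance = p$alpha_variance %||% 1000,
    wishart_scale = p$wishart_scale %||% 1)
  list(spec = spec, priors = priors)
}
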