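#' The fully crossed simulation design grid
#'
#' Crosses censoring target x number of groups x group size x
#' group-level longitudinal variance x group-level frailty variance x
#' interval count, in deterministic order (the last factor varies
#' fastest). The default levels give the 72-cell design.
#'
#' @param censoring,L,group_size,var_v,var_g,Q factor levels.
#' @param truths a [true_params()] copied into every cell.
#' @param seed master seed; each cell gets a derived scenario seed.
#' @return List of [scenario_config()]s with names `scenario_<i>`.
#' @export
scenario_grid <- function(censoring = c(0.2, 0.6), L = c(50, 100, 200),
                          group_size = 30, var_v = c(5, 18), var_g = c(0.4, 1),
                          Q = c(11, 7, 3), truths = true_params(), seed = 1L) {
  cells <- expand.grid(Q = Q, var_g = var_g, var_v = var_v, group_size = group_size,
                       L = L, censoring = censoring,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("censoring", "L", "group_size", "var_v", "var_g", "Q")]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    scenario_config(censoring_target = cells$censoring[i], L = cells$L[i],
                    group_size = cells$group_size[i], var_v = cells$var_v[i],
                    var_g = cells$var_g[i], Q = cells$Q[i], truths = truths,
                    seed = derive_seed(seed, "scenario", i))
  })
  names(out) <- paste0("scenario_", seq_along(out))
  out
}

#' Desk-scale scenario preset
#'
#' A reduced configuration (30 groups of 15, Q = 3) that preserves the
#' generative structure of the full design while fitting in minutes on
#' one core; used for smoke runs and calibration/recovery checks.
#'
#' @param censoring_target censoring target.
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
desk_scenario <- function(censoring_target = 0.2, seed = 1L, ...) {
  scenario_config(censoring_target = censoring_target, L = 30, group_size = 15,
                  var_v = 5, var_g = 0.4, Q = 3, seed = seed, ...)
}

# Canonical parameter names whose recovery is tracked, mapped to the
# generative truths.
truth_map <- function(truths, spec = mjm_spec()) {
  out <- c("(Intercept)" = truths$beta000, "time" = truths$beta100,
           "treatment" = truths$beta001, "time:treatment" = truths$beta101,
           "alpha" = truths$alpha,
           "Sigma_u[1,1]" = truths$var_u0,
           "sigma_eps" = sqrt(truths$var_eps))
  if (spec$p_u == 2)
    out <- c(out, "Sigma_u[2,2]" = truths$var_u1,
             "Sigma_u[1,2]" = truths$rho_u * sqrt(truths$var_u0 * truths$var_u1))
  if (spec$multilevel)
    out <- c(out, "sigma_v" = sqrt(truths$var_v), "sigma_g" = sqrt(truths$var_g))
  out
}

#' Generate and fit one simulation replicate
#'
#' Generates one dataset from the replicate's substream and fits the
#' three-level MJM, and optionally also the two-level JM on the SAME
#' dataset (the paired design: both models always see byte-identical
#' data, asserted via the data fingerprint). A sampler failure is
#' recorded as a non-converged replicate rather than an error.
#'
#' @param scenario a [scenario_config()].
#' @param replicate_index replicate number.
#' @param mcmc an [mcmc_config()].
#' @param fit_both also fit the group-ignoring two-level JM.
#' @param eval_rule passed to [fit_mjm()].
#' @return List with `mjm` (and `jm` if requested), each carrying
#'   `summary`, `converged`, `error`, `fingerprint`; plus `truths`.
#' @export
run_replicate <- function(scenario, replicate_index, mcmc, fit_both = FALSE,
                          eval_rule = "interval_start") {
  sim <- generate_dataset(scenario, replicate_index)
  grid <- equal_length_grid(scenario$survival_follow_up, scenario$Q)
  cfg <- mcmc
  cfg$seed <- derive_seed(mcmc$seed, "replicate", replicate_index)
  one <- function(multilevel) {
    spec <- mjm_spec(multilevel = multilevel)
    res <- tryCatch(
      fit_mjm(sim$data, spec, grid, config = cfg, eval_rule = eval_rule,
              monitor_random_effects = FALSE, compute_dic = FALSE),
      error = function(e) e)
    if (inherits(res, "error"))
      return(list(summary = NULL, converged = FALSE,
                  error = conditionMessage(res),
                  fingerprint = data_fingerprint(sim$data)))
    list(summary = res$summary, converged = res$convergence$converged,
         error = NULL, fingerprint = res$data_fingerprint)
  }
  out <- list(mjm = one(TRUE), truths = sim$truth$params,
              replicate_index = replicate_index)
  if (fit_both) out$jm <- one(FALSE)
  out
}

#' Estimator performance metrics over replicates
#'
#' For each tracked parameter: mean posterior-mean estimate, bias (mean
#' estimate minus true value), relative bias (bias / true; `NA` when the
#' true value is 0), MESE (mean over replicates of the posterior SD) and
#' ESE (standard deviation over replicates of the posterior means).
#' Non-converged replicates are excluded (and counted).
#'
#' @param summaries list of `posterior_summary` objects, one per
#'   converged replicate (entries may be `NULL` for failed replicates).
#' @param truths a [true_params()].
#' @param converged logical vector marking converged replicates (same
#'   length as `summaries`); defaults to all converged.
#' @param spec the [mjm_spec()] the summaries came from.
#' @return Data frame with one row per parameter: `parameter`, `true`,
#'   `mean_est`, `bias`, `relative_bias`, `MESE`, `ESE`,
#'   `n_replicates`, `n_converged`.
#' @export
replicate_metrics <- function(summaries, truths, converged = NULL,
                              spec = mjm_spec()) {
  if (is.null(converged)) converged <- !vapply(summaries, is.null, TRUE)
  stopifnot(length(converged) == length(summaries))
  keep <- which(converged & !vapply(summaries, is.null, TRUE))
  if (!length(keep)) stop_mjm("argument", "no converged replicates")
  tm <- truth_map(truths, spec)
  rows <- lapply(names(tm), function(par) {
    est <- vapply(summaries[keep], function(s) s[par, "mean"], 0)
    psd <- vapply(summaries[keep], function(s) s[par, "sd"], 0)
    true <- tm[[par]]
    bias <- mean(est) - true
    data.frame(parameter = par, true = true, mean_est = mean(est), bias = bias,
               relative_bias = if (true != 0) bias / true else NA_real_,
               MESE = mean(psd),
               ESE = if (length(keep) > 1) stats::sd(est) else NA_real_,
               n_replicates = length(summaries), n_converged = length(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of the MJM and the group-ignoring JM
#'
#' Runs `n_replicates` paired replicates (both models on identical
#' datasets) and tabulates the performance metrics side by side,
#' including the difference in relative bias. The headline rows are the
#' treatment-by-time interaction, the time slope, and the association.
#'
#' @param scenario a [scenario_config()].
#' @param n_replicates number of paired replicates.
#' @param mcmc an [mcmc_config()].
#' @param eval_rule passed to [fit_mjm()].
#' @param gate `"converged"` (default) restricts metrics to replicates
#'   passing the R-hat gate; `"all"` keeps every completed replicate.
#' @return List with `comparison` (data frame: per-parameter metrics
#'   under both models and `delta_relative_bias` = JM minus MJM),
#'   `mjm_metrics`, `jm_metrics`, and replicate bookkeeping.
#' @export
compare_models <- function(scenario, n_replicates, mcmc,
                           eval_rule = "interval_start",
                           gate = c("converged", "all")) {
  gate <- match.arg(gate)
  reps <- lapply(seq_len(n_replicates), function(r)
    run_replicate(scenario, r, mcmc, fit_both = TRUE, eval_rule = eval_rule))
  for (r in reps)
    stopifnot(identical(r$mjm$fingerprint, r$jm$fingerprint))
  truths <- reps[[1]]$truths
  ms <- lapply(reps, function(r) r$mjm$summary)
  js <- lapply(reps, function(r) r$jm$summary)
  mc <- vapply(reps, function(r) isTRUE(r$mjm$converged), TRUE)
  jc <- vapply(reps, function(r) isTRUE(r$jm$converged), TRUE)
  if (gate == "all") {
    mc <- !vapply(ms, is.null, TRUE)
    jc <- !vapply(js, is.null, TRUE)
  }
  m_met <- replicate_metrics(ms, truths, mc, mjm_spec(multilevel = TRUE))
  j_met <- replicate_metrics(js, truths, jc, mjm_spec(multilevel = FALSE))
  shared <- intersect(m_met$parameter, j_met$parameter)
  mi <- match(shared, m_met$parameter); ji <- match(shared, j_met$parameter)
  comparison <- data.frame(
    parameter = shared, true = m_met$true[mi],
    mjm_mean_est = m_met$mean_est[mi], jm_mean_est = j_met$mean_est[ji],
    mjm_relative_bias = m_met$relative_bias[mi],
    jm_relative_bias = j_met$relative_bias[ji],
    delta_relative_bias = j_met$relative_bias[ji] - m_met$relative_bias[mi],
    mjm_MESE = m_met$MESE[mi], jm_MESE = j_met$MESE[ji],
    mjm_ESE = m_met$ESE[mi], jm_ESE = j_met$ESE[ji],
    stringsAsFactors = FALSE)
  list(comparison = comparison, mjm_metrics = m_met, jm_metrics = j_met,
       n_replicates = n_replicates,
       n_converged = c(mjm = sum(mc), jm = sum(jc)))
}

#' Run a simulation study over a set of scenarios
#'
#' Drives [run_replicate()] over scenarios x replicates and writes one
#' metrics table; the full 72-cell design at 200 replicates is
#' cluster-scale and is driven by the same runner via a plain-text job
#' manifest (one scenario per job).
#'
#' @param scenarios list of [scenario_config()]s (see [scenario_grid()]).
#' @param n_replicates replicates per scenario.
#' @param mcmc an [mcmc_config()].
#' @param fit_both also fit the two-level JM per replicate.
#' @param out_csv optional path; metrics are appended per scenario.
#' @param gate `"converged"` (default) restricts metrics to replicates
#'   passing the R-hat gate; `"all"` keeps every completed replicate
#'   (smoke runs with deliberately short chains).
#' @return Data frame of metrics with `scenario_id` and `model` columns
#'   (schema of `metrics.csv`).
#' @export
run_study <- function(scenarios, n_replicates, mcmc, fit_both = FALSE,
                      out_csv = NULL, gate = c("converged", "all")) {
  gate <- match.arg(gate)
  all_rows <- list()
  for (sid in names(scenarios)) {
    sc <- scenarios[[sid]]
    reps <- lapply(seq_len(n_replicates), function(r)
      run_replicate(sc, r, mcmc, fit_both = fit_both))
    truths <- reps[[1]]$truths
    add <- function(model, summaries, conv, spec) {
      if (gate == "all") conv <- !vapply(summaries, is.null, TRUE)
      met <- replicate_metrics(summaries, truths, conv, spec)
      cbind(data.frame(scenario_id = sid, model = model,
                       stringsAsFactors = FALSE),
            met[, c("parameter", "true", "mean_est", "bias", "relative_bias",
                    "MESE", "ESE")],
            n_reps = met$n_replicates, n_converged = met$n_converged)
    }
    rows <- add("mjm", lapply(reps, function(r) r$mjm$summary),
                vapply(reps, function(r) isTRUE(r$mjm$converged), TRUE),
                mjm_spec(multilevel = TRUE))
    if (fit_both)
      rows <- rbind(rows, add("jm", lapply(reps, function(r) r$jm$summary),
                              vapply(reps, function(r) isTRUE(r$jm$converged), TRUE),
                              mjm_spec(multilevel = FALSE)))
    all_rows[[sid]] <- rows
    if (!is.null(out_csv))
      utils::write.table(rows, out_csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_csv), append = file.exists(out_csv))
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out
}
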