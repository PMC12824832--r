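# Small hand-built fixture: 3 subjects in 2 groups, 7 longitudinal rows,
# events at 3.2 and 0.4 years plus one administratively censored subject.
fixture_tables <- function() {
  list(
    longitudinal = data.frame(
      subject_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s3"),
      group_id = c("gA", "gA", "gA", "gB", "gB", "gB", "gA"),
      time = c(0, 0.5, 1, 0, 0.5, 1, 0),
      y = c(15.2, 14.812345678901, 14.1, 17.3, 16.9, 17.8, 16.4),
      stringsAsFactors = FALSE),
    survival = data.frame(
      subject_id = c("s1", "s2", "s3"),
      group_id = c("gA", "gB", "gA"),
      observed_time = c(3.2, 12.25, 0.4),
      event = c(1L, 0L, 1L),
      stringsAsFactors = FALSE),
    groups = data.frame(group_id = c("gA", "gB"), treatment = c(1L, 0L),
                        stringsAsFactors = FALSE))
}

fixture_dataset <- function() do.call(trial_dataset, fixture_tables())

# The three-piece grid mirroring a 0.5 / 4.5 / 12.5-year scheme.
fixture_grid <- function() interval_grid(c(0, 0.5, 4.5, 12.5))

# A fully populated parameter state for the fixture dataset.
fixture_state <- function(spec = mjm_spec(), seed = 1) {
  set.seed(seed)
  n <- 3L; L <- 2L; Q <- 3L
  mjm_state(
    beta = c(16, -0.8, 1.6, -2) + rnorm(4, 0, 0.3),
    sigma_eps = sqrt(33), Sigma_u = matrix(c(10, 1, 1, 10), 2),
    alpha = -0.2, lam = c(0.05, 0.1, 0.2) * exp(rnorm(Q, 0, 0.1)),
    u = matrix(rnorm(n * 2, 0, 1), n, 2),
    sigma_v = sqrt(5), sigma_g = sqrt(0.4),
    v = rnorm(L, 0, 1), g = rnorm(L, 0, 0.5))
}

# A small simulated dataset shared by MCMC-exercising tests.
small_sim <- function(seed = 5, L = 8, group_size = 8, Q = 2,
                      censoring_target = 0.2) {
  generate_dataset(scenario_config(censoring_target = censoring_target, L = L,
                                   group_size = group_size, Q = Q, seed = seed))
}

# Central finite difference of log_posterior along one coordinate update
# function; used for the gradient check.
central_diff <- function(f, state, set, get, h = NULL) {
  x <- get(state)
  if (is.null(h)) h <- 1e-5 * (abs(x) + 1)
  (f(set(state, x + h)) - f(set(state, x - h))) / (2 * h)
}
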