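# Fixture protocol parameters for testing only. The gamma detection
# parameters and extraction efficiency of a real assay are laboratory
# calibrations; these values are invented so the model has a convenient,
# well-behaved sensitivity curve on the test grids.
fixture_params <- function(phi = 0.5, alpha_f = 2, beta_f = 3,
                           alpha_s = 2, beta_s = 5, k = 8L) {
  protocol_params(phi = phi, alpha_f = alpha_f, beta_f = beta_f,
                  alpha_s = alpha_s, beta_s = beta_s, k = k)
}

small_grid <- function(theta_max = 100, step = 5) {
  concentration_grid(theta_max = theta_max, step = step)
}

# hand-built likelihood table (e.g. with prescribed columns) for engine tests
manual_table <- function(values, grid) {
  stopifnot(nrow(values) == length(grid$midpoints), ncol(values) == 101L)
  structure(list(grid = grid, bins = sensitivity_bins(), values = values,
                 nu = NA_integer_, seed = NA_integer_,
                 zero_floor = NA_real_, params = NULL),
            class = "likelihood_table")
}

evidence_record <- function(n_samples, n_positive, reach = "T",
                            date = as.Date("2020-06-01")) {
  data.frame(reach_id = reach, event_date = as.Date(date),
             n_samples = as.integer(n_samples),
             n_positive = as.integer(n_positive),
             stringsAsFactors = FALSE)
}

evidence_frame <- function(n_samples, n_positive, reach = "T",
                           start = as.Date("2020-06-01")) {
  if (length(n_positive) == 1L)
    n_positive <- rep(n_positive, length(n_samples))
  stopifnot(length(n_samples) == length(n_positive))
  data.frame(reach_id = reach,
             event_date = start + seq_along(n_samples) - 1L,
             n_samples = as.integer(n_samples),
             n_positive = as.integer(n_positive),
             stringsAsFactors = FALSE)
}

# exact expected survey sensitivity at concentration theta:
# E[p(A+ | N_S)] summed over the Poisson pmf of N_S (tail below 1e-12)
exact_mean_sensitivity <- function(theta, params) {
  mu <- theta * params$v_s
  n_max <- max(1L, stats::qpois(1e-12, mu, lower.tail = FALSE) + 1L)
  k <- 0:n_max
  sum(stats::dpois(k, mu) * sample_positive_prob(k, params))
}
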