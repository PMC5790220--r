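#' Design of a synthetic eDNA survey
#'
#' Describes a simulated monitoring campaign on one reach with a known true
#' marker concentration: repeated sampling events, each collecting the same
#' number of water samples, analyzed under a given protocol. Used for
#' parameter-recovery and calibration experiments.
#'
#' @param true_theta True ambient concentration, copies/L (`>= 0`).
#' @param n_events Number of sampling events (`>= 1`).
#' @param samples_per_event Water samples collected per event (`>= 1`).
#' @param params A [protocol_params()] object.
#' @param seed Integer seed.
#' @param reach_id Label for the simulated reach.
#' @param start_date Date of the first event; events follow fortnightly.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(true_theta, n_events, samples_per_event, params,
                          seed = 1L, reach_id = "SYN",
                          start_date = as.Date("2020-01-01")) {
  validate_protocol_params(params)
  if (!is.finite(true_theta) || true_theta < 0)
    stop("true_theta must be >= 0")
  n_events <- as.integer(n_events)
  samples_per_event <- as.integer(samples_per_event)
  if (is.na(n_events) || n_events < 1L) stop("n_events must be >= 1")
  if (is.na(samples_per_event) || samples_per_event < 1L)
    stop("samples_per_event must be >= 1")
  structure(list(true_theta = true_theta, n_events = n_events,
                 samples_per_event = samples_per_event, params = params,
                 seed = as.integer(seed), reach_id = reach_id,
                 start_date = as.Date(start_date)),
            class = "survey_design")
}

#' Simulate an eDNA survey under the hierarchical detection model
#'
#' Generates presence/absence survey results with exactly the structure the
#' inference assumes. For each water sample, the captured copy count is
#' `N_S ~ Poisson(true_theta * v_s)`; each of the `k` PCR replicates then
#' independently receives `N_R ~ Poisson(phi * N_S * v_a / v_e)` copies and
#' tests positive when `N_R` exceeds both its gamma-distributed fluorescence
#' and sequencing thresholds. A sample is positive when at least one
#' replicate is positive; an event records the number of positive samples.
#'
#' @param design A [survey_design()].
#' @return Evidence data frame (one row per event) with columns `reach_id`,
#'   `event_date`, `n_samples`, `n_positive`, `fraction_positive`.
#' @examples
#' pp <- protocol_params(phi = 0.5, alpha_f = 2, beta_f = 3,
#'                       alpha_s = 2, beta_s = 5)
#' ev <- simulate_survey(survey_design(50, n_events = 4,
#'                                     samples_per_event = 10, pp, seed = 7))
#' ev
#' @export
simulate_survey <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  p <- design$params
  set.seed(design$seed)
  n_total <- design$n_events * design$samples_per_event
  n_s <- stats::rpois(n_total, lambda = design$true_theta * p$v_s)
  n_rep <- n_total * p$k
  mu_r <- rep(p$phi * n_s * p$v_a / p$v_e, each = p$k)
  n_r <- stats::rpois(n_rep, lambda = mu_r)
  thr_f <- stats::rgamma(n_rep, shape = p$alpha_f, scale = p$beta_f)
  thr_s <- stats::rgamma(n_rep, shape = p$alpha_s, scale = p$beta_s)
  rep_pos <- n_r > thr_f & n_r > thr_s
  sample_pos <- colSums(matrix(rep_pos, nrow = p$k)) > 0L
  n_positive <- colSums(matrix(sample_pos, nrow = design$samples_per_event))
  data.frame(
    reach_id = design$reach_id,
    event_date = design$start_date + 14L * (seq_len(design$n_events) - 1L),
    n_samples = design$samples_per_event,
    n_positive = as.integer(n_positive),
    fraction_positive = n_positive / design$samples_per_event,
    stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment for the full inference pipeline
#'
#' Simulation-based calibration check: for each true concentration and
#' replicate, simulate a survey with [simulate_survey()], run the whole
#' inference ([run_updates()] + [fit_gamma_moments()]) against `table`, and
#' record whether the 90% credibility interval covers the truth and the
#' relative error of the posterior median. Because the generative model and
#' the inference likelihood are the same hierarchical model, coverage should
#' be near nominal when the table's Monte-Carlo resolution is high.
#'
#' @param true_thetas True concentrations to test (copies/L).
#' @param design A [survey_design()] used as a template (`true_theta` and
#'   `seed` are overridden per run).
#' @param table Likelihood table built with the same [protocol_params()] as
#'   `design` (checked when the table carries provenance).
#' @param replicates Simulation replicates per concentration.
#' @param seed Base seed; run `j` of concentration `i` uses
#'   `seed + 1000 * i + j`.
#' @return A list with `runs` (data frame: one row per simulated survey with
#'   `true_theta`, `median`, `ci_low`, `ci_high`, `covered`, `rel_error`) and
#'   `summary` (per true concentration: `coverage`, `median_rel_error`,
#'   `mean_median`).
#' @export
recovery_experiment <- function(true_thetas, design, table,
                                replicates = 100L, seed = 1L) {
  stopifnot(inherits(design, "survey_design"),
            inherits(table, "likelihood_table"))
  if (!is.null(table$params) &&
      !isTRUE(all.equal(unclass(table$params), unclass(design$params))))
    stop("likelihood table and survey design use different protocol parameters")
  runs <- vector("list", length(true_thetas) * replicates)
  idx <- 0L
  for (i in seq_along(true_thetas)) {
    th <- true_thetas[i]
    for (j in seq_len(replicates)) {
      d <- design
      d$true_theta <- th
      d$seed <- as.integer(seed + 1000L * i + j)
      ev <- simulate_survey(d)
      states <- run_updates(ev, table)
      fit <- fit_gamma_moments(states[[length(states)]])
      idx <- idx + 1L
      runs[[idx]] <- data.frame(
        true_theta = th, median = fit$median,
        ci_low = fit$ci_low, ci_high = fit$ci_high,
        covered = fit$ci_low <= th & th <= fit$ci_high,
        rel_error = if (th > 0) abs(fit$median - th) / th else NA_real_)
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(unique(runs$true_theta), function(th) {
    r <- runs[runs$true_theta == th, , drop = FALSE]
    data.frame(true_theta = th,
               replicates = nrow(r),
               coverage = mean(r$covered),
               median_rel_error = stats::median(r$rel_error),
               mean_median = mean(r$median))
  }))
  list(runs = runs, summary = summary)
}
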