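#' Uniform prior over the discretized concentration axis
#'
#' A uniform distribution on `[theta_min, theta_max]` is the non-informative
#' starting prior: it encodes only that the concentration is non-negative and
#' below the saturation bound of the survey protocol. Each interval receives
#' the uniform mass of its (clipped) width: interior intervals
#' `[theta - delta, theta + delta]` get `2*delta / (theta_max - theta_min)`;
#' the two boundary intervals (midpoints at the grid ends) are clipped to
#' half width and get `delta / (theta_max - theta_min)`.
#'
#' @param grid A [concentration_grid()].
#' @return A `posterior_state`: list with `grid`, `pmf` (sums to 1), and an
#'   empty `history` of applied evidence.
#' @examples
#' ps <- uniform_prior(concentration_grid())
#' ps$pmf[2] * 3000  # interior interval width, 5 copies/L
#' @export
uniform_prior <- function(grid) {
  stopifnot(inherits(grid, "concentration_grid"))
  lo <- pmax(grid$midpoints - grid$delta, grid$theta_min)
  hi <- pmin(grid$midpoints + grid$delta, grid$theta_max)
  pmf <- (hi - lo) / (grid$theta_max - grid$theta_min)
  new_posterior_state(grid, pmf, history = empty_evidence())
}

new_posterior_state <- function(grid, pmf, history) {
  stopifnot(length(pmf) == length(grid$midpoints), all(pmf >= 0))
  structure(list(grid = grid, pmf = pmf, history = history),
            class = "posterior_state")
}

empty_evidence <- function() {
  data.frame(reach_id = character(), event_date = as.Date(character()),
              n_samples = integer(), n_positive = integer(),
              stringsAsFactors = FALSE)
}

#' @export
print.posterior_state <- function(x, ...) {
  m <- sum(x$pmf * x$grid$midpoints)
  cat(sprintf(
    "Posterior over %d concentration intervals; mean %.2f copies/L; %d evidence record(s) applied\n",
    length(x$pmf), m, nrow(x$history)))
  invisible(x)
}

#' Map an observed positive fraction to a sensitivity bin
#'
#' Evidence enters updating as the fraction of water samples in an event that
#' tested positive, matched to the nearest of the 101 tabulated sensitivity
#' levels (half-up rounding) — the same binning used when the likelihood
#' table was built.
#'
#' @param fraction_positive Value in `[0, 1]` (vectorized).
#' @return Integer bin index in `0:100`.
#' @examples
#' evidence_to_bin(c(0, 3 / 7, 1))  # 0, 43, 100
#' @export
evidence_to_bin <- function(fraction_positive) {
  if (any(!is.finite(fraction_positive)) ||
      any(fraction_positive < 0) || any(fraction_positive > 1))
    stop("fraction_positive must lie in [0, 1]")
  bin_index(fraction_positive)
}

#' One Bayesian update of the concentration posterior
#'
#' Applies Bayes rule on the discretized concentration axis: the posterior
#' mass at each midpoint is proportional to the prior mass times the
#' tabulated likelihood of the observed evidence bin at that concentration,
#' renormalized to sum to 1. The updated state appends the evidence record to
#' its history. Events with zero water samples carry no evidence and are
#' rejected with a warning (the state is returned unchanged).
#'
#' @param prior A `posterior_state` (e.g. from [uniform_prior()] or a
#'   previous update).
#' @param record One evidence record: a list or one-row data frame with
#'   `reach_id`, `event_date`, `n_samples`, `n_positive`.
#' @param table A [build_likelihood_table()] result (or one read with
#'   [read_likelihood_table()]) on the same grid.
#' @param verbose If `TRUE`, log the reach, date, evidence bin and posterior
#'   mean of the update (an audit trail of the iteration history).
#' @return The updated `posterior_state`.
#' @export
update_posterior <- function(prior, record, table, verbose = FALSE) {
  stopifnot(inherits(prior, "posterior_state"),
            inherits(table, "likelihood_table"))
  if (!grids_identical(prior$grid, table$grid))
    stop("likelihood table grid does not match the posterior grid")
  rec <- as_evidence_record(record)
  if (rec$n_samples == 0L) {
    warning(sprintf("event %s/%s has no water samples; evidence skipped",
                    rec$reach_id, format(rec$event_date)))
    return(prior)
  }
  bin <- evidence_to_bin(rec$n_positive / rec$n_samples)
  unnorm <- prior$pmf * table$values[, bin + 1L]
  z <- sum(unnorm)
  if (z <= 0)
    stop("evidence has zero likelihood everywhere on the grid; ",
         "was the table built with zero-correction?")
  pmf <- unnorm / z
  if (verbose)
    message(sprintf("update %s %s: bin %d (%d/%d), posterior mean %.2f copies/L",
                    rec$reach_id, format(rec$event_date), bin,
                    rec$n_positive, rec$n_samples,
                    sum(pmf * prior$grid$midpoints)))
  new_posterior_state(prior$grid, pmf,
                      history = rbind(prior$history, rec))
}

as_evidence_record <- function(record) {
  r <- as.list(record)
  need <- c("reach_id", "event_date", "n_samples", "n_positive")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("evidence record missing field(s): ", paste(miss, collapse = ", "))
  ns <- as.integer(r$n_samples)
  np <- as.integer(r$n_positive)
  if (is.na(ns) || ns < 0L) stop("n_samples must be a count >= 0")
  if (is.na(np) || np < 0L || np > ns)
    stop("n_positive must satisfy 0 <= n_positive <= n_samples")
  data.frame(reach_id = as.character(r$reach_id),
             event_date = as.Date(r$event_date),
             n_samples = ns, n_positive = np,
             stringsAsFactors = FALSE)
}

#' Iterative Bayesian updating over a reach's sampling history
#'
#' Starting from the uniform prior, applies [update_posterior()] once per
#' sampling event in date order; the posterior after each event becomes the
#' prior for the next. Returns the full iteration history; the last element
#' is the end-of-monitoring concentration estimate.
#'
#' @param records Evidence records for a single reach: data frame with
#'   columns `reach_id`, `event_date`, `n_samples`, `n_positive`.
#' @param table A likelihood table on `grid`.
#' @param grid Concentration grid (defaults to the table's own grid).
#' @param verbose Passed to [update_posterior()].
#' @return List of `posterior_state`, one per applied event; with no usable
#'   events the list holds just the uniform prior.
#' @export
run_updates <- function(records, table, grid = table$grid, verbose = FALSE) {
  stopifnot(inherits(table, "likelihood_table"))
  state <- uniform_prior(grid)
  if (is.null(records) || nrow(records) == 0L) return(list(state))
  records <- records[order(as.Date(records$event_date)), , drop = FALSE]
  out <- vector("list", nrow(records))
  n_applied <- 0L
  for (i in seq_len(nrow(records))) {
    new_state <- update_posterior(state, records[i, , drop = FALSE],
                                  table, verbose = verbose)
    if (nrow(new_state$history) > nrow(state$history)) {
      n_applied <- n_applied + 1L
      out[[n_applied]] <- new_state
      state <- new_state
    }
  }
  if (n_applied == 0L) return(list(state))
  out[seq_len(n_applied)]
}

#' Summarize a posterior by a method-of-moments gamma fit
#'
#' The discrete posterior mass function is summarized by the gamma
#' distribution matching its first two moments over the interval midpoints:
#' `shape = mean^2 / var`, `scale = var / mean`. Reported are the fitted
#' median and the 90% credibility interval (5th and 95th gamma percentiles).
#' A degenerate posterior (zero variance) admits no gamma fit and is an
#' error.
#'
#' @param posterior A `posterior_state`.
#' @return An object of class `gamma_summary`: list with `shape`, `scale`,
#'   `mean`, `median`, `ci_low`, `ci_high`.
#' @examples
#' ps <- uniform_prior(concentration_grid())
#' fit_gamma_moments(ps)
#' @export
fit_gamma_moments <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_state"))
  mids <- posterior$grid$midpoints
  p <- posterior$pmf
  m <- sum(p * mids)
  v <- sum(p * (mids - m)^2)
  if (!is.finite(v) || v <= 0)
    stop("posterior is degenerate (zero variance); gamma summary unavailable")
  shape <- m^2 / v
  scale <- v / m
  q <- stats::qgamma(c(0.05, 0.5, 0.95), shape = shape, scale = scale)
  structure(list(shape = shape, scale = scale, mean = m,
                 median = q[2], ci_low = q[1], ci_high = q[3]),
            class = "gamma_summary")
}

#' @export
print.gamma_summary <- function(x, ...) {
  cat(sprintf(
    "Gamma(shape %.4g, scale %.4g): median %.1f copies/L, 90%% CI %.1f-%.1f\n",
    x$shape, x$scale, x$median, x$ci_low, x$ci_high))
  invisible(x)
}

#' Raw posterior quantiles (diagnostic)
#'
#' Quantiles of the discrete posterior itself, before any gamma smoothing:
#' the smallest midpoint at which the cumulative mass reaches each requested
#' probability. Useful for checking how much the gamma summary smooths the
#' raw posterior.
#'
#' @param posterior A `posterior_state`.
#' @param probs Probabilities (default 5%, 50%, 95%).
#' @return Named numeric vector of concentrations (copies/L).
#' @export
posterior_quantiles <- function(posterior, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(posterior, "posterior_state"))
  cdf <- cumsum(posterior$pmf)
  out <- vapply(probs, function(p) {
    posterior$grid$midpoints[which(cdf >= p - 1e-12)[1]]
  }, numeric(1))
  stats::setNames(out, sprintf("q%g", 100 * probs))
}

#' Posterior trace of a reach's updating history
#'
#' Runs [run_updates()] and tabulates, per sampling event, the evidence and
#' the fitted gamma summary of the posterior after that event — one row per
#' iteration, mirroring a monitoring report.
#'
#' @inheritParams run_updates
#' @return Data frame with columns `reach_id`, `event_date`, `n_samples`,
#'   `n_positive`, `fraction_positive`, `shape`, `scale`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
posterior_trace <- function(records, table, grid = table$grid,
                            verbose = FALSE) {
  states <- run_updates(records, table, grid, verbose = verbose)
  rows <- lapply(states, function(st) {
    if (nrow(st$history) == 0L) return(NULL)  # bare prior, nothing applied
    rec <- st$history[nrow(st$history), , drop = FALSE]
    fit <- fit_gamma_moments(st)
    data.frame(rec,
               fraction_positive = rec$n_positive / rec$n_samples,
               shape = fit$shape, scale = fit$scale, median = fit$median,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(empty_evidence(),
                 data.frame(fraction_positive = numeric(), shape = numeric(),
                            scale = numeric(), median = numeric(),
                            ci_low = numeric(), ci_high = numeric()))
  }
  rownames(out) <- NULL
  out
}
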