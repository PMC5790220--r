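#' Evidentiary criteria for Bayesian updating
#'
#' Two filters on the evidence admitted to updating: each sampling event must
#' be based on at least `min_samples` water samples (evidence from very few
#' samples is weak), and a reach must retain at least `min_events` qualifying
#' events (too few updates leave the estimate dominated by the diffuse
#' initial prior; the monitoring analysis requires three).
#'
#' @param min_samples Minimum water samples per event (>= 1).
#' @param min_events Minimum qualifying sampling events (>= 1, default 3).
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(min_samples = 1L, min_events = 3L) {
  min_samples <- as.integer(min_samples)
  min_events <- as.integer(min_events)
  if (is.na(min_samples) || min_samples < 1L) stop("min_samples must be >= 1")
  if (is.na(min_events) || min_events < 1L) stop("min_events must be >= 1")
  structure(list(min_samples = min_samples, min_events = min_events),
            class = "criterion_spec")
}

#' Filter a reach's evidence by the evidentiary criteria
#'
#' Keeps events with at least `spec$min_samples` water samples. If fewer than
#' `spec$min_events` events survive the filter, no concentration estimate is
#' considered supportable and `NULL` is returned ("unavailable").
#'
#' @param records Evidence records for one reach.
#' @param spec A [criterion_spec()].
#' @return The qualifying records (data frame), or `NULL` when the reach does
#'   not meet the criteria.
#' @export
apply_criteria <- function(records, spec) {
  stopifnot(inherits(spec, "criterion_spec"))
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  keep <- records[records$n_samples >= spec$min_samples, , drop = FALSE]
  if (nrow(keep) < spec$min_events) return(NULL)
  keep
}

#' Stability of a reach's estimate across evidentiary criterion levels
#'
#' Recomputes the end-of-monitoring median concentration under each
#' `min_samples` level: filter the evidence with [apply_criteria()], rerun the
#' full updating sequence, and take the fitted gamma median of the final
#' posterior. The spread of medians across levels is summarized by the
#' stability ratio `(max - min) / min` — near 0 for well-sampled reaches
#' whose estimate is indifferent to dropping the weakest evidence, large for
#' reaches whose estimate leans on a few small events.
#'
#' @param records Evidence records for a single reach.
#' @param table Likelihood table.
#' @param grid Concentration grid (defaults to the table's).
#' @param levels `min_samples` levels to sweep (the monitoring analysis used
#'   1, 2, 4, 5, 6, 8, 10, 12, 14).
#' @param min_events Minimum qualifying events at every level (default 3).
#' @return A one-row `sensitivity_row` data frame: one `median_<level>`
#'   column per level (NA where unavailable), plus `min_median`,
#'   `max_median`, `range` and `ratio` over the available levels. `ratio` is
#'   NA when no level is available or the minimum median is 0.
#' @export
sensitivity_table <- function(records, table, grid = table$grid,
                              levels = c(1, 2, 4, 5, 6, 8, 10, 12, 14),
                              min_events = 3L) {
  if (length(levels) == 0L) stop("levels must be non-empty")
  reach <- if (!is.null(records) && nrow(records) > 0L)
    records$reach_id[1] else NA_character_
  medians <- vapply(levels, function(lv) {
    q <- apply_criteria(records, criterion_spec(lv, min_events))
    if (is.null(q)) return(NA_real_)
    states <- run_updates(q, table, grid)
    final <- states[[length(states)]]
    if (nrow(final$history) == 0L) return(NA_real_)
    fit_gamma_moments(final)$median
  }, numeric(1))
  avail <- medians[!is.na(medians)]
  if (length(avail)) {
    mn <- min(avail); mx <- max(avail)
    rng <- mx - mn
    ratio <- if (mn > 0) rng / mn else NA_real_
  } else {
    mn <- mx <- rng <- ratio <- NA_real_
  }
  out <- data.frame(reach_id = reach, t(medians),
                    min_median = mn, max_median = mx,
                    range = rng, ratio = ratio,
                    stringsAsFactors = FALSE)
  names(out)[seq_along(levels) + 1L] <- sprintf("median_%g", levels)
  class(out) <- c("sensitivity_row", class(out))
  out
}

#' Criterion-sensitivity report over all reaches
#'
#' Applies [sensitivity_table()] reach by reach to a full evidence table and
#' stacks the rows, giving the monitoring-wide stability report.
#'
#' @param evidence Evidence records for any number of reaches (see
#'   [read_evidence()]).
#' @inheritParams sensitivity_table
#' @return Data frame with one row per reach.
#' @export
sensitivity_report <- function(evidence, table, grid = table$grid,
                               levels = c(1, 2, 4, 5, 6, 8, 10, 12, 14),
                               min_events = 3L) {
  reaches <- unique(evidence$reach_id)
  rows <- lapply(reaches, function(r) {
    sensitivity_table(evidence[evidence$reach_id == r, , drop = FALSE],
                      table, grid, levels = levels, min_events = min_events)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
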