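#' Read an evidence table of eDNA survey results
#'
#' The evidence CSV has one row per sampling event with columns `reach_id`,
#' `date` (ISO-8601), `n_samples` (water samples collected), `n_positive`
#' (samples classified positive for the target marker). Rows are validated
#' (`0 <= n_positive <= n_samples`, parseable dates) and returned sorted by
#' reach then date; malformed rows are reported with their line numbers.
#'
#' @param path Path to the evidence CSV.
#' @return Data frame with columns `reach_id`, `event_date` (Date),
#'   `n_samples`, `n_positive`, `fraction_positive` (NA when `n_samples` is
#'   0), sorted by reach then date.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("reach_id", "date", "n_samples", "n_positive")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence file missing column(s): ", paste(miss, collapse = ", "))
  # data line i of the file is CSV row i + 1 (header)
  line_no <- seq_len(nrow(df)) + 1L
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  ns <- suppressWarnings(as.integer(df$n_samples))
  np <- suppressWarnings(as.integer(df$n_positive))
  problems <- character(0)
  bad_date <- which(is.na(dates))
  if (length(bad_date))
    problems <- c(problems, sprintf("line %d: unparseable date '%s'",
                                    line_no[bad_date], df$date[bad_date]))
  bad_ns <- which(is.na(ns) | ns < 0L)
  if (length(bad_ns))
    problems <- c(problems, sprintf("line %d: invalid n_samples '%s'",
                                    line_no[bad_ns], df$n_samples[bad_ns]))
  bad_np <- which(is.na(np) | np < 0L | (!is.na(ns) & np > ns))
  if (length(bad_np))
    problems <- c(problems,
                  sprintf("line %d: invalid n_positive '%s' (n_samples %s)",
                          line_no[bad_np], df$n_positive[bad_np],
                          df$n_samples[bad_np]))
  if (length(problems))
    stop("malformed evidence rows:\n  ", paste(problems, collapse = "\n  "))
  out <- data.frame(reach_id = df$reach_id, event_date = dates,
                    n_samples = ns, n_positive = np,
                    stringsAsFactors = FALSE)
  out <- out[order(out$reach_id, out$event_date), , drop = FALSE]
  out$fraction_positive <- ifelse(out$n_samples > 0,
                                  out$n_positive / out$n_samples, NA_real_)
  rownames(out) <- NULL
  out
}

#' @rdname read_evidence
#' @param records Evidence data frame (columns `reach_id`, `event_date`,
#'   `n_samples`, `n_positive`).
#' @export
write_evidence <- function(records, path) {
  df <- data.frame(reach_id = records$reach_id,
                   date = format(as.Date(records$event_date), "%Y-%m-%d"),
                   n_samples = records$n_samples,
                   n_positive = records$n_positive)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write likelihood tables as CSV
#'
#' The native likelihood-table format is a CSV whose first column (`theta`)
#' holds the concentration midpoints in copies/L and whose remaining 101
#' columns are headed by the sensitivity bin centers `0.00` ... `1.00`.
#' Values are written at full float precision (17 significant digits), so a
#' write/read round trip reproduces the matrix bit-exactly. On read, the grid
#' must be uniformly spaced and there must be exactly 101 bins; row sums that
#' stray from 1 only produce a warning, so externally produced tables load.
#'
#' @param path CSV path.
#' @return `read_likelihood_table()` returns a `likelihood_table`; for
#'   externally built files the Monte-Carlo provenance fields (`nu`, `seed`,
#'   `params`) are `NA`/`NULL`.
#' @export
read_likelihood_table <- function(path) {
  if (!file.exists(path)) stop("likelihood table file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "theta")
    stop("likelihood table must have first column 'theta'")
  if (ncol(df) - 1L != 101L)
    stop(sprintf("likelihood table must have 101 sensitivity bins, found %d",
                 ncol(df) - 1L))
  bins_hdr <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(bins_hdr) || max(abs(bins_hdr - sensitivity_bins())) > 1e-9)
    stop("bin headers must be the sensitivity levels 0.00 ... 1.00")
  mids <- as.numeric(df$theta)
  if (length(mids) < 2L) stop("likelihood table needs at least 2 rows")
  steps <- diff(mids)
  if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9)
    stop("concentration midpoints must be strictly increasing and uniform")
  grid <- concentration_grid(theta_min = mids[1],
                             theta_max = mids[length(mids)],
                             step = steps[1])
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- NULL
  if (any(values < 0)) stop("likelihood values must be non-negative")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-6))
    warning(sprintf("%d likelihood row(s) do not sum to 1 (max |dev| %.3g)",
                    sum(abs(rs - 1) > 1e-6), max(abs(rs - 1))))
  structure(
    list(grid = grid, bins = sensitivity_bins(), values = values,
         nu = NA_integer_, seed = NA_integer_, zero_floor = NA_real_,
         params = NULL),
    class = "likelihood_table")
}

#' @rdname read_likelihood_table
#' @param table A `likelihood_table`.
#' @export
write_likelihood_table <- function(table, path) {
  stopifnot(inherits(table, "likelihood_table"))
  header <- paste(c("theta", sprintf("%.2f", sensitivity_bins())),
                  collapse = ",")
  body <- vapply(seq_len(nrow(table$values)), function(i) {
    paste(c(sprintf("%.17g", table$grid$midpoints[i]),
            sprintf("%.17g", table$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a posterior trace or final-summary table
#'
#' Serializes the output of [posterior_trace()] (or any data frame of
#' posterior summaries) to CSV, rounding nothing.
#'
#' @param trace Data frame.
#' @param path CSV path.
#' @export
write_posterior_trace <- function(trace, path) {
  df <- trace
  if ("event_date" %in% names(df))
    df$event_date <- format(as.Date(df$event_date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_trace
#' @param report Sensitivity report data frame from [sensitivity_report()];
#'   unavailable cells are written as `NA`.
#' @export
write_sensitivity_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
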