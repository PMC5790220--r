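#' Protocol parameters for an eDNA field survey assay
#'
#' Bundles the physical and assay constants of one water-sampling and PCR
#' protocol: volumes, replication, extraction efficiency, and the gamma
#' detection-threshold parameters for amplicon fluorescence and sequence
#' confirmation. These parameters drive the hierarchical Poisson detection
#' model used both to simulate surveys and to build likelihood tables.
#'
#' The fluorescence and sequencing thresholds are modelled as gamma-distributed
#' copy numbers: a PCR replicate containing `N_R` marker copies produces
#' visible fluorescence with probability `pgamma(N_R, alpha_f, scale = beta_f)`
#' and is sequence-confirmed with probability
#' `pgamma(N_R, alpha_s, scale = beta_s)`. These four parameters and the
#' extraction efficiency `phi` are assay-specific laboratory calibrations and
#' have no defaults.
#'
#' @param phi Extraction efficiency: the fraction of marker copies in the raw
#'   water sample that survive into the DNA elution, in `[0, 1]`.
#' @param alpha_f,beta_f Gamma shape and scale of the fluorescence
#'   copy-number threshold (copies).
#' @param alpha_s,beta_s Gamma shape and scale of the sequencing
#'   copy-number threshold (copies).
#' @param v_s Water-sample volume in liters (default 2 L grab samples).
#' @param v_e Elution volume of the DNA extract in microliters (default 100).
#' @param v_a PCR aliquot volume drawn from the elution, microliters
#'   (default 1).
#' @param k Number of PCR replicates analyzed per water sample (default 8).
#'
#' @return An object of class `protocol_params` (a named list).
#' @examples
#' pp <- protocol_params(phi = 0.5, alpha_f = 2, beta_f = 3,
#'                       alpha_s = 2, beta_s = 5)
#' pp
#' @seealso [replicate_positive_prob()], [build_likelihood_table()]
#' @export
protocol_params <- function(phi, alpha_f, beta_f, alpha_s, beta_s,
                            v_s = 2.0, v_e = 100.0, v_a = 1.0, k = 8L) {
  p <- list(
    v_s = as.numeric(v_s), v_e = as.numeric(v_e), v_a = as.numeric(v_a),
    k = as.integer(k), phi = as.numeric(phi),
    alpha_f = as.numeric(alpha_f), beta_f = as.numeric(beta_f),
    alpha_s = as.numeric(alpha_s), beta_s = as.numeric(beta_s)
  )
  class(p) <- "protocol_params"
  validate_protocol_params(p)
  p
}

validate_protocol_params <- function(p) {
  stopifnot(inherits(p, "protocol_params"))
  if (!is.finite(p$v_s) || p$v_s <= 0) stop("v_s must be > 0")
  if (!is.finite(p$v_e) || p$v_e <= 0) stop("v_e must be > 0")
  if (!is.finite(p$v_a) || p$v_a <= 0 || p$v_a > p$v_e)
    stop("v_a must satisfy 0 < v_a <= v_e")
  if (is.na(p$k) || p$k < 1L) stop("k must be an integer >= 1")
  if (!is.finite(p$phi) || p$phi < 0 || p$phi > 1)
    stop("phi must lie in [0, 1]")
  for (nm in c("alpha_f", "beta_f", "alpha_s", "beta_s")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("%s must be > 0", nm))
  }
  invisible(p)
}

#' @export
print.protocol_params <- function(x, ...) {
  cat("eDNA survey protocol parameters\n")
  cat(sprintf("  water sample volume  V_S = %g L\n", x$v_s))
  cat(sprintf("  elution volume       V_E = %g uL\n", x$v_e))
  cat(sprintf("  PCR aliquot volume   V_A = %g uL\n", x$v_a))
  cat(sprintf("  PCR replicates       K   = %d\n", x$k))
  cat(sprintf("  extraction efficiency phi = %g\n", x$phi))
  cat(sprintf("  fluorescence threshold ~ Gamma(shape %g, scale %g)\n",
              x$alpha_f, x$beta_f))
  cat(sprintf("  sequencing threshold   ~ Gamma(shape %g, scale %g)\n",
              x$alpha_s, x$beta_s))
  invisible(x)
}

#' Read or write protocol parameters as a key-value config file
#'
#' The config format is one `key = value` pair per line, `#` comments
#' allowed. Keys: `v_s_liters`, `v_e_microliters`, `v_a_microliters`,
#' `k_replicates`, `phi`, `alpha_f`, `beta_f`, `alpha_s`, `beta_s`.
#' Volume/replicate keys are optional (protocol defaults apply); `phi` and
#' the four gamma parameters are required.
#'
#' @param path Path to the config file.
#' @return `read_protocol_config()` returns a [protocol_params()] object;
#'   `write_protocol_config()` returns `path` invisibly.
#' @export
read_protocol_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric config value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "))
  cfg <- stats::setNames(as.list(vals), keys)
  need <- c("phi", "alpha_f", "beta_f", "alpha_s", "beta_s")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("config missing required key(s): ", paste(miss, collapse = ", "))
  protocol_params(
    phi = cfg$phi,
    alpha_f = cfg$alpha_f, beta_f = cfg$beta_f,
    alpha_s = cfg$alpha_s, beta_s = cfg$beta_s,
    v_s = if (!is.null(cfg$v_s_liters)) cfg$v_s_liters else 2.0,
    v_e = if (!is.null(cfg$v_e_microliters)) cfg$v_e_microliters else 100.0,
    v_a = if (!is.null(cfg$v_a_microliters)) cfg$v_a_microliters else 1.0,
    k = if (!is.null(cfg$k_replicates)) as.integer(cfg$k_replicates) else 8L
  )
}

#' @rdname read_protocol_config
#' @param params A [protocol_params()] object to serialize.
#' @export
write_protocol_config <- function(params, path) {
  validate_protocol_params(params)
  lines <- c(
    sprintf("v_s_liters = %.17g", params$v_s),
    sprintf("v_e_microliters = %.17g", params$v_e),
    sprintf("v_a_microliters = %.17g", params$v_a),
    sprintf("k_replicates = %d", params$k),
    sprintf("phi = %.17g", params$phi),
    sprintf("alpha_f = %.17g", params$alpha_f),
    sprintf("beta_f = %.17g", params$beta_f),
    sprintf("alpha_s = %.17g", params$alpha_s),
    sprintf("beta_s = %.17g", params$beta_s)
  )
  writeLines(lines, path)
  invisible(path)
}
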