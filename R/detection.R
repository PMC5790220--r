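#' Probability that one PCR replicate tests positive
#'
#' Given `n_s` marker copies captured in the raw water sample, the number of
#' copies `N_R` carried into a single PCR aliquot is Poisson with mean
#' `phi * n_s * v_a / v_e` (extraction losses plus subsampling of the
#' elution). Conditional on `N_R`, the replicate is classified positive when
#' the amplicons both produce visible fluorescence and are sequence-confirmed;
#' each event is governed by a gamma-distributed copy-number threshold, so the
#' conditional probability is the product of the two gamma CDFs evaluated at
#' `N_R`. The returned value marginalizes over `N_R`:
#'
#' \deqn{p(R^+ \mid n_s) = \sum_{N_R \ge 0}
#'   \mathrm{Pois}(N_R;\, \phi n_s V_A/V_E)\,
#'   F_{\Gamma}(N_R; \alpha_F, \beta_F)\,
#'   F_{\Gamma}(N_R; \alpha_S, \beta_S)}
#'
#' The Poisson sum is truncated where the remaining tail mass is at most
#' 1e-12, far below Monte-Carlo noise in any downstream use.
#'
#' @param n_s Non-negative integer count (vectorized) of marker copies in the
#'   water sample.
#' @param params A [protocol_params()] object.
#' @return Probability in `[0, 1]`, one per element of `n_s`. Non-decreasing
#'   in `n_s`.
#' @examples
#' pp <- protocol_params(phi = 0.5, alpha_f = 2, beta_f = 3,
#'                       alpha_s = 2, beta_s = 5)
#' replicate_positive_prob(c(0, 100, 2000), pp)
#' @export
replicate_positive_prob <- function(n_s, params) {
  validate_protocol_params(params)
  check_copy_counts(n_s)
  mu <- params$phi * n_s * params$v_a / params$v_e
  out <- numeric(length(n_s))
  pos <- mu > 0
  if (any(pos)) {
    mu_pos <- mu[pos]
    n_max <- poisson_upper_bound(max(mu_pos))
    gamma_prod <- function(k)
      stats::pgamma(k, shape = params$alpha_f, scale = params$beta_f) *
        stats::pgamma(k, shape = params$alpha_s, scale = params$beta_s)
    if (length(mu_pos) * (n_max + 1) <= 2e7) {
      # rows = n_s values, cols = N_R support; tail beyond n_max <= 1e-12
      k <- 0:n_max
      g <- gamma_prod(k)
      pk <- outer(mu_pos, k, function(m, x) stats::dpois(x, m))
      out[pos] <- pmin(1, pmax(0, as.vector(pk %*% g)))
    } else {
      # mixed very large/small means: per-element truncated sums
      out[pos] <- vapply(mu_pos, function(m) {
        k <- 0:poisson_upper_bound(m)
        min(1, max(0, sum(stats::dpois(k, m) * gamma_prod(k))))
      }, numeric(1))
    }
  }
  out
}

# smallest n with upper-tail Poisson mass <= 1e-12
poisson_upper_bound <- function(mu) {
  max(1L, stats::qpois(1e-12, lambda = mu, lower.tail = FALSE) + 1L)
}

check_copy_counts <- function(n_s) {
  if (length(n_s) == 0L) stop("n_s must be non-empty")
  if (any(!is.finite(n_s)) || any(n_s < 0) || any(n_s != floor(n_s)))
    stop("n_s must be non-negative integer count(s)")
  invisible(n_s)
}

#' Probability that a water sample tests positive
#'
#' A water sample is classified positive when at least one of the `K` PCR
#' replicates run on its extract tests positive and is sequence-confirmed.
#' All replicates share the sample's captured copy count `n_s`; conditional
#' on `n_s` they are independent, so
#' `p(A+ | n_s) = 1 - (1 - r)^K` with `r = replicate_positive_prob(n_s)`.
#'
#' @inheritParams replicate_positive_prob
#' @return Probability in `[0, 1]`, vectorized over `n_s`.
#' @export
sample_positive_prob <- function(n_s, params) {
  r <- replicate_positive_prob(n_s, params)
  1 - (1 - r)^params$k
}

# Memoized per-sample positive probability over integer copy counts:
# dense table on 0..n_max, overflow draws (rare Poisson tail excursions)
# computed on their unique values only.
sample_positive_lookup <- function(params, n_max) {
  tab <- sample_positive_prob(0:n_max, params)
  function(n_s) {
    out <- numeric(length(n_s))
    small <- n_s <= n_max
    out[small] <- tab[n_s[small] + 1L]
    if (!all(small)) {
      u <- unique(n_s[!small])
      out[!small] <- sample_positive_prob(u, params)[match(n_s[!small], u)]
    }
    out
  }
}

#' Simulate realizations of field-survey sensitivity
#'
#' One realization of the protocol's sensitivity at ambient concentration
#' `theta` draws the copies captured in a water sample,
#' `N_S ~ Poisson(theta * v_s)`, and returns the conditional probability that
#' the sample tests positive, [sample_positive_prob()] at that `N_S`. The
#' spread of these realizations at fixed `theta` reflects capture randomness
#' between water samples and is what the likelihood table bins.
#'
#' @param theta Ambient marker concentration, copies/L (scalar, `>= 0`).
#' @param nu Number of Monte-Carlo realizations.
#' @param params A [protocol_params()] object.
#' @param seed Optional integer seed; fixed seed gives reproducible output.
#' @return Numeric vector of `nu` sensitivities in `[0, 1]`.
#' @export
simulate_sensitivity <- function(theta, nu, params, seed = NULL) {
  validate_protocol_params(params)
  if (length(theta) != 1L || !is.finite(theta) || theta < 0)
    stop("theta must be a single non-negative concentration")
  if (nu < 1) stop("nu must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_s <- stats::rpois(nu, lambda = theta * params$v_s)
  if (theta == 0) return(numeric(nu))
  u <- unique(n_s)
  sample_positive_prob(u, params)[match(n_s, u)]
}

#' Sensitivity bin centers
#'
#' The 101 sensitivity levels 0.00, 0.01, ..., 1.00 into which simulated
#' sensitivities (and observed positive fractions) are sorted.
#' @return Numeric vector of length 101.
#' @export
sensitivity_bins <- function() seq(0, 100) / 100

# round-half-up assignment of a sensitivity/fraction in [0,1] to bin 0..100
bin_index <- function(s) as.integer(floor(100 * s + 0.5))

#' Build the Monte-Carlo likelihood table
#'
#' Tabulates `p(e | theta)`: for each concentration midpoint of `grid`,
#' simulates `nu` realizations of survey sensitivity
#' (see [simulate_sensitivity()]), sorts them into the 101 bins
#' 0.00, 0.01, ..., 1.00 (nearest bin, half-up), and records the fraction of
#' realizations per bin. A sensitivity level that is physically possible can
#' come out with likelihood exactly 0 purely from finite sampling; at
#' concentrations above 0 every zero cell is therefore replaced with the
#' half-draw floor `1/(2*nu)` and the row renormalized, so no possible
#' evidence is ever assigned probability 0. The row at `theta = 0` keeps all
#' its mass in bin 0.00 (a truly impossible detection stays impossible).
#'
#' Reproducibility: each concentration row uses the deterministic substream
#' seed `seed + row index`, so rows are independent of grid ordering and the
#' whole table is bit-reproducible for a fixed seed.
#'
#' @param grid A [concentration_grid()].
#' @param nu Monte-Carlo realizations per concentration (the study protocol
#'   uses 400,000).
#' @param params A [protocol_params()] object.
#' @param seed Integer seed for the table build.
#' @return An object of class `likelihood_table`: list with `grid`, `bins`,
#'   `values` (matrix, rows = midpoints, cols = bins), `nu`, `seed`,
#'   `zero_floor` (= `1/(2*nu)`), and `params`.
#' @examples
#' \donttest{
#' pp <- protocol_params(phi = 0.5, alpha_f = 2, beta_f = 3,
#'                       alpha_s = 2, beta_s = 5)
#' lt <- build_likelihood_table(concentration_grid(theta_max = 100),
#'                              nu = 5000, pp, seed = 1)
#' rowSums(lt$values)[1:3]
#' }
#' @export
build_likelihood_table <- function(grid, nu, params, seed = 1L) {
  stopifnot(inherits(grid, "concentration_grid"))
  validate_protocol_params(params)
  if (nu < 1) stop("nu must be >= 1")
  nu <- as.integer(nu)
  mids <- grid$midpoints
  n_bins <- 101L
  values <- matrix(0, nrow = length(mids), ncol = n_bins)
  floor_val <- 1 / (2 * nu)
  # shared memoized sensitivity lookup across rows
  n_cap <- poisson_upper_bound(max(mids) * params$v_s)
  lookup <- sample_positive_lookup(params, n_cap)
  for (i in seq_along(mids)) {
    theta <- mids[i]
    if (theta == 0) {
      values[i, 1L] <- 1
      next
    }
    set.seed(seed + i)
    n_s <- stats::rpois(nu, lambda = theta * params$v_s)
    s <- lookup(n_s)
    f <- tabulate(bin_index(s) + 1L, nbins = n_bins) / nu
    f[f == 0] <- floor_val
    values[i, ] <- f / sum(f)
  }
  structure(
    list(grid = grid, bins = sensitivity_bins(), values = values,
         nu = nu, seed = as.integer(seed), zero_floor = floor_val,
         params = params),
    class = "likelihood_table")
}

#' @export
print.likelihood_table <- function(x, ...) {
  cat(sprintf(
    "Likelihood table: %d concentrations x %d sensitivity bins (%d cells)\n",
    nrow(x$values), ncol(x$values), length(x$values)))
  cat(sprintf("  Monte-Carlo realizations per concentration: %d (seed %d)\n",
              x$nu, x$seed))
  cat(sprintf("  zero-correction floor: %g\n", x$zero_floor))
  invisible(x)
}
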