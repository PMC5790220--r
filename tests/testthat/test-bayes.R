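test_that("uniform prior clips the boundary intervals and sums to 1", {
  ps <- uniform_prior(concentration_grid())
  expect_equal(sum(ps$pmf), 1, tolerance = 1e-12)
  expect_equal(ps$pmf[2], 5 / 3000)          # interior interval
  expect_equal(ps$pmf[1], 2.5 / 3000)        # clipped lower edge
  expect_equal(ps$pmf[601], 2.5 / 3000)      # clipped upper edge
  expect_equal(unique(ps$pmf[2:600]), 5 / 3000)
})

test_that("observed fractions map to the nearest sensitivity bin, half-up", {
  expect_identical(evidence_to_bin(0), 0L)
  expect_identical(evidence_to_bin(1), 100L)
  expect_identical(evidence_to_bin(3 / 7), 43L)   # 42.857 rounds up
  expect_identical(evidence_to_bin(0.005), 1L)    # tie rounds up
  expect_identical(evidence_to_bin(c(0.004999, 0.015)), c(0L, 2L))
  expect_error(evidence_to_bin(-0.01), "\\[0, 1\\]")
  expect_error(evidence_to_bin(1.01), "\\[0, 1\\]")
})

test_that("a flat likelihood column leaves the posterior unchanged", {
  g <- small_grid()
  vals <- matrix(1 / 101, nrow = length(g$midpoints), ncol = 101)
  tab <- manual_table(vals, g)
  prior <- uniform_prior(g)
  post <- update_posterior(prior, evidence_record(10, 3), tab)
  expect_equal(post$pmf, prior$pmf, tolerance = 1e-12)
  expect_equal(nrow(post$history), 1L)
})

test_that("a degenerate likelihood column produces a point-mass posterior", {
  g <- small_grid()
  vals <- matrix(0, nrow = length(g$midpoints), ncol = 101)
  vals[, 31] <- 1e-6
  vals[7, 31] <- 1   # only midpoint 30 can produce a 30% positive fraction
  tab <- manual_table(vals, g)
  post <- update_posterior(uniform_prior(g), evidence_record(10, 3), tab)
  expect_gt(post$pmf[7], 0.999)
})

test_that("updating normalizes and is insensitive to evidence order", {
  set.seed(71)
  g <- small_grid()
  vals <- matrix(rexp(length(g$midpoints) * 101), ncol = 101)
  vals <- vals / rowSums(vals)
  tab <- manual_table(vals, g)
  records <- evidence_frame(n_samples = c(10, 8, 20, 12, 7),
                            n_positive = c(0, 2, 5, 1, 7))
  state <- uniform_prior(g)
  for (i in seq_len(nrow(records))) {
    state <- update_posterior(state, records[i, ], tab)
    expect_equal(sum(state$pmf), 1, tolerance = 1e-9)
  }
  # any permutation yields the same final pmf
  for (rep in 1:5) {
    perm <- sample(nrow(records))
    st <- uniform_prior(g)
    for (i in perm) st <- update_posterior(st, records[i, ], tab)
    expect_equal(st$pmf, state$pmf, tolerance = 1e-12)
  }
})

test_that("repeated identical evidence equals one combined product update", {
  set.seed(72)
  g <- small_grid()
  vals <- matrix(rexp(length(g$midpoints) * 101), ncol = 101)
  vals <- vals / rowSums(vals)
  tab <- manual_table(vals, g)
  n <- 6L
  records <- evidence_frame(rep(10L, n), rep(2L, n))
  states <- run_updates(records, tab)
  expect_length(states, n)
  prior <- uniform_prior(g)
  col <- vals[, evidence_to_bin(0.2) + 1L]
  combined <- prior$pmf * col^n
  combined <- combined / sum(combined)
  expect_equal(states[[n]]$pmf, combined, tolerance = 1e-12)
})

test_that("events without water samples are skipped with a warning", {
  g <- small_grid()
  tab <- manual_table(matrix(1 / 101, length(g$midpoints), 101), g)
  records <- evidence_frame(c(10L, 0L, 8L), c(1L, 0L, 0L))
  expect_warning(states <- run_updates(records, tab), "no water samples")
  expect_length(states, 2L)  # only the two informative events applied
  expect_equal(nrow(states[[2]]$history), 2L)
  # empty history: just the prior
  expect_length(run_updates(NULL, tab), 1L)
  expect_equal(run_updates(empty <- NULL, tab)[[1]]$pmf,
               uniform_prior(g)$pmf)
})

test_that("mismatched grids and impossible evidence are rejected", {
  g <- small_grid()
  tab <- manual_table(matrix(1 / 101, length(g$midpoints), 101), g)
  prior_other <- uniform_prior(small_grid(theta_max = 50))
  expect_error(update_posterior(prior_other, evidence_record(5, 1), tab),
               "grid")
  # all-zero likelihood column (no zero-correction)
  vals0 <- matrix(0, length(g$midpoints), 101)
  vals0[, 1] <- 1
  tab0 <- manual_table(vals0, g)
  expect_error(update_posterior(uniform_prior(g), evidence_record(2, 1), tab0),
               "zero likelihood")
  expect_error(update_posterior(uniform_prior(g),
                                evidence_record(5, 6), tab),
               "n_positive")
})

test_that("all-negative evidence monotonically pulls the posterior mean down", {
  # exact bin-0 likelihood P(sensitivity < 0.005 | theta): since sensitivity
  # is non-decreasing in the captured copy count, this is a Poisson CDF and
  # is non-increasing in theta, the precondition of the property
  pp <- fixture_params()
  g <- small_grid()
  bin0 <- vapply(g$midpoints, function(th) {
    if (th == 0) return(1)
    n_max <- qpois(1e-12, th * pp$v_s, lower.tail = FALSE) + 1L
    k <- 0:n_max
    sum(dpois(k, th * pp$v_s) * (sample_positive_prob(k, pp) < 0.005))
  }, numeric(1))
  expect_true(all(diff(bin0) <= 1e-12))
  vals <- matrix((1 - bin0) / 100, nrow = length(bin0), ncol = 101)
  vals[, 1] <- bin0
  tab <- manual_table(vals, g)
  state <- uniform_prior(g)
  means <- sum(state$pmf * g$midpoints)
  for (i in 1:8) {
    state <- update_posterior(
      state, evidence_record(10, 0, date = as.Date("2020-06-01") + i), tab)
    means <- c(means, sum(state$pmf * g$midpoints))
  }
  expect_true(all(diff(means) <= 1e-10))
})

test_that("method-of-moments gamma fit recovers a discretized gamma", {
  g <- concentration_grid()
  # discretize Gamma(shape 2, scale 10) onto the interval structure
  lo <- pmax(g$midpoints - g$delta, 0)
  hi <- pmin(g$midpoints + g$delta, g$theta_max)
  pmf <- pgamma(hi, shape = 2, scale = 10) - pgamma(lo, shape = 2, scale = 10)
  pmf <- pmf / sum(pmf)
  ps <- structure(list(grid = g, pmf = pmf, history = NULL),
                  class = "posterior_state")
  fit <- fit_gamma_moments(ps)
  expect_lt(abs(fit$shape - 2), 0.05)
  expect_lt(abs(fit$scale - 10), 0.25)
  expect_true(fit$ci_low <= fit$median && fit$median <= fit$ci_high)
  # moment-matching identity: fitted mean reproduces the pmf mean
  expect_equal(fit$shape * fit$scale, sum(pmf * g$midpoints),
               tolerance = 1e-9)
})

test_that("degenerate posteriors admit no gamma summary", {
  g <- small_grid()
  pmf <- rep(0, length(g$midpoints))
  pmf[5] <- 1
  ps <- structure(list(grid = g, pmf = pmf, history = NULL),
                  class = "posterior_state")
  expect_error(fit_gamma_moments(ps), "degenerate")
})

test_that("raw posterior quantiles track the discrete mass function", {
  g <- small_grid()
  pmf <- rep(1 / length(g$midpoints), length(g$midpoints))
  ps <- structure(list(grid = g, pmf = pmf, history = NULL),
                  class = "posterior_state")
  q <- posterior_quantiles(ps, probs = c(0.05, 0.5, 0.95))
  expect_equal(unname(q[2]), 50)
  expect_true(q[1] <= q[2] && q[2] <= q[3])
})

test_that("posterior trace reports one fitted row per applied event", {
  pp <- fixture_params()
  g <- small_grid()
  tab <- build_likelihood_table(g, 3000, pp, seed = 13)
  records <- evidence_frame(c(10L, 10L, 10L), c(0L, 1L, 0L))
  tr <- posterior_trace(records, tab)
  expect_equal(nrow(tr), 3L)
  expect_named(tr, c("reach_id", "event_date", "n_samples", "n_positive",
                     "fraction_positive", "shape", "scale", "median",
                     "ci_low", "ci_high"))
  expect_true(all(tr$ci_low <= tr$median & tr$median <= tr$ci_high))
})

test_that("Bayes engine is calibrated when evidence follows the tabulated likelihood", {
  # Draw the true concentration from the prior and evidence bins from the
  # table's own rows: the model is then exactly well-specified, and the 90%
  # credibility interval of the fitted posterior should cover the truth at
  # close to the nominal rate.
  pp <- fixture_params()
  g <- concentration_grid()
  tab <- build_likelihood_table(g, 20000, pp, seed = 6)
  set.seed(60)
  n_rep <- 60L
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    prior <- uniform_prior(g)
    i_true <- sample.int(length(g$midpoints), 1L, prob = prior$pmf)
    theta <- g$midpoints[i_true]
    st <- prior
    for (e in 1:20) {
      bin <- sample(0:100, 1L, prob = tab$values[i_true, ])
      st <- update_posterior(
        st, evidence_record(100L, bin,
                            date = as.Date("2020-01-01") + e), tab)
    }
    fit <- fit_gamma_moments(st)
    covered[r] <- fit$ci_low <= theta && theta <= fit$ci_high
  }
  # binomial noise on 60 replicates at nominal 0.9: 3 SE is about 0.12
  expect_gte(mean(covered), 0.75)
})
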