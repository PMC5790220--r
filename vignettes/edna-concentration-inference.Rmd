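---
title: "Inferring eDNA marker concentrations from presence/absence surveys"
author: "ednaconc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring eDNA marker concentrations from presence/absence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Environmental DNA (eDNA) field surveys detect a species-specific genetic
marker in water samples with conventional PCR. Each water sample yields a
binary outcome — positive or negative for the marker — so a monitoring
program's raw product is, per sampling event, the fraction of water samples
that tested positive. That fraction says nothing directly about *how much*
marker is in the water, yet the ambient concentration is what supports
inference about the location and strength of eDNA sources (for example,
whether live invasive fish are present upstream of a barrier).

`ednaconc` turns presence/absence survey histories into concentration
estimates by combining three ingredients:

1. a mechanistic model of the survey protocol's *sensitivity* — the
   probability a single water sample tests positive as a function of the
   ambient marker concentration $\theta$ (copies/L);
2. a Monte-Carlo *likelihood table* $p(e \mid \theta)$ tabulating how likely
   each observable positive fraction is at each candidate concentration;
3. iterative *Bayesian updating* of a discretized prior on $\theta$, one
   update per sampling event, summarized by a method-of-moments gamma fit.

## The hierarchical detection model

One water sample of volume $V_S$ (default 2 L) collected where the marker
concentration is $\theta$ captures a Poisson number of marker copies,

$$N_S \sim \mathrm{Poisson}(\theta\, V_S).$$

The sample is filtered and the DNA eluted into $V_E$ (default 100 µL), with
extraction efficiency $\phi$; a PCR aliquot of $V_A$ (default 1 µL) then
contains

$$N_R \sim \mathrm{Poisson}\!\left(\phi\, N_S\, V_A / V_E\right)$$

copies. A replicate is classified positive only if its amplicons both
fluoresce visibly and are sequence-confirmed; each requirement is modelled
by a gamma-distributed copy-number threshold, so conditionally on $N_R$,

$$p(R^+ \mid N_R) = F_\Gamma(N_R;\alpha_F,\beta_F)\,
                    F_\Gamma(N_R;\alpha_S,\beta_S).$$

`replicate_positive_prob()` marginalizes over $N_R$ (Poisson sum truncated
where the tail mass drops below $10^{-12}$, an error far below Monte-Carlo
noise in every use). A water sample is positive when at least one of $K$
replicates (default 8), all drawn from the same extract and hence sharing
$N_S$, is positive:

$$p(A^+ \mid N_S) = 1 - \left(1 - p(R^+ \mid N_S)\right)^K.$$

The protocol's sensitivity at concentration $\theta$ is the random quantity
$p(A^+ \mid N_S)$ with $N_S \sim \mathrm{Poisson}(\theta V_S)$: capture
randomness between water samples makes sensitivity a distribution, not a
number, at every $\theta$.

The five parameters $\phi, \alpha_F, \beta_F, \alpha_S, \beta_S$ are
laboratory calibrations of a particular assay and are required inputs with
no defaults. All examples below use the package's synthetic fixture
calibration ($\phi = 0.5$, fluorescence threshold $\Gamma(2, 3)$,
sequencing threshold $\Gamma(2, 5)$), which produces a conveniently shaped
sensitivity curve but corresponds to no real assay.

## The likelihood table

`build_likelihood_table()` simulates, at each midpoint of the concentration
grid, $\nu$ realizations of the sensitivity and sorts them into the 101
bins $0.00, 0.01, \ldots, 1.00$ (nearest bin, half-up — the binning the
table applies to simulated sensitivities and `evidence_to_bin()` applies to
observed fractions, so the two sides agree by construction). The fraction
of realizations per bin is the likelihood of observing that positive
fraction. The default axis discretizes $[0, 3000]$ copies/L into 601
intervals with midpoints every 5 copies/L (half-width $\delta = 2.5$),
giving a $601 \times 101$ table of 60,701 cells; the production setting is
$\nu = 400{,}000$ realizations per concentration.

Finite $\nu$ leaves some physically possible bins with estimated
probability exactly 0, which would let a single observation veto whole
regions of the concentration axis forever. Every zero cell at $\theta > 0$
is therefore replaced by the half-draw floor $1/(2\nu)$ —
$1.25 \times 10^{-6}$ at the production $\nu$ — and the row renormalized.
Renormalization is our choice (the added mass, at most $101/(2\nu)$, is
negligible, and it keeps every row an exact probability distribution, which
the updating engine asserts). The $\theta = 0$ row is exempt: with no
marker present no sample can test positive, so all mass stays in bin 0.00.

Two implementation choices matter for reproducibility and speed:

* each concentration row draws from its own deterministic substream
  (`seed + row index`), so a table is bit-reproducible and its rows do not
  depend on grid ordering;
* $p(A^+ \mid N_S)$ depends only on the integer $N_S$, so it is memoized
  over the Poisson support once and the $601 \times 400{,}000$ build
  reduces to table lookups after one pass (tens of seconds on one CPU).

The grid ceiling of 3000 copies/L is where a typical protocol's sensitivity
saturates at 1: above it every sample would test positive and the data
could not distinguish concentrations anyway. For assays that saturate lower
(like the test fixture, which saturates within a few hundred copies/L) a
smaller `theta_max` gives the same resolution for less work; tests in this
package use grids up to 100 copies/L for that reason.

## Bayesian updating and the gamma summary

`uniform_prior()` places the uniform mass of each interval's clipped width
on its midpoint: interior intervals get $2\delta/(\theta_{max} -
\theta_{min})$ ($= 5/3000$ by default) and the two boundary intervals,
clipped to half width, get $\delta/(\theta_{max} - \theta_{min})$. Each
sampling event contributes its positive fraction, mapped to a bin; the
posterior is prior × likelihood column, renormalized
(`update_posterior()`), and becomes the prior for the next event
(`run_updates()`). Two consequences follow directly from this product
form and are asserted as tests: evidence order does not matter (to
$10^{-12}$ element-wise), and $n$ identical events equal one update with
the $n$-fold product column.

Deliberately, the likelihood depends only on the *fraction* positive, not
on how many samples produced it: an event of 2 samples and an event of 30
samples carry equal weight. This mirrors the equal-weighting of evidence
in the updating scheme the package implements; a binomial likelihood that
would weight by sample count is out of scope (see the sensitivity analysis
below for how the consequences are diagnosed instead). Events with zero
samples are skipped with a warning rather than aborting a run.

Posteriors over 601 intervals are awkward to report, so
`fit_gamma_moments()` matches a gamma distribution to the posterior's first
two moments over the interval midpoints (moments over midpoints rather than
interval-averaged densities: $\delta = 2.5$ copies/L is small against any
posterior spread of interest). The reported estimate is the fitted
median with the 5th–95th percentile 90% credibility interval. A degenerate
(point-mass) posterior has no gamma fit and raises an error;
`posterior_quantiles()` exposes raw pmf quantiles as a diagnostic for how
much the fit smooths.

## Evidentiary criteria and stability

Sampling intensity varies enormously between reaches of a real monitoring
program, but the fraction-only evidence hides it. `sensitivity_table()`
diagnoses the consequence: sweep a minimum-samples-per-event criterion over
levels (default 1, 2, 4, 5, 6, 8, 10, 12, 14, requiring at least 3
qualifying events throughout), re-run the whole updating sequence on the
qualifying evidence at each level, and compare the resulting medians. The
stability ratio $(\max - \min)/\min$ is near 0 where the estimate does not
care whether the weakest evidence is dropped, and large where a few small
events drive the answer. Levels with fewer than the required events
propagate as `NA`, never as zeros; the filter is applied first and the
event count checked jointly after it. A ratio with a zero minimum median is
reported `NA` (undefined) rather than infinite.

## The survey simulator and what the tests show

`simulate_survey()` generates presence/absence surveys from exactly the
hierarchical model above — shared $N_S$ per sample, independent $N_R$ and
thresholds per replicate — and `recovery_experiment()` closes the loop:
simulate, infer, and score coverage of the 90% interval and relative error
of the median against the known truth.

The test suite verifies the detection probabilities against brute-force
Monte-Carlo oracles (draw $N_R$ and the two thresholds directly), the
simulated sensitivity mean against exact Poisson summation, and the
updating engine's calibration in the *well-specified* regime: when the true
concentration is drawn from the prior and evidence bins are drawn from the
likelihood table's own rows, the 90% interval covers the truth at close to
the nominal rate.

**Known limitation — survey-level calibration.** The evidence model treats
an observed positive fraction as a direct draw of the protocol
*sensitivity*. A fraction computed from $n$ samples is a binomial estimate
of that sensitivity: it carries sampling noise of order
$\sqrt{s(1-s)/n}$ and is quantized to multiples of $1/n$, neither of which
the likelihood table represents. With small per-event sample counts and low
sensitivities this mismatch is material: at 30 samples per event the
achievable fractions $0, 1/30, 2/30, \ldots$ map to bins 0, 3, 7, …, so a
concentration whose sensitivity distribution sits in bins 1–2 can never see
its own most probable evidence, and the posterior both biases and
overstates its precision. Recovery experiments in this package show
near-nominal coverage for low concentrations (wide posteriors), but
substantial under-coverage in regimes where binomial noise spans several
bins; accuracy is restored as samples per event grow and the fraction
converges to the sensitivity. Users should read credibility intervals as
conditional on the fraction-as-sensitivity evidence model, lean on the
evidentiary-criteria stability diagnostics, and prefer large per-event
sample counts where design permits.

A second structural limitation: the grid ceiling truncates the posterior.
If the true concentration exceeds `theta_max`, medians pile up near the
ceiling and intervals cannot cover the truth — visible in practice as
estimates hugging the top of the axis.

The simulator emulates repeated events with equal per-event sample counts
at a constant true concentration. Real monitoring data differ in ways the
simulator does not model: concentrations drift over time, sampling is
spatially clustered within a reach, and event sizes vary — so passing
recovery tests demonstrate correctness of the inference machinery under
its own assumptions, not robustness to those field realities.

## Problem sizes used in the tests

Unit tests run on reduced grids (ceiling 50–100 copies/L) with
$\nu$ between 2,000 and 20,000; the end-to-end recovery experiment uses the
full 601-point grid at $\nu = 10^5$ with 100 simulated surveys of
30 events × 30 samples per true concentration, and the Monte-Carlo oracle
checks use $10^6$ draws per fixture point. These sizes keep the full suite
under a minute on one core while leaving every Monte-Carlo comparison's
standard error well inside its assertion margin.

## A worked run

```{r worked, eval = FALSE}
library(ednaconc)

assay <- protocol_params(phi = 0.5, alpha_f = 2, beta_f = 3,
                         alpha_s = 2, beta_s = 5)
grid <- concentration_grid(theta_max = 100)
table <- build_likelihood_table(grid, nu = 50000, assay, seed = 1)

survey <- simulate_survey(survey_design(true_theta = 20, n_events = 12,
                                        samples_per_event = 25,
                                        params = assay, seed = 7))
trace <- posterior_trace(survey, table)
tail(trace[, c("event_date", "n_positive", "median", "ci_low", "ci_high")], 3)

sensitivity_table(survey, table, levels = c(1, 5, 10, 25))
```

The same pipeline is available from the shell through the `ednaconc`
script (see `?edna_cli`): `simulate`, `build-table`, `update`, `summarize`
and `sensitivity` subcommands over the CSV formats documented in
`?read_evidence` and `?read_likelihood_table`.
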