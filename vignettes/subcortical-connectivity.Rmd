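---
title: "Bayesian structure learning for subcortical functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian structure learning for subcortical functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state functional connectivity between $d$ regions of interest is
often summarised by partial correlations: the correlation between two
regions' BOLD signals after removing the linear effect of all other
regions. For zero-mean Gaussian data $x_t \sim N(0, K^{-1})$ the partial
correlations are determined by the precision matrix,

$$\rho_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii}\,K_{jj}}},$$

and a zero entry $K_{ij} = 0$ encodes conditional independence of regions
$i$ and $j$ given the rest. **subconn** treats connectivity as a pair
$(G, K)$: a binary skeleton $G$ saying *which* regions are conditionally
dependent, and partial correlations saying *how strongly*. Estimating
strengths only where the skeleton permits them keeps the effective number of
parameters small, which matters when a session contributes only
$T = 110$ volumes against $d(d-1)/2 = 91$ candidate connections for
$d = 14$ subcortical ROIs.

The prior is a spike-and-slab over structures: edges are included
independently with probability $\pi$ (default $1/2$, i.e. uniform over
graphs), and given $G$ the precision follows a G-Wishart distribution

$$p(K \mid G) \propto |K|^{(\delta-2)/2}
  \exp\!\big(-\tfrac{1}{2}\,\mathrm{tr}(D K)\big),
  \qquad K \in M^+(G),$$

with $\delta = 3$ degrees of freedom and identity scale $D$ by default —
weakly informative choices standard for this family. With standardised data
the posterior of $K$ given $G$ is again G-Wishart with parameters
$(\delta + T,\ D + X^\top X)$.

## The sampler

The per-subject posterior over $(G, K)$ is explored by MCMC
(`run_mcmc()`). Each iteration:

1. proposes toggling one uniformly chosen edge $(i, j)$. Holding every
   element of $K$ fixed except $(K_{ij}, K_{jj})$, the posterior odds of the
   two skeletons reduce to a one-dimensional Gaussian integral (a
   conditional Bayes factor) — analytic — times a ratio of G-Wishart
   normalising constants, which is intractable. That ratio is handled by an
   exchange-style auxiliary draw: a single prior sample from the proposed
   graph, evaluated through the same conditional integral, stands in for
   the constant ratio inside the Metropolis–Hastings acceptance.
2. resamples $K \mid G, X$ from the conjugate G-Wishart conditional with a
   direct sampler: an unconstrained Bartlett–Wishart draw followed by an
   iterative covariance completion that zeroes the precision off the graph
   (tolerance $10^{-8}$, at most 200 sweeps; failures are counted in the
   diagnostics and are rare).

Retained post-burn-in samples define the three subject-level summaries: the
edge-probability matrix $\Pr(G_{ij} = 1 \mid X)$, the expected partial
correlations $E[\rho_{ij} \mid X]$, and the posterior expected network
density $E[|E|/91 \mid X]$.

The auxiliary-draw acceptance makes the skeleton move approximate in the
same sense as the widely used double Metropolis–Hastings samplers for this
model class. The package therefore carries its own exactness check: for
$d \le 3$ every graph is decomposable, the normalising constants factorise
over cliques and separators in closed form, and the full posterior over all
$2^{3}$ graphs can be enumerated. The test suite compares MCMC edge
probabilities against this enumeration (agreement within 0.03; observed
discrepancies are an order of magnitude smaller), and checks the saturated
limit, where with $\pi \to 1$ and $T = 10^4$ the expected partials must
approach the sample partial correlations of the inverse sample covariance.

Defaults `mcmc_settings(20000, 5000, 5)` are sized so that chains at
$d = 14$ mix well beyond these tolerances; the analysis scripts and tests
use shorter desk-scale chains (stated in each script) where the quantity
being measured — e.g. a t-test's calibration, which depends only on the
subject-level noise being exchangeable across groups — does not require
long chains. Columns are standardised before inference; partial
correlations are scale-invariant, so this only conditions the numerics.
MCMC draws go through R's RNG, so a seed fixes every summary bit-exactly.

## The synthetic cohort

No ROI time series are deposited with the emulated study, so the package
generates them (`simulate_cohort()`). The generator encodes the study
conditions once:

* **Design point.** $T = 110$ volumes, TR $= 2.38$ s, groups of 72
  (patient-like, "a") and 39 (control-like, "b") subjects by default.
* **Structure.** The template graph forces all 7 homotopic (left–right)
  edges and adds each remaining edge with probability 0.2, giving expected
  density $\approx 0.26$ — the scale of the posterior expected densities
  reported for these ROIs. Homotopic partial-correlation targets are 0.55
  (thalamus pair) and 0.41 (caudate pair) — the two strongest group-mean
  values reported for healthy controls — and 0.30 for the other five pairs,
  a value chosen
  once as a plausible mid-strength homotopic coupling. Non-homotopic edges
  draw magnitudes from $[0.1, 0.2]$.
* **Precision construction.** `generate_precision()` builds a
  unit-diagonal precision with $K_{ij} = -\rho_{ij}$, so targets are met
  exactly; if the matrix is not positive definite the untargeted edges are
  shrunk first (factor 0.9), then everything by a gentle 0.99 backoff, and
  an error names any edge whose realised value drifts more than 0.02 from
  target. On the default template no shrinkage is needed.
* **Group effect.** Group b multiplies every partial correlation by
  $1 - \texttt{group\_effect}$ on the shared skeleton — the simplest
  mechanism that makes the group test's power measurable. The default is 0
  (no difference), matching the emulated finding.
* **Contamination.** Observed series add
  `drift_amplitude` $\times$ (sinusoid of period 100–160 s with random
  phase + linear trend) and `confound_coupling` $\times$ a random linear
  mix of the 16 nuisance regressors: six AR(1) motion surrogates
  (coefficient 0.9), AR(1) white-matter and CSF means (coefficient 0.5),
  and backward-difference derivatives of all eight (first row
  zero-padded). Both amplitudes default to 0.5 of the unit signal SD —
  moderate contamination a well-behaved scanning session would show. The
  exact confound spectra are not the point; what matters downstream is that
  the contamination is linear in known regressors plus slow drift, i.e.
  removable by the preprocessing the package implements.

Group-mean partial correlations for homotopic pairs are sometimes quoted
with a very small dispersion (of order 0.01) whose meaning — SD over
subjects versus a posterior or standard error — is rarely stated; the
generator makes no attempt to match such a dispersion, only the mean
targets.

What the generator does **not** emulate: hemodynamic autocorrelation,
spatial noise, motion spikes, nonlinearity, or between-subject variation in
the generating graph. Passing tests therefore demonstrate that the
estimator and test behave correctly *when the model's assumptions hold*,
not that real fMRI meets those assumptions.

## Preprocessing

`regress_confounds()` removes the least-squares projection onto the
confounds plus an always-included intercept (the residuals are orthogonal
to every regressor; exact duplicates are dropped and remaining collinearity
is an error). Ordinary least squares is used throughout — no temporal
pre-whitening, which tools built around film-style GLMs may add but which
is immaterial for a projection whose only job is removing the nuisance
span. `highpass_filter()` interprets the conventional "100"
high-pass setting as a 100-second cutoff — at TR $= 2.38$ s a 100 Hz
cutoff is not meaningful, since the Nyquist frequency is 0.21 Hz. Two
implementations are offered:

* `"gaussian"` (default): Gaussian-weighted running-line detrending with
  $\sigma = \text{cutoff}/(2\,\text{TR})$ volumes, the FSL convention. It
  removes means and linear trends exactly and preserves the pass band
  (20 s components within 5%), but like any local-linear smoother it has a
  soft roll-off near the cutoff.
* `"dct"`: projection onto the complement of the discrete-cosine basis
  functions slower than the cutoff. A true projection — idempotent,
  symmetric — it attenuates the stop band by well over 90% and makes
  filtering commute exactly with regression on pre-filtered regressors.
  The commuting property is tested at $10^{-6}$; for the Gaussian filter it
  holds only approximately.

The pipeline applies regression before filtering (`order =
"regress-first"`, the default, matching the order the steps are usually
described in); the commuting bound shows the choice is immaterial for
projection filtering.

## Group analysis

`compare_groups()` averages expected-partial matrices entrywise per group,
collects per-subject expected densities, and compares them with a
two-tailed t-test (`density_test()`). Welch's unequal-variance form is the
default — robust, and nearly identical to the pooled form at these group
sizes; `var_equal = TRUE` gives the pooled test. If both groups have zero
variance and equal means the test returns $t = 0$, $p = 1$ with a
degenerate-variance flag rather than dividing by zero (and $p = 0$ when
such degenerate groups differ). `rank_homotopic_dominance()` orders edges
by $|\bar\rho_{ij}|$ (ties broken by row/column index) and flags whether
the leading edges are all homotopic.

The calibration of this pipeline is property-based: under
`group_effect = 0` the rejection rate at $\alpha = 0.05$ over 500 reduced
replicate cohorts ($n = 10/10$, $d = 6$, $T = 110$) must lie in
$[0.03, 0.07]$, and permuting group labels must reproduce the $t$
reference distribution (Kolmogorov–Smirnov distance $< 0.05$). Power is
probed at `group_effect = 0.5` with $n = 30/30$, where the rejection rate
must exceed 0.8. The printed densities and p-value of the emulated study
derive from undeposited scans and are not targets; what the package can
and does establish is that its test is calibrated and sensitive under the
stated design point.

## Numerical choices and limitations

* Problem sizes in the tests and analysis scripts are desk-scale choices:
  20-subject template cohorts at $d = 14$, 500 calibration replicates at
  $d = 6$, chains of 600–40000 iterations depending on what the assertion
  needs. The `analysis/` scripts state their sizes inline.
* The exchange-style acceptance uses a single auxiliary draw; its adequacy
  is established empirically by the enumeration oracle rather than by a
  formal exactness proof, which matches how this sampler family is used in
  practice.
* The G-Wishart completion tolerance ($10^{-8}$) bounds the off-graph
  leakage of each precision draw; non-converged completions are counted
  per run in `diagnostics$n_ips_nonconverged`.
* Inference is strictly per subject, and the group stage only compares
  scalar densities and mean matrices; no hierarchical pooling, no edgewise
  multiple-comparison machinery.
* The cohort generator and the inference model share the Gaussian
  graphical assumption, so recovery results are upper bounds on what less
  idealised data would give.
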