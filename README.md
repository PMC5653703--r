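# subconn

Bayesian estimation of subcortical resting-state functional connectivity
networks, with a synthetic cohort generator for end-to-end validation.

## The problem

Resting-state fMRI connectivity between subcortical structures (left and
right nucleus accumbens, amygdala, caudate nucleus, hippocampus, putamen,
pallidum, thalamus — 14 ROIs, 91 candidate connections) is hard to estimate
from a single session: a typical acquisition contributes only ~110 volumes.
**subconn** implements the Bayesian approach of estimating, per subject, a
joint posterior over

* a **binary skeleton** `G` — which ROI pairs are conditionally dependent —
  and
* the **partial correlations** `rho_ij = -K_ij / sqrt(K_ii * K_jj)` of the
  precision matrix `K`, constrained to be supported on `G` via a G-Wishart
  prior,

using a Markov chain Monte Carlo sampler over `(G, K)`. Per subject the
posterior is summarised as edge-inclusion probabilities, expected partial
correlations and the posterior expected network density
`E[|E| / 91 | data]`; densities are then compared between two groups with a
two-tailed t-test. Because estimation happens only where the skeleton
permits an edge, connection strengths are not underestimated when volumes
are scarce relative to the 91 connections.

The package also provides ROI-level preprocessing (nuisance regression
against motion/WM/CSF surrogates and their derivatives; 100-second
high-pass filtering) and a synthetic two-group cohort generator whose
ground truth is a sparse Gaussian graphical model dominated by homotopic
(left–right) edges — so every stage is testable without any scanner data.

## Worked example

```r
library(subconn)

# a small two-group cohort from the 14-ROI homotopic template
cfg <- pipeline_config(
  cohort  = cohort_spec(n_group_a = 10, n_group_b = 8, n_volumes = 110,
                        group_effect = 0, seed = 1),
  mcmc    = mcmc_settings(4000, 1000, 2, seed = 2),
  out_dir = tempfile("subconn-demo-"))
res <- run_pipeline(cfg)
print(res)
```

```
Group comparison: density a = 0.271 (SD 0.017, n=10), b = 0.248 (SD 0.019, n=8)
t = 2.693, two-tailed p = 0.017 (welch)
strongest edges (group-a mean):
        roi_i         roi_j    mean_a    mean_b homotopic
1  L_Thalamus    R_Thalamus 0.5519726 0.5429789      TRUE
2   L_Caudate     R_Caudate 0.3872068 0.3430592      TRUE
3 R_Accumbens R_Hippocampus 0.2888458 0.1718846     FALSE
```

Read: both simulated groups have posterior expected network densities near
the template density of ~0.26, and the strongest group-mean partial
correlations sit on the thalamus and caudate homotopic pairs — the
qualitative pattern the generating model encodes (targets 0.55 and 0.41).
The nominal rejection (p = 0.017) at this particular seed is exactly the
kind of small-sample false positive a 5%-level test produces by
construction with only 10 + 8 subjects; the test suite verifies that the
rejection rate over 500 null cohorts stays within [0.03, 0.07].

The same stages are available as an explicit workflow in `analysis/`
(01_simulate → 02_preprocess → 03_infer → 04_group_compare), each script a
thin driver over the package functions, writing its tables under
`results/`.

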