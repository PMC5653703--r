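# Shared fixtures. The 14-ROI template cohort fit is expensive (20 subjects
# at T = 110), so it is computed once per test session and memoised; both
# the homotopic-dominance check and the edge-recovery property read it.

.fixture_cache <- new.env(parent = emptyenv())

quick_mcmc <- function(n_iterations = 2000, burn_in = 500, thinning = 2,
                       seed = 1L) {
  mcmc_settings(n_iterations, burn_in, thinning, seed)
}

# 20 subjects (12 group a, 8 group b) from the default 14-ROI template at
# the study design point T = 110, preprocessed and fitted.
template_cohort_fit <- function() {
  if (!is.null(.fixture_cache$template_fit)) return(.fixture_cache$template_fit)
  spec <- cohort_spec(n_group_a = 12, n_group_b = 8, n_volumes = 110,
                      group_effect = 0, seed = 20260924L)
  coh <- simulate_cohort(spec)
  fits <- lapply(seq_along(coh$subjects), function(k) {
    s <- coh$subjects[[k]]
    cleaned <- preprocess_subject(s$series, s$confounds)
    suppressWarnings(run_mcmc(cleaned, prior_spec(),
                              mcmc_settings(4000, 1000, 2,
                                            seed = derive_seed_t(4242, k))))
  })
  groups <- vapply(coh$subjects, function(s) s$series$group, character(1))
  out <- list(cohort = coh, fits = fits, groups = groups)
  .fixture_cache$template_fit <- out
  out
}

# local copy of the package's deterministic seed derivation for fixtures
derive_seed_t <- function(root, k) {
  as.integer(((root %% 2147483629) * 48271 + 7919 * (k + 1)) %% 2147483629 + 1)
}

# 500 reduced null cohorts (group_effect = 0, n = 10/10, d = 6, T = 110),
# each yielding the two groups' per-subject posterior expected densities.
# Memoised: both the type-I calibration and the t-reference check read it.
null_calibration_densities <- function() {
  if (!is.null(.fixture_cache$null_calib)) return(.fixture_cache$null_calib)
  rs6 <- synthetic_roi_set(3)
  reps <- lapply(1:500, function(rep) {
    spec <- cohort_spec(10, 10, 110, group_effect = 0,
                        seed = 20260924L + rep)
    coh <- simulate_cohort(spec, rs6)
    dens <- vapply(seq_along(coh$subjects), function(k) {
      s <- coh$subjects[[k]]
      cl <- preprocess_subject(s$series, s$confounds)
      suppressWarnings(run_mcmc(cl, prior_spec(),
                                mcmc_settings(600, 200, 1,
                                              seed = rep * 1000 + k)))$expected_density
    }, numeric(1))
    grp <- vapply(coh$subjects, function(s) s$series$group, character(1))
    list(a = dens[grp == "a"], b = dens[grp == "b"])
  })
  .fixture_cache$null_calib <- reps
  reps
}
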