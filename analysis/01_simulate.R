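#!/usr/bin/env Rscript
# Stage 1: simulate a two-group cohort of subcortical ROI time series.
#
# The generating model is a sparse Gaussian graphical model over the 14
# subcortical ROIs whose strongest partial correlations sit on the homotopic
# (left-right) pairs: 0.55 for the thalamus pair, 0.41 for the caudate pair,
# 0.30 for the remaining five, with extra non-homotopic edges at probability
# 0.2 (template density about 0.26). Each subject contributes T = 110
# volumes at TR = 2.38 s, contaminated by slow drift and nuisance-coupled
# signal. Desk-scale group sizes (16 / 10) keep the downstream inference
# stage to a few minutes; the generator itself defaults to the full 72 / 39
# design.
#
# Writes per-subject TSVs plus a cohort manifest under results/cohort/.

suppressPackageStartupMessages(library(subconn))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(n_group_a = 16, n_group_b = 10, n_volumes = 110,
                    group_effect = 0, seed = 7L)
cohort <- simulate_cohort(spec)

manifest <- list()
for (s in cohort$subjects) {
  sid <- s$series$subject_id
  write_series_tsv(s$series, file.path(out_dir, paste0(sid, ".tsv")))
  write_series_tsv(s$confounds$regressors,
                   file.path(out_dir, paste0(sid, "_confounds.tsv")))
  manifest[[sid]] <- list(group = s$series$group, seed = s$seed,
                          series = paste0(sid, ".tsv"),
                          confounds = paste0(sid, "_confounds.tsv"))
}
write_json_report(list(spec = unclass(spec), subjects = manifest),
                  file.path(out_dir, "manifest.json"))

hp <- cohort$roi_set$homotopic_pairs
message(sprintf("simulated %d subjects (%d a / %d b), %d x %d each",
                length(cohort$subjects), spec$n_group_a, spec$n_group_b,
                spec$n_volumes, length(cohort$roi_set$labels)))
message(sprintf("template density %.3f; homotopic partials: %s",
                sum(cohort$model_a$graph[upper.tri(cohort$model_a$graph)]) /
                  n_possible_edges(cohort$roi_set),
                paste(round(cohort$model_a$partials[hp], 2), collapse = " ")))
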