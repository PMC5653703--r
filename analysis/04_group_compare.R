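#!/usr/bin/env Rscript
# Stage 4: group comparison.
#
# Averages the per-subject expected partial-correlation matrices per group,
# compares the posterior expected network densities with a two-tailed Welch
# t-test, and ranks the strongest connections. Writes the group report JSON
# and the two group-mean matrices under results/group/.

suppressPackageStartupMessages(library(subconn))

in_raw <- "results/cohort"
in_post <- "results/posterior"
out_dir <- "results/group"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_json_report(file.path(in_raw, "manifest.json"))
rs <- default_roi_set()

summaries <- list()
groups <- character()
for (sid in names(manifest$subjects)) {
  mat_p <- read_matrix_csv(file.path(in_post, paste0(sid, "_partials.csv")))
  js <- read_json_report(file.path(in_post, paste0(sid, "_summary.json")))
  summaries[[sid]] <- structure(
    list(edge_probability = read_matrix_csv(
      file.path(in_post, paste0(sid, "_edge_prob.csv"))),
      expected_partials = mat_p,
      expected_density = js$expected_density,
      n_retained_samples = js$n_retained_samples,
      roi_labels = colnames(mat_p)),
    class = "posterior_summary")
  groups[sid] <- manifest$subjects[[sid]]$group
}

res <- compare_groups(summaries[groups == "a"], summaries[groups == "b"], rs)
print(res)

write_matrix_csv(res$mean_partials_a$mean,
                 file.path(out_dir, "mean_partials_a.csv"))
write_matrix_csv(res$mean_partials_b$mean,
                 file.path(out_dir, "mean_partials_b.csv"))
write_json_report(list(
  mean_density_a = res$density_test$mean_a,
  sd_density_a = res$density_test$sd_a,
  mean_density_b = res$density_test$mean_b,
  sd_density_b = res$density_test$sd_b,
  t_statistic = res$t_statistic, p_value = res$p_value,
  top_edges = utils::head(res$strongest_edges, 10),
  top_k_all_homotopic = res$dominance$top_k_all_homotopic),
  file.path(out_dir, "report.json"))
message(sprintf("dominance: top-%d edges all homotopic = %s",
                res$dominance$top_k, res$dominance$top_k_all_homotopic))
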