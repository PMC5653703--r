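#!/usr/bin/env Rscript
# Stage 2: nuisance regression and temporal high-pass filtering.
#
# Reads the raw cohort TSVs from results/cohort/, regresses out the 16
# nuisance regressors (6 motion surrogates, mean WM, mean CSF, and their
# backward-difference derivatives) plus an intercept, then removes
# fluctuations slower than 100 s with the Gaussian running-line filter.
# Writes cleaned TSVs under results/clean/.

suppressPackageStartupMessages(library(subconn))

in_dir <- "results/cohort"
out_dir <- "results/clean"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_json_report(file.path(in_dir, "manifest.json"))
tr <- manifest$spec$tr_seconds

for (sid in names(manifest$subjects)) {
  entry <- manifest$subjects[[sid]]
  series <- roi_time_series(read_series_tsv(file.path(in_dir, entry$series)),
                            group = entry$group, subject_id = sid,
                            tr_seconds = tr)
  confounds <- confound_set(read_series_tsv(file.path(in_dir,
                                                      entry$confounds)))
  cleaned <- preprocess_subject(series, confounds,
                                list(cutoff_seconds = 100,
                                     filter_method = "gaussian",
                                     order = "regress-first"))
  write_series_tsv(cleaned, file.path(out_dir, paste0(sid, "_clean.tsv")))
}
message(sprintf("preprocessed %d subjects (confound regression + 100 s high-pass)",
                length(manifest$subjects)))
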