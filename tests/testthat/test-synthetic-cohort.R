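test_that("template graph forces homotopic edges and respects the edge probability", {
  rs <- default_roi_set()
  g0 <- build_template_graph(rs, extra_edge_prob = 0, seed = 1)
  expect_equal(sum(g0[upper.tri(g0)]), 7)
  hp <- rs$homotopic_pairs
  expect_true(all(g0[hp] == 1))

  g1 <- build_template_graph(rs, extra_edge_prob = 1, seed = 1)
  expect_equal(sum(g1[upper.tri(g1)]), n_possible_edges(14))

  ga <- build_template_graph(rs, extra_edge_prob = 0.3, seed = 7)
  gb <- build_template_graph(rs, extra_edge_prob = 0.3, seed = 7)
  expect_identical(ga, gb)
  expect_identical(ga, t(ga))
  expect_true(all(diag(ga) == 0))

  expect_error(build_template_graph(rs, extra_edge_prob = 1.2),
               "probability")
})

test_that("generated precision matrices are SPD, on-graph, and hit their targets", {
  rs <- default_roi_set()
  # empty graph -> diagonal K, zero partials
  d <- 5
  empty <- matrix(0, d, d)
  pm <- generate_precision(empty, seed = 1)
  expect_equal(pm$precision, diag(diag(pm$precision)))
  expect_equal(pm$partials - diag(d), matrix(0, d, d))

  # d = 2 single edge with target 0.5: K_12 = -0.5 * sqrt(K_11 * K_22)
  g2 <- matrix(c(0, 1, 1, 0), 2)
  t2 <- matrix(c(NA, 0.5, 0.5, NA), 2)
  pm2 <- generate_precision(g2, t2)
  expect_equal(pm2$precision[1, 2],
               -0.5 * sqrt(pm2$precision[1, 1] * pm2$precision[2, 2]))

  # default template with the two strongest homotopic targets
  graph <- build_template_graph(rs, 0.2, seed = 2)
  pm14 <- generate_precision(graph, default_pair_targets(rs), seed = 3)
  expect_true(min(eigen(pm14$precision, TRUE, TRUE)$values) > 0)
  expect_lt(abs(pm14$partials["L_Thalamus", "R_Thalamus"] - 0.55), 0.02)
  expect_lt(abs(pm14$partials["L_Caudate", "R_Caudate"] - 0.41), 0.02)
  off_graph <- pm14$precision[graph == 0 & upper.tri(graph)]
  expect_true(all(off_graph == 0))

  # unreachable targets raise a convergence error naming the edges
  # (an equicorrelated triangle at +0.95 has smallest eigenvalue 1 - 2*0.95)
  g3 <- matrix(1, 3, 3) - diag(3)
  t3 <- matrix(0.95, 3, 3); diag(t3) <- NA
  expect_error(generate_precision(g3, t3), "unreachable.*1-2")
})

test_that("clean simulated signal matches the generating model (law of large numbers)", {
  rs6 <- synthetic_roi_set(3)
  graph <- build_template_graph(rs6, 0.3, seed = 4)
  model <- generate_precision(graph, default_pair_targets(rs6), seed = 5)
  spec <- cohort_spec(1, 1, n_volumes = 1e5, drift_amplitude = 0,
                      confound_coupling = 0, seed = 6)
  sub <- simulate_subject(model, spec, seed = 10)
  # sample covariance vs inverse precision, entrywise
  expect_lt(max(abs(cov(sub$series$values) - solve(model$precision))), 0.01)
  # sample partial correlations vs model partials
  expect_lt(max(abs(sample_partials(sub$series$values) - model$partials)),
            0.02)
})

test_that("subject simulation is deterministic and contamination is removable", {
  rs4 <- synthetic_roi_set(2)
  model <- generate_precision(build_template_graph(rs4, 0.3, seed = 1),
                              default_pair_targets(rs4), seed = 2)
  # long series so the clean signal's incidental overlap with the
  # 16-regressor confound span is negligible
  spec <- cohort_spec(1, 1, n_volumes = 5000, drift_amplitude = 0,
                      confound_coupling = 3, seed = 3)
  s1 <- simulate_subject(model, spec, seed = 42)
  s2 <- simulate_subject(model, spec, seed = 42)
  expect_identical(s1$series$values, s2$series$values)
  expect_identical(s1$confounds$regressors, s2$confounds$regressors)

  # heavy confound coupling, then regression: residual tracks the clean signal
  cleaned <- regress_confounds(s1$series, s1$confounds)
  cors <- vapply(seq_len(ncol(cleaned$values)), function(j)
    cor(cleaned$values[, j], s1$clean[, j]), numeric(1))
  expect_true(all(cors > 0.99))

  expect_error(simulate_subject(model, cohort_spec(1, 1, n_volumes = 1)),
               "at least 2")
})

test_that("cohort generation honours group structure, sizes and determinism", {
  rs4 <- synthetic_roi_set(2)
  spec <- cohort_spec(n_group_a = 5, n_group_b = 3, n_volumes = 40,
                      group_effect = 0.4, seed = 11)
  coh <- simulate_cohort(spec, rs4)
  expect_length(coh$subjects, 8)
  groups <- vapply(coh$subjects, function(s) s$series$group, character(1))
  expect_equal(sum(groups == "a"), 5)
  expect_equal(sum(groups == "b"), 3)
  expect_equal(dim(coh$subjects[[1]]$series$values), c(40L, 4L))

  # same skeleton, uniformly shrunk partials in group b
  expect_identical(coh$model_a$graph, coh$model_b$graph)
  off <- upper.tri(coh$model_a$partials)
  expect_equal(coh$model_b$partials[off], 0.6 * coh$model_a$partials[off],
               tolerance = 1e-12)

  # pure function of (spec, roi_set)
  coh2 <- simulate_cohort(spec, rs4)
  expect_identical(coh$subjects[[4]]$series$values,
                   coh2$subjects[[4]]$series$values)

  # group_effect extremes
  coh0 <- simulate_cohort(cohort_spec(2, 2, 30, group_effect = 0, seed = 1), rs4)
  expect_identical(coh0$model_a$precision, coh0$model_b$precision)
  coh1 <- simulate_cohort(cohort_spec(2, 2, 30, group_effect = 1, seed = 1), rs4)
  expect_equal(max(abs(coh1$model_b$partials[off])), 0)
})

test_that("full-size defaults mirror the study design point", {
  spec <- cohort_spec()
  expect_equal(spec$n_group_a, 72L)
  expect_equal(spec$n_group_b, 39L)
  expect_equal(spec$n_volumes, 110L)
  expect_equal(spec$tr_seconds, 2.38)
  rs <- default_roi_set()
  expect_length(rs$labels, 14)
  expect_equal(nrow(rs$homotopic_pairs), 7)
})

test_that("roi_set and cohort_spec validate their invariants", {
  expect_error(roi_set(c("a", "a")), "unique")
  expect_error(roi_set(c("a", "b"), cbind(1, 3)), "out of range")
  expect_error(roi_set(c("a", "b", "c", "d"), rbind(c(1, 2), c(2, 3))),
               "at most one")
  expect_error(cohort_spec(group_effect = 1.5), "group_effect")
  expect_error(cohort_spec(n_group_a = 0), "at least one")
  expect_error(confound_set(cbind(a = rep(0, 5), b = rnorm(5))), "all-zero")
})
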