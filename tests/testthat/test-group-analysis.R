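test_that("group mean matrices average subjects entrywise", {
  m1 <- matrix(c(1, .3, .3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  gm <- group_mean_matrix(list(m1))
  expect_equal(gm$mean, m1)
  expect_equal(gm$sd, matrix(0, 2, 2), ignore_attr = TRUE)

  m2 <- m1; m2[1, 2] <- m2[2, 1] <- -.3
  gm2 <- group_mean_matrix(list(m1, m2))
  expect_equal(gm2$mean[1, 2], 0)
  expect_equal(gm2$sd[1, 2], sd(c(.3, -.3)))

  m3 <- matrix(1, 3, 3)
  expect_error(group_mean_matrix(list(m1, m3)), "mismatched")
})

test_that("the group mean recovers the generating partials (simulation oracle)", {
  # 20 subjects from one model; average their sample partial-correlation
  # matrices and compare entrywise with the generating partials at 2 SE
  rs4 <- synthetic_roi_set(2)
  model <- generate_precision(build_template_graph(rs4, 0.5, seed = 21),
                              default_pair_targets(rs4), seed = 22)
  spec <- cohort_spec(1, 1, n_volumes = 800, drift_amplitude = 0,
                      confound_coupling = 0, seed = 23)
  mats <- lapply(1:20, function(k)
    sample_partials(simulate_subject(model, spec, seed = 300 + k)$series$values))
  gm <- group_mean_matrix(mats)
  se <- gm$sd / sqrt(gm$n)
  diffs <- abs(gm$mean - model$partials)
  expect_true(all(diffs[upper.tri(diffs)] <= 2 * se[upper.tri(se)] + 1e-9))
})

test_that("density test handles equal groups, symmetry and degeneracy", {
  a <- c(0.2, 0.3, 0.4)
  b <- c(0.4, 0.3, 0.2)  # same mean, same variance
  res <- density_test(a, b)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(31)
  x <- runif(8, 0.2, 0.4); y <- runif(8, 0.25, 0.45)
  r1 <- density_test(x, y)
  r2 <- density_test(y, x)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value, r2$p_value)

  dg <- density_test(rep(0.3, 4), rep(0.3, 5))
  expect_true(dg$degenerate)
  expect_equal(dg$t_statistic, 0)
  expect_equal(dg$p_value, 1)
  dg2 <- density_test(rep(0.4, 4), rep(0.3, 5))
  expect_true(dg2$degenerate)
  expect_equal(dg2$p_value, 0)

  expect_error(density_test(0.3, c(0.1, 0.2)), "at least two")
})

test_that("null-cohort t statistics follow the t reference; groups are exchangeable (KS)", {
  # under group_effect = 0 the group labels are exchangeable, so the pooled
  # t statistic over replicate null cohorts must follow t with n - 2 df
  reps <- null_calibration_densities()
  tstats <- vapply(reps, function(r)
    density_test(r$a, r$b, var_equal = TRUE)$t_statistic, numeric(1))
  df <- length(reps[[1]]$a) + length(reps[[1]]$b) - 2
  ref <- function(x) 2 * pt(x, df = df) - 1  # cdf of |T_df|
  xs <- sort(abs(tstats))
  ecdf_vals <- seq_along(xs) / length(xs)
  ks <- max(pmax(abs(ecdf_vals - ref(xs)),
                 abs(c(0, ecdf_vals[-length(xs)]) - ref(xs))))
  expect_lt(ks, 0.05)
})

test_that("homotopic dominance ranking orders edges and flags the pattern", {
  rs4 <- synthetic_roi_set(2)
  m <- matrix(0.1, 4, 4, dimnames = list(rs4$labels, rs4$labels))
  diag(m) <- 1
  hp <- rs4$homotopic_pairs
  for (r in seq_len(nrow(hp)))
    m[hp[r, 1], hp[r, 2]] <- m[hp[r, 2], hp[r, 1]] <- 0.5
  rep1 <- rank_homotopic_dominance(m, rs4)
  expect_true(rep1$top_k_all_homotopic)
  expect_true(all(rep1$edges$homotopic[1:2]))

  # all-zero matrix: no dominance, stable index ordering
  z <- matrix(0, 4, 4, dimnames = dimnames(m)); diag(z) <- 1
  z0 <- z; diag(z0) <- 0
  rep0 <- rank_homotopic_dominance(z0, rs4)
  expect_false(rep0$top_k_all_homotopic)
  expect_equal(rep0$edges$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(rep0$edges$j, c(2, 3, 4, 3, 4, 4))
})

test_that("the density test rejects strongly shrunk patient-like cohorts (power)", {
  rs6 <- synthetic_roi_set(3)
  rejections <- vapply(1:25, function(rep) {
    spec <- cohort_spec(30, 30, 110, group_effect = 0.5,
                        seed = 5000 + rep)
    coh <- simulate_cohort(spec, rs6)
    dens <- vapply(seq_along(coh$subjects), function(k) {
      s <- coh$subjects[[k]]
      cl <- preprocess_subject(s$series, s$confounds)
      suppressWarnings(run_mcmc(cl, prior_spec(),
                                mcmc_settings(600, 200, 1,
                                              seed = rep * 100 + k)))$expected_density
    }, numeric(1))
    grp <- vapply(coh$subjects, function(s) s$series$group, character(1))
    density_test(dens[grp == "a"], dens[grp == "b"])$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("compare_groups assembles a coherent group result", {
  fit <- template_cohort_fit()
  res <- compare_groups(fit$fits[fit$groups == "a"],
                        fit$fits[fit$groups == "b"],
                        fit$cohort$roi_set)
  expect_s3_class(res, "group_result")
  expect_equal(res$mean_partials_a$mean, t(res$mean_partials_a$mean))
  expect_equal(diag(res$mean_partials_a$mean), rep(1, 14),
               ignore_attr = TRUE)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # strongest edges sorted descending by group-a mean
  expect_true(!is.unsorted(rev(res$strongest_edges$mean_a)))
  expect_length(res$density_a, 12)
  expect_length(res$density_b, 8)
})
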