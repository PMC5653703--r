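test_that("confound regression projects out the nuisance span exactly", {
  set.seed(1)
  n <- 110
  conf <- simulate_confounds(n, seed = 2)
  # a series that IS a confound column (replicated) residualises to zero
  y <- matrix(conf$regressors[, "motion1"], n, 3)
  res <- regress_confounds(roi_time_series(y), conf)
  expect_lt(max(abs(res$values)), 1e-10)

  # residuals orthogonal to every regressor
  sig <- matrix(rnorm(n * 4), n, 4)
  res2 <- regress_confounds(roi_time_series(sig), conf)
  proj <- crossprod(conf$regressors, res2$values) /
    sqrt(colSums(conf$regressors^2) %o% colSums(res2$values^2))
  expect_lt(max(abs(proj)), 1e-8)

  # confounds orthogonal to the series leave a mean-centred series
  q <- qr.Q(qr(cbind(1, sig)))
  orth <- diag(n) - tcrossprod(q)
  conf_orth <- confound_set(orth[, 1:5] %*% matrix(rnorm(25), 5, 5))
  res3 <- regress_confounds(roi_time_series(sig), conf_orth)
  centred <- sweep(sig, 2, colMeans(sig))
  expect_equal(res3$values, centred, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("known mixing is undone by regression (projection oracle)", {
  set.seed(3)
  n <- 5000  # long series: the clean signal is near-orthogonal to the span
  conf <- simulate_confounds(n, seed = 4)
  clean <- matrix(rnorm(n * 3), n, 3)
  mixed <- clean + 2 * conf$regressors[, "motion2"]
  res <- regress_confounds(roi_time_series(mixed), conf)
  # direct projection oracle
  design <- cbind(1, conf$regressors)
  oracle <- mixed - design %*% qr.solve(design, mixed)
  expect_equal(res$values, oracle, ignore_attr = TRUE, tolerance = 1e-10)
  cors <- vapply(1:3, function(j) cor(res$values[, j], clean[, j]),
                 numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("rank-deficient confound designs are rejected with the collinear columns named", {
  set.seed(5)
  n <- 50
  a <- rnorm(n)
  cmat <- cbind(m1 = a, m2 = rnorm(n), m3 = 2 * a)
  expect_error(regress_confounds(matrix(rnorm(n * 2), n), cmat),
               "rank deficient.*m[13]")
  # exact duplicates are silently dropped instead
  cmat2 <- cbind(m1 = a, m2 = rnorm(n), m1_copy = a)
  res <- regress_confounds(matrix(rnorm(n * 2), n), cmat2)
  expect_equal(nrow(res$values), n)
})

test_that("regression is idempotent and preserves shape", {
  set.seed(6)
  n <- 80
  conf <- simulate_confounds(n, seed = 7)
  x <- roi_time_series(matrix(rnorm(n * 5), n, 5))
  r1 <- regress_confounds(x, conf)
  r2 <- regress_confounds(r1, conf)
  expect_lt(max(abs(r1$values - r2$values)), 1e-10)
  expect_equal(dim(r1$values), dim(x$values))
})

test_that("gaussian running-line filter removes DC and drift, keeps the pass band", {
  n <- 110; tr <- 2.38
  tt <- seq_len(n) * tr
  # constant column -> all zero
  z <- highpass_filter(matrix(rep(5, n)), 100, tr, "gaussian")
  expect_lt(max(abs(z$values)), 1e-10)
  # 20 s sinusoid passes within 5 %
  x <- sin(2 * pi * tt / 20 + 0.7)
  y <- highpass_filter(matrix(x), 100, tr, "gaussian")$values[, 1]
  ratio <- sinusoid_amplitude(y, tt, 20) / sinusoid_amplitude(x, tt, 20)
  expect_lt(abs(ratio - 1), 0.05)
  # linear drift over 110 volumes is essentially removed
  drift <- tt / max(tt)
  yd <- highpass_filter(matrix(drift), 100, tr, "gaussian")$values[, 1]
  expect_lt(var(yd) / var(drift), 0.1)
  # zero mean output
  set.seed(8)
  r <- highpass_filter(matrix(rnorm(n * 3), n), 100, tr, "gaussian")
  expect_lt(max(abs(colMeans(r$values))), 1e-12)
})

test_that("dct filter attenuates the stop band by more than 90 percent", {
  n <- 110; tr <- 2.38
  tt <- seq_len(n) * tr
  for (period in c(130, 150, 200, 260)) for (ph in c(0, 1.3)) {
    x <- sin(2 * pi * tt / period + ph)
    y <- highpass_filter(matrix(x), 100, tr, "dct")$values[, 1]
    expect_lt(sinusoid_amplitude(y, tt, period) /
                sinusoid_amplitude(x, tt, period), 0.1)
  }
  # pass band preserved within 5 %
  x <- sin(2 * pi * tt / 20 + 1.1)
  y <- highpass_filter(matrix(x), 100, tr, "dct")$values[, 1]
  expect_lt(abs(sinusoid_amplitude(y, tt, 20) /
                  sinusoid_amplitude(x, tt, 20) - 1), 0.05)
})

test_that("filter rejects cutoffs at or below the resolvable period", {
  expect_error(highpass_filter(matrix(rnorm(50)), 4, 2.38), "twice")
  expect_error(highpass_filter(matrix(rnorm(50)), 100, -1), "positive")
})

test_that("filtering and regression commute when regressors are pre-filtered", {
  set.seed(9)
  n <- 110; tr <- 2.38
  conf <- simulate_confounds(n, seed = 10)
  y <- roi_time_series(matrix(rnorm(n * 4), n, 4), tr_seconds = tr)
  conf_f <- highpass_filter(clean_series(conf$regressors, tr_seconds = tr),
                            100, method = "dct")
  # order A: filter series then regress on filtered confounds
  a <- regress_confounds(highpass_filter(y, 100, method = "dct"),
                         conf_f$values)
  # order B: regress on filtered confounds then filter
  b0 <- regress_confounds(y, conf_f$values)
  b0$tr_seconds <- tr
  b <- highpass_filter(b0, 100, method = "dct")
  expect_lt(max(abs(a$values - b$values)), 1e-6)
})

test_that("exclusion accounting reproduces retained group sizes", {
  led <- cohort_ledger(
    87, 42,
    excluded_a = data.frame(subject = sprintf("p%02d", 1:15),
                            reason = rep("image quality", 15)),
    excluded_b = data.frame(subject = sprintf("c%02d", 1:3),
                            reason = c("scanner artefacts",
                                       "low contrast", "low contrast")))
  ret <- apply_exclusions(led)
  expect_equal(unname(ret["retained_a"]), 72L)
  expect_equal(unname(ret["retained_b"]), 39L)

  led0 <- cohort_ledger(10, 5)
  expect_equal(unname(apply_exclusions(led0)), c(10L, 5L))

  expect_error(cohort_ledger(2, 2, excluded_a = data.frame(
    subject = c("a", "b", "c"), reason = rep("x", 3))), "more subjects")
  expect_error(cohort_ledger(5, 5, excluded_a = data.frame(
    subject = "a", reason = "")), "non-empty")
})
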