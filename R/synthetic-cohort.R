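# Synthetic two-group cohort generator: sparse Gaussian graphical models with
# homotopically dominated structure, observed through drift and
# nuisance-coupled contamination. Stands in for (undeposited) resting-state
# ROI time series so the whole pipeline is testable end to end.

#' Ground-truth precision model for simulation
#'
#' Couples a binary conditional-independence graph `G`, a symmetric positive
#' definite precision matrix `K` supported on `G`, and the implied partial
#' correlations `rho_ij = -K_ij / sqrt(K_ii * K_jj)`.
#'
#' @param graph Symmetric binary adjacency matrix with zero diagonal.
#' @param precision Symmetric positive definite matrix; `precision[i, j]`
#'   must be zero wherever `graph[i, j]` is zero (off-diagonal).
#' @return An object of class `precision_model` with elements `graph`,
#'   `precision` and `partials`.
#' @export
precision_model <- function(graph, precision) {
  check_symmetric(graph, "graph")
  check_symmetric(precision, "precision")
  d <- nrow(graph)
  if (nrow(precision) != d)
    stop("graph and precision dimensions differ", call. = FALSE)
  if (any(diag(graph) != 0)) stop("graph diagonal must be zero", call. = FALSE)
  if (!all(graph %in% c(0, 1)))
    stop("graph must be binary", call. = FALSE)
  off <- abs(precision) > 1e-12 & graph == 0
  diag(off) <- FALSE
  if (any(off))
    stop("precision has support outside the graph", call. = FALSE)
  if (!is_spd(precision))
    stop("precision must be positive definite", call. = FALSE)
  partials <- partial_from_precision(precision)
  if (any(abs(partials[upper.tri(partials)]) >= 1))
    stop("off-diagonal partial correlations must have |rho| < 1",
         call. = FALSE)
  structure(list(graph = graph, precision = precision, partials = partials),
            class = "precision_model")
}

#' Specification of a simulated two-group cohort
#'
#' Defaults mirror the emulated study's design point: 72 subjects in group a
#' (patients) and 39 in group b (controls), 110 volumes at TR = 2.38 s over
#' 14 ROIs. `group_effect` shrinks every partial correlation of the group-b
#' generating model by a factor `1 - group_effect`; the default 0 encodes no
#' group difference.
#'
#' @param n_group_a,n_group_b Subject counts per group (each `>= 1`).
#' @param n_volumes Time points per subject (`T`).
#' @param tr_seconds Repetition time in seconds.
#' @param group_effect Uniform shrinkage in `[0, 1]` applied to group-b
#'   partial correlations.
#' @param drift_amplitude Amplitude of the slow sinusoid-plus-trend drift
#'   added to the BOLD signal, in units of the (unit) signal SD.
#' @param confound_coupling Amplitude of the nuisance-correlated signal mixed
#'   into the BOLD series.
#' @param seed Integer root seed; all subject-level seeds derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 72, n_group_b = 39, n_volumes = 110,
                        tr_seconds = 2.38, group_effect = 0,
                        drift_amplitude = 0.5, confound_coupling = 0.5,
                        seed = 1L) {
  if (n_group_a < 1 || n_group_b < 1)
    stop("each group needs at least one subject", call. = FALSE)
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (group_effect < 0 || group_effect > 1)
    stop("group_effect must lie in [0, 1]", call. = FALSE)
  if (n_volumes < 2) stop("n_volumes must be at least 2", call. = FALSE)
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 group_effect = group_effect,
                 drift_amplitude = drift_amplitude,
                 confound_coupling = confound_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build the homotopically dominated template graph
#'
#' Every homotopic (left-right) pair is forced to be an edge; every other
#' pair is included independently with probability `extra_edge_prob`. With
#' the default 14-ROI set and `extra_edge_prob = 0.2` the expected density is
#' about 0.26, the scale reported for subcortical resting-state networks.
#'
#' @param roi_set A [roi_set()].
#' @param extra_edge_prob Probability in `[0, 1]` for each non-homotopic
#'   pair.
#' @param seed Optional integer seed; the same seed always yields the same
#'   graph.
#' @return Symmetric binary `d x d` adjacency matrix with ROI labels.
#' @export
build_template_graph <- function(roi_set, extra_edge_prob = 0.2,
                                 seed = NULL) {
  stopifnot(inherits(roi_set, "roi_set"))
  if (!is.numeric(extra_edge_prob) || length(extra_edge_prob) != 1 ||
      is.na(extra_edge_prob) || extra_edge_prob < 0 || extra_edge_prob > 1)
    stop("extra_edge_prob must be a probability in [0, 1]", call. = FALSE)
  d <- length(roi_set$labels)
  G <- matrix(0L, d, d, dimnames = list(roi_set$labels, roi_set$labels))
  homo <- matrix(FALSE, d, d)
  hp <- roi_set$homotopic_pairs
  if (nrow(hp) > 0)
    for (r in seq_len(nrow(hp))) homo[hp[r, 1], hp[r, 2]] <-
        homo[hp[r, 2], hp[r, 1]] <- TRUE
  with_seed(seed, {
    for (j in seq_len(d - 1)) for (i in seq(j + 1, d)) {
      G[i, j] <- G[j, i] <-
        if (homo[i, j]) 1L else as.integer(runif(1) < extra_edge_prob)
    }
  })
  G
}

#' Construct a precision matrix realising target partial correlations
#'
#' Builds a unit-diagonal precision matrix supported exactly on `graph` whose
#' implied partial correlations hit the requested targets. Edges without a
#' target receive a magnitude drawn uniformly from `fill_range` (positive
#' sign). If the assembled matrix is not positive definite, unspecified-edge
#' values are shrunk first, then all off-diagonal values by a gentle
#' geometric backoff; if any target then deviates by more than `tol`, a
#' convergence error names the offending edges.
#'
#' @param graph Symmetric binary adjacency matrix, zero diagonal.
#' @param targets Optional `d x d` matrix of target partial correlations with
#'   `NA` for unspecified entries; targets may only sit on edges of `graph`
#'   and must satisfy `|target| < 1`.
#' @param seed Optional seed for the unspecified-edge draws.
#' @param fill_range Length-2 numeric range of magnitudes for unspecified
#'   edges.
#' @param tol Maximum tolerated deviation of a realised partial correlation
#'   from its target.
#' @param spd_margin Required smallest eigenvalue of the assembled precision.
#' @return A [precision_model()].
#' @export
generate_precision <- function(graph, targets = NULL, seed = NULL,
                               fill_range = c(0.1, 0.2), tol = 0.02,
                               spd_margin = 1e-3) {
  check_symmetric(graph, "graph")
  d <- nrow(graph)
  if (any(diag(graph) != 0)) stop("graph diagonal must be zero", call. = FALSE)
  if (is.null(targets)) targets <- matrix(NA_real_, d, d)
  check_symmetric(ifelse(is.na(targets), 0, targets), "targets")
  bad <- !is.na(targets) & graph == 0
  diag(bad) <- FALSE
  if (any(bad))
    stop("targets given on non-edges of the graph", call. = FALSE)
  if (any(abs(targets) >= 1, na.rm = TRUE))
    stop("target partial correlations must satisfy |target| < 1",
         call. = FALSE)

  rho <- matrix(0, d, d)
  specified <- matrix(FALSE, d, d)
  up <- which(upper.tri(graph) & graph == 1, arr.ind = TRUE)
  with_seed(seed, {
    if (nrow(up) > 0) for (r in seq_len(nrow(up))) {
      i <- up[r, 1]; j <- up[r, 2]
      if (!is.na(targets[i, j])) {
        rho[i, j] <- rho[j, i] <- targets[i, j]
        specified[i, j] <- specified[j, i] <- TRUE
      } else {
        rho[i, j] <- rho[j, i] <- runif(1, fill_range[1], fill_range[2])
      }
    }
  })

  # K has unit diagonal and K_ij = -rho_ij, so realised partials equal rho
  # exactly; positive definiteness is restored by shrinking fill edges first.
  scale_fill <- 1
  scale_all <- 1
  assemble <- function() {
    K <- matrix(0, d, d)
    K[!specified] <- -rho[!specified] * scale_fill * scale_all
    K[specified] <- -rho[specified] * scale_all
    diag(K) <- 1
    K
  }
  K <- assemble()
  it <- 0
  has_fill <- any(!specified & rho != 0)
  while (!is_spd(K, spd_margin) && it < 300) {
    if (it < 30 && has_fill) scale_fill <- scale_fill * 0.9 else
      scale_all <- scale_all * 0.95
    K <- assemble()
    it <- it + 1
  }
  if (!is_spd(K, spd_margin))
    stop("could not reach positive definiteness for the requested targets",
         call. = FALSE)
  realised <- partial_from_precision(K)
  dev <- abs(realised - ifelse(is.na(targets), realised, targets))
  if (any(dev > tol)) {
    off <- which(dev > tol & upper.tri(dev), arr.ind = TRUE)
    stop(sprintf(
      "target partial correlations unreachable under positive definiteness for edges: %s",
      paste(apply(off, 1, paste, collapse = "-"), collapse = ", ")),
      call. = FALSE)
  }
  if (!is.null(dimnames(graph))) dimnames(K) <- dimnames(graph)
  precision_model(graph, K)
}

#' Default homotopic partial-correlation targets
#'
#' Thalamus and caudate pairs get the two strongest targets (0.55 and 0.41,
#' the control-group values of the emulated design); every other homotopic
#' pair defaults to 0.30.
#'
#' @param roi_set A [roi_set()].
#' @param thalamus,caudate,other Target partial correlations.
#' @return A `d x d` target matrix with `NA` off the homotopic pairs,
#'   suitable for [generate_precision()].
#' @export
default_pair_targets <- function(roi_set, thalamus = 0.55, caudate = 0.41,
                                 other = 0.30) {
  d <- length(roi_set$labels)
  targets <- matrix(NA_real_, d, d,
                    dimnames = list(roi_set$labels, roi_set$labels))
  hp <- roi_set$homotopic_pairs
  if (nrow(hp) == 0) return(targets)
  for (r in seq_len(nrow(hp))) {
    i <- hp[r, 1]; j <- hp[r, 2]
    lab <- tolower(roi_set$labels[i])
    val <- if (grepl("thalamus", lab)) thalamus else
      if (grepl("caudate", lab)) caudate else other
    targets[i, j] <- targets[j, i] <- val
  }
  targets
}

# AR(1) series of length n with coefficient phi, unit marginal SD.
ar1_series <- function(n, phi, innov_sd = sqrt(1 - phi^2)) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1, sd = innov_sd)
  x
}

# Backward difference, first row zero-padded.
backward_diff <- function(x) {
  if (is.matrix(x)) rbind(0, diff(x)) else c(0, diff(x))
}

#' Simulate the nuisance regressors of one subject
#'
#' Six autocorrelated motion-like series (AR(1), coefficient 0.9), mean white
#' matter and CSF signals, and the backward-difference temporal derivatives
#' of all eight: 16 regressors.
#'
#' @param n_volumes Number of time points.
#' @param seed Optional seed.
#' @return An object of class `confound_set` (matrix `regressors`, character
#'   `names`).
#' @export
simulate_confounds <- function(n_volumes, seed = NULL) {
  with_seed(seed, {
    motion <- sapply(1:6, function(i) ar1_series(n_volumes, 0.9))
    wm <- ar1_series(n_volumes, 0.5)
    csf <- ar1_series(n_volumes, 0.5)
    base <- cbind(motion, wm, csf)
    colnames(base) <- c(paste0("motion", 1:6), "wm_mean", "csf_mean")
    deriv <- backward_diff(base)
    colnames(deriv) <- paste0(colnames(base), "_deriv")
    confound_set(cbind(base, deriv))
  })
}

#' Bundle nuisance regressors
#'
#' @param regressors Numeric `T x k` matrix with column names.
#' @return An object of class `confound_set`.
#' @export
confound_set <- function(regressors) {
  regressors <- as.matrix(regressors)
  if (is.null(colnames(regressors)))
    colnames(regressors) <- paste0("confound", seq_len(ncol(regressors)))
  if (any(apply(regressors, 2, function(x) all(x == 0))))
    stop("confound regressors must not contain an all-zero column",
         call. = FALSE)
  structure(list(regressors = regressors, names = colnames(regressors)),
            class = "confound_set")
}

#' One subject's ROI time-series matrix
#'
#' @param values Numeric `T x d` matrix, one column per ROI.
#' @param roi_labels Character vector of ROI names (defaults to column
#'   names).
#' @param group Group tag (e.g. `"a"` or `"b"`).
#' @param subject_id Identifier string.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `roi_time_series`.
#' @export
roi_time_series <- function(values, roi_labels = colnames(values),
                            group = NA_character_,
                            subject_id = NA_character_, tr_seconds = 2.38) {
  values <- as.matrix(values)
  if (is.null(roi_labels))
    roi_labels <- paste0("ROI", seq_len(ncol(values)))
  colnames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels, group = group,
                 subject_id = subject_id, tr_seconds = tr_seconds),
            class = "roi_time_series")
}

#' Simulate one subject's contaminated BOLD series
#'
#' The clean signal is i.i.d. zero-mean Gaussian with covariance
#' `solve(model$precision)`. The observed series adds
#' `drift_amplitude * (slow sinusoid + linear trend)` and
#' `confound_coupling * (linear mix of the nuisance regressors)`.
#'
#' @param model A [precision_model()].
#' @param spec A [cohort_spec()] providing `n_volumes`, `tr_seconds` and the
#'   contamination amplitudes.
#' @param seed Optional seed; a fixed seed gives bit-identical output.
#' @param subject_id,group Metadata attached to the returned series.
#' @return List with elements `series` ([roi_time_series()]), `confounds`
#'   ([confound_set()]) and `clean` (the uncontaminated `T x d` matrix).
#' @export
simulate_subject <- function(model, spec, seed = NULL,
                             subject_id = "sub-01", group = "a") {
  stopifnot(inherits(model, "precision_model"), inherits(spec, "cohort_spec"))
  n_t <- spec$n_volumes
  if (n_t < 2) stop("n_volumes must be at least 2", call. = FALSE)
  d <- nrow(model$precision)
  with_seed(seed, {
    sigma <- solve(model$precision)
    clean <- matrix(rnorm(n_t * d), n_t, d) %*% chol(sigma)
    colnames(clean) <- colnames(model$precision)

    tt <- seq_len(n_t) * spec$tr_seconds
    drift <- sapply(seq_len(d), function(j) {
      phase <- runif(1, 0, 2 * pi)
      period <- runif(1, 100, 160)
      slope <- runif(1, -1, 1)
      sin(2 * pi * tt / period + phase) + slope * (tt / max(tt) - 0.5)
    })

    confounds <- simulate_confounds(n_t)
    k <- ncol(confounds$regressors)
    mixing <- matrix(rnorm(k * d), k, d) / sqrt(k)

    observed <- clean + spec$drift_amplitude * drift +
      spec$confound_coupling * (confounds$regressors %*% mixing)
    list(series = roi_time_series(observed, colnames(clean), group,
                                  subject_id, spec$tr_seconds),
         confounds = confounds, clean = clean)
  })
}

#' Simulate a two-group cohort from the homotopic template
#'
#' Group a uses the template model built from `roi_set`; group b shares the
#' same conditional-independence skeleton with every partial correlation
#' multiplied by `1 - spec$group_effect`. Subject seeds are derived
#' deterministically from `spec$seed`, so the cohort is a pure function of
#' `(spec, roi_set)`.
#'
#' @param spec A [cohort_spec()].
#' @param roi_set A [roi_set()]; defaults to the 14-region subcortical set.
#' @param pair_targets Target matrix for the homotopic pairs, defaulting to
#'   [default_pair_targets()].
#' @param extra_edge_prob Probability of each non-homotopic edge in the
#'   template.
#' @param fill_range Magnitude range for non-homotopic edge partials.
#' @return An object of class `cohort`: list with `subjects` (each as
#'   returned by [simulate_subject()]), `spec`, `roi_set`, `model_a`,
#'   `model_b`.
#' @export
simulate_cohort <- function(spec, roi_set = default_roi_set(),
                            pair_targets = default_pair_targets(roi_set),
                            extra_edge_prob = 0.2, fill_range = c(0.1, 0.2)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(roi_set, "roi_set"))
  graph <- build_template_graph(roi_set, extra_edge_prob,
                                seed = derive_seed(spec$seed, 0))
  model_a <- generate_precision(graph, pair_targets,
                                seed = derive_seed(spec$seed, 1),
                                fill_range = fill_range)
  shrink <- 1 - spec$group_effect
  Kb <- model_a$precision * shrink
  diag(Kb) <- diag(model_a$precision)
  model_b <- precision_model(graph, Kb)

  n_total <- spec$n_group_a + spec$n_group_b
  groups <- rep(c("a", "b"), c(spec$n_group_a, spec$n_group_b))
  subjects <- lapply(seq_len(n_total), function(s) {
    grp <- groups[s]
    sid <- sprintf("sub-%s-%03d", grp, if (grp == "a") s else
      s - spec$n_group_a)
    sub_seed <- derive_seed(spec$seed, s + 1)
    out <- simulate_subject(if (grp == "a") model_a else model_b, spec,
                            seed = sub_seed, subject_id = sid, group = grp)
    out$seed <- sub_seed
    out
  })
  structure(list(subjects = subjects, spec = spec, roi_set = roi_set,
                 model_a = model_a, model_b = model_b),
            class = "cohort")
}
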