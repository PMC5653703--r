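# ROI-level nuisance regression, temporal high-pass filtering and
# participant-exclusion accounting.

#' A residualised ROI time series with provenance
#'
#' @param values Numeric `T x d` matrix.
#' @param provenance List recording the applied steps (regressor names,
#'   filter cutoff and method).
#' @param roi_labels ROI names.
#' @param tr_seconds Repetition time.
#' @return Object of class `clean_series`.
#' @export
clean_series <- function(values, provenance = list(), roi_labels = colnames(values),
                         tr_seconds = NA_real_) {
  values <- as.matrix(values)
  if (!is.null(roi_labels)) colnames(values) <- roi_labels
  structure(list(values = values, provenance = provenance,
                 roi_labels = colnames(values), tr_seconds = tr_seconds),
            class = "clean_series")
}

series_values <- function(x) {
  if (inherits(x, c("roi_time_series", "clean_series"))) x$values
  else as.matrix(x)
}

#' Regress nuisance signals out of ROI time series
#'
#' Removes the least-squares projection of every ROI column onto the span of
#' the confound regressors plus an intercept; residuals are orthogonal to
#' every regressor. Exactly duplicated confound columns are dropped before
#' fitting; remaining rank deficiency is an error naming the collinear
#' columns.
#'
#' @param series A [roi_time_series()], [clean_series()] or `T x d` matrix.
#' @param confounds A [confound_set()] or `T x k` matrix.
#' @return A [clean_series()] of the same shape with provenance recording
#'   the regressor names.
#' @export
regress_confounds <- function(series, confounds) {
  y <- series_values(series)
  cmat <- if (inherits(confounds, "confound_set")) confounds$regressors
          else as.matrix(confounds)
  if (nrow(y) != nrow(cmat))
    stop("series and confounds must have the same number of rows",
         call. = FALSE)
  if (is.null(colnames(cmat)))
    colnames(cmat) <- paste0("confound", seq_len(ncol(cmat)))
  dup <- duplicated(t(cmat))
  cmat <- cmat[, !dup, drop = FALSE]
  design <- cbind(`(intercept)` = 1, cmat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[seq(qr_d$rank + 1, ncol(design))]]
    stop(sprintf("confound design is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  resid <- qr.resid(qr_d, y)
  prov <- if (inherits(series, "clean_series")) series$provenance else list()
  prov$steps <- c(prov$steps, "regress_confounds")
  prov$regressors <- colnames(cmat)
  tr <- if (is.list(series) && !is.null(series$tr_seconds))
    series$tr_seconds else NA_real_
  clean_series(resid, prov, colnames(y), tr)
}

# Gaussian-weighted running-line smoother matrix (local linear fit),
# sigma in volumes. Rows give the fitted value at each time point.
running_line_matrix <- function(n_t, sigma) {
  s <- seq_len(n_t)
  L <- matrix(0, n_t, n_t)
  for (t in s) {
    u <- s - t
    w <- dnorm(u, sd = sigma)
    s0 <- sum(w); s1 <- sum(w * u); s2 <- sum(w * u^2)
    L[t, ] <- w * (s2 - u * s1) / (s0 * s2 - s1^2)
  }
  L
}

#' High-pass filter ROI time series
#'
#' Removes fluctuations slower than `cutoff_seconds`. `method = "gaussian"`
#' subtracts a Gaussian-weighted running line (local linear fit with
#' `sigma = cutoff / (2 * TR)` volumes, the convention used by FSL for its
#' high-pass filter); `method = "dct"` projects out the discrete-cosine
#' basis functions with period longer than the cutoff, which annihilates the
#' stop band exactly. Output columns are zero mean.
#'
#' @param series A [roi_time_series()], [clean_series()] or matrix.
#' @param cutoff_seconds High-pass cutoff period in seconds; must exceed
#'   `2 * tr_seconds`.
#' @param tr_seconds Repetition time in seconds (taken from the series when
#'   available).
#' @param method `"gaussian"` (running-line detrend) or `"dct"` (projection).
#' @return A [clean_series()] of the same shape.
#' @export
highpass_filter <- function(series, cutoff_seconds = 100,
                            tr_seconds = NULL,
                            method = c("gaussian", "dct")) {
  method <- match.arg(method)
  y <- series_values(series)
  if (is.null(tr_seconds)) {
    tr_seconds <- if (is.list(series) && !is.null(series$tr_seconds))
      series$tr_seconds else NA
  }
  if (!is.numeric(tr_seconds) || is.na(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number", call. = FALSE)
  if (cutoff_seconds <= 2 * tr_seconds)
    stop("cutoff_seconds must exceed twice the repetition time",
         call. = FALSE)
  n_t <- nrow(y)
  if (method == "gaussian") {
    sigma <- cutoff_seconds / (2 * tr_seconds)
    fitted <- running_line_matrix(n_t, sigma) %*% y
    out <- y - fitted
  } else {
    k_max <- floor(2 * n_t * tr_seconds / cutoff_seconds)
    tgrid <- (seq_len(n_t) - 0.5) / n_t
    basis <- cbind(1, if (k_max >= 1)
      sapply(seq_len(k_max), function(k) cos(pi * k * tgrid)))
    out <- qr.resid(qr(basis), y)
  }
  out <- sweep(out, 2, colMeans(out))
  prov <- if (inherits(series, "clean_series")) series$provenance else list()
  prov$steps <- c(prov$steps, "highpass_filter")
  prov$cutoff_seconds <- cutoff_seconds
  prov$filter_method <- method
  clean_series(out, prov, colnames(y), tr_seconds)
}

#' Cohort accounting ledger
#'
#' Records how many subjects were acquired per group and which were excluded
#' with a stated reason.
#'
#' @param acquired_a,acquired_b Acquired subject counts.
#' @param excluded_a,excluded_b Data frames (or lists coercible to them)
#'   with columns `subject` and `reason`; reasons must be non-empty.
#' @return Object of class `cohort_ledger`.
#' @export
cohort_ledger <- function(acquired_a, acquired_b,
                          excluded_a = data.frame(subject = character(),
                                                  reason = character()),
                          excluded_b = data.frame(subject = character(),
                                                  reason = character())) {
  excluded_a <- as.data.frame(excluded_a)
  excluded_b <- as.data.frame(excluded_b)
  for (ex in list(excluded_a, excluded_b)) {
    if (nrow(ex) > 0 && (!all(c("subject", "reason") %in% names(ex)) ||
                         any(!nzchar(ex$reason))))
      stop("exclusions need a subject id and a non-empty reason",
           call. = FALSE)
  }
  if (nrow(excluded_a) > acquired_a || nrow(excluded_b) > acquired_b)
    stop("cannot exclude more subjects than were acquired", call. = FALSE)
  structure(list(acquired_a = as.integer(acquired_a),
                 acquired_b = as.integer(acquired_b),
                 excluded_a = excluded_a, excluded_b = excluded_b),
            class = "cohort_ledger")
}

#' Retained subject counts after exclusions
#'
#' @param ledger A [cohort_ledger()].
#' @return Named integer vector with `retained_a` and `retained_b`.
#' @export
#' @examples
#' led <- cohort_ledger(87, 42,
#'   excluded_a = data.frame(subject = sprintf("p%02d", 1:15),
#'                           reason = rep("image quality", 15)),
#'   excluded_b = data.frame(subject = sprintf("c%02d", 1:3),
#'                           reason = rep("artefacts", 3)))
#' apply_exclusions(led)
apply_exclusions <- function(ledger) {
  stopifnot(inherits(ledger, "cohort_ledger"))
  c(retained_a = ledger$acquired_a - nrow(ledger$excluded_a),
    retained_b = ledger$acquired_b - nrow(ledger$excluded_b))
}
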