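# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed runs `code` against the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds below 2^31, derived from one root seed.
derive_seed <- function(root, k) {
  root <- as.numeric(root) %% 2147483629
  as.integer((root * 48271 + 7919 * (as.numeric(k) + 1)) %% 2147483629 + 1)
}

is_square_numeric <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

check_symmetric <- function(x, name = "matrix", tol = 1e-8) {
  if (!is_square_numeric(x))
    stop(sprintf("%s must be a square numeric matrix", name), call. = FALSE)
  if (max(abs(x - t(x))) > tol)
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  invisible(TRUE)
}

is_spd <- function(x, tol = 1e-10) {
  ev <- tryCatch(eigen(x, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > tol
}

#' Number of possible connections between ROIs
#'
#' For `d` regions there are `d * (d - 1) / 2` undirected pairs, each a
#' potential conditional-dependence connection. With the 14 subcortical ROIs
#' this gives the 91 connections whose presence and strength are estimated
#' per subject.
#'
#' @param d Number of regions of interest (or an object with ROI labels,
#'   e.g. a [roi_set()]).
#' @return Integer count of unordered ROI pairs.
#' @export
#' @examples
#' n_possible_edges(14)
n_possible_edges <- function(d) {
  if (inherits(d, "roi_set")) d <- length(d$labels)
  d <- as.integer(d)
  stopifnot(length(d) == 1L, d >= 1L)
  (d * (d - 1L)) %/% 2L
}
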