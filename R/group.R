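# Group-level aggregation: mean connectivity matrices, density comparison,
# homotopic-dominance report.

#' Entrywise mean and SD of expected partial-correlation matrices
#'
#' @param summaries List of [run_mcmc()] posterior summaries (or plain
#'   matrices) sharing one ROI set.
#' @param field Which matrix to average, `"expected_partials"` (default) or
#'   `"edge_probability"`.
#' @return List with `mean` and `sd` matrices, `n` subjects and `labels`.
#' @export
group_mean_matrix <- function(summaries, field = "expected_partials") {
  if (length(summaries) < 1)
    stop("need at least one subject summary", call. = FALSE)
  mats <- lapply(summaries, function(s) {
    if (inherits(s, "posterior_summary")) s[[field]] else as.matrix(s)
  })
  labels <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), dim(mats[[1]])) ||
        !identical(colnames(m), labels))
      stop("subject summaries use mismatched ROI sets", call. = FALSE)
  }
  arr <- simplify2array(mats)
  mu <- apply(arr, c(1, 2), mean)
  sdm <- if (length(mats) > 1) apply(arr, c(1, 2), sd) else
    matrix(0, nrow(mu), ncol(mu))
  dimnames(mu) <- dimnames(sdm) <- dimnames(mats[[1]])
  list(mean = mu, sd = sdm, n = length(mats), labels = labels)
}

#' Two-tailed t-test on posterior expected network densities
#'
#' Welch's unequal-variance form by default (`var_equal = TRUE` for the
#' pooled test). When both groups have zero variance and equal means the
#' degenerate result `t = 0, p = 1` is returned with a flag instead of a
#' division by zero.
#'
#' @param density_a,density_b Numeric vectors of per-subject densities, each
#'   of length at least 2.
#' @param var_equal Use the pooled-variance test.
#' @return List with `t_statistic`, `p_value`, per-group means and SDs,
#'   `method` and `degenerate` flag.
#' @export
density_test <- function(density_a, density_b, var_equal = FALSE) {
  if (length(density_a) < 2 || length(density_b) < 2)
    stop("each group needs at least two subjects", call. = FALSE)
  out <- list(mean_a = mean(density_a), sd_a = sd(density_a),
              mean_b = mean(density_b), sd_b = sd(density_b),
              n_a = length(density_a), n_b = length(density_b),
              method = if (var_equal) "pooled" else "welch",
              degenerate = FALSE)
  if (out$sd_a == 0 && out$sd_b == 0) {
    out$degenerate <- TRUE
    if (out$mean_a == out$mean_b) {
      out$t_statistic <- 0
      out$p_value <- 1
    } else {
      out$t_statistic <- sign(out$mean_a - out$mean_b) * Inf
      out$p_value <- 0
    }
    return(out)
  }
  tt <- t.test(density_a, density_b, var.equal = var_equal)
  out$t_statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}

#' Rank connections by mean partial correlation and flag homotopic dominance
#'
#' Edges are ordered by decreasing `|mean partial correlation|`, ties broken
#' by (row, column) index. The report flags whether the top `k` edges (one
#' per homotopic pair by default) are all homotopic.
#'
#' @param mean_matrix Symmetric matrix of group-mean partial correlations.
#' @param roi_set A [roi_set()] matching the matrix.
#' @param top_k How many leading edges the dominance flag inspects; defaults
#'   to the number of homotopic pairs.
#' @return List with `edges` (data frame: indices, labels, value, homotopic
#'   flag, rank) and `top_k_all_homotopic`.
#' @export
rank_homotopic_dominance <- function(mean_matrix, roi_set,
                                     top_k = nrow(roi_set$homotopic_pairs)) {
  check_symmetric(mean_matrix, "mean_matrix")
  d <- length(roi_set$labels)
  stopifnot(nrow(mean_matrix) == d)
  homo <- matrix(FALSE, d, d)
  hp <- roi_set$homotopic_pairs
  if (nrow(hp) > 0)
    for (r in seq_len(nrow(hp))) homo[hp[r, 1], hp[r, 2]] <-
        homo[hp[r, 2], hp[r, 1]] <- TRUE
  idx <- which(upper.tri(mean_matrix), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      roi_i = roi_set$labels[idx[, 1]],
                      roi_j = roi_set$labels[idx[, 2]],
                      value = mean_matrix[idx],
                      homotopic = homo[idx])
  ord <- order(-abs(edges$value), edges$i, edges$j)
  edges <- edges[ord, , drop = FALSE]
  edges$rank <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  top_k <- min(top_k, nrow(edges))
  flag <- top_k > 0 && all(edges$homotopic[seq_len(top_k)]) &&
    all(abs(edges$value[seq_len(top_k)]) > 0)
  list(edges = edges, top_k = top_k, top_k_all_homotopic = flag)
}

#' Compare the two groups' posterior connectivity summaries
#'
#' Aggregates per-subject posterior summaries into group-mean
#' partial-correlation matrices, per-subject density vectors, the two-tailed
#' t-test on densities and a ranked strongest-edge list.
#'
#' @param summaries_a,summaries_b Lists of [run_mcmc()] summaries.
#' @param roi_set A [roi_set()].
#' @param var_equal Passed to [density_test()].
#' @return Object of class `group_result`.
#' @export
compare_groups <- function(summaries_a, summaries_b, roi_set,
                           var_equal = FALSE) {
  mean_a <- group_mean_matrix(summaries_a)
  mean_b <- group_mean_matrix(summaries_b)
  dens_a <- vapply(summaries_a, function(s) s$expected_density, numeric(1))
  dens_b <- vapply(summaries_b, function(s) s$expected_density, numeric(1))
  test <- density_test(dens_a, dens_b, var_equal = var_equal)
  dom_a <- rank_homotopic_dominance(mean_a$mean, roi_set)
  idx <- cbind(dom_a$edges$i, dom_a$edges$j)
  strongest <- data.frame(dom_a$edges[, c("roi_i", "roi_j")],
                          mean_a = dom_a$edges$value,
                          mean_b = mean_b$mean[idx],
                          homotopic = dom_a$edges$homotopic)
  strongest <- strongest[order(-strongest$mean_a), , drop = FALSE]
  rownames(strongest) <- NULL
  structure(list(mean_partials_a = mean_a, mean_partials_b = mean_b,
                 density_a = dens_a, density_b = dens_b,
                 t_statistic = test$t_statistic, p_value = test$p_value,
                 density_test = test, strongest_edges = strongest,
                 dominance = dom_a, roi_set = roi_set),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "Group comparison: density a = %.3f (SD %.3f, n=%d), b = %.3f (SD %.3f, n=%d)\n",
    x$density_test$mean_a, x$density_test$sd_a, x$density_test$n_a,
    x$density_test$mean_b, x$density_test$sd_b, x$density_test$n_b))
  cat(sprintf("t = %.3f, two-tailed p = %.3f (%s)\n", x$t_statistic,
              x$p_value, x$density_test$method))
  top <- utils::head(x$strongest_edges, 3)
  cat("strongest edges (group-a mean):\n")
  print(top)
  invisible(x)
}
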