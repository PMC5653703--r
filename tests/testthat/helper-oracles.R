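# Independent oracles used to validate the MCMC code path.
#
# For d <= 3 every conditional-independence graph is decomposable, so the
# G-Wishart normalising constant factorises over cliques and separators in
# closed form. The exact posterior over all graphs follows by enumeration,
# fully independent of the sampler.

lmvgamma_o <- function(a, p) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# log normalising constant of |K|^((delta-2)/2) exp(-tr(D K)/2) over SPD
# matrices (complete graph): a Wishart integral with nu = delta + d - 1.
log_i_complete <- function(delta, D) {
  D <- as.matrix(D)
  d <- nrow(D)
  nu <- delta + d - 1
  (nu * d / 2) * log(2) -
    (nu / 2) * as.numeric(determinant(D)$modulus) + lmvgamma_o(nu / 2, d)
}

# Clique/separator factorisation for graphs on up to 3 nodes.
log_i_g <- function(G, delta, D) {
  d <- nrow(G)
  stopifnot(d <= 3)
  if (d < 3) {
    ne <- sum(G[upper.tri(G)])
    if (d == 1 || ne == sum(upper.tri(G)))
      return(log_i_complete(delta, D))
  }
  edges <- which(upper.tri(G) & G == 1, arr.ind = TRUE)
  ne <- nrow(edges)
  if (d == 2) {
    if (ne == 1) return(log_i_complete(delta, D))
    return(sum(vapply(1:2, function(i)
      log_i_complete(delta, D[i, i, drop = FALSE]), numeric(1))))
  }
  if (ne == 0)
    return(sum(vapply(1:3, function(i)
      log_i_complete(delta, D[i, i, drop = FALSE]), numeric(1))))
  if (ne == 1) {
    i <- edges[1, 1]; j <- edges[1, 2]; k <- setdiff(1:3, c(i, j))
    return(log_i_complete(delta, D[c(i, j), c(i, j)]) +
             log_i_complete(delta, D[k, k, drop = FALSE]))
  }
  if (ne == 2) {
    deg <- rowSums(G)
    ctr <- which(deg == 2)
    ends <- which(deg == 1)
    return(log_i_complete(delta, D[c(ends[1], ctr), c(ends[1], ctr)]) +
             log_i_complete(delta, D[c(ctr, ends[2]), c(ctr, ends[2])]) -
             log_i_complete(delta, D[ctr, ctr, drop = FALSE]))
  }
  log_i_complete(delta, D)
}

# Exact posterior over all 2^(d(d-1)/2) graphs for d <= 3, matching the
# likelihood convention of run_mcmc (columns standardised, S = X'X).
enumerate_graph_posterior <- function(X, delta = 3, edge_prior = 0.5) {
  n <- nrow(X)
  d <- ncol(X)
  S <- crossprod(scale(X))
  D <- diag(d)
  pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
  m <- nrow(pairs)
  glist <- vector("list", 2^m)
  lml <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    G <- matrix(0, d, d)
    for (b in seq_len(m))
      if (bitwAnd(code, bitwShiftL(1, b - 1)) > 0)
        G[pairs[b, 1], pairs[b, 2]] <- G[pairs[b, 2], pairs[b, 1]] <- 1
    ne <- sum(G[upper.tri(G)])
    lml[code + 1] <- ne * log(edge_prior) + (m - ne) * log(1 - edge_prior) +
      log_i_g(G, delta + n, D + S) - log_i_g(G, delta, D)
    glist[[code + 1]] <- G
  }
  w <- exp(lml - max(lml))
  w <- w / sum(w)
  edge_marginal <- Reduce(`+`, Map(`*`, glist, w))
  density <- sum(w * vapply(glist, function(G)
    sum(G[upper.tri(G)]) / m, numeric(1)))
  list(edge_marginal = edge_marginal, density = density, weights = w,
       graphs = glist)
}

# Gaussian data with precision K, via the covariance Cholesky factor.
draw_gaussian <- function(n, K) {
  d <- nrow(K)
  matrix(rnorm(n * d), n, d) %*% chol(solve(K))
}

# Sample partial correlations: invert the sample covariance and normalise.
sample_partials <- function(X) {
  P <- solve(cov(X))
  rho <- -P / sqrt(tcrossprod(diag(P)))
  diag(rho) <- 1
  rho
}

# Least-squares amplitude of a sinusoid of given period in x (times tt).
sinusoid_amplitude <- function(x, tt, period) {
  B <- cbind(sin(2 * pi * tt / period), cos(2 * pi * tt / period))
  sqrt(sum(qr.solve(B, x)^2))
}
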