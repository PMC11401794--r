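# Random fixtures used across the suite. All callers set the RNG seed.

# a random PD covariance with means, as a moment set
rand_moments <- function(J, names = paste0("x", seq_len(J)), N = 120) {
  A <- matrix(stats::rnorm(J * J), J)
  S <- crossprod(A) / J + diag(J) * 0.5
  sc <- stats::runif(J, 0.5, 3)
  S <- S * tcrossprod(sc)
  mu <- stats::runif(J, -2, 8)
  gsca_moments_set(stats::setNames(mu, names), S, N)
}

# random model: P blocks of given sizes, chain edges, mixed scales
rand_model <- function(P = NULL, Jp = NULL, p_std = 0.3, chain = TRUE) {
  if (is.null(P)) P <- sample(2:4, 1)
  if (is.null(Jp)) Jp <- sample(2:4, P, replace = TRUE)
  idx <- split(seq_len(sum(Jp)), rep(seq_len(P), Jp))
  blocks <- lapply(idx, function(i) paste0("x", i))
  names(blocks) <- paste0("g", seq_len(P))
  scale <- ifelse(stats::runif(P) < p_std, "standardized", "convex")
  names(scale) <- names(blocks)
  edges <- if (chain && P > 1) {
    paste0("g", seq_len(P - 1), " -> g", seq(2L, P))
  } else NULL
  gsca_model(blocks, scale = scale, edges = edges)
}

# draw raw data consistent with a model (indicators get varied scales)
rand_data <- function(model, N = 100) {
  J <- model$J
  A <- matrix(stats::rnorm(J * J), J)
  S <- crossprod(A) / J + diag(J) * 0.5
  sc <- stats::runif(J, 0.5, 4)
  S <- S * tcrossprod(sc)
  mu <- stats::runif(J, 0, 8)
  X <- MASS::mvrnorm(N, mu = mu, Sigma = S)
  colnames(X) <- model$indicators
  X
}

sample_skewness <- function(v) {
  v <- v - mean(v)
  mean(v^3) / (sqrt(mean(v^2)))^3
}

sample_kurtosis <- function(v) {  # raw kurtosis, normal = 3
  v <- v - mean(v)
  mean(v^4) / mean(v^2)^2
}
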