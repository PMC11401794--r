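#' Goodness-of-fit indexes for a GSCA fit
#'
#' Computes, from the fitted parameters and the moment set:
#' * `fit_ud` — the proportion of the weighted total variance of all
#'   dependent variables (indicators and dependent components) explained by
#'   the model, where each variable's contribution is divided by the
#'   squared average SD of its block;
#' * `fit_m_ud`, `fit_s_ud` — the same ratio restricted to dependent
#'   indicators (measurement model) and dependent components (structural
#'   model); `fit_s_ud` is `NA` when no component is dependent;
#' * `r_squared` — per dependent component, the unweighted proportion of
#'   its variance explained by its structural equation;
#' * `gfi`, `srmr` — covariance-discrepancy indexes between the sample and
#'   model-implied indicator matrices on the correlation metric (`NA` for
#'   cyclic structural graphs, where the implied covariance is undefined);
#' * `fit`, `afit` — the classic unweighted indexes, reported only when
#'   every variable in the model is standardized (they are undefined
#'   otherwise).
#'
#' @param fit A `gsca_fit`.
#' @return A list with the elements above (also stored in `fit$indices`
#'   and surfaced by [glance()]).
#' @export
gsca_fit_indices <- function(fit) {
  model <- fit$est_model
  S <- fit$pre$S
  J <- model$J; P <- model$P
  W <- fit$weights
  A <- cbind(fit$loadings, fit$paths)
  o <- c(fit$penalty$O_z, fit$penalty$O_gamma)
  V <- cbind(diag(J), W)
  R <- V - W %*% A
  res_ss <- colSums(R * (S %*% R))   # per-variable residual variance
  tot_ss <- colSums(V * (S %*% V))   # per-variable total variance
  o2 <- o^2

  fit_ud <- 1 - sum(o2 * res_ss) / sum(o2 * tot_ss)
  zi <- seq_len(J); gi <- J + seq_len(P)
  fit_m_ud <- 1 - sum(o2[zi] * res_ss[zi]) / sum(o2[zi] * tot_ss[zi])
  dep_g <- model$components %in% model$dependent_components
  fit_s_ud <- if (any(dep_g)) {
    1 - sum(o2[gi] * res_ss[gi]) / sum(o2[gi] * tot_ss[gi])
  } else NA_real_

  r2 <- stats::setNames(
    1 - res_ss[gi][dep_g] / tot_ss[gi][dep_g],
    model$components[dep_g]
  )

  gs <- tryCatch(gsca_gfi_srmr(fit), error = function(e) {
    list(gfi = NA_real_, srmr = NA_real_)
  })

  fit_std <- afit <- NA_real_
  if (all(model$scale == "standardized")) {
    fit_std <- 1 - sum(res_ss) / sum(tot_ss)
    npar <- sum(model$W_pattern) + sum(model$C_pattern) + sum(model$B_pattern)
    d0 <- fit$moments$N * (J + P)
    d1 <- d0 - npar
    afit <- 1 - (1 - fit_std) * d0 / d1
  }

  list(fit_ud = fit_ud, fit_m_ud = fit_m_ud, fit_s_ud = fit_s_ud,
       r_squared = r2, gfi = gs$gfi, srmr = gs$srmr,
       fit = fit_std, afit = afit)
}

#' Model-implied covariance, GFI and SRMR
#'
#' Builds the model-implied indicator covariance under the GSCA reading of
#' the model: the components jointly carry *all* association between
#' indicator blocks, while errors within a block stay freely correlated
#' (error covariances across blocks are zero). Concretely, with
#' `Lambda = S W (W'SW)^-1` the multivariate regression of the indicators
#' on the components, the implied cross-block covariance is
#' `Lambda Phi-hat Lambda'`, where `Phi-hat` propagates the component
#' covariances recursively through the structural equations (exogenous
#' components keep their sample covariances; structural residuals are
#' uncorrelated across equations; component variances stay at their sample
#' values). Within-block covariances equal their sample values (the free
#' within-block error covariances absorb them), so the diagonal residual is
#' zero. Both matrices are put on the correlation metric via the sample
#' SDs, giving `GFI = 1 - SS(R - Rhat) / SS(R)` and `SRMR` as the root
#' mean square over the J(J+1)/2 unique elements. Requires a recursive
#' (acyclic) structural graph.
#'
#' The construction is deliberately isolated here: it follows the usual
#' GSCA fit-evaluation conventions, and swapping in an alternative
#' convention is a one-function change.
#'
#' @param fit A `gsca_fit`.
#' @return List with `gfi`, `srmr`, and the implied correlation matrix
#'   `implied`.
#' @export
gsca_gfi_srmr <- function(fit) {
  model <- fit$est_model
  if (has_cycle(model$B_pattern)) {
    stop("Implied covariance is undefined for a cyclic structural graph.",
         call. = FALSE)
  }
  S <- fit$pre$S
  W <- fit$weights
  B <- fit$paths
  P <- model$P
  Phi_s <- crossprod(W, S %*% W)  # sample component covariance

  # topological order of components
  ord <- integer(0)
  indeg <- colSums(model$B_pattern)
  left <- rep(TRUE, P)
  while (any(left)) {
    src <- which(left & indeg == 0L)
    ord <- c(ord, src)
    for (s in src) indeg <- indeg - model$B_pattern[s, ]
    left[src] <- FALSE
  }

  Phi <- matrix(0, P, P, dimnames = dimnames(Phi_s))
  exo <- colSums(model$B_pattern) == 0L
  Phi[exo, exo] <- Phi_s[exo, exo]
  for (p in ord) {
    if (exo[p]) next
    b <- B[, p]
    done <- ord[seq_len(match(p, ord) - 1L)]
    for (q in done) Phi[p, q] <- Phi[q, p] <- sum(b * Phi[, q])
    Phi[p, p] <- Phi_s[p, p]  # variance pinned to the sample value
  }

  Lambda <- S %*% W %*% solve(Phi_s)
  Sigma <- Lambda %*% Phi %*% t(Lambda)
  for (p in model$components) {   # within-block part is saturated
    i <- which(model$block_of == p)
    Sigma[i, i] <- S[i, i]
  }

  d <- 1 / sqrt(diag(S))
  Rs <- S * tcrossprod(d)
  Rh <- Sigma * tcrossprod(d)
  gfi <- 1 - sum((Rs - Rh)^2) / sum(Rs^2)
  ut <- upper.tri(Rs, diag = TRUE)
  srmr <- sqrt(mean((Rs - Rh)[ut]^2))
  list(gfi = gfi, srmr = srmr, implied = Rh)
}
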