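#' Bootstrap standard errors and percentile confidence intervals
#'
#' Resamples rows with replacement, refits the model on each replicate
#' (warm-started from the full-sample solution, which stabilises sign and
#' label switching), and summarises every free parameter by its replicate
#' SD and 2.5/97.5 percentiles. Standardized-component weight columns are
#' additionally sign-aligned to the full-sample solution by maximal inner
#' product before aggregation; convex columns need no alignment because the
#' sum-to-one constraint fixes their sign. Replicates that fail to converge
#' are dropped and counted (a warning above 5%).
#'
#' @param data N x J raw data (resampling needs rows; for moment-only
#'   problems draw surrogate data first, see [draw_sample()]).
#' @param model A [gsca_model()].
#' @param K Number of bootstrap replicates (4000 in typical reporting).
#' @param seed Seed for the resampling.
#' @param method,tol,max_iter Passed to [gsca_fit()].
#' @param keep_replicates Keep the K x n_par matrix of replicate estimates.
#' @return An object of class `gsca_bootstrap`: tibble `estimates` with
#'   columns `type`, `term`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   plus `K`, `n_dropped`, and optionally `replicates`.
#' @export
gsca_bootstrap <- function(data, model, K = 4000, seed = NULL,
                           method = "convex", tol = 1e-5, max_iter = 1000,
                           keep_replicates = FALSE) {
  X <- as.matrix(data)
  if (!is.null(seed)) set.seed(seed)
  base <- gsca_fit(X, model, method = method, tol = tol, max_iter = max_iter)
  theta0 <- flatten_params(base)
  N <- nrow(X)
  reps <- matrix(NA_real_, K, length(theta0$value))
  dropped <- 0L
  for (k in seq_len(K)) {
    idx <- sample.int(N, N, replace = TRUE)
    fit_k <- tryCatch(
      refit_warm(X[idx, , drop = FALSE], base, tol, max_iter),
      error = function(e) NULL
    )
    if (is.null(fit_k) || !fit_k$converged) { dropped <- dropped + 1L; next }
    fit_k <- align_to_base(fit_k, base)
    reps[k, ] <- flatten_params(fit_k)$value
  }
  if (dropped > 0.05 * K) {
    warning(sprintf("%d of %d bootstrap replicates dropped.", dropped, K),
            call. = FALSE)
  }
  ok <- stats::complete.cases(reps)
  reps <- reps[ok, , drop = FALSE]
  est <- tibble::tibble(
    type = theta0$type, term = theta0$term, estimate = theta0$value,
    se = apply(reps, 2L, stats::sd),
    ci_lower = apply(reps, 2L, stats::quantile, probs = 0.025, names = FALSE),
    ci_upper = apply(reps, 2L, stats::quantile, probs = 0.975, names = FALSE)
  )
  structure(
    list(estimates = est, K = K, n_dropped = dropped, fit = base,
         replicates = if (keep_replicates) reps else NULL),
    class = "gsca_bootstrap"
  )
}

refit_warm <- function(X, base, tol, max_iter) {
  moments <- gsca_moments(X)
  est_model <- base$est_model
  pre <- preprocess_moments(moments, est_model)
  pen <- penalty_from_pre(est_model, pre)
  o <- c(pen$O_z, pen$O_gamma)
  sol <- als_engine(est_model, pre, o, base$weights, tol = tol,
                    max_iter = max_iter)
  finalize_fit(sol, base$model, est_model, moments, pre, pen, X,
               base$method)
}

# flip standardized components whose weights point away from the
# full-sample solution (maximal inner product alignment)
align_to_base <- function(fit, base) {
  J <- fit$est_model$J
  for (p in seq_len(fit$est_model$P)) {
    if (fit$est_model$scale[[p]] != "standardized") next
    if (sum(fit$weights[, p] * base$weights[, p]) < 0) {
      fit$weights[, p] <- -fit$weights[, p]
      fit$loadings[p, ] <- -fit$loadings[p, ]
      fit$paths[p, ] <- -fit$paths[p, ]
      fit$paths[, p] <- -fit$paths[, p]
      fit$b0[p] <- -fit$b0[p]
      fit$component_mean[p] <- -fit$component_mean[p]
    }
  }
  fit
}

flatten_params <- function(fit) {
  m <- fit$est_model
  wi <- which(m$W_pattern, arr.ind = TRUE)
  ci <- which(t(m$C_pattern), arr.ind = TRUE)  # by indicator
  bi <- which(m$B_pattern, arr.ind = TRUE)
  type <- c(rep("weight", nrow(wi)), rep("loading", nrow(ci)),
            rep("path", nrow(bi)),
            rep("intercept_c0", m$J), rep("intercept_b0", m$P),
            rep("component_mean", m$P), rep("component_sd", m$P))
  lbl <- function(a, sep, b) if (length(a)) paste0(a, sep, b) else character(0)
  term <- c(lbl(m$components[wi[, 2]], ":", m$indicators[wi[, 1]]),
            lbl(m$components[ci[, 2]], "->", m$indicators[ci[, 1]]),
            lbl(m$components[bi[, 1]], "->", m$components[bi[, 2]]),
            m$indicators, m$components, m$components, m$components)
  value <- c(fit$weights[m$W_pattern], t(fit$loadings)[t(m$C_pattern)],
             fit$paths[m$B_pattern], fit$c0, fit$b0,
             fit$component_mean, fit$component_sd)
  list(type = type, term = term, value = unname(value))
}

#' @export
print.gsca_bootstrap <- function(x, ...) {
  cat("<gsca_bootstrap> K = ", x$K, " (", x$n_dropped, " dropped)\n",
      sep = "")
  print(x$estimates, n = 20)
  invisible(x)
}

#' Out-of-bag prediction error for dependent variables
#'
#' Bootstrap cross-validation: each replicate fits the model on a bootstrap
#' sample and evaluates its weighted prediction error on the rows left out
#' of that sample, relative to predicting every dependent variable by the
#' training-sample mean. Averaged over replicates this gives `ope_ud`
#' (0 = perfect prediction, 1 = no better than the mean-only null model),
#' with local variants restricted to dependent indicators (`ope_m_ud`) and
#' dependent components (`ope_s_ud`). The penalty weights of each replicate
#' come from the bootstrap sample's SDs, and standardized blocks are scored
#' on the training sample's standardization, matching the fitting metric.
#'
#' @inheritParams gsca_bootstrap
#' @return A tibble with one row: `ope_ud`, `ope_m_ud`, `ope_s_ud`, `K`,
#'   `n_dropped`.
#' @export
gsca_ope <- function(data, model, K = 100, seed = NULL, method = "convex",
                     tol = 1e-5, max_iter = 1000) {
  X <- as.matrix(data)
  if (!is.null(seed)) set.seed(seed)
  base <- gsca_fit(X, model, method = method, tol = tol, max_iter = max_iter)
  N <- nrow(X)
  acc <- matrix(NA_real_, K, 3L)
  dropped <- 0L
  for (k in seq_len(K)) {
    idx <- sample.int(N, N, replace = TRUE)
    oob <- setdiff(seq_len(N), unique(idx))
    if (length(oob) == 0L) { dropped <- dropped + 1L; next }
    fit_k <- tryCatch(
      refit_warm(X[idx, , drop = FALSE], base, tol, max_iter),
      error = function(e) NULL
    )
    if (is.null(fit_k)) { dropped <- dropped + 1L; next }
    acc[k, ] <- oob_ratios(fit_k, X[oob, , drop = FALSE])
  }
  if (dropped > 0L) {
    warning(sprintf(
      "%d of %d replicates dropped (no out-of-bag rows or failed refit).",
      dropped, K), call. = FALSE)
  }
  m <- colMeans(acc, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  tibble::tibble(ope_ud = m[1], ope_m_ud = m[2], ope_s_ud = m[3],
                 K = K, n_dropped = dropped)
}

# Per-replicate weighted prediction-error ratios on held-out rows.
oob_ratios <- function(fit, X_oob) {
  m <- fit$est_model
  J <- m$J; P <- m$P
  X_oob <- X_oob[, m$indicators, drop = FALSE]
  D <- preprocess_rows(X_oob, fit)      # training-sample metric
  G <- D %*% fit$weights
  obs <- cbind(D, G)
  A <- cbind(fit$loadings, fit$paths)
  a0 <- c(fit$c0, fit$b0)
  pred <- matrix(a0, nrow(D), J + P, byrow = TRUE) + G %*% A
  mu_t <- c(fit$pre$mu, as.numeric(crossprod(fit$weights, fit$pre$mu)))
  nullp <- matrix(mu_t, nrow(D), J + P, byrow = TRUE)
  o <- c(fit$penalty$O_z, fit$penalty$O_gamma)
  num <- colSums((obs - pred)^2) * o^2
  den <- colSums((obs - nullp)^2) * o^2
  zi <- seq_len(J); gi <- J + seq_len(P)
  c(sum(num) / sum(den),
    sum(num[zi]) / sum(den[zi]),
    if (sum(den[gi]) > 0) sum(num[gi]) / sum(den[gi]) else NA_real_)
}

#' Compare models by out-of-bag prediction error
#'
#' Runs [gsca_ope()] for each model on the same data with the same seed
#' (so all models see identical bootstrap splits) and returns one row per
#' model, ordered as given. Lower `ope_ud` means better predictive
#' generalizability.
#'
#' @param data N x J raw data.
#' @param models Named list of [gsca_model()] objects.
#' @inheritParams gsca_ope
#' @return A tibble with a `model` column plus the [gsca_ope()] columns.
#' @export
gsca_compare <- function(data, models, K = 100, seed = NULL,
                         method = "convex") {
  stopifnot(is.list(models), length(models) > 0L)
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  purrr::list_rbind(purrr::imap(models, function(m, i) {
    dplyr::mutate(
      gsca_ope(data, m, K = K, seed = seed, method = method),
      model = i, .before = 1L
    )
  }))
}
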