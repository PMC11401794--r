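#' Fit a convex or standardized GSCA model
#'
#' Estimates component weights, loadings, path coefficients and intercepts
#' by alternating least squares (ALS). The objective is the weighted sum of
#' error variances of all dependent variables, where each error is divided
#' by the average standard deviation of its indicator block (see
#' [build_penalty_matrix()]); convex components are constrained to
#' sum-to-one weights (optionally non-negative), standardized components to
#' unit variance. The whole fit runs on first and second moments, so a raw
#' data table and its exact moment set give identical estimates.
#'
#' @param data Either an N x J data frame / matrix of raw indicator scores,
#'   or a [gsca_moments()] object.
#' @param model A [gsca_model()].
#' @param method `"convex"` (default) fits the model as specified;
#'   `"standardized"` fits classic GSCA: every block is standardized and
#'   every component constrained to unit variance (the moment matrix is
#'   replaced by the correlation matrix internally).
#' @param tol Absolute convergence tolerance on the objective change
#'   between full ALS cycles (default `1e-5`).
#' @param max_iter Maximum ALS cycles (default 1000); non-convergence is
#'   flagged in the result, not raised.
#' @param init `"equal"` starts convex blocks at equal weights `1/J_p` and
#'   standardized blocks at equal weights rescaled to unit component
#'   variance; `"random"` draws starts uniformly on the simplex / sphere.
#' @param n_starts Number of random multistarts (the best objective wins);
#'   only used with `init = "random"`.
#' @param seed Optional seed for random starts.
#'
#' @return An object of class `gsca_fit` with the estimated `weights` (J x
#'   P), `loadings` (P x J), `paths` (P x P), intercept vectors `c0` and
#'   `b0`, the objective trajectory, convergence flag, fit indexes (see
#'   [gsca_fit_indices()]), and per-component summaries. Use [tidy()] /
#'   [glance()] for tibble views.
#'
#' @examples
#' fit <- gsca_fit(acsi_moments(), acsi_model())
#' tidy(fit, "weights")
#' glance(fit)
#' @export
gsca_fit <- function(data, model, method = c("convex", "standardized"),
                     tol = 1e-5, max_iter = 1000, init = c("equal", "random"),
                     n_starts = 1, seed = NULL) {
  method <- match.arg(method)
  init <- match.arg(init)
  stopifnot(inherits(model, "gsca_model"))

  raw <- NULL
  if (inherits(data, "gsca_moments")) {
    moments <- data
  } else {
    raw <- as.matrix(data)[, , drop = FALSE]
    moments <- gsca_moments(data)
  }

  est_model <- model
  if (method == "standardized") {
    est_model$scale[] <- "standardized"
    # under the unit-variance constraint a single standardized indicator
    # gets weight 1 from the solver itself; nothing is hard-fixed
    est_model$weight_fixed[] <- FALSE
  }

  pre <- preprocess_moments(moments, est_model)
  pen <- penalty_from_pre(est_model, pre)
  o <- c(pen$O_z, pen$O_gamma)

  run_one <- function(W0) {
    als_engine(est_model, pre, o, W0, tol = tol, max_iter = max_iter)
  }

  if (init == "equal") {
    best <- run_one(init_weights(est_model, pre$S))
  } else {
    if (!is.null(seed)) set.seed(seed)
    best <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      W0 <- init_weights(est_model, pre$S, random = TRUE)
      cand <- run_one(W0)
      if (is.null(best) || cand$objective < best$objective) best <- cand
    }
  }

  finalize_fit(best, model, est_model, moments, pre, pen, raw, method)
}

finalize_fit <- function(sol, model, est_model, moments, pre, pen, raw,
                         method) {
  J <- est_model$J; P <- est_model$P
  sol <- align_signs(sol, est_model)
  W <- sol$W
  C <- sol$A[, 1:J, drop = FALSE]
  B <- sol$A[, J + 1:P, drop = FALSE]
  dimnames(W) <- list(est_model$indicators, est_model$components)
  dimnames(C) <- list(est_model$components, est_model$indicators)
  dimnames(B) <- list(est_model$components, est_model$components)
  c0 <- stats::setNames(sol$a0[1:J], est_model$indicators)
  b0 <- stats::setNames(sol$a0[J + 1:P], est_model$components)

  tau <- as.numeric(crossprod(W, pre$mu))
  phi <- diag(crossprod(W, pre$S %*% W))
  names(tau) <- names(phi) <- est_model$components

  fit <- structure(
    list(
      model = model, est_model = est_model, method = method,
      moments = moments, pre = pre, penalty = pen,
      weights = W, loadings = C, paths = B, c0 = c0, b0 = b0,
      component_mean = tau, component_sd = sqrt(pmax(phi, 0)),
      objective = sol$objective, objective_trace = sol$trace,
      converged = sol$converged, n_iter = sol$n_iter,
      data = raw
    ),
    class = "gsca_fit"
  )
  if (method == "standardized") {
    # ad-hoc unstandardized rescaling of classic GSCA: divide each weight
    # by its indicator's original SD; implied score means follow
    W_uni <- W / pre$orig_sd
    fit$W_uni <- W_uni
    fit$uni_score_mean <- as.numeric(crossprod(W_uni, pre$orig_mu))
    names(fit$uni_score_mean) <- est_model$components
  }
  fit$indices <- gsca_fit_indices(fit)
  fit
}

#' @export
print.gsca_fit <- function(x, digits = 3, ...) {
  cat("<gsca_fit> ", x$method, " GSCA: ", x$model$P, " components, ",
      x$model$J, " indicators, N = ", x$moments$N, "\n", sep = "")
  cat(if (x$converged) "  converged" else "  NOT converged",
      " in ", x$n_iter, " cycles; objective = ",
      format(x$objective, digits = 6), "\n", sep = "")
  idx <- x$indices
  cat(sprintf("  FIT^UD = %.3f  FIT_M^UD = %.3f  FIT_S^UD = %s",
              idx$fit_ud, idx$fit_m_ud,
              if (is.na(idx$fit_s_ud)) "-" else sprintf("%.3f", idx$fit_s_ud)))
  if (!is.na(idx$gfi)) {
    cat(sprintf("  GFI = %.3f  SRMR = %.3f", idx$gfi, idx$srmr))
  }
  cat("\n")
  invisible(x)
}

# ---- ALS internals --------------------------------------------------------

init_weights <- function(model, S, random = FALSE) {
  W <- matrix(0, model$J, model$P,
              dimnames = list(model$indicators, model$components))
  for (p in seq_len(model$P)) {
    b <- model$blocks[[p]]
    Jp <- length(b)
    w <- if (random) stats::runif(Jp) else rep(1, Jp)
    if (model$scale[[p]] == "convex") {
      w <- w / sum(w)
    } else {
      if (random) w <- w - 0.5
      v <- as.numeric(crossprod(w, S[b, b, drop = FALSE] %*% w))
      if (v <= 0) { w <- rep(1, Jp); v <- sum(S[b, b]) }
      w <- w / sqrt(v)
    }
    W[b, p] <- w
  }
  W
}

# objective tr(R' S R O^2) with intercepts concentrated out (a0 = R'mu)
als_objective <- function(W, A, S, o) {
  R <- cbind(diag(nrow(W)), W) - W %*% A
  sum(o^2 * colSums(R * (S %*% R)))
}

# exact per-equation least squares for loadings/paths given W
update_A <- function(W, S, model) {
  J <- model$J; P <- model$P
  A <- matrix(0, P, J + P)
  free_C <- model$C_pattern
  free_B <- model$B_pattern
  WSW <- crossprod(W, S %*% W)
  SW <- S %*% W
  for (t in seq_len(J + P)) {
    free <- if (t <= J) which(free_C[, t]) else which(free_B[, t - J])
    if (length(free) == 0L) next
    # W_f' S v_t : v_t is the unit vector e_t (indicator) or w_{t-J}
    rhs <- if (t <= J) SW[t, free] else WSW[free, t - J]
    G <- WSW[free, free, drop = FALSE]
    A[free, t] <- solve_ls(G, rhs)
  }
  A
}

solve_ls <- function(G, rhs) {
  out <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(out)) {
    warning("Singular normal equations; using a small ridge.", call. = FALSE)
    out <- solve(G + diag(1e-8 * max(diag(G), 1), nrow(G)), rhs)
  }
  out
}

# exact minimizer of the objective over one weight column, all else fixed.
# The objective as a function of w_p is
#   c1 * w' S w + 2 w' S R0 O^2 delta + const,  restricted to block rows,
# with delta_t = [t == J+p] - A[p, t]; both the quadratic matrix and the
# unit-variance constraint use the same block covariance, so the
# constrained solutions below are exact (no ascent possible).
update_w_col <- function(p, W, A, S, o, model) {
  J <- model$J
  b <- model$blocks[[p]]
  bidx <- match(b, model$indicators)
  if (model$weight_fixed[[p]]) return(W)  # single-indicator convex: w = 1

  delta <- -A[p, ]
  delta[J + p] <- delta[J + p] + 1
  W0 <- W; W0[, p] <- 0
  R0 <- cbind(diag(J), W0) - W0 %*% A
  o2 <- o^2
  c1 <- sum(o2 * delta^2)
  if (c1 < 1e-14) return(W)  # component unused by the objective
  lvec <- as.numeric(S %*% (R0 %*% (o2 * delta)))[bidx]
  M <- S[bidx, bidx, drop = FALSE]

  if (model$scale[[p]] == "standardized") {
    wnew <- -solve_ls(M, lvec)
    nrm <- as.numeric(crossprod(wnew, M %*% wnew))
    if (nrm < 1e-14) return(W)  # degenerate direction: keep current
    wnew <- wnew / sqrt(nrm)
  } else if (!model$nonneg) {
    wnew <- simplex_eq_ls(M, lvec, c1)
  } else {
    wnew <- simplex_nn_ls(M, lvec, c1)
  }
  W[bidx, p] <- wnew
  W
}

# minimize c1 w'Mw + 2 l'w  subject to 1'w = 1 (single equality constraint)
simplex_eq_ls <- function(M, l, c1, free = seq_along(l)) {
  w <- numeric(length(l))
  Mf <- M[free, free, drop = FALSE]
  u <- solve_ls(Mf, rep(1, length(free)))
  v <- solve_ls(Mf, l[free])
  lam_half <- -(c1 + sum(v)) / sum(u)
  w[free] <- -(v + lam_half * u) / c1
  attr(w, "lam_half") <- lam_half
  w
}

# active-set solve of  min c1 w'Mw + 2 l'w  s.t. 1'w = 1, w >= 0
simplex_nn_ls <- function(M, l, c1) {
  n <- length(l)
  free <- rep(TRUE, n)
  for (iter in seq_len(10L * n + 10L)) {
    w <- simplex_eq_ls(M, l, c1, which(free))
    lam_half <- attr(w, "lam_half")
    neg <- which(free)[w[free] < -1e-12]
    if (length(neg) > 0L) {
      free[neg[which.min(w[neg])]] <- FALSE
      if (!any(free)) stop("Infeasible weight subproblem.", call. = FALSE)
      next
    }
    w <- pmax(as.numeric(w), 0)
    # KKT for variables at the bound: reduced gradient must be >= 0
    grad <- 2 * c1 * as.numeric(M %*% w) + 2 * l + 2 * lam_half
    bound <- which(!free)
    viol <- bound[grad[bound] < -1e-10]
    if (length(viol) == 0L) {
      return(w / sum(w))
    }
    free[viol[which.min(grad[viol])]] <- TRUE
  }
  w / sum(w)
}

als_engine <- function(model, pre, o, W0, tol = 1e-5, max_iter = 1000) {
  S <- pre$S
  W <- W0
  A <- update_A(W, S, model)
  f <- als_objective(W, A, S, o)
  trace <- f
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- update_A(W, S, model)
    for (p in seq_len(model$P)) {
      W <- update_w_col(p, W, A, S, o, model)
    }
    f_new <- als_objective(W, A, S, o)
    trace <- c(trace, f_new)
    if (abs(f - f_new) < tol) {
      converged <- TRUE
      f <- f_new
      break
    }
    f <- f_new
  }
  A <- update_A(W, S, model)  # consistent with the final W
  f <- als_objective(W, A, S, o)
  a0 <- as.numeric(crossprod(cbind(diag(model$J), W) - W %*% A, pre$mu))
  list(W = W, A = A, a0 = a0, objective = f, trace = trace,
       converged = converged, n_iter = iter)
}

# sign convention for standardized components: weights sum to a positive
# number; flipping a component's sign flips its outgoing row of [C, B], its
# incoming path column and its structural intercept, leaving the model (and
# the objective) unchanged
align_signs <- function(sol, model) {
  J <- model$J
  for (p in seq_len(model$P)) {
    if (model$scale[[p]] != "standardized") next
    s <- sum(sol$W[, p])
    if (s == 0) s <- sol$W[match(model$blocks[[p]][1], model$indicators), p]
    if (s < 0) {
      sol$W[, p] <- -sol$W[, p]
      sol$A[p, ] <- -sol$A[p, ]
      sol$A[, J + p] <- -sol$A[, J + p]
      sol$a0[J + p] <- -sol$a0[J + p]
    }
  }
  sol
}

# ---- objective as an exported, moment-form quantity -----------------------

#' Evaluate the convex-GSCA objective from moments
#'
#' Computes the weighted sum of expected squared errors of the model at
#' given parameter values, purely from the indicator means and covariances:
#' each dependent variable's error variance (plus squared mean residual,
#' when intercepts are not mean-matching) is divided by the squared average
#' SD of its block. This is the per-observation scale of the raw-data sum
#' of squares (the raw-data value divided by N - 1 matches it exactly for
#' moment sets computed with the N - 1 denominator).
#'
#' @param model A [gsca_model()].
#' @param moments A [gsca_moments()] set.
#' @param W J x P weight matrix (rows in the model's indicator order; on the
#'   estimation metric, i.e. standardized blocks take weights for
#'   standardized indicators).
#' @param C,B Loadings (P x J) and paths (P x P); default zero.
#' @param a0 Intercept vector of length J + P; default the mean-matching
#'   intercepts implied by the other parameters.
#' @return Non-negative scalar.
#' @export
gsca_objective <- function(model, moments, W, C = NULL, B = NULL, a0 = NULL) {
  pre <- preprocess_moments(moments, model)
  pen <- penalty_from_pre(model, pre)
  o <- c(pen$O_z, pen$O_gamma)
  J <- model$J; P <- model$P
  if (is.null(C)) C <- matrix(0, P, J)
  if (is.null(B)) B <- matrix(0, P, P)
  A <- cbind(C, B)
  stopifnot(nrow(W) == J, ncol(W) == P, nrow(A) == P, ncol(A) == J + P)
  R <- cbind(diag(J), W) - W %*% A
  if (is.null(a0)) a0 <- as.numeric(crossprod(R, pre$mu))
  mres <- as.numeric(crossprod(R, pre$mu)) - a0
  sum(o^2 * (colSums(R * (pre$S %*% R)) + mres^2))
}

#' Rescaled (unstandardized) weights from a standardized fit
#'
#' Applies the classic ad-hoc rescaling: each standardized weight is
#' divided by its indicator's sample SD, and unstandardized component
#' scores are the raw data times these weights. Returned alongside the
#' implied score means. Mostly useful for comparison against convex
#' components, whose means and SDs are estimated on the original scale
#' instead.
#'
#' @param fit A `gsca_fit` with `method = "standardized"`.
#' @return A tibble with columns `indicator`, `component`, `weight_std`,
#'   `weight_uni`, plus attribute `score_mean` (named per component).
#' @export
rescale_weights_unstandardized <- function(fit) {
  stopifnot(inherits(fit, "gsca_fit"))
  if (fit$method != "standardized") {
    stop("Rescaling applies to standardized fits.", call. = FALSE)
  }
  W <- fit$weights; W_uni <- fit$W_uni
  idx <- which(fit$est_model$W_pattern, arr.ind = TRUE)
  out <- tibble::tibble(
    indicator = fit$est_model$indicators[idx[, 1]],
    component = fit$est_model$components[idx[, 2]],
    weight_std = W[idx],
    weight_uni = W_uni[idx]
  )
  attr(out, "score_mean") <- fit$uni_score_mean
  out
}
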