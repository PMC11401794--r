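#' Moment set: means, covariances and sample size
#'
#' The whole convex-GSCA estimator runs on sufficient statistics: the
#' indicator mean vector, the (unbiased, `N - 1` denominator) covariance
#' matrix and the sample size. `gsca_moments()` computes them from a raw
#' data table; `gsca_moments_set()` wraps printed moments (e.g. a published
#' covariance table) directly.
#'
#' @param data A data frame or matrix of N observations by J numeric
#'   indicators, with column names. No missing values, no constant column,
#'   N >= 3.
#' @return An object of class `gsca_moments` with fields `mu`, `S`, `N`,
#'   `names`.
#' @examples
#' d <- data.frame(t1 = c(49, 50, 51), t2 = c(0, 50, 100))
#' m <- gsca_moments(d)
#' sqrt(diag(m$S))  # SDs 1 and 50
#' @export
gsca_moments <- function(data) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("`data` must be numeric.", call. = FALSE)
  if (is.null(colnames(X))) stop("`data` needs column names.", call. = FALSE)
  if (anyNA(X)) stop("`data` contains missing values.", call. = FALSE)
  if (nrow(X) < 3L) stop("At least 3 observations are required.", call. = FALSE)
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    stop("Constant column(s): ", paste(colnames(X)[v <= 0], collapse = ", "),
         call. = FALSE)
  }
  gsca_moments_set(colMeans(X), stats::cov(X), nrow(X))
}

#' @rdname gsca_moments
#' @param mu Mean vector (length J, named or names via `S`).
#' @param S J x J symmetric covariance matrix.
#' @param N Sample size the moments were computed from.
#' @export
gsca_moments_set <- function(mu, S, N) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("`S` must be square.", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("`S` must be symmetric.", call. = FALSE)
  }
  S <- (S + t(S)) / 2
  nm <- names(mu)
  if (is.null(nm)) nm <- colnames(S)
  if (is.null(nm)) stop("Indicator names are required (name `mu` or `S`).",
                        call. = FALSE)
  if (length(mu) != nrow(S)) stop("`mu` and `S` dimensions disagree.",
                                  call. = FALSE)
  dimnames(S) <- list(nm, nm)
  structure(
    list(mu = stats::setNames(as.numeric(mu), nm), S = S,
         N = as.integer(N), names = nm),
    class = "gsca_moments"
  )
}

#' @export
print.gsca_moments <- function(x, ...) {
  cat("<gsca_moments> ", length(x$mu), " indicators, N = ", x$N, "\n",
      sep = "")
  invisible(x)
}

#' Standardize a score vector to mean 0, SD 1
#'
#' Uses the `N - 1` denominator, so `c(49, 50, 51)` maps to `c(-1, 0, 1)`.
#'
#' @param scores Numeric vector, non-constant.
#' @return Standardized vector.
#' @export
standardize_block <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s <= 0) stop("Constant input cannot be standardized.",
                                    call. = FALSE)
  (scores - mean(scores)) / s
}

# Reorder and, for standardized blocks, standardize the moment set to the
# metric the estimator works in: indicators of standardized components get
# mean 0 / SD 1 (rows and columns of S rescaled accordingly).
preprocess_moments <- function(moments, model) {
  missing <- setdiff(model$indicators, moments$names)
  if (length(missing) > 0L) {
    stop("Moments lack indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(model$indicators, moments$names)
  mu <- moments$mu[idx]
  S <- moments$S[idx, idx, drop = FALSE]
  # convex components need linearly independent block indicators for their
  # weights to be identified; standardized blocks tolerate collinearity
  # (the estimator falls back to a ridge solve there)
  for (p in model$components[model$scale == "convex"]) {
    b <- model$blocks[[p]]
    check_pd(S[b, b, drop = FALSE])
  }
  sds <- sqrt(diag(S))
  std_ind <- unlist(model$blocks[model$scale == "standardized"],
                    use.names = FALSE)
  scl <- rep(1, length(mu))
  names(scl) <- model$indicators
  if (length(std_ind) > 0L) {
    scl[std_ind] <- 1 / sds[std_ind]
    mu[std_ind] <- 0
    S <- S * tcrossprod(scl)
  }
  list(mu = mu, S = S, N = moments$N,
       orig_sd = sds, orig_mu = moments$mu[idx], scl = scl)
}

check_pd <- function(S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    stop("Indicator covariance matrix is singular or near-singular; ",
         "convex components require linearly independent indicators.",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Penalty weights for the convex-GSCA objective
#'
#' Each dependent variable's prediction error is divided by the average
#' standard deviation of its indicator block, so blocks on large scales do
#' not dominate the objective. The returned entries are those reciprocals:
#' `1 / mean(block SDs)` for dependent indicators (`O_z`) and dependent
#' components (`O_gamma`), `0` for non-dependent variables, and exactly `1`
#' for standardized blocks (their SDs are all one).
#'
#' @param model A [gsca_model()].
#' @param moments A [gsca_moments()] set covering the model's indicators.
#' @return A list with numeric vectors `O_z` (length J, named by indicator)
#'   and `O_gamma` (length P, named by component).
#' @export
build_penalty_matrix <- function(model, moments) {
  pre <- preprocess_moments(moments, model)
  penalty_from_pre(model, pre)
}

penalty_from_pre <- function(model, pre) {
  sds <- sqrt(diag(pre$S))  # standardized blocks already have SD 1
  block_avg <- vapply(model$blocks,
                      function(b) mean(sds[b]), numeric(1))
  O_z <- 1 / block_avg[model$block_of]
  names(O_z) <- model$indicators
  O_z[!model$indicators %in% model$dependent_indicators] <- 0
  O_gamma <- 1 / block_avg
  O_gamma[!model$components %in% model$dependent_components] <- 0
  names(O_gamma) <- model$components
  list(O_z = O_z, O_gamma = O_gamma)
}
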