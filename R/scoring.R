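#' Component scores for a fitted model
#'
#' Computes the N x P table of component scores `D W`, standardizing the
#' indicators of standardized blocks first (using the standardization
#' parameters stored in the fit, so out-of-sample rows are scored on the
#' training metric). Convex component scores lie within the range of their
#' block's scores row by row; standardized component scores have mean 0 and
#' SD 1 on the fitting sample.
#'
#' @param fit A `gsca_fit`.
#' @param data Raw indicator rows to score; defaults to the data the model
#'   was fitted on (an error if the fit was moment-only).
#' @return A tibble of component scores.
#' @export
gsca_scores <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "gsca_fit"))
  if (is.null(data)) data <- fit$data
  if (is.null(data)) {
    stop("Scores need raw data rows; this fit was made from moments only.",
         call. = FALSE)
  }
  X <- as.matrix(data)
  miss <- setdiff(fit$est_model$indicators, colnames(X))
  if (length(miss) > 0L) {
    stop("Data lack indicator(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, fit$est_model$indicators, drop = FALSE]
  Xp <- preprocess_rows(X, fit)
  out <- Xp %*% fit$weights
  tibble::as_tibble(as.data.frame(out))
}

# put raw rows on the estimation metric of a fit (standardized blocks are
# centered/scaled with the fit's stored moments)
preprocess_rows <- function(X, fit) {
  scl <- fit$pre$scl
  ctr <- ifelse(scl != 1, fit$pre$orig_mu, 0)
  sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "*")
}

#' Summary statistics of a component from its block moments
#'
#' For weights `w`, block means `mu` and block covariance `S`, the
#' component mean is `w'mu` and its SD is `sqrt(w'Sw)`. For a convex
#' component the mean always lies within the range of the indicator means,
#' and the SD between 0 and the largest indicator SD.
#'
#' @param weights Block weight vector.
#' @param block_mu Means of the block's indicators.
#' @param block_S Covariance matrix of the block's indicators.
#' @return A tibble with `mean` and `sd`.
#' @export
component_summary <- function(weights, block_mu, block_S) {
  w <- as.numeric(weights)
  stopifnot(length(w) == length(block_mu), length(w) == nrow(block_S))
  tibble::tibble(
    mean = sum(w * block_mu),
    sd = sqrt(max(0, as.numeric(crossprod(w, as.matrix(block_S) %*% w))))
  )
}

#' Per-component summary table of a fit
#'
#' Mirrors the usual reporting layout: component mean and SD (convex
#' components on the original indicator scale; standardized ones 0 / 1),
#' and the observed score range when raw data are available (`NA`
#' otherwise: ranges need individual rows, not just moments).
#'
#' @param fit A `gsca_fit`.
#' @return A tibble with columns `component`, `mean`, `sd`, `min`, `max`.
#' @export
gsca_component_summary <- function(fit) {
  stopifnot(inherits(fit, "gsca_fit"))
  out <- tibble::tibble(
    component = fit$est_model$components,
    mean = unname(fit$component_mean),
    sd = unname(fit$component_sd),
    min = NA_real_, max = NA_real_
  )
  if (!is.null(fit$data)) {
    sc <- as.matrix(gsca_scores(fit))
    out$min <- apply(sc, 2L, min)
    out$max <- apply(sc, 2L, max)
  }
  out
}

#' Recover convex weights from component scores
#'
#' Given linearly independent indicator columns, a convex component's score
#' vector identifies its weights uniquely: this solves the linear system
#' `scores = block_data %*% w` by least squares and returns the recovered
#' weights, erroring when the block data are rank-deficient (the uniqueness
#' premise fails) or when the scores are not an exact combination of the
#' columns.
#'
#' @param scores N-vector of component scores.
#' @param block_data N x Jp matrix of the block's indicator scores.
#' @return Numeric weight vector of length Jp.
#' @export
check_weight_uniqueness <- function(scores, block_data) {
  X <- as.matrix(block_data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("Block data are rank-deficient: weights are not identifiable.",
         call. = FALSE)
  }
  w <- qr.coef(qr_x, as.numeric(scores))
  resid <- as.numeric(scores) - X %*% w
  if (sqrt(mean(resid^2)) > 1e-8 * max(1, stats::sd(scores))) {
    stop("Scores are not an exact combination of the block columns.",
         call. = FALSE)
  }
  as.numeric(w)
}
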