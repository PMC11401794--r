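#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GSCA fit into a parameter tibble
#'
#' @param x A `gsca_fit`.
#' @param type `"all"` (default) or one of `"weights"`, `"loadings"`,
#'   `"paths"`, `"intercepts"`, `"summary"` (component means/SDs).
#' @param ... Unused.
#' @return A tibble with columns `type`, `term`, `estimate`.
#' @export
tidy.gsca_fit <- function(x, type = "all", ...) {
  fp <- flatten_params(x)
  out <- tibble::tibble(type = fp$type, term = fp$term, estimate = fp$value)
  keep <- switch(type,
    all = unique(out$type),
    weights = "weight",
    loadings = "loading",
    paths = "path",
    intercepts = c("intercept_c0", "intercept_b0"),
    summary = c("component_mean", "component_sd"),
    stop("Unknown `type`.", call. = FALSE)
  )
  dplyr::filter(out, .data$type %in% keep)
}

#' One-row summary of a GSCA fit
#'
#' @param x A `gsca_fit`.
#' @param ... Unused.
#' @return A tibble with the fit indexes, per-equation R-squared left in a
#'   list column, objective value, convergence flag and iteration count.
#' @export
glance.gsca_fit <- function(x, ...) {
  idx <- x$indices
  tibble::tibble(
    fit_ud = idx$fit_ud, fit_m_ud = idx$fit_m_ud, fit_s_ud = idx$fit_s_ud,
    gfi = idx$gfi, srmr = idx$srmr, fit = idx$fit, afit = idx$afit,
    r_squared = list(idx$r_squared),
    objective = x$objective, converged = x$converged, n_iter = x$n_iter,
    N = x$moments$N
  )
}

#' @rdname tidy.gsca_fit
#' @export
tidy.gsca_bootstrap <- function(x, ...) {
  x$estimates
}

#' @export
glance.gsca_bootstrap <- function(x, ...) {
  tibble::tibble(K = x$K, n_dropped = x$n_dropped)
}

#' R-squared per dependent structural equation
#'
#' @param fit A `gsca_fit`.
#' @return A tibble with `component` and `r_squared`.
#' @export
gsca_r_squared <- function(fit) {
  r2 <- fit$indices$r_squared
  tibble::tibble(component = names(r2), r_squared = unname(r2))
}
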