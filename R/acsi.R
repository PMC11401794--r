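#' American Customer Satisfaction Index (ACSI) example
#'
#' A published moment set for 774 customers' responses on fourteen items of
#' the ACSI survey, together with the classic six-component ACSI structural
#' model. The items are: z1-z3 customer expectations (overall quality,
#' reliability, customization), z4-z6 perceived quality (same three
#' aspects), z7-z8 perceived value (price given quality, quality given
#' price), z9-z11 customer satisfaction (overall satisfaction, fulfilment
#' of expectations, distance to ideal), z12 complaint behavior (binary),
#' z13-z14 customer loyalty (repurchase intention on a 10-point scale,
#' price tolerance in percent). Because z13 and z14 are on different
#' scales, the loyalty component is standardized; all other components are
#' convex composites of the original 1-10 (or 0/1) scales.
#'
#' `acsi_moments()` returns the printed means and covariances (2-decimal
#' precision, which induces roughly a +/- .01 tolerance on downstream
#' estimates) as a [gsca_moments()] set with N = 774; `acsi_model()` returns
#' the matching [gsca_model()]; `acsi_ranges()` the printed per-item
#' minimum/maximum.
#'
#' @return See above.
#' @examples
#' fit <- gsca_fit(acsi_moments(), acsi_model())
#' glance(fit)
#' @export
acsi_moments <- function() {
  nm <- paste0("z", 1:14)
  means <- c(7.34, 7.75, 6.67, 7.66, 7.59, 7.39, 5.96, 7.12, 7.59, 6.82,
             6.76, 0.14, 7.73, 31.82)
  # variances (diagonal) and upper-triangle covariances, row by row
  upper <- list(
    z1  = c(5.81, 3.61, 2.71, 2.92, 2.91, 2.10, 1.96, 2.79, 3.01, 2.73,
            3.23, -0.14, 2.62, 11.78),
    z2  = c(5.38, 2.88, 2.69, 2.92, 2.36, 1.48, 2.63, 2.79, 2.30, 2.64,
            -0.13, 2.05, 7.65),
    z3  = c(6.90, 2.03, 2.15, 2.56, 1.49, 2.18, 2.16, 1.96, 2.41, -0.12,
            1.74, 7.77),
    z4  = c(5.31, 4.77, 3.76, 2.52, 4.15, 4.87, 4.35, 4.42, -0.32, 3.94,
            16.86),
    z5  = c(6.11, 3.98, 2.48, 4.37, 5.23, 4.80, 5.01, -0.36, 4.29, 17.20),
    z6  = c(6.93, 2.46, 3.65, 3.95, 3.67, 3.75, -0.23, 3.18, 13.58),
    z7  = c(6.67, 3.43, 3.05, 2.88, 2.78, -0.14, 2.42, 11.31),
    z8  = c(6.18, 4.74, 4.42, 4.70, -0.29, 3.60, 16.60),
    z9  = c(6.19, 5.06, 5.09, -0.35, 4.55, 19.55),
    z10 = c(6.27, 4.96, -0.29, 3.98, 16.71),
    z11 = c(6.93, -0.32, 4.74, 20.79),
    z12 = c(0.12, -0.33, -1.55),
    z13 = c(8.79, 35.21),
    z14 = c(241.11)
  )
  S <- matrix(0, 14, 14, dimnames = list(nm, nm))
  for (i in 1:14) S[i, i:14] <- upper[[i]]
  S <- S + t(S) - diag(diag(S))
  gsca_moments_set(stats::setNames(means, nm), S, 774L)
}

#' @rdname acsi_moments
#' @export
acsi_model <- function() {
  gsca_model(
    blocks = list(
      CE = c("z1", "z2", "z3"),
      PQ = c("z4", "z5", "z6"),
      PV = c("z7", "z8"),
      CS = c("z9", "z10", "z11"),
      CC = "z12",
      CL = c("z13", "z14")
    ),
    scale = c(CE = "convex", PQ = "convex", PV = "convex", CS = "convex",
              CC = "convex", CL = "standardized"),
    edges = c("CE -> PQ", "CE -> PV", "PQ -> PV", "CE -> CS", "PQ -> CS",
              "PV -> CS", "CS -> CC", "CS -> CL", "CC -> CL")
  )
}

#' @rdname acsi_moments
#' @export
acsi_ranges <- function() {
  tibble::tibble(
    indicator = paste0("z", 1:14),
    min = c(rep(1, 11), 0, 1, 0),
    max = c(rep(10, 11), 1, 10, 50)
  )
}

# printed lower-triangle correlations of the ACSI table (used in tests)
acsi_printed_correlations <- function() {
  nm <- paste0("z", 1:14)
  rows <- list(
    z2  = 0.65,
    z3  = c(0.43, 0.47),
    z4  = c(0.53, 0.50, 0.33),
    z5  = c(0.49, 0.51, 0.33, 0.84),
    z6  = c(0.33, 0.39, 0.37, 0.62, 0.61),
    z7  = c(0.31, 0.25, 0.22, 0.42, 0.39, 0.36),
    z8  = c(0.47, 0.46, 0.33, 0.72, 0.71, 0.56, 0.53),
    z9  = c(0.50, 0.48, 0.33, 0.85, 0.85, 0.60, 0.47, 0.77),
    z10 = c(0.45, 0.40, 0.30, 0.75, 0.78, 0.56, 0.44, 0.71, 0.81),
    z11 = c(0.51, 0.43, 0.35, 0.73, 0.77, 0.54, 0.41, 0.72, 0.78, 0.75),
    z12 = c(-0.17, -0.17, -0.13, -0.40, -0.42, -0.25, -0.16, -0.34, -0.41,
            -0.34, -0.36),
    z13 = c(0.37, 0.30, 0.22, 0.58, 0.58, 0.41, 0.32, 0.49, 0.62, 0.54,
            0.61, -0.33),
    z14 = c(0.31, 0.21, 0.19, 0.47, 0.45, 0.33, 0.28, 0.43, 0.51, 0.43,
            0.51, -0.29, 0.76)
  )
  R <- diag(14)
  dimnames(R) <- list(nm, nm)
  for (i in 2:14) R[i, 1:(i - 1)] <- rows[[i - 1]]
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  R
}
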