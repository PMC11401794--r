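#' Specify a structured component model
#'
#' Declares the three sub-models of a generalized structured component
#' analysis (GSCA): the weighted relation model (components as weighted sums
#' of their indicator blocks), the component measurement model (indicators
#' regressed on their component), and the structural model (directed paths
#' among components). Each component is either *convex* — a weighted sum of
#' unstandardized indicators whose weights sum to one, so that its scores
#' stay on the indicators' original scale — or *standardized* — a
#' unit-variance composite of standardized indicators, as in classic GSCA.
#'
#' @param blocks Named list; one entry per component, each a character vector
#'   of indicator names. Indicators must be disjoint across components and
#'   every block non-empty.
#' @param scale Scale type per component: either a single string recycled to
#'   all components or a named character vector with entries `"convex"` or
#'   `"standardized"`. Defaults to `"convex"`. A block whose indicators mix
#'   measurement scales should be declared `"standardized"` by the caller;
#'   scales are never inferred from data.
#' @param edges Structural paths, as a character vector of `"FROM -> TO"`
#'   strings or a two-column data frame (`from`, `to`). `NULL` for a model
#'   with no structural part.
#' @param nonneg Logical; constrain convex weights to be non-negative in
#'   addition to summing to one. Off by default: a negative weight can flag
#'   an indicator that works against the rest of its block.
#'
#' @return An object of class `gsca_model`: the validated specification with
#'   derived free-parameter patterns for the weight (`W`), loading (`C`) and
#'   path (`B`) matrices, the dependency bookkeeping (`T = P + J` variables,
#'   `T_Y` dependent ones), and a `weight_fixed` flag for single-indicator
#'   convex blocks (their weight is identically 1).
#'
#' @details A component is *dependent* when it has at least one incoming
#'   path; indicators are always dependent because within-block loadings are
#'   always estimated (reflective measurement). Cyclic structural graphs are
#'   accepted by the estimator but trigger a warning, and the model-implied
#'   covariance (hence GFI/SRMR) is unavailable for them.
#'
#' @examples
#' m <- gsca_model(
#'   blocks = list(g1 = c("z1", "z2", "z3"), g2 = c("z4", "z5")),
#'   edges  = "g1 -> g2"
#' )
#' m$T_Y  # 6 dependent variables: 5 indicators + g2
#' @export
gsca_model <- function(blocks, scale = "convex", edges = NULL, nonneg = FALSE) {
  if (!is.list(blocks) || length(blocks) == 0L || is.null(names(blocks)) ||
      any(!nzchar(names(blocks)))) {
    stop("`blocks` must be a non-empty named list of indicator-name vectors.",
         call. = FALSE)
  }
  components <- names(blocks)
  if (anyDuplicated(components)) {
    stop("Component names must be unique.", call. = FALSE)
  }
  blocks <- lapply(blocks, as.character)
  if (any(lengths(blocks) == 0L)) {
    stop("Every block must contain at least one indicator (empty block: ",
         paste(components[lengths(blocks) == 0L], collapse = ", "), ").",
         call. = FALSE)
  }
  indicators <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(indicators)) {
    dup <- unique(indicators[duplicated(indicators)])
    stop("Indicator(s) assigned to more than one block: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  P <- length(components)
  J <- length(indicators)

  scale <- expand_scale(scale, components)
  edges <- normalize_edges(edges, components)

  block_of <- rep(components, lengths(blocks))
  names(block_of) <- indicators

  # free-parameter patterns: W (J x P), C (P x J), B (P x P)
  W_pattern <- matrix(FALSE, J, P, dimnames = list(indicators, components))
  for (p in components) W_pattern[blocks[[p]], p] <- TRUE
  C_pattern <- t(W_pattern)
  B_pattern <- matrix(FALSE, P, P, dimnames = list(components, components))
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) {
      stop("Structural self-loops are not allowed.", call. = FALSE)
    }
    B_pattern[cbind(edges$from, edges$to)] <- TRUE
  }

  dependent_components <- components[colSums(B_pattern) > 0L]
  dependent_indicators <- indicators  # reflective: all loadings estimated

  model <- structure(
    list(
      components = components,
      blocks = blocks,
      scale = scale,
      edges = edges,
      nonneg = nonneg,
      indicators = indicators,
      block_of = block_of,
      J = J,
      P = P,
      W_pattern = W_pattern,
      C_pattern = C_pattern,
      B_pattern = B_pattern,
      weight_fixed = lengths(blocks) == 1L & scale == "convex",
      dependent_indicators = dependent_indicators,
      dependent_components = dependent_components,
      T = P + J,
      T_Y = length(dependent_indicators) + length(dependent_components)
    ),
    class = "gsca_model"
  )
  if (has_cycle(B_pattern)) {
    warning("The structural graph contains a cycle; estimation proceeds, ",
            "but the model-implied covariance (GFI/SRMR) is unavailable.",
            call. = FALSE)
  }
  model
}

expand_scale <- function(scale, components) {
  ok <- c("convex", "standardized")
  if (is.null(names(scale)) && length(scale) == 1L) {
    scale <- rep(scale, length(components))
    names(scale) <- components
  }
  if (is.null(names(scale)) && length(scale) == length(components)) {
    names(scale) <- components
  }
  if (!all(components %in% names(scale))) {
    stop("`scale` must name every component (missing: ",
         paste(setdiff(components, names(scale)), collapse = ", "), ").",
         call. = FALSE)
  }
  scale <- scale[components]
  bad <- !scale %in% ok
  if (any(bad)) {
    stop("Unknown scale type(s): ", paste(unique(scale[bad]), collapse = ", "),
         " (use \"convex\" or \"standardized\").", call. = FALSE)
  }
  scale
}

normalize_edges <- function(edges, components) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    return(tibble::tibble(from = character(), to = character()))
  }
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("Edges given as strings must have the form \"FROM -> TO\".",
           call. = FALSE)
    }
    edges <- tibble::tibble(
      from = trimws(vapply(parts, `[`, "", 1L)),
      to   = trimws(vapply(parts, `[`, "", 2L))
    )
  } else {
    edges <- tibble::as_tibble(as.data.frame(edges))
    names(edges)[1:2] <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  unknown <- setdiff(c(edges$from, edges$to), components)
  if (length(unknown) > 0L) {
    stop("Structural edge references unknown component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(edges$from, edges$to))) {
    stop("Duplicated structural edges.", call. = FALSE)
  }
  edges
}

has_cycle <- function(B_pattern) {
  # Kahn's algorithm; leftover nodes imply a cycle
  adj <- B_pattern
  indeg <- colSums(adj)
  remaining <- rep(TRUE, nrow(adj))
  repeat {
    src <- which(remaining & indeg == 0L)
    if (length(src) == 0L) break
    for (s in src) {
      indeg <- indeg - adj[s, ]
      remaining[s] <- FALSE
    }
  }
  any(remaining)
}

#' @export
print.gsca_model <- function(x, ...) {
  cat("<gsca_model> ", x$P, " components, ", x$J, " indicators\n", sep = "")
  for (p in x$components) {
    cat(sprintf("  %s (%s%s): %s\n", p, x$scale[[p]],
                if (x$weight_fixed[[p]]) ", weight fixed" else "",
                paste(x$blocks[[p]], collapse = " ")))
  }
  if (nrow(x$edges) > 0L) {
    cat("  paths: ", paste(x$edges$from, "->", x$edges$to, collapse = ", "),
        "\n", sep = "")
  }
  cat("  T = ", x$T, ", dependent variables T_Y = ", x$T_Y,
      if (x$nonneg) ", non-negative weights" else "", "\n", sep = "")
  invisible(x)
}

#' Write / read a model specification as a text config
#'
#' Round-trips a [gsca_model()] losslessly through a small YAML document
#' listing components (indicators + scale type), edges as `"FROM -> TO"`
#' strings, and the non-negativity flag.
#'
#' @param model A `gsca_model`.
#' @param path File path.
#' @return `write_gsca_model()` returns `path` invisibly;
#'   `read_gsca_model()` returns the reconstructed `gsca_model`.
#' @export
write_gsca_model <- function(model, path) {
  stopifnot(inherits(model, "gsca_model"))
  doc <- list(
    components = lapply(model$components, function(p) {
      list(name = p, scale = unname(model$scale[[p]]),
           indicators = as.list(model$blocks[[p]]))
    }),
    edges = as.list(paste(model$edges$from, "->", model$edges$to)),
    nonneg = model$nonneg
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_gsca_model
#' @export
read_gsca_model <- function(path) {
  doc <- yaml::read_yaml(path)
  blocks <- stats::setNames(
    lapply(doc$components, function(cp) unlist(cp$indicators)),
    vapply(doc$components, `[[`, "", "name")
  )
  scale <- stats::setNames(
    vapply(doc$components, `[[`, "", "scale"),
    names(blocks)
  )
  edges <- unlist(doc$edges)
  gsca_model(blocks, scale = scale, edges = edges,
             nonneg = isTRUE(doc$nonneg))
}
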