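#' @title Discriminative patterns of the fitted classifiers
#'
#' @description
#' For interpretation, the linear models' weight vectors are mapped back onto
#' the features they weigh: the cortical pattern assigns one score per ROI
#' (the coefficients of the vector orthogonal to the SVM hyperplane) and the
#' striatal pattern assigns one weight per template pixel (the composite
#' weight `w = M_PCA x M_LDA`). Each pattern is normalized by its maximum
#' absolute value; signs are preserved (range `[-1, 1]`), and visualisations
#' of contribution magnitude use `|score|`.
#'
#' @name discriminative
NULL

#' Cortical discriminative pattern (one score per ROI)
#'
#' @param classifier a fitted `cortical_classifier` (or a `staging_model`).
#' @return object of class `discriminative_pattern` with `step = "cortical"`,
#'   `scores` (length 8, max |score| = 1) and the normalization constant.
#' @export
cortical_pattern <- function(classifier) {
  if (inherits(classifier, "staging_model"))
    classifier <- classifier$cortical
  if (!inherits(classifier, "cortical_classifier"))
    stop("a fitted cortical classifier is required", call. = FALSE)
  w <- classifier$w
  m <- max(abs(w))
  if (m == 0) stop("degenerate classifier: zero weight vector",
                   call. = FALSE)
  structure(list(step = "cortical", scores = w / m, normalization = m),
            class = "discriminative_pattern")
}

#' Striatal discriminative pattern (weight map over the template mask)
#'
#' The per-pixel composite weight `w = M_PCA x M_LDA` of the PCA basis and
#' the LDA discriminant, mapped back onto the 2D template mask and normalized
#' by its maximum absolute value. Pixels outside the mask are zero.
#'
#' @param model a fitted `striatal_classifier` (or a `staging_model`).
#' @param template_mask logical matrix whose `TRUE` pixels (row-major order)
#'   correspond to the feature vector; when omitted the flat weight vector is
#'   returned as `scores` without a 2D map.
#' @return object of class `discriminative_pattern` with `step = "striatal"`,
#'   `scores` (per-pixel weights, max |weight| = 1), optional `map` (2D), and
#'   the normalization constant.
#' @export
striatal_pattern <- function(model, template_mask = NULL) {
  if (inherits(model, "staging_model")) model <- model$striatal
  if (!inherits(model, "striatal_classifier"))
    stop("a fitted striatal classifier is required", call. = FALSE)
  w <- drop(model$rotation %*% model$disc$scaling)
  m <- max(abs(w))
  if (m == 0) stop("degenerate model: zero weight vector", call. = FALSE)
  w <- w / m
  map <- NULL
  if (!is.null(template_mask)) {
    if (sum(template_mask) != length(w))
      stop("template mask pixel count does not match the fitted model",
           call. = FALSE)
    map <- matrix(0, nrow(template_mask), ncol(template_mask))
    map[.row_major_order(template_mask)] <- w
  }
  structure(list(step = "striatal", scores = w, map = map,
                 normalization = m),
            class = "discriminative_pattern")
}

#' @export
print.discriminative_pattern <- function(x, ...) {
  cat("<discriminative_pattern> step =", x$step, "\n")
  if (x$step == "cortical") print(round(x$scores, 3))
  else cat(length(x$scores), "pixel weights, max |w| =",
           max(abs(x$scores)), "\n")
  invisible(x)
}
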