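#' @title Hierarchical two-step amyloid staging
#'
#' @description
#' Step 1 trains one linear-kernel support-vector regressor per cortical ROI,
#' mapping the 12-bin uptake curve to the visual RCTU score; the eight
#' predicted scores (pRCTU) are averaged into the quantification marker and
#' fed to a linear SVM that decides cortical amyloid positivity. Step 2,
#' applied only to cortical-positive scans, decides striatal positivity with
#' PCA for dimension reduction followed by linear discriminant analysis on
#' the striatal pixel features. The resulting stage is 0 (cortical-negative),
#' 1 (cortical-positive, striatal-negative) or 2 (cortical- and
#' striatal-positive).
#'
#' SVR and SVM use box constraint 1, kernel scale 1 (no feature scaling) and,
#' for regression, the epsilon-insensitive band `IQR(y) / 13.49` -- the
#' conventional default rule tying the band width to the response spread.
#' A decision value of exactly zero classifies positive, favouring
#' sensitivity in screening use.
#'
#' @name staging
NULL

#' Stack per-subject uptake-curve matrices into an array
#' @param curve_list list of 8 x n_used matrices, one per subject.
#' @return numeric array, subjects x 8 x n_used.
#' @export
feature_array <- function(curve_list) {
  n <- length(curve_list)
  d <- dim(curve_list[[1]])
  arr <- array(NA_real_, c(n, d[1], d[2]),
               dimnames = list(names(curve_list), rownames(curve_list[[1]]),
                               NULL))
  for (i in seq_len(n)) arr[i, , ] <- curve_list[[i]]
  arr
}

#' Fit the eight per-region RCTU regressors
#'
#' @param curves array subjects x 8 x n_used of uptake-curve features.
#' @param rctu integer matrix subjects x 8 of visual RCTU scores.
#' @return object of class `rctu_regressors`.
#' @export
fit_rctu_regressors <- function(curves, rctu) {
  stopifnot(length(dim(curves)) == 3, dim(curves)[2] == 8,
            nrow(rctu) == dim(curves)[1], ncol(rctu) == 8)
  n <- dim(curves)[1]
  if (n < 10)
    stop("need at least 10 training subjects for RCTU regression",
         call. = FALSE)
  fits <- vector("list", 8)
  eps <- numeric(8)
  for (k in 1:8) {
    y <- as.numeric(rctu[, k])
    if (length(unique(y)) < 2)
      stop("region ", k, " has constant RCTU labels; regressor degenerate",
           call. = FALSE)
    eps[k] <- IQR(y) / 13.49
    fits[[k]] <- e1071::svm(x = curves[, k, , drop = TRUE], y = y,
                            type = "eps-regression", kernel = "linear",
                            cost = 1, epsilon = eps[k], scale = FALSE)
  }
  structure(list(fits = fits, epsilon = eps, n_train = n,
                 roi = rownames(.roi_table())),
            class = "rctu_regressors")
}

#' Predict pRCTU from fitted regressors
#'
#' @param model an `rctu_regressors` fit.
#' @param curves one subject's 8 x n_used matrix, or an array
#'   subjects x 8 x n_used.
#' @return for a single subject, list with `prctu` (length-8 vector) and
#'   `mean_prctu`; for an array, list with `prctu` (n x 8 matrix) and
#'   `mean_prctu` (length-n vector). Outputs are unclipped regression values.
#' @export
predict_prctu <- function(model, curves) {
  stopifnot(inherits(model, "rctu_regressors"))
  single <- is.matrix(curves)
  if (single) curves <- array(curves, c(1, dim(curves)))
  if (length(dim(curves)) != 3 || dim(curves)[2] != 8)
    stop("curve features must cover all 8 cortical ROIs", call. = FALSE)
  if (any(!is.finite(curves)))
    stop("curve features contain missing values", call. = FALSE)
  n <- dim(curves)[1]
  prctu <- matrix(NA_real_, n, 8,
                  dimnames = list(dimnames(curves)[[1]], model$roi))
  for (k in 1:8)
    prctu[, k] <- predict(model$fits[[k]],
                          newdata = matrix(curves[, k, ], nrow = n))
  mean_prctu <- rowMeans(prctu)
  if (single)
    list(prctu = prctu[1, ], mean_prctu = unname(mean_prctu[1]))
  else
    list(prctu = prctu, mean_prctu = unname(mean_prctu))
}

#' Fit the cortical positivity SVM on pRCTU vectors
#'
#' @param prctu numeric matrix subjects x 8 of predicted RCTU values.
#' @param positive logical vector, cortical amyloid positivity labels.
#' @return object of class `cortical_classifier` exposing the hyperplane
#'   weight vector `w` (length 8), intercept `b`, and signed decision values.
#' @export
fit_cortical_classifier <- function(prctu, positive) {
  stopifnot(is.matrix(prctu), ncol(prctu) == 8,
            length(positive) == nrow(prctu))
  positive <- as.logical(positive)
  if (length(unique(positive)) < 2)
    stop("both positivity classes are required to fit the classifier",
         call. = FALSE)
  if (nrow(prctu) < 10)
    stop("need at least 10 training subjects", call. = FALSE)
  fit <- e1071::svm(x = prctu, y = factor(positive, c(FALSE, TRUE)),
                    type = "C-classification", kernel = "linear",
                    cost = 1, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(prctu %*% w) + b
  if (mean(d[positive]) < mean(d[!positive])) { w <- -w; b <- -b }
  structure(list(w = setNames(w, colnames(prctu)), b = b,
                 n_train = nrow(prctu)),
            class = "cortical_classifier")
}

#' Decision values and positivity calls of the cortical classifier
#' @param object a `cortical_classifier`.
#' @param prctu matrix (or length-8 vector) of pRCTU values.
#' @param ... unused.
#' @return list with `decision` and logical `positive` (`decision >= 0`).
#' @export
predict.cortical_classifier <- function(object, prctu, ...) {
  if (is.null(dim(prctu))) prctu <- matrix(prctu, nrow = 1)
  d <- drop(prctu %*% object$w) + object$b
  list(decision = d, positive = d >= 0)
}

#' Fit the striatal positivity model (PCA + LDA)
#'
#' PCA retains the smallest number of components explaining at least
#' `var_explained` of the variance, capped at `n_train - 2` so the
#' discriminant stays well-posed; LDA separates the classes on the PCA
#' scores. `method = "svm"` substitutes a linear SVM for the LDA step (used
#' to check robustness of the classification to that choice).
#'
#' @param features numeric matrix subjects x pixels of striatal template
#'   intensities (cortical-positive subjects only).
#' @param positive logical vector of striatal positivity labels.
#' @param var_explained PCA variance-retention target.
#' @param method `"lda"` (default) or `"svm"` for the discriminative step.
#' @return object of class `striatal_classifier`.
#' @export
fit_striatal_classifier <- function(features, positive, var_explained = 0.95,
                                    method = c("lda", "svm")) {
  method <- match.arg(method)
  stopifnot(is.matrix(features), length(positive) == nrow(features))
  positive <- as.logical(positive)
  if (nrow(features) < 10)
    stop("need at least 10 cortical-positive training subjects",
         call. = FALSE)
  if (length(unique(positive)) < 2)
    stop("both striatal classes are required to fit the classifier",
         call. = FALSE)
  pca <- prcomp(features, center = TRUE, scale. = FALSE)
  pvar <- pca$sdev^2 / sum(pca$sdev^2)
  ncomp <- which(cumsum(pvar) >= var_explained)[1]
  ncomp <- max(1L, min(ncomp, nrow(features) - 2L, ncol(pca$rotation)))
  scores <- pca$x[, seq_len(ncomp), drop = FALSE]
  grouping <- factor(positive, c(FALSE, TRUE))
  if (method == "lda") {
    lda_fit <- MASS::lda(x = scores, grouping = grouping)
    scaling <- lda_fit$scaling[, 1]
    proj <- drop(scores %*% scaling)
    flip <- mean(proj[positive]) < mean(proj[!positive])
    if (flip) scaling <- -scaling
    disc <- list(kind = "lda", fit = lda_fit, scaling = scaling)
  } else {
    svm_fit <- e1071::svm(x = scores, y = grouping,
                          type = "C-classification", kernel = "linear",
                          cost = 1, scale = FALSE)
    w <- drop(t(svm_fit$coefs) %*% svm_fit$SV)
    b <- -svm_fit$rho
    d <- drop(scores %*% w) + b
    if (mean(d[positive]) < mean(d[!positive])) { w <- -w; b <- -b }
    disc <- list(kind = "svm", scaling = w, b = b)
  }
  structure(list(center = pca$center,
                 rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
                 ncomp = ncomp, disc = disc, n_train = nrow(features),
                 n_pixels = ncol(features)),
            class = "striatal_classifier")
}

#' Decision values and positivity calls of the striatal model
#' @param object a `striatal_classifier`.
#' @param features matrix (or single feature vector) of striatal intensities.
#' @param ... unused.
#' @return list with `decision` and logical `positive` (`decision >= 0`).
#'   For LDA the decision value is the log posterior ratio
#'   (positive vs negative).
#' @export
predict.striatal_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(object$center))
    stop("striatal feature length does not match the fitted template",
         call. = FALSE)
  scores <- sweep(features, 2, object$center) %*% object$rotation
  if (object$disc$kind == "lda") {
    post <- predict(object$disc$fit,
                    newdata = as.data.frame(scores))$posterior
    eps <- 1e-300
    d <- log(pmax(post[, "TRUE"], eps)) - log(pmax(post[, "FALSE"], eps))
  } else {
    d <- drop(scores %*% object$disc$scaling) + object$disc$b
  }
  list(decision = unname(d), positive = unname(d >= 0))
}

#' Fit the complete staging model on a training set
#'
#' @param curves array subjects x 8 x n_used of uptake curves.
#' @param rctu matrix subjects x 8 of visual RCTU scores (SVR targets).
#' @param cortical_positive logical, cortical positivity labels.
#' @param striatal_features matrix subjects x pixels (rows aligned with
#'   `curves`; only cortical-positive rows are used in step 2).
#' @param striatal_positive logical striatal labels (evaluated on
#'   cortical-positive subjects).
#' @param striatal_method passed to [fit_striatal_classifier()].
#' @param config optional list of feature-extraction settings; its hash is
#'   stored and checked at prediction time.
#' @return object of class `staging_model`.
#' @export
fit_staging_model <- function(curves, rctu, cortical_positive,
                              striatal_features, striatal_positive,
                              striatal_method = "lda", config = list()) {
  regressors <- fit_rctu_regressors(curves, rctu)
  prctu <- predict_prctu(regressors, curves)$prctu
  cortical <- fit_cortical_classifier(prctu, cortical_positive)
  pos <- which(as.logical(cortical_positive))
  striatal <- fit_striatal_classifier(
    striatal_features[pos, , drop = FALSE],
    as.logical(striatal_positive)[pos],
    method = striatal_method
  )
  structure(list(regressors = regressors, cortical = cortical,
                 striatal = striatal, config_hash = config_hash(config)),
            class = "staging_model")
}

#' Predict the amyloid stage of one subject
#'
#' Hierarchical decision: the cortical SVM on the pRCTU vector decides
#' positivity; a negative call yields stage 0 without consulting the striatal
#' model; a positive call passes the striatal feature to PCA+LDA to decide
#' stage 1 versus 2.
#'
#' @param model a `staging_model`.
#' @param curves the subject's 8 x n_used uptake-curve matrix.
#' @param striatal_feature the subject's striatal template feature vector.
#' @param config_hash optional hash of the feature configuration used to
#'   extract the inputs; prediction is refused on mismatch.
#' @return list of class `stage_result`: `prctu`, `mean_prctu`,
#'   `cortical_positive`, `cortical_decision`, `striatal_positive` (`NA` when
#'   not consulted), `striatal_decision`, `stage`.
#' @export
predict_stage <- function(model, curves, striatal_feature,
                          config_hash = NULL) {
  stopifnot(inherits(model, "staging_model"))
  if (!is.null(config_hash) && !identical(config_hash, model$config_hash))
    stop("feature configuration hash does not match the fitted model",
         call. = FALSE)
  pr <- predict_prctu(model$regressors, curves)
  cort <- predict(model$cortical, pr$prctu)
  if (!cort$positive) {
    res <- list(prctu = pr$prctu, mean_prctu = pr$mean_prctu,
                cortical_positive = FALSE,
                cortical_decision = cort$decision,
                striatal_positive = NA, striatal_decision = NA_real_,
                stage = 0L)
  } else {
    stri <- predict(model$striatal, striatal_feature)
    res <- list(prctu = pr$prctu, mean_prctu = pr$mean_prctu,
                cortical_positive = TRUE,
                cortical_decision = cort$decision,
                striatal_positive = stri$positive,
                striatal_decision = stri$decision,
                stage = if (stri$positive) 2L else 1L)
  }
  class(res) <- "stage_result"
  res
}

#' @export
print.stage_result <- function(x, ...) {
  cat("<stage_result> stage ", x$stage, ", mean pRCTU ",
      signif(x$mean_prctu, 4), ", cortical ",
      if (x$cortical_positive) "positive" else "negative", sep = "")
  if (!is.na(x$striatal_positive))
    cat(", striatal ", if (x$striatal_positive) "positive" else "negative",
        sep = "")
  cat("\n")
  invisible(x)
}

# stable hash of a configuration list (FNV-1a over its serialisation)
#' Hash a feature/model configuration
#' @param config a list of settings.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
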