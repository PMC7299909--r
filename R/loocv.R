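#' @title Leave-one-out evaluation of the staging pipeline
#'
#' @description
#' Every fold refits the complete pipeline -- the eight RCTU regressors, the
#' cortical SVM (on in-fold pRCTU predictions of the training subjects) and
#' the striatal PCA+LDA -- on all subjects but one, then stages the held-out
#' subject. The standard of truth is either the visual assessment or
#' SUVr-cutoff-based stages, with cutoffs derived from the cohort's normal
#' reference subjects by the iterative outlier method.
#'
#' @name loocv
NULL

# rank-based (Mann-Whitney) AUC; ties share averaged ranks
.auc_mw <- function(decision, truth) {
  keep <- is.finite(decision) | is.infinite(decision)
  decision <- decision[keep]; truth <- as.logical(truth[keep])
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(decision)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.binary_metrics <- function(truth, pred, decision = NULL) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (!is.null(decision)) .auc_mw(decision, truth) else NA_real_,
    n = length(truth)
  )
}

#' Staging performance report
#'
#' @param true_stage,pred_stage integer vectors of stages in `{0,1,2}`.
#' @param cortical_decision signed step-1 decision values (for AUC).
#' @param striatal_decision signed step-2 decision values (`NA` where step 2
#'   was not reached; AUC uses the available values).
#' @return object of class `performance_report`: 3x3 confusion matrix (rows =
#'   true stage), `overall_accuracy`, per-step metrics, and macro-averaged
#'   (unweighted across the three stages, one-vs-rest) sensitivity and
#'   specificity.
#' @export
performance_report <- function(true_stage, pred_stage,
                               cortical_decision = NULL,
                               striatal_decision = NULL) {
  stopifnot(length(true_stage) == length(pred_stage))
  lv <- factor(true_stage, 0:2)
  pv <- factor(pred_stage, 0:2)
  confusion <- table(true = lv, predicted = pv)
  overall <- sum(diag(confusion)) / length(true_stage)

  step1 <- .binary_metrics(true_stage >= 1, pred_stage >= 1,
                           cortical_decision)
  in2 <- true_stage >= 1
  dec2 <- if (is.null(striatal_decision)) NULL else striatal_decision[in2]
  step2 <- .binary_metrics(true_stage[in2] == 2, pred_stage[in2] == 2, dec2)

  per_stage <- lapply(0:2, function(s)
    .binary_metrics(true_stage == s, pred_stage == s))
  macro_sens <- mean(vapply(per_stage, `[[`, 0, "sensitivity"), na.rm = TRUE)
  macro_spec <- mean(vapply(per_stage, `[[`, 0, "specificity"), na.rm = TRUE)

  structure(list(confusion = confusion, overall_accuracy = overall,
                 step1 = step1, step2 = step2,
                 macro_sensitivity = macro_sens,
                 macro_specificity = macro_spec,
                 n = length(true_stage)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> n =", x$n, "\n")
  print(x$confusion)
  cat(sprintf("overall accuracy %.3f | step 1 acc %.3f (AUC %.3f) | step 2 acc %.3f (AUC %.3f)\n",
              x$overall_accuracy, x$step1$accuracy, x$step1$auc,
              x$step2$accuracy, x$step2$auc))
  cat(sprintf("macro sensitivity %.3f, macro specificity %.3f\n",
              x$macro_sensitivity, x$macro_specificity))
  invisible(x)
}

# truth labels for a cohort under the chosen standard
.truth_labels <- function(manifest, truth, suvr = NULL, cn = NULL) {
  if (truth == "visual") {
    stage <- manifest$stage_va
    list(stage = stage, cortical = stage >= 1, striatal = stage == 2,
         cutoffs = NULL)
  } else {
    if (is.null(suvr))
      suvr <- manifest[, c("global_suvr", "striatal_suvr")]
    if (is.null(cn))
      cn <- if (!is.null(manifest$cn)) as.logical(manifest$cn)
            else manifest$stage_va == 0
    cut_c <- iterative_outlier_cutoff(suvr$global_suvr[cn])
    cut_s <- iterative_outlier_cutoff(suvr$striatal_suvr[cn])
    cortical <- suvr$global_suvr > cut_c
    striatal <- cortical & suvr$striatal_suvr > cut_s
    stage <- ifelse(!cortical, 0L, ifelse(striatal, 2L, 1L))
    list(stage = stage, cortical = cortical, striatal = striatal,
         cutoffs = c(cortical = cut_c, striatal = cut_s))
  }
}

#' Leave-one-out evaluation with full per-fold refitting
#'
#' @param features list with `curves` (array subjects x 8 x n_used) and
#'   `striatal` (matrix subjects x template pixels).
#' @param manifest validated manifest aligned row-wise with `features`.
#' @param truth `"visual"` (visual-assessment stages) or `"suvr_cutoff"`
#'   (stages from SUVr cutoffs; needs `global_suvr`/`striatal_suvr` columns or
#'   the `suvr` argument; the normal reference group is the `cn` column, the
#'   `cn` argument, or by default the visually negative subjects).
#' @param suvr optional data.frame with `global_suvr` and `striatal_suvr`.
#' @param cn optional logical vector marking the normal reference group.
#' @param striatal_method discriminative step of the striatal model
#'   (`"lda"` or `"svm"`).
#' @return list of class `loocv_result`: `report` (a `performance_report`),
#'   `predictions` (per-subject data.frame with stage, decisions and mean
#'   pRCTU), `prctu` (held-out n x 8 matrix), `folds` (per-fold training index
#'   sets), `truth` labels used, and `cutoffs` when SUVr-based.
#' @export
loocv_evaluate <- function(features, manifest,
                           truth = c("visual", "suvr_cutoff"),
                           suvr = NULL, cn = NULL, striatal_method = "lda") {
  truth <- match.arg(truth)
  curves <- features$curves
  striatal <- features$striatal
  n <- dim(curves)[1]
  stopifnot(nrow(manifest) == n, nrow(striatal) == n)
  if (n < 20)
    stop("leave-one-out evaluation needs at least 20 subjects",
         call. = FALSE)
  lab <- .truth_labels(manifest, truth, suvr, cn)
  if (length(unique(lab$stage)) < 3)
    stop("all three stages must be represented in the cohort", call. = FALSE)
  rctu <- rctu_matrix(manifest)

  pred_stage <- integer(n)
  cort_dec <- numeric(n)
  stri_dec <- rep(NA_real_, n)
  mean_prctu <- numeric(n)
  prctu_mat <- matrix(NA_real_, n, 8, dimnames = list(manifest$subject_id,
                                                      rownames(.roi_table())))
  folds <- vector("list", n)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    folds[[i]] <- tr
    if (length(unique(lab$cortical[tr])) < 2)
      stop("fold ", i, ": training set lost a cortical positivity class",
           call. = FALSE)
    pos_tr <- tr[lab$cortical[tr]]
    if (length(unique(lab$striatal[pos_tr])) < 2)
      stop("fold ", i, ": training set lost a striatal class", call. = FALSE)
    model <- fit_staging_model(
      curves[tr, , , drop = FALSE], rctu[tr, , drop = FALSE],
      lab$cortical[tr], striatal[tr, , drop = FALSE], lab$striatal[tr],
      striatal_method = striatal_method
    )
    res <- predict_stage(model, curves[i, , ], striatal[i, ])
    pred_stage[i] <- res$stage
    cort_dec[i] <- res$cortical_decision
    stri_dec[i] <- res$striatal_decision
    mean_prctu[i] <- res$mean_prctu
    prctu_mat[i, ] <- res$prctu
  }

  report <- performance_report(lab$stage, pred_stage, cort_dec, stri_dec)
  structure(list(
    report = report,
    predictions = data.frame(subject_id = manifest$subject_id,
                             true_stage = lab$stage,
                             pred_stage = pred_stage,
                             cortical_decision = cort_dec,
                             striatal_decision = stri_dec,
                             mean_prctu = mean_prctu,
                             stringsAsFactors = FALSE),
    prctu = prctu_mat, folds = folds, truth = lab$stage,
    truth_source = truth, cutoffs = lab$cutoffs
  ), class = "loocv_result")
}
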