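#' @title Outcome statistics: ANCOVA, pRCTU regression, mediation
#'
#' @description
#' The downstream analyses relate the amyloid stage and the mean pRCTU to
#' clinical and structural outcomes: covariate-adjusted stage comparisons
#' (ANCOVA with Bonferroni-corrected pairwise contrasts and a linear trend
#' contrast), multiple linear regression of each outcome on mean pRCTU, and a
#' two-equation OLS mediation path model (stage -> mean pRCTU -> outcome)
#' with a bootstrap confidence interval for the indirect effect. Missing
#' values are deleted listwise per model, and the n actually used is reported
#' with every result.
#'
#' @name outcome_stats
NULL

.model_frame <- function(outcome, covariates, ...) {
  df <- data.frame(..., check.names = FALSE)
  df$.outcome <- outcome
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df[complete.cases(df), , drop = FALSE]
}

.cov_terms <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) NULL
  else paste0("`", colnames(as.data.frame(covariates)), "`")
}

#' Covariate-adjusted comparison of an outcome across stages
#'
#' Fits `outcome ~ stage + covariates` with stage categorical, computes
#' covariate-adjusted group means (at covariate means), all three pairwise
#' contrasts with Bonferroni correction (`p_corrected = min(1, 3 p)`), and
#' the linear trend contrast with weights `(-1, 0, +1)` across stages 0/1/2.
#'
#' @param outcome numeric vector.
#' @param stage integer vector of stages in `{0,1,2}`.
#' @param covariates optional data.frame of covariates.
#' @return object of class `ancova_result`: `adjusted_means`, `pairwise`
#'   (data.frame with raw and corrected p), `trend` (estimate, SE, p), `n`.
#' @export
ancova_compare <- function(outcome, stage, covariates = NULL) {
  df <- .model_frame(outcome, covariates, .stage = factor(stage, 0:2))
  counts <- table(df$.stage)
  if (any(counts < 3))
    stop("each stage needs at least 3 subjects after listwise deletion",
         call. = FALSE)
  rhs <- paste(c(".stage", .cov_terms(covariates)), collapse = " + ")
  fit <- lm(as.formula(paste(".outcome ~", rhs)), data = df)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design (collinear covariates)", call. = FALSE)
  emm <- emmeans::emmeans(fit, ".stage")
  emm_df <- as.data.frame(emm)
  adjusted_means <- setNames(emm_df$emmean, paste0("stage", emm_df$.stage))

  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "none"))
  pw$p_corrected <- pmin(1, 3 * pw$p.value)
  pairwise <- data.frame(comparison = as.character(pw$contrast),
                         estimate = pw$estimate, se = pw$SE,
                         p_raw = pw$p.value, p_corrected = pw$p_corrected,
                         stringsAsFactors = FALSE)

  tr <- as.data.frame(emmeans::contrast(emm,
                                        method = list(trend = c(-1, 0, 1))))
  structure(list(adjusted_means = adjusted_means, pairwise = pairwise,
                 trend = list(estimate = tr$estimate, se = tr$SE,
                              p = tr$p.value),
                 n = nrow(df)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("<ancova_result> n =", x$n, "| adjusted means:",
      paste(sprintf("%s=%.3f", names(x$adjusted_means), x$adjusted_means),
            collapse = ", "), "\n")
  print(x$pairwise, digits = 3)
  cat(sprintf("linear trend: %.3f (SE %.3f), p = %.3g\n",
              x$trend$estimate, x$trend$se, x$trend$p))
  invisible(x)
}

#' Linear regression of an outcome on mean pRCTU
#'
#' @param outcome numeric vector.
#' @param mean_prctu numeric vector, the quantification marker.
#' @param covariates optional data.frame of covariates.
#' @param subset `"all"` or `"positive_only"` (stages 1 and 2; requires
#'   `stage`).
#' @param stage stage vector, needed for `subset = "positive_only"`.
#' @return object of class `regression_result`: `B`, `se`, `p`,
#'   `adj_r_squared`, `r_squared`, `n`, `subset`.
#' @export
prctu_regression <- function(outcome, mean_prctu, covariates = NULL,
                             subset = c("all", "positive_only"),
                             stage = NULL) {
  subset <- match.arg(subset)
  keep <- rep(TRUE, length(outcome))
  if (subset == "positive_only") {
    if (is.null(stage))
      stop("subset = 'positive_only' requires the stage vector",
           call. = FALSE)
    keep <- stage >= 1
  }
  covariates <- if (is.null(covariates)) NULL
                else as.data.frame(covariates)[keep, , drop = FALSE]
  df <- .model_frame(outcome[keep], covariates, .prctu = mean_prctu[keep])
  if (nrow(df) <= (if (is.null(covariates)) 0 else ncol(covariates)) + 2)
    stop("too few complete cases for the regression", call. = FALSE)
  if (var(df$.prctu) == 0)
    stop("mean pRCTU is constant on the chosen subset", call. = FALSE)
  rhs <- paste(c(".prctu", .cov_terms(covariates)), collapse = " + ")
  fit <- lm(as.formula(paste(".outcome ~", rhs)), data = df)
  sm <- summary(fit)
  structure(list(B = sm$coefficients[".prctu", "Estimate"],
                 se = sm$coefficients[".prctu", "Std. Error"],
                 p = sm$coefficients[".prctu", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = nrow(df), subset = subset),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> B = %.4g (SE %.4g), p = %.3g, adj R2 = %.3f, n = %d (%s)\n",
              x$B, x$se, x$p, x$adj_r_squared, x$n, x$subset))
  invisible(x)
}

# fast OLS coefficient of the named columns via .lm.fit
.ols_coefs <- function(X, y) {
  fit <- .lm.fit(X, y)
  setNames(fit$coefficients, colnames(X))
}

#' Mediation path analysis (stage -> mean pRCTU -> outcome)
#'
#' Two-equation OLS path model for the just-identified single-mediator
#' design: `M ~ X + covariates` gives the a path, `Y ~ X + M + covariates`
#' gives the b path and the direct effect c', and `Y ~ X + covariates` gives
#' the total effect c. The OLS identity `c = c' + a b` holds exactly.
#' Standardized coefficients come from the same fits on z-scored X, M and Y.
#' The indirect effect `a b` gets a nonparametric bootstrap percentile
#' confidence interval; a delta-method (Sobel) p-value is reported alongside.
#'
#' Verdict (two-sided alpha 0.05): `complete` when the indirect CI excludes 0
#' and the direct effect is not significant; `partial` when both are
#' significant with the same sign; `inconsistent` when both are significant
#' with opposite signs; `none` when the indirect CI covers 0.
#'
#' @param stage numeric 0/1/2 stage, the predictor X.
#' @param mean_prctu numeric mediator M.
#' @param outcome numeric outcome Y.
#' @param covariates optional data.frame.
#' @param n_boot bootstrap resamples for the indirect-effect CI.
#' @param conf confidence level of the percentile interval.
#' @return object of class `mediation_result` with unstandardized and
#'   standardized paths `a`, `b`, `c_prime` (direct), `c_total`, `indirect`,
#'   per-path p-values, `indirect_ci`, `sobel_p`, `verdict`, `n`.
#' @export
mediation_path <- function(stage, mean_prctu, outcome, covariates = NULL,
                           n_boot = 2000, conf = 0.95) {
  df <- .model_frame(outcome, covariates, .x = as.numeric(stage),
                     .m = mean_prctu)
  n <- nrow(df)
  n_par <- 3 + (if (is.null(covariates)) 0 else ncol(as.data.frame(covariates)))
  if (n < 10 * n_par)
    stop("need at least 10 observations per estimated parameter",
         call. = FALSE)
  if (var(df$.m) == 0 || var(df$.outcome) == 0)
    stop("mediator and outcome must vary", call. = FALSE)

  cov_cols <- setdiff(names(df), c(".x", ".m", ".outcome"))
  C <- if (length(cov_cols)) as.matrix(df[cov_cols]) else NULL
  X1 <- cbind(intercept = 1, x = df$.x, C)                 # M ~ X + C
  X2 <- cbind(intercept = 1, x = df$.x, m = df$.m, C)      # Y ~ X + M + C

  fit_a <- lm(df$.m ~ X1 - 1)
  fit_b <- lm(df$.outcome ~ X2 - 1)
  fit_c <- lm(df$.outcome ~ X1 - 1)
  co_a <- summary(fit_a)$coefficients
  co_b <- summary(fit_b)$coefficients
  co_c <- summary(fit_c)$coefficients
  a <- co_a["X1x", "Estimate"]; a_se <- co_a["X1x", "Std. Error"]
  b <- co_b["X2m", "Estimate"]; b_se <- co_b["X2m", "Std. Error"]
  c_prime <- co_b["X2x", "Estimate"]
  c_total <- co_c["X1x", "Estimate"]
  p_a <- co_a["X1x", "Pr(>|t|)"]
  p_b <- co_b["X2m", "Pr(>|t|)"]
  p_direct <- co_b["X2x", "Pr(>|t|)"]
  p_total <- co_c["X1x", "Pr(>|t|)"]

  sx <- sd(df$.x); sm_ <- sd(df$.m); sy <- sd(df$.outcome)
  std <- c(a = a * sx / sm_, b = b * sm_ / sy,
           c_prime = c_prime * sx / sy, c_total = c_total * sx / sy)
  std["indirect"] <- std["a"] * std["b"]

  boot_ab <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ca <- .lm.fit(X1[idx, , drop = FALSE], df$.m[idx])$coefficients[2]
    cb <- .lm.fit(X2[idx, , drop = FALSE], df$.outcome[idx])$coefficients[3]
    boot_ab[r] <- ca * cb
  }
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_ab, c(alpha, 1 - alpha), type = 6))
  sobel_se <- sqrt(a^2 * b_se^2 + b^2 * a_se^2)
  sobel_p <- 2 * pnorm(-abs(a * b) / sobel_se)

  indirect_sig <- ci[1] > 0 || ci[2] < 0
  direct_sig <- p_direct < 0.05
  verdict <- if (!indirect_sig) "none"
             else if (!direct_sig) "complete"
             else if (sign(c_prime) != sign(a * b)) "inconsistent"
             else "partial"

  structure(list(a = a, b = b, c_prime = c_prime, c_total = c_total,
                 indirect = a * b, standardized = std,
                 p = c(a = p_a, b = p_b, direct = p_direct,
                       total = p_total),
                 indirect_ci = ci, sobel_p = sobel_p, n_boot = n_boot,
                 verdict = verdict, n = n),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, verdict: %s\n", x$n, x$verdict))
  cat(sprintf("  a = %.4g, b = %.4g, direct c' = %.4g (p = %.3g), indirect ab = %.4g\n",
              x$a, x$b, x$c_prime, x$p["direct"], x$indirect))
  cat(sprintf("  indirect %d%% bootstrap CI [%.4g, %.4g], Sobel p = %.3g, total c = %.4g\n",
              95L, x$indirect_ci[1], x$indirect_ci[2], x$sobel_p, x$c_total))
  invisible(x)
}
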