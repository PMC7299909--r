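# synthetic curve features affine in a known true score, for regressor tests
affine_curves <- function(n, noise = 0, seed = 21) {
  set.seed(seed)
  r <- matrix(sample(1:3, n * 8, replace = TRUE), n, 8)
  slope <- runif(12, -0.3, 0.5)
  offset <- runif(12, 0.5, 1.5)
  curves <- array(NA_real_, c(n, 8, 12))
  for (k in 1:8)
    curves[, k, ] <- outer(r[, k], slope) +
      matrix(offset, n, 12, byrow = TRUE) +
      matrix(rnorm(n * 12, 0, noise), n, 12)
  list(curves = curves, r = r)
}

test_that("SVR recovers RCTU from noiseless affine features", {
  sim <- affine_curves(60)
  tr <- 1:50; te <- 51:60
  model <- fit_rctu_regressors(sim$curves[tr, , ], sim$r[tr, ])
  expect_equal(model$epsilon, apply(sim$r[tr, ], 2, IQR) / 13.49)
  pred <- predict_prctu(model, sim$curves[te, , ])
  for (k in 1:8)
    expect_gte(cor(pred$prctu[, k], sim$r[te, k]), 0.95)
  # in-sample predictions are finite everywhere
  expect_true(all(is.finite(predict_prctu(model, sim$curves)$prctu)))
  # constant labels in one region are degenerate
  r_const <- sim$r; r_const[, 3] <- 2L
  expect_error(fit_rctu_regressors(sim$curves, r_const), "constant")
})

test_that("mean pRCTU is the arithmetic mean of the eight predictions", {
  sim <- affine_curves(30)
  model <- fit_rctu_regressors(sim$curves, sim$r)
  one <- predict_prctu(model, sim$curves[1, , ])
  expect_length(one$prctu, 8)
  expect_equal(one$mean_prctu, mean(one$prctu))
  expect_error(predict_prctu(model, sim$curves[1, 1:7, ]), "8")
})

test_that("linear SVM separates well-separated pRCTU clouds perfectly", {
  set.seed(22)
  n <- 60
  pos <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  x[pos, ] <- x[pos, ] + 3          # 3-SD margin in every dimension
  hit <- logical(n)
  for (i in seq_len(n)) {
    cl <- fit_cortical_classifier(x[-i, ], pos[-i])
    hit[i] <- predict(cl, x[i, ])$positive == pos[i]
  }
  expect_equal(mean(hit), 1.0)
  cl <- fit_cortical_classifier(x, pos)
  expect_length(cl$w, 8)
  # positive class sits on the positive side of the hyperplane
  expect_gt(mean(predict(cl, x)$decision[pos]), 0)
  expect_error(fit_cortical_classifier(x, rep(TRUE, n)), "classes")
})

test_that("PCA+LDA separates classes differing in a planted pixel block", {
  set.seed(23)
  n <- 60; p <- 200
  pos <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  block <- 41:90                     # 50-pixel "anterior striatum"
  x[pos, block] <- x[pos, block] + 3
  hit <- logical(n)
  for (i in seq_len(n)) {
    m <- fit_striatal_classifier(x[-i, ], pos[-i])
    hit[i] <- predict(m, x[i, ])$positive == pos[i]
  }
  expect_gte(mean(hit), 0.95)
  m <- fit_striatal_classifier(x, pos)
  expect_lte(m$ncomp, n - 2)
  expect_error(fit_striatal_classifier(x, rep(FALSE, n)), "classes")
  expect_error(fit_striatal_classifier(x[1:6, ], pos[1:6]), "at least 10")
})

test_that("stage prediction is hierarchical and checks the config hash", {
  run <- cohort_run()
  feats <- run$features
  lab <- run$manifest$stage_va
  cfg <- list(n_bins = 15)
  model <- fit_staging_model(feats$curves, rctu_matrix(run$manifest),
                             lab >= 1, feats$striatal, lab == 2,
                             config = cfg)
  i_neg <- which(lab == 0)[1]
  i_s1 <- which(lab == 1)[1]
  i_s2 <- which(lab == 2)[1]
  r_neg <- predict_stage(model, feats$curves[i_neg, , ],
                         feats$striatal[i_neg, ])
  expect_equal(r_neg$stage, 0L)
  expect_true(is.na(r_neg$striatal_positive))  # step 2 never consulted
  r1 <- predict_stage(model, feats$curves[i_s1, , ], feats$striatal[i_s1, ])
  r2 <- predict_stage(model, feats$curves[i_s2, , ], feats$striatal[i_s2, ])
  expect_true(r1$cortical_positive && r2$cortical_positive)
  expect_equal(r2$stage, 2L)
  expect_error(predict_stage(model, feats$curves[i_s2, , ],
                             feats$striatal[i_s2, ],
                             config_hash = config_hash(list(n_bins = 11))),
               "hash")
  expect_silent(predict_stage(model, feats$curves[i_s2, , ],
                              feats$striatal[i_s2, ],
                              config_hash = config_hash(cfg)))
})

test_that("performance report counts perturbed predictions exactly", {
  truth <- rep(0:2, times = c(10, 6, 14))
  perfect <- performance_report(truth, truth)
  expect_equal(perfect$overall_accuracy, 1.0)
  expect_true(all(perfect$confusion == diag(c(10, 6, 14))))
  k <- 5
  perturbed <- truth
  perturbed[1:k] <- (truth[1:k] + 1) %% 3
  rep_p <- performance_report(truth, perturbed)
  expect_equal(rep_p$overall_accuracy, (30 - k) / 30)
  expect_equal(as.numeric(rowSums(rep_p$confusion)), c(10, 6, 14))
})

test_that("swapping LDA for a linear SVM in step 2 barely moves accuracy", {
  run <- cohort_run()
  cv_svm <- loocv_evaluate(run$features, run$manifest, truth = "visual",
                           striatal_method = "svm")
  expect_lte(abs(cv_svm$report$step2$accuracy -
                   run$cv$report$step2$accuracy), 0.03)
})

test_that("SUVr-cutoff truth labels plug into the same pipeline", {
  run <- cohort_run()
  cv <- loocv_evaluate(run$features, run$manifest, truth = "suvr_cutoff")
  expect_length(cv$cutoffs, 2)
  expect_gte(cv$report$overall_accuracy, 0.8)
  # cutoffs derive from the visually negative reference group
  ref <- run$manifest$stage_va == 0
  expect_equal(unname(cv$cutoffs["cortical"]),
               iterative_outlier_cutoff(run$manifest$global_suvr[ref]))
})
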