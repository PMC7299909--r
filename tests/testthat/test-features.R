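corridor <- function(n = 61) {
  grey <- matrix(FALSE, 1, n); grey[1, 1] <- TRUE
  white <- matrix(TRUE, 1, n); white[1, 1] <- FALSE
  list(grey = grey, white = white)
}

test_that("uptake curve of a constant field is constant at that value", {
  cr <- corridor()
  slice <- matrix(1.0, 1, 61)
  cv <- uptake_curve(slice, cr$grey, cr$white, dilate_px = 100)
  expect_equal(as.numeric(cv), rep(1, 12))
  expect_equal(attr(cv, "n_bins"), 15)
})

test_that("uptake curve reproduces closed-form bin means of a linear ramp", {
  cr <- corridor()
  d_max <- 60
  slice <- matrix(1 + (0:60) / d_max, 1, 61)  # intensity 1 + d/d_max
  cv <- uptake_curve(slice, cr$grey, cr$white, dilate_px = 100)
  # bin b holds distances {4b-4 .. 4b-1}: mean intensity 1 + (4b - 2.5)/60
  want <- 1 + (4 * (1:12) - 2.5) / d_max
  expect_equal(as.numeric(cv), want, tolerance = 1e-12)
  expect_true(all(diff(cv) > 0))
})

test_that("raising grey amplitude raises early bins and the grey/white ratio", {
  cr <- corridor(31)
  base <- matrix(1.0, 1, 31)
  lo <- base; lo[1, 1] <- 0.6
  hi <- base; hi[1, 1] <- 1.4
  cv_lo <- uptake_curve(lo, cr$grey, cr$white, dilate_px = 100)
  cv_hi <- uptake_curve(hi, cr$grey, cr$white, dilate_px = 100)
  expect_gt(mean(cv_hi[1:3]), mean(cv_lo[1:3]))
  expect_gt(mean(cv_hi[1:3]) / mean(cv_hi[10:12]),
            mean(cv_lo[1:3]) / mean(cv_lo[10:12]))
})

test_that("a grey-only ROI with no adjacent white matter is rejected", {
  grey <- matrix(TRUE, 3, 3)
  white <- matrix(FALSE, 3, 3)
  expect_error(uptake_curve(matrix(1, 3, 3), grey, white),
               "white matter")
})

test_that("features are invariant to global PET rescaling", {
  ph <- make_phantom(phantom_spec(rctu = rep(2, 8), seed = 3))
  f1 <- subject_features(ph$labels, ph$pet)
  f2 <- subject_features(ph$labels, pet_volume(ph$pet$data * 10))
  expect_equal(f2$curves, f1$curves, tolerance = 1e-12)
  expect_equal(f2$striatal, f1$striatal, tolerance = 1e-12)
  expect_equal(f2$norm_constant, 10 * f1$norm_constant, tolerance = 1e-12)
})

test_that("normalization scalar makes the 8-ROI union mean exactly 1", {
  ph <- make_phantom(phantom_spec(rctu = runif(8, 1, 3), seed = 4))
  masks <- roi_masks(ph$labels)
  norm <- normalize_pet_slices(ph$pet, masks)
  vals <- unlist(lapply(masks$cortical, function(r)
    norm$slices[[as.character(r$k)]][r$grey]))
  expect_equal(mean(vals), 1, tolerance = 1e-12)
  # zero intensity across the ROIs is rejected
  zero <- ph$pet$data
  for (r in masks$cortical) zero[, , r$k][r$grey] <- 0
  expect_error(normalize_pet_slices(pet_volume(zero), masks), "positive")
})

test_that("striatal features sample the template in fixed order", {
  set.seed(5)
  slice <- matrix(runif(40 * 40), 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[15:20, 12:25] <- TRUE
  f <- striatal_feature(slice, mask, mask, "identity")
  expect_length(f, sum(mask))
  # identity equals the direct masked read-out
  idx <- which(mask, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  expect_equal(as.numeric(f), slice[cbind(idx[o, 1], idx[o, 2])])
  # a translated subject is recovered by the affine (translation) alignment
  sh <- function(m, a, b) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + max(a, 0)):(nrow(m) + min(a, 0)),
        (1 + max(b, 0)):(ncol(m) + min(b, 0))] <-
      m[(1 - min(a, 0)):(nrow(m) - max(a, 0)),
        (1 - min(b, 0)):(ncol(m) - max(b, 0))]
    out
  }
  f2 <- striatal_feature(sh(slice, 3, -2), sh(mask, 3, -2) > 0, mask,
                         "affine")
  expect_equal(as.numeric(f2), as.numeric(f), tolerance = 1e-12)
  expect_equal(attr(f2, "shift"), c(-3, 2))
})

test_that("SUVr is the cortical-composite to cerebellum intensity ratio", {
  lab <- array(0L, c(16, 16, 16))
  lab[2:5, 2:5, 10] <- 21L   # frontal
  lab[8:11, 2:5, 10] <- 22L  # parietal
  lab[2:5, 8:11, 10] <- 23L  # precuneus/PCC
  lab[8:11, 8:11, 10] <- 24L # lateral temporal
  lab[4:12, 4:12, 2] <- 8L   # cerebellum
  lv <- label_volume(lab, phantom_label_map())
  pet <- array(0.5, c(16, 16, 16))
  pet[lab %in% 21:24] <- 2
  pet[lab == 8L] <- 1
  expect_equal(global_suvr(pet_volume(pet), lv), 2.0)
  pet[lab %in% 21:24] <- 1
  expect_equal(global_suvr(pet_volume(pet), lv), 1.0)
  lab2 <- lab; lab2[lab2 == 8L] <- 0L
  lv2 <- label_volume(lab2, phantom_label_map())
  expect_error(global_suvr(pet_volume(pet), lv2), "cerebellum")
})

test_that("iterative outlier cutoff trims above mean + 2 SD until stable", {
  expect_equal(iterative_outlier_cutoff(rep(2.5, 5)), 2.5)  # zero spread
  expect_equal(iterative_outlier_cutoff(c(rep(1, 10), 3)), 1.0)
  expect_error(iterative_outlier_cutoff(c(1, 2)), "at least 3")
  # removing the largest value never increases the cutoff
  set.seed(6)
  for (i in 1:20) {
    v <- rlnorm(sample(5:40, 1))
    expect_lte(iterative_outlier_cutoff(sort(v)[-length(v)]),
               iterative_outlier_cutoff(v) + 1e-12)
  }
})
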