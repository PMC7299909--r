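test_that("phantoms are deterministic and carry the designed contrast", {
  sp <- phantom_spec(rctu = rep(1, 8), seed = 9)
  ph1 <- make_phantom(sp)
  ph2 <- make_phantom(sp)
  expect_identical(ph1$labels$data, ph2$labels$data)
  expect_identical(ph1$pet$data, ph2$pet$data)

  # no binding (r = 1): grey below white in every cortical ROI, pre-noise
  grey <- region_mask(ph1$labels, c("frontal", "parietal", "precuneus_pcc",
                                    "lateral_temporal"))
  white <- region_mask(ph1$labels, "cerebral_white_matter")
  expect_lt(mean(ph1$clean[grey]), mean(ph1$clean[white]))

  # pronounced binding reverses the contrast
  ph3 <- make_phantom(phantom_spec(rctu = rep(3, 8), seed = 9))
  expect_gt(mean(ph3$clean[grey]), mean(ph3$clean[white]))

  # striatal uptake separates stage 2 from stage 1 by construction
  s1 <- make_phantom(phantom_spec(rctu = rep(2.5, 8), striatal_r = 1.1))
  s2 <- make_phantom(phantom_spec(rctu = rep(2.5, 8), striatal_r = 2.8))
  stri <- region_mask(s1$labels, c("caudate", "putamen"))
  expect_gt(mean(s2$clean[stri]), mean(s1$clean[stri]))

  expect_error(phantom_spec(ribbon_px = 2), "ribbon")
  expect_error(phantom_spec(rctu = rep(4, 8)), "rctu")
})

test_that("noise-free, blur-free curves are piecewise constant", {
  ph <- make_phantom(phantom_spec(rctu = rep(2, 8), psf_sigma = 0,
                                  noise_sd = 0))
  f <- subject_features(ph$labels, ph$pet)
  # only two intensity levels exist: bins past the first sit exactly on the
  # white plateau; bin 1 mixes the grey seed (normalized level 1) with its
  # immediate white neighbours, so it lies strictly between the two levels
  plateau <- f$curves[, 2:12]
  expect_lt(max(apply(plateau, 1, function(r) diff(range(r)))), 1e-10)
  white_level <- plateau[, 1]
  expect_true(all(f$curves[, 1] >= 1 - 1e-10))
  expect_true(all(f$curves[, 1] < white_level))
})

test_that("cohorts are reproducible and validate as manifests", {
  spec <- cohort_spec(n = 40, seed = 13)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truth, c2$truth)

  td <- withr::local_tempdir()
  path <- file.path(td, "manifest.tsv")
  write_manifest(c1$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$stage_va, c1$manifest$stage_va)
  expect_equal(rctu_matrix(back), rctu_matrix(c1$manifest),
               ignore_attr = TRUE)

  # truth stage and the VA-derived stage agree (no rater noise by default)
  expect_equal(c1$manifest$stage_va, c1$truth$stage)
  # cohort-mean true burden increases with stage by construction
  mm <- tapply(c1$truth$mean_r, c1$truth$stage, mean)
  expect_true(all(diff(mm) > 0))
  expect_error(cohort_spec(stage_probs = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("realised stage counts stay inside binomial 99% bounds", {
  co <- make_cohort(cohort_spec(n = 1000, seed = 14))
  counts <- tabulate(co$truth$stage + 1L, 3)
  probs <- c(0.374, 0.104, 0.522)
  for (s in 1:3) {
    lo <- qbinom(0.005, 1000, probs[s])
    hi <- qbinom(0.995, 1000, probs[s])
    expect_gte(counts[s], lo)
    expect_lte(counts[s], hi)
  }
})

test_that("rater label noise perturbs visual scores at the requested rate", {
  co <- make_cohort(cohort_spec(n = 200, seed = 15, label_flip_rate = 0.2))
  clean <- pmin(pmax(round(as.matrix(
    co$truth[, paste0("r", 1:8)])), 1), 3)
  flipped <- mean(rctu_matrix(co$manifest) != clean)
  expect_gt(flipped, 0.1)
  expect_lt(flipped, 0.3)
  # manifests stay internally consistent even with noisy labels
  expect_s3_class(validate_manifest(as.data.frame(co$manifest)),
                  "subject_manifest")
})
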