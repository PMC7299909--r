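# superior-to-inferior index of array plane k in a K-slice volume: K - k + 1

test_that("top slice is the superior tip of the lateral ventricles", {
  K <- 48
  lv <- slice_phantom(K, vent_k = (K - 19):(K - 9), temporal_k = 5:9,
                      striatal_k = 20:24)
  expect_equal(find_top_slice(lv), 10)   # occupied superior indices 10..20
  single <- slice_phantom(K, vent_k = K - 6, temporal_k = 5:9,
                          striatal_k = 20:24)
  expect_equal(find_top_slice(single), 7)
  lab <- array(0L, c(16, 16, K)); lab[8, 8, 5] <- 31L
  no_vent <- label_volume(lab, phantom_label_map())
  expect_error(find_top_slice(no_vent), "ventricle")
})

test_that("bottom slice is the rounded temporal centre of mass", {
  K <- 48
  all40 <- slice_phantom(K, vent_k = 44:46, temporal_k = K - 39,
                         striatal_k = 20:24)
  expect_equal(find_bottom_slice(all40), 40)
  # voxels on superior indices 30, 34, 36 -> mean 33.33 -> 33
  com <- slice_phantom(K, vent_k = 44:46,
                       temporal_k = K + 1 - c(30, 34, 36),
                       striatal_k = 20:24)
  expect_equal(find_bottom_slice(com), 33)
  lab <- array(0L, c(16, 16, K)); lab[4, 4, 40] <- 4L
  no_temp <- label_volume(lab, phantom_label_map())
  expect_error(find_bottom_slice(no_temp), "temporal")
})

test_that("S1-S5 follow the interpolation formulas with half-to-even rounding", {
  K <- 80
  # SN_top = 20, SN_bottom = 60 -> S1..S4 = 20, 30, 40, 60
  lv <- slice_phantom(K, vent_k = K + 1 - 20, temporal_k = K + 1 - 60,
                      striatal_k = K + 1 - 45)
  s <- select_slices(lv)
  expect_equal(c(s$s1, s$s2, s$s3, s$s4, s$s5), c(20, 30, 40, 60, 45))
  expect_equal(s$axial[["s1"]], K + 1 - 20)

  # SN_top = 10, SN_bottom = 51: s2 = round(20.25) = 20, s3 = round(30.5) = 30
  lv2 <- slice_phantom(K, vent_k = K + 1 - 10, temporal_k = K + 1 - 51,
                       striatal_k = K + 1 - 30)
  s2 <- select_slices(lv2)
  expect_equal(c(s2$s1, s2$s2, s2$s3, s2$s4), c(10, 20, 30, 51))

  # degenerate: temporal centre of mass at/above the ventricle top
  flat <- slice_phantom(K, vent_k = K + 1 - 30, temporal_k = K + 1 - 30,
                        striatal_k = K + 1 - 40)
  expect_error(select_slices(flat), "not inferior")

  lab <- array(0L, c(16, 16, K))
  lab[4:6, 4:6, K + 1 - 20] <- 4L; lab[8, 8, K + 1 - 60] <- 31L
  no_stri <- label_volume(lab, phantom_label_map())
  expect_error(select_slices(no_stri), "striatal")
})

test_that("slice selection is translation-equivariant and idempotent", {
  K <- 80
  # superior-inferior extent of 32 slices: the quarter and half interpolants
  # are exact integers, so equivariance holds for every shift (with fractional
  # interpolants, rounding half to even ties equivariance to shift parity)
  base <- slice_phantom(K, vent_k = K + 1 - 18, temporal_k = K + 1 - c(48, 52),
                        striatal_k = K + 1 - c(33, 35))
  s0 <- select_slices(base)
  for (d in c(3, 7)) {
    shifted <- slice_phantom(K, vent_k = K + 1 - (18 + d),
                             temporal_k = K + 1 - (c(48, 52) + d),
                             striatal_k = K + 1 - (c(33, 35) + d))
    sd_ <- select_slices(shifted)
    expect_equal(c(sd_$s1, sd_$s2, sd_$s3, sd_$s4, sd_$s5),
                 c(s0$s1, s0$s2, s0$s3, s0$s4, s0$s5) + d)
  }
  expect_identical(select_slices(base), s0)
  # interpolants land within half a slice of the exact quarter/half points
  frac <- (s0$s2 - s0$s1) / (s0$s4 - s0$s1)
  expect_lt(abs(frac - 0.25), 0.5 / (s0$s4 - s0$s1) + 1e-12)
})
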