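# One shared end-to-end run of the default synthetic cohort (n = 90,
# default noise, fixed seed, full per-fold refit LOOCV), computed lazily and
# reused by the staging, discriminative and acceptance tests.
.test_cache <- new.env(parent = emptyenv())

cohort_run <- function() {
  if (is.null(.test_cache$run)) {
    cohort <- make_cohort(cohort_spec(n = 90, seed = 1))
    feats <- cohort_features(cohort)
    manifest <- cohort$manifest
    manifest$global_suvr <- feats$suvr$global_suvr
    manifest$striatal_suvr <- feats$suvr$striatal_suvr
    cv <- loocv_evaluate(feats, manifest, truth = "visual")
    .test_cache$run <- list(cohort = cohort, features = feats,
                            manifest = manifest, cv = cv)
  }
  .test_cache$run
}

# small hand-built label volume for slice-selection tests: ventricle top,
# temporal centre of mass and striatal centre of mass are all placed
# explicitly (in array plane coordinates, axis 3 inferior -> superior)
slice_phantom <- function(K, vent_k, temporal_k, striatal_k,
                          nx = 16, ny = 16) {
  lab <- array(0L, c(nx, ny, K))
  lab[4:6, 4:6, vent_k] <- 4L
  lab[8:10, 8:10, temporal_k] <- 31L
  lab[12:13, 4:5, striatal_k] <- 11L
  label_volume(lab, phantom_label_map())
}
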