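#' @title Synthetic brain phantoms and cohorts with known ground truth
#'
#' @description
#' The phantom emulates, at desk scale, exactly the tissue contrast the
#' staging pipeline reads: an ellipsoidal brain with a cortical grey ribbon
#' over subcortical white matter, lateral ventricles whose superior tip
#' anchors the top slice, temporal-lobe parcels anchoring the bottom slice,
#' caudate and putamen for the striatal slice, and a cerebellum reference.
#' White matter carries constant nonspecific binding; each cortical ROI's
#' grey intensity is graded by its continuous true RCTU `r` as
#' `baseline * (0.55 + 0.30 (r - 1))`, so `r = 1` gives grey well below
#' white and `r = 3` gives grey above white; the striatum brightens only in
#' stage 2. A Gaussian point-spread blur and additive noise follow.
#' Phantoms are generated in template space: the striatal template mask is
#' the generator's own S5 striatal mask, so identity registration is exact.
#'
#' Cohorts sample stages at the prevalence of a memory-clinic population
#' (37.4 / 10.4 / 52.2 percent for stages 0/1/2), draw continuous regional
#' RCTU conditional on stage, derive visual scores by rounding (rater
#' quantisation), and generate outcome variables under a
#' stage -> cortical-burden -> outcome mediation structure with known
#' coefficients.
#'
#' @name synthetic_data
NULL

#' Phantom specification
#'
#' @param shape grid dimensions (x, y, z), axis 3 inferior to superior.
#' @param ribbon_px cortical ribbon thickness in voxels (>= 3).
#' @param rctu length-8 vector of continuous true RCTU values in `[1, 3]`,
#'   in the fixed ROI order of [rctu_columns()].
#' @param striatal_r continuous striatal uptake grade in `[1, 3]`.
#' @param wm_baseline white-matter nonspecific binding level.
#' @param psf_sigma Gaussian point-spread sigma in voxels.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed for the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), ribbon_px = 4,
                         rctu = rep(1, 8), striatal_r = 1,
                         wm_baseline = 100, psf_sigma = 1, noise_sd = 3,
                         seed = 1) {
  if (ribbon_px < 3)
    stop("ribbon thickness must be at least 3 voxels", call. = FALSE)
  if (length(rctu) != 8 || any(rctu < 1 | rctu > 3))
    stop("rctu must be 8 values in [1, 3]", call. = FALSE)
  if (striatal_r < 1 || striatal_r > 3)
    stop("striatal_r must lie in [1, 3]", call. = FALSE)
  if (any(shape < c(48, 48, 40)))
    stop("phantom grid must be at least 48 x 48 x 40", call. = FALSE)
  structure(list(shape = as.integer(shape), ribbon_px = as.integer(ribbon_px),
                 rctu = as.numeric(rctu), striatal_r = striatal_r,
                 wm_baseline = wm_baseline, psf_sigma = psf_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# phantom label ids
.ph_ids <- list(white = 2L, ventricle = 4L, cerebellum = 8L, caudate = 11L,
                putamen = 12L, frontal = 21L, parietal = 22L,
                precuneus_pcc = 23L, lateral_temporal = 24L,
                temporal = 31:39)

#' Label map of the synthetic phantom
#' @return named list of integer label vectors covering [required_regions()].
#' @export
phantom_label_map <- function() {
  ids <- .ph_ids
  m <- list(
    lateral_ventricle = ids$ventricle,
    frontal = ids$frontal, parietal = ids$parietal,
    precuneus_pcc = ids$precuneus_pcc,
    lateral_temporal = ids$lateral_temporal,
    caudate = ids$caudate, putamen = ids$putamen,
    cerebellum = ids$cerebellum,
    cerebral_white_matter = ids$white,
    grey_matter = c(ids$frontal, ids$parietal, ids$precuneus_pcc,
                    ids$lateral_temporal, ids$temporal)
  )
  for (i in seq_along(.temporal_parcel_names))
    m[[.temporal_parcel_names[i]]] <- ids$temporal[i]
  m
}

.erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, ax, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) out <- out & sh(mask, ax, 1) & sh(mask, ax, -1)
  out
}

.box_mask <- function(d, xr, yr, zr) {
  m <- array(FALSE, d)
  m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  m
}

# deterministic label geometry; scaled from the default 64 x 64 x 48 grid
.phantom_labels <- function(spec) {
  d <- spec$shape
  sc <- d / c(64, 64, 48)
  rg <- function(xr, yr, zr) list(x = round(xr * sc[1]), y = round(yr * sc[2]),
                                  z = round(zr * sc[3]))
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz0 <- 26 * sc[3]
  radii <- c(26, 30, 21) * sc

  xg <- slice.index(array(0, d), 1)
  yg <- slice.index(array(0, d), 2)
  zg <- slice.index(array(0, d), 3)
  rho2 <- ((xg - cx) / radii[1])^2 + ((yg - cy) / radii[2])^2 +
    ((zg - cz0) / radii[3])^2
  brain <- rho2 <= 1

  interior <- brain
  for (i in seq_len(spec$ribbon_px)) interior <- .erode6(interior)
  ribbon <- brain & !interior

  z_cereb <- round(9 * sc[3])
  cerebellum <- brain & zg <= z_cereb
  cerebrum <- brain & zg > z_cereb

  lab <- array(0L, d)
  lab[interior & cerebrum] <- .ph_ids$white

  # cortical sectors on the ribbon (cerebrum only)
  band <- 6 * sc[2]
  rib <- ribbon & cerebrum
  lab[rib & yg < cy - band] <- .ph_ids$frontal
  lab[rib & abs(yg - cy) <= band] <- .ph_ids$lateral_temporal
  post <- rib & yg > cy + band
  lab[post & abs(xg - cx) >= 6 * sc[1]] <- .ph_ids$parietal
  lab[post & abs(xg - cx) < 6 * sc[1]] <- .ph_ids$precuneus_pcc

  lab[cerebellum] <- .ph_ids$cerebellum

  # temporal parcel blocks (bottom-slice anchor), 9 strips along y
  tz <- rg(c(0, 0), c(0, 0), c(10, 14))$z
  for (xr in list(rg(c(20, 28), c(0, 0), c(0, 0))$x,
                  rg(c(36, 44), c(0, 0), c(0, 0))$x)) {
    yr <- rg(c(0, 0), c(30, 44), c(0, 0))$y
    ys <- seq(yr[1], yr[2])
    strip <- pmin(1L + ((ys - yr[1]) * 9L) %/% (yr[2] - yr[1] + 1L), 9L)
    for (jj in seq_along(ys)) {
      blk <- .box_mask(d, xr, c(ys[jj], ys[jj]), tz) & brain
      lab[blk] <- .ph_ids$temporal[strip[jj]]
    }
  }

  # lateral ventricles (superior tip anchors the top slice)
  vz <- rg(c(0, 0), c(0, 0), c(23, 40))$z
  vy <- rg(c(0, 0), c(32, 42), c(0, 0))$y
  for (xr in list(rg(c(27, 30), c(0, 0), c(0, 0))$x,
                  rg(c(35, 38), c(0, 0), c(0, 0))$x))
    lab[.box_mask(d, xr, vy, vz) & brain] <- .ph_ids$ventricle

  # striatum
  cz <- rg(c(0, 0), c(0, 0), c(24, 30))$z
  cyr <- rg(c(0, 0), c(24, 30), c(0, 0))$y
  for (xr in list(rg(c(23, 26), c(0, 0), c(0, 0))$x,
                  rg(c(39, 42), c(0, 0), c(0, 0))$x))
    lab[.box_mask(d, xr, cyr, cz) & brain] <- .ph_ids$caudate
  pz <- rg(c(0, 0), c(0, 0), c(23, 29))$z
  pyr <- rg(c(0, 0), c(26, 34), c(0, 0))$y
  for (xr in list(rg(c(18, 22), c(0, 0), c(0, 0))$x,
                  rg(c(43, 47), c(0, 0), c(0, 0))$x))
    lab[.box_mask(d, xr, pyr, pz) & brain] <- .ph_ids$putamen

  lv <- label_volume(lab, phantom_label_map())
  empty <- names(which(vapply(required_regions(),
                              function(r) !any(region_mask(lv, r)),
                              logical(1))))
  if (length(empty))
    stop("phantom geometry empties required region(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  lv
}

.grey_level <- function(baseline, r) baseline * (0.55 + 0.30 * (r - 1))

# noise-free intensity field for given true uptake grades
.phantom_intensity <- function(labels, spec) {
  d <- dim(labels$data)
  lab <- labels$data
  pet <- array(0, d)
  W <- spec$wm_baseline
  pet[lab == .ph_ids$white] <- W
  pet[lab == .ph_ids$ventricle] <- 0.25 * W
  pet[lab == .ph_ids$cerebellum] <- 0.70 * W

  roi <- .roi_table()
  hemi <- list(left = .hemi_mask(d, "left"), right = .hemi_mask(d, "right"))
  for (i in seq_len(nrow(roi))) {
    ids <- .ph_ids[[roi$region[i]]]
    m <- array(lab %in% ids, d) & hemi[[roi$hemisphere[i]]]
    pet[m] <- .grey_level(W, spec$rctu[i])
  }
  pet[array(lab %in% .ph_ids$temporal, d)] <- .grey_level(W, mean(spec$rctu))
  stri <- array(lab %in% c(.ph_ids$caudate, .ph_ids$putamen), d)
  pet[stri] <- .grey_level(W, spec$striatal_r)
  pet
}

.gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
  K / rowSums(K)
}

.smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  for (ax in 1:3) {
    d <- dim(a)
    K <- .gauss_kernel_matrix(d[1], sigma)
    a <- array(K %*% matrix(a, d[1], prod(d[-1])), d)
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

#' Generate a phantom label/PET pair
#'
#' Deterministic for a given spec (the seed drives only the noise draw).
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (a `label_volume`), `pet` (a `pet_volume`),
#'   `clean` (the pre-noise, pre-blur intensity array) and `truth` (the
#'   continuous grades used).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- .phantom_labels(spec)
  clean <- .phantom_intensity(labels, spec)
  pet <- .smooth3d(clean, spec$psf_sigma)
  if (spec$noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(spec$seed)
    pet <- pet + array(rnorm(length(pet), 0, spec$noise_sd), dim(pet))
  }
  pet <- pmax(pet, 1e-6)
  list(labels = labels, pet = pet_volume(pet), clean = clean,
       truth = list(rctu = spec$rctu, striatal_r = spec$striatal_r))
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Default outcome-generating models for synthetic cohorts
#'
#' Each outcome is `intercept + beta_m * mean(r) + beta_x * stage +
#' covariate terms + N(0, sd)`; `beta_x = 0` (the default) builds in complete
#' mediation of the stage effect through the cortical burden. Scales mimic a
#' memory-clinic cohort (MMSE points, z-scored memory composite, mm cortical
#' thickness, cubic-mm hippocampal volume).
#'
#' @param beta_x direct stage effect shared by all outcomes.
#' @return named list of model coefficient lists.
#' @export
default_outcome_models <- function(beta_x = 0) {
  list(
    k_mmse = list(intercept = 32, beta_m = -4, beta_x = beta_x, sd = 2.5,
                  age = -0.05, education = 0.15),
    memory = list(intercept = 1.8, beta_m = -0.7, beta_x = beta_x, sd = 0.6,
                  age = -0.01),
    global_thickness = list(intercept = 3.35, beta_m = -0.07,
                            beta_x = beta_x, sd = 0.12, age = -0.003),
    hippocampal_volume = list(intercept = 4200, beta_m = -450,
                              beta_x = beta_x, sd = 350, age = -8,
                              icv = 0.4)
  )
}

#' Cohort specification
#'
#' @param n number of subjects (>= 20 for leave-one-out use).
#' @param stage_probs stage 0/1/2 proportions (default 0.374/0.104/0.522,
#'   the prevalence of the emulated clinical population).
#' @param outcome_models outcome-generating coefficients
#'   ([default_outcome_models()]).
#' @param label_flip_rate probability that a visual RCTU score is perturbed
#'   by one grade (rater noise; 0 by default).
#' @param phantom baseline [phantom_spec()] shared by all subjects (geometry
#'   and acquisition parameters; per-subject grades override `rctu`,
#'   `striatal_r` and `seed`).
#' @param seed cohort RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 90, stage_probs = c(0.374, 0.104, 0.522),
                        outcome_models = default_outcome_models(),
                        label_flip_rate = 0, phantom = phantom_spec(),
                        seed = 1) {
  if (abs(sum(stage_probs) - 1) > 1e-8)
    stop("stage proportions must sum to 1", call. = FALSE)
  if (n < 20)
    stop("cohort size must be at least 20", call. = FALSE)
  structure(list(n = as.integer(n), stage_probs = stage_probs,
                 outcome_models = outcome_models,
                 label_flip_rate = label_flip_rate, phantom = phantom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort manifest with known truth
#'
#' Samples stages, continuous regional grades conditional on stage, visual
#' scores by rounding, covariates, and mediation-structured outcomes.
#' Volumes are not materialised here; [cohort_features()] generates each
#' subject's phantom on demand from the recorded truth.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `manifest` (validated,
#'   passes [validate_manifest()]), `truth` (per-subject continuous grades
#'   and phantom seeds) and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n
  stage <- sample(0:2, n, replace = TRUE, prob = spec$stage_probs)

  r <- matrix(NA_real_, n, 8)
  striatal_r <- numeric(n)
  for (i in seq_len(n)) {
    if (stage[i] == 0) {
      r[i, ] <- runif(8, 1, 1.4)
      striatal_r[i] <- runif(1, 1, 1.3)
    } else {
      sev <- if (stage[i] == 1) runif(1, 1.8, 2.5) else runif(1, 2.2, 3.0)
      r[i, ] <- pmin(pmax(sev + runif(8, -0.35, 0.35), 1), 3)
      if (max(round(r[i, ])) < 2) r[i, which.max(r[i, ])] <- 1.6
      striatal_r[i] <- if (stage[i] == 2) runif(1, 2.2, 3.0)
                       else runif(1, 1, 1.3)
    }
  }
  va <- pmin(pmax(round(r), 1), 3)
  if (spec$label_flip_rate > 0) {
    flip <- matrix(runif(n * 8) < spec$label_flip_rate, n, 8)
    dir <- matrix(sample(c(-1, 1), n * 8, replace = TRUE), n, 8)
    va <- pmin(pmax(va + flip * dir, 1), 3)
  }
  striatal_va <- as.integer(stage == 2)
  stage_va <- .stage_from_va(va, striatal_va)

  age <- rnorm(n, 70.5, 9.2)
  sex <- rbinom(n, 1, 0.49)
  education <- pmax(rnorm(n, 12.5, 4.6), 0)
  icv <- rnorm(n, 1450, 120)
  cov <- data.frame(age = age, sex = sex, education = education, icv = icv)

  mean_r <- rowMeans(r)
  outcomes <- lapply(names(spec$outcome_models), function(nm) {
    m <- spec$outcome_models[[nm]]
    y <- m$intercept + m$beta_m * mean_r + m$beta_x * stage
    for (cv in intersect(names(m), names(cov))) y <- y + m[[cv]] * cov[[cv]]
    y + rnorm(n, 0, m$sd)
  })
  names(outcomes) <- names(spec$outcome_models)

  manifest <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
  va_df <- as.data.frame(va)
  names(va_df) <- rctu_columns()
  manifest <- cbind(manifest, va_df,
                    striatal_va = striatal_va, stage_va = stage_va,
                    cov, as.data.frame(outcomes))
  manifest <- validate_manifest(manifest)

  truth <- data.frame(subject_id = manifest$subject_id,
                      stage = stage, mean_r = mean_r,
                      striatal_r = striatal_r,
                      phantom_seed = sample.int(2^30, n),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, setNames(as.data.frame(r), paste0("r", 1:8)))

  structure(list(manifest = manifest, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Extract pipeline features for every subject of a synthetic cohort
#'
#' All subjects share the phantom geometry (template space), so the label
#' volume, slice set and ROI masks are computed once; each subject's PET is
#' generated from their recorded grades and seed, normalized, and reduced to
#' the 8 uptake curves, the striatal template feature and the SUVr values.
#'
#' @param cohort output of [make_cohort()].
#' @param n_bins,n_used,dilate_px uptake-curve parameters
#'   (see [uptake_curve()]).
#' @param verbose print per-subject progress.
#' @return list with `curves` (n x 8 x n_used array), `striatal` (n x pixels
#'   matrix), `suvr` (data.frame with `global_suvr`, `striatal_suvr`),
#'   `template_mask`, `labels`, `slices`, `norm_constants` and `config`.
#' @export
cohort_features <- function(cohort, n_bins = 15, n_used = 12,
                            dilate_px = 20, verbose = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  base <- cohort$spec$phantom
  labels <- .phantom_labels(base)
  slices <- select_slices(labels)
  masks <- roi_masks(labels, slices)
  template_mask <- masks$striatal$left$mask | masks$striatal$right$mask
  n <- cohort$spec$n
  curves <- array(NA_real_, c(n, 8, n_used),
                  dimnames = list(cohort$manifest$subject_id,
                                  rownames(.roi_table()), NULL))
  striatal <- matrix(NA_real_, n, sum(template_mask),
                     dimnames = list(cohort$manifest$subject_id, NULL))
  suvr <- data.frame(global_suvr = numeric(n), striatal_suvr = numeric(n))
  consts <- numeric(n)
  for (i in seq_len(n)) {
    sp <- base
    sp$rctu <- as.numeric(cohort$truth[i, paste0("r", 1:8)])
    sp$striatal_r <- cohort$truth$striatal_r[i]
    sp$seed <- cohort$truth$phantom_seed[i]
    ph <- make_phantom(sp)
    f <- subject_features(ph$labels, ph$pet, template_mask = template_mask,
                          slices = slices, masks = masks, n_bins = n_bins,
                          n_used = n_used, dilate_px = dilate_px)
    curves[i, , ] <- f$curves
    striatal[i, ] <- f$striatal
    suvr$global_suvr[i] <- global_suvr(ph$pet, ph$labels)
    suvr$striatal_suvr[i] <- striatal_suvr(ph$pet, ph$labels)
    consts[i] <- f$norm_constant
    if (verbose && i %% 10 == 0)
      message("  features: ", i, "/", n, " subjects")
  }
  list(curves = curves, striatal = striatal, suvr = suvr,
       template_mask = template_mask, labels = labels, slices = slices,
       norm_constants = consts,
       config = list(n_bins = n_bins, n_used = n_used,
                     dilate_px = dilate_px,
                     template_pixels = sum(template_mask)))
}
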