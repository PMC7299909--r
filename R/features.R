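#' @title Uptake-curve and striatal feature extraction
#'
#' @description
#' The cortical feature is an uptake curve: mean normalized PET intensity as a
#' function of geodesic distance from the grey matter, computed on the
#' assessment slice of each of the eight cortical ROIs (frontal,
#' precuneus/posterior cingulate, lateral temporal, parietal; both
#' hemispheres). The distance range is split into 15 equal-width bins and the
#' first 12 bin means form the feature vector. Intensities are normalized by
#' a single per-subject scalar, the mean intensity over all pixels of the
#' eight cortical ROIs, which makes every feature invariant to global
#' rescaling of the PET volume and removes the need for a reference region.
#' The striatal feature is the vector of normalized intensities at the pixels
#' of a fixed template striatal mask on the S5 slice.
#'
#' @name feature_extraction
NULL

#' Cortical and striatal ROI masks on the assessment slices
#'
#' Builds the ten per-subject ROI masks: the grey-matter parcels of each
#' cortical region on its designated slice (parietal on S1, precuneus/PCC on
#' S2, frontal on S3, lateral temporal on S4), split by hemisphere at the
#' midline, plus the left and right striatum (caudate and putamen) on S5.
#'
#' @param labels a `label_volume`.
#' @param slices a `slice_set` from [select_slices()]; computed if `NULL`.
#' @return list with `cortical` (8 entries: `region`, `hemisphere`, `slice`,
#'   `k`, logical `grey` mask), `striatal` (2 entries with `mask`), the
#'   white-matter slice masks `white` (one per assessment slice, by plane
#'   index), and `slices`.
#' @export
roi_masks <- function(labels, slices = NULL) {
  if (is.null(slices)) slices <- select_slices(labels)
  roi <- .roi_table()
  dims <- dim(labels$data)
  hemi <- list(left = .hemi_mask(dims, "left")[, , 1],
               right = .hemi_mask(dims, "right")[, , 1])
  cortical <- vector("list", nrow(roi))
  names(cortical) <- rownames(roi)
  for (i in seq_len(nrow(roi))) {
    k <- slices$axial[[roi$slice[i]]]
    mask <- region_mask(labels, roi$region[i])[, , k] & hemi[[roi$hemisphere[i]]]
    if (!any(mask))
      stop("empty ", roi$region[i], " (", roi$hemisphere[i],
           ") ROI on its assessment slice", call. = FALSE)
    cortical[[i]] <- list(region = roi$region[i],
                          hemisphere = roi$hemisphere[i],
                          slice = roi$slice[i], k = k, grey = mask)
  }
  k5 <- slices$axial[["s5"]]
  striatal_full <- region_mask(labels, c("caudate", "putamen"))[, , k5]
  striatal <- list(
    left = list(hemisphere = "left", k = k5,
                mask = striatal_full & hemi$left),
    right = list(hemisphere = "right", k = k5,
                 mask = striatal_full & hemi$right)
  )
  white3d <- region_mask(labels, "cerebral_white_matter")
  ks <- sort(unique(c(vapply(cortical, `[[`, 0, "k"), k5)))
  white <- lapply(ks, function(k) white3d[, , k])
  names(white) <- as.character(ks)
  list(cortical = cortical, striatal = striatal, white = white,
       slices = slices)
}

#' Per-subject intensity normalization over the eight cortical ROIs
#'
#' Divides the assessment slices by the mean PET intensity of all pixels
#' within the eight cortical ROI masks, so that the normalized mean over that
#' union is exactly 1.
#'
#' @param pet a `pet_volume`.
#' @param masks output of [roi_masks()].
#' @return list with `constant` (the scalar divisor) and `slices` (normalized
#'   2D intensity matrices, named by array plane index).
#' @export
normalize_pet_slices <- function(pet, masks) {
  stopifnot(inherits(pet, "pet_volume"))
  vals <- unlist(lapply(masks$cortical, function(r) {
    pet$data[, , r$k][r$grey]
  }))
  if (length(vals) == 0)
    stop("union of cortical ROI pixels is empty", call. = FALSE)
  constant <- mean(vals)
  if (!is.finite(constant) || constant <= 0)
    stop("cortical ROI mean intensity must be positive (got ",
         signif(constant, 4), ")", call. = FALSE)
  ks <- as.integer(names(masks$white))
  slices <- lapply(ks, function(k) pet$data[, , k] / constant)
  names(slices) <- as.character(ks)
  list(constant = constant, slices = slices)
}

# pixels within `px` of `mask` (Euclidean, via the distance transform)
.dilate_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  full <- matrix(TRUE, nrow(mask), ncol(mask))
  d <- geodesic_distance(full, mask)
  d <= px
}

#' Grey-to-white uptake curve of one cortical ROI
#'
#' Computes the geodesic distance from the ROI grey matter within the domain
#' grey-plus-adjacent-white-matter, splits the distance range `[0, d_max]`
#' into `n_bins` equal-width bins, averages the normalized intensity per bin,
#' and returns the first `n_used` bin means. An empty interior bin is filled
#' by linear interpolation from its non-empty neighbours.
#'
#' @param norm_slice normalized 2D intensity matrix.
#' @param grey logical matrix, the ROI grey-matter seed.
#' @param white logical matrix, white matter on the same slice.
#' @param n_bins number of distance bins (15).
#' @param n_used number of leading bins kept (12).
#' @param dilate_px white matter is clipped to this dilation of the grey seed
#'   to keep the curve regional.
#' @param spacing pixel spacing passed to [geodesic_distance()].
#' @return numeric vector of `n_used` bin means, class `uptake_curve`, with
#'   attributes `d_max` and `n_bins`.
#' @export
uptake_curve <- function(norm_slice, grey, white, n_bins = 15, n_used = 12,
                         dilate_px = 20, spacing = c(1, 1)) {
  if (n_used > n_bins)
    stop("n_used must not exceed n_bins", call. = FALSE)
  if (!any(grey)) stop("grey seed mask is empty", call. = FALSE)
  domain <- grey | (white & .dilate_mask(grey, dilate_px))
  if (!any(domain & !grey))
    stop("no white matter adjacent to the ROI; uptake curve undefined",
         call. = FALSE)
  d <- geodesic_distance(domain, grey, spacing)
  ok <- is.finite(d) & domain
  d_max <- max(d[ok])
  if (d_max <= 0)
    stop("no reachable white matter in the ROI domain", call. = FALSE)
  width <- d_max / n_bins
  bin <- pmin(floor(d[ok] / width) + 1L, n_bins)
  vals <- norm_slice[ok]
  means <- vapply(seq_len(n_bins),
                  function(b) if (any(bin == b)) mean(vals[bin == b]) else NA_real_,
                  numeric(1))
  filled <- which(!is.na(means))
  if (length(filled) < 2)
    stop("fewer than 2 non-empty distance bins", call. = FALSE)
  if (anyNA(means))
    means <- approx(filled, means[filled], xout = seq_len(n_bins),
                    rule = 2)$y
  structure(means[seq_len(n_used)], class = "uptake_curve",
            d_max = d_max, n_bins = n_bins)
}

#' Striatal pixel-intensity feature in template space
#'
#' Samples the normalized S5 slice at the pixels of a fixed template striatal
#' mask, in row-major scan order, so that every subject yields a vector of
#' identical length. `registration = "identity"` assumes the subject is
#' already on the template grid (true for synthetic phantoms generated in
#' template space); `"affine"` estimates the translation component by
#' exhaustive integer-shift overlap maximisation between the subject's
#' striatal mask and the template mask before sampling.
#'
#' @param norm_s5 normalized 2D intensity matrix of the S5 slice.
#' @param subject_mask logical matrix, the subject's striatal (caudate and
#'   putamen) mask on S5.
#' @param template_mask logical matrix, the template striatal mask.
#' @param registration `"identity"` or `"affine"`.
#' @param max_shift search radius (pixels) for `"affine"`.
#' @return numeric vector of length `sum(template_mask)`.
#' @export
striatal_feature <- function(norm_s5, subject_mask, template_mask,
                             registration = c("identity", "affine"),
                             max_shift = 8) {
  registration <- match.arg(registration)
  if (!identical(dim(norm_s5), dim(template_mask)))
    stop("slice and template mask shapes differ", call. = FALSE)
  shift <- c(0L, 0L)
  if (registration == "affine") {
    shift <- .best_shift(subject_mask, template_mask, max_shift)
    norm_s5 <- .shift_matrix(norm_s5, shift)
  }
  ord <- .row_major_order(template_mask)
  v <- norm_s5[ord]
  if (any(!is.finite(v)))
    stop("registration moved template pixels outside the subject slice",
         call. = FALSE)
  structure(v, shift = shift)
}

.row_major_order <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  (idx[o, 2] - 1L) * nrow(mask) + idx[o, 1]
}

.best_shift <- function(subject_mask, template_mask, max_shift) {
  if (!any(subject_mask))
    stop("subject striatal mask is empty; registration failed", call. = FALSE)
  best <- c(0L, 0L); best_score <- -1L
  for (a in -max_shift:max_shift)
    for (b in -max_shift:max_shift) {
      score <- sum(.shift_matrix(subject_mask, c(a, b)) & template_mask,
                   na.rm = TRUE)
      if (score > best_score) { best_score <- score; best <- c(a, b) }
    }
  if (best_score <= 0)
    stop("striatal masks do not overlap within the search radius; ",
         "registration failed", call. = FALSE)
  best
}

# shift so that out[i, j] = m[i - shift[1], j - shift[2]]
.shift_matrix <- function(m, shift) {
  out <- matrix(if (is.logical(m)) FALSE else NA_real_, nrow(m), ncol(m))
  src_i <- seq_len(nrow(m)) - shift[1]
  src_j <- seq_len(ncol(m)) - shift[2]
  ok_i <- src_i >= 1 & src_i <= nrow(m)
  ok_j <- src_j >= 1 & src_j <= ncol(m)
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' Global cortical SUVr
#'
#' Mean PET intensity over the cortical composite (the union of the four
#' assessed cortical regions) divided by the mean over the whole cerebellum.
#'
#' @param pet a `pet_volume`.
#' @param labels a `label_volume`.
#' @return numeric scalar.
#' @export
global_suvr <- function(pet, labels) {
  .suvr(pet, labels, .cortical_region_names)
}

#' Striatal SUVr
#'
#' Mean PET intensity over caudate and putamen divided by the whole-cerebellum
#' mean.
#'
#' @inheritParams global_suvr
#' @return numeric scalar.
#' @export
striatal_suvr <- function(pet, labels) {
  .suvr(pet, labels, c("caudate", "putamen"))
}

.suvr <- function(pet, labels, target_regions) {
  target <- region_mask(labels, target_regions)
  ref <- region_mask(labels, "cerebellum")
  if (!any(target))
    stop("target region mask is empty", call. = FALSE)
  if (!any(ref))
    stop("cerebellum (reference region) absent from labels", call. = FALSE)
  ref_mean <- mean(pet$data[ref])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("cerebellar reference mean must be positive", call. = FALSE)
  mean(pet$data[target]) / ref_mean
}

#' Iterative-outlier positivity cutoff
#'
#' Repeatedly removes values above mean + 2 SD of the current set until none
#' remain, then returns mean + 2 SD of the surviving values: the conventional
#' cutoff for SUVr positivity derived from a normal reference group.
#'
#' @param values numeric vector, length >= 3.
#' @return numeric cutoff.
#' @export
iterative_outlier_cutoff <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3)
    stop("need at least 3 values for the iterative outlier cutoff",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  repeat {
    cut <- mean(values) + 2 * sd(values)
    keep <- values <= cut
    if (all(keep)) return(cut)
    values <- values[keep]
  }
}

#' @importFrom stats approx
NULL
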