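#' Extract all staging features for one subject
#'
#' Runs slice selection, per-subject normalization, the eight grey-to-white
#' uptake curves and the striatal template feature on a co-registered
#' label/PET pair.
#'
#' @param labels a `label_volume`.
#' @param pet the paired `pet_volume`.
#' @param template_mask logical matrix: the striatal template mask on the S5
#'   plane. Defaults to the subject's own striatal mask (appropriate when the
#'   data are already in template space).
#' @param registration passed to [striatal_feature()].
#' @param slices,masks optional precomputed [select_slices()] /
#'   [roi_masks()] results (reused across subjects sharing geometry).
#' @param n_bins,n_used,dilate_px uptake-curve parameters.
#' @return list with `curves` (8 x `n_used` matrix in the fixed ROI order),
#'   `striatal` (template feature vector), `norm_constant`, `slices` and
#'   `config`.
#' @export
subject_features <- function(labels, pet, template_mask = NULL,
                             registration = "identity",
                             slices = NULL, masks = NULL,
                             n_bins = 15, n_used = 12, dilate_px = 20) {
  if (!identical(dim(labels$data), dim(pet$data)))
    stop("label and PET grids differ", call. = FALSE)
  if (is.null(masks)) masks <- roi_masks(labels, slices)
  slices <- masks$slices
  norm <- normalize_pet_slices(pet, masks)
  spacing <- labels$voxel_size[1:2]

  curves <- matrix(NA_real_, 8, n_used,
                   dimnames = list(names(masks$cortical), NULL))
  for (i in seq_along(masks$cortical)) {
    r <- masks$cortical[[i]]
    curves[i, ] <- uptake_curve(norm$slices[[as.character(r$k)]],
                                grey = r$grey,
                                white = masks$white[[as.character(r$k)]],
                                n_bins = n_bins, n_used = n_used,
                                dilate_px = dilate_px, spacing = spacing)
  }

  subject_mask <- masks$striatal$left$mask | masks$striatal$right$mask
  if (is.null(template_mask)) template_mask <- subject_mask
  k5 <- slices$axial[["s5"]]
  stri <- striatal_feature(norm$slices[[as.character(k5)]], subject_mask,
                           template_mask, registration = registration)

  list(curves = curves, striatal = as.numeric(stri),
       norm_constant = norm$constant, slices = slices,
       config = list(n_bins = n_bins, n_used = n_used,
                     dilate_px = dilate_px,
                     template_pixels = sum(template_mask)))
}
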