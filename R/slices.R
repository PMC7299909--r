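#' @title Automatic axial slice selection
#'
#' @description
#' Emulates the slices a visual rater picks: the top slice at the superior tip
#' of the lateral ventricles (suited to the parietal cortex), the bottom slice
#' at the temporal-lobe centre of mass (lateral temporal cortex), two
#' interpolated slices in between (precuneus/posterior cingulate at one
#' quarter, frontal at one half), and a striatal slice at the centre of mass
#' of caudate plus putamen.
#'
#' Slice arithmetic uses a superior-to-inferior index `s = K - k + 1` (where
#' `k` indexes the stored array plane `data[,,k]` and `K` is the axial
#' extent), so that the top slice has the smaller number and the interpolation
#' formulas read in their natural form. Fractional slice numbers are rounded
#' half to even.
#'
#' @name slice_selection
NULL

.si_index <- function(k, K) K - k + 1          # array plane -> superior index
.axial_index <- function(s, K) K - s + 1       # superior index -> array plane

.region_slice_profile <- function(labels, region) {
  mask <- region_mask(labels, region)
  counts <- apply(mask, 3, sum)
  counts
}

#' Top assessment slice (superior tip of the lateral ventricles)
#'
#' @param labels a `label_volume`.
#' @return superior-to-inferior slice index `SN_top`.
#' @export
find_top_slice <- function(labels) {
  counts <- .region_slice_profile(labels, "lateral_ventricle")
  if (!any(counts > 0))
    stop("no lateral-ventricle voxels in label volume", call. = FALSE)
  K <- dim(labels$data)[3]
  .si_index(max(which(counts > 0)), K)
}

#' Bottom assessment slice (temporal-lobe centre of mass)
#'
#' The unweighted voxel centre of mass of the union of the nine temporal
#' parcels, rounded half to even to the nearest slice.
#'
#' @param labels a `label_volume`.
#' @return superior-to-inferior slice index `SN_bottom`.
#' @export
find_bottom_slice <- function(labels) {
  counts <- .region_slice_profile(labels, .temporal_parcel_names)
  if (!any(counts > 0))
    stop("no temporal-parcel voxels in label volume", call. = FALSE)
  K <- dim(labels$data)[3]
  s <- .si_index(seq_len(K), K)
  round(sum(s * counts) / sum(counts))
}

#' Select the five assessment slices
#'
#' `s1 = SN_top`, `s2 = SN_top + 0.25 (SN_bottom - SN_top)`,
#' `s3 = SN_top + 0.5 (SN_bottom - SN_top)`, `s4 = SN_bottom`, and `s5` at the
#' centre of mass of the caudate and putamen, all rounded half to even.
#'
#' @param labels a `label_volume`.
#' @return a `slice_set`: list with `sn_top`, `sn_bottom`, `s1`..`s5`
#'   (superior-to-inferior indices) and `axial` (the corresponding array plane
#'   indices `data[,,k]`).
#' @export
select_slices <- function(labels) {
  sn_top <- find_top_slice(labels)
  sn_bottom <- find_bottom_slice(labels)
  if (sn_bottom <= sn_top)
    stop("temporal centre of mass (", sn_bottom,
         ") not inferior to ventricle top (", sn_top, ")", call. = FALSE)
  counts <- .region_slice_profile(labels, c("caudate", "putamen"))
  if (!any(counts > 0))
    stop("no striatal (caudate/putamen) voxels in label volume",
         call. = FALSE)
  K <- dim(labels$data)[3]
  si <- .si_index(seq_len(K), K)
  s5 <- round(sum(si * counts) / sum(counts))

  s1 <- sn_top
  s2 <- round(sn_top + 0.25 * (sn_bottom - sn_top))
  s3 <- round(sn_top + 0.50 * (sn_bottom - sn_top))
  s4 <- sn_bottom
  if (s2 == s1 || s3 == s4 || s2 == s3)
    warning("interpolated slices coincide (small superior-inferior extent)",
            call. = FALSE)
  s <- c(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5)
  if (any(s < 1 | s > K))
    stop("selected slice outside volume bounds", call. = FALSE)
  structure(
    list(sn_top = sn_top, sn_bottom = sn_bottom,
         s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5,
         axial = setNames(.axial_index(s, K), names(s)),
         n_slices = K),
    class = "slice_set"
  )
}

#' @export
print.slice_set <- function(x, ...) {
  cat("<slice_set> SN_top=", x$sn_top, " SN_bottom=", x$sn_bottom,
      "  S1..S5 = ", paste(c(x$s1, x$s2, x$s3, x$s4, x$s5), collapse = ", "),
      " (superior-to-inferior)\n", sep = "")
  invisible(x)
}

#' @export
format.slice_set <- function(x, ...) {
  jsonlite::toJSON(x[c("sn_top", "sn_bottom", "s1", "s2", "s3", "s4", "s5")],
                   auto_unbox = TRUE)
}
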