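#' @title Volume containers and NIfTI input/output
#'
#' @description
#' All geometry in the package is anchored on a `label_volume`: a 3D integer
#' parcellation (FreeSurfer-style aparc+aseg labelling or the synthetic
#' phantom's own labels) together with a `label_map` that names the label sets
#' the staging pipeline needs. The paired `pet_volume` holds tracer uptake on
#' the identical voxel grid. The canonical orientation places axis 3
#' inferior-to-superior, so that the most superior axial plane is
#' `data[,,dim(data)[3]]`.
#'
#' @name volumes
NULL

# temporal-lobe parcels whose voxel centre of mass anchors the bottom slice
.temporal_parcel_names <- c(
  "inferior_temporal", "middle_temporal", "superior_temporal",
  "temporal_pole", "transverse_temporal", "bankssts",
  "fusiform", "entorhinal", "parahippocampal"
)

# the four visually assessed cortical regions, in slice order S1..S4
.cortical_region_names <- c("parietal", "precuneus_pcc", "frontal",
                            "lateral_temporal")

.required_regions <- c(
  "lateral_ventricle", .temporal_parcel_names, .cortical_region_names,
  "caudate", "putamen", "cerebellum", "cerebral_white_matter", "grey_matter"
)

#' Construct a label volume
#'
#' @param data 3D integer array of parcellation labels, axis 3 running
#'   inferior to superior.
#' @param label_map named list mapping region names to integer label sets.
#'   Must cover all regions in `required_regions()`.
#' @param voxel_size numeric length 3, mm per axis.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, label_map, voxel_size = c(1, 1, 1)) {
  data <- .as_volume_array(data)
  if (any(dim(data) < 16L))
    stop("label volume must be at least 16 voxels along every axis",
         call. = FALSE)
  validate_label_map(label_map)
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE))
    stop("label volume contains negative labels", call. = FALSE)
  structure(
    list(data = data, label_map = label_map,
         voxel_size = as.numeric(voxel_size)),
    class = "label_volume"
  )
}

#' Construct a PET volume
#'
#' @param data 3D numeric array of tracer uptake (arbitrary units).
#' @param voxel_size numeric length 3, mm per axis.
#' @return object of class `pet_volume`.
#' @export
pet_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- .as_volume_array(data)
  if (!all(is.finite(data)))
    stop("PET volume contains non-finite values", call. = FALSE)
  if (all(data == 0))
    stop("PET volume is identically zero", call. = FALSE)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size)),
    class = "pet_volume"
  )
}

.as_volume_array <- function(data) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  data
}

#' Region names every label map must define
#' @return character vector of required region names.
#' @export
required_regions <- function() .required_regions

#' Validate a label map
#'
#' Checks that every required region is present and maps to non-negative
#' integer labels, and that `lateral_ventricle` is non-empty.
#'
#' @param label_map named list of integer vectors.
#' @return the label map, invisibly, with labels coerced to integer.
#' @export
validate_label_map <- function(label_map) {
  if (!is.list(label_map) || is.null(names(label_map)))
    stop("label_map must be a named list", call. = FALSE)
  missing <- setdiff(.required_regions, names(label_map))
  if (length(missing))
    stop("label_map is missing required regions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in names(label_map)) {
    v <- label_map[[nm]]
    if (length(v) == 0 && nm == "lateral_ventricle")
      stop("label_map entry 'lateral_ventricle' is empty", call. = FALSE)
    if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v != round(v))))
      stop("label_map entry '", nm, "' must hold non-negative integers",
           call. = FALSE)
  }
  invisible(lapply(label_map, function(v) as.integer(v)))
}

#' Default FreeSurfer aparc+aseg label map
#'
#' Lobar composites follow the standard Desikan-Killiany groupings (the
#' temporal parcels are listed individually because the bottom-slice anchor
#' uses their union). Users working with other parcellations can supply their
#' own map as a JSON file of the same shape.
#'
#' @param path optional path to a JSON label-map file overriding the default.
#' @return named list of integer label vectors.
#' @export
default_label_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "freesurfer_label_map.json",
                        package = "amystage", mustWork = TRUE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lapply(m, as.integer)
  validate_label_map(m)
  m
}

#' Read a co-registered label/PET volume pair
#'
#' Both images are reoriented to the canonical RAS-like axis order (axis 3
#' inferior to superior) when orientation metadata is present; grids must then
#' match voxel-for-voxel. Registration itself is accepted as input, not
#' performed.
#'
#' @param label_path path to the parcellation NIfTI.
#' @param pet_path path to the PET NIfTI.
#' @param label_map named list of integer label sets (see
#'   [default_label_map()]).
#' @return list with elements `labels` (a `label_volume`) and `pet`
#'   (a `pet_volume`).
#' @export
read_volume_pair <- function(label_path, pet_path,
                             label_map = default_label_map()) {
  lab_img <- .read_canonical(label_path)
  pet_img <- .read_canonical(pet_path)
  if (!identical(dim(lab_img$data)[1:3], dim(pet_img$data)[1:3]))
    stop("label grid ", paste(dim(lab_img$data), collapse = "x"),
         " does not match PET grid ",
         paste(dim(pet_img$data), collapse = "x"), call. = FALSE)
  labels <- label_volume(round(lab_img$data), label_map,
                         voxel_size = lab_img$voxel_size)
  known <- sort(unique(as.integer(unlist(label_map))))
  present <- unique(as.vector(labels$data))
  if (!any(present %in% known))
    stop("no label in the volume matches the supplied label_map",
         call. = FALSE)
  list(labels = labels,
       pet = pet_volume(pet_img$data, voxel_size = pet_img$voxel_size))
}

.read_canonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  ornt <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ornt) && nzchar(ornt) && !identical(ornt, "RAS"))
    RNifti::orientation(img) <- "RAS"
  voxdim <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) > 3) arr <- arr[, , , 1, drop = TRUE]
  list(data = arr, voxel_size = as.numeric(voxdim[1:3]))
}

#' Write a label/PET volume pair as NIfTI
#'
#' @param labels a `label_volume`.
#' @param pet a `pet_volume`.
#' @param label_path,pet_path output paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_volume_pair <- function(labels, pet, label_path, pet_path) {
  stopifnot(inherits(labels, "label_volume"), inherits(pet, "pet_volume"))
  lab_arr <- structure(labels$data, pixdim = labels$voxel_size)
  RNifti::writeNifti(RNifti::asNifti(lab_arr, datatype = "int32"),
                     label_path)
  pet_arr <- structure(pet$data, pixdim = pet$voxel_size)
  RNifti::writeNifti(RNifti::asNifti(pet_arr, datatype = "float"),
                     pet_path)
  invisible(c(label_path, pet_path))
}

#' Binary mask of a named region
#'
#' @param labels a `label_volume`.
#' @param region region name present in the label map, or a character vector
#'   of names (the union is returned).
#' @return logical array of the same shape.
#' @export
region_mask <- function(labels, region) {
  stopifnot(inherits(labels, "label_volume"))
  unknown <- setdiff(region, names(labels$label_map))
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ids <- unique(as.integer(unlist(labels$label_map[region])))
  array(labels$data %in% ids, dim = dim(labels$data))
}

# hemisphere masks by midline split on axis 1 (left = lower x)
.hemi_mask <- function(dims, hemisphere) {
  mid <- dims[1] / 2
  x <- slice.index(array(0, dims), 1)
  if (hemisphere == "left") x <= mid else x > mid
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", length(x$label_map), " mapped regions\n", sep = "")
  invisible(x)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, intensity range [",
      signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}
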