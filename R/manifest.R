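#' @title Subject manifests and visual-assessment scoring rules
#'
#' @description
#' A subject manifest is a TSV with one row per scan: the eight regional
#' cortical tracer uptake (RCTU) visual scores (1 = no binding, 2 = minor,
#' 3 = pronounced) for frontal, precuneus/posterior-cingulate, lateral
#' temporal and parietal cortex in each hemisphere (left column first),
#' a binary striatal positivity read, and optional clinical/structural
#' outcome and covariate columns. The scan-level BAPL grade and the amyloid
#' stage are derived from these scores when not supplied.
#'
#' @name manifest
NULL

# fixed ROI ordering shared by manifests, features and pRCTU vectors:
# region-major, left hemisphere first
.roi_table <- function() {
  regions <- c("frontal", "precuneus_pcc", "lateral_temporal", "parietal")
  slice_of <- c(frontal = "s3", precuneus_pcc = "s2",
                lateral_temporal = "s4", parietal = "s1")
  data.frame(
    region = rep(regions, each = 2),
    hemisphere = rep(c("left", "right"), times = 4),
    slice = slice_of[rep(regions, each = 2)],
    stringsAsFactors = FALSE,
    row.names = paste0(rep(regions, each = 2), "_",
                       rep(c("lh", "rh"), times = 4))
  )
}

#' Canonical RCTU column names
#' @return character vector of the 8 manifest RCTU column names, in the fixed
#'   ROI order used throughout the package.
#' @export
rctu_columns <- function() paste0("rctu_", rownames(.roi_table()))

.covariate_columns <- c("age", "sex", "education", "icv")

#' Condense regional RCTU scores to the scan-level BAPL grade
#'
#' BAPL (brain amyloid-beta plaque load) is 3 if any region scores 3,
#' otherwise 2 if any region scores 2, otherwise 1. A scan is
#' amyloid-positive when BAPL is 2 or 3.
#'
#' @param rctu integer vector (any length >= 1) of RCTU scores in `{1,2,3}`.
#' @return integer BAPL grade in `{1,2,3}`.
#' @export
bapl_from_rctu <- function(rctu) {
  rctu <- as.numeric(rctu)
  if (length(rctu) == 0 || any(!rctu %in% c(1, 2, 3)))
    stop("RCTU scores must all lie in {1, 2, 3}", call. = FALSE)
  as.integer(max(rctu))
}

.stage_from_va <- function(rctu_mat, striatal_va) {
  positive <- apply(rctu_mat, 1, function(r) bapl_from_rctu(r) >= 2)
  ifelse(!positive, 0L, ifelse(striatal_va == 1, 2L, 1L))
}

#' Read and validate a subject manifest
#'
#' @param tsv_path path to a tab-separated manifest with header. Required
#'   columns: `subject_id`, the eight [rctu_columns()], and `striatal_va`.
#'   `stage_va` is derived from the BAPL rule and `striatal_va` when absent.
#'   Columns `age`, `sex`, `education`, `icv` are treated as covariates; any
#'   other numeric column is an outcome. Missing outcome values stay `NA`
#'   (models delete listwise).
#' @return validated manifest `data.frame` of class `subject_manifest`.
#' @export
read_manifest <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("file not found: ", tsv_path, call. = FALSE)
  df <- read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_manifest(df)
}

#' Validate an in-memory manifest
#'
#' @param df data.frame with the manifest columns (see [read_manifest()]).
#' @return the manifest with `stage_va` present, class `subject_manifest`.
#' @export
validate_manifest <- function(df) {
  req <- c("subject_id", rctu_columns(), "striatal_va")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  rctu <- as.matrix(df[, rctu_columns()])
  if (any(!rctu %in% c(1, 2, 3)))
    stop("RCTU scores must lie in {1, 2, 3}", call. = FALSE)
  if (any(!df$striatal_va %in% c(0, 1)))
    stop("striatal_va must be 0 or 1", call. = FALSE)
  derived <- .stage_from_va(rctu, df$striatal_va)
  if (is.null(df$stage_va)) {
    df$stage_va <- derived
  } else {
    if (any(!df$stage_va %in% 0:2))
      stop("stage_va must lie in {0, 1, 2}", call. = FALSE)
    bad <- which((df$stage_va == 0) != (derived == 0) |
                   (df$stage_va == 2 & df$striatal_va != 1))
    if (length(bad))
      stop("stage_va inconsistent with RCTU/striatal scores for subject(s): ",
           paste(df$subject_id[bad], collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(req, "stage_va"))
  for (cl in extra) {
    v <- df[[cl]]
    if (is.numeric(v) && any(is.infinite(v)))
      stop("column '", cl, "' contains non-finite values", call. = FALSE)
  }
  class(df) <- c("subject_manifest", "data.frame")
  df
}

#' Write a manifest TSV
#' @param manifest a manifest data.frame.
#' @param tsv_path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, tsv_path) {
  write.table(manifest, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tsv_path)
}

#' Extract the n x 8 RCTU score matrix from a manifest
#' @param manifest a validated manifest.
#' @return integer matrix, rows = subjects, columns in the fixed ROI order.
#' @export
rctu_matrix <- function(manifest) {
  m <- as.matrix(manifest[, rctu_columns()])
  storage.mode(m) <- "integer"
  rownames(m) <- manifest$subject_id
  colnames(m) <- rownames(.roi_table())
  m
}

#' Names of outcome columns present in a manifest
#' @param manifest a validated manifest.
#' @return character vector (possibly empty).
#' @export
outcome_columns <- function(manifest) {
  reserved <- c("subject_id", rctu_columns(), "striatal_va", "stage_va",
                .covariate_columns, "cn", "global_suvr", "striatal_suvr")
  nm <- setdiff(names(manifest), reserved)
  nm[vapply(manifest[nm], is.numeric, logical(1))]
}
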