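#' Write an image to NIfTI
#'
#' Stores the image as a float32 NIfTI volume with the voxel spacing in the
#' header (`pixdim`). A 2-D image is stored as a single-slice volume.
#'
#' @param u an [image_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_image_nifti <- function(u, path) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  arr <- array(u$values, dim = c(dim(u$values), 1L))
  attr(arr, "pixdim") <- c(u$spacing_mm[1], u$spacing_mm[2], 1)
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image from NIfTI
#'
#' @param path NIfTI file written by [write_image_nifti()] (or any
#'   single-slice volume).
#' @return an [image_grid] with the spacing taken from the header.
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 3L) {
    if (d[3] != 1L) stop("expected a single-slice volume", call. = FALSE)
    arr <- arr[, , 1L]
  } else if (length(d) != 2L) {
    stop("expected a 2-D image or single-slice volume", call. = FALSE)
  }
  # header pixdim is float32 (~7 significant digits); round so metric voxel
  # sizes such as 1.2 mm survive the round trip exactly
  sp <- signif(RNifti::pixdim(img)[1:2], 6)
  image_grid(matrix(as.numeric(arr), nrow(arr), ncol(arr)), sp)
}

#' Write a label map to NIfTI plus a JSON legend
#'
#' The integer labels go into `<path>` (int16 NIfTI) and the legend into
#' `<path>.legend.json`.
#'
#' @param rois a [roi_label_map].
#' @param path output NIfTI path.
#' @return the path, invisibly.
#' @export
write_rois_nifti <- function(rois, path) {
  arr <- array(rois$labels, dim = c(dim(rois$labels), 1L))
  attr(arr, "pixdim") <- c(rois$spacing_mm[1], rois$spacing_mm[2], 1)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(rois$legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by [write_rois_nifti()]
#'
#' @param path NIfTI path (the legend is read from `<path>.legend.json`).
#' @return a [roi_label_map].
#' @export
read_rois_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  sp <- signif(RNifti::pixdim(img)[1:2], 6)
  legend_list <- jsonlite::read_json(paste0(path, ".legend.json"))
  legend <- vapply(legend_list, as.integer, integer(1))
  roi_label_map(matrix(as.integer(round(arr)), nrow(arr), ncol(arr)), legend, sp)
}

#' Write a sinogram (gzipped CSV + JSON sidecar)
#'
#' The count matrix goes into `<path>` as a headerless gzipped CSV (one row
#' per projection angle), and the geometry and dose fraction into
#' `<path>.json`.
#'
#' @param s a [sinogram].
#' @param path output path (conventionally `.csv.gz`).
#' @param model optional [system_model] whose geometry is recorded in the
#'   sidecar.
#' @return the path, invisibly.
#' @export
write_sinogram <- function(s, path, model = NULL) {
  con <- gzfile(path, "w")
  utils::write.table(s$values, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  meta <- list(n_angles = nrow(s$values), n_radial_bins = ncol(s$values),
               dose_fraction = s$dose_fraction)
  if (!is.null(model)) {
    meta$bin_spacing_mm <- model$bin_spacing_mm
    meta$psf_fwhm_mm <- model$psf_fwhm_mm
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path path passed to [write_sinogram()].
#' @return a [sinogram].
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vals <- as.matrix(utils::read.table(gzfile(path), sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  sinogram(vals, dose_fraction = meta$dose_fraction)
}
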