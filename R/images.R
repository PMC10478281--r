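# HU image container and file I/O.

#' Hounsfield-unit image
#'
#' Lightweight container for a single 2-D slice in Hounsfield units with its
#' in-plane pixel spacing. Most functions in the package also accept a plain
#' matrix, in which case the default spacing of 0.977 mm (a typical planning
#' CT in-plane resolution) is assumed.
#'
#' @param values numeric matrix of HU values
#' @param spacing length-2 positive numeric, pixel size in mm (row, col)
#' @return an object of class `"hu_image"`
#' @export
hu_image <- function(values, spacing = c(0.977, 0.977)) {
  if (is.array(values) && length(dim(values)) == 3L && dim(values)[3] == 1L)
    values <- values[, , 1L]
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive numbers (mm)")
  structure(list(values = values, spacing = spacing), class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image> %d x %d, spacing %.3f x %.3f mm, HU range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.hu_image <- function(x) dim(x$values)

#' @export
as.matrix.hu_image <- function(x, ...) x$values

image_values <- function(x) {
  if (inherits(x, "hu_image")) x$values
  else if (inherits(x, "normalized_image")) x$values
  else if (is.matrix(x)) x
  else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L) x[, , 1L]
  else stop("expected an hu_image, normalized_image or matrix")
}

image_like <- function(values, template) {
  if (inherits(template, "hu_image")) hu_image(values, template$spacing)
  else if (inherits(template, "normalized_image"))
    normalized_image(values, template$window)
  else if (is.matrix(template)) values
  else array(values, dim(template))
}

#' Read a 2-D image from disk
#'
#' Supports single-slice NIfTI (`.nii`, `.nii.gz`) and plain CSV matrices
#' (`.csv`; no header). NIfTI pixel dimensions populate the spacing; CSV
#' files get the default spacing.
#'
#' @param path file path
#' @return an [hu_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    v <- as.array(img)
    if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1L]
    if (!is.matrix(v)) v <- matrix(v, dim(v)[1], dim(v)[2])
    sp <- RNifti::pixdim(img)[1:2]
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(0.977, 0.977)
    hu_image(v, sp)
  } else if (ext == "csv") {
    v <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(v) <- NULL
    storage.mode(v) <- "double"
    hu_image(v)
  } else {
    stop("unsupported image format '.", ext,
         "': supported formats are .nii, .nii.gz and .csv")
  }
}

#' Write a 2-D image to disk
#'
#' @param image an [hu_image()] or numeric matrix
#' @param path destination path; format chosen from the extension
#'   (`.nii`/`.nii.gz`/`.csv`)
#' @return invisibly, the path
#' @export
write_image <- function(image, path) {
  v <- image_values(image)
  sp <- if (inherits(image, "hu_image")) image$spacing else c(0.977, 0.977)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    arr <- array(v, c(dim(v), 1L))
    nim <- RNifti::asNifti(arr, reference = list(
      pixdim = c(-1, sp[1], sp[2], 1, 0, 0, 0, 0)))
    RNifti::writeNifti(nim, path)
  } else if (ext == "csv") {
    utils::write.table(v, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported image format '.", ext,
         "': supported formats are .nii, .nii.gz and .csv")
  }
  invisible(path)
}

#' Write a displacement field to disk as a 2-volume NIfTI
#' @param field an (H, W, 2) array ([deformation_field()])
#' @param path destination `.nii`/`.nii.gz` path
#' @return invisibly, the path
#' @export
write_field <- function(field, path) {
  stopifnot(length(dim(field)) == 3L, dim(field)[3] == 2L)
  RNifti::writeNifti(RNifti::asNifti(unclass(field)), path)
  invisible(path)
}

#' Read a displacement field written by [write_field()]
#' @param path `.nii`/`.nii.gz` path
#' @return an (H, W, 2) [deformation_field()] array
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  v <- as.array(RNifti::readNifti(path))
  deformation_field(v)
}
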