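#' 3D scalar volume with grid geometry
#'
#' A `b0_volume` bundles a 3D array of intensities with its voxel size (mm)
#' and the 4x4 grid-to-world affine.  The world frame is RAS
#' (right-anterior-superior), grid indices are 0-based in the affine
#' convention (voxel centers sit at integer indices), matching NIfTI.
#' All data are stored as double but written to disk as float32.
#'
#' @param data 3D numeric array, all values finite, each dim >= 8.
#' @param voxel_size numeric length-3, strictly positive, mm per axis.
#' @param affine 4x4 invertible grid-to-world matrix; if `NULL`, an axis
#'   aligned RAS affine is built from `voxel_size` with the volume center at
#'   the world origin.
#' @return An object of class `b0_volume` with elements `data`, `voxel_size`,
#'   `affine`.
#' @export
b0_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 8L))
    stop("volume dims must all be >= 8, got ", paste(dim(data), collapse = "x"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive numbers")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dim(data) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "b0_volume")
}

#' @export
print.b0_volume <- function(x, ...) {
  cat(sprintf("<b0_volume %s, voxel %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.b0_volume <- function(x) dim(x$data)

#' Test whether two volumes share grid shape and affine
#' @param a,b `b0_volume` objects.
#' @param tol tolerance on affine entries.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-5) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " must share grid shape and affine")
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii` / `.nii.gz` file; intensities are rescaled by the header's
#' scl_slope / scl_inter (done by RNifti) and nothing else.  Only 3D images
#' are accepted.
#'
#' @param path path to an existing NIfTI-1 file.
#' @return A [b0_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
    dat <- img2
  } else if (length(d) != 3L) {
    stop("expected 3D volume in ", path, ", got ", length(d), "D")
  } else {
    dat <- array(as.numeric(img), d)
  }
  if (any(!is.finite(dat)))
    stop("volume contains non-finite voxels: ", path)
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  vox <- RNifti::pixdim(img)[1:3]
  b0_volume(dat, voxel_size = abs(vox), affine = aff)
}

#' Write a volume as float32 NIfTI
#'
#' @param vol a [b0_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "b0_volume"))
  arr <- vol$data
  attr(arr, "pixdim") <- vol$voxel_size
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
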