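#' 3D volumes with voxel spacing
#'
#' A `volume3d` is a plain 3D numeric array carrying a `voxel_mm` attribute
#' (spacing along each axis, in mm).  All pipeline stages consume and return
#' this type; NIfTI-1 files are read and written through the RNifti package.
#'
#' @param data 3D numeric array.
#' @param voxel_mm Numeric length-3 voxel spacing in mm (scalar recycled).
#' @return A `volume3d` object.
#' @export
vol3d <- function(data, voxel_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(data, voxel_mm = as.numeric(voxel_mm), class = c("volume3d", "array"))
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s, voxel %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x), collapse = "x"),
              paste(signif(attr(x, "voxel_mm"), 3), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' @rdname vol3d
#' @param vol A `volume3d`.
#' @export
voxel_mm <- function(vol) attr(vol, "voxel_mm") %||% c(1, 1, 1)

# strip class/attrs down to a bare array (for C++ kernels)
bare_array <- function(vol) {
  a <- unclass(vol)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Read / write volumes as NIfTI-1
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `volume3d`; `write_volume` returns `path`
#'   invisibly.
#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @param vol A `volume3d`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(bare_array(vol))
  RNifti::pixdim(img) <- voxel_mm(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# mean-pool downsample by 2 along every axis (trailing odd slice dropped);
# used for the multi-resolution registration pyramid
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2L
  stopifnot(all(d >= 1L))
  a <- bare_array(vol)[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3]),
                       drop = FALSE]
  i1 <- seq(1, 2 * d[1], 2); i2 <- seq(1, 2 * d[2], 2); i3 <- seq(1, 2 * d[3], 2)
  out <- (a[i1, i2, i3, drop = FALSE] + a[i1 + 1, i2, i3, drop = FALSE] +
          a[i1, i2 + 1, i3, drop = FALSE] + a[i1 + 1, i2 + 1, i3, drop = FALSE] +
          a[i1, i2, i3 + 1, drop = FALSE] + a[i1 + 1, i2, i3 + 1, drop = FALSE] +
          a[i1, i2 + 1, i3 + 1, drop = FALSE] +
          a[i1 + 1, i2 + 1, i3 + 1, drop = FALSE]) / 8
  vol3d(out, voxel_mm(vol) * 2)
}
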