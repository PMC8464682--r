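#' Construct a voxel volume
#'
#' A voxel volume is a plain 3D integer array in `(z, y, x)` axis order with
#' a `spacing` attribute giving millimetres per voxel along each axis.
#' Intensities are 16-bit unsigned gray levels (0..65535); no gray-level
#' rebinning is ever applied downstream, so the stored values are the values
#' the texture features see.
#'
#' @param intensities 3D numeric/integer array, values in `[0, 65535]`.
#' @param spacing Numeric length-3, mm per voxel along `(z, y, x)`.
#' @return The array with class `voxel_volume` and a `spacing` attribute.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(intensities)) == 3, length(spacing) == 3, all(spacing > 0))
  if (any(intensities < 0 | intensities > 65535)) {
    stop("intensities must lie in the 16-bit range [0, 65535]")
  }
  v <- array(as.integer(round(intensities)), dim = dim(intensities))
  attr(v, "spacing") <- as.numeric(spacing)
  class(v) <- c("voxel_volume", class(v))
  v
}

#' Construct an ROI mask
#'
#' A binary mask congruent with a [voxel_volume()] grid: a 3D logical array
#' in `(z, y, x)` order marking the segmented edema voxels.
#'
#' @param voxels 3D logical (or coercible) array.
#' @return Logical array with class `roi_mask`.
#' @export
roi_mask <- function(voxels) {
  stopifnot(length(dim(voxels)) == 3)
  m <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(m)) stop("mask may not contain NA")
  class(m) <- c("roi_mask", class(m))
  m
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_volume %dx%dx%d (z,y,x), spacing %s mm, range [%d, %d]>\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<roi_mask %dx%dx%d (z,y,x), %d voxels set>\n",
              d[1], d[2], d[3], sum(x)))
  invisible(x)
}

check_volume_mask <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) {
    stop(sprintf("volume grid %s and mask grid %s do not match",
                 paste(dim(volume), collapse = "x"),
                 paste(dim(mask), collapse = "x")))
  }
  invisible(TRUE)
}

#' Voxel coordinates of the set voxels of a mask
#'
#' @param mask Logical 3D array.
#' @return Integer matrix with columns `z, y, x` (0-based indices).
#' @keywords internal
mask_coords <- function(mask) {
  w <- which(mask)
  d <- dim(mask)
  k0 <- w - 1L
  z <- k0 %% d[1]
  y <- (k0 %/% d[1]) %% d[2]
  x <- k0 %/% (d[1] * d[2])
  cbind(z = z, y = y, x = x)
}
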