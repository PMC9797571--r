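#' @useDynLib toothcrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile median cov
#' @importFrom utils read.csv write.csv head
NULL

# Label codes are fixed package-wide and persisted as unsigned 8-bit.
LABEL_AIR    <- 0L
LABEL_ENAMEL <- 1L
LABEL_DENTIN <- 2L
LABEL_CRACK  <- 3L

#' Label codes used throughout the package
#'
#' Voxel classes are coded as integers: 0 = air (including the pulp cavity),
#' 1 = enamel, 2 = dentin, 3 = crack.
#'
#' @return Named integer vector of the four codes.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(air = LABEL_AIR, enamel = LABEL_ENAMEL, dentin = LABEL_DENTIN,
    crack = LABEL_CRACK)
}

#' Construct a greyscale attenuation volume
#'
#' A `grey_volume` is a rank-3 numeric array of non-negative attenuation
#' values in the unsigned 16-bit range, together with an isotropic voxel
#' pitch in micrometres. The axis order is fixed as `(z, y, x)` with `z`
#' the vertical tooth axis; all readers, writers and algorithms in the
#' package preserve this convention.
#'
#' @param data Rank-3 numeric array, values in `[0, 65535]`.
#' @param voxel_pitch_um Positive scalar, isotropic voxel edge in micrometres.
#' @return An object of class `grey_volume` (the array with attributes).
#' @export
#' @examples
#' v <- grey_volume(array(0, c(4, 4, 4)), voxel_pitch_um = 5)
#' dim(v)
grey_volume <- function(data, voxel_pitch_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("grey_volume: `data` must be a rank-3 array")
  if (!is.numeric(data))
    stop("grey_volume: `data` must be numeric")
  if (anyNA(data) || min(data) < 0 || max(data) > 65535)
    stop("grey_volume: values must lie in [0, 65535] with no NA")
  if (!is.numeric(voxel_pitch_um) || length(voxel_pitch_um) != 1L ||
      !is.finite(voxel_pitch_um) || voxel_pitch_um <= 0)
    stop("grey_volume: `voxel_pitch_um` must be a positive scalar")
  structure(data, voxel_pitch_um = as.numeric(voxel_pitch_um),
            class = c("grey_volume", "array"))
}

#' Construct a label volume
#'
#' A `label_volume` is a rank-3 integer array over the four voxel classes
#' (see [label_codes()]), sharing shape and pitch with its source greyscale
#' volume.
#'
#' @param data Rank-3 array of integer codes in `{0, 1, 2, 3}`.
#' @param voxel_pitch_um Positive scalar voxel pitch in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_pitch_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label_volume: `data` must be a rank-3 array")
  d <- as.integer(data)
  if (anyNA(d) || any(d < 0L | d > 3L))
    stop("label_volume: codes must lie in {0, 1, 2, 3}")
  if (!is.numeric(voxel_pitch_um) || length(voxel_pitch_um) != 1L ||
      !is.finite(voxel_pitch_um) || voxel_pitch_um <= 0)
    stop("label_volume: `voxel_pitch_um` must be a positive scalar")
  out <- array(d, dim(data))
  structure(out, voxel_pitch_um = as.numeric(voxel_pitch_um),
            class = c("label_volume", "array"))
}

#' Voxel pitch of a volume
#' @param x A `grey_volume` or `label_volume`.
#' @return Voxel pitch in micrometres.
#' @export
voxel_pitch <- function(x) {
  p <- attr(x, "voxel_pitch_um")
  if (is.null(p)) stop("object carries no voxel pitch")
  p
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<grey_volume> %d x %d x %d (z,y,x), pitch %.3g um, range [%g, %g]\n",
              d[1], d[2], d[3], voxel_pitch(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cts <- tabulate(as.integer(x) + 1L, nbins = 4L)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), pitch %.3g um\n",
              d[1], d[2], d[3], voxel_pitch(x)))
  cat(sprintf("  air %d | enamel %d | dentin %d | crack %d\n",
              cts[1], cts[2], cts[3], cts[4]))
  invisible(x)
}

#' Binary tooth mask from a label volume
#'
#' The tooth is defined as hard tissue plus cracks (enamel, dentin, crack);
#' air and the pulp cavity are excluded. This is the denominator used by
#' [volume_fraction()] and the domain of the slab/sector partitions.
#'
#' @param labels A `label_volume`.
#' @return Logical rank-3 array.
#' @export
tooth_mask <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  m <- array(as.integer(labels) != LABEL_AIR, dim(labels))
  m
}

# internal: strip class/attrs to a plain array
as_plain_array <- function(x) {
  array(as.vector(unclass(x)), dim(x))
}
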