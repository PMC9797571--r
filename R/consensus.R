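# Three-axis consensus. The same volume is segmented slice-by-slice three
# times (slices perpendicular to x, y and z); a voxel is crack when at
# least two of the three axis labellings say crack, remaining voxels take
# the majority non-crack code, and a slice-by-slice fill-in reconstructs
# the tooth as if it had no cracks.

check_three <- function(labels_x, labels_y, labels_z) {
  stopifnot(inherits(labels_x, "label_volume"),
            inherits(labels_y, "label_volume"),
            inherits(labels_z, "label_volume"))
  if (!all(dim(labels_x) == dim(labels_y)) ||
      !all(dim(labels_x) == dim(labels_z)))
    stop("axis label volumes differ in shape")
}

#' Two-of-three crack vote across axis segmentations
#'
#' A voxel is identified as crack if it was classified as crack in at least
#' two of the three slicing planes.
#'
#' @param labels_x,labels_y,labels_z [label_volume()]s from [segment_axis()]
#'   along x, y and z.
#' @return Logical rank-3 crack mask.
#' @export
vote_crack <- function(labels_x, labels_y, labels_z) {
  check_three(labels_x, labels_y, labels_z)
  votes <- (as.integer(labels_x) == LABEL_CRACK) +
    (as.integer(labels_y) == LABEL_CRACK) +
    (as.integer(labels_z) == LABEL_CRACK)
  array(votes >= 2L, dim(labels_x))
}

#' Resolve non-crack voxels by majority over the axis labels
#'
#' Crack-mask voxels take the crack code. Elsewhere crack votes are
#' discarded and the majority of the remaining axis codes wins; ties (and
#' voxels where every vote was a minority crack call) are broken by the
#' z-axis label, then y, then x.
#'
#' @param labels_x,labels_y,labels_z Axis [label_volume()]s.
#' @param crack_mask Logical mask from [vote_crack()].
#' @return A consensus [label_volume()].
#' @export
resolve_noncrack <- function(labels_x, labels_y, labels_z, crack_mask) {
  check_three(labels_x, labels_y, labels_z)
  stopifnot(all(dim(crack_mask) == dim(labels_x)))
  lx <- as.integer(labels_x); ly <- as.integer(labels_y)
  lz <- as.integer(labels_z)
  n <- length(lx)
  counts <- matrix(0L, n, 3L) # columns: air, enamel, dentin
  for (l in list(lx, ly, lz))
    for (k in 0:2)
      counts[, k + 1L] <- counts[, k + 1L] + (l == k)
  best <- max.col(counts, ties.method = "first") - 1L
  top <- counts[cbind(seq_len(n), best + 1L)]
  # tie (or all-crack) resolution: prefer z label, then y, then x
  tied <- top == 0L | (rowSums(counts == top) > 1L & top > 0L)
  pick <- lz
  pick[pick == LABEL_CRACK] <- ly[pick == LABEL_CRACK]
  pick[pick == LABEL_CRACK] <- lx[pick == LABEL_CRACK]
  pick[pick == LABEL_CRACK] <- LABEL_AIR # every axis said crack, mask said no
  out <- best
  out[tied] <- pick[tied]
  out[as.vector(crack_mask)] <- LABEL_CRACK
  label_volume(array(out, dim(labels_x)), voxel_pitch(labels_x))
}

#' Slice-by-slice fill-in of the crack mask
#'
#' Reconstructs the tooth "as if it had no cracks": per z-slice the crack
#' mask is dilated by `dilation_radius` (square structuring element), and
#' every masked pixel that lies in the tooth is reassigned the code of its
#' nearest (Euclidean) non-masked enamel or dentin pixel in that slice.
#' Voxels outside the dilated mask are untouched and the output contains no
#' crack-coded voxels. Masked pixels in slices with no surrounding tissue
#' anywhere raise an error; masked pixels outside the tooth silhouette
#' (air) stay air.
#'
#' @param final_labels Consensus [label_volume()].
#' @param crack_mask Logical crack mask (defaults to the crack-coded voxels
#'   of `final_labels`).
#' @param dilation_radius Non-negative integer, default 1 (3x3 square).
#' @return A crack-free [label_volume()].
#' @export
fill_in <- function(final_labels, crack_mask = NULL, dilation_radius = 1L) {
  stopifnot(inherits(final_labels, "label_volume"), dilation_radius >= 0)
  lab <- as_plain_array(final_labels)
  if (is.null(crack_mask)) crack_mask <- lab == LABEL_CRACK
  stopifnot(all(dim(crack_mask) == dim(lab)))
  d <- dim(lab)
  out <- lab
  for (z in seq_len(d[1])) {
    m <- crack_mask[z, , , drop = TRUE]
    if (!any(m)) {
      # crack-coded voxels with no mask stay as labelled; contract keeps
      # voxels outside the mask unchanged
      next
    }
    dil <- matrix(cpp_dilate2d(as.vector(m), d[2:3],
                               as.integer(dilation_radius)), d[2], d[3])
    sl <- lab[z, , , drop = TRUE]
    target <- dil & (sl == LABEL_ENAMEL | sl == LABEL_DENTIN |
                       sl == LABEL_CRACK)
    if (!any(target)) next
    sites <- !dil & (sl == LABEL_ENAMEL | sl == LABEL_DENTIN)
    if (!any(sites))
      stop("fill_in: slice ", z, " has its whole tooth region masked")
    nv <- cpp_nearest_site2d(as.vector(sites), as.integer(sl), d[2:3])
    nv <- matrix(nv, d[2], d[3])
    sl2 <- sl
    sl2[target] <- nv[target]
    # any remaining crack codes outside the tooth collapse to air
    sl2[sl2 == LABEL_CRACK] <- LABEL_AIR
    out[z, , ] <- sl2
  }
  label_volume(out, voxel_pitch(final_labels))
}
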