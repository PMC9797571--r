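# Visual summaries: projected density maps (optionally square-root scaled
# for enhancement of faint crack sheets) and depth-shaded first-hit
# projections.

#' Projected density map along an axis
#'
#' Sums a volume (or mask) along the axis, applies the chosen intensity
#' scale and normalizes to `[0, 1]`. Square-root scaling enhances faint
#' thin structures such as crack sheets.
#'
#' @param volume_or_mask Rank-3 numeric or logical array.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param scale `"linear"` or `"sqrt"`.
#' @return 2D matrix in `[0, 1]`.
#' @export
projected_density <- function(volume_or_mask, axis = c("z", "y", "x"),
                              scale = c("linear", "sqrt")) {
  axis <- match.arg(axis)
  scale <- match.arg(scale)
  stopifnot(is.array(volume_or_mask), length(dim(volume_or_mask)) == 3)
  if (length(volume_or_mask) == 0) stop("projected_density: empty volume")
  ax <- match(axis, c("z", "y", "x"))
  m <- apply(volume_or_mask, setdiff(1:3, ax), sum)
  if (scale == "sqrt") m <- sqrt(m)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  m
}

#' Depth-shaded first-hit projection of a mask
#'
#' Each line of sight is shaded by the depth of its first mask voxel:
#' nearer hits are lighter, farther hits darker, lines with no hit are 0.
#'
#' @param mask Logical rank-3 array.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @return 2D matrix in `[0, 1]` (0 = no hit; otherwise
#'   `1 - depth / extent`, so value 1 is a hit on the viewer-side face).
#' @export
depth_shaded_projection <- function(mask, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  d <- distance_to_crack_projection(mask, axis)
  extent <- dim(mask)[match(axis, c("z", "y", "x"))]
  out <- 1 - d / extent
  out[is.na(out)] <- 0
  out
}

write_png_map <- function(m, path) {
  png::writePNG(t(m)[, , drop = FALSE], path)
  invisible(path)
}
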