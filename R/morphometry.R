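# Crack-network morphometry: connected-component isolation of the crack
# mask, size filtering, volume fractions, local width by distance-transform
# thickness, structure-tensor plane orientations, and line-of-sight
# distance maps.

#' Connected components of a crack mask
#'
#' Maximal connected voxel groups under 26- (default) or 6-connectivity.
#' Component ids are deterministic: decreasing voxel count, ties broken by
#' the smallest linear voxel index. Thin oblique crack sheets fragment
#' under 6-connectivity, hence the 26-connected default.
#'
#' @param crack_mask Logical rank-3 array.
#' @param connectivity 26 or 6.
#' @param voxel_pitch_um Voxel pitch carried into the component summaries.
#' @return A list of class `crack_components`: `labels` (integer array,
#'   0 background), `components` (list of per-component summaries with
#'   `id`, `voxel_count`, `centroid`, `bbox`, covariance eigenvalues,
#'   `planarity`, `normal`), `connectivity`, `voxel_pitch_um`.
#' @export
connected_components <- function(crack_mask, connectivity = 26L,
                                 voxel_pitch_um = 1) {
  stopifnot(is.array(crack_mask), length(dim(crack_mask)) == 3)
  d <- dim(crack_mask)
  labs <- array(cpp_cc_label(as.vector(crack_mask), d, as.integer(connectivity)),
                d)
  k <- max(labs)
  comps <- vector("list", k)
  if (k > 0) {
    idx_all <- which(labs > 0)
    by_id <- split(idx_all, labs[idx_all])
    for (i in seq_len(k)) {
      idx <- by_id[[as.character(i)]]
      comps[[i]] <- summarize_component(i, idx, d)
    }
  }
  structure(list(labels = labs, components = comps,
                 connectivity = as.integer(connectivity),
                 voxel_pitch_um = voxel_pitch_um),
            class = "crack_components")
}

summarize_component <- function(id, idx, dims) {
  co <- arrayInd(idx, dims) # (z, y, x), 1-based
  n <- nrow(co)
  centroid <- colMeans(co)
  bbox <- rbind(min = apply(co, 2, min), max = apply(co, 2, max))
  if (n >= 3) {
    S <- cov(co)
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, 0) # descending
    planarity <- if (lam[1] > 0) (lam[2] - lam[3]) / lam[1] else 0
    normal_zyx <- ev$vectors[, 3]
    normal <- normal_zyx[c(3, 2, 1)] # report as (x, y, z)
    if (normal[3] < 0 || (normal[3] == 0 && normal[1] < 0)) normal <- -normal
  } else {
    lam <- c(0, 0, 0); planarity <- 0; normal <- c(0, 0, 1)
  }
  list(id = id, voxel_count = n, voxel_index = idx, centroid = centroid,
       bbox = bbox, eigenvalues = lam, planarity = planarity, normal = normal)
}

#' @export
print.crack_components <- function(x, ...) {
  k <- length(x$components)
  cat(sprintf("<crack_components> %d component(s), %d-connectivity\n",
              k, x$connectivity))
  if (k) {
    sizes <- vapply(x$components, `[[`, numeric(1), "voxel_count")
    cat("  sizes:", paste(utils::head(sizes, 10), collapse = ", "),
        if (k > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Drop components below a minimum voxel count
#'
#' The default working-scale threshold of 27 voxels removes single 3x3x3
#' noise blobs.
#'
#' @param components A `crack_components` object or its `components` list.
#' @param min_voxels Minimum size kept (>= 1).
#' @return Same type as the input, filtered (label array voxels of dropped
#'   components are zeroed when a `crack_components` object is given).
#' @export
filter_by_size <- function(components, min_voxels = 27L) {
  stopifnot(min_voxels >= 1)
  if (inherits(components, "crack_components")) {
    keep <- vapply(components$components, function(cp)
      cp$voxel_count >= min_voxels, logical(1))
    dropped <- components$components[!keep]
    for (cp in dropped) components$labels[cp$voxel_index] <- 0L
    components$components <- components$components[keep]
    components
  } else {
    Filter(function(cp) cp$voxel_count >= min_voxels, components)
  }
}

#' Largest k components
#'
#' @param components A `crack_components` object or component list.
#' @param k Number of components to keep (component ids are already ordered
#'   by decreasing size, so this keeps ids 1..k of those present).
#' @return Component list of length `min(k, n)`, stable order.
#' @export
largest_k <- function(components, k = 3L) {
  stopifnot(k >= 1)
  cl <- if (inherits(components, "crack_components")) components$components
        else components
  ord <- order(-vapply(cl, `[[`, numeric(1), "voxel_count"),
               vapply(cl, `[[`, numeric(1), "id"))
  cl[ord][seq_len(min(k, length(cl)))]
}

#' Volume fraction of a component within the tooth
#'
#' @param component One component summary (or a voxel count).
#' @param tooth_mask Logical mask of tooth voxels (hard tissue + cracks).
#' @return `voxel_count / sum(tooth_mask)`.
#' @export
volume_fraction <- function(component, tooth_mask) {
  n_tooth <- sum(tooth_mask)
  if (n_tooth == 0) stop("volume_fraction: empty tooth mask")
  n <- if (is.list(component)) component$voxel_count else as.numeric(component)
  if (!length(n) || is.na(n)) n <- 0
  n / n_tooth
}

#' Component summary table
#'
#' @param components A `crack_components` object.
#' @param tooth_mask Optional tooth mask for volume fractions.
#' @return Data frame with one row per component: id, voxel count, volume
#'   (um^3), centroid and bounding box (voxel coordinates), eigenvalues,
#'   planarity and dominant plane normal.
#' @export
component_table <- function(components, tooth_mask = NULL) {
  cl <- components$components
  p <- components$voxel_pitch_um
  if (!length(cl)) {
    return(data.frame(component_id = integer(), voxel_count = integer(),
                      volume_um3 = numeric(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(),
                      bbox_z0 = integer(), bbox_z1 = integer(),
                      bbox_y0 = integer(), bbox_y1 = integer(),
                      bbox_x0 = integer(), bbox_x1 = integer(),
                      lambda1 = numeric(), lambda2 = numeric(),
                      lambda3 = numeric(), planarity = numeric(),
                      normal_x = numeric(), normal_y = numeric(),
                      normal_z = numeric(), volume_fraction = numeric()))
  }
  df <- do.call(rbind, lapply(cl, function(cp) {
    data.frame(component_id = cp$id, voxel_count = cp$voxel_count,
               volume_um3 = cp$voxel_count * p^3,
               centroid_z = cp$centroid[1], centroid_y = cp$centroid[2],
               centroid_x = cp$centroid[3],
               bbox_z0 = cp$bbox[1, 1], bbox_z1 = cp$bbox[2, 1],
               bbox_y0 = cp$bbox[1, 2], bbox_y1 = cp$bbox[2, 2],
               bbox_x0 = cp$bbox[1, 3], bbox_x1 = cp$bbox[2, 3],
               lambda1 = cp$eigenvalues[1], lambda2 = cp$eigenvalues[2],
               lambda3 = cp$eigenvalues[3], planarity = cp$planarity,
               normal_x = cp$normal[1], normal_y = cp$normal[2],
               normal_z = cp$normal[3],
               volume_fraction = if (is.null(tooth_mask)) NA_real_
                                 else volume_fraction(cp, tooth_mask))
  }))
  rownames(df) <- NULL
  df
}

#' Local crack width map (micrometres)
#'
#' Width is the local thickness in the porous-media sense: twice the
#' Euclidean distance-transform radius of the largest inscribed sphere
#' covering each voxel, scaled by the voxel pitch. Widths at or below one
#' voxel are below the measurement resolution and flagged.
#'
#' @param crack_mask Logical rank-3 array.
#' @param voxel_pitch_um Voxel pitch in micrometres.
#' @return List with `width_um` (numeric array, 0 outside the mask),
#'   `sub_resolution` (logical array: mask voxels with width <= pitch).
#' @export
local_width <- function(crack_mask, voxel_pitch_um) {
  stopifnot(is.array(crack_mask), length(dim(crack_mask)) == 3,
            voxel_pitch_um > 0)
  d <- dim(crack_mask)
  th <- array(cpp_local_thickness(as.vector(crack_mask), d), d)
  width <- th * voxel_pitch_um
  sub <- crack_mask & width <= voxel_pitch_um + 1e-9
  width[sub] <- voxel_pitch_um # reported as <= pitch, flagged
  list(width_um = width, sub_resolution = sub)
}

#' Dominant crack-plane orientation modes
#'
#' Local plane normals are estimated per crack voxel from the structure
#' tensor of the Gaussian-smoothed crack indicator (dominant eigenvector of
#' the smoothed gradient outer product - the direction across the sheet).
#' Normals are sign-folded onto the upper hemisphere and binned on a
#' 36 x 18 (azimuth x elevation) grid of 5/10-degree cells (648 bins); the
#' two strongest well-separated modes and their mutual angle summarize the
#' main crack-plane families.
#'
#' @param crack_mask Logical rank-3 array with at least 100 crack voxels.
#' @param sigma_smooth Gaussian sigma (voxels) for the indicator smoothing
#'   and tensor averaging (default 2).
#' @param min_separation_deg Minimum angular separation between reported
#'   modes (default 25).
#' @return List of class `orientation_modes`: `normals` (n x 3 matrix,
#'   `(x, y, z)`), `histogram` (36 x 18 counts), `modes` (2 x 3 matrix of
#'   mode directions), `mode_angle_deg` (in `[0, 90]`), `mode_mass`
#'   (fraction of voxels within 20 degrees of each mode).
#' @export
orientation_modes <- function(crack_mask, sigma_smooth = 2,
                              min_separation_deg = 25) {
  stopifnot(is.array(crack_mask), length(dim(crack_mask)) == 3)
  idx <- which(crack_mask)
  if (length(idx) < 100)
    stop("orientation_modes: need at least 100 crack voxels")
  d <- dim(crack_mask)
  f <- cpp_gauss3(as.numeric(crack_mask), d, sigma_smooth)
  nz <- cpp_plane_normals(f, d, sigma_smooth, as.integer(idx - 1L))
  # (z, y, x) components -> (x, y, z), folded to the z >= 0 hemisphere
  normals <- nz[, c(3, 2, 1), drop = FALSE]
  flip <- normals[, 3] < 0 |
    (normals[, 3] == 0 & (normals[, 2] < 0 |
                            (normals[, 2] == 0 & normals[, 1] < 0)))
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  az <- atan2(normals[, 2], normals[, 1]) %% (2 * pi)
  el <- asin(pmin(pmax(normals[, 3], 0), 1))
  bin_az <- pmin(floor(az / (2 * pi) * 36) + 1L, 36L)
  bin_el <- pmin(floor(el / (pi / 2) * 18) + 1L, 18L)
  hist2 <- matrix(0L, 36, 18)
  for (i in seq_along(az))
    hist2[bin_az[i], bin_el[i]] <- hist2[bin_az[i], bin_el[i]] + 1L
  # mode 1: heaviest bin, direction = mean of its member normals
  mode_dir <- function(sel) {
    v <- colSums(normals[sel, , drop = FALSE])
    v / sqrt(sum(v^2))
  }
  b1 <- which(hist2 == max(hist2), arr.ind = TRUE)[1, ]
  sel1 <- bin_az == b1[1] & bin_el == b1[2]
  m1 <- mode_dir(sel1)
  # mode 2: heaviest bin at sufficient angular separation from mode 1
  ang_to <- function(v, w) {
    acos(pmin(abs(sum(v * w)), 1)) * 180 / pi
  }
  bins <- which(hist2 > 0, arr.ind = TRUE)
  bins <- bins[order(-hist2[bins]), , drop = FALSE]
  m2 <- NULL
  for (r in seq_len(nrow(bins))) {
    sel <- bin_az == bins[r, 1] & bin_el == bins[r, 2]
    cand <- mode_dir(sel)
    if (ang_to(cand, m1) >= min_separation_deg) { m2 <- cand; break }
  }
  if (is.null(m2)) m2 <- m1
  angle <- ang_to(m1, m2)
  near <- function(m) mean(apply(normals, 1, function(v) ang_to(v, m) < 20))
  structure(list(normals = normals, histogram = hist2,
                 modes = rbind(m1, m2), mode_angle_deg = angle,
                 mode_mass = c(near(m1), near(m2))),
            class = "orientation_modes")
}

#' @export
print.orientation_modes <- function(x, ...) {
  cat(sprintf("<orientation_modes> %d normals, mode angle %.1f deg\n",
              nrow(x$normals), x$mode_angle_deg))
  invisible(x)
}

#' Line-of-sight distance to the nearest crack voxel
#'
#' For each line of sight along `axis`, the distance (voxels, 0-based) from
#' the viewer-side face to the first crack voxel; lines that never hit a
#' crack are `NA`.
#'
#' @param crack_mask Logical rank-3 array.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @return 2D numeric matrix of first-hit depths (`NA` where no crack).
#' @export
distance_to_crack_projection <- function(crack_mask, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("z", "y", "x"))
  m <- crack_mask
  depth <- dim(m)[ax]
  pos <- apply(m, setdiff(1:3, ax), function(line) {
    w <- which(line)
    if (length(w)) w[1] - 1 else NA_real_
  })
  pos
}
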