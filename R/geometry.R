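# Geometric preparation of tooth volumes: block-mean resampling to a
# coarser pitch, principal-axis alignment, and the partition of the tooth
# into three equal-height slabs (cervical, middle, occlusal thirds) by four
# surface sectors (buccal, contact right, palatal, contact left).

#' Resample a volume to a coarser pitch by block averaging
#'
#' Downsampling is by the integer ratio `target_pitch_um / voxel_pitch(v)`;
#' each output voxel is the arithmetic mean of its source block, which
#' conserves mean grey value and preserves thin-crack contrast better than
#' interpolation. Values are kept as (possibly fractional) doubles; rounding
#' to the 16-bit grid happens on write. Trailing slices that do not fill a
#' block are dropped.
#'
#' @param volume A [grey_volume()].
#' @param target_pitch_um Target pitch; must be an integer multiple of the
#'   source pitch (no silent interpolation).
#' @return A [grey_volume()] at the target pitch.
#' @export
resample <- function(volume, target_pitch_um) {
  stopifnot(inherits(volume, "grey_volume"))
  p <- voxel_pitch(volume)
  if (target_pitch_um < p) stop("resample: target pitch must be >= source pitch")
  ratio <- target_pitch_um / p
  f <- round(ratio)
  if (abs(ratio - f) > 1e-9)
    stop("resample: pitch ratio ", ratio, " is not an integer")
  if (f == 1L) return(volume)
  d <- dim(volume)
  m <- d %/% f
  if (any(m < 1)) stop("resample: volume smaller than one block")
  arr <- as_plain_array(volume)[seq_len(m[1] * f), seq_len(m[2] * f),
                                seq_len(m[3] * f), drop = FALSE]
  out <- cpp_block_mean(as.numeric(arr), dim(arr), as.integer(f))
  grey_volume(array(out, m), target_pitch_um)
}

#' Align a volume to the principal axes of a tooth mask
#'
#' Rotates the volume (nearest-neighbour resampling about the mask centroid)
#' so the mask's largest principal-moment axis maps to z and the second to
#' x, matching the convention of x along the palatal surface, y along the
#' contact surfaces and z along the vertical extent of the tooth.
#'
#' @param volume A [grey_volume()].
#' @param mask Logical rank-3 array marking tooth voxels.
#' @return A list with `volume` (rotated [grey_volume()]) and `rotation`
#'   (the 3x3 matrix applied, in `(z, y, x)` voxel coordinates).
#' @export
align_axes <- function(volume, mask) {
  stopifnot(inherits(volume, "grey_volume"), is.array(mask),
            all(dim(mask) == dim(volume)))
  idx <- which(mask)
  if (!length(idx)) stop("align_axes: empty mask")
  d <- dim(mask)
  co <- arrayInd(idx, d) - 1 # (z, y, x) voxel coords
  cm <- colMeans(co)
  S <- cov(co)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] < 1e-9)
    stop("align_axes: degenerate mask (voxels are collinear)")
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  # deterministic signs: principal axis toward +z, secondary toward +x
  if (e1[1] < 0) e1 <- -e1
  if (e2[3] < 0) e2 <- -e2
  # third axis completes a proper rotation (det +1) in (z, y, x) order
  e3 <- c(e2[2] * e1[3] - e2[3] * e1[2],
          e2[3] * e1[1] - e2[1] * e1[3],
          e2[1] * e1[2] - e2[2] * e1[1])
  # rows of R map old axes to new: new = R %*% old, e1 -> z, e2 -> x, e3 -> y
  R <- rbind(z = e1, y = e3, x = e2)
  # output voxel p samples input at R^{-1} p (R orthogonal: inverse = t(R))
  arr <- as_plain_array(volume)
  out <- cpp_rotate_nn(as.numeric(arr), d, t(R), cm)
  list(volume = grey_volume(array(pmin(pmax(out, 0), 65535), d),
                            voxel_pitch(volume)),
       rotation = unname(R))
}

#' Partition the tooth extent into three equal-height slabs
#'
#' The vertical extent of the mask is split into three contiguous half-open
#' z-intervals of equal height; remainder slices are assigned bottom-up
#' (cervical slab first). Slab 1 is the cervical third, 2 the middle, 3 the
#' occlusal third.
#'
#' @param mask Logical rank-3 array of tooth voxels.
#' @return List with `slab` (integer array, 0 outside the tooth, 1..3
#'   inside), `breaks` (z start of each interval plus the end, 1-based
#'   slice indices, half-open).
#' @export
partition_slabs <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  zr <- which(apply(mask, 1, any))
  if (!length(zr)) stop("partition_slabs: empty mask")
  z0 <- min(zr); z1 <- max(zr)
  extent <- z1 - z0 + 1L
  if (extent < 3L) stop("partition_slabs: tooth spans fewer than 3 slices")
  base <- extent %/% 3L
  rem <- extent %% 3L
  sizes <- rep(base, 3L) + c(rem >= 1L, rem >= 2L, 0L)
  breaks <- z0 + cumsum(c(0L, sizes))
  slab <- array(0L, dim(mask))
  for (s in 1:3) {
    zz <- breaks[s]:(breaks[s + 1] - 1L)
    sl <- mask[zz, , , drop = FALSE]
    tmp <- array(0L, dim(sl)); tmp[sl] <- s
    slab[zz, , ] <- tmp
  }
  list(slab = slab, breaks = breaks, sizes = sizes)
}

# Boundary radius profile of one slice mask on a regular angle grid.
slice_radius_profile <- function(m, n_theta = 360L) {
  idx <- which(m, arr.ind = TRUE) - 1 # 0-based pixel coordinates
  cyx <- colMeans(idx)
  th <- atan2(idx[, 1] - cyx[1], idx[, 2] - cyx[2]) # angle from +x toward +y
  r <- sqrt((idx[, 1] - cyx[1])^2 + (idx[, 2] - cyx[2])^2)
  bin <- pmin(floor((th + pi) / (2 * pi) * n_theta) + 1L, n_theta)
  prof <- vapply(seq_len(n_theta), function(b) {
    v <- r[bin == b]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  # fill gaps by circular interpolation
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    if (length(ok) < 8) return(NULL)
    for (b in which(is.na(prof))) {
      dists <- pmin(abs(ok - b), n_theta - abs(ok - b))
      prof[b] <- prof[ok[which.min(dists)]]
    }
  }
  list(theta = seq(-pi, pi, length.out = n_theta + 1)[1:n_theta] +
         pi / n_theta, r = prof, centre = cyx)
}

# Low-order Fourier fit of the closed radius profile r(theta): returns the
# fitted profile and its analytic first/second derivatives. Boundary pixel
# quantization makes finite-difference curvature useless; a smooth global
# fit is deterministic and differentiable.
fourier_profile <- function(r, theta, n_harm = 6L) {
  n <- length(r)
  a0 <- mean(r)
  fit <- rep(a0, n); d1 <- numeric(n); d2 <- numeric(n)
  amp2 <- 0
  for (k in seq_len(n_harm)) {
    ak <- 2 * mean(r * cos(k * theta))
    bk <- 2 * mean(r * sin(k * theta))
    amp2 <- amp2 + ak^2 + bk^2
    fit <- fit + ak * cos(k * theta) + bk * sin(k * theta)
    d1 <- d1 - k * ak * sin(k * theta) + k * bk * cos(k * theta)
    d2 <- d2 - k^2 * (ak * cos(k * theta) + bk * sin(k * theta))
  }
  list(fit = fit, d1 = d1, d2 = d2, rel_amp = sqrt(amp2) / a0)
}

# curvature of a polar curve from its value and derivatives
polar_curvature <- function(r, rp, rpp) {
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

#' Partition the tooth into four surface sectors
#'
#' Per slab, the mid-slab slice's boundary is traced as a polar radius
#' profile around the centroid; transition points between convex (buccal,
#' palatal) and flatter (contact) surface arcs are located where the
#' smoothed boundary curvature crosses its median, and the two chords
#' connecting opposite transition points split the slice into four sectors,
#' propagated through the slab. When fewer than four robust transitions are
#' found the partition falls back to centroid-anchored +/-45 degree
#' quadrants (flagged in the output).
#'
#' Sector codes: 1 = buccal (-x side), 2 = contact_right (+y), 3 = palatal
#' (+x), 4 = contact_left (-y).
#'
#' @param mask Logical rank-3 array of tooth voxels.
#' @param slab Optional slab assignment from [partition_slabs()]; computed
#'   when missing. Sector chords are computed once per slab on its middle
#'   slice.
#' @return List with `sector` (integer array, 0 outside, 1..4 inside),
#'   `fallback` (logical per slab), and `sector_names`.
#' @export
partition_sectors <- function(mask, slab = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (is.null(slab)) slab <- partition_slabs(mask)
  d <- dim(mask)
  sector <- array(0L, d)
  fallback <- logical(3)
  sector_names <- c("buccal", "contact_right", "palatal", "contact_left")
  for (s in 1:3) {
    zz <- slab$breaks[s]:(slab$breaks[s + 1] - 1L)
    zm <- zz[ceiling(length(zz) / 2)]
    m <- mask[zm, , , drop = TRUE]
    if (!any(m)) {
      nz <- zz[vapply(zz, function(z) any(mask[z, , ]), logical(1))]
      if (!length(nz)) stop("partition_sectors: empty slice inside extent")
      zm <- nz[ceiling(length(nz) / 2)]
      m <- mask[zm, , , drop = TRUE]
    }
    prof <- slice_radius_profile(m)
    trans <- NULL
    if (!is.null(prof)) {
      fp <- fourier_profile(prof$r, prof$theta)
      kap <- polar_curvature(fp$fit, fp$d1, fp$d2)
      med <- median(kap)
      # a near-circular section (relative harmonic amplitude < 3%) has no
      # robust convex-to-flat transitions
      if (fp$rel_amp > 0.03) {
        above <- kap > med
        cross <- which(above != above[c(length(above), 1:(length(above) - 1))])
        if (length(cross) > 4L) {
          # keep the 4 steepest median crossings
          n <- length(kap)
          slope <- abs(kap[cross] - kap[((cross - 2L) %% n) + 1L])
          cross <- sort(cross[order(-slope)][1:4])
        }
        if (length(cross) == 4L) trans <- prof$theta[cross]
      }
    }
    if (is.null(trans)) {
      fallback[s] <- TRUE
      trans <- c(-3, -1, 1, 3) * pi / 4 # +/-45 degree quadrants
      centre <- if (is.null(prof)) (d[2:3] - 1) / 2 else prof$centre
    } else centre <- prof$centre
    trans <- sort(trans)
    # crossing chords connect transition 1-3 and 2-4
    p <- lapply(trans, function(a) centre + max(d[2:3]) * c(sin(a), cos(a)))
    yy <- matrix(rep(seq_len(d[2]) - 1, d[3]), d[2], d[3])
    xx <- matrix(rep(seq_len(d[3]) - 1, each = d[2]), d[2], d[3])
    side <- function(a, b) {
      sign((b[2] - a[2]) * (yy - a[1]) - (b[1] - a[1]) * (xx - a[2])) >= 0
    }
    s13 <- side(p[[1]], p[[3]])
    s24 <- side(p[[2]], p[[4]])
    quad <- ifelse(s13 & s24, 1L, ifelse(!s13 & s24, 2L,
                   ifelse(!s13 & !s24, 3L, 4L)))
    # name the four regions by the cardinal direction of their mean angle
    centres <- vapply(1:4, function(q) {
      sel <- quad == q
      atan2(mean(yy[sel]) - centre[1], mean(xx[sel]) - centre[2])
    }, numeric(1))
    # map region whose centre is closest to -x -> buccal(1), +y -> 2,
    # +x -> palatal(3), -y -> 4
    card <- c(pi, pi / 2, 0, -pi / 2)
    lab_of <- integer(4)
    for (q in 1:4) {
      dd <- abs(atan2(sin(centres[q] - card), cos(centres[q] - card)))
      lab_of[q] <- which.min(dd)
    }
    if (length(unique(lab_of)) != 4L) lab_of <- 1:4 # degenerate: keep order
    for (zi in zz) {
      sl <- mask[zi, , , drop = TRUE]
      lab2 <- array(0L, dim(sl))
      lab2[sl] <- lab_of[quad[sl]]
      sector[zi, , ] <- lab2
    }
  }
  list(sector = sector, fallback = fallback, sector_names = sector_names)
}

#' Combine slab and sector partitions into 3 x 4 regions
#'
#' @param mask Logical rank-3 tooth mask.
#' @return List with `region` (integer array, 0 outside, 1..12 inside,
#'   region = (slab - 1) * 4 + sector), `slab`, `sector`, `fallback`, and a
#'   `table` data frame of per-region voxel counts.
#' @export
slab_sector_regions <- function(mask) {
  sl <- partition_slabs(mask)
  se <- partition_sectors(mask, sl)
  region <- array(0L, dim(mask))
  inside <- sl$slab > 0L & se$sector > 0L
  region[inside] <- (sl$slab[inside] - 1L) * 4L + se$sector[inside]
  tab <- data.frame(region_id = 1:12,
                    slab = rep(1:3, each = 4),
                    sector = rep(se$sector_names, 3),
                    voxel_count = vapply(1:12, function(r) sum(region == r),
                                         numeric(1)))
  list(region = region, slab = sl$slab, sector = se$sector,
       fallback = se$fallback, table = tab)
}
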