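# Synthetic tooth phantoms: a half-ellipsoid crown with an enamel shell of
# z-interpolated thickness, a dentin core, a pulp cavity opening through the
# cervical base, and a network of thin planar cracks carved from the hard
# tissue. Grey values are density-proportional with sub-voxel (partial
# volume) crack rendering, additive Gaussian noise, and optional scan
# artifacts. Ground-truth labels accompany every phantom so the whole
# downstream pipeline is testable without real scans.

GREY_PER_DENSITY <- 0.6 * 65535 / 2.69 # enamel mean density maps to 60% range

#' Crack-network specification for a tooth phantom
#'
#' Primary planes are finite planar slabs that (by default) all contain the
#' vertical tooth axis, producing the star-shaped connected network observed
#' in real teeth; their two default orientation families are perpendicular.
#' Isolated cracks are small discs biased toward the outer surface.
#'
#' @param n_primary_planes Number of primary (axis-sharing) crack planes.
#' @param orientation_mode `"radial_two_perpendicular"` (azimuths alternate
#'   between two families 90 degrees apart) or `"random"`.
#' @param plane_normals Optional matrix (one row per plane) of explicit
#'   normals in `(x, y, z)` components; overrides `orientation_mode`.
#' @param widths_um Sampling range for crack widths in micrometres.
#' @param connect_to_axis If `TRUE`, primary planes contain the tooth axis.
#' @param n_isolated_cracks Number of small unconnected disc cracks.
#' @param isolated_depth_bias Fraction of isolated cracks kept near the
#'   outer surface.
#' @param target_volume_fraction Optional target for the connected-network
#'   volume fraction of the tooth; when set, primary-plane widths are solved
#'   by bisection to meet it.
#' @return A list of class `crack_network_spec`.
#' @export
crack_network_spec <- function(n_primary_planes = 2L,
                               orientation_mode = c("radial_two_perpendicular",
                                                    "random"),
                               plane_normals = NULL,
                               widths_um = c(0.3, 30),
                               connect_to_axis = TRUE,
                               n_isolated_cracks = 6L,
                               isolated_depth_bias = 0.7,
                               target_volume_fraction = 0.02) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(n_primary_planes >= 0, n_isolated_cracks >= 0,
            all(widths_um > 0), length(widths_um) == 2)
  if (!is.null(target_volume_fraction))
    stopifnot(target_volume_fraction > 0, target_volume_fraction < 1)
  stopifnot(isolated_depth_bias >= 0, isolated_depth_bias <= 1)
  if (!is.null(plane_normals)) {
    plane_normals <- as.matrix(plane_normals)
    stopifnot(ncol(plane_normals) == 3)
    nrm <- sqrt(rowSums(plane_normals^2))
    stopifnot(all(nrm > 0))
    plane_normals <- plane_normals / nrm
  }
  structure(list(n_primary_planes = as.integer(n_primary_planes),
                 orientation_mode = orientation_mode,
                 plane_normals = plane_normals,
                 widths_um = widths_um,
                 connect_to_axis = isTRUE(connect_to_axis),
                 n_isolated_cracks = as.integer(n_isolated_cracks),
                 isolated_depth_bias = isolated_depth_bias,
                 target_volume_fraction = target_volume_fraction),
            class = "crack_network_spec")
}

#' Tooth-phantom specification
#'
#' Defaults describe a premolar-like crown at desk scale: a 128^3 grid at
#' 50 um pitch (6.4 mm extent), enamel 0.5 mm thick cervically rising to
#' 2.5 mm at the cusp, enamel density 2.61-2.77 g/cm^3 and dentin
#' 1.79-2.12 g/cm^3, and a crack network targeting the ~2% connected-network
#' volume fraction reported for real teeth.
#'
#' @param grid_shape Integer vector `(nz, ny, nx)`.
#' @param voxel_pitch_um Isotropic voxel pitch in micrometres.
#' @param crown List with `height_mm`, `radius_x_mm`, `radius_y_mm`
#'   (half-ellipsoid outer surface; unequal radii give the convex-buccal /
#'   flatter-contact asymmetry).
#' @param enamel_thickness_mm Length-2 vector `(cervical, cuspal)` in mm,
#'   linearly interpolated along z; must lie within `[0.3, 3]` mm.
#' @param pulp_scale Scale of the pulp half-ellipsoid relative to the crown
#'   radii (the cavity opens through the base plane).
#' @param densities_g_cm3 List with `enamel` and `dentin` density ranges.
#' @param crack_network A [crack_network_spec()].
#' @param noise_sd Gaussian noise standard deviation in grey units.
#' @param artifacts List of flags `cylinder_void`, `top_rays`.
#' @param rng_seed Integer seed; phantoms are bit-reproducible per seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_pitch_um = 50,
                         crown = list(height_mm = 5.5, radius_x_mm = 2.7,
                                      radius_y_mm = 2.2),
                         enamel_thickness_mm = c(0.5, 2.5),
                         pulp_scale = 0.35,
                         densities_g_cm3 = list(enamel = c(2.61, 2.77),
                                                dentin = c(1.79, 2.12)),
                         crack_network = crack_network_spec(),
                         noise_sd = 1500,
                         artifacts = list(cylinder_void = FALSE,
                                          top_rays = FALSE),
                         rng_seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            voxel_pitch_um > 0,
            length(enamel_thickness_mm) == 2,
            all(enamel_thickness_mm >= 0.3),
            all(enamel_thickness_mm <= 3.0),
            pulp_scale > 0, pulp_scale < 1,
            length(densities_g_cm3$enamel) == 2,
            length(densities_g_cm3$dentin) == 2,
            noise_sd >= 0)
  stopifnot(inherits(crack_network, "crack_network_spec"))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_pitch_um = voxel_pitch_um,
                 crown = crown,
                 enamel_thickness_mm = enamel_thickness_mm,
                 pulp_scale = pulp_scale,
                 densities_g_cm3 = densities_g_cm3,
                 crack_network = crack_network,
                 noise_sd = noise_sd,
                 artifacts = artifacts,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# coordinate fields and tissue geometry, shared by labels and rendering
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  p <- spec$voxel_pitch_um
  mm2vox <- 1000 / p
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  # air margin below the cervical base; generous enough that per-slice
  # morphology near the base cannot bridge the tooth to the volume edge
  z0 <- 8
  h <- spec$crown$height_mm * mm2vox
  rx <- spec$crown$radius_x_mm * mm2vox
  ry <- spec$crown$radius_y_mm * mm2vox
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  z <- array(rep(seq_len(nz) - 1, times = ny * nx), d)
  y <- array(rep(rep(seq_len(ny) - 1, each = nz), times = nx), d)
  x <- array(rep(seq_len(nx) - 1, each = nz * ny), d)
  zq <- (z - z0) / h
  dx <- x - cx; dy <- y - cy
  rho <- sqrt((dx / rx)^2 + (dy / ry)^2 + pmax(zq, 0)^2)
  inside <- zq >= 0 & zq <= 1 & rho <= 1
  # geometric distance (voxels) to outer surface along the radial ray
  rpt <- sqrt(dx^2 + dy^2 + (pmax(zq, 0) * h)^2)
  d_out <- ifelse(rho > 0, (1 - rho) / pmax(rho, 1e-9) * rpt, h * (1 - zq))
  t0 <- spec$enamel_thickness_mm[1] * mm2vox
  t1 <- spec$enamel_thickness_mm[2] * mm2vox
  tz <- t0 + (t1 - t0) * pmax(pmin(zq, 1), 0)
  enamel <- inside & d_out <= tz
  # pulp chamber: gently tapering, flat-topped (chamber + canal), open
  # through the base plane; a pointed tip would narrow below the scan's
  # resolvable width, which real pulp chambers do not
  ps <- spec$pulp_scale
  pulp <- zq >= 0 & zq <= 0.5 &
    ((dx / (ps * rx))^2 + (dy / (ps * ry))^2) <= 1 - 0.5 * (zq / 0.5)^2
  dentin <- inside & !enamel & !pulp
  enamel <- enamel & !pulp
  list(dims = d, z0 = z0, h = h, rx = rx, ry = ry, cx = cx, cy = cy,
       z = z, y = y, x = x, zq = zq, dx = dx, dy = dy, rho = rho,
       inside = inside, d_out = d_out, tz = tz,
       enamel = enamel, dentin = dentin, pulp = pulp)
}

# occupancy of one planar slab crack given signed distances and width (vox)
slab_occupancy <- function(dist, width) {
  pmax(0, pmin(dist + 0.5, width / 2) - pmax(dist - 0.5, -width / 2))
}

# unit normal from azimuth (degrees) in the horizontal plane, (x,y,z) comps
azimuth_normal <- function(az_deg, tilt_deg = 0) {
  a <- az_deg * pi / 180; t <- tilt_deg * pi / 180
  c(cos(t) * cos(a), cos(t) * sin(a), sin(t))
}

#' Generate a synthetic tooth phantom with ground truth
#'
#' Deterministic for a fixed `rng_seed`. Grey levels are ordered
#' enamel > dentin > (pulp = crack = air); cracks are carved from the hard
#' tissue according to the crack-network specification, with voxels labelled
#' crack when crack occupancy reaches 0.5 (thinner cracks still leave a
#' partial-volume grey dip but stay below the labelling threshold).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `grey` (a [grey_volume()]), and `truth`: a
#'   list with `labels` (a [label_volume()]), `crack_plane_normals` (matrix,
#'   `(x, y, z)` rows, primary planes), and
#'   `connected_network_voxel_fraction` (primary-network voxels over tooth
#'   voxels).
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 48), voxel_pitch_um = 120,
#'                      crack_network = crack_network_spec(
#'                        target_volume_fraction = 0.02))
#' ph <- generate_phantom(spec)
#' ph$truth$connected_network_voxel_fraction
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$rng_seed)
  geo <- phantom_geometry(spec)
  cs <- spec$crack_network
  p <- spec$voxel_pitch_um
  tissue <- geo$enamel | geo$dentin
  tooth_idx <- which(tissue)
  n_tooth <- length(tooth_idx)

  # ---- primary planes (the connected star network) ----
  normals <- NULL
  if (!is.null(cs$plane_normals)) {
    normals <- cs$plane_normals
  } else if (cs$n_primary_planes > 0) {
    k <- seq_len(cs$n_primary_planes) - 1
    if (cs$orientation_mode == "radial_two_perpendicular") {
      # small azimuth jitter: the two families are "almost" perpendicular,
      # and off-lattice plane traces make sub-voxel occupancy (and thus the
      # achievable volume fraction) vary smoothly with width
      jit <- runif(cs$n_primary_planes, -7, 7)
      az <- (k %% 2) * 90 + jit
      normals <- t(vapply(az, azimuth_normal, numeric(3)))
    } else {
      az <- runif(cs$n_primary_planes, 0, 180)
      tilt <- runif(cs$n_primary_planes, -20, 20)
      normals <- t(mapply(azimuth_normal, az, tilt))
    }
  }
  n_planes <- if (is.null(normals)) 0L else nrow(normals)

  # signed distance of each tooth voxel to every primary plane (voxels) and
  # horizontal in-plane distance from the tooth axis; planes contain the
  # tooth axis (or the crown centroid when not)
  plane_dist <- inplane_r2 <- NULL
  rmax <- sqrt(geo$rx^2 + geo$ry^2)
  if (n_planes > 0) {
    ax <- geo$x[tooth_idx] - geo$cx
    ay <- geo$y[tooth_idx] - geo$cy
    az_ <- geo$z[tooth_idx] - (geo$z0 + if (cs$connect_to_axis) 0 else geo$h / 2)
    plane_dist <- matrix(0, n_tooth, n_planes)
    inplane_r2 <- matrix(0, n_tooth, n_planes)
    for (i in seq_len(n_planes)) {
      n_i <- normals[i, ]
      plane_dist[, i] <- ax * n_i[1] + ay * n_i[2] + az_ * n_i[3]
      nh <- sqrt(n_i[1]^2 + n_i[2]^2)
      if (nh > 1e-6) {
        dh <- (ax * n_i[1] + ay * n_i[2]) / nh
        inplane_r2[, i] <- pmax(ax^2 + ay^2 - dh^2, 0)
      }
    }
  }

  widths_vox <- exp(runif(max(n_planes, 1), log(cs$widths_um[1]),
                          log(cs$widths_um[2]))) / p
  plane_reach <- 1
  primary_occ_for <- function(w, reach = 1) {
    occ <- numeric(n_tooth)
    for (i in seq_len(n_planes)) {
      o <- slab_occupancy(plane_dist[, i], w[i])
      o[inplane_r2[, i] > (reach * rmax)^2] <- 0
      occ <- occ + o
    }
    pmin(occ, 1)
  }
  if (n_planes > 0 && !is.null(cs$target_volume_fraction)) {
    target <- cs$target_volume_fraction
    f_of <- function(w, reach) {
      sum(primary_occ_for(rep(w, n_planes), reach) >= 0.5) / n_tooth
    }
    if (f_of(25, 1) < target)
      stop("generate_phantom: crack network cannot reach target_volume_fraction ",
           target, " within the tooth")
    # thinnest width that still labels an unbroken one-voxel sheet (a
    # narrower band can miss every lattice centre along some rows and
    # fragment the network)
    w_act <- 1.0
    if (f_of(w_act, 1) >= target) {
      # full-reach planes already overshoot at the activation width: shrink
      # the planes' horizontal reach (the star keeps its topology, the arms
      # get shorter), which varies the labelled volume near-continuously
      lo <- 0.02; hi <- 1
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (f_of(w_act, mid) < target) lo <- mid else hi <- mid
      }
      widths_vox <- rep(w_act, n_planes)
      plane_reach <- hi
    } else {
      lo <- w_act; hi <- 25
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (f_of(mid, 1) < target) lo <- mid else hi <- mid
      }
      widths_vox <- rep(hi, n_planes)
    }
  }
  occ_primary <- if (n_planes > 0) primary_occ_for(widths_vox, plane_reach)
                 else numeric(n_tooth)

  # ---- isolated disc cracks ----
  occ_isolated <- numeric(n_tooth)
  if (cs$n_isolated_cracks > 0) {
    rho_t <- geo$rho[tooth_idx]
    for (i in seq_len(cs$n_isolated_cracks)) {
      near <- runif(1) < cs$isolated_depth_bias
      band <- if (near) c(0.75, 0.95) else c(0.3, 0.75)
      cand <- which(rho_t >= band[1] & rho_t <= band[2])
      if (!length(cand)) next
      ci <- cand[ceiling(runif(1) * length(cand))]
      cxyz <- c(geo$x[tooth_idx[ci]], geo$y[tooth_idx[ci]], geo$z[tooth_idx[ci]])
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      rad <- runif(1, 4, 9)
      w <- exp(runif(1, log(cs$widths_um[1]), log(cs$widths_um[2]))) / p
      px <- geo$x[tooth_idx] - cxyz[1]
      py <- geo$y[tooth_idx] - cxyz[2]
      pz <- geo$z[tooth_idx] - cxyz[3]
      dn <- px * v[1] + py * v[2] + pz * v[3]
      inplane2 <- px^2 + py^2 + pz^2 - dn^2
      o <- slab_occupancy(dn, w)
      o[inplane2 > rad^2] <- 0
      occ_isolated <- pmin(occ_isolated + o, 1)
    }
  }
  occ_total <- pmin(occ_primary + occ_isolated, 1)

  # ---- labels ----
  lab <- array(LABEL_AIR, geo$dims)
  lab[geo$enamel] <- LABEL_ENAMEL
  lab[geo$dentin] <- LABEL_DENTIN
  crack_vox <- tooth_idx[occ_total >= 0.5]
  lab[crack_vox] <- LABEL_CRACK
  labels <- label_volume(lab, p)

  network_frac <- if (n_planes > 0) sum(occ_primary >= 0.5) / n_tooth else 0

  occ_field <- array(0, geo$dims)
  occ_field[tooth_idx] <- occ_total

  grey <- render_attenuation(labels, spec, crack_occupancy = occ_field)

  list(grey = grey,
       truth = list(labels = labels,
                    crack_plane_normals = normals,
                    connected_network_voxel_fraction = network_frac))
}

#' Render a density-proportional attenuation volume from labels
#'
#' Grey value is proportional to local density (enamel densities graded from
#' the dentin-enamel junction to the outer surface, dentin graded toward the
#' core), reduced by sub-voxel crack occupancy (partial volume: a crack
#' thinner than one voxel lowers, not zeroes, its voxel value), plus
#' Gaussian noise and optional scan artifacts.
#'
#' @param labels A [label_volume()].
#' @param spec The [phantom_spec()] that produced the labels.
#' @param crack_occupancy Optional array of per-voxel crack occupancy in
#'   `[0, 1]`; when `NULL`, label-crack voxels are treated as fully open
#'   (occupancy 1).
#' @return A [grey_volume()].
#' @export
render_attenuation <- function(labels, spec, crack_occupancy = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  d <- dim(labels)
  lab <- as_plain_array(labels)
  dens <- array(0, d)
  de <- spec$densities_g_cm3$enamel
  dd <- spec$densities_g_cm3$dentin
  en <- lab == LABEL_ENAMEL | (lab == LABEL_CRACK & geo$enamel)
  dn <- lab == LABEL_DENTIN | (lab == LABEL_CRACK & geo$dentin)
  # enamel: denser toward the outer surface; dentin: denser toward the DEJ
  depth_frac <- pmax(pmin(geo$d_out / pmax(geo$tz, 1e-9), 1), 0)
  dens[en] <- de[2] - (de[2] - de[1]) * depth_frac[en]
  dens[dn] <- dd[1] + (dd[2] - dd[1]) * pmax(pmin(geo$rho[dn], 1), 0)
  grey <- dens * GREY_PER_DENSITY
  if (is.null(crack_occupancy)) {
    grey[lab == LABEL_CRACK] <- 0
  } else {
    grey <- grey * (1 - crack_occupancy)
  }
  if (isTRUE(spec$artifacts$cylinder_void)) {
    r2 <- (geo$x - (geo$cx + geo$rx / 3))^2 + (geo$y - geo$cy)^2
    grey[r2 <= 5^2] <- 0
  }
  if (isTRUE(spec$artifacts$top_rays)) {
    top <- geo$zq > 1
    theta <- atan2(geo$dy, geo$dx)
    grey[top] <- grey[top] + 2000 * abs(sin(6 * theta[top]))
  }
  if (spec$noise_sd > 0)
    grey <- grey + rnorm(length(grey), 0, spec$noise_sd)
  grey <- round(pmin(pmax(grey, 0), 65535))
  grey_volume(array(grey, d), spec$voxel_pitch_um)
}

#' Sample labelled training tiles from a phantom
#'
#' Tiles are cropped from z-slices of the greyscale phantom, pixelwise
#' aligned with the corresponding ground-truth label tiles. Sampling is
#' reproducible for a fixed seed, and restricted to the z-range of the
#' crown so all four classes appear across a modest number of tiles.
#'
#' @param grey A [grey_volume()].
#' @param labels The matching [label_volume()].
#' @param n_tiles Number of tiles (positive).
#' @param tile_size Tile side in pixels (must fit in a z-slice).
#' @param seed Integer seed.
#' @return A list of `n_tiles` elements, each `list(grey =, labels =)` with
#'   `tile_size x tile_size` matrices.
#' @export
generate_training_tiles <- function(grey, labels, n_tiles, tile_size,
                                    seed = 1L) {
  stopifnot(inherits(grey, "grey_volume"), inherits(labels, "label_volume"),
            all(dim(grey) == dim(labels)))
  if (n_tiles <= 0) stop("generate_training_tiles: n_tiles must be positive")
  d <- dim(grey)
  if (tile_size > d[2] || tile_size > d[3])
    stop("generate_training_tiles: tile larger than slice")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  lab <- as_plain_array(labels)
  has_tooth <- which(apply(lab != LABEL_AIR, 1, any))
  zr <- if (length(has_tooth)) range(has_tooth) else c(1L, d[1])
  out <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    z <- sample(zr[1]:zr[2], 1)
    r0 <- sample.int(d[2] - tile_size + 1L, 1)
    c0 <- sample.int(d[3] - tile_size + 1L, 1)
    out[[i]] <- list(
      grey = unclass(grey)[z, r0:(r0 + tile_size - 1L),
                           c0:(c0 + tile_size - 1L)],
      labels = lab[z, r0:(r0 + tile_size - 1L), c0:(c0 + tile_size - 1L)])
  }
  out
}
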