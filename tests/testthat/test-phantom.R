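test_that("a crack-free spec yields zero crack voxels", {
  ph <- ph_small_nocrack()
  expect_identical(sum(as.integer(ph$truth$labels) ==
                         label_codes()[["crack"]]), 0L)
})

test_that("explicit perpendicular plane normals are stored as given", {
  ph <- generate_phantom(small_spec(crack_network = crack_network_spec(
    plane_normals = rbind(c(1, 0, 0), c(0, 1, 0)),
    n_isolated_cracks = 0L, target_volume_fraction = NULL,
    widths_um = c(80, 130))))
  n <- ph$truth$crack_plane_normals
  expect_equal(nrow(n), 2L)
  ang <- acos(abs(sum(n[1, ] * n[2, ]))) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-9)
})

test_that("the connected network hits its target volume fraction", {
  # study-scale phantom; oracle = direct voxel count on the truth volume
  ph <- generate_phantom(phantom_spec(rng_seed = 42L))
  target <- 0.02
  expect_lt(abs(ph$truth$connected_network_voxel_fraction / target - 1), 0.10)
  crack <- crack_mask_of(ph$truth$labels)
  cc <- connected_components(crack)
  largest <- largest_k(cc, 1)[[1]]
  frac <- volume_fraction(largest, tooth_mask(ph$truth$labels))
  expect_lt(abs(frac / target - 1), 0.10)
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  s <- phantom_spec(grid_shape = c(48L, 48L, 48L), voxel_pitch_um = 120,
                    rng_seed = 9L)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(unclass(a$grey)[TRUE], unclass(b$grey)[TRUE])
  expect_identical(unclass(a$truth$labels)[TRUE],
                   unclass(b$truth$labels)[TRUE])
})

test_that("tissue shells are nested: pulp inside dentin inside enamel", {
  spec <- small_spec()
  geo <- toothcrack:::phantom_geometry(spec)
  # pulp strictly interior to the crown, tissues disjoint, shells inside grid
  expect_true(all(geo$rho[geo$pulp & geo$zq >= 0] < 1))
  expect_identical(sum(geo$enamel & geo$dentin), 0L)
  expect_identical(sum(geo$enamel & geo$pulp), 0L)
  expect_true(all(geo$rho[geo$dentin] <= 1))
  # the enamel shell separates dentin from outside air along x rays
  lab <- as_label <- unclass(ph_small_nocrack()$truth$labels)
  z <- 40
  for (y in c(35, 48, 60)) {
    row <- lab[z, y, ]
    dent <- which(row == label_codes()[["dentin"]])
    if (!length(dent)) next
    en <- which(row == label_codes()[["enamel"]])
    expect_true(min(en) < min(dent) && max(en) > max(dent))
  }
})

test_that("more primary planes never means fewer crack voxels", {
  counts <- vapply(c(0L, 2L, 4L), function(k) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = c(48L, 48L, 48L), voxel_pitch_um = 120, rng_seed = 3L,
      crack_network = crack_network_spec(
        n_primary_planes = k, n_isolated_cracks = 0L,
        target_volume_fraction = NULL, widths_um = c(130, 260))))
    sum(as.integer(ph$truth$labels) == label_codes()[["crack"]])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0)
})

test_that("rendered grey bands are ordered enamel > dentin > background", {
  ph <- generate_phantom(small_spec(noise_sd = 0,
    crack_network = crack_network_spec(n_primary_planes = 0L,
      n_isolated_cracks = 0L, target_volume_fraction = NULL)))
  g <- unclass(ph$grey)
  lab <- unclass(ph$truth$labels)
  enamel <- g[lab == label_codes()[["enamel"]]]
  dentin <- g[lab == label_codes()[["dentin"]]]
  crackfree_air <- g[lab == label_codes()[["air"]]]
  expect_gt(min(enamel), max(dentin))
  expect_gt(min(dentin), 0)
})

test_that("a half-voxel crack renders at half the tissue grey", {
  w_um <- 0.5 * 65 # half the pitch
  # plane tilted 10 degrees off the lattice so sub-voxel occupancy is
  # realized exactly (an axis-aligned plane sits between voxel centres)
  nrm <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)
  ph <- generate_phantom(small_spec(noise_sd = 0,
    crack_network = crack_network_spec(
      plane_normals = matrix(nrm, 1),
      n_isolated_cracks = 0L, target_volume_fraction = NULL,
      widths_um = c(w_um, w_um))))
  ph0 <- generate_phantom(small_spec(noise_sd = 0,
    crack_network = crack_network_spec(n_primary_planes = 0L,
      n_isolated_cracks = 0L, target_volume_fraction = NULL)))
  lab <- unclass(ph$truth$labels)
  crack <- lab == label_codes()[["crack"]]
  expect_gt(sum(crack), 0)
  ratio <- unclass(ph$grey)[crack] / pmax(unclass(ph0$grey)[crack], 1)
  expect_lt(max(abs(ratio - 0.5)), 0.05)
})

test_that("the cylinder-void scan artifact zeroes a vertical cylinder", {
  ph <- generate_phantom(small_spec(noise_sd = 0,
    artifacts = list(cylinder_void = TRUE, top_rays = FALSE)))
  spec <- small_spec()
  geo_cx <- (96 - 1) / 2
  rx <- 2.7 * 1000 / 65
  x0 <- round(geo_cx + rx / 3) + 1
  y0 <- round(geo_cx) + 1
  expect_true(all(unclass(ph$grey)[, y0, x0] == 0))
})

test_that("training tiles are reproducible, aligned, and class-complete", {
  ph <- ph_small()
  a <- generate_training_tiles(ph$grey, ph$truth$labels, 10, 64, seed = 21)
  b <- generate_training_tiles(ph$grey, ph$truth$labels, 10, 64, seed = 21)
  expect_identical(a, b)
  expect_length(a, 10L)
  expect_true(all(vapply(a, function(t) all(dim(t$grey) == c(64, 64)) &&
                           all(dim(t$labels) == c(64, 64)), logical(1))))
  census <- table(unlist(lapply(
    generate_training_tiles(ph$grey, ph$truth$labels, 100, 64, seed = 1),
    `[[`, "labels")))
  expect_setequal(names(census), as.character(0:3))
  expect_error(generate_training_tiles(ph$grey, ph$truth$labels, 0, 64),
               "positive")
})
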