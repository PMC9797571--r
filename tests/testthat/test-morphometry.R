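test_that("connected components follow the stated connectivity rules", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE
  m[4, 4, 4] <- TRUE
  cc <- connected_components(m)
  expect_length(cc$components, 2L)
  expect_true(all(vapply(cc$components, `[[`, numeric(1),
                         "voxel_count") == 1))

  corner <- array(FALSE, c(4, 4, 4))
  corner[2, 2, 2] <- TRUE
  corner[3, 3, 3] <- TRUE
  expect_length(connected_components(corner, 26L)$components, 1L)
  expect_length(connected_components(corner, 6L)$components, 2L)

  expect_length(connected_components(array(FALSE, c(3, 3, 3)))$components,
                0L)
})

test_that("component partition matches a brute-force flood fill", {
  set.seed(20)
  for (i in 1:8) {
    m <- array(runif(20^3) < 0.1, c(20, 20, 20))
    cc <- connected_components(m)
    fl <- flood_fill_labels(m)
    expect_true(same_partition(cc$labels, fl, m))
    expect_identical(length(cc$components), max(fl))
    # partition property: component sizes sum to the mask count
    expect_equal(sum(vapply(cc$components, `[[`, numeric(1),
                            "voxel_count")), sum(m))
  }
})

test_that("size filtering and largest-k behave like their sort oracles", {
  set.seed(21)
  m <- array(runif(18^3) < 0.12, c(18, 18, 18))
  cc <- connected_components(m)
  sizes <- vapply(cc$components, `[[`, numeric(1), "voxel_count")

  expect_identical(length(filter_by_size(cc, 1L)$components), length(sizes))
  expect_length(filter_by_size(cc, max(sizes) + 1L)$components, 0L)
  for (ms in c(2L, 5L, 9L))
    expect_identical(length(filter_by_size(cc, ms)$components),
                     sum(sizes >= ms))
  filt <- filter_by_size(cc, 3L)
  expect_equal(sum(filt$labels > 0),
               sum(vapply(filt$components, `[[`, numeric(1),
                          "voxel_count")))

  top <- largest_k(cc, 3L)
  expect_identical(vapply(top, `[[`, numeric(1), "voxel_count"),
                   head(sort(sizes, decreasing = TRUE), 3))
  # ties keep id order
  m2 <- array(FALSE, c(3, 9, 9))
  m2[2, 2, 2:6] <- TRUE; m2[2, 8, 2:6] <- TRUE; m2[2, 5, 8] <- TRUE
  cc2 <- connected_components(m2)
  top2 <- largest_k(cc2, 2L)
  expect_identical(vapply(top2, `[[`, numeric(1), "id"), c(1, 2))
  expect_length(largest_k(cc2, 5L), 3L)
})

test_that("volume fractions are simple voxel ratios", {
  tooth <- array(FALSE, c(5, 5, 5)); tooth[1:4, , ] <- TRUE # 100 voxels
  expect_equal(volume_fraction(list(voxel_count = 2), tooth), 0.02)
  expect_equal(volume_fraction(list(voxel_count = integer()), tooth), 0)
  expect_error(volume_fraction(list(voxel_count = 2),
                               array(FALSE, c(2, 2, 2))), "empty")
})

test_that("local width recovers slab thickness and flags sub-resolution", {
  m <- array(FALSE, c(24, 24, 24))
  m[11:13, 3:22, 3:22] <- TRUE # 3-voxel slab
  w <- local_width(m, 10)
  expect_lt(abs(median(w$width_um[m]) - 30), 10)
  expect_true(all(w$width_um[!m] == 0))

  thin <- array(FALSE, c(10, 16, 16)); thin[5, 3:14, 3:14] <- TRUE
  wt <- local_width(thin, 10)
  expect_true(all(wt$sub_resolution[thin]))

  # invariance to 90-degree volume rotation
  m_rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]
  wr <- local_width(m_rot, 10)
  expect_equal(sort(wr$width_um[m_rot]), sort(w$width_um[m]))
})

test_that("planarity separates sheets from threads", {
  sheet <- array(FALSE, c(24, 24, 5)); sheet[2:23, 2:23, 3] <- TRUE
  cs <- connected_components(sheet)$components[[1]]
  expect_gte(cs$planarity, 0.9)
  expect_equal(abs(cs$normal), c(1, 0, 0), tolerance = 1e-6)

  line <- array(FALSE, c(24, 5, 5)); line[2:23, 3, 3] <- TRUE
  cl <- connected_components(line)$components[[1]]
  expect_lte(cl$planarity, 0.1)
})

test_that("orientation modes find two perpendicular plane families", {
  ph <- generate_phantom(small_spec(seed = 3L,
    crack_network = crack_network_spec(
      plane_normals = rbind(c(1, 0, 0), c(0, 1, 0)),
      n_isolated_cracks = 0L, target_volume_fraction = NULL,
      widths_um = c(80, 130))))
  crack <- crack_mask_of(ph$truth$labels)
  om <- orientation_modes(crack)
  expect_lt(abs(om$mode_angle_deg - 90), 5)
  expect_identical(sum(om$histogram), sum(crack))
  expect_identical(nrow(om$normals), sum(crack))
})

test_that("a single plane produces one dominant orientation mode", {
  m <- array(FALSE, c(32, 32, 32))
  m[4:29, 4:29, 15:16] <- TRUE
  om <- orientation_modes(m)
  expect_gte(om$mode_mass[1], 0.8)
  expect_error(orientation_modes(array(FALSE, c(10, 10, 10))), "at least")
})

test_that("line-of-sight distances equal an explicit per-line scan", {
  m <- array(FALSE, c(10, 6, 6))
  m[6, 3, 4] <- TRUE
  d <- distance_to_crack_projection(m, "z")
  expect_equal(d[3, 4], 5) # sixth slice, 0-based depth 5
  expect_true(all(is.na(d[-(3 + (4 - 1) * 6)])))

  expect_true(all(is.na(
    distance_to_crack_projection(array(FALSE, c(4, 4, 4)), "x"))))

  set.seed(22)
  for (axis in c("z", "y", "x")) {
    m <- array(runif(7 * 8 * 9) < 0.15, c(7, 8, 9))
    got <- distance_to_crack_projection(m, axis)
    ax <- match(axis, c("z", "y", "x"))
    want <- apply(m, setdiff(1:3, ax), function(line) {
      w <- which(line)
      if (length(w)) w[1] - 1 else NA_real_
    })
    expect_identical(got, want)
  }
})
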