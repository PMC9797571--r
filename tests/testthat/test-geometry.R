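test_that("block-mean resampling averages blocks and conserves mass", {
  const <- grey_volume(array(100, c(8, 8, 8)), 5)
  r <- resample(const, 10)
  expect_identical(dim(r), c(4L, 4L, 4L))
  expect_true(all(unclass(r) == 100))
  expect_equal(voxel_pitch(r), 10)

  blk <- grey_volume(array(as.numeric(0:7), c(2, 2, 2)), 5)
  expect_equal(as.vector(unclass(resample(blk, 10))), 3.5)

  expect_identical(resample(const, 5), const)
  expect_error(resample(const, 12), "integer")
  expect_error(resample(const, 2), ">=")

  set.seed(4)
  v <- grey_volume(array(runif(8^3, 0, 65535), c(8, 8, 8)), 5)
  expect_equal(mean(unclass(resample(v, 20))), mean(unclass(v)),
               tolerance = 1e-12)
})

test_that("slab partition uses half-open equal thirds, remainder bottom-up", {
  m99 <- array(FALSE, c(101, 4, 4)); m99[2:100, 2:3, 2:3] <- TRUE
  ps <- partition_slabs(m99)
  expect_identical(ps$sizes, c(33L, 33L, 33L))
  expect_identical(ps$breaks, c(2L, 35L, 68L, 101L))

  m10 <- array(FALSE, c(12, 4, 4)); m10[2:11, 2:3, 2:3] <- TRUE
  expect_identical(partition_slabs(m10)$sizes, c(4L, 3L, 3L))

  set.seed(7)
  for (extent in sample(3:40, 8)) {
    m <- array(FALSE, c(extent + 2, 4, 4))
    m[2:(extent + 1), 2:3, 2:3] <- TRUE
    ps <- partition_slabs(m)
    expect_identical(sum(ps$sizes), extent)
    expect_true(all(ps$sizes >= 1L))
    expect_lte(max(ps$sizes) - min(ps$sizes), 1L)
  }
  expect_error(partition_slabs(array(FALSE, c(4, 4, 4))), "empty")
  m2 <- array(FALSE, c(6, 4, 4)); m2[2:3, 2, 2] <- TRUE
  expect_error(partition_slabs(m2), "fewer than 3")
})

test_that("sectors of an elliptical section contain their cardinal points", {
  yy <- matrix(rep(0:95, 96), 96); xx <- t(yy)
  m <- array(FALSE, c(9, 96, 96))
  for (z in 1:9) m[z, , ] <- ((xx - 47.5) / 40)^2 + ((yy - 47.5) / 25)^2 <= 1
  se <- partition_sectors(m)
  expect_false(any(se$fallback))
  # +x extreme -> palatal(3), -x -> buccal(1), +y -> contact_right(2),
  # -y -> contact_left(4)
  expect_identical(se$sector[5, 48, 86], 3L)
  expect_identical(se$sector[5, 48, 10], 1L)
  expect_identical(se$sector[5, 71, 48], 2L)
  expect_identical(se$sector[5, 25, 48], 4L)
  expect_true(all((se$sector > 0) == m))
})

test_that("a circular section falls back to near-equal quadrants", {
  yy <- matrix(rep(0:95, 96), 96); xx <- t(yy)
  m <- array(FALSE, c(9, 96, 96))
  for (z in 1:9) m[z, , ] <- (xx - 47.5)^2 + (yy - 47.5)^2 <= 30^2
  se <- partition_sectors(m)
  expect_true(all(se$fallback))
  counts <- tabulate(se$sector[se$sector > 0], 4)
  expect_lt(max(abs(counts / mean(counts) - 1)), 0.05)
})

test_that("slab-sector regions form an exact 12-part partition", {
  ph <- ph_small()
  tm <- tooth_mask(ph$truth$labels)
  reg <- slab_sector_regions(tm)
  expect_identical(nrow(reg$table), 12L)
  expect_true(all(reg$table$voxel_count > 0))
  expect_equal(sum(reg$table$voxel_count), sum(tm))
  inside <- reg$region > 0
  expect_true(all(inside == tm))
  # region id composes slab and sector consistently
  expect_true(all(reg$region[inside] ==
                    (reg$slab[inside] - 1L) * 4L + reg$sector[inside]))
})

test_that("principal-axis alignment recovers an applied rotation", {
  ph <- ph_small_nocrack()
  tm <- tooth_mask(ph$truth$labels)
  al <- align_axes(ph$grey, tm)
  expect_lt(rotation_angle_deg(al$rotation), 1)

  th <- 30 * pi / 180
  Rz <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  cm <- colMeans(arrayInd(which(tm), dim(tm)) - 1)
  rot <- toothcrack:::cpp_rotate_nn(as.numeric(unclass(ph$grey)), dim(tm),
                                    t(Rz), cm)
  vr <- grey_volume(array(pmin(pmax(rot, 0), 65535), dim(tm)),
                    voxel_pitch(ph$grey))
  mr <- array(unclass(vr) > 20000, dim(tm))
  al2 <- align_axes(vr, mr)
  expect_lt(rotation_angle_deg(al2$rotation %*% Rz), 2)

  m3 <- array(unclass(al2$volume) > 20000, dim(tm))
  al3 <- align_axes(al2$volume, m3)
  expect_lt(rotation_angle_deg(al3$rotation), 1)

  expect_error(align_axes(ph$grey, array(FALSE, dim(tm))), "empty")
})
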