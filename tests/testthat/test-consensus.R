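lv1 <- function(code) label_volume(array(code, c(1, 1, 1)), 1)

test_that("the crack vote matches exhaustive enumeration on all triples", {
  for (cx in 0:3) for (cy in 0:3) for (cz in 0:3) {
    got <- vote_crack(lv1(cx), lv1(cy), lv1(cz))[1]
    want <- sum(c(cx, cy, cz) == 3L) >= 2L # brute-force vote counter
    expect_identical(got, want)
  }
})

test_that("the crack vote is permutation-invariant", {
  set.seed(12)
  vols <- lapply(1:3, function(i)
    label_volume(array(sample(0:3, 216, TRUE, prob = c(1, 1, 1, 2)),
                       c(6, 6, 6)), 1))
  ref <- vote_crack(vols[[1]], vols[[2]], vols[[3]])
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms)
    expect_identical(vote_crack(vols[[p[1]]], vols[[p[2]]], vols[[p[3]]]),
                     ref)
})

test_that("non-crack voxels take the majority, ties go z then y then x", {
  # (x, y, z) = (enamel, enamel, dentin), not crack -> enamel
  m <- array(FALSE, c(1, 1, 1))
  out <- resolve_noncrack(lv1(1), lv1(1), lv1(2), m)
  expect_identical(as.integer(out)[1], 1L)
  # (enamel, dentin, air): three-way tie -> z label (air)
  out <- resolve_noncrack(lv1(1), lv1(2), lv1(0), m)
  expect_identical(as.integer(out)[1], 0L)
  # z vote is crack (discarded), y breaks the tie
  out <- resolve_noncrack(lv1(1), lv1(2), lv1(3), m)
  expect_identical(as.integer(out)[1], 2L)
  # crack-mask voxels take the crack code regardless of labels
  out <- resolve_noncrack(lv1(1), lv1(1), lv1(1), array(TRUE, c(1, 1, 1)))
  expect_identical(as.integer(out)[1], 3L)
})

test_that("resolution honours its full-volume contract", {
  set.seed(13)
  vols <- lapply(1:3, function(i)
    label_volume(array(sample(0:3, 512, TRUE), c(8, 8, 8)), 1))
  crack <- vote_crack(vols[[1]], vols[[2]], vols[[3]])
  out <- resolve_noncrack(vols[[1]], vols[[2]], vols[[3]], crack)
  expect_true(all(as.integer(out) %in% 0:3))
  expect_identical(array(as.integer(out) == 3L, dim(out)), crack)
})

test_that("fill-in leaves crack-free volumes untouched", {
  ph <- ph_small_nocrack()
  out <- fill_in(ph$truth$labels)
  expect_identical(unclass(out)[TRUE], unclass(ph$truth$labels)[TRUE])
})

test_that("an isolated crack voxel in enamel is restored to enamel", {
  lab <- array(label_codes()[["enamel"]], c(3, 9, 9))
  lab[2, 5, 5] <- label_codes()[["crack"]]
  lv <- label_volume(lab, 10)
  out <- fill_in(lv)
  expect_identical(as.integer(out[2, 5, 5]), 1L)
  expect_identical(sum(as.integer(out) == 3L), 0L)
})

test_that("fill-in restores the crack-free tooth on phantom labels", {
  ph <- ph_small()
  ph0 <- ph_small_nocrack()
  lab <- ph$truth$labels
  crack <- crack_mask_of(lab)
  filled <- fill_in(lab, crack, 1L)
  expect_identical(sum(as.integer(filled) == 3L), 0L)
  dil <- dilate_mask_z(crack, 1L)
  # unchanged outside the dilated mask
  expect_true(all(unclass(filled)[!dil] == unclass(lab)[!dil]))
  # at least 95% of filled voxels match the crack-free twin phantom
  expect_gte(mean(unclass(filled)[dil] == unclass(ph0$truth$labels)[dil]),
             0.95)
  # idempotent
  again <- fill_in(filled, dilation_radius = 1L)
  expect_identical(unclass(again)[TRUE], unclass(filled)[TRUE])
})

test_that("fill-in fails loudly when a slice has no tissue left", {
  lab <- array(label_codes()[["crack"]], c(1, 5, 5))
  expect_error(fill_in(label_volume(lab, 10)), "masked")
})
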