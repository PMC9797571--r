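test_that("tile grids cover the slice minimally with a flush last tile", {
  g <- make_tile_grid(c(1000L, 1000L), 512L, 244L)
  expect_identical(nrow(g$origins), 9L) # ceil((1000-512)/244)+1 = 3 per dim
  expect_identical(max(g$origins[, 1]), 489L) # flush: 489 + 512 - 1 = 1000

  g1 <- make_tile_grid(c(512L, 512L), 512L)
  expect_identical(unname(g1$origins), matrix(c(1L, 1L), 1))

  set.seed(11)
  for (i in 1:50) {
    shape <- sample(40:160, 2, replace = TRUE)
    ts <- sample(16:min(shape), 1)
    st <- sample(seq_len(ts), 1)
    g <- make_tile_grid(shape, ts, st)
    cov <- matrix(0L, shape[1], shape[2])
    for (k in seq_len(nrow(g$origins))) {
      r0 <- g$origins[k, 1]; c0 <- g$origins[k, 2]
      cov[r0:(r0 + ts - 1), c0:(c0 + ts - 1)] <-
        cov[r0:(r0 + ts - 1), c0:(c0 + ts - 1)] + 1L
    }
    expect_true(all(cov >= 1L))
  }
  expect_error(make_tile_grid(c(100L, 100L), 128L), "smaller")
})

test_that("three-channel replication copies the grey tile exactly", {
  set.seed(3)
  t2 <- matrix(runif(64, 0, 65535), 8, 8)
  x <- to_three_channel(t2)
  expect_identical(dim(x), c(8L, 8L, 3L))
  expect_identical(x[, , 1], t2)
  expect_identical(x[, , 2], t2)
  expect_identical(x[, , 3], t2)
  expect_true(all(to_three_channel(matrix(0, 4, 4)) == 0))
})

test_that("pixel accuracy equals the confusion-matrix trace fraction", {
  a <- label_volume(array(sample(0:3, 1000, TRUE), c(10, 10, 10)), 1)
  expect_identical(pixel_accuracy(a, a), 1)
  b <- unclass(a)
  b[1] <- (b[1] + 1L) %% 4L
  b100 <- label_volume(array(b[1:100], c(4, 5, 5)), 1)
  a100 <- label_volume(array(unclass(a)[1:100], c(4, 5, 5)), 1)
  expect_equal(pixel_accuracy(b100, a100), 0.99)
  set.seed(5)
  for (i in 1:5) {
    p <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
    q <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
    cm <- table(factor(p, 0:3), factor(q, 0:3))
    expect_equal(pixel_accuracy(p, q), sum(diag(cm)) / sum(cm))
  }
  expect_error(pixel_accuracy(a, a100), "shape")
})

test_that("the thresholding oracle classifies noise-free phantom slices", {
  ph <- ph_small_noise0()
  b <- rule_based_oracle()
  for (z in c(30, 45, 60)) {
    pr <- predict(b, unclass(ph$grey)[z, , ])
    pred <- apply(pr, c(1, 2), which.max) - 1L
    expect_gte(mean(pred == unclass(ph$truth$labels)[z, , ]), 0.98)
  }
})

test_that("oracle degenerate slices: all air, and no cracks without holes", {
  b <- rule_based_oracle()
  z0 <- matrix(0, 32, 32)
  pr <- predict(b, z0)
  expect_true(all(apply(pr, c(1, 2), which.max) - 1L == 0L))
  en <- matrix(40000, 32, 32)
  pr2 <- predict(b, en)
  lab <- apply(pr2, c(1, 2), which.max) - 1L
  expect_true(all(lab == label_codes()[["enamel"]]))
  expect_identical(sum(lab == label_codes()[["crack"]]), 0L)
  expect_error(rule_based_oracle(30000, 20000), "ordered")
})

test_that("backend probability maps are per-pixel simplex vectors", {
  ph <- ph_small()
  pr <- predict(rule_based_oracle(), unclass(ph$grey)[45, , ])
  expect_true(all(abs(apply(pr, c(1, 2), sum) - 1) < 1e-5))
  expect_true(min(pr) >= 0)
})

test_that("axis segmentation census matches truth within 2% per class", {
  # study-scale noise-free phantom, z axis
  ph <- generate_phantom(phantom_spec(rng_seed = 9L, noise_sd = 0))
  lz <- segment_axis(ph$grey, rule_based_oracle(), "z")
  expect_true(all(as.integer(lz) %in% 0:3))
  ct <- tabulate(as.integer(lz) + 1L, 4L)
  tt <- tabulate(as.integer(ph$truth$labels) + 1L, 4L)
  expect_true(all(abs(ct / tt - 1) <= 0.02))
})

test_that("a constant-prediction backend yields a constant label volume", {
  const_backend <- toothcrack:::new_backend("const", function(tile) {
    pr <- array(0, c(dim(tile), 4))
    pr[, , 3] <- 1
    pr
  })
  v <- grey_volume(array(runif(16^3, 0, 65535), c(16, 16, 16)), 10)
  out <- segment_axis(v, const_backend, "y")
  expect_true(all(unclass(out) == 2L))
})

test_that("tiled assembly is lossless for a pure per-pixel backend", {
  pixel_backend <- toothcrack:::new_backend("pixel", function(tile) {
    pr <- array(0, c(dim(tile), 4))
    cls <- 1L + (tile > 20000) + (tile > 40000)
    for (k in 1:4) pr[, , k] <- (cls == k - 1L) + (cls == k)
    pr / array(rep(apply(pr, c(1, 2), sum), 4), dim(pr))
  })
  v <- grey_volume(array(runif(24 * 24 * 24, 0, 65535), c(24, 24, 24)), 10)
  full <- segment_axis(v, pixel_backend, "z")
  for (st in c(8L, 12L, 16L)) {
    tiled <- segment_axis(v, pixel_backend, "z", tile_size = 16L, stride = st)
    expect_identical(unclass(tiled)[TRUE], unclass(full)[TRUE])
  }
  # tile equal to the slice reduces to the single-tile result
  one <- segment_axis(v, pixel_backend, "z", tile_size = 24L)
  expect_identical(unclass(one)[TRUE], unclass(full)[TRUE])
})

test_that("training on a constant-label dataset collapses to that class", {
  set.seed(8)
  tiles <- replicate(4, matrix(runif(32 * 32, 0, 65535), 32, 32),
                     simplify = FALSE)
  labs <- replicate(4, matrix(2L, 32, 32), simplify = FALSE)
  b <- train_classifier(tiles, labs,
                        train_config(epochs = 4, learning_rate = 1e-2,
                                     batch_size = 2, seed = 1))
  pr <- predict(b, tiles[[1]])
  expect_true(all(apply(pr, c(1, 2), which.max) - 1L == 2L))
})

test_that("training is deterministic for a fixed seed", {
  ph <- ph_small()
  tiles <- generate_training_tiles(ph$grey, ph$truth$labels, 10, 32, seed = 6)
  g <- lapply(tiles, `[[`, "grey")
  l <- lapply(tiles, `[[`, "labels")
  cfg <- train_config(epochs = 2, learning_rate = 1e-3, seed = 4)
  acc_of <- function() {
    b <- train_classifier(g[1:8], l[1:8], cfg)
    mean(unlist(lapply(9:10, function(i) {
      (apply(predict(b, g[[i]]), c(1, 2), which.max) - 1L) == l[[i]]
    })))
  }
  a1 <- acc_of()
  a2 <- acc_of()
  expect_equal(round(a1, 3), round(a2, 3))
  expect_error(train_classifier(g[1], list(matrix(9L, 32, 32)),
                                cfg), "codes")
})

test_that("a small training set already segments held-out tiles well", {
  ph <- ph_default128()
  tiles <- generate_training_tiles(ph$grey, ph$truth$labels, 65, 96,
                                   seed = 4)
  g <- lapply(tiles, `[[`, "grey")
  l <- lapply(tiles, `[[`, "labels")
  b <- train_classifier(g[1:50], l[1:50],
                        train_config(epochs = 30, learning_rate = 2e-3,
                                     seed = 2))
  # training loss decreases on average across epochs
  lh <- b$meta$loss_history
  expect_lt(mean(tail(lh, 5)), mean(head(lh, 5)))
  acc <- mean(unlist(lapply(51:65, function(i) {
    (apply(predict(b, g[[i]]), c(1, 2), which.max) - 1L) == l[[i]]
  })))
  expect_gte(acc, 0.99)
})
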