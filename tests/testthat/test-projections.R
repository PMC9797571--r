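test_that("projected density sums columns and normalizes", {
  m <- array(TRUE, c(5, 4, 3))
  p <- projected_density(m, "z", "sqrt")
  expect_identical(dim(p), c(4L, 3L))
  expect_true(all(p == 1)) # constant depth -> constant normalized map

  single <- array(FALSE, c(4, 4, 4)); single[2, 3, 1] <- TRUE
  ps <- projected_density(single, "z")
  expect_identical(sum(ps > 0), 1L)
  expect_equal(ps[3, 1], 1)

  set.seed(40)
  v <- array(runif(5 * 6 * 7), c(5, 6, 7))
  for (axis in c("z", "y", "x")) {
    got <- projected_density(v, axis, "linear")
    ax <- match(axis, c("z", "y", "x"))
    want <- apply(v, setdiff(1:3, ax), sum)
    want <- want / max(want)
    expect_equal(got, want)
  }
  expect_error(projected_density(array(numeric(0), c(0, 0, 0)), "z"),
               "empty")
})

test_that("depth shading inverts first-hit depth and respects occlusion", {
  m <- array(FALSE, c(10, 6, 6))
  m[4, , ] <- TRUE
  s <- depth_shaded_projection(m, "z")
  expect_true(all(s == 1 - 3 / 10))

  m[8, 1:3, ] <- TRUE # farther plane, partially behind the nearer one
  s2 <- depth_shaded_projection(m, "z")
  expect_true(all(s2 == 1 - 3 / 10)) # nearer plane occludes everywhere

  empty <- depth_shaded_projection(array(FALSE, c(4, 4, 4)), "y")
  expect_true(all(empty == 0))

  # consistency with the distance map through the shade transfer
  set.seed(41)
  r <- array(runif(6^3) < 0.2, c(6, 6, 6))
  d <- distance_to_crack_projection(r, "x")
  sh <- 1 - d / 6
  sh[is.na(sh)] <- 0
  expect_equal(depth_shaded_projection(r, "x"), sh)
})

test_that("projections commute with 90-degree volume rotations", {
  set.seed(42)
  m <- array(runif(6 * 6 * 6) < 0.3, c(6, 6, 6))
  # rotate 90 degrees in the (y, x) plane: y' = x, x' = rev(y)
  mr <- aperm(m, c(1, 3, 2))[, , dim(m)[2]:1]
  pz <- projected_density(m, "z")
  pzr <- projected_density(mr, "z")
  expect_equal(pzr, t(pz)[, nrow(pz):1])
})

test_that("the pipeline produces its artifact set deterministically", {
  cfg <- default_pipeline_config(seed = 3L)
  cfg$phantom$grid <- 64L
  cfg$phantom$pitch_um <- 100
  cfg$phantom$noise_sd <- 800
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  unlink(c(d1, d2), recursive = TRUE)
  res <- run_pipeline(cfg, d1)
  for (f in c("grey.nrrd", "labels.nrrd", "labels_filled.nrrd",
              "components.csv", "regions.csv", "provenance.json", "run.log",
              "crack_density_z.png", "crack_density_y.png",
              "crack_density_x.png", "crack_depth_y.png"))
    expect_true(file.exists(file.path(d1, f)), label = f)
  reg <- read.csv(file.path(d1, "regions.csv"))
  expect_identical(nrow(reg), 12L)
  expect_gt(nrow(read_component_table(file.path(d1, "components.csv"))), 0L)
  # labels contain no crack after fill-in
  filled <- read_volume(file.path(d1, "labels_filled.nrrd"))
  expect_identical(sum(as.integer(filled) == 3L), 0L)

  run_pipeline(cfg, d2)
  expect_identical(readLines(file.path(d1, "components.csv")),
                   readLines(file.path(d2, "components.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a crack-free configuration yields an empty component table", {
  cfg <- default_pipeline_config(seed = 4L)
  cfg$phantom$grid <- 64L
  cfg$phantom$pitch_um <- 100
  cfg$phantom$n_planes <- 0L
  cfg$phantom$n_isolated <- 0L
  d <- file.path(tempdir(), "run_nocrack")
  unlink(d, recursive = TRUE)
  run_pipeline(cfg, d)
  tab <- read_component_table(file.path(d, "components.csv"))
  expect_identical(nrow(tab), 0L)
  unlink(d, recursive = TRUE)
})
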