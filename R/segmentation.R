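# Per-slice voxel classification. Slices taken perpendicular to x, y or z
# are cut into overlapping square tiles, each tile is classified pixelwise
# into {air, enamel, dentin, crack} by a pluggable backend, and the
# per-pixel class probabilities are assembled back to full-slice maps
# (overlaps resolved by probability averaging, then argmax). Two backends
# are provided: a small trainable CNN and a deterministic grey-level
# thresholding oracle with a morphological enclosure criterion for cracks.

#' Build a minimal covering tile grid for a slice
#'
#' Origins advance by `stride` and the final origin per dimension is clamped
#' so the last tile ends flush with the slice edge; every pixel is covered
#' by at least one tile.
#'
#' @param slice_shape Integer `(rows, cols)`.
#' @param tile_size Tile side in pixels (default 512, the full-scale
#'   convention; desk-scale work uses 64-128).
#' @param stride Origin step, `<= tile_size` (default `tile_size / 2`).
#' @return A list of class `tile_grid` with `origins` (matrix of 1-based
#'   `(row0, col0)`), `tile_size`, `stride`, `slice_shape`.
#' @export
make_tile_grid <- function(slice_shape, tile_size = 512L,
                           stride = tile_size %/% 2L) {
  stopifnot(length(slice_shape) == 2, stride >= 1, stride <= tile_size)
  if (any(tile_size > slice_shape))
    stop("make_tile_grid: slice smaller than tile")
  starts <- function(n) {
    if (n == tile_size) return(1L)
    s <- seq.int(1L, n - tile_size + 1L, by = stride)
    if (s[length(s)] != n - tile_size + 1L) s <- c(s, n - tile_size + 1L)
    as.integer(s)
  }
  r0 <- starts(slice_shape[1]); c0 <- starts(slice_shape[2])
  origins <- cbind(row0 = rep(r0, times = length(c0)),
                   col0 = rep(c0, each = length(r0)))
  structure(list(origins = origins, tile_size = as.integer(tile_size),
                 stride = as.integer(stride),
                 slice_shape = as.integer(slice_shape)),
            class = "tile_grid")
}

#' Replicate a greyscale tile to three identical channels
#'
#' Greyscale tiles are expanded to 3-channel arrays (the RGB-replication
#' convention used to feed grey µCT slices to image networks).
#'
#' @param tile 2D numeric matrix.
#' @return `nrow x ncol x 3` array with identical channels.
#' @export
to_three_channel <- function(tile) {
  stopifnot(is.matrix(tile))
  array(rep(tile, 3L), c(dim(tile), 3L))
}

#' Training configuration for the slice classifier
#'
#' Defaults follow the reference training recipe: 50 epochs, Adam with
#' learning rate 1e-5, batch size 5, random contrast and flip/rotation
#' augmentations, categorical cross-entropy loss. The learning rate is
#' scaled up (typically to 1e-3) for the desk-scale network, which is far
#' smaller than a full ResNet-backbone segmenter.
#'
#' @param epochs Positive integer.
#' @param learning_rate Positive scalar.
#' @param batch_size Positive integer.
#' @param augment Logical: apply random contrast (+/-20%), horizontal and
#'   vertical flips and k*90-degree rotations during training.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-5, batch_size = 5L,
                         augment = TRUE, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = "adam",
                 loss = "categorical_crossentropy",
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

new_backend <- function(name, predict_fn, meta = list()) {
  structure(list(name = name, predict = predict_fn, meta = meta),
            class = "crack_backend")
}

#' @export
print.crack_backend <- function(x, ...) {
  cat(sprintf("<crack_backend> %s\n", x$name))
  if (length(x$meta)) utils::str(x$meta, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Predict per-pixel class probabilities for one slice or tile
#'
#' @param object A `crack_backend`.
#' @param tile Numeric matrix of raw grey values (0-65535).
#' @param ... Unused.
#' @return `nrow x ncol x 4` array of class probabilities (air, enamel,
#'   dentin, crack), each pixel summing to 1.
#' @export
predict.crack_backend <- function(object, tile, ...) {
  object$predict(tile)
}

aug_apply <- function(m, flip_h, flip_v, rot_k) {
  if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
  k <- rot_k %% 4L
  while (k > 0L) { m <- t(m[nrow(m):1, , drop = FALSE]); k <- k - 1L }
  m
}

#' Train the reference CNN slice classifier
#'
#' A small dilated-context encoder-decoder network (two downsampling
#' stages, dilated 3x3 convolutions at the deepest stage for context, a
#' nearest-neighbour upsampling decoder with a full-resolution skip
#' connection for boundary accuracy) trained with Adam on categorical
#' cross-entropy. Training is deterministic for a fixed config seed.
#'
#' @param tiles List of greyscale tiles (square matrices, raw grey values;
#'   side divisible by 4).
#' @param label_tiles List of matching label tiles (codes 0..3).
#' @param config A [train_config()].
#' @return A `crack_backend` with the trained weights in `meta$weights` and
#'   the per-epoch mean loss in `meta$loss_history`.
#' @export
train_classifier <- function(tiles, label_tiles, config = train_config()) {
  stopifnot(length(tiles) >= 1, length(tiles) == length(label_tiles),
            inherits(config, "train_config"))
  hw <- dim(tiles[[1]])
  stopifnot(hw[1] %% 4 == 0, hw[2] %% 4 == 0)
  for (lt in label_tiles) {
    l <- as.integer(lt)
    if (anyNA(l) || any(l < 0L | l > 3L))
      stop("train_classifier: label codes outside {0..3}")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  net <- cpp_cnn_new()
  n <- length(tiles)
  t_step <- 0L
  loss_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq.int(1L, n, by = config$batch_size)) {
      ids <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xs <- vector("list", length(ids))
      ys <- vector("list", length(ids))
      for (j in seq_along(ids)) {
        g <- tiles[[ids[j]]]
        l <- label_tiles[[ids[j]]]
        if (config$augment) {
          fh <- runif(1) < 0.5; fv <- runif(1) < 0.5
          rk <- sample(0:3, 1)
          ct <- runif(1, 0.8, 1.2)
          g <- aug_apply(g, fh, fv, rk) * ct
          l <- aug_apply(l, fh, fv, rk)
        }
        x <- pmin(pmax(as.numeric(g) / 65535, 0), 1)
        xs[[j]] <- matrix(rep(x, 3L), ncol = 3L)
        ys[[j]] <- as.integer(l)
      }
      t_step <- t_step + 1L
      losses <- c(losses, cpp_cnn_train_batch(net, xs, ys,
                                              config$learning_rate, t_step,
                                              dim(g)))
    }
    loss_hist[ep] <- mean(losses)
  }
  w <- cpp_cnn_get_weights(net)
  predict_fn <- make_cnn_predict(w)
  new_backend("cnn", predict_fn,
              meta = list(weights = w, config = config,
                          loss_history = loss_hist, tile_size = hw[1]))
}

make_cnn_predict <- function(weights) {
  force(weights)
  function(tile) {
    stopifnot(is.matrix(tile))
    d <- dim(tile)
    pad <- (4L - d %% 4L) %% 4L
    g <- tile
    if (any(pad > 0L)) {
      g <- rbind(g, g[rep(nrow(g), pad[1]), , drop = FALSE])
      g <- cbind(g, g[, rep(ncol(g), pad[2]), drop = FALSE])
    }
    x <- pmin(pmax(as.numeric(g) / 65535, 0), 1)
    net <- cpp_cnn_new()
    cpp_cnn_set_weights(net, weights)
    pr <- cpp_cnn_predict(net, matrix(rep(x, 3L), ncol = 3L), dim(g))
    out <- array(pr, c(dim(g), 4L))
    out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  }
}

#' Rebuild a CNN backend from stored weights
#'
#' @param weights Weight list from a trained backend (`meta$weights`),
#'   e.g. after serialisation.
#' @param config Optional [train_config()] metadata to carry along.
#' @return A `crack_backend`.
#' @export
cnn_backend <- function(weights, config = NULL) {
  new_backend("cnn", make_cnn_predict(weights),
              meta = list(weights = weights, config = config))
}

#' Deterministic grey-level thresholding oracle backend
#'
#' Classifies by two ordered grey thresholds: above the dentin/enamel
#' threshold is enamel, between the thresholds is dentin, below the
#' air/dentin threshold is air - except that low pixels enclosed by tooth
#' tissue in the slice (a morphological hole criterion: the tissue mask is
#' closed to bridge narrow surface openings, then everything not reachable
#' from the slice border is interior) are classified as crack. The principal
#' tooth components of a µCT slice are separable by grey level by eye,
#' which motivates this reference backend; the enclosure step fixes
#' the one genuine ambiguity (cracks, pulp and outside air share grey
#' values).
#'
#' @param threshold_air_dentin Grey value separating air from dentin.
#' @param threshold_dentin_enamel Grey value separating dentin from enamel;
#'   must exceed `threshold_air_dentin`.
#' @param closing_radius Radius (pixels) of the square closing used to seal
#'   narrow crack mouths at the tooth surface before the enclosure test.
#' @param pulp_opening_radius Radius (pixels) of the square opening that
#'   separates wide enclosed dark areas (the pulp cavity, scan voids) from
#'   thin cracks: anything surviving the opening is classified air.
#' @return A `crack_backend`.
#' @export
rule_based_oracle <- function(threshold_air_dentin = 14000,
                              threshold_dentin_enamel = 34500,
                              closing_radius = 3L,
                              pulp_opening_radius = 2L) {
  if (!(threshold_air_dentin < threshold_dentin_enamel))
    stop("rule_based_oracle: thresholds must be ordered")
  t1 <- threshold_air_dentin; t2 <- threshold_dentin_enamel
  r <- closing_radius; rp <- pulp_opening_radius
  predict_fn <- function(tile) {
    stopifnot(is.matrix(tile))
    d2 <- dim(tile)
    tissue <- tile >= t1
    closed <- cpp_erode2d(cpp_dilate2d(as.vector(tissue), d2, r), d2, r)
    outside <- cpp_flood_outside(closed | as.vector(tissue), d2)
    lab <- matrix(LABEL_AIR, d2[1], d2[2])
    lab[tile >= t1 & tile < t2] <- LABEL_DENTIN
    lab[tile >= t2] <- LABEL_ENAMEL
    inside <- !matrix(outside, d2[1], d2[2])
    # "low" for the crack step is contrast-relative: below half the local
    # tissue grey, with the reference recovered by a grey-value closing
    # (partial-volume cracks in enamel are not low on the absolute air
    # threshold but are clear local dips)
    ref <- matrix(cpp_grey_close2d(as.numeric(tile), d2, r), d2[1], d2[2])
    lowrel <- tile < 0.5 * ref
    enclosed_abs <- tile < t1 & inside
    cand <- lowrel & inside
    if (any(cand)) {
      # wide enclosed dark areas survive an opening (the pulp cavity);
      # thin ones are cracks -- provided they run between tissue walls
      # (sealed surface notches just outside the tooth have tissue on the
      # inward side only)
      blob <- matrix(cpp_dilate2d(cpp_erode2d(as.vector(enclosed_abs), d2,
                                              rp), d2, rp),
                     d2[1], d2[2])
      # thin dark caps of the cavity wall escape the square opening and
      # mimic cracks; a cavity-adjacent dark pixel is kept as crack only
      # when its dark line continues away from the cavity (a crack
      # piercing the wall does, a tangential cap does not)
      blobm <- matrix(cpp_dilate2d(as.vector(blob), d2, 2L), d2[1], d2[2])
      ring <- blobm & !blob
      continues <- matrix(cpp_dilate2d(as.vector(cand & !blobm), d2, 2L),
                          d2[1], d2[2])
      walled <- cpp_walled2d(as.numeric(tile), d2, t1, 4L)
      crackpix <- cand & !blob & matrix(walled, d2[1], d2[2]) &
        (!ring | continues)
      if (any(crackpix)) {
        # partial-volume shoulders next to a crack dip toward dentin grey;
        # reassign them from a tight local tissue reference
        shoulder <- matrix(cpp_dilate2d(as.vector(crackpix), d2, 2L),
                           d2[1], d2[2]) & !crackpix & inside
        ref2 <- matrix(cpp_grey_close2d(as.numeric(tile), d2, 2L),
                       d2[1], d2[2])
        lab[shoulder & tile >= t1 & ref2 >= t2] <- LABEL_ENAMEL
      }
      lab[crackpix] <- LABEL_CRACK
    }
    pr <- array(0, c(d2, 4L))
    for (k in 0:3) pr[, , k + 1][lab == k] <- 1
    pr
  }
  new_backend("rule_based_oracle", predict_fn,
              meta = list(threshold_air_dentin = t1,
                          threshold_dentin_enamel = t2,
                          closing_radius = r,
                          pulp_opening_radius = rp))
}

#' Segment a volume slice-by-slice along one axis
#'
#' Every slice perpendicular to `axis` is tiled, each tile is classified by
#' the backend, per-pixel class probabilities are averaged over overlapping
#' tiles and the argmax taken. With `tile_size = NULL` each slice is
#' processed as a single tile (the natural choice for context-dependent
#' backends such as the thresholding oracle).
#'
#' @param volume A [grey_volume()].
#' @param backend A `crack_backend`.
#' @param axis One of `"z"`, `"y"`, `"x"` (slices are perpendicular to it).
#' @param tile_size Optional tile side; `NULL` = whole slice.
#' @param stride Optional stride (default half the tile).
#' @return A [label_volume()] of the same shape.
#' @export
segment_axis <- function(volume, backend, axis = c("z", "y", "x"),
                         tile_size = NULL, stride = NULL) {
  stopifnot(inherits(volume, "grey_volume"), inherits(backend, "crack_backend"))
  axis <- match.arg(axis)
  d <- dim(volume)
  arr <- as_plain_array(volume)
  ax <- match(axis, c("z", "y", "x"))
  n_slices <- d[ax]
  out <- array(LABEL_AIR, d)
  for (s in seq_len(n_slices)) {
    sl <- switch(axis,
                 z = arr[s, , , drop = TRUE],
                 y = arr[, s, , drop = TRUE],
                 x = arr[, , s, drop = TRUE])
    lab <- segment_slice(sl, backend, tile_size, stride)
    switch(axis,
           z = { out[s, , ] <- lab },
           y = { out[, s, ] <- lab },
           x = { out[, , s] <- lab })
  }
  label_volume(out, voxel_pitch(volume))
}

segment_slice <- function(sl, backend, tile_size, stride) {
  d2 <- dim(sl)
  if (is.null(tile_size) || all(tile_size >= d2)) {
    pr <- predict(backend, sl)
    return(matrix(max.col(matrix(pr, prod(d2), 4L), ties.method = "first") - 1L,
                  d2[1], d2[2]))
  }
  if (is.null(stride)) stride <- max(1L, tile_size %/% 2L)
  grid <- make_tile_grid(d2, tile_size, stride)
  acc <- array(0, c(d2, 4L))
  cnt <- matrix(0, d2[1], d2[2])
  for (i in seq_len(nrow(grid$origins))) {
    r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    rr <- r0:(r0 + tile_size - 1L); cc <- c0:(c0 + tile_size - 1L)
    pr <- predict(backend, sl[rr, cc, drop = FALSE])
    acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] + pr
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  pr <- acc / array(cnt, c(d2, 4L))
  matrix(max.col(matrix(pr, prod(d2), 4L), ties.method = "first") - 1L,
         d2[1], d2[2])
}

#' Overall per-pixel agreement between two label volumes
#'
#' @param pred,truth Label volumes (or plain integer arrays) of equal shape.
#' @return Fraction of voxels with identical codes, in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pixel_accuracy: shape mismatch")
  mean(as.integer(pred) == as.integer(truth))
}
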