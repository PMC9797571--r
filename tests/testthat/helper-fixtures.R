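# Shared fixtures, generated once per test session. All phantoms are small
# (96^3 or less) desk-scale teeth; the 128^3 default-geometry phantom is
# used only where a test reproduces a study-scale measurement.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_spec <- function(seed = 5L, noise_sd = 1500, ...) {
  phantom_spec(grid_shape = c(96L, 96L, 96L), voxel_pitch_um = 65,
               noise_sd = noise_sd, rng_seed = seed, ...)
}

ph_small <- function() fixture("ph_small", function() {
  generate_phantom(small_spec())
})

ph_small_nocrack <- function() fixture("ph_small_nocrack", function() {
  generate_phantom(small_spec(crack_network = crack_network_spec(
    n_primary_planes = 0L, n_isolated_cracks = 0L,
    target_volume_fraction = NULL)))
})

ph_small_noise0 <- function() fixture("ph_small_noise0", function() {
  generate_phantom(small_spec(noise_sd = 0))
})

ph_default128 <- function() fixture("ph_default128", function() {
  generate_phantom(phantom_spec(rng_seed = 7L))
})

# brute-force 26/6-connectivity flood fill, the independent oracle for
# connected-component tests
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        n <- co + offs[k, ]
        if (any(n < 1L) || any(n > d)) next
        li <- n[1] + d[1] * ((n[2] - 1L) + d[2] * (n[3] - 1L))
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition iff the label pairing is 1:1
same_partition <- function(a, b, mask) {
  pairs <- unique(cbind(a[mask], b[mask]))
  nrow(pairs) == length(unique(pairs[, 1])) &&
    nrow(pairs) == length(unique(pairs[, 2]))
}

rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

crack_mask_of <- function(labels) {
  array(as.integer(labels) == label_codes()[["crack"]], dim(labels))
}

dilate_mask_z <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in seq_len(d[1]))
    out[z, , ] <- matrix(toothcrack:::cpp_dilate2d(as.vector(mask[z, , ]),
                                                   d[2:3], as.integer(radius)),
                         d[2], d[3])
  out
}
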