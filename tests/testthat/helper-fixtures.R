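# Shared fixtures, all generated in code.

# Straight axial tube: circular cross-section of radius r mm, n_slices
# coronal slices, centered in a dims grid (centerline on the voxel lattice
# unless offset is given).
straight_tube <- function(r = 1.5, n_slices = 20, spacing = 0.6,
                          dims = c(32, max(n_slices + 8, 32), 32),
                          offset = c(0, 0), first_slice = 5L,
                          segment = "wholeAVP", side = "left",
                          subject_id = "tube") {
  g <- array(0L, dims)
  cx <- (dims[1] / 2 + offset[1]) * spacing
  cz <- (dims[3] / 2 + offset[2]) * spacing
  xs <- (seq_len(dims[1]) - 1) * spacing
  zs <- (seq_len(dims[3]) - 1) * spacing
  disc <- outer((xs - cx)^2, rep(1, dims[3])) +
    outer(rep(1, dims[1]), (zs - cz)^2) <= r^2
  for (k in first_slice + seq_len(n_slices) - 1L)
    g[, k, ] <- as.integer(disc)
  labeled_mask(g, rep(spacing, 3), segment, side, subject_id)
}

# Random blob mask: a dilated random walk, contiguous along y.
random_blob <- function(n_slices = 10, dims = c(24, 24, 24), seed = 1,
                        segment = "wholeAVP") {
  set.seed(seed)
  g <- array(0L, dims)
  cx <- dims[1] / 2; cz <- dims[3] / 2
  for (k in seq_len(n_slices)) {
    cx <- min(max(cx + sample(-1:1, 1), 5), dims[1] - 5)
    cz <- min(max(cz + sample(-1:1, 1), 5), dims[3] - 5)
    w <- sample(1:3, 1)
    g[(cx - w):(cx + w), k + 4L, (cz - w):(cz + w)] <- 1L
  }
  labeled_mask(g, c(0.6, 0.6, 0.6), segment)
}

# Five abutting box segments on one grid: a crude but valid segment set.
box_segment_set <- function(slices_per_seg = c(8, 3, 6, 3, 4),
                            dims = c(24, 40, 24), half_width = 2L,
                            subject_id = "box", side = "left") {
  masks <- list()
  k0 <- 3L
  mid <- dims[1] %/% 2
  for (i in seq_along(avp_segments())) {
    g <- array(0L, dims)
    ks <- k0 + seq_len(slices_per_seg[i]) - 1L
    g[(mid - half_width):(mid + half_width), ks,
      (mid - half_width):(mid + half_width)] <- 1L
    masks[[avp_segments()[i]]] <-
      labeled_mask(g, c(0.6, 0.6, 0.6), avp_segments()[i], side, subject_id)
    k0 <- k0 + slices_per_seg[i]
  }
  segment_set(subject_id, side, masks)
}
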