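test_that("slice centroids equal the brute-force coordinate mean", {
  sl <- matrix(0L, 16, 16)
  sl[4, 6] <- 1L   # 0-based (3, 5)
  expect_equal(slice_centroid(sl, c(0.6, 0.6)), c(1.8, 3.0))

  sl2 <- matrix(0L, 8, 8)
  sl2[3:4, 5:6] <- 1L  # 0-based x {2,3}, z {4,5}
  expect_equal(slice_centroid(sl2, c(1, 1)), c(2.5, 4.5))

  set.seed(11)
  for (rep in 1:5) {
    sl3 <- matrix(as.integer(stats::runif(400) < 0.15), 20, 20)
    if (!sum(sl3)) next
    idx <- which(sl3 != 0, arr.ind = TRUE)
    oracle <- c(mean(idx[, 1] - 1) * 0.6, mean(idx[, 2] - 1) * 0.6)
    expect_equal(slice_centroid(sl3, c(0.6, 0.6)), oracle)
  }
  expect_error(slice_centroid(matrix(0L, 4, 4)), "empty")
})

test_that("centroid paths have the expected total length", {
  # 5 coaxial discs at 0.6 mm pitch: TL = 4 gaps x 0.6 = 2.4 mm
  tube <- straight_tube(r = 1.2, n_slices = 5)
  p <- centroid_path(tube)
  expect_equal(nrow(p$slices), 5)
  expect_equal(length(p$D), 4)
  expect_equal(p$TL, 2.4)
  expect_equal(sum(p$D), p$TL)

  # 0.8 mm in-plane drift per 0.6 mm axial step: D = 1.0 (3-4-5 triangle)
  g <- array(0L, c(64, 10, 16))
  for (k in 1:6) {
    x0 <- 10 + (k - 1) * 4  # 4 voxels x 0.2 mm... use whole-voxel drift
    g[x0:(x0 + 2), k + 2, 7:9] <- 1L
  }
  # drift per step = 4 voxels * 0.6 mm = 2.4 mm; instead build exact 0.8 mm
  g <- array(0L, c(64, 10, 16))
  for (k in 1:6) {
    sl <- matrix(0L, 64, 16)
    # 3-voxel row: centroid at middle voxel
    x0 <- 10 + (k - 1) * 4
    sl[x0 + (0:2), 8] <- 1L
    g[, k + 2, ] <- sl
  }
  m <- labeled_mask(g, c(0.2, 0.6, 0.6))  # 4 voxels x 0.2 mm = 0.8 mm drift
  p2 <- centroid_path(m)
  expect_equal(p2$D, rep(1.0, 5), tolerance = 1e-12)

  # sinusoidal centerline: TL equals the brute-force polyline length
  ph <- generate_phantom(phantom_spec())
  mask <- ph$segments$masks$iOrb
  p3 <- centroid_path(mask)
  ks <- avpmorph:::nonempty_slices(mask$grid)
  oracle <- 0
  prev <- NULL
  for (k in ks) {
    cen <- slice_centroid(mask$grid[, k, ], c(0.6, 0.6))
    pt <- c(cen[1], (k - 1) * 0.6, cen[2])
    if (!is.null(prev)) oracle <- oracle + sqrt(sum((pt - prev)^2))
    prev <- pt
  }
  expect_equal(p3$TL, oracle, tolerance = 1e-12)

  # non-contiguous masks are rejected
  g2 <- tube$grid; g2[, 8, ] <- 0L
  expect_error(centroid_path(labeled_mask(g2)), "contiguous")
})

test_that("TL is invariant under rigid in-plane translation", {
  ph <- generate_phantom(phantom_spec())
  m <- ph$segments$masks$iCran
  g <- m$grid * 0L
  g[(1:40) + 6, , ] <- m$grid[1:40, , ]  # shift +6 voxels in x
  p1 <- centroid_path(m)
  p2 <- centroid_path(labeled_mask(g, m$spacing, m$segment))
  expect_equal(p2$TL, p1$TL, tolerance = 1e-10)
})

test_that("equivalent-ellipse shape matches analytic moments", {
  mk_ellipse <- function(h1, h2, spacing, n = 96) {
    xs <- (seq_len(n) - 1) * spacing - n / 2 * spacing
    m <- outer(xs^2 / h1^2, rep(1, n)) + outer(rep(1, n), xs^2 / h2^2)
    matrix(as.integer(m <= 1), n, n)
  }
  # digitized circle: ellipticity near zero
  circ <- mk_ellipse(3, 3, 0.6)
  sh <- slice_shape(circ, c(0.6, 0.6))
  expect_lt(sh$epsilon, 0.05)
  expect_equal(sh$csa, sum(circ) * 0.36)

  # 3 x 1.5 mm ellipse: eps = 0.5 within discretization tolerance;
  # refined grid converges toward the analytic value
  ell_coarse <- mk_ellipse(3, 1.5, 0.6)
  expect_equal(slice_shape(ell_coarse, c(0.6, 0.6))$epsilon, 0.5,
               tolerance = 0.1)
  ell_fine <- mk_ellipse(3, 1.5, 0.15, n = 128)
  sh_f <- slice_shape(ell_fine, c(0.15, 0.15))
  expect_equal(sh_f$epsilon, 0.5, tolerance = 0.03)
  expect_equal(sh_f$h1, 3, tolerance = 0.05)
  expect_equal(sh_f$h2, 1.5, tolerance = 0.05)

  # CSA is plain pixel counting
  sl <- matrix(0L, 8, 8); sl[2:6, 3] <- 1L; sl[2:6, 4] <- 1L
  expect_equal(slice_shape(sl, c(0.6, 0.6))$csa, 10 * 0.36)

  # scale invariance of epsilon: same pattern, different pixel size
  e1 <- slice_shape(ell_coarse, c(0.6, 0.6))$epsilon
  e2 <- slice_shape(ell_coarse, c(1.2, 1.2))$epsilon
  expect_equal(e1, e2)

  # single voxel: eps 0 by convention
  one <- matrix(0L, 4, 4); one[2, 2] <- 1L
  expect_equal(slice_shape(one, c(0.6, 0.6))$epsilon, 0)
})

test_that("cylinder biometrics match the analytic tube", {
  # grid-refined straight cylinder r = 1.5 mm: digitization error is below
  # the tolerance being verified (pixel count within ~1.3% at 0.15 mm)
  tube <- straight_tube(r = 1.5, n_slices = 81, spacing = 0.15,
                        dims = c(32, 96, 32),
                        offset = c(0.618, 0.382))
  b <- segment_biometrics(tube)
  expect_equal(b$length_mm, 12, tolerance = 0.05)       # (81-1) x 0.15
  true_vol <- pi * 1.5^2 * (81 * 0.15)                   # slab-count volume
  expect_equal(b$volume_mm3, true_vol, tolerance = 0.02)
  expect_equal(b$mcsa_mm2 * b$length_mm, b$volume_mm3)   # exact by design
  expect_lt(b$epsilon, 0.05)

  # counting identities at 0.6 mm
  tube6 <- straight_tube(r = 1.5, n_slices = 20)
  b6 <- segment_biometrics(tube6)
  expect_equal(b6$volume_mm3, sum(tube6$grid) * 0.216)
  expect_equal(b6$length_mm, 19 * 0.6)
  expect_equal(b6$mcsa_mm2, b6$volume_mm3 / b6$length_mm)
})

test_that("biometry tables are additive for compound segments", {
  ph <- generate_phantom(phantom_spec())
  bt <- biometry_table(ph$segments)
  seg <- function(s, col) bt[bt$segment == s, col]
  expect_equal(seg("ON", "volume_mm3"),
               sum(sapply(c("iOrb", "iCan", "iCran"), seg,
                          col = "volume_mm3")))
  expect_equal(seg("wholeAVP", "volume_mm3"),
               sum(sapply(avp_segments(), seg, col = "volume_mm3")))
  expect_equal(seg("wholeAVP", "length_mm"),
               sum(sapply(avp_segments(), seg, col = "length_mm")))
  expect_equal(seg("wholeAVP", "mcsa_mm2") * seg("wholeAVP", "length_mm"),
               seg("wholeAVP", "volume_mm3"))
})
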