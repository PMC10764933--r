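test_that("the cohort target length is the plain mean of TLs", {
  expect_equal(target_tl(c(60, 62)), 61.0)
  expect_equal(target_tl(c(61.1, 61.1)), 61.1)
  set.seed(3)
  tls <- stats::runif(10, 45, 70)
  expect_equal(target_tl(tls), mean(tls))
  expect_error(target_tl(numeric(0)), "empty")
})

test_that("length rescaling replans fine slices and keeps proportions", {
  ph <- generate_phantom(phantom_spec(subject_id = "rs"))
  sv <- straighten_set(ph$segments)
  f <- dim(sv$grid)[2]

  # identity at s = 1
  rv1 <- rescale_length(sv, straightened_length(sv))
  expect_identical(rv1$grid, sv$grid)

  # slice-count arithmetic: round(F * target / current)
  cur <- straightened_length(sv)
  rv2 <- rescale_length(sv, cur * 61.1 / 60)
  expect_equal(dim(rv2$grid)[2], round(f * 61.1 / 60))
  expect_lte(abs(straightened_length(rv2) - cur * 61.1 / 60), 0.03)

  # shrinking works too
  rv3 <- rescale_length(sv, cur * 0.8)
  expect_equal(dim(rv3$grid)[2], round(f * 0.8))

  # per-segment proportions preserved within 0.2 percentage points
  prop_in <- diff(c(0, sv$boundaries$end)) / f
  for (rv in list(rv2, rv3)) {
    prop_out <- diff(c(0, rv$boundaries$end)) / dim(rv$grid)[2]
    expect_true(all(abs(prop_out - prop_in) < 0.002))
  }

  # every output slice is a verbatim copy of some input slice (CSA exact)
  counts_in <- apply(sv$grid, 2, sum)
  counts_out <- apply(rv2$grid, 2, sum)
  expect_true(all(counts_out %in% counts_in))
  expect_error(rescale_length(sv, -5), "positive")
})

test_that("post-normalization TL hits the target within one voxel", {
  # subjects spanning the anatomical 45-70 mm range
  for (tl in seq(45, 70, length.out = 4)) {
    ph <- generate_phantom(phantom_spec(subject_id = sprintf("tl%.0f", tl),
                                        total_length = tl))
    sv <- straighten_set(ph$segments)
    rv <- rescale_length(sv, 61.1)
    expect_lte(abs(straightened_length(rv) - 61.1), 0.6)
    nv <- resample_isotropic(rv)
    expect_lte(abs(max(nv$boundaries_mm$end_mm) - 61.1), 0.6)
  }
})

test_that("isotropic resampling aggregates by majority occupancy", {
  # constant fine stack: output slice equals the pattern
  pat_a <- matrix(0L, 16, 16); pat_a[6:10, 6:10] <- 1L
  grid <- array(0L, c(16, 20, 16))
  for (f in 1:20) grid[, f, ] <- pat_a
  sv <- avpmorph:::new_straightened(
    grid, 0.06, c(0.6, 0.6),
    data.frame(fine = 1:20, segment = "iOrb", source_k = 0L),
    data.frame(segment = "iOrb", start = 1L, end = 20L),
    c(iOrb = 1.2), "t", "left")
  nv <- resample_isotropic(sv, out_dims = c(16, 8, 16))
  expect_equal(dim(nv$grid)[2], 8)
  expect_identical(nv$grid[, 1, ], pat_a)
  expect_identical(nv$grid[, 2, ], pat_a)
  expect_equal(sum(nv$grid), 2 * sum(pat_a))

  # 6-of-10 pattern A vs 4-of-10 pattern B: threshold keeps A, plus voxels
  # where both are set
  pat_b <- matrix(0L, 16, 16); pat_b[8:14, 8:14] <- 1L
  grid2 <- array(0L, c(16, 10, 16))
  for (f in 1:6) grid2[, f, ] <- pat_a
  for (f in 7:10) grid2[, f, ] <- pat_b
  sv2 <- avpmorph:::new_straightened(
    grid2, 0.06, c(0.6, 0.6),
    data.frame(fine = 1:10, segment = "iOrb", source_k = 0L),
    data.frame(segment = "iOrb", start = 1L, end = 10L),
    c(iOrb = 0.6), "t", "left")
  nv2 <- resample_isotropic(sv2, out_dims = c(16, 8, 16))
  expect_identical(nv2$grid[, 1, ], pat_a)  # occupancy .6 or 1 where A set

  # non-multiple spacing is rejected
  expect_error(resample_isotropic(sv, out_spacing = 0.5), "multiple")
})

test_that("resampling a uniform tube preserves per-slice CSA within 5%", {
  # constant cross-section profile: groups never mix dissimilar patterns
  ph <- generate_phantom(phantom_spec(
    subject_id = "csa5",
    mcsa = stats::setNames(rep(7.5, 5), avp_segments()),
    epsilon = stats::setNames(rep(0.2, 5), avp_segments())))
  sv <- straighten_set(ph$segments)
  nv <- resample_isotropic(sv)
  fine_counts <- apply(sv$grid, 2, sum)
  out_counts <- apply(nv$grid, 2, sum)
  out_counts <- out_counts[out_counts > 0]
  for (o in seq_along(out_counts)) {
    group <- fine_counts[((o - 1) * 10 + 1):min(o * 10, length(fine_counts))]
    # within 5% of the group's mean CSA, or an exact copy of one of the
    # group's source cross-sections (even-tie groups resolve to a source)
    ok <- abs(out_counts[o] - mean(group)) / mean(group) <= 0.05 ||
      out_counts[o] %in% group
    expect_true(ok, label = sprintf("slice %d: %d vs group mean %.1f", o,
                                    out_counts[o], mean(group)))
  }
})

test_that("the origin sits at the nerve head and is idempotent", {
  ph <- generate_phantom(phantom_spec(subject_id = "orig"))
  sv <- straighten_set(ph$segments)
  nv <- resample_isotropic(sv)
  expect_equal(nv$origin_vox, c(32, 0, 32))
  expect_equal(min(nv$boundaries_mm$start_mm), 0)
  nv2 <- set_origin(nv)
  expect_identical(nv2, nv)
  # boundaries in mm equal the per-segment fine-slice extents
  expect_equal(nv$boundaries_mm$end_mm - nv$boundaries_mm$start_mm,
               (sv$boundaries$end - sv$boundaries$start + 1L) * 0.06)
  # segment boundary example: iCan starts where iOrb ends
  expect_equal(nv$boundaries_mm$start_mm[2], nv$boundaries_mm$end_mm[1])
})

test_that("the full pipeline is near-identity on a straight cylinder", {
  tube <- straight_tube(r = 1.8, n_slices = 30, dims = c(64, 48, 64),
                        offset = c(0.618, 0.382))
  masks <- list()
  # carve the tube into five abutting segments
  ks <- avpmorph:::nonempty_slices(tube$grid)
  cuts <- round(stats::quantile(seq_along(ks), c(0.366, 0.48, 0.737, 0.844)))
  bins <- findInterval(seq_along(ks), c(0, cuts) + 0.5)
  for (i in seq_along(avp_segments())) {
    g <- array(0L, dim(tube$grid))
    g[, ks[bins == i], ] <- tube$grid[, ks[bins == i], ]
    masks[[avp_segments()[i]]] <- labeled_mask(g, tube$spacing,
                                               avp_segments()[i])
  }
  s <- segment_set("cyl", "left", masks)
  sv <- straighten_set(s)
  own_tl <- straightened_length(sv)
  nv <- resample_isotropic(rescale_length(sv, own_tl))
  out_counts <- apply(nv$grid, 2, sum)
  out_counts <- out_counts[out_counts > 0]
  in_counts <- vapply(ks, function(k) sum(tube$grid[, k, ]), numeric(1))
  # every output slice carries the cylinder's cross-section verbatim
  expect_true(all(out_counts == in_counts[1]))
  # slice count within one boundary slice per segment junction
  expect_lte(abs(length(out_counts) - length(ks)), 5)
})
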