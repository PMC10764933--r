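# Synthetic aVP-like phantoms: curved elliptical tubes voxelized on the
# acquisition grid, with five contiguous labeled segments and analytic
# ground truth, so every pipeline stage is testable without scan data.

# Irrational sub-voxel offset of the centerline from the voxel lattice.
# A lattice-aligned circle systematically over- or under-counts pixels
# (e.g. radius 2.5 voxels centered on a voxel counts 21 pixels vs a true
# area of 19.6); a generic offset avoids that commensuration resonance.
GOLDEN_OFFSET <- c(0.6180339887, 0.3819660113)

#' Specification of one synthetic aVP phantom
#'
#' Describes a curved tube with elliptical cross-section and five contiguous
#' segments. The centerline is parameterized by arc length: transverse
#' offsets `u(s)` (left-right) and `w(s)` (inferior-superior) are cubic
#' splines through control points, and the axial coordinate is
#' `y(s) = integral sqrt(1 - u'^2 - w'^2) ds`, so `total_length` IS the arc
#' length of the centerline. Per-segment cross-sections are ellipses with
#' hemi-axes `h1 >= h2` derived from the requested mCSA (`pi h1 h2`) and
#' ellipticity (`(h1 - h2)/h1`). Defaults reproduce normative adult aVP
#' geometry ([reference_biometry()]): total length 61.1 mm, segment
#' arc-length fractions 36.6/11.4/25.7/10.7/15.6%, segment mCSA
#' 7.67/5.62/6.92/14.37/7.61 mm^2 and ellipticity 0.15/0.20/0.43/0.57/0.39
#' (left/right averages).
#'
#' @param subject_id,side Tags for the generated masks.
#' @param total_length Centerline arc length, mm.
#' @param fractions Named per-segment arc-length fractions (normalized to
#'   sum to 1).
#' @param mcsa Named per-segment mean cross-sectional areas, mm^2.
#' @param epsilon Named per-segment ellipticity indices in [0, 1).
#' @param bend_x,bend_z Transverse control-point offsets (mm) of the
#'   centerline, equally spaced in arc length; defaults emulate the orbital
#'   S-bend and the gentler vertical course.
#' @param angle In-plane rotation of the cross-section ellipse, radians
#'   (h1 axis from x toward z).
#' @param spacing Isotropic voxel size, mm; default 0.6.
#' @param dims Grid dimensions; default `c(64, 128, 64)`.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(subject_id = "phantom", side = "left",
                         total_length = 61.1,
                         fractions = c(iOrb = 0.366, iCan = 0.114,
                                       iCran = 0.257, OC = 0.107,
                                       OT = 0.156),
                         mcsa = c(iOrb = 7.67, iCan = 5.62, iCran = 6.92,
                                  OC = 14.37, OT = 7.61),
                         epsilon = c(iOrb = 0.15, iCan = 0.20,
                                     iCran = 0.43, OC = 0.57, OT = 0.39),
                         bend_x = c(0, 2.5, -1.5, 0, 0.8, 0),
                         bend_z = c(0, 1.0, 0.3, -0.8, 0, 0.5),
                         angle = 0, spacing = 0.6,
                         dims = c(64, 128, 64)) {
  stopifnot(all(AVP_SEGMENTS %in% names(fractions)),
            all(AVP_SEGMENTS %in% names(mcsa)),
            all(AVP_SEGMENTS %in% names(epsilon)))
  fractions <- fractions[AVP_SEGMENTS] / sum(fractions[AVP_SEGMENTS])
  if (any(epsilon < 0 | epsilon >= 1)) stop("epsilon must be in [0, 1)")
  h1 <- sqrt(mcsa[AVP_SEGMENTS] / (pi * (1 - epsilon[AVP_SEGMENTS])))
  h2 <- h1 * (1 - epsilon[AVP_SEGMENTS])
  if (any(h2 <= spacing))
    stop("minor hemi-axis must exceed one voxel (", spacing, " mm)")
  structure(list(subject_id = subject_id, side = side,
                 total_length = total_length, fractions = fractions,
                 mcsa = mcsa[AVP_SEGMENTS],
                 epsilon = epsilon[AVP_SEGMENTS], h1 = h1, h2 = h2,
                 bend_x = bend_x, bend_z = bend_z, angle = angle,
                 spacing = spacing, dims = dims),
            class = "phantom_spec")
}

# Evaluate the centerline: returns functions u(s), w(s) (transverse offsets
# in mm) and the monotone map y(s); errors if the bends are too steep or
# curvature is tighter than the largest hemi-axis (self-intersection).
phantom_centerline <- function(spec) {
  L <- spec$total_length
  sk <- seq(0, L, length.out = length(spec$bend_x))
  u <- stats::splinefun(sk, spec$bend_x, method = "natural")
  w <- stats::splinefun(sk, spec$bend_z, method = "natural")
  ss <- seq(0, L, by = 0.01)
  du <- u(ss, deriv = 1); dw <- w(ss, deriv = 1)
  slack <- 1 - du^2 - dw^2
  if (any(slack <= 0.25))
    stop("centerline bends too steep (transverse slope > ~0.87); ",
         "reduce bend amplitudes")
  # curvature of (u(s), y(s), w(s)); guard against self-intersection
  ddu <- u(ss, deriv = 2); ddw <- w(ss, deriv = 2)
  curv <- sqrt(ddu^2 + ddw^2)   # leading order for small slopes
  if (any(curv * max(spec$h1) >= 1))
    stop("centerline curvature radius smaller than the tube hemi-axis; ",
         "the tube would self-intersect")
  dyds <- sqrt(slack)
  y <- c(0, cumsum((dyds[-1] + dyds[-length(dyds)]) / 2) * 0.01)
  list(u = u, w = w, s_grid = ss, y_grid = y)
}

#' Generate one voxelized phantom
#'
#' Voxelizes the tube described by a [phantom_spec()] on the 0.6 mm grid:
#' every coronal slice through the tube is the filled ellipse of the local
#' segment profile centered on the centerline (a voxel is set iff its center
#' lies inside), and segment labels follow the arc-length fractions. The
#' tube is placed so the centroid-path total length of the voxelized masks
#' matches the specified arc length (slices at both ends of the centerline).
#'
#' @param spec A [phantom_spec()].
#' @return List: `segments` (a [segment_set()]), `truth` (data.frame of
#'   analytic per-segment and whole-aVP ground truth: length, volume, mCSA,
#'   ellipticity), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  dims <- spec$dims
  cl <- phantom_centerline(spec)
  L <- spec$total_length
  # grid placement: anterior end at y-slice 4, centerline around grid center,
  # dithered off-lattice by the golden offset
  cx0 <- (dims[1] / 2 + GOLDEN_OFFSET[1]) * sp
  cz0 <- (dims[3] / 2 + GOLDEN_OFFSET[2]) * sp
  y0 <- (4 + GOLDEN_OFFSET[2]) * sp
  # slice y-positions: voxel centers within the tube's axial span; each
  # slice's 0.6 mm slab then tiles the span with at most half a slab of
  # over/under-coverage per end (unbiased slab-center sampling)
  y_end <- y0 + max(cl$y_grid)
  k_first <- as.integer(ceiling(y0 / sp))
  k_last <- as.integer(floor(y_end / sp))
  if (k_last + 1L > dims[2])
    stop("phantom does not fit the grid axially; enlarge dims[2]")
  ks <- k_first:k_last
  # arc length s at each slice (invert the monotone y(s) map)
  s_at <- stats::approx(cl$y_grid, cl$s_grid, xout = ks * sp - y0,
                        rule = 2)$y
  cuts <- cumsum(spec$fractions) * L
  seg_of <- AVP_SEGMENTS[pmin(5L, findInterval(s_at, c(0, cuts),
                                               rightmost.closed = TRUE))]
  grids <- lapply(stats::setNames(nm = AVP_SEGMENTS),
                  function(s) array(0L, dims))
  xs <- (seq_len(dims[1]) - 1) * sp
  zs <- (seq_len(dims[3]) - 1) * sp
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  for (i in seq_along(ks)) {
    seg <- seg_of[i]
    cx <- cx0 + cl$u(s_at[i])
    cz <- cz0 + cl$w(s_at[i])
    # local frame: the cross-section is the h1/h2 ellipse in the plane
    # perpendicular to the centerline tangent; the coronal cut is that
    # ellipse sheared along the drift direction (area pi h1 h2 / cos theta),
    # obtained by evaluating the perpendicular-plane coordinates of the
    # in-plane displacement d = (dx, 0, dz)
    tu <- cl$u(s_at[i], deriv = 1); tw <- cl$w(s_at[i], deriv = 1)
    tv <- c(tu, sqrt(max(0, 1 - tu^2 - tw^2)), tw)     # unit tangent
    e1 <- c(1, 0, 0) - tu * tv; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    if (spec$angle != 0) {
      e1r <- ca * e1 + sa * e2; e2 <- -sa * e1 + ca * e2; e1 <- e1r
    }
    dx <- outer(xs - cx, rep(1, dims[3]))
    dz <- outer(rep(1, dims[1]), zs - cz)
    a <- dx * e1[1] + dz * e1[3]
    b <- dx * e2[1] + dz * e2[3]
    inside <- (a / spec$h1[seg])^2 + (b / spec$h2[seg])^2 <= 1
    grids[[seg]][, ks[i] + 1L, ] <- as.integer(inside)
  }
  masks <- lapply(AVP_SEGMENTS, function(s)
    labeled_mask(grids[[s]], rep(sp, 3), s, spec$side, spec$subject_id))
  names(masks) <- AVP_SEGMENTS
  seg_len <- spec$fractions * L
  truth <- data.frame(
    subject_id = spec$subject_id, side = spec$side,
    segment = c(AVP_SEGMENTS, "wholeAVP"),
    length_mm = c(seg_len, L),
    volume_mm3 = c(spec$mcsa * seg_len, sum(spec$mcsa * seg_len)),
    mcsa_mm2 = c(spec$mcsa, sum(spec$mcsa * seg_len) / L),
    epsilon = c(spec$epsilon,
                sum(spec$epsilon * spec$fractions)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(segments = segment_set(spec$subject_id, spec$side, masks),
       truth = truth, spec = spec)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws per-subject phantom parameters around the normative defaults:
#' total length lognormal about `mean_tl`, segment fractions, mCSA and
#' ellipticity profiles and bend control points jittered with fractional
#' standard deviation `variability`. Left and right sides get independent
#' jitter (the right side's bend is mirrored). The same seed always yields
#' the identical cohort.
#'
#' @param n Number of subjects (>= 1).
#' @param variability Fractional standard deviation applied to the
#'   parameters; 0 makes all subjects identical to the template.
#' @param seed Integer RNG seed.
#' @param mean_tl Cohort mean total length, mm; default 61.1.
#' @param ... Further arguments forwarded to [phantom_spec()].
#' @return List: `cohort` (named list of [segment_set()], 2 per subject),
#'   `truth` (row-bound ground-truth table), `specs`.
#' @export
generate_cohort <- function(n, variability = 0.05, seed = 1,
                            mean_tl = 61.1, ...) {
  stopifnot(n >= 1, variability >= 0)
  set.seed(seed)
  template <- phantom_spec(...)
  cohort <- list(); truth <- NULL; specs <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    tl_i <- mean_tl * exp(stats::rnorm(1, 0, variability) -
                            variability^2 / 2)
    for (side in c("left", "right")) {
      jit <- function(x, s = variability) x * exp(stats::rnorm(length(x),
                                                               0, s))
      bend_sign <- if (side == "right") -1 else 1
      sp_i <- phantom_spec(
        subject_id = sid, side = side,
        total_length = tl_i * exp(stats::rnorm(1, 0, variability / 4)),
        fractions = jit(template$fractions, variability / 2),
        mcsa = jit(template$mcsa),
        epsilon = pmin(jit(template$epsilon), 0.9),
        bend_x = bend_sign * (template$bend_x +
                                stats::rnorm(length(template$bend_x), 0,
                                             variability * 8)),
        bend_z = template$bend_z +
          stats::rnorm(length(template$bend_z), 0, variability * 8),
        angle = template$angle, spacing = template$spacing,
        dims = template$dims)
      ph <- generate_phantom(sp_i)
      cohort[[paste(sid, side, sep = ":")]] <- ph$segments
      truth <- rbind(truth, ph$truth)
      specs[[paste(sid, side, sep = ":")]] <- sp_i
    }
  }
  list(cohort = cohort, truth = truth, specs = specs)
}

#' Write a phantom cohort to NIfTI files plus a manifest
#'
#' @param cohort Named list of [segment_set()]s (as from
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly; files are written under
#'   `dir` and listed in `dir/manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- NULL
  for (s in cohort) for (seg in names(s$masks)) {
    fn <- sprintf("%s_%s_%s.nii.gz", s$subject_id, s$side, seg)
    write_mask(s$masks[[seg]], file.path(dir, fn))
    manifest <- rbind(manifest, data.frame(
      subject = s$subject_id, side = s$side, segment = seg, path = fn,
      stringsAsFactors = FALSE))
  }
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
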