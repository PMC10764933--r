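# Per-slice and per-segment geometric primitives: centroids, the centroid
# path and its total length TL, cross-sectional area, and equivalent-ellipse
# hemi-axes for the ellipticity index.

# Extract coronal slice k (1-based) as a 2-D (x, z) matrix.
coronal_slice <- function(grid, k) grid[, k, ]

#' In-plane centroid of a coronal slice
#'
#' Arithmetic mean of the set-voxel center coordinates, in mm. Voxel centers
#' sit at `(index) * spacing` with 0-based indices.
#'
#' @param slice 2-D binary array (x by z).
#' @param spacing Length-2 in-plane spacing `(sx, sz)` in mm.
#' @return Numeric `(cx, cz)` in mm.
#' @export
slice_centroid <- function(slice, spacing = c(0.6, 0.6)) {
  idx <- which(slice != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty slice has no centroid")
  c(mean(idx[, 1] - 1) * spacing[1], mean(idx[, 2] - 1) * spacing[2])
}

#' Centroid path and total length of a segment mask
#'
#' For every nonempty coronal slice the in-plane centroid and cross-sectional
#' area are computed; consecutive centroids are joined by straight chords
#' whose 3-D Euclidean lengths `D_i` (axial component = slice pitch, plus the
#' in-plane centroid drift) sum to the segment's total length
#' `TL = sum(D_i)`.
#'
#' @param mask A [labeled_mask()]; must be nonempty and contiguous along y.
#' @return Object of class `centroid_path`: `slices` (data.frame with 0-based
#'   slice index `k`, centroid `cx`, `cz` in mm, `csa` in mm^2), `D` (numeric
#'   inter-centroid distances, mm), `TL` (total length, mm), plus the mask
#'   tags and spacing.
#' @export
centroid_path <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  grid <- mask$grid
  sp <- mask$spacing
  ks <- nonempty_slices(grid)
  if (!length(ks)) stop("empty mask has no centroid path")
  if (!identical(ks, seq(min(ks), max(ks))))
    stop("mask is not contiguous along the tube axis; run ",
         "validate_segment_set() for details")
  n <- length(ks)
  cx <- cz <- csa <- numeric(n)
  inplane <- sp[c(1, 3)]
  for (i in seq_len(n)) {
    sl <- coronal_slice(grid, ks[i])
    cen <- slice_centroid(sl, inplane)
    cx[i] <- cen[1]; cz[i] <- cen[2]
    csa[i] <- sum(sl != 0) * inplane[1] * inplane[2]
  }
  D <- if (n > 1L)
    sqrt(diff(cx)^2 + diff(cz)^2 + (sp[2] * diff(ks))^2)
  else numeric(0)
  structure(
    list(segment = mask$segment, side = mask$side,
         subject_id = mask$subject_id, spacing = sp,
         slices = data.frame(k = ks - 1L, cx = cx, cz = cz, csa = csa),
         D = D, TL = sum(D)),
    class = "centroid_path")
}

#' @export
print.centroid_path <- function(x, ...) {
  cat(sprintf("<centroid_path> %s %s/%s  %d slices  TL = %.2f mm\n",
              x$subject_id, x$side, x$segment, nrow(x$slices), x$TL))
  invisible(x)
}

#' Cross-sectional shape of a coronal slice
#'
#' The cross-sectional area is the set-voxel count times the pixel area. The
#' two orthogonal hemi-axes `h1 >= h2` come from the equivalent ellipse of
#' the in-plane second central moments: with `lambda1 >= lambda2` the
#' eigenvalues of the coordinate covariance of the pixelated region (voxel
#' centers plus the per-pixel uniform variance `s^2/12` per axis),
#' `h = 2 * sqrt(lambda)` -- a filled ellipse with hemi-axes a, b has
#' coordinate variance `a^2/4`, `b^2/4`. The ellipticity index
#' `eps = (h1 - h2)/h1` is 0 for a circle and approaches 1 for a flat
#' ellipse; a single-voxel slice has `eps = 0` by convention.
#'
#' @inheritParams slice_centroid
#' @return List of class `slice_shape`: `csa` (mm^2), `h1`, `h2` (mm),
#'   `epsilon`.
#' @export
slice_shape <- function(slice, spacing = c(0.6, 0.6)) {
  idx <- which(slice != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty slice has no shape")
  csa <- n * spacing[1] * spacing[2]
  xs <- (idx[, 1] - 1) * spacing[1]
  zs <- (idx[, 2] - 1) * spacing[2]
  # population covariance of voxel centers + uniform-square pixel term
  cxx <- mean((xs - mean(xs))^2) + spacing[1]^2 / 12
  czz <- mean((zs - mean(zs))^2) + spacing[2]^2 / 12
  cxz <- mean((xs - mean(xs)) * (zs - mean(zs)))
  ev <- eigen(matrix(c(cxx, cxz, cxz, czz), 2L), symmetric = TRUE,
              only.values = TRUE)$values
  h <- 2 * sqrt(pmax(ev, 0))
  eps <- if (n == 1L) 0 else (h[1] - h[2]) / h[1]
  structure(list(csa = csa, h1 = h[1], h2 = h[2], epsilon = eps),
            class = "slice_shape")
}

#' Biometrics of one segment mask
#'
#' Volume is the voxel count times the voxel volume; length is the
#' centroid-path total length `TL`; the mean cross-sectional area is
#' `mCSA = volume / length` (the standard spinal-cord-style estimate, which
#' is unbiased by the segment's curvature); the ellipticity index is the
#' unweighted mean of per-slice ellipticities over slices with at least 3
#' voxels (fewer voxels make the second moments degenerate).
#'
#' @param mask A nonempty [labeled_mask()].
#' @return One-row data.frame: `subject_id`, `side`, `segment`,
#'   `volume_mm3`, `length_mm`, `mcsa_mm2`, `epsilon`, `n_slices`.
#' @export
segment_biometrics <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  path <- centroid_path(mask)
  vol <- n_voxels(mask) * voxel_volume(mask)
  if (path$TL <= 0)
    stop("single-slice segment has zero centroid-path length; ",
         "mCSA is undefined")
  inplane <- mask$spacing[c(1, 3)]
  eps <- vapply(path$slices$k + 1L, function(k) {
    sl <- coronal_slice(mask$grid, k)
    if (sum(sl != 0) < 3L) NA_real_ else slice_shape(sl, inplane)$epsilon
  }, numeric(1))
  data.frame(subject_id = mask$subject_id, side = mask$side,
             segment = mask$segment, volume_mm3 = vol, length_mm = path$TL,
             mcsa_mm2 = vol / path$TL,
             epsilon = mean(eps, na.rm = TRUE),
             n_slices = nrow(path$slices),
             stringsAsFactors = FALSE)
}

# Union of several masks sharing one grid (used for compound segments).
union_mask <- function(masks, segment = "wholeAVP") {
  g <- Reduce(`+`, lapply(masks, function(m) m$grid))
  labeled_mask(g, masks[[1]]$spacing, segment, masks[[1]]$side,
               masks[[1]]$subject_id)
}

#' Biometry table for one subject/side
#'
#' Per-segment biometrics for the five aVP segments plus the compound optic
#' nerve (ON = iOrb + iCan + iCran) and entire aVP rows. Compound volumes
#' and lengths are exact sums of the member segments (the same voxels and
#' the same centroid chords), compound mCSA is compound volume over
#' compound length, and compound ellipticity is the slice-count-weighted
#' mean (equal to the slice-mean over the compound extent, since segments
#' occupy disjoint coronal slices).
#'
#' @param s A [segment_set()].
#' @param compound Also emit `ON` and `wholeAVP` rows (default `TRUE`).
#' @return data.frame, one row per segment (7 rows with compounds).
#' @export
biometry_table <- function(s, compound = TRUE) {
  stopifnot(inherits(s, "segment_set"))
  rows <- lapply(s$masks, segment_biometrics)
  out <- do.call(rbind, rows)
  if (compound) {
    comp <- function(segs, name) {
      rr <- out[match(segs, out$segment), ]
      v <- sum(rr$volume_mm3); l <- sum(rr$length_mm)
      data.frame(subject_id = rr$subject_id[1], side = rr$side[1],
                 segment = name, volume_mm3 = v, length_mm = l,
                 mcsa_mm2 = v / l,
                 epsilon = sum(rr$epsilon * rr$n_slices) / sum(rr$n_slices),
                 n_slices = sum(rr$n_slices), stringsAsFactors = FALSE)
    }
    out <- rbind(out, comp(c("iOrb", "iCan", "iCran"), "ON"),
                 comp(AVP_SEGMENTS, "wholeAVP"))
  }
  rownames(out) <- NULL
  out
}

#' Whole-structure centroid-path length
#'
#' Total length of the centroid path measured on the union of all five
#' segment masks, i.e. including the chords that cross segment boundaries.
#' This is the geometrically faithful length of the whole pathway: summing
#' per-segment lengths instead omits one inter-centroid chord per boundary
#' (about one slice pitch each).
#'
#' @param s A [segment_set()].
#' @return Length in mm.
#' @export
avp_total_length <- function(s) {
  stopifnot(inherits(s, "segment_set"))
  centroid_path(union_mask(s$masks))$TL
}
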