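# Length normalization to a common cohort total length and resampling of the
# fine straightened stack back to the isotropic acquisition grid, with the
# origin at the nerve head.

#' Cohort target total length
#'
#' Arithmetic mean of the whole-aVP total length over all subjects and both
#' sides -- the common length every normalized aVP is rescaled to.
#'
#' @param tls Numeric vector of whole-aVP TLs (mm), one per subject/side, or
#'   a list of `straightened_volume`s / `centroid_path` lists whose TLs are
#'   summed per entry.
#' @return Mean TL in mm.
#' @export
target_tl <- function(tls) {
  if (is.list(tls))
    tls <- vapply(tls, function(x) {
      if (inherits(x, "straightened_volume")) sum(x$tl_path)
      else if (inherits(x, "centroid_path")) x$TL
      else sum(vapply(x, function(p) p$TL, numeric(1)))
    }, numeric(1))
  if (!length(tls)) stop("empty cohort")
  mean(tls)
}

#' Rescale a straightened aVP to a target length
#'
#' Every fine inter-slice gap is scaled by `s = target / current length` and
#' the fine stack re-planned by nearest-neighbour replication (or deletion,
#' for subjects longer than the target): the output has
#' `round(F * s)` fine slices, slice `m` copying source slice
#' `ceiling((m - 0.5) / s)`. Whole slices are only ever copied, so the CSA of
#' every slice is preserved exactly, per-segment length proportions are kept
#' within one fine slice per boundary, and the rescaled length matches the
#' target within half a fine pitch.
#'
#' @param v A `straightened_volume`.
#' @param target Target length, mm (> 0); typically [target_tl()] of the
#'   cohort.
#' @return A `straightened_volume` of the target length.
#' @export
rescale_length <- function(v, target) {
  stopifnot(inherits(v, "straightened_volume"))
  if (target <= 0) stop("target length must be positive")
  f <- dim(v$grid)[2]
  s <- target / (f * v$pitch)
  m <- max(1L, as.integer(round_half_away(f * s)))
  src <- pmin(f, pmax(1L, as.integer(ceiling((seq_len(m) - 0.5) / s))))
  d <- dim(v$grid)
  grid <- array(0L, c(d[1], m, d[3]))
  grid[, seq_len(m), ] <- v$grid[, src, ]
  prov <- v$provenance[src, ]
  prov$fine <- seq_len(m)
  rownames(prov) <- NULL
  # segment boundaries follow the source mapping
  bnd <- v$boundaries
  for (i in seq_len(nrow(bnd))) {
    inside <- which(src >= bnd$start[i] & src <= bnd$end[i])
    bnd$start[i] <- min(inside); bnd$end[i] <- max(inside)
  }
  new_straightened(grid, v$pitch, v$spacing, prov, bnd,
                   v$tl_path * s, v$subject_id, v$side)
}

new_normalized <- function(grid, spacing, boundaries_mm, subject_id, side,
                           origin_vox = NULL) {
  structure(list(grid = grid, spacing = spacing,
                 boundaries_mm = boundaries_mm, subject_id = subject_id,
                 side = side, origin_vox = origin_vox),
            class = "normalized_avp")
}

#' @export
print.normalized_avp <- function(x, ...) {
  cat(sprintf("<normalized_avp> %s %s  %s voxels on %s @ %s mm\n",
              x$subject_id, x$side, format(sum(x$grid)),
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = " ")))
  invisible(x)
}

#' Resample a straightened volume to the isotropic output grid
#'
#' Groups of `out_spacing / pitch` consecutive fine slices (10 by default)
#' are aggregated into one output slice: an output voxel is set iff its
#' occupancy across the group exceeds 0.5; voxels at exactly 0.5 (possible
#' when a group straddles two source slices evenly) follow the group's
#' dominant source pattern (ties resolved to the anterior source), which
#' keeps the output cross-section a faithful copy rather than the union or
#' intersection of the two patterns. The result is placed centered in-plane
#' on a fixed cohort-wide grid, anterior slice first.
#'
#' @param v A `straightened_volume`.
#' @param out_spacing Isotropic output spacing, mm; must be an integer
#'   multiple of the fine pitch. Default 0.6.
#' @param out_dims Cohort output grid, default `c(64, 128, 64)` voxels
#'   (covers 76.8 mm axially at 0.6 mm).
#' @return A `normalized_avp` with segment boundaries in mm from the
#'   anterior face and the origin set at the nerve head ([set_origin()]).
#' @export
resample_isotropic <- function(v, out_spacing = 0.6,
                               out_dims = c(64, 128, 64)) {
  stopifnot(inherits(v, "straightened_volume"))
  fct <- out_spacing / v$pitch
  if (abs(fct - round(fct)) > 1e-8)
    stop("out_spacing must be an integer multiple of the fine pitch")
  fct <- as.integer(round(fct))
  f <- dim(v$grid)[2]
  n_out <- as.integer(ceiling(f / fct))
  if (n_out > out_dims[2])
    stop("output grid too short axially: need ", n_out, " slices, have ",
         out_dims[2])
  d <- dim(v$grid)
  if (d[1] > out_dims[1] || d[3] > out_dims[3])
    stop("in-plane working grid exceeds the output grid")
  offx <- (out_dims[1] - d[1]) %/% 2L
  offz <- (out_dims[3] - d[3]) %/% 2L
  grid <- array(0L, out_dims)
  for (o in seq_len(n_out)) {
    lo <- (o - 1L) * fct + 1L
    hi <- min(f, o * fct)
    block <- v$grid[, lo:hi, , drop = FALSE]
    occ <- apply(block, c(1, 3), mean)
    out_slice <- occ > 0.5
    tie <- abs(occ - 0.5) < 1e-9
    if (any(tie)) {
      src <- v$provenance$source_k[lo:hi]
      dominant <- as.integer(names(which.max(table(src))))
      ref <- block[, match(dominant, src), ]
      out_slice[tie] <- ref[tie] != 0
    }
    grid[(offx + 1L):(offx + d[1]), o, (offz + 1L):(offz + d[3])] <-
      as.integer(out_slice)
  }
  bnd <- data.frame(segment = v$boundaries$segment,
                    start_mm = (v$boundaries$start - 1L) * v$pitch,
                    end_mm = v$boundaries$end * v$pitch,
                    stringsAsFactors = FALSE)
  out <- new_normalized(grid, rep(out_spacing, 3), bnd, v$subject_id,
                        v$side)
  set_origin(out)
}

#' Set the image origin at the nerve head
#'
#' The world origin (0, 0, 0) is placed at the centerline of the most
#' anterior slice -- the optic nerve head -- i.e. at voxel coordinates
#' `(Nx/2, 0, Nz/2)` (0-based). Segment boundaries are expressed in mm from
#' that origin. Applying the function twice is a no-op.
#'
#' @param v A `normalized_avp` with a segment boundary table.
#' @return The volume with `origin_vox` set and boundaries anchored at 0.
#' @export
set_origin <- function(v) {
  stopifnot(inherits(v, "normalized_avp"))
  if (is.null(v$boundaries_mm)) stop("missing segment boundary table")
  d <- dim(v$grid)
  v$origin_vox <- c(d[1] / 2, 0, d[3] / 2)
  shift <- min(v$boundaries_mm$start_mm)
  v$boundaries_mm$start_mm <- v$boundaries_mm$start_mm - shift
  v$boundaries_mm$end_mm <- v$boundaries_mm$end_mm - shift
  v
}

#' Normalize one straightened aVP end to end
#'
#' Convenience wrapper: [rescale_length()] to the target, then
#' [resample_isotropic()].
#'
#' @param v A `straightened_volume` of the whole aVP.
#' @param target Target TL in mm (e.g. the cohort mean).
#' @param out_spacing,out_dims Passed to [resample_isotropic()].
#' @return A `normalized_avp`.
#' @export
normalize_avp <- function(v, target, out_spacing = 0.6,
                          out_dims = c(64, 128, 64)) {
  resample_isotropic(rescale_length(v, target), out_spacing, out_dims)
}

#' Map output slices to segments by slice center
#'
#' Assigns every nonempty-range output slice of a normalized aVP to the
#' segment whose boundary interval contains the slice center, giving a
#' partition (no slice belongs to two segments).
#'
#' @param v A `normalized_avp`.
#' @return Named list: per segment, the 1-based y indices of its slices.
#' @export
segment_slices <- function(v) {
  stopifnot(inherits(v, "normalized_avp"))
  sy <- v$spacing[2]
  centers <- (seq_len(dim(v$grid)[2]) - 0.5) * sy
  out <- list()
  b <- v$boundaries_mm
  for (i in seq_len(nrow(b))) {
    hit <- which(centers >= b$start_mm[i] & centers < b$end_mm[i])
    if (i == nrow(b))   # include the last boundary slice
      hit <- union(hit, which(centers >= b$start_mm[i] &
                                centers <= b$end_mm[i] + sy / 2))
    out[[b$segment[i]]] <- hit
  }
  out
}

#' Write the segment boundary sidecar table
#'
#' @param v A `normalized_avp`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(v, path) {
  utils::write.table(v$boundaries_mm, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
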