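#' @keywords internal
"_PACKAGE"

# Canonical segment order, anterior to posterior.
AVP_SEGMENTS <- c("iOrb", "iCan", "iCran", "OC", "OT")

#' Anatomical segments of the anterior visual pathway
#'
#' Returns the five aVP segment tags in anatomical (anterior-to-posterior)
#' order: intraorbital (`iOrb`), intracanalicular (`iCan`) and intracranial
#' (`iCran`) optic nerve, optic chiasm hemi-trunk (`OC`), and optic tract
#' (`OT`).
#'
#' @return Character vector of length five.
#' @export
avp_segments <- function() AVP_SEGMENTS

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct a labeled binary mask
#'
#' The basic container of the package: a 3-D binary occupancy grid with voxel
#' spacing and a segment/side tag. The canonical axis convention is
#' x = left-right, y = anterior-posterior (slice index increasing
#' posteriorly), z = inferior-superior. Voxel indices are 0-based with the
#' voxel center at `index * spacing` mm.
#'
#' @param grid 3-D array; any nonzero value is treated as inside the mask.
#' @param spacing Numeric length-3, mm per voxel along (x, y, z).
#'   Default `c(0.6, 0.6, 0.6)`.
#' @param segment Segment tag: one of `avp_segments()` or `"wholeAVP"`.
#' @param side `"left"`, `"right"` or `"right-flipped"`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `labeled_mask`.
#' @export
labeled_mask <- function(grid, spacing = c(0.6, 0.6, 0.6),
                         segment = "wholeAVP", side = "left",
                         subject_id = "unknown") {
  if (length(dim(grid)) != 3L)
    stop("mask grid must be a 3-D array, got ", length(dim(grid)),
         " dimensions")
  if (!all(spacing > 0) || length(spacing) != 3L)
    stop("spacing must be three strictly positive values")
  segment <- match.arg(segment, c(AVP_SEGMENTS, "wholeAVP"))
  side <- match.arg(side, c("left", "right", "right-flipped"))
  g <- array(as.integer(grid != 0), dim = dim(grid))
  structure(
    list(grid = g, spacing = as.numeric(spacing), segment = segment,
         side = side, subject_id = as.character(subject_id)),
    class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %s %s/%s  %s voxels of %s  spacing %s mm\n",
              x$subject_id, x$side, x$segment,
              format(sum(x$grid)), paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = " ")))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$grid)

voxel_volume <- function(mask) prod(mask$spacing)

# Indices (1-based, R) of nonempty coronal slices.
nonempty_slices <- function(grid) {
  occ <- apply(grid, 2L, function(s) any(s != 0))
  which(occ)
}

#' Read a binary segment mask from a NIfTI file
#'
#' Reads a 3-D volume, reorients it to the canonical axis convention
#' (x = left-right, y increasing anterior to posterior, z = inferior-superior;
#' NIfTI orientation code "RPS") when the file carries a usable qform/sform,
#' binarizes at > 0, and takes the voxel spacing from the header. Files
#' without spatial metadata are assumed already canonical.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param segment,side,subject_id Tags attached to the returned mask.
#' @return A [labeled_mask()].
#' @export
read_mask <- function(path, segment = "wholeAVP", side = "left",
                      subject_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  img <- canonicalize_orientation(img)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)),
         " dimensions in ", path)
  spacing <- signif(RNifti::pixdim(img)[1:3], 7)  # undo float32 header noise
  grid <- array(as.integer(as.array(img) != 0), dim = dim(img))
  if (sum(grid) == 0L)
    stop("mask is empty (all-zero segmentation): ", path)
  labeled_mask(grid, spacing = spacing, segment = segment, side = side,
               subject_id = subject_id)
}

# Reorient a niftiImage to the canonical "RPS" axes if it has a usable xform;
# idempotent (reorienting an already canonical image is a no-op).
canonicalize_orientation <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    if (!identical(RNifti::orientation(img), "RPS"))
      RNifti::orientation(img) <- "RPS"
  }
  img
}

# qform matrix encoding the canonical axes (i -> Right, j -> Posterior,
# k -> Superior) with the world origin at voxel `origin_vox` (0-based).
canonical_qform <- function(spacing, dims, origin_vox = c(0, 0, 0)) {
  m <- diag(c(spacing[1], -spacing[2], spacing[3], 1))
  m[1, 4] <- -origin_vox[1] * spacing[1]
  m[2, 4] <-  origin_vox[2] * spacing[2]
  m[3, 4] <- -origin_vox[3] * spacing[3]
  structure(m, code = 2L)
}

#' Write a mask or probabilistic atlas to a NIfTI file
#'
#' Binary masks round-trip bit-exactly through [read_mask()]; atlases are
#' written as double-precision volumes (values 0-100). The header records the
#' voxel spacing and the canonical orientation.
#'
#' @param x A [labeled_mask()], `normalized_avp`, or `probabilistic_atlas`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path) {
  if (inherits(x, "probabilistic_atlas")) {
    grid <- x$grid
    datatype <- "double"
    origin_vox <- if (!is.null(x$origin_vox)) x$origin_vox else c(0, 0, 0)
  } else if (inherits(x, c("labeled_mask", "normalized_avp"))) {
    grid <- x$grid
    datatype <- "uint8"
    origin_vox <- if (!is.null(x$origin_vox)) x$origin_vox else c(0, 0, 0)
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- x$spacing
  RNifti::qform(img) <- canonical_qform(x$spacing, dim(grid), origin_vox)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a probabilistic atlas volume
#'
#' Reads a float NIfTI volume written by [write_mask()] for an atlas, without
#' binarization.
#'
#' @param path File path.
#' @return A `probabilistic_atlas` with unknown `n_masks` (set to `NA`).
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  img <- canonicalize_orientation(img)
  structure(list(grid = as.array(img),
                 spacing = signif(RNifti::pixdim(img)[1:3], 7),
                 n_masks = NA_integer_, origin_vox = NULL, segments = NULL),
            class = "probabilistic_atlas")
}

#' Split an optic chiasm mask at the midsagittal plane
#'
#' The chiasm is the one aVP segment where left and right pathways merge into
#' a single trunk; for per-side processing it is split into hemi-trunks at a
#' sagittal plane. Voxels with 0-based x index `< plane_x` fall on the left
#' (low x is the left side under the canonical orientation), `>= plane_x` on
#' the right.
#'
#' @param oc A [labeled_mask()] with `segment == "OC"`.
#' @param plane_x 0-based x voxel index of the splitting plane, or `"auto"`
#'   for the grid x midline (`nx %/% 2`).
#' @return List with elements `left` and `right`, two disjoint OC hemi-trunk
#'   masks whose union is the input.
#' @export
split_oc_midsagittal <- function(oc, plane_x = "auto") {
  stopifnot(inherits(oc, "labeled_mask"))
  if (oc$segment != "OC") stop("split_oc_midsagittal expects an OC mask")
  nx <- dim(oc$grid)[1]
  if (identical(plane_x, "auto")) plane_x <- nx %/% 2L
  if (plane_x < 1L || plane_x > nx - 1L)
    stop("splitting plane x=", plane_x, " outside grid x-range [1, ",
         nx - 1L, "]")
  left_grid <- oc$grid
  left_grid[(plane_x + 1L):nx, , ] <- 0L   # keep 0-based x < plane_x
  right_grid <- oc$grid
  right_grid[1:plane_x, , ] <- 0L          # keep 0-based x >= plane_x
  if (sum(left_grid) == 0L || sum(right_grid) == 0L)
    stop("empty hemi-trunk after split: plane x=", plane_x,
         " is off-center for this chiasm")
  list(
    left = labeled_mask(left_grid, oc$spacing, "OC", "left", oc$subject_id),
    right = labeled_mask(right_grid, oc$spacing, "OC", "right", oc$subject_id))
}

#' Bundle the five segment masks of one subject and side
#'
#' @param subject_id,side Tags shared by the member masks.
#' @param masks Named list of [labeled_mask()] objects, one per segment in
#'   `avp_segments()` order (the OC member is a hemi-trunk).
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(subject_id, side, masks) {
  if (!all(AVP_SEGMENTS %in% names(masks)))
    stop("all five segments are required; missing: ",
         paste(setdiff(AVP_SEGMENTS, names(masks)), collapse = ", "))
  masks <- masks[AVP_SEGMENTS]
  dims <- lapply(masks, function(m) dim(m$grid))
  if (length(unique(dims)) != 1L)
    stop("segment masks must share one grid")
  structure(list(subject_id = subject_id, side = side, masks = masks),
            class = "segment_set")
}

#' Validate segment ordering, disjointness and contiguity
#'
#' Checks that the five segment masks of one subject/side are pairwise
#' voxel-disjoint, axially ordered anterior to posterior with no overlap and
#' no axial gap larger than one slice between consecutive segments, and that
#' each segment is contiguous along the tube axis (no empty coronal slice
#' between its first and last nonempty slice).
#'
#' @param s A [segment_set()].
#' @return A list of class `segment_validation`: `pass` (logical),
#'   `disjointness` (data.frame of violating pairs), `axial` (data.frame of
#'   gap/overlap findings with 0-based slice indices), `contiguity`
#'   (data.frame of empty intermediate slices).
#' @export
validate_segment_set <- function(s) {
  stopifnot(inherits(s, "segment_set"))
  masks <- s$masks
  disj <- data.frame(segment_a = character(), segment_b = character(),
                     shared_voxels = integer())
  for (i in seq_len(length(masks) - 1L)) for (j in (i + 1L):length(masks)) {
    shared <- sum(masks[[i]]$grid & masks[[j]]$grid)
    if (shared > 0L)
      disj <- rbind(disj, data.frame(segment_a = names(masks)[i],
                                     segment_b = names(masks)[j],
                                     shared_voxels = shared))
  }
  axial <- data.frame(segment_a = character(), segment_b = character(),
                      type = character(), from_slice = integer(),
                      to_slice = integer())
  contig <- data.frame(segment = character(), empty_slice = integer())
  extents <- lapply(masks, function(m) nonempty_slices(m$grid))
  for (nm in names(masks)) {
    ks <- extents[[nm]]
    if (length(ks)) {
      missing <- setdiff(seq(min(ks), max(ks)), ks)
      if (length(missing))
        contig <- rbind(contig, data.frame(segment = nm,
                                           empty_slice = missing - 1L))
    }
  }
  for (i in seq_len(length(masks) - 1L)) {
    a <- extents[[i]]; b <- extents[[i + 1L]]
    if (!length(a) || !length(b)) next
    gap <- min(b) - max(a) - 1L   # empty slices between the two segments
    if (gap < 0L)
      axial <- rbind(axial, data.frame(
        segment_a = names(masks)[i], segment_b = names(masks)[i + 1L],
        type = "overlap", from_slice = min(b) - 1L, to_slice = max(a) - 1L))
    else if (gap > 1L)
      axial <- rbind(axial, data.frame(
        segment_a = names(masks)[i], segment_b = names(masks)[i + 1L],
        type = "gap", from_slice = max(a), to_slice = min(b) - 2L))
  }
  structure(list(pass = nrow(disj) == 0L && nrow(axial) == 0L &&
                   nrow(contig) == 0L,
                 disjointness = disj, axial = axial, contiguity = contig),
            class = "segment_validation")
}

#' @export
print.segment_validation <- function(x, ...) {
  cat("<segment_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$disjointness)) { cat("disjointness violations:\n")
    print(x$disjointness) }
  if (nrow(x$axial)) { cat("axial ordering findings:\n"); print(x$axial) }
  if (nrow(x$contiguity)) { cat("empty intermediate slices:\n")
    print(x$contiguity) }
  invisible(x)
}

#' Read a cohort manifest
#'
#' A manifest is a plain-text delimited table (tab or comma) with columns
#' `subject`, `side`, `segment`, `path`, one row per mask file. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return data.frame with the four columns, paths made absolute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("subject", "side", "segment", "path")
  if (!all(req %in% names(m)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  bad <- !m$segment %in% AVP_SEGMENTS
  if (any(bad))
    stop("unknown segment tag(s) in manifest: ",
         paste(unique(m$segment[bad]), collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(normalizePath(path)), m$path[rel])
  m
}

#' Write a cohort manifest
#'
#' @param manifest data.frame with columns `subject`, `side`, `segment`,
#'   `path`.
#' @param path Output file path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a cohort of segment sets from a manifest
#'
#' @param manifest data.frame as returned by [read_manifest()], or a path.
#' @return Named list of [segment_set()]s, one per `subject:side`.
#' @export
read_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- list()
  for (key in unique(paste(manifest$subject, manifest$side, sep = ":"))) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    rows <- manifest[manifest$subject == parts[1] &
                       manifest$side == parts[2], ]
    masks <- list()
    for (r in seq_len(nrow(rows)))
      masks[[rows$segment[r]]] <- read_mask(rows$path[r], rows$segment[r],
                                            parts[2], parts[1])
    out[[key]] <- segment_set(parts[1], parts[2], masks)
  }
  out
}
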