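# Probabilistic atlas construction by voxel-wise averaging of normalized
# binary masks (left and right-to-left flipped), thresholding, Dice
# similarity, and leave-one-out validation.

#' Mirror a right-side normalized mask to the left
#'
#' The grid is mirrored about the x (left-right) mid-plane; axial geometry
#' and segment boundaries are untouched. Atlas construction pools left and
#' flipped-right masks so both sides contribute to a single-sided atlas.
#'
#' @param m A `normalized_avp` (or any object with a 3-D `grid`).
#' @return The mask with mirrored grid and side tag `"right-flipped"`.
#' @export
flip_right_to_left <- function(m) {
  if (!is.null(m$side) && m$side %in% c("left", "right-flipped"))
    warning("flipping a ", m$side, " mask")
  nx <- dim(m$grid)[1]
  m$grid <- m$grid[rev(seq_len(nx)), , , drop = FALSE]
  if (!is.null(m$side))
    m$side <- if (identical(m$side, "right")) "right-flipped" else m$side
  m
}

restrict_to_segment <- function(m, segment) {
  g <- array(0L, dim(m$grid))
  ks <- segment_slices(m)[[segment]]
  if (length(ks)) g[, ks, ] <- m$grid[, ks, ]
  g
}

#' Build a probabilistic atlas from normalized masks
#'
#' Voxel values are `100 * (number of masks containing the voxel) / n`, the
#' percentage overlap across the cohort (0-100). Right-side masks are
#' flipped to the left before averaging by default. Per-segment child
#' atlases are built identically from the segment-restricted masks.
#'
#' @param masks List of `normalized_avp`s on one common grid.
#' @param flip_right Mirror right-side masks first (default `TRUE`).
#' @param per_segment Also build the five per-segment atlases
#'   (default `TRUE`).
#' @return An object of class `probabilistic_atlas`: float `grid` (0-100),
#'   `n_masks`, `spacing`, `origin_vox`, and optionally `segments`, a named
#'   list of per-segment atlas grids.
#' @export
build_atlas <- function(masks, flip_right = TRUE, per_segment = TRUE) {
  if (!length(masks)) stop("empty mask list")
  dims <- lapply(masks, function(m) dim(m$grid))
  if (length(unique(dims)) != 1L)
    stop("all masks must share one grid")
  prep <- lapply(masks, function(m) {
    if (flip_right && identical(m$side, "right"))
      suppressWarnings(flip_right_to_left(m)) else m
  })
  n <- length(prep)
  acc <- Reduce(`+`, lapply(prep, function(m) m$grid))
  segs <- NULL
  if (per_segment && !is.null(prep[[1]]$boundaries_mm)) {
    segs <- lapply(stats::setNames(nm = AVP_SEGMENTS), function(seg) {
      sacc <- Reduce(`+`, lapply(prep, restrict_to_segment, segment = seg))
      100 * sacc / n
    })
  }
  structure(list(grid = 100 * acc / n, n_masks = n,
                 spacing = prep[[1]]$spacing,
                 origin_vox = prep[[1]]$origin_vox, segments = segs),
            class = "probabilistic_atlas")
}

#' @export
print.probabilistic_atlas <- function(x, ...) {
  cat(sprintf(
    "<probabilistic_atlas> %s voxels > 0 on %s  (n = %s masks%s)\n",
    format(sum(x$grid > 0)), paste(dim(x$grid), collapse = "x"),
    format(x$n_masks),
    if (!is.null(x$segments)) ", with per-segment children" else ""))
  invisible(x)
}

#' Threshold a probabilistic atlas into a binary mask
#'
#' @param a A `probabilistic_atlas`.
#' @param level Overlap percentage in (0, 100]; voxels with value `>= level`
#'   are kept (inclusive, so the 50% level is well defined for even cohort
#'   sizes). Default 50.
#' @return A [labeled_mask()].
#' @export
threshold_atlas <- function(a, level = 50) {
  stopifnot(inherits(a, "probabilistic_atlas"))
  if (level <= 0 || level > 100)
    stop("threshold level must be in (0, 100]")
  labeled_mask(array(as.integer(a$grid >= level), dim(a$grid)),
               spacing = a$spacing, segment = "wholeAVP", side = "left",
               subject_id = "atlas")
}

#' Dice Similarity Index of two binary masks
#'
#' `DSI(A, B) = 2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`. Two empty
#' masks are defined as identical (`1`); one empty operand gives `0` (this
#' matters for segment-restricted comparisons, which can legitimately be
#' empty).
#'
#' @param a,b [labeled_mask()]s / `normalized_avp`s on the same grid, or
#'   plain arrays.
#' @return DSI in `[0, 1]`.
#' @export
dsi <- function(a, b) {
  ga <- if (is.list(a)) a$grid else a
  gb <- if (is.list(b)) b$grid else b
  if (!identical(dim(ga), dim(gb))) stop("DSI operands must share one grid")
  na <- sum(ga != 0); nb <- sum(gb != 0)
  if (na + nb == 0L) return(1)
  2 * sum(ga != 0 & gb != 0) / (na + nb)
}

#' Leave-one-out Dice validation of the atlas
#'
#' For each subject, both of that subject's masks are withheld; the
#' leave-one-out atlas is built from the remaining `2(n-1)` masks (right
#' flipped to left), thresholded at the given probability level, and
#' compared by DSI with each withheld mask (right masks flipped into atlas
#' space first). A subject's score is the mean of its two DSIs. The summary
#' reports the 50th percentile (the typical subject) and the 5th percentile
#' (the similarity reached by 95% of subjects).
#'
#' @param masks List of `normalized_avp`s, two per subject (left and right).
#' @param level Atlas probability threshold, percent; default 50.
#' @return List of class `loo_validation`: `results` (data.frame subject,
#'   side, dsi), `subject_scores` (data.frame subject, score), `summary`
#'   (named vector `median`, `p05`), `level`.
#' @export
loo_validation <- function(masks, level = 50) {
  subjects <- vapply(masks, function(m) m$subject_id, character(1))
  if (length(unique(subjects)) < 2L)
    stop("leave-one-out validation needs at least 2 subjects")
  results <- NULL
  for (sid in unique(subjects)) {
    keep <- masks[subjects != sid]
    held <- masks[subjects == sid]
    ref <- threshold_atlas(build_atlas(keep, flip_right = TRUE,
                                       per_segment = FALSE), level)
    for (m in held) {
      mm <- if (identical(m$side, "right"))
        suppressWarnings(flip_right_to_left(m)) else m
      results <- rbind(results, data.frame(
        subject_id = sid, side = m$side, dsi = dsi(mm, ref),
        stringsAsFactors = FALSE))
    }
  }
  scores <- stats::aggregate(dsi ~ subject_id, results, mean)
  names(scores)[2] <- "score"
  structure(list(
    results = results, subject_scores = scores,
    summary = c(median = stats::median(scores$score),
                p05 = unname(stats::quantile(scores$score, 0.05))),
    level = level), class = "loo_validation")
}

#' @export
print.loo_validation <- function(x, ...) {
  cat(sprintf(
    "<loo_validation> %d subjects @ %g%% threshold  median DSI %.3f, 5th pct %.3f\n",
    nrow(x$subject_scores), x$level, x$summary["median"], x$summary["p05"]))
  invisible(x)
}
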