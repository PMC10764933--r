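# Cohort-level biometry summaries: descriptive statistics, paired left-right
# comparison, coefficients of variation and standardized (proportion-of-total
# / variation-from-mean) metrics.

#' Normative reference biometry of the adult aVP
#'
#' Published normative means and standard deviations of aVP biometrics
#' (volume, centroid-path length, mCSA, ellipticity index) by segment and
#' side, from a 24-participant healthy-adult cohort imaged at 0.6 mm
#' isotropic resolution with manual segmentation. Useful as plausibility
#' bounds for new cohorts and as the source of the phantom generator's
#' default geometry.
#'
#' @return data.frame with columns `metric` (`volume_mm3`, `length_mm`,
#'   `mcsa_mm2`, `epsilon`), `segment` (five segments plus compound `ON` and
#'   `wholeAVP`), `left_mean`, `left_sd`, `right_mean`, `right_sd`.
#' @export
reference_biometry <- function() {
  seg <- c("ON", "iOrb", "iCan", "iCran", "OC", "OT", "wholeAVP")
  rbind(
    data.frame(metric = "volume_mm3", segment = seg,
      left_mean  = c(319.02, 172.48, 38.82, 107.73, 94.18, 72.55, 485.76),
      left_sd    = c(50.76, 36.58, 7.02, 16.77, 21.36, 12.04, 75.41),
      right_mean = c(319.14, 172.61, 39.07, 107.46, 94.17, 72.33, 485.65),
      right_sd   = c(50.96, 37.15, 6.59, 16.75, 21.73, 12.26, 74.89)),
    data.frame(metric = "length_mm", segment = seg,
      left_mean  = c(45.27, 22.40, 6.87, 16.01, 6.53, 9.57, 61.37),
      left_sd    = c(2.28, 2.18, 0.66, 1.85, 0.82, 1.06, 2.73),
      right_mean = c(45.03, 22.38, 7.19, 15.45, 6.53, 9.46, 61.02),
      right_sd   = c(4.51, 2.64, 2.06, 1.80, 0.82, 0.97, 4.90)),
    data.frame(metric = "mcsa_mm2", segment = seg,
      left_mean  = c(7.04, 7.65, 5.66, 6.82, 14.33, 7.58, 8.41),
      left_sd    = c(1.04, 1.14, 0.81, 1.35, 2.10, 0.91, 1.06),
      right_mean = c(7.11, 7.70, 5.59, 7.03, 14.42, 7.64, 8.48),
      right_sd   = c(1.13, 1.34, 1.02, 1.29, 2.71, 0.98, 1.16)),
    data.frame(metric = "epsilon", segment = seg,
      left_mean  = c(0.26, 0.15, 0.20, 0.43, 0.57, 0.40, 0.35),
      left_sd    = c(0.04, 0.03, 0.08, 0.06, 0.08, 0.07, 0.04),
      right_mean = c(0.27, 0.15, 0.21, 0.43, 0.57, 0.38, 0.35),
      right_sd   = c(0.04, 0.04, 0.07, 0.08, 0.08, 0.07, 0.04)))
}

#' Round for reporting (half away from zero)
#'
#' Decimal rounding as printed in biometry tables: halves round away from
#' zero (so 38.945 -> 38.95 at 2 decimals), with a tiny tolerance so values
#' that are decimally exact halves but sit just below them in binary
#' floating point still round up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_report <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-8) / m
}

#' Derive compound ON and whole-aVP rows from per-segment records
#'
#' For each subject/side with all five segments present, adds an `ON` row
#' (iOrb + iCan + iCran) and a `wholeAVP` row. Volumes and lengths are sums
#' (the same voxels and the same centroid chords, so additivity is exact);
#' compound mCSA is compound volume over compound length; compound
#' ellipticity is the length-weighted mean of the segment ellipticities
#' (the exact slice-mean is available via [biometry_table()] when the masks
#' themselves are at hand).
#'
#' @param records data.frame with columns `subject_id`, `side`, `segment`,
#'   `volume_mm3`, `length_mm`, `mcsa_mm2`, `epsilon`.
#' @return The records plus `ON` and `wholeAVP` rows per subject/side.
#' @export
derive_compound_segments <- function(records) {
  base <- records
  extra <- NULL
  for (key in unique(paste(records$subject_id, records$side, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    r <- records[records$subject_id == parts[1] & records$side == parts[2], ]
    if (!all(AVP_SEGMENTS %in% r$segment))
      stop("missing segment(s) for ", parts[1], "/", parts[2], ": ",
           paste(setdiff(AVP_SEGMENTS, r$segment), collapse = ", "))
    compound <- function(segs, name) {
      rr <- r[match(segs, r$segment), ]
      v <- sum(rr$volume_mm3); l <- sum(rr$length_mm)
      data.frame(subject_id = parts[1], side = parts[2], segment = name,
                 volume_mm3 = v, length_mm = l, mcsa_mm2 = v / l,
                 epsilon = sum(rr$epsilon * rr$length_mm) / l,
                 stringsAsFactors = FALSE)
    }
    extra <- rbind(extra, compound(c("iOrb", "iCan", "iCran"), "ON"),
                   compound(AVP_SEGMENTS, "wholeAVP"))
  }
  extra <- merge_cols(extra, names(base))
  rbind(base, extra)
}

merge_cols <- function(df, cols) {
  for (c in setdiff(cols, names(df))) df[[c]] <- NA
  df[, cols]
}

#' Paired left-right comparison
#'
#' Two-tailed paired t-test on per-subject left minus right differences.
#' All-zero differences return `t = 0`, `p = 1`; constant nonzero
#' differences (zero variance) are an error, as the statistic is undefined.
#'
#' @param left,right Paired numeric vectors (same subjects, same order).
#' @return List: `mean_diff`, `ci` (95% confidence interval of the mean
#'   difference), `t`, `df`, `p`, `n`.
#' @export
paired_lr_comparison <- function(left, right) {
  if (length(left) != length(right)) stop("left and right must be paired")
  n <- length(left)
  if (n < 2L) stop("need at least 2 pairs")
  d <- left - right
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(mean_diff = 0, ci = c(0, 0), t = 0, df = n - 1, p = 1,
                  n = n))
    stop("differences have zero variance but nonzero mean; ",
         "the paired t statistic is undefined")
  }
  tt <- stats::t.test(left, right, paired = TRUE)
  list(mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n)
}

#' Coefficient of variation
#'
#' `100 * sd / mean` (sample standard deviation, n-1 denominator), the
#' normalized between-subject variability of a biometric.
#'
#' @param values Numeric vector, `n >= 2`, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' Standardized (relative) biometrics
#'
#' Volume and length are expressed as percentage of the subject's entire
#' aVP (the proportion of the pathway located in the segment); mCSA and
#' ellipticity as percentage deviation from the subject's whole-aVP value
#' (the variation of the segment from a hypothetical nerve of constant
#' mCSA / ellipticity).
#'
#' @param records Biometry records incl. `wholeAVP` rows (added via
#'   [derive_compound_segments()] if absent).
#' @return data.frame: `subject_id`, `side`, `segment` (five segments),
#'   `volume_prop_pct`, `length_prop_pct`, `mcsa_var_pct`,
#'   `epsilon_var_pct`.
#' @export
standardized_metrics <- function(records) {
  if (!"wholeAVP" %in% records$segment)
    records <- derive_compound_segments(records)
  out <- NULL
  for (key in unique(paste(records$subject_id, records$side, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    r <- records[records$subject_id == parts[1] & records$side == parts[2], ]
    tot <- r[r$segment == "wholeAVP", ]
    if (nrow(tot) != 1L) stop("no unique wholeAVP row for ", key)
    if (tot$volume_mm3 == 0 || tot$length_mm == 0 || tot$mcsa_mm2 == 0 ||
        tot$epsilon == 0)
      stop("zero whole-aVP denominator for ", parts[1], "/", parts[2])
    segs <- r[r$segment %in% AVP_SEGMENTS, ]
    out <- rbind(out, data.frame(
      subject_id = parts[1], side = parts[2], segment = segs$segment,
      volume_prop_pct = 100 * segs$volume_mm3 / tot$volume_mm3,
      length_prop_pct = 100 * segs$length_mm / tot$length_mm,
      mcsa_var_pct = 100 * (segs$mcsa_mm2 / tot$mcsa_mm2 - 1),
      epsilon_var_pct = 100 * (segs$epsilon / tot$epsilon - 1),
      stringsAsFactors = FALSE))
  }
  out
}

summarize_values <- function(x) {
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  ci <- mean(x) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  sw <- if (n >= 3 && stats::sd(x) > 0)
    stats::shapiro.test(x)$p.value else NA_real_
  data.frame(n = n, mean = mean(x), sd = stats::sd(x), min = min(x),
             max = max(x), ci_lo = ci[1], ci_hi = ci[2],
             median = stats::median(x),
             q1 = unname(stats::quantile(x, 0.25)),
             q3 = unname(stats::quantile(x, 0.75)), shapiro_p = sw)
}

#' Cohort descriptive summary of biometrics
#'
#' Mean, SD, min, max, 95% confidence interval (t-based), median and
#' quartiles per segment, side and metric; a Shapiro-Wilk p-value flags
#' metrics better presented as median/quartiles (conventional alpha 0.05).
#'
#' @param records Cohort biometry records.
#' @return data.frame, one row per metric x segment x side.
#' @export
cohort_summary <- function(records) {
  metrics <- c("volume_mm3", "length_mm", "mcsa_mm2", "epsilon")
  out <- NULL
  for (met in metrics)
    for (seg in unique(records$segment))
      for (sd_ in unique(records$side)) {
        x <- records[records$segment == seg & records$side == sd_, met]
        if (length(x) < 2L) next
        out <- rbind(out, cbind(
          data.frame(metric = met, segment = seg, side = sd_,
                     stringsAsFactors = FALSE),
          summarize_values(x)))
      }
  out
}

#' Paired left-right comparison table for all metrics and segments
#'
#' @param records Cohort biometry records with both sides per subject.
#' @return data.frame: metric, segment, mean difference (left - right),
#'   95% CI, t, p.
#' @export
lr_comparison_table <- function(records) {
  metrics <- c("volume_mm3", "length_mm", "mcsa_mm2", "epsilon")
  out <- NULL
  for (met in metrics)
    for (seg in unique(records$segment)) {
      l <- records[records$segment == seg & records$side == "left", ]
      r <- records[records$segment == seg & records$side == "right", ]
      common <- intersect(l$subject_id, r$subject_id)
      if (length(common) < 2L) next
      cmp <- paired_lr_comparison(
        l[match(common, l$subject_id), met],
        r[match(common, r$subject_id), met])
      out <- rbind(out, data.frame(
        metric = met, segment = seg, mean_diff = cmp$mean_diff,
        ci_lo = cmp$ci[1], ci_hi = cmp$ci[2], t = cmp$t, p = cmp$p,
        n = cmp$n, stringsAsFactors = FALSE))
    }
  out
}

#' Between-subject coefficient-of-variation table
#'
#' CVs of the left/right-averaged per-subject values, the plain
#' between-subject sd/mean (no variance-components modelling).
#'
#' @param records Cohort biometry records.
#' @return data.frame: metric, segment, cv_pct, n.
#' @export
cv_table <- function(records) {
  metrics <- c("volume_mm3", "length_mm", "mcsa_mm2", "epsilon")
  out <- NULL
  for (met in metrics)
    for (seg in unique(records$segment)) {
      r <- records[records$segment == seg, ]
      avg <- stats::aggregate(r[[met]], list(subject_id = r$subject_id),
                              mean)
      if (nrow(avg) < 2L) next
      out <- rbind(out, data.frame(
        metric = met, segment = seg,
        cv_pct = coefficient_of_variation(avg$x), n = nrow(avg),
        stringsAsFactors = FALSE))
    }
  out
}
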