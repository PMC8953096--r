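#' ROI summary of one parameter map
#'
#' Mean and sample SD over the in-mask voxels that were classified
#' biexponential; degenerate voxels are excluded and never contaminate the
#' summary.
#'
#' @param map 3-D numeric array (one map of a `map_stack`).
#' @param label 3-D integer label mask.
#' @param validity 3-D logical validity mask (from [reconstruct_volume()]).
#' @param roi_label integer label selecting the ROI.
#' @return list with `mean`, `sd`, `n_valid`, `n_mask`, `empty` (TRUE when
#'   no valid voxel falls inside the mask; `mean`/`sd` are then `NA`).
#' @export
roi_summary <- function(map, label, validity, roi_label = 1L) {
  in_mask <- label == roi_label
  sel <- in_mask & validity
  vals <- map[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, n_valid = 0L,
                n_mask = sum(in_mask), empty = TRUE))
  }
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n_valid = length(vals), n_mask = sum(in_mask), empty = FALSE)
}

#' Combine two repeated segmentations of the same structure
#'
#' The structure was segmented twice; the ROI summary is computed per mask
#' and the two means (and SDs) are averaged — the average of the two
#' measurements is what enters further statistics. If one mask yields an
#' empty summary, the other is used alone, with a warning.
#'
#' @inheritParams roi_summary
#' @param labelA,labelB the two label masks.
#' @return list as [roi_summary()], with `n_valid` the sum over both masks.
#' @export
average_segmentations <- function(map, labelA, labelB, validity,
                                  roi_label = 1L) {
  sa <- roi_summary(map, labelA, validity, roi_label)
  sb <- roi_summary(map, labelB, validity, roi_label)
  if (sa$empty && sb$empty) {
    return(sa)
  }
  if (sa$empty || sb$empty) {
    warning("one segmentation has no valid voxels; using the other alone",
            call. = FALSE)
    return(if (sa$empty) sb else sa)
  }
  list(mean = (sa$mean + sb$mean) / 2, sd = (sa$sd + sb$sd) / 2,
       n_valid = sa$n_valid + sb$n_valid, n_mask = sa$n_mask + sb$n_mask,
       empty = FALSE)
}

#' Pooled-variance two-sample Student t-test from summary statistics
#'
#' Classical equal-variance two-sample t-test computed from per-group
#' means, SDs and sizes: `df = nA + nB - 2`, two-sided p from the t
#' distribution. `welch = TRUE` switches to the Welch form
#' (Satterthwaite df). When the pooled variance is zero the limit
#' convention applies: p = 1 for equal means, p = 0 otherwise.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB per-group summaries (`n >= 2`,
#'   `sd >= 0`).
#' @param welch use the Welch unequal-variance form instead of pooling.
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t_test <- function(meanA, sdA, nA, meanB, sdB, nB, welch = FALSE) {
  if (nA < 2 || nB < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sdA < 0 || sdB < 0) stop("SDs must be >= 0", call. = FALSE)
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) {
      return(list(t = 0, df = nA + nB - 2, p = 1))
    }
    return(list(t = sign(meanA - meanB) * Inf, df = nA + nB - 2, p = 0))
  }
  if (welch) {
    vA <- sdA^2 / nA
    vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  }
  t <- (meanA - meanB) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise alpha divided by the number of comparisons; with the default
#' four components per structure, 0.05 / 4 = 0.0125.
#'
#' @param family_alpha family-wise error rate.
#' @param m number of comparisons.
#' @return Per-comparison threshold.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 4L) {
  if (family_alpha <= 0 || family_alpha > 1) {
    stop("family_alpha must be in (0, 1]", call. = FALSE)
  }
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  family_alpha / m
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard W statistic (3 <= n <= 5000); a
#' constant sample is an error.
#'
#' @param x numeric sample.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Pearson product-moment correlation
#'
#' Standard r with a two-sided p from the t transform on n - 2 df.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  res <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(res$estimate), p = res$p.value)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_obs - p_exp) / (1 - p_exp)` between two
#' categorical rating vectors. Perfect agreement gives 1; agreement at
#' chance level gives 0.
#'
#' @param ratings1,ratings2 vectors of categorical labels, equal length.
#' @return Scalar kappa in [-1, 1].
#' @export
cohens_kappa <- function(ratings1, ratings2) {
  if (length(ratings1) != length(ratings2)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  lev <- union(unique(ratings1), unique(ratings2))
  r1 <- factor(ratings1, levels = lev)
  r2 <- factor(ratings2, levels = lev)
  tab <- table(r1, r2)
  n <- sum(tab)
  p_obs <- sum(diag(tab)) / n
  p_exp <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_exp == 1) return(1) # both raters constant and identical
  (p_obs - p_exp) / (1 - p_exp)
}

#' Intersection over union of two segmentation masks
#'
#' `|A intersect B| / |A union B|`; symmetric, in [0, 1]. Both masks empty
#' is an error (the measure is undefined).
#'
#' @param maskA,maskB logical (or 0/1) arrays of identical shape.
#' @return Scalar overlap fraction.
#' @export
intersection_over_union <- function(maskA, maskB) {
  a <- as.logical(maskA)
  b <- as.logical(maskB)
  if (length(a) != length(b)) {
    stop("masks must have identical shape", call. = FALSE)
  }
  uni <- sum(a | b)
  if (uni == 0L) stop("IoU is undefined for two empty masks", call. = FALSE)
  sum(a & b) / uni
}
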