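#' Paired t-test p-value for a feature
#'
#' Two-sided paired Student's t-test of post- versus pre-milking values.
#' When the per-teat differences have zero variance the p-value is
#' undefined; the result then carries `zero_variance = TRUE` and `p = NA`.
#'
#' @param pre,post numeric vectors of equal length (n >= 2), same teats in
#'   the same order.
#' @param paired paired test (default) or two-sample Welch variant.
#' @return list with `p_value`, `statistic`, `df`, `zero_variance`.
#' @export
paired_ttest <- function(pre, post, paired = TRUE) {
  if (length(pre) != length(post)) stop("pre/post length mismatch")
  if (length(pre) < 2L) stop("need at least 2 pairs")
  flagged <- list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                  zero_variance = TRUE)
  # zero variance up to float round-off (e.g. an exact constant shift)
  d <- post - pre
  if (paired && stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1e-300))
    return(flagged)
  if (!paired && stats::var(pre) == 0 && stats::var(post) == 0)
    return(flagged)
  tt <- tryCatch(stats::t.test(post, pre, paired = paired),
                 error = function(e) NULL)   # "data are essentially constant"
  if (is.null(tt)) return(flagged)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), zero_variance = FALSE)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(post) - mean(pre)) / s_pooled` with
#' the pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`. Positive d
#' means the post-milking mean is higher. Identical constant groups give
#' d = 0; a zero pooled SD with a nonzero mean difference is an error.
#'
#' @param pre,post numeric vectors (n >= 2 each).
#' @return signed Cohen's d.
#' @export
cohens_d <- function(pre, post) {
  n1 <- length(pre); n2 <- length(post)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(pre) + (n2 - 1) * stats::var(post)) /
               (n1 + n2 - 2))
  dm <- mean(post) - mean(pre)
  if (sp == 0) {
    if (dm == 0) return(0)
    stop("zero pooled variance with nonzero mean difference")
  }
  dm / sp
}

#' Screen features for pre/post-milking expression
#'
#' For every feature shared by the two tables, computes the paired t-test
#' p-value, Cohen's d (pooled-SD form), and the absolute percent difference
#' of means `|post - pre| / |pre| * 100`. A feature is *expressed* when
#' `p < p_thresh` and `|d| > d_thresh` (defaults 0.01 and 1.2). No
#' multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted p-values.
#'
#' @param pre,post numeric matrices (rows = teats in identical order,
#'   columns = features with identical names), n >= 2 rows.
#' @param p_thresh,d_thresh expression thresholds.
#' @param paired use the paired t-test (default).
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method).
#' @return data.frame (one row per feature) with columns `feature`,
#'   `p_value`, `cohens_d`, `abs_d`, `percent_diff`, `zero_variance`,
#'   `expressed`; the counts of significant-only, effect-only and jointly
#'   expressed features are attached as attribute `"counts"` (and returned
#'   by [expression_counts()]).
#' @export
expression_screen <- function(pre, post, p_thresh = 0.01, d_thresh = 1.2,
                              paired = TRUE, adjust = "none") {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (nrow(pre) == 0L || ncol(pre) == 0L) stop("empty feature table")
  if (nrow(pre) != nrow(post)) stop("pre/post row mismatch")
  if (!identical(sort(colnames(pre)), sort(colnames(post))))
    stop("pre/post feature names differ")
  post <- post[, colnames(pre), drop = FALSE]
  res <- lapply(colnames(pre), function(f) {
    a <- pre[, f]; b <- post[, f]
    tt <- paired_ttest(a, b, paired = paired)
    d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
    mp <- mean(a)
    data.frame(feature = f, p_value = tt$p_value, cohens_d = d,
               abs_d = abs(d),
               percent_diff = if (mp != 0) abs(mean(b) - mp) / abs(mp) * 100
                              else NA_real_,
               zero_variance = tt$zero_variance)
  })
  res <- do.call(rbind, res)
  if (adjust != "none")
    res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  sig <- !is.na(res$p_value) & res$p_value < p_thresh
  eff <- !is.na(res$abs_d) & res$abs_d > d_thresh
  res$expressed <- sig & eff
  attr(res, "counts") <- list(significant = sum(sig), effect_size = sum(eff),
                              expressed = sum(sig & eff))
  res
}

#' @rdname expression_screen
#' @param screen a result of `expression_screen()`.
#' @export
expression_counts <- function(screen) attr(screen, "counts")

#' Compare feature tables from two observers
#'
#' Per-feature paired t-test p-value and absolute Cohen's d across the
#' shared ROI set, quantifying how much the extracted biomarkers depend on
#' who drew the segmentations. Requires the two tables to describe the same
#' ROIs in the same order (matching row names) and the same features.
#'
#' @param feat_a,feat_b numeric feature matrices with identical row and
#'   column names.
#' @return list with `per_feature` (data.frame of `feature`, `p_value`,
#'   `abs_d`) and `summary` (`min_p`, `max_abs_d`).
#' @export
interobserver_compare <- function(feat_a, feat_b) {
  feat_a <- as.matrix(feat_a); feat_b <- as.matrix(feat_b)
  if (!identical(dim(feat_a), dim(feat_b)))
    stop("observer tables have different shapes")
  if (!identical(rownames(feat_a), rownames(feat_b)))
    stop("ROI correspondence mismatch between observers")
  if (!identical(colnames(feat_a), colnames(feat_b)))
    stop("feature name mismatch between observers")
  if (nrow(feat_a) < 2L) stop("need at least 2 shared ROIs")
  per <- lapply(colnames(feat_a), function(f) {
    tt <- paired_ttest(feat_a[, f], feat_b[, f])
    d <- tryCatch(abs(cohens_d(feat_a[, f], feat_b[, f])),
                  error = function(e) NA_real_)
    data.frame(feature = f, p_value = tt$p_value, abs_d = d,
               zero_variance = tt$zero_variance)
  })
  per <- do.call(rbind, per)
  list(per_feature = per,
       summary = list(min_p = suppressWarnings(min(per$p_value, na.rm = TRUE)),
                      max_abs_d = max(per$abs_d, na.rm = TRUE)))
}
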