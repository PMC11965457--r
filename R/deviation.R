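#' Threshold a deviation matrix into extreme-deviation masks
#'
#' Flags extreme positive (\code{Z > threshold}) and extreme negative
#' (\code{Z < -threshold}) deviations with strict inequalities: a score
#' exactly at the threshold is not extreme.
#'
#' @param dev a [deviation_matrix()].
#' @param threshold positive threshold on |Z| (default 2).
#' @return object of class \code{extreme_mask}: logical matrices
#'   \code{positive} and \code{negative}, plus \code{threshold} and
#'   \code{modality}.
#' @export
threshold_extremes <- function(dev, threshold = 2) {
  stopifnot(inherits(dev, "deviation_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_field("threshold", "must be > 0")
  if (any(!is.finite(dev$z)))
    stop("deviation matrix contains non-finite Z-scores", call. = FALSE)
  structure(list(positive = dev$z > threshold,
                 negative = dev$z < -threshold,
                 threshold = threshold, modality = dev$modality),
            class = "extreme_mask")
}

#' @export
print.extreme_mask <- function(x, ...) {
  cat(sprintf("Extreme-deviation mask [%s], |Z| > %g: %d/%d positive, %d/%d negative cells\n",
              x$modality, x$threshold, sum(x$positive), length(x$positive),
              sum(x$negative), length(x$negative)))
  invisible(x)
}

tier_label <- function(pct, tiers = c(5, 7.5, 10)) {
  t <- sort(tiers)
  lab <- rep(NA_character_, length(pct))
  for (k in seq_along(t)) lab[pct >= t[k]] <- sprintf(">=%g%%", t[k])
  lab
}

#' Per-ROI extreme-deviation frequencies by group
#'
#' For each (group, ROI, sign), the count and percentage of group members
#' flagged as extreme, with frequency-tier labels at the 5 / 7.5 / 10
#' percent levels. Percentages are reported to one decimal in the
#' \code{pct_label} column; exact values and raw counts are retained.
#'
#' @param mask an [threshold_extremes()] mask.
#' @param groups character vector of group labels, one per subject (mask
#'   row order).
#' @param tiers frequency tiers in percent.
#' @return data frame with columns \code{group}, \code{roi}, \code{sign},
#'   \code{n_group}, \code{count}, \code{pct}, \code{pct_label},
#'   \code{tier}.
#' @export
roi_extreme_frequency <- function(mask, groups, tiers = c(5, 7.5, 10)) {
  stopifnot(inherits(mask, "extreme_mask"))
  if (length(groups) != nrow(mask$positive))
    stop("groups must label every subject in the mask", call. = FALSE)
  tab <- table(groups)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  out <- list()
  for (g in names(tab)) {
    idx <- which(groups == g)
    for (sgn in c("positive", "negative")) {
      cnt <- colSums(mask[[sgn]][idx, , drop = FALSE])
      pct <- 100 * cnt / length(idx)
      out[[length(out) + 1L]] <- data.frame(
        group = g, roi = colnames(mask[[sgn]]), sign = sgn,
        n_group = length(idx), count = as.integer(cnt), pct = pct,
        pct_label = sprintf("%.1f", pct), tier = tier_label(pct, tiers),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Top regions by extreme-deviation frequency
#'
#' Deterministic "top-k" listing for one group and sign; ties broken by
#' (percentage desc, count desc, ROI name asc).
#'
#' @param freq output of [roi_extreme_frequency()].
#' @param group group label.
#' @param sign \code{"negative"} or \code{"positive"}.
#' @param k number of regions (default 15).
#' @return the top-\code{k} rows of \code{freq}.
#' @export
top_regions <- function(freq, group, sign = "negative", k = 15L) {
  f <- freq[freq$group == group & freq$sign == sign, , drop = FALSE]
  f <- f[order(-f$pct, -f$count, f$roi), , drop = FALSE]
  utils::head(f, k)
}

#' Per-subject extreme-deviation burden
#'
#' Counts, per subject, the extreme positive and negative deviations
#' aggregated across the supplied modality masks, plus a \code{has_any}
#' flag (at least one extreme of either sign).
#'
#' @param masks a single \code{extreme_mask} or list of masks (one per
#'   modality) sharing the same subjects in the same order.
#' @return data frame with columns \code{subject_id}, \code{n_positive},
#'   \code{n_negative}, \code{has_any}.
#' @export
subject_extreme_burden <- function(masks) {
  if (inherits(masks, "extreme_mask")) masks <- list(masks)
  ids <- rownames(masks[[1]]$positive)
  for (m in masks) {
    stopifnot(inherits(m, "extreme_mask"))
    if (!identical(rownames(m$positive), ids))
      stop("masks disagree on subjects across modalities", call. = FALSE)
  }
  npos <- Reduce(`+`, lapply(masks, function(m) rowSums(m$positive)))
  nneg <- Reduce(`+`, lapply(masks, function(m) rowSums(m$negative)))
  data.frame(subject_id = ids, n_positive = as.integer(npos),
             n_negative = as.integer(nneg),
             has_any = (npos + nneg) > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group mean extreme-deviation rate
#'
#' Per (group, sign): the group mean of each subject's percentage of ROIs
#' flagged as extreme in this modality (default), or the pooled flag
#' percentage across all group cells (\code{pooled = TRUE}; the two differ
#' only through subject weighting and are equal for equal-size rows).
#'
#' @inheritParams roi_extreme_frequency
#' @param pooled pool flags across the group instead of averaging
#'   per-subject percentages.
#' @return data frame with columns \code{group}, \code{modality},
#'   \code{sign}, \code{mean_pct}.
#' @export
group_mean_extreme_rate <- function(mask, groups, pooled = FALSE) {
  stopifnot(inherits(mask, "extreme_mask"))
  tab <- table(groups)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  R <- ncol(mask$positive)
  out <- list()
  for (g in names(tab)) {
    idx <- which(groups == g)
    for (sgn in c("positive", "negative")) {
      m <- mask[[sgn]][idx, , drop = FALSE]
      mean_pct <- if (pooled) 100 * sum(m) / length(m)
                  else mean(100 * rowSums(m) / R)
      out[[length(out) + 1L]] <- data.frame(
        group = g, modality = mask$modality, sign = sgn,
        mean_pct = mean_pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
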