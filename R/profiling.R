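#' Marker importances from aggregated kernel weights
#'
#' Every marker contributes P kernels to the learned similarity, each
#' with a fitted weight; a marker's importance is the sum of its P
#' kernel weights. Because the weights live on the probability simplex,
#' importances are nonnegative and sum to 1. Markers are ranked by
#' decreasing importance with a stable tie-break on marker id.
#'
#' @param fit A [cimlr()] model.
#' @return A data frame (marker, importance, rank), sorted by rank.
#' @export
marker_importance <- function(fit) {
  stopifnot(inherits(fit, "cimlr"))
  agg <- tapply(fit$weights$weight, fit$weights$marker, sum)
  df <- data.frame(marker = names(agg), importance = as.numeric(agg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$importance, df$marker), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Per-cluster marker profiles with ANOVA validation
#'
#' Describes each cluster's blood-marker profile on the scaled values:
#' per (cluster, marker) mean and SD, the direction relative to the
#' population mean ("higher"/"lower"), and a one-way fixed-effects ANOVA
#' p-value testing equality of the marker's mean across clusters
#' (computed with [stats::oneway.test()] assuming equal variances, the
#' classical one-way ANOVA F test). Significance is flagged at
#' `p < alpha` (default 0.001); no further multiple-testing correction
#' is applied across markers.
#'
#' @param x Numeric subjects-by-markers matrix (typically min-max
#'   scaled).
#' @param labels Cluster labels, one per subject.
#' @param markers Marker (column) names to profile; default all. A
#'   typical choice is the top 10 of [marker_importance()].
#' @param alpha Significance threshold on the ANOVA p-value.
#' @return A data frame with one row per (cluster, marker): cluster,
#'   marker, n, mean, sd, direction, anova_p, significant. Markers are
#'   skipped (p = NA, with a warning) when any cluster has fewer than
#'   2 members.
#' @export
cluster_profiles <- function(x, labels, markers = colnames(x),
                             alpha = 0.001) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (is.null(markers)) markers <- sprintf("marker_%03d", seq_len(ncol(x)))
  labels <- factor(labels)
  sizes <- table(labels)
  degenerate <- any(sizes < 2L) || nlevels(labels) < 2L
  if (degenerate)
    warning("a cluster has fewer than 2 members (or only one cluster); ",
            "ANOVA p-values are NA")
  out <- list()
  for (mk in markers) {
    vals <- x[, mk]
    p <- if (degenerate) NA_real_ else
      stats::oneway.test(vals ~ labels, var.equal = TRUE)$p.value
    gm <- mean(vals)
    for (cl in levels(labels)) {
      v <- vals[labels == cl]
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, marker = mk, n = length(v), mean = mean(v),
        sd = stats::sd(v),
        direction = if (mean(v) > gm) "higher" else "lower",
        anova_p = p, significant = !is.na(p) && p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
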