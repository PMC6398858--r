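#' Estimate the number of clusters
#'
#' Scores candidate cluster counts with two heuristics and returns each
#' heuristic's preferred set, leaving the final choice to the caller (a
#' common convention is to take the intersection of the two sets).
#'
#' Because the block structure of this model only becomes visible after
#' kernel-weight learning — the unweighted average kernel is dominated
#' by the uninformative markers — both heuristics score full model fits:
#' the model is fitted once per candidate C (fast spectral labelling
#' path, no embedding) and the resulting partitions are evaluated.
#'
#' \strong{Separation.} Each candidate's partition is scored by its
#' mean silhouette width under a common dissimilarity derived from the
#' average kernel (sparsified to the `knn` strongest neighbours per
#' subject, symmetrised; dissimilarity = max similarity minus
#' similarity). Scoring every candidate against the same reference
#' keeps the scores comparable: partitions that cut through genuine
#' similarity blocks, or leave distinct blocks merged, score lower than
#' the partition matching the data's block structure.
#'
#' \strong{Elbow.} The within-cluster dispersion (total within-cluster
#' sum of squares on the min-max-scaled marker matrix) of each
#' candidate's partition is a decreasing curve in C; each C is scored by
#' its discrete curvature (second difference, using the one-cluster
#' total dispersion and one extra fit beyond the range as flanks), so
#' the "elbow" where further splitting stops paying receives the
#' largest score.
#'
#' Each heuristic's selected set is its `top` highest-scoring
#' candidates.
#'
#' @param x Numeric subjects-by-markers matrix.
#' @param c_range Candidate cluster counts (within `[2, N/2]`).
#' @param top Size of each heuristic's selected set (default 2).
#' @param knn Neighbours kept per subject when sparsifying the learned
#'   similarity for the silhouette score (default 20, clamped to N - 1).
#' @param scale Min-max scale `x` first (default `TRUE`).
#' @param bank Optional prebuilt [kernel_bank()] to reuse; when supplied
#'   it must have been built from (scaled) `x`.
#' @param k,sigma,normalize Kernel-bank settings (see [kernel_bank()]),
#'   used when `bank` is not supplied.
#' @param seed Optional seed making the per-candidate labellings
#'   reproducible.
#' @param ... Passed to [cimlr()] (e.g. `gamma`, `beta`, `entropy`).
#' @return An object of class `"cluster_estimate"`: a list with `table`
#'   (candidate C, silhouette, WSS, curvature), `separation_set`,
#'   `elbow_set`, and `suggested` (smallest member of the intersection,
#'   or of the separation set when the intersection is empty).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_subjects = 80, n_markers = 25,
#'                                      n_informative = 8, n_clusters = 2,
#'                                      cluster_proportions = c(.5, .5),
#'                                      n_regions = 10, seed = 1))
#' estimate_clusters(coh$markers, c_range = 2:4, seed = 1)
#' }
#' @export
estimate_clusters <- function(x, c_range = 2:6, top = 2, knn = 20,
                              scale = TRUE, bank = NULL,
                              k = NULL,
                              sigma = sigma_grid("wide")$sigma,
                              normalize = "spectral", seed = NULL,
                              ...) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  c_range <- sort(unique(as.integer(c_range)))
  if (length(c_range) == 0L) stop("'c_range' is empty")
  if (min(c_range) < 2L || max(c_range) > n %/% 2L)
    stop("'c_range' must lie within [2, N/2]")
  if (scale) x <- minmax_scale(x)
  if (is.null(bank))
    bank <- kernel_bank(x, k = k, sigma = sigma, normalize = normalize)
  stopifnot(inherits(bank, "kernel_bank"), bank$n == n)
  if (!is.null(seed)) set.seed(seed)
  knn <- min(knn, n - 1L)

  flank <- max(c_range) + 1L
  cs <- c(c_range, if (2L * flank <= n) flank)
  fits <- lapply(cs, function(C)
    cimlr(bank, clusters = C, embed = FALSE, ...))
  names(fits) <- cs

  Wavg <- .sparsify_knn(matrix(rowMeans(bank$kernels), n, n), knn)
  DM <- max(Wavg) - Wavg
  diag(DM) <- 0
  Dref <- stats::as.dist(DM)
  silh <- vapply(seq_along(c_range), function(i) {
    mean(cluster::silhouette(as.integer(fits[[i]]$labels),
                             Dref)[, "sil_width"])
  }, numeric(1))

  wss_of <- function(labels) {
    sum(vapply(unique(labels), function(l)
      sum(scale(x[labels == l, , drop = FALSE], scale = FALSE)^2),
      numeric(1)))
  }
  wss <- vapply(fits, function(f) wss_of(f$labels), numeric(1))
  wss_all <- c(sum(scale(x, scale = FALSE)^2), wss)
  cs_all <- c(1L, cs)
  curvature <- vapply(c_range, function(C) {
    i <- match(C, cs_all)
    if (i >= length(cs_all)) return(NA_real_)
    (wss_all[i - 1L] - wss_all[i]) - (wss_all[i] - wss_all[i + 1L])
  }, numeric(1))

  tab <- data.frame(clusters = c_range, silhouette = silh,
                    wss = wss_all[match(c_range, cs_all)],
                    curvature = curvature)
  pick <- function(score) {
    ok <- c_range[!is.na(score)]
    sc <- score[!is.na(score)]
    sort(ok[order(-sc, ok)][seq_len(min(top, length(ok)))])
  }
  separation_set <- pick(silh)
  elbow_set <- pick(curvature)
  both <- intersect(separation_set, elbow_set)
  structure(list(table = tab, separation_set = separation_set,
                 elbow_set = elbow_set,
                 suggested = if (length(both)) min(both)
                             else separation_set[1L]),
            class = "cluster_estimate")
}

# keep each row's knn strongest entries, symmetrise by elementwise max
.sparsify_knn <- function(W, knn) {
  n <- nrow(W)
  diag(W) <- 0
  Wk <- matrix(0, n, n)
  for (i in seq_len(n)) {
    o <- order(W[i, ], decreasing = TRUE)[seq_len(knn)]
    Wk[i, o] <- W[i, o]
  }
  pmax(Wk, t(Wk))
}

#' @export
print.cluster_estimate <- function(x, ...) {
  cat("Cluster-number estimate\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("  separation set: {", paste(x$separation_set, collapse = ", "),
      "}; elbow set: {", paste(x$elbow_set, collapse = ", "), "}\n",
      sep = "")
  cat("  suggested C =", x$suggested, "\n")
  invisible(x)
}
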