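#' Jaccard index of two subject sets
#'
#' Intersection over union after collapsing duplicates. Two empty sets
#' give 0 with a warning (the index is undefined there; 0 is the
#' conservative convention for degenerate bootstrap clusters).
#'
#' @param a,b Vectors of subject identifiers.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard_index(1:3, 2:4)  # 0.5
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard of two empty sets; returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Optimally match candidate clusters to reference clusters
#'
#' Finds the one-to-one assignment of candidate clusters to reference
#' clusters that maximises the total Jaccard index, by exact dynamic
#' programming over subsets (feasible for the small cluster counts used
#' in subtyping). If the two labelings have different numbers of
#' clusters, the smaller side is padded with empty pseudo-clusters. Ties
#' are broken deterministically in favour of the lowest candidate index
#' for the lowest reference index.
#'
#' @param reference,candidate Either two label vectors over the same
#'   subjects (names are used as ids when present, positions otherwise)
#'   or two lists of id sets.
#' @return A list with `mapping` (named integer vector: candidate cluster
#'   -> reference cluster), `jaccard` (per reference cluster, under the
#'   optimal assignment) and `total`.
#' @export
match_clusters <- function(reference, candidate) {
  ref_sets <- .as_sets(reference)
  cand_sets <- .as_sets(candidate)
  C <- max(length(ref_sets), length(cand_sets))
  if (C > 16L) stop("more than 16 clusters not supported")
  length(ref_sets) <- C
  length(cand_sets) <- C
  ref_sets[vapply(ref_sets, is.null, TRUE)] <- list(character(0))
  cand_sets[vapply(cand_sets, is.null, TRUE)] <- list(character(0))
  J <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    u <- length(union(ref_sets[[i]], cand_sets[[j]]))
    J[i, j] <- if (u == 0L) 0 else
      length(intersect(ref_sets[[i]], cand_sets[[j]])) / u
  }
  assign <- .max_assignment(J)
  jac <- J[cbind(seq_len(C), assign)]
  mapping <- integer(C)
  mapping[assign] <- seq_len(C)   # candidate j -> reference mapping[j]
  names(mapping) <- names(cand_sets)
  list(mapping = mapping,
       jaccard = stats::setNames(jac, names(ref_sets)),
       total = sum(jac))
}

.as_sets <- function(x) {
  if (is.list(x)) return(lapply(x, function(s) unique(as.character(s))))
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  lv <- sort(unique(x))
  stats::setNames(lapply(lv, function(l) ids[x == l]), as.character(lv))
}

# exact maximum-total-weight assignment by bitmask DP; returns, for each
# row i, the assigned column. Deterministic tie-break: smallest column
# for the smallest row.
.max_assignment <- function(J) {
  C <- nrow(J)
  nmask <- bitwShiftL(1L, C)
  best <- rep(-Inf, nmask)
  choice <- integer(nmask)
  best[1L] <- 0
  for (mask in 0:(nmask - 2L)) {
    if (!is.finite(best[mask + 1L])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(C - 1L))) != 0L) + 1L
    for (j in seq_len(C)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nm <- bitwOr(mask, bit) + 1L
      val <- best[mask + 1L] + J[i, j]
      if (val > best[nm] + 1e-15) {
        best[nm] <- val
        choice[nm] <- j
      }
    }
  }
  # backtrack; among equally optimal paths the DP above keeps the first
  # (lowest-column) choice found at each state
  assign <- integer(C)
  mask <- nmask - 1L
  for (i in rev(seq_len(C))) {
    j <- choice[mask + 1L]
    assign[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  assign
}

#' Bootstrap stability of a clustering
#'
#' Assesses how stable reference clusters are under resampling: each
#' bootstrap replicate draws N subjects with replacement, refits the
#' chosen clustering method on the resample, collapses duplicate
#' subjects to unique-id sets per cluster, optimally matches those sets
#' to the reference clusters ([match_clusters()]) and records each
#' reference cluster's Jaccard index. Reference clusters are restricted
#' to the subjects present in the resample first, so out-of-sample
#' subjects do not mechanically depress the index. Replicates whose
#' resample contains fewer distinct subjects than clusters are redrawn
#' (counted in the report).
#'
#' Methods: `"cimlr"` refits the full multi-kernel model (fast spectral
#' labelling path), `"kmeans"` runs Euclidean k-means on the resampled
#' marker matrix, `"random"` draws labels uniformly — the chance
#' baseline a structured clustering must beat.
#'
#' @param x Numeric subjects-by-markers matrix (the same one the
#'   reference labels were fitted on).
#' @param labels Reference cluster labels (one per row of `x`).
#' @param method `"cimlr"`, `"kmeans"` or `"random"`.
#' @param n_boot Number of bootstrap replicates.
#' @param clusters Number of clusters to refit with (default: number of
#'   distinct reference labels).
#' @param seed Seed for the resampling (and refitting) stream.
#' @param indices Optional list of prespecified resample index vectors
#'   (length `n_boot`), bypassing the random draw; intended for tests
#'   and sensitivity checks.
#' @param ... Passed to [cimlr()] for `method = "cimlr"` (e.g. `k`,
#'   `sigma`, `gamma`).
#' @return An object of class `"stability_report"`: list with `method`,
#'   `n_boot`, `per_replicate` (n_boot x C Jaccard matrix),
#'   `mean_jaccard` (per reference cluster), `redraws`, `seed`.
#' @export
cluster_stability <- function(x, labels,
                              method = c("cimlr", "kmeans", "random"),
                              n_boot = 100, clusters = NULL, seed = NULL,
                              indices = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), length(labels) == nrow(x), n_boot >= 1)
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  labels <- as.integer(factor(labels))
  C <- if (is.null(clusters)) max(labels) else as.integer(clusters)
  ref_sets <- lapply(seq_len(C), function(cl) ids[labels == cl])
  if (!is.null(seed)) set.seed(seed)
  per <- matrix(NA_real_, n_boot, C,
                dimnames = list(NULL, paste0("C", seq_len(C))))
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    if (!is.null(indices)) {
      idx <- indices[[b]]
    } else {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= C) break
        redraws <- redraws + 1L
      }
    }
    cand_labels <- switch(method,
      # refits run quietly: resamples may trigger benign scaling or
      # neighbourhood-clamping warnings on duplicated subjects
      cimlr = suppressWarnings(
        cimlr(x[idx, , drop = FALSE], clusters = C, embed = FALSE,
              ...)$labels),
      kmeans = stats::kmeans(x[idx, , drop = FALSE], centers = C,
                             nstart = 20, iter.max = 100)$cluster,
      random = sample.int(C, length(idx), replace = TRUE)
    )
    uids <- ids[idx]
    cand_sets <- lapply(seq_len(C),
                        function(cl) unique(uids[cand_labels == cl]))
    present <- unique(uids)
    ref_here <- lapply(ref_sets, function(s) intersect(s, present))
    per[b, ] <- match_clusters(ref_here, cand_sets)$jaccard
  }
  structure(list(method = method, n_boot = n_boot,
                 per_replicate = per, mean_jaccard = colMeans(per),
                 redraws = redraws, seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability (%s, %d replicates%s)\n", x$method,
              x$n_boot,
              if (x$redraws) sprintf(", %d redraws", x$redraws) else ""))
  print(round(x$mean_jaccard, 3))
  invisible(x)
}
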